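# shared fixture helpers

rand_points <- function(n, lo = -100, hi = 100) {
  cbind(runif(n, lo, hi), runif(n, lo, hi))
}

rand_affine <- function() {
  repeat {
    m <- cbind(matrix(runif(4, -1.5, 1.5), 2, 2), runif(2, -20, 20))
    if (abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) > 0.1) return(transform_affine(m))
  }
}

rand_mls <- function(n = 4) {
  src <- rand_points(n, 0, 100)
  dst <- src + matrix(runif(2 * n, -5, 5), n, 2)
  transform_mls(src, dst, model = "affine", alpha = 1)
}

# a small deterministic test image with structure
test_image <- function(h = 32, w = 32, seed = 1) {
  set.seed(seed)
  matrix(round(runif(h * w, 0, 255)), h, w)
}

expect_points_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b)), tol)
}
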