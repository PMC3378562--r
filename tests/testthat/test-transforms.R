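test_that("identity and inverse-pair chains flatten to the identity mapping", {
  ch <- transform_chain(transform_identity(), transform_identity())
  fl <- flatten_chain(ch)
  p <- rand_points(20)
  expect_points_equal(apply_chain(fl, p), p)

  ch2 <- transform_chain(transform_translation(3, 4), transform_translation(-3, -4))
  fl2 <- flatten_chain(ch2)
  expect_length(fl2$transforms, 1L)
  expect_points_equal(apply_chain(fl2, p), p)
})

test_that("flattened chains equal sequential application within 1e-6 px", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(1:5, 1)
    elts <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.7) rand_affine() else rand_mls()
    })
    ch <- transform_chain(elts)
    fl <- flatten_chain(ch)
    p <- rand_points(100, 0, 100)
    expect_points_equal(apply_chain(fl, p), apply_chain(ch, p), tol = 1e-6)
  }
})

test_that("flattening collapses adjacent linear transforms", {
  ch <- transform_chain(rand_affine(), rand_affine(), rand_mls(), rand_affine(),
                        rand_affine(), rand_affine())
  fl <- flatten_chain(ch)
  expect_length(fl$transforms, 3L)
})

test_that("degenerate linear transforms are rejected", {
  expect_error(transform_affine(cbind(matrix(0, 2, 2), c(1, 1))),
               "invalid-transform")
})

test_that("landmark fits: identity, forced translation, exact minimal fits", {
  src <- rbind(c(0, 0), c(1, 0), c(0, 1))
  tid <- affine_from_landmarks(src, src, "affine")
  expect_points_equal(tid$matrix, cbind(diag(2), c(0, 0)))

  dst <- rbind(c(1, 0), c(2, 0), c(1, 1))
  tt <- affine_from_landmarks(src, dst, "translation")
  expect_points_equal(apply_transform(tt, src), dst)
  expect_equal(tt$matrix[, 3], c(1, 0))

  set.seed(7)
  for (i in 1:20) {
    s <- rand_points(3)
    # ensure non-collinear
    while (abs((s[2, 1] - s[1, 1]) * (s[3, 2] - s[1, 2]) -
               (s[2, 2] - s[1, 2]) * (s[3, 1] - s[1, 1])) < 1) s <- rand_points(3)
    d <- rand_points(3)
    tr <- affine_from_landmarks(s, d, "affine")
    expect_points_equal(apply_transform(tr, s), d, tol = 1e-8)
  }
})

test_that("rigid/similarity landmark fits recover known motions", {
  set.seed(11)
  s <- rand_points(10)
  truth <- transform_rigid(0.3, 5, -2)
  d <- apply_transform(truth, s)
  fit <- affine_from_landmarks(s, d, "rigid")
  expect_points_equal(fit$matrix, truth$matrix, tol = 1e-9)

  truth2 <- transform_similarity(1.4, -0.2, 1, 2)
  d2 <- apply_transform(truth2, s)
  fit2 <- affine_from_landmarks(s, d2, "similarity")
  expect_points_equal(fit2$matrix, truth2$matrix, tol = 1e-9)
})

test_that("collinear triples for affine fits raise degenerate-landmarks", {
  s <- rbind(c(0, 0), c(1, 1), c(2, 2))
  d <- rbind(c(0, 0), c(1, 0), c(2, 1))
  expect_error(affine_from_landmarks(s, d, "affine"), "degenerate-landmarks")
})

test_that("MLS interpolates landmarks exactly and degrades to global model", {
  set.seed(3)
  src <- rand_points(6, 0, 50)
  # identity when targets equal sources
  tid <- transform_mls(src, src, "affine")
  p <- rand_points(30, 0, 50)
  expect_points_equal(apply_transform(tid, p), p, tol = 1e-9)

  # single pair, translation class: uniform translation
  t1 <- transform_mls(cbind(10, 10), cbind(13, 14), "translation")
  expect_points_equal(apply_transform(t1, p), p + rep(c(3, 4), each = 30))

  # landmark sources map exactly to their targets
  for (model in c("affine", "similarity", "rigid", "translation")) {
    dst <- src + matrix(runif(12, -3, 3), 6, 2)
    tr <- transform_mls(src, dst, model)
    expect_points_equal(apply_transform(tr, src), dst, tol = 1e-6)
  }

  # far from landmarks the affine MLS approaches the global LS affine
  dst <- apply_transform(rand_affine(), src)
  tr <- transform_mls(src, dst, "affine")
  glob <- affine_from_landmarks(src, dst, "affine")
  far <- cbind(c(5000, -5000), c(5000, 5000))
  expect_points_equal(apply_transform(tr, far), apply_transform(glob, far),
                      tol = 1)
})

test_that("inconsistent duplicate landmarks are rejected", {
  src <- rbind(c(0, 0), c(0, 0), c(5, 5))
  dst <- rbind(c(1, 1), c(2, 2), c(5, 5))
  expect_error(transform_mls(src, dst), "inconsistent-landmarks")
})

test_that("mesh transforms map vertices exactly and invert piecewise", {
  set.seed(5)
  g <- expand.grid(x = seq(0, 60, by = 20), y = seq(0, 60, by = 20))
  rest <- cbind(g$x, g$y)
  moved <- rest + matrix(runif(nrow(rest) * 2, -3, 3), ncol = 2)
  tri <- emrecon:::grid_triangles(4L, 4L)
  tr <- transform_mesh(rest, moved, tri)
  expect_points_equal(apply_transform(tr, rest), moved, tol = 1e-9)
  inv <- invert_transform(tr)
  p <- rand_points(50, 5, 55)
  expect_points_equal(apply_transform(inv, apply_transform(tr, p)), p, tol = 1e-6)
})

test_that("linear transform inversion is exact", {
  set.seed(9)
  for (i in 1:10) {
    tr <- rand_affine()
    inv <- invert_transform(tr)
    p <- rand_points(20)
    expect_points_equal(apply_transform(inv, apply_transform(tr, p)), p, 1e-9)
  }
})
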