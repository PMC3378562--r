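# montaging, series alignment and global pose optimization on
# generator fixtures with known ground truth (scaled-down sizes; the
# full-size recovery experiments live in the acceptance suite)

test_that("a single tile montages to its initial pose (gauge)", {
  tex <- make_texture(256, seed = 30)
  p <- patch(id = 1, image = tex)
  res <- montage_layer(layer(1, 0, 50, list(p)))
  expect_equal(res$residual, 0)
  expect_points_equal(res$poses[[1]]$matrix, cbind(diag(2), c(0, 0)))
})

test_that("zero-jitter tile grids montage back to the exact cut positions", {
  tex <- make_texture(520, seed = 31)
  ct <- cut_tiles(tex, 2, 2, overlap = 0.25, jitter_model = "none", seed = 32)
  res <- montage_layer(layer(1, 0, 50, ct$patches), params = list(seed = 1))
  rms <- pose_error_rms(res$poses, ct$truth$transforms,
                        ct$truth$tile_w, ct$truth$tile_h)
  expect_lt(rms, 0.1)
})

test_that("rigid jitter with image noise is recovered well below a pixel", {
  tex <- make_texture(520, seed = 33)
  ct <- cut_tiles(tex, 2, 2, overlap = 0.25, jitter_model = "rigid",
                  jitter_sigma = 2, rot_sigma = 0.5, noise_sigma = 5, seed = 34)
  res <- montage_layer(layer(1, 0, 50, ct$patches), params = list(seed = 2))
  rms <- pose_error_rms(res$poses, ct$truth$transforms,
                        ct$truth$tile_w, ct$truth$tile_h)
  expect_lt(rms, 0.5)
})

test_that("montage relaxation residual is non-increasing (monotone descent)", {
  tex <- make_texture(520, seed = 35)
  ct <- cut_tiles(tex, 2, 2, overlap = 0.25, jitter_model = "translation",
                  jitter_sigma = 2, noise_sigma = 3, seed = 36)
  l <- layer(1, 0, 50, ct$patches)
  lc <- emrecon:::layer_correspondences(l$patches, list(seed = 3))
  init <- lapply(l$patches, function(p)
    emrecon:::flatten_chain(p$chain)$transforms[[1]]$matrix)
  sol <- relax_poses(4, lc$corr, init = init, model_class = "rigid")
  tr <- sol$residual_trace
  expect_true(all(diff(tr) <= 1e-3)) # monotone descent up to tolerance
})

test_that("series of one layer aligns to the identity", {
  tex <- make_texture(256, seed = 37)
  ls <- layerset(list(layer(1, 0, 50, list(patch(id = 1, image = tex)))))
  res <- align_series_linear(ls)
  expect_equal(res$residual, 0)
})

test_that("duplicated sections align to identity; known rotations are recovered", {
  tex <- make_texture(384, seed = 38)
  noisy <- function(seed) {
    set.seed(seed)
    round(clamp8(tex + matrix(rnorm(length(tex), 0, 2), nrow(tex))))
  }
  ls <- layerset(lapply(1:3, function(i)
    layer(i, (i - 1) * 50, 50, list(patch(id = i, image = noisy(i))))))
  res <- align_series_linear(ls, params = list(seed = 4))
  for (p in res$poses) {
    expect_lt(sqrt(sum(p$matrix[, 3]^2)), 0.2)
    expect_lt(abs(p$matrix[1, 2]), 1e-3)
  }

  # rotate section 2 by a known angle about the image centre
  theta <- 3 * pi / 180
  c0 <- 192
  rot_about <- function(img, th) {
    pts <- cbind(rep(seq_len(ncol(img)) - 0.5, each = nrow(img)),
                 rep(seq_len(nrow(img)) - 0.5, times = ncol(img)))
    src <- apply_transform(transform_rigid(th, 0, 0),
                           pts - c0) + c0
    v <- bilinear_sample(img, src)
    v[is.na(v)] <- mean(img)
    matrix(v, nrow(img), ncol(img))
  }
  ls2 <- layerset(list(
    layer(1, 0, 50, list(patch(id = 1, image = tex))),
    layer(2, 50, 50, list(patch(id = 2, image = rot_about(tex, theta))))))
  res2 <- align_series_linear(ls2, params = list(seed = 5))
  got_theta <- atan2(res2$poses[[2]]$matrix[2, 1], res2$poses[[2]]$matrix[1, 1])
  expect_lt(abs(got_theta - theta) * 180 / pi, 0.1)
})

test_that("global pose optimization recovers a tile linked only across sections", {
  big <- make_texture(640, seed = 40)
  sec_a <- big[1:512, 1:512]
  set.seed(41)
  sec_b <- round(clamp8(sec_a + matrix(rnorm(512 * 512, 0, 3), 512)))
  # section 1: two overlapping tiles; section 2: two tiles, the second
  # of which overlaps nothing in its own section
  a1 <- patch(id = "a1", image = sec_a[1:256, 1:320],
              chain = transform_chain(transform_translation(0, 0)))
  a2 <- patch(id = "a2", image = sec_a[1:256, 193:512],
              chain = transform_chain(transform_translation(192, 0)))
  b1 <- patch(id = "b1", image = sec_b[1:256, 1:256],
              chain = transform_chain(transform_translation(0, 0)))
  # true origin (230, 0); start from a wrong initial guess
  b2 <- patch(id = "b2", image = sec_b[1:256, 231:486],
              chain = transform_chain(transform_translation(238, 6)))
  ls <- layerset(list(layer(1, 0, 50, list(a1, a2)),
                      layer(2, 50, 50, list(b1, b2))))
  feats <- list(
    a1 = extract_features(emrecon:::patch_pixels(a1)),
    a2 = extract_features(emrecon:::patch_pixels(a2)),
    b1 = extract_features(emrecon:::patch_pixels(b1)),
    b2 = extract_features(emrecon:::patch_pixels(b2)))
  mk <- function(fa, fb, seed) {
    m <- match_and_filter(feats[[fa]], feats[[fb]], model_class = "rigid",
                          seed = seed)
    inl <- m$matches[m$matches$inlier, ]
    list(pa = cbind(inl$xa, inl$ya), pb = cbind(inl$xb, inl$yb))
  }
  corrs <- list(
    c(list(layer_a = 1, patch_a = 1, layer_b = 1, patch_b = 2), mk("a1", "a2", 1)),
    c(list(layer_a = 1, patch_a = 1, layer_b = 2, patch_b = 1), mk("a1", "b1", 2)),
    c(list(layer_a = 1, patch_a = 2, layer_b = 2, patch_b = 2), mk("a2", "b2", 3)))
  res <- optimize_global_pose(ls, corrs)
  # all poses recovered: b2's true offset is (230, 0)
  truth <- list(transform_translation(0, 0), transform_translation(192, 0),
                transform_translation(0, 0), transform_translation(230, 0))
  got <- c(res$poses[[1]], res$poses[[2]])
  rms <- pose_error_rms(got, truth, 256, 256)
  expect_lt(rms, 0.5)
})

test_that("poses already satisfying their correspondences stay put", {
  set.seed(42)
  pts <- rand_points(30, 0, 100)
  corr <- list(list(a = 1L, b = 2L, pa = pts, pb = pts - 10))
  init <- list(cbind(diag(2), c(0, 0)), cbind(diag(2), c(10, 10)))
  sol <- relax_poses(2, corr, init = init, model_class = "rigid")
  expect_lt(sol$residual, 1e-9)
  expect_points_equal(sol$poses[[2]]$matrix, init[[2]], tol = 1e-8)
})

test_that("a globally disconnected graph errors naming its components", {
  corr <- list(list(a = 1L, b = 2L, pa = cbind(0, 0), pb = cbind(0, 0)))
  expect_error(relax_poses(4, corr, on_disconnected = "error"),
               "disconnected.*3")
  expect_warning(relax_poses(4, corr, on_disconnected = "warn"),
                 "disconnected")
})
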