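make_patch_at <- function(img, tx = 0, ty = 0, ...) {
  patch(id = paste0("p", tx, "_", ty), image = img,
        chain = transform_chain(transform_translation(tx, ty)), ...)
}

single_layerset <- function(patches) {
  layerset(list(layer(1, 0, 50, patches)))
}

test_that("a single identity patch renders its source pixels under the display map", {
  img <- test_image(16, 16)
  ls <- single_layerset(list(make_patch_at(img)))
  out <- render_region(ls, 1, c(0, 0, 16, 16), 1)
  expect_equal(dim(out), c(16L, 16L))
  expect_equal(out, img, tolerance = 1e-8, ignore_attr = TRUE)

  # narrowed display range remaps linearly with clamping
  p2 <- patch(id = 1, image = img, display_range = c(50, 150))
  out2 <- render_region(single_layerset(list(p2)), 1, c(0, 0, 16, 16), 1)
  expect_equal(out2, pmin(pmax((img - 50) / 100 * 255, 0), 255),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("zero-alpha pixels never affect the rendered output", {
  img_a <- test_image(16, 16, seed = 1)
  img_b1 <- test_image(16, 16, seed = 2)
  img_b2 <- test_image(16, 16, seed = 3) # randomized intensities
  mask0 <- matrix(0, 16, 16)
  ls1 <- single_layerset(list(make_patch_at(img_a),
                              patch(id = 2, image = img_b1, mask = mask0)))
  ls2 <- single_layerset(list(make_patch_at(img_a),
                              patch(id = 2, image = img_b2, mask = mask0)))
  o1 <- render_region(ls1, 1, c(0, 0, 16, 16), 1)
  o2 <- render_region(ls2, 1, c(0, 0, 16, 16), 1)
  expect_identical(o1, o2)
  expect_equal(o1, img_a, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("'difference' composite of a patch with itself is identically zero", {
  img <- test_image(20, 20)
  ls <- single_layerset(list(
    make_patch_at(img),
    patch(id = 2, image = img, composite = "difference")))
  out <- render_region(ls, 1, c(0, 0, 20, 20), 1)
  expect_true(all(abs(out) < 1e-8))
})

test_that("add/subtract/multiply composites follow standard pixel arithmetic", {
  a <- matrix(100, 8, 8); b <- matrix(30, 8, 8)
  mk <- function(mode) single_layerset(list(
    make_patch_at(a), patch(id = 2, image = b, composite = mode)))
  expect_equal(render_region(mk("add"), 1, c(0, 0, 8, 8), 1)[1, 1], 130)
  expect_equal(render_region(mk("subtract"), 1, c(0, 0, 8, 8), 1)[1, 1], 70)
  expect_equal(render_region(mk("multiply"), 1, c(0, 0, 8, 8), 1)[1, 1],
               100 * 30 / 255)
})

test_that("overlay rendering is traversal-order independent for disjoint binary alphas", {
  img1 <- test_image(16, 16, seed = 4)
  img2 <- test_image(16, 16, seed = 5)
  m1 <- matrix(0, 16, 16); m1[, 1:8] <- 1
  m2 <- 1 - m1
  p1 <- patch(id = 1, image = img1, mask = m1)
  p2 <- patch(id = 2, image = img2, mask = m2)
  o12 <- render_region(single_layerset(list(p1, p2)), 1, c(0, 0, 16, 16), 1)
  o21 <- render_region(single_layerset(list(p2, p1)), 1, c(0, 0, 16, 16), 1)
  expect_equal(o12, o21, tolerance = 1e-10)
})

test_that("layer index out of range raises a range error", {
  ls <- single_layerset(list(make_patch_at(test_image())))
  expect_error(render_region(ls, 3, c(0, 0, 4, 4), 1), "range error")
})

test_that("split_patch produces complementary masks that render like the original", {
  img <- test_image(24, 24, seed = 6)
  p <- patch(id = 1, image = img)
  halves <- split_patch(p, rbind(c(12, -2), c(12, 26)))
  ma <- halves[[1]]$mask; mb <- halves[[2]]$mask
  expect_true(all(ma + mb == 1))
  expect_gt(sum(ma), 0); expect_gt(sum(mb), 0)
  expect_equal(sum(ma * mb), 0) # disjoint supports

  orig <- render_region(single_layerset(list(p)), 1, c(0, 0, 24, 24), 1)
  both <- render_region(single_layerset(halves), 1, c(0, 0, 24, 24), 1)
  expect_equal(both, orig, tolerance = 1e-8)
})

test_that("a polyline that does not cross the tile is an invalid cut", {
  p <- patch(id = 1, image = test_image(24, 24))
  expect_error(split_patch(p, rbind(c(10, 10), c(14, 14))), "invalid-cut")
})

test_that("mipmap levels follow the ceil(dim / 2^l) rule and block means", {
  img <- test_image(256, 256, seed = 8)
  p <- patch(id = 1, image = img)
  mm <- build_mipmaps(p, max_level = 3)
  expect_equal(vapply(mm$levels, nrow, 0L), c(256L, 128L, 64L, 32L))
  expect_equal(vapply(mm$levels, ncol, 0L), c(256L, 128L, 64L, 32L))

  # level-1 pixel equals the mean of its 2x2 level-0 block within rounding
  l0 <- mm$levels[[1]]; l1 <- mm$levels[[2]]
  blk <- (l0[1:2, 1:2])
  expect_lt(abs(l1[1, 1] - mean(blk)), 0.51)

  # constant tile stays constant at every level
  pc <- patch(id = 2, image = matrix(77, 64, 64))
  mmc <- build_mipmaps(pc, max_level = 2)
  for (l in mmc$levels) expect_true(all(l == 77))

  # odd dimensions: ceil rule
  po <- patch(id = 3, image = test_image(37, 51, seed = 9))
  mmo <- build_mipmaps(po, max_level = 2)
  expect_equal(dim(mmo$levels[[2]]), c(19L, 26L))
  expect_equal(dim(mmo$levels[[3]]), c(10L, 13L))

  expect_equal(mipmap_level_for_scale(1), 0L)
  expect_equal(mipmap_level_for_scale(0.5), 1L)
  expect_equal(mipmap_level_for_scale(0.3), 1L)
  expect_equal(mipmap_level_for_scale(0.25), 2L)
})

test_that("the preprocessor hook alters pixels before mask and transform", {
  img <- matrix(10, 8, 8)
  p <- patch(id = 1, image = img, preprocessor = function(m) m * 2)
  out <- render_region(single_layerset(list(p)), 1, c(0, 0, 8, 8), 1)
  expect_true(all(out == 20))
})

test_that("CLAHE output is bounded and per-block transfer functions are monotone", {
  set.seed(10)
  img <- matrix(round(runif(128 * 128, 0, 255)), 128, 128)
  out <- clahe_filter(img, block_size = 32, histogram_bins = 64, clip_limit = 2)
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
  maps <- emrecon:::clahe_mappings(img, 32L, 64L, 2)
  for (by in seq_len(maps$nby)) {
    for (bx in seq_len(maps$nbx)) {
      expect_true(all(diff(maps$maps[by, bx, ]) >= -1e-9))
    }
  }
})

test_that("CLAHE falls back to global equalization for oversized blocks", {
  img <- test_image(32, 32)
  expect_message(out <- clahe_filter(img, block_size = 64), "global")
  expect_equal(dim(out), dim(img))
})

test_that("CLAHE increases contrast inside a dark occluding blob", {
  set.seed(12)
  base_tex <- matrix(round(runif(128 * 128, 80, 200)), 128, 128)
  art <- add_artifacts(base_tex, "dark_blob",
                       params = list(radius = 30, strength = 0.85), seed = 13)
  inside <- art$mask > 0.5
  sd_before <- stats::sd(art$raster[inside])
  out <- clahe_filter(art$raster, block_size = 32, clip_limit = 4)
  sd_after <- stats::sd(out[inside])
  expect_gt(sd_after, sd_before)
})

test_that("dual-range composition restores in-band contrast", {
  set.seed(14)
  tex <- matrix(round(runif(96 * 96, 100, 220)), 96, 96)
  art <- add_artifacts(tex, "fold_band",
                       params = list(width = 20, offset = 90), seed = 15)
  mask <- art$mask
  # degenerate masks reduce to single-range mapping
  ra <- c(90, 230); rb <- c(5, 140)
  none <- dual_range_compose(art$raster, ra, rb, matrix(0, 96, 96))
  expect_equal(none, emrecon:::apply_display_range(art$raster, ra))
  full <- dual_range_compose(art$raster, ra, rb, matrix(1, 96, 96))
  expect_equal(full, emrecon:::apply_display_range(art$raster, rb))

  before <- emrecon:::apply_display_range(art$raster, ra)
  composed <- dual_range_compose(art$raster, ra, rb, mask)
  inband <- mask > 0.5
  expect_gt(stats::sd(composed[inband]), stats::sd(before[inband]))
})

test_that("colorize_ycbcr overlays chroma of an RGB patch onto the grayscale base", {
  gray <- matrix(128, 8, 8)
  rgb <- array(0, dim = c(8, 8, 3)); rgb[, , 1] <- 200 # reddish overlay
  ls <- single_layerset(list(
    patch(id = 1, image = gray),
    patch(id = 2, image = rgb, composite = "colorize_ycbcr")))
  out <- render_region(ls, 1, c(0, 0, 8, 8), 1)
  expect_equal(dim(out), c(8L, 8L, 3L))
  expect_gt(out[1, 1, 1], out[1, 1, 2]) # red channel dominates
})

test_that("raster I/O round-trips 8- and 16-bit grayscale images", {
  img8 <- test_image(16, 16)
  f8 <- tempfile(fileext = ".png")
  save_raster(img8, f8, 8)
  back8 <- load_raster(f8)
  expect_equal(back8, img8, tolerance = 1e-9, ignore_attr = TRUE)

  img16 <- matrix(round(runif(64, 0, 65535)), 8, 8)
  f16 <- tempfile(fileext = ".tif")
  save_raster(img16, f16, 16)
  back16 <- load_raster(f16)
  expect_equal(back16, img16, tolerance = 0.51, ignore_attr = TRUE)

  expect_error(load_raster(tempfile(fileext = ".png")), "I/O error")
})
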