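square <- function(x0, y0, s) rbind(c(x0, y0), c(x0 + s, y0),
                                    c(x0 + s, y0 + s), c(x0, y0 + s))

unit_ls <- function(n = 3, thickness = 1, calib = 1) {
  layerset(lapply(seq_len(n), function(i) layer(i, (i - 1) * thickness, thickness)),
           calibration = list(x = calib, y = calib, unit = "nm"))
}

# area list approximating a sphere: one polygon circle per layer
sphere_arealist <- function(r = 20, n_layers = 2 * r + 1, n_vert = 128) {
  al <- arealist("sphere")
  for (i in seq_len(n_layers)) {
    z <- (i - 0.5) - n_layers / 2 # layer centre rel. sphere centre
    if (abs(z) >= r) next
    rad <- sqrt(r^2 - z^2)
    th <- seq(0, 2 * pi, length.out = n_vert + 1)[-1]
    al <- paint(al, i, cbind(rad * cos(th), rad * sin(th)))
  }
  al
}

test_that("painting adds and subtracts polygon areas exactly on the pixel grid", {
  ls <- unit_ls()
  al <- paint(arealist("a"), 1, square(0, 0, 10))
  m <- measure_arealist(al, ls)
  expect_equal(m$per_layer$area, 100)

  al2 <- paint(al, 1, square(0, 0, 10), mode = "subtract")
  expect_equal(measure_arealist(al2, ls)$volume, 0)

  al3 <- paint(al, 1, square(5, 0, 10)) # overlapping square
  expect_equal(measure_arealist(al3, ls)$per_layer$area, 150)

  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(paint(arealist("b"), 1, bow), "geometry error")
})

test_that("disjoint polygons sum exactly; unions never exceed the sum", {
  ls <- unit_ls()
  set.seed(3)
  for (i in 1:10) {
    s1 <- square(runif(1, 0, 20), runif(1, 0, 20), runif(1, 3, 8))
    s2 <- square(runif(1, 0, 20), runif(1, 0, 20), runif(1, 3, 8))
    a1 <- measure_arealist(paint(arealist("x"), 1, s1), ls)$volume
    a2 <- measure_arealist(paint(arealist("x"), 1, s2), ls)$volume
    u <- measure_arealist(paint(paint(arealist("x"), 1, s1), 1, s2), ls)$volume
    expect_lte(u, a1 + a2 + 1e-9)
    s3 <- square(60, 60, 5) # guaranteed disjoint
    a3 <- measure_arealist(paint(arealist("x"), 1, s3), ls)$volume
    u2 <- measure_arealist(paint(paint(arealist("x"), 1, s1), 1, s3), ls)$volume
    expect_equal(u2, a1 + a3)
  }
})

test_that("volume = sum of layer area x thickness, calibrated", {
  ls <- unit_ls(3)
  al <- arealist("box")
  for (i in 1:3) al <- paint(al, i, square(0, 0, 10))
  expect_equal(measure_arealist(al, ls)$volume, 300)

  ls2 <- unit_ls(3, thickness = 2, calib = 3)
  expect_equal(measure_arealist(al, ls2)$volume, 3 * (100 * 9) * 2)
})

test_that("rasterization fills slabs and conserves volume within 1%", {
  ls <- unit_ls(3)
  al <- arealist("empty")
  r0 <- rasterize_arealist(al, ls, bbox = c(0, 0, 8, 8))
  expect_true(all(r0$volume == 0))

  al <- paint(arealist("rect"), 2, square(0, 0, 8))
  r <- rasterize_arealist(al, ls, bbox = c(0, 0, 8, 8))
  expect_true(all(r$volume[, , r$z_factors[1] + 1] == 1))
  expect_true(all(r$volume[, , 1] == 0))

  sph <- sphere_arealist(12, n_layers = 25)
  lss <- unit_ls(25)
  rs <- rasterize_arealist(sph, lss)
  vox_vol <- sum(rs$volume) * rs$voxel^3
  expect_equal(vox_vol, measure_arealist(sph, lss)$volume, tolerance = 0.01)
})

test_that("a single interior voxel meshes to a closed surface with Euler characteristic 2", {
  ls <- unit_ls(3)
  al <- paint(arealist("dot"), 2, square(4, 4, 1))
  m <- mesh_object(al, ls)
  expect_gt(nrow(m$triangles), 0)
  expect_true(mesh_is_watertight(m))
  expect_equal(mesh_euler_characteristic(m), 2)
})

test_that("empty objects mesh to empty meshes", {
  ls <- unit_ls()
  m <- mesh_object(arealist("none"), ls)
  expect_equal(nrow(m$triangles), 0L)
})

test_that("area-list sphere volume converges within 2% of the analytic value", {
  r <- 20
  sph <- sphere_arealist(r)
  ls <- unit_ls(2 * r + 1)
  vol <- measure_arealist(sph, ls)$volume
  expect_lt(abs(vol - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.02)
})

test_that("ball meshes reproduce sphere surface area within 5% and are watertight", {
  r <- 20
  ls <- unit_ls(9, thickness = 10)
  bs <- ball_set("nucleus", data.frame(x = 0, y = 0, layer = 5, radius = r))
  m <- mesh_object(bs, ls)
  expect_true(mesh_is_watertight(m))
  expect_equal(mesh_euler_characteristic(m), 2)
  expect_lt(abs(mesh_area(m) - 4 * pi * r^2) / (4 * pi * r^2), 0.05)
})

test_that("pipe meshes approximate tube surfaces and close at the caps", {
  ls <- unit_ls(9, thickness = 10)
  pp <- pipe("process", data.frame(x = c(0, 40), y = c(0, 0),
                                   layer = c(5, 5), radius = c(5, 5)))
  m <- mesh_object(pp, ls)
  expect_true(mesh_is_watertight(m))
  # cylinder + sphere caps: 2*pi*r*L + 4*pi*r^2
  analytic <- 2 * pi * 5 * 40 + 4 * pi * 5^2
  expect_lt(abs(mesh_area(m) - analytic) / analytic, 0.08)
})

test_that("mesh export writes valid OBJ and PLY", {
  ls <- unit_ls(3)
  m <- mesh_object(paint(arealist("dot"), 2, square(4, 4, 2)), ls)
  fo <- tempfile(fileext = ".obj")
  export_mesh(m, fo)
  lines <- readLines(fo)
  expect_equal(sum(startsWith(lines, "v ")), nrow(m$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(m$triangles))
  fp <- tempfile(fileext = ".ply")
  export_mesh(m, fp)
  expect_equal(readLines(fp)[1], "ply")
})

test_that("vesicle-cleft distances match containment, plane distance and brute force", {
  ls <- unit_ls(5, thickness = 1, calib = 1)
  cleft <- paint(arealist("cleft"), 3, square(0, 0, 10))
  bs <- ball_set("ves", data.frame(x = 5.5, y = 5.5, layer = 3, radius = 1))
  d <- vesicle_cleft_distances(bs, cleft, ls)
  expect_equal(d$table$distance, 0)

  ls4 <- unit_ls(5, thickness = 4, calib = 4)
  cleft4 <- paint(arealist("cleft"), 3, rbind(c(0, 0), c(10, 0), c(10, 40), c(0, 40)))
  bs4 <- ball_set("ves", data.frame(x = 20.5, y = 20.5, layer = 3, radius = 1))
  # nearest cleft voxel centre sits at x = 9.5 px; 11 px * 4 units/px
  d4 <- vesicle_cleft_distances(bs4, cleft4, ls4)
  expect_equal(d4$table$distance, (20.5 - 9.5) * 4)
  expect_error(vesicle_cleft_distances(bs4, arealist("empty"), ls4), "empty-input")

  # brute-force oracle on a small fixture
  set.seed(8)
  cl <- paint(arealist("c"), 2, square(3, 3, 4))
  balls <- data.frame(x = runif(5, 0, 12), y = runif(5, 0, 12),
                      layer = sample(1:3, 5, replace = TRUE), radius = 1)
  lsx <- unit_ls(3, thickness = 2, calib = 1.5)
  got <- vesicle_cleft_distances(ball_set("b", balls), cl, lsx)
  vox <- NULL
  for (ix in 3:6) for (iy in 3:6) vox <- rbind(vox, c((ix + 0.5) * 1.5, (iy + 0.5) * 1.5, 3))
  zc <- c(1, 3, 5)
  for (i in 1:5) {
    bx <- balls$x[i] * 1.5; by <- balls$y[i] * 1.5; bz <- zc[balls$layer[i]]
    expect_equal(got$table$distance[i],
                 sqrt(min((vox[, 1] - bx)^2 + (vox[, 2] - by)^2 + (vox[, 3] - bz)^2)))
  }
})

test_that("double disector counts insertions and recovers planted new objects exactly", {
  set.seed(9)
  ref <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  d0 <- double_disector(ref, ref, grid_cell = 10, match_radius = 5)
  expect_equal(d0$new_count, 0L)

  d1 <- double_disector(ref, rbind(ref, c(200, 200)), grid_cell = 10, match_radius = 5)
  expect_equal(d1$new_count, 1L)

  # planted truth: n = 200, jitter < radius / 2
  n <- 200; radius <- 50
  base_pts <- cbind(runif(n, 0, 5000), runif(n, 0, 5000))
  surviving <- base_pts[1:150, , drop = FALSE]
  jitter <- matrix(runif(150 * 2, -radius / (2 * sqrt(2)), radius / (2 * sqrt(2))), ncol = 2)
  new_pts <- cbind(runif(50, 0, 5000), runif(50, 0, 5000))
  # keep planted new points away from any reference marker
  ok <- vapply(seq_len(50), function(i) {
    min(sqrt((base_pts[, 1] - new_pts[i, 1])^2 +
             (base_pts[, 2] - new_pts[i, 2])^2)) > 2 * radius
  }, logical(1))
  new_pts <- new_pts[ok, , drop = FALSE]
  nxt <- rbind(surviving + jitter, new_pts)
  res <- double_disector(base_pts, nxt, grid_cell = 1000, match_radius = radius)
  expect_equal(res$new_count, nrow(new_pts))
  nxt_tab <- res$table[res$table$section == "next", ]
  expect_equal(which(nxt_tab$match == "NEW"), 150 + seq_len(nrow(new_pts)))

  # symmetric under relabeling of marker order
  perm <- sample(nrow(nxt))
  res2 <- double_disector(base_pts, nxt[perm, ], grid_cell = 1000,
                          match_radius = radius)
  expect_equal(res2$new_count, res$new_count)
})
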