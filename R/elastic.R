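# Non-linear section alignment: block matching between neighbouring
# sections produces a displacement field; quality filtering removes
# low-correlation and locally inconsistent samples; a triangulated
# spring mesh relaxes correspondence forces against internal springs
# that penalise local deformation.

#' Block matching between two pre-aligned sections
#'
#' At every grid point, finds the integer displacement (within
#' `search_radius`) maximising the normalised cross-correlation of
#' `block_radius` blocks between `section_a` and `section_b`, then
#' refines it to sub-pixel precision by fitting a parabola through the
#' correlation peak. Constant blocks are emitted with `r = 0` so the
#' quality filter can drop them.
#'
#' @param section_a Raster whose blocks are looked up.
#' @param section_b Raster searched for each block.
#' @param grid_spacing Sample spacing (px).
#' @param block_radius Block half-size (block edge `2r + 1` px).
#' @param search_radius Maximum displacement searched (px).
#' @return An `em_dispfield`: data.frame with `x`, `y`, `dx`, `dy`,
#'   `r`, and attribute `grid_spacing`.
#' @export
block_match <- function(section_a, section_b, grid_spacing = 32L,
                        block_radius = 16L, search_radius = 8L) {
  stopifnot(all(dim(section_a) == dim(section_b)), grid_spacing > 0)
  h <- nrow(section_a); w <- ncol(section_a)
  br <- block_radius; sr <- search_radius
  margin <- br + sr + 1L
  gx <- seq(margin + 1L, w - margin, by = grid_spacing)
  gy <- seq(margin + 1L, h - margin, by = grid_spacing)
  if (!length(gx) || !length(gy)) {
    stop("sections too small for the requested block/search radii")
  }
  grid <- expand.grid(cx = gx, cy = gy)
  ng <- nrow(grid)
  bw <- 2L * br + 1L
  npx <- bw * bw
  # linear indices of each grid point's block in section_a
  off <- as.vector(outer((-br):br, (-br):br, function(dy, dx) dx * h + dy))
  base_idx <- (grid$cx - 1L) * h + grid$cy
  idx_a <- outer(base_idx, off, "+")
  blk_a <- base::matrix(section_a[idx_a], ng, npx)
  mean_a <- rowMeans(blk_a)
  cen_a <- blk_a - mean_a
  ss_a <- sqrt(rowSums(cen_a^2))
  flat_a <- ss_a < 1e-9
  best_r <- rep(-2, ng); best_dx <- integer(ng); best_dy <- integer(ng)
  # correlation surface around the best offset for subpixel refinement
  rmap <- array(-2, dim = c(ng, 2L * sr + 1L, 2L * sr + 1L))
  for (dx in (-sr):sr) {
    for (dy in (-sr):sr) {
      idx_b <- idx_a + dx * h + dy
      blk_b <- base::matrix(section_b[idx_b], ng, npx)
      cen_b <- blk_b - rowMeans(blk_b)
      ss_b <- sqrt(rowSums(cen_b^2))
      r <- rowSums(cen_a * cen_b) / (ss_a * ss_b)
      r[!is.finite(r)] <- 0
      rmap[, dx + sr + 1L, dy + sr + 1L] <- r
      upd <- r > best_r
      best_r[upd] <- r[upd]; best_dx[upd] <- dx; best_dy[upd] <- dy
    }
  }
  # parabolic sub-pixel refinement, per axis
  sub <- function(best, rm, rp) {
    den <- rm - 2 * best + rp
    ifelse(is.finite(den) & den < 0, 0.5 * (rm - rp) / den, 0)
  }
  fx <- numeric(ng); fy <- numeric(ng)
  ix <- best_dx + sr + 1L; iy <- best_dy + sr + 1L
  inner_x <- ix > 1L & ix < 2L * sr + 1L
  inner_y <- iy > 1L & iy < 2L * sr + 1L
  fx[inner_x] <- sub(best_r[inner_x],
                     rmap[cbind(which(inner_x), ix[inner_x] - 1L, iy[inner_x])],
                     rmap[cbind(which(inner_x), ix[inner_x] + 1L, iy[inner_x])])
  fy[inner_y] <- sub(best_r[inner_y],
                     rmap[cbind(which(inner_y), ix[inner_y], iy[inner_y] - 1L)],
                     rmap[cbind(which(inner_y), ix[inner_y], iy[inner_y] + 1L)])
  fx <- pmin(pmax(fx, -0.5), 0.5); fy <- pmin(pmax(fy, -0.5), 0.5)
  out <- data.frame(x = grid$cx - 0.5, y = grid$cy - 0.5,
                    dx = best_dx + fx, dy = best_dy + fy,
                    r = ifelse(flat_a, 0, best_r))
  out$dx[flat_a] <- 0; out$dy[flat_a] <- 0
  attr(out, "grid_spacing") <- grid_spacing
  class(out) <- c("em_dispfield", class(out))
  out
}

#' Quality-filter a displacement field
#'
#' Removes samples with correlation below `min_r` and samples whose
#' displacement deviates from the local median (neighbours within
#' `neighbor_radius`) by more than `max_deviation`.
#'
#' @param field An `em_dispfield`.
#' @param min_r Minimum correlation coefficient.
#' @param neighbor_radius Radius of the median neighbourhood (px).
#' @param max_deviation Maximum deviation from the local median (px).
#' @return The filtered field (empty field raises a warning).
#' @export
filter_matches <- function(field, min_r = 0.7, neighbor_radius = 80,
                           max_deviation = 3) {
  stopifnot(nrow(field) > 0)
  keep <- field$r >= min_r
  f <- field[keep, , drop = FALSE]
  if (nrow(f)) {
    ok <- rep(TRUE, nrow(f))
    for (i in seq_len(nrow(f))) {
      nb <- which(abs(f$x - f$x[i]) <= neighbor_radius &
                  abs(f$y - f$y[i]) <= neighbor_radius)
      nb <- setdiff(nb, i)
      if (length(nb) < 2L) next
      mdx <- stats::median(f$dx[nb]); mdy <- stats::median(f$dy[nb])
      if (sqrt((f$dx[i] - mdx)^2 + (f$dy[i] - mdy)^2) > max_deviation) {
        ok[i] <- FALSE
      }
    }
    f <- f[ok, , drop = FALSE]
  }
  if (!nrow(f)) warning("all displacement samples were filtered out")
  attr(f, "grid_spacing") <- attr(field, "grid_spacing")
  class(f) <- c("em_dispfield", "data.frame")
  f
}

#' Build an equilateral spring mesh over a section
#'
#' Triangulated grid of vertices (alternate rows offset by half a
#' spacing) covering `[0, width] x [0, height]`, with internal springs
#' on the triangle edges at their rest lengths.
#'
#' @param width,height Section dimensions (px).
#' @param spacing Vertex spacing (px); the default 32 px keeps the
#'   piecewise-linear interpolation error of smooth deformation
#'   fields (wavelengths >= ~250 px) well below the matching noise.
#' @param stiffness Internal spring stiffness.
#' @return An `em_springmesh`: list with `rest`, `current` (n x 2),
#'   `triangles`, `springs` (data.frame `a`, `b`, `rest_length`,
#'   `k`).
#' @export
spring_mesh <- function(width, height, spacing = 32, stiffness = 0.1) {
  row_h <- spacing * sqrt(3) / 2
  ny <- max(2L, ceiling(height / row_h) + 1L)
  nx <- max(2L, ceiling(width / spacing) + 1L)
  verts <- list(); rows_idx <- vector("list", ny)
  for (iy in seq_len(ny)) {
    offs <- if (iy %% 2L == 0L) spacing / 2 else 0
    xs <- seq(0, by = spacing, length.out = nx + 1L) - offs
    rows_idx[[iy]] <- length(verts) + seq_along(xs)
    for (x in xs) verts[[length(verts) + 1L]] <- c(x, (iy - 1L) * row_h)
  }
  rest <- do.call(rbind, verts)
  tris <- list()
  for (iy in seq_len(ny - 1L)) {
    r0 <- rows_idx[[iy]]; r1 <- rows_idx[[iy + 1L]]
    n0 <- length(r0)
    for (ix in seq_len(n0 - 1L)) {
      if (iy %% 2L == 1L) {
        tris[[length(tris) + 1L]] <- c(r0[ix], r0[ix + 1L], r1[ix])
        tris[[length(tris) + 1L]] <- c(r0[ix + 1L], r1[ix + 1L], r1[ix])
      } else {
        tris[[length(tris) + 1L]] <- c(r0[ix], r0[ix + 1L], r1[ix + 1L])
        tris[[length(tris) + 1L]] <- c(r0[ix], r1[ix + 1L], r1[ix])
      }
    }
  }
  triangles <- do.call(rbind, tris)
  e <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(1, 3)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  rl <- sqrt(rowSums((rest[e[, 1], , drop = FALSE] -
                      rest[e[, 2], , drop = FALSE])^2))
  structure(list(rest = rest, current = rest, triangles = triangles,
                 springs = data.frame(a = e[, 1], b = e[, 2],
                                      rest_length = rl, k = stiffness)),
            class = "em_springmesh")
}

# attach a displacement field to a mesh as external springs: each
# sample point is tied into its containing triangle by barycentric
# weights and pulled toward (x + dx, y + dy)
mesh_external_springs <- function(mesh, field, stiffness = 1.0) {
  pts <- cbind(field$x, field$y)
  tri <- mesh$triangles
  a <- mesh$rest[tri[, 1], , drop = FALSE]
  b <- mesh$rest[tri[, 2], , drop = FALSE]
  c_ <- mesh$rest[tri[, 3], , drop = FALSE]
  det <- (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
         (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1])
  out <- list()
  for (i in seq_len(nrow(pts))) {
    vx <- pts[i, 1] - a[, 1]; vy <- pts[i, 2] - a[, 2]
    l2 <- ((c_[, 2] - a[, 2]) * vx - (c_[, 1] - a[, 1]) * vy) / det
    l3 <- (-(b[, 2] - a[, 2]) * vx + (b[, 1] - a[, 1]) * vy) / det
    l1 <- 1 - l2 - l3
    k <- which(l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9)[1L]
    if (is.na(k)) next
    out[[length(out) + 1L]] <- data.frame(
      tri = k, b1 = l1[k], b2 = l2[k], b3 = l3[k],
      tx = pts[i, 1] + field$dx[i], ty = pts[i, 2] + field$dy[i],
      k = stiffness, w = max(field$r[i], 0))
  }
  if (!length(out)) stop("no displacement sample lies inside the mesh")
  do.call(rbind, out)
}

#' Relax spring meshes against external correspondence springs
#'
#' Explicit damped integration of spring forces: internal springs pull
#' vertices toward their rest-length configuration (bounding local
#' deformation), external springs pull displacement-field sample
#' points toward their matched targets. Iteration stops when the
#' maximum vertex force drops below `tol` or after `max_iterations`
#' steps; if the total energy rises for `diverge_steps` consecutive
#' steps the step size is halved, and a step size collapse is an
#' error.
#'
#' @param mesh An `em_springmesh`.
#' @param external External springs from a displacement field
#'   (data.frame as built internally from [filter_matches()] output),
#'   or `NULL` for none (mesh stays at rest).
#' @param params List: `tol` (0.05), `max_iterations` (3000), `step`
#'   (initial step, 0.8), `damping` (0.9), `diverge_steps` (10).
#' @return The mesh with relaxed `current` vertices; attribute
#'   `iterations`.
#' @export
elastic_relax_mesh <- function(mesh, external = NULL, params = list()) {
  p <- utils::modifyList(list(tol = 0.05, max_iterations = 3000L,
                              step = 0.8, damping = 0.9,
                              diverge_steps = 10L), params)
  x <- mesh$current
  sp <- mesh$springs
  if (is.null(external) || !nrow(external)) {
    return(mesh)
  }
  tri <- mesh$triangles
  v1 <- tri[external$tri, 1]; v2 <- tri[external$tri, 2]; v3 <- tri[external$tri, 3]
  vel <- x * 0
  step <- p$step
  last_energy <- Inf; rising <- 0L
  it <- 0L
  repeat {
    it <- it + 1L
    f <- x * 0
    # internal springs
    d <- x[sp$b, , drop = FALSE] - x[sp$a, , drop = FALSE]
    len <- sqrt(rowSums(d^2)); len[len < 1e-12] <- 1e-12
    fmag <- sp$k * (len - sp$rest_length) / len
    fv <- d * fmag
    fa_x <- tapply_add(fv[, 1], sp$a, nrow(x)); fa_y <- tapply_add(fv[, 2], sp$a, nrow(x))
    fb_x <- tapply_add(-fv[, 1], sp$b, nrow(x)); fb_y <- tapply_add(-fv[, 2], sp$b, nrow(x))
    f <- cbind(fa_x + fb_x, fa_y + fb_y)
    # external springs at barycentric points
    px <- external$b1 * x[v1, 1] + external$b2 * x[v2, 1] + external$b3 * x[v3, 1]
    py <- external$b1 * x[v1, 2] + external$b2 * x[v2, 2] + external$b3 * x[v3, 2]
    ex <- external$k * external$w * (external$tx - px)
    ey <- external$k * external$w * (external$ty - py)
    for (bi in 1:3) {
      vv <- tri[external$tri, bi]
      bw <- external[[paste0("b", bi)]]
      f[, 1] <- f[, 1] + tapply_add(ex * bw, vv, nrow(x))
      f[, 2] <- f[, 2] + tapply_add(ey * bw, vv, nrow(x))
    }
    energy_int <- sum(0.5 * sp$k * (len - sp$rest_length)^2)
    energy_ext <- sum(0.5 * external$k * external$w *
                      ((external$tx - px)^2 + (external$ty - py)^2))
    energy <- energy_int + energy_ext
    if (energy > last_energy + 1e-12) {
      rising <- rising + 1L
      if (rising >= p$diverge_steps) {
        step <- step / 2
        rising <- 0L
        vel <- vel * 0
        if (step < 1e-4) stop("elastic relaxation diverged (step size collapsed)")
      }
    } else rising <- 0L
    last_energy <- energy
    maxf <- sqrt(max(rowSums(f^2)))
    if (maxf < p$tol || it >= p$max_iterations) break
    vel <- (vel + step * f) * p$damping
    x <- x + vel
  }
  mesh$current <- x
  attr(mesh, "iterations") <- it
  mesh
}

# sparse accumulation helper: sum values by integer index
tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  acc <- rowsum(vals, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Elastic alignment of one section onto a reference
#'
#' The full non-linear pipeline for a pre-aligned pair: block matching
#' from the moving section into the reference, quality filtering, and
#' spring-mesh relaxation. Returns the mesh transform mapping moving
#' section coordinates into the reference frame.
#'
#' @param reference,moving Rasters of equal size.
#' @param params List: `grid_spacing` (24), `block_radius` (16),
#'   `search_radius` (8), `min_r` (0.7), `max_deviation` (3),
#'   `mesh_spacing` (32), `internal_stiffness` (0.1),
#'   `external_stiffness` (1.0) plus [elastic_relax_mesh()] controls.
#' @return List with `transform` (an `em_transform` of kind mesh),
#'   `mesh`, `field` (raw) and `filtered`.
#' @export
elastic_align <- function(reference, moving, params = list()) {
  p <- utils::modifyList(list(grid_spacing = 24L, block_radius = 16L,
                              search_radius = 8L, min_r = 0.7,
                              max_deviation = 3, mesh_spacing = 32,
                              internal_stiffness = 0.1,
                              external_stiffness = 1.0), params)
  field <- block_match(moving, reference, p$grid_spacing, p$block_radius,
                       p$search_radius)
  filt <- filter_matches(field, p$min_r, 2.5 * p$grid_spacing, p$max_deviation)
  mesh <- spring_mesh(ncol(moving), nrow(moving), p$mesh_spacing,
                      p$internal_stiffness)
  ext <- mesh_external_springs(mesh, filt, p$external_stiffness)
  relaxed <- elastic_relax_mesh(mesh, ext, params)
  list(transform = transform_mesh(relaxed$rest, relaxed$current,
                                  relaxed$triangles),
       mesh = relaxed, field = field, filtered = filt)
}
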