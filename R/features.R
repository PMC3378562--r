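# Scale/rotation-invariant interest points: difference-of-Gaussians
# detection over an octave pyramid, orientation assignment from
# gradient histograms, and 4x4x8 oriented gradient-histogram
# descriptors (the SIFT family of invariant image features).

#' Extract invariant image features
#'
#' Difference-of-Gaussians keypoints with subpixel localisation, edge
#' rejection, dominant-orientation assignment and 128-element oriented
#' gradient-histogram descriptors. Constant images yield an empty
#' feature set (not an error). Fully deterministic.
#'
#' @param raster Numeric matrix (8-bit scale); at least 64 x 64 for
#'   meaningful output.
#' @param params Optional list: `scales_per_octave` (3), `sigma0`
#'   (1.6), `contrast_thresh` (3, DoG units on the 0..255 scale),
#'   `edge_ratio` (10), `min_octave_size` (32).
#' @return data.frame with `x`, `y` (px, original image coordinates),
#'   `sigma`, `orientation` (radians) and a `descriptor` matrix
#'   attribute (one row per feature, L2-normalised).
#' @export
extract_features <- function(raster, params = list()) {
  p <- utils::modifyList(list(scales_per_octave = 3L, sigma0 = 1.6,
                              contrast_thresh = 3, edge_ratio = 10,
                              min_octave_size = 32L), params)
  if (stats::sd(raster) < 1e-9) {
    return(empty_features())
  }
  S <- p$scales_per_octave
  img <- raster / 255
  octave <- 0L
  rows <- list()
  descs <- list()
  base_img <- gauss_blur(img, sqrt(max(p$sigma0^2 - 0.25, 0.01)))
  while (min(dim(base_img)) >= p$min_octave_size) {
    sigmas <- p$sigma0 * 2^((0:(S + 2)) / S)
    gs <- vector("list", S + 3L)
    gs[[1]] <- base_img
    for (s in 2:(S + 3L)) {
      add <- sqrt(sigmas[s]^2 - sigmas[s - 1]^2)
      gs[[s]] <- gauss_blur(gs[[s - 1]], add)
    }
    dog <- lapply(1:(S + 2L), function(s) gs[[s + 1]] - gs[[s]])
    kp <- dog_extrema(dog, S, p)
    if (nrow(kp)) {
      for (ki in seq_len(nrow(kp))) {
        s_i <- kp$scale[ki]
        glevel <- gs[[s_i + 1L]]
        sig <- sigmas[s_i + 1L]
        oris <- keypoint_orientations(glevel, kp$x[ki], kp$y[ki], sig)
        for (ori in oris) {
          d <- keypoint_descriptor(glevel, kp$x[ki], kp$y[ki], sig, ori)
          if (is.null(d)) next
          rows[[length(rows) + 1L]] <- data.frame(
            x = (kp$x[ki]) * 2^octave, y = (kp$y[ki]) * 2^octave,
            sigma = sig * 2^octave, orientation = ori)
          descs[[length(descs) + 1L]] <- d
        }
      }
    }
    base_img <- halve_raster(gs[[S + 1L]])
    octave <- octave + 1L
  }
  if (!length(rows)) return(empty_features())
  out <- do.call(rbind, rows)
  attr(out, "descriptor") <- do.call(rbind, descs)
  out
}

empty_features <- function() {
  out <- data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                    orientation = numeric(0))
  attr(out, "descriptor") <- base::matrix(0, 0, 128)
  out
}

# 3D local extrema of the DoG stack with contrast and edge tests and
# in-plane subpixel refinement
dog_extrema <- function(dog, S, p) {
  h <- nrow(dog[[1]]); w <- ncol(dog[[1]])
  th <- p$contrast_thresh / 255
  out <- list()
  for (s in 2:(S + 1L)) {
    d0 <- dog[[s]]
    neigh_max <- neigh_min <- NULL
    for (lv in (s - 1L):(s + 1L)) {
      m <- dog[[lv]]
      for (dy in -1:1) for (dx in -1:1) {
        if (lv == s && dy == 0 && dx == 0) next
        sh <- m[(2 + dy):(h - 1 + dy), (2 + dx):(w - 1 + dx)]
        neigh_max <- if (is.null(neigh_max)) sh else pmax(neigh_max, sh)
        neigh_min <- if (is.null(neigh_min)) sh else pmin(neigh_min, sh)
      }
    }
    cen <- d0[2:(h - 1), 2:(w - 1)]
    is_ext <- (cen > neigh_max | cen < neigh_min) & abs(cen) > th
    idx <- which(is_ext, arr.ind = TRUE)
    if (!nrow(idx)) next
    iy <- idx[, 1] + 1L; ix <- idx[, 2] + 1L
    # Hessian edge rejection
    dxx <- d0[cbind(iy, ix + 1L)] + d0[cbind(iy, ix - 1L)] - 2 * d0[cbind(iy, ix)]
    dyy <- d0[cbind(iy + 1L, ix)] + d0[cbind(iy - 1L, ix)] - 2 * d0[cbind(iy, ix)]
    dxy <- (d0[cbind(iy + 1L, ix + 1L)] - d0[cbind(iy + 1L, ix - 1L)] -
            d0[cbind(iy - 1L, ix + 1L)] + d0[cbind(iy - 1L, ix - 1L)]) / 4
    tr <- dxx + dyy; det <- dxx * dyy - dxy^2
    r <- p$edge_ratio
    ok <- det > 0 & tr^2 / det < (r + 1)^2 / r
    if (!any(ok)) next
    iy <- iy[ok]; ix <- ix[ok]
    dxx <- dxx[ok]; dyy <- dyy[ok]; dxy <- dxy[ok]
    gx <- (d0[cbind(iy, ix + 1L)] - d0[cbind(iy, ix - 1L)]) / 2
    gy <- (d0[cbind(iy + 1L, ix)] - d0[cbind(iy - 1L, ix)]) / 2
    det2 <- dxx * dyy - dxy^2
    offx <- -(dyy * gx - dxy * gy) / det2
    offy <- -(-dxy * gx + dxx * gy) / det2
    good <- abs(offx) < 1 & abs(offy) < 1
    out[[length(out) + 1L]] <- data.frame(
      x = ix[good] - 0.5 + offx[good], y = iy[good] - 0.5 + offy[good],
      scale = s - 1L)
  }
  if (!length(out)) return(data.frame(x = numeric(0), y = numeric(0),
                                      scale = integer(0)))
  do.call(rbind, out)
}

# gradients of a smoothed level at integer grid, cached per call site
level_gradients <- function(g) {
  h <- nrow(g); w <- ncol(g)
  gx <- base::matrix(0, h, w); gy <- base::matrix(0, h, w)
  gx[, 2:(w - 1)] <- (g[, 3:w] - g[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (g[3:h, ] - g[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

# dominant orientation(s) from a 36-bin gradient histogram
keypoint_orientations <- function(g, x, y, sigma) {
  h <- nrow(g); w <- ncol(g)
  r <- max(2L, round(4.5 * sigma))
  cx <- round(x + 0.5); cy <- round(y + 0.5)
  x0 <- max(2L, cx - r); x1 <- min(w - 1L, cx + r)
  y0 <- max(2L, cy - r); y1 <- min(h - 1L, cy + r)
  if (x1 <= x0 || y1 <= y0) return(numeric(0))
  sub <- g[(y0 - 1L):(y1 + 1L), (x0 - 1L):(x1 + 1L)]
  gr <- level_gradients(sub)
  hh <- y1 - y0 + 1L; ww <- x1 - x0 + 1L
  gx <- gr$gx[2:(hh + 1L), 2:(ww + 1L)]
  gy <- gr$gy[2:(hh + 1L), 2:(ww + 1L)]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  xs <- base::matrix(rep((x0:x1) - 0.5, each = hh), hh, ww) - x
  ys <- base::matrix(rep((y0:y1) - 0.5, times = ww), hh, ww) - y
  wgt <- exp(-(xs^2 + ys^2) / (2 * (1.5 * sigma)^2))
  bins <- (floor((ang + pi) / (2 * pi) * 36) %% 36) + 1L
  hist <- vapply(1:36, function(b) sum((mag * wgt)[bins == b]), 0)
  # circular smoothing
  for (i in 1:2) hist <- (hist + hist[c(36, 1:35)] + hist[c(2:36, 1)]) / 3
  pk <- max(hist)
  if (pk <= 0) return(numeric(0))
  cand <- which(hist >= 0.8 * pk &
                hist > hist[c(36, 1:35)] & hist >= hist[c(2:36, 1)])
  cand <- cand[order(-hist[cand])][seq_len(min(2L, length(cand)))]
  vapply(cand, function(b) {
    l <- hist[ifelse(b == 1, 36, b - 1)]; c_ <- hist[b]
    rr <- hist[ifelse(b == 36, 1, b + 1)]
    off <- if ((l - 2 * c_ + rr) != 0) 0.5 * (l - rr) / (l - 2 * c_ + rr) else 0
    ((b - 0.5 + off) / 36) * 2 * pi - pi
  }, 0)
}

# 4x4 spatial cells x 8 orientation bins over a rotated window
keypoint_descriptor <- function(g, x, y, sigma, ori) {
  nsamp <- 16L
  radius <- 6 * sigma
  ticks <- (seq_len(nsamp) - (nsamp + 1) / 2) / nsamp * 2 * radius
  sx <- rep(ticks, times = nsamp); sy <- rep(ticks, each = nsamp)
  ca <- cos(ori); sa <- sin(ori)
  px <- x + ca * sx - sa * sy
  py <- y + sa * sx + ca * sy
  h <- nrow(g); w <- ncol(g)
  # gradient by central differences via four bilinear samples
  eps <- max(0.6, sigma / 2)
  v_xp <- bilinear_sample(g, cbind(px + eps, py))
  v_xm <- bilinear_sample(g, cbind(px - eps, py))
  v_yp <- bilinear_sample(g, cbind(px, py + eps))
  v_ym <- bilinear_sample(g, cbind(px, py - eps))
  bad <- is.na(v_xp) | is.na(v_xm) | is.na(v_yp) | is.na(v_ym)
  if (mean(bad) > 0.25) return(NULL)
  gx <- (v_xp - v_xm) / (2 * eps); gy <- (v_yp - v_ym) / (2 * eps)
  gx[bad] <- 0; gy[bad] <- 0
  # rotate gradients into the keypoint frame
  rgx <- ca * gx + sa * gy
  rgy <- -sa * gx + ca * gy
  mag <- sqrt(rgx^2 + rgy^2)
  ang <- atan2(rgy, rgx)
  wgt <- exp(-(sx^2 + sy^2) / (2 * (radius / 2)^2))
  cell_x <- pmin(pmax(floor((sx + radius) / (2 * radius) * 4), 0), 3)
  cell_y <- pmin(pmax(floor((sy + radius) / (2 * radius) * 4), 0), 3)
  obin <- (floor((ang + pi) / (2 * pi) * 8) %% 8)
  idx <- cell_y * 32 + cell_x * 8 + obin + 1
  desc <- vapply(1:128, function(i) sum((mag * wgt)[idx == i]), 0)
  n <- sqrt(sum(desc^2))
  if (n < 1e-12) return(NULL)
  desc <- pmin(desc / n, 0.2)
  desc / sqrt(sum(desc^2))
}
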