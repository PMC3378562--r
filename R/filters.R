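# Contrast filters: CLAHE and dual-range composition.

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-based CLAHE on an 8-bit raster: the image is divided into
#' blocks of `block_size`, each block's histogram is clipped at
#' `clip_limit` times the mean bin count with the excess redistributed
#' uniformly, and the resulting per-block monotone transfer functions
#' are bilinearly interpolated between block centres for every pixel.
#' Blocks larger than the image fall back to global equalization (with
#' a message).
#'
#' @param raster Numeric matrix, values 0..255.
#' @param block_size Block edge length in px (>= 8).
#' @param histogram_bins Number of histogram bins (default 256).
#' @param clip_limit Clip factor (>= 1) relative to the uniform bin
#'   count.
#' @return Equalized raster, values 0..255.
#' @export
clahe_filter <- function(raster, block_size = 64L, histogram_bins = 256L,
                         clip_limit = 3) {
  stopifnot(block_size >= 8L, clip_limit >= 1, histogram_bins >= 2L)
  maps <- clahe_mappings(raster, block_size, histogram_bins, clip_limit)
  clahe_apply(raster, maps)
}

# per-block clipped-histogram transfer functions
clahe_mappings <- function(raster, block_size, bins, clip_limit) {
  h <- nrow(raster); w <- ncol(raster)
  if (block_size > min(h, w)) {
    message("CLAHE block larger than image; falling back to global equalization")
    block_size <- min(h, w)
  }
  nbx <- max(1L, round(w / block_size))
  nby <- max(1L, round(h / block_size))
  xb <- round(seq(0, w, length.out = nbx + 1L))
  yb <- round(seq(0, h, length.out = nby + 1L))
  bin_of <- pmin(floor(raster / 256 * bins), bins - 1L) # 0-based bin index
  maps <- array(0, dim = c(nby, nbx, bins))
  centers_x <- numeric(nbx); centers_y <- numeric(nby)
  for (by in seq_len(nby)) {
    for (bx in seq_len(nbx)) {
      rows <- (yb[by] + 1L):yb[by + 1L]
      cols <- (xb[bx] + 1L):xb[bx + 1L]
      bb <- bin_of[rows, cols]
      counts <- tabulate(as.vector(bb) + 1L, nbins = bins)
      n <- sum(counts)
      clip <- clip_limit * n / bins
      excess <- sum(pmax(counts - clip, 0))
      counts <- pmin(counts, clip) + excess / bins
      cdf <- cumsum(counts) / n
      maps[by, bx, ] <- cdf * 255
      centers_x[bx] <- (xb[bx] + xb[bx + 1L]) / 2
      centers_y[by] <- (yb[by] + yb[by + 1L]) / 2
    }
  }
  list(maps = maps, centers_x = centers_x, centers_y = centers_y,
       bins = bins, nbx = nbx, nby = nby)
}

# bilinear interpolation between the 4 surrounding block mappings
clahe_apply <- function(raster, m) {
  h <- nrow(raster); w <- ncol(raster)
  bin_of <- pmin(floor(raster / 256 * m$bins), m$bins - 1L) + 1L
  px <- rep(seq_len(w) - 0.5, each = h)
  py <- rep(seq_len(h) - 0.5, times = w)
  ix <- findInterval(px, m$centers_x)            # 0..nbx
  iy <- findInterval(py, m$centers_y)
  x0 <- pmax(ix, 1L); x1 <- pmin(ix + 1L, m$nbx)
  y0 <- pmax(iy, 1L); y1 <- pmin(iy + 1L, m$nby)
  fx <- ifelse(x1 > x0,
               (px - m$centers_x[x0]) / (m$centers_x[x1] - m$centers_x[x0]), 0)
  fy <- ifelse(y1 > y0,
               (py - m$centers_y[y0]) / (m$centers_y[y1] - m$centers_y[y0]), 0)
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  b <- as.vector(bin_of)
  look <- function(yy, xx) m$maps[cbind(yy, xx, b)]
  v <- (1 - fy) * ((1 - fx) * look(y0, x0) + fx * look(y0, x1)) +
       fy * ((1 - fx) * look(y1, x0) + fx * look(y1, x1))
  base::matrix(v, h, w)
}

#' Compose an image from two display ranges
#'
#' Maps pixels outside `region_mask` through display range `range_a`
#' and pixels inside through `range_b` — restoring content hidden in a
#' different part of the histogram (e.g. the dark band under a
#' support-film fold).
#'
#' @param raster16 Numeric matrix on the source intensity scale.
#' @param range_a,range_b `c(min, max)` display ranges.
#' @param region_mask Logical/0-1 matrix matching `raster16`; `TRUE` /
#'   1 selects `range_b`.
#' @return 8-bit raster.
#' @export
dual_range_compose <- function(raster16, range_a, range_b, region_mask) {
  stopifnot(all(dim(region_mask) == dim(raster16)),
            range_a[1] < range_a[2], range_b[1] < range_b[2])
  mk <- region_mask > 0.5
  out <- apply_display_range(raster16, range_a)
  inb <- apply_display_range(raster16, range_b)
  out[mk] <- inb[mk]
  out
}
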