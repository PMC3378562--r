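# Raster helpers. A raster is a plain numeric matrix indexed
# [row = y + 1, col = x + 1] holding intensities on the source scale
# (0..255 for 8-bit, 0..65535 for 16-bit). Continuous coordinates put
# the centre of pixel (x, y) at (x + 0.5, y + 0.5).

#' Read an image tile
#'
#' Reads 8/16-bit grayscale (or RGB) PNG and TIFF images. Grayscale
#' images are returned as a numeric matrix on their native integer
#' scale; RGB images as an H x W x 3 array scaled 0..255.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @return Numeric matrix (grayscale) or array (RGB) with attribute
#'   `bit_depth`.
#' @export
load_raster <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read image ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(img, "bits.per.sample")
    depth <- if (!is.null(bps)) bps else 8L
  } else {
    stop("I/O error: unsupported image format '", ext, "'")
  }
  scale <- 2^depth - 1
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      out <- img[, , 1:3, drop = FALSE] * 255
      attr(out, "bit_depth") <- depth
      return(out)
    }
    img <- img[, , 1L]
  }
  out <- img * scale
  attr(out, "bit_depth") <- as.integer(depth)
  out
}

#' Write an image
#'
#' @param raster Numeric matrix (grayscale) or H x W x 3 array (RGB),
#'   values 0..`2^bit_depth - 1`.
#' @param path Output path (`.png` or `.tif`).
#' @param bit_depth 8 or 16.
#' @export
save_raster <- function(raster, path, bit_depth = 8L) {
  scale <- 2^bit_depth - 1
  x <- pmin(pmax(raster / scale, 0), 1)
  attributes(x) <- attributes(x)["dim"]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(x, path, dpi = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bit_depth))
  } else stop("I/O error: unsupported image format '", ext, "'")
  invisible(path)
}

raster_width <- function(m) ncol(m)
raster_height <- function(m) nrow(m)

#' Bilinear sampling of a raster at continuous points
#'
#' Pixel centres sit at integer + 0.5; samples outside the raster
#' return `NA`.
#'
#' @param m Numeric matrix.
#' @param pts n x 2 matrix of (x, y) continuous coordinates.
#' @return Numeric vector of length n.
#' @export
bilinear_sample <- function(m, pts) {
  h <- nrow(m); w <- ncol(m)
  x <- pts[, 1] - 0.5; y <- pts[, 2] - 0.5
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp index lookups, mark outside separately
  outside <- x < -0.5 | y < -0.5 | x > w - 0.5 | y > h - 0.5
  x0c <- pmin(pmax(x0, 0), w - 1); x1c <- pmin(x0c + 1, w - 1)
  y0c <- pmin(pmax(y0, 0), h - 1); y1c <- pmin(y0c + 1, h - 1)
  # replicate border when the 2x2 support sticks out but centre is in
  fx[x0 < 0] <- 0; fx[x0 >= w - 1] <- 0
  fy[y0 < 0] <- 0; fy[y0 >= h - 1] <- 0
  i00 <- y0c + 1 + x0c * h; i10 <- y0c + 1 + x1c * h
  i01 <- y1c + 1 + x0c * h; i11 <- y1c + 1 + x1c * h
  v <- (1 - fy) * ((1 - fx) * m[i00] + fx * m[i10]) +
       fy * ((1 - fx) * m[i01] + fx * m[i11])
  v[outside] <- NA_real_
  v
}

#' Separable Gaussian blur
#'
#' @param m Numeric matrix.
#' @param sigma Standard deviation in px; returns `m` unchanged when
#'   `sigma <= 0.01`.
#' @return Blurred matrix of the same size (edge-replicated support).
#' @export
gauss_blur <- function(m, sigma) {
  if (sigma <= 0.01) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv_sep(m, k)
}

conv_sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  # pad by edge replication, filter columns, then rows
  padv <- m[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  a <- stats::filter(padv, k, sides = 2)
  a <- a[(r + 1L):(r + h), , drop = FALSE]
  padh <- a[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  b <- t(stats::filter(t(padh), k, sides = 2))
  out <- b[, (r + 1L):(r + w), drop = FALSE]
  storage.mode(out) <- "double"
  out
}

#' Bilinear resize
#'
#' @param m Numeric matrix.
#' @param new_h,new_w Target dimensions.
#' @return Resized matrix.
#' @export
bilinear_resize <- function(m, new_h, new_w) {
  h <- nrow(m); w <- ncol(m)
  xs <- (seq_len(new_w) - 0.5) * w / new_w
  ys <- (seq_len(new_h) - 0.5) * h / new_h
  pts <- cbind(rep(xs, each = new_h), rep(ys, times = new_w))
  base::matrix(bilinear_sample(m, pts), new_h, new_w)
}

#' 2x2 area-mean downsampling
#'
#' Odd trailing rows/columns average over the available pixels, so the
#' output has dimensions `ceiling(dim / 2)`.
#'
#' @param m Numeric matrix.
#' @return Downsampled matrix.
#' @export
halve_raster <- function(m) {
  h <- nrow(m); w <- ncol(m)
  h2 <- ceiling(h / 2); w2 <- ceiling(w / 2)
  # pad to even by edge replication then 2x2 block mean
  if (h %% 2L) m <- m[c(seq_len(h), h), , drop = FALSE]
  if (w %% 2L) m <- m[, c(seq_len(w), w), drop = FALSE]
  a <- m[seq(1, 2 * h2, by = 2), , drop = FALSE] +
       m[seq(2, 2 * h2, by = 2), , drop = FALSE]
  (a[, seq(1, 2 * w2, by = 2), drop = FALSE] +
   a[, seq(2, 2 * w2, by = 2), drop = FALSE]) / 4
}

clamp8 <- function(x) pmin(pmax(x, 0), 255)

# map source intensities through a display range to 0..255
apply_display_range <- function(m, range) {
  lo <- range[1]; hi <- range[2]
  clamp8((m - lo) / (hi - lo) * 255)
}
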