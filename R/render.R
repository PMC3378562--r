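# Composed rendering of world-space regions from stacked patches.

# Build an inverse mapping (world -> local) for a patch chain. Linear
# elements invert exactly; mesh elements invert piecewise-affinely; MLS
# elements are inverted through a mesh discretisation over the bounding
# box their input occupies for this tile.
chain_inverse_mapping <- function(chain, width, height, spacing = 8) {
  trs <- chain$transforms
  if (!length(trs)) return(function(pts) pts)
  # forward bounding boxes of the tile entering each element
  bbs <- vector("list", length(trs))
  corners <- cbind(c(0, width, 0, width, width / 2),
                   c(0, 0, height, height, height / 2))
  pts <- corners
  for (i in seq_along(trs)) {
    bbs[[i]] <- c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
    pts <- apply_transform(trs[[i]], pts)
  }
  invs <- vector("list", length(trs))
  for (i in seq_along(trs)) {
    tr <- trs[[i]]
    if (is_linear(tr) || tr$kind == "mesh") {
      invs[[i]] <- invert_transform(tr)
    } else {
      bb <- bbs[[i]]
      pad <- 0.05 * max(bb[3] - bb[1], bb[4] - bb[2]) + 1
      invs[[i]] <- invert_transform(tr, bbox = bb + c(-pad, -pad, pad, pad),
                                    spacing = spacing)
    }
  }
  function(pts) {
    for (i in rev(seq_along(invs))) pts <- apply_transform(invs[[i]], pts)
    pts
  }
}

# Render a list of patches into a world bbox at a given scale.
# Returns the composed 8-bit grayscale canvas, the accumulated alpha,
# and (if a colorize_ycbcr patch contributed) chroma planes.
render_patches <- function(patches, bbox, scale = 1, with_alpha = FALSE) {
  x0 <- bbox[1]; y0 <- bbox[2]; x1 <- bbox[3]; y1 <- bbox[4]
  stopifnot(x1 > x0, y1 > y0, scale > 0, scale <= 1)
  w <- max(1L, as.integer(round((x1 - x0) * scale)))
  h <- max(1L, as.integer(round((y1 - y0) * scale)))
  wx <- x0 + (rep(seq_len(w), each = h) - 0.5) / scale
  wy <- y0 + (rep(seq_len(h), times = w) - 0.5) / scale
  world <- cbind(wx, wy)
  out <- base::matrix(0, h, w)
  acc_alpha <- base::matrix(0, h, w)
  cb <- NULL; cr <- NULL
  for (p in patches) {
    inv <- chain_inverse_mapping(p$chain, p$width, p$height)
    loc <- inv(world)
    img <- patch_pixels(p)
    is_rgb <- length(dim(img)) == 3L
    if (is_rgb) {
      rch <- base::matrix(bilinear_sample(img[, , 1], loc), h, w)
      gch <- base::matrix(bilinear_sample(img[, , 2], loc), h, w)
      bch <- base::matrix(bilinear_sample(img[, , 3], loc), h, w)
      src <- 0.299 * rch + 0.587 * gch + 0.114 * bch
    } else {
      src <- base::matrix(bilinear_sample(img, loc), h, w)
    }
    a <- if (is.null(p$mask)) {
      ifelse(is.na(src), 0, 1)
    } else {
      av <- bilinear_sample(p$mask, loc)
      av[is.na(av)] <- 0
      base::matrix(av, h, w)
    }
    a[is.na(src)] <- 0
    src[is.na(src)] <- 0
    src8 <- apply_display_range(src, p$display_range)
    out <- composite_onto(out, src8, a, p$composite)
    if (p$composite == "colorize_ycbcr" && is_rgb) {
      r8 <- apply_display_range(rch, p$display_range); r8[is.na(r8)] <- 0
      g8 <- apply_display_range(gch, p$display_range); g8[is.na(g8)] <- 0
      b8 <- apply_display_range(bch, p$display_range); b8[is.na(b8)] <- 0
      pcb <- -0.168736 * r8 - 0.331264 * g8 + 0.5 * b8
      pcr <- 0.5 * r8 - 0.418688 * g8 - 0.081312 * b8
      if (is.null(cb)) { cb <- base::matrix(0, h, w); cr <- base::matrix(0, h, w) }
      cb <- (1 - a) * cb + a * pcb
      cr <- (1 - a) * cr + a * pcr
    }
    acc_alpha <- pmax(acc_alpha, a)
  }
  list(gray = out, alpha = acc_alpha, cb = cb, cr = cr, width = w, height = h)
}

# standard per-pixel composite arithmetic, weighted by the patch alpha
composite_onto <- function(base_, src8, alpha, mode) {
  switch(mode,
    overlay = (1 - alpha) * base_ + alpha * src8,
    add = clamp8(base_ + alpha * src8),
    subtract = clamp8(base_ - alpha * src8),
    multiply = (1 - alpha) * base_ + alpha * (base_ * src8 / 255),
    difference = (1 - alpha) * base_ + alpha * abs(base_ - src8),
    colorize_ycbcr = base_, # luma untouched; chroma handled by caller
    stop("unknown composite mode ", mode)
  )
}

#' Render a world-space region of a section
#'
#' Composes the patches of one layer in stacking order: each output
#' pixel is inverse-mapped through every patch's transform chain,
#' sampled bilinearly, mapped through the patch display range to 8
#' bits, weighted by its alpha mask and combined using its composite
#' mode. Optional filters (e.g. [clahe_filter()]) are applied last.
#'
#' @param ls An `em_layerset`.
#' @param layer_index Index into `ls$layers` (1-based).
#' @param bbox World bounding box `c(x0, y0, x1, y1)`, half-open.
#' @param scale Rendering scale in `(0, 1]`.
#' @param filters Optional list of functions `raster -> raster`.
#' @return 8-bit raster: numeric matrix (grayscale) or H x W x 3 array
#'   when a `colorize_ycbcr` patch contributed chroma.
#' @export
render_region <- function(ls, layer_index, bbox, scale = 1, filters = NULL) {
  stopifnot(inherits(ls, "em_layerset"))
  if (layer_index < 1L || layer_index > length(ls$layers)) {
    stop("range error: layer index ", layer_index, " out of range")
  }
  l <- ls$layers[[layer_index]]
  r <- render_patches(l$patches, bbox, scale)
  out <- r$gray
  for (f in filters %||% list()) out <- f(out)
  if (!is.null(r$cb)) {
    y <- out
    rr <- clamp8(y + 1.402 * r$cr)
    gg <- clamp8(y - 0.344136 * r$cb - 0.714136 * r$cr)
    bb <- clamp8(y + 1.772 * r$cb)
    out <- array(c(rr, gg, bb), dim = c(nrow(y), ncol(y), 3L))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
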