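# Patch: one image tile with its transform chain, alpha mask, display
# range and composite mode. Layers stack patches; a LayerSet stacks
# calibrated layers.

COMPOSITE_MODES <- c("overlay", "subtract", "add", "multiply",
                     "difference", "colorize_ycbcr")

#' Create a Patch
#'
#' A Patch encapsulates an image tile (on disk or in memory), a chain
#' of coordinate transforms mapping local pixel coordinates to world
#' coordinates, an alpha mask, the display range used to map source
#' intensities to 8 bits, a composite mode, and an optional
#' preprocessor applied to the raw pixels at load time.
#'
#' @param id Integer or character id.
#' @param path Image file path (PNG/TIFF); may be `NA` if `image` is
#'   given.
#' @param image Optional in-memory raster (numeric matrix, source
#'   intensity scale).
#' @param width,height Tile dimensions in px (taken from `image` when
#'   omitted).
#' @param chain An [transform_chain()] (default: identity).
#' @param mask Alpha mask matrix in `[0, 1]` matching the tile
#'   dimensions, or `NULL` for all-ones.
#' @param display_range `c(min, max)` in source intensity units.
#' @param composite One of `r paste0('"', COMPOSITE_MODES, '"', collapse = ", ")`.
#' @param preprocessor Optional function `raster -> raster` applied
#'   after loading, before mask and transforms.
#' @return An object of class `em_patch`.
#' @export
patch <- function(id, path = NA_character_, image = NULL,
                  width = NULL, height = NULL,
                  chain = transform_chain(), mask = NULL,
                  display_range = c(0, 255),
                  composite = "overlay", preprocessor = NULL) {
  composite <- match.arg(composite, COMPOSITE_MODES)
  if (is.null(image) && is.na(path)) stop("patch needs a path or an image")
  if (!is.null(image)) {
    if (length(dim(image)) == 2L) { height <- nrow(image); width <- ncol(image) }
    else { height <- dim(image)[1]; width <- dim(image)[2] }
  }
  stopifnot(!is.null(width), !is.null(height))
  if (!is.null(mask)) {
    stopifnot(nrow(mask) == height, ncol(mask) == width,
              min(mask) >= 0, max(mask) <= 1)
  }
  if (!(display_range[1] < display_range[2])) {
    stop("display range min must be < max")
  }
  if (inherits(chain, "em_transform")) chain <- transform_chain(chain)
  stopifnot(inherits(chain, "em_chain"))
  structure(list(id = id, path = path, image = image,
                 width = as.integer(width), height = as.integer(height),
                 chain = chain, mask = mask,
                 display_range = as.numeric(display_range),
                 composite = composite, preprocessor = preprocessor),
            class = "em_patch")
}

# raw pixels of a patch after the preprocessor hook
patch_pixels <- function(p) {
  img <- if (!is.null(p$image)) p$image else load_raster(p$path)
  if (!is.null(p$preprocessor)) img <- p$preprocessor(img)
  img
}

patch_mask <- function(p) {
  if (!is.null(p$mask)) p$mask
  else base::matrix(1, p$height, p$width)
}

#' Create a Layer / LayerSet
#'
#' A Layer holds the data for a single tissue section: its index,
#' z-range and the ordered list of patches (stacking order = insertion
#' order; later patches composite over earlier ones). A LayerSet is the
#' calibrated ordered stack of layers.
#'
#' @param index Integer section index.
#' @param z_start Section start along z, in calibrated units.
#' @param thickness Section thickness (> 0), calibrated units.
#' @param patches List of [patch()] objects.
#' @return `layer()`: an `em_layer`; `layerset()`: an `em_layerset`.
#' @export
layer <- function(index, z_start, thickness, patches = list()) {
  stopifnot(thickness > 0)
  structure(list(index = as.integer(index), z_start = z_start,
                 thickness = thickness, patches = patches),
            class = "em_layer")
}

#' @rdname layer
#' @param layers List of `em_layer`s, strictly ordered by z.
#' @param calibration List with `x`, `y` (units per px, > 0) and
#'   `unit` (name).
#' @export
layerset <- function(layers = list(),
                     calibration = list(x = 1, y = 1, unit = "px")) {
  stopifnot(calibration$x > 0, calibration$y > 0)
  if (length(layers) > 1L) {
    z <- vapply(layers, function(l) l$z_start, 0)
    if (any(diff(z) <= 0)) stop("layers must be strictly ordered by z")
  }
  structure(list(layers = layers, calibration = calibration),
            class = "em_layerset")
}

layer_z_center <- function(l) l$z_start + l$thickness / 2

#' Split a patch in two along a polygonal line
#'
#' The polyline must cross the tile (both endpoints outside or on the
#' tile bounding box). The two resulting patches share the source image
#' and receive complementary alpha masks (pointwise sum equals the
#' original mask) and independent copies of the transform chain.
#'
#' @param p An `em_patch`.
#' @param polyline n x 2 matrix of local-coordinate vertices of an open
#'   path.
#' @return List of two `em_patch` objects.
#' @export
split_patch <- function(p, polyline) {
  polyline <- as_points(polyline)
  stopifnot(nrow(polyline) >= 2L)
  w <- p$width; h <- p$height
  inside <- function(q) q[1] > 0 && q[1] < w && q[2] > 0 && q[2] < h
  if (inside(polyline[1, ]) || inside(polyline[nrow(polyline), ])) {
    stop("invalid-cut: polyline does not cross the tile")
  }
  # label each pixel centre by the side of its nearest polyline segment
  xs <- rep(seq_len(w) - 0.5, each = h)
  ys <- rep(seq_len(h) - 0.5, times = w)
  side <- polyline_side(polyline, xs, ys)
  ind_a <- base::matrix(as.numeric(side > 0), h, w)
  if (all(ind_a == 1) || all(ind_a == 0)) {
    stop("invalid-cut: polyline does not separate the tile")
  }
  m0 <- patch_mask(p)
  pa <- p; pb <- p
  pa$mask <- m0 * ind_a
  pb$mask <- m0 * (1 - ind_a)
  pa$id <- paste0(p$id, "a"); pb$id <- paste0(p$id, "b")
  list(pa, pb)
}

# signed side of the nearest segment of an open polyline, vectorised
# over query points
polyline_side <- function(poly, xs, ys) {
  ns <- nrow(poly) - 1L
  best_d2 <- rep(Inf, length(xs))
  best_s <- rep(0, length(xs))
  for (i in seq_len(ns)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    len2 <- dx * dx + dy * dy
    if (len2 < 1e-12) next
    t <- ((xs - a[1]) * dx + (ys - a[2]) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * dx; py <- a[2] + t * dy
    d2 <- (xs - px)^2 + (ys - py)^2
    s <- sign(dx * (ys - a[2]) - dy * (xs - a[1]))
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- s[upd]
  }
  best_s
}

#' Build a mipmap pyramid for a patch
#'
#' Level 0 is the fully transformed, display-mapped, alpha-masked tile
#' rendered into its world bounding box; each further level halves the
#' previous one by 2x2 area averaging (dimensions `ceiling(dim / 2^l)`).
#'
#' @param p An `em_patch`.
#' @param max_level Highest pyramid level (>= 0).
#' @return An `em_mipmaps` object: list with `levels` (8-bit rasters),
#'   `alphas`, `origin` (world x0, y0) and `bbox`.
#' @export
build_mipmaps <- function(p, max_level = 3L) {
  bb <- patch_world_bbox(p)
  bb <- c(floor(bb[1]), floor(bb[2]), ceiling(bb[3]), ceiling(bb[4]))
  r <- render_patches(list(p), bb, scale = 1, with_alpha = TRUE)
  levels <- list(r$gray)
  alphas <- list(r$alpha)
  for (l in seq_len(max_level)) {
    levels[[l + 1L]] <- halve_raster(levels[[l]])
    alphas[[l + 1L]] <- halve_raster(alphas[[l]])
  }
  structure(list(levels = lapply(levels, round), alphas = alphas,
                 origin = bb[1:2], bbox = bb, patch_id = p$id),
            class = "em_mipmaps")
}

#' @rdname build_mipmaps
#' @param scale Requested rendering scale in `(0, 1]`.
#' @return `mipmap_level_for_scale()`: the pyramid level used for a
#'   given scale, `floor(-log2(scale))`.
#' @export
mipmap_level_for_scale <- function(scale) {
  stopifnot(scale > 0, scale <= 1)
  max(0L, floor(-log2(scale)))
}

# world bounding box of a patch by forward-mapping a boundary grid
patch_world_bbox <- function(p) {
  nx <- 9L
  gx <- seq(0, p$width, length.out = nx)
  gy <- seq(0, p$height, length.out = nx)
  pts <- rbind(cbind(gx, 0), cbind(gx, p$height),
               cbind(0, gy), cbind(p$width, gy))
  wpts <- apply_chain(p$chain, pts)
  c(min(wpts[, 1]), min(wpts[, 2]), max(wpts[, 1]), max(wpts[, 2]))
}
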