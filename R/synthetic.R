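# Deterministic fixture generators: EM-like textures, overlapping tile
# sets with known pose perturbations, smooth section deformations with
# known displacement fields, fold/blob artifacts, random arbors and
# connector-linked circuits. Every generator is a pure function of its
# parameters and seed.

#' Generate an EM-like texture
#'
#' Band-limited noise plus dark curvilinear cell boundaries (Voronoi
#' edges) and dark blob organelles, quantised to 8 bits. Deterministic
#' per seed.
#'
#' @param size Edge length in px (>= 256 for registration-grade
#'   texture; smaller sizes are allowed for light fixtures).
#' @param seed Integer seed.
#' @return 8-bit raster (numeric matrix).
#' @export
make_texture <- function(size = 512L, seed = 1L) {
  set.seed(seed)
  n_seeds <- max(16L, round((size / 72)^2))
  sx <- runif(n_seeds, 0, size); sy <- runif(n_seeds, 0, size)
  noise <- gauss_blur(base::matrix(stats::rnorm(size * size), size, size), 1.2)
  noise <- noise / stats::sd(noise)
  # distance to 1st and 2nd nearest Voronoi seed, running best/second
  xs <- seq_len(size) - 0.5
  xx <- rep(xs, each = size)
  yy <- rep(seq_len(size) - 0.5, times = size)
  d1 <- rep(Inf, size * size); dsec <- rep(Inf, size * size)
  for (s in seq_len(n_seeds)) {
    d <- (xx - sx[s])^2 + (yy - sy[s])^2
    better <- d < d1
    dsec[better] <- d1[better]
    d1[better] <- d[better]
    mid <- !better & d < dsec
    dsec[mid] <- d[mid]
  }
  gap <- sqrt(dsec) - sqrt(d1)
  edge <- base::matrix(exp(-(gap / 2.5)^2), size, size)
  img <- 150 + 35 * noise - 95 * edge
  # blob organelles
  n_blob <- max(4L, round(n_seeds / 3))
  bx <- runif(n_blob, 0, size); by <- runif(n_blob, 0, size)
  br <- runif(n_blob, 3, 9)
  xg <- base::matrix(xs, size, size, byrow = TRUE)
  yg <- base::matrix(seq_len(size) - 0.5, size, size)
  for (b in seq_len(n_blob)) {
    img <- img - 70 * exp(-((xg - bx[b])^2 + (yg - by[b])^2) / (2 * br[b]^2))
  }
  round(clamp8(img))
}

#' Cut a texture into overlapping tiles with known pose perturbations
#'
#' Emulates camera-stage acquisition: a grid of overlapping crops, each
#' perturbed by a known translation (or rigid) jitter, with additive
#' Gaussian noise and a linear shading gradient. The ground-truth
#' local-to-world transform of every tile is recorded, so that
#' registration results can be scored without human input.
#'
#' @param texture 8-bit raster.
#' @param rows,cols Grid dimensions.
#' @param overlap Overlap fraction between adjacent tiles, in (0, 0.5).
#' @param jitter_model `"none"`, `"translation"` or `"rigid"`.
#' @param jitter_sigma Translation jitter SD (px).
#' @param rot_sigma Rotation jitter SD (degrees; rigid only).
#' @param noise_sigma Additive Gaussian noise SD (gray levels).
#' @param shading Peak-to-peak linear shading amplitude (gray levels).
#' @param seed Integer seed.
#' @return List with `patches` (list of [patch()], chains set to the
#'   nominal stage position) and `truth` (list: `transforms`
#'   ground-truth chains, `table` data.frame, `tile_w`, `tile_h`).
#' @export
cut_tiles <- function(texture, rows = 3L, cols = 3L, overlap = 0.2,
                      jitter_model = c("translation", "rigid", "none"),
                      jitter_sigma = 2, rot_sigma = 0.5,
                      noise_sigma = 0, shading = 0, seed = 1L) {
  jitter_model <- match.arg(jitter_model)
  stopifnot(overlap > 0, overlap < 0.5)
  set.seed(seed + 1L)
  h <- nrow(texture); w <- ncol(texture)
  tw <- floor(w / (cols - (cols - 1) * overlap))
  th <- floor(h / (rows - (rows - 1) * overlap))
  if (tw < 32 || th < 32) stop("size error: grid larger than texture allows")
  # integer grid steps: exact crops in the jitter-free case
  step_x <- round((1 - overlap) * tw)
  step_y <- round((1 - overlap) * th)
  patches <- list()
  truths <- list()
  tab <- NULL
  k <- 0L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      k <- k + 1L
      ox <- (cc - 1) * step_x
      oy <- (r - 1) * step_y
      theta <- if (jitter_model == "rigid") stats::rnorm(1, 0, rot_sigma * pi / 180) else 0
      jx <- if (jitter_model != "none") stats::rnorm(1, 0, jitter_sigma) else 0
      jy <- if (jitter_model != "none") stats::rnorm(1, 0, jitter_sigma) else 0
      # truth local->world: rotate about tile centre, then translate
      cx <- tw / 2; cy <- th / 2
      rot <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
      tvec <- c(ox + jx + cx, oy + jy + cy) - rot %*% c(cx, cy)
      truth <- transform_linear(if (theta != 0) "rigid" else "translation",
                                cbind(rot, tvec))
      # sample the texture under the truth transform
      px <- rep(seq_len(tw) - 0.5, each = th)
      py <- rep(seq_len(th) - 0.5, times = tw)
      wp <- apply_transform(truth, cbind(px, py))
      img <- base::matrix(bilinear_sample(texture, wp), th, tw)
      img[is.na(img)] <- mean(img, na.rm = TRUE)
      if (shading > 0) {
        dir <- stats::runif(1, 0, 2 * pi)
        gx <- cos(dir) * (px - tw / 2) / tw
        gy <- sin(dir) * (py - th / 2) / th
        img <- img + base::matrix(shading * (gx + gy), th, tw)
      }
      if (noise_sigma > 0) {
        img <- img + base::matrix(stats::rnorm(th * tw, 0, noise_sigma), th, tw)
      }
      img <- round(clamp8(img))
      patches[[k]] <- patch(id = k, image = img,
                            chain = transform_chain(transform_translation(ox, oy)))
      truths[[k]] <- truth
      tab <- rbind(tab, data.frame(tile = k, row = r, col = cc,
                                   origin_x = ox, origin_y = oy,
                                   theta = theta, jx = jx, jy = jy))
    }
  }
  list(patches = patches,
       truth = list(transforms = truths, table = tab,
                    tile_w = tw, tile_h = th, overlap = overlap))
}

#' Gauge-invariant RMS pose error against ground truth
#'
#' Maps each tile's corner points through the recovered and the
#' ground-truth transforms, removes the arbitrary global frame (the
#' solver's gauge) by fitting one rigid transform from all recovered
#' to all truth points, and reports the RMS of the remaining
#' per-corner errors.
#'
#' @param poses,truths Lists of recovered / ground-truth
#'   `em_transform`s (same length and order).
#' @param tile_w,tile_h Tile dimensions (px).
#' @return RMS corner error in px.
#' @export
pose_error_rms <- function(poses, truths, tile_w, tile_h) {
  corners <- rbind(c(0, 0), c(tile_w, 0), c(0, tile_h), c(tile_w, tile_h),
                   c(tile_w / 2, tile_h / 2))
  got <- do.call(rbind, lapply(poses, apply_transform, pts = corners))
  want <- do.call(rbind, lapply(truths, apply_transform, pts = corners))
  g <- affine_from_landmarks(got, want, "rigid")
  aligned <- apply_transform(g, got)
  sqrt(mean(rowSums((aligned - want)^2)))
}

#' Smooth ground-truth deformation fields
#'
#' Either a sinusoid (`dx = A sin(2 pi y / lambda)`,
#' `dy = A sin(2 pi x / lambda)`) or a sum of random Gaussian bumps of
#' the given amplitude.
#'
#' @param kind `"sinusoid"` or `"bumps"`.
#' @param amplitude Peak displacement (px).
#' @param wavelength Sinusoid wavelength (px).
#' @param n_bumps Number of Gaussian bumps.
#' @param size Section edge length (bump placement range).
#' @param seed Integer seed.
#' @return An `em_deformation` with a `field_at(pts)`-compatible
#'   description.
#' @export
deformation_truth <- function(kind = c("sinusoid", "bumps"), amplitude = 5,
                              wavelength = 256, n_bumps = 4L, size = 512L,
                              seed = 1L) {
  kind <- match.arg(kind)
  obj <- list(kind = kind, amplitude = amplitude, wavelength = wavelength,
              seed = seed, size = size)
  if (kind == "bumps") {
    set.seed(seed + 2L)
    obj$centers <- cbind(runif(n_bumps, 0.2 * size, 0.8 * size),
                         runif(n_bumps, 0.2 * size, 0.8 * size))
    obj$sigmas <- runif(n_bumps, size / 10, size / 5)
    ang <- runif(n_bumps, 0, 2 * pi)
    amp <- runif(n_bumps, 0.5, 1) * amplitude
    obj$vecs <- cbind(amp * cos(ang), amp * sin(ang))
  }
  structure(obj, class = "em_deformation")
}

#' @rdname deformation_truth
#' @param truth An `em_deformation`.
#' @param pts n x 2 point matrix.
#' @return `field_at()`: n x 2 matrix of displacement vectors.
#' @export
field_at <- function(truth, pts) {
  pts <- as_points(pts)
  if (truth$kind == "sinusoid") {
    cbind(truth$amplitude * sin(2 * pi * pts[, 2] / truth$wavelength),
          truth$amplitude * sin(2 * pi * pts[, 1] / truth$wavelength))
  } else {
    out <- base::matrix(0, nrow(pts), 2L)
    for (b in seq_len(nrow(truth$centers))) {
      g <- exp(-((pts[, 1] - truth$centers[b, 1])^2 +
                 (pts[, 2] - truth$centers[b, 2])^2) / (2 * truth$sigmas[b]^2))
      out <- out + cbind(g * truth$vecs[b, 1], g * truth$vecs[b, 2])
    }
    out
  }
}

#' Apply a known smooth deformation to a section image
#'
#' Backward warp: `out(x) = in(x + d(x))` with bilinear sampling, where
#' `d` is the truth displacement field.
#'
#' @param raster 8-bit raster.
#' @param truth An [deformation_truth()] object; amplitude must be
#'   below a quarter of the raster size.
#' @return Deformed raster.
#' @export
deform_section <- function(raster, truth) {
  stopifnot(truth$amplitude < min(dim(raster)) / 4)
  if (truth$amplitude == 0) return(raster)
  h <- nrow(raster); w <- ncol(raster)
  px <- rep(seq_len(w) - 0.5, each = h)
  py <- rep(seq_len(h) - 0.5, times = w)
  d <- field_at(truth, cbind(px, py))
  v <- bilinear_sample(raster, cbind(px + d[, 1], py + d[, 2]))
  v[is.na(v)] <- mean(raster)
  base::matrix(v, h, w)
}

#' Composite a fold-band or dark-blob artifact onto a raster
#'
#' Emulates a support-film fold (dark band across the image) or an
#' occluding precipitate blob; the truth mask of affected pixels is
#' returned for mask/filter tests.
#'
#' @param raster 8-bit raster.
#' @param kind `"fold_band"` or `"dark_blob"`.
#' @param params For `fold_band`: `width` (px) and `offset` (gray
#'   levels subtracted). For `dark_blob`: `radius` (px) and `strength`
#'   in (0, 1) (fraction of intensity removed at the blob centre).
#' @param seed Integer seed (placement).
#' @return List with `raster` and `mask` (1 inside the artifact).
#' @export
add_artifacts <- function(raster, kind = c("fold_band", "dark_blob"),
                          params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed + 3L)
  h <- nrow(raster); w <- ncol(raster)
  xg <- base::matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  yg <- base::matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  if (kind == "fold_band") {
    width <- params$width %||% 24
    offset <- params$offset %||% 80
    ang <- stats::runif(1, 0, pi)
    c0 <- stats::runif(1, 0.3, 0.7) * (cos(ang) * w + sin(ang) * h)
    d <- cos(ang) * xg + sin(ang) * yg - c0
    mask <- (abs(d) <= width / 2) * 1
    out <- clamp8(raster - offset * mask)
  } else {
    radius <- params$radius %||% (min(h, w) / 5)
    strength <- params$strength %||% 0.8
    cx <- stats::runif(1, 0.3 * w, 0.7 * w)
    cy <- stats::runif(1, 0.3 * h, 0.7 * h)
    r2 <- (xg - cx)^2 + (yg - cy)^2
    mask <- (r2 <= radius^2) * 1
    soft <- exp(-r2 / (2 * (radius / 1.5)^2))
    out <- clamp8(raster * (1 - strength * soft))
  }
  list(raster = round(out), mask = mask)
}

#' Simulate a random neuronal arbor
#'
#' Grows a rooted tree by a biased random walk: each new node extends
#' the current tip with a persistent direction, or with probability
#' `branch_prob` branches from a random existing node. Layers drift by
#' at most one section per step. The result is always a valid
#' [skeleton_tree()].
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param branch_prob Branching probability per node.
#' @param step Mean step length (px).
#' @param layer_range Integer range of allowed layer indices.
#' @param seed Integer seed.
#' @param id Tree id.
#' @param origin Root position `c(x, y)`.
#' @param conf_range Confidences are sampled uniformly from this
#'   integer range.
#' @return An `em_tree` (treeline subtype, positive radii).
#' @export
simulate_arbor <- function(n_nodes, branch_prob = 0.12, step = 12,
                           layer_range = c(1L, 5L), seed = 1L, id = "arbor",
                           origin = c(0, 0), conf_range = c(1L, 5L)) {
  stopifnot(n_nodes >= 1)
  set.seed(seed + 4L)
  n <- as.integer(n_nodes)
  parent <- rep(NA_integer_, n)
  x <- numeric(n); y <- numeric(n)
  lay <- integer(n); conf <- rep(NA_integer_, n)
  rad <- stats::runif(n, 0.5, 4)
  dirs <- numeric(n)
  x[1] <- origin[1]; y[1] <- origin[2]
  lay[1] <- as.integer(round(mean(layer_range)))
  dirs[1] <- stats::runif(1, 0, 2 * pi)
  rad[1] <- stats::runif(1, 1, 4)
  for (k in seq_len(n)[-1]) {
    if (stats::runif(1) < branch_prob) {
      parent_i <- sample.int(k - 1L, 1L)
      ang <- stats::runif(1, 0, 2 * pi)
    } else {
      parent_i <- k - 1L
      ang <- dirs[parent_i] + stats::rnorm(1, 0, 0.5)
    }
    len <- stats::rexp(1, 1 / step) + 1
    parent[k] <- parent_i
    x[k] <- x[parent_i] + len * cos(ang)
    y[k] <- y[parent_i] + len * sin(ang)
    lay[k] <- min(max(lay[parent_i] + sample(c(-1L, 0L, 1L), 1L),
                      layer_range[1]), layer_range[2])
    conf[k] <- sample(seq(conf_range[1], conf_range[2]), 1L)
    dirs[k] <- ang
  }
  skeleton_tree(id, data.frame(id = seq_len(n), parent = parent, x = x, y = y,
                               layer = lay, confidence = conf, radius = rad),
                "treeline")
}

#' Simulate a connector-linked circuit project
#'
#' Places `n_neurons` random arbors in a shared volume and links nodes
#' of distinct arbors with polyadic connectors (origin + 1..3 targets
#' within `max_reach`), confidences sampled 1..5. The result is a
#' template-legal [project()].
#'
#' @param n_neurons Number of arbors (>= 2).
#' @param n_connectors Number of connectors.
#' @param max_reach Maximum link length (px).
#' @param n_layers Number of sections in the project layerset.
#' @param nodes_per_arbor Arbor size.
#' @param seed Integer seed.
#' @return An `em_project`.
#' @export
simulate_circuit <- function(n_neurons = 5L, n_connectors = 10L,
                             max_reach = 60, n_layers = 5L,
                             nodes_per_arbor = 30L, seed = 1L) {
  stopifnot(n_neurons >= 2)
  set.seed(seed + 5L)
  ls <- layerset(lapply(seq_len(n_layers), function(i) layer(i, (i - 1) * 50, 50)),
                 calibration = list(x = 4, y = 4, unit = "nm"))
  arbors <- list()
  for (i in seq_len(n_neurons)) {
    org <- c(stats::runif(1, 0, 220), stats::runif(1, 0, 220))
    arbors[[paste0("neuron", i)]] <-
      simulate_arbor(nodes_per_arbor, seed = seed * 101L + i,
                     id = paste0("neuron", i), origin = org,
                     layer_range = c(1L, n_layers))
  }
  # gather all node positions for reach queries
  allpos <- do.call(rbind, lapply(names(arbors), function(nm) {
    nd <- arbors[[nm]]$nodes
    data.frame(tree = nm, node = nd$id, x = nd$x, y = nd$y, layer = nd$layer)
  }))
  connectors <- list()
  cid <- 0L
  attempts <- 0L
  while (length(connectors) < n_connectors && attempts < n_connectors * 50L) {
    attempts <- attempts + 1L
    oi <- sample.int(nrow(allpos), 1L)
    o <- allpos[oi, ]
    d <- sqrt((allpos$x - o$x)^2 + (allpos$y - o$y)^2)
    cand <- which(d <= max_reach & allpos$tree != o$tree)
    if (!length(cand)) next
    nt <- min(length(cand), sample(1:3, 1L))
    ti <- cand[sample.int(length(cand), nt)]
    cid <- cid + 1L
    connectors[[as.character(cid)]] <- connector(
      id = cid,
      origin = link_end(tree = o$tree, node = o$node,
                        confidence = sample(1:5, 1L)),
      targets = lapply(ti, function(j) link_end(
        tree = allpos$tree[j], node = allpos$node[j],
        confidence = sample(1:5, 1L))),
      layer = o$layer)
  }
  proj <- project(template = example_template(), layerset = ls)
  proj$arbors <- arbors
  proj$connectors <- connectors
  brain <- project_add_node(proj, NULL, "brain", "brain")
  proj <- brain$project
  lin <- project_add_node(proj, brain$id, "lineage", "lineage A")
  proj <- lin$project
  neuron_node <- stats::setNames(integer(length(arbors)), names(arbors))
  for (nm in names(arbors)) {
    nn <- project_add_node(proj, lin$id, "neuron", nm)
    proj <- nn$project
    neuron_node[nm] <- nn$id
    proj <- project_add_node(proj, nn$id, "treeline",
                             paste0(nm, " skeleton"), object = nm)$project
  }
  # each connector files under the neuron of its origin (free origins
  # under the first neuron)
  for (cn in proj$connectors) {
    host <- if (!link_is_free(cn$origin)) cn$origin$tree else names(arbors)[1]
    proj <- project_add_node(proj, neuron_node[[host]], "connector",
                             paste0("connector ", cn$id),
                             object = as.character(cn$id))$project
  }
  validate_connectors(proj)
  proj
}
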