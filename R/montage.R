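# Pose recovery: iterative relaxation of tile/section poses against
# point correspondences, within-section montaging, cross-section
# linear series alignment and joint global pose optimization.

#' Iterative pose relaxation over a correspondence graph
#'
#' The shared solver behind montaging, series alignment and global
#' pose optimization. Each unit (tile or section) is repeatedly
#' re-fitted to all its inlier correspondences mapped through the
#' current poses of its neighbours (Gauss-Seidel sweeps), following a
#' translation -> rigid -> affine model schedule that avoids early
#' shear. The first unit (or the given gauge) stays fixed at its
#' initial pose. Iteration stops when the mean point-transfer error
#' changes by less than `tol` or after `max_iterations` sweeps.
#'
#' @param n_units Number of units being posed.
#' @param corr List of correspondence entries: each a list with `a`,
#'   `b` (unit indices) and `pa`, `pb` (k x 2 matrices of matched
#'   points in the local coordinates of `a` and `b`).
#' @param init Optional list of initial 2x3 pose matrices (default
#'   identity).
#' @param model_class Final model class of the schedule
#'   (`"translation"`, `"rigid"`, `"similarity"` or `"affine"`).
#' @param gauge Index of the unit fixed at its initial pose.
#' @param tol Convergence threshold on the change of the mean residual
#'   between sweeps (px). Kept small (1e-4): the global modes of the
#'   pose graph reduce the residual slowly per sweep while still far
#'   from equilibrium.
#' @param max_iterations Sweep budget per schedule phase.
#' @param on_disconnected `"warn"` (solve each component around its
#'   own gauge) or `"error"`.
#' @return List with `poses` (list of `em_transform`), `residual`
#'   (mean final point-transfer error), `residual_trace` and
#'   `components`.
#' @export
relax_poses <- function(n_units, corr, init = NULL, model_class = "rigid",
                        gauge = 1L, tol = 1e-4, max_iterations = 2000L,
                        on_disconnected = c("warn", "error")) {
  on_disconnected <- match.arg(on_disconnected)
  poses <- init %||% replicate(n_units, cbind(diag(2), c(0, 0)),
                               simplify = FALSE)
  poses <- lapply(poses, function(m) {
    if (inherits(m, "em_transform")) m$matrix else m
  })
  # connectivity
  comp <- seq_len(n_units)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (cc in corr) {
    a <- find(cc$a); b <- find(cc$b)
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_len(n_units), find, 0L)
  comp_ids <- unique(roots)
  if (length(comp_ids) > 1L) {
    msg <- paste0("correspondence graph is disconnected: components {",
                  paste(vapply(comp_ids, function(r)
                    paste(which(roots == r), collapse = ","), ""),
                    collapse = "} {"), "}")
    if (on_disconnected == "error") stop(msg) else warning(msg)
  }
  # per-component gauges: requested gauge for its component, smallest
  # index elsewhere
  fixed <- rep(FALSE, n_units)
  for (r in comp_ids) {
    members <- which(roots == r)
    fixed[if (roots[gauge] == r) gauge else members[1L]] <- TRUE
  }
  # neighbour lists: for unit i, correspondences (pa in i, pb in j)
  by_unit <- vector("list", n_units)
  for (ci in seq_along(corr)) {
    cc <- corr[[ci]]
    by_unit[[cc$a]] <- c(by_unit[[cc$a]], list(list(p = cc$pa, j = cc$b, q = cc$pb)))
    by_unit[[cc$b]] <- c(by_unit[[cc$b]], list(list(p = cc$pb, j = cc$a, q = cc$pa)))
  }
  apply_m <- function(m, p) cbind(p[, 1] * m[1, 1] + p[, 2] * m[1, 2] + m[1, 3],
                                  p[, 1] * m[2, 1] + p[, 2] * m[2, 2] + m[2, 3])
  mean_residual <- function() {
    tot <- 0; cnt <- 0L
    for (cc in corr) {
      d <- apply_m(poses[[cc$a]], cc$pa) - apply_m(poses[[cc$b]], cc$pb)
      tot <- tot + sum(sqrt(rowSums(d^2))); cnt <- cnt + nrow(cc$pa)
    }
    if (cnt == 0L) 0 else tot / cnt
  }
  schedule <- switch(model_class,
    translation = "translation",
    rigid = c("translation", "rigid"),
    similarity = c("translation", "rigid", "similarity"),
    affine = c("translation", "rigid", "affine"))
  trace <- mean_residual()
  # translation phase: the global optimum is a sparse weighted
  # Laplacian system; solve it directly (Gauss-Seidel diffuses global
  # modes too slowly through large correspondence graphs)
  poses <- solve_translations(poses, corr, fixed, apply_m)
  trace <- c(trace, mean_residual())
  schedule <- setdiff(schedule, "translation")
  for (phase in schedule) {
    prev <- Inf
    for (it in seq_len(max_iterations)) {
      for (i in seq_len(n_units)) {
        if (fixed[i] || !length(by_unit[[i]])) next
        src <- do.call(rbind, lapply(by_unit[[i]], `[[`, "p"))
        dst <- do.call(rbind, lapply(by_unit[[i]], function(e)
          apply_m(poses[[e$j]], e$q)))
        need <- min_model_points(phase)
        if (nrow(src) < need) next
        fit <- tryCatch(affine_from_landmarks(src, dst, phase),
                        error = function(e) NULL)
        if (!is.null(fit)) poses[[i]] <- fit$matrix
      }
      cur <- mean_residual()
      trace <- c(trace, cur)
      if (abs(prev - cur) < tol) break
      prev <- cur
    }
  }
  list(poses = lapply(poses, function(m) transform_linear("affine", m)),
       residual = mean_residual(), residual_trace = trace,
       components = roots)
}

# exact least-squares update of the translation components with the
# linear parts of all poses held fixed
solve_translations <- function(poses, corr, fixed, apply_m) {
  n <- length(poses)
  free <- which(!fixed)
  if (!length(free) || !length(corr)) return(poses)
  col_of <- stats::setNames(rep(NA_integer_, n), NULL)
  col_of[free] <- seq_along(free)
  m <- length(free)
  A <- base::matrix(0, m, m); bx <- numeric(m); by <- numeric(m)
  for (cc in corr) {
    k <- nrow(cc$pa)
    wa <- apply_m(poses[[cc$a]], cc$pa)
    wb <- apply_m(poses[[cc$b]], cc$pb)
    d <- colMeans(wb - wa) # desired t_a - t_b adjustment
    ia <- col_of[cc$a]; ib <- col_of[cc$b]
    if (!is.na(ia)) { A[ia, ia] <- A[ia, ia] + k; bx[ia] <- bx[ia] + k * d[1]; by[ia] <- by[ia] + k * d[2] }
    if (!is.na(ib)) { A[ib, ib] <- A[ib, ib] + k; bx[ib] <- bx[ib] - k * d[1]; by[ib] <- by[ib] - k * d[2] }
    if (!is.na(ia) && !is.na(ib)) { A[ia, ib] <- A[ia, ib] - k; A[ib, ia] <- A[ib, ia] - k }
  }
  keep <- which(diag(A) > 0)
  if (!length(keep)) return(poses)
  sol_x <- numeric(m); sol_y <- numeric(m)
  Ak <- A[keep, keep, drop = FALSE]
  sol_x[keep] <- solve(Ak, bx[keep])
  sol_y[keep] <- solve(Ak, by[keep])
  for (j in seq_along(free)) {
    i <- free[j]
    poses[[i]][1, 3] <- poses[[i]][1, 3] + sol_x[j]
    poses[[i]][2, 3] <- poses[[i]][2, 3] + sol_y[j]
  }
  poses
}

# overlap-driven pairwise matching between patches of one layer
layer_correspondences <- function(patches, params) {
  feats <- lapply(patches, function(p) extract_features(patch_pixels(p),
                                                        params$features %||% list()))
  n <- length(patches)
  bbs <- lapply(patches, patch_world_bbox)
  corr <- list()
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      bi <- bbs[[i]]; bj <- bbs[[j]]
      ow <- min(bi[3], bj[3]) - max(bi[1], bj[1])
      oh <- min(bi[4], bj[4]) - max(bi[2], bj[2])
      if (ow <= 0 || oh <= 0) next
      m <- match_and_filter(feats[[i]], feats[[j]],
                            rod = params$rod %||% 0.92,
                            model_class = params$pair_model %||% "rigid",
                            max_epsilon = params$max_epsilon %||% 3,
                            min_inlier_ratio = params$min_inlier_ratio %||% 0.05,
                            iterations = params$iterations %||% 1000L,
                            seed = (params$seed %||% 1L) + i * 131L + j)
      if (is.null(m$model)) next
      inl <- m$matches[m$matches$inlier, , drop = FALSE]
      corr[[length(corr) + 1L]] <- list(a = i, b = j,
                                        pa = cbind(inl$xa, inl$ya),
                                        pb = cbind(inl$xb, inl$yb))
      pairs[[length(pairs) + 1L]] <- data.frame(a = i, b = j,
                                                inliers = nrow(inl),
                                                inlier_ratio = m$inlier_ratio)
    }
  }
  list(corr = corr, feats = feats,
       pairs = if (length(pairs)) do.call(rbind, pairs) else NULL)
}

#' Montage the tiles of one section
#'
#' Extracts invariant features from every tile, matches overlapping
#' pairs, and relaxes all tile poses against the inlier
#' correspondences (translation -> rigid -> affine schedule, first
#' tile fixed as gauge). Initial poses come from the patches' current
#' transform chains (e.g. nominal stage positions).
#'
#' @param l An `em_layer`.
#' @param params List: `model_class` (default `"rigid"`), `rod`,
#'   `max_epsilon`, `min_inlier_ratio`, `iterations`, `seed`, `tol`,
#'   `max_iterations`, plus `features` sub-list.
#' @return List with `poses` (per-patch `em_transform`), `residual`
#'   (mean point-transfer error, px), `pairs` summary and `layer`
#'   (the layer with updated patch chains).
#' @export
montage_layer <- function(l, params = list()) {
  patches <- l$patches
  n <- length(patches)
  if (n == 0L) stop("layer has no patches")
  init <- lapply(patches, function(p) {
    fl <- flatten_chain(p$chain)
    if (length(fl$transforms)) fl$transforms[[1L]]$matrix else cbind(diag(2), c(0, 0))
  })
  if (n == 1L) {
    return(list(poses = list(transform_linear("affine", init[[1L]])),
                residual = 0, pairs = NULL, layer = l))
  }
  lc <- layer_correspondences(patches, params)
  # matches are in tile-local coordinates already
  sol <- relax_poses(n, lc$corr, init = init,
                     model_class = params$model_class %||% "rigid",
                     gauge = 1L, tol = params$tol %||% 1e-4,
                     max_iterations = params$max_iterations %||% 2000L,
                     on_disconnected = "warn")
  if (isTRUE(params$polish %||% TRUE) && !is.null(lc$pairs)) {
    sol <- montage_polish(patches, sol, lc$pairs, params)
  }
  for (i in seq_len(n)) {
    l$patches[[i]]$chain <- transform_chain(sol$poses[[i]])
  }
  list(poses = sol$poses, residual = sol$residual, pairs = lc$pairs, layer = l)
}

# refine feature-based poses by normalized cross-correlation block
# matching in the rendered overlap of each connected pair, then
# re-relax; removes the correlated sub-pixel localization bias of
# feature detections on resampled/noisy tiles
montage_polish <- function(patches, sol, pairs, params) {
  n <- length(patches)
  corr <- list()
  invs <- vector("list", n)
  for (pi in seq_len(nrow(pairs))) {
    i <- pairs$a[pi]; j <- pairs$b[pi]
    p_i <- patches[[i]]; p_j <- patches[[j]]
    p_i$chain <- transform_chain(sol$poses[[i]])
    p_j$chain <- transform_chain(sol$poses[[j]])
    bi <- patch_world_bbox(p_i); bj <- patch_world_bbox(p_j)
    ov <- c(max(bi[1], bj[1]), max(bi[2], bj[2]),
            min(bi[3], bj[3]), min(bi[4], bj[4]))
    if (ov[3] - ov[1] < 48 || ov[4] - ov[2] < 48) next
    ov <- c(floor(ov[1]), floor(ov[2]), ceiling(ov[3]), ceiling(ov[4]))
    ra <- render_patches(list(p_i), ov, 1, with_alpha = TRUE)
    rb <- render_patches(list(p_j), ov, 1, with_alpha = TRUE)
    short <- min(dim(ra$gray))
    br <- as.integer(min(12, floor((short - 12) / 3)))
    if (br < 5) next
    bm <- tryCatch(block_match(ra$gray, rb$gray,
                               grid_spacing = params$polish_spacing %||% 12L,
                               block_radius = br, search_radius = 4L),
                   error = function(e) NULL)
    if (is.null(bm)) next
    # keep well-correlated samples fully inside both alpha supports
    av <- bilinear_sample(ra$alpha, cbind(bm$x, bm$y))
    bv <- bilinear_sample(rb$alpha, cbind(bm$x, bm$y))
    bm <- bm[bm$r >= 0.6 & !is.na(av) & av > 0.99 & !is.na(bv) & bv > 0.99, ,
             drop = FALSE]
    if (nrow(bm) < 3L) next
    if (is.null(invs[[i]])) invs[[i]] <- invert_transform(sol$poses[[i]])
    if (is.null(invs[[j]])) invs[[j]] <- invert_transform(sol$poses[[j]])
    wa <- cbind(ov[1] + bm$x, ov[2] + bm$y)
    wb <- cbind(ov[1] + bm$x + bm$dx, ov[2] + bm$y + bm$dy)
    corr[[length(corr) + 1L]] <- list(
      a = i, b = j,
      pa = apply_transform(invs[[i]], wa),
      pb = apply_transform(invs[[j]], wb))
  }
  if (!length(corr)) return(sol)
  relax_poses(n, corr, init = lapply(sol$poses, `[[`, "matrix"),
              model_class = params$model_class %||% "rigid",
              gauge = 1L, tol = params$tol %||% 1e-4,
              max_iterations = params$max_iterations %||% 2000L,
              on_disconnected = "warn")
}

#' Linear alignment of a section series
#'
#' Renders every montaged layer at a working scale (longest side
#' `working_px`), extracts features, estimates sequential pairwise
#' models between adjacent sections, propagates them, and globally
#' relaxes all layers as units. Unmatched adjacent pairs keep the
#' identity step with a warning.
#'
#' @param ls An `em_layerset`.
#' @param params List: `model_class` (default `"rigid"`),
#'   `working_px` (default 1024), matching parameters as in
#'   [montage_layer()].
#' @return List with `poses` (per-layer world transforms, full
#'   resolution), `residual` (px at full resolution) and `layerset`
#'   (with the per-layer transform appended to every patch chain).
#' @export
align_series_linear <- function(ls, params = list()) {
  n <- length(ls$layers)
  if (n == 0L) stop("empty layerset")
  if (n == 1L) {
    return(list(poses = list(transform_identity()), residual = 0,
                layerset = ls))
  }
  # common world bbox across layers
  bbs <- lapply(ls$layers, function(l)
    do.call(rbind, lapply(l$patches, patch_world_bbox)))
  allbb <- do.call(rbind, bbs)
  bbox <- c(min(allbb[, 1]), min(allbb[, 2]), max(allbb[, 3]), max(allbb[, 4]))
  scale <- min(1, (params$working_px %||% 1024) / max(bbox[3] - bbox[1],
                                                      bbox[4] - bbox[2]))
  imgs <- lapply(seq_len(n), function(k) render_region(ls, k, bbox, scale))
  feats <- lapply(imgs, function(im) extract_features(im, params$features %||% list()))
  corr <- list()
  for (k in seq_len(n - 1L)) {
    m <- match_and_filter(feats[[k]], feats[[k + 1L]],
                          rod = params$rod %||% 0.92,
                          model_class = params$model_class %||% "rigid",
                          max_epsilon = params$max_epsilon %||% 3,
                          min_inlier_ratio = params$min_inlier_ratio %||% 0.05,
                          iterations = params$iterations %||% 1000L,
                          seed = (params$seed %||% 1L) + k)
    if (is.null(m$model)) {
      warning("layers ", k, " and ", k + 1, " could not be matched; ",
              "keeping identity for this step")
      next
    }
    inl <- m$matches[m$matches$inlier, , drop = FALSE]
    # working-scale render coords -> world px
    corr[[length(corr) + 1L]] <- list(
      a = k + 1L, b = k,
      pa = cbind(inl$xb / scale + bbox[1], inl$yb / scale + bbox[2]),
      pb = cbind(inl$xa / scale + bbox[1], inl$ya / scale + bbox[2]))
  }
  sol <- relax_poses(n, corr, model_class = params$model_class %||% "rigid",
                     gauge = 1L, tol = params$tol %||% 1e-4,
                     max_iterations = params$max_iterations %||% 2000L,
                     on_disconnected = "warn")
  for (k in seq_len(n)) {
    for (i in seq_along(ls$layers[[k]]$patches)) {
      ch <- ls$layers[[k]]$patches[[i]]$chain
      ls$layers[[k]]$patches[[i]]$chain <-
        transform_chain(c(ch$transforms, list(sol$poses[[k]])))
    }
  }
  list(poses = sol$poses, residual = sol$residual, layerset = ls)
}

#' Jointly optimize all tile poses within and across sections
#'
#' One relaxation pool over every tile of every section, driven by
#' correspondences tagged same-section or cross-section. Supports
#' sparse montages whose tiles are disconnected in the section plane
#' but related across sections. A globally disconnected graph is an
#' error naming the components.
#'
#' @param ls An `em_layerset`.
#' @param corrs List of entries `list(layer_a, patch_a, layer_b,
#'   patch_b, pa, pb)` with matched points in tile-local coordinates.
#' @param params As in [relax_poses()].
#' @return List with `poses` (nested per layer, per patch), `residual`
#'   and `layerset` (patch chains replaced by the optimized poses).
#' @export
optimize_global_pose <- function(ls, corrs, params = list()) {
  n_layers <- length(ls$layers)
  key <- function(k, i) paste0(k, ":", i)
  ids <- character(0)
  for (k in seq_len(n_layers)) {
    for (i in seq_along(ls$layers[[k]]$patches)) ids <- c(ids, key(k, i))
  }
  idx <- stats::setNames(seq_along(ids), ids)
  init <- vector("list", length(ids))
  for (k in seq_len(n_layers)) {
    for (i in seq_along(ls$layers[[k]]$patches)) {
      fl <- flatten_chain(ls$layers[[k]]$patches[[i]]$chain)
      init[[idx[[key(k, i)]]]] <- if (length(fl$transforms))
        fl$transforms[[1L]]$matrix else cbind(diag(2), c(0, 0))
    }
  }
  corr <- lapply(corrs, function(cc) list(
    a = idx[[key(cc$layer_a, cc$patch_a)]],
    b = idx[[key(cc$layer_b, cc$patch_b)]],
    pa = as_points(cc$pa), pb = as_points(cc$pb)))
  sol <- relax_poses(length(ids), corr, init = init,
                     model_class = params$model_class %||% "rigid",
                     gauge = 1L, tol = params$tol %||% 1e-4,
                     max_iterations = params$max_iterations %||% 2000L,
                     on_disconnected = "error")
  poses <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    poses[[k]] <- vector("list", length(ls$layers[[k]]$patches))
    for (i in seq_along(ls$layers[[k]]$patches)) {
      tr <- sol$poses[[idx[[key(k, i)]]]]
      poses[[k]][[i]] <- tr
      ls$layers[[k]]$patches[[i]]$chain <- transform_chain(tr)
    }
  }
  list(poses = poses, residual = sol$residual, layerset = ls)
}
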