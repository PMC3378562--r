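# Descriptor matching with the ratio-of-distances test and robust
# model consensus by random sampling.

#' Match two feature sets and fit a robust model
#'
#' Candidate matches by nearest-neighbour descriptor distance with the
#' ratio-of-distances test, followed by random-sampling consensus of
#' the requested linear model class. Returns the inlier
#' correspondences and the refitted model, or an empty result (not an
#' error) when no consistent model reaches the minimum inlier ratio —
#' the "no overlap" signal.
#'
#' @param feats_a,feats_b Feature sets from [extract_features()].
#' @param rod Ratio-of-distances threshold (nearest / second-nearest).
#' @param model_class `"translation"`, `"rigid"`, `"similarity"` or
#'   `"affine"`.
#' @param max_epsilon Inlier residual threshold (px).
#' @param min_inlier_ratio Minimum fraction of candidates that must be
#'   inliers.
#' @param iterations Random-sampling iterations.
#' @param seed Integer seed (reproducible consensus).
#' @return An `em_matches`: list with `matches` (data.frame `xa`,
#'   `ya`, `xb`, `yb`, `inlier`), `model` (an `em_transform` or
#'   `NULL`) and `inlier_ratio`.
#' @export
match_and_filter <- function(feats_a, feats_b, rod = 0.92,
                             model_class = "rigid", max_epsilon = 3,
                             min_inlier_ratio = 0.05, iterations = 1000L,
                             seed = 1L) {
  empty <- structure(list(matches = data.frame(xa = numeric(0), ya = numeric(0),
                                               xb = numeric(0), yb = numeric(0),
                                               inlier = logical(0)),
                          model = NULL, inlier_ratio = 0),
                     class = "em_matches")
  if (!nrow(feats_a) || !nrow(feats_b)) return(empty)
  da <- attr(feats_a, "descriptor"); db <- attr(feats_b, "descriptor")
  # squared euclidean distances between unit descriptors
  cross <- da %*% t(db)
  d2 <- 2 - 2 * cross
  d2[d2 < 0] <- 0
  nn <- apply(d2, 1L, function(v) {
    o <- order(v)[1:2]
    c(o[1], v[o[1]], v[o[2]])
  })
  keep <- which(sqrt(nn[2, ]) < rod * sqrt(pmax(nn[3, ], 1e-12)))
  if (length(keep) < 1L) return(empty)
  cand <- data.frame(xa = feats_a$x[keep], ya = feats_a$y[keep],
                     xb = feats_b$x[nn[1, keep]], yb = feats_b$y[nn[1, keep]])
  res <- ransac_fit(cand, model_class, max_epsilon, min_inlier_ratio,
                    iterations, seed)
  if (is.null(res)) {
    empty$matches <- cbind(cand, inlier = FALSE)
    return(empty)
  }
  structure(list(matches = cbind(cand, inlier = res$inlier),
                 model = res$model,
                 inlier_ratio = mean(res$inlier)),
            class = "em_matches")
}

min_model_points <- function(model_class) {
  switch(model_class, translation = 1L, rigid = 2L, similarity = 2L,
         affine = 3L, stop("unknown model class ", model_class))
}

# random-sampling consensus over candidate correspondences
ransac_fit <- function(cand, model_class, max_epsilon, min_inlier_ratio,
                       iterations, seed) {
  n <- nrow(cand)
  k <- min_model_points(model_class)
  if (n < k) return(NULL)
  src <- cbind(cand$xa, cand$ya); dst <- cbind(cand$xb, cand$yb)
  set.seed(seed)
  best <- NULL; best_n <- 0L
  samples <- base::matrix(0L, iterations, k)
  for (i in seq_len(iterations)) samples[i, ] <- sample.int(n, k)
  for (i in seq_len(iterations)) {
    s <- samples[i, ]
    model <- tryCatch(
      affine_from_landmarks(src[s, , drop = FALSE], dst[s, , drop = FALSE],
                            model_class),
      error = function(e) NULL)
    if (is.null(model)) next
    pred <- apply_transform(model, src)
    resid <- sqrt(rowSums((pred - dst)^2))
    inl <- resid <= max_epsilon
    if (sum(inl) > best_n) { best_n <- sum(inl); best <- inl }
  }
  if (is.null(best) || best_n < max(k, ceiling(min_inlier_ratio * n)) ||
      best_n < 1L) {
    return(NULL)
  }
  # iterative least-squares refinement on the consensus set
  inl <- best
  for (it in 1:3) {
    model <- tryCatch(
      affine_from_landmarks(src[inl, , drop = FALSE], dst[inl, , drop = FALSE],
                            model_class),
      error = function(e) NULL)
    if (is.null(model)) return(NULL)
    resid <- sqrt(rowSums((apply_transform(model, src) - dst)^2))
    new_inl <- resid <= max_epsilon
    if (identical(new_inl, inl)) break
    if (sum(new_inl) < max(min_model_points(model_class), 1L)) break
    inl <- new_inl
  }
  if (mean(inl) < min_inlier_ratio) return(NULL)
  list(model = model, inlier = inl)
}

#' Export correspondences as CSV
#'
#' @param matches An `em_matches` (or list of them with names
#'   "`a`:`b`").
#' @param path Output CSV path.
#' @param tile_a,tile_b Tile ids recorded in the rows.
#' @return The path, invisibly.
#' @export
export_correspondences <- function(matches, path, tile_a = "a", tile_b = "b") {
  m <- matches$matches
  utils::write.csv(data.frame(tile_a = tile_a, tile_b = tile_b,
                              xa = m$xa, ya = m$ya, xb = m$xb, yb = m$yb,
                              inlier = m$inlier),
                   path, row.names = FALSE)
  invisible(path)
}
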