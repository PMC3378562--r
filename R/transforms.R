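# 2D coordinate transforms: linear families, moving least squares, and
# piecewise-affine triangle meshes.  All transforms map local pixel
# coordinates (0-based, x right, y down) to world coordinates.

LINEAR_KINDS <- c("translation", "rigid", "similarity", "affine")

#' Create a linear 2D transform
#'
#' Linear transforms are stored as a 2x3 matrix `M` acting on column
#' vectors: `world = M %*% c(x, y, 1)`.
#'
#' @param kind One of `"translation"`, `"rigid"`, `"similarity"`, `"affine"`.
#' @param matrix A 2x3 numeric matrix. The 2x2 linear part must be
#'   invertible.
#' @return An object of class `em_transform`.
#' @export
transform_linear <- function(kind, matrix) {
  kind <- match.arg(kind, LINEAR_KINDS)
  m <- base::matrix(as.numeric(matrix), 2L, 3L)
  d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (!is.finite(d) || abs(d) < 1e-12) {
    stop("invalid-transform: degenerate linear transform (det = ", d, ")")
  }
  structure(list(kind = kind, matrix = m), class = "em_transform")
}

#' @rdname transform_linear
#' @param tx,ty Translation components (world px).
#' @export
transform_translation <- function(tx, ty) {
  transform_linear("translation", cbind(diag(2), c(tx, ty)))
}

#' @rdname transform_linear
#' @param theta Rotation angle in radians (counter-clockwise in image
#'   coordinates).
#' @export
transform_rigid <- function(theta, tx, ty) {
  r <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  transform_linear("rigid", cbind(r, c(tx, ty)))
}

#' @rdname transform_linear
#' @param s Isotropic scale factor.
#' @export
transform_similarity <- function(s, theta, tx, ty) {
  r <- s * rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  transform_linear("similarity", cbind(r, c(tx, ty)))
}

#' @rdname transform_linear
#' @export
transform_affine <- function(matrix) transform_linear("affine", matrix)

#' @rdname transform_linear
#' @export
transform_identity <- function() transform_translation(0, 0)

#' Moving-least-squares transform from landmark pairs
#'
#' Smooth deformation that interpolates every landmark pair exactly and
#' decays towards the global least-squares model of the requested class
#' away from the landmarks (the standard image-deformation MLS scheme
#' with weights `1 / d^(2 * alpha)`).
#'
#' @param src,dst n x 2 matrices of corresponding source and target
#'   points.
#' @param model Model class applied locally: `"translation"`,
#'   `"rigid"`, `"similarity"` or `"affine"`.
#' @param alpha Weight fall-off exponent (> 0).
#' @return An `em_transform` of kind `"mls"`.
#' @export
transform_mls <- function(src, dst, model = c("affine", "similarity", "rigid", "translation"),
                          alpha = 1) {
  model <- match.arg(model)
  src <- as_points(src); dst <- as_points(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 1, alpha > 0)
  key <- paste(signif(src[, 1], 12), signif(src[, 2], 12))
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    grp <- split(seq_len(nrow(src))[dup], key[dup])
    for (g in grp) {
      if (nrow(unique(dst[g, , drop = FALSE])) > 1L) {
        stop("inconsistent-landmarks: duplicate source points with different targets")
      }
    }
    keep <- !duplicated(key)
    src <- src[keep, , drop = FALSE]; dst <- dst[keep, , drop = FALSE]
  }
  structure(list(kind = "mls", src = src, dst = dst,
                 model = model, alpha = alpha),
            class = "em_transform")
}

#' Piecewise-affine mesh transform
#'
#' A triangulated grid whose vertices move from `rest` to `moved`
#' positions; points are mapped by the affine transform of the triangle
#' containing them (nearest triangle outside the mesh).
#'
#' @param rest,moved n x 2 matrices of vertex positions.
#' @param triangles m x 3 integer matrix of vertex indices (1-based).
#' @return An `em_transform` of kind `"mesh"`.
#' @export
transform_mesh <- function(rest, moved, triangles) {
  rest <- as_points(rest); moved <- as_points(moved)
  triangles <- base::matrix(as.integer(triangles), ncol = 3L)
  stopifnot(nrow(rest) == nrow(moved), max(triangles) <= nrow(rest),
            min(triangles) >= 1L)
  a <- rest[triangles[, 1], , drop = FALSE]
  b <- rest[triangles[, 2], , drop = FALSE]
  c_ <- rest[triangles[, 3], , drop = FALSE]
  area2 <- (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
           (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1])
  if (any(abs(area2) < 1e-12)) stop("invalid-transform: degenerate mesh triangle")
  structure(list(kind = "mesh", rest = rest, moved = moved,
                 triangles = triangles),
            class = "em_transform")
}

as_points <- function(p) {
  if (is.null(dim(p))) p <- base::matrix(p, ncol = 2L, byrow = TRUE)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  stopifnot(ncol(p) == 2L)
  unname(p)
}

is_linear <- function(tr) tr$kind %in% LINEAR_KINDS

#' Apply a transform to points
#'
#' @param tr An `em_transform`, `em_chain`, or flattened mapping.
#' @param pts n x 2 matrix (or length-2 vector) of points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_transform <- function(tr, pts) {
  pts <- as_points(pts)
  if (inherits(tr, "em_chain")) return(apply_chain(tr, pts))
  stopifnot(inherits(tr, "em_transform"))
  if (is_linear(tr)) {
    m <- tr$matrix
    return(cbind(pts[, 1] * m[1, 1] + pts[, 2] * m[1, 2] + m[1, 3],
                 pts[, 1] * m[2, 1] + pts[, 2] * m[2, 2] + m[2, 3]))
  }
  switch(tr$kind,
    mls = mls_apply(tr, pts),
    mesh = mesh_apply(tr, pts),
    stop("unknown transform kind: ", tr$kind)
  )
}

# Moving least squares (affine / similarity / rigid / translation),
# evaluated at each query point with weights w_i = 1 / |p_i - v|^(2a).
mls_apply <- function(tr, pts) {
  p <- tr$src; q <- tr$dst
  n <- nrow(p)
  out <- base::matrix(0, nrow(pts), 2L)
  if (n == 1L) {
    # single control point: pure translation whatever the class
    return(cbind(pts[, 1] + (q[1, 1] - p[1, 1]),
                 pts[, 2] + (q[1, 2] - p[1, 2])))
  }
  for (i in seq_len(nrow(pts))) {
    v <- pts[i, ]
    d2 <- (p[, 1] - v[1])^2 + (p[, 2] - v[2])^2
    hit <- which(d2 < 1e-18)
    if (length(hit)) { out[i, ] <- q[hit[1L], ]; next }
    w <- 1 / d2^tr$alpha
    sw <- sum(w)
    ps <- c(sum(w * p[, 1]), sum(w * p[, 2])) / sw
    qs <- c(sum(w * q[, 1]), sum(w * q[, 2])) / sw
    ph <- cbind(p[, 1] - ps[1], p[, 2] - ps[2])
    qh <- cbind(q[, 1] - qs[1], q[, 2] - qs[2])
    vh <- v - ps
    if (tr$model == "translation") {
      out[i, ] <- v - ps + qs
    } else if (tr$model == "affine") {
      a11 <- sum(w * ph[, 1]^2); a12 <- sum(w * ph[, 1] * ph[, 2])
      a22 <- sum(w * ph[, 2]^2)
      b11 <- sum(w * ph[, 1] * qh[, 1]); b12 <- sum(w * ph[, 1] * qh[, 2])
      b21 <- sum(w * ph[, 2] * qh[, 1]); b22 <- sum(w * ph[, 2] * qh[, 2])
      det <- a11 * a22 - a12 * a12
      if (abs(det) < 1e-12) { out[i, ] <- v - ps + qs; next }
      # M = A^-1 B, f(v) = vh M + qs
      i11 <- a22 / det; i12 <- -a12 / det; i22 <- a11 / det
      m11 <- i11 * b11 + i12 * b21; m12 <- i11 * b12 + i12 * b22
      m21 <- i12 * b11 + i22 * b21; m22 <- i12 * b12 + i22 * b22
      out[i, ] <- c(vh[1] * m11 + vh[2] * m21, vh[1] * m12 + vh[2] * m22) + qs
    } else { # similarity or rigid
      # f(v) = sum_i qh_i (1/mu) w_i (ph_i; -ph_i^perp) (vh; -vh^perp)^T
      mu <- sum(w * (ph[, 1]^2 + ph[, 2]^2))
      # complex formulation: z = sum w * conj(ph) * qh / mu acting on vh
      zr <- sum(w * (ph[, 1] * qh[, 1] + ph[, 2] * qh[, 2])) / mu
      zi <- sum(w * (ph[, 1] * qh[, 2] - ph[, 2] * qh[, 1])) / mu
      if (tr$model == "rigid") {
        nz <- sqrt(zr^2 + zi^2)
        if (nz > 1e-15) { zr <- zr / nz; zi <- zi / nz }
      }
      out[i, ] <- c(vh[1] * zr - vh[2] * zi, vh[1] * zi + vh[2] * zr) + qs
    }
  }
  out
}

# barycentric point location + per-triangle affine; outside points use
# the triangle whose centroid is nearest
mesh_apply <- function(tr, pts) {
  tri <- tr$triangles
  a <- tr$rest[tri[, 1], , drop = FALSE]
  b <- tr$rest[tri[, 2], , drop = FALSE]
  c_ <- tr$rest[tri[, 3], , drop = FALSE]
  det <- (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
         (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1])
  cen <- (a + b + c_) / 3
  out <- base::matrix(0, nrow(pts), 2L)
  for (i in seq_len(nrow(pts))) {
    v <- pts[i, ]
    vx <- v[1] - a[, 1]; vy <- v[2] - a[, 2]
    l2 <- ((c_[, 2] - a[, 2]) * vx - (c_[, 1] - a[, 1]) * vy) / det
    l3 <- (-(b[, 2] - a[, 2]) * vx + (b[, 1] - a[, 1]) * vy) / det
    l1 <- 1 - l2 - l3
    inside <- which(l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9)
    k <- if (length(inside)) {
      inside[1L]
    } else {
      which.min((cen[, 1] - v[1])^2 + (cen[, 2] - v[2])^2)
    }
    out[i, ] <- l1[k] * tr$moved[tri[k, 1], ] +
                l2[k] * tr$moved[tri[k, 2], ] +
                l3[k] * tr$moved[tri[k, 3], ]
  }
  out
}

#' Invert a transform
#'
#' Linear transforms invert exactly; mesh transforms swap rest and
#' moved vertices (piecewise-affine inverse). MLS transforms are
#' inverted approximately through a mesh discretisation over the given
#' bounding box.
#'
#' @param tr An `em_transform`.
#' @param bbox For MLS: numeric `c(x0, y0, x1, y1)` region to
#'   discretise.
#' @param spacing Mesh spacing for the MLS approximation (px).
#' @return An `em_transform`.
#' @export
invert_transform <- function(tr, bbox = NULL, spacing = 16) {
  stopifnot(inherits(tr, "em_transform"))
  if (is_linear(tr)) {
    m <- tr$matrix
    a <- m[, 1:2]
    ai <- solve(a)
    t <- -ai %*% m[, 3]
    return(transform_linear(tr$kind, cbind(ai, t)))
  }
  if (tr$kind == "mesh") {
    return(transform_mesh(tr$moved, tr$rest, tr$triangles))
  }
  if (tr$kind == "mls") {
    stopifnot(!is.null(bbox))
    mesh <- mesh_from_mapping(function(p) mls_apply(tr, p), bbox, spacing)
    return(transform_mesh(mesh$moved, mesh$rest, mesh$triangles))
  }
  stop("cannot invert transform of kind ", tr$kind)
}

# Discretise an arbitrary point mapping into a triangulated grid mesh
mesh_from_mapping <- function(fun, bbox, spacing) {
  xs <- seq(bbox[1], bbox[3], length.out = max(2L, ceiling((bbox[3] - bbox[1]) / spacing) + 1L))
  ys <- seq(bbox[2], bbox[4], length.out = max(2L, ceiling((bbox[4] - bbox[2]) / spacing) + 1L))
  g <- expand.grid(x = xs, y = ys)
  rest <- cbind(g$x, g$y)
  moved <- fun(rest)
  nx <- length(xs); ny <- length(ys)
  tri <- grid_triangles(nx, ny)
  list(rest = rest, moved = moved, triangles = tri)
}

grid_triangles <- function(nx, ny) {
  idx <- function(ix, iy) (iy - 1L) * nx + ix
  tris <- vector("list", (nx - 1L) * (ny - 1L))
  k <- 0L
  for (iy in seq_len(ny - 1L)) {
    for (ix in seq_len(nx - 1L)) {
      k <- k + 1L
      v00 <- idx(ix, iy); v10 <- idx(ix + 1L, iy)
      v01 <- idx(ix, iy + 1L); v11 <- idx(ix + 1L, iy + 1L)
      tris[[k]] <- rbind(c(v00, v10, v11), c(v00, v11, v01))
    }
  }
  do.call(rbind, tris)
}

#' Transform chains
#'
#' An ordered list of transforms applied first-to-last, mapping local
#' pixel coordinates to world coordinates. The empty chain is the
#' identity.
#'
#' @param ... `em_transform` objects (or a single list of them).
#' @return An object of class `em_chain`.
#' @export
transform_chain <- function(...) {
  elts <- list(...)
  if (length(elts) == 1L && !inherits(elts[[1L]], "em_transform") && is.list(elts[[1L]])) {
    elts <- elts[[1L]]
  }
  for (e in elts) stopifnot(inherits(e, "em_transform"))
  structure(list(transforms = elts), class = "em_chain")
}

#' @rdname transform_chain
#' @param chain An `em_chain`.
#' @param pts n x 2 point matrix.
#' @export
apply_chain <- function(chain, pts) {
  pts <- as_points(pts)
  for (tr in chain$transforms) pts <- apply_transform(tr, pts)
  pts
}

#' Flatten a transform chain into a single mapping
#'
#' Collapses runs of adjacent linear transforms into one matrix so that
#' an arbitrarily long chain evaluates in a single pass; the flattened
#' mapping equals sequential application of the chain.
#'
#' @param chain An `em_chain`.
#' @return An `em_chain` with maximally collapsed elements (still
#'   usable with [apply_transform()] / [apply_chain()]).
#' @export
flatten_chain <- function(chain) {
  stopifnot(inherits(chain, "em_chain"))
  out <- list()
  pend <- NULL # pending accumulated 2x3 linear matrix
  push_linear <- function(m) {
    if (is.null(pend)) return(m)
    # compose: world = m2 (m1 p) -> matrix m2[,1:2] %*% m1 plus t
    a <- m[, 1:2] %*% pend[, 1:2]
    t <- m[, 1:2] %*% pend[, 3] + m[, 3]
    cbind(a, t)
  }
  for (tr in chain$transforms) {
    if (is_linear(tr)) {
      pend <- push_linear(tr$matrix)
    } else {
      if (!is.null(pend)) {
        out[[length(out) + 1L]] <- transform_linear("affine", pend)
        pend <- NULL
      }
      out[[length(out) + 1L]] <- tr
    }
  }
  if (!is.null(pend)) out[[length(out) + 1L]] <- transform_linear("affine", pend)
  structure(list(transforms = out, flattened = TRUE), class = "em_chain")
}

#' Fit a linear transform to landmark pairs
#'
#' Least-squares estimate of the requested model class mapping `src`
#' onto `dst`. With exactly the minimal number of pairs the residuals
#' are zero.
#'
#' @param src,dst n x 2 matrices of corresponding points.
#' @param model `"translation"` (n >= 1), `"rigid"` / `"similarity"`
#'   (n >= 2) or `"affine"` (n >= 3 non-collinear).
#' @return An `em_transform` of the requested kind.
#' @export
affine_from_landmarks <- function(src, dst,
                                  model = c("affine", "translation", "rigid", "similarity")) {
  model <- match.arg(model)
  src <- as_points(src); dst <- as_points(dst)
  stopifnot(nrow(src) == nrow(dst))
  n <- nrow(src)
  if (model == "translation") {
    stopifnot(n >= 1)
    t <- colMeans(dst) - colMeans(src)
    return(transform_translation(t[1], t[2]))
  }
  if (model %in% c("rigid", "similarity")) {
    stopifnot(n >= 2)
    pc <- colMeans(src); qc <- colMeans(dst)
    ph <- sweep(src, 2, pc); qh <- sweep(dst, 2, qc)
    # complex least squares dst ~ a * src + b
    zr <- sum(ph[, 1] * qh[, 1] + ph[, 2] * qh[, 2])
    zi <- sum(ph[, 1] * qh[, 2] - ph[, 2] * qh[, 1])
    den <- sum(ph^2)
    if (den < 1e-12) stop("degenerate-landmarks: coincident source points")
    ar <- zr / den; ai <- zi / den
    if (model == "rigid") {
      nz <- sqrt(ar^2 + ai^2)
      if (nz < 1e-15) stop("degenerate-landmarks: no rotation defined")
      ar <- ar / nz; ai <- ai / nz
    }
    rot <- rbind(c(ar, -ai), c(ai, ar))
    t <- qc - rot %*% pc
    return(transform_linear(model, cbind(rot, t)))
  }
  # affine
  stopifnot(n >= 3)
  x <- cbind(src, 1)
  xtx <- crossprod(x)
  if (abs(det(xtx)) < 1e-9 * max(abs(xtx))^3 || qr(x)$rank < 3L) {
    stop("degenerate-landmarks: collinear landmark triple for affine fit")
  }
  beta <- solve(xtx, crossprod(x, dst)) # 3x2
  transform_linear("affine", t(beta))
}

#' @rdname transform_mls
#' @details `mls_from_landmarks()` is an alias of `transform_mls()`
#'   matching the operation naming used elsewhere in the package.
#' @export
mls_from_landmarks <- transform_mls

#' @export
print.em_transform <- function(x, ...) {
  cat("<em_transform:", x$kind, ">\n")
  if (is_linear(x)) print(x$matrix)
  else if (x$kind == "mls") cat(" ", nrow(x$src), "control points, model", x$model, "\n")
  else cat(" ", nrow(x$rest), "vertices,", nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' @export
print.em_chain <- function(x, ...) {
  cat("<em_chain of", length(x$transforms), "transforms>\n")
  invisible(x)
}
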