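# Connectors, partner tables, confidence-filtered circuit graphs and
# exchange formats (SWC, NeuroML, adjacency CSV).

#' Connector link endpoints
#'
#' An endpoint either references a skeleton node (`tree` + `node`) or
#' is a free world point (no neuron identity yet); each carries a
#' confidence 0-5.
#'
#' @param tree Tree id (or `NA` for a free point).
#' @param node Node id within the tree.
#' @param point Numeric `c(x, y)` for free endpoints.
#' @param confidence Integer 0-5.
#' @return A link-end list.
#' @export
link_end <- function(tree = NA_character_, node = NA_integer_, point = NULL,
                     confidence = 5L) {
  if (confidence < 0 || confidence > 5) stop("range error: confidence in [0, 5]")
  list(tree = as.character(tree), node = as.integer(node), point = point,
       confidence = as.integer(confidence))
}

link_is_free <- function(e) is.na(e$tree) || is.null(e$node) || is.na(e$node)

#' Create a synapse connector
#'
#' One origin and any number of targets (monadic to polyadic
#' synapses); connectors without targets are allowed and flagged
#' incomplete in partner tables.
#'
#' @param id Connector id.
#' @param origin An [link_end()].
#' @param targets List of [link_end()]s.
#' @param layer Layer index the connector sits in.
#' @return An `em_connector`.
#' @export
connector <- function(id, origin, targets = list(), layer = 1L) {
  structure(list(id = id, origin = origin, targets = targets,
                 layer = as.integer(layer)),
            class = "em_connector")
}

# check every linked endpoint references an existing node
validate_connectors <- function(proj) {
  for (cn in proj$connectors) {
    ends <- c(list(cn$origin), cn$targets)
    for (e in ends) {
      if (link_is_free(e)) next
      tr <- proj$arbors[[e$tree]]
      if (is.null(tr)) stop("connector ", cn$id, ": unknown tree ", e$tree)
      if (!(e$node %in% tr$nodes$id)) {
        stop("connector ", cn$id, ": node ", e$node, " not in tree ", e$tree)
      }
    }
  }
  invisible(proj)
}

#' Incoming and outgoing partners of a skeleton
#'
#' One row per connector link touching the tree, split into outgoing
#' (tree at a connector origin) and incoming (tree at a target); rows
#' with a free-point opposite end are flagged incomplete. Recomputed
#' from current project state on every call.
#'
#' @param proj An `em_project`.
#' @param tree_id Skeleton id.
#' @return List with data.frames `outgoing` and `incoming` (columns
#'   `connector`, `partner_tree`, `partner_node`, `own_node`,
#'   `confidence`, `incomplete`).
#' @export
partner_table <- function(proj, tree_id) {
  if (!(tree_id %in% names(proj$arbors))) {
    stop("not-found: tree ", tree_id, " not in project")
  }
  out_rows <- list(); in_rows <- list()
  for (cn in proj$connectors) {
    o <- cn$origin
    if (!link_is_free(o) && o$tree == tree_id) {
      if (!length(cn$targets)) {
        out_rows[[length(out_rows) + 1L]] <- data.frame(
          connector = cn$id, partner_tree = NA_character_,
          partner_node = NA_integer_, own_node = o$node,
          confidence = NA_integer_, incomplete = TRUE)
      }
      for (t in cn$targets) {
        out_rows[[length(out_rows) + 1L]] <- data.frame(
          connector = cn$id,
          partner_tree = if (link_is_free(t)) NA_character_ else t$tree,
          partner_node = if (link_is_free(t)) NA_integer_ else t$node,
          own_node = o$node, confidence = t$confidence,
          incomplete = link_is_free(t))
      }
    }
    for (t in cn$targets) {
      if (!link_is_free(t) && t$tree == tree_id) {
        in_rows[[length(in_rows) + 1L]] <- data.frame(
          connector = cn$id,
          partner_tree = if (link_is_free(o)) NA_character_ else o$tree,
          partner_node = if (link_is_free(o)) NA_integer_ else o$node,
          own_node = t$node, confidence = t$confidence,
          incomplete = link_is_free(o))
      }
    }
  }
  empty <- data.frame(connector = character(0), partner_tree = character(0),
                      partner_node = integer(0), own_node = integer(0),
                      confidence = integer(0), incomplete = logical(0))
  list(outgoing = if (length(out_rows)) do.call(rbind, out_rows) else empty,
       incoming = if (length(in_rows)) do.call(rbind, in_rows) else empty)
}

# connected components of a tree after dropping low-confidence edges;
# returns a named vector node id -> component label. The component
# holding the smallest node id keeps the bare tree id.
tree_components <- function(tree, min_edge_confidence) {
  nd <- tree$nodes
  comp <- seq_len(nrow(nd))
  idx <- match(nd$parent, nd$id)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (k in seq_len(nrow(nd))) {
    if (is.na(idx[k])) next
    if (nd$confidence[k] >= min_edge_confidence) {
      a <- find(k); b <- find(idx[k])
      if (a != b) comp[a] <- b
    }
  }
  roots <- vapply(seq_len(nrow(nd)), find, 0L)
  uroots <- unique(roots)
  # deterministic labels ordered by smallest member node id
  min_id <- vapply(uroots, function(r) min(nd$id[roots == r]), 0L)
  ord <- order(min_id)
  labels <- character(length(uroots))
  for (j in seq_along(ord)) {
    labels[ord[j]] <- if (j == 1L) as.character(tree$id)
                      else paste0(tree$id, "#", j)
  }
  stats::setNames(labels[match(roots, uroots)], nd$id)
}

#' Build a confidence-filtered circuit graph
#'
#' Connector links with confidence below `min_link_confidence` are
#' dropped (the origin confidence gates all of a connector's links;
#' each target link is additionally gated by its own confidence).
#' Skeleton edges below `min_edge_confidence` sever arbors into
#' components and links re-attach to the component containing their
#' linked node — restricting the circuit to the most trustable subsets
#' of the skeletons. Edge weights count surviving origin-to-target
#' links; free-point endpoints carry no neuron identity and are
#' excluded.
#'
#' @param proj An `em_project`.
#' @param min_link_confidence Minimum link confidence (0-5).
#' @param min_edge_confidence Minimum skeleton edge confidence (0-5).
#' @return An `em_circuit`: list with `vertices`, `edges`
#'   (data.frame `pre`, `post`, `weight`) and `contributors` (named
#'   list of connector-id vectors).
#' @export
build_circuit <- function(proj, min_link_confidence = 0L, min_edge_confidence = 0L) {
  comp_of <- lapply(proj$arbors, tree_components, min_edge_confidence)
  resolve <- function(e) {
    if (link_is_free(e)) return(NA_character_)
    comp_of[[e$tree]][[as.character(e$node)]]
  }
  edges <- list()
  for (cn in proj$connectors) {
    o <- cn$origin
    if (link_is_free(o)) next
    if (o$confidence < min_link_confidence) next
    pre <- resolve(o)
    for (t in cn$targets) {
      if (link_is_free(t)) next
      if (t$confidence < min_link_confidence) next
      post <- resolve(t)
      key <- paste0(pre, "\r", post)
      if (is.null(edges[[key]])) edges[[key]] <- list(pre = pre, post = post,
                                                      ids = c())
      edges[[key]]$ids <- c(edges[[key]]$ids, cn$id)
    }
  }
  verts <- sort(unique(unlist(lapply(comp_of, unname), use.names = FALSE)))
  ed <- if (length(edges)) {
    data.frame(pre = vapply(edges, function(e) e$pre, ""),
               post = vapply(edges, function(e) e$post, ""),
               weight = vapply(edges, function(e) length(e$ids), 0L))
  } else data.frame(pre = character(0), post = character(0), weight = integer(0))
  rownames(ed) <- NULL
  contrib <- lapply(edges, function(e) e$ids)
  names(contrib) <- if (nrow(ed)) paste0(ed$pre, "->", ed$post) else character(0)
  structure(list(vertices = verts, edges = ed, contributors = contrib,
                 min_link_confidence = min_link_confidence,
                 min_edge_confidence = min_edge_confidence),
            class = "em_circuit")
}

#' Export a circuit graph as an adjacency matrix CSV
#'
#' Square matrix, rows = presynaptic, columns = postsynaptic, cell =
#' link count; header row and column carry the vertex ids in
#' deterministic (sorted) order.
#'
#' @param graph An `em_circuit`.
#' @param path Output CSV path.
#' @return The adjacency matrix, invisibly.
#' @export
export_adjacency <- function(graph, path) {
  ids <- graph$vertices
  m <- base::matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    m[e$pre, e$post] <- e$weight
  }
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(m)
}

#' Export / import skeletons as SWC
#'
#' One data line per node: `id type x y z radius parent` with 1-based
#' sequential ids, coordinates and radii in calibrated units, root
#' parent -1 and root type 1 (soma, the root sits at the soma by
#' convention; other nodes type 0). Edge confidences, tags, original
#' node ids and layer indices are stored in a `#` comment annex and
#' restored on import, making `import_swc(export_swc(t))` lossless.
#'
#' @param tree An `em_tree` (treeline; areatrees export a centroid
#'   radius approximation, with a message).
#' @param ls An `em_layerset` (calibration and layer z-centres).
#' @param path Output path.
#' @return `export_swc()`: the path, invisibly.
#' @export
export_swc <- function(tree, ls, path) {
  if (tree$subtype == "areatree") {
    message("areatree ", tree$id, ": exporting centroid radius approximation")
  }
  nd <- tree$nodes
  # order root-first so every parent precedes its children
  pidx <- match(nd$parent, nd$id)
  depth <- ifelse(is.na(nd$parent), 0L, NA_integer_)
  while (anyNA(depth)) {
    ready <- is.na(depth) & !is.na(depth[pidx])
    if (!any(ready)) stop("tree invariant: disconnected")
    depth[ready] <- depth[pidx[ready]] + 1L
  }
  ord <- order(depth)
  nd <- nd[ord, ]
  swc_id <- stats::setNames(seq_len(nrow(nd)), nd$id)
  xyz <- node_xyz(tree, ls)[ord, , drop = FALSE]
  radius <- ifelse(is.na(nd$radius), 1, nd$radius) * ls$calibration$x
  lines <- c(
    "# SWC export",
    sprintf("# @tree id=%s subtype=%s", tree$id, tree$subtype),
    sprintf("# @calibration x=%.17g y=%.17g unit=%s",
            ls$calibration$x, ls$calibration$y, ls$calibration$unit),
    vapply(seq_len(nrow(nd)), function(i) {
      tg <- node_tags(tree, nd$id[i])
      sprintf("# @node %d orig=%d layer=%d conf=%s tags=%s", i, nd$id[i],
              nd$layer[i],
              if (is.na(nd$confidence[i])) "NA" else nd$confidence[i],
              paste(utils::URLencode(tg, reserved = TRUE), collapse = "|"))
    }, ""),
    vapply(seq_len(nrow(nd)), function(i) {
      par <- if (is.na(nd$parent[i])) -1L else swc_id[[as.character(nd$parent[i])]]
      typ <- if (is.na(nd$parent[i])) 1L else 0L
      sprintf("%d %d %.17g %.17g %.17g %.17g %d", i, typ,
              xyz[i, 1], xyz[i, 2], xyz[i, 3], radius[i], par)
    }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_swc
#' @return `import_swc()`: an `em_tree` (plus attribute `layerset`
#'   when calibration metadata is present).
#' @export
import_swc <- function(path) {
  lines <- readLines(path)
  ann <- list(); meta <- list(id = "swc", subtype = "treeline")
  calib <- list(x = 1, y = 1, unit = "px")
  data <- list()
  for (ln in seq_along(lines)) {
    l <- trimws(lines[ln])
    if (!nzchar(l)) next
    if (startsWith(l, "#")) {
      if (grepl("^# @tree ", l)) {
        meta$id <- sub(".*id=(\\S+).*", "\\1", l)
        meta$subtype <- sub(".*subtype=(\\S+).*", "\\1", l)
      } else if (grepl("^# @calibration ", l)) {
        calib$x <- as.numeric(sub(".*x=(\\S+).*", "\\1", l))
        calib$y <- as.numeric(sub(".*y=(\\S+).*", "\\1", l))
        calib$unit <- sub(".*unit=(\\S+).*", "\\1", l)
      } else if (grepl("^# @node ", l)) {
        p <- strsplit(sub("^# @node ", "", l), " ")[[1]]
        ann[[p[1]]] <- list(
          orig = as.integer(sub("orig=", "", p[2])),
          layer = as.integer(sub("layer=", "", p[3])),
          conf = sub("conf=", "", p[4]),
          tags = sub("tags=", "", p[5]))
      }
      next
    }
    f <- strsplit(l, "\\s+")[[1]]
    if (length(f) != 7L) {
      stop("parse error at line ", ln, ": expected 7 SWC fields")
    }
    data[[length(data) + 1L]] <- as.numeric(f)
  }
  if (!length(data)) stop("parse error: no SWC data lines")
  m <- do.call(rbind, data)
  if (sum(m[, 7] == -1) != 1L) {
    stop("parse error: SWC must contain exactly one root (parent -1)")
  }
  swc_ids <- as.integer(m[, 1])
  get_ann <- function(i, field, default) {
    a <- ann[[as.character(swc_ids[i])]]
    if (is.null(a)) default else a[[field]]
  }
  orig <- vapply(seq_len(nrow(m)), function(i) get_ann(i, "orig", swc_ids[i]), 0L)
  layer_i <- vapply(seq_len(nrow(m)), function(i) get_ann(i, "layer", 1L), 0L)
  confs <- vapply(seq_len(nrow(m)), function(i) {
    cv <- get_ann(i, "conf", "5")
    if (identical(cv, "NA")) NA_integer_ else as.integer(cv)
  }, 0L)
  # z -> layer index comes from the annex; coordinates back to px
  nd <- data.frame(
    id = orig,
    parent = ifelse(m[, 7] == -1, NA_integer_,
                    orig[match(as.integer(m[, 7]), swc_ids)]),
    x = m[, 3] / calib$x, y = m[, 4] / calib$y,
    layer = layer_i,
    confidence = ifelse(m[, 7] == -1, NA_integer_, confs),
    radius = m[, 6] / calib$x)
  tags <- list()
  for (i in seq_len(nrow(m))) {
    tgs <- get_ann(i, "tags", "")
    if (nzchar(tgs)) {
      tags[[as.character(orig[i])]] <-
        vapply(strsplit(tgs, "\\|")[[1]], utils::URLdecode, "", USE.NAMES = FALSE)
    }
  }
  tr <- skeleton_tree(meta$id, nd, meta$subtype, tags = tags)
  attr(tr, "calibration") <- calib
  tr
}

#' Export a project's arbors and connectors as NeuroML
#'
#' Writes a NeuroML Level 3 (v1.8.1, MorphML + NetworkML) document:
#' one `<cell>` per arbor with one `<segment>` per skeleton edge
#' (proximal/distal points and radii in calibrated units) and one
#' `<connection>` per connector link between identified cells, with
#' the connector id and link confidence as properties.
#'
#' @param proj An `em_project` with at least one arbor.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_neuroml <- function(proj, path) {
  if (!length(proj$arbors)) stop("empty-input: project has no arbors")
  ls <- proj$layerset
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<neuroml xmlns="http://morphml.org/neuroml/schema" ',
           'xmlns:mml="http://morphml.org/morphml/schema" ',
           'xmlns:meta="http://morphml.org/metadata/schema" ',
           'xmlns:net="http://morphml.org/networkml/schema" ',
           'length_units="', esc(ls$calibration$unit), '" ',
           'lengthUnits="', esc(ls$calibration$unit), '">'),
    '  <meta:notes>NeuroML Level 3 v1.8.1 (MorphML + NetworkML)</meta:notes>',
    '  <cells>')
  for (nm in names(proj$arbors)) {
    tr <- proj$arbors[[nm]]
    nd <- tr$nodes
    xyz <- node_xyz(tr, ls)
    rad <- ifelse(is.na(nd$radius), 1, nd$radius) * ls$calibration$x
    out <- c(out, paste0('    <cell name="', esc(nm), '">'),
             '      <mml:segments>')
    seg_id <- 0L
    for (i in which(!is.na(nd$parent))) {
      p <- match(nd$parent[i], nd$id)
      out <- c(out, paste0(
        '        <mml:segment id="', seg_id, '" name="seg', seg_id,
        '" cable="0">',
        '<mml:proximal x="', xyz[p, 1], '" y="', xyz[p, 2], '" z="', xyz[p, 3],
        '" diameter="', 2 * rad[p], '"/>',
        '<mml:distal x="', xyz[i, 1], '" y="', xyz[i, 2], '" z="', xyz[i, 3],
        '" diameter="', 2 * rad[i], '"/>',
        '</mml:segment>'))
      seg_id <- seg_id + 1L
    }
    out <- c(out, '      </mml:segments>', '    </cell>')
  }
  out <- c(out, '  </cells>', '  <net:projections units="Physiological Units">',
           '    <net:projection name="connectors">', '      <net:connections>')
  k <- 0L
  for (cn in proj$connectors) {
    o <- cn$origin
    if (link_is_free(o)) next
    for (t in cn$targets) {
      if (link_is_free(t)) next
      out <- c(out, paste0(
        '        <net:connection id="', k, '" pre_cell_id="', esc(o$tree),
        '" post_cell_id="', esc(t$tree), '">',
        '<net:properties><meta:property tag="connector" value="', cn$id, '"/>',
        '<meta:property tag="confidence" value="', t$confidence, '"/>',
        '</net:properties></net:connection>'))
      k <- k + 1L
    }
  }
  out <- c(out, '      </net:connections>', '    </net:projection>',
           '  </net:projections>', '</neuroml>')
  writeLines(out, path)
  invisible(path)
}
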