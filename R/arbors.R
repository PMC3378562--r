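# Confidence-weighted skeleton trees. Nodes live at world (x, y) in a
# given layer; each non-root node carries the confidence (integer 0-5)
# of the edge to its parent, a tag list, and a payload: a radius
# (treeline) or a 2d area (areatree).

#' Create a skeleton tree
#'
#' @param id Tree id.
#' @param nodes data.frame with columns `id`, `parent` (`NA` for the
#'   root), `x`, `y`, `layer`, `confidence` (0-5; `NA` for the root)
#'   and `radius` (treeline payload; `NA` allowed).
#' @param subtype `"treeline"` (radius payload) or `"areatree"` (2d
#'   area payload).
#' @param tags Named list mapping node id (as character) to a character
#'   vector of tags.
#' @param areas Named list mapping node id to a polygon list (areatree
#'   payload).
#' @return An object of class `em_tree`.
#' @export
skeleton_tree <- function(id, nodes, subtype = c("treeline", "areatree"),
                          tags = list(), areas = list()) {
  subtype <- match.arg(subtype)
  nodes <- as.data.frame(nodes)
  need <- c("id", "parent", "x", "y", "layer", "confidence", "radius")
  for (cn in setdiff(need, names(nodes))) nodes[[cn]] <- NA_real_
  nodes <- nodes[, need]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$layer <- as.integer(nodes$layer)
  tr <- structure(list(id = id, subtype = subtype, nodes = nodes,
                       tags = tags, areas = areas),
                  class = "em_tree")
  validate_tree(tr)
  tr
}

#' Validate skeleton tree invariants
#'
#' Checks unique ids, exactly one root, parents existing, confidences
#' in 0..5, connectivity and acyclicity.
#'
#' @param tree An `em_tree`.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_tree <- function(tree) {
  nd <- tree$nodes
  if (anyDuplicated(nd$id)) stop("tree invariant: duplicate node ids")
  roots <- which(is.na(nd$parent))
  if (length(roots) != 1L) stop("tree invariant: expected exactly one root, found ",
                                length(roots))
  nonroot <- nd[!is.na(nd$parent), ]
  if (nrow(nonroot)) {
    if (!all(nonroot$parent %in% nd$id)) stop("tree invariant: missing parent")
    cf <- nonroot$confidence
    if (any(is.na(cf)) || any(cf < 0 | cf > 5)) {
      stop("tree invariant: edge confidence must be in [0, 5]")
    }
  }
  # connectivity/acyclicity: walk up from every node
  idx <- match(nd$parent, nd$id)
  n <- nrow(nd)
  for (i in seq_len(n)) {
    seen <- 0L; j <- i
    while (!is.na(idx[j])) {
      j <- idx[j]
      seen <- seen + 1L
      if (seen > n) stop("tree invariant: cycle detected")
    }
    if (j != roots) stop("tree invariant: node not reachable from root")
  }
  invisible(tree)
}

#' Basic tree accessors
#'
#' @param tree An `em_tree`.
#' @return `tree_size()`: the node count; `tree_root()`: the root
#'   node id.
#' @export
tree_size <- function(tree) nrow(tree$nodes)

node_row <- function(tree, node_id) {
  i <- match(as.integer(node_id), tree$nodes$id)
  if (is.na(i)) stop("not-found: node ", node_id, " not in tree ", tree$id)
  i
}

node_tags <- function(tree, node_id) {
  tg <- tree$tags[[as.character(node_id)]]
  if (is.null(tg)) character(0) else tg
}

#' Edit a skeleton node
#'
#' Adds/removes tags, sets the edge confidence to the parent, or
#' updates the payload (radius or area); everything else is untouched.
#'
#' @param tree An `em_tree`.
#' @param node_id Node id.
#' @param add_tags,remove_tags Character vectors of tags.
#' @param confidence New confidence of the edge to the parent (0-5).
#' @param radius New radius (treeline payload).
#' @param area New polygon list (areatree payload).
#' @return The modified tree.
#' @export
edit_node <- function(tree, node_id, add_tags = NULL, remove_tags = NULL,
                      confidence = NULL, radius = NULL, area = NULL) {
  i <- node_row(tree, node_id)
  key <- as.character(tree$nodes$id[i])
  if (!is.null(add_tags) || !is.null(remove_tags)) {
    tg <- union(setdiff(node_tags(tree, node_id), remove_tags %||% character(0)),
                add_tags %||% character(0))
    tree$tags[[key]] <- tg
  }
  if (!is.null(confidence)) {
    if (confidence < 0 || confidence > 5) {
      stop("range error: confidence must be in [0, 5]")
    }
    if (is.na(tree$nodes$parent[i])) stop("root has no parent edge")
    tree$nodes$confidence[i] <- as.integer(confidence)
  }
  if (!is.null(radius)) tree$nodes$radius[i] <- radius
  if (!is.null(area)) tree$areas[[key]] <- area
  tree
}

# ids of children of a node
tree_children <- function(tree, node_id) {
  tree$nodes$id[!is.na(tree$nodes$parent) & tree$nodes$parent == node_id]
}

#' @rdname tree_size
#' @export
tree_root <- function(tree) tree$nodes$id[is.na(tree$nodes$parent)]

# path of node ids from a node up to the root (inclusive)
path_to_root <- function(tree, node_id) {
  out <- integer(0)
  i <- node_row(tree, node_id)
  repeat {
    out <- c(out, tree$nodes$id[i])
    p <- tree$nodes$parent[i]
    if (is.na(p)) break
    i <- node_row(tree, p)
  }
  out
}

#' Reroot a skeleton tree
#'
#' Reverses parent pointers along the path from the old root to the
#' new root. Confidences stay attached to their undirected edge; the
#' node set and undirected edge set are unchanged ("rerooting changes
#' the perspective, but not the topology").
#'
#' @param tree An `em_tree`.
#' @param node_id The node to become the root.
#' @return The rerooted tree.
#' @export
reroot <- function(tree, node_id) {
  i <- node_row(tree, node_id)
  if (is.na(tree$nodes$parent[i])) return(tree)
  path <- path_to_root(tree, node_id) # new root ... old root
  nd <- tree$nodes
  # edge (path[k] -> path[k+1]) with confidence stored at path[k]
  conf <- nd$confidence[match(path[-length(path)], nd$id)]
  # reverse: parent(path[k+1]) <- path[k], confidence moves with edge
  for (k in seq_len(length(path) - 1L)) {
    child <- path[k + 1L]; parentv <- path[k]
    j <- match(child, nd$id)
    nd$parent[j] <- parentv
    nd$confidence[j] <- conf[k]
  }
  j0 <- match(node_id, nd$id)
  nd$parent[j0] <- NA_integer_
  nd$confidence[j0] <- NA_integer_
  tree$nodes <- nd
  validate_tree(tree)
  tree
}

#' Split a skeleton tree at a node
#'
#' Removes the edge from `node_id` to its parent; the subtree rooted at
#' `node_id` becomes a new tree. Node counts of the two results sum to
#' the original count.
#'
#' @param tree An `em_tree`.
#' @param node_id A non-root node.
#' @param new_id Id for the split-off tree.
#' @return List of two `em_tree`s: the remainder and the subtree.
#' @export
split_tree <- function(tree, node_id, new_id = paste0(tree$id, "-split")) {
  i <- node_row(tree, node_id)
  if (is.na(tree$nodes$parent[i])) {
    stop("invalid-split: cannot split a tree at its root")
  }
  # collect subtree ids
  sub <- as.integer(node_id)
  frontier <- sub
  while (length(frontier)) {
    kids <- tree$nodes$id[!is.na(tree$nodes$parent) &
                          tree$nodes$parent %in% frontier]
    sub <- c(sub, kids)
    frontier <- kids
  }
  in_sub <- tree$nodes$id %in% sub
  nd_b <- tree$nodes[in_sub, , drop = FALSE]
  j <- match(node_id, nd_b$id)
  nd_b$parent[j] <- NA_integer_
  nd_b$confidence[j] <- NA_integer_
  keysub <- as.character(sub)
  tb <- skeleton_tree(new_id, nd_b, tree$subtype,
                      tags = tree$tags[names(tree$tags) %in% keysub],
                      areas = tree$areas[names(tree$areas) %in% keysub])
  ta <- skeleton_tree(tree$id, tree$nodes[!in_sub, , drop = FALSE], tree$subtype,
                      tags = tree$tags[!(names(tree$tags) %in% keysub)],
                      areas = tree$areas[!(names(tree$areas) %in% keysub)])
  list(ta, tb)
}

#' Merge two skeleton trees
#'
#' `tree_b` is rerooted at `node_b` and attached as a child of
#' `node_a` in `tree_a` with the given edge confidence. Colliding node
#' ids of `tree_b` are re-issued from `max(tree_a ids) + 1`,
#' order-preserving.
#'
#' @param tree_a,tree_b Distinct `em_tree`s.
#' @param node_a Attachment node in `tree_a`.
#' @param node_b Node of `tree_b` that becomes the child of `node_a`.
#' @param confidence Confidence of the new edge (0-5).
#' @return The merged `em_tree` (id of `tree_a`).
#' @export
merge_trees <- function(tree_a, node_a, tree_b, node_b, confidence = 5L) {
  if (identical(tree_a$id, tree_b$id)) {
    stop("self-merge: cannot merge a tree with itself")
  }
  node_row(tree_a, node_a)
  tb <- reroot(tree_b, node_b)
  # re-issue colliding ids deterministically
  old_ids <- tb$nodes$id
  remap <- old_ids
  nxt <- max(tree_a$nodes$id) + 1L
  for (k in seq_along(old_ids)) {
    if (old_ids[k] %in% tree_a$nodes$id) { remap[k] <- nxt; nxt <- nxt + 1L }
  }
  nd <- tb$nodes
  nd$id <- remap[match(nd$id, old_ids)]
  nd$parent <- ifelse(is.na(nd$parent), NA_integer_,
                      remap[match(nd$parent, old_ids)])
  rootb_new <- remap[match(node_b, old_ids)]
  j <- match(rootb_new, nd$id)
  nd$parent[j] <- as.integer(node_a)
  nd$confidence[j] <- as.integer(confidence)
  tags_b <- tb$tags
  if (length(tags_b)) names(tags_b) <- as.character(remap[match(as.integer(names(tags_b)), old_ids)])
  areas_b <- tb$areas
  if (length(areas_b)) names(areas_b) <- as.character(remap[match(as.integer(names(areas_b)), old_ids)])
  out <- tree_a
  out$nodes <- rbind(tree_a$nodes, nd)
  out$tags <- c(tree_a$tags, tags_b)
  out$areas <- c(tree_a$areas, areas_b)
  validate_tree(out)
  out
}

# 3D node coordinates in calibrated units (z at the layer centre)
node_xyz <- function(tree, ls) {
  nd <- tree$nodes
  zc <- vapply(ls$layers, layer_z_center, 0)
  li <- vapply(ls$layers, function(l) l$index, 0L)
  z <- zc[match(nd$layer, li)]
  cbind(x = nd$x * ls$calibration$x, y = nd$y * ls$calibration$y, z = z)
}

# per-edge 3D lengths (units); rows follow non-root nodes
edge_lengths <- function(tree, ls) {
  nd <- tree$nodes
  xyz <- node_xyz(tree, ls)
  sel <- which(!is.na(nd$parent))
  pi_ <- match(nd$parent[sel], nd$id)
  d <- xyz[sel, , drop = FALSE] - xyz[pi_, , drop = FALSE]
  data.frame(node = nd$id[sel], parent = nd$parent[sel],
             confidence = nd$confidence[sel],
             length = sqrt(rowSums(d^2)))
}

#' Total cable length of a skeleton
#'
#' Sum over edges of the 3D Euclidean distance between node positions
#' (z from layer z-centres, x/y calibrated). Optionally restricted to
#' edges with confidence at or above a threshold, to confine analysis
#' to the most trustable subsets of a skeleton.
#'
#' @param tree An `em_tree`.
#' @param ls An `em_layerset` supplying calibration and layer z.
#' @param min_confidence Minimum edge confidence to count (default 0 =
#'   all edges).
#' @return Length in calibrated units.
#' @export
cable_length <- function(tree, ls, min_confidence = 0L) {
  el <- edge_lengths(tree, ls)
  sum(el$length[el$confidence >= min_confidence])
}

#' Geodesic distances from the root to tagged nodes
#'
#' Along-tree path length from the root to every node whose tags match
#' the regular expression (e.g. distances from the soma to every node
#' tagged "presynaptic site").
#'
#' @param tree An `em_tree`.
#' @param ls An `em_layerset`.
#' @param tag_regex Regular expression matched against each node's
#'   tags; `NULL` selects all nodes.
#' @return data.frame with `node` and `distance` (units).
#' @export
path_distances <- function(tree, ls, tag_regex = NULL) {
  if (!is.null(tag_regex)) check_regex(tag_regex)
  nd <- tree$nodes
  el <- edge_lengths(tree, ls)
  dist_up <- stats::setNames(rep(NA_real_, nrow(nd)), nd$id)
  dist_up[as.character(tree_root(tree))] <- 0
  # propagate root-first (nodes may be in any order)
  remaining <- nd$id[!is.na(nd$parent)]
  elen <- stats::setNames(el$length, el$node)
  while (length(remaining)) {
    ready <- remaining[!is.na(dist_up[as.character(nd$parent[match(remaining, nd$id)])])]
    if (!length(ready)) stop("tree invariant: disconnected")
    dist_up[as.character(ready)] <-
      dist_up[as.character(nd$parent[match(ready, nd$id)])] + elen[as.character(ready)]
    remaining <- setdiff(remaining, ready)
  }
  sel <- nd$id
  if (!is.null(tag_regex)) {
    keep <- vapply(sel, function(id) any(grepl(tag_regex, node_tags(tree, id))),
                   logical(1))
    sel <- sel[keep]
  }
  data.frame(node = sel, distance = unname(dist_up[as.character(sel)]))
}

check_regex <- function(pattern) {
  ok <- tryCatch({ grepl(pattern, ""); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop("pattern error: invalid regular expression '", pattern, "'")
  invisible(pattern)
}

#' Betweenness centrality of skeleton nodes
#'
#' Unweighted betweenness via Brandes' dependency accumulation on the
#' undirected tree: the number of unordered source/target pairs whose
#' (unique) path passes through a node as an interior vertex.
#' `restrict` limits the counted pairs to branch nodes or to nodes
#' bearing a synapse-marking tag.
#'
#' @param tree An `em_tree`.
#' @param restrict `"all"`, `"branches"` or `"synapse_nodes"`.
#' @param synapse_tag Regex identifying synapse nodes (for
#'   `restrict = "synapse_nodes"`).
#' @return Named numeric vector, node id -> score.
#' @export
betweenness_centrality <- function(tree, restrict = c("all", "branches", "synapse_nodes"),
                                   synapse_tag = "synapse|presynaptic|postsynaptic") {
  restrict <- match.arg(restrict)
  nd <- tree$nodes
  n <- nrow(nd)
  adj <- adjacency_list(tree)
  subset <- switch(restrict,
    all = seq_len(n),
    branches = which(vapply(nd$id, function(id) length(tree_children(tree, id)) >= 2L,
                            logical(1))),
    synapse_nodes = which(vapply(nd$id, function(id)
      any(grepl(synapse_tag, node_tags(tree, id))), logical(1)))
  )
  bc <- numeric(n)
  in_subset <- seq_len(n) %in% subset
  for (s in subset) {
    # BFS from s (unique paths in a tree: sigma = 1 throughout)
    dist <- rep(-1L, n); dist[s] <- 0L
    order_ <- integer(0)
    frontier <- s
    pred <- rep(NA_integer_, n)
    while (length(frontier)) {
      order_ <- c(order_, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; pred[w] <- v; nxt <- c(nxt, w) }
        }
      }
      frontier <- nxt
    }
    delta <- numeric(n)
    for (v in rev(order_)) {
      p <- pred[v]
      if (!is.na(p)) delta[p] <- delta[p] + delta[v] + (if (in_subset[v]) 1 else 0)
    }
    delta[s] <- 0
    bc <- bc + delta
  }
  # each unordered pair counted twice (once per endpoint as source)
  stats::setNames(bc / 2, nd$id)
}

adjacency_list <- function(tree) {
  nd <- tree$nodes
  n <- nrow(nd)
  adj <- vector("list", n)
  for (k in which(!is.na(nd$parent))) {
    p <- match(nd$parent[k], nd$id)
    adj[[k]] <- c(adj[[k]], p)
    adj[[p]] <- c(adj[[p]], k)
  }
  adj
}

#' Tabulate skeleton nodes
#'
#' One row per node with its topological class (`root`, `slab`,
#' `branch`, `end`), tags, confidence and calibrated coordinates;
#' optionally filtered by a tag regular expression and stably sorted by
#' any column.
#'
#' @param tree An `em_tree`.
#' @param ls An `em_layerset`.
#' @param filter_regex Regex applied to tags (`NULL` = all nodes).
#' @param sort_key Column name to sort by (`NULL` = tree order).
#' @return data.frame with columns `node`, `class`, `tags`,
#'   `confidence`, `x`, `y`, `z`, `reviewed`.
#' @export
node_table <- function(tree, ls, filter_regex = NULL, sort_key = NULL) {
  if (!is.null(filter_regex)) check_regex(filter_regex)
  nd <- tree$nodes
  xyz <- node_xyz(tree, ls)
  nchild <- vapply(nd$id, function(id) length(tree_children(tree, id)), 0L)
  cls <- ifelse(is.na(nd$parent), "root",
                ifelse(nchild == 0L, "end",
                       ifelse(nchild >= 2L, "branch", "slab")))
  tags <- vapply(nd$id, function(id) paste(node_tags(tree, id), collapse = "|"), "")
  tab <- data.frame(node = nd$id, class = cls, tags = tags,
                    confidence = nd$confidence,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    reviewed = FALSE)
  if (!is.null(filter_regex)) {
    keep <- vapply(nd$id, function(id) any(grepl(filter_regex, node_tags(tree, id))),
                   logical(1))
    tab <- tab[keep, , drop = FALSE]
  }
  if (!is.null(sort_key)) {
    stopifnot(sort_key %in% names(tab))
    tab <- tab[order(tab[[sort_key]]), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Render a review fly-through for a branch
#'
#' One frame per node along a root-to-branch/end path, each
#' `fov_size` x `fov_size` px world-centred on the node in its layer —
#' the optic-flow review stack used to catch misassignments across
#' sections.
#'
#' @param tree An `em_tree`.
#' @param branch_path Integer vector of node ids (in tree).
#' @param ls An `em_layerset` with image patches.
#' @param fov_size Frame edge length in world px.
#' @param scale Rendering scale.
#' @return List of rasters, one per node (zeros + warning for nodes in
#'   missing layers).
#' @export
review_stack <- function(tree, branch_path, ls, fov_size = 512, scale = 1) {
  if (!length(branch_path)) stop("empty-input: branch path has no nodes")
  li <- vapply(ls$layers, function(l) l$index, 0L)
  out_px <- max(1L, as.integer(round(fov_size * scale)))
  frames <- vector("list", length(branch_path))
  for (k in seq_along(branch_path)) {
    i <- node_row(tree, branch_path[k])
    nd <- tree$nodes[i, ]
    half <- fov_size / 2
    bbox <- c(nd$x - half, nd$y - half, nd$x + half, nd$y + half)
    j <- match(nd$layer, li)
    if (is.na(j)) {
      warning("node ", nd$id, " lies in missing layer ", nd$layer)
      frames[[k]] <- base::matrix(0, out_px, out_px)
    } else {
      frames[[k]] <- render_region(ls, j, bbox, scale)
    }
  }
  frames
}
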