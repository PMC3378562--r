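# Template-constrained project trees: a controlled vocabulary of
# nested abstract types (the template) and its instance hierarchy (the
# project tree) grouping primitive reconstruction objects.

PRIMITIVE_KINDS <- c("area_list", "treeline", "areatree", "connector",
                     "ball", "pipe")

#' Define a project template
#'
#' The template restricts which nested abstract concepts a project may
#' express: each abstract type lists the child types (abstract or
#' primitive) it may be represented with. Primitive kinds are always
#' leaves.
#'
#' @param types Named list: abstract type name -> character vector of
#'   allowed child type names.
#' @return An `em_template`.
#' @export
template <- function(types) {
  stopifnot(is.list(types), length(names(types)) == length(types))
  if (anyDuplicated(names(types))) stop("template type names must be unique")
  if (any(names(types) %in% PRIMITIVE_KINDS)) {
    stop("primitive kinds are leaves and cannot define children")
  }
  structure(list(types = types), class = "em_template")
}

#' @rdname template
#' @details `example_template()` ships the brain -> lineage -> neuron
#'   -> primitives vocabulary used by the circuit simulator.
#' @export
example_template <- function() {
  template(list(
    brain = c("lineage"),
    lineage = c("neuron"),
    neuron = c("treeline", "areatree", "connector", "ball")
  ))
}

#' Create a reconstruction project
#'
#' An `em_project` holds the template, the instance tree of project
#' nodes, the registries of primitive objects (arbors, connectors,
#' area lists, balls, pipes) and the calibrated layerset.
#'
#' @param template An [template()].
#' @param layerset An [layerset()].
#' @return An `em_project`.
#' @export
project <- function(template = example_template(), layerset = NULL) {
  structure(list(
    template = template,
    nodes = data.frame(id = integer(0), type = character(0),
                       title = character(0), parent = integer(0),
                       object = character(0), stringsAsFactors = FALSE),
    arbors = list(), connectors = list(), arealists = list(),
    balls = list(), pipes = list(),
    layerset = layerset %||% layerset()
  ), class = "em_project")
}

#' Add a node to the project tree
#'
#' @param proj An `em_project`.
#' @param parent_id Parent project-node id (`NULL` for the root).
#' @param type Template type (abstract or primitive kind).
#' @param title Display title.
#' @param object For primitive-kind nodes: the id of the bound
#'   primitive object in the matching registry.
#' @return List with `project` (updated) and `id` (the new node id).
#' @export
project_add_node <- function(proj, parent_id, type, title, object = NA_character_) {
  id <- if (nrow(proj$nodes)) max(proj$nodes$id) + 1L else 1L
  proj$nodes <- rbind(proj$nodes, data.frame(
    id = id, type = type, title = title,
    parent = if (is.null(parent_id)) NA_integer_ else as.integer(parent_id),
    object = as.character(object), stringsAsFactors = FALSE))
  list(project = proj, id = id)
}

template_allowed <- function(tmpl, type) {
  if (type %in% names(tmpl$types)) tmpl$types[[type]] else character(0)
}

# kind of a registered primitive object, or NA
project_object_kind <- function(proj, object_id) {
  oid <- as.character(object_id)
  if (oid %in% names(proj$arbors)) return(proj$arbors[[oid]]$subtype)
  if (oid %in% names(proj$connectors)) return("connector")
  if (oid %in% names(proj$arealists)) return("area_list")
  if (oid %in% names(proj$balls)) return("ball")
  if (oid %in% names(proj$pipes)) return("pipe")
  NA_character_
}

#' Validate a project against its template
#'
#' Returns one row per violation: a parent/child relation not allowed
#' by the template, an unknown type, or a primitive binding whose
#' object kind does not match the node's template leaf kind. An empty
#' result means the project is template-legal.
#'
#' @param proj An `em_project`.
#' @param tmpl Template to validate against (default: the project's).
#' @return data.frame with columns `node`, `found`, `allowed`,
#'   `message`.
#' @export
validate_project <- function(proj, tmpl = proj$template) {
  v <- data.frame(node = integer(0), found = character(0),
                  allowed = character(0), message = character(0))
  nd <- proj$nodes
  for (i in seq_len(nrow(nd))) {
    row <- nd[i, ]
    known <- row$type %in% names(tmpl$types) || row$type %in% PRIMITIVE_KINDS
    if (!known) {
      v <- rbind(v, data.frame(node = row$id, found = row$type,
                               allowed = paste(names(tmpl$types), collapse = ","),
                               message = "unknown type"))
      next
    }
    if (!is.na(row$parent)) {
      ptype <- nd$type[match(row$parent, nd$id)]
      allowed <- template_allowed(tmpl, ptype)
      if (!(row$type %in% allowed)) {
        v <- rbind(v, data.frame(node = row$id, found = row$type,
                                 allowed = paste(allowed, collapse = ","),
                                 message = paste0("type not allowed under '",
                                                  ptype, "'")))
      }
    }
    if (!is.na(row$object) && row$object != "NA") {
      kind <- project_object_kind(proj, row$object)
      if (is.na(kind)) {
        v <- rbind(v, data.frame(node = row$id, found = row$object,
                                 allowed = "", message = "bound object not found"))
      } else if (kind != row$type) {
        v <- rbind(v, data.frame(node = row$id, found = kind,
                                 allowed = row$type,
                                 message = "bound object kind mismatch"))
      }
    }
  }
  # single-parent rule for bound primitives
  bound <- nd$object[!is.na(nd$object) & nd$object != "NA"]
  dup <- unique(bound[duplicated(bound)])
  for (d in dup) {
    ids <- nd$id[!is.na(nd$object) & nd$object == d]
    v <- rbind(v, data.frame(node = ids[-1], found = d, allowed = "",
                             message = "primitive bound under multiple groups"))
  }
  rownames(v) <- NULL
  v
}

#' Search project nodes by regular expression
#'
#' Matches node titles and/or the tags of skeletons bound below each
#' node, returning matching nodes in document order.
#'
#' @param proj An `em_project`.
#' @param pattern Regular expression.
#' @param scope `"titles"`, `"tags"` or `"both"`.
#' @return data.frame of matching project nodes.
#' @export
project_search <- function(proj, pattern, scope = c("titles", "tags", "both")) {
  scope <- match.arg(scope)
  check_regex(pattern)
  nd <- proj$nodes
  hit <- rep(FALSE, nrow(nd))
  if (scope %in% c("titles", "both")) hit <- hit | grepl(pattern, nd$title)
  if (scope %in% c("tags", "both")) {
    for (i in seq_len(nrow(nd))) {
      if (hit[i]) next
      oid <- nd$object[i]
      if (!is.na(oid) && oid %in% names(proj$arbors)) {
        tr <- proj$arbors[[oid]]
        hit[i] <- any(vapply(tr$tags, function(tg) any(grepl(pattern, tg)),
                             logical(1)))
      }
    }
  }
  out <- nd[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ids of all project nodes in the subtree below (and including) a node
project_descendants <- function(proj, node_id) {
  out <- as.integer(node_id)
  frontier <- out
  while (length(frontier)) {
    kids <- proj$nodes$id[!is.na(proj$nodes$parent) &
                          proj$nodes$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Aggregate measurements over a project group
#'
#' Depth-first aggregation over every primitive bound below the node:
#' one row per object with its kind-specific measures (cable length
#' and node count for skeletons, volume for area lists, volumes for
#' balls, length for pipes) and a `TOTAL` row summing volumes, cable
#' lengths and counts.
#'
#' @param proj An `em_project`.
#' @param node_id Project node id (group).
#' @return data.frame with columns `object`, `kind`, `count`,
#'   `cable_length`, `volume`.
#' @export
group_measure <- function(proj, node_id) {
  ids <- project_descendants(proj, node_id)
  nd <- proj$nodes[proj$nodes$id %in% ids, , drop = FALSE]
  objs <- nd$object[!is.na(nd$object) & nd$object != "NA"]
  rows <- list()
  ls <- proj$layerset
  for (o in objs) {
    kind <- project_object_kind(proj, o)
    if (is.na(kind)) next
    if (kind %in% c("treeline", "areatree")) {
      tr <- proj$arbors[[o]]
      rows[[length(rows) + 1L]] <- data.frame(
        object = o, kind = kind, count = tree_size(tr),
        cable_length = cable_length(tr, ls), volume = 0)
    } else if (kind == "area_list") {
      m <- measure_arealist(proj$arealists[[o]], ls)
      rows[[length(rows) + 1L]] <- data.frame(
        object = o, kind = kind, count = 1, cable_length = 0,
        volume = m$volume)
    } else if (kind == "ball") {
      bs <- proj$balls[[o]]
      vol <- sum(4 / 3 * pi * (bs$balls$radius * ls$calibration$x)^3)
      rows[[length(rows) + 1L]] <- data.frame(
        object = o, kind = kind, count = nrow(bs$balls),
        cable_length = 0, volume = vol)
    } else if (kind == "pipe") {
      pp <- proj$pipes[[o]]
      xyz <- pipe_xyz(pp, ls)
      len <- sum(sqrt(rowSums(diff(xyz)^2)))
      rows[[length(rows) + 1L]] <- data.frame(
        object = o, kind = kind, count = 1, cable_length = len, volume = 0)
    } else if (kind == "connector") {
      cn <- proj$connectors[[o]]
      rows[[length(rows) + 1L]] <- data.frame(
        object = o, kind = kind, count = length(cn$targets),
        cable_length = 0, volume = 0)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object = character(0), kind = character(0), count = numeric(0),
               cable_length = numeric(0), volume = numeric(0))
  tot <- data.frame(object = "TOTAL", kind = "", count = sum(tab$count),
                    cable_length = sum(tab$cable_length),
                    volume = sum(tab$volume))
  rbind(tab, tot)
}
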