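# Project XML: the package's documented serialization dialect.
# Stores calibration, layers with per-patch path / transform chain /
# mask reference / display range / composite mode, the template and
# project tree, skeletons with tags and confidences, connectors, area
# lists, balls and pipes. Alpha masks and in-memory tile images are
# written as PNGs beside the XML file.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

num <- function(x) sprintf("%.17g", x)

serialize_chain <- function(chain) {
  vapply(chain$transforms, function(tr) {
    if (is_linear(tr)) {
      sprintf('<transform kind="%s" matrix="%s"/>', tr$kind,
              paste(num(tr$matrix), collapse = " "))
    } else if (tr$kind == "mls") {
      sprintf('<transform kind="mls" model="%s" alpha="%s" src="%s" dst="%s"/>',
              tr$model, num(tr$alpha),
              paste(num(t(tr$src)), collapse = " "),
              paste(num(t(tr$dst)), collapse = " "))
    } else {
      sprintf('<transform kind="mesh" rest="%s" moved="%s" triangles="%s"/>',
              paste(num(t(tr$rest)), collapse = " "),
              paste(num(t(tr$moved)), collapse = " "),
              paste(as.integer(t(tr$triangles)), collapse = " "))
    }
  }, "")
}

parse_chain <- function(node) {
  trs <- lapply(xml2::xml_find_all(node, "./transform"), function(tn) {
    kind <- xml2::xml_attr(tn, "kind")
    if (kind %in% LINEAR_KINDS) {
      m <- base::matrix(as.numeric(strsplit(xml2::xml_attr(tn, "matrix"),
                                            " ")[[1]]), 2, 3)
      transform_linear(kind, m)
    } else if (kind == "mls") {
      src <- base::matrix(as.numeric(strsplit(xml2::xml_attr(tn, "src"), " ")[[1]]),
                          ncol = 2, byrow = TRUE)
      dst <- base::matrix(as.numeric(strsplit(xml2::xml_attr(tn, "dst"), " ")[[1]]),
                          ncol = 2, byrow = TRUE)
      transform_mls(src, dst, xml2::xml_attr(tn, "model"),
                    as.numeric(xml2::xml_attr(tn, "alpha")))
    } else {
      rest <- base::matrix(as.numeric(strsplit(xml2::xml_attr(tn, "rest"), " ")[[1]]),
                           ncol = 2, byrow = TRUE)
      moved <- base::matrix(as.numeric(strsplit(xml2::xml_attr(tn, "moved"), " ")[[1]]),
                            ncol = 2, byrow = TRUE)
      tri <- base::matrix(as.integer(strsplit(xml2::xml_attr(tn, "triangles"), " ")[[1]]),
                          ncol = 3, byrow = TRUE)
      transform_mesh(rest, moved, tri)
    }
  })
  transform_chain(trs)
}

serialize_tree <- function(tr) {
  nd <- tr$nodes
  c(sprintf('<tree id="%s" subtype="%s">', xml_escape(as.character(tr$id)),
            tr$subtype),
    vapply(seq_len(nrow(nd)), function(i) {
      tags <- node_tags(tr, nd$id[i])
      sprintf('<node id="%d" parent="%s" x="%s" y="%s" layer="%d" confidence="%s" radius="%s" tags="%s"/>',
              nd$id[i],
              if (is.na(nd$parent[i])) "" else as.character(nd$parent[i]),
              num(nd$x[i]), num(nd$y[i]), nd$layer[i],
              if (is.na(nd$confidence[i])) "" else as.character(nd$confidence[i]),
              if (is.na(nd$radius[i])) "" else num(nd$radius[i]),
              xml_escape(paste(utils::URLencode(tags, reserved = TRUE),
                               collapse = "|")))
    }, ""),
    "</tree>")
}

parse_tree <- function(node) {
  nn <- xml2::xml_find_all(node, "./node")
  gi <- function(a) xml2::xml_attr(nn, a)
  pr <- gi("parent"); cf <- gi("confidence"); rd <- gi("radius")
  nd <- data.frame(
    id = as.integer(gi("id")),
    parent = ifelse(pr == "", NA_integer_, suppressWarnings(as.integer(pr))),
    x = as.numeric(gi("x")), y = as.numeric(gi("y")),
    layer = as.integer(gi("layer")),
    confidence = ifelse(cf == "", NA_integer_, suppressWarnings(as.integer(cf))),
    radius = ifelse(rd == "", NA_real_, suppressWarnings(as.numeric(rd))))
  tags <- list()
  tg <- gi("tags")
  for (i in seq_along(tg)) {
    if (!is.na(tg[i]) && nzchar(tg[i])) {
      tags[[as.character(nd$id[i])]] <-
        vapply(strsplit(tg[i], "|", fixed = TRUE)[[1]], utils::URLdecode, "",
               USE.NAMES = FALSE)
    }
  }
  skeleton_tree(xml2::xml_attr(node, "id"), nd,
                xml2::xml_attr(node, "subtype"), tags = tags)
}

serialize_end <- function(e, tag) {
  if (link_is_free(e)) {
    sprintf('<%s x="%s" y="%s" confidence="%d"/>', tag,
            num(e$point[1]), num(e$point[2]), e$confidence)
  } else {
    sprintf('<%s tree="%s" node="%d" confidence="%d"/>', tag,
            xml_escape(e$tree), e$node, e$confidence)
  }
}

parse_end <- function(node) {
  tr <- xml2::xml_attr(node, "tree")
  if (is.na(tr)) {
    link_end(point = c(as.numeric(xml2::xml_attr(node, "x")),
                       as.numeric(xml2::xml_attr(node, "y"))),
             confidence = as.integer(xml2::xml_attr(node, "confidence")))
  } else {
    link_end(tree = tr, node = as.integer(xml2::xml_attr(node, "node")),
             confidence = as.integer(xml2::xml_attr(node, "confidence")))
  }
}

#' Write / read a project XML file
#'
#' Serializes an entire `em_project` — calibration, layers, patches
#' (path, transform chain, display range, composite mode, mask),
#' template, project tree, skeletons, connectors, area lists, balls
#' and pipes — into a single XML document. Alpha masks and in-memory
#' patch images are written as PNG files next to the XML. The round
#' trip `read_project_xml(write_project_xml(p))` is lossless for all
#' annotation objects.
#'
#' @param proj An `em_project`.
#' @param path Output XML path.
#' @return `write_project_xml()`: the path, invisibly.
#' @export
write_project_xml <- function(proj, path) {
  dir <- dirname(path)
  stem <- tools::file_path_sans_ext(basename(path))
  ls <- proj$layerset
  out <- c('<?xml version="1.0" encoding="UTF-8"?>', "<emrecon_project>",
           sprintf('<calibration x="%s" y="%s" unit="%s"/>',
                   num(ls$calibration$x), num(ls$calibration$y),
                   xml_escape(ls$calibration$unit)))
  # template
  out <- c(out, "<template>")
  for (tn in names(proj$template$types)) {
    out <- c(out, sprintf('<type name="%s" children="%s"/>', xml_escape(tn),
                          xml_escape(paste(proj$template$types[[tn]],
                                           collapse = ","))))
  }
  out <- c(out, "</template>")
  # layers + patches
  out <- c(out, "<layers>")
  for (l in ls$layers) {
    out <- c(out, sprintf('<layer index="%d" z_start="%s" thickness="%s">',
                          l$index, num(l$z_start), num(l$thickness)))
    for (p in l$patches) {
      ppath <- p$path
      if (is.na(ppath) && !is.null(p$image)) {
        ppath <- file.path(dir, sprintf("%s_patch_%s.png", stem, p$id))
        save_raster(p$image, ppath, 8)
      }
      mpath <- ""
      if (!is.null(p$mask)) {
        mpath <- file.path(dir, sprintf("%s_mask_%s.png", stem, p$id))
        png::writePNG(p$mask, mpath)
      }
      out <- c(out, sprintf(
        '<patch id="%s" path="%s" width="%d" height="%d" mask="%s" display_min="%s" display_max="%s" composite="%s">',
        xml_escape(as.character(p$id)), xml_escape(ppath), p$width, p$height,
        xml_escape(mpath), num(p$display_range[1]), num(p$display_range[2]),
        p$composite),
        serialize_chain(p$chain), "</patch>")
    }
    out <- c(out, "</layer>")
  }
  out <- c(out, "</layers>")
  # project tree
  out <- c(out, "<project_tree>")
  nd <- proj$nodes
  for (i in seq_len(nrow(nd))) {
    out <- c(out, sprintf('<pnode id="%d" type="%s" title="%s" parent="%s" object="%s"/>',
                          nd$id[i], xml_escape(nd$type[i]),
                          xml_escape(nd$title[i]),
                          if (is.na(nd$parent[i])) "" else as.character(nd$parent[i]),
                          if (is.na(nd$object[i])) "" else xml_escape(nd$object[i])))
  }
  out <- c(out, "</project_tree>", "<arbors>")
  for (tr in proj$arbors) out <- c(out, serialize_tree(tr))
  out <- c(out, "</arbors>", "<connectors>")
  for (cn in proj$connectors) {
    out <- c(out, sprintf('<connector id="%s" layer="%d">',
                          xml_escape(as.character(cn$id)), cn$layer),
             serialize_end(cn$origin, "origin"),
             vapply(cn$targets, serialize_end, "", tag = "target"),
             "</connector>")
  }
  out <- c(out, "</connectors>", "<arealists>")
  for (al in proj$arealists) {
    out <- c(out, sprintf('<arealist id="%s" color="%s">',
                          xml_escape(as.character(al$id)), xml_escape(al$color)))
    for (lk in names(al$layers)) {
      for (op in al$layers[[lk]]) {
        out <- c(out, sprintf('<area layer="%s" mode="%s" points="%s"/>', lk,
                              op$mode, paste(num(t(op$poly)), collapse = " ")))
      }
    }
    out <- c(out, "</arealist>")
  }
  out <- c(out, "</arealists>", "<balls>")
  for (bs in proj$balls) {
    out <- c(out, sprintf('<ballset id="%s">', xml_escape(as.character(bs$id))),
             sprintf('<ball x="%s" y="%s" layer="%d" radius="%s"/>',
                     vapply(bs$balls$x, num, ""), vapply(bs$balls$y, num, ""),
                     bs$balls$layer, vapply(bs$balls$radius, num, "")),
             "</ballset>")
  }
  out <- c(out, "</balls>", "<pipes>")
  for (pp in proj$pipes) {
    out <- c(out, sprintf('<pipe id="%s">', xml_escape(as.character(pp$id))),
             sprintf('<point x="%s" y="%s" layer="%d" radius="%s"/>',
                     vapply(pp$points$x, num, ""), vapply(pp$points$y, num, ""),
                     pp$points$layer, vapply(pp$points$radius, num, "")),
             "</pipe>")
  }
  out <- c(out, "</pipes>", "</emrecon_project>")
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_project_xml
#' @return `read_project_xml()`: an `em_project`.
#' @export
read_project_xml <- function(path) {
  doc <- xml2::read_xml(path)
  cal <- xml2::xml_find_first(doc, "./calibration")
  calibration <- list(x = as.numeric(xml2::xml_attr(cal, "x")),
                      y = as.numeric(xml2::xml_attr(cal, "y")),
                      unit = xml2::xml_attr(cal, "unit"))
  types <- list()
  for (tn in xml2::xml_find_all(doc, "./template/type")) {
    ch <- xml2::xml_attr(tn, "children")
    types[[xml2::xml_attr(tn, "name")]] <-
      if (nzchar(ch)) strsplit(ch, ",")[[1]] else character(0)
  }
  layers <- lapply(xml2::xml_find_all(doc, "./layers/layer"), function(ln) {
    patches <- lapply(xml2::xml_find_all(ln, "./patch"), function(pn) {
      mpath <- xml2::xml_attr(pn, "mask")
      mask <- if (nzchar(mpath)) {
        m <- png::readPNG(mpath)
        if (length(dim(m)) == 3L) m <- m[, , 1L]
        m
      } else NULL
      patch(id = xml2::xml_attr(pn, "id"),
            path = xml2::xml_attr(pn, "path"),
            width = as.integer(xml2::xml_attr(pn, "width")),
            height = as.integer(xml2::xml_attr(pn, "height")),
            chain = parse_chain(pn), mask = mask,
            display_range = c(as.numeric(xml2::xml_attr(pn, "display_min")),
                              as.numeric(xml2::xml_attr(pn, "display_max"))),
            composite = xml2::xml_attr(pn, "composite"))
    })
    layer(as.integer(xml2::xml_attr(ln, "index")),
          as.numeric(xml2::xml_attr(ln, "z_start")),
          as.numeric(xml2::xml_attr(ln, "thickness")), patches)
  })
  proj <- project(template = template(types),
                  layerset = layerset(layers, calibration))
  pn <- xml2::xml_find_all(doc, "./project_tree/pnode")
  if (length(pn)) {
    pr <- xml2::xml_attr(pn, "parent"); ob <- xml2::xml_attr(pn, "object")
    proj$nodes <- data.frame(
      id = as.integer(xml2::xml_attr(pn, "id")),
      type = xml2::xml_attr(pn, "type"),
      title = xml2::xml_attr(pn, "title"),
      parent = ifelse(pr == "", NA_integer_, suppressWarnings(as.integer(pr))),
      object = ifelse(ob == "", NA_character_, ob),
      stringsAsFactors = FALSE)
  }
  for (tn in xml2::xml_find_all(doc, "./arbors/tree")) {
    tr <- parse_tree(tn)
    proj$arbors[[as.character(tr$id)]] <- tr
  }
  for (cn in xml2::xml_find_all(doc, "./connectors/connector")) {
    id <- xml2::xml_attr(cn, "id")
    proj$connectors[[id]] <- connector(
      id = id,
      origin = parse_end(xml2::xml_find_first(cn, "./origin")),
      targets = lapply(xml2::xml_find_all(cn, "./target"), parse_end),
      layer = as.integer(xml2::xml_attr(cn, "layer")))
  }
  for (an in xml2::xml_find_all(doc, "./arealists/arealist")) {
    al <- arealist(xml2::xml_attr(an, "id"), xml2::xml_attr(an, "color"))
    for (area in xml2::xml_find_all(an, "./area")) {
      poly <- base::matrix(as.numeric(strsplit(xml2::xml_attr(area, "points"),
                                               " ")[[1]]), ncol = 2, byrow = TRUE)
      al$layers[[xml2::xml_attr(area, "layer")]] <-
        c(al$layers[[xml2::xml_attr(area, "layer")]],
          list(list(poly = poly, mode = xml2::xml_attr(area, "mode"))))
    }
    proj$arealists[[as.character(al$id)]] <- al
  }
  for (bn in xml2::xml_find_all(doc, "./balls/ballset")) {
    bb <- xml2::xml_find_all(bn, "./ball")
    proj$balls[[xml2::xml_attr(bn, "id")]] <- ball_set(
      xml2::xml_attr(bn, "id"),
      data.frame(x = as.numeric(xml2::xml_attr(bb, "x")),
                 y = as.numeric(xml2::xml_attr(bb, "y")),
                 layer = as.integer(xml2::xml_attr(bb, "layer")),
                 radius = as.numeric(xml2::xml_attr(bb, "radius"))))
  }
  for (pn2 in xml2::xml_find_all(doc, "./pipes/pipe")) {
    pb <- xml2::xml_find_all(pn2, "./point")
    proj$pipes[[xml2::xml_attr(pn2, "id")]] <- pipe(
      xml2::xml_attr(pn2, "id"),
      data.frame(x = as.numeric(xml2::xml_attr(pb, "x")),
                 y = as.numeric(xml2::xml_attr(pb, "y")),
                 layer = as.integer(xml2::xml_attr(pb, "layer")),
                 radius = as.numeric(xml2::xml_attr(pb, "radius"))))
  }
  proj
}
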