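two_node_tree <- function(id, x0 = 0) {
  skeleton_tree(id, data.frame(id = 1:2, parent = c(NA, 1),
                               x = c(x0, x0 + 3), y = 0, layer = 1L,
                               confidence = c(NA, 5L), radius = 1))
}

tiny_project <- function() {
  proj <- project(layerset = layerset(list(layer(1, 0, 50))))
  proj$arbors <- list(A = two_node_tree("A", 0),
                      B = two_node_tree("B", 10),
                      C = two_node_tree("C", 20))
  proj
}

test_that("partner tables list incoming/outgoing links and flag incomplete ends", {
  proj <- tiny_project()
  proj$connectors <- list(
    "1" = connector(1, link_end("A", 1, confidence = 4),
                    list(link_end("B", 1, confidence = 3),
                         link_end("C", 2, confidence = 5))),
    "2" = connector(2, link_end("B", 2),
                    list(link_end(point = c(5, 5), confidence = 2))))
  pa <- partner_table(proj, "A")
  expect_equal(sort(pa$outgoing$partner_tree), c("B", "C"))
  expect_equal(nrow(pa$incoming), 0L)
  pb <- partner_table(proj, "B")
  expect_equal(pb$incoming$partner_tree, "A")
  expect_true(pb$outgoing$incomplete) # free-point target
  expect_error(partner_table(proj, "Z"), "not-found")

  # conservation: total outgoing rows across trees = total target links
  tot <- sum(vapply(names(proj$arbors), function(id)
    nrow(partner_table(proj, id)$outgoing), 0L))
  expect_equal(tot, 3L)
})

test_that("build_circuit counts links and applies the link-confidence threshold", {
  proj <- tiny_project()
  proj$connectors <- list(
    "1" = connector(1, link_end("A", 1, confidence = 5), list(link_end("B", 1, confidence = 5))),
    "2" = connector(2, link_end("A", 2, confidence = 5), list(link_end("B", 2, confidence = 5))),
    "3" = connector(3, link_end("A", 1, confidence = 5), list(link_end("B", 1, confidence = 2))))
  g <- build_circuit(proj, 0, 0)
  expect_equal(g$edges$weight[g$edges$pre == "A" & g$edges$post == "B"], 3L)
  g3 <- build_circuit(proj, 3, 0)
  expect_equal(sum(g3$edges$weight), 2L) # the confidence-2 link is gone
})

test_that("low-confidence skeleton edges sever arbors and links re-attach to components", {
  proj <- tiny_project()
  # A: path 1-2-3 with a weak middle edge
  proj$arbors$A <- skeleton_tree("A", data.frame(
    id = 1:3, parent = c(NA, 1, 2), x = c(0, 3, 6), y = 0, layer = 1L,
    confidence = c(NA, 5L, 1L), radius = 1))
  proj$connectors <- list(
    "1" = connector(1, link_end("A", 3, confidence = 5),
                    list(link_end("B", 1, confidence = 5))))
  g0 <- build_circuit(proj, 0, 0)
  expect_equal(g0$edges$pre, "A")
  g2 <- build_circuit(proj, 0, 2) # severs edge 2-3; node 3 in component A#2
  expect_equal(g2$edges$pre, "A#2")
  expect_equal(sum(g2$edges$weight), 1L)
})

test_that("circuit conservation and monotonicity hold on random simulated circuits", {
  set.seed(5)
  for (rep in 1:12) {
    proj <- simulate_circuit(n_neurons = 4, n_connectors = 8, seed = 500 + rep)
    n_links <- sum(vapply(proj$connectors, function(cn)
      sum(!vapply(cn$targets, emrecon:::link_is_free, TRUE)), 0L))
    g <- build_circuit(proj, 0, 0)
    expect_equal(sum(g$edges$weight), n_links)

    prev <- Inf
    for (th in 0:5) {
      w <- sum(build_circuit(proj, th, 0)$edges$weight)
      expect_lte(w, prev); prev <- w
    }
    prev <- Inf
    for (th in 0:5) {
      w <- sum(build_circuit(proj, 0, th)$edges$weight)
      expect_lte(w, prev); prev <- w
    }
  }
})

test_that("SWC export writes the format contract and round-trips losslessly", {
  ls <- layerset(lapply(1:6, function(i) layer(i, (i - 1) * 50, 50)))
  tr <- simulate_arbor(25, seed = 42, id = "n1", layer_range = c(1, 6))
  tr <- edit_node(tr, 5, add_tags = c("TODO", "presynaptic site"))
  tr <- edit_node(tr, 7, add_tags = "uncertain continuation")
  f <- tempfile(fileext = ".swc")
  export_swc(tr, ls, f)
  lines <- readLines(f)
  data_lines <- lines[!startsWith(lines, "#")]
  expect_length(data_lines, 25L)
  fields <- do.call(rbind, strsplit(data_lines, " "))
  expect_equal(sum(fields[, 7] == "-1"), 1L)
  root_line <- fields[fields[, 7] == "-1", ]
  expect_equal(root_line[2], "1") # soma type for the root

  back <- import_swc(f)
  expect_equal(back$nodes[order(back$nodes$id), ],
               tr$nodes[order(tr$nodes$id), ],
               ignore_attr = TRUE)
  expect_equal(back$tags[order(names(back$tags))],
               tr$tags[order(names(tr$tags))])
  expect_equal(back$subtype, tr$subtype)
  expect_equal(back$id, tr$id)
})

test_that("malformed SWC files raise parse errors", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 1 -1", "2 0 1 0 0 1"), f) # 6 fields
  expect_error(import_swc(f), "parse error at line 2")
  writeLines(c("1 1 0 0 0 1 -1", "2 0 1 0 0 1 -1"), f) # two roots
  expect_error(import_swc(f), "exactly one root")
})

test_that("SWC round trips are lossless over many simulated trees", {
  ls <- layerset(lapply(1:8, function(i) layer(i, (i - 1) * 45, 45)))
  f <- tempfile(fileext = ".swc")
  for (i in 1:40) {
    tr <- simulate_arbor(sample(2:200, 1), seed = 600 + i, id = paste0("t", i),
                         layer_range = c(1, 8))
    export_swc(tr, ls, f)
    back <- import_swc(f)
    bo <- back$nodes[order(back$nodes$id), ]
    to <- tr$nodes[order(tr$nodes$id), ]
    expect_equal(bo[, c("id", "parent", "layer", "confidence")],
                 to[, c("id", "parent", "layer", "confidence")],
                 ignore_attr = TRUE)
    expect_equal(bo$x, to$x, tolerance = 1e-12)
    expect_equal(bo$radius, to$radius, tolerance = 1e-12)
  }
})

test_that("NeuroML export is well-formed with one segment per edge and one connection per link", {
  proj <- tiny_project()
  proj$connectors <- list(
    "1" = connector(1, link_end("A", 1, confidence = 4),
                    list(link_end("B", 1, confidence = 3),
                         link_end("C", 1, confidence = 2))))
  f <- tempfile(fileext = ".xml")
  export_neuroml(proj, f)
  doc <- xml2::read_xml(f) # parses => well-formed
  segs <- xml2::xml_find_all(doc, "//*[local-name() = 'segment']")
  expect_length(segs, 3L) # 3 arbors x (2 nodes - 1)
  cons <- xml2::xml_find_all(doc, "//*[local-name() = 'connection']")
  expect_length(cons, 2L)
  expect_equal(xml2::xml_attr(cons[[1]], "pre_cell_id"), "A")

  tr <- simulate_arbor(17, seed = 4, id = "solo")
  proj2 <- project(layerset = proj$layerset)
  proj2$arbors <- list(solo = tr)
  export_neuroml(proj2, f)
  doc2 <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(doc2, "//*[local-name() = 'segment']"), 16L)
})

test_that("adjacency export is a deterministic square matrix conserving links", {
  proj <- tiny_project()
  proj$connectors <- list(
    "1" = connector(1, link_end("A", 1), list(link_end("B", 1), link_end("B", 2))),
    "2" = connector(2, link_end("C", 1), list(link_end("A", 1))))
  g <- build_circuit(proj, 0, 0)
  f <- tempfile(fileext = ".csv")
  m <- export_adjacency(g, f)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m["A", "B"], 3L - 1L) # two A->B links
  expect_equal(m["B", "A"], 0L)
  expect_equal(sum(m), sum(g$edges$weight))
  back <- utils::read.csv(f, row.names = 1)
  expect_equal(unname(as.matrix(back)), unname(m), ignore_attr = TRUE)

  g_empty <- build_circuit(project(), 0, 0)
  f2 <- tempfile(fileext = ".csv")
  m2 <- export_adjacency(g_empty, f2)
  expect_equal(dim(m2), c(0L, 0L))
  expect_true(file.exists(f2))
})
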