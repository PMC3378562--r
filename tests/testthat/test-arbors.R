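path_tree <- function(n = 3, spacing = 1) {
  # unit-spaced path 1-2-...-n in one layer
  skeleton_tree("path", data.frame(
    id = seq_len(n), parent = c(NA, seq_len(n - 1)),
    x = (seq_len(n) - 1) * spacing, y = 0, layer = 1L,
    confidence = c(NA, rep(5L, n - 1)), radius = 1))
}

flat_layerset <- function(n_layers = 5, thickness = 50, calib = 1) {
  layerset(lapply(seq_len(n_layers), function(i)
    layer(i, (i - 1) * thickness, thickness)),
    calibration = list(x = calib, y = calib, unit = "nm"))
}

# independent oracle: betweenness by enumerating the unique tree path
# of every unordered node pair
brute_betweenness <- function(tree, subset = tree$nodes$id) {
  ids <- tree$nodes$id
  score <- stats::setNames(numeric(length(ids)), ids)
  up <- function(id) emrecon:::path_to_root(tree, id)
  for (i in seq_along(subset)) {
    for (j in seq_along(subset)) {
      if (i >= j) next
      a <- up(subset[i]); b <- up(subset[j])
      common <- intersect(a, b)
      lca <- common[1]
      pth <- c(a[seq_len(match(lca, a))], rev(b[seq_len(match(lca, b) - 1)]))
      interior <- setdiff(pth, c(subset[i], subset[j]))
      score[as.character(interior)] <- score[as.character(interior)] + 1
    }
  }
  score
}

undirected_edges <- function(tree) {
  nd <- tree$nodes[!is.na(tree$nodes$parent), ]
  key <- paste(pmin(nd$id, nd$parent), pmax(nd$id, nd$parent), nd$confidence)
  sort(key)
}

test_that("edit_node round-trips tags, confidence and payload", {
  tr <- path_tree(3)
  tr <- edit_node(tr, 2, add_tags = "TODO")
  ls <- flat_layerset()
  tab <- node_table(tr, ls, filter_regex = "^TODO$")
  expect_equal(tab$node, 2L)

  tr <- edit_node(tr, 2, remove_tags = "TODO")
  expect_equal(nrow(node_table(tr, ls, filter_regex = "TODO")), 0L)

  tr <- edit_node(tr, 3, confidence = 0)
  expect_equal(cable_length(tr, ls, min_confidence = 1), 1) # edge 2-3 excluded
  expect_equal(cable_length(tr, ls, min_confidence = 0), 2)

  expect_error(edit_node(tr, 99, add_tags = "x"), "not-found")
  expect_error(edit_node(tr, 2, confidence = 7), "range error")

  tr <- edit_node(tr, 2, radius = 5)
  f <- tempfile(fileext = ".swc")
  calib <- flat_layerset(calib = 4)
  export_swc(tr, calib, f)
  dat <- read.table(f)
  expect_equal(dat$V6[dat$V1 == 2], 5 * 4) # radius in calibrated units
})

test_that("reroot reverses the root path but preserves the undirected graph", {
  tr <- path_tree(3)
  expect_identical(reroot(tr, 1), tr) # reroot at current root

  r3 <- reroot(tr, 3)
  nd <- r3$nodes
  expect_true(is.na(nd$parent[nd$id == 3]))
  expect_equal(nd$parent[nd$id == 2], 3L)
  expect_equal(nd$parent[nd$id == 1], 2L)

  set.seed(21)
  ls <- flat_layerset(10)
  for (i in 1:10) {
    tr <- simulate_arbor(50, seed = i, layer_range = c(1, 10), id = "t")
    target <- sample(tr$nodes$id, 1)
    rr <- reroot(tr, target)
    expect_equal(undirected_edges(rr), undirected_edges(tr))
    expect_equal(cable_length(rr, ls), cable_length(tr, ls))
    expect_silent(validate_tree(rr))
  }
})

test_that("split produces the subtree and remainder; split+merge restores the graph", {
  tr <- path_tree(3)
  parts <- split_tree(tr, 2)
  expect_equal(sort(parts[[1]]$nodes$id), 1L)
  expect_equal(sort(parts[[2]]$nodes$id), c(2L, 3L))
  expect_error(split_tree(tr, 1), "invalid-split")

  set.seed(31)
  for (i in 1:10) {
    tr <- simulate_arbor(40, seed = 100 + i, id = "t")
    nonroot <- setdiff(tr$nodes$id, 1L)
    at <- sample(nonroot, 1)
    conf <- tr$nodes$confidence[tr$nodes$id == at]
    parts <- split_tree(tr, at)
    expect_equal(tree_size(parts[[1]]) + tree_size(parts[[2]]), 40L)
    parent_at <- tr$nodes$parent[tr$nodes$id == at]
    back <- merge_trees(parts[[1]], parent_at, parts[[2]], at, conf)
    expect_equal(undirected_edges(back), undirected_edges(tr))
  }
})

test_that("merge conserves node and edge counts and cable length", {
  ls <- flat_layerset()
  ta <- path_tree(3)
  tb <- skeleton_tree("b", data.frame(id = 1L, parent = NA, x = 2, y = 4,
                                      layer = 1L, confidence = NA, radius = 1))
  m <- merge_trees(ta, 3, tb, 1, confidence = 2L)
  expect_equal(tree_size(m), 4L)
  expect_equal(sum(!is.na(m$nodes$parent)), 3L) # e_a + e_b + 1
  new_edge <- m$nodes[m$nodes$parent == 3 & !is.na(m$nodes$parent), ]
  expect_equal(new_edge$confidence, 2L)
  # cable = len_a + len_b + new edge length (new node at (2,4): dist 4 from (2,0))
  expect_equal(cable_length(m, ls), cable_length(ta, ls) + 0 + 4)
  expect_error(merge_trees(ta, 1, ta, 2), "self-merge")
})

test_that("cable length follows 3D euclidean edges with layer z-centres", {
  ls <- flat_layerset()
  single <- skeleton_tree("s", data.frame(id = 1, parent = NA, x = 0, y = 0,
                                          layer = 1, confidence = NA, radius = 1))
  expect_equal(cable_length(single, ls), 0)

  t2 <- skeleton_tree("t", data.frame(id = 1:2, parent = c(NA, 1),
                                      x = c(0, 3), y = c(0, 4), layer = 1L,
                                      confidence = c(NA, 5), radius = 1))
  expect_equal(cable_length(t2, ls), 5)

  t3 <- skeleton_tree("t", data.frame(id = 1:2, parent = c(NA, 1),
                                      x = 0, y = 0, layer = c(1L, 2L),
                                      confidence = c(NA, 5), radius = 1))
  expect_equal(cable_length(t3, ls), 50) # z-only edge, thickness 50
})

test_that("path distances from the root respect tags and the triangle inequality", {
  ls <- flat_layerset()
  tr <- path_tree(3)
  tr <- edit_node(tr, 1, add_tags = "soma")
  tr <- edit_node(tr, 3, add_tags = "presynaptic site")
  d <- path_distances(tr, ls, "soma")
  expect_equal(d$distance, 0)
  d3 <- path_distances(tr, ls, "presynaptic")
  expect_equal(d3$distance, 2)
  expect_error(path_distances(tr, ls, "("), "pattern error")

  set.seed(41)
  tr <- simulate_arbor(60, seed = 7, id = "t", layer_range = c(1, 5))
  d <- path_distances(tr, ls)
  xyz <- emrecon:::node_xyz(tr, ls)
  root_i <- which(is.na(tr$nodes$parent))
  straight <- sqrt(rowSums(sweep(xyz, 2, xyz[root_i, ])^2))
  expect_true(all(d$distance >= straight[match(d$node, tr$nodes$id)] - 1e-9))
})

test_that("betweenness matches closed forms on paths and stars", {
  expect_equal(unname(betweenness_centrality(path_tree(5))), c(0, 3, 4, 3, 0))
  star <- skeleton_tree("star", data.frame(
    id = 1:5, parent = c(NA, 1, 1, 1, 1), x = 0, y = 0, layer = 1,
    confidence = c(NA, rep(5, 4)), radius = 1))
  expect_equal(unname(betweenness_centrality(star)), c(6, 0, 0, 0, 0))
})

test_that("betweenness agrees exactly with brute-force enumeration on random trees", {
  set.seed(51)
  for (i in 1:8) {
    n <- sample(5:30, 1)
    tr <- simulate_arbor(n, seed = 200 + i, id = "t")
    bc <- betweenness_centrality(tr)
    expect_equal(bc, brute_betweenness(tr))
  }
})

test_that("betweenness agrees with igraph as an independent implementation", {
  skip_if_not_installed("igraph")
  tr <- simulate_arbor(40, seed = 9, id = "t")
  nd <- tr$nodes[!is.na(tr$nodes$parent), ]
  g <- igraph::graph_from_edgelist(cbind(as.character(nd$parent),
                                         as.character(nd$id)), directed = FALSE)
  ig <- igraph::betweenness(g, directed = FALSE)
  bc <- betweenness_centrality(tr)
  expect_equal(bc[names(ig)], ig, tolerance = 1e-12)
})

test_that("restricted betweenness counts only subset pairs", {
  set.seed(61)
  tr <- simulate_arbor(30, seed = 33, id = "t")
  branch_ids <- tr$nodes$id[vapply(tr$nodes$id, function(id)
    length(emrecon:::tree_children(tr, id)) >= 2, logical(1))]
  bb <- betweenness_centrality(tr, restrict = "branches")
  expect_equal(bb, brute_betweenness(tr, branch_ids))

  tr <- edit_node(tr, 5, add_tags = "synapse")
  tr <- edit_node(tr, 20, add_tags = "presynaptic site")
  bs <- betweenness_centrality(tr, restrict = "synapse_nodes")
  expect_equal(bs, brute_betweenness(tr, c(5L, 20L)))
})

test_that("node_table classes, filters and sorting behave as documented", {
  ls <- flat_layerset()
  tr <- simulate_arbor(30, seed = 3, id = "t")
  tab <- node_table(tr, ls)
  expect_equal(nrow(tab), 30L)
  expect_equal(sum(tab$class == "root"), 1L)
  nchild <- vapply(tab$node, function(id)
    length(emrecon:::tree_children(tr, id)), 0L)
  expect_true(all(tab$class[nchild == 0 & tab$class != "root"] == "end"))
  expect_true(all(tab$class[nchild >= 2] %in% c("branch", "root")))

  tz <- node_table(tr, ls, sort_key = "z")
  expect_true(all(diff(tz$z) >= 0))
  expect_error(node_table(tr, ls, filter_regex = "("), "pattern error")
})

test_that("confidence-threshold filtering is monotone in the threshold", {
  ls <- flat_layerset()
  set.seed(71)
  for (i in 1:5) {
    tr <- simulate_arbor(50, seed = 300 + i, id = "t")
    lens <- vapply(0:5, function(th) cable_length(tr, ls, th), 0)
    expect_true(all(diff(lens) <= 1e-9))
  }
})

test_that("review stacks produce one centred frame per path node", {
  img <- test_image(64, 64, seed = 80)
  ls <- layerset(list(layer(1, 0, 50, list(patch(id = 1, image = img)))))
  tr <- skeleton_tree("t", data.frame(
    id = 1:3, parent = c(NA, 1, 2), x = c(10, 20, 30), y = c(12, 22, 32),
    layer = 1L, confidence = c(NA, 5, 5), radius = 1))
  frames <- review_stack(tr, c(1, 2, 3), ls, fov_size = 16, scale = 1)
  expect_length(frames, 3L)
  for (f in frames) expect_equal(dim(f), c(16L, 16L))
  # frame equals render_region centred on the node's world point
  direct <- render_region(ls, 1, c(20 - 8, 22 - 8, 20 + 8, 22 + 8), 1)
  expect_equal(frames[[2]], direct)

  expect_error(review_stack(tr, integer(0), ls, 16), "empty-input")
  tr2 <- edit_node(tr, 3, radius = 1)
  tr2$nodes$layer[3] <- 9L # missing layer
  expect_warning(f3 <- review_stack(tr2, 3, ls, 16), "missing layer")
  expect_true(all(f3[[1]] == 0))
})

test_that("editing operations always preserve tree validity", {
  set.seed(91)
  for (i in 1:20) {
    tr <- simulate_arbor(sample(2:40, 1), seed = 400 + i, id = "t")
    expect_silent(validate_tree(tr))
  }
})
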