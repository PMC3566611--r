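write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

edge_set <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0) return(character(0))
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

test_that("edge-list reading deduplicates, drops self-loops, flags bad lines", {
  suppressMessages({
    net <- read_edge_list(write_lines_tmp(c("a b", "b a", "a b", "c c")))
  })
  expect_setequal(igraph::V(net)$name, c("a", "b"))
  expect_identical(edge_set(net), "a b")

  empty <- read_edge_list(write_lines_tmp(character(0)))
  expect_equal(igraph::vcount(empty), 0)
  expect_equal(igraph::ecount(empty), 0)

  net2 <- read_edge_list(write_lines_tmp(c("a b", "b c")))
  expect_equal(igraph::vcount(net2), 3)
  expect_equal(igraph::ecount(net2), 2)

  expect_error(read_edge_list(write_lines_tmp(c("a b", "oops"))), "line 2")
  expect_error(read_edge_list(write_lines_tmp(c("a b c"))), "line 1")
})

test_that("edge lists round-trip byte-identically through the writer", {
  net <- interaction_network(rbind(c("z", "a"), c("a", "b"), c("b", "z")))
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_edge_list(net, p1)
  write_edge_list(read_edge_list(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("merging unions node and edge sets", {
  n1 <- interaction_network(rbind(c("a", "b")))
  n2 <- interaction_network(rbind(c("a", "b"), c("b", "c")))
  merged <- merge_networks(list(n1, n2))
  expect_identical(edge_set(merged), c("a b", "b c"))

  expect_identical(edge_set(merge_networks(list(n2))), edge_set(n2))

  singles <- lapply(1:5, function(i) {
    interaction_network(rbind(c(sprintf("x%d", i), sprintf("y%d", i))))
  })
  expect_equal(igraph::ecount(merge_networks(singles)), 5)
  expect_error(merge_networks(list()), "non-empty")
})

test_that("node restriction induces, prunes isolates and is idempotent", {
  path <- interaction_network(rbind(c("a", "b"), c("b", "c")))
  r <- restrict_nodes(path, c("a", "b"))
  expect_setequal(igraph::V(r)$name, c("a", "b"))
  expect_identical(edge_set(r), "a b")

  expect_identical(edge_set(restrict_nodes(path, c("a", "b", "c"))),
                   edge_set(path))
  expect_equal(igraph::vcount(restrict_nodes(path, character(0))), 0)

  # keeping {a, c} severs both edges, so both nodes drop out
  expect_equal(igraph::vcount(restrict_nodes(path, c("a", "c"))), 0)

  set.seed(3)
  rl <- random_labelled_net()
  keep <- sample(igraph::V(rl$net)$name, 15)
  once <- restrict_nodes(rl$net, keep)
  twice <- restrict_nodes(once, keep)
  expect_identical(edge_set(once), edge_set(twice))
  expect_setequal(igraph::V(once)$name, igraph::V(twice)$name)
})

test_that("toy-graph subnetworks match hand enumeration", {
  tg <- toy_graph()
  mm <- subnetwork(tg$net, tg$labels, "M", "M")
  expect_identical(mm$nodes, c("m1", "m2"))
  expect_identical(unname(mm$edges), rbind(c("m1", "m2")))

  mf <- subnetwork(tg$net, tg$labels, "M", "F")
  expect_identical(mf$nodes, "m1")
  expect_identical(unname(mf$edges), rbind(c("f1", "m1")))

  ua <- subnetwork(tg$net, tg$labels, "U", "A")
  expect_identical(ua$nodes, "u1")
  expect_identical(nrow(ua$edges), 2L)

  expect_error(subnetwork(tg$net, tg$labels[-1], "M", "M"), "unlabeled")

  no_m <- subnetwork(tg$net, setNames(rep("U", 4), names(tg$labels)), "M", "M")
  expect_identical(no_m$nodes, character(0))
})

test_that("X-Y and Y-X subnetworks share the same edge set", {
  set.seed(5)
  for (i in 1:10) {
    rl <- random_labelled_net()
    for (X in c("M", "F", "U")) for (Y in c("M", "F", "U", "A")) {
      exy <- subnetwork(rl$net, rl$labels, X, Y)$edges
      eyx <- subnetwork(rl$net, rl$labels, Y, X)$edges
      expect_identical(exy, eyx)
    }
  }
})

test_that("class-pair edge counts partition the total edge count", {
  set.seed(9)
  for (i in 1:10) {
    rl <- random_labelled_net()
    pairs <- list(c("U", "U"), c("U", "F"), c("U", "M"),
                  c("F", "F"), c("F", "M"), c("M", "M"))
    parts <- vapply(pairs, function(p) {
      nrow(subnetwork(rl$net, rl$labels, p[1], p[2])$edges)
    }, numeric(1))
    expect_identical(sum(parts), as.numeric(igraph::ecount(rl$net)))
  }
})

test_that("X-A node counts over a partition cover every non-isolated node", {
  set.seed(13)
  rl <- random_labelled_net()
  n_by_class <- vapply(c("M", "F", "U"), function(X) {
    length(subnetwork(rl$net, rl$labels, X, "A")$nodes)
  }, numeric(1))
  expect_identical(sum(n_by_class), as.numeric(igraph::vcount(rl$net)))
})

test_that("subnetwork summaries use the requested degree convention", {
  # triangle of three same-class nodes
  tri <- interaction_network(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
  lab <- setNames(rep("U", 3), c("a", "b", "c"))
  s <- summarize_subnetwork(tri, lab, "A", "A")
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_edges, 3)
  expect_equal(s$edges_per_node, 1)
  expect_equal(s$mean_degree, 2)
  expect_equal(s$sd_degree, 0)

  tg <- toy_graph()
  s_within <- summarize_subnetwork(tg$net, tg$labels, "M", "M",
                                   degree_mode = "within")
  expect_equal(s_within$mean_degree, 1)
  s_full <- summarize_subnetwork(tg$net, tg$labels, "M", "M",
                                 degree_mode = "full")
  expect_equal(s_full$mean_degree, 2)  # deg(m1)=3, deg(m2)=1

  # within-subnetwork degree of every member node is >= 1
  set.seed(17)
  rl <- random_labelled_net()
  for (X in c("M", "F", "U")) {
    sub <- subnetwork(rl$net, rl$labels, X, "A")
    deg <- sexbiasnet:::subnetwork_degrees(rl$net, sub, "within")
    if (length(deg)) expect_true(all(deg >= 1))
  }
})

test_that("handshake identity holds for the full network summary", {
  set.seed(21)
  for (i in 1:5) {
    rl <- random_labelled_net(n = 40, p = 0.1)
    s <- summarize_subnetwork(rl$net, rl$labels, "A", "A")
    expect_equal(s$mean_degree, 2 * s$n_edges / s$n_nodes)
  }
})

test_that("empty subnetworks summarise to flagged zeros", {
  tg <- toy_graph()
  lab <- setNames(rep("U", 4), names(tg$labels))
  s <- summarize_subnetwork(tg$net, lab, "M", "M")
  expect_equal(s$n_nodes, 0)
  expect_equal(s$n_edges, 0)
  expect_true(is.nan(s$edges_per_node))
})
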