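#' Build an undirected simple interaction network from an edge table
#'
#' All interaction evidence types (protein-protein, TF-target, genetic) are
#' flattened to undirected edges; direction is discarded, reversed
#' duplicates collapse to one edge and self-loops are dropped. The network
#' is held as an undirected simple [igraph::graph] whose vertex names are
#' gene identifiers.
#'
#' @param edges two-column character matrix or data.frame of gene-identifier
#'   pairs (one edge per row).
#' @return An undirected simple `igraph` graph.
#' @export
interaction_network <- function(edges) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (ncol(edges) != 2) stop("`edges` must have exactly two columns")
  storage.mode(edges) <- "character"
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read an interaction network from a two-column edge-list file
#'
#' Each non-empty line names one edge as two whitespace-separated gene
#' identifiers (the dialect of the `ppi_strict.txt` / `ppi_permissive.txt`
#' interactome exports). Duplicate and reversed-duplicate edges collapse to
#' one undirected edge; self-loops are dropped with a message.
#'
#' @param path path to the edge-list file.
#' @return An undirected simple `igraph` graph.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  toks <- strsplit(trimws(lines[nonempty]), "[[:space:]]+")
  bad <- which(lengths(toks) != 2)
  if (length(bad)) {
    stop("malformed edge list ", path, ": line ", nonempty[bad[1]],
         " does not have exactly two fields")
  }
  interaction_network(matrix(unlist(toks), ncol = 2, byrow = TRUE))
}

#' Write a network as a two-column edge list
#'
#' Edges are written with lexicographically smaller endpoint first and rows
#' sorted, so repeated runs produce byte-identical files.
#'
#' @param net an `igraph` network.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el)) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, c(2, 1)]
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(net)
}

#' Union of several interaction networks
#'
#' Used to pool edge-list files into a single evidence set, e.g. six
#' physical-evidence files into a strict network or all available files into
#' a permissive one. Node and edge sets are unioned and deduplicated.
#'
#' @param networks non-empty list of `igraph` networks.
#' @return An undirected simple `igraph` graph.
#' @export
merge_networks <- function(networks) {
  if (!is.list(networks) || length(networks) == 0) {
    stop("`networks` must be a non-empty list of networks")
  }
  els <- lapply(networks, igraph::as_edgelist, names = TRUE)
  all_nodes <- unique(unlist(lapply(networks, function(g) igraph::V(g)$name)))
  g <- interaction_network(do.call(rbind, els))
  iso <- setdiff(all_nodes, igraph::V(g)$name)
  if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)
  g
}

#' Restrict a network to a set of scored genes
#'
#' Induced subgraph on `keep`; nodes left without any surviving edge are
#' removed as well, since a gene enters the analysis network only through an
#' interaction. Idempotent.
#'
#' @param net an `igraph` network.
#' @param keep character vector of gene identifiers to retain (typically the
#'   genes holding a sex-bias value).
#' @return The restricted `igraph` network.
#' @export
restrict_nodes <- function(net, keep) {
  g <- igraph::induced_subgraph(net, intersect(igraph::V(net)$name, keep))
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
}

match_class <- function(lab, cls) {
  if (cls == "A") rep(TRUE, length(lab)) else lab == cls
}

check_labels <- function(net, labels) {
  nodes <- igraph::V(net)$name
  missing <- nodes[!(nodes %in% names(labels))]
  if (length(missing)) {
    stop("unlabeled network nodes: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  }
  labels[nodes]
}

#' Extract the X-Y subnetwork of a labelled network
#'
#' The X-Y subnetwork consists of every class-X node that has at least one
#' class-Y neighbour, together with the unique undirected edges joining a
#' class-X node to a class-Y node. The class code `"A"` matches any label,
#' so `subnetwork(net, labels, "A", "A")` returns the whole network and
#' `subnetwork(net, labels, "M", "A")` all male-biased nodes with any
#' interaction.
#'
#' @param net an `igraph` network (already restricted to scored genes).
#' @param labels named character vector mapping every network node to a
#'   class label (e.g. `"M"`, `"F"`, `"U"`).
#' @param X,Y class codes; `"A"` is a wildcard.
#' @return A list with `nodes` (sorted character vector) and `edges`
#'   (two-column character matrix, smaller endpoint first, rows sorted).
#' @export
subnetwork <- function(net, labels, X, Y) {
  labels <- check_labels(net, labels)
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0) {
    return(list(nodes = character(0),
                edges = matrix(character(0), ncol = 2)))
  }
  l1 <- labels[el[, 1]]
  l2 <- labels[el[, 2]]
  fwd <- match_class(l1, X) & match_class(l2, Y)  # end1 is the X node
  rev <- match_class(l2, X) & match_class(l1, Y)
  nodes <- sort(unique(c(el[fwd, 1], el[rev, 2])))
  edges <- el[fwd | rev, , drop = FALSE]
  if (nrow(edges)) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, c(2, 1)]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  list(nodes = nodes, edges = edges)
}

#' Summarise an X-Y subnetwork
#'
#' Computes the nine per-subnetwork statistics: node count, unique edge
#' count, overall edges-per-node ratio, mean / SD / 25th / 75th percentile
#' of node degree, and the power-law tail exponent with its degree cutoff.
#' Degree statistics are computed under one of two conventions:
#' `"full"` (default) counts each subnetwork node's degree in the whole
#' analysis network, so the all-all row satisfies mean degree = 2E/N;
#' `"within"` counts only the subnetwork's own edges.
#'
#' @inheritParams subnetwork
#' @param degree_mode `"full"` or `"within"`.
#' @param bin_size degree bin width for the tail fit (default 5).
#' @param fit_cutoff lower degree limit for the power-law fit; `NA` skips
#'   the fit.
#' @return A one-row data.frame with columns `network`, `n_nodes`,
#'   `n_edges`, `edges_per_node`, `mean_degree`, `sd_degree`, `p25_degree`,
#'   `p75_degree`, `exponent`, `cutoff`. Empty subnetworks yield zeros with
#'   `NaN` ratio.
#' @export
summarize_subnetwork <- function(net, labels, X, Y,
                                 degree_mode = c("full", "within"),
                                 bin_size = 5, fit_cutoff = NA) {
  degree_mode <- match.arg(degree_mode)
  sub <- subnetwork(net, labels, X, Y)
  n_nodes <- length(sub$nodes)
  n_edges <- nrow(sub$edges)
  deg <- subnetwork_degrees(net, sub, degree_mode)
  exponent <- NA_real_
  if (!is.na(fit_cutoff) && n_nodes > 0) {
    fit <- tryCatch(
      fit_power_law(bin_degrees(deg, bin_size = bin_size), cutoff = fit_cutoff),
      error = function(e) NULL)
    if (!is.null(fit)) exponent <- fit$exponent
  }
  data.frame(
    network = paste0(X, "-", Y),
    n_nodes = n_nodes,
    n_edges = n_edges,
    edges_per_node = if (n_nodes > 0) n_edges / n_nodes else NaN,
    mean_degree = if (n_nodes > 0) mean(deg) else 0,
    sd_degree = if (n_nodes > 1) stats::sd(deg) else 0,
    p25_degree = if (n_nodes > 0) unname(stats::quantile(deg, 0.25)) else 0,
    p75_degree = if (n_nodes > 0) unname(stats::quantile(deg, 0.75)) else 0,
    exponent = exponent,
    cutoff = fit_cutoff,
    stringsAsFactors = FALSE)
}

# Degrees of the subnetwork's nodes, either in the full analysis network or
# counting only subnetwork edges.
subnetwork_degrees <- function(net, sub, degree_mode) {
  if (length(sub$nodes) == 0) return(numeric(0))
  if (degree_mode == "full") {
    unname(igraph::degree(net)[sub$nodes])
  } else {
    counts <- table(factor(c(sub$edges[, 1], sub$edges[, 2]),
                           levels = sub$nodes))
    as.numeric(counts)
  }
}
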