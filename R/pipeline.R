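# The 13 subnetwork codes reported in the summary table, in report order.
TABLE_CODES <- c("A-A", "U-A", "U-U", "U-F", "U-M",
                 "F-A", "F-U", "F-F", "F-M",
                 "M-A", "M-U", "M-F", "M-M")

# Default power-law fit cutoffs per subnetwork (degree units), chosen where
# the empirical strict-network distributions straighten on log-log axes.
default_fit_cutoffs <- function() {
  c("A-A" = 25, "U-A" = 25, "U-U" = 25, "U-F" = 5, "U-M" = 5,
    "F-A" = 25, "F-U" = 20, "F-F" = 10, "F-M" = 5,
    "M-A" = 15, "M-U" = 15, "M-F" = 5, "M-M" = 5)
}

#' Configuration for the full analysis pipeline
#'
#' One pipeline run consumes either a precomputed gene-bias table or a
#' count table plus sample sheet, and one or more named groups of edge-list
#' files (e.g. `strict` = physical-evidence files only, `permissive` = all
#' evidence types). Each group is analysed independently against the shared
#' bias table. Two classification schemes coexist: a four-fold scheme
#' labels the network for the subnetwork summaries, and a stringent 32-fold
#' / two-fold scheme drives conflict detection.
#'
#' @param edge_files named list; each element is a character vector of
#'   edge-list file paths merged into one network.
#' @param bias_path path to a precomputed two-column gene-bias TSV, or
#'   `NULL` to compute from counts.
#' @param counts_path,sample_sheet_path count-table route (used when
#'   `bias_path` is `NULL`).
#' @param out_dir output directory.
#' @param network_scheme [bias_scheme()] for subnetwork labelling.
#' @param conflict_scheme [bias_scheme()] for conflict detection.
#' @param bin_size degree bin width.
#' @param fit_cutoffs named numeric vector of per-subnetwork power-law
#'   cutoffs (names over `TABLE_CODES`); defaults to
#'   `default_fit_cutoffs()`.
#' @param degree_mode `"full"` or `"within"` degree convention for the
#'   summary statistics.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(edge_files, bias_path = NULL,
                            counts_path = NULL, sample_sheet_path = NULL,
                            out_dir = "sexbiasnet_out",
                            network_scheme = bias_scheme(2),
                            conflict_scheme = bias_scheme(5, 1),
                            bin_size = 5,
                            fit_cutoffs = default_fit_cutoffs(),
                            degree_mode = c("full", "within")) {
  degree_mode <- match.arg(degree_mode)
  if (!is.list(edge_files) || length(edge_files) == 0 ||
      is.null(names(edge_files)) || any(!nzchar(names(edge_files)))) {
    stop("`edge_files` must be a non-empty named list of file-path vectors")
  }
  if (is.null(bias_path) && (is.null(counts_path) || is.null(sample_sheet_path))) {
    stop("provide either `bias_path` or both `counts_path` and `sample_sheet_path`")
  }
  cutoffs <- default_fit_cutoffs()
  cutoffs[names(fit_cutoffs)] <- fit_cutoffs
  if (any(cutoffs < 1)) stop("fit cutoffs must be >= 1")
  structure(list(edge_files = edge_files, bias_path = bias_path,
                 counts_path = counts_path,
                 sample_sheet_path = sample_sheet_path,
                 out_dir = out_dir,
                 network_scheme = network_scheme,
                 conflict_scheme = conflict_scheme,
                 bin_size = bin_size, fit_cutoffs = cutoffs,
                 degree_mode = degree_mode),
            class = "pipeline_config")
}

#' Run the full sex-bias network analysis
#'
#' Stages: load or compute the gene-bias table; for every edge-file group,
#' merge its edge lists, restrict the network to scored genes, label nodes
#' under the four-fold scheme, write the 13-row subnetwork summary and
#' degree-distribution TSVs, and detect indirect and direct conflict under
#' the stringent scheme. A JSON manifest records the configuration, the
#' gene funnel (scored genes, nodes before/after restriction) and package
#' versions. All outputs are sorted, so reruns on identical inputs are
#' byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the bias table and, per group, the
#'   restricted network, summary table and conflict report.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (p in c(cfg$bias_path, cfg$counts_path, cfg$sample_sheet_path,
              unlist(cfg$edge_files))) {
    if (!file.exists(p)) stop("input not found: ", p)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$bias_path)) {
    bias <- read_bias_table(cfg$bias_path)
    n_discarded <- NA_integer_
  } else {
    res <- compute_bias_table(read_expression(cfg$counts_path,
                                              cfg$sample_sheet_path))
    bias <- res$bias
    n_discarded <- res$intermediates$n_discarded
    write_bias_table(bias, file.path(cfg$out_dir, "gene_bias.txt"))
  }
  message(nrow(bias), " genes with a sex-bias value",
          if (!is.na(n_discarded)) sprintf(" (%d all-zero genes discarded)",
                                           n_discarded))

  groups <- list()
  manifest_groups <- list()
  for (grp in names(cfg$edge_files)) {
    net0 <- merge_networks(lapply(cfg$edge_files[[grp]], read_edge_list))
    net <- restrict_nodes(net0, bias$gene)
    message(sprintf(
      "[%s] %d nodes / %d edges merged; %d nodes / %d edges after restriction to scored genes",
      grp, igraph::vcount(net0), igraph::ecount(net0),
      igraph::vcount(net), igraph::ecount(net)))

    b <- bias_lookup(bias)[igraph::V(net)$name]
    labels <- c(male = "M", female = "F", unbiased = "U",
                unclassified = "X")[classify_bias(b, cfg$network_scheme)]
    names(labels) <- igraph::V(net)$name

    summary_tab <- summarize_all_subnetworks(
      net, labels, degree_mode = cfg$degree_mode, bin_size = cfg$bin_size,
      fit_cutoffs = cfg$fit_cutoffs)
    write_table1_summary(summary_tab,
                         file.path(cfg$out_dir, sprintf("summary_%s.tsv", grp)),
                         degree_mode = cfg$degree_mode)

    for (code in c("A-A", "U-U", "F-F", "M-M")) {
      xy <- strsplit(code, "-")[[1]]
      sub <- subnetwork(net, labels, xy[1], xy[2])
      deg <- subnetwork_degrees(net, sub, cfg$degree_mode)
      if (length(deg)) {
        write_degree_distribution(
          bin_degrees(deg, bin_size = cfg$bin_size),
          file.path(cfg$out_dir, sprintf("degree_%s_%s.tsv", code, grp)))
      }
    }

    report <- conflict_report(net, bias, cfg$conflict_scheme)
    write_conflict_report(report, cfg$out_dir, tag = grp)

    groups[[grp]] <- list(network = net, summary = summary_tab,
                          conflict = report)
    manifest_groups[[grp]] <- list(
      edge_files = cfg$edge_files[[grp]],
      nodes_merged = igraph::vcount(net0), edges_merged = igraph::ecount(net0),
      nodes_restricted = igraph::vcount(net),
      edges_restricted = igraph::ecount(net),
      indirect = length(report$indirect),
      direct_pairs = nrow(report$direct_pairs))
  }

  manifest <- list(
    package = "sexbiasnet",
    version = as.character(utils::packageVersion("sexbiasnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = list(
      bias_path = cfg$bias_path, counts_path = cfg$counts_path,
      network_scheme = unclass(cfg$network_scheme),
      conflict_scheme = unclass(cfg$conflict_scheme),
      bin_size = cfg$bin_size, degree_mode = cfg$degree_mode,
      fit_cutoffs = as.list(cfg$fit_cutoffs)),
    n_bias_genes = nrow(bias),
    n_discarded = n_discarded,
    groups = manifest_groups)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(bias = bias, groups = groups))
}

#' Summarise all 13 sex-classed subnetworks
#'
#' @inheritParams summarize_subnetwork
#' @param fit_cutoffs named numeric vector of power-law cutoffs per code.
#' @return A 13-row data.frame, one [summarize_subnetwork()] row per code.
#' @export
summarize_all_subnetworks <- function(net, labels,
                                      degree_mode = c("full", "within"),
                                      bin_size = 5,
                                      fit_cutoffs = default_fit_cutoffs()) {
  degree_mode <- match.arg(degree_mode)
  rows <- lapply(TABLE_CODES, function(code) {
    xy <- strsplit(code, "-")[[1]]
    summarize_subnetwork(net, labels, xy[1], xy[2], degree_mode = degree_mode,
                         bin_size = bin_size,
                         fit_cutoff = unname(fit_cutoffs[code]))
  })
  do.call(rbind, rows)
}

#' Write / read the 13-row subnetwork summary table
#'
#' TSV with one row per subnetwork code and the nine summary statistics;
#' a leading comment line records the degree convention used.
#'
#' @param summaries data.frame from [summarize_all_subnetworks()]; all 13
#'   codes must be present.
#' @param path output path.
#' @param degree_mode degree convention recorded in the header.
#' @export
write_table1_summary <- function(summaries, path, degree_mode = "full") {
  missing <- setdiff(TABLE_CODES, summaries$network)
  if (length(missing)) {
    stop("missing subnetwork codes: ", paste(missing, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# degree_mode=%s", degree_mode), con)
  utils::write.table(summaries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(summaries)
}

#' @rdname write_table1_summary
#' @export
read_table1_summary <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
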