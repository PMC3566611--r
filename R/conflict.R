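#' Indirect conflict nodes: sex-unbiased genes bridging both sexes
#'
#' A sex-unbiased gene whose interaction partners include at least one
#' strongly male-biased and at least one strongly female-biased gene sits at
#' a potential node of interlocus sexual conflict: selection acting through
#' its male- and female-side partners can pull the shared locus in opposing
#' directions. Under the default stringent scheme a partner counts as
#' strongly biased only beyond a 32-fold expression difference
#' (`|b| > 5`) while the focal gene must be within two-fold (`|b| <= 1`).
#'
#' @param net an `igraph` network restricted to genes with bias values.
#' @param bias a `sex_bias_table` data.frame (columns `gene`, `bias`)
#'   covering every network node.
#' @param scheme a [bias_scheme()]; default `bias_scheme(5, 1)`.
#' @return Sorted character vector of indirect conflict gene identifiers.
#' @export
find_indirect <- function(net, bias, scheme = bias_scheme(5, 1)) {
  stopifnot(inherits(scheme, "bias_scheme"))
  b <- check_bias_cover(net, bias)
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0) return(character(0))
  b1 <- b[el[, 1]]
  b2 <- b[el[, 2]]
  tb <- scheme$biased_cutoff
  tu <- scheme$unbiased_cutoff
  # neighbours of each unbiased endpoint, split by partner class
  unb1 <- abs(b1) <= tu
  unb2 <- abs(b2) <= tu
  with_male <- unique(c(el[unb1 & b2 > tb, 1], el[unb2 & b1 > tb, 2]))
  with_female <- unique(c(el[unb1 & b2 < -tb, 1], el[unb2 & b1 < -tb, 2]))
  sort(intersect(with_male, with_female))
}

#' Direct conflict pairs: edges joining strongly male- and female-biased genes
#'
#' Every undirected edge whose endpoints are a strongly male-biased gene
#' (`b > biased_cutoff`) and a strongly female-biased gene
#' (`b < -biased_cutoff`) is a candidate pair of direct interlocus conflict.
#'
#' @inheritParams find_indirect
#' @return A data.frame with columns `male` and `female` (one row per
#'   qualifying edge), sorted lexicographically.
#' @export
find_direct <- function(net, bias, scheme = bias_scheme(5, 1)) {
  stopifnot(inherits(scheme, "bias_scheme"))
  b <- check_bias_cover(net, bias)
  el <- igraph::as_edgelist(net, names = TRUE)
  tb <- scheme$biased_cutoff
  empty <- data.frame(male = character(0), female = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(el) == 0) return(empty)
  b1 <- b[el[, 1]]
  b2 <- b[el[, 2]]
  mf <- b1 > tb & b2 < -tb
  fm <- b2 > tb & b1 < -tb
  pairs <- rbind(
    data.frame(male = el[mf, 1], female = el[mf, 2], stringsAsFactors = FALSE),
    data.frame(male = el[fm, 2], female = el[fm, 1], stringsAsFactors = FALSE))
  pairs <- unique(pairs)
  pairs[order(pairs$male, pairs$female), , drop = FALSE]
}

check_bias_cover <- function(net, bias) {
  b <- bias_lookup(bias)
  nodes <- igraph::V(net)$name
  missing <- nodes[!(nodes %in% names(b))]
  if (length(missing)) {
    stop("network nodes without a bias value: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  }
  b[nodes]
}

#' Full conflict report for a network and bias table
#'
#' Runs [find_indirect()] and [find_direct()] and packages the results with
#' the per-side projections of the direct pairs. The pair count and the
#' per-side gene counts generally differ (one male gene can oppose several
#' female genes), so both are carried.
#'
#' @inheritParams find_indirect
#' @return An object of class `conflict_report`: list with `scheme`,
#'   `indirect` (sorted gene IDs), `direct_pairs` (data.frame `male`,
#'   `female`), `direct_male`, `direct_female` (sorted projections).
#' @export
conflict_report <- function(net, bias, scheme = bias_scheme(5, 1)) {
  pairs <- find_direct(net, bias, scheme)
  structure(list(
    scheme = scheme,
    indirect = find_indirect(net, bias, scheme),
    direct_pairs = pairs,
    direct_male = sort(unique(pairs$male)),
    direct_female = sort(unique(pairs$female))),
    class = "conflict_report")
}

#' @export
print.conflict_report <- function(x, ...) {
  cat(sprintf(paste0(
    "conflict_report (biased |b| > %g, unbiased |b| <= %g):\n",
    "  indirect conflict genes : %d\n",
    "  direct conflict pairs   : %d (%d male / %d female genes)\n"),
    x$scheme$biased_cutoff, x$scheme$unbiased_cutoff,
    length(x$indirect), nrow(x$direct_pairs),
    length(x$direct_male), length(x$direct_female)))
  invisible(x)
}

#' Write a conflict report as plain-text gene lists
#'
#' Emits `indirect_sexconflict_<tag>.txt`, `direct_sexconflict_m_<tag>.txt`
#' and `direct_sexconflict_f_<tag>.txt` (one gene identifier per line,
#' sorted) plus `direct_pairs_<tag>.txt` (two-column male/female TSV).
#'
#' @param report a [conflict_report()].
#' @param dir output directory (created if absent).
#' @param tag file-name tag, e.g. `"strict"` or `"permissive"`.
#' @return Invisibly, the written file paths.
#' @export
write_conflict_report <- function(report, dir, tag = "strict") {
  stopifnot(inherits(report, "conflict_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    indirect = file.path(dir, sprintf("indirect_sexconflict_%s.txt", tag)),
    direct_m = file.path(dir, sprintf("direct_sexconflict_m_%s.txt", tag)),
    direct_f = file.path(dir, sprintf("direct_sexconflict_f_%s.txt", tag)),
    pairs = file.path(dir, sprintf("direct_pairs_%s.txt", tag)))
  writeLines(report$indirect, paths["indirect"])
  writeLines(report$direct_male, paths["direct_m"])
  writeLines(report$direct_female, paths["direct_f"])
  utils::write.table(report$direct_pairs, paths["pairs"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
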