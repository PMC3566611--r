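#' Hypergeometric probability mass
#'
#' Probability of drawing exactly `k` marked elements when `n` elements are
#' drawn without replacement from a universe of `N` containing `K` marked
#' ones. Thin validated wrapper over [stats::dhyper()] (log-space
#' internals); out-of-support `k` returns 0.
#'
#' @param N universe size.
#' @param K number of marked elements.
#' @param n draw size.
#' @param k observed number of marked draws (vectorised).
#' @return Probability (numeric vector along `k`).
#' @export
#' @examples
#' hypergeom_pmf(4, 2, 2, 1)  # 2/3
hypergeom_pmf <- function(N, K, n, k) {
  if (any(c(N, K, n) < 0) || K > N || n > N ||
      any(c(N, K, n) != floor(c(N, K, n)))) {
    stop("invalid hypergeometric parameters: need 0 <= K, n <= N (integers)")
  }
  stats::dhyper(k, m = K, n = N - K, k = n)
}

#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether the intersection of two gene sets is larger (enrichment)
#' or smaller (depletion) than expected when both are drawn independently
#' from a shared finite universe. The enrichment tail is `P[X >= k]`, the
#' depletion tail `P[X <= k]`, and the two-tailed value is twice the
#' smaller tail capped at 1. Used e.g. to compare conflict-candidate lists
#' against an external screen, where a significantly *small* overlap
#' (depletion) is itself informative.
#'
#' @param setA,setB character vectors (duplicates ignored); must be subsets
#'   of `universe`.
#' @param universe character vector of all genes eligible for both sets,
#'   e.g. every gene in the analysis network.
#' @return A list of class `overlap_test`: `universe_size`, `size_a`,
#'   `size_b`, `overlap`, `p_enrich`, `p_deplete`, `p_two_tailed`.
#' @export
#' @examples
#' overlap_test(letters[1:8], letters[5:9], letters)
overlap_test <- function(setA, setB, universe) {
  universe <- unique(as.character(universe))
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  outside <- c(setdiff(setA, universe), setdiff(setB, universe))
  if (length(outside)) {
    stop("set elements outside the universe: ",
         paste(utils::head(outside, 10), collapse = ", "))
  }
  N <- length(universe)
  K <- length(setA)
  n <- length(setB)
  k <- length(intersect(setA, setB))
  p_enrich <- stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  p_deplete <- stats::phyper(k, m = K, n = N - K, k = n, lower.tail = TRUE)
  structure(list(universe_size = N, size_a = K, size_b = n, overlap = k,
                 p_enrich = p_enrich, p_deplete = p_deplete,
                 p_two_tailed = min(1, 2 * min(p_enrich, p_deplete))),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(paste0(
    "hypergeometric overlap test: |A|=%d, |B|=%d, overlap=%d, universe=%d\n",
    "  P[enrich] = %.4g, P[deplete] = %.4g, two-tailed = %.4g\n"),
    x$size_a, x$size_b, x$overlap, x$universe_size,
    x$p_enrich, x$p_deplete, x$p_two_tailed))
  invisible(x)
}

#' Write an overlap test result as a one-row TSV
#'
#' @param x an [overlap_test()] result.
#' @param path output path.
#' @export
write_overlap_test <- function(x, path) {
  stopifnot(inherits(x, "overlap_test"))
  utils::write.table(as.data.frame(unclass(x)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Kendall rank concordance between two sex-bias tables
#'
#' Tie-corrected Kendall tau (tau-b) over the genes shared by both tables,
#' used to gauge agreement between two independent sex-bias estimates
#' (e.g. this pipeline's statistic versus a meta-analysis database).
#'
#' @param bias1,bias2 `sex_bias_table` data.frames (columns `gene`, `bias`).
#' @return A list with `tau`, `n_shared`.
#' @export
kendall_tau <- function(bias1, bias2) {
  b1 <- bias_lookup(bias1)
  b2 <- bias_lookup(bias2)
  shared <- intersect(names(b1), names(b2))
  if (length(shared) < 2) {
    stop("insufficient data: need >= 2 shared genes, have ", length(shared))
  }
  list(tau = stats::cor(b1[shared], b2[shared], method = "kendall"),
       n_shared = length(shared))
}
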