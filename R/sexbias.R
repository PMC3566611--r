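#' Classification scheme for sex-bias values
#'
#' Genes are labelled by their capped log2 sex-bias `b`:
#' `b > biased_cutoff` is male-biased, `b < -biased_cutoff` female-biased,
#' `|b| <= unbiased_cutoff` sex-unbiased, and anything between the two
#' cutoffs is `unclassified`. The whole-network classification uses a
#' four-fold window (`biased_cutoff = 2`, `unbiased_cutoff = 2`, so every
#' gene gets a label); conflict detection uses the far more stringent
#' 32-fold rule with a two-fold unbiased window
#' (`biased_cutoff = 5`, `unbiased_cutoff = 1`), which leaves genes with
#' intermediate bias unclassified on purpose.
#'
#' @param biased_cutoff positive log2 threshold above which a gene counts as
#'   sex-biased (2 = four-fold, 5 = 32-fold). Strict inequality.
#' @param unbiased_cutoff log2 threshold at or below which `|b|` counts as
#'   unbiased (inclusive). Must not exceed `biased_cutoff`. Defaults to
#'   `biased_cutoff`.
#' @return An object of class `bias_scheme`.
#' @export
#' @examples
#' bias_scheme(2)        # network classification, no unclassified gap
#' bias_scheme(5, 1)     # conflict detection, stringent
bias_scheme <- function(biased_cutoff = 2, unbiased_cutoff = biased_cutoff) {
  if (!is.numeric(biased_cutoff) || length(biased_cutoff) != 1 || biased_cutoff <= 0) {
    stop("`biased_cutoff` must be a single positive number")
  }
  if (!is.numeric(unbiased_cutoff) || length(unbiased_cutoff) != 1 ||
      unbiased_cutoff > biased_cutoff) {
    stop("`unbiased_cutoff` must be a single number <= `biased_cutoff`")
  }
  structure(list(biased_cutoff = biased_cutoff, unbiased_cutoff = unbiased_cutoff),
            class = "bias_scheme")
}

#' @export
print.bias_scheme <- function(x, ...) {
  cat(sprintf("bias_scheme: biased |b| > %g, unbiased |b| <= %g\n",
              x$biased_cutoff, x$unbiased_cutoff))
  invisible(x)
}

#' Global average read bias between the sexes
#'
#' `B = log2(Nhat_m / Nhat_f)`, where `Nhat` is a sex's total read depth
#' divided by its number of samples. `B` absorbs systematic depth
#' differences between the male and female libraries so that per-gene bias
#' values are centred on zero for equally expressed genes.
#'
#' @param expr an [expression_matrix()].
#' @return A single number, in log2 units.
#' @export
global_read_bias <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  tot <- vapply(c("male", "female"), function(s) {
    cols <- expr$sample_sex == s
    sum(expr$counts[, cols, drop = FALSE])
  }, numeric(1))
  if (any(tot == 0)) {
    stop("global read bias undefined: zero total depth in the ",
         paste(names(tot)[tot == 0], collapse = " and "), " samples")
  }
  k <- c(male = sum(expr$sample_sex == "male"),
         female = sum(expr$sample_sex == "female"))
  log2((tot["male"] / k["male"]) / (tot["female"] / k["female"]))[[1]]
}

# Depth-weighted per-gene means for one sex: w_i = N_i / N within the sex,
# Nbar_g = sum_i w_i N_ig. Deeper samples get proportionally more weight.
sex_weighted_means <- function(counts, cols) {
  sub <- counts[, cols, drop = FALSE]
  Ni <- colSums(sub)
  N <- sum(Ni)
  if (N == 0) {
    return(list(w = rep(NA_real_, ncol(sub)), nbar = rep(0, nrow(sub)),
                nhat = 0, n_total = 0))
  }
  w <- Ni / N
  list(w = w, nbar = as.vector(sub %*% w), nhat = N / ncol(sub), n_total = N)
}

#' Compute the capped log2 sex-bias statistic for every expressed gene
#'
#' For each gene `g`, `b_g = log2(Nbar_g_male / Nbar_g_female) - B`, where
#' `Nbar_g` is the depth-weighted mean read depth of the gene within a sex
#' (weights `w_i = N_i / N` computed over that sex's samples) and `B` is the
#' global read bias from [global_read_bias()]. Final values are capped to
#' `[-10, 10]` (beyond a 1000-fold difference), which also maps genes
#' expressed in only one sex to the cap with the sign of the expressed sex.
#' Genes with zero depth in every sample are discarded.
#'
#' @param expr an [expression_matrix()].
#' @param cap positive cap on `|b|` in log2 units; default 10.
#' @return A list with class `bias_result`:
#' \describe{
#'   \item{bias}{data.frame with columns `gene`, `bias` (class
#'     `sex_bias_table`), one row per gene with any nonzero count, in the
#'     input gene order.}
#'   \item{intermediates}{per-sex weights, weighted gene means, per-sample
#'     average totals and the global read bias `B`.}
#' }
#' @export
#' @examples
#' m <- matrix(c(10, 60, 5, 5), nrow = 1,
#'             dimnames = list("gA", c("m1", "m2", "f1", "f2")))
#' m <- rbind(m, gZ = 0)
#' res <- compute_bias_table(expression_matrix(
#'   m, c("male", "male", "female", "female")))
#' res$bias    # gZ discarded; gA bias reflects depth-weighted means
compute_bias_table <- function(expr, cap = 10) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0) {
    stop("`cap` must be a single positive number")
  }
  counts <- expr$counts
  keep <- rowSums(counts) > 0
  B <- global_read_bias(expr)  # errors if either sex has zero total depth

  male <- sex_weighted_means(counts, expr$sample_sex == "male")
  female <- sex_weighted_means(counts, expr$sample_sex == "female")

  ratio <- male$nbar[keep] / female$nbar[keep]  # 0 or Inf when one sex silent
  b <- log2(ratio) - B
  b <- pmin(pmax(b, -cap), cap)

  bias <- data.frame(gene = rownames(counts)[keep], bias = b,
                     stringsAsFactors = FALSE, row.names = NULL)
  class(bias) <- c("sex_bias_table", "data.frame")
  intermediates <- list(
    weights = list(male = male$w, female = female$w),
    weighted_means = list(male = male$nbar, female = female$nbar),
    avg_totals = c(male = male$nhat, female = female$nhat),
    global_read_bias = B,
    n_discarded = sum(!keep))
  structure(list(bias = bias, intermediates = intermediates),
            class = "bias_result")
}

#' Classify sex-bias values under a scheme
#'
#' @param b numeric vector of (capped) log2 sex-bias values.
#' @param scheme a [bias_scheme()].
#' @return Character vector over `"male"`, `"female"`, `"unbiased"`,
#'   `"unclassified"`. Boundary values `|b| = biased_cutoff` are not biased
#'   (strict inequality); `|b| = unbiased_cutoff` is unbiased (inclusive).
#' @export
#' @examples
#' classify_bias(c(2.5, 2, 0, -3), bias_scheme(2))
#' classify_bias(3, bias_scheme(5, 1))  # neither 32-fold nor < two-fold
classify_bias <- function(b, scheme = bias_scheme()) {
  stopifnot(inherits(scheme, "bias_scheme"))
  if (!is.numeric(b)) stop("`b` must be numeric")
  if (any(!is.finite(b))) stop("`b` must be finite (cap bias values upstream)")
  out <- rep("unclassified", length(b))
  out[b > scheme$biased_cutoff] <- "male"
  out[b < -scheme$biased_cutoff] <- "female"
  out[abs(b) <= scheme$unbiased_cutoff] <- "unbiased"
  names(out) <- names(b)
  out
}

#' Read / write a two-column gene-bias table
#'
#' Plain TSV dialect `gene<TAB>bias`, one row per gene with nonzero
#' expression, no header.
#'
#' @param path file path.
#' @return `read_bias_table()` returns a `sex_bias_table` data.frame with
#'   columns `gene` and `bias`.
#' @export
read_bias_table <- function(path) {
  if (!file.exists(path)) stop("bias table not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("gene", "bias"),
                           colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$gene)) stop("duplicate gene identifiers in ", path)
  class(tab) <- c("sex_bias_table", "data.frame")
  tab
}

#' @param bias a `sex_bias_table` data.frame (columns `gene`, `bias`).
#' @rdname read_bias_table
#' @export
write_bias_table <- function(bias, path) {
  stopifnot(is.data.frame(bias), all(c("gene", "bias") %in% names(bias)))
  utils::write.table(bias[, c("gene", "bias")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(bias)
}

# Named numeric lookup vector from a sex_bias_table.
bias_lookup <- function(bias) {
  stopifnot(is.data.frame(bias), all(c("gene", "bias") %in% names(bias)))
  stats::setNames(bias$bias, bias$gene)
}
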