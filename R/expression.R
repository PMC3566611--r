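#' Per-gene, per-sample read-depth matrix with sample sex labels
#'
#' Container for whole-body RNA-seq read depths quantified per gene (rows)
#' and sample (columns), together with a male/female label for every sample.
#' Counts are accepted as non-negative reals: coverage estimators may return
#' fractional depths, so integrality is not enforced.
#'
#' @param counts numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene identifiers) and colnames (sample identifiers). All
#'   entries must be finite and >= 0.
#' @param sample_sex character vector of `"male"`/`"female"`, one per column
#'   of `counts`. May be named by sample identifier; if named, names must
#'   match `colnames(counts)` (order is taken from the matrix).
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `counts` (the validated matrix) and `sample_sex` (named character
#'   vector aligned to the columns).
#' @export
#' @examples
#' m <- matrix(c(10, 0, 60, 0, 5, 0, 5, 0), nrow = 2,
#'             dimnames = list(c("gA", "gB"), c("m1", "m2", "f1", "f2")))
#' expression_matrix(m, c("male", "male", "female", "female"))
expression_matrix <- function(counts, sample_sex) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene identifiers as rownames and sample identifiers as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers in `counts`")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample identifiers in `counts`")
  if (any(!is.finite(counts))) stop("`counts` contains non-finite values")
  if (any(counts < 0)) stop("`counts` contains negative values")

  sample_sex <- as.character(sample_sex)
  if (length(sample_sex) != ncol(counts)) {
    stop("`sample_sex` must have one label per sample column")
  }
  if (!all(sample_sex %in% c("male", "female"))) {
    stop("`sample_sex` labels must be 'male' or 'female'")
  }
  nm <- names(sample_sex)
  if (!is.null(nm)) {
    if (!setequal(nm, colnames(counts))) {
      stop("names of `sample_sex` do not match the sample columns")
    }
    sample_sex <- sample_sex[colnames(counts)]
  }
  names(sample_sex) <- colnames(counts)
  for (s in c("male", "female")) {
    if (!any(sample_sex == s)) stop("at least one ", s, " sample is required")
  }
  structure(list(counts = counts, sample_sex = sample_sex),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d male, %d female)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$sample_sex == "male"), sum(x$sample_sex == "female")))
  invisible(x)
}

#' Read a count table and its sample sheet
#'
#' The count table is a TSV whose first column holds gene identifiers and
#' whose remaining columns hold per-sample read depths. The sample sheet is
#' a two-column TSV (`sample_id`, `sex`) with `sex` in `male`/`female`; a
#' header row is detected and skipped if present.
#'
#' @param counts_path path to the count TSV.
#' @param sample_sheet_path path to the sample-sheet TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(counts_path, sample_sheet_path) {
  if (!file.exists(counts_path)) stop("count table not found: ", counts_path)
  if (!file.exists(sample_sheet_path)) stop("sample sheet not found: ", sample_sheet_path)
  tab <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes

  sheet <- utils::read.table(sample_sheet_path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (ncol(sheet) < 2) stop("sample sheet must have two columns: sample_id, sex")
  if (nrow(sheet) > 0 && !(sheet[1, 2] %in% c("male", "female"))) {
    sheet <- sheet[-1, , drop = FALSE]  # header row
  }
  sex <- stats::setNames(as.character(sheet[[2]]), as.character(sheet[[1]]))
  missing <- setdiff(colnames(m), names(sex))
  if (length(missing)) {
    stop("samples missing from the sample sheet: ", paste(missing, collapse = ", "))
  }
  expression_matrix(m, sex[colnames(m)])
}

#' Write a count table and sample sheet
#'
#' Inverse of [read_expression()]; both files are plain TSV.
#'
#' @param expr an [expression_matrix()].
#' @param counts_path,sample_sheet_path output paths.
#' @return Invisibly, `expr`.
#' @export
write_expression <- function(expr, counts_path, sample_sheet_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene = rownames(expr$counts), expr$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(expr$sample_sex), sex = unname(expr$sample_sex)),
    sample_sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr)
}
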