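#' Bin a degree sequence into fixed-width bins
#'
#' Degrees are binned into contiguous windows `[1, s]`, `[s+1, 2s]`, ...
#' for bin width `s` (counts unnormalised). Degrees below `min_degree` are
#' discarded before binning, and bins outside the occupied range are
#' trimmed; interior empty bins are kept so the grid stays contiguous.
#' The bin representative used downstream is the arithmetic midpoint
#' (e.g. 3 for `[1, 5]`).
#'
#' @param degrees vector of positive integer node degrees.
#' @param bin_size bin width in degree units (default 5).
#' @param min_degree discard degrees below this value before binning.
#' @return A data.frame of class `degree_distribution` with columns
#'   `lower`, `upper`, `count`, `midpoint`, and attributes `bin_size` and
#'   `total_nodes` (the number of retained degrees).
#' @export
#' @examples
#' bin_degrees(c(1, 1, 2, 6, 11), bin_size = 5)
bin_degrees <- function(degrees, bin_size = 5, min_degree = 1) {
  if (!is.numeric(degrees)) stop("`degrees` must be numeric")
  if (length(degrees) && any(degrees < 1 | degrees != floor(degrees))) {
    stop("`degrees` must be positive integers")
  }
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size < 1) {
    stop("`bin_size` must be a single integer >= 1")
  }
  d <- degrees[degrees >= min_degree]
  if (length(d) == 0) {
    stop("no degrees remain at or above min_degree = ", min_degree)
  }
  idx <- floor((d - 1) / bin_size)  # 0-based bin index on the 1-anchored grid
  rng <- range(idx)
  counts <- tabulate(idx - rng[1] + 1, nbins = rng[2] - rng[1] + 1)
  lower <- (rng[1]:rng[2]) * bin_size + 1
  out <- data.frame(lower = lower, upper = lower + bin_size - 1,
                    count = counts, midpoint = lower + (bin_size - 1) / 2)
  attr(out, "bin_size") <- bin_size
  attr(out, "total_nodes") <- length(d)
  class(out) <- c("degree_distribution", "data.frame")
  out
}

#' Fit a power law to the tail of a binned degree distribution
#'
#' Interaction-network degree distributions typically follow a power law
#' only in their high-degree tail, so the fit uses a lower degree cutoff:
#' only bins whose lower edge is at or above `cutoff` and whose count is
#' nonzero enter an ordinary least-squares regression of `log10(count)` on
#' `log10(midpoint)`. The slope is the reported exponent (base-invariant
#' since both axes share the base).
#'
#' @param dist a [bin_degrees()] result.
#' @param cutoff lower degree limit (>= 1); bins starting below it are
#'   excluded. Cutoffs are chosen per subnetwork, typically by inspecting
#'   where the empirical distribution straightens on log-log axes.
#' @return A list of class `power_law_fit` with `exponent` (slope),
#'   `cutoff`, `n_bins_used`, and `goodness` (R^2 of the log-log fit).
#' @export
#' @examples
#' d <- bin_degrees(rep(c(3, 8, 13, 18), c(1000, 125, 37, 15)))
#' fit_power_law(d, cutoff = 1)
fit_power_law <- function(dist, cutoff = 1) {
  stopifnot(inherits(dist, "degree_distribution"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 1) {
    stop("`cutoff` must be a single number >= 1")
  }
  use <- dist$count > 0 & dist$lower >= cutoff
  if (sum(use) < 3) {
    stop("insufficient data: need >= 3 nonzero bins at or above the cutoff, have ",
         sum(use))
  }
  x <- log10(dist$midpoint[use])
  y <- log10(dist$count[use])
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 cutoff = cutoff,
                 n_bins_used = sum(use),
                 goodness = r2),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law tail fit: exponent %.3f (cutoff %g, %d bins, R^2 %.3f)\n",
              x$exponent, x$cutoff, x$n_bins_used, x$goodness))
  invisible(x)
}

#' Write a binned degree distribution as TSV
#'
#' Columns `bin_lower`, `bin_upper`, `count`.
#'
#' @param dist a [bin_degrees()] result.
#' @param path output path.
#' @export
write_degree_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "degree_distribution"))
  utils::write.table(
    data.frame(bin_lower = dist$lower, bin_upper = dist$upper,
               count = dist$count),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dist)
}
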