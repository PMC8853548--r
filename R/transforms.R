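#' Replace zeros with a multiplicative pseudocount
#'
#' Zeros in a relative-abundance table are replaced by
#' `factor` times the smallest non-zero value of the whole table, after which
#' rows are re-closed to sum 1. The default factor of 0.65 is the standard
#' multiplicative zero-replacement constant for compositional microbiome
#' data. The minimum is global over the table so the replacement value is
#' common across samples.
#'
#' @param table A `feature_table` with space `relative`.
#' @param factor Positive multiplier of the minimum non-zero value
#'   (default 0.65).
#' @return A strictly positive `feature_table` with space `relative`; the
#'   pseudocount actually used is recorded in the transform log and in
#'   attribute `pseudocount`.
#' @export
add_pseudocount <- function(table, factor = 0.65) {
  if (factor <= 0) stop("`factor` must be positive")
  if (table$space != "relative")
    stop("add_pseudocount requires space 'relative'; call closure() first")
  m <- table$values
  nz <- m[m > 0]
  if (!length(nz)) stop("table has no positive values")
  pc <- factor * min(nz)
  m[m == 0] <- pc
  m <- m / rowSums(m)
  out <- ft_update(table, m, space = "relative",
                   log_entry = sprintf("add_pseudocount(factor=%g, value=%g)",
                                       factor, pc))
  attr(out, "pseudocount") <- pc
  out
}

#' Centered log-ratio transform
#'
#' Maps each composition x to `log(x_i / G(x))` with `G(x)` the row geometric
#' mean, using natural logarithms. Every output row sums to zero; the
#' transform removes any per-sample multiplicative factor, which is what
#' makes study-specific multiplicative bias visible to PCA as an additive
#' shift.
#'
#' @param table A strictly positive `feature_table` (space `relative` after
#'   [add_pseudocount()], or `generic`).
#' @return A `feature_table` with space `clr`.
#' @export
clr_transform <- function(table) {
  m <- table$values
  if (any(m <= 0))
    stop("clr_transform requires strictly positive values; ",
         "call add_pseudocount() to replace zeros")
  lm <- log(m)
  out <- lm - rowMeans(lm)
  ft_update(table, out, space = "clr", log_entry = "clr")
}

#' Inverse centered log-ratio transform
#'
#' Softmax per row: `exp(y_i) / sum_j exp(y_j)`. The row maximum is
#' subtracted before exponentiation to guard against overflow; the result is
#' mathematically unchanged because the output is invariant to adding a
#' constant to a row.
#'
#' @param table A `feature_table` in `clr` (or `generic`) space with finite
#'   values.
#' @return A `feature_table` with space `relative`.
#' @export
inverse_clr <- function(table) {
  m <- table$values
  e <- exp(m - apply(m, 1, max))
  out <- e / rowSums(e)
  ft_update(table, out, space = "relative", log_entry = "inverse_clr")
}

#' Log counts-per-million transform
#'
#' `log2((c + prior) / (L + 2 * prior) * 1e6)` per cell, with `L` the sample
#' library size. The prior appears symmetrically in numerator and
#' denominator so the transform is exact on the closed library.
#'
#' @param table A `feature_table` with space `counts`.
#' @param prior Positive prior count (default 0.5).
#' @return A `feature_table` with space `log`.
#' @export
log_cpm <- function(table, prior = 0.5) {
  stopifnot(prior > 0)
  if (table$space != "counts")
    stop("log_cpm requires space 'counts'")
  L <- rowSums(table$values)
  zero <- L == 0
  if (any(zero))
    stop("zero library size for sample(s): ",
         paste(sample_ids(table)[zero], collapse = ", "))
  out <- log2((table$values + prior) / (L + 2 * prior) * 1e6)
  ft_update(table, out, space = "log",
            log_entry = sprintf("log_cpm(prior=%g)", prior))
}
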