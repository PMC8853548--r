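#' Correlation of principal components with sample covariates
#'
#' For each of the top `n_pcs` score vectors and each covariate: a
#' continuous covariate contributes the absolute Pearson correlation with a
#' two-sided t-test p-value; a categorical covariate with L levels
#' contributes the first canonical correlation between the scores and the
#' L-1 dummy matrix, computed as sqrt(R^2) of the OLS of scores on dummies
#' plus intercept, with the regression F-test p-value. Both quantities are
#' non-negative, which is what makes heatmaps across mixed covariate types
#' comparable.
#'
#' @param model A `pc_model`.
#' @param meta A `sample_metadata` aligned with the model's samples.
#' @param covariates Metadata columns to test; default all columns.
#' @param n_pcs Number of leading components to test (default 15, capped at
#'   the model's K).
#' @return A `correlation_matrix`: list with `correlations` and `p_values`
#'   (n_pcs x covariates matrices) plus a `test` matrix naming the test used
#'   per cell.
#' @export
pc_covariate_correlation <- function(model, meta, covariates = names(meta),
                                     n_pcs = 15) {
  n_pcs <- min(n_pcs, ncol(model$scores))
  if (!all(rownames(model$scores) == rownames(meta)))
    stop("metadata is not aligned with the PC model's samples")
  types <- attr(meta, "col_types")
  cors <- ps <- matrix(NA_real_, n_pcs, length(covariates),
                       dimnames = list(paste0("PC", seq_len(n_pcs)), covariates))
  tests <- matrix(NA_character_, n_pcs, length(covariates),
                  dimnames = dimnames(cors))
  for (cv in covariates) {
    v <- meta[[cv]]
    if (anyNA(v)) stop("covariate '", cv, "' has missing values")
    continuous <- identical(types[[cv]], "continuous")
    for (k in seq_len(n_pcs)) {
      s <- model$scores[, k]
      if (continuous) {
        if (stats::sd(v) == 0 || stats::sd(s) == 0) {
          warning("constant covariate or scores: '", cv, "' vs PC", k)
          cors[k, cv] <- 0; ps[k, cv] <- 1; tests[k, cv] <- "constant"
          next
        }
        ct <- stats::cor.test(s, as.numeric(v))
        cors[k, cv] <- abs(ct$estimate)
        ps[k, cv] <- ct$p.value
        tests[k, cv] <- "pearson-t"
      } else {
        f <- droplevels(factor(v))
        if (nlevels(f) < 2) {
          warning("constant covariate: '", cv, "'")
          cors[k, cv] <- 0; ps[k, cv] <- 1; tests[k, cv] <- "constant"
          next
        }
        fit <- stats::lm(s ~ f)
        sm <- summary(fit)
        cors[k, cv] <- sqrt(max(sm$r.squared, 0))
        fs <- sm$fstatistic
        ps[k, cv] <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
        tests[k, cv] <- "anova-F"
      }
    }
  }
  structure(list(correlations = cors, p_values = ps, test = tests),
            class = "correlation_matrix")
}

#' Compare two correlation distributions cell by cell
#'
#' Paired one-sided Wilcoxon signed-rank test on matched (PC, covariate)
#' cells, alternative "after greater than before". Zero differences are
#' dropped (the signed-rank convention); the exact distribution is used for
#' 25 or fewer non-zero pairs and the normal approximation with continuity
#' correction above that.
#'
#' @param before,after `correlation_matrix` objects over the same PC and
#'   covariate grid.
#' @param covariates Optional subset of covariate columns to compare.
#' @return List with `statistic`, `p_value`, `n_pairs` (non-zero pairs),
#'   `median_before`, `median_after`.
#' @export
compare_correlation_distributions <- function(before, after,
                                              covariates = NULL) {
  if (!identical(dimnames(before$correlations), dimnames(after$correlations)))
    stop("correlation matrices are not on the same PC x covariate grid")
  b <- before$correlations
  a <- after$correlations
  if (!is.null(covariates)) {
    b <- b[, covariates, drop = FALSE]
    a <- a[, covariates, drop = FALSE]
  }
  d <- as.vector(a) - as.vector(b)
  nz <- sum(d != 0)
  if (nz < 5)
    stop("fewer than 5 non-tied pairs: the signed-rank comparison is ",
         "undefined at useful power")
  wt <- stats::wilcox.test(as.vector(a), as.vector(b), paired = TRUE,
                           alternative = "greater", exact = nz <= 25,
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n_pairs = nz,
       median_before = stats::median(as.vector(b)),
       median_after = stats::median(as.vector(a)))
}

#' Variance explained by the leading components
#'
#' @param model A `pc_model`.
#' @param top Number of leading components to summarize.
#' @return List with `fractions` (per-component variance fractions) and
#'   `cumulative` (their sum).
#' @export
variance_explained_summary <- function(model, top) {
  if (top < 1 || top > length(model$variance_fraction))
    stop("`top` must be between 1 and ", length(model$variance_fraction))
  fr <- model$variance_fraction[seq_len(top)]
  list(fractions = fr, cumulative = sum(fr))
}
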