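#' Build a batch design from labels
#'
#' @param batch_labels Factor or character vector of per-sample batch/study
#'   labels, named by sample id or aligned with the table it will be used on.
#' @param min_per_batch Minimum samples required per level (2 for linear
#'   corrections, 3 for ComBat).
#' @param allow_single_batch Permit a single level (degenerates to global
#'   centering in [bmc()]).
#' @return A `batch_design` with the factor labels and the n-by-b indicator
#'   matrix.
#' @export
batch_design <- function(batch_labels, min_per_batch = 2,
                         allow_single_batch = FALSE) {
  f <- droplevels(factor(batch_labels))
  if (anyNA(f)) stop("batch labels contain missing values")
  if (nlevels(f) < 2 && !allow_single_batch)
    stop("batch design requires >= 2 batch levels")
  sizes <- table(f)
  small <- names(sizes)[sizes < min_per_batch]
  if (length(small))
    stop("batch level(s) with fewer than ", min_per_batch, " samples: ",
         paste(small, collapse = ", "))
  dummy <- vapply(levels(f), function(l) as.numeric(f == l),
                  numeric(length(f)))
  dim(dummy) <- c(length(f), nlevels(f))
  colnames(dummy) <- levels(f)
  rownames(dummy) <- names(batch_labels)
  structure(list(batch = f, dummy = dummy), class = "batch_design")
}

# space of a corrected matrix: log-space data stay log; zero row sums mean
# clr; anything else is generic
derive_space <- function(out, input_space) {
  if (input_space == "log") return("log")
  if (max(abs(rowSums(out))) <= 1e-8) "clr" else "generic"
}

correction_result <- function(corrected, method, params = list(),
                              removed_components = NULL, beta = NULL) {
  structure(list(corrected = corrected, method = method, params = params,
                 removed_components = removed_components, beta = beta),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("correction_result: %s on %d samples x %d features\n",
              x$method, nrow(x$corrected$values), ncol(x$corrected$values)))
  invisible(x)
}

check_design_align <- function(table, design) {
  if (length(design$batch) != nrow(table$values))
    stop("batch design length does not match number of samples")
  invisible(TRUE)
}

#' Batch mean centering (BMC)
#'
#' Subtracts, per feature, the mean of each batch, so every batch's feature
#' means become zero.
#'
#' @param table A `feature_table` (space `relative`, `log`, `clr` or
#'   `generic`).
#' @param design A `batch_design`.
#' @return A `correction_result`; the corrected table has space `generic`
#'   unless the input was `clr` (batch centering preserves zero row sums on
#'   average but not exactly; the output is declared `generic` except for
#'   `clr`, where per-feature centering keeps row sums unchanged only when
#'   batch means themselves sum to zero — the space is re-derived from the
#'   values).
#' @export
bmc <- function(table, design) {
  if (table$space == "counts")
    stop("bmc is not defined on raw counts; transform first")
  check_design_align(table, design)
  m <- table$values
  out <- m
  for (lev in levels(design$batch)) {
    idx <- design$batch == lev
    out[idx, ] <- sweep(m[idx, , drop = FALSE], 2,
                        colMeans(m[idx, , drop = FALSE]))
  }
  corrected <- ft_update(table, out, space = derive_space(out, table$space),
                         log_entry = "bmc")
  correction_result(corrected, "bmc",
                    params = list(batch_levels = levels(design$batch)))
}

build_design_matrix <- function(meta, covariates) {
  types <- attr(meta, "col_types")
  cols <- list(`(Intercept)` = rep(1, nrow(meta)))
  for (cv in covariates) {
    if (!cv %in% names(meta)) stop("covariate not in metadata: ", cv)
    v <- meta[[cv]]
    if (anyNA(v)) stop("missing values in covariate '", cv,
                       "' for samples used in the analysis")
    if (identical(types[[cv]], "continuous")) {
      cols[[cv]] <- as.numeric(v)
    } else {
      f <- droplevels(factor(v))
      if (nlevels(f) > 1) {
        d <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(d) <- paste0(cv, levels(f)[-1])
        for (j in seq_len(ncol(d))) cols[[colnames(d)[j]]] <- d[, j]
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(meta)
  X
}

#' Direct covariate correction (DCC)
#'
#' Per-feature ordinary least squares of the feature values on a covariate
#' design (with intercept); the residual matrix is the corrected data. With
#' a single categorical covariate this is exactly batch mean centering.
#'
#' @param table A `feature_table` (not raw counts).
#' @param meta A `sample_metadata` aligned with `table`.
#' @param covariates Character vector of metadata column names to regress
#'   out.
#' @return A `correction_result` with the coefficient matrix in `$beta`
#'   (features x design columns).
#' @export
dcc <- function(table, meta, covariates) {
  if (table$space == "counts")
    stop("dcc is not defined on raw counts; transform first")
  if (nrow(meta) != nrow(table$values) ||
      !all(rownames(meta) == sample_ids(table)))
    stop("metadata is not aligned with the feature table; call align_samples()")
  X <- build_design_matrix(meta, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  fit <- qr.coef(qrX, table$values)
  resid <- qr.resid(qrX, table$values)
  corrected <- ft_update(table, resid,
                         space = derive_space(resid, table$space),
                         log_entry = sprintf("dcc(%s)",
                                             paste(covariates, collapse = ",")))
  correction_result(corrected, "dcc",
                    params = list(covariates = covariates),
                    beta = t(fit))
}

#' Linear batch removal (limma-style)
#'
#' Fits per-feature OLS on batch indicators (and, optionally, protected
#' phenotype columns), then subtracts only the batch contribution. With no
#' protected variable this equals [dcc()] on the batch column alone.
#'
#' @param table A `feature_table` in `log` or `clr` (or `generic`) space.
#' @param design A `batch_design`.
#' @param meta Optional `sample_metadata`, required when `protect` is given.
#' @param protect Optional name of a phenotype column whose fitted
#'   contribution is retained.
#' @return A `correction_result`.
#' @export
linear_batch_removal <- function(table, design, meta = NULL, protect = NULL) {
  if (table$space %in% c("counts", "relative"))
    stop("linear_batch_removal expects log-scale (log/clr/generic) data")
  check_design_align(table, design)
  # batch enters as sum-to-zero contrasts; the intercept and the batch
  # contribution are both subtracted, so with nothing protected this equals
  # dcc on the batch column (per-feature OLS residuals)
  b <- design$batch
  Cb <- stats::model.matrix(~ b, contrasts.arg = list(b = "contr.sum"))[, -1, drop = FALSE]
  colnames(Cb) <- paste0("batch", seq_len(ncol(Cb)))
  X <- cbind(`(Intercept)` = 1, Cb)
  if (!is.null(protect)) {
    if (is.null(meta)) stop("`meta` is required when `protect` is given")
    P <- build_design_matrix(meta, protect)[, -1, drop = FALSE]
    X <- cbind(X, P)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrX, table$values)           # design columns x features
  rm_cols <- c("(Intercept)", colnames(Cb))
  out <- table$values - X[, rm_cols, drop = FALSE] %*% beta[rm_cols, , drop = FALSE]
  corrected <- ft_update(table, out, space = derive_space(out, table$space),
                         log_entry = "linear_batch_removal")
  correction_result(corrected, "linear_batch_removal",
                    params = list(protect = protect), beta = t(beta))
}

#' ComBat empirical-Bayes batch adjustment (parametric)
#'
#' Location-scale batch model with empirical-Bayes shrinkage of per-batch
#' per-feature means and variances. Data are standardized per feature with
#' the size-weighted grand mean and pooled variance; batch locations get a
#' normal prior and batch variances an inverse-gamma prior, both with
#' method-of-moments hyperparameters, solved by the standard iterative
#' update; the adjusted data are back-scaled to the original units.
#'
#' Features with zero within-batch variance are location-adjusted only
#' (scale factor 1) and reported in `params$location_only_features`.
#'
#' @param table A `feature_table` in `log` or `clr` (or `generic`) space.
#' @param design A `batch_design` whose every level has at least 3 samples.
#' @param tol Convergence tolerance on the EB iteration (maximum absolute
#'   change, default 1e-6).
#' @param max_iter Maximum EB iterations (default 500).
#' @return A `correction_result`.
#' @export
combat <- function(table, design, tol = 1e-6, max_iter = 500) {
  if (table$space %in% c("counts", "relative"))
    stop("combat expects log-scale (log/clr/generic) data")
  check_design_align(table, design)
  sizes <- table(design$batch)
  if (any(sizes < 3))
    stop("combat requires >= 3 samples per batch; too small: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  m <- table$values                      # samples x features
  n <- nrow(m); G <- ncol(m)
  batches <- levels(design$batch)
  B <- length(batches)
  idx <- lapply(batches, function(l) which(design$batch == l))
  ni <- vapply(idx, length, integer(1))

  batch_means <- do.call(rbind, lapply(idx, function(i)
    colMeans(m[i, , drop = FALSE])))                 # B x G
  grand <- as.numeric((ni / n) %*% batch_means)      # size-weighted grand mean
  # pooled variance of residuals after removing batch means (divide by n)
  resid <- m
  for (b in seq_len(B)) resid[idx[[b]], ] <-
      sweep(m[idx[[b]], , drop = FALSE], 2, batch_means[b, ])
  var_pooled <- colSums(resid^2) / n
  zero_var <- var_pooled <= .Machine$double.eps * 100
  if (all(zero_var)) stop("all features have zero pooled variance")
  sd_pooled <- sqrt(var_pooled)
  sd_pooled[zero_var] <- 1

  Z <- sweep(sweep(m, 2, grand), 2, sd_pooled, "/")
  gamma_hat <- do.call(rbind, lapply(idx, function(i)
    colMeans(Z[i, , drop = FALSE])))                 # B x G
  # within-batch scale as the MLE (divide by n_b), consistent with the /n
  # pooled variance: a table with no batch effect then adjusts to itself
  delta_hat <- do.call(rbind, lapply(seq_len(B), function(b)
    colSums(sweep(Z[idx[[b]], , drop = FALSE], 2, gamma_hat[b, ])^2) / ni[b]))

  loc_only <- colnames(m)[apply(delta_hat <= .Machine$double.eps * 100, 2, any) |
                            zero_var]

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(B)) {
    gh <- gamma_hat[b, ]; dh <- delta_hat[b, ]
    usable <- is.finite(dh) & dh > 0
    if (sum(usable) < 2) { next }                    # EB degenerates to own estimates
    g_bar <- mean(gh[usable]); t2 <- stats::var(gh[usable])
    dbar <- mean(dh[usable]); s2 <- stats::var(dh[usable])
    if (!is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0) next
    a_prior <- (2 * s2 + dbar^2) / s2
    b_prior <- (dbar * s2 + dbar^3) / s2
    g_new <- gh; d_new <- dh
    nb <- ni[b]
    Zb <- Z[idx[[b]], , drop = FALSE]
    for (it in seq_len(max_iter)) {
      g_old <- g_new; d_old <- d_new
      g_new <- (t2 * nb * gh + d_old * g_bar) / (t2 * nb + d_old)
      sum2 <- colSums(sweep(Zb, 2, g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      if (change < tol) break
      if (it == max_iter)
        stop("combat EB iteration did not converge for batch '", batches[b], "'")
    }
    gamma_star[b, ] <- g_new
    delta_star[b, ] <- d_new
  }
  # zero-variance features: location adjustment only
  delta_star[, colnames(m) %in% loc_only] <- 1

  adj <- Z
  for (b in seq_len(B)) {
    adj[idx[[b]], ] <- sweep(sweep(Z[idx[[b]], , drop = FALSE], 2,
                                   gamma_star[b, ]),
                             2, sqrt(delta_star[b, ]), "/")
  }
  out <- sweep(sweep(adj, 2, sd_pooled, "*"), 2, grand, "+")
  corrected <- ft_update(table, out, space = derive_space(out, table$space),
                         log_entry = "combat")
  correction_result(corrected, "combat",
                    params = list(batch_levels = batches,
                                  location_only_features = loc_only,
                                  grand = grand, sd_pooled = sd_pooled,
                                  gamma_star = gamma_star,
                                  delta_star = delta_star))
}

#' Percentile normalization against within-batch controls
#'
#' Within each batch, every sample's value for each feature is replaced by
#' its percentile in that batch's control distribution, with midrank tie
#' handling: `100 * (#controls below + 0.5 * #controls equal) / n_controls`.
#'
#' @param table A `feature_table` with space `relative`.
#' @param design A `batch_design`; every batch must contain controls.
#' @param control Logical per-sample vector (TRUE = control), aligned with
#'   the table rows.
#' @param fallback_pooled When TRUE, a batch without any control sample is
#'   normalized against the pooled controls of all batches instead of
#'   raising an error; the titration pipeline uses this at full mixing,
#'   where the case study no longer holds controls of its own.
#' @return A `correction_result` with values in `[0, 100]` (space
#'   `generic`).
#' @export
percentile_normalize <- function(table, design, control,
                                 fallback_pooled = FALSE) {
  if (!table$space %in% c("relative", "generic"))
    stop("percentile_normalize expects relative abundance (or generic ",
         "values; only within-batch ranks matter)")
  check_design_align(table, design)
  stopifnot(is.logical(control), length(control) == nrow(table$values))
  m <- table$values
  out <- m
  for (lev in levels(design$batch)) {
    idx <- which(design$batch == lev)
    ctrl <- idx[control[idx]]
    if (!length(ctrl)) {
      if (!fallback_pooled)
        stop("batch '", lev, "' has no control samples")
      ctrl <- which(control)
    }
    ref <- m[ctrl, , drop = FALSE]
    nr <- length(ctrl)
    for (j in seq_len(ncol(m))) {
      r <- ref[, j]
      v <- m[idx, j]
      below <- vapply(v, function(x) sum(r < x), numeric(1))
      ties <- vapply(v, function(x) sum(r == x), numeric(1))
      out[idx, j] <- 100 * (below + 0.5 * ties) / nr
    }
  }
  corrected <- ft_update(table, out, space = "generic",
                         log_entry = "percentile_normalize")
  correction_result(corrected, "percentile_normalize")
}

#' Back-transform corrected data to relative abundance
#'
#' `log`-space data are exponentiated (natural exponent) and closed;
#' `clr`-space data go through [inverse_clr()]. Downstream filtering and
#' rank-based testing operate on the result.
#'
#' @param result A `correction_result` (or a `feature_table`) whose values
#'   are in `log` or `clr` space.
#' @return A `feature_table` with space `relative`.
#' @export
to_relative_abundance <- function(result) {
  tab <- if (inherits(result, "correction_result")) result$corrected else result
  if (tab$space == "log") {
    e <- exp(tab$values)
    out <- e / rowSums(e)
    return(ft_update(tab, out, space = "relative", log_entry = "exp+closure"))
  }
  if (tab$space == "clr") return(inverse_clr(tab))
  stop("no declared back-transform for space '", tab$space, "'")
}
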