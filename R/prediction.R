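#' Random-forest hyperparameter grid
#'
#' The default grid crosses number of trees (100, 1000, 1500), minimum node
#' size to attempt a split (2, 5, 10) and minimum terminal node size
#' (1, 5, 10) — 27 points. Split quality uses the Gini impurity; maximum
#' depth is unlimited and the number of candidate features per split is
#' sqrt(n_features), the standard classification default.
#'
#' @param n_trees,min_node,min_bucket Candidate values for the three tuned
#'   hyperparameters.
#' @return Data frame with one row per grid point.
#' @export
rf_grid <- function(n_trees = c(100, 1000, 1500),
                    min_node = c(2, 5, 10),
                    min_bucket = c(1, 5, 10)) {
  expand.grid(n_trees = n_trees, min_node = min_node,
              min_bucket = min_bucket, KEEP.OUT.ATTRS = FALSE)
}

# split ids into named fractions, stratified; remainder rounding goes to the
# first group. RNG state of the caller is used.
stratified_split <- function(ids, strata, fracs) {
  stopifnot(abs(sum(fracs) - 1) < 1e-8)
  out <- stats::setNames(vector("list", length(fracs)), names(fracs))
  for (s in unique(strata)) {
    sub <- sample(ids[strata == s])
    n <- length(sub)
    sizes <- floor(fracs * n)
    extra <- n - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    at <- cumsum(c(0, sizes))
    for (g in seq_along(fracs))
      out[[g]] <- c(out[[g]], sub[seq.int(at[g] + 1, length.out = sizes[g])])
  }
  out
}

strata_of <- function(phen) {
  if (is.numeric(phen)) {
    q <- stats::quantile(phen, probs = c(0.25, 0.5, 0.75), type = 7)
    cut(phen, breaks = c(-Inf, unique(q), Inf), labels = FALSE)
  } else as.character(phen)
}

#' Leave-one-dataset-out fold construction
#'
#' One fold per study/batch unit: that unit is the test set, and the
#' remaining samples are split 70/30 into training and validation,
#' stratified by phenotype (binary) or phenotype quartile (continuous).
#' Units containing only one phenotype class (binary case) cannot yield an
#' AUC and are skipped with a warning.
#'
#' @param meta A `sample_metadata`.
#' @param train_frac Fraction of non-test samples used for training
#'   (default 0.7).
#' @param seed Integer seed.
#' @return List of folds, each with `unit`, `train`, `validation`, `test`
#'   sample-id vectors.
#' @export
lodo_splits <- function(meta, train_frac = 0.7, seed = 1) {
  units <- batch_of(meta)
  if (nlevels(units) < 2) stop("LODO needs at least 2 study/batch units")
  phen <- phenotype_of(meta)
  if (anyNA(phen)) stop("phenotype has missing values; drop those samples first")
  binary <- !is.numeric(phen)
  strata <- strata_of(phen)
  seeds <- substream_seeds(seed, paste0("lodo-", levels(units)))
  folds <- list()
  for (u in levels(units)) {
    test <- rownames(meta)[units == u]
    if (binary && length(unique(phen[test])) < 2) {
      warning("unit '", u, "' has a single phenotype class; fold skipped")
      next
    }
    rest <- rownames(meta)[units != u]
    sp <- with_seed(seeds[paste0("lodo-", u)],
                    stratified_split(rest, strata[match(rest, rownames(meta))],
                                     c(train = train_frac,
                                       validation = 1 - train_frac)))
    folds[[u]] <- list(unit = u, train = sp$train,
                       validation = sp$validation, test = test)
  }
  if (!length(folds)) stop("no usable LODO folds")
  folds
}

#' Fit a background-noise correction on training samples only
#'
#' Returns a frozen parameter object that [apply_noise_correction()] uses on
#' any other table; nothing outside `table` influences the fit, which is
#' what makes a cross-validation fold leak-free.
#'
#' Methods: `"none"`; `"bmc"` (per-batch feature means learned on training
#' batches; a batch unseen at fit time is centered by its own feature means,
#' which needs no phenotype labels); `"pca_fixed"` (component model from
#' training samples; new data are centered with training means and projected
#' on training loadings); `"combat"` (EB location-scale model on training
#' batches; an unseen batch is standardized with the training grand
#' mean/pooled scale and adjusted by its own location and scale, again
#' label-free).
#'
#' @param table Training `feature_table` (clr or other log-scale space).
#' @param batch Training batch labels.
#' @param method Correction method.
#' @param p Components removed for `"pca_fixed"`.
#' @return A `noise_correction_fit`.
#' @export
fit_noise_correction <- function(table, batch,
                                 method = c("none", "bmc", "pca_fixed",
                                            "combat"),
                                 p = 3) {
  method <- match.arg(method)
  fit <- switch(
    method,
    none = list(),
    bmc = {
      f <- droplevels(factor(batch))
      means <- lapply(levels(f), function(l)
        colMeans(table$values[f == l, , drop = FALSE]))
      names(means) <- levels(f)
      list(batch_means = means)
    },
    pca_fixed = list(p = p, model = fit_pca(table, K = p)),
    combat = {
      res <- combat(table, batch_design(batch, min_per_batch = 3))
      list(grand = res$params$grand, sd_pooled = res$params$sd_pooled,
           gamma_star = res$params$gamma_star,
           delta_star = res$params$delta_star,
           batch_levels = res$params$batch_levels)
    })
  structure(c(list(method = method), fit), class = "noise_correction_fit")
}

#' Apply a fitted noise correction to new data
#'
#' @param fit A `noise_correction_fit` from [fit_noise_correction()].
#' @param table A `feature_table` over the same features.
#' @param batch Batch labels for `table`'s samples.
#' @return The corrected `feature_table`.
#' @export
apply_noise_correction <- function(fit, table, batch) {
  m <- table$values
  out <- switch(
    fit$method,
    none = return(table),
    bmc = {
      o <- m
      for (l in unique(as.character(batch))) {
        idx <- which(as.character(batch) == l)
        ctr <- if (l %in% names(fit$batch_means)) fit$batch_means[[l]]
               else colMeans(m[idx, , drop = FALSE])
        o[idx, ] <- sweep(m[idx, , drop = FALSE], 2, ctr)
      }
      o
    },
    pca_fixed = {
      return(pca_correct_fixed(table, p = fit$p, model = fit$model)$corrected)
    },
    combat = {
      Z <- sweep(sweep(m, 2, fit$grand), 2, fit$sd_pooled, "/")
      o <- Z
      for (l in unique(as.character(batch))) {
        idx <- which(as.character(batch) == l)
        if (l %in% fit$batch_levels) {
          b <- match(l, fit$batch_levels)
          g <- fit$gamma_star[b, ]; d <- fit$delta_star[b, ]
        } else {
          g <- colMeans(Z[idx, , drop = FALSE])
          d <- colSums(sweep(Z[idx, , drop = FALSE], 2, g)^2) / length(idx)
          d[d <= .Machine$double.eps * 100] <- 1
        }
        o[idx, ] <- sweep(sweep(Z[idx, , drop = FALSE], 2, g), 2, sqrt(d), "/")
      }
      sweep(sweep(o, 2, fit$sd_pooled, "*"), 2, fit$grand, "+")
    })
  space <- if (max(abs(rowSums(out))) <= 1e-8) "clr" else "generic"
  ft_update(table, out, space = space,
            log_entry = paste0("apply_noise_correction(", fit$method, ")"))
}

# Closure + train-derived pseudocount + CLR for one fold. All replacement
# parameters come from the training partition.
fold_clr_tables <- function(rel, fold, pseudocount_factor = 0.65) {
  parts <- list(train = fold$train, validation = fold$validation,
                test = fold$test)
  tr <- rel$values[parts$train, , drop = FALSE]
  nz <- tr[tr > 0]
  if (!length(nz)) stop("training partition has no positive values")
  pc <- pseudocount_factor * min(nz)
  lapply(parts, function(ids) {
    m <- rel$values[ids, , drop = FALSE]
    m[m == 0] <- pc
    m <- m / rowSums(m)
    lm <- log(m)
    feature_table(lm - rowMeans(lm), space = "clr",
                  transform_log = list(sprintf("fold clr (pseudocount %g)", pc)))
  })
}

#' Train and evaluate a binary phenotype predictor on one fold
#'
#' Full pipeline per fold: closure, training-derived pseudocount, CLR,
#' noise correction fitted on training samples only, random-forest grid
#' search scored by validation AUC, test AUC reported for the winning grid
#' point.
#'
#' @param table A `feature_table` (counts or relative).
#' @param meta A `sample_metadata` with a binary phenotype.
#' @param fold A fold from [lodo_splits()] (or any list with `train`,
#'   `validation`, `test` id vectors).
#' @param correction Correction method passed to [fit_noise_correction()].
#' @param p Components removed when `correction = "pca_fixed"`.
#' @param grid Hyperparameter grid from [rf_grid()].
#' @param pseudocount_factor Zero-replacement factor (default 0.65).
#' @param seed Integer seed for the forests.
#' @return List with `auc` (test AUC), `validation_auc` (per grid point),
#'   `best` (winning grid row), `fit` (the frozen correction parameters).
#' @export
train_eval_binary <- function(table, meta, fold, correction = "none", p = 3,
                              grid = rf_grid(), pseudocount_factor = 0.65,
                              seed = 1) {
  al <- align_samples(table, meta)
  rel <- if (al$table$space == "relative") al$table else closure(al$table)
  phen <- factor(phenotype_of(al$meta))
  stopifnot(nlevels(phen) == 2)
  if (length(unique(phen[fold$test])) < 2) {
    warning("single-class test set; fold skipped")
    return(list(auc = NA_real_, skipped = TRUE))
  }
  batch <- batch_of(al$meta)
  tabs <- fold_clr_tables(rel, fold, pseudocount_factor)
  cfit <- fit_noise_correction(tabs$train, batch[fold$train],
                               method = correction, p = p)
  x <- lapply(names(tabs), function(part)
    apply_noise_correction(cfit, tabs[[part]], batch[get_part(fold, part)])$values)
  names(x) <- names(tabs)
  y <- lapply(names(tabs), function(part) droplevels(phen[get_part(fold, part)]))
  names(y) <- names(tabs)
  pos <- levels(phen)[2]
  fit_rf <- function(g, seed_i) {
    ranger::ranger(x = x$train, y = factor(y$train, levels = levels(phen)),
                   num.trees = g$n_trees, min.node.size = g$min_node,
                   min.bucket = g$min_bucket, probability = TRUE,
                   seed = seed_i, num.threads = 1)
  }
  val_auc <- vapply(seq_len(nrow(grid)), function(i) {
    rf <- fit_rf(grid[i, ], seed)
    pr <- stats::predict(rf, data = x$validation)$predictions[, pos]
    auc_score(pr, y$validation == pos)
  }, numeric(1))
  best <- which.max(val_auc)
  rf <- fit_rf(grid[best, ], seed)
  pr <- stats::predict(rf, data = x$test)$predictions[, pos]
  list(auc = auc_score(pr, y$test == pos), validation_auc = val_auc,
       best = grid[best, ], fit = cfit, skipped = FALSE)
}

get_part <- function(fold, part) fold[[part]]

# minimum-norm least squares / ridge with unpenalized intercept
ridge_fit <- function(X, y, lambda) {
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx)
  if (lambda == 0) {
    sv <- svd(Xc)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% (y - my)) / sv$d[pos])
  } else {
    A <- crossprod(Xc) + diag(lambda, ncol(Xc))
    beta <- solve(A, crossprod(Xc, y - my))
  }
  list(beta = beta, mx = mx, my = my)
}

ridge_predict <- function(fit, X) {
  as.numeric(sweep(X, 2, fit$mx) %*% fit$beta + fit$my)
}

#' Train and evaluate a continuous phenotype predictor on one fold
#'
#' Linear least-squares regression on the corrected features, with an
#' optional ridge penalty chosen on the validation partition (lambda = 0
#' reproduces plain least squares via the minimum-norm solution, which is
#' what OLS degenerates to when features outnumber samples). Accuracy is the
#' Pearson correlation of predicted and true phenotype on the test
#' partition.
#'
#' @inheritParams train_eval_binary
#' @param lambda_grid Ridge penalties evaluated on validation
#'   (default `c(0, 0.01, 1, 100)`).
#' @return List with `r` (test Pearson correlation), `lambda` (chosen
#'   penalty), `validation_r`, `fit`.
#' @export
train_eval_continuous <- function(table, meta, fold, correction = "none",
                                  p = 3, lambda_grid = c(0, 0.01, 1, 100),
                                  pseudocount_factor = 0.65) {
  al <- align_samples(table, meta)
  rel <- if (al$table$space == "relative") al$table else closure(al$table)
  phen <- phenotype_of(al$meta)
  stopifnot(is.numeric(phen))
  batch <- batch_of(al$meta)
  tabs <- fold_clr_tables(rel, fold, pseudocount_factor)
  cfit <- fit_noise_correction(tabs$train, batch[fold$train],
                               method = correction, p = p)
  x <- lapply(names(tabs), function(part)
    apply_noise_correction(cfit, tabs[[part]], batch[get_part(fold, part)])$values)
  names(x) <- names(tabs)
  y <- lapply(names(tabs), function(part) phen[get_part(fold, part)])
  names(y) <- names(tabs)
  safe_r <- function(pred, truth) {
    if (stats::sd(pred) == 0) {
      warning("zero-variance predictions; r recorded as 0")
      return(0)
    }
    stats::cor(pred, truth)
  }
  val_r <- vapply(lambda_grid, function(l) {
    f <- ridge_fit(x$train, y$train, l)
    safe_r(ridge_predict(f, x$validation), y$validation)
  }, numeric(1))
  lambda <- lambda_grid[which.max(val_r)]
  f <- ridge_fit(x$train, y$train, lambda)
  list(r = safe_r(ridge_predict(f, x$test), y$test), lambda = lambda,
       validation_r = val_r, fit = cfit)
}

#' Repeated cross-validated phenotype prediction
#'
#' Two schemes. `"lodo"`: one fold per study/batch with a 70/30
#' train/validation split of the remaining samples, the whole procedure
#' repeated with fresh splits. `"pooled_56_24_20"`: five-fold
#' cross-validation of the pooled cohort (each fold in turn is the 20% test
#' set, the rest is split 70/30 into 56% training and 24% validation),
#' repeated ten times by default; partitions are stratified so the study
#' composition stays similar across them.
#'
#' @param table A `feature_table`.
#' @param meta A `sample_metadata`.
#' @param scheme `"lodo"` or `"pooled_56_24_20"`.
#' @param task `"binary"` (random forest, AUC) or `"continuous"`
#'   (linear/ridge regression, Pearson r).
#' @param correction,p Passed to the per-fold evaluators.
#' @param grid RF grid for binary tasks.
#' @param n_folds Folds per repeat for the pooled scheme (default 5).
#' @param n_repeats Repeats (default 10).
#' @param seed Integer seed.
#' @return A `prediction_result`: per-fold metric data frame, `mean`, and
#'   the 2.5/97.5 percentile interval.
#' @export
repeated_cv <- function(table, meta, scheme = c("lodo", "pooled_56_24_20"),
                        task = c("binary", "continuous"),
                        correction = "none", p = 3, grid = rf_grid(),
                        n_folds = 5, n_repeats = 10, seed = 1) {
  scheme <- match.arg(scheme)
  task <- match.arg(task)
  rep_seeds <- substream_seeds(seed, paste0("cv-rep", seq_len(n_repeats)))
  phen <- phenotype_of(meta)
  strata <- paste(strata_of(phen), as.character(batch_of(meta)))
  rows <- list()
  for (r in seq_len(n_repeats)) {
    folds <- if (scheme == "lodo") {
      lodo_splits(meta, seed = rep_seeds[r])
    } else {
      ids <- rownames(meta)
      chunks <- with_seed(rep_seeds[r], stratified_split(
        ids, strata, stats::setNames(rep(1 / n_folds, n_folds),
                                     paste0("fold", seq_len(n_folds)))))
      lapply(seq_len(n_folds), function(k) {
        test <- chunks[[k]]
        rest <- setdiff(ids, test)
        sp <- with_seed(rep_seeds[r] + k, stratified_split(
          rest, strata[match(rest, ids)],
          c(train = 0.7, validation = 0.3)))
        list(unit = paste0("fold", k), train = sp$train,
             validation = sp$validation, test = test)
      })
    }
    for (fold in folds) {
      res <- if (task == "binary") {
        ev <- train_eval_binary(table, meta, fold, correction = correction,
                                p = p, grid = grid, seed = rep_seeds[r])
        ev$auc
      } else {
        train_eval_continuous(table, meta, fold, correction = correction,
                              p = p)$r
      }
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_i = r, unit = fold$unit, metric = res)
    }
  }
  df <- do.call(rbind, rows)
  v <- df$metric[!is.na(df$metric)]
  structure(list(folds = df, mean = mean(v),
                 ci = stats::quantile(v, c(0.025, 0.975), names = FALSE),
                 scheme = scheme, task = task, correction = correction,
                 seed = seed),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: %s / %s / correction '%s'\n",
              x$scheme, x$task, x$correction))
  cat(sprintf("mean metric %.3f [%.3f, %.3f] over %d fold evaluations\n",
              x$mean, x$ci[1], x$ci[2], nrow(x$folds)))
  invisible(x)
}

#' Compare two metric distributions
#'
#' One-sided Wilcoxon rank-sum test of `a` against `b`. With very few folds
#' the smallest attainable p-value (1 / choose(na + nb, na)) can exceed
#' 0.05; the result is annotated when that is the case, since such
#' comparisons cannot reach significance regardless of the data.
#'
#' @param a,b Numeric metric vectors (at least 3 values each).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return List with `p_value`, `min_attainable_p`, `attainable` (whether
#'   p < 0.05 is possible at these sample sizes), `note`.
#' @export
compare_methods <- function(a, b, alternative = c("greater", "less",
                                                  "two.sided")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 values per group")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative))
  min_p <- 1 / choose(length(a) + length(b), length(a))
  if (alternative == "two.sided") min_p <- min(2 * min_p, 1)
  attainable <- min_p < 0.05
  list(p_value = wt$p.value, min_attainable_p = min_p,
       attainable = attainable,
       note = if (!attainable)
         sprintf("with %d vs %d folds the smallest attainable p is %.3g; p < 0.05 cannot be reached",
                 length(a), length(b), min_p))
}
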