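#' Fit a principal-component model
#'
#' Covariance (unscaled) PCA of the feature-centered matrix via singular
#' value decomposition. CLR-transformed data already put all features on a
#' common log scale, so no variance scaling is applied. Loadings follow the
#' sign convention that each column's largest-magnitude entry is positive.
#'
#' @param table A `feature_table` (typically `clr` space).
#' @param K Number of components, `K <= min(n_samples - 1, n_features)`.
#' @return A `pc_model` with `scores` (n x K), `loadings` (features x K),
#'   `variance_fraction` (length K) and `feature_means`.
#' @export
fit_pca <- function(table, K) {
  m <- table$values
  kmax <- min(nrow(m) - 1L, ncol(m))
  if (K < 1 || K > kmax)
    stop("K must be between 1 and ", kmax)
  mu <- colMeans(m)
  X <- sweep(m, 2, mu)
  sv <- svd(X, nu = K, nv = K)
  total <- sum(X^2)
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v, 2, flip, "*")
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(K)], K), 2, flip, "*")
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(K))
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = sv$d[seq_len(K)]^2 / total,
                 feature_means = mu),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model: %d components over %d samples x %d features\n",
              ncol(x$scores), nrow(x$scores), nrow(x$loadings)))
  cat("variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Remove a fixed number of principal components
#'
#' Regresses the top `p` PCs out of a CLR-transformed table: the projection
#' of the centered data onto the top-p component subspace is subtracted and
#' the feature means are restored. `p = 0` is the identity. The removed
#' components dominate when study-specific multiplicative bias is the
#' largest source of variance, which is the premise of unsupervised PC
#' correction.
#'
#' @param table A `feature_table` in `clr` (or `generic`) space.
#' @param p Number of leading components to remove (default 3).
#' @param model Optional pre-fitted `pc_model` (e.g. fitted on training
#'   samples only); when given, `table` is centered with the model's feature
#'   means and projected on the model's loadings — no refit.
#' @param restore_means Restore per-feature means after projection removal
#'   (default TRUE). Per-sample constants cancel under [inverse_clr()] but
#'   per-feature constants do not, so the default keeps the back-transformed
#'   composition comparable to the input.
#' @return A `correction_result` with the fitted `pc_model` in
#'   `$removed_components`.
#' @export
pca_correct_fixed <- function(table, p = 3, model = NULL, restore_means = TRUE) {
  if (table$space %in% c("counts", "relative"))
    stop("pca_correct_fixed expects clr (or other log-scale) data; ",
         "apply add_pseudocount() and clr_transform() first")
  if (p == 0) {
    return(correction_result(table, "pca_fixed", params = list(p = 0)))
  }
  if (is.null(model)) model <- fit_pca(table, K = p)
  if (p > ncol(model$scores))
    stop("p exceeds the number of available components (",
         ncol(model$scores), ")")
  X <- sweep(table$values, 2, model$feature_means)
  L <- model$loadings[, seq_len(p), drop = FALSE]
  out <- X - (X %*% L) %*% t(L)
  if (restore_means) out <- sweep(out, 2, model$feature_means, "+")
  space <- if (max(abs(rowSums(out))) <= 1e-8) "clr" else "generic"
  corrected <- ft_update(table, out, space = space,
                         log_entry = sprintf("pca_correct_fixed(p=%d)", p))
  correction_result(corrected, "pca_fixed", params = list(p = p),
                    removed_components = model)
}

#' Tune the number of removed components on validation data
#'
#' For each candidate `p`, the PC model fitted on the training samples is
#' used to correct both training and validation tables (validation data are
#' centered with the training feature means and projected on the training
#' loadings; nothing is refitted), a predictor is trained on the corrected
#' training data and scored on the corrected validation data, and the `p`
#' with the best validation metric wins. Ties go to the smallest `p`, which
#' removes the least phenotype signal.
#'
#' @param train,validation `feature_table`s in `clr` space over disjoint
#'   samples.
#' @param train_labels,validation_labels Phenotype values for the two sample
#'   sets (binary factor for AUC, numeric for Pearson correlation).
#' @param p_grid Candidate numbers of removed components; default `1:20`,
#'   capped at the training rank minus one. `0` may be included to score the
#'   uncorrected baseline.
#' @param predictor Either `"ranger"` (random forest, the default; AUC for
#'   binary labels, Pearson r for numeric) or a function
#'   `f(train_x, train_y, valid_x, valid_y)` returning a scalar metric.
#' @param num_trees Trees for the default random-forest predictor.
#' @param seed Integer seed controlling the predictor's randomness.
#' @return List with `result` (the `correction_result` at the chosen `p`),
#'   `chosen_p`, and `metrics` (named per-p validation metric vector).
#' @export
pca_correct_tuned <- function(train, validation, train_labels,
                              validation_labels, p_grid = 1:20,
                              predictor = "ranger", num_trees = 100,
                              seed = 1) {
  if (length(intersect(sample_ids(train), sample_ids(validation))))
    stop("train and validation samples must be disjoint")
  if (nrow(validation$values) == 0) stop("empty validation set")
  binary <- !is.numeric(train_labels)
  if (binary) {
    train_labels <- factor(train_labels)
    validation_labels <- factor(validation_labels,
                                levels = levels(train_labels))
    if (length(unique(validation_labels)) < 2)
      stop("single-class validation set: AUC is undefined")
  }
  kmax <- min(nrow(train$values) - 1L, ncol(train$values)) - 1L
  p_grid <- sort(unique(pmin(p_grid, kmax)))
  model <- fit_pca(train, K = max(max(p_grid), 1L))
  eval_p <- function(p) {
    tr <- pca_correct_fixed(train, p = p, model = model)$corrected$values
    va <- pca_correct_fixed(validation, p = p, model = model)$corrected$values
    if (is.function(predictor))
      return(predictor(tr, train_labels, va, validation_labels))
    fit <- with_seed(seed, ranger::ranger(
      x = tr, y = train_labels, num.trees = num_trees,
      probability = binary, seed = seed, num.threads = 1))
    if (binary) {
      pr <- stats::predict(fit, data = va)$predictions[, levels(train_labels)[2]]
      auc_score(pr, validation_labels == levels(train_labels)[2])
    } else {
      pr <- stats::predict(fit, data = va)$predictions
      if (stats::sd(pr) == 0) 0 else stats::cor(pr, validation_labels)
    }
  }
  metrics <- vapply(p_grid, eval_p, numeric(1))
  names(metrics) <- p_grid
  chosen_p <- p_grid[which.max(metrics)]   # which.max takes the first (smallest p) tie
  list(result = pca_correct_fixed(train, p = chosen_p, model = model),
       chosen_p = chosen_p, metrics = metrics)
}
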