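#' Per-feature differential-abundance testing
#'
#' Two-sided Wilcoxon rank-sum test of each feature between two phenotype
#' classes, with Benjamini-Hochberg adjustment; a feature is called
#' significant when its q-value is below `q_threshold`.
#'
#' @param table A `feature_table` of relative abundances (or any values on
#'   which a rank test is meaningful).
#' @param labels Binary per-sample labels (logical, factor or 2-level
#'   vector), aligned with the table rows.
#' @param q_threshold FDR threshold (default 0.05).
#' @return Data frame with one row per feature: `feature`, `statistic`
#'   (rank-sum W), `p`, `q`, `significant`.
#' @export
differential_abundance <- function(table, labels, q_threshold = 0.05) {
  f <- factor(labels)
  if (nlevels(f) != 2)
    stop("labels must have exactly 2 classes, got ", nlevels(f))
  if (length(f) != nrow(table$values))
    stop("labels are not aligned with the feature table")
  if (any(table(f) < 3))
    stop("each class needs at least 3 samples")
  g1 <- f == levels(f)[1]
  m <- table$values
  res <- apply(m, 2, function(v) {
    wt <- suppressWarnings(stats::wilcox.test(v[g1], v[!g1]))
    c(wt$statistic, wt$p.value)
  })
  p <- res[2, ]
  p[is.na(p)] <- 1       # fully tied feature (e.g. all zeros): no evidence
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature = colnames(m), statistic = res[1, ], p = p, q = q,
             significant = q < q_threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Score a significant set against simulation ground truth
#'
#' @param significant Character vector of feature ids called significant.
#' @param truth A `ground_truth` object from [simulate_dataset()].
#' @param all_features All feature ids tested (defaults to the truth's
#'   feature universe).
#' @return List with `false_positive_count`, `true_positive_count`, `FPR`
#'   (false positives over truly-null features) and `TPR` (true positives
#'   over truly-differential features).
#' @export
evaluate_against_truth <- function(significant, truth,
                                   all_features = truth$feature_ids) {
  unknown <- setdiff(significant, all_features)
  if (length(unknown))
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "))
  pos <- intersect(all_features, truth$differential_features)
  neg <- setdiff(all_features, truth$differential_features)
  tp <- length(intersect(significant, pos))
  fp <- length(intersect(significant, neg))
  list(false_positive_count = fp, true_positive_count = tp,
       FPR = if (length(neg)) fp / length(neg) else 0,
       TPR = if (length(pos)) tp / length(pos) else 0)
}
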