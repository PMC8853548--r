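# Run code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive named substream seeds from one user seed; keeps every seed < 2^31.
substream_seeds <- function(seed, names) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(names))
    stats::setNames(s, names)
  })
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of a score vector against binary truth,
#' with midranks for tied scores.
#'
#' @param scores Numeric predicted scores, larger meaning more positive.
#' @param truth Logical (or 0/1) vector of true labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
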