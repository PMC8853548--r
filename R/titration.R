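#' Describe a titration correction pipeline
#'
#' The titration experiment re-applies a full transform/correct/back-transform
#' pipeline to every mixed sample set. This helper freezes the pipeline's
#' choices:
#' \itemize{
#'   \item `"none"`: relative abundance used directly.
#'   \item `"bmc"`, `"dcc"`, `"pca_fixed"`: closure, pseudocount zero
#'     replacement, CLR, correction in CLR space, inverse CLR back to
#'     relative abundance.
#'   \item `"combat"`, `"limma"`: closure, pseudocount, natural log of
#'     relative abundance, correction, exponent and closure back.
#'   \item `"percentile"`: percentile normalization of relative abundance
#'     against within-study controls, applied once to the full two-study
#'     cohort before any mixing (the method requires each study's own
#'     labeled controls, which the mixed subsets no longer contain); the
#'     percentile scores feed the rank test directly.
#' }
#'
#' @param correction One of `"none"`, `"bmc"`, `"dcc"`, `"limma"`,
#'   `"combat"`, `"percentile"`, `"pca_fixed"`.
#' @param p Components removed when `correction = "pca_fixed"` (default 3).
#' @param pseudocount_factor Zero-replacement factor (default 0.65); the
#'   pseudocount is recomputed on every input table the pipeline sees.
#' @param min_prevalence Prevalence filter applied to the back-transformed
#'   relative abundances before testing (default 0.1).
#' @return A `titration_pipeline` spec.
#' @export
titration_pipeline <- function(correction = c("none", "bmc", "dcc", "limma",
                                              "combat", "percentile",
                                              "pca_fixed"),
                               p = 3, pseudocount_factor = 0.65,
                               min_prevalence = 0.1) {
  correction <- match.arg(correction)
  structure(list(correction = correction, p = p,
                 pseudocount_factor = pseudocount_factor,
                 min_prevalence = min_prevalence),
            class = "titration_pipeline")
}

# Apply a titration pipeline to one mixed sample set and return the set of
# significant features. `batch` is the study of origin, `case` logical.
apply_titration_pipeline <- function(rel, batch, case, pipeline,
                                     q_threshold = 0.05) {
  method <- pipeline$correction
  multi_batch <- nlevels(droplevels(factor(batch))) >= 2
  tab <- switch(
    method,
    none = ,                               # pre-normalized percentile data
    percentile = rel,                      # arrive here ready for testing
    {
      tabp <- add_pseudocount(rel, pipeline$pseudocount_factor)
      if (method %in% c("combat", "limma")) {
        work <- ft_update(tabp, log(tabp$values), space = "log",
                          log_entry = "log")
      } else {
        work <- clr_transform(tabp)
      }
      corrected <- if (method == "pca_fixed") {
        pca_correct_fixed(work, p = pipeline$p)
      } else if (!multi_batch) {
        # degenerate single-batch mix (proportion 0): per-feature global
        # centering, which leaves every rank test unchanged
        bmc(work, batch_design(batch, allow_single_batch = TRUE))
      } else if (method == "bmc") {
        bmc(work, batch_design(batch))
      } else if (method == "dcc") {
        meta <- sample_metadata(
          data.frame(sample_id = rownames(work$values),
                     study = as.character(batch),
                     case = as.character(case),
                     stringsAsFactors = FALSE),
          phenotype = "case", batch = "study")
        dcc(work, meta, covariates = "study")
      } else if (method == "limma") {
        linear_batch_removal(work, batch_design(batch))
      } else {
        combat(work, batch_design(batch, min_per_batch = 3))
      }
      to_relative_abundance(corrected)
    })
  tab <- prevalence_filter(tab, pipeline$min_prevalence)
  da <- differential_abundance(tab, labels = case, q_threshold = q_threshold)
  da$feature[da$significant]
}

#' Control-titration false-positive experiment
#'
#' Measures how many new case-control associations appear as controls from
#' one study are progressively replaced by controls from a second study. For
#' each replicate, `m` cases and `m` controls are drawn from study 1 (with
#' `m` the minimum class size across both studies); the significant feature
#' set of that draw is the baseline. For each mixing proportion `f`,
#' `round(f * m)` of the drawn controls are swapped for study-2 controls
#' (nested across proportions within a replicate), the full pipeline is
#' re-applied, and features significant in the mixed set but absent from the
#' baseline are counted as new (likely false-positive) associations. At
#' `f = 1` the study label completely confounds case-control status.
#'
#' @param table A `feature_table` with space `counts` or `relative`.
#' @param meta A `sample_metadata` aligned with `table`; its phenotype
#'   column must be binary and its batch column identifies studies.
#' @param study1,study2 Study labels: cases and baseline controls come from
#'   `study1`, replacement controls from `study2`.
#' @param case_level Phenotype level treated as "case"; default the second
#'   factor level.
#' @param proportions Mixing fractions (default `c(0, 0.25, 0.5, 0.75, 1)`).
#' @param pipeline A [titration_pipeline()] spec.
#' @param replicates Number of seeded re-draws (default 5).
#' @param q_threshold FDR threshold for significance (default 0.05).
#' @param seed Integer seed; every draw flows from it.
#' @return A `titration_result`: per-cell data frame (`replicate`,
#'   `proportion`, `n_significant`, `new_associations`), per-proportion mean
#'   summary, and the per-replicate baseline and titrated significant sets.
#' @export
run_titration <- function(table, meta, study1, study2, case_level = NULL,
                          proportions = c(0, 0.25, 0.5, 0.75, 1),
                          pipeline = titration_pipeline("none"),
                          replicates = 5, q_threshold = 0.05, seed = 1) {
  stopifnot(all(proportions >= 0), all(proportions <= 1))
  al <- align_samples(table, meta)
  rel <- if (al$table$space == "relative") al$table else closure(al$table)
  study <- as.character(batch_of(al$meta))
  phen <- factor(phenotype_of(al$meta))
  if (nlevels(phen) != 2) stop("titration needs a binary phenotype")
  if (is.null(case_level)) case_level <- levels(phen)[2]
  is_case <- phen == case_level
  pools <- list(cases1 = which(study == study1 & is_case),
                controls1 = which(study == study1 & !is_case),
                cases2 = which(study == study2 & is_case),
                controls2 = which(study == study2 & !is_case))
  m <- min(lengths(pools))
  if (m < 6) stop("minimum class membership across the two studies is ", m,
                  "; need at least 6")
  if (pipeline$correction == "percentile") {
    # supervised normalization against each study's own controls, applied to
    # the full cohort before mixing; the mixed subsets then carry percentile
    # scores in place of relative abundances
    rel <- percentile_normalize(rel,
                                batch_design(study, allow_single_batch = TRUE),
                                control = !is_case)$corrected
  }
  rep_seeds <- substream_seeds(seed, paste0("titration-rep", seq_len(replicates)))
  cells <- list(); sets <- list()
  for (r in seq_len(replicates)) {
    draws <- with_seed(rep_seeds[r], list(
      cases = sample(pools$cases1, m),
      controls = sample(pools$controls1, m),
      order = sample.int(m),                 # replacement order, nested in f
      pool2 = sample(pools$controls2, m)))
    run_cell <- function(f) {
      k <- round(f * m)
      controls <- draws$controls
      if (k > 0) controls[draws$order[seq_len(k)]] <- draws$pool2[seq_len(k)]
      idx <- c(draws$cases, controls)
      sub <- ft_update(rel, rel$values[idx, , drop = FALSE])
      apply_titration_pipeline(sub, batch = study[idx],
                               case = c(rep(TRUE, m), rep(FALSE, m)),
                               pipeline = pipeline, q_threshold = q_threshold)
    }
    baseline_set <- run_cell(0)            # baseline: unmixed study-1 draw
    for (f in proportions) {
      sig <- if (f == 0) baseline_set else run_cell(f)
      new_assoc <- length(setdiff(sig, baseline_set))
      cells[[length(cells) + 1L]] <-
        data.frame(replicate = r, proportion = f,
                   n_significant = length(sig),
                   new_associations = new_assoc)
      sets[[length(sets) + 1L]] <- list(replicate = r, proportion = f,
                                        significant = sig,
                                        baseline = baseline_set)
    }
  }
  cells <- do.call(rbind, cells)
  summary <- stats::aggregate(new_associations ~ proportion, cells, mean)
  names(summary)[2] <- "mean_new_associations"
  structure(list(study_pair = c(study1, study2), proportions = proportions,
                 replicates = replicates, pipeline = pipeline,
                 cells = cells, summary = summary, sets = sets, seed = seed),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("titration_result: %s vs %s, %d replicates, pipeline '%s'\n",
              x$study_pair[1], x$study_pair[2], x$replicates,
              x$pipeline$correction))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
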