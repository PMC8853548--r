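#' Configuration for the multi-study compositional simulator
#'
#' Defaults describe a modest two-study case-control comparison: 40 samples
#' per study, 200 features with log-normal baseline abundances, per-feature
#' per-study multiplicative bias of one natural-log unit (the scale at which
#' study membership dominates the leading principal components of CLR
#' data), no planted phenotype effects, and libraries of about 50,000 reads
#' with moderate negative-binomial dispersion.
#'
#' @param n_studies Number of studies/batches (default 2).
#' @param samples_per_study Samples per study, recycled to `n_studies`
#'   (default 40).
#' @param n_features Number of features (default 200).
#' @param baseline_logmean_sd SD of per-feature baseline log-abundance
#'   (default 2; produces the skewed compositions that make multinomial
#'   sampling generate zeros).
#' @param bias_sd SD of the per-feature per-study log-normal multiplicative
#'   bias, recycled per study (default 1).
#' @param n_differential Number of truly differential features (default 0).
#' @param effect_logfold Log (natural) fold change applied to differential
#'   features in cases (default `log(4)`).
#' @param effect_direction `"balanced"` (default): half the differential
#'   features go up in cases and half down, so the planted signal conserves
#'   compositional mass and does not bleed into null features after
#'   closure; `"up"`: all planted effects share one sign, which shifts the
#'   relative abundance of every null feature in cases (a known
#'   compositional artifact, available for studying exactly that).
#' @param effect_features `"non_dominant"` (default): differential features
#'   are drawn from features whose baseline log-abundance is below the
#'   median, so a 4-fold change never rescales the entire composition of a
#'   class (a fold change in a dominant feature makes every other feature
#'   genuinely differ between classes after closure, which no batch
#'   correction can or should undo); `"any"`: drawn uniformly.
#' @param phenotype_type `"binary"` or `"continuous"`.
#' @param confounding_rho In `[0, 1]`: 0 means phenotype independent of
#'   study, 1 means phenotype fully determined by study (odd studies all
#'   case, even all control, for binary; for continuous, the study mean
#'   shift scales with rho).
#' @param sample_noise_sd SD of per-sample per-feature log noise
#'   (default 0.3).
#' @param library_size_mean,library_size_dispersion Negative-binomial mean
#'   and size parameter of library sizes (defaults 5e4 and 10).
#' @param zero_inflation Extra probability of forcing a count to zero
#'   (default 0; sparsity otherwise arises from multinomial sampling alone).
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_studies = 2, samples_per_study = 40,
                              n_features = 200, baseline_logmean_sd = 2,
                              bias_sd = 1, n_differential = 0,
                              effect_logfold = log(4),
                              effect_direction = c("balanced", "up"),
                              effect_features = c("non_dominant", "any"),
                              phenotype_type = c("binary", "continuous"),
                              confounding_rho = 0, sample_noise_sd = 0.3,
                              library_size_mean = 5e4,
                              library_size_dispersion = 10,
                              zero_inflation = 0, seed = 1) {
  phenotype_type <- match.arg(phenotype_type)
  effect_direction <- match.arg(effect_direction)
  effect_features <- match.arg(effect_features)
  stopifnot(n_studies >= 1, n_features >= 1,
            n_differential <= n_features, n_differential >= 0,
            confounding_rho >= 0, confounding_rho <= 1,
            baseline_logmean_sd >= 0, all(bias_sd >= 0),
            sample_noise_sd >= 0, zero_inflation >= 0, zero_inflation < 1,
            library_size_mean > 0, library_size_dispersion > 0)
  structure(list(
    n_studies = n_studies,
    samples_per_study = rep_len(samples_per_study, n_studies),
    n_features = n_features, baseline_logmean_sd = baseline_logmean_sd,
    bias_sd = rep_len(bias_sd, n_studies),
    n_differential = n_differential, effect_logfold = effect_logfold,
    effect_direction = effect_direction,
    effect_features = effect_features,
    phenotype_type = phenotype_type, confounding_rho = confounding_rho,
    sample_noise_sd = sample_noise_sd,
    library_size_mean = library_size_mean,
    library_size_dispersion = library_size_dispersion,
    zero_inflation = zero_inflation, seed = seed),
    class = "simulation_config")
}

#' Simulate a multi-study compositional count dataset with ground truth
#'
#' Generative model: per-feature baseline log-abundances are normal; each
#' study adds its own per-feature log-normal multiplicative bias (a global
#' per-study factor would cancel under closure, so the bias must be
#' feature-specific to create a batch effect); a phenotype is assigned with
#' study dependence controlled by `confounding_rho`; the chosen differential
#' features get `effect_logfold` added in log space for cases (binary) or
#' `effect_logfold` times the standardized phenotype (continuous); per-cell
#' log noise is added; each sample's composition is the closure of the
#' exponentiated log abundances; counts are multinomial draws at a
#' negative-binomial library size. All draws flow from the config seed, so
#' identical configs give bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return List with `table` (`feature_table`, space `counts`), `meta`
#'   (`sample_metadata` with `phenotype` and `study` columns) and `truth`
#'   (`ground_truth`: differential feature ids, per-feature per-study log
#'   bias, true compositions' effect sizes, per-sample phenotype).
#' @export
simulate_dataset <- function(config) {
  cf <- config
  with_seed(cf$seed, {
    n <- sum(cf$samples_per_study)
    study <- factor(rep(paste0("study", seq_len(cf$n_studies)),
                        cf$samples_per_study))
    fid <- sprintf("f%03d", seq_len(cf$n_features))
    sid <- sprintf("s%03d", seq_len(n))
    baseline <- stats::rnorm(cf$n_features, 0, cf$baseline_logmean_sd)
    bias <- vapply(seq_len(cf$n_studies), function(b)
      stats::rnorm(cf$n_features, 0, cf$bias_sd[b]), numeric(cf$n_features))
    dimnames(bias) <- list(fid, levels(study))
    # phenotype with tunable study confounding
    rho <- cf$confounding_rho
    study_idx <- as.integer(study)
    if (cf$phenotype_type == "binary") {
      study_case <- (study_idx %% 2) == 1   # odd studies lean "case"
      pcase <- 0.5 * (1 - rho) + rho * as.numeric(study_case)
      # fixed class counts per study (a designed case-control cohort), with
      # randomized positions; per-sample Bernoulli draws would let random
      # per-study case fractions correlate the phenotype with study
      # membership even at rho = 0
      phen <- character(n)
      for (b in seq_len(cf$n_studies)) {
        idx_b <- which(study_idx == b)
        n_case <- round(pcase[idx_b[1]] * length(idx_b))
        lab <- c(rep("case", n_case),
                 rep("control", length(idx_b) - n_case))
        phen[idx_b] <- sample(lab)
      }
      phen <- factor(phen, levels = c("control", "case"))
      effect_mult <- as.numeric(phen == "case")
    } else {
      shift <- rho * (study_idx - mean(seq_len(cf$n_studies)))
      phen <- shift + stats::rnorm(n)
      effect_mult <- as.numeric(scale(phen))
    }
    pool <- if (identical(cf$effect_features, "non_dominant"))
      fid[baseline < stats::median(baseline)] else fid
    if (length(pool) < cf$n_differential)
      stop("not enough eligible features to plant ", cf$n_differential,
           " differential effects")
    diff_feats <- if (cf$n_differential > 0)
      sort(sample(pool, cf$n_differential)) else character(0)
    effect_sign <- if (identical(cf$effect_direction, "up"))
      rep(1, length(diff_feats))
    else sample(rep_len(c(1, -1), length(diff_feats)))
    names(effect_sign) <- diff_feats
    logab <- matrix(rep(baseline, each = n), n, cf$n_features,
                    dimnames = list(sid, fid))
    logab <- logab + t(bias[, study_idx])
    if (length(diff_feats))
      logab[, diff_feats] <- logab[, diff_feats] +
        outer(effect_mult, cf$effect_logfold * effect_sign)
    logab <- logab + matrix(stats::rnorm(n * cf$n_features, 0,
                                         cf$sample_noise_sd),
                            n, cf$n_features)
    comp <- exp(logab - apply(logab, 1, max))
    comp <- comp / rowSums(comp)
    libs <- stats::rnbinom(n, size = cf$library_size_dispersion,
                           mu = cf$library_size_mean)
    libs <- pmax(libs, 1000L)               # guard against degenerate libraries
    counts <- t(vapply(seq_len(n), function(i)
      as.numeric(stats::rmultinom(1, libs[i], comp[i, ])),
      numeric(cf$n_features)))
    if (cf$zero_inflation > 0) {
      drop <- matrix(stats::runif(n * cf$n_features) < cf$zero_inflation,
                     n, cf$n_features)
      counts[drop] <- 0
    }
    dimnames(counts) <- list(sid, fid)
    keep_samples <- rowSums(counts) > 0
    counts <- counts[keep_samples, , drop = FALSE]
    table <- feature_table(counts, space = "counts")
    meta <- sample_metadata(
      data.frame(sample_id = rownames(counts),
                 phenotype = if (is.factor(phen)) as.character(phen[keep_samples])
                             else phen[keep_samples],
                 study = as.character(study[keep_samples]),
                 stringsAsFactors = FALSE),
      phenotype = "phenotype", batch = "study")
    truth <- structure(list(
      feature_ids = fid,
      differential_features = diff_feats,
      log_bias = bias,
      effect_logfold = cf$effect_logfold,
      effect_sign = effect_sign,
      phenotype = stats::setNames(phen[keep_samples], rownames(counts)),
      true_composition = comp[keep_samples, , drop = FALSE]),
      class = "ground_truth")
    list(table = table, meta = meta, truth = truth)
  })
}
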