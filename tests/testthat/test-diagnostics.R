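# brute-force sqrt(R^2) through the normal equations, independent of lm()
oracle_sqrt_r2 <- function(scores, fac) {
  f <- droplevels(factor(fac))
  D <- cbind(1, vapply(levels(f)[-1], function(l) as.numeric(f == l),
                       numeric(length(f))))
  b <- solve(t(D) %*% D, t(D) %*% scores)
  fitted <- D %*% b
  ss_res <- sum((scores - fitted)^2)
  ss_tot <- sum((scores - mean(scores))^2)
  sqrt(1 - ss_res / ss_tot)
}

fake_pc_model <- function(scores) {
  K <- ncol(scores)
  structure(list(scores = scores,
                 loadings = diag(1, K, K),
                 variance_fraction = rep(1 / K, K),
                 feature_means = rep(0, K)),
            class = "pc_model")
}

test_that("binary covariates reduce to the absolute Pearson correlation", {
  scores <- matrix(c(1, 2, 3, 4), 4, 1,
                   dimnames = list(paste0("s", 1:4), "PC1"))
  meta <- toy_metadata(rep("x", 4), phenotype = c("0", "0", "1", "1"))
  cm <- pc_covariate_correlation(fake_pc_model(scores), meta,
                                 covariates = "phenotype", n_pcs = 1)
  expect_equal(cm$correlations[1, 1], 2 / sqrt(5), tolerance = 1e-12)
  # and equals |Pearson| with 0/1 coding
  expect_equal(cm$correlations[1, 1],
               abs(cor(scores[, 1], c(0, 0, 1, 1))), tolerance = 1e-12)

  # covariate identical to the scores correlates perfectly
  meta2 <- sample_metadata(
    data.frame(sample_id = paste0("s", 1:4), study = "x",
               phenotype = "a", v = c(1, 2, 3, 4)),
    phenotype = "phenotype", batch = "study")
  cm2 <- pc_covariate_correlation(fake_pc_model(scores), meta2,
                                  covariates = "v", n_pcs = 1)
  expect_equal(cm2$correlations[1, 1], 1, tolerance = 1e-12)
})

test_that("categorical correlations match the brute-force OLS oracle", {
  set.seed(40)
  for (i in 1:100) {
    n <- sample(12:40, 1)
    scores <- matrix(rnorm(n), n, 1,
                     dimnames = list(paste0("s", 1:n), "PC1"))
    L <- sample(2:4, 1)
    fac <- sample(letters[1:L], n, replace = TRUE)
    if (length(unique(fac)) < 2) next
    meta <- toy_metadata(rep("x", n), phenotype = fac)
    cm <- pc_covariate_correlation(fake_pc_model(scores), meta,
                                   covariates = "phenotype", n_pcs = 1)
    expect_equal(cm$correlations[1, 1], oracle_sqrt_r2(scores[, 1], fac),
                 tolerance = 1e-10)
  }
})

test_that("correlations are invariant to relabeling and affine covariate maps", {
  set.seed(41)
  n <- 30
  scores <- matrix(rnorm(2 * n), n, 2,
                   dimnames = list(paste0("s", 1:n), c("PC1", "PC2")))
  fac <- sample(c("a", "b", "c"), n, replace = TRUE)
  age <- rnorm(n)
  build <- function(f, a) sample_metadata(
    data.frame(sample_id = paste0("s", 1:n), study = "x", phenotype = f,
               age = a), phenotype = "phenotype", batch = "study")
  m1 <- pc_covariate_correlation(fake_pc_model(scores), build(fac, age),
                                 covariates = c("phenotype", "age"), n_pcs = 2)
  relabeled <- c(a = "zebra", b = "yak", c = "xerus")[fac]
  m2 <- pc_covariate_correlation(fake_pc_model(scores),
                                 build(relabeled, 3 * age - 7),
                                 covariates = c("phenotype", "age"), n_pcs = 2)
  expect_equal(m1$correlations, m2$correlations, tolerance = 1e-10)

  # constant covariate degrades gracefully
  expect_warning(
    m3 <- pc_covariate_correlation(fake_pc_model(scores),
                                   build(rep("a", n), age),
                                   covariates = "phenotype", n_pcs = 1),
    "constant")
  expect_equal(m3$correlations[1, 1], 0)
  expect_equal(m3$p_values[1, 1], 1)
})

test_that("the paired signed-rank comparison detects a uniform increase", {
  set.seed(42)
  base <- matrix(runif(30, 0.1, 0.6), 15, 2,
                 dimnames = list(paste0("PC", 1:15), c("u", "v")))
  mk <- function(m) structure(list(correlations = m,
                                   p_values = m * 0 + 0.5,
                                   test = m), class = "correlation_matrix")
  up <- compare_correlation_distributions(mk(base), mk(base + 0.1))
  expect_lt(up$p_value, 0.01)
  expect_equal(up$median_after - up$median_before, 0.1, tolerance = 1e-12)

  # all-tied input has no information for the test
  expect_error(compare_correlation_distributions(mk(base), mk(base)),
               "fewer than 5 non-tied pairs")
  one_up <- base; one_up[1, 1] <- one_up[1, 1] + 0.2
  expect_error(compare_correlation_distributions(mk(base), mk(one_up)),
               "fewer than 5 non-tied pairs")
})

test_that("variance-explained summaries respect conservation", {
  tab <- random_generic(20, 6, seed = 43)
  pm <- fit_pca(tab, 6)
  vs <- variance_explained_summary(pm, 6)
  expect_equal(vs$cumulative, 1, tolerance = 1e-8)
  expect_equal(variance_explained_summary(pm, 2)$fractions,
               pm$variance_fraction[1:2])

  # isotropic noise spreads variance roughly evenly
  iso <- random_generic(4000, 5, seed = 44)
  pi5 <- fit_pca(iso, 5)
  expect_true(all(abs(pi5$variance_fraction - 0.2) < 0.05))

  expect_error(variance_explained_summary(pm, 9), "between 1 and")
})
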