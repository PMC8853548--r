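test_that("bmc centers each batch and is idempotent", {
  tab <- make_table(matrix(c(1, 3, 10, 20), 4, 1))
  d <- batch_design(two_batch_labels(2, 2))
  out <- bmc(tab, d)$corrected$values
  expect_equal(as.numeric(out), c(-1, 1, -5, 5))

  again <- bmc(bmc(tab, d)$corrected, d)$corrected$values
  expect_equal(again, out, tolerance = 1e-12)

  # within-batch means are zero after correction
  tab2 <- random_generic(30, 15, seed = 10)
  d2 <- batch_design(two_batch_labels(14, 16))
  out2 <- bmc(tab2, d2)$corrected$values
  expect_lt(max(abs(colMeans(out2[1:14, ]))), 1e-10)
  expect_lt(max(abs(colMeans(out2[15:30, ]))), 1e-10)

  expect_error(batch_design(rep("A", 5)), ">= 2 batch levels")
  expect_silent(batch_design(rep("A", 5), allow_single_batch = TRUE))
})

test_that("dcc equals bmc for a single categorical covariate", {
  for (seed in 1:50) {
    n1 <- 5 + seed %% 7
    n2 <- 6 + seed %% 5
    tab <- random_generic(n1 + n2, 8, seed = seed)
    study <- two_batch_labels(n1, n2)
    meta <- toy_metadata(study, phenotype = rep("x", n1 + n2))
    a <- dcc(tab, meta, "study")$corrected$values
    b <- bmc(tab, batch_design(study))$corrected$values
    expect_lt(max(abs(a - b)), 1e-9)
  }
})

test_that("dcc residuals are orthogonal to the design", {
  tab <- random_generic(40, 12, seed = 11)
  meta <- toy_metadata(two_batch_labels(20, 20),
                       phenotype = rep(c("a", "b"), 20),
                       extra = data.frame(age = rnorm(40)))
  res <- dcc(tab, meta, c("study", "age"))
  X <- cbind(1, as.numeric(meta$study == "B"), meta$age)
  expect_lt(max(abs(t(X) %*% res$corrected$values)), 1e-8)

  # constant feature comes back as all-zero residuals
  m <- tab$values; m[, 1] <- 7
  res2 <- dcc(make_table(m), meta, "study")
  expect_lt(max(abs(res2$corrected$values[, 1])), 1e-12)

  # an aliased design is rejected with the offending columns named
  meta2 <- toy_metadata(two_batch_labels(20, 20),
                        phenotype = c(rep("a", 20), rep("b", 20)))
  expect_error(dcc(tab, meta2, c("study", "phenotype")),
               "aliased columns.*phenotype")
})

test_that("linear batch removal matches dcc when nothing is protected", {
  tab <- random_generic(24, 10, seed = 12)
  study <- two_batch_labels(12, 12)
  d <- batch_design(study)
  meta <- toy_metadata(study, phenotype = rep(c("a", "b"), 12))
  a <- linear_batch_removal(tab, d)$corrected$values
  b <- dcc(tab, meta, "study")$corrected$values
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("linear batch removal erases a planted offset but keeps a protected signal", {
  set.seed(13)
  n <- 40
  study <- two_batch_labels(20, 20)
  phen <- rep(c("case", "ctrl"), 20)
  base <- matrix(rnorm(n * 6), n, 6)
  delta <- 2.0
  m <- base
  m[study == "B", ] <- m[study == "B", ] + delta
  sig <- 1.5 * as.numeric(phen == "case")
  m[, 1] <- m[, 1] + sig
  tab <- make_table(m)
  meta <- toy_metadata(study, phenotype = phen)

  out <- linear_batch_removal(tab, batch_design(study), meta = meta,
                              protect = "phenotype")$corrected$values
  gap <- colMeans(out[study == "A", ]) - colMeans(out[study == "B", ])
  expect_lt(max(abs(gap[-1])), 1e-9)
  # protected phenotype contrast survives in feature 1
  contrast <- mean(out[phen == "case", 1]) - mean(out[phen == "ctrl", 1])
  expect_gt(contrast, 1)

  # perfect confounding of protected phenotype with batch is rejected
  meta2 <- toy_metadata(study, phenotype = c(rep("a", 20), rep("b", 20)))
  expect_error(linear_batch_removal(tab, batch_design(study), meta = meta2,
                                    protect = "phenotype"), "aliased")
})

test_that("limma's removeBatchEffect agrees with linear batch removal", {
  skip_if_not_installed("limma")
  tab <- random_generic(30, 20, seed = 14)
  study <- two_batch_labels(15, 15)
  mine <- linear_batch_removal(tab, batch_design(study))$corrected$values
  ref <- t(limma::removeBatchEffect(t(tab$values), batch = study))
  ref <- sweep(ref, 2, colMeans(ref))   # same data up to the retained grand mean
  expect_lt(max(abs(mine - ref)), 1e-10)
})

test_that("combat leaves identical batches untouched and removes a planted shift", {
  set.seed(15)
  block <- matrix(rnorm(20 * 50), 20, 50)
  m <- rbind(block, block)
  tab <- make_table(m)
  d <- batch_design(two_batch_labels(20, 20))
  out <- combat(tab, d)$corrected$values
  expect_lt(max(abs(out - m)), 1e-8)

  # null data with a location shift of 3.0 on batch B
  set.seed(16)
  m2 <- matrix(rnorm(40 * 50), 40, 50)
  m2[21:40, ] <- m2[21:40, ] + 3.0
  tab2 <- make_table(m2)
  gap <- function(x) abs(colMeans(x[1:20, ]) - colMeans(x[21:40, ]))
  out2 <- combat(tab2, d)$corrected$values
  expect_lt(mean(gap(out2)), 0.1 * mean(gap(m2)))

  small <- make_table(matrix(rnorm(10), 5, 2))
  expect_error(combat(small, batch_design(rep(c("A", "B"), c(2, 3)))),
               ">= 3 samples per batch")
})

test_that("combat with a single feature equalizes batch means via its own estimates", {
  set.seed(17)
  v <- c(rnorm(10, 0, 1), rnorm(10, 4, 1))
  tab <- make_table(matrix(v, 20, 1))
  d <- batch_design(two_batch_labels(10, 10))
  out <- combat(tab, d)$corrected$values
  expect_lt(abs(mean(out[1:10, 1]) - mean(out[11:20, 1])), 1e-6)
})

test_that("sva's ComBat is numerically close on well-conditioned data", {
  skip_if_not_installed("sva")
  set.seed(18)
  m <- matrix(rnorm(80 * 40), 80, 40)
  m[41:80, ] <- m[41:80, ] + rep(rnorm(40, 1, 0.5), each = 40)
  tab <- make_table(m)
  study <- two_batch_labels(40, 40)
  mine <- combat(tab, batch_design(study))$corrected$values
  ref <- suppressMessages(t(sva::ComBat(t(m), batch = study)))
  # estimator details differ (variance divisor, stopping rule); agreement is
  # expected to O(1/n_batch)
  expect_gt(stats::cor(as.vector(mine), as.vector(ref)), 0.999)
  expect_lt(max(abs(mine - ref)), 0.1)
})

test_that("percentile normalization scores values against batch controls", {
  # one batch, controls hold values 1..4 on the single feature
  m <- matrix(c(1, 2, 3, 4, 2.5), 5, 1)
  tab <- make_table(m, space = "generic")
  d <- batch_design(rep("A", 5), allow_single_batch = TRUE)
  ctrl <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  out <- percentile_normalize(tab, d, ctrl)$corrected$values
  expect_equal(out[5, 1], 50)      # 2 controls below, no ties
  expect_equal(out[2, 1], 37.5)    # 1 below + half the self-tie
  expect_true(all(out >= 0 & out <= 100))

  # all-equal controls put any tied case at 50
  m2 <- matrix(c(2, 2, 2, 2), 4, 1)
  out2 <- percentile_normalize(make_table(m2),
                               batch_design(rep("A", 4),
                                            allow_single_batch = TRUE),
                               c(TRUE, TRUE, TRUE, FALSE))$corrected$values
  expect_equal(out2[4, 1], 50)

  expect_error(percentile_normalize(tab, d, rep(FALSE, 5)), "no control")
})

test_that("percentile scores are invariant to monotone within-batch transforms", {
  tab <- random_generic(20, 6, seed = 19)
  d <- batch_design(two_batch_labels(10, 10))
  ctrl <- rep(c(TRUE, FALSE), 10)
  a <- percentile_normalize(tab, d, ctrl)$corrected$values
  warped <- make_table(exp(tab$values) + tab$values^3)
  b <- percentile_normalize(warped, d, ctrl)$corrected$values
  expect_equal(a, b)
})

test_that("corrections preserve identifiers and ordering", {
  tab <- random_generic(12, 5, seed = 20)
  study <- two_batch_labels(6, 6)
  meta <- toy_metadata(study, phenotype = rep(c("a", "b"), 6))
  for (res in list(bmc(tab, batch_design(study)),
                   dcc(tab, meta, "study"),
                   linear_batch_removal(tab, batch_design(study)),
                   combat(tab, batch_design(study)))) {
    expect_identical(sample_ids(res$corrected), sample_ids(tab))
    expect_identical(feature_ids(res$corrected), feature_ids(tab))
  }
})

test_that("back-transform dispatches on space and round-trips compositions", {
  comp <- random_composition(8, 5, seed = 21)
  clr <- clr_transform(comp)
  back <- to_relative_abundance(clr)
  expect_lt(max(abs(back$values - comp$values)), 1e-12)

  logt <- make_table(matrix(c(0, log(3)), 1, 2), space = "log")
  out <- to_relative_abundance(logt)
  expect_equal(as.numeric(out$values), c(0.25, 0.75))

  expect_error(to_relative_abundance(random_generic(2, 2)),
               "no declared back-transform")
})
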