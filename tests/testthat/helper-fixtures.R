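# Fixture builders shared across the suite. Everything is generated in code;
# seeds are fixed where values are asserted.

make_table <- function(values, space = "generic") {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  feature_table(values, space = space)
}

# strictly positive random composition matrix (rows sum to 1)
random_composition <- function(n, k, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n * k), n, k)
  make_table(m / rowSums(m), space = "relative")
}

random_generic <- function(n, k, seed = 1) {
  set.seed(seed)
  make_table(matrix(rnorm(n * k), n, k), space = "generic")
}

two_batch_labels <- function(n1, n2) {
  factor(rep(c("A", "B"), c(n1, n2)))
}

toy_metadata <- function(study, phenotype, extra = NULL) {
  df <- data.frame(sample_id = paste0("s", seq_along(study)),
                   study = as.character(study),
                   phenotype = phenotype,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  sample_metadata(df, phenotype = "phenotype", batch = "study")
}
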