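#' Construct a feature table
#'
#' A feature table holds a samples-by-features numeric matrix together with a
#' declaration of the space its values live in and a log of the transforms
#' that produced it. Samples are rows and features are columns throughout the
#' package; the usual statistical-genomics convention of features-by-samples
#' is the transpose of this layout.
#'
#' @param values Numeric matrix with unique row names (sample identifiers)
#'   and unique column names (feature identifiers). No missing values.
#' @param space One of `"counts"`, `"relative"`, `"log"`, `"clr"`,
#'   `"generic"`. Declares the scale of `values` and is checked:
#'   counts must be non-negative, relative rows must sum to 1 (tolerance
#'   1e-8), clr rows must sum to 0 (tolerance 1e-8).
#' @param transform_log List of character descriptors of operations already
#'   applied, most recent last.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values,
                          space = c("generic", "counts", "relative", "log", "clr"),
                          transform_log = list()) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample (row) and feature (column) names")
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  dup_f <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_f))
    stop("duplicate feature identifiers: ", paste(dup_f, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` contains missing or non-finite entries")
  check_space(values, space)
  structure(list(values = values, space = space,
                 transform_log = transform_log),
            class = "feature_table")
}

check_space <- function(values, space) {
  if (space == "counts" && any(values < 0))
    stop("space = 'counts' requires non-negative values")
  if (space == "relative") {
    if (any(values < 0))
      stop("space = 'relative' requires non-negative values")
    if (any(abs(rowSums(values) - 1) > 1e-8))
      stop("space = 'relative' requires every row to sum to 1 (tolerance 1e-8)")
  }
  if (space == "clr" && any(abs(rowSums(values)) > 1e-8))
    stop("space = 'clr' requires every row to sum to 0 (tolerance 1e-8)")
  invisible(TRUE)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features [space: %s]\n",
              nrow(x$values), ncol(x$values), x$space))
  if (length(x$transform_log))
    cat("transforms:", paste(unlist(x$transform_log), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Sample identifiers of a feature table
#' @param table A `feature_table`.
#' @return Character vector of sample ids, in row order.
#' @export
sample_ids <- function(table) rownames(table$values)

#' Feature identifiers of a feature table
#' @param table A `feature_table`.
#' @return Character vector of feature ids, in column order.
#' @export
feature_ids <- function(table) colnames(table$values)

ft_update <- function(table, values, space = table$space, log_entry = NULL) {
  tl <- table$transform_log
  if (!is.null(log_entry)) tl <- c(tl, list(log_entry))
  feature_table(values, space = space, transform_log = tl)
}

#' Sample metadata with declared phenotype and batch columns
#'
#' Wraps a data frame of per-sample covariates. Each column is typed
#' categorical or continuous; the phenotype and batch/study columns are
#' designated by name and must be fully observed for the samples used in any
#' analysis (no imputation is ever performed).
#'
#' @param data Data frame with one row per sample and a `sample_id` column
#'   (or unique row names used as sample ids).
#' @param phenotype Name of the phenotype column.
#' @param batch Name of the batch/study column.
#' @param types Optional named character vector mapping column names to
#'   `"categorical"` or `"continuous"`; unlisted columns are inferred
#'   (factor/character/logical -> categorical, numeric -> continuous).
#'
#' @return An object of class `sample_metadata` (a data frame with
#'   attributes `phenotype_col`, `batch_col` and `col_types`).
#' @export
sample_metadata <- function(data, phenotype, batch, types = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(data)) {
    ids <- as.character(data$sample_id)
    data$sample_id <- NULL
  } else {
    ids <- rownames(data)
  }
  if (is.null(ids) || anyDuplicated(ids))
    stop("sample identifiers must be present and unique")
  rownames(data) <- ids
  for (col in c(phenotype, batch)) {
    if (!col %in% names(data)) stop("column not found in metadata: ", col)
  }
  inferred <- vapply(data, function(v) {
    if (is.numeric(v)) "continuous" else "categorical"
  }, character(1))
  if (!is.null(types)) {
    bad <- setdiff(names(types), names(data))
    if (length(bad)) stop("type declared for unknown column: ",
                          paste(bad, collapse = ", "))
    stopifnot(all(types %in% c("categorical", "continuous")))
    inferred[names(types)] <- types
  }
  structure(data, phenotype_col = phenotype, batch_col = batch,
            col_types = inferred, class = c("sample_metadata", "data.frame"))
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("sample_metadata: %d samples, %d columns (phenotype: %s, batch: %s)\n",
              nrow(x), ncol(x), attr(x, "phenotype_col"), attr(x, "batch_col")))
  invisible(x)
}

#' Phenotype values of a metadata object
#' @param meta A `sample_metadata`.
#' @return The phenotype column, named by sample id.
#' @export
phenotype_of <- function(meta) {
  v <- meta[[attr(meta, "phenotype_col")]]
  names(v) <- rownames(meta)
  v
}

#' Batch labels of a metadata object
#' @param meta A `sample_metadata`.
#' @return The batch column as a factor, named by sample id.
#' @export
batch_of <- function(meta) {
  v <- factor(meta[[attr(meta, "batch_col")]])
  names(v) <- rownames(meta)
  v
}

meta_subset <- function(meta, ids) {
  out <- meta[ids, , drop = FALSE]
  structure(out, phenotype_col = attr(meta, "phenotype_col"),
            batch_col = attr(meta, "batch_col"),
            col_types = attr(meta, "col_types"),
            class = c("sample_metadata", "data.frame"))
}

#' Align a feature table with sample metadata
#'
#' Restricts both objects to their common samples, in the feature table's
#' order. Samples present in only one input are dropped with a warning.
#'
#' @param table A `feature_table`.
#' @param meta A `sample_metadata`.
#' @return List with elements `table` and `meta` over the common samples in
#'   identical order.
#' @export
align_samples <- function(table, meta) {
  common <- intersect(sample_ids(table), rownames(meta))
  if (!length(common))
    stop("no samples in common between feature table and metadata")
  dropped <- c(setdiff(sample_ids(table), common), setdiff(rownames(meta), common))
  if (length(dropped))
    warning("dropping samples absent from one input: ",
            paste(dropped, collapse = ", "))
  keep <- sample_ids(table)[sample_ids(table) %in% common]
  tab <- ft_update(table, table$values[keep, , drop = FALSE])
  list(table = tab, meta = meta_subset(meta, keep))
}

#' Close each sample to relative abundance
#'
#' Divides every row by its row sum so each sample sums to 1, converting
#' counts (or any non-negative table) to a composition.
#'
#' @param table A `feature_table` with space `counts` or `relative`.
#' @return A `feature_table` with space `relative`.
#' @export
closure <- function(table) {
  if (!table$space %in% c("counts", "relative"))
    stop("closure requires space 'counts' or 'relative', got '", table$space, "'")
  rs <- rowSums(table$values)
  zero <- rs == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(sample_ids(table)[zero], collapse = ", "))
  ft_update(table, table$values / rs, space = "relative", log_entry = "closure")
}

#' Filter features by prevalence
#'
#' Keeps features detected (value > 0) in at least a given fraction of
#' samples; feature order is preserved.
#'
#' @param table A `feature_table`.
#' @param min_prevalence Fraction in `[0, 1]`. Default 0.1, the package
#'   default for the titration pipeline.
#' @return The filtered `feature_table`.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.1) {
  stopifnot(min_prevalence >= 0, min_prevalence <= 1)
  prev <- colMeans(table$values > 0)
  keep <- prev >= min_prevalence
  if (!any(keep))
    stop("prevalence filter at ", min_prevalence, " removes all features")
  # dropping features breaks the unit-sum / zero-sum invariant; values are
  # left untouched (no re-closure) so the space degrades to generic
  space <- if (all(keep) || !table$space %in% c("relative", "clr"))
    table$space else "generic"
  ft_update(table, table$values[, keep, drop = FALSE], space = space,
            log_entry = sprintf("prevalence_filter(%g)", min_prevalence))
}
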