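#' Read a feature table from TSV
#'
#' Reads a tab-delimited table with one header row and one identifier column
#' and returns it in the package's internal samples-in-rows orientation. The
#' value space is inferred: `counts` when all values are non-negative
#' integers, `relative` when every row sums to 1 within 1e-6, otherwise
#' `generic`; an explicit `space` overrides inference.
#'
#' @param path Path to a TSV file. The first column holds sample ids (or
#'   feature ids when `orientation = "features_in_rows"`).
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @param space Optional explicit space overriding inference.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_in_rows", "features_in_rows"),
                               space = NULL) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate identifiers in ", path, ": ", paste(dup, collapse = ", "))
  other <- names(df)[-1]
  mat <- matrix(NA_real_, nrow(df), length(other),
                dimnames = list(ids, other))
  for (j in seq_along(other)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                   path, ids[bad[1]], other[j]))
    mat[, j] <- v
  }
  if (orientation == "features_in_rows") mat <- t(mat)
  if (is.null(space)) space <- infer_space(mat)
  feature_table(mat, space = space)
}

infer_space <- function(mat) {
  if (all(mat >= 0) && all(abs(mat - round(mat)) < 1e-9)) return("counts")
  if (all(mat >= 0) && all(abs(rowSums(mat) - 1) < 1e-6)) return("relative")
  "generic"
}

#' Write a feature table to TSV
#'
#' Writes samples in rows with a leading `sample_id` column; values are
#' formatted with 12 significant digits so a read/write cycle round-trips
#' within formatting precision.
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  m <- table$values
  df <- data.frame(sample_id = rownames(m),
                   signif(m, 12), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV file with a `sample_id` column.
#' @param phenotype,batch Column names designating the phenotype and
#'   batch/study variables.
#' @param types Optional named vector of column types
#'   (`"categorical"`/`"continuous"`), as in [sample_metadata()].
#' @return A `sample_metadata`.
#' @export
read_sample_metadata <- function(path, phenotype, batch, types = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("metadata file must contain a 'sample_id' column")
  sample_metadata(df, phenotype = phenotype, batch = batch, types = types)
}

#' Read a BIOM 2.1 feature table
#'
#' Available when the `biomformat` package is installed; produces the same
#' `feature_table` as the TSV reader.
#'
#' @param path Path to a BIOM file.
#' @param space Optional explicit space overriding inference.
#' @return A `feature_table`.
#' @export
read_biom_table <- function(path, space = NULL) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- t(as(biomformat::biom_data(b), "matrix"))  # biom stores features x samples
  if (is.null(space)) space <- infer_space(m)
  feature_table(m, space = space)
}
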