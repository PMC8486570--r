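#' Expression matrix container
#'
#' A light S3 container for a samples-by-miRNAs abundance matrix with the two
#' state flags the preprocessing contracts depend on: whether per-sample
#' 50th-percentile normalization has been applied and whether values are on
#' the log2 scale. Raw values are absolute ddPCR concentrations in
#' copies per microliter and must be non-negative.
#'
#' @param values Numeric matrix, samples as rows (rownames = sample ids),
#'   miRNAs as columns (colnames = assay ids). `NA` entries are allowed only
#'   for raw matrices destined for [detectability_filter()].
#' @param normalized Logical flag: values divided by each sample's panel
#'   median.
#' @param log2 Logical flag: values on the log2 scale.
#' @return Object of class `mir_matrix`.
#' @export
mir_matrix <- function(values, normalized = FALSE, log2 = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry sample ids (rownames) and miRNA ids (colnames)")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicated miRNA ids")
  if (!log2 && any(values < 0, na.rm = TRUE)) {
    stop("raw/normalized abundances must be non-negative")
  }
  structure(
    list(values = values, normalized = isTRUE(normalized), log2 = isTRUE(log2)),
    class = "mir_matrix"
  )
}

#' @export
print.mir_matrix <- function(x, ...) {
  cat(sprintf(
    "mir_matrix: %d samples x %d miRNAs [%s%s]\n",
    nrow(x$values), ncol(x$values),
    if (x$normalized) "normalized" else "raw copies/uL",
    if (x$log2) ", log2" else ""
  ))
  invisible(x)
}

#' @export
dim.mir_matrix <- function(x) dim(x$values)

#' @export
as.matrix.mir_matrix <- function(x, ...) x$values

#' Sample and miRNA identifiers of a `mir_matrix`
#' @param x A [mir_matrix()].
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
mirna_ids <- function(x) colnames(x$values)

# internal: check meta covers matrix samples one-to-one
check_meta <- function(matrix, meta) {
  if (!all(c("sample_id") %in% names(meta))) stop("meta must have sample_id")
  missing <- setdiff(sample_ids(matrix), meta$sample_id)
  if (length(missing) > 0) {
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  meta[match(sample_ids(matrix), meta$sample_id), , drop = FALSE]
}
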