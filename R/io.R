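# TSV/CSV readers and writers and JSON model serialization binding the
# pipeline stages together. TSV is the primary format; .csv extensions are
# read/written comma-separated. Matrices are samples-as-rows with a leading
# sample_id column; empty cells or "NA" encode missing values.

.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read and write expression matrices
#'
#' @param path File path (`.tsv`/`.txt` tab-separated, `.csv`
#'   comma-separated). First column `sample_id`, remaining columns one per
#'   miRNA assay.
#' @param normalized,log2 Flags recorded on the returned [mir_matrix()].
#' @return `read_expression_matrix()` returns a [mir_matrix()];
#'   `write_expression_matrix()` returns the path invisibly.
#' @export
read_expression_matrix <- function(path, normalized = FALSE, log2 = FALSE) {
  df <- utils::read.delim(path, sep = .sep_for(path), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("first column must be sample_id (got ", names(df)[1], ")")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$sample_id
  mir_matrix(vals, normalized = normalized, log2 = log2)
}

#' @rdname read_expression_matrix
#' @param matrix A [mir_matrix()].
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(sample_id = sample_ids(matrix), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write sample metadata tables
#'
#' Expected columns: `sample_id`, `patient_id`, `sex`, `role`,
#' `class_label`, `biopsy_site`, `time_months`, `event` (missing columns are
#' filled with `NA`).
#'
#' @param path File path (TSV or CSV).
#' @return `read_sample_meta()` returns a data frame.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, sep = .sep_for(path), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata needs a sample_id column")
  for (col in c("patient_id", "sex", "role", "class_label", "biopsy_site")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  for (col in c("time_months", "event")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df
}

#' @rdname read_sample_meta
#' @param meta Metadata data frame.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read per-sample QC records
#'
#' @param path TSV/CSV with columns `sample_id`, `snord44_ct`, and
#'   optionally `unisp6_ct`.
#' @return Data frame of QC records.
#' @export
read_qc_records <- function(path) {
  df <- utils::read.delim(path, sep = .sep_for(path), stringsAsFactors = FALSE)
  need <- c("sample_id", "snord44_ct")
  if (!all(need %in% names(df))) {
    stop("QC table needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Serialize fitted models to versioned JSON
#'
#' Stores the model type, a format version, and all parameters (classes,
#' centroids or coefficients, training feature order and scaling) so a model
#' fitted once can be reloaded for prediction.
#'
#' @param model An `nsc_model` or `mnlasso_model`.
#' @param path Output `.json` path.
#' @return `save_model_json()` the path, invisibly; `load_model_json()` the
#'   restored model.
#' @export
save_model_json <- function(model, path) {
  type <- if (inherits(model, "nsc_model")) "nsc"
          else if (inherits(model, "mnlasso_model")) "mnlasso"
          else stop("unsupported model class")
  payload <- unclass(model)
  # matrices serialize with their dimnames
  doc <- list(format = "mirtoo-model", version = 1L, type = type,
              model = payload)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "mirtoo-model")) stop("not a mirtoo model file")
  m <- doc$model
  if (doc$type == "nsc") {
    for (f in c("centroid", "d", "d_shrunk", "shrunken_centroid")) {
      m[[f]] <- matrix(as.numeric(m[[f]]), nrow = length(m$classes),
                       byrow = FALSE, dimnames = list(m$classes, m$features))
    }
    for (f in c("overall_centroid", "s")) m[[f]] <- stats::setNames(as.numeric(m[[f]]), m$features)
    m$mk <- stats::setNames(as.numeric(m$mk), m$classes)
    m$prior <- stats::setNames(as.numeric(m$prior), m$classes)
    class(m) <- "nsc_model"
  } else if (doc$type == "mnlasso") {
    m$beta <- matrix(as.numeric(m$beta), nrow = length(m$classes),
                     dimnames = list(m$classes, m$features))
    m$beta0 <- stats::setNames(as.numeric(m$beta0), m$classes)
    m$center <- stats::setNames(as.numeric(m$center), m$features)
    m$scale <- stats::setNames(as.numeric(m$scale), m$features)
    class(m) <- "mnlasso_model"
  } else {
    stop("unknown model type: ", doc$type)
  }
  m
}
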