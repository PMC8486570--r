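#' Average same-patient reference replicates
#'
#' Reference-cohort primary tumors sampled twice from the same patient are
#' collapsed to a single row, the per-miRNA arithmetic mean of the
#' replicates, before normalization (averaging normalized values would mix
#' per-sample scaling factors, so calling this on a normalized matrix is an
#' error). All other rows are untouched.
#'
#' @param matrix Raw [mir_matrix()].
#' @param meta Sample metadata with `sample_id`, `patient_id`, `role`,
#'   `class_label`.
#' @return List with the collapsed `matrix` and `meta` (replicate rows
#'   merged; the first replicate's sample id is kept).
#' @export
average_replicates <- function(matrix, meta) {
  if (matrix$normalized) {
    stop("replicates must be averaged before normalization")
  }
  meta <- check_meta(matrix, meta)
  is_ref <- meta$role == "reference_primary"
  dup_pts <- names(which(table(meta$patient_id[is_ref]) > 1))
  if (length(dup_pts) == 0) return(list(matrix = matrix, meta = meta))

  drop <- logical(nrow(meta))
  vals <- matrix$values
  for (pt in dup_pts) {
    rows <- which(is_ref & meta$patient_id == pt)
    if (length(unique(meta$class_label[rows])) > 1) {
      stop("cannot average replicates with different class labels (patient ",
           pt, ")")
    }
    keep <- rows[1]
    vals[keep, ] <- colMeans(vals[rows, , drop = FALSE])
    drop[rows[-1]] <- TRUE
  }
  list(
    matrix = mir_matrix(vals[!drop, , drop = FALSE]),
    meta = meta[!drop, , drop = FALSE]
  )
}

#' 50th-percentile normalization
#'
#' Divides each sample's abundances by that sample's median over the panel
#' miRNAs (linear-interpolation median; control assays, if present as
#' columns, are excluded from the median but rescaled along with the rest).
#' After normalization every sample's panel median equals 1. Normalization is
#' applied on the full panel before any prediction exclusions are made.
#' Idempotent: renormalizing divides by a median of 1 and changes nothing.
#'
#' @param matrix A [mir_matrix()] on the linear scale.
#' @return Normalized [mir_matrix()].
#' @export
normalize_median <- function(matrix) {
  if (matrix$log2) stop("normalization operates on the linear scale")
  vals <- matrix$values
  panel_cols <- setdiff(colnames(vals), too_controls())
  if (length(panel_cols) == 0) stop("no panel miRNAs in the matrix")
  med <- apply(vals[, panel_cols, drop = FALSE], 1L, stats::median)
  bad <- !is.finite(med) | med <= 0
  if (any(bad)) {
    stop("zero or undefined panel median for sample(s): ",
         paste(rownames(vals)[bad], collapse = ", "))
  }
  mir_matrix(vals / med, normalized = TRUE)
}

#' Log2 feature transform
#'
#' Maps normalized abundances to `log2(x + 0.01)`; the pseudo-count is far
#' below one copy/uL and preserves the ordering of low values. Applying the
#' transform twice is an error.
#'
#' @param matrix Normalized [mir_matrix()].
#' @param pseudo Pseudo-count added before the log (default 0.01).
#' @return Log2-scale [mir_matrix()].
#' @export
log_transform <- function(matrix, pseudo = 0.01) {
  if (matrix$log2) stop("matrix is already log2-transformed")
  if (!matrix$normalized) stop("log transform expects a normalized matrix")
  mir_matrix(log2(matrix$values + pseudo), normalized = TRUE, log2 = TRUE)
}

#' Drop miRNAs from the feature space
#'
#' By default removes miR-122-5p and miR-21-5p, the two assays excluded from
#' prediction, reducing the 89-assay panel to 87 features. Names absent from
#' the matrix raise an error (guards against typos and double exclusion).
#'
#' @param matrix A [mir_matrix()].
#' @param exclusions Character vector of miRNA ids
#'   (default [default_exclusions()]).
#' @return [mir_matrix()] without the listed columns.
#' @export
exclude_mirnas <- function(matrix, exclusions = default_exclusions()) {
  if (length(exclusions) == 0) return(matrix)
  missing <- setdiff(exclusions, mirna_ids(matrix))
  if (length(missing) > 0) {
    stop("miRNA(s) not in the matrix: ", paste(missing, collapse = ", "))
  }
  keep <- setdiff(mirna_ids(matrix), exclusions)
  out <- matrix
  out$values <- matrix$values[, keep, drop = FALSE]
  out
}

#' Two-step detectability filter
#'
#' Step 1 keeps samples with non-missing values for at least `sample_frac`
#' of the miRNAs; step 2 keeps miRNAs with no missing value among the
#' retained samples. The step order is fixed; the output contains no missing
#' values.
#'
#' @param matrix A [mir_matrix()] possibly containing `NA`s.
#' @param sample_frac Minimum fraction of detected miRNAs per sample
#'   (default 0.8).
#' @return Filtered [mir_matrix()].
#' @export
detectability_filter <- function(matrix, sample_frac = 0.8) {
  vals <- matrix$values
  frac_detected <- rowMeans(!is.na(vals))
  keep_samples <- frac_detected >= sample_frac
  if (!any(keep_samples)) {
    stop("detectability filter removed every sample")
  }
  vals <- vals[keep_samples, , drop = FALSE]
  keep_mirnas <- colSums(is.na(vals)) == 0
  out <- matrix
  out$values <- vals[, keep_mirnas, drop = FALSE]
  out
}

#' Per-class mean and SD expression profiles
#'
#' @param matrix A [mir_matrix()].
#' @param labels Class label per sample (length `nrow(matrix)`).
#' @return List with matrices `mean` and `sd` (classes x miRNAs; SD uses the
#'   n-1 denominator and is `NA` for singleton classes) and the per-class
#'   count `n`.
#' @export
class_mean_profiles <- function(matrix, labels) {
  vals <- matrix$values
  stopifnot(length(labels) == nrow(vals))
  classes <- sort(unique(as.character(labels)))
  mu <- t(vapply(classes, function(k) {
    colMeans(vals[labels == k, , drop = FALSE])
  }, numeric(ncol(vals))))
  sd_ <- t(vapply(classes, function(k) {
    rows <- vals[labels == k, , drop = FALSE]
    if (nrow(rows) < 2) rep(NA_real_, ncol(vals)) else apply(rows, 2L, stats::sd)
  }, numeric(ncol(vals))))
  dimnames(mu) <- dimnames(sd_) <- list(classes, colnames(vals))
  list(mean = mu, sd = sd_, n = table(factor(labels, levels = classes)))
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with complete linkage. The default distance is
#' plain Manhattan (L1); Pearson correlation distance (1 - r) is available as
#' an alternative. Deterministic given the input row order.
#'
#' @param profiles Numeric matrix, one profile per row (e.g. the `mean`
#'   component of [class_mean_profiles()]), or a [mir_matrix()].
#' @param distance `"manhattan"` (default) or `"correlation"`.
#' @return An [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(profiles, distance = c("manhattan", "correlation")) {
  distance <- match.arg(distance)
  x <- if (inherits(profiles, "mir_matrix")) profiles$values else as.matrix(profiles)
  if (nrow(x) < 2) stop("need at least two profiles to cluster")
  if (anyNA(x)) stop("profiles contain missing values")
  d <- if (distance == "manhattan") {
    stats::dist(x, method = "manhattan")
  } else {
    stats::as.dist(1 - stats::cor(t(x)))
  }
  stats::hclust(d, method = "complete")
}
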