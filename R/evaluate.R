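#' Bootstrap out-of-bag error of a classifier
#'
#' For each of `n_boot` replicates the training set is resampled with
#' replacement (stratified within class by default, so no class disappears
#' from a replicate), the model is refit on the resample, and the samples
#' left out of the resample (out-of-bag) are predicted. First-choice
#' misclassifications are pooled across replicates into per-class error
#' rates and an overall error (the sample-weighted mean of the per-class
#' errors). A replicate whose out-of-bag set misses a class simply
#' contributes nothing to that class. Deterministic given `seed`; running
#' both model types with the same seed evaluates them on identical
#' resamples, so the comparison is paired.
#'
#' @param x Feature matrix.
#' @param y Class labels (>= 2 samples per class).
#' @param model `"nsc"` or `"lasso"`.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param stratified Resample within class (default `TRUE`).
#' @param ... Passed to the fit function.
#' @return Object of class `bootstrap_result`: `per_class_error`,
#'   `overall_error`, `n_boot`, `seed`, `n_oob` (per-class out-of-bag
#'   prediction counts).
#' @export
bootstrap_error <- function(x, y, model = c("nsc", "lasso"), n_boot = 100L,
                            seed = 1L, stratified = TRUE, ...) {
  model <- match.arg(model)
  x <- as.matrix(x); y <- as.character(y)
  classes <- sort(unique(y))
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  wrong <- stats::setNames(numeric(length(classes)), classes)
  total <- stats::setNames(numeric(length(classes)), classes)
  n <- nrow(x)
  for (b in seq_len(n_boot)) {
    idx <- if (stratified) {
      unlist(lapply(classes, function(k) {
        rows <- which(y == k)
        sample(rows, length(rows), replace = TRUE)
      }), use.names = FALSE)
    } else {
      sample.int(n, n, replace = TRUE)
    }
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) == 0) next
    if (model == "nsc") {
      fit <- fit_nsc(x[idx, , drop = FALSE], y[idx], ...)
      p <- predict_nsc(fit, x[oob, , drop = FALSE])
    } else {
      fit <- fit_multinomial_lasso(x[idx, , drop = FALSE], y[idx], ...)
      p <- predict_lasso(fit, x[oob, , drop = FALSE])
    }
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    for (i in seq_along(oob)) {
      k <- y[oob[i]]
      total[k] <- total[k] + 1
      if (pred[i] != k) wrong[k] <- wrong[k] + 1
    }
  }
  per_class <- ifelse(total > 0, wrong / total, NA_real_)
  structure(
    list(
      per_class_error = per_class,
      overall_error = sum(wrong) / sum(total),
      n_boot = as.integer(n_boot), seed = as.integer(seed),
      n_oob = total, model = model
    ),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap (%s, N = %d): overall error %.1f%%\n",
              x$model, x$n_boot, 100 * x$overall_error))
  invisible(x)
}

#' Confusion matrix and positive prediction rate
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Optional class universe (default: union of observed
#'   labels).
#' @return List with `counts` (K x K matrix, rows = truth, columns =
#'   prediction), `ppr` (per-class diagonal over row sum), and `median_ppr`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(classes)) classes <- sort(union(y_true, y_pred))
  counts <- table(
    factor(as.character(y_true), levels = classes),
    factor(as.character(y_pred), levels = classes)
  )
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("true", "predicted")
  rs <- rowSums(counts)
  ppr <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  list(counts = counts, ppr = ppr,
       median_ppr = stats::median(ppr, na.rm = TRUE))
}

#' Top-two accuracy
#'
#' Fraction of samples whose true class appears among a model's two
#' top-ranked predictions.
#'
#' @param y_true True class labels.
#' @param top2 Two-column matrix or data frame of top-1/top-2 predicted
#'   classes (one row per sample), e.g. the `top1_nsc`/`top2_nsc` columns of
#'   a [predict_too()] report.
#' @return Fraction in `[0, 1]`.
#' @export
top2_accuracy <- function(y_true, top2) {
  top2 <- as.matrix(top2)
  stopifnot(nrow(top2) == length(y_true), ncol(top2) == 2)
  mean(y_true == top2[, 1] | y_true == top2[, 2])
}

#' Concordance of predictions across multiple metastases
#'
#' A patient with several profiled metastases is concordant when the
#' intersection of the final prioritized sites across their samples is
#' non-empty; the cohort rate is the fraction of concordant multi-sample
#' patients.
#'
#' @param report A [predict_too()] report (uses `patient_id` and
#'   `final_sites`), or a data frame with those columns.
#' @return List with `per_patient` (data frame: patient_id, n_samples,
#'   concordant, shared_sites) and `rate`.
#' @export
metastasis_concordance <- function(report) {
  stopifnot(all(c("patient_id", "final_sites") %in% names(report)))
  sites <- strsplit(report$final_sites, ";", fixed = TRUE)
  by_pt <- split(sites, report$patient_id)
  by_pt <- by_pt[vapply(by_pt, length, 0L) >= 2]
  if (length(by_pt) == 0) {
    return(list(per_patient = data.frame(), rate = NA_real_))
  }
  per_patient <- do.call(rbind, lapply(names(by_pt), function(pt) {
    shared <- Reduce(intersect, by_pt[[pt]])
    data.frame(
      patient_id = pt,
      n_samples = length(by_pt[[pt]]),
      concordant = length(shared) > 0,
      shared_sites = paste(shared, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  list(per_patient = per_patient, rate = mean(per_patient$concordant))
}
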