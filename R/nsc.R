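#' Fit a nearest-shrunken-centroids classifier
#'
#' Class centroids are compared with the overall centroid on a standardized
#' scale: for class k and feature j,
#' `d_kj = (centroid_kj - overall_j) / (m_k * (s_j + s0))`, with `s_j` the
#' pooled within-class SD (n - K denominator), `s0` the median of the `s_j`
#' (guards against near-zero variances), and `m_k = sqrt(1/n_k - 1/n)`. The
#' deviations are soft-thresholded by `delta`
#' (`d'_kj = sign(d) * max(|d| - delta, 0)`) and the shrunken centroids are
#' rebuilt as `overall_j + m_k * (s_j + s0) * d'_kj`. A feature is used by
#' the classifier iff its shrunken deviation is nonzero in at least one
#' class; with `delta = 0` on continuous data every feature is used and the
#' model is exactly a diagonal-covariance Gaussian discriminant with
#' variances `(s_j + s0)^2`.
#'
#' @param x Numeric feature matrix (samples x features, named columns), no
#'   missing values. Typically normalized, log2-transformed expression.
#' @param y Class label per sample; every class needs >= 2 samples.
#' @param delta Shrinkage threshold (>= 0; default 0, using all features).
#' @param prior `"empirical"` class frequencies (default) or `"uniform"`.
#' @param s0 Optional explicit offset added to every `s_j`; default the
#'   median of the pooled SDs.
#' @return Object of class `nsc_model`.
#' @seealso [predict_nsc()]
#' @export
fit_nsc <- function(x, y, delta = 0, prior = c("empirical", "uniform"),
                    s0 = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), delta >= 0)
  if (anyNA(x)) stop("feature matrix contains missing values")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes")
  nk <- table(factor(y, levels = classes))
  small <- names(nk)[nk < 2]
  if (length(small) > 0) {
    stop("class(es) with fewer than 2 samples: ", paste(small, collapse = ", "))
  }
  n <- nrow(x); K <- length(classes); J <- ncol(x)

  centroid <- matrix(
    unlist(lapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]))),
    nrow = K, ncol = J, byrow = TRUE
  )
  rownames(centroid) <- classes
  overall <- colMeans(x)
  # pooled within-class SD, n - K denominator
  ss <- numeric(J)
  for (k in classes) {
    rows <- x[y == k, , drop = FALSE]
    ss <- ss + colSums(sweep(rows, 2L, centroid[k, ])^2)
  }
  s <- sqrt(ss / (n - K))
  if (is.null(s0)) s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  names(mk) <- classes

  denom <- outer(mk, s + s0)            # K x J
  d <- (centroid - matrix(overall, K, J, byrow = TRUE)) / denom
  d_shrunk <- soft_threshold(d, delta)
  shrunken_centroid <- matrix(overall, K, J, byrow = TRUE) + denom * d_shrunk
  dimnames(centroid) <- dimnames(d) <- dimnames(d_shrunk) <-
    dimnames(shrunken_centroid) <- list(classes, colnames(x))

  prior_vec <- if (is.character(prior)) {
    switch(match.arg(prior),
           empirical = as.numeric(nk) / n,
           uniform = rep(1 / K, K))
  } else {
    stopifnot(length(prior) == K, all(prior > 0))
    prior / sum(prior)
  }
  names(prior_vec) <- classes

  structure(
    list(
      classes = classes, centroid = centroid, overall_centroid = overall,
      s = s, s0 = s0, mk = mk, delta = delta, prior = prior_vec,
      d = d, d_shrunk = d_shrunk, shrunken_centroid = shrunken_centroid,
      features = colnames(x),
      features_used = colnames(x)[colSums(d_shrunk != 0) > 0],
      n = n, nk = as.numeric(nk)
    ),
    class = "nsc_model"
  )
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf(
    "nearest-shrunken-centroids model: %d classes, %d/%d features used, delta = %g\n",
    length(x$classes), length(x$features_used), length(x$features), x$delta
  ))
  invisible(x)
}

#' Per-class probabilities from a nearest-shrunken-centroids model
#'
#' The discriminant score of class k for a profile x is
#' `delta_k(x) = sum_j (x_j - c'_kj)^2 / (s_j + s0)^2 - 2 log pi_k`, i.e. the
#' squared distance to the shrunken centroid in the standardized metric,
#' penalized by the log prior; the sample is assigned the class with the
#' smallest score. Probabilities are `softmax(-delta_k / 2)`, computed with
#' max subtraction for overflow safety.
#'
#' @param model A [fit_nsc()] model.
#' @param x Numeric vector (one profile) or matrix (samples x features) with
#'   the model's feature set.
#' @return Probability matrix (samples x classes), rows summing to 1.
#' @export
predict_nsc <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, 1L, dimnames = list(NULL, names(x))) else as.matrix(x)
  if (!is.null(colnames(x))) {
    missing <- setdiff(model$features, colnames(x))
    if (length(missing) > 0) {
      stop("missing feature(s): ", paste(missing, collapse = ", "))
    }
    x <- x[, model$features, drop = FALSE]
  } else if (ncol(x) != length(model$features)) {
    stop("feature count mismatch")
  }
  sc <- model$s + model$s0
  disc <- vapply(model$classes, function(k) {
    rowSums(sweep(x, 2L, model$shrunken_centroid[k, ])^2 / rep(sc^2, each = nrow(x))) -
      2 * log(model$prior[[k]])
  }, numeric(nrow(x)))
  disc <- matrix(disc, nrow = nrow(x),
                 dimnames = list(rownames(x), model$classes))
  probs <- row_softmax(-disc / 2)
  rownames(probs) <- rownames(x)
  probs
}
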