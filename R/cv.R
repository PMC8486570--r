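#' Cross-validate a shrinkage/penalty threshold
#'
#' Stratified K-fold cross-validation of the misclassification rate over a
#' grid of thresholds: the NSC shrinkage `delta` or the lasso penalty
#' `lambda`, depending on `model`. Returns the grid minimizer; ties go to the
#' larger threshold (the sparser model). Folds are deterministic given
#' `seed`. If some class has fewer samples than folds, the fold count is
#' reduced (with a warning) so every fold can be stratified.
#'
#' @param x Feature matrix.
#' @param y Class labels.
#' @param grid Numeric vector of candidate thresholds.
#' @param n_folds Number of folds (>= 2; default 5).
#' @param model `"nsc"` or `"lasso"`.
#' @param seed Integer seed for fold assignment.
#' @param ... Passed to [fit_nsc()] or [fit_multinomial_lasso()].
#' @return List with `best` (chosen threshold), `grid`, `error`
#'   (CV misclassification per grid value), and `n_folds` used.
#' @export
cross_validate_threshold <- function(x, y, grid, n_folds = 5L,
                                     model = c("nsc", "lasso"), seed = 1L, ...) {
  model <- match.arg(model)
  x <- as.matrix(x); y <- as.character(y)
  stopifnot(n_folds >= 2, length(grid) >= 1)
  grid <- sort(grid)

  min_class <- min(table(y))
  if (min_class < n_folds) {
    n_folds <- max(2L, as.integer(min_class))
    warning("fold count reduced to ", n_folds,
            " (smallest class has ", min_class, " samples)")
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (k in unique(y)) {
    idx <- sample(which(y == k))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }

  err <- vapply(grid, function(g) {
    wrong <- 0L; total <- 0L
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- !tr
      if (model == "nsc") {
        fit <- fit_nsc(x[tr, , drop = FALSE], y[tr], delta = g, ...)
        p <- predict_nsc(fit, x[te, , drop = FALSE])
      } else {
        fit <- fit_multinomial_lasso(x[tr, , drop = FALSE], y[tr], lambda = g, ...)
        p <- predict_lasso(fit, x[te, , drop = FALSE])
      }
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      wrong <- wrong + sum(pred != y[te])
      total <- total + sum(te)
    }
    wrong / total
  }, numeric(1))

  best <- max(grid[err == min(err)])   # ties -> larger threshold
  list(best = best, grid = grid, error = stats::setNames(err, grid),
       n_folds = n_folds)
}
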