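#' Fit an L1-penalized multinomial regression by coordinate descent
#'
#' Minimizes the penalized average negative log-likelihood
#' `(1/n) * NLL(beta0, beta) + lambda * sum_{k,j} |beta_kj|` over the
#' symmetric multinomial parameterization (one intercept and coefficient
#' vector per class; intercepts unpenalized). Features are standardized
#' internally to mean 0 and (population) SD 1, and coefficients are reported
#' on that standardized scale; the training centering/scaling is stored for
#' prediction.
#'
#' Optimization is proximal-Newton in the glmnet style: the algorithm cycles
#' over classes, forms a partial quadratic approximation of the
#' log-likelihood in the current class's parameters with weights
#' `w_i = p_ik (1 - p_ik)` (floored at 1e-5), and solves the penalized
#' weighted least-squares subproblem by cyclic coordinate descent with
#' soft-thresholding and an active-set strategy. If a cycle ever increases
#' the objective, it is redone with the conservative uniform curvature bound
#' 1/4, which majorizes the likelihood and guarantees descent, so the
#' objective is non-increasing across cycles. A fixed point satisfies the
#' KKT conditions of the exact objective: zero coefficients have subgradient
#' `|grad| <= lambda`, active coefficients have `grad = -lambda *
#' sign(beta)`. Non-convergence within `max_iter` outer cycles is reported
#' via `converged = FALSE`, not an error.
#'
#' @param x Numeric feature matrix (samples x features, named columns).
#' @param y Class labels (>= 2 classes).
#' @param lambda Penalty weight on the mean-log-likelihood scale
#'   (default 0.019).
#' @param max_iter Maximum outer cycles (default 500).
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   outer cycle (default 1e-6).
#' @param debug Record the objective after every outer cycle in
#'   `$objective_trace` (used to verify monotone descent).
#' @return Object of class `mnlasso_model` with `classes`, `beta0` (K),
#'   `beta` (K x J, standardized scale), `center`, `scale`, `lambda`,
#'   `converged`, `n_iter`, `features`, `features_used`.
#' @seealso [predict_lasso()], [lasso_kkt()]
#' @export
fit_multinomial_lasso <- function(x, y, lambda = 0.019, max_iter = 500L,
                                  tol = 1e-6, debug = FALSE) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), lambda >= 0)
  if (anyNA(x)) stop("feature matrix contains missing values")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) stop("need at least two classes")
  n <- nrow(x); J <- ncol(x)

  Y <- 1 * outer(y, classes, "==")               # n x K indicator
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2L, ctr)^2))     # population SD: mean(z^2) = 1
  scl[scl == 0] <- 1
  Z <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")

  beta0 <- log(pmax(colMeans(Y), 1e-12))
  beta0 <- beta0 - mean(beta0)
  B <- matrix(0, K, J, dimnames = list(classes, colnames(x)))
  Fs <- matrix(beta0, n, K, byrow = TRUE)        # score matrix

  objective <- function(Fs) {
    P <- row_softmax(Fs)
    i <- cbind(seq_len(n), match(y, classes))
    mean(-log(pmax(P[i], 1e-300))) + lambda * sum(abs(B))
  }

  run_cycle <- function(B, beta0, Fs, uniform_w) {
    delta_max <- 0
    for (k in seq_len(K)) {
      P <- row_softmax(Fs)
      pk <- P[, k]
      w <- if (uniform_w) rep(0.25, n) else pmax(pk * (1 - pk), 1e-5)
      rr <- (Y[, k] - pk) / w                    # z - f at expansion point
      hj <- colMeans(Z^2 * w)
      # penalized WLS subproblem solved by compiled coordinate descent
      fit <- .cd_solve_class(Z, w, rr, B[k, ], beta0[k], hj, lambda, tol, 20L)
      delta_max <- max(delta_max, abs(fit$b - B[k, ]), abs(fit$b0 - beta0[k]))
      B[k, ] <- fit$b
      beta0[k] <- fit$b0
      Fs[, k] <- drop(Z %*% fit$b) + fit$b0
    }
    m0 <- mean(beta0)                            # fix the softmax shift freedom
    beta0 <- beta0 - m0
    Fs <- Fs - m0
    list(B = B, beta0 = beta0, Fs = Fs, delta_max = delta_max)
  }

  converged <- FALSE
  it <- 0L
  obj <- objective(Fs)
  trace <- if (debug) obj else NULL
  repeat {
    it <- it + 1L
    st <- run_cycle(B, beta0, Fs, uniform_w = FALSE)
    obj_new <- local({ P <- row_softmax(st$Fs)
      i <- cbind(seq_len(n), match(y, classes))
      mean(-log(pmax(P[i], 1e-300))) + lambda * sum(abs(st$B)) })
    if (obj_new > obj + 1e-12) {
      # Newton step overshot: redo the cycle with the majorizing bound
      st <- run_cycle(B, beta0, Fs, uniform_w = TRUE)
      obj_new <- local({ P <- row_softmax(st$Fs)
        i <- cbind(seq_len(n), match(y, classes))
        mean(-log(pmax(P[i], 1e-300))) + lambda * sum(abs(st$B)) })
    }
    B <- st$B; beta0 <- st$beta0; Fs <- st$Fs
    obj <- obj_new
    if (debug) trace <- c(trace, obj)
    if (st$delta_max < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }

  structure(
    list(
      classes = classes,
      beta0 = stats::setNames(beta0, classes),
      beta = B,
      center = ctr, scale = scl,
      lambda = lambda, converged = converged, n_iter = it,
      features = colnames(x),
      features_used = colnames(x)[colSums(B != 0) > 0],
      objective = obj,
      objective_trace = trace
    ),
    class = "mnlasso_model"
  )
}

#' @export
print.mnlasso_model <- function(x, ...) {
  cat(sprintf(
    "multinomial lasso: %d classes, %d/%d features with nonzero coefficients, lambda = %g%s\n",
    length(x$classes), length(x$features_used), length(x$features), x$lambda,
    if (x$converged) "" else " (NOT converged)"
  ))
  invisible(x)
}

#' Per-class probabilities from a multinomial lasso model
#'
#' Computes `softmax(beta0_k + sum_j beta_kj * z_j)` where `z` is the input
#' standardized with the training centering and scaling.
#'
#' @param model A [fit_multinomial_lasso()] model.
#' @param x Numeric vector or matrix with the model's feature set (raw,
#'   unstandardized scale).
#' @return Probability matrix (samples x classes), rows summing to 1.
#' @export
predict_lasso <- function(model, x) {
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
  Z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  scores <- Z %*% t(model$beta) + matrix(model$beta0, nrow(Z),
                                         length(model$classes), byrow = TRUE)
  probs <- row_softmax(scores)
  dimnames(probs) <- list(rownames(x), model$classes)
  probs
}

#' Penalized multinomial objective and KKT residuals
#'
#' `lasso_objective()` evaluates the fitted objective
#' (mean negative log-likelihood + L1 penalty) on the training data;
#' `lasso_kkt()` returns the worst violation of the stationarity conditions:
#' for zero coefficients `max(|grad| - lambda, 0)`, for active coefficients
#' `|grad + lambda * sign(beta)|`.
#'
#' @param model A fitted `mnlasso_model`.
#' @param x,y The training data.
#' @return A scalar (objective value or maximum KKT violation).
#' @export
lasso_objective <- function(model, x, y) {
  P <- predict_lasso(model, x)
  i <- cbind(seq_len(nrow(P)), match(as.character(y), model$classes))
  mean(-log(pmax(P[i], 1e-300))) + model$lambda * sum(abs(model$beta))
}

#' @rdname lasso_objective
#' @export
lasso_kkt <- function(model, x, y) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  Z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  P <- predict_lasso(model, x)
  Y <- 1 * outer(as.character(y), model$classes, "==")
  G <- t(P - Y) %*% Z / nrow(Z)                  # K x J gradient of mean NLL
  active <- model$beta != 0
  viol_zero <- pmax(abs(G[!active]) - model$lambda, 0)
  viol_active <- abs(G[active] + model$lambda * sign(model$beta[active]))
  max(c(0, viol_zero, viol_active))
}
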