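#' ROC-optimal expression cutoff
#'
#' Scans the midpoints between consecutive sorted unique expression values
#' and returns the threshold maximizing sensitivity + specificity for the
#' event indicator (a Youden-type cutoff on the empirical ROC curve), where
#' "high" means expression strictly above the cutoff. Ties go to the lowest
#' threshold.
#'
#' @param expression Numeric marker values.
#' @param status Binary outcome (1 = event/death, 0 = censored/alive); both
#'   groups must be non-empty.
#' @return The cutoff, with attributes `sensitivity`, `specificity`, and
#'   `youden` (sens + spec - 1) at the optimum.
#' @export
optimal_cutoff <- function(expression, status) {
  stopifnot(length(expression) == length(status))
  status <- as.integer(status)
  if (!all(status %in% 0:1)) stop("status must be 0/1")
  if (all(status == 1) || all(status == 0)) {
    stop("both status groups must be non-empty")
  }
  u <- sort(unique(expression))
  if (length(u) < 2) stop("constant expression: no informative cutoff")
  cand <- (u[-1] + u[-length(u)]) / 2
  n_event <- sum(status == 1)
  n_ctrl <- sum(status == 0)
  sens <- vapply(cand, function(c) sum(expression > c & status == 1), 0) / n_event
  spec <- vapply(cand, function(c) sum(expression <= c & status == 0), 0) / n_ctrl
  # direction-free: a marker can mark events by low expression too
  score <- pmax(sens + spec, (1 - sens) + (1 - spec))
  best <- which(score == max(score))[1]          # ties -> lowest threshold
  structure(cand[best],
            sensitivity = sens[best], specificity = spec[best],
            youden = score[best] - 1)
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit survival estimates per group and the two-sample log-rank
#' statistic (chi-squared with 1 degree of freedom).
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level grouping vector.
#' @return List with `fit` (a [survival::survfit] object), `chisq`, `df`,
#'   `p`, and the per-group observed/expected event counts.
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  ev_by_group <- tapply(event, group, sum)
  if (any(ev_by_group == 0)) {
    warning("a group has zero events; the log-rank statistic is still defined")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(lr$n) - 1
  list(
    fit = fit,
    chisq = unname(lr$chisq),
    df = df,
    p = stats::pchisq(lr$chisq, df, lower.tail = FALSE),
    observed = lr$obs,
    expected = lr$exp
  )
}

#' Univariate Cox proportional-hazards fit on a binary group
#'
#' Hazard ratio of the high- vs low-expression group from a univariate Cox
#' partial-likelihood fit with Breslow tie handling; the 95% CI is
#' `exp(beta +/- 1.96 * SE)` from the observed information. A group with no
#' events makes the partial likelihood monotone; the fit is then flagged and
#' the CI is unbounded.
#'
#' @param time,event Survival outcome.
#' @param group Binary covariate (high = 1/TRUE vs low = 0/FALSE, or a
#'   two-level factor).
#' @return List with `hr`, `ci_low`, `ci_high`, `beta`, `se`, `p`
#'   (Wald), and `monotone` flag.
#' @export
cox_univariate <- function(time, event, group) {
  if (is.factor(group) || is.character(group)) {
    group <- as.integer(as.factor(group)) - 1L
  } else {
    group <- as.integer(as.logical(group))
  }
  if (length(unique(group)) != 2) stop("group must be binary")
  ev_by_group <- tapply(event, group, sum)
  monotone <- any(ev_by_group == 0)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ group, ties = "breslow")
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (monotone) {
    ci <- c(0, Inf)
  } else {
    ci <- exp(beta + c(-1.96, 1.96) * se)
  }
  list(
    hr = exp(beta), ci_low = ci[1], ci_high = ci[2],
    beta = beta, se = se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    monotone = monotone
  )
}

#' Screen a miRNA panel for prognostic effect
#'
#' For every miRNA in the matrix: estimate the ROC-optimal cutoff against
#' vital status, dichotomize the cohort into high/low expressors, compare
#' survival by log-rank test, and estimate the hazard ratio with 95% CI by
#' univariate Cox regression. Raw p-values at `alpha` define the significant
#' subset (no multiplicity correction, but a Benjamini-Hochberg column is
#' included for transparency). Per-miRNA failures (e.g. constant expression)
#' are recorded in the `note` column, not fatal.
#'
#' @param matrix A [mir_matrix()] (normalized values recommended).
#' @param meta Metadata with `time_months` and `event` for >= 10 samples.
#' @param alpha Significance level on the raw log-rank p (default 0.05).
#' @return Object of class `survival_screen`: a data frame with one row per
#'   miRNA (`mirna_id`, `cutoff`, `n_high`, `n_low`, `hr`, `ci_low`,
#'   `ci_high`, `logrank_p`, `p_bh`, `significant`, `note`).
#' @export
screen_panel <- function(matrix, meta, alpha = 0.05) {
  meta <- check_meta(matrix, meta)
  have <- !is.na(meta$time_months) & !is.na(meta$event)
  if (sum(have) < 10) {
    stop("survival screening needs at least 10 samples with follow-up (got ",
         sum(have), ")")
  }
  time <- meta$time_months[have]
  event <- as.integer(meta$event[have])
  vals <- matrix$values[have, , drop = FALSE]

  rows <- lapply(colnames(vals), function(mir) {
    out <- data.frame(
      mirna_id = mir, cutoff = NA_real_, n_high = NA_integer_,
      n_low = NA_integer_, hr = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, logrank_p = NA_real_, note = "",
      stringsAsFactors = FALSE
    )
    tryCatch({
      cut <- optimal_cutoff(vals[, mir], event)
      high <- vals[, mir] > cut
      if (all(high) || !any(high)) stop("degenerate dichotomization")
      lr <- suppressWarnings(km_logrank(time, event, high))
      cx <- cox_univariate(time, event, high)
      out$cutoff <- as.numeric(cut)
      out$n_high <- sum(high); out$n_low <- sum(!high)
      out$hr <- cx$hr; out$ci_low <- cx$ci_low; out$ci_high <- cx$ci_high
      out$logrank_p <- lr$p
      out
    }, error = function(e) {
      out$note <- conditionMessage(e)
      out
    })
  })
  res <- do.call(rbind, rows)
  res$p_bh <- stats::p.adjust(res$logrank_p, method = "BH")
  res$significant <- !is.na(res$logrank_p) & res$logrank_p <= alpha
  res <- res[, c("mirna_id", "cutoff", "n_high", "n_low", "hr", "ci_low",
                 "ci_high", "logrank_p", "p_bh", "significant", "note")]
  class(res) <- c("survival_screen", "data.frame")
  res
}

#' @export
print.survival_screen <- function(x, ...) {
  cols <- c("mirna_id", "hr", "ci_low", "ci_high", "logrank_p", "significant")
  if (!all(cols %in% names(x))) return(NextMethod())
  cat(sprintf("survival screen: %d miRNAs, %d significant at raw p\n",
              nrow(x), sum(x$significant)))
  sig <- as.data.frame(x)[x$significant, cols[1:5]]
  if (nrow(sig) > 0) print.data.frame(sig, row.names = FALSE, digits = 3)
  invisible(x)
}
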