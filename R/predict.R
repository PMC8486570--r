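#' Zero out sex-incompatible predictions
#'
#' Female patients cannot harbor testicular (TGSC) or prostate (PRAD)
#' primaries, males cannot harbor ovarian (OV) or endometrial (UCEC) ones;
#' the corresponding class probabilities are set to zero and the remaining
#' mass is renormalized to 1. Unknown sex leaves the vector unchanged.
#'
#' @param probs Named probability vector summing to 1.
#' @param sex `"male"`, `"female"`, or `"unknown"`.
#' @return Renormalized probability vector; the zeroed classes are recorded
#'   in the `"excluded"` attribute.
#' @export
sex_filter <- function(probs, sex = c("unknown", "male", "female")) {
  sex <- match.arg(sex)
  excluded <- switch(sex,
    female = intersect(.male_only_classes, names(probs)),
    male = intersect(.female_only_classes, names(probs)),
    unknown = character(0)
  )
  probs[excluded] <- 0
  total <- sum(probs)
  if (total <= 0) stop("sex filter removed all probability mass")
  out <- probs / total
  attr(out, "excluded") <- excluded
  out
}

#' Top-two predicted classes
#'
#' @param probs Named probability vector over >= 2 classes.
#' @return Character vector of the two highest-probability classes in
#'   descending order; ties are broken alphabetically.
#' @export
top_two <- function(probs) {
  if (length(probs) < 2) stop("need at least two classes")
  ord <- order(-probs, names(probs))
  names(probs)[ord[1:2]]
}

#' Prioritize the final tissue-of-origin call
#'
#' Combines the sex-filtered probability vectors of the two classifiers into
#' the final call. Rule A: any class predicted with probability above
#' `p_single` by at least one model. Rule B (when A yields nothing): classes
#' present in both models' top-two lists with probability above `p_shared`
#' in at least one model. Fallback: the union of both top-two lists. All
#' qualifying sites are reported, ordered by their maximum probability
#' across the two models.
#'
#' @param probs_nsc,probs_lasso Named probability vectors (sex filter already
#'   applied).
#' @param p_single Rule A threshold, strict (default 0.80).
#' @param p_shared Rule B threshold, strict (default 0.30).
#' @return List with `final_sites` (non-empty character vector) and `rule`
#'   (`"A"`, `"B"`, or `"fallback"`).
#' @export
prioritize <- function(probs_nsc, probs_lasso, p_single = 0.80, p_shared = 0.30) {
  stopifnot(setequal(names(probs_nsc), names(probs_lasso)))
  probs_lasso <- probs_lasso[names(probs_nsc)]
  pmax_both <- pmax(probs_nsc, probs_lasso)

  rule_a <- names(probs_nsc)[pmax_both > p_single]
  if (length(rule_a) > 0) {
    return(list(final_sites = rule_a[order(-pmax_both[rule_a], rule_a)],
                rule = "A"))
  }
  t_nsc <- top_two(probs_nsc)
  t_lasso <- top_two(probs_lasso)
  shared <- intersect(t_nsc, t_lasso)
  rule_b <- shared[pmax_both[shared] > p_shared]
  if (length(rule_b) > 0) {
    return(list(final_sites = rule_b[order(-pmax_both[rule_b], rule_b)],
                rule = "B"))
  }
  fb <- union(t_nsc, t_lasso)
  list(final_sites = fb[order(-pmax_both[fb], fb)], rule = "fallback")
}

#' Predict tissue of origin for a set of samples
#'
#' Runs both classifiers, applies the sex filter to each probability vector,
#' extracts each model's top-two sites, and prioritizes the final call.
#'
#' @param x Feature matrix (samples x features) on the classifiers' training
#'   scale, or a [mir_matrix()].
#' @param meta Sample metadata with `sample_id` and `sex` (and `patient_id`
#'   for downstream concordance analysis).
#' @param nsc_model A [fit_nsc()] model.
#' @param lasso_model A [fit_multinomial_lasso()] model.
#' @param p_single,p_shared Prioritization thresholds (see [prioritize()]).
#' @return Object of class `too_report`: a data frame with one row per
#'   sample (top-two sites and probabilities per model, fired rule,
#'   `final_sites` separated by `";"`), carrying the full sex-filtered
#'   probability matrices as attributes `probs_nsc` and `probs_lasso`.
#' @export
predict_too <- function(x, meta, nsc_model, lasso_model,
                        p_single = 0.80, p_shared = 0.30) {
  if (inherits(x, "mir_matrix")) x <- x$values
  meta <- meta[match(rownames(x), meta$sample_id), , drop = FALSE]
  p_nsc <- predict_nsc(nsc_model, x)
  p_lasso <- predict_lasso(lasso_model, x)

  rows <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    sex <- if (is.na(meta$sex[i])) "unknown" else meta$sex[i]
    pn <- sex_filter(p_nsc[i, ], sex)
    pl <- sex_filter(p_lasso[i, ], sex)
    p_nsc[i, ] <- pn
    p_lasso[i, ] <- pl
    tn <- top_two(pn); tl <- top_two(pl)
    pr <- prioritize(pn, pl, p_single, p_shared)
    rows[[i]] <- data.frame(
      sample_id = meta$sample_id[i],
      patient_id = meta$patient_id[i] %||% meta$sample_id[i],
      sex = sex,
      top1_nsc = tn[1], p1_nsc = unname(pn[tn[1]]),
      top2_nsc = tn[2], p2_nsc = unname(pn[tn[2]]),
      top1_lasso = tl[1], p1_lasso = unname(pl[tl[1]]),
      top2_lasso = tl[2], p2_lasso = unname(pl[tl[2]]),
      sex_excluded = paste(attr(pn, "excluded"), collapse = ";"),
      rule = pr$rule,
      final_sites = paste(pr$final_sites, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  report <- do.call(rbind, rows)
  attr(report, "probs_nsc") <- p_nsc
  attr(report, "probs_lasso") <- p_lasso
  class(report) <- c("too_report", "data.frame")
  report
}

#' Long-format prediction table
#'
#' Reshapes a [predict_too()] report to one row per sample x model x rank,
#' the layout used for plotting prediction outcomes across a cohort.
#'
#' @param report A `too_report`.
#' @return Data frame with columns `sample_id`, `model`, `rank`, `class`,
#'   `probability`.
#' @export
report_long <- function(report) {
  out <- list()
  for (m in c("nsc", "lasso")) {
    for (r in 1:2) {
      out[[paste(m, r)]] <- data.frame(
        sample_id = report$sample_id,
        model = m,
        rank = r,
        class = report[[sprintf("top%d_%s", r, m)]],
        probability = report[[sprintf("p%d_%s", r, m)]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$sample_id, out$model, out$rank), ]
}
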