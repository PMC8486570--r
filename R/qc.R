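#' RT/qPCR quality-control record
#'
#' One record per sample: the UniSp6 spike-in threshold cycle (reporting RT
#' reaction efficiency; logged but never used to block a sample, since no
#' numeric acceptance window is defined for it) and the SNORD44 threshold
#' cycle (RNA integrity/amplifiability), which drives the cDNA dilution
#' decision ahead of ddPCR.
#'
#' @param sample_id Sample identifier.
#' @param snord44_ct SNORD44 threshold cycle (cycles; finite, > 0) or `NA`.
#' @param unisp6_ct UniSp6 threshold cycle or `NA`.
#' @param fluorescence_threshold Instrument fluorescence threshold used when
#'   calling Ct (arbitrary units; default 160).
#' @return Object of class `qc_record`.
#' @export
qc_record <- function(sample_id, snord44_ct = NA_real_, unisp6_ct = NA_real_,
                      fluorescence_threshold = 160) {
  for (ct in c(snord44_ct, unisp6_ct)) {
    if (!is.na(ct) && (!is.finite(ct) || ct <= 0)) {
      stop("Ct values must be finite and > 0")
    }
  }
  structure(
    list(sample_id = sample_id, snord44_ct = snord44_ct,
         unisp6_ct = unisp6_ct,
         fluorescence_threshold = fluorescence_threshold),
    class = "qc_record"
  )
}

#' cDNA dilution decision from the SNORD44 quality control
#'
#' Encodes the dilution bands gating entry into ddPCR profiling: SNORD44 Ct
#' in `[24, 30]` (inclusive) means the cDNA is diluted 1:50; Ct below 24
#' (abundant template, saturation risk) means a stronger dilution, 1:100 by
#' default and configurable up to 1:200; Ct above 30 means the reverse
#' transcription is repeated from undiluted RNA. Every dilute decision also
#' carries the two wells that receive an additional 1:10 dilution
#' (miR-21-5p and UniSp6), which would otherwise saturate the droplet reader.
#'
#' @param record A [qc_record()] with `snord44_ct` present.
#' @param low_ct_factor Dilution fold applied when Ct < 24; one of 100, 150,
#'   200 (default 100).
#' @return Object of class `dilution_decision`: list with `action`
#'   (`"dilute"` or `"repeat_rt"`), `dilution_factor` (`NULL` when the RT is
#'   repeated), and `extra_dilution_wells`.
#' @examples
#' choose_dilution(qc_record("S1", snord44_ct = 26))
#' @export
choose_dilution <- function(record, low_ct_factor = 100) {
  if (!inherits(record, "qc_record")) stop("record must be a qc_record")
  ct <- record$snord44_ct
  if (is.na(ct)) {
    stop("QC incomplete for sample ", record$sample_id,
         ": SNORD44 Ct is missing")
  }
  stopifnot(low_ct_factor >= 100, low_ct_factor <= 200)
  if (ct > 30) {
    decision <- list(action = "repeat_rt", dilution_factor = NULL)
  } else if (ct >= 24) {
    decision <- list(action = "dilute", dilution_factor = 50L)
  } else {
    decision <- list(action = "dilute",
                     dilution_factor = as.integer(low_ct_factor))
  }
  decision$extra_dilution_wells <- c("miR-21-5p", "UniSp6")
  decision$sample_id <- record$sample_id
  class(decision) <- "dilution_decision"
  decision
}

#' @export
print.dilution_decision <- function(x, ...) {
  if (x$action == "dilute") {
    cat(sprintf("%s: dilute cDNA 1:%d (+1:10 in %s wells)\n", x$sample_id,
                x$dilution_factor, paste(x$extra_dilution_wells, collapse = ", ")))
  } else {
    cat(sprintf("%s: repeat RT from undiluted RNA\n", x$sample_id))
  }
  invisible(x)
}

#' Batch dilution decisions from a QC table
#'
#' @param qc Data frame with columns `sample_id`, `snord44_ct`, and
#'   optionally `unisp6_ct` (e.g. from [read_qc_records()]).
#' @param low_ct_factor See [choose_dilution()].
#' @return Data frame with one decision row per sample.
#' @export
choose_dilutions <- function(qc, low_ct_factor = 100) {
  out <- lapply(seq_len(nrow(qc)), function(i) {
    d <- choose_dilution(
      qc_record(qc$sample_id[i], snord44_ct = qc$snord44_ct[i],
                unisp6_ct = qc$unisp6_ct[i] %||% NA_real_),
      low_ct_factor = low_ct_factor
    )
    data.frame(
      sample_id = d$sample_id,
      action = d$action,
      dilution_factor = if (is.null(d$dilution_factor)) NA_integer_ else d$dilution_factor,
      extra_dilution_wells = paste(d$extra_dilution_wells, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
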