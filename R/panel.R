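#' The 89-assay ddPCR miRNA panel
#'
#' Returns the identifiers of the 89 microRNA assays of the prespotted ddPCR
#' plate used for tissue-of-origin profiling. Control assays (small RNAs and
#' synthetic spike-ins) are listed separately by [too_controls()] and never
#' enter normalization or classification.
#'
#' @return Character vector of 89 miRNA assay names.
#' @seealso [too_controls()], [default_exclusions()]
#' @export
too_panel <- function() {
  .mirtoo_panel
}

# 89 assays: the two microenvironment/specificity exclusions, the prognostic
# miRNAs, the candidate-reference additions, and tissue-informative miRNAs
# commonly carried by site-of-origin signatures.
.mirtoo_panel <- c(
  "miR-122-5p", "miR-21-5p",
  # prognostic set
  "miR-124-3p", "miR-9-3p", "miR-149-5p", "miR-372-3p", "miR-485-5p",
  "miR-375", "miR-25-3p", "miR-27b-3p", "miR-181a-2-3p", "miR-10b-5p",
  "miR-96-5p", "miR-423-5p", "miR-214-3p",
  # candidate-reference / panel-widening additions
  "miR-661", "miR-649", "miR-24-3p", "miR-16-5p", "miR-320a",
  "miR-224-5p", "miR-331-3p", "miR-103a-3p",
  # tissue-informative assays
  "let-7a-5p", "let-7b-5p", "let-7c-5p", "miR-1-3p", "miR-7-5p",
  "miR-10a-5p", "miR-17-5p", "miR-18a-5p", "miR-19b-3p", "miR-20a-5p",
  "miR-22-3p", "miR-26a-5p", "miR-29a-3p", "miR-30a-5p", "miR-31-5p",
  "miR-34a-5p", "miR-92a-3p", "miR-99a-5p", "miR-100-5p", "miR-106b-5p",
  "miR-125b-5p", "miR-126-3p", "miR-127-3p", "miR-128-3p", "miR-130a-3p",
  "miR-133a-3p", "miR-135b-5p", "miR-138-5p", "miR-141-3p", "miR-142-3p",
  "miR-143-3p", "miR-145-5p", "miR-146a-5p", "miR-148a-3p", "miR-150-5p",
  "miR-152-3p", "miR-155-5p", "miR-182-5p", "miR-183-5p", "miR-187-3p",
  "miR-192-5p", "miR-194-5p", "miR-196a-5p", "miR-199a-5p", "miR-200a-3p",
  "miR-200b-3p", "miR-200c-3p", "miR-203a-3p", "miR-204-5p", "miR-205-5p",
  "miR-210-3p", "miR-216a-5p", "miR-217-5p", "miR-218-5p", "miR-221-3p",
  "miR-222-3p", "miR-223-3p", "miR-296-5p", "miR-335-5p", "miR-338-3p",
  "miR-342-3p", "miR-429", "miR-449a", "miR-451a", "miR-483-5p",
  "miR-885-5p"
)

#' Control assays on the ddPCR plate
#'
#' Candidate reference small RNAs, interplate calibrator, and the RT spike-in.
#' None is used as a normalizer: per-sample 50th-percentile normalization over
#' the 89 panel assays is applied instead.
#'
#' @return Character vector of control assay names.
#' @export
too_controls <- function() {
  c("SNORD44", "SNORD48", "snRNAU6", "UniSp3", "UniSp6")
}

#' Default prediction exclusions
#'
#' miR-122-5p (dominated by liver-microenvironment signal in liver-site
#' biopsies) and miR-21-5p (broadly expressed across solid tumors, hence
#' non-specific) are dropped from the feature space before classification,
#' leaving 87 of the 89 panel assays.
#'
#' @return Character vector of length 2.
#' @export
default_exclusions <- function() {
  c("miR-122-5p", "miR-21-5p")
}

#' Histological and prediction class labels
#'
#' `histology_classes()` lists the 19 histological labels of the reference
#' cohort; `prediction_classes()` lists the 17 classes used for prediction
#' after merging gastric with colorectal adenocarcinoma (STAD-CRC) and the two
#' renal carcinomas (KICA).
#'
#' @return Character vector of class labels.
#' @export
histology_classes <- function() {
  c("BLCA", "CHOL", "CRC", "GI-NET", "HNSC", "KIRC", "KIRP", "LBC",
    "LIHC", "LUAD", "LUSC", "OV", "PAAD", "PRAD", "SKCM", "STAD",
    "TGSC", "TNBC", "UCEC")
}

#' @rdname histology_classes
#' @export
prediction_classes <- function() {
  sort(unique(unname(default_class_map())))
}

#' Map from histological labels to prediction classes
#'
#' STAD and CRC share a largely overlapping miRNA expression pattern and are
#' merged into a single STAD-CRC class; KIRC and KIRP are merged into KICA.
#' Every other histological label maps to itself, collapsing 19 labels into
#' 17 prediction classes.
#'
#' @return Named character vector: names are histological labels, values the
#'   prediction class each maps to.
#' @export
default_class_map <- function() {
  labs <- histology_classes()
  map <- stats::setNames(labs, labs)
  map[c("STAD", "CRC")] <- "STAD-CRC"
  map[c("KIRC", "KIRP")] <- "KICA"
  map
}

#' Merge histological labels into prediction classes
#'
#' @param labels Character vector of histological class labels.
#' @param class_map Named character vector mapping labels to merged classes
#'   (default [default_class_map()]). Idempotent: merged labels map to
#'   themselves.
#' @return Character vector of merged labels, same length as `labels`.
#' @examples
#' merge_classes(c("STAD", "KIRP", "LUAD"))
#' @export
merge_classes <- function(labels, class_map = default_class_map()) {
  labels <- as.character(labels)
  # allow already-merged labels to pass through (idempotence)
  merged_ids <- unique(unname(class_map))
  extra <- stats::setNames(merged_ids, merged_ids)
  full_map <- c(class_map, extra[!names(extra) %in% names(class_map)])
  unknown <- setdiff(unique(labels), names(full_map))
  if (length(unknown) > 0) {
    stop("unknown class label(s): ", paste(unknown, collapse = ", "))
  }
  unname(full_map[labels])
}

# Sex-restricted prediction classes
.male_only_classes <- c("TGSC", "PRAD")
.female_only_classes <- c("OV", "UCEC")
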