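#' Simulation configuration
#'
#' Bundles every tunable of the synthetic ddPCR cohort generator. The seed
#' fully determines all generator output (bit-reproducible); each generator
#' stage draws from an offset of the same seed so reference cohorts,
#' metastases, and survival times can be generated independently.
#'
#' @param n_per_class Samples per tumor class in the reference cohort
#'   (default 5, within the 3-7 range typical of small FFPE reference sets).
#' @param class_separation Log2-unit shift added to a class's discriminant
#'   miRNAs relative to baseline (effect size; default 2.5).
#' @param n_discriminant Number of up-shifted discriminant miRNAs per class
#'   (default 5).
#' @param sigma_within Within-class log2-scale SD of each miRNA (default 0.8).
#' @param baseline_log2 Baseline log2 abundance (log2 copies/uL; default 6,
#'   i.e. 64 copies/uL).
#' @param liver_spike_factor Multiplicative inflation of miR-122-5p in
#'   liver-site biopsies, emulating the liver-microenvironment signal
#'   (default 50; must be >= 1).
#' @param survival_hr_map Named numeric vector, miRNA id -> true hazard ratio
#'   of the above-median expression group (all > 0), or `NULL` for no
#'   expression-survival association.
#' @param censoring_rate Fraction of samples censored, in `[0, 1)`
#'   (default 0.2).
#' @param baseline_hazard Baseline hazard in month^-1 (default 1/12, i.e.
#'   median survival about 8 months in the no-effect group).
#' @param seed Integer seed controlling all randomness.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_per_class = 5L,
                       class_separation = 2.5,
                       n_discriminant = 5L,
                       sigma_within = 0.8,
                       baseline_log2 = 6,
                       liver_spike_factor = 50,
                       survival_hr_map = NULL,
                       censoring_rate = 0.2,
                       baseline_hazard = 1 / 12,
                       seed = 1L) {
  stopifnot(n_per_class >= 2, sigma_within >= 0, liver_spike_factor >= 1,
            censoring_rate >= 0, censoring_rate < 1, baseline_hazard > 0)
  if (!is.null(survival_hr_map)) {
    if (is.null(names(survival_hr_map)) || any(survival_hr_map <= 0)) {
      stop("survival_hr_map must be a named vector of positive hazard ratios")
    }
  }
  structure(
    list(
      n_per_class = as.integer(n_per_class),
      class_separation = class_separation,
      n_discriminant = as.integer(n_discriminant),
      sigma_within = sigma_within,
      baseline_log2 = baseline_log2,
      liver_spike_factor = liver_spike_factor,
      survival_hr_map = survival_hr_map,
      censoring_rate = censoring_rate,
      baseline_hazard = baseline_hazard,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Build class-specific miRNA expression profiles
#'
#' Each tumor class receives a disjoint set of `config$n_discriminant`
#' discriminant miRNAs whose log2 mean is shifted up by
#' `config$class_separation`; all remaining panel miRNAs share the common
#' baseline mean. The default prediction exclusions (miR-122-5p, miR-21-5p)
#' are never used as discriminants so that dropping them before
#' classification does not erase class signal. Profiles are deterministic
#' given the config seed.
#'
#' @param n_classes Number of tumor classes (>= 2; default 17). Up to 17
#'   classes use the canonical prediction-class labels.
#' @param panel Character vector of miRNA assay ids (default [too_panel()]).
#' @param config A [sim_config()].
#' @param class_labels Optional explicit class labels (length `n_classes`).
#' @param overlap Number of discriminant miRNAs each class shares with the
#'   previous class (default 0 = fully disjoint; used to emulate confusable
#'   class pairs).
#' @return Object of class `class_profiles`: a list of per-class profiles,
#'   each with `class_label`, `mu` (named log2 means), `sigma_within`
#'   (named log2 SDs), `prevalence`, and `discriminant` (miRNA ids).
#' @export
make_class_profiles <- function(n_classes = 17L, panel = too_panel(),
                                config = sim_config(), class_labels = NULL,
                                overlap = 0L) {
  stopifnot(n_classes >= 2, overlap >= 0, overlap < config$n_discriminant)
  if (is.null(class_labels)) {
    base <- prediction_classes()
    class_labels <- if (n_classes <= length(base)) base[seq_len(n_classes)]
                    else sprintf("CLASS%02d", seq_len(n_classes))
  }
  stopifnot(length(class_labels) == n_classes, !anyDuplicated(class_labels))
  candidates <- setdiff(panel, default_exclusions())
  stride <- config$n_discriminant - overlap
  needed <- config$n_discriminant + stride * (n_classes - 1L)
  if (length(candidates) < needed) {
    stop(sprintf(
      "panel too small: %d discriminant slots needed, %d candidate miRNAs",
      needed, length(candidates)
    ))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  perm <- sample(candidates)
  profiles <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    start <- (k - 1L) * stride + 1L
    disc <- perm[start:(start + config$n_discriminant - 1L)]
    mu <- stats::setNames(rep(config$baseline_log2, length(panel)), panel)
    mu[disc] <- mu[disc] + config$class_separation
    profiles[[k]] <- list(
      class_label = class_labels[k],
      mu = mu,
      sigma_within = stats::setNames(rep(config$sigma_within, length(panel)), panel),
      prevalence = 1 / n_classes,
      discriminant = disc
    )
  }
  structure(profiles, class = "class_profiles", panel = panel)
}

# draw n log-normal expression rows from one profile; sigma may be zero
.draw_samples <- function(profile, n) {
  J <- length(profile$mu)
  eps <- matrix(stats::rnorm(n * J, 0, 1), n, J)
  eps <- sweep(eps, 2L, profile$sigma_within, "*")
  x <- 2^(sweep(eps, 2L, profile$mu, "+"))
  colnames(x) <- names(profile$mu)
  x
}

.assign_sex <- function(class_label, n) {
  if (class_label %in% .male_only_classes) rep("male", n)
  else if (class_label %in% .female_only_classes) rep("female", n)
  else sample(c("male", "female"), n, replace = TRUE)
}

#' Simulate a reference cohort of primary tumors
#'
#' Draws `config$n_per_class` samples from each class profile. Abundances are
#' log-normal: for sample i of class k and miRNA j, the value is
#' `2^(mu_kj + e)` with `e ~ Normal(0, sigma_within_j)`, so all values are
#' strictly positive. Sex is assigned consistently with the class label (no
#' female TGSC/PRAD, no male OV/UCEC).
#'
#' @param profiles A [make_class_profiles()] result.
#' @param config A [sim_config()].
#' @return List with `matrix` (raw [mir_matrix()]) and `meta` (data frame of
#'   sample_id, patient_id, sex, role, class_label, biopsy_site,
#'   time_months, event).
#' @export
simulate_reference_cohort <- function(profiles, config = sim_config()) {
  stopifnot(inherits(profiles, "class_profiles"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)
  mats <- list(); metas <- list()
  for (p in profiles) {
    n <- config$n_per_class
    x <- .draw_samples(p, n)
    ids <- sprintf("REF-%s-%02d", p$class_label, seq_len(n))
    rownames(x) <- ids
    mats[[p$class_label]] <- x
    metas[[p$class_label]] <- data.frame(
      sample_id = ids,
      patient_id = ids,
      sex = .assign_sex(p$class_label, n),
      role = "reference_primary",
      class_label = p$class_label,
      biopsy_site = NA_character_,
      time_months = NA_real_,
      event = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  list(
    matrix = mir_matrix(do.call(rbind, mats)),
    meta = do.call(rbind, c(metas, list(make.row.names = FALSE)))
  )
}

#' Biopsy sites the metastasis generator accepts
#' @return Character vector of site labels.
#' @export
valid_biopsy_sites <- function() {
  c("liver", "lymph node", "lung", "bone", "bone marrow", "brain", "breast",
    "colon", "dermis", "kidney", "muscle", "pleura", "prostate", "skin",
    "soft tissue", "stomach", "thyroid", "other")
}

#' Simulate metastatic biopsies with liver miR-122-5p inflation
#'
#' Each row of `biopsy_sites` describes one metastatic sample: the simulated
#' patient it belongs to, the hidden-truth origin class, and the biopsy site.
#' Samples are drawn from their origin-class profile; samples biopsied from
#' the liver have miR-122-5p multiplied by `config$liver_spike_factor`,
#' emulating the microenvironment signal that contaminates liver-site
#' biopsies regardless of tumor origin. Patients with several rows share a
#' patient id (and must share an origin); sex is drawn once per patient,
#' consistent with the origin class.
#'
#' @param profiles A [make_class_profiles()] result.
#' @param config A [sim_config()].
#' @param biopsy_sites Data frame with columns `patient_id`, `origin`,
#'   `site` (and optionally `sample_id`).
#' @param role Cohort role recorded in metadata: `"cup"` (default) or
#'   `"known_metastasis"`. For CUPs the class label is withheld (NA) and the
#'   origin is kept only as the hidden-truth `true_class` column.
#' @return List with `matrix` (raw [mir_matrix()]) and `meta` (data frame;
#'   includes `true_class`).
#' @export
simulate_metastases <- function(profiles, config = sim_config(), biopsy_sites,
                                role = c("cup", "known_metastasis")) {
  stopifnot(inherits(profiles, "class_profiles"))
  role <- match.arg(role)
  req <- c("patient_id", "origin", "site")
  if (!all(req %in% names(biopsy_sites))) {
    stop("biopsy_sites needs columns: ", paste(req, collapse = ", "))
  }
  labels <- vapply(profiles, `[[`, "", "class_label")
  bad_origin <- setdiff(unique(biopsy_sites$origin), labels)
  if (length(bad_origin) > 0) {
    stop("origin class not in profiles: ", paste(bad_origin, collapse = ", "))
  }
  bad_site <- setdiff(unique(biopsy_sites$site), valid_biopsy_sites())
  if (length(bad_site) > 0) {
    stop("unknown biopsy site label(s): ", paste(bad_site, collapse = ", "))
  }
  multi <- tapply(biopsy_sites$origin, biopsy_sites$patient_id,
                  function(o) length(unique(o)))
  if (any(multi > 1)) {
    stop("a patient cannot have metastases from different origins: ",
         paste(names(multi)[multi > 1], collapse = ", "))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 2L)

  n <- nrow(biopsy_sites)
  if (is.null(biopsy_sites$sample_id)) {
    within <- stats::ave(seq_len(n), biopsy_sites$patient_id, FUN = seq_along)
    sample_id <- sprintf("%s-M%02d", biopsy_sites$patient_id, within)
  } else {
    sample_id <- biopsy_sites$sample_id
  }

  prof_by_label <- stats::setNames(unclass(profiles), labels)
  x <- matrix(NA_real_, n, length(attr(profiles, "panel")),
              dimnames = list(sample_id, attr(profiles, "panel")))
  for (i in seq_len(n)) {
    x[i, ] <- .draw_samples(prof_by_label[[biopsy_sites$origin[i]]], 1L)
  }
  is_liver <- biopsy_sites$site == "liver"
  if ("miR-122-5p" %in% colnames(x) && any(is_liver)) {
    x[is_liver, "miR-122-5p"] <- x[is_liver, "miR-122-5p"] * config$liver_spike_factor
  }

  pts <- unique(biopsy_sites$patient_id)
  sex_by_pt <- stats::setNames(vapply(pts, function(p) {
    .assign_sex(biopsy_sites$origin[match(p, biopsy_sites$patient_id)], 1L)
  }, ""), pts)

  meta <- data.frame(
    sample_id = sample_id,
    patient_id = biopsy_sites$patient_id,
    sex = unname(sex_by_pt[biopsy_sites$patient_id]),
    role = role,
    class_label = if (role == "known_metastasis") biopsy_sites$origin else NA_character_,
    true_class = biopsy_sites$origin,
    biopsy_site = biopsy_sites$site,
    time_months = NA_real_,
    event = NA_integer_,
    stringsAsFactors = FALSE
  )
  list(matrix = mir_matrix(x), meta = meta)
}

#' Simulate overall survival driven by dichotomized miRNA expression
#'
#' Event times are exponential with hazard `h0 * prod(HR_j^g_ij)` where
#' `g_ij` indicates that sample i's expression of driver miRNA j lies above
#' the cohort median. Censoring is independent exponential, calibrated so the
#' expected censored fraction equals `config$censoring_rate`; with rate 0 all
#' events are observed.
#'
#' @param meta Sample metadata (rows matched to `matrix` by sample_id).
#' @param matrix A [mir_matrix()] holding the driver miRNAs.
#' @param config A [sim_config()]; `survival_hr_map` names the driver miRNAs.
#' @return `meta` with `time_months` and `event` filled.
#' @export
simulate_survival <- function(meta, matrix, config = sim_config()) {
  meta <- check_meta(matrix, meta)
  hr_map <- config$survival_hr_map
  if (!is.null(hr_map)) {
    missing <- setdiff(names(hr_map), mirna_ids(matrix))
    if (length(missing) > 0) {
      stop("survival_hr_map names absent from the matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 3L)

  n <- nrow(meta)
  hazard <- rep(config$baseline_hazard, n)
  for (mir in names(hr_map)) {
    expr <- matrix$values[, mir]
    g <- expr > stats::median(expr)
    hazard <- hazard * hr_map[[mir]]^g
  }
  t_event <- stats::rexp(n, rate = hazard)
  if (config$censoring_rate > 0) {
    # one global censoring rate, calibrated so the expected censored fraction
    # equals censoring_rate under the baseline hazard; censoring stays
    # independent of expression, so high-hazard groups die observably more
    r <- config$censoring_rate
    t_cens <- stats::rexp(n, rate = config$baseline_hazard * r / (1 - r))
    meta$event <- as.integer(t_event <= t_cens)
    meta$time_months <- pmin(t_event, t_cens)
  } else {
    meta$event <- 1L
    meta$time_months <- t_event
  }
  meta
}
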