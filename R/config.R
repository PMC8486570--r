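#' Pipeline configuration
#'
#' Defaults reproduce the published analysis settings exactly: the
#' miR-122-5p/miR-21-5p exclusion, the 19-to-17 class map, NSC shrinkage
#' threshold 0, lasso penalty 0.019, prioritization thresholds 0.80/0.30,
#' and 100 bootstrap replicates.
#'
#' @param ... Overrides of the default entries.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_defaults <- function(...) {
  cfg <- list(
    exclusions = default_exclusions(),
    nsc_delta = 0,
    lasso_lambda = 0.019,
    p_single = 0.80,
    p_shared = 0.30,
    n_boot = 100L,
    seed = 1L,
    log_transform = TRUE,
    log_pseudo = 0.01,
    prior = "empirical",
    alpha = 0.05
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers where possible, comma-separated lists become vectors. Keys
#' must belong to [pipeline_defaults()].
#'
#' @param path Path to the config file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed config line: ", ln)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    items <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(items))
    parsed <- if (!anyNA(num)) num else items
    if (identical(parsed, "TRUE")) parsed <- TRUE
    if (identical(parsed, "FALSE")) parsed <- FALSE
    kv[[key]] <- parsed
  }
  do.call(pipeline_defaults, kv)
}

#' Write a timestamped run-log entry
#'
#' Appends a line carrying the timestamp, package version, seed, and a
#' fingerprint of the configuration, so every pipeline artifact can be
#' traced to its settings.
#'
#' @param log_path Log file path (created if needed).
#' @param config A `pipeline_config`.
#' @param message Free-text description of the step.
#' @return The log line, invisibly.
#' @export
log_run <- function(log_path, config, message) {
  cfg_str <- paste(names(config), vapply(config, function(v)
    paste(format(v), collapse = ","), ""), sep = "=", collapse = "; ")
  line <- sprintf("[%s] mirtoo %s | seed=%s | config=%s | %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  as.character(utils::packageVersion("mirtoo")),
                  config$seed, config_hash(cfg_str), message)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  invisible(line)
}
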