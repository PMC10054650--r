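#' Read a bioassay file
#'
#' Comma-separated text, one row per well, header
#' `treatment,concentration_ng_ml,n_exposed,n_dead,replicate,is_control`.
#' Missing values are disallowed; every row is validated against the
#' well-level invariants.
#'
#' @param path file path.
#' @return a `bioassay` data frame.
#' @examples
#' demo <- system.file("extdata", "demo_bioassay_synthetic.csv",
#'                     package = "quantalmix")
#' head(read_bioassay(demo))
#' @export
read_bioassay <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("no such file: %s", path),
                        class = c("quantalmix_parse_error", "error",
                                  "condition")))
  }
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      stop(errorCondition(
        sprintf("cannot parse bioassay file %s: %s", path, conditionMessage(e)),
        class = c("quantalmix_parse_error", "error", "condition")))
    }
  )
  expected <- c("treatment", "concentration_ng_ml", "n_exposed", "n_dead",
                "replicate", "is_control")
  if (!all(expected %in% names(raw))) {
    stop(errorCondition(
      sprintf("bioassay file %s must have header: %s", path,
              paste(expected, collapse = ",")),
      class = c("quantalmix_parse_error", "error", "condition")))
  }
  bioassay_observations(
    treatment = raw$treatment,
    concentration = raw$concentration_ng_ml,
    n_exposed = raw$n_exposed,
    n_dead = raw$n_dead,
    replicate = raw$replicate,
    is_control = as.logical(raw$is_control)
  )
}

#' Write a bioassay file
#'
#' Inverse of [read_bioassay()]: the write -> read round trip is lossless.
#'
#' @param x a `bioassay` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bioassay <- function(x, path) {
  x <- validate_bioassay(as.data.frame(x))
  out <- data.frame(
    treatment = x$treatment,
    concentration_ng_ml = x$concentration,
    n_exposed = x$n_exposed,
    n_dead = x$n_dead,
    replicate = x$replicate,
    is_control = x$is_control
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mixture definition file
#'
#' Comma-separated text with header
#' `mixture,component,proportion,treatment_ref`; each mixture's component
#' proportions must sum to 1.
#'
#' @param path file path.
#' @return data frame with those four columns.
#' @export
read_mixture_def <- function(path) {
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) {
                    stop(errorCondition(
                      sprintf("cannot parse mixture file %s", path),
                      class = c("quantalmix_parse_error", "error",
                                "condition")))
                  })
  expected <- c("mixture", "component", "proportion", "treatment_ref")
  if (!all(expected %in% names(raw)) || anyNA(raw[expected])) {
    stop(errorCondition(
      sprintf("mixture file %s must have complete columns: %s", path,
              paste(expected, collapse = ",")),
      class = c("quantalmix_parse_error", "error", "condition")))
  }
  sums <- tapply(raw$proportion, raw$mixture, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad) > 0) {
    stop(sprintf("proportions do not sum to 1 for mixture(s): %s",
                 paste(bad, collapse = ", ")))
  }
  raw[expected]
}

#' Run configuration
#'
#' Bundles the analysis options that every report echoes so a run can be
#' reproduced exactly.
#'
#' @param link `"logit"` or `"probit"`.
#' @param ci_method `"fieller"` or `"delta"`.
#' @param confidence confidence level in (0, 1).
#' @param activity_threshold corrected-mortality activity cutoff in (0, 1).
#' @param thresholds see [interaction_thresholds()].
#' @param seed integer seed recorded in every output.
#' @param digits significant figures for rendered reports.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(link = "logit", ci_method = "fieller",
                       confidence = 0.95, activity_threshold = 0.10,
                       thresholds = interaction_thresholds(),
                       seed = 1L, digits = 3L) {
  link <- match.arg(link, c("logit", "probit"))
  ci_method <- match.arg(ci_method, c("fieller", "delta"))
  stopifnot(confidence > 0, confidence < 1,
            activity_threshold > 0, activity_threshold < 1,
            digits >= 1)
  structure(list(link = link, ci_method = ci_method,
                 confidence = confidence,
                 activity_threshold = activity_threshold,
                 thresholds = thresholds, seed = as.integer(seed),
                 digits = as.integer(digits)),
            class = "run_config")
}

#' Write a report table with its configuration sidecar
#'
#' Writes the table as comma-separated text and the full-precision
#' machine-readable configuration echo (seed, link, method, thresholds)
#' as JSON next to it (`<path>.config.json`), so every report carries
#' what is needed to reproduce it.
#'
#' @param report a data frame.
#' @param path output path.
#' @param config a [run_config()].
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, config) {
  stopifnot(inherits(config, "run_config"))
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# render a number to `digits` significant figures, or a censored bound
# as ">BOUND" (never with fabricated limits)
render_value <- function(x, digits = 3) {
  if (is.na(x)) "" else format(signif(x, digits))
}

#' Render a censored bound
#' @param bound ng/mL.
#' @return string such as `">1e+05"`.
#' @export
render_censored <- function(bound) paste0(">", format(bound))
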