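#' Analyse every treatment in a bioassay data set
#'
#' The per-treatment pipeline behind the report tables: pool replicate
#' wells with Abbott's correction, screen for activity at the highest
#' tested dose, fit the quantal dose-response model for active treatments
#' and invert it for the LC50 with confidence limits. Treatments failing
#' the activity screen, or with degenerate (unfittable) responses, get a
#' censored LC50 at the appropriate bound instead of a fit, with a
#' warning logged for degenerate data.
#'
#' @param data a `bioassay` data frame covering one or more treatments.
#' @param config a [run_config()].
#' @return An object of class `"treatment_analysis"`: a data frame with
#'   one row per treatment and numeric columns `lc50, lower, upper, chi2,
#'   df, slope, se_slope, intercept` (NA when censored), logical
#'   `censored`, numeric `censor_bound`, plus the fitted `quantal_fit`
#'   objects in `attr(, "fits")` and the config in `attr(, "config")`.
#' @export
analyze_treatments <- function(data, config = run_config()) {
  data <- validate_bioassay(as.data.frame(data))
  stopifnot(inherits(config, "run_config"))
  treatments <- unique(data$treatment)
  fits <- list()
  rows <- lapply(treatments, function(tr) {
    sub <- data[data$treatment == tr, , drop = FALSE]
    censored_row <- function(bound) {
      data.frame(treatment = tr, lc50 = NA_real_, lower = NA_real_,
                 upper = NA_real_, chi2 = NA_real_, df = NA_integer_,
                 slope = NA_real_, se_slope = NA_real_,
                 intercept = NA_real_, censored = TRUE,
                 censor_bound = bound)
    }
    pooled <- pool_doses(sub)
    high <- max(pooled$concentration)
    mort <- stats::setNames(pooled$dead / pooled$n,
                            format(pooled$concentration, digits = 15))
    screen <- activity_screen(mort, high,
                              activity_threshold = config$activity_threshold)
    if (screen$verdict == "non_active") return(censored_row(high))
    fit <- tryCatch(
      fit_quantal(pooled, link = config$link),
      quantalmix_degenerate_error = function(e) e,
      quantalmix_convergence_error = function(e) e
    )
    if (inherits(fit, "condition")) {
      warning(sprintf("treatment %s: %s; reporting censored LC50 > %g",
                      tr, conditionMessage(fit), high))
      return(censored_row(high))
    }
    fits[[tr]] <<- fit
    lc <- confidence_limits(fit, p_level = 0.5, method = config$ci_method,
                            confidence = config$confidence)
    data.frame(treatment = tr, lc50 = lc$estimate, lower = lc$lower,
               upper = lc$upper, chi2 = fit$chi2, df = fit$df,
               slope = fit$slope, se_slope = fit$slope_se,
               intercept = fit$intercept, censored = FALSE,
               censor_bound = NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "config") <- config
  class(out) <- c("treatment_analysis", class(out))
  out
}

#' Render the per-treatment fit report
#'
#' One row per treatment with columns
#' `treatment, lc50, lower, upper, chi2, df, slope, se_slope, intercept`,
#' values rendered to the configured number of significant figures
#' (default 3) and censored treatments rendered as `>BOUND` with blank
#' limits (never fabricated ones).
#'
#' @param x a `bioassay` data frame or a [analyze_treatments()] result.
#' @param config a [run_config()]; ignored when `x` is already analysed.
#' @return character-rendered data frame mirroring the published LC50
#'   table layout, with the analysis in `attr(, "analysis")`.
#' @export
fit_report <- function(x, config = run_config()) {
  ana <- if (inherits(x, "treatment_analysis")) x else
    analyze_treatments(x, config)
  config <- attr(ana, "config")
  dg <- config$digits
  rows <- lapply(seq_len(nrow(ana)), function(i) {
    r <- ana[i, ]
    if (r$censored) {
      data.frame(treatment = r$treatment,
                 lc50 = render_censored(r$censor_bound),
                 lower = "", upper = "", chi2 = "", df = "",
                 slope = "", se_slope = "", intercept = "")
    } else {
      data.frame(treatment = r$treatment,
                 lc50 = render_value(r$lc50, dg),
                 lower = render_value(r$lower, dg),
                 upper = render_value(r$upper, dg),
                 chi2 = render_value(r$chi2, dg),
                 df = as.character(r$df),
                 slope = render_value(r$slope, dg),
                 se_slope = render_value(r$se_slope, dg),
                 intercept = render_value(r$intercept, dg))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "analysis") <- ana
  attr(out, "config") <- config
  out
}

#' Mixture interaction report
#'
#' For each mixture in the definition table, takes the observed mixture
#' LC50 from the mixture's own fitted treatment, builds the components
#' from their referenced treatments (censored components enter at their
#' censoring bound), and reports the simple-similar-action expectation,
#' synergism factor, interaction class and, where a component is
#' individually non-active, the enabling factor.
#'
#' @param analysis a [analyze_treatments()] result covering both the
#'   mixture treatments and their components.
#' @param mixture_def data frame with columns
#'   `mixture,component,proportion,treatment_ref` (see
#'   [read_mixture_def()]).
#' @return data frame with columns `treatment, observed_lc50,
#'   expected_lc50, lower, upper, chi2, df, slope, se_slope, intercept,
#'   synergism_factor, enabling_factor, interaction_class`; numeric
#'   columns are full precision (render with [fit_report()]-style
#'   significant figures for publication).
#' @export
mixture_report <- function(analysis, mixture_def) {
  stopifnot(inherits(analysis, "treatment_analysis"))
  expected_cols <- c("mixture", "component", "proportion", "treatment_ref")
  stopifnot(all(expected_cols %in% names(mixture_def)))
  config <- attr(analysis, "config")

  lookup <- function(ref) {
    i <- which(analysis$treatment == ref)
    if (length(i) != 1) {
      stop(errorCondition(
        sprintf("treatment '%s' referenced by the mixture definition was not analysed", ref),
        class = c("quantalmix_reference_error", "error", "condition")))
    }
    analysis[i, ]
  }

  rows <- lapply(unique(mixture_def$mixture), function(mx) {
    def <- mixture_def[mixture_def$mixture == mx, , drop = FALSE]
    if (abs(sum(def$proportion) - 1) > 1e-9) {
      stop(sprintf("proportions for mixture '%s' do not sum to 1", mx))
    }
    obs <- lookup(mx)
    if (obs$censored) {
      stop(sprintf("mixture '%s' has a censored LC50; no interaction assessment possible", mx))
    }
    lcs <- lapply(def$treatment_ref, function(ref) {
      r <- lookup(ref)
      if (r$censored) censored_lc(r$censor_bound) else r$lc50
    })
    comps <- mixture_components(def$component, def$proportion, lcs)
    as_ <- assess_interaction(comps, observed_lc50 = obs$lc50,
                              thresholds = config$thresholds)
    data.frame(
      treatment = mx,
      observed_lc50 = obs$lc50,
      expected_lc50 = as_$expected_lc50,
      lower = obs$lower, upper = obs$upper, chi2 = obs$chi2, df = obs$df,
      slope = obs$slope, se_slope = obs$se_slope, intercept = obs$intercept,
      synergism_factor = as_$synergism_factor,
      enabling_factor = if (is.null(as_$enabling_factor)) NA_real_ else
        as_$enabling_factor,
      interaction_class = as_$interaction_class
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  out
}
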