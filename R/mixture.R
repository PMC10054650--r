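#' Define the components of a toxin mixture
#'
#' Each component carries its mass fraction of the total spore-and-crystal
#' preparation and its individually observed LC50 -- either a point
#' estimate in ng/mL or a censored bound for a component with no activity
#' of its own (see [censored_lc()]).
#'
#' @param label character labels.
#' @param proportion mass fractions in (0, 1], summing to 1 within 1e-9.
#' @param lc50 numeric vector of LC50s (ng/mL), or a list mixing numbers
#'   and `lethal_conc` objects (censored components allowed).
#' @return list of class `"mixture_components"`.
#' @examples
#' mixture_components(c("Cyt1Aa", "Cry11Aa"), c(0.5, 0.5), c(171, 228))
#' @export
mixture_components <- function(label, proportion, lc50) {
  stopifnot(length(label) == length(proportion),
            length(label) == length(lc50))
  if (length(label) < 2) stop("a mixture needs at least 2 components")
  proportion <- as.numeric(proportion)
  if (any(proportion <= 0) || any(proportion > 1)) {
    stop("proportions must lie in (0, 1]")
  }
  if (abs(sum(proportion) - 1) > 1e-9) {
    stop("component proportions must sum to 1")
  }
  comps <- lapply(seq_along(label), function(i) {
    lc <- if (is.list(lc50)) lc50[[i]] else lc50[i]
    if (is.numeric(lc)) {
      if (lc <= 0) stop("component LC50 must be > 0 ng/mL")
      lc <- structure(list(p_level = 0.5, estimate = as.numeric(lc),
                           censored = FALSE), class = "lethal_conc")
    }
    stopifnot(inherits(lc, "lethal_conc"))
    list(label = as.character(label[i]), proportion = proportion[i],
         lc50 = lc)
  })
  structure(comps, class = "mixture_components")
}

#' Expected mixture LC50 under simple similar action
#'
#' The no-interaction null for mixtures of similarly acting toxins with
#' parallel dose-response lines (Tabashnik's model): the mixture LC50 is
#' the proportion-weighted harmonic combination
#' `LC50(m) = (sum_i r_i / LC50_i)^-1`. A component with a censored
#' ("greater-than") LC50 enters at its censoring bound; the result is then
#' flagged as a lower bound on the expected LC50 (and any synergism factor
#' derived from it is a lower bound on the synergy).
#'
#' @param components a [mixture_components()] object.
#' @return list with `expected` (ng/mL) and `lower_bound` (flag, `TRUE`
#'   when any censored bound was substituted).
#' @examples
#' m <- mixture_components(c("A", "B"), c(0.5, 0.5), c(171, 228))
#' expected_lc50_ssa(m)$expected  # 195.4 ng/mL
#' @export
expected_lc50_ssa <- function(components) {
  stopifnot(inherits(components, "mixture_components"))
  vals <- vapply(components, function(cp) {
    lc <- cp$lc50
    if (is_censored(lc)) {
      if (lc$censor_direction != "greater_than") {
        stop(errorCondition(
          "less-than censored component LC50s are not supported",
          class = c("quantalmix_unsupported_censor_error", "error",
                    "condition")
        ))
      }
      lc$censor_bound
    } else {
      lc$estimate
    }
  }, numeric(1))
  if (any(vals <= 0)) stop("component LC50s must be > 0")
  r <- vapply(components, `[[`, numeric(1), "proportion")
  list(
    expected = 1 / sum(r / vals),
    lower_bound = any(vapply(components,
                             function(cp) is_censored(cp$lc50), logical(1)))
  )
}

#' Synergism factor
#'
#' The ratio of the expected mixture LC50 under simple similar action to
#' the observed mixture LC50. Values well above 1 indicate synergy.
#'
#' @param expected expected LC50 (ng/mL), `> 0`.
#' @param observed observed mixture LC50 (ng/mL), `> 0`.
#' @return dimensionless factor `expected / observed`.
#' @examples
#' synergism_factor(195.6, 17.1)  # 11.44
#' @export
synergism_factor <- function(expected, observed) {
  if (any(expected <= 0) || any(observed <= 0)) {
    stop("expected and observed LC50s must be > 0")
  }
  expected / observed
}

#' Enabling factor
#'
#' When one mixture component has no activity of its own, the expected
#' mixture LC50 under no interaction reduces (up to the proportion scale)
#' to the active component's potency; the fold-change in activity
#' attributable to the non-toxic partner being "enabled" is the active
#' component's LC50 over the mixture LC50.
#'
#' @param active_component_lc50 ng/mL, `> 0`.
#' @param mixture_lc50 ng/mL, `> 0`.
#' @return dimensionless fold-enhancement.
#' @examples
#' enabling_factor(171, 23.3)  # 7.34-fold
#' @export
enabling_factor <- function(active_component_lc50, mixture_lc50) {
  if (any(active_component_lc50 <= 0) || any(mixture_lc50 <= 0)) {
    stop("LC50s must be > 0")
  }
  active_component_lc50 / mixture_lc50
}

#' Interaction classification thresholds
#'
#' @param synergy synergism-factor threshold above which the interaction
#'   is called synergistic (default 2).
#' @param antagonism threshold below which it is antagonistic (default 0.5).
#' @return list of thresholds.
#' @export
interaction_thresholds <- function(synergy = 2, antagonism = 0.5) {
  stopifnot(synergy > 1, antagonism < 1, antagonism > 0)
  list(synergy = synergy, antagonism = antagonism)
}

#' Assess the interaction in a toxin mixture
#'
#' Combines the component LC50s, the observed mixture LC50 and the
#' simple-similar-action expectation into a single assessment: expected
#' LC50 (flagged as a lower bound when a censored component entered at its
#' bound), synergism factor, enabling factor (only when at least one
#' component is individually non-active), and an interaction class.
#'
#' Classes: `enabling` when every component is individually censored
#' non-active yet the mixture shows a finite LC50 below the screening
#' bound; `synergistic` when SF exceeds the synergy threshold;
#' `antagonistic` when SF falls below the antagonism threshold;
#' `additive` otherwise.
#'
#' @param components a [mixture_components()] object.
#' @param observed_lc50 observed mixture LC50 in ng/mL (`> 0`).
#' @param thresholds see [interaction_thresholds()].
#' @return list of class `"interaction_assessment"`.
#' @examples
#' m <- mixture_components(c("Cyt1Aa", "Cry11Aa"), c(0.5, 0.5), c(171, 228))
#' assess_interaction(m, observed_lc50 = 17.1)
#' @export
assess_interaction <- function(components, observed_lc50,
                               thresholds = interaction_thresholds()) {
  stopifnot(observed_lc50 > 0)
  exp_lc <- expected_lc50_ssa(components)
  sf <- synergism_factor(exp_lc$expected, observed_lc50)
  censored_i <- vapply(components, function(cp) is_censored(cp$lc50),
                       logical(1))
  ef <- NULL
  if (any(censored_i) && !all(censored_i)) {
    active <- components[!censored_i]
    # fold-enhancement relative to the most potent active component
    active_lc <- min(vapply(active, function(cp) cp$lc50$estimate,
                            numeric(1)))
    ef <- enabling_factor(active_lc, observed_lc50)
  }
  out <- list(
    expected_lc50 = exp_lc$expected,
    expected_is_lower_bound = exp_lc$lower_bound,
    observed_lc50 = observed_lc50,
    synergism_factor = sf,
    enabling_factor = ef,
    components = components
  )
  out$interaction_class <- classify_interaction(out, components, thresholds)
  class(out) <- "interaction_assessment"
  out
}

#' Classify a mixture interaction
#'
#' @param assessment a list with at least `synergism_factor` and
#'   `observed_lc50` (an [assess_interaction()] result qualifies).
#' @param components the [mixture_components()] the assessment refers to.
#' @param thresholds see [interaction_thresholds()].
#' @return one of `"enabling"`, `"synergistic"`, `"antagonistic"`,
#'   `"additive"`.
#' @export
classify_interaction <- function(assessment, components,
                                 thresholds = interaction_thresholds()) {
  censored_i <- vapply(components, function(cp) is_censored(cp$lc50),
                       logical(1))
  if (all(censored_i)) {
    bounds <- vapply(components, function(cp) cp$lc50$censor_bound,
                     numeric(1))
    if (is.finite(assessment$observed_lc50) &&
        assessment$observed_lc50 < min(bounds)) {
      return("enabling")
    }
  }
  sf <- assessment$synergism_factor
  if (sf > thresholds$synergy) "synergistic"
  else if (sf < thresholds$antagonism) "antagonistic"
  else "additive"
}

#' @export
print.interaction_assessment <- function(x, ...) {
  cat(sprintf("Mixture interaction: %s\n", x$interaction_class))
  cat(sprintf("  expected LC50 %s%.4g ng/mL, observed %.4g ng/mL\n",
              if (x$expected_is_lower_bound) ">= " else "",
              x$expected_lc50, x$observed_lc50))
  cat(sprintf("  synergism factor %.4g%s\n", x$synergism_factor,
              if (x$expected_is_lower_bound) " (lower bound)" else ""))
  if (!is.null(x$enabling_factor)) {
    cat(sprintf("  enabling factor %.4g\n", x$enabling_factor))
  }
  invisible(x)
}

#' Preliminary mortality-based synergy screen
#'
#' Flags a potential synergy when the 1:1 mixture's mortality exceeds the
#' sum of the components' individual mortalities (the sum capped at 1, so
#' a saturated mixture response is never flagged against an impossible
#' expectation).
#'
#' @param mix_mortality mixture mortality proportion in `[0, 1]`.
#' @param individual_mortalities numeric vector of component mortalities.
#' @return logical flag.
#' @examples
#' mortality_synergy_screen(0.90, c(0.30, 0.20))  # TRUE
#' @export
mortality_synergy_screen <- function(mix_mortality, individual_mortalities) {
  stopifnot(mix_mortality >= 0, mix_mortality <= 1,
            all(individual_mortalities >= 0),
            all(individual_mortalities <= 1))
  mix_mortality > min(1, sum(individual_mortalities))
}
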