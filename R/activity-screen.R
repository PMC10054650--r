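#' Screen a treatment for larvicidal activity
#'
#' Classifies a treatment as active or non-active from its corrected
#' mortality at the highest tested dose. A treatment whose corrected
#' mortality at the high dose falls below the threshold (default 10%) is
#' declared non-active and its LC50 is reported as censored at the high
#' dose (`LC50 > high_dose`), matching the convention of reporting
#' "LC50 > 1e5 ng/mL" for preparations without measurable activity.
#'
#' @param treatment_mortality named numeric vector or list mapping dose
#'   (ng/mL) to Abbott-corrected mortality proportion.
#' @param high_dose ng/mL; must be one of the doses in the map.
#' @param activity_threshold corrected mortality below which the treatment
#'   is non-active; default 0.10.
#' @return list with `verdict` (`"active"` or `"non_active"`) and, when
#'   non-active, `lc50`, a censored [censored_lc()].
#' @examples
#' activity_screen(c(`1e5` = 0), 1e5)           # non-active, LC50 > 1e5
#' activity_screen(c(`1000` = 0.7333), 1000)    # active
#' @export
activity_screen <- function(treatment_mortality, high_dose,
                            activity_threshold = 0.10) {
  tm <- unlist(treatment_mortality)
  if (length(tm) == 0) {
    stop(errorCondition(
      "empty dose-mortality map",
      class = c("quantalmix_missing_data_error", "error", "condition")
    ))
  }
  doses <- as.numeric(names(tm))
  if (anyNA(doses)) stop("dose-mortality map must be named by dose (ng/mL)")
  idx <- which(abs(doses - high_dose) <= 1e-9 * abs(high_dose))
  if (length(idx) != 1) stop("high_dose must appear exactly once in the map")
  stopifnot(all(tm >= 0 & tm <= 1), activity_threshold > 0)
  if (tm[idx] < activity_threshold) {
    list(verdict = "non_active",
         lc50 = censored_lc(high_dose, "greater_than"))
  } else {
    list(verdict = "active", lc50 = NULL)
  }
}
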