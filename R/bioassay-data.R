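#' Construct a validated bioassay data set
#'
#' One row per well: a treatment label, the concentration of the
#' spore-and-crystal preparation (ng/mL), the number of larvae exposed and
#' dead, a replicate label and a control flag. This is the single
#' interchange container every other function in the package consumes.
#'
#' @param treatment character vector of treatment labels.
#' @param concentration numeric vector, ng/mL, `>= 0`. Zero concentration
#'   marks a control well.
#' @param n_exposed integer vector, larvae placed in the well (`>= 1`).
#' @param n_dead integer vector, larvae dead (`0 <= n_dead <= n_exposed`).
#' @param replicate replicate labels; defaults to `"R1"`.
#' @param is_control logical; defaults to `concentration == 0` and must
#'   agree with it.
#' @return A `data.frame` of class `"bioassay"` with the six columns above.
#' @examples
#' bioassay_observations("Cyt1Aa", c(1000, 500), c(12, 12), c(11, 8))
#' @export
bioassay_observations <- function(treatment, concentration, n_exposed,
                                  n_dead, replicate = "R1",
                                  is_control = concentration == 0) {
  x <- data.frame(
    treatment = as.character(treatment),
    concentration = as.numeric(concentration),
    n_exposed = as.integer(n_exposed),
    n_dead = as.integer(n_dead),
    replicate = as.character(replicate),
    is_control = as.logical(is_control),
    stringsAsFactors = FALSE
  )
  validate_bioassay(x)
}

#' Validate a bioassay data frame
#'
#' Checks the schema and the well-level invariants: counts are coherent
#' (`0 <= n_dead <= n_exposed`, `n_exposed >= 1`), concentrations are
#' non-negative and finite, no value is missing, and `is_control` is true
#' exactly when the concentration is zero.
#'
#' @param x a data frame with the bioassay columns.
#' @return `x`, with class `"bioassay"` prepended, invisibly usable.
#' @export
validate_bioassay <- function(x) {
  required <- c("treatment", "concentration", "n_exposed", "n_dead",
                "replicate", "is_control")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop(errorCondition(
      sprintf("bioassay data is missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = c("quantalmix_parse_error", "error", "condition")
    ))
  }
  for (col in required) {
    if (anyNA(x[[col]])) {
      bad <- which(is.na(x[[col]]))[1]
      stop(errorCondition(
        sprintf("missing value in column '%s' at row %d", col, bad),
        class = c("quantalmix_parse_error", "error", "condition")
      ))
    }
  }
  if (any(x$concentration < 0) || any(!is.finite(x$concentration))) {
    stop("concentrations must be finite and >= 0 ng/mL")
  }
  if (any(x$n_exposed < 1)) stop("each well must expose at least one larva")
  if (any(x$n_dead < 0) || any(x$n_dead > x$n_exposed)) {
    stop("n_dead must satisfy 0 <= n_dead <= n_exposed")
  }
  if (any(x$is_control != (x$concentration == 0))) {
    stop("is_control must be TRUE exactly when concentration is 0")
  }
  class(x) <- unique(c("bioassay", class(x)))
  x
}

#' Abbott's correction for control mortality
#'
#' Rescales treated mortality by the surviving fraction in controls:
#' `(p_treated - p_control) / (1 - p_control)`, clamped to `[0, 1]`. With
#' zero control mortality (the situation in the motivating assays, where
#' control insects experienced no mortality) the correction is the
#' identity.
#'
#' @param p_treated treated mortality proportion in `[0, 1]`.
#' @param p_control control mortality proportion in `[0, 1)`.
#' @return Corrected mortality proportion in `[0, 1]`. Vectorised.
#' @examples
#' abbott_correct(0.55, 0.10)  # 0.5
#' @export
abbott_correct <- function(p_treated, p_control) {
  if (any(p_control >= 1)) {
    stop(errorCondition(
      "control mortality of 100%: no surviving control baseline",
      class = c("quantalmix_invalid_control_error", "error", "condition")
    ))
  }
  if (any(p_control < 0) || any(p_treated < 0) || any(p_treated > 1)) {
    stop("proportions must lie in [0, 1] (control in [0, 1))")
  }
  pmin(1, pmax(0, (p_treated - p_control) / (1 - p_control)))
}

#' Pool replicate wells and apply Abbott's correction
#'
#' Collapses a single treatment's wells to one row per distinct nonzero
#' concentration. Control wells never enter the pooled dose-response data;
#' they only set the control mortality used in Abbott's correction, which
#' is applied per replicate before pooling. Corrected deaths may be
#' fractional when control mortality is nonzero; the binomial
#' log-likelihood handles fractional counts as quasi-likelihood weights.
#'
#' @param x a bioassay data frame for one treatment.
#' @param abbott apply Abbott's correction using the treatment's own
#'   control wells (default `TRUE`; a no-op when control mortality is 0).
#' @return data frame with columns `concentration`, `n`, `dead` (one row
#'   per dose, decreasing concentration).
#' @export
pool_doses <- function(x, abbott = TRUE) {
  x <- validate_bioassay(as.data.frame(x))
  if (length(unique(x$treatment)) > 1) {
    stop("pool_doses expects wells from a single treatment")
  }
  ctrl <- x[x$is_control, , drop = FALSE]
  trt <- x[!x$is_control, , drop = FALSE]
  if (nrow(trt) == 0) stop("no nonzero-concentration wells to pool")

  if (abbott && nrow(ctrl) > 0) {
    # per-replicate control baseline; replicates without controls use the
    # overall control mortality
    p_ctrl_all <- sum(ctrl$n_dead) / sum(ctrl$n_exposed)
    p_ctrl_rep <- tapply(ctrl$n_dead, ctrl$replicate, sum) /
      tapply(ctrl$n_exposed, ctrl$replicate, sum)
    pc <- p_ctrl_rep[trt$replicate]
    pc[is.na(pc)] <- p_ctrl_all
    p_corr <- abbott_correct(trt$n_dead / trt$n_exposed, as.numeric(pc))
    dead <- p_corr * trt$n_exposed
  } else {
    dead <- trt$n_dead
  }

  conc <- trt$concentration
  out <- data.frame(
    concentration = sort(unique(conc), decreasing = TRUE)
  )
  out$n <- vapply(out$concentration,
                  function(d) sum(trt$n_exposed[conc == d]), numeric(1))
  out$dead <- vapply(out$concentration,
                     function(d) sum(dead[conc == d]), numeric(1))
  out
}
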