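#' Serial dilution dose series
#'
#' Doses formed by repeated division of a top dose `c1`, as prepared in a
#' 1:2 serial-dilution bioassay: `c(c1, c1/factor, ..., c1/factor^(k-1))`.
#' Doses are kept at full precision (exact halving, never rounded).
#'
#' @param c1 top dose, ng/mL, `> 0`.
#' @param factor dilution factor, `> 1` (default 2).
#' @param k number of doses, `>= 2`.
#' @return numeric vector of `k` strictly decreasing doses.
#' @examples
#' serial_dilution(1000, 2, 6)  # 1000 500 250 125 62.5 31.25
#' @export
serial_dilution <- function(c1, factor = 2, k = 6) {
  if (factor <= 1) {
    stop(errorCondition("dilution factor must exceed 1",
                        class = c("quantalmix_design_error", "error",
                                  "condition")))
  }
  stopifnot(c1 > 0, k >= 2)
  c1 / factor^(0:(k - 1))
}

#' Bioassay design
#'
#' The layout of a serial-dilution well-plate assay: top dose, dilution
#' factor, number of doses, larvae per well (an inclusive range, drawn
#' uniformly), replicate wells per dose, and whether untreated control
#' wells are included.
#'
#' @param c1 top dose ng/mL.
#' @param dilution_factor `> 1`, default 2.
#' @param n_doses `>= 3`, default 6.
#' @param larvae_range inclusive integer range, default `c(10, 15)`.
#' @param replicates wells per dose, default 3.
#' @param include_controls add zero-concentration wells, default `TRUE`.
#' @return list of class `"assay_design"` with a `doses` vector.
#' @export
assay_design <- function(c1, dilution_factor = 2, n_doses = 6,
                         larvae_range = c(10L, 15L), replicates = 3,
                         include_controls = TRUE) {
  stopifnot(n_doses >= 3, replicates >= 1,
            length(larvae_range) == 2, larvae_range[1] >= 1,
            larvae_range[2] >= larvae_range[1])
  doses <- serial_dilution(c1, dilution_factor, n_doses)
  structure(list(
    c1 = c1, dilution_factor = dilution_factor, n_doses = as.integer(n_doses),
    larvae_range = as.integer(larvae_range),
    replicates = as.integer(replicates),
    include_controls = isTRUE(include_controls),
    doses = doses
  ), class = "assay_design")
}

#' Ground-truth dose-response model for simulation
#'
#' @param slope per log10(ng/mL), `> 0`.
#' @param lc50 ng/mL, `> 0`.
#' @param link `"logit"` (default) or `"probit"`.
#' @param control_mortality background mortality proportion, default 0.
#' @param interaction_multiplier synergy multiplier `s >= 0` for mixture
#'   truths; `s = 1` is the simple-similar-action null.
#' @return list of class `"true_model"`.
#' @export
true_model <- function(slope, lc50, link = c("logit", "probit"),
                       control_mortality = 0, interaction_multiplier = 1) {
  link <- match.arg(link)
  stopifnot(slope > 0, lc50 > 0,
            control_mortality >= 0, control_mortality < 1,
            interaction_multiplier >= 0)
  structure(list(
    link = link, slope = slope, lc50 = lc50,
    control_mortality = control_mortality,
    interaction_multiplier = interaction_multiplier
  ), class = "true_model")
}

#' True mortality probability at given doses
#' @param truth a [true_model()].
#' @param dose ng/mL (`> 0`).
#' @return mortality proportions, background mortality mixed in.
#' @export
true_mortality <- function(truth, dose) {
  lf <- link_funs(truth$link)
  p <- lf$F(truth$slope * (log10(dose) - log10(truth$lc50)))
  truth$control_mortality + (1 - truth$control_mortality) * p
}

#' Choose a top dose meeting the 90-100% mortality rule
#'
#' Serial-dilution assays anchor the series at a top dose C1 producing
#' between 90 and 100% mortality. This helper returns the smallest dose
#' whose predicted mortality under the stated truth is `p_top` (default
#' 0.90), i.e. the LC(p_top) of the true model.
#'
#' @param truth a [true_model()].
#' @param p_top target mortality at the top dose, default 0.90.
#' @return dose in ng/mL.
#' @export
choose_c1 <- function(truth, p_top = 0.90) {
  stopifnot(p_top >= 0.9, p_top < 1)
  lf <- link_funs(truth$link)
  base <- (p_top - truth$control_mortality) / (1 - truth$control_mortality)
  truth$lc50 * 10^(lf$Q(base) / truth$slope)
}

#' Prefix-stable per-assay seeds
#'
#' Derives `n` integer seeds from a master seed so that replicated
#' simulations are independent while extending the run never perturbs
#' earlier draws: `derive_seeds(s, n + 1)[1:n]` always equals
#' `derive_seeds(s, n)`.
#'
#' @param master_seed integer.
#' @param n number of seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

#' Simulate a serial-dilution bioassay
#'
#' For each dose and replicate, draws the larvae count uniformly from the
#' design's inclusive range and the deaths binomially with the true
#' mortality at that dose (background mortality mixed in). Control wells,
#' when included, draw deaths at the background mortality. A fixed seed
#' gives byte-identical output.
#'
#' @param design an [assay_design()].
#' @param truth a [true_model()].
#' @param seed integer seed.
#' @param treatment treatment label for the output rows.
#' @return a `bioassay` data frame (see [bioassay_observations()]).
#' @examples
#' d <- assay_design(c1 = 2634)
#' tm <- true_model(slope = 1.85, lc50 = 171)
#' head(simulate_assay(d, tm, seed = 1))
#' @export
simulate_assay <- function(design, truth, seed, treatment = "sim") {
  stopifnot(inherits(design, "assay_design"), inherits(truth, "true_model"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  doses <- design$doses
  reps <- design$replicates
  grid <- expand.grid(replicate = seq_len(reps), dose = doses,
                      KEEP.OUT.ATTRS = FALSE)
  if (design$include_controls) {
    grid <- rbind(grid, data.frame(replicate = seq_len(reps), dose = 0))
  }
  n <- sample(design$larvae_range[1]:design$larvae_range[2],
              nrow(grid), replace = TRUE)
  p <- ifelse(grid$dose > 0, true_mortality(truth, pmax(grid$dose, 1e-300)),
              truth$control_mortality)
  dead <- stats::rbinom(nrow(grid), size = n, prob = p)
  bioassay_observations(
    treatment = treatment,
    concentration = grid$dose,
    n_exposed = n,
    n_dead = dead,
    replicate = paste0("R", grid$replicate),
    is_control = grid$dose == 0
  )
}

#' Simulate a mixture bioassay under (or off) the SSA null
#'
#' The mixture truth assumes parallel component dose-response lines with a
#' shared reference slope. The expected mixture LC50 under simple similar
#' action is `LC50_SSA = (sum_i r_i / LC50_i)^-1`; mortality at total dose
#' `d` is `F(slope * (log10(d * s) - log10(LC50_SSA)))`, so the synergy
#' multiplier `s = 1` reproduces the no-interaction null exactly and
#' `s > 1` shifts the true mixture LC50 to `LC50_SSA / s`.
#'
#' @param design an [assay_design()].
#' @param components a [mixture_components()] object (censored components
#'   enter at their censoring bound), or a two-column structure of
#'   proportions and true LC50s.
#' @param reference_slope shared slope per log10(ng/mL).
#' @param s synergy multiplier, default 1 (SSA null).
#' @param seed integer seed.
#' @param treatment label for the output rows.
#' @param link `"logit"` or `"probit"`.
#' @param control_mortality background mortality, default 0.
#' @return a `bioassay` data frame.
#' @export
simulate_mixture_assay <- function(design, components, reference_slope,
                                   s = 1, seed, treatment = "mix",
                                   link = "logit", control_mortality = 0) {
  stopifnot(inherits(components, "mixture_components"), s >= 0)
  lc_ssa <- expected_lc50_ssa(components)$expected
  truth <- true_model(slope = reference_slope, lc50 = lc_ssa / s,
                      link = link, control_mortality = control_mortality)
  simulate_assay(design, truth, seed = seed, treatment = treatment)
}
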