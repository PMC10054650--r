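---
title: "Quantal dose-response analysis and mixture synergism: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal dose-response analysis and mixture synergism: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantalmix)
```

## The model

A larvicide bioassay records, for each well, how many larvae were exposed
to a concentration $d$ (ng/mL of spore-and-crystal preparation) and how
many died. `quantalmix` models the death count at each dose as binomial
with mortality probability

$$\pi(d) = F(\alpha + \beta \log_{10} d),$$

where $F$ is the logistic distribution function (`link = "logit"`, the
default) or the standard-normal one (`"probit"`). The slope $\beta$ is per
$\log_{10}$(ng/mL); the LC$_p$ follows by inversion,
$\mathrm{LC}_p = 10^{(F^{-1}(p) - \alpha)/\beta}$, so that
$\mathrm{LC}_{50} = 10^{-\alpha/\beta}$ exactly under both links.

The $\log_{10}$ dose metameter is not an arbitrary choice: it is the only
scale on which published slope/intercept pairs of the kind this package
reports reproduce their published LC50s through $10^{-\alpha/\beta}$.

Replicate wells are pooled within concentration before fitting; control
(zero-concentration) wells never enter the regression. They act only
through Abbott's correction $(p - c)/(1 - c)$, applied per replicate
before pooling. When control mortality is zero — the usual and intended
situation — the correction is the identity. With nonzero control
mortality the corrected death counts are fractional; the binomial
log-likelihood accepts them as quasi-likelihood weights.

## Fitting and its numerical choices

`fit_quantal()` maximises the binomial log-likelihood by Newton–Raphson
with step-halving, started from the least-squares line through the
empirical link-transformed mortalities. Convergence is declared when the
relative deviance change or the gradient max-norm falls below `tol`
(default `1e-8`), within `max_iter = 100` iterations. The reported
covariance is the inverse *observed* information at the optimum; for the
canonical logit link this coincides with the expected information that
IRLS uses, and the estimates agree with `glm()` to at least six decimals
(the test suite checks this, and also checks the optimum against a
brute-force likelihood grid search).

A fit needs at least two distinct nonzero concentrations (two doses give
the saturated fit through the empirical link values, with zero residual
degrees of freedom); three or more are needed for any goodness-of-fit
assessment, and the 6-dose serial-dilution design yields the familiar
$df = k - 2 = 4$.

Data that cannot identify a finite positive slope are refused rather than
forced: uniform zero mortality, uniform complete mortality, a flat
response, or an all-or-none (completely separated) response raise a
classed error (`quantalmix_degenerate_error`) telling the caller to
report a censored LC50 through `activity_screen()` instead. This matches
how non-active preparations are reported in practice
(“LC50 > $10^5$ ng/mL”) and avoids penalised fits whose estimates would
be artefacts of the penalty. All-or-none data with a non-monotone pattern
are exceedingly rare in serial-dilution assays and are treated the same
way.

## Goodness of fit and heterogeneity

`goodness_of_fit()` computes the Pearson statistic over pooled doses,
$\chi^2 = \sum_k (y_k - n_k\hat\pi_k)^2 / (n_k\hat\pi_k(1-\hat\pi_k))$,
with $df = k - 2$. Doses whose fitted probability is numerically 0 or 1
carry no information and are dropped with a warning, reducing $df$.
Following Finney's convention, the heterogeneity factor
$h = \max(1, \chi^2/df)$ inflates the coefficient covariance when
replicate variation exceeds binomial expectation, and $t_{df}$ quantiles
replace normal ones in the confidence limits.

## Confidence limits: Fieller by default

The LC$_p$ is a ratio of regression parameters, so its classical
(fiducial) limits come from Fieller's theorem applied to
$m = (F^{-1}(p) - \alpha)/\beta$ with the fitted covariance; the
`g`-statistic $g = q^2 v_{\beta\beta} / \beta^2$ must be below 1, else
the slope is not significantly positive and the limits are unbounded (a
classed error). A first-order delta-method interval
$m \pm q\,\mathrm{SE}(m)$ is provided for comparison. Both are computed
on the $\log_{10}$ scale and back-transformed.

Fieller is the default because it tracks the skew of the sampling
distribution of $m$ when the slope is estimated with modest precision —
exactly the situation in a 6-dose assay with 10–15 larvae per well. In
the package's own calibration (a fixed simulated assay at 12 larvae/well,
3 replicates, checked against a 2000-draw parametric-bootstrap percentile
interval), the Fieller limits agree with the bootstrap within 15% on each
side while the delta lower limit can be off by more than half; with 100
larvae per well both methods agree with the bootstrap within 5%. The
heterogeneity inflation is applied identically to both methods so they
remain comparable on overdispersed data; with $h \le 1$ the delta
interval is the plain $z$-interval.

## Activity screening and censoring

`activity_screen()` declares a treatment non-active when its corrected
mortality at the highest tested dose falls below 10% (configurable). The
threshold is a package choice: “no activity” reports in the motivating
assays come without a numeric cutoff, and 10% is low enough that any
fit-worthy dose-response would clear it while binomially plausible noise
at typical well sizes (one death in twelve larvae) does not. Non-active
treatments carry a censored LC50 (`censored_lc()`): a bound and a
direction, never fabricated limits; reports render them as `>1e+05`.

## Mixtures: simple similar action, synergism, enabling

For a mixture of toxins with similar modes of action and parallel
dose-response lines, the no-interaction expectation of the mixture LC50
is the proportion-weighted harmonic combination (Tabashnik's formulation
of simple similar action):

$$\mathrm{LC}_{50}(m) = \Big(\sum_i \frac{r_i}{\mathrm{LC}_{50,i}}\Big)^{-1},$$

with $r_i$ the mass fractions (1:1 mixtures give $r = 0.5$ each). The
synergism factor is SF = expected / observed; SF $\gg 1$ indicates
synergy. Two design choices deserve note:

* **Censored components enter at their censoring bound.** When a
  component is individually non-active (LC50 > bound), the bound is
  substituted in the harmonic sum and the result is flagged as a *lower
  bound* on the expected LC50 (hence SF is a lower bound on the synergy).
  This is the only reading under which published expectations of the
  form “456 from a $>10^5$ partner and a 228 ng/mL partner at 1:1”
  follow from their inputs, and it is conservative: the true expectation
  can only be larger.
* **Parallelism is assumed, not tested.** The model itself presumes
  parallel lines; no parallelism test is implemented, matching standard
  practice for mixtures of closely related toxins.

Classification uses conventional, configurable SF thresholds —
synergistic above 2, antagonistic below 0.5, additive between. A mixture
of components that are *all* individually non-active but which itself
kills below the screening bound is classed `enabling`, and an enabling
factor (the active component's LC50 over the mixture LC50, or for
all-censored pairs the bound-substituted expectation over the observed)
quantifies the fold-enhancement. No significance test on SF is computed
by default; the parametric-bootstrap machinery used in the tests can
propagate both fits' covariances, but is deliberately not part of the
reported tables.

With $r = 0.5$ and a censoring bound far above the active partner's
LC50, the SSA expectation approaches $2\,\mathrm{LC}_{50,\text{active}}$,
so the synergism and enabling factors nearly coincide — the test suite
checks this algebraic limit at a bound of $10^{12}$.

The preliminary mortality screen (`mortality_synergy_screen()`) flags a
candidate synergy when the 1:1 mixture's mortality strictly exceeds the
sum of the individual mortalities, with the sum capped at 1 — a mixture
cannot be asked to beat an impossible 130% expectation; the capped rule
is this package's decision.

## The synthetic bioassay generator

`simulate_assay()` emulates the serial-dilution design: 6 concentrations
in exact 1:2 steps from a top dose (doses are stored at full precision —
31.25, 15.625 — treating rounded published dose listings like “31.5” as
display rounding), 10–15 larvae per well drawn uniformly (the design
range; per-assay counts in published work are unstated), 3 replicate
wells per dose (a package default; the replicate structure is likewise
unstated), zero control mortality by default, and binomial deaths under
the logit truth. `choose_c1()` anchors the series at the dose producing
90% predicted mortality, implementing the rule that the top dose should
produce 90–100% kill. `simulate_mixture_assay()` draws the mixture's
response from the parallel-lines truth
$F(\beta(\log_{10}(ds) - \log_{10}\mathrm{LC}_{50,\mathrm{SSA}}))$, so
the synergy multiplier $s = 1$ *is* the SSA null and $s > 1$ shifts the
true mixture LC50 to $\mathrm{LC}_{50,\mathrm{SSA}}/s$; unequal true
component slopes (a parallelism violation) are outside the generator's
default contract.

Reproducibility: every simulation takes an explicit integer seed, and
`derive_seeds()` produces prefix-stable per-assay seeds — extending a
simulation study never perturbs the assays already drawn.

What the generator does *not* emulate: between-well overdispersion beyond
binomial, larval development or feeding behaviour, dose-preparation
error, and non-parallel component curves. Passing calibration therefore
shows the estimators are correct *under the assumed model at the stated
design sizes*, not that real assays are free of extra-binomial noise —
the heterogeneity machinery exists precisely because they often are not.

## Calibration results and problem sizes

The package's own calibration (run by the test suite and by
`analysis/04_calibration.R`) uses 500 simulated assays at the reference
truth (LC50 171 ng/mL, slope 1.85, 6 doses, 12 larvae/well, 3
replicates) for parameter recovery and coverage, 2000 bootstrap draws
for the limit comparison, and 200 simulated mixtures each for the SSA
null (s = 1) and the synergy-recovery (s = 11.44) checks — sizes at
which the Monte-Carlo error is small relative to the tolerances while
the whole suite stays quick to run. Observed behaviour: median LC50
recovery within a few percent of truth, Fieller coverage near the
nominal 95%, mean SF under the null within Monte-Carlo error of 1, and
median SF at s = 11.44 within a few percent of the target.

## Known limitations

* No time-to-death or survival modelling; mortality is a single endpoint.
* No comparison tests between dose-response curves (parallelism,
  relative-potency); the SSA model assumes what such a test would check.
* The SSA null is the only mixture reference model: independent action
  and multiplicative-survival alternatives are out of scope, as is any
  mechanistic receptor/pore-formation modelling of Cyt–Cry interaction.
* Published LC50 tables cannot be *refit* without the raw well counts;
  consistency with published values is checked through coefficient
  inversion and the mixture arithmetic, not by reproducing the fits.
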