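# Published single-toxin fits (LC50 table of the motivating study):
# observed LC50, limits, chi2, df, slope, slope SE, intercept.
table1 <- data.frame(
  treatment = c("Cry4Aa", "Cry4Ba", "Cry11Aa", "Cyt1Aa", "AM 65-52"),
  lc50      = c(178, 46, 228, 171, 0.019),
  lower     = c(142, 30.4, 144, 133, 0.013),
  upper     = c(226, 65.7, 324, 219, 0.024),
  chi2      = c(6.66, 2.45, 3.14, 4.55, 4.20),
  df        = c(4, 4, 4, 4, 4),
  slope     = c(1.80, 1.17, 1.11, 1.85, 1.66),
  se_slope  = c(0.202, 0.182, 0.166, 0.223, 0.191),
  intercept = c(-4.04, -1.95, -2.61, -4.12, 2.90)
)

# quantal_fit object from printed coefficients (covariance optional)
make_fit <- function(intercept, slope, covariance = matrix(0, 2, 2),
                     link = "logit", chi2 = 0, df = 4L) {
  structure(list(
    link = link, intercept = intercept, slope = slope,
    covariance = covariance, slope_se = sqrt(covariance[2, 2]),
    k_doses = df + 2L, chi2 = chi2, df = as.integer(df),
    heterogeneity = if (df >= 1) max(1, chi2 / df) else 1,
    converged = TRUE, iterations = 0L
  ), class = "quantal_fit")
}

# covariance consistent with a printed slope SE and a stated dose design:
# expected binomial information at the printed coefficients, rescaled so
# the slope standard error matches the printed one
synth_covariance <- function(intercept, slope, doses, n_per_dose,
                             target_slope_se) {
  x <- log10(doses)
  p <- plogis(intercept + slope * x)
  w <- n_per_dose * p * (1 - p)
  info <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2, 2)
  V <- solve(info)
  V * target_slope_se^2 / V[2, 2]
}

# independent maximum-likelihood oracle: iteratively refined dense grid
# search of the binomial log-likelihood over (intercept, slope)
grid_ml_oracle <- function(pooled, link = "logit",
                           intercept_range = c(-20, 20),
                           slope_range = c(0.01, 20),
                           n_grid = 61, n_zoom = 7) {
  F <- if (link == "logit") plogis else pnorm
  x <- log10(pooled$concentration)
  n <- pooled$n
  y <- pooled$dead
  ll <- function(a, b) {
    p <- pmin(1 - 1e-12, pmax(1e-12, F(a + b * x)))
    sum(y * log(p) + (n - y) * log1p(-p))
  }
  ar <- intercept_range
  br <- slope_range
  best <- c(NA, NA)
  for (z in seq_len(n_zoom)) {
    as <- seq(ar[1], ar[2], length.out = n_grid)
    bs <- seq(br[1], br[2], length.out = n_grid)
    vals <- outer(as, bs, Vectorize(ll))
    idx <- arrayInd(which.max(vals), dim(vals))
    best <- c(as[idx[1]], bs[idx[2]])
    da <- diff(ar) / (n_grid - 1)
    db <- diff(br) / (n_grid - 1)
    ar <- best[1] + c(-3, 3) * da
    br <- best[2] + c(-3, 3) * db
  }
  list(intercept = best[1], slope = best[2],
       resolution = max(diff(ar), diff(br)) / (n_grid - 1))
}

# one simulated single-toxin assay under the study's reference truth
# (LC50 171 ng/mL, slope 1.85 per log10 ng/mL, 6-dose 1:2 series from a
# top dose at 90% predicted mortality, 12 larvae/well, 3 replicates)
reference_truth <- function() true_model(slope = 1.85, lc50 = 171)

reference_design <- function(truth = reference_truth(), larvae = c(12, 12)) {
  assay_design(c1 = choose_c1(truth), larvae_range = larvae)
}
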