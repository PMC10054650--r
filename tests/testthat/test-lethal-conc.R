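test_that("LC50 is the closed-form 10^(-intercept/slope) for both links", {
  for (link in c("logit", "probit")) {
    fit <- make_fit(intercept = -1.95, slope = 1.17, link = link)
    expect_equal(lc_p(fit)$estimate, 10^(1.95 / 1.17), tolerance = 1e-12)
  }
  expect_equal(lc_p(make_fit(0, 1))$estimate, 1)
})

test_that("published slope/intercept pairs invert to the published LC50s", {
  # coefficients printed to 3 significant figures, hence the 2% band
  for (i in which(table1$treatment != "AM 65-52")) {
    fit <- make_fit(table1$intercept[i], table1$slope[i])
    expect_equal(lc_p(fit)$estimate, table1$lc50[i],
                 tolerance = 0.02, label = table1$treatment[i])
  }
})

test_that("inverse prediction round-trips through the fitted curve", {
  obs <- simulate_assay(reference_design(), reference_truth(), seed = 21)
  for (link in c("logit", "probit")) {
    fit <- fit_quantal(obs, link = link)
    for (p in c(0.1, 0.5, 0.9)) {
      expect_equal(predict(fit, lc_p(fit, p)$estimate), p,
                   tolerance = 1e-10)
    }
  }
})

test_that("non-positive slopes are rejected for inversion", {
  fit <- make_fit(intercept = 1, slope = -0.5)
  expect_error(lc_p(fit), class = "quantalmix_nonmonotone_error")
})

test_that("zero sampling variance collapses the limits onto the estimate", {
  fit <- make_fit(intercept = -2, slope = 1, covariance = matrix(0, 2, 2))
  for (method in c("fieller", "delta")) {
    lc <- confidence_limits(fit, method = method)
    expect_equal(lc$lower, lc$estimate)
    expect_equal(lc$upper, lc$estimate)
  }
})

test_that("Fieller limits from published-style coefficients bracket the LC50", {
  # covariance consistent with the printed slope SE and the stated
  # 6-dose 1:2 series for this toxin
  i <- which(table1$treatment == "Cry4Ba")
  V <- synth_covariance(table1$intercept[i], table1$slope[i],
                        doses = serial_dilution(500, 2, 6), n_per_dose = 36,
                        target_slope_se = table1$se_slope[i])
  fit <- make_fit(table1$intercept[i], table1$slope[i], covariance = V,
                  chi2 = table1$chi2[i])
  lc <- confidence_limits(fit, method = "fieller")
  expect_lt(lc$lower, 46)
  expect_gt(lc$upper, 46)
  # same order as the printed 30.4-65.7 band (loose: within a factor 2)
  expect_gt(lc$lower, 30.4 / 2)
  expect_lt(lc$lower, 46)
  expect_gt(lc$upper, 46)
  expect_lt(lc$upper, 65.7 * 2)
})

test_that("confidence limits agree with a parametric-bootstrap oracle", {
  # percentile interval from refitting 2000 binomial resamples of the
  # fitted model at the realised design
  boot_interval <- function(fit, n_draws = 2000) {
    pooled <- fit$pooled
    p_hat <- predict(fit, pooled$concentration)
    boot <- vapply(derive_seeds(4242, n_draws), function(s) {
      set.seed(s)
      bd <- pooled
      bd$dead <- rbinom(nrow(bd), size = bd$n, prob = p_hat)
      bf <- tryCatch(fit_quantal(bd), error = function(e) NULL)
      if (is.null(bf)) NA_real_ else lc_p(bf)$estimate
    }, numeric(1))
    quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  tm <- reference_truth()

  # small study design (12 larvae/well x 3 replicates): the sampling
  # distribution of the LC50 is skewed and only Fieller tracks it
  fit_small <- fit_quantal(simulate_assay(reference_design(), tm, seed = 42))
  qs <- boot_interval(fit_small)
  lc_f <- confidence_limits(fit_small, method = "fieller")
  expect_equal(lc_f$lower, qs[1], tolerance = 0.15)
  expect_equal(lc_f$upper, qs[2], tolerance = 0.15)

  # larger wells (100 larvae): first-order propagation becomes accurate
  # and both methods agree with the bootstrap
  des_big <- reference_design(larvae = c(100, 100))
  fit_big <- fit_quantal(simulate_assay(des_big, tm, seed = 3))
  qs_big <- boot_interval(fit_big)
  for (method in c("delta", "fieller")) {
    lc <- confidence_limits(fit_big, method = method)
    expect_equal(lc$lower, qs_big[1], tolerance = 0.15)
    expect_equal(lc$upper, qs_big[2], tolerance = 0.15)
  }
})

test_that("delta-method SE of log10 LC50 matches MASS::dose.p on a glm fit", {
  skip_if_not_installed("MASS")
  obs <- simulate_assay(reference_design(), reference_truth(), seed = 13)
  fit <- fit_quantal(obs)
  pooled <- fit$pooled
  g <- glm(cbind(dead, n - dead) ~ log10(concentration),
           family = binomial(), data = pooled)
  dp <- MASS::dose.p(g, p = 0.5)
  lc <- confidence_limits(fit, method = "delta")
  # our limits are 10^(m +/- q * SE); recover SE and compare
  q <- qnorm(0.975)
  se_ours <- (log10(lc$upper) - log10(lc$lower)) / (2 * q)
  expect_equal(unname(as.numeric(dp)), log10(lc$estimate),
               tolerance = 1e-6)
  expect_equal(unname(attr(dp, "SE")[1, 1]), se_ours, tolerance = 1e-6)
})

test_that("heterogeneity inflates the limits with t quantiles", {
  V <- synth_covariance(-4, 1.8, serial_dilution(1000, 2, 6), 36, 0.2)
  good <- make_fit(-4, 1.8, covariance = V, chi2 = 2)       # h = 1
  noisy <- make_fit(-4, 1.8, covariance = V, chi2 = 12)     # h = 3
  for (method in c("fieller", "delta")) {
    l1 <- confidence_limits(good, method = method)
    l2 <- confidence_limits(noisy, method = method)
    expect_lt(l2$lower, l1$lower)
    expect_gt(l2$upper, l1$upper)
  }
})

test_that("a slope not significantly positive gives unbounded Fieller limits", {
  V <- diag(c(4, 4))  # slope SE 2 against slope 1.2: g > 1
  fit <- make_fit(-2, 1.2, covariance = V)
  expect_error(confidence_limits(fit, method = "fieller"),
               class = "quantalmix_unbounded_limits_error")
})

test_that("censored LC objects render and validate", {
  lc <- censored_lc(1e5)
  expect_true(is_censored(lc))
  expect_equal(lc$censor_bound, 1e5)
  expect_equal(lc$censor_direction, "greater_than")
  expect_true(is.na(lc$estimate))
  expect_output(print(lc), ">")
})
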