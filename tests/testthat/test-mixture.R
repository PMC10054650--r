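test_that("SSA expected LC50 reproduces the published mixture expectations", {
  m <- mixture_components(c("Cyt1Aa", "Cry11Aa"), c(0.5, 0.5), c(171, 228))
  e <- expected_lc50_ssa(m)
  expect_equal(e$expected, 195.6, tolerance = 0.002)
  expect_false(e$lower_bound)

  # non-active partner enters at its censoring bound; result is a lower bound
  m2 <- mixture_components(c("Cyt1A-like", "Cry11Aa"), c(0.5, 0.5),
                           list(censored_lc(1e5), 228))
  e2 <- expected_lc50_ssa(m2)
  expect_equal(e2$expected, 456, tolerance = 0.003)
  expect_true(e2$lower_bound)
})

test_that("SSA combination obeys its algebraic identities", {
  # equal potency is a fixed point
  for (L in c(0.5, 171, 3e4)) {
    m <- mixture_components(c("A", "B"), c(0.5, 0.5), c(L, L))
    expect_equal(expected_lc50_ssa(m)$expected, L)
  }
  # k-component formula, evaluated by hand
  m3 <- mixture_components(c("A", "B", "C"), c(0.2, 0.3, 0.5),
                           c(100, 200, 400))
  expect_equal(expected_lc50_ssa(m3)$expected,
               1 / (0.2 / 100 + 0.3 / 200 + 0.5 / 400))
  # two-component call equals the k-component formula at k = 2
  m2 <- mixture_components(c("A", "B"), c(0.3, 0.7), c(50, 400))
  expect_equal(expected_lc50_ssa(m2)$expected, 1 / (0.3 / 50 + 0.7 / 400))
})

test_that("SSA expectation is bounded by and monotone in the component LC50s", {
  set.seed(1)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    r <- runif(k); r <- r / sum(r)
    lc <- 10^runif(k, -1, 5)
    m <- mixture_components(paste0("C", 1:k), r, lc)
    e <- expected_lc50_ssa(m)$expected
    expect_gte(e, min(lc))
    expect_lte(e, max(lc))
    # raising one component's LC50 never lowers the expectation
    j <- sample(k, 1)
    lc2 <- lc; lc2[j] <- lc2[j] * 3
    e2 <- expected_lc50_ssa(mixture_components(paste0("C", 1:k), r, lc2))
    expect_gte(e2$expected, e)
  }
})

test_that("a censored bound pushed to infinity leaves the active path only", {
  m <- mixture_components(c("inert", "active"), c(0.5, 0.5),
                          list(censored_lc(1e12), 171))
  expect_equal(expected_lc50_ssa(m)$expected, 171 / 0.5, tolerance = 1e-6)
})

test_that("component validation rejects malformed mixtures", {
  expect_error(mixture_components("A", 1, 100), "at least 2")
  expect_error(mixture_components(c("A", "B"), c(0.5, 0.4), c(1, 1)),
               "sum to 1")
  expect_error(mixture_components(c("A", "B"), c(0.5, 0.5), c(-1, 1)),
               "> 0")
  m <- mixture_components(c("A", "B"), c(0.5, 0.5),
                          list(censored_lc(10, "less_than"), 228))
  expect_error(expected_lc50_ssa(m),
               class = "quantalmix_unsupported_censor_error")
})

test_that("synergism factors reproduce every published mixture-table value", {
  published <- data.frame(
    expected = c(170, 100, 195.6, 456),
    observed = c(6.04, 3.08, 17.1, 19.7),
    sf       = c(28.14, 32.46, 11.44, 23.14)
  )
  sf <- synergism_factor(published$expected, published$observed)
  expect_equal(sf, published$sf, tolerance = 0.005)
  expect_equal(synergism_factor(5, 5), 1)
  expect_error(synergism_factor(-1, 2), "> 0")
  # scale invariance: rescaling all LC50s leaves SF unchanged
  expect_equal(synergism_factor(195.6 * 7, 17.1 * 7),
               synergism_factor(195.6, 17.1))
})

test_that("enabling factor matches the published fold-enhancement", {
  expect_equal(enabling_factor(171, 23.3), 7.3, tolerance = 0.01)
  expect_equal(enabling_factor(88, 88), 1)
  expect_error(enabling_factor(0, 1), "> 0")
  # with r = 0.5 and a bound far above the partner LC50, the
  # bound-substituted SSA expectation approaches 2 * LC50_active, so the
  # synergism and enabling factors coincide up to the bound term
  m <- mixture_components(c("inert", "active"), c(0.5, 0.5),
                          list(censored_lc(1e5), 228))
  sf <- synergism_factor(expected_lc50_ssa(m)$expected, 19.7)
  expect_equal(sf, 23.15, tolerance = 0.005)
  expect_equal(sf, enabling_factor(2 * 228, 19.7), tolerance = 0.005)
})

test_that("interaction classification follows the SF thresholds and enabling rule", {
  # two active components with strong synergy
  m <- mixture_components(c("Cyt1Aa", "Cry11Aa"), c(0.5, 0.5), c(171, 228))
  a <- assess_interaction(m, observed_lc50 = 17.1)
  expect_equal(a$interaction_class, "synergistic")
  expect_equal(a$synergism_factor, 11.44, tolerance = 0.005)
  expect_null(a$enabling_factor)

  # both components individually non-active, finite mixture LC50: enabling
  m2 <- mixture_components(c("Cyt1A-like", "Cry53-like"), c(0.5, 0.5),
                           list(censored_lc(1e5), censored_lc(1e5)))
  a2 <- assess_interaction(m2, observed_lc50 = 1331)
  expect_equal(a2$interaction_class, "enabling")
  expect_true(a2$expected_is_lower_bound)

  # SF of 1 with two active components: additive
  m3 <- mixture_components(c("A", "B"), c(0.5, 0.5), c(100, 100))
  a3 <- assess_interaction(m3, observed_lc50 = 100)
  expect_equal(a3$interaction_class, "additive")

  # SF below the antagonism threshold
  a4 <- assess_interaction(m3, observed_lc50 = 300)
  expect_equal(a4$interaction_class, "antagonistic")

  # one censored partner: enabling factor reported from the active component
  m5 <- mixture_components(c("Cyt1Aa", "Cry56A-like"), c(0.5, 0.5),
                           list(171, censored_lc(1e5)))
  a5 <- assess_interaction(m5, observed_lc50 = 23.3)
  expect_equal(a5$enabling_factor, 171 / 23.3)
  expect_equal(a5$interaction_class, "synergistic")
})

test_that("the preliminary mortality screen uses the capped-sum rule", {
  expect_true(mortality_synergy_screen(0.90, c(0.30, 0.20)))
  expect_false(mortality_synergy_screen(0.40, c(0.30, 0.20)))
  # sum capped at 1: a saturated mixture cannot beat it strictly
  expect_false(mortality_synergy_screen(1.00, c(0.70, 0.60)))
  expect_error(mortality_synergy_screen(1.2, 0.1))
})
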