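#' Control parameters for the quantal fit
#'
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance: relative deviance change and gradient
#'   max-norm must fall below it.
#' @param max_abs_slope slopes beyond this magnitude (per log10 ng/mL) are
#'   treated as complete separation.
#' @return list of control parameters.
#' @export
fit_control <- function(max_iter = 100L, tol = 1e-8, max_abs_slope = 50) {
  stopifnot(max_iter >= 1, tol > 0, max_abs_slope > 0)
  list(max_iter = as.integer(max_iter), tol = tol,
       max_abs_slope = max_abs_slope)
}

# link functions on the linear predictor eta = intercept + slope * log10(d)
link_funs <- function(link) {
  switch(link,
    logit = list(F = stats::plogis, Q = stats::qlogis,
                 f = stats::dlogis),
    probit = list(F = stats::pnorm, Q = stats::qnorm,
                  f = stats::dnorm),
    stop("link must be 'logit' or 'probit'")
  )
}

# binomial deviance-scale log-likelihood; y may be fractional (Abbott)
binom_loglik <- function(theta, x, n, y, F) {
  p <- F(theta[1] + theta[2] * x)
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  sum(y * log(p) + (n - y) * log1p(-p))
}

# gradient and observed information of the log-likelihood in (a, b)
loglik_derivs <- function(theta, x, n, y, link) {
  lf <- link_funs(link)
  eta <- theta[1] + theta[2] * x
  p <- pmin(1 - 1e-12, pmax(1e-12, lf$F(eta)))
  f <- lf$f(eta)
  q <- 1 - p
  u <- f / (p * q)              # d loglik / d eta per unit (y - n p)
  g_eta <- (y - n * p) * u
  if (link == "logit") {
    # canonical link: observed = expected information
    h_eta <- -n * p * q
  } else {
    # probit: d/d eta [(y - n p) * phi/(p q)]
    fp <- -eta * f                       # phi'(eta)
    up <- (fp * p * q - f * f * (q - p)) / (p * q)^2
    h_eta <- -n * f * u + (y - n * p) * up
  }
  grad <- c(sum(g_eta), sum(g_eta * x))
  hess <- -matrix(c(sum(-h_eta), sum(-h_eta * x),
                    sum(-h_eta * x), sum(-h_eta * x^2)), 2, 2)
  list(grad = grad, hess = hess, p = p)
}

#' Maximum-likelihood quantal dose-response fit
#'
#' Fits mortality probability `F(intercept + slope * log10(concentration))`
#' to pooled well counts by maximising the binomial log-likelihood, with
#' `F` the logistic (default) or standard-normal distribution function.
#' Newton-Raphson with step-halving; the reported covariance is the
#' inverse observed information at the optimum. Control wells never enter
#' the regression: they act only through Abbott's correction (see
#' [pool_doses()]).
#'
#' Degenerate data -- flat response, all dead, none dead, or complete
#' separation -- cannot identify a finite positive slope; such data raise a
#' classed error (`quantalmix_degenerate_error`) directing the caller to
#' report a censored LC50 via [activity_screen()] instead.
#'
#' @param observations a bioassay data frame (see
#'   [bioassay_observations()]), or a pre-pooled data frame with columns
#'   `concentration`, `n`, `dead`.
#' @param link `"logit"` (default) or `"probit"`.
#' @param control see [fit_control()].
#' @param abbott apply Abbott's correction from control wells.
#' @return An object of class `"quantal_fit"`: link, coefficients
#'   (`intercept`, `slope` per log10 ng/mL), `covariance` (2x2, order
#'   intercept then slope), `slope_se`, `k_doses`, `chi2`, `df`,
#'   `heterogeneity`, `converged`, `iterations`, `loglik`, and the pooled
#'   data used.
#' @examples
#' d <- data.frame(concentration = c(1000, 500, 250, 125, 62.5, 31.25),
#'                 n = rep(30, 6), dead = c(28, 24, 17, 9, 4, 2))
#' fit <- fit_quantal(d)
#' coef(fit)
#' @export
fit_quantal <- function(observations, link = c("logit", "probit"),
                        control = fit_control(), abbott = TRUE) {
  link <- match.arg(link)
  if (inherits(observations, "bioassay") ||
      all(c("n_exposed", "n_dead") %in% names(observations))) {
    pooled <- pool_doses(observations, abbott = abbott)
  } else {
    stopifnot(all(c("concentration", "n", "dead") %in% names(observations)))
    pooled <- observations[order(-observations$concentration),
                           c("concentration", "n", "dead")]
    if (any(pooled$concentration <= 0)) {
      stop("pre-pooled data must contain nonzero concentrations only")
    }
  }

  k <- nrow(pooled)
  if (k < 2) stop("need at least 2 distinct nonzero concentrations")
  x <- log10(pooled$concentration)
  n <- pooled$n
  y <- pooled$dead
  prop <- y / n

  degenerate <- function(msg, direction) {
    stop(errorCondition(
      paste0(msg, "; report a censored LC50 via activity_screen()"),
      direction = direction,
      class = c("quantalmix_degenerate_error", "error", "condition")
    ))
  }
  if (all(y == 0)) degenerate("no mortality at any dose", "greater_than")
  if (all(y == n)) degenerate("complete mortality at every dose", "less_than")
  if (max(prop) - min(prop) < sqrt(.Machine$double.eps)) {
    degenerate("flat response: identical mortality at every dose",
               "greater_than")
  }
  if (all(y == 0 | y == n)) {
    # every dose fully dead or fully alive: the likelihood is maximised
    # only as slope -> Inf (complete separation)
    degenerate("complete separation: all-or-none response at every dose",
               NA_character_)
  }

  lf <- link_funs(link)
  # start from the least-squares line through the empirical link values
  emp <- lf$Q(pmin(1 - 0.5 / n, pmax(0.5 / n, prop)))
  b0 <- stats::cov(x, emp) / stats::var(x)
  theta <- c(mean(emp) - b0 * mean(x), b0)

  ll <- binom_loglik(theta, x, n, y, lf$F)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(control$max_iter)) {
    d <- loglik_derivs(theta, x, n, y, link)
    step <- tryCatch(-solve(d$hess, d$grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      # information singular: fall back on a tiny gradient step
      step <- d$grad / max(1, max(abs(d$grad)))
    }
    # step-halving until the likelihood does not decrease
    lam <- 1
    repeat {
      cand <- theta + lam * step
      ll_new <- binom_loglik(cand, x, n, y, lf$F)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- theta; ll_new <- ll; break }
    }
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    theta <- cand
    ll <- ll_new
    if (abs(theta[2]) > control$max_abs_slope) {
      degenerate(
        "slope diverging: complete separation between doses",
        if (theta[2] > 0) "greater_than" else "less_than")
    }
    if (rel_change < control$tol ||
        max(abs(loglik_derivs(theta, x, n, y, link)$grad)) < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(errorCondition(
      sprintf("no convergence after %d iterations (last: intercept %.4g, slope %.4g)",
              control$max_iter, theta[1], theta[2]),
      last = theta,
      class = c("quantalmix_convergence_error", "error", "condition")
    ))
  }

  d <- loglik_derivs(theta, x, n, y, link)
  covm <- tryCatch(solve(d$hess * -1), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  dimnames(covm) <- list(c("intercept", "slope"), c("intercept", "slope"))

  fit <- structure(list(
    link = link,
    intercept = theta[1],
    slope = theta[2],
    covariance = covm,
    slope_se = sqrt(covm[2, 2]),
    k_doses = k,
    converged = converged,
    iterations = iter,
    loglik = ll,
    pooled = pooled
  ), class = "quantal_fit")

  gof <- if (k >= 3) goodness_of_fit(fit, pooled) else
    list(chi2 = NA_real_, df = 0L, heterogeneity = 1)
  fit$chi2 <- gof$chi2
  fit$df <- gof$df
  fit$heterogeneity <- gof$heterogeneity
  fit
}

#' @export
coef.quantal_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
vcov.quantal_fit <- function(object, ...) object$covariance

#' @export
print.quantal_fit <- function(x, ...) {
  cat(sprintf("Quantal %s fit on log10(ng/mL), %d doses\n", x$link, x$k_doses))
  cat(sprintf("  slope %.4g (SE %.3g), intercept %.4g\n",
              x$slope, x$slope_se, x$intercept))
  cat(sprintf("  chi2 %.4g on %d df (heterogeneity %.3g), %d iterations\n",
              x$chi2, x$df, x$heterogeneity, x$iterations))
  invisible(x)
}

#' Predicted mortality at given concentrations
#'
#' @param object a `quantal_fit`.
#' @param concentration ng/mL, `> 0`.
#' @param ... unused.
#' @return predicted mortality proportions.
#' @export
predict.quantal_fit <- function(object, concentration, ...) {
  stopifnot(all(concentration > 0))
  lf <- link_funs(object$link)
  lf$F(object$intercept + object$slope * log10(concentration))
}

#' Pearson goodness of fit for a quantal fit
#'
#' Pearson chi-square over pooled doses,
#' `sum((dead - n p)^2 / (n p (1 - p)))`, with `df = k_doses - 2` and
#' Finney's heterogeneity factor `h = max(1, chi2 / df)`. Doses where the
#' fitted probability is numerically 0 or 1 contribute no information and
#' are dropped with a warning, reducing the degrees of freedom.
#'
#' @param fit a converged `quantal_fit`.
#' @param observations optional bioassay or pooled data (defaults to the
#'   data the fit was computed from).
#' @return list with `chi2`, `df`, `heterogeneity`.
#' @export
goodness_of_fit <- function(fit, observations = NULL) {
  stopifnot(inherits(fit, "quantal_fit"), fit$converged)
  pooled <- if (is.null(observations)) {
    fit$pooled
  } else if (all(c("concentration", "n", "dead") %in% names(observations))) {
    observations
  } else {
    pool_doses(observations)
  }
  p <- predict(fit, pooled$concentration)
  eps <- sqrt(.Machine$double.eps)
  usable <- p > eps & p < 1 - eps
  if (any(!usable)) {
    warning(sprintf(
      "%d dose(s) with fitted mortality of 0 or 1 excluded from chi-square",
      sum(!usable)))
  }
  k <- sum(usable)
  chi2 <- sum((pooled$dead[usable] - pooled$n[usable] * p[usable])^2 /
                (pooled$n[usable] * p[usable] * (1 - p[usable])))
  df <- max(0L, k - 2L)
  h <- if (df >= 1) max(1, chi2 / df) else 1
  list(chi2 = chi2, df = as.integer(df), heterogeneity = h)
}
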