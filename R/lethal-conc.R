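#' Censored lethal concentration
#'
#' Records an LC50 (or LCp) that could only be bounded by the bioassay,
#' e.g. "LC50 > 1e5 ng/mL" when the highest tested dose produced no
#' appreciable mortality.
#'
#' @param bound ng/mL, the censoring bound (usually the highest tested
#'   concentration).
#' @param direction `"greater_than"` (no activity up to the bound; the
#'   usual case) or `"less_than"`.
#' @param p_level target mortality proportion, default 0.5.
#' @return object of class `"lethal_conc"` with `censored = TRUE`.
#' @export
censored_lc <- function(bound, direction = c("greater_than", "less_than"),
                        p_level = 0.5) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(bound), bound > 0)
  structure(list(
    p_level = p_level, estimate = NA_real_,
    lower = NA_real_, upper = NA_real_, confidence = NA_real_,
    method = NA_character_, censored = TRUE,
    censor_bound = bound, censor_direction = direction
  ), class = "lethal_conc")
}

#' Is an LC estimate censored?
#' @param x a `lethal_conc`.
#' @return logical.
#' @export
is_censored <- function(x) isTRUE(x$censored)

#' @export
print.lethal_conc <- function(x, ...) {
  if (is_censored(x)) {
    cat(sprintf("LC%g %s %s ng/mL (censored)\n", 100 * x$p_level,
                if (x$censor_direction == "greater_than") ">" else "<",
                format(x$censor_bound)))
  } else {
    cat(sprintf("LC%g = %.4g ng/mL, %g%% limits (%.4g, %.4g) [%s]\n",
                100 * x$p_level, x$estimate, 100 * x$confidence,
                x$lower, x$upper, x$method))
  }
  invisible(x)
}

#' Lethal concentration point estimate
#'
#' Inverts a fitted quantal dose-response curve:
#' `LCp = 10^((F^-1(p) - intercept) / slope)`. For `p = 0.5` the quantile
#' is 0 under both links, so `LC50 = 10^(-intercept / slope)` exactly.
#'
#' @param fit a converged `quantal_fit` with positive slope.
#' @param p_level target mortality proportion in (0, 1), default 0.5.
#' @return `lethal_conc` with the point estimate only (no limits).
#' @examples
#' # Published coefficients can be inverted directly:
#' f <- structure(list(link = "logit", intercept = -4.12, slope = 1.85,
#'                     converged = TRUE), class = "quantal_fit")
#' lc_p(f)$estimate  # about 168.7 ng/mL
#' @export
lc_p <- function(fit, p_level = 0.5) {
  stopifnot(inherits(fit, "quantal_fit"), fit$converged,
            p_level > 0, p_level < 1)
  if (fit$slope <= 0) {
    stop(errorCondition(
      "fitted slope is not positive: mortality does not increase with dose",
      class = c("quantalmix_nonmonotone_error", "error", "condition")
    ))
  }
  lf <- link_funs(fit$link)
  m <- (lf$Q(p_level) - fit$intercept) / fit$slope
  structure(list(
    p_level = p_level, estimate = 10^m,
    lower = NA_real_, upper = NA_real_, confidence = NA_real_,
    method = NA_character_, censored = FALSE,
    censor_bound = NA_real_, censor_direction = NA_character_
  ), class = "lethal_conc")
}

#' Confidence limits for a lethal concentration
#'
#' Limits for `LCp` on the log10 scale, back-transformed to ng/mL.
#'
#' `method = "fieller"` applies Fieller's theorem to the parameter ratio
#' `m = (F^-1(p) - intercept) / slope` using the fit covariance -- the
#' classical fiducial limits of probit analysis. `method = "delta"`
#' propagates the covariance to first order and returns
#' `m +/- q * SE(m)`. Following Finney's heterogeneity convention, when
#' the Pearson `chi2/df` exceeds 1 the covariance is inflated by the
#' heterogeneity factor and t(df) quantiles replace normal quantiles.
#'
#' @param fit a converged `quantal_fit` with positive slope.
#' @param p_level target mortality proportion, default 0.5.
#' @param method `"fieller"` (default) or `"delta"`.
#' @param confidence confidence level, default 0.95.
#' @return `lethal_conc` with estimate and limits in ng/mL.
#' @export
confidence_limits <- function(fit, p_level = 0.5,
                              method = c("fieller", "delta"),
                              confidence = 0.95) {
  method <- match.arg(method)
  stopifnot(confidence > 0, confidence < 1)
  point <- lc_p(fit, p_level)
  lf <- link_funs(fit$link)
  a <- fit$intercept
  b <- fit$slope
  m <- (lf$Q(p_level) - a) / b

  V <- fit$covariance
  h <- if (is.null(fit$heterogeneity)) 1 else fit$heterogeneity
  df <- if (is.null(fit$df)) 0L else fit$df
  if (h > 1 && df >= 1) {
    V <- V * h
    q <- stats::qt(1 - (1 - confidence) / 2, df = df)
  } else {
    q <- stats::qnorm(1 - (1 - confidence) / 2)
  }
  v11 <- V[1, 1]; v12 <- V[1, 2]; v22 <- V[2, 2]

  if (all(abs(V) < .Machine$double.eps)) {
    lims <- c(m, m)
  } else if (method == "fieller") {
    g <- q^2 * v22 / b^2
    if (g >= 1) {
      stop(errorCondition(
        sprintf("Fieller g = %.3g >= 1: slope not significantly positive, limits unbounded", g),
        class = c("quantalmix_unbounded_limits_error", "error", "condition")
      ))
    }
    disc <- v11 + 2 * m * v12 + m^2 * v22 - g * (v11 - v12^2 / v22)
    half <- (q / abs(b)) * sqrt(max(0, disc))
    centre <- m + g * v12 / v22
    lims <- (centre + c(-1, 1) * half) / (1 - g)
  } else {
    se_m <- sqrt(max(0, v11 + 2 * m * v12 + m^2 * v22)) / abs(b)
    lims <- m + c(-1, 1) * q * se_m
  }

  point$lower <- 10^min(lims)
  point$upper <- 10^max(lims)
  point$confidence <- confidence
  point$method <- method
  point
}
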