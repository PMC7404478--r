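# Agreement statistics: Jeffreys evidence classification, intraclass
# correlation, Jeffreys-prior correlation test, Bland-Altman limits of
# agreement and the linear power-correction function.

#' Classify a Bayes factor on the Jeffreys evidence scale
#'
#' `BF10 >= 100`, 30-100, 10-30, 3-10 and 1-3 map to extreme, very strong,
#' strong, moderate and anecdotal evidence for H1; `BF10 = 1` is no
#' evidence either way; below 1 the inverse scale applies in favour of H0.
#'
#' @param bf10 Bayes factor, > 0.
#' @return Character label.
#' @examples
#' classify_bf(150)   # extreme evidence for H1
#' classify_bf(0.05)  # strong evidence for H0
#' @export
classify_bf <- function(bf10) {
  if (!is.numeric(bf10) || length(bf10) != 1L || is.na(bf10) || bf10 <= 0) {
    stop_input("`bf10` must be a single positive number.")
  }
  if (bf10 == 1) {
    return("no evidence of an hypothesis over the other")
  }
  hyp <- if (bf10 > 1) "H1" else "H0"
  b <- if (bf10 > 1) bf10 else 1 / bf10
  grade <- if (b >= 100) "extreme" else if (b >= 30) "very strong" else
    if (b >= 10) "strong" else if (b >= 3) "moderate" else "anecdotal"
  sprintf("%s evidence for %s", grade, hyp)
}

#' Intraclass correlation from variance components
#'
#' Per-draw `ICC = var_subject / (var_subject + var_residual)`, evaluated at
#' the covariate reference point (standardised speed 0, where the
#' random-slope variance drops out). For an `spm_lmm` fit the posterior
#' draws of the random-intercept and residual variances are used; numeric
#' vectors of variance draws can be supplied directly (single values give
#' the exact closed form).
#'
#' @param x An `spm_lmm` fit, or numeric draws of the between-subject
#'   variance.
#' @param var_residual Numeric draws of the residual variance (when `x` is
#'   numeric).
#' @param ... Unused.
#' @return Tibble with `estimate` (posterior median), `conf.low`,
#'   `conf.high` (95% credible interval) and an `icc_draws` attribute.
#' @examples
#' icc(3, 1)   # 0.75
#' @export
icc <- function(x, ...) UseMethod("icc")

#' @rdname icc
#' @export
icc.default <- function(x, var_residual, ...) {
  if (missing(var_residual)) stop_input("Missing residual variance component.")
  if (length(x) != length(var_residual)) {
    stop_input("Variance-component draws must have equal length.")
  }
  if (any(x < 0) || any(var_residual < 0)) {
    stop_input("Variance components must be >= 0.")
  }
  draws <- x / (x + var_residual)
  qs <- quantile(draws, c(0.5, 0.025, 0.975), names = FALSE)
  out <- tibble::tibble(estimate = qs[1], conf.low = qs[2], conf.high = qs[3])
  attr(out, "icc_draws") <- draws
  out
}

#' @rdname icc
#' @export
icc.spm_lmm <- function(x, ...) {
  if (!all(c("sd__(Intercept)", "sigma") %in% colnames(x$draws))) {
    stop_input("Fit lacks the required variance components.")
  }
  icc.default(x$draws[, "sd__(Intercept)"]^2, x$draws[, "sigma"]^2)
}

#' Bayesian correlation test with a Jeffreys prior
#'
#' Posterior for the Pearson correlation of a bivariate normal under the
#' Jeffreys analysis: `p(rho | r, n)` proportional to
#' `(1 - rho^2)^((n-1)/2) / (1 - rho r)^(n - 3/2)` with a uniform prior on
#' (-1, 1), evaluated on a fine grid, and the Bayes factor against
#' `rho = 0` by numerical integration of the marginal-likelihood ratio.
#'
#' @param x,y Numeric vectors, n >= 4, non-degenerate.
#' @return Tibble: `estimate` (posterior median of rho), `conf.low`,
#'   `conf.high`, `bf10`, `n`, `r` (sample correlation).
#' @export
bayesian_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) {
    stop_input("Need paired x, y with n >= 4.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_input("Zero-variance input; correlation undefined.")
  }
  n <- length(x)
  r <- stats::cor(x, y)
  rho <- seq(-1 + 1e-6, 1 - 1e-6, length.out = 8001)
  loglr <- ((n - 1) / 2) * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r)
  m <- max(loglr)
  w <- exp(loglr - m)
  Z <- pracma::trapz(rho, w)
  post <- w / Z
  cdf <- cumsum(c(0, (post[-1] + post[-length(post)]) / 2 * diff(rho)))
  cdf <- cdf / cdf[length(cdf)]
  qat <- function(p) {
    i <- which(cdf >= p)[1]
    rho[if (is.na(i)) length(rho) else i]
  }
  bf10 <- exp(m) * Z / 2                  # uniform prior density 1/2
  tibble::tibble(estimate = qat(0.5), conf.low = qat(0.025),
                 conf.high = qat(0.975), bf10 = bf10, n = n, r = r)
}

#' Bland-Altman agreement analysis
#'
#' Bias (`mean(device - reference)`), 1.96-SD limits of agreement, 95%
#' confidence intervals for the bias and each limit by the standard
#' normal-theory formulas, and a proportional-error diagnostic (slope of
#' the differences on the pair means).
#'
#' @param reference,device Paired measurements, equal length, n >= 3.
#' @return A `spm_bland_altman` object: `n`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `ci_bias`, `ci_loa_lower`, `ci_loa_upper`,
#'   `prop_slope` and the per-pair `data`.
#' @export
bland_altman <- function(reference, device) {
  if (length(reference) != length(device)) {
    stop_input("`reference` and `device` must have equal length.")
  }
  n <- length(reference)
  if (n < 3) stop_input("Bland-Altman needs n >= 3 pairs.")
  diffs <- device - reference
  means <- (device + reference) / 2
  bias <- mean(diffs)
  s <- sd(diffs)
  loa <- bias + c(-1, 1) * 1.96 * s
  tq <- qt(0.975, n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(1 / n + 1.96^2 / (2 * (n - 1)))
  prop_slope <- if (s > 0 && sd(means) > 0) {
    unname(coef(lm(diffs ~ means))[2])
  } else 0
  structure(
    list(n = n, bias = bias, sd_diff = s,
         loa_lower = loa[1], loa_upper = loa[2],
         ci_bias = bias + c(-1, 1) * tq * se_bias,
         ci_loa_lower = loa[1] + c(-1, 1) * tq * se_loa,
         ci_loa_upper = loa[2] + c(-1, 1) * tq * se_loa,
         prop_slope = prop_slope,
         data = tibble::tibble(mean = means, diff = diffs)),
    class = "spm_bland_altman"
  )
}

#' @export
print.spm_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, bias %.3f [%.3f, %.3f], LoA [%.3f, %.3f], prop. slope %.3g\n",
    x$n, x$bias, x$ci_bias[1], x$ci_bias[2], x$loa_lower, x$loa_upper,
    x$prop_slope))
  invisible(x)
}

#' @export
tidy.spm_bland_altman <- function(x, ...) {
  tibble::tibble(
    term = c("bias", "loa_lower", "loa_upper"),
    estimate = c(x$bias, x$loa_lower, x$loa_upper),
    conf.low = c(x$ci_bias[1], x$ci_loa_lower[1], x$ci_loa_upper[1]),
    conf.high = c(x$ci_bias[2], x$ci_loa_lower[2], x$ci_loa_upper[2])
  )
}

#' Linear power-correction function
#'
#' Least-squares line mapping device power to reference power fitted on
#' per-speed averaged values, `f(x) = a x + b`, so that `a * device + b`
#' rescales the device reading onto the reference scale.
#'
#' @param reference Per-speed averaged reference power (W).
#' @param device Per-speed averaged device power (W), at the same speeds.
#' @return A `spm_correction` object with coefficients `a`, `b`, fitted
#'   values, residuals and `r_squared`. Use [predict()] to apply it.
#' @examples
#' ref <- c(400, 500, 600); dev <- 0.5 * ref - 10
#' correction_function(ref, dev)   # a = 2, b = 20
#' @export
correction_function <- function(reference, device) {
  if (length(reference) != length(device) || length(reference) < 2) {
    stop_input("Need >= 2 paired per-speed averages.")
  }
  if (sd(device) == 0) {
    stop_input("Device power is constant; correction line undefined.")
  }
  fit <- lm(reference ~ device)
  # summary() warns on exact fits; an exact inverse-affine map is legitimate
  r2 <- suppressWarnings(summary(fit)$r.squared)
  res <- stats::residuals(fit)
  structure(
    list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
         fitted = unname(stats::fitted(fit)), residuals = unname(res),
         r_squared = r2, n = length(reference),
         data = tibble::tibble(reference = reference, device = device)),
    class = "spm_correction"
  )
}

#' @export
predict.spm_correction <- function(object, device, ...) {
  object$a * device + object$b
}

#' @export
print.spm_correction <- function(x, ...) {
  cat(sprintf("<spm_correction> f(x) = %.4g x + %.4g (R^2 %.3f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}
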