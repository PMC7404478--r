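# Bayesian linear and linear mixed models for device/reference agreement.
# Models are sampled with JAGS (Gibbs/slice MCMC); priors follow the
# metric-specific choices of the validity analysis: vague Student-t
# intercepts, metric-scaled normal priors on the device, speed and
# interaction terms, half-t priors on standard deviations and an LKJ(2)
# prior on the intercept-slope correlation.

#' Prior specification helpers
#'
#' `prior_normal()` and `prior_t()` build single-parameter prior
#' specifications; scales are standard deviations.
#'
#' @param location,scale,df Prior location, scale (sd) and degrees of freedom.
#' @return A `spm_prior` list.
#' @export
prior_normal <- function(location = 0, scale = 1) {
  structure(list(dist = "normal", location = location, scale = scale),
            class = "spm_prior")
}

#' @rdname prior_normal
#' @export
prior_t <- function(df = 3, location = 0, scale = 10) {
  structure(list(dist = "t", df = df, location = location, scale = scale),
            class = "spm_prior")
}

#' Default agreement-model priors per metric
#'
#' Mirrors the validity analysis: for mechanical power a vague
#' `t(3, 0, 10)` intercept with `N(0, 1000)` on the device term and
#' `N(0, 200)` on the speed term; for ground contact time `N(0, 1)` on
#' device and speed; for leg spring stiffness `N(0, 10)` on device and
#' `N(0, 1)` on speed. The interaction term, whose prior the analysis leaves
#' unstated, receives the same prior as the speed term. Standard deviations
#' (residual and random effects) get half-t(3, 0, 2.5 sd(y)) priors and the
#' intercept-slope correlation an LKJ(2) prior.
#'
#' @param metric One of `"power"`, `"gct"`, `"lss"`.
#' @return Named list of `spm_prior` objects for `intercept`, `device`,
#'   `speed` and `device:speed`.
#' @export
default_priors <- function(metric = c("power", "gct", "lss")) {
  metric <- match.arg(metric)
  sc <- switch(metric,
    power = c(device = 1000, speed = 200),
    gct = c(device = 1, speed = 1),
    lss = c(device = 10, speed = 1)
  )
  list(
    intercept = prior_t(3, 0, 10),
    device = prior_normal(0, sc[["device"]]),
    speed = prior_normal(0, sc[["speed"]]),
    `device:speed` = prior_normal(0, sc[["speed"]])
  )
}

#' MCMC sampler settings
#'
#' @param chains Number of chains.
#' @param iter Total iterations per chain (including warm-up).
#' @param warmup Warm-up iterations per chain (adaptation plus burn-in).
#' @return A list of settings.
#' @export
sampler_settings <- function(chains = 4, iter = 2000, warmup = 1000) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 200)
  list(chains = as.integer(chains), iter = as.integer(iter),
       warmup = as.integer(warmup))
}

prior_jags <- function(p) {
  switch(p$dist,
    normal = sprintf("dnorm(%.10g, %.10g)", p$location, 1 / p$scale^2),
    t = sprintf("dt(%.10g, %.10g, %d)", p$location, 1 / p$scale^2,
                as.integer(p$df)),
    stop_input("Unknown prior distribution '%s'.", p$dist)
  )
}

prior_logdens <- function(p, x) {
  switch(p$dist,
    normal = dnorm(x, p$location, p$scale, log = TRUE),
    t = dt((x - p$location) / p$scale, df = p$df, log = TRUE) - log(p$scale)
  )
}

half_t_logdens <- function(x, scale, df = 3) {
  ifelse(x <= 0, -Inf,
         log(2) + dt(x / scale, df = df, log = TRUE) - log(scale))
}

ensure_glm_module <- local({
  done <- FALSE
  function() {
    if (!done) {
      # block updating of linear submodels; greatly improves mixing of
      # correlated regression coefficients
      try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
      done <<- TRUE
    }
    invisible(NULL)
  }
})

run_jags <- function(model_string, data, monitors, settings, seed,
                     inits_base = list()) {
  ensure_glm_module()
  inits <- lapply(seq_len(settings$chains), function(ch) {
    c(inits_base,
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (as.integer(seed) * 11L + ch) %% .Machine$integer.max))
  })
  n_adapt <- min(500L, settings$warmup %/% 2L)
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  jm <- rjags::jags.model(con, data = data, inits = inits,
                          n.chains = settings$chains, n.adapt = n_adapt,
                          quiet = TRUE)
  stats::update(jm, n.iter = settings$warmup - n_adapt, progress.bar = "none")
  rjags::coda.samples(jm, variable.names = monitors,
                      n.iter = settings$iter - settings$warmup,
                      progress.bar = "none")
}

# split-Rhat (Gelman-Rubin on half-chains) for one parameter
split_rhat <- function(mat) {
  n <- nrow(mat)
  h <- n %/% 2
  halves <- cbind(mat[seq_len(h), , drop = FALSE],
                  mat[(n - h + 1):n, , drop = FALSE])
  m <- ncol(halves)
  if (m < 2) return(NA_real_)
  W <- mean(apply(halves, 2, var))
  B <- h * var(colMeans(halves))
  if (W < 1e-300) return(1)
  sqrt(((h - 1) / h * W + B / h) / W)
}

mcmc_diagnostics <- function(samples) {
  params <- colnames(samples[[1]])
  arr <- vapply(samples, function(ch) as.matrix(ch),
                matrix(0, nrow(samples[[1]]), length(params)))
  rhat <- vapply(seq_along(params), function(p) split_rhat(arr[, p, ]),
                 numeric(1))
  ess <- as.numeric(coda::effectiveSize(samples))
  names(rhat) <- names(ess) <- params
  list(rhat = rhat, ess = ess)
}

#' Bayesian simple linear regression
#'
#' Fits `y = b0 + b1 x + e` by MCMC with a weakly informative normal prior
#' on the slope (default `N(0, 10)`), a vague Student-t prior on the
#' intercept centred on the response median, and a half-t prior on the
#' residual standard deviation. A posterior-predictive R-squared (per draw,
#' `var(fit) / (var(fit) + sigma^2)`) is reported with its credible
#' interval. The fit is flagged non-converged when any split-Rhat exceeds
#' 1.01.
#'
#' @param y,x Response and covariate vectors (finite, n >= 3).
#' @param slope_prior,intercept_prior,sigma_scale Priors; `sigma_scale`
#'   defaults to 2.5 sd(y).
#' @param settings [sampler_settings()].
#' @param seed Integer seed.
#' @return A `spm_blm` fit object (draws, diagnostics, R-squared draws);
#'   see [tidy()] and [glance()] methods.
#' @export
fit_simple_linear <- function(y, x, slope_prior = prior_normal(0, 10),
                              intercept_prior = NULL, sigma_scale = NULL,
                              settings = sampler_settings(), seed = 1L) {
  if (length(y) != length(x) || length(y) < 3) {
    stop_input("Need matched y and x with n >= 3.")
  }
  if (any(!is.finite(y)) || any(!is.finite(x))) {
    stop_input("y and x must be finite.")
  }
  sdy <- max(sd(y), 1e-6)
  intercept_prior <- intercept_prior %||% prior_t(3, median(y), 2.5 * sdy)
  sigma_scale <- sigma_scale %||% (2.5 * sdy)
  # the covariate is centred for sampling (near-orthogonal intercept/slope);
  # the intercept prior applies to the centred intercept, as is conventional
  xbar <- mean(x)
  model <- paste0(
    "model {\n",
    "  for (n in 1:N) { y[n] ~ dnorm(b0c + b1 * xc[n], tau) }\n",
    "  b0c ~ ", prior_jags(intercept_prior), "\n",
    "  b1 ~ ", prior_jags(slope_prior), "\n",
    # the tiny truncation floor keeps conditional densities finite when the
    # data are an exact fit (zero residual variance)
    "  sigma ~ dt(0, ", sprintf("%.10g", 1 / sigma_scale^2), ", 3) T(",
    sprintf("%.10g", 1e-6 * sigma_scale), ",)\n",
    "  tau <- 1 / (sigma * sigma)\n",
    "}\n")
  samples <- run_jags(model, list(y = y, xc = x - xbar, N = length(y)),
                      c("b0c", "b1", "sigma"), settings, seed)
  # back-transform to the original-scale intercept before diagnostics
  samples <- coda::as.mcmc.list(lapply(samples, function(ch) {
    m <- as.matrix(ch)
    out <- cbind(b0 = m[, "b0c"] - m[, "b1"] * xbar, b1 = m[, "b1"],
                 sigma = m[, "sigma"])
    coda::mcmc(out, start = stats::start(ch), thin = coda::thin(ch))
  }))
  diag <- mcmc_diagnostics(samples)
  draws <- as.matrix(do.call(rbind, lapply(samples, as.matrix)))
  vfit <- draws[, "b1"]^2 * var(x)
  r2 <- vfit / (vfit + draws[, "sigma"]^2)
  structure(
    list(draws = draws, samples = samples, params = colnames(draws),
         terms = c("(Intercept)", "x"), y = y, x = x, xbar = xbar,
         priors = list(intercept = intercept_prior, slope = slope_prior,
                       sigma_scale = sigma_scale),
         r2_draws = r2, rhat = diag$rhat, ess = diag$ess,
         converged = all(diag$rhat <= 1.01, na.rm = TRUE),
         settings = settings, seed = as.integer(seed)),
    class = c("spm_blm", "spm_bayes_fit")
  )
}

lmm_design <- function(data, terms) {
  need <- c("value", "subject", "device_num", "speed_s")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_input("Comparison data lacks column(s): %s.",
                               paste(miss, collapse = ", "))
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  for (tm in terms) {
    cols[[tm]] <- switch(tm,
      device = data$device_num,
      speed = data$speed_s,
      `device:speed` = data$device_num * data$speed_s,
      stop_input("Unknown model term '%s'.", tm))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Bayesian linear mixed model for device agreement
#'
#' Fits the agreement model
#' `y_ijk = b0 + S0_i + b1 device_k + (b2 + S1_i) speed_j +
#'  b3 (speed_j device_k) + e_ijk`
#' with per-subject random intercepts and speed slopes (correlated via an
#' LKJ(2) prior), metric-specific fixed-effect priors ([default_priors()])
#' and half-t priors on all standard deviations. Speed enters standardised;
#' the device indicator is 0 (reference) / 1 (pod). Unbalanced designs and
#' missing laps are handled naturally. Reduced models (for Bayes factors)
#' are requested by dropping entries from `terms`.
#'
#' @param data Long comparison table ([build_comparison_table()]) or any
#'   tibble with `value`, `subject`, `device_num`, `speed_s` (and optionally
#'   `metric`).
#' @param metric Metric to model; filters `data$metric` when present and
#'   selects the default priors.
#' @param terms Fixed-effect terms beyond the intercept, a subset of
#'   `c("device", "speed", "device:speed")`.
#' @param priors Named list of `spm_prior` (see [default_priors()]).
#' @param settings [sampler_settings()].
#' @param seed Integer seed.
#' @return A `spm_lmm` fit object; see [tidy()], [glance()],
#'   [posterior_table()], [icc()], [bayes_factor()].
#' @export
fit_lmm <- function(data, metric = "power",
                    terms = c("device", "speed", "device:speed"),
                    priors = NULL, settings = sampler_settings(), seed = 1L) {
  if ("metric" %in% names(data) && !is.null(metric)) {
    data <- data[data$metric == metric, ]
  }
  if (nrow(data) == 0) stop_input("No rows to fit for metric '%s'.", metric)
  terms <- match.arg(terms, several.ok = TRUE)
  priors <- priors %||%
    default_priors(if (metric %in% c("power", "gct", "lss")) metric else "power")
  subj <- as.integer(factor(data$subject))
  if (length(unique(subj)) < 2) {
    stop_input("Random effects need at least 2 subjects.")
  }
  X <- lmm_design(data, terms)
  y <- data$value
  sdy <- max(sd(y), 1e-9)
  sd_scale <- 2.5 * sdy
  beta_priors <- c(list(priors$intercept),
                   lapply(terms, function(tm) priors[[tm]]))
  beta_lines <- paste0(
    vapply(seq_along(beta_priors), function(p) {
      sprintf("  beta[%d] ~ %s", p, prior_jags(beta_priors[[p]]))
    }, character(1)), collapse = "\n")
  # non-centred random effects. The heavy-tailed vague-location intercept
  # prior admits a spurious posterior mode in which the grand mean migrates
  # into the random intercepts with an inflated between-subject SD; the
  # non-centred Gibbs scheme started from data-informed values stays in the
  # data-supported mode (the behaviour the published modelling stacks
  # exhibit), at the cost of slower mixing along the weakly identified
  # intercept direction.
  model <- paste0(
    "model {\n",
    "  for (n in 1:N) {\n",
    "    mu[n] <- inprod(X[n,], beta) + S0[subj[n]] + S1[subj[n]] * zsp[n]\n",
    "    y[n] ~ dnorm(mu[n], tau)\n",
    "  }\n",
    beta_lines, "\n",
    "  for (j in 1:J) {\n",
    "    z0[j] ~ dnorm(0, 1)\n",
    "    z1[j] ~ dnorm(0, 1)\n",
    "    S0[j] <- sd0 * z0[j]\n",
    "    S1[j] <- sd1 * (rho * z0[j] + sqrt(1 - rho * rho) * z1[j])\n",
    "  }\n",
    sprintf("  sd0 ~ dt(0, %.10g, 3) T(%.10g,)\n", 1 / sd_scale^2,
            1e-6 * sd_scale),
    sprintf("  sd1 ~ dt(0, %.10g, 3) T(%.10g,)\n", 1 / sd_scale^2,
            1e-6 * sd_scale),
    sprintf("  sigma ~ dt(0, %.10g, 3) T(%.10g,)\n", 1 / sd_scale^2,
            1e-6 * sd_scale),
    "  tau <- 1 / (sigma * sigma)\n",
    "  u ~ dbeta(2, 2)\n",
    "  rho <- 2 * u - 1\n",
    "}\n")
  jdata <- list(y = y, X = X, zsp = data$speed_s, subj = subj,
                N = length(y), J = max(subj))
  ols <- stats::lm.fit(X, y)
  resid_by_subj <- as.numeric(tapply(ols$residuals, subj, mean))
  sd0_init <- max(sd(resid_by_subj), 1e-3 * sdy)
  sig_init <- max(sd(ols$residuals), 1e-3 * sdy)
  inits_base <- list(beta = as.numeric(ols$coefficients),
                     z0 = resid_by_subj / sd0_init,
                     z1 = rep(0, max(subj)),
                     sd0 = sd0_init, sd1 = 0.5 * sd0_init,
                     sigma = sig_init, u = 0.5)
  samples <- run_jags(model, jdata,
                      c("beta", "sd0", "sd1", "rho", "sigma"),
                      settings, seed, inits_base = inits_base)
  diag <- mcmc_diagnostics(samples)
  draws <- as.matrix(do.call(rbind, lapply(samples, as.matrix)))
  nice <- colnames(draws)
  nice[match(sprintf("beta[%d]", seq_len(ncol(X))), nice)] <- colnames(X)
  nice[nice == "sd0"] <- "sd__(Intercept)"
  nice[nice == "sd1"] <- "sd__speed"
  nice[nice == "rho"] <- "cor__(Intercept).speed"
  colnames(draws) <- nice
  names(diag$rhat) <- names(diag$ess) <- nice
  structure(
    list(draws = draws, samples = samples, params = nice,
         terms = colnames(X), metric = metric,
         model_data = list(y = y, X = X, zsp = data$speed_s, subj = subj),
         priors = priors, sd_scale = sd_scale,
         rhat = diag$rhat, ess = diag$ess,
         converged = all(diag$rhat <= 1.01, na.rm = TRUE),
         settings = settings, seed = as.integer(seed),
         logml_cache = new.env(parent = emptyenv())),
    class = c("spm_lmm", "spm_bayes_fit")
  )
}

summarise_draws_tbl <- function(fit) {
  qs <- apply(fit$draws, 2, quantile, probs = c(0.025, 0.975))
  tibble::tibble(
    term = colnames(fit$draws),
    estimate = colMeans(fit$draws),
    std.error = apply(fit$draws, 2, sd),
    conf.low = qs[1, ], conf.high = qs[2, ],
    rhat = unname(fit$rhat[colnames(fit$draws)]),
    ess = unname(fit$ess[colnames(fit$draws)])
  )
}

#' @export
tidy.spm_lmm <- function(x, ...) {
  out <- summarise_draws_tbl(x)
  out$effect <- ifelse(out$term %in% x$terms, "fixed", "ran_pars")
  out
}

#' @export
tidy.spm_blm <- function(x, ...) {
  out <- summarise_draws_tbl(x)
  out$effect <- "fixed"
  out
}

#' @export
glance.spm_lmm <- function(x, ...) {
  tibble::tibble(
    nobs = length(x$model_data$y),
    n_subjects = max(x$model_data$subj),
    sigma = mean(x$draws[, "sigma"]),
    max_rhat = max(x$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' @export
glance.spm_blm <- function(x, ...) {
  r2q <- quantile(x$r2_draws, c(0.5, 0.025, 0.975), names = FALSE)
  tibble::tibble(
    nobs = length(x$y), sigma = mean(x$draws[, "sigma"]),
    r.squared = r2q[1], r.squared.low = r2q[2], r.squared.high = r2q[3],
    max_rhat = max(x$rhat, na.rm = TRUE), converged = x$converged
  )
}

#' Posterior summary table
#'
#' Publication-shaped posterior summary (Estimate, Est.Error, credible
#' bounds, grouped into population-level, group-level and family-specific
#' rows).
#'
#' @param fit A `spm_lmm` or `spm_blm` fit.
#' @return A tibble.
#' @export
posterior_table <- function(fit) {
  out <- summarise_draws_tbl(fit)
  eff <- dplyr::case_when(
    out$term %in% c(fit$terms) ~ "Population-level effects",
    grepl("^(sd__|cor__)", out$term) ~ "Group-level effects",
    TRUE ~ "Family specific parameters"
  )
  tibble::tibble(Parameter = out$term, Estimate = out$estimate,
                 Est.Error = out$std.error, CI_lower = out$conf.low,
                 CI_upper = out$conf.high, Effects = eff)
}

#' @export
print.spm_lmm <- function(x, ...) {
  cat(sprintf("<spm_lmm '%s'> %d obs, %d subjects, %d draws%s\n",
              x$metric %||% "", length(x$model_data$y),
              max(x$model_data$subj), nrow(x$draws),
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(as.data.frame(posterior_table(x)), digits = 4)
  invisible(x)
}

#' @export
print.spm_blm <- function(x, ...) {
  cat(sprintf("<spm_blm> %d obs, %d draws%s\n", length(x$y), nrow(x$draws),
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(as.data.frame(summarise_draws_tbl(x)), digits = 4)
  invisible(x)
}
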