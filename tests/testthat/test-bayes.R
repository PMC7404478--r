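test_that("a noiseless line is recovered with R-squared near one", {
  x <- seq(1, 5, length.out = 50)
  f <- fit_simple_linear(2 * x, x, settings = fast_settings(), seed = 1)
  td <- tidy(f)
  b1 <- td$estimate[td$term == "b1"]
  expect_gt(b1, 1.95); expect_lt(b1, 2.05)
  expect_gt(glance(f)$r.squared, 0.99)
  # the degenerate zero-noise posterior is rightly flagged by the Rhat guard;
  # a well-behaved noisy regression converges cleanly
  set.seed(2)
  xn <- runif(60, 1, 5)
  fn <- fit_simple_linear(3 + 2 * xn + rnorm(60), xn, seed = 4)
  expect_true(fn$converged)
})

test_that("a permuted covariate yields a slope interval covering zero", {
  set.seed(3)
  y <- rnorm(200)
  x <- sample(y)
  f <- fit_simple_linear(y, x, settings = fast_settings(), seed = 2)
  td <- tidy(f)
  expect_lt(td$conf.low[td$term == "b1"], 0)
  expect_gt(td$conf.high[td$term == "b1"], 0)
})

test_that("the regression slope is covered by its credible interval across seeds", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    x <- runif(80, 200, 600)
    y <- 3 + 0.08 * x + rnorm(80, 0, 2)
    f <- fit_simple_linear(y, x, settings = sampler_settings(2, 1000, 400),
                           seed = seed)
    td <- tidy(f)
    if (td$conf.low[td$term == "b1"] <= 0.08 &&
        td$conf.high[td$term == "b1"] >= 0.08) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("the agreement mixed model recovers an injected device offset", {
  d <- sim_agreement_data(101)
  f <- fit_lmm(d, metric = "power", settings = fast_settings(), seed = 7)
  td <- tidy(f)
  dev <- td[td$term == "device", ]
  expect_lt(abs(dev$estimate + 300), 30)
  expect_gt(dev$conf.high - dev$conf.low, 5)       # a real interval
  expect_true(all(is.finite(td$rhat)))             # recorded per parameter
  expect_true(all(is.finite(td$ess)))
  expect_error(fit_lmm(d[d$subject == "s1", ], metric = "power"),
               "2 subjects")
})

test_that("posterior tables carry the publication shape", {
  d <- sim_agreement_data(5)
  f <- fit_lmm(d, metric = "power", settings = fast_settings(), seed = 3)
  pt <- posterior_table(f)
  expect_setequal(
    pt$Parameter,
    c("(Intercept)", "device", "speed", "device:speed", "sd__(Intercept)",
      "sd__speed", "cor__(Intercept).speed", "sigma"))
  expect_true(all(pt$CI_lower <= pt$Estimate & pt$Estimate <= pt$CI_upper))
  expect_setequal(unique(pt$Effects),
                  c("Population-level effects", "Group-level effects",
                    "Family specific parameters"))
})

test_that("a model compared with itself gives a Bayes factor of one", {
  d <- sim_agreement_data(11, n_laps = 10)
  f <- fit_lmm(d, metric = "power", settings = fast_settings(), seed = 5)
  bf <- bayes_factor(f, f)
  expect_lt(abs(bf$log_bf10), 3 * max(bf$relse, 0.02))
  expect_lt(bf$relse, 0.10)
})

test_that("evidence classification reproduces the printed scale with its inverse", {
  expect_equal(classify_bf(150), "extreme evidence for H1")
  expect_equal(classify_bf(100), "extreme evidence for H1")
  expect_equal(classify_bf(50), "very strong evidence for H1")
  expect_equal(classify_bf(15), "strong evidence for H1")
  expect_equal(classify_bf(5), "moderate evidence for H1")
  expect_equal(classify_bf(2), "anecdotal evidence for H1")
  expect_equal(classify_bf(1), "no evidence of an hypothesis over the other")
  expect_equal(classify_bf(0.5), "anecdotal evidence for H0")
  expect_equal(classify_bf(0.05), "strong evidence for H0")
  expect_equal(classify_bf(1 / 150), "extreme evidence for H0")
  expect_error(classify_bf(0), "positive")
  expect_error(classify_bf(-2), "positive")
})

test_that("intraclass correlation matches closed forms and stays in [0, 1]", {
  expect_equal(icc(3, 1)$estimate, 0.75)
  expect_equal(icc(0, 1)$estimate, 0)
  set.seed(2)
  draws <- icc(rexp(500), rexp(500))
  expect_true(all(attr(draws, "icc_draws") >= 0 &
                    attr(draws, "icc_draws") <= 1))
  expect_error(icc(c(1, 2), 1), "equal length")
  expect_error(icc(3), "residual")
})

test_that("the Jeffreys correlation test behaves across regimes", {
  x <- seq_len(50)
  r1 <- bayesian_correlation(x, x + 0)             # degenerate r = 1
  expect_gt(r1$estimate, 0.9)
  expect_gt(r1$bf10, 100)
  set.seed(9)
  ok <- 0
  for (i in 1:10) {
    a <- rnorm(200); b <- rnorm(200)
    rn <- bayesian_correlation(a, b)
    if (rn$conf.low <= 0 && rn$conf.high >= 0) ok <- ok + 1
  }
  expect_gte(ok, 9)
  err <- numeric(10)
  for (i in 1:10) {
    z <- rnorm(100); e <- rnorm(100)
    a <- z; b <- 0.9 * z + sqrt(1 - 0.81) * e
    err[i] <- bayesian_correlation(a, b)$estimate - cor(a, b)
  }
  expect_lt(max(abs(err)), 0.07)
  expect_error(bayesian_correlation(1:3, 1:3), "n >= 4")
  expect_error(bayesian_correlation(rep(1, 10), rnorm(10)), "Zero-variance")
})

test_that("Bland-Altman handles identity, constant offset and antisymmetry", {
  ref <- c(400, 500, 600, 700)
  ba0 <- bland_altman(ref, ref)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_upper - ba0$loa_lower, 0)
  ba <- bland_altman(ref, ref - 300)
  expect_equal(ba$bias, -300)
  expect_equal(ba$sd_diff, 0)
  set.seed(12)
  a <- rnorm(50, 500, 40); b <- a + rnorm(50, -100, 20)
  f <- bland_altman(a, b); g <- bland_altman(b, a)
  expect_equal(g$bias, -f$bias)
  expect_equal(g$loa_lower, -f$loa_upper)
  expect_equal(g$loa_upper, -f$loa_lower)
  expect_error(bland_altman(1:4, 1:5), "equal length")
})

test_that("the correction function inverts affine device errors", {
  ref <- seq(400, 900, by = 100)
  idc <- correction_function(ref, ref)
  expect_equal(idc$a, 1, tolerance = 1e-12)
  expect_equal(idc$b, 0, tolerance = 1e-9)
  dev <- 0.5 * ref - 10
  cf <- correction_function(ref, dev)
  expect_equal(cf$a, 2, tolerance = 1e-12)
  expect_equal(cf$b, 20, tolerance = 1e-9)
  expect_equal(predict(cf, dev), ref, tolerance = 1e-9)
  expect_error(correction_function(ref, rep(300, 6)), "constant")
  expect_error(correction_function(500, 300), "2 paired")
})

test_that("tidy and glance return well-formed summaries", {
  d <- sim_agreement_data(21, n_laps = 8)
  f <- fit_lmm(d, metric = "power", settings = fast_settings(), seed = 2)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high",
                    "rhat", "ess", "effect") %in% names(td)))
  g <- glance(f)
  expect_equal(g$nobs, nrow(d))
  expect_equal(g$n_subjects, 6)
  ba <- bland_altman(rnorm(20), rnorm(20))
  expect_equal(nrow(tidy(ba)), 3)
})
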