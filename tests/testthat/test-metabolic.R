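test_that("second-by-second interpolation is linear and bounded by the breaths", {
  br <- tibble::tibble(t = c(0, 2), vo2 = c(10, 20))
  out <- resample_to_seconds(br)
  expect_equal(out$vo2[out$t == 1], 15)
  # constant input stays constant
  brc <- tibble::tibble(t = c(0.3, 1.7, 2.2, 5.9), vo2 = 12)
  expect_equal(unique(resample_to_seconds(brc)$vo2), 12)
  # piecewise-linear truth sampled irregularly is recovered at interior seconds
  knots <- tibble::tibble(t = c(0, 4, 9), vo2 = c(10, 30, 5))
  tt <- sort(c(0, 4, 9, runif(30, 0, 9)))
  irr <- tibble::tibble(t = tt, vo2 = approx(knots$t, knots$vo2, tt)$y)
  out2 <- resample_to_seconds(irr)
  expect_equal(out2$vo2, approx(knots$t, knots$vo2, out2$t)$y, tolerance = 1e-9)
  expect_error(resample_to_seconds(br[1, ]), "at least 2")
  expect_error(resample_to_seconds(tibble::tibble(t = c(1, 1), vo2 = 1:2)),
               "increasing")
})

test_that("moving average has the 5-tap impulse response and shrinking edges", {
  x <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(moving_average(x, 5), c(0, 0, 0.2, 0.2, 0.2, 0.2, 0.2, 0, 0))
  expect_equal(moving_average(rep(7, 12), 5), rep(7, 12))
  r <- moving_average(1:10, 5)
  expect_equal(r[3:8], as.numeric(3:8))            # centred mean of a ramp
  expect_error(moving_average(numeric(0)), "empty")
  expect_error(moving_average(1:5, 4), "odd")
})

test_that("moving average preserves the mean envelope properties", {
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(100)
    y <- moving_average(x, 5)
    expect_gte(min(y), min(x))
    expect_lte(max(y), max(x))
  }
  expect_equal(mean(moving_average(rep(3.5, 50), 5)), 3.5)
})

test_that("metabolic power uses the 21.1 J/ml equivalent and is bilinear", {
  expect_equal(metabolic_power(50, 70), 50 * 70 / 60 * 21.1)
  expect_equal(metabolic_power(50, 70), 1230.83, tolerance = 1e-2)
  expect_equal(metabolic_power(0, 70), 0)
  expect_equal(metabolic_power(25, 70), metabolic_power(50, 70) / 2)
  expect_equal(metabolic_power(50, 35), metabolic_power(50, 70) / 2)
  expect_error(metabolic_power(-1, 70), "non-negative")
})

test_that("net mechanical efficiency follows its definition", {
  expect_equal(mechanical_efficiency(336, 610), 55.08, tolerance = 1e-2)
  expect_equal(mechanical_efficiency(0, 500), 0)
  expect_error(mechanical_efficiency(336, 0), "baseline")
  expect_error(mechanical_efficiency(336, -10), "baseline")
})

test_that("habituation truncation drops the first seconds only", {
  s <- tibble::tibble(t = 0:119, v = 1)
  expect_equal(nrow(truncate_habituation(s, 60)), 60)
  expect_identical(truncate_habituation(s, 0), s)
  expect_equal(nrow(truncate_habituation(s, 500)), 0)
  expect_error(truncate_habituation(s, -1), ">= 0")
})

test_that("breath processing chains resample, filter, truncate and power", {
  set.seed(4)
  br <- tibble::tibble(t = sort(runif(200, 0, 180)), vo2 = 40)
  out <- process_breaths(br, mass = 70, vo2_rest = 5, cutoff_s = 60)
  expect_true(all(out$t >= 60))
  expect_equal(unique(round(out$vo2_filtered, 9)), 40)
  expect_equal(out$w_met, metabolic_power(out$vo2_filtered, 70))
  expect_equal(out$delta_w_met, out$w_met - metabolic_power(5, 70))
})

test_that("configured efficiency is recovered per stage from a simulated ramp", {
  # affine VO2-power coupling of known slope, noiseless breaths; the first
  # two stages still carry O2 deficit with tau = 30 s and 60 s stages
  s <- subject_profile(70, 1.75, vo2max = 300, initial_speed = 10)
  sess <- suppressWarnings(simulate_session(
    s, protocol_config(max_stages = 6), zero_bias(), seed = 8,
    vo2_noise_sd = 0, vo2_tau = 30, vo2_slope = 2.7))
  met <- process_breaths(sess$breath, mass = 70, vo2_rest = s$vo2_rest,
                         cutoff_s = 60)
  prof <- tibble::tibble(
    t = seq(0, max(sess$stages$t_end)),
    w_ext = sess$truth$w_ext[pmax(1, findInterval(seq(0, max(sess$stages$t_end)),
                                                  sess$truth$t))])
  eff <- stage_efficiency(met, prof, sess$stages)
  me_conf <- 100 * 60 / (21.1 * 2.7)
  late <- eff$me[eff$stage >= 3]
  expect_gt(length(late), 2)
  expect_lt(max(abs(late - me_conf) / me_conf), 0.03)
})
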