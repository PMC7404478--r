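half_sine_trace <- function(durations, gaps, peak = 1500, fs = 500) {
  dt <- 1 / fs
  t <- seq(0, sum(durations) + sum(gaps) + 0.2, by = dt)
  fz <- numeric(length(t))
  start <- 0.05
  for (i in seq_along(durations)) {
    sel <- t >= start & t < start + durations[i]
    fz[sel] <- peak * sin(pi * (t[sel] - start) / durations[i])
    start <- start + durations[i] + ifelse(i <= length(gaps), gaps[i], 0)
  }
  tibble::tibble(t = t, fz = fz, fx = 0)
}

test_that("contacts are detected with correct durations", {
  tr <- half_sine_trace(0.250, numeric(0))
  ev <- detect_contacts(tr, threshold = 20)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$gct - 0.250), 0.004)

  tr2 <- half_sine_trace(c(0.25, 0.22), 0.10)
  ev2 <- detect_contacts(tr2, threshold = 20)
  expect_equal(nrow(ev2), 2)
  expect_lt(max(abs(ev2$gct - c(0.25, 0.22))), 0.004)

  empty <- tibble::tibble(t = seq(0, 1, by = 0.002), fz = 0, fx = 0)
  expect_equal(nrow(detect_contacts(empty)), 0)
  expect_equal(nrow(detect_contacts(empty[0, ])), 0)
})

test_that("contact detection validates sampling and is threshold-monotone", {
  tr <- half_sine_trace(c(0.25, 0.22), 0.10)
  bad <- tr; bad$t[10] <- bad$t[10] + 0.0005
  expect_error(detect_contacts(bad), "uniform")
  g1 <- detect_contacts(tr, threshold = 20)$gct
  for (thr in c(50, 120, 400)) {
    g2 <- detect_contacts(tr, threshold = thr)$gct
    expect_true(all(g2 <= g1 + 1e-12))
  }
  # debounce removes spuriously short contacts
  spike <- tr
  spike$fz[200] <- 500
  ev <- detect_contacts(spike, threshold = 20, debounce = 0.010)
  expect_equal(nrow(ev), 2)
})

test_that("acceleration decomposition matches hand arithmetic", {
  tr <- tibble::tibble(t = c(0, 0.002, 0.004), fz = c(70 * 9.80665, 2 * 70 * 9.80665, 1500),
                       fx = c(0, 70, -35))
  acc <- decompose_acceleration(tr, mass = 70)
  expect_equal(acc$az, c(0, 9.80665, (1500 - 686.4655) / 70), tolerance = 1e-9)
  expect_equal(acc$ax, c(0, 1, -0.5))
  expect_equal(acc$az[3], 11.622, tolerance = 1e-4)
  expect_error(decompose_acceleration(tr, mass = 0), "mass")
})

test_that("trapezoidal integration matches the closed form for a sinusoid", {
  f <- 2
  t <- seq(0, 1, by = 0.002)
  w <- tibble::tibble(t = t, az = sin(2 * pi * f * t), ax = 0)
  out <- integrate_motion(w, initial_sx = 3)
  sz_true <- -cos(2 * pi * f * t) / (2 * pi * f)
  sz_true <- sz_true - mean(sz_true)
  expect_lt(max(abs(out$sz - sz_true)) / max(abs(sz_true)), 1e-3)
  expect_equal(out$sx, rep(3, length(t)))
  expect_equal(out$dx, 3 * t, tolerance = 1e-9)
  expect_error(integrate_motion(w[1:2, ], 3), "3 samples")
})

test_that("constant motion integrates to a linear distance and strides close on themselves", {
  t <- seq(0, 0.7, by = 0.002)
  w <- tibble::tibble(t = t, az = 0, ax = 0)
  out <- integrate_motion(w, initial_sx = 3)
  expect_equal(out$sz, rep(0, length(t)))
  expect_equal(out$dz, rep(0, length(t)))
  # noiseless simulated stride: zero-mean vertical speed constraint
  sess <- noiseless_session()
  tr <- sess$force[sess$force$lap == 1, ]
  ev <- detect_contacts(tr[c("t", "fz", "fx")])
  acc <- decompose_acceleration(tr[c("t", "fz", "fx")], 70)
  win <- acc[acc$t >= ev$strike_time[1] & acc$t <= ev$strike_time[2], ]
  got <- integrate_motion(win, initial_sx = sess$stages$speed[1])
  expect_lt(abs(mean(got$sz)), 1e-9)
  expect_lt(abs(got$sz[1] - got$sz[nrow(got)]), 0.05 * max(abs(got$sz)))
})

test_that("stride works match hand arithmetic and are additive", {
  expect_equal(stride_work(c(0, -0.08), c(3, 3), 70)$wp, 70 * 9.80665 * 0.08,
               tolerance = 1e-12)
  expect_equal(stride_work(c(0, -0.08), c(3, 3), 70)$wp, 54.92, tolerance = 1e-3)
  wk <- stride_work(c(0, 0), c(3.8, 4.2), 70)
  expect_equal(wk$wk, 35 * (4.2^2 - 3.8^2), tolerance = 1e-12)
  expect_equal(wk$wk, 112, tolerance = 1e-12)
  expect_equal(stride_work(c(0, -0.1), c(4, 4), 70)$wk, 0)
  for (i in 1:5) {
    set.seed(i)
    w <- stride_work(rnorm(50), 3 + rnorm(50, 0, 0.2), 70)
    expect_identical(w$wt, w$wp + w$wk)
  }
})

test_that("external power and mechanical cost follow their definitions", {
  expect_equal(external_power(240, 1.4), 336)
  expect_equal(external_power(0, 2), 0)
  expect_error(external_power(240, 0), "omega")
  expect_equal(mechanical_cost(336, 3.5, 70), 1.3714, tolerance = 1e-4)
  expect_equal(mechanical_cost(0, 3, 70), 0)
  expect_equal(mechanical_cost(336, 3.5, 140),
               mechanical_cost(336, 3.5, 70) / 2)
  expect_error(mechanical_cost(336, 0, 70), "speed")
})

test_that("outputs are invariant to shifting the time axis", {
  sess <- noiseless_session()
  tr <- sess$force[sess$force$lap == 1, c("t", "fz", "fx")]
  a <- process_force_trace(tr, 70, sess$stages$speed[1], 0.53 * 1.75)
  tr2 <- dplyr::mutate(tr, t = t + 1000)
  b <- process_force_trace(tr2, 70, sess$stages$speed[1], 0.53 * 1.75)
  expect_equal(b$strike_time, a$strike_time + 1000, tolerance = 1e-9)
  for (col in c("gct", "wp", "wk", "wt", "w_ext", "cm", "kleg")) {
    expect_equal(b[[col]], a[[col]], tolerance = 1e-9)
  }
})

test_that("noiseless sessions round-trip through the kinetic chain", {
  sess <- noiseless_session()
  pr <- noiseless_processed()
  tru <- sess$truth |>
    dplyr::filter(.data$x_in_lap < sess$protocol$platform_span) |>
    dplyr::group_by(.data$lap) |>
    dplyr::summarise(gct = mean(.data$tc), w_ext = mean(.data$w_ext),
                     kleg = mean(.data$kleg))
  j <- dplyr::inner_join(pr$reference, tru, by = "lap",
                         suffix = c("_est", "_tru"))
  expect_gt(nrow(j), 2)
  expect_lt(max(abs(j$gct_est - j$gct_tru)), 0.002)        # one sample
  expect_lt(max(abs(j$power - j$w_ext) / j$w_ext), 0.02)
  expect_lt(max(abs(j$lss - j$kleg) / j$kleg), 0.05)
})
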