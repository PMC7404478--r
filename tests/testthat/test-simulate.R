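test_that("force peak satisfies whole-cycle impulse balance", {
  s <- subject_profile(70, 1.75)
  st <- spring_mass_stride(3, s, kleg_true = NULL, stride_period = 0.7,
                           duty_factor = 0.25 / 0.7)
  expect_equal(st$truth$tc, 0.25, tolerance = 1e-12)
  expect_equal(st$truth$fz_peak, 70 * 9.80665 * (pi / 2) * (0.7 / 0.25),
               tolerance = 1e-12)
  expect_equal(st$truth$fz_peak, 3019.233, tolerance = 1e-6)
})

test_that("emitted trace conserves vertical impulse and has zero net horizontal impulse", {
  s <- subject_profile(70, 1.75)
  for (v in c(2.5, 3.3, 4.5)) {
    st <- spring_mass_stride(v, s, kleg_true = 10)
    imp <- pracma::trapz(st$trace$t, st$trace$fz)
    expect_equal(imp, 70 * 9.80665 * st$truth$stride_period,
                 tolerance = 1e-3)
    imp_x <- pracma::trapz(st$trace$t, st$trace$fx)
    # relative to the one-sided braking impulse A*Tc/pi
    expect_lt(abs(imp_x), 1e-2 * st$truth$fx_amp * st$truth$tc / pi)
  }
})

test_that("stride generator solves the requested leg stiffness and rejects bad input", {
  s <- subject_profile(70, 1.75)
  for (k in c(8, 10, 12)) {
    st <- spring_mass_stride(3.3, s, kleg_true = k)
    expect_equal(st$truth$kleg, k, tolerance = 1e-8)
  }
  expect_error(spring_mass_stride(-1, s), "speed")
  expect_error(spring_mass_stride(3, s, duty_factor = 1.2), "duty_factor")
  expect_error(spring_mass_stride(3, s, kleg_true = NULL), "stride_period")
})

test_that("stage speeds follow the 0.5 km/h-per-minute progression", {
  sess <- noiseless_session()
  expect_equal(sess$stages$speed_kmh, c(10, 10.5, 11, 11.5))
  expect_equal(sess$stages$speed, c(10, 10.5, 11, 11.5) / 3.6)
})

test_that("identical seed reproduces a session exactly; streams share one origin", {
  s <- subject_profile(68, 1.70, initial_speed = 10)
  p <- protocol_config(max_stages = 2)
  a <- suppressWarnings(simulate_session(s, p, device_bias(), seed = 5))
  b <- suppressWarnings(simulate_session(s, p, device_bias(), seed = 5))
  expect_identical(a$force, b$force)
  expect_identical(a$pod, b$pod)
  expect_identical(a$breath, b$breath)
  expect_identical(a$marker, b$marker)
  expect_identical(min(a$marker$t), 0)
  expect_equal(a$pod$t[1], 0)
  c2 <- suppressWarnings(simulate_session(s, p, device_bias(), seed = 6))
  expect_false(identical(a$breath, c2$breath))
})

test_that("zero-stage stop rule errors", {
  s <- subject_profile(70, 1.75, initial_speed = 10)
  expect_error(
    simulate_session(s, protocol_config(max_stages = 3, max_speed = 5)),
    "zero stages")
})

test_that("identity bias makes the pod stream equal ground truth at 1 Hz", {
  sess <- noiseless_session()
  tru <- sess$truth
  idx <- pmax(1, findInterval(sess$pod$t, tru$t))
  expect_equal(sess$pod$power, tru$w_ext[idx], tolerance = 1e-12)
  expect_equal(sess$pod$gct_ms, 1000 * tru$tc[idx], tolerance = 1e-12)
  expect_equal(sess$pod$lss, tru$kleg[idx], tolerance = 1e-12)
})

test_that("device bias shifts power by offset plus speed-proportional term", {
  truth <- tibble::tibble(t = 0:99, speed = 3, w_ext = 600, tc = 0.25,
                          kleg = 10)
  pod <- apply_device_bias(truth, device_bias(-300, 0, 0, 0,
                                              c(power = 0, gct = 0, lss = 0)))
  expect_equal(pod$power, rep(300, 100))
  expect_true(all(diff(pod$distance) >= 0))
  # Monte-Carlo: mean bias of a noisy channel is recovered near -300
  podn <- apply_device_bias(truth, device_bias(-300, 0, 0, 0,
                                               c(power = 20, gct = 0, lss = 0)),
                            seed = 11)
  expect_lt(abs(mean(podn$power - truth$w_ext[pmax(1, findInterval(podn$t, truth$t))]) + 300), 6)
})

test_that("mean vertical force over whole strides equals body weight within 0.5%", {
  sess <- noiseless_session()
  tr <- sess$force[sess$force$lap == 2, ]
  contacts <- detect_contacts(tr[c("t", "fz", "fx")])
  t0 <- contacts$strike_time[1]
  t1 <- contacts$strike_time[nrow(contacts)]
  seg <- tr[tr$t >= t0 & tr$t <= t1, ]
  mean_f <- pracma::trapz(seg$t, seg$fz) / (t1 - t0)
  expect_equal(mean_f, 70 * 9.80665, tolerance = 5e-3)
})

test_that("first-order uptake kinetics complete 63.2% of a step after one time constant", {
  s <- subject_profile(70, 1.75, vo2max = 300)
  prof <- tibble::tibble(t = 0:900, w_ext = c(rep(0, 301), rep(700, 600)))
  # noiseless response on the 1 Hz grid via the deterministic core
  br <- simulate_vo2(prof, s, tau = 30, noise_sd = 0, slope = 2.7, seed = 3)
  v <- approx(br$t, br$vo2, xout = c(300, 330, 880))$y
  dA <- 2.7 * 700 / 70
  expect_equal((v[2] - v[1]) / dA, 1 - exp(-1), tolerance = 0.05)
  expect_equal(v[3], 5 + dA, tolerance = 0.01)
})

test_that("zero power keeps oxygen uptake at rest", {
  s <- subject_profile(70, 1.75)
  prof <- tibble::tibble(t = 0:120, w_ext = 0)
  br <- simulate_vo2(prof, s, noise_sd = 0, seed = 2)
  expect_equal(br$vo2, rep(s$vo2_rest, nrow(br)), tolerance = 1e-9)
  expect_error(simulate_vo2(prof[0, ], s), "non-empty")
})

test_that("VO2-power regression recovers the configured coupling slope", {
  s <- subject_profile(70, 1.75, vo2max = 300)
  w <- rep(seq(400, 1100, by = 100), each = 120)
  prof <- tibble::tibble(t = seq_along(w) - 1, w_ext = w)
  hits <- 0
  for (seed in 1:20) {
    br <- simulate_vo2(prof, s, tau = 30, noise_sd = 1.5, slope = 2.7,
                       seed = seed)
    # steady-state windows: last 30 s of each stage
    stage <- findInterval(br$t, seq(0, length(w), by = 120))
    in_ss <- (br$t %% 120) > 90
    d <- data.frame(vo2 = br$vo2, p = w[pmin(length(w), floor(br$t) + 1)])[in_ss, ]
    ci <- confint(lm(vo2 ~ p, data = d))["p", ]
    if (ci[1] <= 2.7 / 70 && 2.7 / 70 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 17)
})

test_that("study cohort is reproducible and mirrors the protocol split", {
  st <- simulate_study(n_subjects = 4, protocol = protocol_config(max_stages = 2),
                       seed = 9)
  st2 <- simulate_study(n_subjects = 4, protocol = protocol_config(max_stages = 2),
                        seed = 9)
  expect_identical(st$subjects, st2$subjects)
  expect_identical(st$sessions$s01$pod, st2$sessions$s01$pod)
  expect_setequal(st$subjects$initial_speed[st$subjects$sex == "F"], 8)
  expect_setequal(st$subjects$initial_speed[st$subjects$sex == "M"], 10)
})
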