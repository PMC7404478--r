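test_that("COM displacement matches the free-fall closed form", {
  t <- seq(0, 0.3, by = 0.002)
  expect_equal(vertical_com_displacement(rep(0, length(t)), t, 0), 0)
  dy <- vertical_com_displacement(rep(-9.80665, length(t)), t, 0)
  expect_equal(dy, 0.5 * 9.80665 * 0.3^2, tolerance = 1e-6)
  expect_error(vertical_com_displacement(c(1, 2), c(0, 1), 0), "too short")
})

test_that("COM displacement recovers the simulator excursion on a noiseless contact", {
  s <- subject_profile(70, 1.75)
  st <- spring_mass_stride(3.3, s, kleg_true = 10)
  acc <- decompose_acceleration(st$trace, 70)
  contact <- acc[acc$t < st$truth$tc, ]
  v0 <- -9.80665 * (st$truth$stride_period - st$truth$tc) / 2
  dy <- vertical_com_displacement(contact$az, contact$t, v0)
  expect_lt(abs(dy - st$truth$dy) / st$truth$dy, 0.05)
})

test_that("leg stiffness matches hand arithmetic and its stationary limit", {
  r <- leg_stiffness(2000, 0.05, v = 0, tc = 0.25, L = 0.95)
  expect_equal(r$theta, 0)
  expect_equal(r$kleg, 2000 / 0.05 / 1000)           # 40 kN/m, exact
  r2 <- leg_stiffness(2000, 0.04, v = 4, tc = 0.25, L = 0.95)
  expect_equal(r2$theta, asin(4 * 0.25 / (2 * 0.95)), tolerance = 1e-12)
  expect_equal(r2$theta, 0.5546, tolerance = 1e-3)
  expect_equal(r2$delta_l, 0.1822, tolerance = 1e-3)
  expect_equal(r2$kleg, 10.98, tolerance = 1e-3)
  expect_error(leg_stiffness(2000, 0.04, v = 9, tc = 0.25, L = 0.95),
               "half-sweep")
})

test_that("literal compatibility mode uses the printed angle expression", {
  x <- 3 * 0.24 / (2 * 0.95)
  lit <- leg_stiffness(2000, 0.04, 3, 0.24, 0.95, theta_mode = "literal")
  expect_equal(lit$theta, sin(x), tolerance = 1e-12)
  std <- leg_stiffness(2000, 0.04, 3, 0.24, 0.95)
  expect_equal(std$theta, asin(x), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(lit$kleg, std$kleg)))
})

test_that("stiffness decreases with larger displacement and longer contact", {
  dys <- seq(0.02, 0.12, by = 0.01)
  ks <- vapply(dys, function(d) leg_stiffness(2500, d, 3.5, 0.24, 0.95)$kleg,
               numeric(1))
  expect_true(all(diff(ks) < 0))
  tcs <- seq(0.18, 0.32, by = 0.01)
  kt <- vapply(tcs, function(tc) leg_stiffness(2500, 0.06, 3.5, tc, 0.95)$kleg,
               numeric(1))
  expect_true(all(diff(kt) < 0))
})

test_that("stride time halves the inter-strike interval", {
  st <- stride_time(c(10.00, 10.70))
  expect_equal(st$ts, 0.35)
  expect_equal(st$omega, 2.857, tolerance = 1e-3)
  st2 <- stride_time(c(10, 11.4))
  expect_equal(st2$ts, 2 * st$ts)
  expect_equal(st2$omega, st$omega / 2)
  # strikes at an exact period P give Ts = P/2
  st3 <- stride_time(seq(0, 7, by = 0.7))
  expect_equal(st3$ts, 0.35, tolerance = 1e-12)
  expect_error(stride_time(5), "at least 2")
  expect_error(stride_time(c(2, 1)), "increasing")
})

test_that("heel strikes are found at constructed minima within one sample", {
  period <- 0.72
  t <- seq(0, 5, by = 1 / 400)
  z <- 0.03 + 0.06 * (1 - cos(2 * pi * t / period))
  got <- detect_heel_strikes(tibble::tibble(t = t, z_heel = z))
  truth <- seq(period, 4.9, by = period)
  expect_equal(length(got), length(truth))
  for (tt in truth) expect_lt(min(abs(got - tt)), 1 / 400 + 1e-9)
  expect_warning(
    out <- detect_heel_strikes(tibble::tibble(t = t, z_heel = 0.05)),
    "No heel-strike")
  expect_length(out, 0)
})

test_that("marker strikes agree with platform contacts within 5 ms", {
  sess <- noiseless_session()
  pr <- noiseless_processed()
  ct <- detect_contacts(sess$force[sess$force$lap == 2, c("t", "fz", "fx")])
  offs <- vapply(ct$strike_time,
                 function(t) min(abs(pr$heel_strikes - t)), numeric(1))
  expect_lt(max(offs), 0.005)
})

test_that("flight time approximates the constructed flight windows", {
  # sharp-edged marker model: flat contacts, raised flights
  t <- seq(0, 3, by = 1 / 400)
  period <- 0.7; tc <- 0.25
  phase <- t %% period
  z <- ifelse(phase < tc, 0.03, 0.03 + 0.1 * sin(pi * (phase - tc) / (period - tc)))
  ft <- flight_time(tibble::tibble(t = t, z_heel = z),
                    height_threshold = 0.035)
  expect_gt(nrow(ft), 2)
  expect_lt(max(abs(ft$tf - (period - tc))), 0.03)
})
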