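# Spring-mass session simulator.
#
# The runner is reduced to a point mass bouncing on a linear leg spring: each
# stride cycle of period T contains one half-sine vertical contact of duration
# Tc = duty * T followed by a ballistic flight. Whole-cycle impulse balance
# fixes the force peak, F = m g (pi/2) (T / Tc), and every derived quantity
# (COM dip, flight rise, works, power, implied leg stiffness) has a closed
# form, which is what makes the generator usable as an oracle for the
# reference pipeline. The horizontal force is a braking/propulsion full sine
# with zero net impulse.

#' Default duty-factor schedule
#'
#' Fraction of the stride cycle spent in ground contact, decreasing linearly
#' with speed (0.38 at 2.2 m/s to 0.28 at 5.5 m/s, clamped outside), which
#' reproduces the negative contact-time-versus-speed trend seen on the track.
#'
#' @param speed Running speed (m/s).
#' @return Duty factor (dimensionless, in (0, 1)).
#' @export
duty_factor_default <- function(speed) {
  d <- 0.38 - 0.10 * (speed - 2.2) / (5.5 - 2.2)
  pmin(0.40, pmax(0.26, d))
}

# All closed-form per-stride mechanics for one spring-mass cycle.
# Returns a one-row tibble of ground truth.
stride_truth <- function(speed, subject, stride_period, duty_factor,
                         fx_ratio = 0.25) {
  m <- subject$mass
  L <- subject$leg_length
  g <- G_ACC
  Tt <- stride_period
  Tc <- duty_factor * Tt
  Tf <- Tt - Tc
  fz_peak <- m * g * (pi / 2) * (Tt / Tc)
  # COM dip during contact (magnitude of the lowest point, strike height = 0):
  # y(t) = v0 t + (g T / 2) (t - (Tc/pi) sin(pi t / Tc)) - g t^2 / 2,
  # with landing velocity v0 = -g Tf / 2; the minimum sits at mid-contact.
  dip <- g * (Tf * Tc / 4 - (Tt * Tc / 2) * (1 / 2 - 1 / pi) + Tc^2 / 8)
  rise <- g * Tf^2 / 8                      # ballistic apex above touch height
  dz_range <- dip + rise
  # horizontal speed excursion from the full-sine braking/propulsion force
  fx_amp <- fx_ratio * m * g
  dsx <- fx_amp * Tc / (m * pi)
  wp <- m * g * dz_range
  wk <- 0.5 * m * ((speed + dsx / 2)^2 - (speed - dsx / 2)^2)
  wt <- wp + wk
  # stride time per the reference convention Ts = (C2 - C1) / 2, so the
  # frequency entering external power is 2 / T
  omega <- 2 / Tt
  w_ext <- wt * omega
  x <- speed * Tc / (2 * L)
  if (x >= 1) stop_input("Non-physical stride: v*Tc/(2L) = %.3f >= 1.", x)
  theta <- asin(x)
  dl <- dip + L * (1 - cos(theta))
  tibble::tibble(
    speed = speed, stride_period = Tt, tc = Tc, duty_factor = duty_factor,
    fz_peak = fz_peak, fx_amp = fx_amp, dy = dip, dz_range = dz_range,
    theta = theta, delta_l = dl, kleg = fz_peak / dl / 1000,
    wp = wp, wk = wk, wt = wt, omega = omega, w_ext = w_ext,
    cm = w_ext / (speed * m)
  )
}

# Solve the stride period that makes the implied leg stiffness equal
# kleg_true (kN/m) at the given speed and duty factor.
solve_stride_period <- function(speed, subject, kleg_true, duty_factor,
                                fx_ratio = 0.25) {
  f <- function(Tt) {
    stride_truth(speed, subject, Tt, duty_factor, fx_ratio)$kleg - kleg_true
  }
  upper <- min(1.6, 2 * subject$leg_length / (speed * duty_factor) * 0.999)
  lo <- 0.25
  if (f(lo) < 0 || f(upper) > 0) {
    stop_input("No stride period in [%.2f, %.2f] s achieves kleg = %g kN/m at %g m/s.",
               lo, upper, kleg_true, speed)
  }
  stats::uniroot(f, c(lo, upper), tol = 1e-10)$root
}

#' Generate one spring-mass stride
#'
#' Builds the force trace of a single stride cycle (one half-sine vertical
#' contact plus flight, and a zero-net-impulse horizontal full sine) together
#' with its closed-form ground truth. The vertical force peak satisfies
#' whole-cycle impulse balance, `Fz_peak = m g (pi/2) (T / Tc)`. When
#' `kleg_true` is supplied the stride period is solved so that the implied
#' McMahon-Cheng leg stiffness equals it; otherwise `stride_period` is used
#' directly.
#'
#' @param speed Forward speed (m/s), > 0.
#' @param subject A [subject_profile()].
#' @param kleg_true Target leg spring stiffness (kN/m), or `NULL`.
#' @param duty_factor Contact fraction of the stride cycle in (0, 1);
#'   defaults to [duty_factor_default()] at `speed`.
#' @param stride_period Stride cycle duration (s); ignored when `kleg_true`
#'   is given. Defaults to the period solving `kleg_true = 10` kN/m.
#' @param grf_rate Sampling rate of the emitted trace (Hz).
#' @param fx_ratio Peak horizontal force as a fraction of body weight.
#'
#' @return A list with `trace` (tibble `t`, `fz`, `fx` covering one cycle)
#'   and `truth` (one-row tibble of true stride mechanics: `tc`,
#'   `stride_period`, `fz_peak`, `dy`, `kleg`, `wp`, `wk`, `wt`, `omega`,
#'   `w_ext`, `cm`, ...).
#' @examples
#' s <- subject_profile(70, 1.75)
#' st <- spring_mass_stride(3.33, s, kleg_true = 10)
#' st$truth$fz_peak
#' @export
spring_mass_stride <- function(speed, subject, kleg_true = 10,
                               duty_factor = NULL, stride_period = NULL,
                               grf_rate = 500, fx_ratio = 0.25) {
  check_number(speed, "speed", positive = TRUE)
  stopifnot(inherits(subject, "subject_profile"))
  duty_factor <- duty_factor %||% duty_factor_default(speed)
  check_number(duty_factor, "duty_factor")
  if (duty_factor <= 0 || duty_factor >= 1) {
    stop_input("`duty_factor` must lie strictly in (0, 1), got %g.", duty_factor)
  }
  if (!is.null(kleg_true)) {
    check_number(kleg_true, "kleg_true", positive = TRUE)
    stride_period <- solve_stride_period(speed, subject, kleg_true,
                                         duty_factor, fx_ratio)
  } else if (is.null(stride_period)) {
    stop_input("Supply either `kleg_true` or `stride_period`.")
  }
  check_number(stride_period, "stride_period", positive = TRUE)
  truth <- stride_truth(speed, subject, stride_period, duty_factor, fx_ratio)
  dt <- 1 / grf_rate
  t <- seq(0, stride_period - dt / 2, by = dt)
  fz <- ifelse(t < truth$tc, truth$fz_peak * sin(pi * t / truth$tc), 0)
  fx <- ifelse(t < truth$tc, -truth$fx_amp * sin(2 * pi * t / truth$tc), 0)
  list(trace = tibble::tibble(t = t, fz = fz, fx = fx), truth = truth)
}

# channel-specific RNG sub-seeds derived from the master seed, so noise on one
# channel never perturbs another
channel_seed <- function(seed, channel) {
  offs <- c(vo2 = 101L, breath = 211L, pod_power = 307L, pod_gct = 401L,
            pod_lss = 503L)
  (as.integer(seed) * 31L + offs[[channel]]) %% .Machine$integer.max
}

#' Simulate breath-by-breath oxygen uptake
#'
#' Drives first-order oxygen-uptake kinetics with a mechanical power profile:
#' the noiseless steady-state target at power `P` is
#' `vo2_rest + slope * P / mass`, saturated at `vo2max`, and transitions follow
#' `VO2(t) = VO2_prev + dA * (1 - exp(-t / tau))`. Breaths are emitted by a
#' renewal process whose mean interval shrinks from about 4 s at rest to
#' 1.5 s near maximal intensity, emulating irregular breath-by-breath
#' sampling.
#'
#' @param power_profile Tibble with columns `t` (s, 1 Hz grid) and `w_ext`
#'   (W), the mechanical power driving the response.
#' @param subject A [subject_profile()].
#' @param tau Time constant of the onset kinetics (s).
#' @param noise_sd Additive Gaussian noise on each breath value
#'   (ml O2 kg^-1 min^-1).
#' @param slope Steady-state coupling (ml O2 kg^-1 min^-1 per W/kg).
#' @param seed Integer seed (breath timing and noise use independent
#'   channel streams derived from it).
#'
#' @return Tibble with `t` (s, irregular) and `vo2` (ml O2 kg^-1 min^-1).
#' @export
simulate_vo2 <- function(power_profile, subject, tau = 30, noise_sd = 1.5,
                         slope = 2.7, seed = 1L) {
  if (!is.data.frame(power_profile) || nrow(power_profile) == 0) {
    stop_input("`power_profile` must be a non-empty data frame with t, w_ext.")
  }
  stopifnot(all(c("t", "w_ext") %in% names(power_profile)))
  check_number(tau, "tau", positive = TRUE)
  m <- subject$mass
  target <- pmin(subject$vo2max,
                 subject$vo2_rest + slope * power_profile$w_ext / m)
  tt <- power_profile$t
  n <- length(tt)
  vo2 <- numeric(n)
  vo2[1] <- subject$vo2_rest
  for (i in seq_len(n - 1)) {           # exact exponential stepping
    dtl <- tt[i + 1] - tt[i]
    vo2[i + 1] <- target[i] + (vo2[i] - target[i]) * exp(-dtl / tau)
  }
  # irregular breath timestamps: gamma renewal, mean interval shrinking with
  # relative intensity
  intensity <- (vo2 - subject$vo2_rest) /
    max(subject$vo2max - subject$vo2_rest, 1e-9)
  intensity <- pmin(1, pmax(0, intensity))
  mean_gap_at <- function(tm) {
    idx <- pmin(n, pmax(1, findInterval(tm, tt)))
    4 - 2.5 * intensity[idx]
  }
  set.seed(channel_seed(seed, "breath"))
  breaths <- numeric(0)
  tm <- tt[1]
  t_end <- tt[n]
  while (TRUE) {
    gap <- stats::rgamma(1, shape = 4, scale = mean_gap_at(tm) / 4)
    tm <- tm + gap
    if (tm > t_end) break
    breaths <- c(breaths, tm)
  }
  v <- approx(tt, vo2, xout = breaths)$y
  if (noise_sd > 0) {
    set.seed(channel_seed(seed, "vo2"))
    v <- v + rnorm(length(v), 0, noise_sd)
  }
  tibble::tibble(t = breaths, vo2 = pmax(0, v))
}

#' Apply a device-bias model to ground truth
#'
#' Converts per-stride ground truth into a 1 Hz footpod stream, injecting the
#' configured constant and speed-proportional biases plus per-channel Gaussian
#' noise: `PO_pod = PO_true + po_offset + po_slope_per_speed * speed + noise`,
#' analogously for contact time and stiffness. Cumulative distance is the
#' exact integral of the speed profile, so it increases monotonically and
#' totals one lap length per lap.
#'
#' @param truth Per-stride ground-truth tibble (columns `t`, `speed`,
#'   `w_ext`, `tc`, `kleg`), e.g. the `truth` element of
#'   [simulate_session()].
#' @param bias A [device_bias()].
#' @param seed Integer seed for the channel noise streams.
#' @param t_end Last second to emit; defaults to the last stride time.
#'
#' @return Tibble `t` (s), `power` (W), `gct_ms` (ms), `lss` (kN/m),
#'   `distance` (m).
#' @export
apply_device_bias <- function(truth, bias, seed = 1L, t_end = NULL) {
  if (!is.data.frame(truth) || nrow(truth) == 0) {
    stop_input("`truth` must be a non-empty data frame.")
  }
  stopifnot(inherits(bias, "device_bias"))
  t_end <- t_end %||% max(truth$t)
  secs <- seq(0, floor(t_end))
  idx <- pmax(1, findInterval(secs, truth$t))
  sp <- truth$speed[idx]
  po <- truth$w_ext[idx] + bias$po_offset + bias$po_slope_per_speed * sp
  gct <- truth$tc[idx] + bias$gct_offset
  lss <- truth$kleg[idx] + bias$lss_offset
  ns <- bias$noise_sd
  if (ns[["power"]] > 0) {
    set.seed(channel_seed(seed, "pod_power"))
    po <- po + rnorm(length(po), 0, ns[["power"]])
  }
  if (ns[["gct"]] > 0) {
    set.seed(channel_seed(seed, "pod_gct"))
    gct <- gct + rnorm(length(gct), 0, ns[["gct"]])
  }
  if (ns[["lss"]] > 0) {
    set.seed(channel_seed(seed, "pod_lss"))
    lss <- lss + rnorm(length(lss), 0, ns[["lss"]])
  }
  # distance: piecewise-linear integral of the stage speed profile
  dist <- cumsum(c(0, sp[-length(sp)]))   # 1 s steps starting at t = 0
  tibble::tibble(t = secs, power = po, gct_ms = gct * 1000, lss = lss,
                 distance = dist)
}

#' Simulate a complete incremental track session
#'
#' Generates every stream a laboratory validity study records, with shared
#' time origin and known ground truth: per-lap force-platform traces covering
#' the platform span at the start of each lap, a heel-marker vertical
#' trajectory with minima at foot strikes, breath-by-breath oxygen uptake
#' driven by the true mechanical power, and the 1 Hz footpod stream produced
#' by [apply_device_bias()]. Stage speeds follow
#' `initial_speed + k * speed_increment`; strides within a stage are
#' identical spring-mass cycles.
#'
#' @param subject A [subject_profile()].
#' @param protocol A [protocol_config()].
#' @param bias A [device_bias()].
#' @param kleg_true True leg spring stiffness (kN/m) used to set the stride
#'   period at each stage speed.
#' @param seed Integer master seed; identical seeds give identical sessions.
#' @param vo2_tau,vo2_noise_sd,vo2_slope Passed to [simulate_vo2()].
#' @param marker_amp Heel-marker vertical oscillation amplitude (m).
#' @param fx_ratio Peak horizontal force as a fraction of body weight.
#'
#' @return A `stride_session` list: `force` (tibble `lap`, `t`, `fz`, `fx`),
#'   `marker` (`t`, `z_heel`), `breath` (`t`, `vo2`), `pod` (1 Hz device
#'   stream), `truth` (per-stride ground truth with lap and position),
#'   `stages` (stage table), plus the subject, protocol, bias and seed.
#' @export
simulate_session <- function(subject, protocol = protocol_config(),
                             bias = device_bias(), kleg_true = 10, seed = 1L,
                             vo2_tau = 30, vo2_noise_sd = 1.5, vo2_slope = 2.7,
                             marker_amp = 0.12, fx_ratio = 0.25) {
  stopifnot(inherits(subject, "subject_profile"),
            inherits(protocol, "protocol_config"),
            inherits(bias, "device_bias"))
  speeds_kmh <- subject$initial_speed +
    protocol$speed_increment * (seq_len(protocol$max_stages) - 1)
  if (!is.null(protocol$max_speed)) {
    speeds_kmh <- speeds_kmh[speeds_kmh <= protocol$max_speed]
  }
  if (length(speeds_kmh) == 0) {
    stop_input("Stop rule leaves zero stages; nothing to simulate.")
  }
  stages <- tibble::tibble(
    stage = seq_along(speeds_kmh),
    speed_kmh = speeds_kmh,
    speed = speeds_kmh / 3.6,
    t_start = (seq_along(speeds_kmh) - 1) * protocol$stage_duration,
    t_end = seq_along(speeds_kmh) * protocol$stage_duration
  )
  # per-stage stride template (identical strides within a stage)
  templates <- lapply(stages$speed, function(v) {
    d <- duty_factor_default(v)
    Tt <- solve_stride_period(v, subject, kleg_true, d, fx_ratio)
    stride_truth(v, subject, Tt, d, fx_ratio)
  })

  t_total <- max(stages$t_end)
  # chain strides through the stages; track strike time and position
  strikes <- list(); tm <- 0; pos <- 0; i <- 0
  while (tm < t_total) {
    stage_i <- min(length(templates), findInterval(tm, stages$t_start))
    tr <- templates[[stage_i]]
    i <- i + 1
    strikes[[i]] <- cbind(t = tm, x = pos, stage = stage_i)
    tm <- tm + tr$stride_period
    pos <- pos + tr$speed * tr$stride_period
  }
  sk <- as.data.frame(do.call(rbind, strikes))
  truth <- dplyr::bind_rows(templates[sk$stage]) |>
    dplyr::mutate(t = sk$t, x = sk$x, stage = sk$stage,
                  lap = floor(sk$x / protocol$lap_length) + 1,
                  x_in_lap = sk$x %% protocol$lap_length, .before = 1)

  # force traces: strides striking within the platform span of each lap,
  # plus one extra stride so every stance has a following strike on record
  on_platform <- truth$x_in_lap < protocol$platform_span
  dt <- 1 / protocol$grf_rate
  force <- lapply(unique(truth$lap[on_platform]), function(lp) {
    idx <- which(truth$lap == lp & on_platform)
    idx <- c(idx, max(idx) + 1)
    idx <- idx[idx <= nrow(truth)]
    t0 <- truth$t[min(idx)] - 5 * dt
    t1 <- truth$t[max(idx)] + truth$tc[max(idx)] + 5 * dt
    tg <- seq(max(0, t0), min(t_total, t1), by = dt)
    j <- pmax(1, findInterval(tg, truth$t))
    phase <- tg - truth$t[j]
    inc <- phase < truth$tc[j]
    fz <- ifelse(inc, truth$fz_peak[j] * sin(pi * phase / truth$tc[j]), 0)
    fx <- ifelse(inc, -truth$fx_amp[j] * sin(2 * pi * phase / truth$tc[j]), 0)
    tibble::tibble(lap = lp, t = tg, fz = fz, fx = fx)
  })
  force <- dplyr::bind_rows(force)

  # heel marker: cosine bump per stride cycle, minimum exactly at each strike
  tg <- seq(0, t_total, by = 1 / protocol$marker_rate)
  j <- pmax(1, findInterval(tg, truth$t))
  z <- 0.03 + marker_amp / 2 *
    (1 - cos(2 * pi * (tg - truth$t[j]) / truth$stride_period[j]))
  marker <- tibble::tibble(t = tg, z_heel = z)

  power_profile <- tibble::tibble(
    t = seq(0, t_total),
    w_ext = truth$w_ext[pmax(1, findInterval(seq(0, t_total), truth$t))]
  )
  breath <- simulate_vo2(power_profile, subject, tau = vo2_tau,
                         noise_sd = vo2_noise_sd, slope = vo2_slope,
                         seed = seed)
  pod <- apply_device_bias(truth, bias, seed = seed, t_end = t_total)

  cm_mean <- mean(truth$cm)
  if (cm_mean < 1.5 || cm_mean > 3.5) {
    warn(sprintf(
      paste("Session mean mechanical cost %.2f J kg^-1 m^-1 falls outside the",
            "typical physiological range 1.5-3.5 (single-support spring-mass",
            "geometry; see the methods vignette)."), cm_mean),
      class = "stridepower_physiology")
  }

  structure(
    list(subject = subject, protocol = protocol, bias = bias,
         kleg_true = kleg_true, seed = as.integer(seed), stages = stages,
         force = force, marker = marker, breath = breath, pod = pod,
         truth = truth),
    class = "stride_session"
  )
}

#' @export
print.stride_session <- function(x, ...) {
  cat(sprintf(
    "<stride_session %s> %d stages (%g-%g km/h), %d strides, %d laps traced, seed %d\n",
    x$subject$id, nrow(x$stages), min(x$stages$speed_kmh),
    max(x$stages$speed_kmh), nrow(x$truth), length(unique(x$force$lap)),
    x$seed))
  invisible(x)
}

#' Simulate a multi-subject validity study
#'
#' Draws a small cohort (defaults mirror a six-runner study: four men starting
#' at 10 km/h, two women at 8 km/h, heterogeneous mass, height and true
#' stiffness) and simulates one incremental session per subject with a shared
#' device-bias model.
#'
#' @param n_subjects Number of runners.
#' @param protocol A [protocol_config()] shared by all subjects.
#' @param bias A [device_bias()] shared by all subjects.
#' @param seed Integer master seed (subject draws and per-session streams).
#' @param quiet Suppress the per-session physiology notes.
#'
#' @return A `stride_study` list with `sessions` (list of
#'   [simulate_session()] results) and `subjects` (tibble of drawn profiles).
#' @export
simulate_study <- function(n_subjects = 6, protocol = protocol_config(),
                           bias = device_bias(), seed = 1L, quiet = TRUE) {
  check_number(n_subjects, "n_subjects", positive = TRUE)
  set.seed(as.integer(seed))
  sex <- rep(c("M", "F"), length.out = n_subjects)
  subjects <- tibble::tibble(
    id = sprintf("s%02d", seq_len(n_subjects)),
    sex = sex,
    mass = round(rnorm(n_subjects, ifelse(sex == "M", 72, 60), 5), 1),
    height = round(rnorm(n_subjects, ifelse(sex == "M", 1.78, 1.66), 0.05), 2),
    vo2max = round(rnorm(n_subjects, ifelse(sex == "M", 53.85, 48.33),
                         ifelse(sex == "M", 6.09, 6.75)), 2),
    initial_speed = ifelse(sex == "M", 10, 8),
    kleg_true = round(runif(n_subjects, 9, 11.5), 2)
  )
  sessions <- purrr::pmap(subjects, function(id, sex, mass, height, vo2max,
                                             initial_speed, kleg_true) {
    subj <- subject_profile(mass = mass, height = height, vo2max = vo2max,
                            initial_speed = initial_speed, id = id)
    run <- function() simulate_session(
      subj, protocol, bias, kleg_true = kleg_true,
      seed = channel_seed(seed, "breath") %% 100000L + match(id, subjects$id))
    if (quiet) suppressWarnings(run()) else run()
  })
  names(sessions) <- subjects$id
  structure(list(subjects = subjects, sessions = sessions,
                 protocol = protocol, bias = bias, seed = as.integer(seed)),
            class = "stride_study")
}

#' @export
print.stride_study <- function(x, ...) {
  cat(sprintf("<stride_study> %d subjects, seed %d\n", nrow(x$subjects), x$seed))
  invisible(x)
}
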