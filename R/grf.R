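# Reference kinetics from force-platform passages: contact events, recursive
# integration of centre-of-mass motion, per-stride works, external mechanical
# power and mechanical cost of running.

validate_force_trace <- function(trace) {
  if (!is.data.frame(trace)) stop_input("Force trace must be a data frame.")
  need <- c("t", "fz")
  miss <- setdiff(need, names(trace))
  if (length(miss)) stop_input("Force trace lacks column(s): %s.",
                               paste(miss, collapse = ", "))
  if (nrow(trace) == 0) return(invisible(0))
  if (any(!is.finite(trace$t)) || any(!is.finite(trace$fz))) {
    stop_input("Force trace contains non-finite values.")
  }
  dtv <- diff(trace$t)
  if (nrow(trace) > 1) {
    if (any(dtv <= 0)) stop_input("Force trace time must be strictly increasing.")
    if (max(dtv) - min(dtv) > 1e-6 * stats::median(dtv)) {
      stop_input("Force trace must be uniformly sampled (step varies by > 1e-6 relative).")
    }
  }
  invisible(if (nrow(trace) > 1) stats::median(dtv) else 0)
}

#' Detect ground contacts from the vertical force
#'
#' A contact opens at the first sample with `fz >= threshold` and closes at
#' the first subsequent sample with `fz < threshold`. Ground contact time is
#' the duration between the two instants. Contacts shorter than the debounce
#' window are discarded, as is a trailing contact that never closes.
#'
#' @param trace Tibble with uniformly sampled `t` (s) and `fz` (N).
#' @param threshold Force threshold (N), > 0.
#' @param debounce Minimum credible contact duration (s).
#'
#' @return Tibble of contact events: `strike_time`, `toe_off_time`, `gct`
#'   (s), `peak_force` (N). Empty trace gives an empty tibble.
#' @examples
#' st <- spring_mass_stride(3.3, subject_profile(70, 1.75))
#' detect_contacts(st$trace)
#' @export
detect_contacts <- function(trace, threshold = 20, debounce = 0.010) {
  check_number(threshold, "threshold", positive = TRUE)
  validate_force_trace(trace)
  empty <- tibble::tibble(strike_time = numeric(), toe_off_time = numeric(),
                          gct = numeric(), peak_force = numeric())
  if (nrow(trace) == 0) return(empty)
  on <- trace$fz >= threshold
  d <- diff(c(FALSE, on))
  opens <- which(d == 1)
  closes <- which(d == -1)          # first sample back below threshold
  if (length(opens) == 0) return(empty)
  if (length(closes) < length(opens)) opens <- opens[seq_along(closes)]
  if (length(opens) == 0) return(empty)
  ev <- tibble::tibble(
    strike_time = trace$t[opens],
    toe_off_time = trace$t[closes],
    gct = trace$t[closes] - trace$t[opens],
    peak_force = vapply(seq_along(opens), function(i) {
      max(trace$fz[opens[i]:(closes[i] - 1)])
    }, numeric(1))
  )
  ev[ev$gct >= debounce, ]
}

#' Decompose ground reaction force into COM acceleration
#'
#' `Az = (Fz - m g) / m` and `Ax = Fx / m`, with g = 9.80665 m/s^2 exactly.
#'
#' @param trace Tibble with `t`, `fz` and `fx` (N).
#' @param mass Subject mass (kg), > 0.
#' @return The trace with acceleration columns `az`, `ax` (m/s^2) appended.
#' @export
decompose_acceleration <- function(trace, mass) {
  check_number(mass, "mass", positive = TRUE)
  validate_force_trace(trace)
  if (!"fx" %in% names(trace)) stop_input("Force trace lacks column(s): fx.")
  dplyr::mutate(trace, az = (.data$fz - mass * G_ACC) / mass,
                ax = .data$fx / mass)
}

#' Integrate COM motion over a stride window
#'
#' Recursive (cumulative trapezoidal) integration of the decomposed
#' acceleration at the native sampling step. Horizontal speed is initialised
#' to the prescribed stage speed; vertical speed is initialised so its mean
#' over the window is zero (steady-state running has no net vertical drift).
#' Displacements start at zero.
#'
#' @param window Tibble with `t`, `az`, `ax` covering one full stride
#'   (ipsilateral strike to next ipsilateral strike).
#' @param initial_sx Prescribed stage speed (m/s).
#' @return The window with `sz`, `sx` (m/s) and `dz`, `dx` (m) appended.
#' @export
integrate_motion <- function(window, initial_sx) {
  check_number(initial_sx, "initial_sx")
  if (!is.data.frame(window) || nrow(window) < 3) {
    stop_input("Stride window must contain at least 3 samples.")
  }
  stopifnot(all(c("t", "az", "ax") %in% names(window)))
  sz <- pracma::cumtrapz(window$t, window$az)[, 1]
  sz <- sz - mean(sz)
  sx <- initial_sx + pracma::cumtrapz(window$t, window$ax)[, 1]
  dz <- pracma::cumtrapz(window$t, sz)[, 1]
  dx <- pracma::cumtrapz(window$t, sx)[, 1]
  dplyr::mutate(window, sz = sz, sx = sx, dz = dz, dx = dx)
}

#' Potential, kinetic and total work over one stride
#'
#' `Wp = m g (max Dz - min Dz)`, `Wk = m/2 (max(Sx)^2 - min(Sx)^2)`,
#' `Wt = Wp + Wk` (external energy summation with no transfer between
#' potential and kinetic energies). Extrema are taken over the full stride
#' window.
#'
#' @param dz Vertical COM displacement series (m) over one stride window.
#' @param sx Horizontal COM speed series (m/s) over the same window.
#' @param mass Subject mass (kg).
#' @return One-row tibble with `wp`, `wk`, `wt` (J).
#' @export
stride_work <- function(dz, sx, mass) {
  check_number(mass, "mass", positive = TRUE)
  if (length(dz) < 2 || length(sx) < 2) {
    stop_input("Work extrema need at least two samples.")
  }
  wp <- mass * G_ACC * (max(dz) - min(dz))
  wk <- 0.5 * mass * (max(sx)^2 - min(sx)^2)
  tibble::tibble(wp = wp, wk = wk, wt = wp + wk)
}

#' External mechanical power
#'
#' `W_ext = Wt * omega`, total stride work times stride frequency.
#'
#' @param wt Total stride work (J).
#' @param omega Stride frequency (Hz), > 0.
#' @return Power (W).
#' @export
external_power <- function(wt, omega) {
  check_number(wt, "wt")
  check_number(omega, "omega")
  if (omega <= 0) stop_input("`omega` must be > 0 (got %g).", omega)
  wt * omega
}

#' Mechanical cost of running
#'
#' `Cm = W_ext / (Sx * m)` in J kg^-1 m^-1.
#'
#' @param w_ext External mechanical power (W).
#' @param speed Mean forward speed (m/s), > 0.
#' @param mass Subject mass (kg), > 0.
#' @return Mechanical cost (J kg^-1 m^-1).
#' @export
mechanical_cost <- function(w_ext, speed, mass) {
  check_number(w_ext, "w_ext")
  check_number(speed, "speed", positive = TRUE)
  check_number(mass, "mass", positive = TRUE)
  w_ext / (speed * mass)
}

#' Process one force-platform passage into per-stride metrics
#'
#' Chains contact detection, stride-window integration, works, external power,
#' mechanical cost and the McMahon-Cheng stiffness inputs for every complete
#' stride in the trace (ipsilateral strike to next strike). Stride frequency
#' comes from the strike times via the halved stride-time convention
#' `Ts = (C2 - C1) / 2`, `omega = 1 / Ts`.
#'
#' @param trace Force trace tibble (`t`, `fz`, `fx`).
#' @param mass Subject mass (kg).
#' @param stage_speed Prescribed stage speed (m/s), used to initialise the
#'   horizontal integration.
#' @param leg_length Initial leg length (m) for the stiffness geometry.
#' @param threshold,debounce Passed to [detect_contacts()].
#'
#' @return Tibble, one row per complete stride: contact timing, `fz_peak`,
#'   works, `omega`, `w_ext`, `cm`, `speed` (mean Sx), `dy`, `kleg` and the
#'   stiffness geometry. Zero complete strides give an empty tibble.
#' @export
process_force_trace <- function(trace, mass, stage_speed, leg_length,
                                threshold = 20, debounce = 0.010) {
  contacts <- detect_contacts(trace, threshold = threshold, debounce = debounce)
  if (nrow(contacts) < 2) {
    return(tibble::tibble())
  }
  acc <- decompose_acceleration(trace, mass)
  st <- stride_time(contacts$strike_time)
  omega <- st$omega
  out <- vector("list", nrow(contacts) - 1)
  for (i in seq_len(nrow(contacts) - 1)) {
    t0 <- contacts$strike_time[i]
    t1 <- contacts$strike_time[i + 1]
    win <- acc[acc$t >= t0 & acc$t <= t1, ]
    win <- integrate_motion(win, initial_sx = stage_speed)
    wk <- stride_work(win$dz, win$sx, mass)
    w_ext <- external_power(wk$wt, omega)
    sbar <- mean(win$sx)
    cm <- mechanical_cost(w_ext, sbar, mass)
    # stiffness inputs over the contact phase of this stride
    contact <- win[win$t < contacts$toe_off_time[i], ]
    dy <- vertical_com_displacement(contact$az, contact$t,
                                    entry_sz = contact$sz[1])
    ks <- leg_stiffness(contacts$peak_force[i], dy, v = sbar,
                        tc = contacts$gct[i], L = leg_length)
    out[[i]] <- dplyr::bind_cols(
      tibble::tibble(stride = i, strike_time = t0, gct = contacts$gct[i],
                     fz_peak = contacts$peak_force[i], speed = sbar,
                     dz_range = max(win$dz) - min(win$dz)),
      wk,
      tibble::tibble(omega = omega, w_ext = w_ext, cm = cm, dy = dy,
                     theta = ks$theta, delta_l = ks$delta_l, kleg = ks$kleg)
    )
  }
  dplyr::bind_rows(out)
}
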