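# McMahon-Cheng leg stiffness from platform kinetics and stride timing from
# the heel marker.

#' Vertical COM displacement over a contact
#'
#' Double trapezoidal integration of the vertical acceleration over the
#' contact phase, starting from the entry vertical velocity taken from the
#' stride-level integration. The returned displacement is the magnitude of
#' the downward excursion (the minimum of the displacement curve).
#'
#' @param az Vertical acceleration samples (m/s^2) over the contact.
#' @param t Matching time samples (s).
#' @param entry_sz Vertical COM velocity at touchdown (m/s).
#' @return Downward COM excursion `dy` (m), >= 0.
#' @examples
#' # free fall: az = -g, entry at rest, duration T -> dy = g T^2 / 2
#' t <- seq(0, 0.3, by = 0.002)
#' vertical_com_displacement(rep(-9.80665, length(t)), t, 0)
#' @export
vertical_com_displacement <- function(az, t, entry_sz) {
  if (length(az) < 3 || length(az) != length(t)) {
    stop_input("Contact window too short for double integration.")
  }
  check_number(entry_sz, "entry_sz")
  vz <- entry_sz + pracma::cumtrapz(t, az)[, 1]
  y <- pracma::cumtrapz(t, vz)[, 1]
  max(0, -min(y))
}

#' McMahon-Cheng leg stiffness
#'
#' Spring-mass leg stiffness `kleg = Fz_peak / dL` with
#' `dL = dy + L (1 - cos theta)` and half-sweep angle
#' `theta = arcsin(v Tc / (2 L))`. The geometry of the cited spring-mass
#' model implies the arcsine form; the dimensionally inconsistent literal
#' reading `theta = sin(v Tc / (2 L))` is available as an explicit
#' compatibility mode (`theta_mode = "literal"`) and should not be used for
#' new analyses.
#'
#' @param fz_peak Peak vertical force (N).
#' @param dy Vertical COM displacement during contact (m).
#' @param v Forward velocity (m/s).
#' @param tc Ground contact time (s).
#' @param L Initial leg length (m), standardised at 0.53 body height.
#' @param theta_mode `"arcsin"` (default) or `"literal"`.
#' @return One-row tibble: `kleg` (kN/m), `fz_peak`, `dy`, `delta_l`,
#'   `theta` (rad), `v`, `tc`, `L`.
#' @examples
#' leg_stiffness(2000, 0.05, v = 0, tc = 0.25, L = 0.95)  # 40 kN/m
#' @export
leg_stiffness <- function(fz_peak, dy, v, tc, L, theta_mode = c("arcsin", "literal")) {
  theta_mode <- match.arg(theta_mode)
  check_number(fz_peak, "fz_peak", positive = TRUE)
  check_number(dy, "dy")
  check_number(v, "v")
  check_number(tc, "tc", positive = TRUE)
  check_number(L, "L", positive = TRUE)
  x <- v * tc / (2 * L)
  if (x < 0 || x >= 1) {
    stop_input("v*Tc/(2L) = %.3f outside [0, 1); non-physical half-sweep.", x)
  }
  theta <- if (theta_mode == "arcsin") asin(x) else sin(x)
  delta_l <- dy + L * (1 - cos(theta))
  if (delta_l <= 0) stop_input("Leg compression dL must be > 0 (got %g).", delta_l)
  tibble::tibble(kleg = fz_peak / delta_l / 1000, fz_peak = fz_peak, dy = dy,
                 delta_l = delta_l, theta = theta, v = v, tc = tc, L = L)
}

#' Stride time and stride frequency from heel strikes
#'
#' Under the equal-limb assumption the stride time is half the interval
#' between consecutive heel strikes of the instrumented foot,
#' `Ts = (C2 - C1) / 2`, and `omega = 1 / Ts` is the stride frequency. For
#' more than two strikes the consecutive intervals are averaged.
#'
#' @param strikes Strictly increasing heel-strike times (s), length >= 2.
#' @return List with `ts` (s) and `omega` (Hz).
#' @examples
#' stride_time(c(10.00, 10.70))   # Ts 0.35 s, omega ~2.857 Hz
#' @export
stride_time <- function(strikes) {
  if (length(strikes) < 2) stop_input("Need at least 2 heel strikes.")
  d <- diff(strikes)
  if (any(d <= 0)) stop_input("Heel-strike times must be strictly increasing.")
  ts <- mean(d) / 2
  list(ts = ts, omega = 1 / ts)
}

#' Detect heel strikes on the marker trace
#'
#' Strikes are local minima of the heel height that fall below a height
#' threshold (default: 10th percentile of the trace plus 5 mm), separated by
#' at least `min_separation` seconds. For flat minima the first sample of the
#' run is taken.
#'
#' @param marker Tibble with uniformly sampled `t` (s) and `z_heel` (m).
#' @param height_threshold Absolute height threshold (m); default derived
#'   from the trace.
#' @param min_separation Minimum time between strikes (s).
#' @return Numeric vector of strike times; empty (with a warning) when no
#'   minima are found.
#' @export
detect_heel_strikes <- function(marker, height_threshold = NULL,
                                min_separation = 0.25) {
  stopifnot(is.data.frame(marker), all(c("t", "z_heel") %in% names(marker)))
  z <- marker$z_heel
  n <- length(z)
  if (n < 3) {
    warn("Marker trace too short; no strikes found.")
    return(numeric(0))
  }
  thr <- height_threshold %||% (quantile(z, 0.10, names = FALSE) + 0.005)
  dz <- diff(z)
  # local minima, first sample of any flat run
  is_min <- c(FALSE, dz[-1] > 0 & dz[-(n - 1)] < 0, FALSE)
  cand <- which(is_min & z < thr)
  if (length(cand) == 0) {
    warn("No heel-strike minima found below the height threshold.")
    return(numeric(0))
  }
  keep <- cand[1]
  for (i in cand[-1]) {
    if (marker$t[i] - marker$t[tail(keep, 1)] >= min_separation) {
      keep <- c(keep, i)
    }
  }
  marker$t[keep]
}

#' Flight time from the heel-marker height
#'
#' Approximates flight as the interval between the heel rising through a
#' height threshold (toe-off) and falling back below it at the next strike.
#' With a smooth marker model this is a coarse estimate and is reported for
#' inspection rather than used by the stiffness chain.
#'
#' @param marker Tibble `t`, `z_heel`.
#' @param height_threshold Height threshold (m); defaults to the 10th
#'   percentile plus 25% of the trace range.
#' @return Tibble `toe_off`, `strike`, `tf` (s); zero rows when no complete
#'   flight is bracketed.
#' @export
flight_time <- function(marker, height_threshold = NULL) {
  stopifnot(is.data.frame(marker), all(c("t", "z_heel") %in% names(marker)))
  z <- marker$z_heel
  thr <- height_threshold %||%
    (quantile(z, 0.10, names = FALSE) + 0.25 * diff(range(z)))
  above <- z > thr
  d <- diff(c(above[1], above))
  ups <- marker$t[d == 1]
  downs <- marker$t[d == -1]
  out <- purrr::map_dfr(ups, function(u) {
    nxt <- downs[downs > u]
    if (length(nxt) == 0) return(tibble::tibble())
    tibble::tibble(toe_off = u, strike = nxt[1], tf = nxt[1] - u)
  })
  out
}
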