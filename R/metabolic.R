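# Breath-by-breath oxygen-uptake processing: second-by-second interpolation,
# moving-average smoothing, habituation truncation, metabolic power and net
# mechanical efficiency. Fixed pipeline order:
# resample -> filter -> truncate -> power -> efficiency.

#' Resample breaths to a 1 Hz grid
#'
#' Linear interpolation of irregular breath-by-breath values evaluated at
#' integer seconds spanning `[ceil(t_first), floor(t_last)]`; no
#' extrapolation beyond the recorded breaths.
#'
#' @param breaths Tibble with strictly increasing `t` (s) and `vo2`.
#' @return Tibble `t` (integer seconds), `vo2`.
#' @export
resample_to_seconds <- function(breaths) {
  if (!is.data.frame(breaths) || nrow(breaths) < 2) {
    stop_input("Need at least 2 breaths to interpolate.")
  }
  stopifnot(all(c("t", "vo2") %in% names(breaths)))
  if (any(diff(breaths$t) <= 0)) {
    stop_input("Breath times must be strictly increasing.")
  }
  secs <- seq(ceiling(min(breaths$t)), floor(max(breaths$t)))
  tibble::tibble(t = secs,
                 vo2 = approx(breaths$t, breaths$vo2, xout = secs)$y)
}

#' Centred moving-average filter
#'
#' A centred FIR mean over `order` samples (an odd number; 5 samples at 1 Hz
#' corresponds to 5-second bins). Edges use the mean of the available samples
#' (shrinking window), so no data are discarded.
#'
#' @param x Numeric series.
#' @param order Odd window length, >= 1.
#' @return Filtered series, same length as `x`.
#' @examples
#' moving_average(c(0, 0, 0, 1, 0, 0, 0))   # five values of 0.2
#' @export
moving_average <- function(x, order = 5) {
  if (length(x) == 0) stop_input("Cannot filter an empty series.")
  check_number(order, "order", positive = TRUE)
  if (order %% 2 != 1) stop_input("`order` must be odd (got %g).", order)
  k <- (order - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - k)
  hi <- pmin(n, seq_len(n) + k)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Metabolic power from oxygen uptake
#'
#' `W_met = vo2 * m / 60 * 21.1` W, using the energy equivalent of 21.1 J per
#' ml O2. Exactly linear in both arguments.
#'
#' @param vo2 Oxygen uptake (ml O2 kg^-1 min^-1), >= 0.
#' @param mass Subject mass (kg), > 0.
#' @return Metabolic power (W).
#' @export
metabolic_power <- function(vo2, mass) {
  check_number(mass, "mass", positive = TRUE)
  if (any(!is.finite(vo2)) || any(vo2 < 0)) {
    stop_input("`vo2` must be finite and non-negative.")
  }
  vo2 * mass / 60 * O2_ENERGY_J
}

#' Net mechanical efficiency
#'
#' `ME = W_ext / dW_met * 100` (%), where `dW_met` is metabolic power above
#' the resting baseline.
#'
#' @param w_ext External mechanical power (W).
#' @param delta_w_met Metabolic power above rest (W), > 0.
#' @return Efficiency (%).
#' @export
mechanical_efficiency <- function(w_ext, delta_w_met) {
  if (any(!is.finite(delta_w_met)) || any(delta_w_met <= 0)) {
    stop_input("`delta_w_met` must be > 0 (pre-exercise or invalid baseline).")
  }
  w_ext / delta_w_met * 100
}

#' Drop the habituation period
#'
#' Removes all samples recorded less than `cutoff_s` seconds after the start
#' of the series (oxygen uptake lags the instantaneous rise of mechanical
#' power at exercise onset).
#'
#' @param series Tibble with a time column `t` (s).
#' @param cutoff_s Cutoff (s), >= 0. An empty result is allowed.
#' @return The series without the first `cutoff_s` seconds.
#' @export
truncate_habituation <- function(series, cutoff_s = 60) {
  check_number(cutoff_s, "cutoff_s")
  if (cutoff_s < 0) stop_input("`cutoff_s` must be >= 0.")
  stopifnot(is.data.frame(series), "t" %in% names(series))
  if (nrow(series) == 0) return(series)
  series[series$t >= min(series$t) + cutoff_s, ]
}

#' Process a breath series into a metabolic time series
#'
#' Fixed chain: resample to 1 Hz, centred moving average, habituation
#' truncation, metabolic power and power above the resting baseline.
#'
#' @param breaths Tibble `t`, `vo2` (irregular).
#' @param mass Subject mass (kg).
#' @param vo2_rest Resting oxygen uptake baseline (ml O2 kg^-1 min^-1).
#' @param cutoff_s Habituation cutoff (s).
#' @param order Moving-average window (odd).
#' @return Tibble `t`, `vo2_filtered`, `w_met`, `delta_w_met` (W).
#' @export
process_breaths <- function(breaths, mass, vo2_rest = 5, cutoff_s = 60,
                            order = 5) {
  s <- resample_to_seconds(breaths)
  s$vo2_filtered <- moving_average(s$vo2, order = order)
  s$vo2 <- NULL
  s <- truncate_habituation(s, cutoff_s = cutoff_s)
  s$w_met <- metabolic_power(s$vo2_filtered, mass)
  s$delta_w_met <- s$w_met - metabolic_power(vo2_rest, mass)
  s
}

#' Per-stage net mechanical efficiency
#'
#' Stage-mean efficiency: true/reference external power is averaged within
#' each stage and divided by the metabolic power above rest averaged over the
#' final `steady_window` seconds of the stage, where the first-order uptake
#' kinetics have most nearly reached steady state.
#'
#' @param metabolic Output of [process_breaths()].
#' @param power_profile Tibble `t`, `w_ext` (1 Hz external power).
#' @param stages Stage table with `stage`, `t_start`, `t_end`
#'   (e.g. `session$stages`).
#' @param steady_window Seconds at the end of each stage to average (s).
#' @return Tibble `stage`, `w_ext`, `delta_w_met`, `me` (%). Stages with no
#'   usable metabolic samples are dropped.
#' @export
stage_efficiency <- function(metabolic, power_profile, stages,
                             steady_window = 20) {
  purrr::map_dfr(seq_len(nrow(stages)), function(i) {
    t0 <- stages$t_start[i]; t1 <- stages$t_end[i]
    pw <- power_profile$w_ext[power_profile$t >= t0 & power_profile$t < t1]
    mets <- metabolic[metabolic$t >= t1 - steady_window & metabolic$t < t1, ]
    if (length(pw) == 0 || nrow(mets) == 0) return(tibble::tibble())
    dwm <- mean(mets$delta_w_met)
    if (dwm <= 0) return(tibble::tibble())
    tibble::tibble(stage = stages$stage[i], w_ext = mean(pw),
                   delta_w_met = dwm,
                   me = mechanical_efficiency(mean(pw), dwm))
  })
}
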