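#' Subject profile
#'
#' Anthropometric and physiological description of one runner. The initial leg
#' length used by the spring-mass stiffness model is standardised at 0.53 times
#' body height, the convention of the McMahon-Cheng reference method.
#'
#' @param mass Body mass (kg).
#' @param height Body height (m).
#' @param vo2_rest Resting oxygen uptake (ml O2 kg^-1 min^-1).
#' @param vo2max Maximal oxygen uptake (ml O2 kg^-1 min^-1).
#' @param initial_speed Starting speed of the incremental protocol (km/h).
#'   The protocol used 10 km/h for men and 8 km/h for women.
#' @param id Optional subject identifier.
#'
#' @return A `subject_profile` list with fields `mass`, `height`, `leg_length`
#'   (= 0.53 * height), `vo2_rest`, `vo2max`, `initial_speed`, `id`.
#' @examples
#' subject_profile(mass = 70, height = 1.75)
#' @export
subject_profile <- function(mass, height, vo2_rest = 5, vo2max = 53.85,
                            initial_speed = 10, id = "s1") {
  check_number(mass, "mass", positive = TRUE)
  check_number(height, "height", positive = TRUE)
  check_number(vo2_rest, "vo2_rest")
  check_number(vo2max, "vo2max", finite = FALSE)
  check_number(initial_speed, "initial_speed", positive = TRUE)
  if (vo2_rest >= vo2max) stop_input("`vo2_rest` must be below `vo2max`.")
  structure(
    list(mass = mass, height = height, leg_length = 0.53 * height,
         vo2_rest = vo2_rest, vo2max = vo2max,
         initial_speed = initial_speed, id = as.character(id)),
    class = "subject_profile"
  )
}

#' Incremental-protocol configuration
#'
#' Describes the maximal-aerobic-speed track protocol and instrument sampling
#' rates: 200 m laps with a force-platform span at the start of each lap, the
#' speed incremented by 0.5 km/h every minute, 500 Hz force platforms, 400 Hz
#' optical marker capture and a 1 Hz footpod stream.
#'
#' @param lap_length Lap length (m).
#' @param platform_span Length of the instrumented platform section at the
#'   start of each lap (m).
#' @param speed_increment Speed increment per stage (km/h).
#' @param stage_duration Stage duration (s).
#' @param grf_rate Force-platform sampling rate (Hz).
#' @param marker_rate Marker-capture sampling rate (Hz).
#' @param pod_rate Footpod sampling rate (Hz).
#' @param max_stages Stop rule: number of completed stages after which the
#'   session ends (abstracts the behavioural cone-failure criterion).
#' @param max_speed Optional stop rule: stop before any stage whose speed
#'   (km/h) exceeds this value.
#'
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(lap_length = 200, platform_span = 9,
                            speed_increment = 0.5, stage_duration = 60,
                            grf_rate = 500, marker_rate = 400, pod_rate = 1,
                            max_stages = 10, max_speed = NULL) {
  for (nm in c("lap_length", "platform_span", "speed_increment",
               "stage_duration", "grf_rate", "marker_rate", "pod_rate")) {
    check_number(get(nm), nm, positive = nm != "platform_span")
  }
  if (platform_span < 0 || platform_span >= lap_length) {
    stop_input("`platform_span` must lie in [0, lap_length).")
  }
  check_number(max_stages, "max_stages", positive = TRUE)
  if (!is.null(max_speed)) check_number(max_speed, "max_speed", positive = TRUE)
  structure(
    list(lap_length = lap_length, platform_span = platform_span,
         speed_increment = speed_increment, stage_duration = stage_duration,
         grf_rate = grf_rate, marker_rate = marker_rate, pod_rate = pod_rate,
         max_stages = max_stages, max_speed = max_speed),
    class = "protocol_config"
  )
}

#' Footpod measurement-bias model
#'
#' Systematic and random error injected into the simulated device stream.
#' Device power is `true + po_offset + po_slope_per_speed * speed + noise`, and
#' analogously for ground contact time and leg spring stiffness. The defaults
#' emulate the validity picture reported for such devices: power underestimated
#' by roughly 300 W at the mid-range speed of an incremental test with the
#' error growing with speed, while contact time and stiffness are unbiased
#' (zero offsets) and carry only measurement noise.
#'
#' @param po_offset Constant power offset (W).
#' @param po_slope_per_speed Speed-proportional power error (W per m/s).
#' @param gct_offset Contact-time offset (s).
#' @param lss_offset Stiffness offset (kN/m).
#' @param noise_sd Named numeric vector of per-channel Gaussian noise standard
#'   deviations: `power` (W), `gct` (s), `lss` (kN/m). The defaults are scaled
#'   so that after averaging the ~3 samples of a platform window the per-lap
#'   spread matches the residual SDs reported for a six-runner reference
#'   study (about 52 W, 0.010 s and 0.97 kN/m).
#'
#' @return A `device_bias` list.
#' @examples
#' device_bias()                     # study defaults
#' device_bias(0, 0, 0, 0, c(power = 0, gct = 0, lss = 0))  # identity device
#' @export
device_bias <- function(po_offset = -210, po_slope_per_speed = -26,
                        gct_offset = 0, lss_offset = 0,
                        noise_sd = c(power = 90, gct = 0.02, lss = 1.7)) {
  for (nm in c("po_offset", "po_slope_per_speed", "gct_offset", "lss_offset")) {
    check_number(get(nm), nm)
  }
  noise <- c(power = 0, gct = 0, lss = 0)
  noise[names(noise_sd)] <- noise_sd
  if (any(noise < 0)) stop_input("`noise_sd` entries must be >= 0.")
  structure(
    list(po_offset = po_offset, po_slope_per_speed = po_slope_per_speed,
         gct_offset = gct_offset, lss_offset = lss_offset, noise_sd = noise),
    class = "device_bias"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile %s> mass %.1f kg, height %.2f m (leg %.3f m), VO2 %g-%g, start %g km/h\n",
    x$id, x$mass, x$height, x$leg_length, x$vo2_rest, x$vo2max, x$initial_speed))
  invisible(x)
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf(
    "<protocol_config> %g m laps (platform %g m), +%g km/h / %g s, rates %g/%g/%g Hz, max %g stages\n",
    x$lap_length, x$platform_span, x$speed_increment, x$stage_duration,
    x$grf_rate, x$marker_rate, x$pod_rate, x$max_stages))
  invisible(x)
}

#' @export
print.device_bias <- function(x, ...) {
  cat(sprintf(
    "<device_bias> PO %+g W %+g W/(m/s), GCT %+g s, LSS %+g kN/m; noise sd [%s]\n",
    x$po_offset, x$po_slope_per_speed, x$gct_offset, x$lss_offset,
    paste(sprintf("%s=%g", names(x$noise_sd), x$noise_sd), collapse = ", ")))
  invisible(x)
}
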