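# Matching the 1 Hz footpod stream to force-platform passages per lap and
# assembling the long-format device/reference comparison table.

#' Match footpod records to the per-lap platform windows
#'
#' The platforms occupy the first `platform_span` metres of each lap, so lap
#' k's device window contains the pod samples whose cumulative distance lies
#' in `[k * lap_length, k * lap_length + platform_span)` (half-open, k
#' starting at 0). Window means are computed per metric; a lap with no pod
#' sample in its window is kept and flagged missing.
#'
#' @param pod Footpod tibble: `t`, `power` (W), `gct_ms`, `lss`, `distance`
#'   (m, non-decreasing cumulative).
#' @param lap_length Lap length (m).
#' @param platform_span Platform section length (m).
#' @return Tibble, one row per started lap: `lap` (1-based), `n_samples`,
#'   `pod_power`, `pod_gct` (s), `pod_lss`, `missing`.
#' @export
match_lap_segments <- function(pod, lap_length = 200, platform_span = 9) {
  stopifnot(is.data.frame(pod),
            all(c("power", "gct_ms", "lss", "distance") %in% names(pod)))
  check_number(lap_length, "lap_length", positive = TRUE)
  check_number(platform_span, "platform_span")
  if (platform_span < 0) stop_input("`platform_span` must be >= 0.")
  if (any(diff(pod$distance) < 0)) {
    stop_input("Pod cumulative distance must be non-decreasing.")
  }
  n_laps <- max(1, ceiling((max(pod$distance) + 1e-9) / lap_length))
  purrr::map_dfr(seq_len(n_laps), function(k) {
    lo <- (k - 1) * lap_length
    sel <- pod$distance >= lo & pod$distance < lo + platform_span
    tibble::tibble(
      lap = k, n_samples = sum(sel),
      pod_power = if (any(sel)) mean(pod$power[sel]) else NA_real_,
      pod_gct = if (any(sel)) mean(pod$gct_ms[sel]) / 1000 else NA_real_,
      pod_lss = if (any(sel)) mean(pod$lss[sel]) else NA_real_,
      missing = !any(sel)
    )
  })
}

#' Build the long-format device/reference comparison table
#'
#' Stacks per-lap reference metrics and matched device metrics into one row
#' per observation, the input shape of the agreement mixed model. A
#' standardised copy of speed (`speed_s`, mean 0, sd 1 across the table) and
#' the 0/1 device indicator (`device_num`, 1 = pod) are appended; the binary
#' indicator is left unstandardised so device effects stay in measurement
#' units.
#'
#' @param reference Per-lap reference tibble with columns `subject`, `lap`,
#'   `speed` and one column per metric (`power`, `gct`, `lss`).
#' @param matched Per-lap device tibble from [match_lap_segments()] with a
#'   `subject` column added.
#' @param metrics Metric names to stack.
#' @return Long tibble: `subject`, `lap`, `speed`, `device`
#'   (`"reference"`/`"pod"`), `metric`, `value`, `device_num`, `speed_s`.
#'   Missing values are dropped; per-subject missingness is recorded in the
#'   `missingness` attribute.
#' @export
build_comparison_table <- function(reference, matched,
                                   metrics = c("power", "gct", "lss")) {
  stopifnot(is.data.frame(reference), is.data.frame(matched))
  if (anyDuplicated(reference[c("subject", "lap")])) {
    stop_input("Duplicate (subject, lap) keys in `reference`.")
  }
  if (anyDuplicated(matched[c("subject", "lap")])) {
    stop_input("Duplicate (subject, lap) keys in `matched`.")
  }
  ref_long <- reference |>
    dplyr::select(dplyr::all_of(c("subject", "lap", "speed", metrics))) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(device = "reference")
  pod_cols <- setNames(paste0("pod_", metrics), metrics)
  pod_long <- matched |>
    dplyr::select(dplyr::all_of(c("subject", "lap", unname(pod_cols)))) |>
    dplyr::rename(!!!setNames(unname(pod_cols), names(pod_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(device = "pod") |>
    dplyr::left_join(dplyr::distinct(reference[c("subject", "lap", "speed")]),
                     by = c("subject", "lap"))
  long <- dplyr::bind_rows(ref_long, pod_long)
  miss <- long |>
    dplyr::group_by(.data$subject, .data$device) |>
    dplyr::summarise(n_missing = sum(is.na(.data$value)), .groups = "drop")
  long <- long[!is.na(long$value) & !is.na(long$speed), ]
  long <- long |>
    dplyr::mutate(device_num = as.integer(.data$device == "pod"),
                  speed_s = as.numeric(scale(.data$speed)))
  attr(long, "missingness") <- miss
  long
}
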