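# CSV readers/writers with schema validation, and session/study persistence.
# Dialect is fixed: comma separator, "." decimal, UTF-8, header row; time in
# seconds, SI units except the footpod's GCT (ms) and LSS (kN/m).

schema_force <- c(t = "d", fz = "d", fx = "d")
schema_marker <- c(t = "d", z_heel = "d")
schema_breath <- c(t = "d", vo2 = "d")
schema_pod <- c(t = "d", power = "d", gct_ms = "d", lss = "d", distance = "d")

#' Read a validated time-series CSV
#'
#' Reads a comma-separated file, checks that the expected columns are
#' present and numeric, that the time column is strictly increasing (or
#' non-decreasing when `monotone = "weak"`) and that all values are finite.
#' Errors name the offending column and row.
#'
#' @param path File path.
#' @param schema Named character vector of readr column shorthand, e.g.
#'   `c(t = "d", fz = "d", fx = "d")`; names define the required columns.
#' @param time_col Name of the time column, or `NULL` to skip the
#'   monotonicity check.
#' @param monotone `"strict"` or `"weak"`.
#' @return A tibble.
#' @export
read_timeseries_csv <- function(path, schema, time_col = "t",
                                monotone = c("strict", "weak")) {
  monotone <- match.arg(monotone)
  if (!file.exists(path)) stop_input("File not found: %s", path)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(names(schema), names(x))
  if (length(miss)) {
    stop_input("%s: missing required column(s) %s.", path,
               paste(miss, collapse = ", "))
  }
  x <- x[names(schema)]
  for (cn in names(schema)) {
    if (!is.numeric(x[[cn]])) stop_input("%s: column '%s' is not numeric.", path, cn)
    bad <- which(!is.finite(x[[cn]]))
    if (length(bad)) {
      stop_input("%s: column '%s' has a non-finite value at row %d.",
                 path, cn, bad[1])
    }
  }
  if (!is.null(time_col) && nrow(x) > 1) {
    d <- diff(x[[time_col]])
    bad <- if (monotone == "strict") which(d <= 0) else which(d < 0)
    if (length(bad)) {
      stop_input("%s: time column '%s' not %s increasing at row %d.",
                 path, time_col,
                 if (monotone == "strict") "strictly" else "weakly",
                 bad[1] + 1)
    }
  }
  x
}

write_plain_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Write a simulated session to CSV files plus a JSON manifest
#'
#' Emits `force_<lap>.csv` (t, fz, fx), `marker.csv`, `breath.csv`,
#' `pod.csv`, `truth.csv` and `manifest.json` (subject, protocol, bias,
#' seed, stage table, file list and a configuration hash).
#'
#' @param session A [simulate_session()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "stride_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  laps <- sort(unique(session$force$lap))
  force_files <- sprintf("force_%d.csv", laps)
  for (i in seq_along(laps)) {
    write_plain_csv(session$force[session$force$lap == laps[i],
                                  c("t", "fz", "fx")],
                    file.path(dir, force_files[i]))
  }
  write_plain_csv(session$marker, file.path(dir, "marker.csv"))
  write_plain_csv(session$breath, file.path(dir, "breath.csv"))
  write_plain_csv(session$pod, file.path(dir, "pod.csv"))
  write_plain_csv(session$truth, file.path(dir, "truth.csv"))
  config <- list(subject = unclass(session$subject),
                 protocol = unclass(session$protocol),
                 bias = unclass(session$bias),
                 kleg_true = session$kleg_true, seed = session$seed)
  manifest <- list(
    subject = config$subject, protocol = config$protocol, bias = config$bias,
    kleg_true = session$kleg_true, seed = session$seed,
    stages = session$stages,
    files = c(force_files, "marker.csv", "breath.csv", "pod.csv", "truth.csv"),
    laps = laps,
    config_hash = rlang::hash(config)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Read a session written by [write_session()]
#'
#' Validates every referenced file against its schema at load.
#'
#' @param dir Session directory containing `manifest.json`.
#' @return A `stride_session`-shaped list (subject/protocol/bias as plain
#'   lists, plus the data tibbles).
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_input("No manifest.json in %s", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  missing_files <- man$files[!file.exists(file.path(dir, man$files))]
  if (length(missing_files)) {
    stop_input("Session %s is missing file(s): %s", dir,
               paste(missing_files, collapse = ", "))
  }
  force <- purrr::map_dfr(man$laps, function(lp) {
    x <- read_timeseries_csv(file.path(dir, sprintf("force_%d.csv", lp)),
                             schema_force)
    dplyr::mutate(x, lap = lp, .before = 1)
  })
  subj <- subject_profile(man$subject$mass, man$subject$height,
                          man$subject$vo2_rest, man$subject$vo2max,
                          man$subject$initial_speed, man$subject$id)
  list(
    subject = subj,
    protocol = do.call(protocol_config,
                       man$protocol[setdiff(names(man$protocol), "max_speed")]),
    bias = man$bias, kleg_true = man$kleg_true, seed = man$seed,
    stages = tibble::as_tibble(man$stages),
    force = force,
    marker = read_timeseries_csv(file.path(dir, "marker.csv"), schema_marker),
    breath = read_timeseries_csv(file.path(dir, "breath.csv"), schema_breath),
    pod = read_timeseries_csv(file.path(dir, "pod.csv"), schema_pod),
    truth = readr::read_csv(file.path(dir, "truth.csv"),
                            show_col_types = FALSE, progress = FALSE),
    config_hash = man$config_hash
  )
}
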