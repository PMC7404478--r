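# Stage chaining: process a session's raw streams into per-lap reference
# metrics, assemble the device/reference comparison, and run the Bayesian
# agreement analysis. Directory-based wrappers mirror the stages for
# command-line use (simulate -> process -> compare -> report).

#' Process a session into per-lap reference metrics
#'
#' Runs every force-platform passage through the kinetic chain
#' ([process_force_trace()]), attaches marker-based stride timing, and
#' processes the breath series. Per-lap values are unweighted means across
#' the valid strides in the platform span.
#'
#' @param session A [simulate_session()] result or [read_session()] list.
#' @param threshold,debounce Contact detection settings (N, s).
#' @param vo2_rest Resting oxygen-uptake baseline (ml O2 kg^-1 min^-1).
#' @param cutoff_s Habituation cutoff (s).
#' @param filter_order Moving-average window (odd).
#' @return List: `reference` (per-lap tibble with `subject`, `lap`,
#'   `speed`, `power`, `gct`, `lss`, `cm`, works, stiffness geometry),
#'   `strides` (per-stride detail), `metabolic`, `heel_strikes`.
#' @export
process_session <- function(session, threshold = 20, debounce = 0.010,
                            vo2_rest = NULL, cutoff_s = 60,
                            filter_order = 5) {
  subject <- session$subject
  mass <- subject$mass
  vo2_rest <- vo2_rest %||% subject$vo2_rest %||% 5
  stages <- session$stages
  heel <- detect_heel_strikes(session$marker)

  laps <- sort(unique(session$force$lap))
  strides <- purrr::map_dfr(laps, function(lp) {
    tr <- session$force[session$force$lap == lp, ]
    stage_i <- max(1, findInterval(tr$t[1], stages$t_start))
    sm <- process_force_trace(tr[c("t", "fz", "fx")], mass = mass,
                              stage_speed = stages$speed[stage_i],
                              leg_length = subject$leg_length,
                              threshold = threshold, debounce = debounce)
    if (nrow(sm) == 0) return(sm)
    # stride timing from the heel marker over this passage
    hs <- heel[heel >= tr$t[1] - 0.05 & heel <= tr$t[nrow(tr)] + 0.05]
    if (length(hs) >= 2) {
      st <- stride_time(hs)
      sm$ts <- st$ts
      sm$omega <- st$omega
      sm$w_ext <- sm$wt * st$omega
      sm$cm <- sm$w_ext / (sm$speed * mass)
    } else {
      sm$ts <- 1 / sm$omega / 1   # fall back to platform timing
      sm$ts <- 0.5 * 2 / sm$omega
    }
    dplyr::mutate(sm, lap = lp, stage = stage_i,
                  stage_speed = stages$speed[stage_i], .before = 1)
  })

  reference <- strides |>
    dplyr::group_by(.data$lap) |>
    dplyr::summarise(
      stage = .data$stage[1], speed = mean(.data$speed),
      stage_speed = .data$stage_speed[1], n_strides = dplyr::n(),
      gct = mean(.data$gct), fz_peak = mean(.data$fz_peak),
      dy = mean(.data$dy), wp = mean(.data$wp), wk = mean(.data$wk),
      wt = mean(.data$wt), ts = mean(.data$ts), omega = mean(.data$omega),
      power = mean(.data$w_ext), cm = mean(.data$cm),
      lss = mean(.data$kleg), .groups = "drop") |>
    dplyr::mutate(subject = subject$id, .before = 1)

  metabolic <- process_breaths(session$breath, mass = mass,
                               vo2_rest = vo2_rest, cutoff_s = cutoff_s,
                               order = filter_order)
  list(reference = reference, strides = strides, metabolic = metabolic,
       heel_strikes = heel)
}

#' Assemble the study-level comparison table
#'
#' Processes every session of a study, matches the footpod stream to the
#' per-lap platform windows and stacks everything into the long
#' device/reference table used by the agreement models.
#'
#' @param study A [simulate_study()] result (or a list with `sessions`).
#' @param ... Passed to [process_session()].
#' @return List: `table` (long comparison tibble), `reference` (per-lap
#'   reference metrics of all subjects), `matched` (per-lap device means),
#'   `processed` (per-session processing results).
#' @export
study_comparison <- function(study, ...) {
  processed <- purrr::map(study$sessions, process_session, ...)
  reference <- purrr::map_dfr(processed, "reference")
  matched <- purrr::imap_dfr(study$sessions, function(s, id) {
    dplyr::mutate(
      match_lap_segments(s$pod, lap_length = s$protocol$lap_length,
                         platform_span = s$protocol$platform_span),
      subject = id, .before = 1)
  })
  table <- build_comparison_table(reference, matched)
  list(table = table, reference = reference, matched = matched,
       processed = processed)
}

wide_pairs <- function(table, metric) {
  table[table$metric == metric, c("subject", "lap", "speed", "device", "value")] |>
    tidyr::pivot_wider(names_from = "device", values_from = "value") |>
    tidyr::drop_na()
}

#' Bayesian agreement analysis for one metric
#'
#' Fits the full agreement mixed model plus the two reduced models (without
#' the device term; without the interaction), computes the bridge-sampled
#' Bayes factors, the ICC, and the Bland-Altman analysis of the per-lap
#' device/reference pairs.
#'
#' @param table Long comparison table ([build_comparison_table()]).
#' @param metric `"power"`, `"gct"` or `"lss"`.
#' @param settings [sampler_settings()].
#' @param seed Integer seed.
#' @return List with the `fit`, `bf_device`, `bf_interaction`, `icc`,
#'   `bland_altman`, and (for power) the `correction` function and
#'   `corrected_rms` (relative RMS of corrected device power, %).
#' @export
compare_metric <- function(table, metric, settings = sampler_settings(),
                           seed = 1L) {
  fit <- fit_lmm(table, metric = metric, settings = settings, seed = seed)
  fit_nodev <- fit_lmm(table, metric = metric,
                       terms = c("speed", "device:speed"),
                       settings = settings, seed = seed + 1L)
  fit_noint <- fit_lmm(table, metric = metric, terms = c("device", "speed"),
                       settings = settings, seed = seed + 2L)
  bf_device <- bayes_factor(fit, fit_nodev)
  bf_interaction <- bayes_factor(fit, fit_noint)
  pairs <- wide_pairs(table, metric)
  ba <- bland_altman(pairs$reference, pairs$pod)
  out <- list(metric = metric, fit = fit, bf_device = bf_device,
              bf_interaction = bf_interaction, icc = icc(fit),
              bland_altman = ba, pairs = pairs)
  if (metric == "power") {
    by_speed <- pairs |>
      dplyr::mutate(speed_bin = round(.data$speed * 3.6 / 0.5) * 0.5) |>
      dplyr::group_by(.data$speed_bin) |>
      dplyr::summarise(reference = mean(.data$reference),
                       pod = mean(.data$pod), .groups = "drop")
    if (nrow(by_speed) >= 2 && sd(by_speed$pod) > 0) {
      corr <- correction_function(by_speed$reference, by_speed$pod)
      corrected <- predict(corr, by_speed$pod)
      out$correction <- corr
      out$corrected_rms <- 100 * sqrt(mean((corrected - by_speed$reference)^2)) /
        mean(by_speed$reference)
      out$by_speed <- by_speed
    }
  }
  out
}

#' Full agreement analysis across metrics
#'
#' @param table Long comparison table.
#' @param metrics Metrics to analyse.
#' @param settings [sampler_settings()].
#' @param seed Integer seed.
#' @return Named list of [compare_metric()] results.
#' @export
compare_study <- function(table, metrics = c("power", "gct", "lss"),
                          settings = sampler_settings(), seed = 1L) {
  res <- purrr::imap(setNames(metrics, metrics), function(mt, nm) {
    compare_metric(table, mt, settings = settings,
                   seed = seed + 10L * match(mt, metrics))
  })
  res
}

# --- directory-based stages (command-line surface) ----------------------

#' Simulate a study to disk
#'
#' Writes one session directory per subject plus a study manifest.
#'
#' @param dir Output directory.
#' @param n_subjects Cohort size.
#' @param seed Integer master seed.
#' @param protocol,bias Shared [protocol_config()] / [device_bias()].
#' @return The study manifest path, invisibly.
#' @export
pipeline_simulate <- function(dir, n_subjects = 6, seed = 1L,
                              protocol = protocol_config(),
                              bias = device_bias()) {
  study <- simulate_study(n_subjects = n_subjects, protocol = protocol,
                          bias = bias, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(study$sessions)) {
    write_session(study$sessions[[id]], file.path(dir, id))
  }
  manifest <- list(
    subjects = study$subjects, seed = study$seed,
    protocol = unclass(protocol), bias = unclass(bias),
    session_dirs = names(study$sessions),
    config_hash = rlang::hash(list(unclass(protocol), unclass(bias),
                                   n_subjects, seed))
  )
  jsonlite::write_json(manifest, file.path(dir, "study_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "study_manifest.json"))
}

read_study_manifest <- function(dir) {
  p <- file.path(dir, "study_manifest.json")
  if (!file.exists(p)) stop_input("No study_manifest.json in %s", dir)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

#' Process every session of an on-disk study
#'
#' Writes `stride_metrics.csv`, `stiffness.csv` and `metabolic.csv` into
#' each session directory.
#'
#' @param dir Study directory created by [pipeline_simulate()].
#' @param ... Passed to [process_session()].
#' @return Invisibly, the list of per-session processing results.
#' @export
pipeline_process <- function(dir, ...) {
  man <- read_study_manifest(dir)
  out <- lapply(man$session_dirs, function(sd) {
    sess <- read_session(file.path(dir, sd))
    pr <- process_session(sess, ...)
    ref <- pr$reference
    write_plain_csv(
      ref[c("subject", "lap", "stage", "speed", "stage_speed", "n_strides",
            "wp", "wk", "wt", "omega", "power", "cm")],
      file.path(dir, sd, "stride_metrics.csv"))
    write_plain_csv(
      ref[c("subject", "lap", "speed", "gct", "fz_peak", "dy", "ts",
            "omega", "lss")],
      file.path(dir, sd, "stiffness.csv"))
    write_plain_csv(pr$metabolic, file.path(dir, sd, "metabolic.csv"))
    pr
  })
  names(out) <- man$session_dirs
  invisible(out)
}

#' Compare device and reference for an on-disk study
#'
#' Reads the processed per-lap tables and pod streams, writes
#' `comparison_long.csv`, one `posterior_<metric>.csv` per metric and one
#' `agreement_<metric>.json` (Bayes factors, ICC, Bland-Altman, correction
#' coefficients).
#'
#' @param dir Study directory (after [pipeline_process()]).
#' @param metrics Metrics to analyse.
#' @param settings [sampler_settings()].
#' @param seed Integer seed.
#' @return Invisibly, the [compare_study()] result list.
#' @export
pipeline_compare <- function(dir, metrics = c("power", "gct", "lss"),
                             settings = sampler_settings(), seed = 1L) {
  man <- read_study_manifest(dir)
  reference <- purrr::map_dfr(man$session_dirs, function(sd) {
    sm <- readr::read_csv(file.path(dir, sd, "stride_metrics.csv"),
                          show_col_types = FALSE, progress = FALSE)
    st <- readr::read_csv(file.path(dir, sd, "stiffness.csv"),
                          show_col_types = FALSE, progress = FALSE)
    dplyr::left_join(sm, st[c("subject", "lap", "gct", "lss")],
                     by = c("subject", "lap"))
  })
  matched <- purrr::map_dfr(man$session_dirs, function(sd) {
    pod <- read_timeseries_csv(file.path(dir, sd, "pod.csv"), schema_pod)
    dplyr::mutate(
      match_lap_segments(pod, lap_length = man$protocol$lap_length,
                         platform_span = man$protocol$platform_span),
      subject = sd, .before = 1)
  })
  table <- build_comparison_table(reference, matched)
  write_plain_csv(table, file.path(dir, "comparison_long.csv"))
  res <- compare_study(table, metrics = metrics, settings = settings,
                       seed = seed)
  for (mt in metrics) {
    r <- res[[mt]]
    pt <- posterior_table(r$fit)
    bf_col <- rep(NA_real_, nrow(pt))
    bf_col[pt$Parameter == "device"] <- r$bf_device$bf10
    bf_col[pt$Parameter == "device:speed"] <- r$bf_interaction$bf10
    pt$BF10 <- bf_col
    write_plain_csv(pt, file.path(dir, sprintf("posterior_%s.csv", mt)))
    agg <- list(
      metric = mt, seed = seed, config_hash = man$config_hash,
      bf10_device = r$bf_device$bf10,
      bf10_interaction = r$bf_interaction$bf10,
      icc = as.list(r$icc),
      bland_altman = list(bias = r$bland_altman$bias,
                          loa_lower = r$bland_altman$loa_lower,
                          loa_upper = r$bland_altman$loa_upper,
                          ci_bias = r$bland_altman$ci_bias,
                          prop_slope = r$bland_altman$prop_slope),
      correction = if (!is.null(r$correction)) {
        list(a = r$correction$a, b = r$correction$b,
             corrected_rms_pct = r$corrected_rms)
      }
    )
    jsonlite::write_json(agg, file.path(dir, sprintf("agreement_%s.json", mt)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

#' Write a markdown summary report for an on-disk study
#'
#' @param dir Study directory (after [pipeline_compare()]).
#' @return The report path, invisibly.
#' @export
pipeline_report <- function(dir) {
  man <- read_study_manifest(dir)
  lines <- c("# Footpod validity report", "",
             sprintf("Seed: %d - config hash: %s", man$seed, man$config_hash),
             "")
  for (mt in c("power", "gct", "lss")) {
    jp <- file.path(dir, sprintf("agreement_%s.json", mt))
    pp <- file.path(dir, sprintf("posterior_%s.csv", mt))
    if (!file.exists(jp) || !file.exists(pp)) next
    agg <- jsonlite::read_json(jp, simplifyVector = TRUE)
    pt <- readr::read_csv(pp, show_col_types = FALSE, progress = FALSE)
    lines <- c(lines, sprintf("## %s", toupper(mt)), "",
               knit_table(pt), "",
               sprintf("- BF10 (device term): %.4g - %s", agg$bf10_device,
                       classify_bf(agg$bf10_device)),
               sprintf("- BF10 (interaction): %.4g - %s",
                       agg$bf10_interaction,
                       classify_bf(agg$bf10_interaction)),
               sprintf("- ICC: %.3f [%.3f, %.3f]", agg$icc$estimate,
                       agg$icc$conf.low, agg$icc$conf.high),
               sprintf("- Bland-Altman bias %.3f, LoA [%.3f, %.3f]",
                       agg$bland_altman$bias, agg$bland_altman$loa_lower,
                       agg$bland_altman$loa_upper))
    if (!is.null(agg$correction) && length(agg$correction)) {
      lines <- c(lines, sprintf(
        "- Correction f(x) = %.4g x + %.4g (corrected RMS %.2f%%)",
        agg$correction$a, agg$correction$b, agg$correction$corrected_rms_pct))
    }
    lines <- c(lines, "")
  }
  out <- file.path(dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}

knit_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
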