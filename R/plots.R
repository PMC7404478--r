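# ggplot2 displays for the main result types.

#' @export
autoplot.spm_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$ci_bias[1], ymax = object$ci_bias[2],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$ci_loa_lower[1],
                      ymax = object$ci_loa_lower[2],
                      alpha = 0.15, fill = "grey40") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$ci_loa_upper[1],
                      ymax = object$ci_loa_upper[2],
                      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::labs(x = "Mean of device and reference",
                  y = "Device - reference",
                  title = sprintf("Bland-Altman: bias %.3g, LoA [%.3g, %.3g]",
                                  object$bias, object$loa_lower,
                                  object$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Plot posterior traces or interval summaries of a Bayesian fit
#'
#' @param object An `spm_lmm` or `spm_blm` fit.
#' @param type `"intervals"` (posterior means with 95% credible bars) or
#'   `"trace"` (per-chain trace plots).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spm_bayes_fit <- function(object, type = c("intervals", "trace"), ...) {
  type <- match.arg(type)
  if (type == "intervals") {
    td <- summarise_draws_tbl(object)
    return(
      ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
        ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                              xmax = .data$conf.high)) +
        ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
        ggplot2::labs(x = "Posterior estimate (95% CrI)", y = NULL) +
        ggplot2::theme_minimal()
    )
  }
  long <- purrr::imap_dfr(object$samples, function(ch, i) {
    m <- as.matrix(ch)
    colnames(m) <- colnames(object$draws)
    tibble::as_tibble(m) |>
      dplyr::mutate(iteration = dplyr::row_number(), chain = factor(i)) |>
      tidyr::pivot_longer(-c("iteration", "chain"), names_to = "term")
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-lap device and reference values against speed
#'
#' @param table Long comparison table ([build_comparison_table()]).
#' @param metric Metric to display.
#' @return A ggplot object.
#' @export
plot_comparison <- function(table, metric = "power") {
  d <- table[table$metric == metric, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$speed, y = .data$value,
                                  colour = .data$device)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "Speed (m/s)", y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}
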