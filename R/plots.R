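#' Plot a visual predictive check
#'
#' Observed percentiles (lines and points) overlaid on the simulated 95%
#' confidence bands of the median (dark ribbon) and of the outer 5th/95th
#' percentiles (light ribbons), against time after dose.
#'
#' @param x A `vpc_result` from [vpc()].
#' @return A ggplot object.
#' @export
plot_vpc <- function(x) {
  stopifnot(inherits(x, "vpc_result"))
  s <- x$stats
  ggplot2::ggplot(s, ggplot2::aes(x = .data$tad_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p5_lo,
                                      ymax = .data$sim_p5_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p95_lo,
                                      ymax = .data$sim_p95_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_med_lo,
                                      ymax = .data$sim_med_hi),
                         fill = "firebrick", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_med), color = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p5), color = "steelblue",
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p95), color = "steelblue",
                       linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_med), color = "firebrick") +
    ggplot2::labs(x = "Time after dose (h)", y = "Concentration (mg/L)",
                  title = "Visual predictive check")
}

#' Goodness-of-fit panels
#'
#' Four standard panels: observations against population and individual
#' predictions, and conditional weighted residuals against time after dose
#' and against population predictions.
#'
#' @param g A data.frame from [gof()].
#' @return A ggplot object (faceted).
#' @export
plot_gof <- function(g) {
  long <- rbind(
    data.frame(panel = "OBS vs PRED", x = g$PRED, y = g$DV),
    data.frame(panel = "OBS vs IPRED", x = g$IPRED, y = g$DV),
    data.frame(panel = "CWRES vs TAD", x = g$TAD, y = g$CWRES),
    data.frame(panel = "CWRES vs PRED", x = g$PRED, y = g$CWRES))
  long$panel <- factor(long$panel, levels = unique(long$panel))
  ref <- data.frame(panel = levels(long$panel),
                    slope = c(1, 1, 0, 0), intercept = 0)
  ref$panel <- factor(ref$panel, levels = levels(long$panel))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(data = ref,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept),
                         linetype = 2, color = "grey40") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = "Goodness of fit")
}

#' Plot probability of target attainment against MIC
#'
#' PTA curve on a log2 MIC axis with dotted 95% and 99% confidence bands
#' and a reference line at 95% attainment.
#'
#' @param x A `pta_result` from [simulate_pta()].
#' @return A ggplot object.
#' @export
plot_pta <- function(x) {
  stopifnot(inherits(x, "pta_result"))
  s <- x$pta
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mic, y = .data$pta)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$lo95), linetype = 3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$hi95), linetype = 3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lo99), linetype = 3,
                       color = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hi99), linetype = 3,
                       color = "grey50") +
    ggplot2::geom_hline(yintercept = 0.95, color = "firebrick", linetype = 2) +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = s$mic,
                                labels = signif(s$mic, 3)) +
    ggplot2::labs(x = "MIC (mg/L)", y = "PTA",
                  title = sprintf("%g mg q%gh, target %s ≥ %g",
                                  x$regimen$dose, x$regimen$interval,
                                  x$target$kind, x$target$threshold))
}
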