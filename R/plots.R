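#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_abline
#'   labs
#' @export
ggplot2::autoplot

#' Diagnostic plot of a Stern-Volmer fit
#' @param object An `sv_fit`.
#' @param ... Unused.
#' @return A ggplot: intensity ratio against quencher concentration with the
#'   fitted line.
#' @export
autoplot.sv_fit <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("ratio", "Q")
  ggplot(d, aes(x = .data$Q, y = .data$ratio)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$K_SV,
                colour = "steelblue") +
    labs(x = "[Q] (mol/L)", y = expression(F[0] / F),
         title = sprintf("Stern-Volmer fit, K_SV = %.3g L/mol", object$K_SV))
}

#' Diagnostic plot of a van't Hoff fit
#' @param object A `vant_hoff_fit`.
#' @param ... Unused.
#' @return A ggplot of ln K_a against 1/T with the regression line.
#' @export
autoplot.vant_hoff_fit <- function(object, ...) {
  d <- object$by_temperature
  ggplot(d, aes(x = 1 / .data$temperature_K, y = log(.data$K_a))) +
    geom_point() +
    geom_line(aes(y = .data$ln_K_a_fitted), colour = "steelblue") +
    labs(x = "1 / T (1/K)", y = expression(ln ~ K[a]),
         title = sprintf("van't Hoff: dH = %.2f kJ/mol, dS = %.2f J/mol/K",
                         object$dH_kJ_mol, object$dS_J_mol_K))
}

#' Diagnostic plot of a decay tail fit
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot of counts (log scale) over the fit window with the fitted
#'   decay.
#' @export
autoplot.decay_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- predict(object$fit)
  ggplot(d, aes(x = .data$time_ns)) +
    geom_point(aes(y = .data$counts), size = 0.3, alpha = 0.5) +
    geom_line(aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::scale_y_log10() +
    labs(x = "time (ns)", y = "counts",
         title = sprintf("%d-exponential tail fit, tau_avg = %.3f ns",
                         object$n_components, object$tau_avg))
}

#' Plot per-frame trajectory metrics
#' @param stats Result of [trajectory_stats()].
#' @return A ggplot of RMSD and Rg against time with the plateau start marked.
#' @export
plot_trajectory_stats <- function(stats) {
  d <- tidyr::pivot_longer(stats$series, c("rmsd_A", "rg_A"),
                           names_to = "metric", values_to = "value")
  ggplot(d, aes(x = .data$time_ps, y = .data$value)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = stats$plateau_start_ps,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "time (ps)", y = NULL)
}
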