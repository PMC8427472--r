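# ggplot2 helpers for the package's result types.

#' Scatter plot of calculated vs experimental relative free energies
#'
#' One point per ligand pair with the identity line; experimental and
#' calculated error bars are drawn when the corresponding columns are
#' present.
#'
#' @param pairs Pair tibble (`ddg_exp`, `ddg_cal`, optional `*_err`).
#' @return A ggplot object.
#' @export
plot_correlation <- function(pairs) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$ddg_exp,
                                           y = .data$ddg_cal)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8)
  if ("ddg_cal_err" %in% names(pairs)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ddg_cal - .data$ddg_cal_err,
                   ymax = .data$ddg_cal + .data$ddg_cal_err),
      width = 0, alpha = 0.4)
  }
  if ("ddg_exp_err" %in% names(pairs)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ddg_exp - .data$ddg_exp_err,
                   xmax = .data$ddg_exp + .data$ddg_exp_err),
      height = 0, alpha = 0.4)
  }
  p + ggplot2::labs(x = expression(Delta * Delta * G[exp] ~ "(kcal/mol)"),
                    y = expression(Delta * Delta * G[cal] ~ "(kcal/mol)"))
}

#' Mean dU/dlambda profile of an ensemble
#'
#' Per-replica window means as thin lines with the ensemble mean overlaid;
#' the area under the ensemble mean is the TI estimate.
#'
#' @param dhdl A `dhdl_ensemble` tibble.
#' @return A ggplot object.
#' @export
plot_dhdl_profile <- function(dhdl) {
  st <- window_stats(dhdl)
  ens <- st |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(mean_dhdl = mean(.data$mean_dhdl), .groups = "drop")
  ggplot2::ggplot(st, ggplot2::aes(x = .data$lambda, y = .data$mean_dhdl)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$replica), alpha = 0.35) +
    ggplot2::geom_line(data = ens, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_point(data = ens, colour = "firebrick") +
    ggplot2::labs(x = expression(lambda),
                  y = expression(paste("<", dU/d * lambda, "> (kcal/mol)")))
}

#' @describeIn evaluate_pairs Bar chart of underestimation percentage per
#'   experimental-magnitude bin.
#' @param object An `eval_report`.
#' @export
autoplot.eval_report <- function(object, ...) {
  b <- dplyr::filter(object$bins, .data$bin != "total", .data$n > 0)
  lab <- sprintf("[%.2f, %s)", b$lo,
                 ifelse(is.finite(b$hi), sprintf("%.2f", b$hi), "Inf"))
  b$label <- factor(lab, levels = lab)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$label,
                                  y = .data$pct_underestimated)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = expression("|" * Delta * Delta * G[exp] * "| bin (kcal/mol)"),
                  y = "pairs underestimated (%)")
}

#' @describeIn run_toy_rest Trajectory traces per replica over time.
#' @param object A `rest_run`.
#' @param ... Unused.
#' @export
autoplot.rest_run <- function(object, ...) {
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(x = .data$step, y = .data$position)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.2) +
    ggplot2::facet_wrap(~ replica, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "step", y = "position")
}
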