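#' Forest plot of pooled MR estimates
#'
#' @param forest A long table with columns `exposure`, `outcome`, `or`,
#'   `ci_low`, `ci_high` (e.g. the `forest` element of [mr_run_study()]).
#' @return A ggplot object (odds-ratio scale, log axis).
#' @export
plot_forest <- function(forest) {
  ggplot2::ggplot(forest,
                  ggplot2::aes(x = .data$or, y = .data$outcome)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$exposure)) +
    ggplot2::labs(x = "Odds ratio per unit exposure (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of SNP-outcome against SNP-exposure effects
#'
#' Each point is one harmonised instrument with its standard-error bars;
#' lines show the fitted causal slopes of the supplied estimates (the Egger
#' line keeps its intercept).
#'
#' @param harmonised Output of [harmonise()] (excluded rows are dropped).
#' @param estimates Optional tibble from [mr_estimate()].
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(harmonised, estimates = NULL) {
  h <- harmonised[!harmonised$excluded, ]
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$gamma, y = .data$Gamma)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$Gamma - .data$se_Gamma,
                                        ymax = .data$Gamma + .data$se_Gamma),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$gamma - .data$se_gamma,
                                         xmax = .data$gamma + .data$se_gamma),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome (log OR)") +
    ggplot2::theme_minimal()
  if (!is.null(estimates)) {
    ab <- dplyr::transmute(estimates, method = .data$method,
                           slope = .data$beta,
                           intercept = dplyr::coalesce(.data$intercept, 0))
    p <- p + ggplot2::geom_abline(
      data = ab,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)) +
      ggplot2::labs(colour = "Method")
  }
  p
}

#' Leave-one-out forest plot
#'
#' @param leave_one_out The `leave_one_out` tibble from [mr_single_snp()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(leave_one_out) {
  ggplot2::ggplot(leave_one_out,
                  ggplot2::aes(x = .data$beta, y = .data$rsid)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "IVW estimate excluding the SNP (log OR)",
                  y = "Excluded SNP") +
    ggplot2::theme_minimal()
}
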