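#' Power of two-sample MR for a binary outcome
#'
#' Asymptotic power of the two-sided Wald test for the causal log odds
#' ratio. On the observed (0/1) scale the causal effect of the probed odds
#' ratio attenuates to `ln(OR) * K * (1 - K)` (K the case fraction), and the
#' IVW estimator's variance is `K(1-K) / (N * R2)`, giving the
#' non-centrality parameter
#' \deqn{NCP = \ln(OR)^2 \; N \; R^2 \; K(1-K)}
#' and power `P(chisq(1, NCP) > chisq_{1-alpha}(1))`.
#'
#' @param or Odds ratio probed (per unit of exposure).
#' @param n Total outcome sample size (cases + controls).
#' @param r2 Proportion of exposure variance explained by the instruments.
#' @param case_fraction Proportion of cases, `ncase / n`.
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @return Power, vectorised over the inputs.
#' @export
mr_power <- function(or, n, r2, case_fraction, alpha = 0.05) {
  stopifnot(all(or > 0), all(n > 0), all(r2 > 0 & r2 < 1),
            all(case_fraction > 0 & case_fraction < 1),
            all(alpha > 0 & alpha < 1))
  ncp <- log(or)^2 * n * r2 * case_fraction * (1 - case_fraction)
  stats::pchisq(stats::qchisq(1 - alpha, 1), df = 1, ncp = ncp,
                lower.tail = FALSE)
}

#' Minimum detectable odds ratio at a target power
#'
#' Inverts [mr_power()] by bisection (tolerance 1e-4 on the OR scale): the
#' smallest OR above 1 (`direction = "risk"`) whose power reaches
#' `target_power`, or the analogous OR below 1 (`"protective"`).
#'
#' @param ncase,ncontrol Case and control counts.
#' @param r2 Instrument variance explained in the exposure.
#' @param alpha Type-I error rate.
#' @param target_power Target power (default 0.8).
#' @param direction `"risk"` or `"protective"`.
#' @return An odds ratio.
#' @export
min_detectable_or <- function(ncase, ncontrol, r2, alpha = 0.05,
                              target_power = 0.8,
                              direction = c("risk", "protective")) {
  direction <- match.arg(direction)
  n <- ncase + ncontrol
  k <- ncase / n
  f <- function(log_or) mr_power(exp(log_or), n, r2, k, alpha) - target_power
  hi <- 1e-4
  while (f(hi) < 0) hi <- hi * 2
  lo <- 0
  while (hi - lo > 1e-4 / 2) {   # bisection to < 1e-4 on the log-OR scale
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  or <- exp(hi)
  if (direction == "protective") 1 / or else or
}

#' Detectable-OR grid over exposure instruments and outcome sample sizes
#'
#' Crosses each exposure (instrument R-squared) with each outcome
#' (case/control totals) and computes the minimum detectable odds ratio at
#' the target power for every combination. With the defaults this is the
#' study design grid: the four epigenetic clocks against the five cancer
#' meta-analyses.
#'
#' @param clocks A data frame with columns `clock` and `r2`
#'   (default [eaa_clocks()]).
#' @param cancers A data frame with columns `cancer`, `ncase`, `ncontrol`
#'   (default [cancer_meta_sizes()]).
#' @param alpha,target_power Passed to [min_detectable_or()].
#' @return A tibble `clock`, `cancer`, `r2`, `ncase`, `ncontrol`,
#'   `or_detectable`.
#' @export
detectable_or_grid <- function(clocks = eaa_clocks(),
                               cancers = cancer_meta_sizes(),
                               alpha = 0.05, target_power = 0.8) {
  grid <- tidyr::crossing(clocks[, c("clock", "r2")],
                          cancers[, c("cancer", "ncase", "ncontrol")])
  dplyr::mutate(grid, or_detectable = purrr::pmap_dbl(
    list(.data$ncase, .data$ncontrol, .data$r2),
    function(ncase, ncontrol, r2) {
      min_detectable_or(ncase, ncontrol, r2, alpha = alpha,
                        target_power = target_power)
    }))
}
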