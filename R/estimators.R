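#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# Internal constructor for a single-method MR result.
new_mr_result <- function(method, beta, se, nsnp, df = Inf,
                          intercept = NA_real_, intercept_se = NA_real_,
                          intercept_p = NA_real_,
                          Q = NA_real_, Q_df = NA_real_, Q_p = NA_real_) {
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  pvalue <- if (is.finite(df)) {
    2 * stats::pt(-abs(beta / se), df)
  } else {
    2 * stats::pnorm(-abs(beta / se))
  }
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pvalue = pvalue, nsnp = nsnp,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_p = intercept_p, Q = Q, Q_df = Q_df, Q_p = Q_p),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: beta = %.4g (se %.3g), 95%% CI [%.4g, %.4g], p = %.3g, %d SNP(s)\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue, x$nsnp))
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept = %.4g (se %.3g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  if (!is.na(x$Q)) {
    cat(sprintf("  Cochran's Q = %.4g on %d df, p = %.3g\n", x$Q, x$Q_df, x$Q_p))
  }
  invisible(x)
}

#' @rdname mr_ivw
#' @param x An `mr_result`.
#' @param ... Unused.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, beta = x$beta, se = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
                 nsnp = x$nsnp, or = exp(x$beta), or_ci_low = exp(x$ci_low),
                 or_ci_high = exp(x$ci_high))
}

#' @rdname mr_ivw
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, nsnp = x$nsnp,
                 intercept = x$intercept, intercept_se = x$intercept_se,
                 intercept_p = x$intercept_p,
                 Q = x$Q, Q_df = x$Q_df, Q_p = x$Q_p)
}

# Drop excluded rows and check the minimum instrument count for a method.
usable_instruments <- function(insts, min_n, method) {
  x <- tibble::as_tibble(insts)
  if ("excluded" %in% names(x)) x <- x[!x$excluded, ]
  if (nrow(x) == 0) stop("no usable (non-excluded) instruments", call. = FALSE)
  if (nrow(x) < min_n) {
    stop(method, " requires at least ", min_n, " instruments; got ", nrow(x),
         call. = FALSE)
  }
  x
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate is `Gamma / gamma` with first-order
#' delta-method standard error `se_Gamma / |gamma|`; the second-order
#' correction additionally propagates `se_gamma`.
#'
#' @param inst One harmonised instrument (a one-row tibble from
#'   [harmonise()]).
#' @param second_order Use the second-order delta-method variance.
#' @return An `mr_result`.
#' @export
mr_wald_ratio <- function(inst, second_order = FALSE) {
  x <- usable_instruments(inst, 1, "wald_ratio")[1, ]
  if (x$gamma == 0) stop("undefined Wald ratio: gamma is zero", call. = FALSE)
  beta <- x$Gamma / x$gamma
  se <- if (second_order) {
    sqrt(x$se_Gamma^2 / x$gamma^2 + x$Gamma^2 * x$se_gamma^2 / x$gamma^4)
  } else {
    x$se_Gamma / abs(x$gamma)
  }
  new_mr_result("wald", beta, se, 1L)
}

# Delta-method Wald ratios and inverse-variance weights for a set.
wald_ratios <- function(x, second_order = FALSE) {
  theta <- x$Gamma / x$gamma
  v <- if (second_order) {
    x$se_Gamma^2 / x$gamma^2 + x$Gamma^2 * x$se_gamma^2 / x$gamma^4
  } else {
    x$se_Gamma^2 / x$gamma^2
  }
  tibble::tibble(rsid = x$rsid, theta = theta, var = v, w = 1 / v)
}

#' Inverse-variance-weighted MR
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects through the origin, with weights `1/se_Gamma^2`. In
#' `"fixed"` mode the coefficient standard error assumes unit residual
#' variance; in `"multiplicative_random"` mode (the default, matching the
#' study's main analysis) it is scaled by the residual standard deviation,
#' without flooring at 1 (set `floor_scale = TRUE` to floor). Cochran's Q
#' over the per-SNP Wald ratios is returned whenever at least two
#' instruments are available. A single instrument reduces to
#' [mr_wald_ratio()].
#'
#' @param insts Harmonised instruments ([harmonise()] output); excluded rows
#'   are dropped.
#' @param mode `"multiplicative_random"` or `"fixed"`.
#' @param floor_scale Floor the multiplicative residual scale at 1.
#' @return An `mr_result`.
#' @export
mr_ivw <- function(insts, mode = c("multiplicative_random", "fixed"),
                   floor_scale = FALSE) {
  mode <- match.arg(mode)
  x <- usable_instruments(insts, 1, "ivw")
  if (nrow(x) == 1) return(mr_wald_ratio(x))
  w <- 1 / x$se_Gamma^2
  beta <- sum(w * x$gamma * x$Gamma) / sum(w * x$gamma^2)
  se_fixed <- sqrt(1 / sum(w * x$gamma^2))
  k <- nrow(x)
  resid <- x$Gamma - beta * x$gamma
  Q <- sum(w * resid^2)
  Q_df <- k - 1L
  Q_p <- stats::pchisq(Q, Q_df, lower.tail = FALSE)
  se <- if (mode == "fixed") {
    se_fixed
  } else {
    phi <- sqrt(Q / Q_df)
    if (floor_scale) phi <- max(1, phi)
    se_fixed * phi
  }
  method <- if (mode == "fixed") "ivw_fe" else "ivw_mre"
  new_mr_result(method, beta, se, k, Q = Q, Q_df = Q_df, Q_p = Q_p)
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome on SNP-exposure effects with a free
#' intercept (weights `1/se_Gamma^2`), after orienting instruments so every
#' `gamma` is non-negative. The slope is the causal estimate; the intercept
#' estimates average directional pleiotropy. Standard errors are scaled by
#' `max(1, residual SD)` and inference uses a t-distribution with `k - 2`
#' degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return An `mr_result` carrying intercept terms and Cochran's Q from the
#'   Egger fit (df `k - 2`).
#' @export
mr_egger <- function(insts, floor_scale = TRUE) {
  x <- usable_instruments(insts, 3, "mr_egger")
  flip <- sign(x$gamma) < 0
  g <- abs(x$gamma)
  G <- ifelse(flip, -x$Gamma, x$Gamma)
  w <- 1 / x$se_Gamma^2
  fit <- stats::lm(G ~ g, weights = w)
  k <- nrow(x)
  coefs <- stats::coef(fit)
  # Unscaled (sigma = 1) covariance of the weighted LS coefficients.
  xw <- cbind(1, g) * sqrt(w)
  cov_unit <- solve(crossprod(xw))
  sigma <- sqrt(sum(w * stats::resid(fit)^2) / (k - 2))
  scale <- if (floor_scale) max(1, sigma) else sigma
  ses <- unname(sqrt(diag(cov_unit))) * scale
  df <- k - 2
  res <- new_mr_result("egger", unname(coefs[2]), ses[2], k, df = df,
                       intercept = unname(coefs[1]), intercept_se = ses[1],
                       intercept_p = 2 * stats::pt(-abs(coefs[1] / ses[1]), df),
                       Q = sum(w * stats::resid(fit)^2), Q_df = k - 2L)
  res$Q_p <- stats::pchisq(res$Q, res$Q_df, lower.tail = FALSE)
  res
}

# Weighted median of values by the interpolated cumulative-weight definition.
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(theta[1])
  if (p[length(p)] <= 0.5) return(theta[length(theta)])
  below <- max(which(p < 0.5))
  theta[below] + (theta[below + 1] - theta[below]) *
    (0.5 - p[below]) / (p[below + 1] - p[below])
}

# Parametric bootstrap over (gamma, Gamma) sampling distributions.
bootstrap_se <- function(x, point_fun, n_boot, seed) {
  set.seed(seed)
  est <- vapply(seq_len(n_boot), function(b) {
    g <- stats::rnorm(nrow(x), x$gamma, x$se_gamma)
    G <- stats::rnorm(nrow(x), x$Gamma, x$se_Gamma)
    point_fun(G / g, g^2 / x$se_Gamma^2)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted-median MR
#'
#' The estimate is the inverse-variance-weighted median of the per-SNP Wald
#' ratios: with normalised weights, the cumulative percentile of the j-th
#' ordered ratio is `sum(w[1:j]) - w[j]/2` and the estimate linearly
#' interpolates the ratio at percentile 0.5. The standard error comes from a
#' parametric bootstrap resampling `(gamma, Gamma)` from their normal
#' sampling distributions.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(insts, n_boot = 1000, seed = 1) {
  x <- usable_instruments(insts, 3, "weighted_median")
  r <- wald_ratios(x)
  beta <- weighted_median_point(r$theta, r$w)
  se <- bootstrap_se(x, weighted_median_point, n_boot, seed)
  new_mr_result("weighted_median", beta, se, nrow(x))
}

# Mode of a weighted kernel density of the ratios; bandwidth is phi times
# the modified Silverman default on the smaller of SD and MAD.
weighted_mode_point <- function(theta, w, phi = 1) {
  if (length(unique(theta)) == 1) return(theta[1])
  s <- 0.9 * min(stats::sd(theta), stats::mad(theta)) / length(theta)^(1 / 5)
  h <- max(1e-8, s * phi)
  d <- stats::density(theta, weights = w / sum(w), bw = h)
  d$x[which.max(d$y)]
}

#' Weighted-mode MR
#'
#' Mode-based estimate: the maximiser of an inverse-variance-weighted kernel
#' density of the per-SNP Wald ratios, with bandwidth `bandwidth_phi` times
#' a dispersion-based default. Standard error by parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_phi Bandwidth multiplier (default 1).
#' @return An `mr_result`.
#' @export
mr_weighted_mode <- function(insts, bandwidth_phi = 1, n_boot = 1000,
                             seed = 1) {
  x <- usable_instruments(insts, 3, "weighted_mode")
  r <- wald_ratios(x)
  beta <- weighted_mode_point(r$theta, r$w, bandwidth_phi)
  se <- bootstrap_se(x, function(th, w) weighted_mode_point(th, w, bandwidth_phi),
                     n_boot, seed)
  new_mr_result("weighted_mode", beta, se, nrow(x))
}

#' Single-SNP and leave-one-out analyses
#'
#' Per-SNP Wald ratios (is the signal driven by one variant?) and k
#' leave-one-out IVW estimates, each re-fitting [mr_ivw()] on the set minus
#' one instrument.
#'
#' @inheritParams mr_ivw
#' @param mode IVW mode for the leave-one-out fits.
#' @return A list with tibbles `single_snp` and `leave_one_out`.
#' @export
mr_single_snp <- function(insts, mode = "multiplicative_random") {
  x <- usable_instruments(insts, 2, "single-SNP/leave-one-out")
  single <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    dplyr::mutate(tidy(mr_wald_ratio(x[i, ])), rsid = x$rsid[i],
                  .before = 1)
  })
  loo <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    dplyr::mutate(tidy(mr_ivw(x[-i, ], mode = mode)), rsid = x$rsid[i],
                  .before = 1)
  })
  list(single_snp = single, leave_one_out = loo)
}

#' Run a suite of MR estimators
#'
#' @inheritParams mr_ivw
#' @param methods Estimators to run; methods whose minimum instrument count
#'   exceeds the usable set are skipped with a message.
#' @param n_boot,seed Bootstrap controls for the median and mode methods.
#' @return A tibble with one row per method (columns as [tidy.mr_result()],
#'   plus intercept and Q columns).
#' @export
mr_estimate <- function(insts,
                        methods = c("ivw_mre", "egger", "weighted_median",
                                    "weighted_mode"),
                        n_boot = 1000, seed = 1) {
  x <- usable_instruments(insts, 1, "mr_estimate")
  k <- nrow(x)
  runner <- list(
    wald = function() mr_wald_ratio(x[1, ]),
    ivw_fe = function() mr_ivw(x, mode = "fixed"),
    ivw_mre = function() mr_ivw(x, mode = "multiplicative_random"),
    egger = function() mr_egger(x),
    weighted_median = function() mr_weighted_median(x, n_boot, seed),
    weighted_mode = function() mr_weighted_mode(x, n_boot = n_boot, seed = seed)
  )
  min_n <- c(wald = 1, ivw_fe = 1, ivw_mre = 1, egger = 3,
             weighted_median = 3, weighted_mode = 3)
  methods <- match.arg(methods, names(runner), several.ok = TRUE)
  purrr::map_dfr(methods, function(m) {
    if (k < min_n[[m]]) {
      message("skipping ", m, ": needs ", min_n[[m]], " instruments, have ", k)
      return(NULL)
    }
    r <- runner[[m]]()
    dplyr::bind_cols(tidy(r), glance(r)[, c("intercept", "intercept_se",
                                            "intercept_p", "Q", "Q_df", "Q_p")])
  })
}

#' Steiger directionality test and filtering
#'
#' Computes per-SNP variance explained in the exposure and in the outcome.
#' Continuous traits use the summary-statistic formula of
#' [instrument_strength()]; binary traits use the observed-scale pseudo
#' r-squared `2 p (1-p) b^2 K (1-K)` from the log odds ratio `b`, allele
#' frequency `p` and case fraction `K` (`scale = "liability"` rescales by
#' `K(1-K)/phi(qnorm(K))^2`). The inferred direction is exposure-to-outcome
#' iff the summed exposure r-squared exceeds the summed outcome r-squared;
#' the p-value is a z-test on the difference of Fisher-transformed
#' correlations. Filtering retains SNPs with `r2_exposure > r2_outcome`.
#'
#' @param insts Harmonised instruments with `eaf_exposure` and `eaf_outcome`.
#' @param exposure_n,outcome_n Total sample sizes.
#' @param exposure_type,outcome_type `"continuous"` or `"binary"`.
#' @param outcome_case_fraction Case fraction for a binary outcome.
#' @param exposure_case_fraction Case fraction for a binary exposure.
#' @param scale Binary-trait variance-explained scale.
#' @return A list of class `steiger_result`: `snps` (per-SNP r-squared and
#'   `retained` flag), `r2_exposure`, `r2_outcome`, `direction`
#'   (`"exposure->outcome"`, `"outcome->exposure"` or `"undetermined"`),
#'   `statistic`, `pvalue`, `retained` rsids.
#' @export
mr_steiger <- function(insts, exposure_n, outcome_n,
                       exposure_type = "continuous", outcome_type = "binary",
                       outcome_case_fraction = NULL,
                       exposure_case_fraction = NULL,
                       scale = c("observed", "liability")) {
  scale <- match.arg(scale)
  x <- usable_instruments(insts, 1, "steiger")
  if (any(is.na(x$eaf_exposure)) || any(is.na(x$eaf_outcome))) {
    stop("eaf required for both traits; missing for: ",
         paste(x$rsid[is.na(x$eaf_exposure) | is.na(x$eaf_outcome)],
               collapse = ", "), call. = FALSE)
  }
  r2_exp <- snp_r2(x$gamma, x$se_gamma, x$eaf_exposure, exposure_n,
                   exposure_type, exposure_case_fraction, scale)
  r2_out <- snp_r2(x$Gamma, x$se_Gamma, x$eaf_outcome, outcome_n,
                   outcome_type, outcome_case_fraction, scale)
  snps <- tibble::tibble(rsid = x$rsid, r2_exposure = r2_exp,
                         r2_outcome = r2_out,
                         retained = r2_exp > r2_out)
  tot_exp <- sum(r2_exp)
  tot_out <- sum(r2_out)
  r_exp <- sqrt(min(tot_exp, 1))
  r_out <- sqrt(min(tot_out, 1))
  if (isTRUE(all.equal(tot_exp, tot_out)) || tot_exp == tot_out) {
    direction <- "undetermined"
    z <- 0
    p <- 1
  } else {
    direction <- if (tot_exp > tot_out) "exposure->outcome" else "outcome->exposure"
    z <- (atanh(r_exp) - atanh(r_out)) /
      sqrt(1 / (exposure_n - 3) + 1 / (outcome_n - 3))
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(snps = snps, r2_exposure = tot_exp, r2_outcome = tot_out,
                 direction = direction, statistic = z, pvalue = p,
                 retained = snps$rsid[snps$retained]),
            class = "steiger_result")
}

# Per-SNP variance explained for one trait.
snp_r2 <- function(beta, se, eaf, n, type, case_fraction, scale) {
  maf <- pmin(eaf, 1 - eaf)
  if (type == "continuous") {
    num <- 2 * beta^2 * maf * (1 - maf)
    return(num / (num + 2 * n * maf * (1 - maf) * se^2))
  }
  if (is.null(case_fraction)) {
    stop("case fraction required for a binary trait", call. = FALSE)
  }
  K <- case_fraction
  r2 <- 2 * maf * (1 - maf) * beta^2 * K * (1 - K)
  if (scale == "liability") {
    r2 <- r2 * K * (1 - K) / stats::dnorm(stats::qnorm(K))^2
  }
  r2
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("<steiger_result> direction %s (z = %.3g, p = %.3g)\n",
              x$direction, x$statistic, x$pvalue))
  cat(sprintf("  sum r2 exposure %.4g vs outcome %.4g; %d/%d SNPs retained\n",
              x$r2_exposure, x$r2_outcome, length(x$retained), nrow(x$snps)))
  invisible(x)
}

#' @rdname mr_steiger
#' @param x A `steiger_result`.
#' @param ... Unused.
#' @method tidy steiger_result
#' @export
tidy.steiger_result <- function(x, ...) x$snps

#' @rdname mr_steiger
#' @method glance steiger_result
#' @export
glance.steiger_result <- function(x, ...) {
  tibble::tibble(direction = x$direction, r2_exposure = x$r2_exposure,
                 r2_outcome = x$r2_outcome, statistic = x$statistic,
                 pvalue = x$pvalue, n_retained = length(x$retained),
                 n_snps = nrow(x$snps))
}
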