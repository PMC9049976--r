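#' Fixed-effect meta-analysis with I-squared and its confidence interval
#'
#' Inverse-variance pooling of per-study estimates on a common (log-OR)
#' scale. Heterogeneity is quantified by the between-study Cochran Q (df
#' `k - 1`) and `I2 = max(0, (Q - df)/Q) * 100`. The I-squared confidence
#' interval uses the test-based method of Higgins & Thompson on the `ln(H)`
#' scale; with fewer than three studies it is reported as `NA`.
#'
#' @param estimates A data frame with columns `beta` and `se` (and
#'   optionally `study`), one row per study.
#' @return A list of class `meta_result` with the pooled `beta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`, `k`, `Q`, `Q_df`, `Q_p`, `I2`,
#'   `I2_ci_low`, `I2_ci_high`, and the per-study inputs in `$studies`.
#' @export
meta_fixed <- function(estimates) {
  x <- tibble::as_tibble(estimates)
  stopifnot(all(c("beta", "se") %in% names(x)), nrow(x) >= 1)
  if (any(x$se <= 0)) stop("study standard errors must be > 0", call. = FALSE)
  if (!"study" %in% names(x)) x$study <- paste0("study_", seq_len(nrow(x)))
  w <- 1 / x$se^2
  beta <- sum(w * x$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  k <- nrow(x)
  if (k > 1) {
    Q <- sum(w * (x$beta - beta)^2)
    Q_df <- k - 1L
    Q_p <- stats::pchisq(Q, Q_df, lower.tail = FALSE)
    I2 <- max(0, (Q - Q_df) / Q) * 100
    ci <- i2_ci(Q, k)
  } else {
    Q <- NA_real_; Q_df <- NA_integer_; Q_p <- NA_real_
    I2 <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  structure(list(beta = beta, se = se,
                 ci_low = beta - stats::qnorm(0.975) * se,
                 ci_high = beta + stats::qnorm(0.975) * se,
                 pvalue = 2 * stats::pnorm(-abs(beta / se)),
                 k = k, Q = Q, Q_df = Q_df, Q_p = Q_p, I2 = I2,
                 I2_ci_low = ci[1], I2_ci_high = ci[2], studies = x),
            class = "meta_result")
}

# Test-based CI for I2 on the ln(H) scale (Higgins & Thompson 2002).
# Reported as NA for k = 2, where the interval is not usefully defined.
i2_ci <- function(Q, k) {
  if (k < 3) return(c(NA_real_, NA_real_))
  df <- k - 1
  H <- sqrt(max(Q, df + 1e-12) / df)
  se_lnH <- if (Q > k) {
    0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * k - 3))
  } else {
    sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  }
  lo <- max(1, exp(log(H) - stats::qnorm(0.975) * se_lnH))
  hi <- max(1, exp(log(H) + stats::qnorm(0.975) * se_lnH))
  h_to_i2 <- function(h) 100 * (h^2 - 1) / h^2
  c(h_to_i2(lo), h_to_i2(hi))
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> pooled beta = %.4g (se %.3g), 95%% CI [%.4g, %.4g], p = %.3g, k = %d\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pvalue, x$k))
  if (!is.na(x$I2)) {
    ci_txt <- if (is.na(x$I2_ci_low)) "NA" else
      sprintf("%.1f%%-%.1f%%", x$I2_ci_low, x$I2_ci_high)
    cat(sprintf("  I2 = %.1f%% (95%% CI %s), Q = %.3g on %d df, p = %.3g\n",
                x$I2, ci_txt, x$Q, x$Q_df, x$Q_p))
  }
  invisible(x)
}

#' @rdname meta_fixed
#' @param x A `meta_result`.
#' @param ... Unused.
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  tibble::tibble(beta = x$beta, se = x$se, ci_low = x$ci_low,
                 ci_high = x$ci_high, pvalue = x$pvalue, k = x$k,
                 I2 = x$I2, I2_ci_low = x$I2_ci_low, I2_ci_high = x$I2_ci_high,
                 Q = x$Q, Q_df = x$Q_df, Q_p = x$Q_p)
}

#' Per-SNP fixed-effect GWAS meta-analysis
#'
#' Harmonises every dataset to the first dataset's effect alleles (via
#' [harmonise()]) and pools betas per rsid by inverse-variance weighting.
#' rsids whose alleles cannot be reconciled in some dataset are dropped with
#' a message. The pooled dataset can be fed back into MR as the outcome
#' (e.g. for single-SNP analyses of a multi-study outcome).
#'
#' @param datasets A list of [summary_dataset()] objects for the same trait.
#' @param trait_name,provenance Labels for the pooled dataset.
#' @return A [summary_dataset()] with pooled `beta`, `se`, `pvalue`, summed
#'   `n`/`ncase`/`ncontrol`, and the first dataset's alleles and eaf.
#' @export
meta_per_snp <- function(datasets, trait_name = NULL, provenance = "meta") {
  stopifnot(length(datasets) >= 1)
  ref <- datasets[[1]]
  if (length(datasets) == 1) return(ref)
  per_study <- list(tibble::tibble(rsid = ref$rsid, beta = ref$beta,
                                   se = ref$se, n = ref$n, ncase = ref$ncase,
                                   ncontrol = ref$ncontrol))
  dropped <- character(0)
  for (d in datasets[-1]) {
    h <- harmonise(ref, d)
    dropped <- c(dropped, h$rsid[h$excluded])
    h <- h[!h$excluded, ]
    per_study <- c(per_study, list(
      tibble::tibble(rsid = h$rsid, beta = h$Gamma, se = h$se_Gamma,
                     n = d$n[match(h$rsid, d$rsid)],
                     ncase = d$ncase[match(h$rsid, d$rsid)],
                     ncontrol = d$ncontrol[match(h$rsid, d$rsid)])))
  }
  if (length(dropped) > 0) {
    message("dropped ", length(unique(dropped)),
            " rsid(s) with irreconcilable alleles: ",
            paste(unique(dropped), collapse = ", "))
  }
  long <- dplyr::bind_rows(per_study, .id = "study")
  long <- long[!long$rsid %in% dropped, ]
  pooled <- long |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(
      beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
      se = sqrt(1 / sum(1 / .data$se^2)),
      n = sum(.data$n), ncase = sum(.data$ncase),
      ncontrol = sum(.data$ncontrol), .groups = "drop") |>
    dplyr::mutate(pvalue = pmax(2 * stats::pnorm(-abs(.data$beta / .data$se)), 1e-300))
  base <- tibble::as_tibble(ref)[match(pooled$rsid, ref$rsid),
                                 c("rsid", "chrom", "pos", "effect_allele",
                                   "other_allele", "eaf")]
  summary_dataset(dplyr::left_join(base, pooled, by = "rsid"),
                  trait_name = trait_name %||% trait_name(ref),
                  trait_type = trait_type(ref), provenance = provenance)
}

#' Benjamini-Hochberg FDR with a configured family size
#'
#' Step-up q-values `q_i = min_{j >= i} p_(j) * m / j` where `m` is the
#' family size — by default the number of p-values supplied, but settable to
#' the design's family (the study corrects its 20 clock-cancer tests with
#' `m = 20` even in partial runs, keeping q-values comparable).
#'
#' @param pvalues Numeric p-values in (0, 1].
#' @param m Family size, at least `length(pvalues)`.
#' @param alpha Discovery threshold for the flag (default 0.05).
#' @return A tibble `pvalue`, `qvalue`, `discovery` in input order.
#' @export
bh_fdr <- function(pvalues, m = length(pvalues), alpha = 0.05) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m < length(p)) stop("family size m must be >= length(pvalues)", call. = FALSE)
  ord <- order(p)
  ranked <- p[ord] * m / seq_along(p)
  q_sorted <- pmin(rev(cummin(rev(ranked))), 1)
  q <- numeric(length(p))
  q[ord] <- q_sorted
  tibble::tibble(pvalue = p, qvalue = q, discovery = q < alpha)
}
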