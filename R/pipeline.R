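#' Analysis settings for the MR pipeline
#'
#' All thresholds default to the study design: genome-wide significance
#' 5e-8, clumping r-squared 0.001, proxy r-squared 0.8, palindromic MAF
#' 0.3, discovery FDR 0.05 over a family of 20 tests.
#'
#' @param p_threshold Instrument significance threshold.
#' @param clump_r2 Clumping independence bound.
#' @param proxy_r2 Minimum (exclusive) proxy r-squared.
#' @param palindromic_maf Palindromic exclusion threshold.
#' @param alpha Discovery threshold.
#' @param fdr_family FDR family size.
#' @param methods Estimators run per pair (see [mr_estimate()]).
#' @param n_boot Bootstrap draws for median/mode.
#' @param seed RNG seed for bootstraps.
#' @return A list of class `mr_settings`.
#' @export
mr_settings <- function(p_threshold = 5e-8, clump_r2 = 0.001, proxy_r2 = 0.8,
                        palindromic_maf = 0.3, alpha = 0.05, fdr_family = 20,
                        methods = c("ivw_mre", "egger", "weighted_median",
                                    "weighted_mode"),
                        n_boot = 1000, seed = 1) {
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 proxy_r2 = proxy_r2, palindromic_maf = palindromic_maf,
                 alpha = alpha, fdr_family = fdr_family, methods = methods,
                 n_boot = n_boot, seed = seed),
            class = "mr_settings")
}

#' Run one exposure-outcome MR analysis
#'
#' The full per-pair protocol: select genome-wide-significant exposure
#' variants, clump, substitute LD proxies for instruments missing from the
#' outcome, harmonise alleles, compute instrument strength, then run the
#' configured estimators plus single-SNP/leave-one-out and, when sample
#' sizes allow, the Steiger directionality test. A stage log records counts
#' in and out of every filtering step.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param ld Optional r-squared matrix for clumping and proxy lookup.
#' @param settings An [mr_settings()].
#' @return A list of class `mr_pair_result`: `exposure`, `outcome` (trait
#'   names), `skipped`/`skip_reason`, `log`, `instruments`, `proxies`,
#'   `harmonised`, `estimates`, `single_snp`, `leave_one_out`, `steiger`.
#' @export
mr_run_pair <- function(exposure, outcome, ld = NULL,
                        settings = mr_settings()) {
  res <- list(exposure = trait_name(exposure), outcome = trait_name(outcome),
              skipped = FALSE, skip_reason = NA_character_)
  class(res) <- "mr_pair_result"
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, n_in = n_in,
                                              n_out = n_out)
  }

  sel <- suppressMessages(select_significant(exposure, settings$p_threshold))
  note("select_significant", nrow(exposure), nrow(sel))
  if (nrow(sel) == 0) {
    res$skipped <- TRUE
    res$skip_reason <- "no genome-wide-significant exposure variants"
    res$log <- dplyr::bind_rows(log)
    return(res)
  }

  cl <- clump(sel, ld, settings$clump_r2)
  note("clump", nrow(sel), nrow(cl))

  missing <- setdiff(cl$rsid, outcome$rsid)
  proxies <- tibble::tibble(rsid = character(0), proxy_rsid = character(0),
                            r2 = numeric(0))
  outcome_use <- tibble::as_tibble(outcome)
  if (length(missing) > 0 && !is.null(ld)) {
    proxies <- substitute_proxies(missing, outcome, ld, settings$proxy_r2)
    if (nrow(proxies) > 0) {
      # Substitute the proxy's association under the instrument's rsid.
      i <- match(proxies$proxy_rsid, outcome_use$rsid)
      outcome_use$rsid[i] <- proxies$rsid
    }
  }
  found <- intersect(cl$rsid, outcome_use$rsid)
  note("outcome_lookup", nrow(cl), length(found))
  if (length(found) == 0) {
    res$skipped <- TRUE
    res$skip_reason <- "no instruments present in the outcome (no proxies found)"
    res$log <- dplyr::bind_rows(log)
    res$proxies <- proxies
    return(res)
  }

  outcome_ds <- summary_dataset(outcome_use[match(found, outcome_use$rsid), ],
                                trait_name = trait_name(outcome),
                                trait_type = trait_type(outcome),
                                provenance = attr(outcome, "provenance") %||% "")
  harm <- harmonise(cl[cl$rsid %in% found, ], outcome_ds,
                    settings$palindromic_maf)
  usable <- sum(!harm$excluded)
  note("harmonise", length(found), usable)
  res$proxies <- proxies
  res$harmonised <- harm
  res$instruments <- tryCatch(
    instrument_strength(cl[cl$rsid %in% harm$rsid[!harm$excluded], ]),
    error = function(e) cl[cl$rsid %in% harm$rsid[!harm$excluded], ])
  if (usable == 0) {
    res$skipped <- TRUE
    res$skip_reason <- "all instruments excluded during harmonisation"
    res$log <- dplyr::bind_rows(log)
    return(res)
  }

  res$estimates <- suppressMessages(
    mr_estimate(harm, methods = settings$methods, n_boot = settings$n_boot,
                seed = settings$seed))
  if (usable >= 2) {
    ss <- mr_single_snp(harm)
    res$single_snp <- ss$single_snp
    res$leave_one_out <- ss$leave_one_out
  }
  n_exp <- stats::median(exposure$n, na.rm = TRUE)
  n_out <- stats::median(outcome$n, na.rm = TRUE)
  if (is.finite(n_exp) && is.finite(n_out)) {
    kf <- if (trait_type(outcome) == "binary") {
      stats::median(outcome$ncase / outcome$n, na.rm = TRUE)
    } else NULL
    kf_exp <- if (trait_type(exposure) == "binary") {
      stats::median(exposure$ncase / exposure$n, na.rm = TRUE)
    } else NULL
    res$steiger <- tryCatch(
      mr_steiger(harm, exposure_n = n_exp, outcome_n = n_out,
                 exposure_type = trait_type(exposure),
                 outcome_type = trait_type(outcome),
                 outcome_case_fraction = kf,
                 exposure_case_fraction = kf_exp),
      error = function(e) NULL)
  }
  res$log <- dplyr::bind_rows(log)
  res
}

#' @export
print.mr_pair_result <- function(x, ...) {
  cat(sprintf("<mr_pair_result> %s -> %s\n", x$exposure, x$outcome))
  if (x$skipped) {
    cat("  skipped:", x$skip_reason, "\n")
  } else {
    print(x$estimates)
  }
  invisible(x)
}

#' Bidirectional MR with Steiger filtering
#'
#' Runs A-to-B and B-to-A analyses, the Steiger directionality test on
#' each, and re-runs each direction on the Steiger-filtered instrument set
#' (dropping SNPs that explain more variance in the outcome than in the
#' exposure).
#'
#' @param trait_a,trait_b [summary_dataset()] objects.
#' @inheritParams mr_run_pair
#' @return A list of class `mr_bidirectional_result` with elements
#'   `forward`, `reverse` (each an `mr_pair_result`) and
#'   `forward_filtered`, `reverse_filtered` (estimate tibbles after Steiger
#'   filtering, `NULL` when no instruments survive).
#' @export
mr_run_bidirectional <- function(trait_a, trait_b, ld = NULL,
                                 settings = mr_settings()) {
  fwd <- mr_run_pair(trait_a, trait_b, ld, settings)
  rev <- mr_run_pair(trait_b, trait_a, ld, settings)
  refit <- function(pair) {
    if (pair$skipped || is.null(pair$steiger)) return(NULL)
    keep <- pair$steiger$retained
    h <- pair$harmonised
    h <- h[!h$excluded & h$rsid %in% keep, ]
    if (nrow(h) == 0) return(NULL)
    suppressMessages(mr_estimate(h, methods = settings$methods,
                                 n_boot = settings$n_boot,
                                 seed = settings$seed))
  }
  structure(list(forward = fwd, reverse = rev,
                 forward_filtered = refit(fwd),
                 reverse_filtered = refit(rev)),
            class = "mr_bidirectional_result")
}

#' Run a full multi-exposure, multi-outcome study plan
#'
#' Executes every exposure-outcome pair, pools per-outcome estimates across
#' study sources by fixed-effect meta-analysis (honouring per-outcome
#' source exclusions such as the colorectal overlap rule), and applies
#' Benjamini-Hochberg FDR over the main pooled IVW family. Negative-control
#' and risk-factor outcomes are ordinary outcomes in the plan; they are
#' analysed by the same machinery but kept out of the FDR family.
#'
#' @param exposures Named list of exposure [summary_dataset()]s.
#' @param outcomes A tibble with columns `outcome`, `source`, `dataset`
#'   (list-column of [summary_dataset()]s) and optionally `in_meta`
#'   (logical, default `TRUE`) and `role` (`"main"`, `"negative_control"`
#'   or `"risk_factor"`, default `"main"`).
#' @param ld Optional shared LD reference.
#' @param settings An [mr_settings()].
#' @return A list of class `mr_study_report`: `estimates` (long per-source
#'   tibble), `pooled` (per exposure-outcome meta rows with q-values on the
#'   main family), `pairs` (named list of `mr_pair_result`s), `failures`
#'   (skip manifest), `forest` (long table ready for forest plotting).
#' @export
mr_run_study <- function(exposures, outcomes, ld = NULL,
                         settings = mr_settings()) {
  outcomes <- tibble::as_tibble(outcomes)
  if (!"in_meta" %in% names(outcomes)) outcomes$in_meta <- TRUE
  if (!"role" %in% names(outcomes)) outcomes$role <- "main"
  pairs <- list()
  rows <- list()
  failures <- list()
  for (en in names(exposures)) {
    for (i in seq_len(nrow(outcomes))) {
      key <- paste(en, outcomes$outcome[i], outcomes$source[i], sep = "|")
      pair <- mr_run_pair(exposures[[en]], outcomes$dataset[[i]], ld, settings)
      pairs[[key]] <- pair
      if (pair$skipped) {
        failures[[key]] <- tibble::tibble(
          exposure = en, outcome = outcomes$outcome[i],
          source = outcomes$source[i], reason = pair$skip_reason)
        next
      }
      rows[[key]] <- dplyr::mutate(pair$estimates, exposure = en,
                                   outcome = outcomes$outcome[i],
                                   source = outcomes$source[i],
                                   in_meta = outcomes$in_meta[i],
                                   role = outcomes$role[i], .before = 1)
    }
  }
  estimates <- dplyr::bind_rows(rows)
  failures <- dplyr::bind_rows(failures)

  pooled <- NULL
  if (nrow(estimates) > 0) {
    main_method <- if ("ivw_mre" %in% settings$methods) "ivw_mre" else
      settings$methods[1]
    ivw_rows <- estimates[estimates$method == main_method & estimates$in_meta, ]
    pooled <- ivw_rows |>
      dplyr::group_by(.data$exposure, .data$outcome, .data$role) |>
      dplyr::group_modify(function(df, key) {
        m <- meta_fixed(tibble::tibble(study = df$source, beta = df$beta,
                                       se = df$se))
        tidy(m)
      }) |>
      dplyr::ungroup()
    main <- pooled$role == "main"
    pooled$qvalue <- NA_real_
    pooled$discovery <- NA
    if (any(main)) {
      fdr <- bh_fdr(pooled$pvalue[main],
                    m = max(settings$fdr_family, sum(main)),
                    alpha = settings$alpha)
      pooled$qvalue[main] <- fdr$qvalue
      pooled$discovery[main] <- fdr$discovery
    }
  }

  forest <- if (!is.null(pooled)) {
    dplyr::transmute(pooled, exposure = .data$exposure,
                     outcome = .data$outcome, method = "ivw_meta",
                     or = exp(.data$beta), ci_low = exp(.data$ci_low),
                     ci_high = exp(.data$ci_high), pvalue = .data$pvalue,
                     qvalue = .data$qvalue)
  } else NULL

  structure(list(estimates = estimates, pooled = pooled, pairs = pairs,
                 failures = failures, forest = forest, settings = settings),
            class = "mr_study_report")
}

#' @export
print.mr_study_report <- function(x, ...) {
  cat(sprintf("<mr_study_report> %d per-source estimate rows, %d pooled rows, %d failures\n",
              nrow(x$estimates) %||% 0,
              if (is.null(x$pooled)) 0 else nrow(x$pooled),
              if (is.null(x$failures)) 0 else nrow(x$failures)))
  if (!is.null(x$pooled)) print(x$pooled)
  invisible(x)
}
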