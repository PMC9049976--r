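#' Configure a two-sample summary-statistics simulation
#'
#' Defines the generative model for a continuous exposure (unit variance,
#' e.g. years of age acceleration) instrumented by `n_snps` independent
#' variants, and a binary outcome on the log-odds scale with
#' `outcome_ncase` cases and `outcome_ncontrol` controls. True per-SNP
#' exposure effects are scaled so their variance explained sums exactly to
#' `r2_total`; true outcome effects are `theta * gamma + alpha` with the
#' pleiotropy term `alpha` drawn per `pleiotropy`:
#' `"none"` (zero), `"balanced"` (mean-zero normal), `"directional"`
#' (mean `pleio_mean`), or `"correlated"` (`alpha = confounder_effect * u`
#' with the confounder loading `u` also added to `gamma`). `pleio_frac`
#' applies the pleiotropy term to a leading fraction of instruments only.
#' `n_reverse` appends reverse-causal SNPs whose true outcome variance
#' explained exceeds their exposure variance explained (for Steiger
#' checks). `ld_blocks = list(n_blocks, block_size, r2)` duplicates lead
#' SNPs into LD blocks (proxies inherit the lead's alleles and eaf) to
#' exercise clumping and proxy lookup.
#'
#' @param n_snps Number of causal instruments.
#' @param r2_total Exposure variance explained by the instruments, in (0,1).
#' @param outcome_ncase,outcome_ncontrol Outcome case/control counts.
#' @param exposure_n Exposure GWAS sample size (default 34,710).
#' @param theta True causal log odds ratio per exposure unit.
#' @param maf_range Minor-allele-frequency range for simulated variants.
#' @param pleiotropy Pleiotropy model (see above).
#' @param pleio_mean,pleio_sd Mean and SD of the pleiotropy / confounder
#'   draws.
#' @param pleio_frac Fraction of instruments carrying pleiotropy.
#' @param confounder_effect Outcome loading of the shared confounder
#'   (correlated model).
#' @param n_reverse Number of planted reverse-causal SNPs.
#' @param reverse_r2_ratio Ratio of a reverse SNP's true outcome variance
#'   explained (observed scale) to its exposure variance explained.
#' @param ld_blocks Optional list `n_blocks`, `block_size`, `r2`.
#' @param seed Mandatory RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps, r2_total, outcome_ncase, outcome_ncontrol,
                       exposure_n = 34710, theta = 0,
                       maf_range = c(0.05, 0.45),
                       pleiotropy = c("none", "balanced", "directional",
                                      "correlated"),
                       pleio_mean = 0, pleio_sd = 0, pleio_frac = 1,
                       confounder_effect = 0, n_reverse = 0,
                       reverse_r2_ratio = 4, ld_blocks = NULL, seed) {
  pleiotropy <- match.arg(pleiotropy)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_snps >= 1, r2_total > 0, r2_total < 1,
            exposure_n > 1, outcome_ncase > 0, outcome_ncontrol > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            pleio_frac >= 0, pleio_frac <= 1, n_reverse >= 0)
  # A diallelic SNP at MAF p explains at most 2p(1-p) gamma^2; with unit
  # exposure variance the requested total must be attainable in principle.
  if (r2_total >= 1) stop("infeasible r2_total", call. = FALSE)
  structure(list(n_snps = as.integer(n_snps), r2_total = r2_total,
                 outcome_ncase = outcome_ncase,
                 outcome_ncontrol = outcome_ncontrol,
                 exposure_n = exposure_n, theta = theta,
                 maf_range = maf_range, pleiotropy = pleiotropy,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 pleio_frac = pleio_frac,
                 confounder_effect = confounder_effect,
                 n_reverse = as.integer(n_reverse),
                 reverse_r2_ratio = reverse_r2_ratio,
                 ld_blocks = ld_blocks, seed = as.integer(seed)),
            class = "sim_config")
}

# Independent sub-stream seeds derived from the master seed by a fixed
# integer hash, so effect draws, pleiotropy and the two noise layers are
# separately reproducible.
stage_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 1000003) %% 2147483647
}

#' Simulate two-sample GWAS summary statistics
#'
#' Draws true effects and observed estimates under the configured model.
#' Observed betas are the truths plus normal noise with standard errors
#' implied by sample size and allele frequency: for the unit-variance
#' continuous exposure `se = 1/sqrt(2 p (1-p) N)`, and for the binary
#' outcome the logistic-score approximation
#' `se = 1/sqrt(2 p (1-p) ncase ncontrol / N)`. P-values are two-sided
#' Wald tests.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed` (used by replicate loops).
#' @return A list with `exposure` and `outcome` ([summary_dataset()]s),
#'   `ld` (r-squared matrix over all emitted rsids) and `truth` (per-SNP
#'   generative record: `rsid`, `maf`, `gamma_true`, `Gamma_true`, `alpha`,
#'   `confounder`, `reverse`, `is_proxy`, `block`), with the full config
#'   attached as attribute `config`.
#' @export
simulate_two_sample <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_snps
  n_out <- config$outcome_ncase + config$outcome_ncontrol

  set.seed(stage_seed(seed, 1))
  maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
  alleles <- t(replicate(k, sample(c("A", "C", "G", "T"), 2)))

  set.seed(stage_seed(seed, 2))
  # Per-SNP shares of the total variance explained are moderately spread
  # (uniform within +/-25% of equal shares) with random effect signs:
  # instruments of one trait are all genome-wide significant, with
  # F-statistics clustered the way published instrument sets are, rather
  # than spanning orders of magnitude.
  share <- stats::runif(k, 0.75, 1.25)
  share <- share / sum(share)
  sign_g <- sample(c(-1, 1), k, replace = TRUE)
  gamma <- sign_g * sqrt(config$r2_total * share / (2 * maf * (1 - maf)))

  set.seed(stage_seed(seed, 3))
  m_pleio <- ceiling(config$pleio_frac * k)
  carrier <- seq_len(k) <= m_pleio
  u <- numeric(k)
  alpha <- numeric(k)
  # Uncorrelated pleiotropy acts on the exposure-increasing allele
  # orientation (the scale on which "directional" is defined), so the draw
  # is applied with the sign of gamma.
  if (config$pleiotropy == "balanced") {
    alpha[carrier] <- sign(gamma[carrier]) *
      stats::rnorm(m_pleio, 0, config$pleio_sd)
  } else if (config$pleiotropy == "directional") {
    alpha[carrier] <- sign(gamma[carrier]) *
      stats::rnorm(m_pleio, config$pleio_mean, config$pleio_sd)
  } else if (config$pleiotropy == "correlated") {
    u[carrier] <- stats::rnorm(m_pleio, 0, config$pleio_sd)
    gamma <- gamma + u
    alpha <- config$confounder_effect * u
  }
  Gamma <- config$theta * gamma + alpha

  reverse <- rep(FALSE, k)
  if (config$n_reverse > 0) {
    kr <- config$n_reverse
    set.seed(stage_seed(seed, 6))
    maf_r <- stats::runif(kr, config$maf_range[1], config$maf_range[2])
    # Exposure effect just past genome-wide significance (z ~ 8), so the
    # SNP is selected as an instrument yet explains little exposure
    # variance (r2 = 64/N regardless of maf); its direct outcome effect is
    # sized to explain reverse_r2_ratio times as much outcome variance on
    # the observed scale.
    gamma_r <- 8 / sqrt(2 * maf_r * (1 - maf_r) * config$exposure_n)
    kf <- config$outcome_ncase / n_out
    r2_exp_rev <- 64 / config$exposure_n
    Gamma_r <- sqrt(config$reverse_r2_ratio * r2_exp_rev /
                      (2 * maf_r * (1 - maf_r) * kf * (1 - kf)))
    maf <- c(maf, maf_r)
    alleles <- rbind(alleles, t(replicate(kr, sample(c("A", "C", "G", "T"), 2))))
    gamma <- c(gamma, gamma_r)
    Gamma <- c(Gamma, Gamma_r)
    alpha <- c(alpha, rep(0, kr))
    u <- c(u, rep(0, kr))
    reverse <- c(reverse, rep(TRUE, kr))
    k <- k + kr
  }

  rsid <- sprintf("rs%06d", seq_len(k))
  block <- rep(NA_integer_, k)
  is_proxy <- rep(FALSE, k)

  if (!is.null(config$ld_blocks)) {
    lb <- config$ld_blocks
    nb <- min(lb$n_blocks, k)
    r <- sqrt(lb$r2)
    for (b in seq_len(nb)) {
      np <- lb$block_size - 1
      if (np < 1) next
      idx <- length(rsid) + seq_len(np)
      rsid <- c(rsid, sprintf("rs%06d_p%d", b, seq_len(np)))
      maf <- c(maf, rep(maf[b], np))
      alleles <- rbind(alleles, matrix(rep(alleles[b, ], np), ncol = 2,
                                       byrow = TRUE))
      gamma <- c(gamma, rep(r * gamma[b], np))
      Gamma <- c(Gamma, rep(r * Gamma[b], np))
      alpha <- c(alpha, rep(r * alpha[b], np))
      u <- c(u, rep(0, np))
      reverse <- c(reverse, rep(reverse[b], np))
      is_proxy[idx] <- TRUE
      block[c(b, idx)] <- b
    }
    k <- length(rsid)
  }

  se_gamma <- 1 / sqrt(2 * maf * (1 - maf) * config$exposure_n)
  se_Gamma <- 1 / sqrt(2 * maf * (1 - maf) * config$outcome_ncase *
                         config$outcome_ncontrol / n_out)
  set.seed(stage_seed(seed, 4))
  gamma_hat <- gamma + stats::rnorm(k, 0, se_gamma)
  set.seed(stage_seed(seed, 5))
  Gamma_hat <- Gamma + stats::rnorm(k, 0, se_Gamma)

  base <- tibble::tibble(
    rsid = rsid,
    chrom = as.character(rep_len(1:22, k)),
    pos = seq_len(k) * 1e5,
    effect_allele = alleles[, 1], other_allele = alleles[, 2],
    eaf = maf)
  exposure <- summary_dataset(
    dplyr::mutate(base, beta = gamma_hat, se = se_gamma,
                  pvalue = pmax(2 * stats::pnorm(-abs(gamma_hat / se_gamma)), 1e-300),
                  n = config$exposure_n),
    trait_name = "simulated exposure", trait_type = "continuous",
    provenance = "simulate_two_sample")
  outcome <- summary_dataset(
    dplyr::mutate(base, beta = Gamma_hat, se = se_Gamma,
                  pvalue = pmax(2 * stats::pnorm(-abs(Gamma_hat / se_Gamma)), 1e-300),
                  n = n_out, ncase = config$outcome_ncase,
                  ncontrol = config$outcome_ncontrol),
    trait_name = "simulated outcome", trait_type = "binary",
    provenance = "simulate_two_sample")

  ld <- diag(1, k)
  dimnames(ld) <- list(rsid, rsid)
  if (!is.null(config$ld_blocks)) {
    for (b in unique(block[!is.na(block)])) {
      members <- which(block == b)
      ld[members, members] <- config$ld_blocks$r2
    }
    diag(ld) <- 1
  }

  truth <- tibble::tibble(rsid = rsid, maf = maf, gamma_true = gamma,
                          Gamma_true = Gamma, alpha = alpha, confounder = u,
                          reverse = reverse, is_proxy = is_proxy,
                          block = block)
  attr(truth, "config") <- config
  list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
}

#' Pair simulated datasets into a harmonised instrument table
#'
#' The generator emits both datasets on the same effect allele, so
#' harmonisation is the identity pairing; this helper builds the
#' [harmonise()]-format table directly (useful in replicate loops, where
#' re-deriving strand orientation per replicate adds nothing).
#'
#' @param sim Output of [simulate_two_sample()].
#' @return A harmonised instrument tibble.
#' @export
sim_instruments <- function(sim) {
  ex <- sim$exposure
  ou <- sim$outcome
  tibble::tibble(
    rsid = ex$rsid, effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    gamma = ex$beta, se_gamma = ex$se, Gamma = ou$beta, se_Gamma = ou$se,
    eaf_exposure = ex$eaf, eaf_outcome = ou$eaf,
    palindromic = purrr::map2_lgl(ex$effect_allele, ex$other_allele,
                                  is_palindromic),
    flipped = FALSE, excluded = FALSE, exclusion_reason = "none")
}

#' Named simulation presets mirroring the study's instrument sets
#'
#' One preset per epigenetic clock, with the published instrument count and
#' total variance explained ("hannum-like": 9 SNPs, 1.48%; "horvath-like":
#' 24, 4.41%; "phenoage-like": 11, 1.86%; "grimage-like": 4, 0.47%), the
#' exposure GWAS size of 34,710, and outcome sizes matching the colorectal
#' meta-analysis (GECCO + FinnGen: 61,153 cases, 241,353 controls).
#'
#' @param seed Seed stored in every preset.
#' @param theta True causal log-OR stored in every preset (default 0).
#' @return A named list of [sim_config()] objects.
#' @export
scenario_presets <- function(seed = 1, theta = 0) {
  clocks <- eaa_clocks()
  crc <- cancer_meta_sizes()
  crc <- crc[crc$cancer == "colorectal", ]
  presets <- purrr::map2(clocks$n_snps, clocks$r2, function(k, r2) {
    sim_config(n_snps = k, r2_total = r2, outcome_ncase = crc$ncase,
               outcome_ncontrol = crc$ncontrol, theta = theta, seed = seed)
  })
  stats::setNames(presets, c("hannum-like", "horvath-like", "phenoage-like",
                             "grimage-like"))
}

#' Read and write simulation configurations as YAML
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_sim_config` returns a [sim_config()]; `write_sim_config`
#'   returns `config` invisibly.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(config)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$maf_range <- as.numeric(x$maf_range)
  do.call(sim_config, x)
}

#' Write the per-SNP truth record as TSV
#' @param truth The `truth` tibble from [simulate_two_sample()].
#' @param path Output path.
#' @return `truth`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(truth)
}
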