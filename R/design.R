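#' Epigenetic-clock instrument summaries
#'
#' Published instrument counts and proportions of trait variance explained
#' (R-squared) for the four epigenetic age acceleration measures, from the
#' biological-ageing GWAS meta-analysis of 34,710 European-ancestry
#' participants: 9 independent genome-wide-significant SNPs for HannumAge
#' (1.48%), 24 for Intrinsic HorvathAge (4.41%), 11 for PhenoAge (1.86%)
#' and 4 for GrimAge (0.47%).
#'
#' @return A tibble `clock`, `n_snps`, `r2`, `exposure_n`.
#' @export
eaa_clocks <- function() {
  tibble::tibble(
    clock = c("HannumAge", "Intrinsic HorvathAge", "PhenoAge", "GrimAge"),
    n_snps = c(9L, 24L, 11L, 4L),
    r2 = c(0.0148, 0.0441, 0.0186, 0.0047),
    exposure_n = 34710L
  )
}

#' Cancer GWAS case/control counts by source
#'
#' Per-source case and control counts for the five cancer outcomes (breast,
#' ovarian, prostate, lung, colorectal) across the international consortia
#' (BCAC, OCAC, PRACTICAL, ILCCO, GECCO), UK Biobank and FinnGen.
#' `in_meta` marks the sources pooled in each cancer's meta-analysis:
#' colorectal excludes UK Biobank because its participants are already in
#' GECCO.
#'
#' @return A tibble `cancer`, `source`, `ncase`, `ncontrol`, `in_meta`.
#' @export
cancer_gwas_sources <- function() {
  x <- tibble::tribble(
    ~cancer,      ~source,      ~ncase, ~ncontrol,
    "breast",     "BCAC",       122977, 105974,
    "breast",     "UK Biobank",  13879, 198523,
    "breast",     "FinnGen",      8401,  99321,
    "ovarian",    "OCAC",        25509,  40941,
    "ovarian",    "UK Biobank",   1218, 198523,
    "ovarian",    "FinnGen",       719,  99321,
    "prostate",   "PRACTICAL",   79148,  61106,
    "prostate",   "UK Biobank",   9132, 173493,
    "prostate",   "FinnGen",      6311,  74685,
    "lung",       "ILCCO",       11348,  15861,
    "lung",       "UK Biobank",   2671, 372016,
    "lung",       "FinnGen",      1681, 173933,
    "colorectal", "GECCO",       58131,  67347,
    "colorectal", "UK Biobank",   5657, 372016,
    "colorectal", "FinnGen",      3022, 174006
  )
  dplyr::mutate(x, in_meta = !(.data$cancer == "colorectal" &
                                 .data$source == "UK Biobank"))
}

#' Pooled case/control totals per cancer meta-analysis
#'
#' Sums [cancer_gwas_sources()] over the sources included in each cancer's
#' meta-analysis (colorectal: GECCO + FinnGen only).
#'
#' @return A tibble `cancer`, `ncase`, `ncontrol`, `n`, `case_fraction`.
#' @export
cancer_meta_sizes <- function() {
  cancer_gwas_sources() |>
    dplyr::filter(.data$in_meta) |>
    dplyr::group_by(.data$cancer) |>
    dplyr::summarise(ncase = sum(.data$ncase), ncontrol = sum(.data$ncontrol),
                     .groups = "drop") |>
    dplyr::mutate(n = .data$ncase + .data$ncontrol,
                  case_fraction = .data$ncase / .data$n)
}
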