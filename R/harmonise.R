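#' Harmonise exposure and outcome summary statistics to a common effect allele
#'
#' For every rsid shared by the two datasets, re-orients the outcome
#' association onto the exposure's effect allele. Allele pairs that match
#' after swapping are sign-flipped (`Gamma = -beta`, `eaf -> 1 - eaf`);
#' non-palindromic pairs matching on the opposite strand are complemented
#' first. Palindromic SNPs (A/T or C/G) cannot be strand-resolved from
#' alleles alone: when the minor allele frequency is below
#' `palindromic_maf_threshold` in both datasets the orientation is inferred
#' by matching minor alleles, otherwise the SNP is excluded
#' (`palindromic_high_maf`). Irreconcilable allele pairs are excluded with
#' reason `allele_mismatch` (disjoint alleles) or `strand_mismatch` (partial
#' overlap). Indels pass through with palindromy undefined and
#' strand-complement matching disabled.
#'
#' @param exposure,outcome [summary_dataset()] objects. `gamma` is the
#'   SNP-exposure effect, `Gamma` the SNP-outcome effect.
#' @param palindromic_maf_threshold Palindromic SNPs with MAF at or above
#'   this value in either dataset are excluded (default 0.3; the comparison
#'   is strict: MAF < threshold is aligned).
#' @return A tibble with one row per shared rsid: `rsid`, `effect_allele`,
#'   `other_allele`, `gamma`, `se_gamma`, `Gamma`, `se_Gamma`,
#'   `eaf_exposure`, `eaf_outcome`, `palindromic`, `flipped`, `excluded`,
#'   `exclusion_reason`.
#' @export
harmonise <- function(exposure, outcome, palindromic_maf_threshold = 0.3) {
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0) {
    stop("no shared rsids between exposure and outcome", call. = FALSE)
  }
  ex <- tibble::as_tibble(exposure)[match(shared, exposure$rsid), ]
  ou <- tibble::as_tibble(outcome)[match(shared, outcome$rsid), ]
  rows <- purrr::map(seq_along(shared), function(i) {
    harmonise_one(ex[i, ], ou[i, ], palindromic_maf_threshold)
  })
  dplyr::bind_rows(rows)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

is_snv <- function(a) a %in% names(.complement)

is_palindromic <- function(a1, a2) {
  is_snv(a1) && is_snv(a2) && .complement[[a1]] == a2
}

# One shared variant: orient the outcome onto the exposure's effect allele.
harmonise_one <- function(ex, ou, maf_thresh) {
  e1 <- ex$effect_allele; e2 <- ex$other_allele
  o1 <- ou$effect_allele; o2 <- ou$other_allele
  snv <- is_snv(e1) && is_snv(e2) && is_snv(o1) && is_snv(o2)
  pal <- snv && is_palindromic(e1, e2)

  out <- tibble::tibble(
    rsid = ex$rsid, effect_allele = e1, other_allele = e2,
    gamma = ex$beta, se_gamma = ex$se, Gamma = NA_real_, se_Gamma = NA_real_,
    eaf_exposure = ex$eaf, eaf_outcome = NA_real_,
    palindromic = pal, flipped = FALSE,
    excluded = FALSE, exclusion_reason = "none"
  )
  exclude <- function(reason) {
    out$excluded <- TRUE
    out$exclusion_reason <- reason
    out
  }
  take <- function(sign_flip) {
    out$Gamma <- if (sign_flip) -ou$beta else ou$beta
    out$se_Gamma <- ou$se
    out$eaf_outcome <- if (sign_flip) 1 - ou$eaf else ou$eaf
    out$flipped <- sign_flip
    out
  }

  if (pal) {
    # Strand is unresolvable from alleles; use minor-allele agreement.
    if (is.na(ex$eaf) || is.na(ou$eaf)) return(exclude("palindromic_missing_eaf"))
    maf_ex <- pmin(ex$eaf, 1 - ex$eaf)
    maf_ou <- pmin(ou$eaf, 1 - ou$eaf)
    if (maf_ex >= maf_thresh || maf_ou >= maf_thresh) {
      return(exclude("palindromic_high_maf"))
    }
    if (!setequal(c(o1, o2), c(e1, e2))) return(exclude("allele_mismatch"))
    # Nominal orientation: as-reported if labels agree, else swapped.
    nominal_flip <- o1 != e1
    eaf_nominal <- if (nominal_flip) 1 - ou$eaf else ou$eaf
    # Flip again if the effect allele is minor in one dataset and major in
    # the other (strand-flipped report).
    freq_disagree <- (ex$eaf < 0.5) != (eaf_nominal < 0.5)
    return(take(xor(nominal_flip, freq_disagree)))
  }

  if (o1 == e1 && o2 == e2) return(take(FALSE))
  if (o1 == e2 && o2 == e1) return(take(TRUE))
  if (snv) {
    c1 <- .complement[[o1]]; c2 <- .complement[[o2]]
    if (c1 == e1 && c2 == e2) return(take(FALSE))
    if (c1 == e2 && c2 == e1) return(take(TRUE))
    if (length(intersect(c(o1, o2), c(e1, e2))) == 1 ||
        length(intersect(c(c1, c2), c(e1, e2))) == 1) {
      return(exclude("strand_mismatch"))
    }
  }
  exclude("allele_mismatch")
}

#' Write a harmonised instrument table as TSV
#'
#' Columns are written in the fixed order documented in [harmonise()].
#'
#' @param x Harmonised tibble from [harmonise()].
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_harmonised <- function(x, path) {
  cols <- c("rsid", "effect_allele", "other_allele", "gamma", "se_gamma",
            "Gamma", "se_Gamma", "eaf_exposure", "eaf_outcome", "palindromic",
            "flipped", "excluded", "exclusion_reason")
  readr::write_tsv(x[, cols], path, progress = FALSE)
  invisible(x)
}
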