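#' Construct a validated summary-statistics dataset
#'
#' A summary dataset is a tibble with one row per variant and the columns
#' `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `pvalue`, `n` and (for binary traits) `ncase`, `ncontrol`, carrying
#' the trait name, trait type and provenance as attributes. `beta` is the
#' per-allele effect: trait units for continuous traits, log odds ratio for
#' binary traits.
#'
#' @param x A data frame with at least `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`. Missing optional columns
#'   (`chrom`, `pos`, `eaf`, `n`, `ncase`, `ncontrol`) are added as `NA`.
#' @param trait_name Label for the trait (e.g. `"GrimAge acceleration"`).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param provenance Free-text source label.
#' @return A tibble of class `summary_dataset`.
#' @export
summary_dataset <- function(x, trait_name = "trait",
                            trait_type = c("continuous", "binary"),
                            provenance = "") {
  trait_type <- match.arg(trait_type)
  x <- tibble::as_tibble(x)
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("chrom", "pos", "eaf", "n", "ncase", "ncontrol")) {
    if (!col %in% names(x)) x[[col]] <- NA
  }
  x <- dplyr::mutate(
    x,
    rsid = as.character(.data$rsid),
    chrom = as.character(.data$chrom),
    pos = as.numeric(.data$pos),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    dplyr::across(dplyr::all_of(c("eaf", "beta", "se", "pvalue", "n",
                                  "ncase", "ncontrol")), as.numeric)
  )
  x <- x[, c("rsid", "chrom", "pos", "effect_allele", "other_allele", "eaf",
             "beta", "se", "pvalue", "n", "ncase", "ncontrol")]
  validate_sumstats(x)
  dup <- x$rsid[duplicated(x$rsid)]
  if (length(dup) > 0) {
    stop("duplicate rsid(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  structure(x,
            class = c("summary_dataset", class(x)),
            trait_name = trait_name,
            trait_type = trait_type,
            provenance = provenance)
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s), %d variants%s\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x),
              if (nzchar(attr(x, "provenance") %||% ""))
                paste0(" [", attr(x, "provenance"), "]") else ""))
  NextMethod()
}

#' Trait metadata accessors
#' @param x A `summary_dataset`.
#' @return A string (`trait_name`, `trait_type`, `provenance`).
#' @export
trait_name <- function(x) attr(x, "trait_name") %||% "trait"

#' @rdname trait_name
#' @export
trait_type <- function(x) attr(x, "trait_type") %||% "continuous"

# Row-level invariant checks; reports offending row numbers.
validate_sumstats <- function(x) {
  bad <- function(cond) which(!is.na(cond) & cond)
  problems <- c(
    if (length(i <- bad(x$se <= 0)) > 0)
      sprintf("row %d: se must be > 0", i),
    if (length(i <- bad(x$effect_allele == x$other_allele)) > 0)
      sprintf("row %d: effect_allele equals other_allele", i),
    if (length(i <- bad(x$eaf <= 0 | x$eaf >= 1)) > 0)
      sprintf("row %d: eaf outside (0,1)", i),
    if (length(i <- bad(x$pvalue <= 0 | x$pvalue > 1)) > 0)
      sprintf("row %d: pvalue outside (0,1]", i),
    if (length(i <- which(!is.na(x$ncase) & !is.na(x$ncontrol) & !is.na(x$n) &
                          x$ncase + x$ncontrol != x$n)) > 0)
      sprintf("row %d: ncase + ncontrol != n", i)
  )
  if (length(problems) > 0) {
    stop("invalid summary statistics:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(x)
}

# Canonical column names and the dialect synonyms recognised by default.
.default_column_map <- list(
  rsid = c("rsid", "snp", "rs_id", "variant_id", "markername", "id"),
  chrom = c("chrom", "chr", "chromosome"),
  pos = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1", "alt"),
  other_allele = c("other_allele", "oa", "a2", "allele2", "ref",
                   "non_effect_allele"),
  eaf = c("eaf", "effect_allele_frequency", "af", "freq", "maf"),
  beta = c("beta", "b", "effect", "effect_size", "loghr", "logor"),
  se = c("se", "standard_error", "stderr", "sebeta"),
  pvalue = c("pvalue", "p", "pval", "p_value"),
  n = c("n", "samplesize", "sample_size", "n_total"),
  ncase = c("ncase", "n_case", "ncases", "cases"),
  ncontrol = c("ncontrol", "n_control", "ncontrols", "controls")
)

#' Read GWAS summary statistics from delimited text
#'
#' Reads tab- or comma-delimited text with a header. Column names are matched
#' case-insensitively against common GWAS dialects (`BETA`/`b`,
#' `SE`/`standard_error`, ...); `column_map` overrides the defaults, e.g.
#' `column_map = c(rsid = "MarkerName", pvalue = "P.value")`.
#'
#' @param path File path.
#' @param trait_name,trait_type,provenance Passed to [summary_dataset()].
#' @param column_map Named character vector mapping canonical names to file
#'   column names.
#' @param delim Field delimiter; guessed from the first line when `NULL`.
#' @return A [summary_dataset()].
#' @export
read_sumstats <- function(path, trait_name = basename(path),
                          trait_type = c("continuous", "binary"),
                          column_map = NULL, provenance = path,
                          delim = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(delim)) {
    header <- readLines(path, n = 1)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  lookup <- .default_column_map
  for (nm in names(column_map)) lookup[[nm]] <- tolower(column_map[[nm]])
  out <- list()
  lowered <- tolower(names(raw))
  for (canon in names(lookup)) {
    hit <- which(lowered %in% lookup[[canon]])
    if (length(hit) > 0) out[[canon]] <- raw[[hit[1]]]
  }
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(mandatory, names(out))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  summary_dataset(tibble::as_tibble(out), trait_name = trait_name,
                  trait_type = trait_type, provenance = provenance)
}

#' Write summary statistics as tab-delimited text
#'
#' @param x A `summary_dataset` (or compatible tibble).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
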