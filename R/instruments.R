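#' Read a pairwise LD (r-squared) reference
#'
#' Accepts either long format (three columns: `rsid_a`, `rsid_b`, `r2`) or a
#' square matrix with rsids as header row and first column. Returns a
#' symmetric matrix with unit diagonal; pairs absent from a long-format file
#' default to r-squared 0.
#'
#' @param path Delimited text file (tab or comma).
#' @return A symmetric numeric matrix with rsid dimnames.
#' @export
read_ld <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(x) == 3 && is.numeric(x[[3]])) {
    ids <- sort(unique(c(as.character(x[[1]]), as.character(x[[2]]))))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    ia <- match(as.character(x[[1]]), ids)
    ib <- match(as.character(x[[2]]), ids)
    m[cbind(ia, ib)] <- x[[3]]
    m[cbind(ib, ia)] <- x[[3]]
  } else {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1])
    dimnames(m) <- list(ids, colnames(m))
    m <- m[, ids, drop = FALSE]
  }
  validate_ld(m)
}

#' Write an LD reference in long format
#' @param ld Symmetric r-squared matrix.
#' @param path Output path.
#' @return `ld`, invisibly.
#' @export
write_ld <- function(ld, path) {
  ids <- rownames(ld)
  idx <- which(upper.tri(ld) & ld > 0, arr.ind = TRUE)
  # Diagonal rows keep isolated variants present in the sparse long format.
  readr::write_tsv(
    tibble::tibble(rsid_a = c(ids, ids[idx[, 1]]),
                   rsid_b = c(ids, ids[idx[, 2]]),
                   r2 = c(rep(1, length(ids)), ld[idx])),
    path, progress = FALSE)
  invisible(ld)
}

validate_ld <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop("LD r2 outside [0,1]", call. = FALSE)
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8) stop("LD matrix not symmetric", call. = FALSE)
  diag(m) <- 1
  m
}

# r2 between one rsid and a set; absent pairs are independent (r2 = 0).
ld_r2 <- function(ld, a, b) {
  out <- stats::setNames(numeric(length(b)), b)
  if (is.null(ld) || !a %in% rownames(ld)) return(out)
  hit <- intersect(b, colnames(ld))
  out[hit] <- ld[a, hit]
  out
}

#' Filter variants at a genome-wide significance threshold
#'
#' @param dataset A [summary_dataset()].
#' @param p_threshold Retain variants with `pvalue` strictly below this
#'   (default 5e-8).
#' @return The subset, still a `summary_dataset`.
#' @export
select_significant <- function(dataset, p_threshold = 5e-8) {
  keep <- dataset$pvalue < p_threshold
  out <- dataset[keep, ]
  if (!any(keep)) message("no variants below p = ", p_threshold)
  out
}

#' Greedy LD clumping
#'
#' Orders candidates by ascending p-value (ties: larger `|beta/se|`, then
#' rsid) and accepts a candidate iff its r-squared with every
#' already-accepted variant is below `r2_threshold`. Pairs absent from the
#' LD reference are treated as independent (r-squared 0) with a warning;
#' `ld = NULL` treats all candidates as independent.
#'
#' @param candidates A `summary_dataset` subset (e.g. from
#'   [select_significant()]).
#' @param ld Symmetric r-squared matrix, or `NULL`.
#' @param r2_threshold Pairwise independence bound (default 0.001).
#' @return The retained subset in acceptance order.
#' @export
clump <- function(candidates, ld = NULL, r2_threshold = 0.001) {
  if (nrow(candidates) == 0) return(candidates)
  z <- abs(candidates$beta / candidates$se)
  ord <- order(candidates$pvalue, -z, candidates$rsid)
  cand <- candidates[ord, ]
  if (!is.null(ld)) {
    absent <- setdiff(cand$rsid, rownames(ld))
    if (length(absent) > 0) {
      warning(length(absent), " candidate(s) absent from the LD reference; ",
              "treated as independent", call. = FALSE)
    }
  }
  accepted <- character(0)
  for (i in seq_len(nrow(cand))) {
    r2 <- ld_r2(ld, cand$rsid[i], accepted)
    if (all(r2 < r2_threshold)) accepted <- c(accepted, cand$rsid[i])
  }
  cand[match(accepted, cand$rsid), ]
}

#' Find LD proxies for instruments missing from an outcome dataset
#'
#' For each missing rsid, returns the outcome variant with maximal
#' r-squared, subject to `r2 > r2_min` (strict). Ties are broken by smaller
#' outcome p-value, then lexicographic rsid. Instruments with no qualifying
#' proxy are omitted from the result.
#'
#' @param missing Character vector of instrument rsids absent from the
#'   outcome.
#' @param outcome A `summary_dataset` supplying candidate proxies.
#' @param ld Symmetric r-squared matrix.
#' @param r2_min Minimum (exclusive) proxy r-squared, default 0.8.
#' @return A tibble `rsid`, `proxy_rsid`, `r2`.
#' @export
substitute_proxies <- function(missing, outcome, ld, r2_min = 0.8) {
  rows <- purrr::map(missing, function(m) {
    r2 <- ld_r2(ld, m, setdiff(outcome$rsid, m))
    r2 <- r2[r2 > r2_min]
    if (length(r2) == 0) return(NULL)
    cand <- names(r2)
    p <- outcome$pvalue[match(cand, outcome$rsid)]
    best <- cand[order(-r2, p, cand)][1]
    tibble::tibble(rsid = m, proxy_rsid = best, r2 = unname(r2[best]))
  })
  dplyr::bind_rows(rows)
}

#' Per-SNP variance explained and instrument strength
#'
#' For each variant, the proportion of trait variance explained is
#' \deqn{r^2_j = \frac{2\beta^2 MAF(1-MAF)}{2\beta^2 MAF(1-MAF) +
#'   2 N\, MAF(1-MAF)\, SE^2}}
#' with `MAF = min(eaf, 1 - eaf)`, and the instrument F-statistic is
#' \eqn{F_j = r^2_j (N-2) / (1 - r^2_j)}. `F <= 10` flags a conventionally
#' weak instrument. The total variance explained by a set is the sum of the
#' per-SNP values.
#'
#' @param snps A `summary_dataset` (or tibble with `beta`, `se`, `eaf`, `n`).
#' @return The input with columns `r2`, `f_stat`, `weak` added; total
#'   R-squared and the F summary are attached as attributes `r2_total` and
#'   `f_summary`.
#' @export
instrument_strength <- function(snps) {
  x <- tibble::as_tibble(snps)
  if (any(is.na(x$eaf)) || any(is.na(x$n))) {
    stop("eaf and n are required to compute instrument strength; missing for: ",
         paste(x$rsid[is.na(x$eaf) | is.na(x$n)], collapse = ", "),
         call. = FALSE)
  }
  maf <- pmin(x$eaf, 1 - x$eaf)
  num <- 2 * x$beta^2 * maf * (1 - maf)
  x$r2 <- num / (num + 2 * x$n * maf * (1 - maf) * x$se^2)
  x$f_stat <- x$r2 * (x$n - 2) / (1 - x$r2)
  x$weak <- x$f_stat <= 10
  attr(x, "r2_total") <- sum(x$r2)
  attr(x, "f_summary") <- c(median = stats::median(x$f_stat),
                            min = min(x$f_stat), max = max(x$f_stat))
  x
}
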