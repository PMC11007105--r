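# Canonical GWAS record columns used throughout the package. A record table is
# a plain data.frame with one row per SNP:
#   snp_id, effect_allele, other_allele, eaf, beta, se, pval, n
# eaf and n may be NA (outcome GWAS files often omit frequency; n may fall back
# to a study-level constant).

.GWAS_COLS <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta",
                "se", "pval", "n")

.NUCLEOTIDES <- c("A", "C", "G", "T")

#' Default column mapping for summary-statistics files
#'
#' Maps the short config keys (`snp`, `ea`, `oa`, `eaf`, `beta`, `se`, `p`,
#' `n`) onto the column names expected in an input file. Override entries to
#' match your file's header.
#'
#' @return Named character vector of file column names keyed by config key.
#' @export
default_column_map <- function() {
  c(snp = "snp_id", ea = "effect_allele", oa = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", p = "pval", n = "n")
}

#' Read and validate GWAS summary statistics
#'
#' Reads a delimited text file (tab or comma, header required) of per-SNP
#' summary associations, renames columns via `column_map`, and validates each
#' record: alleles must be single nucleotides with effect != other, `se > 0`,
#' `0 < eaf < 1` (when present), `pval` in (0, 1]. Invalid records are dropped
#' and counted in the load report attached as attribute `"load_report"`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping config keys
#'   (`snp`, `ea`, `oa`, `beta`, `se`, `p`, and optionally `eaf`, `n`) to the
#'   file's column names. Defaults to [default_column_map()].
#' @param study_n Optional study-level sample size used when the file has no
#'   per-SNP `n` column (or the mapped column is absent).
#' @return A validated record `data.frame` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, and an
#'   attribute `load_report` (data.frame of `reason`, `n_dropped`).
#' @export
read_summary_stats <- function(path, column_map = default_column_map(),
                               study_n = NULL) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  required <- c("snp", "ea", "oa", "beta", "se", "p")
  missing_keys <- setdiff(required, names(column_map))
  if (length(missing_keys))
    stop("column_map lacks required keys: ", paste(missing_keys, collapse = ", "))
  missing_cols <- setdiff(unname(column_map[required]), names(raw))
  if (length(missing_cols))
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))

  pick <- function(key) {
    col <- column_map[[key]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NULL
  }
  rec <- data.frame(
    snp_id        = as.character(pick("snp")),
    effect_allele = toupper(as.character(pick("ea"))),
    other_allele  = toupper(as.character(pick("oa"))),
    beta          = as.numeric(pick("beta")),
    se            = as.numeric(pick("se")),
    pval          = as.numeric(pick("p")),
    stringsAsFactors = FALSE
  )
  eaf <- pick("eaf")
  rec$eaf <- if (is.null(eaf)) NA_real_ else as.numeric(eaf)
  nn <- pick("n")
  rec$n <- if (is.null(nn)) NA_real_ else as.numeric(nn)
  if (!is.null(study_n)) rec$n[is.na(rec$n)] <- as.numeric(study_n)
  rec <- rec[.GWAS_COLS]
  validate_gwas_records(rec)
}

#' Validate GWAS records against the record invariants
#'
#' @param rec Record data.frame (see [read_summary_stats()]).
#' @return The subset of valid rows, with a `load_report` attribute counting
#'   drops per reason.
#' @export
validate_gwas_records <- function(rec) {
  reason <- rep(NA_character_, nrow(rec))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, why, reason)
  }
  reason <- flag(!(rec$effect_allele %in% .NUCLEOTIDES) |
                 !(rec$other_allele %in% .NUCLEOTIDES), "invalid allele")
  reason <- flag(rec$effect_allele == rec$other_allele, "identical alleles")
  reason <- flag(!is.finite(rec$beta), "missing beta")
  reason <- flag(!is.finite(rec$se) | rec$se <= 0, "nonpositive se")
  reason <- flag(!is.finite(rec$pval) | rec$pval <= 0 | rec$pval > 1,
                 "pval out of range")
  # eaf/n are optional: only range-check when present
  bad_eaf <- !is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1)
  reason <- ifelse(is.na(reason) & bad_eaf, "eaf out of range", reason)
  bad_n <- !is.na(rec$n) & rec$n <= 2
  reason <- ifelse(is.na(reason) & bad_n, "sample size too small", reason)

  keep <- is.na(reason)
  report <- if (all(keep)) {
    data.frame(reason = character(), n_dropped = integer())
  } else {
    tab <- table(reason[!keep])
    data.frame(reason = names(tab), n_dropped = as.integer(tab),
               row.names = NULL)
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) stop("no valid records after validation")
  attr(out, "load_report") <- report
  out
}

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) variant has alleles that are reverse
#' complements of each other: A/T or C/G. For such pairs the strand cannot be
#' resolved from the alleles alone.
#'
#' @param effect_allele,other_allele Character vectors of single nucleotides.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele); b <- toupper(other_allele)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Joins the two record tables on `snp_id` and aligns every outcome effect to
#' the exposure's effect allele. If the outcome's alleles are swapped relative
#' to the exposure, the outcome beta is negated and its eaf replaced by
#' `1 - eaf` (`flipped = TRUE`). SNPs whose allele sets do not match even after
#' considering a swap are dropped as non-concordant. Palindromic variants are
#' dropped under the default strict policy; under `maf_infer` they are retained
#' only when both allele frequencies lie on the same side of 0.5 and both are
#' outside `[maf_threshold, 1 - maf_threshold]`, i.e. when frequency makes the
#' strand unambiguous.
#'
#' @param exposure,outcome Validated record data.frames.
#' @param palindrome_policy `"strict_remove"` (default) or `"maf_infer"`.
#' @param maf_threshold Ambiguity band half-width for `maf_infer`
#'   (default 0.42: frequencies in (0.42, 0.58) are considered ambiguous).
#' @param n_exp,n_out Optional study-level sample sizes; default to the median
#'   per-record `n` of each side.
#' @return An object of class `harmonized_set`: a list with per-SNP vectors
#'   `snp_ids`, `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`,
#'   `eaf_out`, `flipped`, scalars `n_exp`, `n_out`, and a `dropped`
#'   data.frame (`snp_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("strict_remove", "maf_infer"),
                      maf_threshold = 0.42,
                      n_exp = NULL, n_out = NULL) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (anyDuplicated(exposure$snp_id))
    stop("duplicate snp_id in exposure records")
  if (anyDuplicated(outcome$snp_id))
    stop("duplicate snp_id in outcome records")
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0L)
    stop("no shared SNPs between exposure and outcome")

  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  aligned <- ou$effect_allele == ex$effect_allele &
             ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
             ou$other_allele == ex$effect_allele
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  # for palindromes an allele swap is indistinguishable from a strand flip, so
  # swap detection is only trusted for non-palindromic pairs
  concordant <- aligned | (swapped & !pal)

  beta_out <- ifelse(swapped & !pal, -ou$beta, ou$beta)
  eaf_out  <- ifelse(swapped & !pal, 1 - ou$eaf, ou$eaf)
  flipped  <- swapped & !pal

  reason <- rep(NA_character_, length(shared))
  reason[!concordant & !pal] <- "non-concordant alleles"
  if (palindrome_policy == "strict_remove") {
    reason[pal & is.na(reason)] <- "palindromic"
  } else {
    amb <- pal & is.na(reason)
    lo <- maf_threshold; hi <- 1 - maf_threshold
    ok <- !is.na(ex$eaf) & !is.na(eaf_out) &
      ((ex$eaf < lo & eaf_out < lo) | (ex$eaf > hi & eaf_out > hi))
    reason[amb & !ok] <- "palindromic"
  }

  keep <- is.na(reason)
  dropped <- data.frame(snp_id = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (!any(keep)) stop("no SNPs retained after harmonization")

  scalar_n <- function(given, n) {
    if (!is.null(given)) return(as.numeric(given))
    if (all(is.na(n))) NA_real_ else stats::median(n, na.rm = TRUE)
  }
  structure(list(
    snp_ids  = shared[keep],
    beta_exp = ex$beta[keep],
    se_exp   = ex$se[keep],
    eaf_exp  = ex$eaf[keep],
    pval_exp = ex$pval[keep],
    beta_out = beta_out[keep],
    se_out   = ou$se[keep],
    eaf_out  = eaf_out[keep],
    flipped  = flipped[keep],
    n_exp    = scalar_n(n_exp, ex$n),
    n_out    = scalar_n(n_out, ou$n),
    dropped  = dropped
  ), class = "harmonized_set")
}

#' Number of instruments in a harmonized set
#' @param h A `harmonized_set`.
#' @return Integer count of retained SNPs.
#' @export
n_instruments <- function(h) length(h$snp_ids)

#' Subset a harmonized set by a logical or index vector
#' @param h A `harmonized_set`.
#' @param keep Logical or integer index over the retained SNPs.
#' @param reason Drop reason recorded for removed SNPs.
#' @return A `harmonized_set` with only the kept SNPs; `dropped` is extended.
#' @export
subset_harmonized <- function(h, keep, reason = "filtered") {
  if (is.logical(keep)) keep <- which(keep)
  per_snp <- c("snp_ids", "beta_exp", "se_exp", "eaf_exp", "pval_exp",
               "beta_out", "se_out", "eaf_out", "flipped")
  gone <- setdiff(seq_along(h$snp_ids), keep)
  if (length(gone))
    h$dropped <- rbind(h$dropped,
                       data.frame(snp_id = h$snp_ids[gone], reason = reason,
                                  stringsAsFactors = FALSE))
  for (f in per_snp) h[[f]] <- h[[f]][keep]
  h
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %d SNP(s), %d flipped, %d dropped\n",
              length(x$snp_ids), sum(x$flipped), nrow(x$dropped)))
  invisible(x)
}

#' Convert a harmonized set to a data.frame (one row per retained SNP)
#' @param x A `harmonized_set`.
#' @param ... Unused.
#' @return data.frame of per-SNP harmonized effects.
#' @export
as.data.frame.harmonized_set <- function(x, ...) {
  data.frame(snp_id = x$snp_ids, beta_exp = x$beta_exp, se_exp = x$se_exp,
             eaf_exp = x$eaf_exp, pval_exp = x$pval_exp,
             beta_out = x$beta_out, se_out = x$se_out, eaf_out = x$eaf_out,
             flipped = x$flipped, stringsAsFactors = FALSE)
}

#' Write a harmonization report (actions and drop reasons) as TSV
#' @param h A `harmonized_set`.
#' @param path Output file path.
#' @export
write_harmonization_report <- function(h, path) {
  kept <- data.frame(snp_id = h$snp_ids,
                     action = ifelse(h$flipped, "flipped", "kept"),
                     reason = "", stringsAsFactors = FALSE)
  drp <- if (nrow(h$dropped)) {
    data.frame(snp_id = h$dropped$snp_id, action = "dropped",
               reason = h$dropped$reason, stringsAsFactors = FALSE)
  } else NULL
  utils::write.table(rbind(kept, drp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
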