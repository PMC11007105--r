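# Instrument selection and quality control: genome-wide significance
# threshold, greedy LD clumping, confounder exclusion list, F-statistic
# strength filter. QC order in the pipeline mirrors the usual workflow:
# p-threshold -> clump -> exclusion list -> harmonize -> F filter.

#' Keep genome-wide significant associations
#'
#' @param records Validated record data.frame.
#' @param p_threshold Significance cutoff; default `5e-8`. Retention uses a
#'   strict `pval < p_threshold` comparison.
#' @return Subset of `records` in original order.
#' @export
select_genome_wide <- function(records, p_threshold = 5e-8) {
  records[records$pval < p_threshold, , drop = FALSE]
}

#' Build a pairwise LD table
#'
#' @param pairs data.frame with columns `snp_a`, `snp_b`, `r2`; symmetry and
#'   the `r2(a, a) = 1` diagonal are implied and need not be listed.
#' @param positions Optional data.frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based base pairs) used for the clumping window test.
#' @return Object of class `ld_table`.
#' @export
ld_table <- function(pairs = NULL, positions = NULL) {
  if (is.null(pairs))
    pairs <- data.frame(snp_a = character(), snp_b = character(),
                        r2 = numeric())
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) stop("r2 must lie in [0, 1]")
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$snp_a[i]; b <- pairs$snp_b[i]
    key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    assign(key, pairs$r2[i], envir = lookup)
  }
  structure(list(pairs = pairs, positions = positions, lookup = lookup),
            class = "ld_table")
}

#' Look up pairwise r-squared in an LD table
#'
#' Missing pairs are treated as unlinked (`r2 = 0`); the diagonal is 1.
#'
#' @param ld An `ld_table`.
#' @param a,b SNP identifiers (scalars).
#' @return Numeric r² in `[0, 1]`.
#' @export
ld_r2 <- function(ld, a, b) {
  if (a == b) return(1)
  key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
  val <- get0(key, envir = ld$lookup, ifnotfound = 0)
  as.numeric(val)
}

#' Read an LD table from TSV files
#'
#' @param path 3-column TSV (`snp_a`, `snp_b`, `r2`) with header.
#' @param positions_path Optional 3-column TSV (`snp_id`, `chrom`, `pos`).
#' @return An `ld_table`.
#' @export
read_ld_table <- function(path, positions_path = NULL) {
  pairs <- data.table::fread(path, header = TRUE, data.table = FALSE,
                             showProgress = FALSE)
  names(pairs)[1:3] <- c("snp_a", "snp_b", "r2")
  pos <- NULL
  if (!is.null(positions_path)) {
    pos <- data.table::fread(positions_path, header = TRUE,
                             data.table = FALSE, showProgress = FALSE)
    names(pos)[1:3] <- c("snp_id", "chrom", "pos")
  }
  ld_table(pairs, pos)
}

#' Write an LD table's pairs to TSV
#' @param ld An `ld_table`.
#' @param path Output path.
#' @export
write_ld_table <- function(ld, path) {
  utils::write.table(ld$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Greedy p-value-ranked LD clumping
#'
#' PLINK-style greedy selection: records are ranked by ascending p-value
#' (ties broken by lexicographic `snp_id`, making the result independent of
#' input order); the best remaining SNP is kept and every other remaining SNP
#' with `r2 >= r2_threshold` against it — and, when positions are available
#' for both SNPs, within `window_kb` on the same chromosome — is discarded.
#' When positions are absent the r² test alone decides.
#'
#' @param records Record data.frame with p-values.
#' @param ld An `ld_table`; missing pairs count as `r2 = 0`.
#' @param r2_threshold LD pruning threshold; default 0.001.
#' @param window_kb Clumping window in kilobases; default 10000.
#' @return The retained records, in the original input order.
#' @export
clump <- function(records, ld, r2_threshold = 0.001, window_kb = 10000) {
  if (nrow(records) <= 1L) return(records)
  ord <- order(records$pval, records$snp_id)
  ids <- records$snp_id[ord]
  pos <- ld$positions
  within_window <- function(a, b) {
    if (is.null(pos)) return(TRUE)
    ia <- match(a, pos$snp_id); ib <- match(b, pos$snp_id)
    if (is.na(ia) || is.na(ib)) return(TRUE)  # unknown position: r2 decides
    pos$chrom[ia] == pos$chrom[ib] &&
      abs(pos$pos[ia] - pos$pos[ib]) <= window_kb * 1000
  }
  alive <- rep(TRUE, length(ids))
  kept <- character()
  for (i in seq_along(ids)) {
    if (!alive[i]) next
    kept <- c(kept, ids[i])
    if (i < length(ids)) {
      for (j in seq(i + 1L, length(ids))) {
        if (alive[j] &&
            ld_r2(ld, ids[i], ids[j]) >= r2_threshold &&
            within_window(ids[i], ids[j]))
          alive[j] <- FALSE
      }
    }
  }
  records[records$snp_id %in% kept, , drop = FALSE]
}

#' Per-SNP variance explained and F statistic
#'
#' Uses the standardized-trait approximation
#' `R² = 2·EAF·(1−EAF)·beta²` and `F = R²·(N−2)/(1−R²)`.
#' Vectorized over SNPs.
#'
#' @param eaf Effect-allele frequency in (0, 1).
#' @param beta Per-allele effect on the standardized trait scale.
#' @param n Sample size (> 2).
#' @return List with numeric vectors `r2` and `f`.
#' @export
compute_f_statistic <- function(eaf, beta, n) {
  stopifnot(all(eaf > 0 & eaf < 1, na.rm = TRUE), all(n > 2, na.rm = TRUE))
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  if (any(r2 >= 1, na.rm = TRUE))
    stop("per-SNP R-squared >= 1: beta appears to be on the wrong scale")
  f <- r2 * (n - 2) / (1 - r2)
  list(r2 = r2, f = f)
}

#' Annotate records with instrument strength
#'
#' Adds `r2` and `f` columns. When `eaf` is missing for a record the
#' approximation `f = (beta/se)^2` is used instead and flagged in the
#' `f_approx` column (this keeps frequency-less outcome GWAS usable as
#' exposures in reverse MR).
#'
#' @param records Record data.frame.
#' @param study_n Fallback sample size for records with missing `n`.
#' @return `records` with `r2`, `f`, `f_approx` columns appended.
#' @export
add_instrument_strength <- function(records, study_n = NULL) {
  n <- records$n
  if (!is.null(study_n)) n[is.na(n)] <- as.numeric(study_n)
  have <- !is.na(records$eaf) & !is.na(n)
  records$r2 <- NA_real_
  records$f <- (records$beta / records$se)^2
  records$f_approx <- !have
  if (any(have)) {
    fs <- compute_f_statistic(records$eaf[have], records$beta[have], n[have])
    records$r2[have] <- fs$r2
    records$f[have] <- fs$f
  }
  records
}

#' Drop weak instruments
#'
#' @param records Record data.frame with an `f` column
#'   (see [add_instrument_strength()]).
#' @param f_min Minimum F statistic; default 10. Retention uses `f >= f_min`.
#' @return Subset of `records`.
#' @export
filter_weak <- function(records, f_min = 10) {
  stopifnot("f" %in% names(records))
  records[records$f >= f_min, , drop = FALSE]
}

#' Remove SNPs on a confounder exclusion list
#'
#' Offline stand-in for a PhenoScanner-style lookup: SNPs known to associate
#' with confounders of the exposure-outcome relationship are removed.
#'
#' @param records Record data.frame.
#' @param excluded_ids Character vector of SNP identifiers to drop.
#' @return Subset of `records`; the removed IDs are recorded in the
#'   `exclusion_report` attribute with reason `"confounder-associated"`.
#' @export
apply_exclusion_list <- function(records, excluded_ids) {
  hit <- records$snp_id %in% excluded_ids
  out <- records[!hit, , drop = FALSE]
  attr(out, "exclusion_report") <-
    data.frame(snp_id = records$snp_id[hit],
               reason = rep("confounder-associated", sum(hit)),
               stringsAsFactors = FALSE)
  out
}

#' Read a one-ID-per-line exclusion list
#' @param path Text file with one snp_id per line (blank lines ignored).
#' @return Character vector of IDs.
#' @export
read_exclusion_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids[nzchar(trimws(ids))]
}
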