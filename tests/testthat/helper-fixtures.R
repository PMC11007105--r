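# Shared fixture builders. Everything is constructed in code; no data files.

# Directly assemble a harmonized_set (bypassing file I/O and allele checks)
# so estimator tests can state exact per-SNP effects.
make_h <- function(beta_exp, beta_out, se_out,
                   se_exp = rep(1e-8, length(beta_exp)),
                   eaf = rep(0.5, length(beta_exp)),
                   n_exp = 14824, n_out = 898130) {
  J <- length(beta_exp)
  stopifnot(length(beta_out) == J, length(se_out) == J)
  structure(list(
    snp_ids = sprintf("rs%07d", seq_len(J)),
    beta_exp = beta_exp, se_exp = se_exp, eaf_exp = eaf,
    pval_exp = 2 * stats::pnorm(-abs(beta_exp / se_exp)),
    beta_out = beta_out, se_out = se_out, eaf_out = eaf,
    flipped = rep(FALSE, J), n_exp = n_exp, n_out = n_out,
    dropped = data.frame(snp_id = character(), reason = character())
  ), class = "harmonized_set")
}

# A small record table with explicit fields.
make_records <- function(snp_id, ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                         se = 0.01, pval = 1e-10, n = 14824) {
  k <- length(snp_id)
  data.frame(snp_id = snp_id,
             effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
             eaf = rep_len(eaf, k), beta = rep_len(beta, k),
             se = rep_len(se, k), pval = rep_len(pval, k),
             n = rep_len(n, k), stringsAsFactors = FALSE)
}

write_tsv_fixture <- function(df, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent brute-force implementation of greedy p-value-ranked clumping,
# written directly from the selection rule (keep best remaining by p, discard
# remaining SNPs correlated at or above the threshold), used as the oracle
# for clump().
brute_clump <- function(ids, pvals, r2mat, thr) {
  alive <- stats::setNames(rep(TRUE, length(ids)), ids)
  kept <- character()
  while (any(alive)) {
    cand <- ids[alive]
    cand <- cand[order(pvals[match(cand, ids)], cand)]
    best <- cand[1]
    kept <- c(kept, best)
    alive[best] <- FALSE
    for (s in names(alive)[alive])
      if (r2mat[best, s] >= thr) alive[s] <- FALSE
  }
  sort(kept)
}

# Random clumping instance on <= n_max SNPs with a sparse symmetric r2 matrix.
random_clump_instance <- function(n_max = 10) {
  n <- sample(1:n_max, 1)
  ids <- sprintf("rs%03d", sample(1:999, n))
  pvals <- stats::setNames(10^stats::runif(n, -30, -2), ids)
  r2mat <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r2 <- if (stats::runif(1) < 0.4) stats::runif(1) else 0
      r2mat[i, j] <- r2mat[j, i] <- r2
    }
  }
  diag(r2mat) <- 1
  thr <- stats::runif(1, 0.001, 0.9)
  list(ids = ids, pvals = pvals, r2mat = r2mat, thr = thr)
}

instance_to_args <- function(inst) {
  rec <- make_records(inst$ids)
  rec$pval <- inst$pvals[rec$snp_id]
  ut <- which(upper.tri(inst$r2mat) & inst$r2mat > 0, arr.ind = TRUE)
  pairs <- if (nrow(ut)) {
    data.frame(snp_a = rownames(inst$r2mat)[ut[, 1]],
               snp_b = colnames(inst$r2mat)[ut[, 2]],
               r2 = inst$r2mat[ut], stringsAsFactors = FALSE)
  } else NULL
  list(records = rec, ld = ld_table(pairs))
}
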