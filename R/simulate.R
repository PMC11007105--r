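# Synthetic two-sample GWAS summary statistics with known ground truth.
#
# The generative model mirrors the structure of a protein-pQTL exposure GWAS
# paired with a disease case-control GWAS: each SNP j has a latent effect g_j
# on the genetically proximal trait, sized so that it explains a target
# fraction of trait variance; an invalid subset carries a direct (pleiotropic)
# effect a_j on the other trait, drawn independently of g_j so the InSIDE
# condition holds by construction. Observed betas are the latent effects plus
# normal noise with MAF-and-N-driven standard errors
# se = 1 / sqrt(2 * N * maf * (1 - maf)), the SE of a per-allele regression
# coefficient on a standardized trait. Binary outcomes are emitted directly on
# the log-odds scale with the same SE form (an approximation; no
# individual-level liability simulation).

#' Simulation configuration
#'
#' Defaults describe a pQTL-style exposure study (N = 14,824) against a large
#' T2D case-control meta-analysis (N = 898,130), with per-SNP exposure
#' variance explained of 0.005 (instrument F around 74, within the range
#' reported for strong protein instruments).
#'
#' @param n_snps Number of SNPs.
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes.
#' @param causal_beta True causal effect of exposure on outcome (log-odds per
#'   SD of exposure).
#' @param maf_range Uniform range for minor-allele frequencies.
#' @param exposure_r2_per_snp Mean variance explained per SNP in the
#'   proximal trait.
#' @param r2_spread_sdlog Log-scale SD of the lognormal spread of per-SNP
#'   variance explained around its mean (default 1: instrument F statistics
#'   span roughly two orders of magnitude, as real pQTL panels do; 0 gives
#'   equally strong instruments).
#' @param pleiotropy_mean,pleiotropy_sd Normal parameters for direct effects
#'   of invalid SNPs on the distal trait.
#' @param prop_invalid Fraction of SNPs with a pleiotropic direct effect.
#' @param prop_palindromic Fraction of SNPs assigned A/T or C/G allele pairs.
#' @param prop_swapped Fraction of outcome records reported with effect and
#'   other allele swapped (harmonization must undo this).
#' @param ld_blocks Optional data.frame (`size`, `r2`) describing LD blocks
#'   for [simulate_ld_table()]; SNPs outside blocks are unlinked.
#' @param reverse_causal If `TRUE`, the SNPs' proximal trait is the outcome
#'   and the causal arrow runs outcome -> exposure.
#' @param seed RNG seed (required: simulation output is a pure function of
#'   the config).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 100, n_exp = 14824, n_out = 898130,
                       causal_beta = 0, maf_range = c(0.05, 0.45),
                       exposure_r2_per_snp = 0.005, r2_spread_sdlog = 1,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       prop_invalid = 0, prop_palindromic = 0,
                       prop_swapped = 0, ld_blocks = NULL,
                       reverse_causal = FALSE, seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  stopifnot(n_snps >= 1, n_exp > 2, n_out > 2,
            maf_range[1] > 0, maf_range[2] < 1, maf_range[1] <= maf_range[2],
            exposure_r2_per_snp > 0, exposure_r2_per_snp < 1,
            r2_spread_sdlog >= 0,
            prop_invalid >= 0, prop_invalid <= 1,
            prop_palindromic >= 0, prop_palindromic <= 1,
            prop_swapped >= 0, prop_swapped <= 1)
  structure(as.list(environment()), class = "sim_config")
}

.NONPAL_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                       c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Draw the latent state of a simulated SNP panel
#'
#' Samples MAFs, allele pairs, per-SNP proximal effects `g` (sized so each
#' SNP explains `exposure_r2_per_snp` of the proximal trait, random sign),
#' the invalid subset, and pleiotropic direct effects `a`. True marginal
#' effects are `g` on the proximal trait and `causal_beta * g + a` on the
#' distal trait; `reverse_causal` decides which trait is the exposure.
#' Consumes the current RNG stream (callers normally use [simulate_pair()],
#' which seeds it).
#'
#' @param cfg A `sim_config`.
#' @return List of latent vectors (`maf`, alleles, `gamma_exp`, `Gamma_out`,
#'   `invalid`, `palindromic`, ...).
#' @export
simulate_truth <- function(cfg) {
  n <- cfg$n_snps
  snp_id <- sprintf("rs%07d", seq_len(n))
  maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
  n_pal <- round(cfg$prop_palindromic * n)
  pal <- seq_len(n) <= n_pal  # leading block; ids are exchangeable
  pick <- function(pairs, k) pairs[sample.int(nrow(pairs), k, replace = TRUE), ,
                                   drop = FALSE]
  alleles <- matrix("", n, 2)
  if (n_pal) alleles[pal, ] <- pick(.PAL_PAIRS, n_pal)
  if (n_pal < n) alleles[!pal, ] <- pick(.NONPAL_PAIRS, n - n_pal)
  # per-SNP variance explained: lognormal spread around the configured mean,
  # so instrument strength varies as it does in real pQTL panels
  sdl <- cfg$r2_spread_sdlog
  r2 <- cfg$exposure_r2_per_snp *
    stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  if (any(r2 >= 1))
    stop("infeasible per-SNP variance explained (>= 1); lower exposure_r2_per_snp")
  g <- sample(c(-1, 1), n, replace = TRUE) *
    sqrt(r2 / (2 * maf * (1 - maf)))
  invalid <- rep(FALSE, n)
  n_inv <- round(cfg$prop_invalid * n)
  if (n_inv) invalid[sample.int(n, n_inv)] <- TRUE
  # direct (pleiotropic) effects are anchored to the exposure-increasing
  # allele: a directional mean then shifts the distal trait the same way for
  # every invalid SNP regardless of which allele is labelled "effect".
  # |a| is drawn independently of g, so InSIDE holds by construction.
  a <- ifelse(invalid,
              stats::rnorm(n, cfg$pleiotropy_mean, cfg$pleiotropy_sd), 0)
  distal <- cfg$causal_beta * g + sign(g) * a
  list(snp_id = snp_id, maf = maf,
       effect_allele = alleles[, 1], other_allele = alleles[, 2],
       palindromic = pal, invalid = invalid,
       g = g, a = a,
       gamma_exp = if (cfg$reverse_causal) distal else g,
       Gamma_out = if (cfg$reverse_causal) g else distal,
       causal_beta = cfg$causal_beta, reverse_causal = cfg$reverse_causal)
}

#' Observe a GWAS from latent true effects
#'
#' Adds sampling noise with MAF-and-N-driven SEs and builds a validated
#' record table. Consumes the current RNG stream.
#'
#' @param truth Output of [simulate_truth()].
#' @param true_beta Vector of true per-SNP effects for this trait.
#' @param n GWAS sample size.
#' @param prop_swapped Fraction of records reported on swapped alleles.
#' @return Record data.frame as produced by [read_summary_stats()].
#' @export
observe_gwas <- function(truth, true_beta, n, prop_swapped = 0) {
  se <- 1 / sqrt(2 * n * truth$maf * (1 - truth$maf))
  beta <- stats::rnorm(length(true_beta), true_beta, se)
  rec <- data.frame(
    snp_id = truth$snp_id,
    effect_allele = truth$effect_allele,
    other_allele = truth$other_allele,
    eaf = truth$maf,
    beta = beta,
    se = se,
    pval = 2 * stats::pnorm(-abs(beta / se)),
    n = n,
    stringsAsFactors = FALSE
  )
  if (prop_swapped > 0) {
    k <- round(prop_swapped * nrow(rec))
    if (k) {
      idx <- sample.int(nrow(rec), k)
      ea <- rec$effect_allele[idx]
      rec$effect_allele[idx] <- rec$other_allele[idx]
      rec$other_allele[idx] <- ea
      rec$beta[idx] <- -rec$beta[idx]
      rec$eaf[idx] <- 1 - rec$eaf[idx]
    }
  }
  rec
}

#' Simulate a paired exposure/outcome summary-statistics set
#'
#' Seeds the RNG from `cfg$seed`, draws the latent panel, then observes the
#' exposure and outcome GWAS independently. With the same config the output
#' is bit-for-bit identical across calls.
#'
#' @param cfg A `sim_config`.
#' @return List with `exposure` and `outcome` record data.frames and the
#'   `truth` latent state.
#' @export
simulate_pair <- function(cfg) {
  set.seed(cfg$seed)
  truth <- simulate_truth(cfg)
  exposure <- observe_gwas(truth, truth$gamma_exp, cfg$n_exp)
  outcome <- observe_gwas(truth, truth$Gamma_out, cfg$n_out,
                          prop_swapped = cfg$prop_swapped)
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate a block-diagonal LD table
#'
#' Consecutive SNPs are grouped into the configured blocks (in order); every
#' within-block pair gets the block's r², every cross-block pair r² = 0
#' (omitted from the table). SNPs beyond the last block are unlinked.
#'
#' @param cfg A `sim_config` with non-NULL `ld_blocks`
#'   (data.frame with columns `size`, `r2`).
#' @return An `ld_table`.
#' @export
simulate_ld_table <- function(cfg) {
  snp_id <- sprintf("rs%07d", seq_len(cfg$n_snps))
  blocks <- cfg$ld_blocks
  pairs <- list()
  if (!is.null(blocks) && nrow(blocks)) {
    start <- 1L
    for (b in seq_len(nrow(blocks))) {
      size <- blocks$size[b]
      ids <- snp_id[seq(start, min(start + size - 1L, cfg$n_snps))]
      if (length(ids) >= 2) {
        cmb <- utils::combn(ids, 2)
        pairs[[b]] <- data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                                 r2 = blocks$r2[b],
                                 stringsAsFactors = FALSE)
      }
      start <- start + size
      if (start > cfg$n_snps) break
    }
  }
  ld_table(if (length(pairs)) do.call(rbind, pairs) else NULL)
}

#' Write simulated records in the summary-statistics TSV format
#' @param records Record data.frame.
#' @param path Output path.
#' @export
write_summary_stats <- function(records, path) {
  utils::write.table(records[.GWAS_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Built-in simulation scenario bank
#'
#' Named configurations, one per headline property the package is validated
#' against: `null` (no causal effect), `causal` (b = 0.15, 100 strong SNPs,
#' pQTL-vs-large-case-control sample sizes), `directional_pleiotropy` (every
#' SNP pleiotropic, mean direct effect 0.05, InSIDE satisfied), `invalid40`
#' (40% of SNPs invalid with large direct effects — weighted-median
#' territory), and `reverse_causal` (the outcome is the genetically proximal
#' trait).
#'
#' @param seed Base RNG seed; each scenario gets a distinct offset.
#' @return Named list of `sim_config` objects.
#' @export
scenario_configs <- function(seed) {
  list(
    null = sim_config(n_snps = 100, causal_beta = 0, seed = seed + 1),
    causal = sim_config(n_snps = 100, causal_beta = 0.15, seed = seed + 2),
    directional_pleiotropy = sim_config(
      n_snps = 100, causal_beta = 0.15, prop_invalid = 1,
      pleiotropy_mean = 0.05, pleiotropy_sd = 0.02, seed = seed + 3),
    invalid40 = sim_config(
      n_snps = 100, causal_beta = 0.15, prop_invalid = 0.4,
      pleiotropy_mean = 0.1, pleiotropy_sd = 0.02, seed = seed + 4),
    reverse_causal = sim_config(
      n_snps = 100, causal_beta = 0.15, n_exp = 10000,
      reverse_causal = TRUE, seed = seed + 5)
  )
}

#' Simulate a multi-protein, multi-outcome screening study
#'
#' Builds a coherent synthetic world for an exposures x outcomes screen:
#' every protein gets its own panel of instrument SNPs (distinct rsIDs), and
#' each outcome observes every protein's SNPs with true effect
#' `effects[protein, outcome] * g`. Outcomes can additionally carry their own
#' polygenic loci — SNPs that affect the outcome directly but none of the
#' proteins — which is what makes reverse (outcome-as-exposure) analyses
#' meaningful: in the forward direction those loci are null in every exposure
#' GWAS and never pass the significance threshold.
#'
#' @param effects Numeric matrix of true causal effects (log-odds per SD),
#'   rows named by exposure (protein), columns by outcome.
#' @param outcomes Named list aligned with `colnames(effects)`; each element
#'   a list with `n` (total sample size) and optionally `cases`, `controls`.
#' @param n_snps Instrument SNPs per protein.
#' @param n_exp Exposure GWAS sample size.
#' @param exposure_r2_per_snp,r2_spread_sdlog,maf_range,prop_palindromic,prop_swapped
#'   As in [sim_config()].
#' @param outcome_own_loci Number of outcome-specific polygenic SNPs per
#'   outcome.
#' @param outcome_r2_per_snp Mean variance explained per own locus in its
#'   outcome.
#' @param seed RNG seed; the study is a pure function of the arguments.
#' @return List with `exposures` (named list of record data.frames),
#'   `outcomes` (named list of outcome specs for [run_screen()]), and
#'   `truth` (the effects matrix, per-protein instrument IDs, per-outcome
#'   own-locus IDs).
#' @export
simulate_screen_study <- function(effects, outcomes, n_snps = 60,
                                  n_exp = 14824,
                                  exposure_r2_per_snp = 0.005,
                                  r2_spread_sdlog = 1,
                                  maf_range = c(0.05, 0.45),
                                  prop_palindromic = 0.05,
                                  prop_swapped = 0.2,
                                  outcome_own_loci = 0,
                                  outcome_r2_per_snp = 1e-4,
                                  seed) {
  stopifnot(is.matrix(effects), !is.null(rownames(effects)),
            !is.null(colnames(effects)),
            identical(sort(names(outcomes)), sort(colnames(effects))))
  if (missing(seed) || is.null(seed)) stop("simulate_screen_study requires a seed")
  set.seed(seed)
  proteins <- rownames(effects)
  out_names <- colnames(effects)

  base_cfg <- function(n) {
    sim_config(n_snps = n, n_exp = n_exp,
               maf_range = maf_range,
               exposure_r2_per_snp = exposure_r2_per_snp,
               r2_spread_sdlog = r2_spread_sdlog,
               prop_palindromic = prop_palindromic, seed = 1)
  }

  offset <- 0L
  relabel <- function(truth, k) {
    truth$snp_id <- sprintf("rs%07d", offset + seq_len(k))
    offset <<- offset + k
    truth
  }

  truths <- list()
  for (p in proteins)
    truths[[p]] <- relabel(simulate_truth(base_cfg(n_snps)), n_snps)

  # outcome-specific polygenic loci: null for every protein
  own <- list()
  if (outcome_own_loci > 0) {
    for (o in out_names) {
      cfg_o <- base_cfg(outcome_own_loci)
      cfg_o$exposure_r2_per_snp <- outcome_r2_per_snp
      own[[o]] <- relabel(simulate_truth(cfg_o), outcome_own_loci)
    }
  }

  exposures <- list()
  for (p in proteins) {
    rec <- observe_gwas(truths[[p]], truths[[p]]$g, n_exp)
    for (o in names(own)) {
      null_rec <- observe_gwas(own[[o]], rep(0, outcome_own_loci), n_exp)
      rec <- rbind(rec, null_rec)
    }
    exposures[[p]] <- rec
  }

  out_specs <- list()
  for (o in out_names) {
    n_o <- outcomes[[o]]$n
    parts <- lapply(proteins, function(p)
      observe_gwas(truths[[p]], effects[p, o] * truths[[p]]$g, n_o,
                   prop_swapped = prop_swapped))
    if (!is.null(own[[o]]))
      parts <- c(parts, list(observe_gwas(own[[o]], own[[o]]$g, n_o,
                                          prop_swapped = prop_swapped)))
    out_specs[[o]] <- list(records = do.call(rbind, parts),
                           n = n_o, cases = outcomes[[o]]$cases,
                           controls = outcomes[[o]]$controls)
  }

  list(exposures = exposures, outcomes = out_specs,
       truth = list(effects = effects,
                    instruments = lapply(truths, `[[`, "snp_id"),
                    own_loci = lapply(own, `[[`, "snp_id")))
}
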