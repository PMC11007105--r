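# Orchestration: run the full instrument-selection -> harmonization ->
# estimation -> sensitivity chain for one exposure-outcome pair, both
# directions, or a full exposures x outcomes screen with cross-cohort
# meta-analysis and Bonferroni control.

#' Analysis configuration
#'
#' Thresholds for the whole pipeline. Defaults are the conventional ones for
#' pQTL-based MR: genome-wide significance 5e-8, clumping at r² < 0.001 in a
#' 10,000 kb window, instrument F >= 10, meta-analysis switches to random
#' effects above I² = 30%, and family-wise alpha 0.05.
#'
#' @param p_instrument Instrument p-value threshold.
#' @param clump_r2 LD-clumping r² threshold.
#' @param clump_window_kb Clumping window (kb).
#' @param f_min Minimum instrument F statistic.
#' @param i2_threshold I² above which meta-analysis uses random effects.
#' @param alpha Family-wise significance level.
#' @param palindrome_policy Passed to [harmonize()].
#' @param n_boot Bootstrap draws for the weighted median.
#' @param seed Base seed for all stochastic steps (required).
#' @return Object of class `mr_config`.
#' @export
mr_config <- function(p_instrument = 5e-8, clump_r2 = 0.001,
                      clump_window_kb = 10000, f_min = 10,
                      i2_threshold = 0.30, alpha = 0.05,
                      palindrome_policy = "strict_remove",
                      n_boot = 1000, seed) {
  if (missing(seed) || is.null(seed)) stop("mr_config requires a seed")
  stopifnot(p_instrument > 0, p_instrument <= 1, clump_r2 >= 0, clump_r2 <= 1,
            clump_window_kb > 0, f_min >= 0, i2_threshold >= 0,
            i2_threshold <= 1, alpha > 0, alpha < 1, n_boot >= 1)
  structure(as.list(environment()), class = "mr_config")
}

#' Read an analysis configuration from a JSON file
#'
#' Keys mirror the arguments of [mr_config()]; unknown keys are ignored.
#'
#' @param path JSON file path.
#' @return An `mr_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(raw), names(formals(mr_config)))
  do.call(mr_config, raw[keep])
}

# Normalize an outcome spec: either a bare record data.frame or a list with
# $records plus optional $binary, $cases, $controls, $n, $family.
as_outcome_spec <- function(x) {
  if (is.data.frame(x)) x <- list(records = x)
  stopifnot(is.data.frame(x$records))
  if (is.null(x$binary)) x$binary <- !is.null(x$cases)
  x
}

not_estimable <- function(exposure_name, outcome_name, reason, counts) {
  list(status = "not_estimable", reason = reason,
       exposure = exposure_name, outcome = outcome_name, counts = counts,
       estimates = list(), sensitivity = NULL, harmonized = NULL)
}

#' Run the full MR chain for one exposure-outcome pair
#'
#' Executes, in order: genome-wide significance selection, LD clumping,
#' confounder exclusion list, harmonization (strict palindrome removal by
#' default), weak-instrument F filtering, all applicable estimators (IVW with
#' multiplicative random effects is the primary one), and the sensitivity
#' report. A pair with no usable instruments returns status
#' `"not_estimable"` with the stage that emptied it.
#'
#' @param exposure Exposure record data.frame.
#' @param outcome Outcome spec: record data.frame, or list with `records`
#'   and optionally `binary`, `cases`, `controls`, `n`.
#' @param config An `mr_config`.
#' @param ld Optional `ld_table` for clumping (skipped when `NULL`).
#' @param exclusion Character vector of SNP IDs to exclude.
#' @param exposure_name,outcome_name Labels carried into the results.
#' @param seed Seed for the weighted-median bootstrap; defaults to
#'   `config$seed`.
#' @return List with `status`, `estimates` (named `mr_estimate`s),
#'   `sensitivity`, `harmonized`, and per-stage `counts`.
#' @export
run_pair <- function(exposure, outcome, config, ld = NULL,
                     exclusion = character(), exposure_name = "exposure",
                     outcome_name = "outcome", seed = config$seed) {
  outcome <- as_outcome_spec(outcome)
  counts <- list(input = nrow(exposure))

  sel <- select_genome_wide(exposure, config$p_instrument)
  counts$genome_wide <- nrow(sel)
  if (nrow(sel) == 0)
    return(not_estimable(exposure_name, outcome_name,
                         "no genome-wide significant SNPs", counts))

  if (!is.null(ld))
    sel <- clump(sel, ld, config$clump_r2, config$clump_window_kb)
  counts$clumped <- nrow(sel)

  sel <- apply_exclusion_list(sel, exclusion)
  counts$post_exclusion <- nrow(sel)
  if (nrow(sel) == 0)
    return(not_estimable(exposure_name, outcome_name,
                         "all instruments on exclusion list", counts))

  h <- tryCatch(
    harmonize(sel, outcome$records,
              palindrome_policy = config$palindrome_policy,
              n_out = outcome$n),
    error = function(e) e
  )
  if (inherits(h, "error"))
    return(not_estimable(exposure_name, outcome_name, conditionMessage(h),
                         counts))
  counts$harmonized <- n_instruments(h)

  # weak-instrument filter on the exposure side; fall back to (beta/se)^2
  # when allele frequency or sample size is unavailable
  f <- if (!any(is.na(h$eaf_exp)) && !is.na(h$n_exp)) {
    compute_f_statistic(h$eaf_exp, h$beta_exp, h$n_exp)$f
  } else {
    (h$beta_exp / h$se_exp)^2
  }
  h <- subset_harmonized(h, f >= config$f_min, reason = "weak instrument")
  counts$strong <- n_instruments(h)
  if (n_instruments(h) == 0)
    return(not_estimable(exposure_name, outcome_name,
                         "no instruments with F >= f_min", counts))

  estimates <- mr_all_methods(h, n_boot = config$n_boot, seed = seed)
  sens <- sensitivity_report(h, outcome_binary = outcome$binary,
                             cases = outcome$cases,
                             controls = outcome$controls)
  list(status = "ok", exposure = exposure_name, outcome = outcome_name,
       estimates = estimates, sensitivity = sens, harmonized = h,
       counts = counts)
}

#' Run a pair in both causal directions
#'
#' The reverse direction re-derives instruments from the outcome GWAS with
#' the same thresholds and treats the original exposure (a continuous trait)
#' as the new outcome.
#'
#' @inheritParams run_pair
#' @param exposure_ld,outcome_ld Optional `ld_table`s for each direction.
#' @return List with `forward` and `reverse` pair results.
#' @export
run_bidirectional <- function(exposure, outcome, config,
                              exposure_ld = NULL, outcome_ld = NULL,
                              exclusion = character(),
                              exposure_name = "exposure",
                              outcome_name = "outcome") {
  outcome <- as_outcome_spec(outcome)
  forward <- run_pair(exposure, outcome, config, ld = exposure_ld,
                      exclusion = exclusion, exposure_name = exposure_name,
                      outcome_name = outcome_name, seed = config$seed)
  reverse <- run_pair(outcome$records, list(records = exposure,
                                            binary = FALSE),
                      config, ld = outcome_ld, exclusion = exclusion,
                      exposure_name = outcome_name,
                      outcome_name = exposure_name, seed = config$seed + 1L)
  list(forward = forward, reverse = reverse)
}

pair_result_rows <- function(res, m_tests, alpha) {
  base <- data.frame(exposure = res$exposure, outcome = res$outcome,
                     status = res$status, stringsAsFactors = FALSE)
  if (res$status != "ok") {
    base$method <- NA_character_
    base$reason <- res$reason
    return(base)
  }
  est <- do.call(rbind, lapply(res$estimates, as.data.frame))
  # the sensitivity block carries the canonical Egger-intercept triple
  est$egger_intercept <- NULL
  est$egger_intercept_p <- NULL
  s <- res$sensitivity
  sens <- data.frame(q = s$q, q_df = s$q_df, q_pval = s$q_pval,
                     egger_intercept = s$egger_intercept,
                     egger_intercept_se = s$egger_intercept_se,
                     egger_intercept_pval = s$egger_intercept_pval,
                     steiger_dir = s$steiger_dir,
                     steiger_pval = s$steiger_pval)
  out <- cbind(base[rep(1, nrow(est)), , drop = FALSE], est,
               sens[rep(1, nrow(est)), , drop = FALSE])
  out$reason <- NA_character_
  out$significance <- ifelse(out$method == "ivw_mre",
                             significance_tier(out$pval, m_tests, alpha),
                             NA_character_)
  rownames(out) <- NULL
  out
}

#' Screen many exposures against many outcomes
#'
#' Runs [run_pair()] for every exposure x outcome combination, tiers the
#' primary (IVW multiplicative random effects) p-values with an explicit
#' Bonferroni family size, and optionally pools named cohort groups with
#' [meta_auto()]. Partial failures are isolated per pair and reported as
#' `not_estimable` rows.
#'
#' @param exposures Named list of exposure record data.frames.
#' @param outcomes Named list of outcome specs (see [run_pair()]).
#' @param config An `mr_config`.
#' @param ld Optional: a single `ld_table` shared by all exposures, or a
#'   named list keyed by exposure name.
#' @param exclusion Character vector of SNP IDs to exclude.
#' @param m_tests Bonferroni family size (explicit, never inferred).
#' @param meta_groups Optional named list; each element is a character vector
#'   of outcome names whose per-exposure primary estimates are pooled.
#' @param out_dir Optional directory; when given, `results.tsv`, `meta.tsv`
#'   and `manifest.json` are written there (deterministically for a fixed
#'   config and inputs).
#' @return List with `results` (data.frame), `meta` (data.frame or NULL),
#'   and `pairs` (the raw per-pair results).
#' @export
run_screen <- function(exposures, outcomes, config, ld = NULL,
                       exclusion = character(), m_tests = length(exposures),
                       meta_groups = NULL, out_dir = NULL) {
  stopifnot(length(names(exposures)) == length(exposures),
            length(names(outcomes)) == length(outcomes))
  pairs <- list()
  rows <- list()
  idx <- 0L
  for (en in names(exposures)) {
    ld_e <- if (inherits(ld, "ld_table")) ld else ld[[en]]
    for (on in names(outcomes)) {
      idx <- idx + 1L
      res <- run_pair(exposures[[en]], outcomes[[on]], config, ld = ld_e,
                      exclusion = exclusion, exposure_name = en,
                      outcome_name = on, seed = config$seed + idx)
      pairs[[paste(en, on, sep = " -> ")]] <- res
      rows[[idx]] <- pair_result_rows(res, m_tests, config$alpha)
    }
  }
  results <- do.call(rbind, lapply(rows, function(r) {
    template <- rows[[which.max(vapply(rows, ncol, 0L))]][0, ]
    for (col in setdiff(names(template), names(r))) r[[col]] <- NA
    r[names(template)]
  }))
  rownames(results) <- NULL

  meta <- NULL
  if (!is.null(meta_groups)) {
    meta_rows <- list()
    for (gname in names(meta_groups)) {
      members <- meta_groups[[gname]]
      for (en in names(exposures)) {
        ests <- lapply(members, function(on)
          pairs[[paste(en, on, sep = " -> ")]]$estimates$ivw_mre)
        ests <- Filter(Negate(is.null), ests)
        if (length(ests) < 2) next
        b <- vapply(ests, `[[`, 0, "beta")
        s <- vapply(ests, `[[`, 0, "se")
        mr <- meta_auto(b, s, i2_threshold = config$i2_threshold)
        meta_rows[[paste(gname, en)]] <- data.frame(
          exposure = en, outcome = gname, model = mr$model,
          n_cohorts = length(b), beta = mr$beta, se = mr$se, pval = mr$pval,
          or = mr$or_, ci_low = mr$ci_low, ci_high = mr$ci_high,
          q_meta = mr$q_meta, i2 = mr$i2, tau2 = mr$tau2,
          significance = significance_tier(mr$pval, m_tests, config$alpha),
          stringsAsFactors = FALSE)
      }
    }
    if (length(meta_rows)) {
      meta <- do.call(rbind, meta_rows)
      rownames(meta) <- NULL
    }
  }

  out <- list(results = results, meta = meta, pairs = pairs)
  if (!is.null(out_dir)) write_screen_outputs(out, config, out_dir)
  out
}

#' Write screen outputs (results, meta, run manifest) to a directory
#'
#' The manifest records per-pair QC counts (input, genome-wide significant,
#' clumped, post-exclusion, harmonized, strong) and the thresholds used; it
#' contains no timestamps, so re-running with identical inputs and seed is
#' byte-identical.
#'
#' @param screen Output of [run_screen()].
#' @param config The `mr_config` used.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_screen_outputs <- function(screen, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(out_dir, "results.tsv")
  utils::write.table(screen$results, res_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- res_path
  if (!is.null(screen$meta)) {
    meta_path <- file.path(out_dir, "meta.tsv")
    utils::write.table(screen$meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, meta_path)
  }
  manifest <- list(
    thresholds = config[c("p_instrument", "clump_r2", "clump_window_kb",
                          "f_min", "i2_threshold", "alpha",
                          "palindrome_policy", "n_boot", "seed")],
    pairs = lapply(screen$pairs, function(p)
      c(list(status = p$status), p$counts))
  )
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, man_path))
}
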