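test_that("the same seed reproduces the simulation bit-for-bit", {
  cfg <- sim_config(n_snps = 50, causal_beta = 0.1, prop_palindromic = 0.1,
                    prop_swapped = 0.3, seed = 11)
  a <- simulate_pair(cfg)
  b <- simulate_pair(cfg)
  expect_identical(a, b)
  pa <- tempfile(fileext = ".tsv"); pb <- tempfile(fileext = ".tsv")
  write_summary_stats(a$exposure, pa)
  write_summary_stats(b$exposure, pb)
  expect_identical(readLines(pa), readLines(pb))
})

test_that("standard errors shrink as 1/sqrt(n)", {
  t1 <- simulate_pair(sim_config(n_snps = 40, n_exp = 10000, seed = 12))
  t2 <- simulate_pair(sim_config(n_snps = 40, n_exp = 40000, seed = 12))
  # same seed => same MAFs; quadrupling n halves every exposure SE
  expect_equal(t2$exposure$se, t1$exposure$se / 2, tolerance = 1e-12)
})

test_that("palindromic fraction is honoured and strict harmonization drops it", {
  cfg <- sim_config(n_snps = 100, prop_palindromic = 0.1, seed = 13)
  sim <- simulate_pair(cfg)
  expect_equal(sum(is_palindromic(sim$exposure$effect_allele,
                                  sim$exposure$other_allele)), 10)
  h <- harmonize(sim$exposure, sim$outcome)
  expect_equal(n_instruments(h), 90)
  expect_true(all(h$dropped$reason == "palindromic"))
})

test_that("allele swapping in the outcome file is undone by harmonization", {
  cfg0 <- sim_config(n_snps = 60, causal_beta = 0.2, seed = 14)
  cfg1 <- sim_config(n_snps = 60, causal_beta = 0.2, prop_swapped = 0.5,
                     seed = 14)
  h0 <- harmonize(simulate_pair(cfg0)$exposure, simulate_pair(cfg0)$outcome)
  sim1 <- simulate_pair(cfg1)
  h1 <- harmonize(sim1$exposure, sim1$outcome)
  expect_equal(sum(h1$flipped), 30)
  # after harmonization the effects are identical to the unswapped world
  expect_equal(h1$beta_out, h0$beta_out, tolerance = 1e-12)
})

test_that("truth record stores the latent state consistently", {
  cfg <- sim_config(n_snps = 30, causal_beta = 0.15, prop_invalid = 0.3,
                    pleiotropy_mean = 0.05, pleiotropy_sd = 0.01, seed = 15)
  sim <- simulate_pair(cfg)
  tr <- sim$truth
  expect_equal(sum(tr$invalid), 9)
  expect_true(all(tr$a[!tr$invalid] == 0))
  expect_equal(tr$Gamma_out,
               0.15 * tr$g + sign(tr$g) * tr$a, tolerance = 1e-12)
  # reverse world swaps the roles
  cfgr <- sim_config(n_snps = 30, causal_beta = 0.15, reverse_causal = TRUE,
                     seed = 15)
  trr <- simulate_pair(cfgr)$truth
  expect_equal(trr$Gamma_out, trr$g)
  expect_equal(trr$gamma_exp, 0.15 * trr$g)
})

test_that("block LD tables drive clumping as designed", {
  cfg <- sim_config(n_snps = 8, seed = 16,
                    ld_blocks = data.frame(size = 5, r2 = 0.9))
  ld <- simulate_ld_table(cfg)
  expect_equal(ld_r2(ld, "rs0000001", "rs0000005"), 0.9)
  expect_equal(ld_r2(ld, "rs0000001", "rs0000006"), 0)
  sim <- simulate_pair(cfg)
  kept <- clump(sim$exposure, ld)
  # one survivor from the correlated block, the 3 unlinked SNPs intact
  expect_equal(nrow(kept), 4)
  expect_equal(sum(kept$snp_id %in% sprintf("rs%07d", 1:5)), 1)
  # size-1 blocks: clumping is the identity
  cfg1 <- sim_config(n_snps = 5, seed = 17,
                     ld_blocks = data.frame(size = rep(1, 5), r2 = 0.9))
  sim1 <- simulate_pair(cfg1)
  expect_equal(nrow(clump(sim1$exposure, simulate_ld_table(cfg1))), 5)
})

test_that("scenario bank covers the five validation worlds", {
  bank <- scenario_configs(seed = 100)
  expect_named(bank, c("null", "causal", "directional_pleiotropy",
                       "invalid40", "reverse_causal"))
  expect_equal(bank$null$causal_beta, 0)
  expect_equal(bank$causal$causal_beta, 0.15)
  expect_equal(bank$causal$n_exp, 14824)
  expect_equal(bank$causal$n_out, 898130)
  expect_equal(bank$directional_pleiotropy$prop_invalid, 1)
  expect_equal(bank$invalid40$prop_invalid, 0.4)
  expect_true(bank$reverse_causal$reverse_causal)
  # distinct seeds => runnable independently
  expect_equal(length(unique(vapply(bank, `[[`, 0, "seed"))), 5L)
})

test_that("sim_config rejects infeasible worlds", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(n_snps = 10, maf_range = c(0.5, 0.2), seed = 1))
  expect_error(sim_config(exposure_r2_per_snp = 1.2, seed = 1))
  expect_error(simulate_pair(sim_config(exposure_r2_per_snp = 0.9,
                                        r2_spread_sdlog = 1.5, seed = 3)),
               "infeasible")
})

test_that("simulate_screen_study builds a coherent multi-trait world", {
  eff <- matrix(c(0.15, 0, 0.3, 0), nrow = 2,
                dimnames = list(c("pA", "pB"), c("o1", "o2")))
  study <- simulate_screen_study(
    eff, outcomes = list(o1 = list(n = 898130, cases = 74124,
                                   controls = 824006),
                         o2 = list(n = 22326)),
    n_snps = 40, outcome_own_loci = 20, seed = 77)
  expect_named(study$exposures, c("pA", "pB"))
  expect_named(study$outcomes, c("o1", "o2"))
  # rsIDs are globally unique across proteins and own-locus panels
  all_ids <- c(unlist(study$truth$instruments), unlist(study$truth$own_loci))
  expect_equal(anyDuplicated(all_ids), 0L)
  # each exposure file carries its own panel plus every outcome's own loci
  expect_equal(nrow(study$exposures$pA), 40 + 2 * 20)
  # each outcome file carries every protein's panel plus its own loci
  expect_equal(nrow(study$outcomes$o1$records), 2 * 40 + 20)
  # own loci are null in the exposures: far from genome-wide significance
  own1 <- study$exposures$pA[study$exposures$pA$snp_id %in%
                               study$truth$own_loci$o1, ]
  expect_true(all(own1$pval > 5e-8))
  # determinism
  study2 <- simulate_screen_study(
    eff, outcomes = list(o1 = list(n = 898130, cases = 74124,
                                   controls = 824006),
                         o2 = list(n = 22326)),
    n_snps = 40, outcome_own_loci = 20, seed = 77)
  expect_identical(study, study2)
  # end-to-end: the causal protein is recovered on its outcome
  mc <- mr_config(seed = 77, n_boot = 100)
  res <- run_pair(study$exposures$pA, study$outcomes$o1, mc,
                  exposure_name = "pA", outcome_name = "o1")
  expect_equal(res$status, "ok")
  expect_lt(abs(res$estimates$ivw_mre$beta - 0.15),
            3 * res$estimates$ivw_mre$se + 0.01)
})
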