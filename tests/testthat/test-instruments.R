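test_that("select_genome_wide applies a strict p < threshold rule", {
  rec <- make_records(c("rs1", "rs2", "rs3"))
  rec$pval <- c(1e-9, 1e-7, 4.9e-8)
  expect_equal(select_genome_wide(rec)$snp_id, c("rs1", "rs3"))
  rec$pval <- c(5e-8, 6e-8, 1e-7)
  expect_equal(nrow(select_genome_wide(rec)), 0)       # boundary excluded
  expect_equal(nrow(select_genome_wide(rec, 1e-5)), 3) # override passes through
})

test_that("clump keeps the hand-traced greedy solution", {
  rec <- make_records(c("rs1", "rs2", "rs3"))
  rec$pval <- c(1e-20, 1e-12, 1e-9)
  ld <- ld_table(data.frame(snp_a = c("rs1", "rs1", "rs2"),
                            snp_b = c("rs2", "rs3", "rs3"),
                            r2 = c(0.5, 0.0002, 0)))
  expect_equal(clump(rec, ld)$snp_id, c("rs1", "rs3"))
  # all independent: everything kept
  expect_equal(clump(rec, ld_table())$snp_id, rec$snp_id)
})

test_that("clump breaks p-value ties lexicographically, independent of order", {
  rec <- make_records(c("rs9", "rs2"))
  rec$pval <- c(1e-10, 1e-10)
  ld <- ld_table(data.frame(snp_a = "rs2", snp_b = "rs9", r2 = 0.9))
  expect_equal(clump(rec, ld)$snp_id, "rs2")
  expect_equal(clump(rec[2:1, ], ld)$snp_id, "rs2")
})

test_that("clump matches an independent brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    inst <- random_clump_instance()
    args <- instance_to_args(inst)
    mine <- sort(clump(args$records, args$ld, r2_threshold = inst$thr)$snp_id)
    oracle <- brute_clump(inst$ids, inst$pvals, inst$r2mat, inst$thr)
    expect_identical(mine, oracle)
  }
})

test_that("clump window test is honoured when positions are present", {
  rec <- make_records(c("rs1", "rs2"))
  rec$pval <- c(1e-20, 1e-10)
  pos_near <- data.frame(snp_id = c("rs1", "rs2"), chrom = c(1, 1),
                         pos = c(1e6, 2e6))
  pos_far <- data.frame(snp_id = c("rs1", "rs2"), chrom = c(1, 1),
                        pos = c(1e6, 2e7 + 1e6 + 1))
  pairs <- data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9)
  expect_equal(clump(rec, ld_table(pairs, pos_near))$snp_id, "rs1")
  # correlated but outside the 10,000 kb window: both retained
  expect_equal(clump(rec, ld_table(pairs, pos_far))$snp_id, c("rs1", "rs2"))
  # different chromosomes: window never satisfied
  pos_chr <- data.frame(snp_id = c("rs1", "rs2"), chrom = c(1, 2),
                        pos = c(1e6, 1e6))
  expect_equal(clump(rec, ld_table(pairs, pos_chr))$snp_id, c("rs1", "rs2"))
})

test_that("compute_f_statistic evaluates the printed formula", {
  got <- compute_f_statistic(0.5, 0.1, 14824)
  expect_equal(got$r2, 0.005)
  expect_equal(got$f, 0.005 * 14822 / 0.995, tolerance = 1e-12)
  expect_equal(compute_f_statistic(0.3, 0, 1000)$f, 0)
  # monotone in n at fixed eaf, beta
  f1 <- compute_f_statistic(0.3, 0.1, 5000)$f
  f2 <- compute_f_statistic(0.3, 0.1, 50000)$f
  expect_gt(f2, f1)
  expect_error(compute_f_statistic(0.5, 2, 1000), "wrong scale")
})

test_that("mean estimated per-SNP r2 recovers the generating value", {
  set.seed(7)
  v <- 0.005; n <- 14824; maf <- stats::runif(4000, 0.05, 0.45)
  g <- sqrt(v / (2 * maf * (1 - maf)))
  se <- 1 / sqrt(2 * n * maf * (1 - maf))
  beta_hat <- stats::rnorm(4000, g, se)
  r2_hat <- compute_f_statistic(maf, beta_hat, n)$r2
  # E[beta_hat^2] = g^2 + se^2, so subtract the known noise floor
  expect_lt(abs(mean(r2_hat - 2 * maf * (1 - maf) * se^2) - v),
            3 * stats::sd(r2_hat) / sqrt(4000))
})

test_that("filter_weak keeps F >= f_min inclusively", {
  rec <- make_records(c("rs1", "rs2", "rs3"))
  rec$f <- c(9.9, 10.0, 74.5)
  expect_equal(filter_weak(rec)$snp_id, c("rs2", "rs3"))
  expect_equal(filter_weak(rec, f_min = 0)$snp_id, rec$snp_id)
})

test_that("add_instrument_strength flags the (beta/se)^2 fallback", {
  rec <- make_records(c("rs1", "rs2"), eaf = c(0.3, NA), beta = 0.1,
                      se = 0.02)
  got <- add_instrument_strength(rec)
  expect_false(got$f_approx[1])
  expect_true(got$f_approx[2])
  expect_equal(got$f[2], (0.1 / 0.02)^2)
  expect_equal(got$f[1], compute_f_statistic(0.3, 0.1, 14824)$f)
})

test_that("exclusion lists drop exactly the listed SNPs", {
  rec <- make_records(c("rs1", "rs2", "rs3"))
  expect_equal(apply_exclusion_list(rec, character())$snp_id, rec$snp_id)
  got <- apply_exclusion_list(rec, "rs2")
  expect_equal(got$snp_id, c("rs1", "rs3"))
  expect_equal(attr(got, "exclusion_report")$reason, "confounder-associated")
  expect_equal(apply_exclusion_list(rec, c("rs99"))$snp_id, rec$snp_id)
})

test_that("LD tables are symmetric with unit diagonal and round-trip", {
  pairs <- data.frame(snp_a = c("rs1", "rs2"), snp_b = c("rs2", "rs3"),
                      r2 = c(0.5, 0.2))
  ld <- ld_table(pairs)
  expect_equal(ld_r2(ld, "rs1", "rs2"), 0.5)
  expect_equal(ld_r2(ld, "rs2", "rs1"), 0.5)
  expect_equal(ld_r2(ld, "rs1", "rs1"), 1)
  expect_equal(ld_r2(ld, "rs1", "rs9"), 0)
  path <- tempfile(fileext = ".tsv")
  write_ld_table(ld, path)
  ld2 <- read_ld_table(path)
  expect_equal(ld2$pairs, ld$pairs)
})
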