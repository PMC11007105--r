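test_that("Wald ratios follow the delta method and its symmetries", {
  h <- make_h(0.2, 0.1, 0.05)
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se, 0.25)
  # zero numerator
  expect_equal(wald_ratios(make_h(0.2, 0, 0.05))$ratio, 0)
  # joint sign flip leaves the ratio invariant
  wr2 <- wald_ratios(make_h(-0.2, -0.1, 0.05))
  expect_equal(wr2$ratio, wr$ratio)
  # zero exposure effect is dropped with a warning
  h0 <- make_h(c(0, 0.2), c(0.1, 0.1), c(0.05, 0.05))
  expect_warning(wr3 <- wald_ratios(h0), "zero exposure effect")
  expect_equal(nrow(wr3), 1)
  # second-order SE adds the exposure-error term
  h4 <- make_h(0.2, 0.1, 0.05, se_exp = 0.02)
  so <- wald_ratios(h4, second_order = TRUE)
  expect_equal(so$se, sqrt(0.05^2 / 0.04 + 0.01 * 4e-4 / 0.0016))
})

test_that("IVW reproduces the hand-computed example and its variants", {
  h <- make_h(c(1, 1), c(0.1, 0.2), c(0.05, 0.05))
  fe <- mr_ivw(h, "fixed")
  expect_equal(fe$beta, 0.15)
  expect_equal(fe$se, sqrt(1 / 800), tolerance = 1e-12)
  expect_equal(fe$extra$q, 2)
  mre <- mr_ivw(h, "mre")
  expect_equal(mre$beta, 0.15)
  expect_equal(mre$se, sqrt(1 / 800) * sqrt(2), tolerance = 1e-12) # = 0.05
  expect_equal(mre$se, 0.05, tolerance = 1e-12)
  # homogeneity: all ratios equal -> Q = 0, MRE collapses to fixed
  hc <- make_h(c(1, 2, 4), c(0.3, 0.6, 1.2), c(0.05, 0.05, 0.05))
  m <- mr_ivw(hc, "mre")
  expect_equal(m$beta, 0.3)
  expect_equal(m$extra$q, 0, tolerance = 1e-20)
  expect_equal(m$se, mr_ivw(hc, "fixed")$se)
  # duplicating every SNP halves the fixed-effect variance
  hd <- make_h(rep(c(1, 1), 2), rep(c(0.1, 0.2), 2), rep(0.05, 4))
  expect_equal(mr_ivw(hd, "fixed")$se^2, fe$se^2 / 2, tolerance = 1e-12)
  expect_error(mr_ivw(make_h(1, 0.1, 0.05)), "insufficient instruments")
})

test_that("MRE standard error never undercuts the fixed-effect one", {
  set.seed(42)
  for (i in 1:50) {
    J <- sample(2:20, 1)
    h <- make_h(stats::runif(J, 0.05, 0.3), stats::rnorm(J, 0.02, 0.05),
                stats::runif(J, 0.01, 0.1))
    expect_gte(mr_ivw(h, "mre")$se, mr_ivw(h, "fixed")$se)
  }
})

test_that("Egger recovers an exact line and shifts with added pleiotropy", {
  h <- make_h(c(0.1, 0.2, 0.3), c(0.06, 0.11, 0.16), rep(0.05, 3))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.5, tolerance = 1e-9)
  expect_equal(e$extra$intercept, 0.01, tolerance = 1e-9)
  # adding a constant to all outcome effects shifts only the intercept
  h2 <- make_h(c(0.1, 0.2, 0.3), c(0.06, 0.11, 0.16) + 0.05, rep(0.05, 3))
  e2 <- mr_egger(h2)
  expect_equal(e2$beta, e$beta, tolerance = 1e-9)
  expect_equal(e2$extra$intercept, 0.06, tolerance = 1e-9)
  expect_error(mr_egger(make_h(c(1, 1), c(0.1, 0.2), c(0.05, 0.05))),
               "insufficient instruments")
})

test_that("Egger orientation makes the fit invariant to allele relabelling", {
  set.seed(9)
  J <- 8
  be <- stats::runif(J, 0.05, 0.3); bo <- 0.4 * be + stats::rnorm(J, 0, 0.01)
  so <- stats::runif(J, 0.01, 0.05)
  flip <- sample(c(-1, 1), J, replace = TRUE)
  e1 <- mr_egger(make_h(be, bo, so))
  e2 <- mr_egger(make_h(flip * be, flip * bo, so))
  expect_equal(e2$beta, e1$beta, tolerance = 1e-10)
  expect_equal(e2$extra$intercept, e1$extra$intercept, tolerance = 1e-10)
})

test_that("Egger slope constrained through the origin equals IVW", {
  set.seed(11)
  J <- 10
  be <- stats::runif(J, 0.05, 0.3)
  bo <- 0.3 * be + stats::rnorm(J, 0, 0.02)
  so <- stats::runif(J, 0.01, 0.05)
  h <- make_h(be, bo, so)
  origin <- stats::lm(bo ~ 0 + be, weights = 1 / so^2)
  expect_equal(unname(stats::coef(origin)), mr_ivw(h, "fixed")$beta,
               tolerance = 1e-12)
})

test_that("weighted median interpolates correctly and resists contamination", {
  h <- make_h(c(1, 1, 1), c(0.1, 0.2, 0.3), c(1, 1, 1))
  wm <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(wm$beta, 0.2)
  # degenerate: identical ratios -> tiny bootstrap SE around c
  hc <- make_h(rep(10, 3), rep(4, 3), rep(0.01, 3), se_exp = rep(0.01, 3))
  wmc <- mr_weighted_median(hc, n_boot = 100, seed = 1)
  expect_equal(wmc$beta, 0.4, tolerance = 1e-6)
  expect_lt(wmc$se, 0.01)
  # 40% contaminated ratios at +5: estimate stays near the valid 0.3
  J <- 20; bad <- 1:8
  be <- rep(0.2, J); bo <- rep(0.06, J); bo[bad] <- 0.2 * 5
  wmr <- mr_weighted_median(make_h(be, bo, rep(0.01, J),
                                   se_exp = rep(1e-6, J)),
                            n_boot = 50, seed = 2)
  expect_lt(abs(wmr$beta - 0.3), 0.05)
  expect_error(mr_weighted_median(make_h(c(1, 1), c(1, 1), c(1, 1))),
               "insufficient instruments")
})

test_that("weighted median bootstrap is reproducible under a seed", {
  h <- make_h(stats::runif(6, 0.1, 0.3), stats::runif(6, 0.02, 0.1),
              rep(0.02, 6), se_exp = rep(0.01, 6))
  a <- mr_weighted_median(h, n_boot = 100, seed = 7)
  b <- mr_weighted_median(h, n_boot = 100, seed = 7)
  expect_identical(a$se, b$se)
})

test_that("maximum likelihood matches IVW in the error-free-exposure limit", {
  set.seed(13)
  J <- 12
  be <- stats::runif(J, 0.1, 0.3)
  bo <- 0.25 * be + stats::rnorm(J, 0, 0.01)
  so <- stats::runif(J, 0.01, 0.03)
  h <- make_h(be, bo, so, se_exp = rep(1e-9, J))
  ml <- mr_max_likelihood(h)
  fe <- mr_ivw(h, "fixed")
  expect_equal(ml$beta, fe$beta, tolerance = 1e-6)
  expect_equal(ml$se, fe$se, tolerance = 1e-4)
  # noiseless recovery and sign antisymmetry
  hb <- make_h(c(0.1, 0.2, 0.3), 0.4 * c(0.1, 0.2, 0.3), rep(0.01, 3),
               se_exp = rep(0.01, 3))
  expect_equal(mr_max_likelihood(hb)$beta, 0.4, tolerance = 1e-6)
  hneg <- make_h(c(0.1, 0.2, 0.3), -0.4 * c(0.1, 0.2, 0.3), rep(0.01, 3),
                 se_exp = rep(0.01, 3))
  expect_equal(mr_max_likelihood(hneg)$beta, -0.4, tolerance = 1e-6)
})

test_that("odds-ratio conversion honours the CI invariants", {
  o <- to_odds_ratio(0, 0.1)
  expect_equal(o$or_, 1)
  expect_equal(o$ci_low, exp(-1.959964 * 0.1))
  expect_equal(o$ci_low, 0.822, tolerance = 1e-3)
  expect_equal(o$ci_high, 1.217, tolerance = 1e-3)
  # zero SE degenerates to the point estimate
  od <- to_odds_ratio(0.3, 0)
  expect_equal(od$ci_low, od$or_)
  expect_equal(od$ci_high, od$or_)
  # OR(-b) = 1 / OR(b)
  expect_equal(to_odds_ratio(-0.3, 0.1)$or_, 1 / to_odds_ratio(0.3, 0.1)$or_)
  # every estimate object satisfies ci_low <= or <= ci_high
  h <- make_h(c(0.8, 1, 1.2), c(0.1, 0.2, 0.3), rep(0.05, 3))
  for (e in mr_all_methods(h, n_boot = 50, seed = 3)) {
    expect_lte(e$ci_low, e$or_)
    expect_lte(e$or_, e$ci_high)
    expect_equal(e$or_, exp(e$beta))
  }
})

test_that("all five estimators recover a strong simulated causal effect", {
  sim <- simulate_pair(sim_config(n_snps = 100, causal_beta = 0.15,
                                  seed = 424242))
  h <- harmonize(sim$exposure, sim$outcome)
  ests <- mr_all_methods(h, n_boot = 200, seed = 424242)
  expect_named(ests, c("ivw_mre", "ivw_fe", "max_likelihood", "egger",
                       "weighted_median"))
  # Egger carries a known small dilution from exposure-side noise, so a flat
  # band is the right check for a single frozen replicate
  for (e in ests)
    expect_lt(abs(e$beta - 0.15), 0.02)
})

test_that("Egger refuses equally strong instruments (slope unidentifiable)", {
  expect_error(mr_egger(make_h(c(1, 1, 1), c(0.1, 0.2, 0.3), rep(0.05, 3))),
               "variation in instrument strength")
})
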