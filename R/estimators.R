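# Two-sample MR causal-effect estimators operating on a harmonized_set.
#
# Notation: for SNP j, beta_exp_j / se_exp_j are the SNP-exposure association
# and its SE, beta_out_j / se_out_j the SNP-outcome association. The Wald
# ratio beta_out_j / beta_exp_j estimates the causal effect through SNP j;
# the estimators below combine the J ratios under different validity
# assumptions.

Z975 <- 1.959964

#' Convert a log-scale effect to an odds ratio with 95% CI
#'
#' @param beta Effect on the log-odds scale.
#' @param se Standard error (>= 0).
#' @return List with `or_`, `ci_low`, `ci_high` (`exp(beta -+ 1.959964 * se)`).
#' @export
to_odds_ratio <- function(beta, se) {
  stopifnot(all(se >= 0))
  list(or_ = exp(beta), ci_low = exp(beta - Z975 * se),
       ci_high = exp(beta + Z975 * se))
}

new_mr_estimate <- function(method, beta, se, pval, n_snp, extra = list()) {
  ors <- to_odds_ratio(beta, se)
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 or_ = ors$or_, ci_low = ors$ci_low, ci_high = ors$ci_high,
                 n_snp = n_snp, extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g, %d SNP(s)\n",
              x$method, x$beta, x$se, x$or_, x$ci_low, x$ci_high, x$pval,
              x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             pval = x$pval, or = x$or_, ci_low = x$ci_low,
             ci_high = x$ci_high,
             egger_intercept = if (!is.null(x$extra$intercept))
               x$extra$intercept else NA_real_,
             egger_intercept_p = if (!is.null(x$extra$intercept_pval))
               x$extra$intercept_pval else NA_real_,
             stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratios
#'
#' `ratio_j = beta_out_j / beta_exp_j`, with the first-order delta-method
#' standard error `se_out_j / |beta_exp_j|` (exposure-side error ignored).
#' SNPs with a zero exposure effect are dropped with a warning.
#'
#' @param h A `harmonized_set`.
#' @param second_order If `TRUE`, use the second-order delta SE which also
#'   propagates exposure-side error:
#'   `sqrt(se_out^2/beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`.
#' @return data.frame with `snp_id`, `ratio`, `se`.
#' @export
wald_ratios <- function(h, second_order = FALSE) {
  keep <- h$beta_exp != 0
  if (!all(keep))
    warning(sum(!keep), " SNP(s) dropped from Wald ratios: zero exposure effect")
  b_exp <- h$beta_exp[keep]; b_out <- h$beta_out[keep]
  se_out <- h$se_out[keep]; se_exp <- h$se_exp[keep]
  se <- if (second_order) {
    sqrt(se_out^2 / b_exp^2 + b_out^2 * se_exp^2 / b_exp^4)
  } else {
    se_out / abs(b_exp)
  }
  data.frame(snp_id = h$snp_ids[keep], ratio = b_out / b_exp, se = se,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimator
#'
#' Combines Wald ratios with weights `w_j = beta_exp_j^2 / se_out_j^2`
#' (equivalent to weighted regression of outcome on exposure effects through
#' the origin). The fixed-effect SE is `sqrt(1 / sum(w))`; under the
#' multiplicative random-effects model (the default, and the primary estimator
#' in this package) the SE is inflated by `sqrt(max(1, Q / (J - 1)))` where Q
#' is Cochran's heterogeneity statistic, so overdispersion widens the interval
#' but homogeneity never narrows it below the fixed-effect one.
#'
#' @param h A `harmonized_set` with at least 2 instruments.
#' @param model `"mre"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return An `mr_estimate`; `extra` carries `q`, `q_df`, `q_pval` and the
#'   applied `scale`.
#' @export
mr_ivw <- function(h, model = c("mre", "fixed")) {
  model <- match.arg(model)
  J <- n_instruments(h)
  if (J < 2) stop("insufficient instruments for IVW (need >= 2)")
  w <- h$beta_exp^2 / h$se_out^2
  ratio <- h$beta_out / h$beta_exp
  beta <- sum(w * ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (ratio - beta)^2)
  scale <- if (model == "mre") sqrt(max(1, q / (J - 1))) else 1
  se <- se_fixed * scale
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(if (model == "mre") "ivw_mre" else "ivw_fe",
                  beta, se, pval, J,
                  extra = list(q = q, q_df = J - 1,
                               q_pval = stats::pchisq(q, J - 1,
                                                      lower.tail = FALSE),
                               scale = scale))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept, weights `1 / se_out^2`, after orienting every SNP
#' so that its exposure effect is nonnegative (required for identifiability
#' of the intercept). The slope is the causal estimate; a nonzero intercept
#' indicates directional horizontal pleiotropy. Standard errors use a
#' multiplicative overdispersion scale floored at 1
#' (`max(1, RSS_w / (J - 2))`) and p-values a t reference with `J - 2` df.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @return An `mr_estimate` for the slope; `extra` carries `intercept`,
#'   `intercept_se`, `intercept_pval`, and the overdispersion `scale`.
#' @export
mr_egger <- function(h) {
  J <- n_instruments(h)
  if (J < 3) stop("insufficient instruments for Egger (need >= 3)")
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  x <- h$beta_exp * flip
  y <- h$beta_out * flip
  if (stats::sd(x) == 0)
    stop("MR-Egger requires variation in instrument strength ",
         "(all oriented exposure effects are identical)")
  w <- 1 / h$se_out^2
  fit <- stats::lm(y ~ x, weights = w)
  # exactly collinear inputs trigger summary.lm's "essentially perfect fit"
  # warning; the floored dispersion handles that case correctly
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w2) {
      if (grepl("essentially perfect fit", conditionMessage(w2)))
        invokeRestart("muffleWarning")
    })
  # lm's sigma estimates sqrt(RSS_w / (J - 2)); floor the dispersion at 1 so
  # underdispersed data do not shrink the SEs below the analytic ones
  coefs <- sm$coefficients
  se_scale <- 1 / min(1, sm$sigma)
  slope <- coefs["x", "Estimate"]
  slope_se <- coefs["x", "Std. Error"] * se_scale
  inter <- coefs["(Intercept)", "Estimate"]
  inter_se <- coefs["(Intercept)", "Std. Error"] * se_scale
  df <- J - 2
  slope_p <- 2 * stats::pt(-abs(slope / slope_se), df)
  inter_p <- 2 * stats::pt(-abs(inter / inter_se), df)
  new_mr_estimate("egger", slope, slope_se, slope_p, J,
                  extra = list(intercept = inter, intercept_se = inter_se,
                               intercept_pval = inter_p,
                               scale = max(1, sm$sigma^2), df = df))
}

# Weighted median of values x with weights w: order by x, form cumulative
# midpoints s_j = cumsum(w')_j - w'_j / 2 with normalized weights, and
# linearly interpolate x at s = 0.5.
weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' The inverse-variance weighted median of the Wald ratios: consistent as long
#' as SNPs contributing at least half of the weight are valid instruments,
#' so it tolerates up to 50% invalid instruments. The SE comes from a
#' parametric bootstrap: per-SNP exposure and outcome effects are resampled
#' from normal distributions centred on the observed effects with the
#' reported SEs, the weighted median recomputed, and the SD over draws taken.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param n_boot Bootstrap draws; default 1000.
#' @param seed RNG seed for the bootstrap (required for reproducible output).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  J <- n_instruments(h)
  if (J < 3) stop("insufficient instruments for weighted median (need >= 3)")
  w <- h$beta_exp^2 / h$se_out^2
  est <- weighted_median(h$beta_out / h$beta_exp, w)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    be <- stats::rnorm(J, h$beta_exp, h$se_exp)
    bo <- stats::rnorm(J, h$beta_out, h$se_out)
    ok <- be != 0
    weighted_median(bo[ok] / be[ok], be[ok]^2 / h$se_out[ok]^2)
  }, numeric(1))
  se <- stats::sd(boots)
  pval <- 2 * stats::pnorm(-abs(est / se))
  new_mr_estimate("weighted_median", est, se, pval, J)
}

#' Maximum-likelihood estimator
#'
#' Joint normal model with per-SNP nuisance true exposure effects gamma_j:
#' `beta_exp_j ~ N(gamma_j, se_exp_j^2)` and
#' `beta_out_j ~ N(b * gamma_j, se_out_j^2)`, independent across SNPs and
#' between samples (two-sample design). For fixed b the gamma_j maximize in
#' closed form, leaving a one-dimensional profile likelihood in b which is
#' maximized numerically; the SE comes from the curvature of the profile
#' log-likelihood at the maximum. Unlike IVW, measurement error on the
#' exposure side is modelled rather than ignored.
#'
#' @param h A `harmonized_set` with at least 2 instruments.
#' @return An `mr_estimate`.
#' @export
mr_max_likelihood <- function(h) {
  J <- n_instruments(h)
  if (J < 2) stop("insufficient instruments for maximum likelihood (need >= 2)")
  v_exp <- h$se_exp^2; v_out <- h$se_out^2
  b_exp <- h$beta_exp; b_out <- h$beta_out
  # profile log-likelihood (up to a constant): maximize over gamma_j at fixed b
  pll <- function(b) {
    g <- (b_exp / v_exp + b * b_out / v_out) / (1 / v_exp + b^2 / v_out)
    -0.5 * sum((b_exp - g)^2 / v_exp + (b_out - b * g)^2 / v_out)
  }
  start <- mr_ivw(h, model = "fixed")$beta
  span <- max(1, 10 * abs(start))
  for (k in 1:10) {
    opt <- stats::optimize(pll, interval = c(start - span, start + span),
                           maximum = TRUE, tol = 1e-10)
    at_edge <- abs(opt$maximum - start) > 0.99 * span
    if (!at_edge) break
    span <- span * 4   # widen until the optimum is interior
  }
  b_hat <- opt$maximum
  eps <- max(1e-6, abs(b_hat) * 1e-5)
  curv <- (pll(b_hat + eps) - 2 * pll(b_hat) + pll(b_hat - eps)) / eps^2
  if (!is.finite(curv) || curv >= 0)
    stop("maximum-likelihood estimation failed: non-concave profile at optimum ",
         "(b_hat = ", signif(b_hat, 4), ")")
  se <- sqrt(-1 / curv)
  pval <- 2 * stats::pnorm(-abs(b_hat / se))
  new_mr_estimate("max_likelihood", b_hat, se, pval, J)
}

#' Run all applicable estimators on a harmonized set
#'
#' IVW (multiplicative random effects, the primary method) and maximum
#' likelihood need >= 2 instruments; MR-Egger and the weighted median need
#' >= 3 and are omitted below that. With exactly one instrument the single
#' Wald ratio is reported.
#'
#' @param h A `harmonized_set`.
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @return Named list of `mr_estimate` objects.
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = NULL) {
  J <- n_instruments(h)
  out <- list()
  if (J == 1) {
    wr <- wald_ratios(h)
    out$wald <- new_mr_estimate("wald", wr$ratio, wr$se,
                                2 * stats::pnorm(-abs(wr$ratio / wr$se)), 1L)
    return(out)
  }
  out$ivw_mre <- mr_ivw(h, "mre")
  out$ivw_fe <- mr_ivw(h, "fixed")
  out$max_likelihood <- mr_max_likelihood(h)
  if (J >= 3) {
    out$egger <- mr_egger(h)
    out$weighted_median <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
  }
  out
}
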