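# Cross-cohort meta-analysis of MR estimates (fixed effect and
# DerSimonian-Laird random effects) plus Bonferroni multiple-testing control.

new_meta_result <- function(model, beta, se, q, df, i2, tau2, inputs) {
  pval <- 2 * stats::pnorm(-abs(beta / se))
  ors <- to_odds_ratio(beta, se)
  structure(list(model = model, beta = beta, se = se, pval = pval,
                 or_ = ors$or_, ci_low = ors$ci_low, ci_high = ors$ci_high,
                 q_meta = q, q_df_meta = df, i2 = i2, tau2 = tau2,
                 inputs = inputs),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effect meta-analysis of %d estimates: beta = %.4f (SE %.4f), p = %.3g, I2 = %.2f\n",
              x$model, nrow(x$inputs), x$beta, x$se, x$pval, x$i2))
  invisible(x)
}

meta_inputs <- function(beta, se) {
  stopifnot(length(beta) == length(se), all(se > 0))
  data.frame(beta = beta, se = se)
}

#' Fixed-effect meta-analysis
#'
#' Inverse-variance pooling: weights `1/se²`, pooled beta the weighted mean,
#' pooled SE `sqrt(1/sum(w))`. The across-study heterogeneity statistic
#' `Q = sum(w * (beta - pooled)^2)` (df = k - 1) and its I² transform are
#' reported alongside.
#'
#' @param beta,se Numeric vectors of per-cohort estimates and SEs.
#' @return A `meta_result` (with a warning and pass-through when only one
#'   estimate is supplied).
#' @export
meta_fixed <- function(beta, se) {
  inp <- meta_inputs(beta, se)
  if (nrow(inp) < 2) {
    warning("fewer than 2 estimates: returning the single estimate unpooled")
    return(new_meta_result("fixed", inp$beta, inp$se, 0, 0L, 0, 0, inp))
  }
  w <- 1 / inp$se^2
  pooled <- sum(w * inp$beta) / sum(w)
  q <- sum(w * (inp$beta - pooled)^2)
  df <- nrow(inp) - 1L
  new_meta_result("fixed", pooled, sqrt(1 / sum(w)), q, df,
                  i_squared(q, df), 0, inp)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-cohort variance
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with the
#' fixed-effect weights, then inverse-variance pooling with the inflated
#' weights `1 / (se^2 + tau2)`.
#'
#' @inheritParams meta_fixed
#' @return A `meta_result`.
#' @export
meta_random_dl <- function(beta, se) {
  inp <- meta_inputs(beta, se)
  if (nrow(inp) < 2) {
    warning("fewer than 2 estimates: returning the single estimate unpooled")
    return(new_meta_result("random", inp$beta, inp$se, 0, 0L, 0, 0, inp))
  }
  w <- 1 / inp$se^2
  pooled_fe <- sum(w * inp$beta) / sum(w)
  q <- sum(w * (inp$beta - pooled_fe)^2)
  df <- nrow(inp) - 1L
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (inp$se^2 + tau2)
  new_meta_result("random", sum(ws * inp$beta) / sum(ws), sqrt(1 / sum(ws)),
                  q, df, i_squared(q, df), tau2, inp)
}

#' Higgins' I-squared heterogeneity proportion
#'
#' `max(0, (Q - df) / Q)` for `Q > 0`, and 0 at `Q = 0`.
#'
#' @param q Cochran's Q (>= 0).
#' @param df Its degrees of freedom (>= 1).
#' @return I² as a fraction in `[0, 1]`.
#' @export
i_squared <- function(q, df) {
  stopifnot(q >= 0, df >= 1)
  if (q == 0) return(0)
  max(0, (q - df) / q)
}

#' Choose the pooling model from I-squared
#'
#' Random effects when heterogeneity exceeds the threshold (default 30%,
#' strict inequality, so I² exactly at the threshold stays fixed-effect).
#'
#' @param i2 I² in `[0, 1]`.
#' @param threshold Heterogeneity cutoff; default 0.30.
#' @return `"random"` or `"fixed"`.
#' @export
choose_model <- function(i2, threshold = 0.30) {
  stopifnot(i2 >= 0, i2 <= 1)
  if (i2 > threshold) "random" else "fixed"
}

#' Meta-analyse with the model chosen by heterogeneity
#'
#' Computes the fixed-effect Q/I² first, then re-pools with
#' DerSimonian-Laird when [choose_model()] calls for random effects.
#'
#' @inheritParams meta_fixed
#' @param i2_threshold Passed to [choose_model()].
#' @param model Optional override (`"fixed"` or `"random"`) bypassing the
#'   automatic choice.
#' @return A `meta_result`.
#' @export
meta_auto <- function(beta, se, i2_threshold = 0.30, model = NULL) {
  fe <- meta_fixed(beta, se)
  if (is.null(model)) model <- choose_model(fe$i2, i2_threshold)
  if (model == "random") meta_random_dl(beta, se) else fe
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate; default 0.05.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Classify a p-value into the significance ladder
#'
#' `"bonferroni"` below `alpha/m`, `"nominal"` between `alpha/m` and `alpha`
#' (suggestive of a potential causal association), `"null"` at or above
#' `alpha`.
#'
#' @param pval P-value(s).
#' @param m Number of tests in the family.
#' @param alpha Nominal level; default 0.05.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(pval, m, alpha = 0.05) {
  thr <- bonferroni(alpha, m)
  ifelse(pval < thr, "bonferroni", ifelse(pval < alpha, "nominal", "null"))
}
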