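# Sensitivity diagnostics for one exposure-outcome pair: Cochran's Q
# heterogeneity across instruments, the Egger intercept test for directional
# pleiotropy, and the Steiger directionality test.

#' Cochran's Q heterogeneity test across instruments
#'
#' `Q = sum(w_j * (ratio_j - beta_ivw)^2)` with the IVW weights
#' `w_j = beta_exp_j^2 / se_out_j^2`; under instrument homogeneity Q follows
#' a chi-square with `J - 1` degrees of freedom. This is the same Q that
#' scales the multiplicative random-effects SE in [mr_ivw()].
#'
#' @param h A `harmonized_set` with at least 2 instruments.
#' @param beta_ivw Optional IVW point estimate to test around; defaults to
#'   the fixed-effect IVW estimate computed from `h`.
#' @return List with `q`, `df`, `pval`.
#' @export
cochrans_q <- function(h, beta_ivw = NULL) {
  J <- n_instruments(h)
  if (J < 2) stop("Cochran's Q requires >= 2 instruments")
  w <- h$beta_exp^2 / h$se_out^2
  ratio <- h$beta_out / h$beta_exp
  if (is.null(beta_ivw)) beta_ivw <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - beta_ivw)^2)
  df <- J - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Egger intercept test for directional pleiotropy
#'
#' Delegates to [mr_egger()] and returns its intercept triple. An intercept
#' significantly different from zero indicates directional horizontal
#' pleiotropy biasing the IVW estimate.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @return List with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  e <- mr_egger(h)$extra
  list(intercept = e$intercept, se = e$intercept_se, pval = e$intercept_pval)
}

# Variance explained by one SNP in a binary trait on the liability-ish scale:
# the log-odds beta is converted via the logistic-variance approximation
# r2 = v / (v + pi^2 / 3) with v = 2*eaf*(1-eaf)*beta^2. Isolated here so the
# conversion can be swapped out wholesale.
r2_binary_logodds <- function(eaf, beta) {
  v <- 2 * eaf * (1 - eaf) * beta^2
  v / (v + pi^2 / 3)
}

#' Effective sample size for a case-control GWAS
#'
#' `4 / (1 / cases + 1 / controls)`, the usual effective-N for unbalanced
#' binary designs.
#'
#' @param cases,controls Case and control counts.
#' @return Effective sample size.
#' @export
effective_n <- function(cases, controls) 4 / (1 / cases + 1 / controls)

#' Steiger directionality test
#'
#' Compares the total variance the instruments explain in the exposure with
#' the variance they explain in the outcome: valid instruments for a causal
#' exposure should explain more variance in the exposure. Per-SNP r² on a
#' standardized continuous trait is `2*eaf*(1-eaf)*beta²`; for a binary
#' outcome the log-odds effect is converted with a logistic-variance
#' approximation and the effective case-control sample size is used. The
#' p-value is a Fisher-z test comparing the two correlation magnitudes
#' `r = sqrt(r2)` with their respective sample sizes.
#'
#' A tie (`r2_exp == r2_out`) is conservatively reported as NOT the correct
#' direction.
#'
#' @param h A `harmonized_set`; exposure-side eaf must be present.
#' @param n_exp,n_out Sample sizes; default to those stored in `h`
#'   (`n_out` is replaced by the effective N when `cases`/`controls` given).
#' @param outcome_binary Is the outcome a binary (log-odds) trait?
#' @param cases,controls Case-control counts for a binary outcome.
#' @return List with `correct_direction`, `pval`, `r2_exp`, `r2_out`.
#' @export
mr_steiger <- function(h, n_exp = h$n_exp, n_out = h$n_out,
                       outcome_binary = TRUE, cases = NULL, controls = NULL) {
  if (any(is.na(h$eaf_exp)))
    stop("Steiger requires allele frequencies on the exposure side")
  eaf_out <- ifelse(is.na(h$eaf_out), h$eaf_exp, h$eaf_out)
  r2_exp <- sum(2 * h$eaf_exp * (1 - h$eaf_exp) * h$beta_exp^2)
  if (outcome_binary) {
    r2_out <- sum(r2_binary_logodds(eaf_out, h$beta_out))
    if (!is.null(cases) && !is.null(controls))
      n_out <- effective_n(cases, controls)
  } else {
    r2_out <- sum(2 * eaf_out * (1 - eaf_out) * h$beta_out^2)
  }
  if (is.na(n_exp) || is.na(n_out))
    stop("Steiger requires exposure and outcome sample sizes")
  r_exp <- sqrt(min(r2_exp, 1 - 1e-12))
  r_out <- sqrt(min(r2_out, 1 - 1e-12))
  z <- (atanh(r_exp) - atanh(r_out)) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(correct_direction = r2_exp > r2_out,
       pval = 2 * stats::pnorm(-abs(z)),
       r2_exp = r2_exp, r2_out = r2_out)
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran's Q, the Egger intercept test (when >= 3 instruments), and
#' the pair-level Steiger directionality test (when exposure eaf and sample
#' sizes are available) into one flat list suitable for appending to a
#' results table.
#'
#' @param h A `harmonized_set`.
#' @param beta_ivw Optional IVW estimate for Q (see [cochrans_q()]).
#' @param outcome_binary,cases,controls Passed to [mr_steiger()].
#' @return List of class `sensitivity_report`.
#' @export
sensitivity_report <- function(h, beta_ivw = NULL, outcome_binary = TRUE,
                               cases = NULL, controls = NULL) {
  out <- list(q = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
              egger_intercept = NA_real_, egger_intercept_se = NA_real_,
              egger_intercept_pval = NA_real_,
              steiger_dir = NA, steiger_pval = NA_real_,
              r2_exposure_total = NA_real_, r2_outcome_total = NA_real_)
  if (n_instruments(h) >= 2) {
    qq <- cochrans_q(h, beta_ivw)
    out$q <- qq$q; out$q_df <- qq$df; out$q_pval <- qq$pval
  }
  if (n_instruments(h) >= 3) {
    eg <- egger_intercept_test(h)
    out$egger_intercept <- eg$intercept
    out$egger_intercept_se <- eg$se
    out$egger_intercept_pval <- eg$pval
  }
  steiger_ok <- !any(is.na(h$eaf_exp)) && !is.na(h$n_exp) &&
    (!is.na(h$n_out) || (!is.null(cases) && !is.null(controls)))
  if (steiger_ok) {
    st <- mr_steiger(h, outcome_binary = outcome_binary,
                     cases = cases, controls = controls)
    out$steiger_dir <- st$correct_direction
    out$steiger_pval <- st$pval
    out$r2_exposure_total <- st$r2_exp
    out$r2_outcome_total <- st$r2_out
  }
  structure(out, class = "sensitivity_report")
}
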