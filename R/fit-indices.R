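#' Chi-square test of exact fit
#'
#' The minimized maximum-likelihood discrepancy times the chi-square
#' multiplier (`N-1` under the Wishart convention, or `N`), referred to the
#' central chi-square distribution with the model's degrees of freedom. A
#' saturated model (df = 0) has p defined as 1.
#'
#' @param f Minimized discrepancy, `>= 0`.
#' @param n Sample size, `> 1`.
#' @param df Model degrees of freedom, `>= 0`.
#' @param multiplier `"N-1"` (default) or `"N"`.
#' @return List with `chi2` and `p`.
#' @examples
#' chi_square_test(15.82 / 1253, n = 1254, df = 5)
#' @export
chi_square_test <- function(f, n, df, multiplier = c("N-1", "N")) {
  multiplier <- match.arg(multiplier)
  check_scalar_number(f, "f"); check_scalar_number(n, "n")
  if (f < 0) stop_field("f", "must be >= 0")
  if (n <= 1) stop_field("n", "must be > 1")
  df <- check_count(df, "df", min = 0L)
  chi2 <- if (multiplier == "N-1") (n - 1) * f else n * f
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, p = p)
}

#' Standardized root mean residual
#'
#' Root of the mean, over the `p(p+1)/2` unique elements, of the squared
#' correlation-scale residuals `(s_ij - sigma_ij) / sqrt(s_ii s_jj)`.
#'
#' @param s Sample covariance matrix (positive diagonal).
#' @param sigma Model-implied covariance matrix.
#' @return Nonnegative scalar.
#' @export
srmr <- function(s, sigma) {
  s <- as.matrix(s); sigma <- as.matrix(sigma)
  if (!all(dim(s) == dim(sigma))) stop_field("sigma", "must be conformable with `s`")
  d <- diag(s)
  if (any(d <= 0)) stop_field("s", "diagonal must be positive")
  sc <- sqrt(outer(d, d))
  r <- (s - sigma) / sc
  ut <- upper.tri(r, diag = TRUE)
  sqrt(mean(r[ut]^2))
}

#' RMSEA point estimate and confidence interval
#'
#' Point estimate `sqrt(max(chi2 - df, 0) / (df * (N - 1)))`; interval bounds
#' obtained by inverting the noncentral chi-square distribution in its
#' noncentrality parameter (bisection to 1e-8) and mapping through the same
#' transform. A bound that hits the lower boundary is reported as 0.
#'
#' @param chi2 Observed chi-square statistic.
#' @param df Degrees of freedom, `> 0` (RMSEA is undefined at df = 0).
#' @param n Sample size.
#' @param confidence Interval level, default 0.90.
#' @return List with `rmsea`, `lower`, `upper`.
#' @examples
#' rmsea_with_ci(15.82, df = 5, n = 1254)
#' @export
rmsea_with_ci <- function(chi2, df, n, confidence = 0.90) {
  check_scalar_number(chi2, "chi2"); check_scalar_number(n, "n")
  df <- check_count(df, "df", min = 0L)
  if (df == 0) stop_field("df", "RMSEA is undefined for a saturated model (df = 0)")
  if (chi2 < 0) stop_field("chi2", "must be >= 0")
  check_probability(confidence, "confidence")
  point <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  alpha <- (1 - confidence) / 2
  # lambda such that P(X <= chi2 | df, ncp = lambda) = prob
  invert_ncp <- function(prob) {
    if (pchisq(chi2, df, ncp = 0) <= prob) return(0)
    lo <- 0; hi <- max(chi2, 1)
    while (pchisq(chi2, df, ncp = hi) > prob) hi <- hi * 2
    while (hi - lo > 1e-8) {
      mid <- (lo + hi) / 2
      if (pchisq(chi2, df, ncp = mid) > prob) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lam_lower <- invert_ncp(1 - alpha)
  lam_upper <- invert_ncp(alpha)
  list(
    rmsea = point,
    lower = sqrt(lam_lower / (df * (n - 1))),
    upper = sqrt(lam_upper / (df * (n - 1)))
  )
}

#' Bentler-Bonett normed fit index
#'
#' `(chi2_null - chi2_model) / chi2_null`, where the null is the independence
#' model (all covariances fixed at zero, variances free) fitted by the same
#' engine on the same sample covariance.
#'
#' @param chi2_model Model chi-square.
#' @param chi2_null Independence-model chi-square, `> 0`.
#' @return Scalar `<= 1`.
#' @export
bb_nfi <- function(chi2_model, chi2_null) {
  check_scalar_number(chi2_model, "chi2_model")
  check_scalar_number(chi2_null, "chi2_null")
  if (chi2_null <= 0) {
    stop_field("chi2_null", "must be > 0 (NFI undefined for a zero null chi-square)")
  }
  (chi2_null - chi2_model) / chi2_null
}

#' Full fit-index set for a fitted path model
#'
#' Computes the chi-square test, SRMR, RMSEA with confidence interval, and
#' the Bentler-Bonett NFI (via an independence-model fit on the same sample
#' covariance), then applies the two-of-four adequacy rule: adequate fit is
#' any two of a nonsignificant chi-square test, RMSEA upper CI bound under
#' 0.08, SRMR under 0.05, or BB-NFI over 0.95.
#'
#' @param fit A [fit_clpm()] object.
#' @param confidence RMSEA interval level.
#' @param alpha Significance level for the chi-square criterion.
#' @return Object of class `fit_index_set`: a one-row tibble with `chi2`,
#'   `df`, `p_chi2`, `srmr`, `rmsea`, `rmsea_lower`, `rmsea_upper`, `bb_nfi`,
#'   `adequate`, plus a `criteria` attribute listing which criteria held.
#' @export
fit_indices <- function(fit, confidence = 0.90, alpha = 0.05) {
  if (!inherits(fit, "clpm_fit")) stop_field("fit", "must be a clpm_fit")
  ct <- chi_square_test(fit$discrepancy, fit$n, fit$df,
                        multiplier = fit$chi2_multiplier)
  sr <- srmr(fit$sample_cov, fit$implied_cov)
  if (fit$df > 0) {
    rm <- rmsea_with_ci(ct$chi2, fit$df, fit$n, confidence)
  } else {
    rm <- list(rmsea = 0, lower = 0, upper = 0)
  }
  null_fit <- fit_clpm(independence_spec(fit$spec$vars),
                       sample_cov = fit$sample_cov, n = fit$n,
                       chi2_multiplier = fit$chi2_multiplier)
  ct_null <- chi_square_test(null_fit$discrepancy, null_fit$n, null_fit$df,
                             multiplier = fit$chi2_multiplier)
  nfi <- bb_nfi(ct$chi2, ct_null$chi2)
  adequacy(tibble(
    chi2 = ct$chi2, df = fit$df, p_chi2 = ct$p, srmr = sr,
    rmsea = rm$rmsea, rmsea_lower = rm$lower, rmsea_upper = rm$upper,
    bb_nfi = nfi
  ), alpha = alpha)
}

#' Apply the two-of-four adequacy rule to a fit-index set
#'
#' @param indices One-row data frame with columns `p_chi2`, `rmsea_upper`,
#'   `srmr`, `bb_nfi` (as produced inside [fit_indices()]).
#' @param alpha Chi-square significance level (criterion is `p > alpha`).
#' @return The input as a `fit_index_set` tibble with an added `adequate`
#'   column and a `criteria` attribute (named logical of the four rules).
#' @export
adequacy <- function(indices, alpha = 0.05) {
  need <- c("p_chi2", "rmsea_upper", "srmr", "bb_nfi")
  if (!all(need %in% names(indices))) {
    stop_field("indices", paste("must contain", paste(need, collapse = ", ")))
  }
  crit <- c(
    chi2_nonsignificant = indices$p_chi2 > alpha,
    rmsea_upper_lt_0.08 = indices$rmsea_upper < 0.08,
    srmr_lt_0.05 = indices$srmr < 0.05,
    nfi_gt_0.95 = indices$bb_nfi > 0.95
  )
  out <- as_tibble(indices)
  out$adequate <- sum(crit) >= 2L
  attr(out, "criteria") <- crit
  class(out) <- c("fit_index_set", class(out))
  out
}

#' @export
print.fit_index_set <- function(x, ...) {
  cat(sprintf(
    paste0("<fit_index_set> chi2 = %.3f (df = %d, p = %.4g), SRMR = %.4f,\n",
           "  RMSEA = %.4f [%.4f, %.4f], BB-NFI = %.4f -> %s (%d/4 criteria)\n"),
    x$chi2, x$df, x$p_chi2, x$srmr, x$rmsea, x$rmsea_lower, x$rmsea_upper,
    x$bb_nfi, if (x$adequate) "adequate" else "inadequate",
    sum(attr(x, "criteria"))
  ))
  invisible(x)
}
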