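#' Polyserial or polychoric correlation (two-step estimator)
#'
#' Estimates the correlation of the latent bivariate normal variables assumed
#' to underlie an ordinal variable and either a continuous variable
#' (polyserial) or a second ordinal variable (polychoric). The two-step
#' estimator first fixes the thresholds at the inverse-normal transforms of
#' the cumulative marginal proportions (and, for the polyserial case,
#' standardizes the continuous variable by its sample moments), then maximizes
#' the bivariate-normal likelihood over the single correlation parameter on
#' (-1, 1).
#'
#' @param x For `kind = "polyserial"`, a numeric (continuous) vector; for
#'   `"polychoric"`, an ordinal vector (integer codes or ordered factor).
#' @param y An ordinal vector (integer codes or ordered factor).
#' @param kind `"polyserial"` or `"polychoric"`.
#' @return The estimated latent correlation (length-1 numeric).
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(500)
#' y <- cut(z + rnorm(500), c(-Inf, -1, 0, 1, Inf), labels = FALSE) - 1
#' latent_correlation(z, y, "polyserial")
latent_correlation <- function(x, y, kind = c("polyserial", "polychoric")) {
  kind <- match.arg(kind)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) abort("Too few complete observations.")
  y <- as_ordinal_codes(y)
  if (length(unique(y)) < 2) {
    abort("`y` has a single observed category; latent correlation undefined.")
  }
  if (kind == "polyserial") {
    if (sd(x) == 0) abort("`x` has zero variance.")
    polyserial_twostep(x, y)
  } else {
    x <- as_ordinal_codes(x)
    if (length(unique(x)) < 2) {
      abort("`x` has a single observed category; latent correlation undefined.")
    }
    polychoric_twostep(x, y)
  }
}

as_ordinal_codes <- function(v) {
  if (is.factor(v)) return(as.integer(v))
  if (!is.numeric(v)) abort("Ordinal variables must be numeric codes or factors.")
  as.integer(v)
}

marginal_thresholds <- function(codes) {
  p <- table(codes) / length(codes)
  qnorm(cumsum(p)[-length(p)])
}

polyserial_twostep <- function(x, y) {
  z <- (x - mean(x)) / sd(x)
  tau <- marginal_thresholds(y)
  # map observed codes to 1..K
  lev <- sort(unique(y))
  k <- match(y, lev)
  lo <- c(-Inf, tau)[k]
  hi <- c(tau, Inf)[k]
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    -sum(log(pmax(pnorm((hi - rho * z) / s) - pnorm((lo - rho * z) / s), 1e-300)))
  }
  optimize(nll, c(-0.999, 0.999), tol = 1e-8)$minimum
}

# bivariate standard normal CDF at (x, y)
binorm_cdf <- function(x, y, rho) {
  if (is.infinite(x) && x > 0) return(pnorm(y))
  if (is.infinite(y) && y > 0) return(pnorm(x))
  if (is.infinite(x) || is.infinite(y)) {
    if (x == -Inf || y == -Inf) return(0)
  }
  mvtnorm::pmvnorm(upper = c(x, y),
                   corr = matrix(c(1, rho, rho, 1), 2))[1]
}

polychoric_twostep <- function(x, y) {
  lev_x <- sort(unique(x)); lev_y <- sort(unique(y))
  tab <- table(factor(x, lev_x), factor(y, lev_y))
  tau_x <- c(-Inf, marginal_thresholds(x), Inf)
  tau_y <- c(-Inf, marginal_thresholds(y), Inf)
  nr <- length(lev_x); nc <- length(lev_y)
  nll <- function(rho) {
    cdf <- matrix(0, nr + 1, nc + 1)
    for (i in seq_len(nr + 1)) {
      for (j in seq_len(nc + 1)) {
        cdf[i, j] <- binorm_cdf(tau_x[i], tau_y[j], rho)
      }
    }
    p <- cdf[-1, -1, drop = FALSE] - cdf[-(nr + 1), -1, drop = FALSE] -
      cdf[-1, -(nc + 1), drop = FALSE] + cdf[-(nr + 1), -(nc + 1), drop = FALSE]
    -sum(tab * log(pmax(p, 1e-300)))
  }
  optimize(nll, c(-0.999, 0.999), tol = 1e-8)$minimum
}

#' Cronbach's coefficient alpha
#'
#' Internal-consistency reliability of a sum score:
#' alpha = k/(k-1) (1 - sum of item variances / total-score variance).
#'
#' @param items A numeric matrix or data frame, respondents in rows, items in
#'   columns; complete rows required.
#' @return Coefficient alpha (length-1 numeric).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2 || nrow(m) < 2) abort("Need at least 2 items and 2 respondents.")
  if (anyNA(m)) abort("`items` must have complete rows.")
  k <- ncol(m)
  total_var <- var(rowSums(m))
  if (total_var == 0) abort("Total-score variance is zero; alpha undefined.")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Compare two dependent overlapping correlations (Zou's CI)
#'
#' Confidence interval for the difference between two correlations that share
#' a variable (r_jk vs r_jh, with r_kh the correlation of the two non-shared
#' variables), using Zou's (2007) modified asymptotic method: per-correlation
#' Fisher-z confidence limits are combined with the asymptotic correlation
#' between the two correlation estimates.
#'
#' @param r_jk,r_jh The two correlations being compared (sharing variable j).
#' @param r_kh Correlation between the non-shared variables.
#' @param n Sample size (common to all three correlations).
#' @param confidence Confidence level (default 0.95).
#' @return A tibble with the difference, CI bounds, and whether the CI
#'   excludes zero.
#' @export
#' @examples
#' compare_dependent_correlations(0.8, 0.6, 0.5, n = 200)
compare_dependent_correlations <- function(r_jk, r_jh, r_kh, n,
                                           confidence = 0.95) {
  rs <- c(r_jk, r_jh, r_kh)
  if (any(abs(rs) >= 1)) abort("Correlations must lie strictly within (-1, 1).")
  if (n <= 3) abort("`n` must exceed 3.")
  zcrit <- qnorm(1 - (1 - confidence) / 2)
  fisher_ci <- function(r) {
    z <- atanh(r)
    tanh(z + c(-1, 1) * zcrit / sqrt(n - 3))
  }
  ci1 <- fisher_ci(r_jk); ci2 <- fisher_ci(r_jh)
  l1 <- ci1[1]; u1 <- ci1[2]; l2 <- ci2[1]; u2 <- ci2[2]
  # asymptotic correlation between the two estimated correlations
  c_r <- ((r_kh * (1 - r_jk^2 - r_jh^2) -
             0.5 * r_jk * r_jh * (1 - r_jk^2 - r_jh^2 - r_kh^2)) /
            ((1 - r_jk^2) * (1 - r_jh^2)))
  diff <- r_jk - r_jh
  lower <- diff - sqrt((r_jk - l1)^2 + (u2 - r_jh)^2 -
                         2 * c_r * (r_jk - l1) * (u2 - r_jh))
  upper <- diff + sqrt((u1 - r_jk)^2 + (r_jh - l2)^2 -
                         2 * c_r * (u1 - r_jk) * (r_jh - l2))
  tibble::tibble(
    r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n,
    difference = diff, ci_lower = lower, ci_upper = upper,
    confidence = confidence,
    excludes_zero = lower > 0 | upper < 0
  )
}

#' Cohen's d for a subgroup versus its complement, from reported moments
#'
#' Recovers the complement group's mean and standard deviation from the
#' subgroup and full-sample moments by exact sum-of-squares decomposition,
#' then computes Cohen's d with the pooled (n-1 weighted) standard deviation
#' and a normal-approximation confidence interval.
#'
#' @param n1,m1,s1 Subgroup size, mean, and SD.
#' @param N,M,S Full-sample size, mean, and SD.
#' @param confidence Confidence level (default 0.95).
#' @return A tibble with `effect = "cohens_d"`, the estimate, CI bounds, and
#'   the recovered complement moments (`m2`, `s2`).
#' @export
#' @examples
#' cohens_d_from_moments(102, 29.69, 10.97, 1403, 32.27, 12.55)
cohens_d_from_moments <- function(n1, m1, s1, N, M, S, confidence = 0.95) {
  if (n1 >= N) abort("Subgroup size must be smaller than the full sample.")
  if (s1 <= 0 || S <= 0) abort("Standard deviations must be positive.")
  n2 <- N - n1
  m2 <- (N * M - n1 * m1) / n2
  ss2 <- (N - 1) * S^2 - (n1 - 1) * s1^2 -
    n1 * (m1 - M)^2 - n2 * (m2 - M)^2
  if (ss2 < -1e-8 * (N - 1) * S^2) {
    abort("Reported moments are inconsistent (negative complement variance).")
  }
  s2 <- sqrt(max(ss2, 0) / (n2 - 1))
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (N - 2))
  d <- (m1 - m2) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  zcrit <- qnorm(1 - (1 - confidence) / 2)
  tibble::tibble(
    effect = "cohens_d", estimate = d,
    ci_lower = d - zcrit * se, ci_upper = d + zcrit * se,
    confidence = confidence, m2 = m2, s2 = s2
  )
}

#' Odds ratio from a 2x2 table
#'
#' OR = (a d) / (b c) with the Woolf logit confidence interval; no continuity
#' correction is applied.
#'
#' @param a,b,c,d Cell counts: rows = group (1, 2), columns = outcome
#'   (present, absent); `a` and `b` are the outcome-present counts of the two
#'   groups.
#' @param confidence Confidence level (default 0.95).
#' @return A tibble with `effect = "odds_ratio"`, the estimate, and CI bounds.
#' @export
#' @examples
#' odds_ratio(74, 28, 643, 658)
odds_ratio <- function(a, b, c, d, confidence = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (any(counts == 0)) {
    abort(paste("Zero cell count; the odds ratio is undefined.",
                "Consider adding a 0.5 continuity correction to every cell."))
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zcrit <- qnorm(1 - (1 - confidence) / 2)
  tibble::tibble(
    effect = "odds_ratio", estimate = or,
    ci_lower = exp(log(or) - zcrit * se),
    ci_upper = exp(log(or) + zcrit * se),
    confidence = confidence
  )
}
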