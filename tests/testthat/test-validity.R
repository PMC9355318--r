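test_that("polyserial correlation recovers the latent correlation", {
  set.seed(401)
  n <- 5000
  rho <- 0.6
  x <- rnorm(n)
  ylat <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  y <- as.integer(cut(ylat, c(-Inf, qnorm(c(0.25, 0.5, 0.75)), Inf))) - 1L
  expect_equal(latent_correlation(x, y, "polyserial"), rho, tolerance = 0.05)
  # independent variables: estimate near zero
  expect_lt(abs(latent_correlation(rnorm(n), y, "polyserial")), 0.05)
})

test_that("polychoric correlation recovers strong latent association", {
  set.seed(402)
  n <- 5000
  z <- rnorm(n)
  x <- as.integer(cut(z + 0.32 * rnorm(n), c(-Inf, -1, 0, 1, Inf))) - 1L
  y <- as.integer(cut(z + 0.32 * rnorm(n), c(-Inf, -0.5, 0.5, 1.5, Inf))) - 1L
  est <- latent_correlation(x, y, "polychoric")
  expect_gt(est, 0.85)
  # fine discretization approaches the Pearson correlation of the latents
  z2 <- rnorm(n)
  w <- 0.6 * z2 + 0.8 * rnorm(n)
  cuts <- qnorm(seq(0.05, 0.95, length.out = 19))
  xz <- as.integer(cut(z2, c(-Inf, cuts, Inf)))
  xw <- as.integer(cut(w / sd(w), c(-Inf, cuts, Inf)))
  expect_equal(latent_correlation(xz, xw, "polychoric"), cor(z2, w),
               tolerance = 0.02)
  expect_error(latent_correlation(rep(1L, 100), y[1:100], "polychoric"),
               "single observed category")
})

test_that("coefficient alpha matches closed forms", {
  set.seed(403)
  # 6 parallel items with population pairwise correlation 0.6: alpha = 0.9
  n <- 20000
  z <- rnorm(n)
  items <- sapply(1:6, function(i) sqrt(0.6) * z + sqrt(0.4) * rnorm(n))
  expect_equal(cronbach_alpha(items), 6 * 0.6 / (1 + 5 * 0.6), tolerance = 0.02)
  # independent items: alpha near zero
  indep <- matrix(rnorm(n * 6), n, 6)
  expect_lt(abs(cronbach_alpha(indep)), 0.05)
  # duplicated column: alpha exactly 1
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "undefined")
})

test_that("dependent-correlation CI is symmetric and tightens with n", {
  r <- compare_dependent_correlations(0.5, 0.5, 0.3, n = 100)
  expect_equal(r$difference, 0)
  expect_equal(r$ci_lower, -r$ci_upper, tolerance = 1e-12)
  expect_true(r$ci_lower <= r$difference && r$difference <= r$ci_upper)
  wide <- compare_dependent_correlations(0.7, 0.5, 0.4, n = 100)
  narrow <- compare_dependent_correlations(0.7, 0.5, 0.4, n = 1000)
  expect_lt(narrow$ci_upper - narrow$ci_lower, wide$ci_upper - wide$ci_lower)
  expect_error(compare_dependent_correlations(1, 0.5, 0.3, 100), "strictly within")
})

test_that("Zou CI approaches the independent Fisher comparison when r_kh = 0", {
  r1 <- 0.6; r2 <- 0.3; n <- 5000
  zou <- compare_dependent_correlations(r1, r2, 0, n)
  # independent-correlation CI: same construction with zero estimate
  # correlation between the two sample correlations
  ci <- function(r) tanh(atanh(r) + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
  c1 <- ci(r1); c2 <- ci(r2)
  indep_lower <- (r1 - r2) - sqrt((r1 - c1[1])^2 + (c2[2] - r2)^2)
  indep_upper <- (r1 - r2) + sqrt((c1[2] - r1)^2 + (r2 - c2[1])^2)
  expect_equal(zou$ci_lower, indep_lower, tolerance = 0.005)
  expect_equal(zou$ci_upper, indep_upper, tolerance = 0.005)
  expect_true(zou$ci_lower < r1 - r2 && r1 - r2 < zou$ci_upper)
})

test_that("Cohen's d from moments reproduces constructed contrasts", {
  # identical groups: d = 0
  r0 <- cohens_d_from_moments(50, 10, 2, 150, 10, 2)
  expect_equal(r0$estimate, 0)
  # two unit-variance groups separated by 1.0
  n1 <- 400; n2 <- 600; m1 <- 1; m2 <- 0
  M <- (n1 * m1 + n2 * m2) / (n1 + n2)
  SS <- (n1 - 1) * 1 + (n2 - 1) * 1 + n1 * (m1 - M)^2 + n2 * (m2 - M)^2
  S <- sqrt(SS / (n1 + n2 - 1))
  r1 <- cohens_d_from_moments(n1, m1, 1, n1 + n2, M, S)
  expect_equal(r1$estimate, 1, tolerance = 1e-9)
  expect_equal(r1$m2, m2, tolerance = 1e-9)
  expect_equal(r1$s2, 1, tolerance = 1e-9)
  # round-trip property at random moments
  set.seed(404)
  for (i in 1:20) {
    g1 <- rnorm(37, 5, 2); g2 <- rnorm(63, 4, 3)
    tot <- c(g1, g2)
    r <- cohens_d_from_moments(37, mean(g1), sd(g1), 100, mean(tot), sd(tot))
    expect_equal(r$m2, mean(g2), tolerance = 1e-9)
    expect_equal(r$s2, sd(g2), tolerance = 1e-9)
  }
  expect_error(cohens_d_from_moments(10, 100, 1, 20, 0, 1), "inconsistent")
})

test_that("odds ratio matches closed form and is symmetric", {
  r <- odds_ratio(1, 1, 1, 1)
  expect_equal(r$estimate, 1)
  a <- odds_ratio(12, 7, 30, 45)
  b <- odds_ratio(7, 12, 45, 30)
  expect_equal(a$estimate, 1 / b$estimate, tolerance = 1e-12)
  expect_true(a$ci_lower < a$estimate && a$estimate < a$ci_upper)
  expect_error(odds_ratio(0, 5, 3, 2), "continuity")
})
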