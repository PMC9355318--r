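test_that("quadrature marginal likelihood matches brute-force integration", {
  # 2 items, 3 categories, unidimensional: every response pattern's marginal
  # probability from a fine rectangle rule vs adaptive 1-D integration
  a1 <- 1.4; a2 <- 0.9
  d1 <- c(0.8, -0.6); d2 <- c(0.3, -1.1)
  pat_prob_quad <- function(x1, x2, nodes) {
    w <- dnorm(nodes); w <- w / sum(w)
    p1 <- grm_probabilities(a1, d1, matrix(nodes))[, x1 + 1]
    p2 <- grm_probabilities(a2, d2, matrix(nodes))[, x2 + 1]
    sum(w * p1 * p2)
  }
  pat_prob_int <- function(x1, x2) {
    f <- function(t) {
      dnorm(t) *
        grm_probabilities(a1, d1, matrix(t))[, x1 + 1] *
        grm_probabilities(a2, d2, matrix(t))[, x2 + 1]
    }
    integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  nodes <- seq(-6, 6, length.out = 1001)
  for (x1 in 0:2) {
    for (x2 in 0:2) {
      expect_equal(pat_prob_quad(x1, x2, nodes), pat_prob_int(x1, x2),
                   tolerance = 1e-6)
    }
  }
})

test_that("EM ascends and recovers a small unidimensional model", {
  set.seed(701)
  a_true <- runif(6, 1, 2.2)
  m <- unidim_model(a_true, seed = 701)
  sim <- simulate_responses(m, 1200, screen = list(p = 1), seed = 702)
  fit <- fit_grm(sim, items = 1:6)
  expect_true(fit$engine$converged)
  expect_true(all(diff(fit$engine$trace) > -1e-8))
  expect_lt(sqrt(mean((fit$model$a[, 1] - a_true)^2)), 0.25)
  expect_lt(sqrt(mean((fit$model$d - m$d)^2)), 0.3)
  # glance carries the convergence record
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$n, 1200)
})

test_that("calibration input rules are enforced", {
  m <- unidim_model(c(1.5, 1.5, 1.5))
  sim <- simulate_responses(m, 300, screen = list(p = 1), seed = 703)
  # an item stuck in a single category is rejected
  sim$q02 <- 0L
  expect_error(fit_grm(sim, items = 1:3), "fewer than 2 categories")
  # non-convergence carries a warning and a flagged result
  sim2 <- simulate_responses(m, 300, screen = list(p = 1), seed = 704)
  expect_warning(f <- fit_grm(sim2, items = 1:3, n_cycles = 2), "did not converge")
  expect_false(f$engine$converged)
})

test_that("screen-negative and incomplete rows are excluded from calibration", {
  m <- unidim_model(c(1.6, 1.6, 1.6, 1.6))
  sim <- simulate_responses(m, 800, seed = 705) # logistic screen: some negatives
  fit <- fit_grm(sim, items = 1:4)
  expect_equal(fit$n, sum(sim$s1))
})

test_that("multigroup estimation recovers null and shifted focal means", {
  m <- unidim_model(runif(6, 1.3, 2), seed = 706)
  dat0 <- simulate_dif_study(m, m, n_per_group = 1500, impact = 0, seed = 707)
  fit0 <- fit_multigroup(dat0, items = 1:6, equated = "all")
  expect_lt(abs(fit0$focal_mean), 0.1)
  dat5 <- simulate_dif_study(m, m, n_per_group = 1500, impact = 0.5, seed = 708)
  fit5 <- fit_multigroup(dat5, items = 1:6, equated = "all")
  expect_lt(abs(fit5$focal_mean - 0.5), 0.1)
})

test_that("equality constraints produce bit-identical parameters", {
  m <- unidim_model(runif(5, 1.3, 2), seed = 709)
  dat <- simulate_dif_study(m, m, n_per_group = 400, impact = 0.2, seed = 710)
  fit <- fit_multigroup(dat, items = 1:5, equated = 1:3,
                        focal_mean = 0.2, focal_sd = 1)
  for (j in 1:3) {
    expect_identical(fit$engine$a[[1]][j, ], fit$engine$a[[2]][j, ])
    expect_identical(fit$engine$d[[1]][[j]], fit$engine$d[[2]][[j]])
  }
  # free items differ between groups
  expect_false(identical(fit$engine$d[[1]][[5]], fit$engine$d[[2]][[5]]))
  # identification guard
  expect_error(fit_multigroup(dat, items = 1:5, equated = "none"),
               "not identified")
})

test_that("the full bifactor model refits data simulated from the published parameters", {
  m <- dvmsq_model("prolific")
  sim <- simulate_responses(m, 3000, screen = list(p = 1), seed = 1101)
  fit <- fit_grm(sim, pattern = m, tol = 1e-3)
  expect_true(all(diff(fit$engine$trace) > -1e-8))
  expect_gt(cor(fit$model$a[, 1], m$a[, 1]), 0.95)
  # model-consistent data fit well locally
  diag <- residual_diagnostics(fit)
  expect_lt(diag$srmr, 0.05)
})

test_that("cross-loading bridge slopes stay near zero when absent from truth", {
  # two specific factors bridged by a freed cross-loading in the fitted
  # pattern, but the generating model has no bridge; pure-general items
  # anchor the general factor (without them the bifactor decomposition is
  # empirically under-identified and the bridge direction is flat)
  set.seed(711)
  J <- 12
  a <- cbind(runif(J, 1.5, 2.3),
             c(0, 0, rep(1.5, 5), rep(0, 5)),
             c(0, 0, rep(0, 5), rep(1.5, 5)))
  d <- t(sapply(seq_len(J), function(j) {
    sort(rnorm(4, 0, 1.3), decreasing = TRUE) - (0:3) * 0.4
  }))
  truth <- bifactor_grm(a, d, items = seq_len(J))
  sim <- simulate_responses(truth, 3000, screen = list(p = 1), seed = 712)
  pattern <- truth$pattern
  pattern[5, 3] <- TRUE # spurious bridge merging the two specifics
  fit <- fit_grm(sim, pattern = pattern, items = seq_len(J), tol = 1e-3)
  expect_lt(abs(fit$model$a[5, 3]), 0.15)
  expect_gt(cor(fit$model$a[, 1], a[, 1]), 0.85)
})
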