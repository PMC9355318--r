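test_that("category probabilities follow the logistic GRM", {
  # trait-free item: probabilities determined by the intercepts alone
  p <- grm_probabilities(0, c(1, 0, -1, -2), 0)
  expect_equal(as.numeric(p), c(0.2689, 0.2311, 0.2311, 0.1497, 0.1192),
               tolerance = 1e-3)
  # theta = 0: cumulative probabilities are logistic(d_k) for any slopes
  m <- dvmsq_model("prolific")
  for (id in c(1, 8, 19)) {
    j <- match(id, m$items)
    p0 <- category_probabilities(m, id, rep(0, 5))
    cum <- rev(cumsum(rev(as.numeric(p0))))[-1]
    expect_equal(cum, as.numeric(plogis(m$d[j, ])), tolerance = 1e-12)
  }
  # probabilities are a finite difference of the cumulative curves and sum to 1
  set.seed(501)
  for (rep in 1:25) {
    a <- runif(3, 0, 3)
    d <- sort(rnorm(4, 0, 2), decreasing = TRUE) - (0:3) * 0.1
    th <- matrix(rnorm(15), 5, 3)
    p <- grm_probabilities(a, d, th)
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
    cum <- t(apply(p[, 5:1], 1, cumsum))[, 5:1] # P(X >= k), k = 0..4
    direct <- plogis(sweep(th %*% a, 2, 0, `+`) %*% t(rep(1, 4)) +
                       matrix(d, 5, 4, byrow = TRUE))
    expect_equal(unname(cum[, 2:5]), unname(direct), tolerance = 1e-12)
  }
  expect_error(grm_probabilities(1, c(0, 0.5, -1, -2), 0), "decreasing")
})

test_that("expected item scores behave across the trait range", {
  m <- dvmsq_model("prolific")
  # hand-checked value: sum of four logistics at theta = 0 for item 8
  expect_equal(expected_item_score(m, 8, rep(0, 5)), 1.0847, tolerance = 5e-4)
  # limits
  expect_equal(expected_item_score(m, 8, c(50, 0, 0, 0, 0)), 4, tolerance = 1e-6)
  # monotone non-decreasing in every positively loaded coordinate
  grid <- seq(-4, 4, by = 0.5)
  for (id in m$items) {
    j <- match(id, m$items)
    for (f in which(m$a[j, ] > 0)) {
      th <- matrix(0, length(grid), 5)
      th[, f] <- grid
      es <- expected_item_score(m, id, th)
      expect_true(all(diff(es) >= -1e-12))
    }
  }
})

test_that("expected total score is additive with the right limits", {
  m <- dvmsq_model("prolific")
  th <- rep(0, 5)
  per_item <- vapply(m$items, function(id) expected_item_score(m, id, th),
                     numeric(1))
  expect_equal(expected_total_score(m, th), sum(per_item), tolerance = 1e-12)
  expect_equal(expected_total_score(m, rep(50, 5)), 68, tolerance = 1e-4)
  expect_equal(expected_total_score(m, th, items = 8),
               expected_item_score(m, 8, th))
  expect_error(expected_total_score(m, th, items = integer(0)), "non-empty")
})

test_that("slope-to-loading conversion matches closed forms", {
  m1 <- bifactor_grm(matrix(1.702, 1, 1), matrix(c(1, 0, -1, -2), 1))
  l1 <- slopes_to_loadings(m1)
  expect_equal(l1$lambda_general, sqrt(1 / 2), tolerance = 1e-12)
  m2 <- bifactor_grm(matrix(c(1.702, 1.702), 1, 2), matrix(c(1, 0, -1, -2), 1))
  l2 <- slopes_to_loadings(m2)
  expect_equal(unname(as.numeric(l2[1, c(2, 3)])), rep(1 / sqrt(3), 2),
               tolerance = 1e-12)
  # absent slope maps to zero loading; residual complements h2
  m3 <- bifactor_grm(matrix(c(1.5, 0), 1, 2), matrix(c(1, 0, -1, -2), 1))
  l3 <- slopes_to_loadings(m3)
  expect_equal(l3$lambda_specific1, 0)
  expect_equal(unname(l3$h2 + l3$residual), 1)
  expect_error(slopes_to_loadings(m3, scaling_constant = 0), "positive")
})

test_that("bifactor indices match closed forms and bounds", {
  # general-only loadings: ECV = 1 and omega_h = omega_t
  lam <- cbind(general = rep(0.7, 3), s1 = 0)
  bi <- bifactor_indices(lam)
  expect_equal(bi$ecv, 1)
  expect_equal(bi$omega_h, bi$omega_t)
  expect_equal(bi$omega_t, 4.41 / 5.94, tolerance = 1e-12)
  # equal general and specific loadings: ECV = 0.5
  lam2 <- cbind(general = rep(0.6, 4), s1 = rep(0.6, 4))
  expect_equal(bifactor_indices(lam2)$ecv, 0.5)
  # fixture model: indices lie in their bounds
  bi3 <- bifactor_indices(slopes_to_loadings(dvmsq_model("prolific")))
  expect_true(bi3$omega_h <= bi3$omega_t && bi3$omega_t <= 1)
  expect_true(bi3$ecv > 0 && bi3$ecv < 1)
})

test_that("packaged parameter fixtures carry the published values", {
  m <- load_model_fixture("prolific_table5")
  expect_equal(unname(m$a["item8", ]), c(2.24, 0, 0, 0, 0))
  expect_equal(unname(m$d["item8", ]), c(0.65, -0.68, -2.43, -4.55))
  s <- load_model_fixture("spark_table5")
  expect_equal(unname(s$a["item12", "overall_impairment"]), 0.49)
  expect_equal(unname(m$a["item12", "overall_impairment"]), 0)
  # every intercept row strictly decreasing, in both fixtures
  for (mod in list(m, s)) {
    expect_true(all(apply(mod$d, 1, function(r) all(diff(r) < 0))))
    expect_true(all(mod$a[, 1] != 0)) # all items load on the general factor
  }
  # the loading pattern follows the published factor structure
  expect_setequal(m$items[m$pattern[, 2]], c(1, 2, 4, 7))
  expect_setequal(m$items[m$pattern[, 3]], c(4, 5, 6, 10, 12))
  expect_setequal(m$items[m$pattern[, 4]], c(13, 14, 15, 16, 18, 19, 20))
  expect_setequal(m$items[m$pattern[, 5]], c(18, 19, 20))
})

test_that("quadrature-marginal expected scores agree with Monte-Carlo", {
  m <- dvmsq_model("prolific")
  set.seed(502)
  n <- 200000
  theta <- matrix(rnorm(n * 5), n, 5)
  for (id in m$items) {
    mc <- mean(expected_item_score(m, id, theta))
    quad <- marginal_expected_score(m, id)
    expect_equal(quad, mc, tolerance = 0.01)
  }
})
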