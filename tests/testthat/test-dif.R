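test_that("identical parameter sets give exactly zero effect sizes", {
  m <- dvmsq_model("prolific")
  es <- dif_effect_sizes(m, m, n_mc = 5000)
  expect_true(all(es$items$sids == 0))
  expect_true(all(es$items$uids == 0))
  expect_true(all(es$items$essd == 0))
  expect_equal(es$dtf$stds, 0)
  expect_equal(es$dtf$uetsds, 0)
  expect_equal(es$dtf$etssd, 0)
  expect_false(es$dtf$practical_dtf)
  # impact alone (a focal mean shift) is not DIF
  es2 <- dif_effect_sizes(m, m, focal_mean = 0.5, n_mc = 5000)
  expect_true(all(es2$items$essd == 0))
})

test_that("a uniform intercept shift drives signed effect sizes", {
  m <- unidim_model(runif(5, 1.3, 2), seed = 901)
  foc <- m
  foc$d[2, ] <- foc$d[2, ] - 1
  es <- dif_effect_sizes(m, foc, n_mc = 20000)
  # the shifted item: lower expected scores in the focal group
  expect_lt(es$items$sids[2], 0)
  expect_equal(es$items$uids[2], abs(es$items$sids[2]), tolerance = 1e-10)
  expect_lt(es$items$essd[2], 0)
  # unshifted items contribute nothing
  expect_true(all(es$items$essd[-2] == 0))
  # single-DIF-item DTF reductions
  expect_equal(es$dtf$stds, es$items$sids[2], tolerance = 1e-10)
  expect_equal(es$dtf$uetsds, es$items$uids[2], tolerance = 0.01)
  # upward shift flips the sign
  foc2 <- m
  foc2$d[2, ] <- foc2$d[2, ] + 1
  expect_gt(dif_effect_sizes(m, foc2, n_mc = 5000)$items$essd[2], 0)
})

test_that("quadrature and Monte-Carlo effect sizes agree closely", {
  m <- unidim_model(runif(5, 1.3, 2), seed = 902)
  foc <- m
  foc$d[1, ] <- foc$d[1, ] - 0.7
  foc$a[4, 1] <- foc$a[4, 1] + 0.5
  eq <- dif_effect_sizes(m, foc, focal_mean = 0.3, method = "quadrature")
  emc <- dif_effect_sizes(m, foc, focal_mean = 0.3, method = "sample",
                          n_mc = 100000)
  expect_equal(eq$items$essd, emc$items$essd, tolerance = 0.005)
})

test_that("Benjamini-Hochberg adjustment matches hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.005, 0.04, 0.2)), c(0.015, 0.06, 0.2))
  p <- runif(20)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("Wald tests expose the tested parameter count and need free items", {
  m <- unidim_model(runif(4, 1.4, 1.9), seed = 903)
  dat <- simulate_dif_study(m, m, n_per_group = 400, impact = 0, seed = 904)
  fit <- fit_multigroup(dat, items = 1:4, equated = 2:4, se = TRUE, tol = 1e-3)
  w_all <- wald_dif_test(fit, 1, "all")
  w_slo <- wald_dif_test(fit, 1, "slopes")
  w_int <- wald_dif_test(fit, 1, "intercepts")
  expect_equal(w_all$df, 5) # 1 slope + 4 intercepts
  expect_equal(w_slo$df, 1)
  expect_equal(w_int$df, 4)
  expect_error(wald_dif_test(fit, 2), "equated")
  # deterministic given the data: identical on re-fit
  fit2 <- fit_multigroup(dat, items = 1:4, equated = 2:4, se = TRUE, tol = 1e-3)
  expect_identical(wald_dif_test(fit2, 1, "all")$chisq, w_all$chisq)
})

test_that("identical groups terminate with all items anchored and unflagged", {
  m <- unidim_model(runif(6, 1.4, 2), seed = 905)
  dat <- simulate_dif_study(m, m, n_per_group = 600, impact = 0.2, seed = 906)
  res <- iterative_anchor_dif(dat, items = 1:6, tol = 1e-3)
  expect_setequal(res$anchors, 1:6)
  expect_false(any(res$dif_table$flag, na.rm = TRUE))
  expect_equal(res$dif_table$essd, rep(0, 6))
  expect_equal(res$dtf$stds, 0)
  expect_lt(abs(res$focal_mean - 0.2), 0.15)
})

test_that("slope-only DIF is detected and labelled non-uniform", {
  set.seed(907)
  m <- unidim_model(runif(8, 1.3, 1.9), seed = 907)
  foc <- m
  # a pure discrimination change; with group impact the expected-score
  # difference is large enough that the item cannot become an anchor
  foc$a[5, 1] <- foc$a[5, 1] + 1.8
  dat <- simulate_dif_study(m, foc, n_per_group = 2000, impact = 0.6, seed = 908)
  res <- iterative_anchor_dif(dat, items = 1:8, tol = 1e-3)
  row <- res$dif_table[res$dif_table$item_id == 5, ]
  expect_lt(row$p_fdr, 0.05)
  expect_false(row$anchor)
  expect_equal(row$dif_type, "non-uniform")
})
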