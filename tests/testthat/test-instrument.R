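test_that("item bank matches the instrument design", {
  items <- dvmsq_items()
  expect_equal(nrow(items), 20)
  expect_equal(sum(items$scored), 17)
  expect_setequal(items$item_id[items$scored & items$scale == "symptom"],
                  c(1, 2, 4, 5, 6, 7, 8, 9, 10, 12))
  expect_setequal(items$item_id[items$scored & items$scale == "impairment"],
                  c(13, 14, 15, 16, 18, 19, 20))
  expect_false(any(items$scored[items$item_id %in% c(3, 11, 17)]))
  # criterion roles and thresholds of the diagnostic algorithm
  expect_equal(items$criterion_threshold[items$item_id == 1], 3)
  expect_equal(items$criterion_threshold[items$item_id == 12], 2)
  expect_equal(items$criterion_threshold[items$item_id == 20], 2)
  expect_setequal(items$item_id[!is.na(items$criterion) & items$criterion == "F"],
                  c(13, 14, 15, 16, 18, 19, 20))
})

test_that("scoring covers the score ranges and skip logic", {
  expect_equal(score_dvmsq(respondent_row(fill = 4L))[, c("total", "symptom", "impairment")],
               tibble::tibble(total = 68L, symptom = 40L, impairment = 28L))
  # screen negative: all-zero imputation, valid
  neg <- tibble::tibble(s1 = FALSE)
  s <- score_dvmsq(neg)
  expect_equal(s$total, 0L)
  expect_true(s$valid)
  # mixed levels
  d <- respondent_row(fill = 0L)
  for (i in c(1, 2, 4, 5, 6, 7, 8, 9, 10, 12)) d[[sprintf("q%02d", i)]] <- 2L
  for (i in c(13, 14, 15, 16, 18, 19, 20)) d[[sprintf("q%02d", i)]] <- 1L
  s <- score_dvmsq(d)
  expect_equal(c(s$total, s$symptom, s$impairment), c(27L, 20L, 7L))
  # unscored items do not contribute
  d$q03 <- 4L; d$q11 <- 4L; d$q17 <- 4L
  expect_equal(score_dvmsq(d)$total, 27L)
})

test_that("missing scored items invalidate the score without prorating", {
  d <- respondent_row(fill = 2L)
  d$q05 <- NA_integer_
  s <- score_dvmsq(d)
  expect_false(s$valid)
  expect_equal(s$n_missing, 1L)
  expect_true(is.na(s$total))
  # missing unscored item is harmless
  d2 <- respondent_row(fill = 2L)
  d2$q17 <- NA_integer_
  expect_true(score_dvmsq(d2)$valid)
})

test_that("out-of-range codes raise a validation error naming the culprit", {
  d <- respondent_row()
  d$respondent_id <- "abc"
  d$q07 <- 7L
  expect_error(score_dvmsq(d), "abc.*q07.*7")
})

test_that("the diagnostic algorithm reproduces the criterion table", {
  # clinical: one endorsement per criterion, two impairment items
  d <- respondent_row(q01 = 3, q12 = 2, q08 = 2, q18 = 2, q19 = 2)
  expect_equal(as.character(classify_misophonia(d)$classification), "clinical")
  # only one impairment item -> subclinical
  d2 <- respondent_row(q01 = 3, q12 = 2, q08 = 2, q18 = 2)
  expect_equal(as.character(classify_misophonia(d2)$classification), "subclinical")
  # screen negative -> none, all criteria false
  neg <- tibble::tibble(s1 = FALSE)
  r <- classify_misophonia(neg)
  expect_equal(as.character(r$classification), "none")
  expect_false(any(unlist(r[paste0("criterion_", letters[1:6])])))
  # criterion C satisfied by item 5 alone at Often
  d3 <- respondent_row(q01 = 3, q05 = 3, q08 = 2, q18 = 2, q19 = 2)
  r3 <- classify_misophonia(d3)
  expect_true(r3$criterion_c)
  expect_equal(as.character(r3$classification), "clinical")
  # item 12 at 1 (below Sometimes) does not satisfy C
  d4 <- respondent_row(q01 = 3, q12 = 1, q08 = 2, q18 = 2, q19 = 2)
  expect_equal(as.character(classify_misophonia(d4)$classification), "none")
})

test_that("missing criterion items count as non-endorsement with a flag", {
  d <- respondent_row(q01 = 3, q12 = 2, q08 = 2, q18 = 2, q19 = 2)
  d$q02 <- NA_integer_
  r <- classify_misophonia(d)
  expect_equal(as.character(r$classification), "clinical")
  expect_false(r$complete)
})

test_that("classification agrees with the oracle on random patterns and is monotone", {
  set.seed(301)
  for (rep in 1:200) {
    q <- setNames(sample(0:4, 20, replace = TRUE), item_columns())
    d <- respondent_row()
    for (nm in names(q)) d[[nm]] <- q[[nm]]
    got <- as.character(classify_misophonia(d)$classification)
    expect_equal(got, oracle_classify(TRUE, q))
    # monotonicity: raising one random item never worsens the class
    rank <- c(clinical = 3, subclinical = 2, none = 1)
    i <- sample(1:20, 1)
    col <- sprintf("q%02d", i)
    d2 <- d
    d2[[col]] <- min(d[[col]] + 1L, 4L)
    expect_gte(rank[as.character(classify_misophonia(d2)$classification)],
               rank[got])
  }
})

test_that("clinical classification implies impairment score of at least 4", {
  set.seed(302)
  n <- 500
  d <- tibble::tibble(s1 = TRUE)
  d <- d[rep(1, n), ]
  for (col in item_columns()) d[[col]] <- sample(0:4, n, replace = TRUE)
  cls <- classify_misophonia(d)
  sc <- score_dvmsq(d)
  clin <- cls$classification == "clinical"
  expect_true(any(clin)) # the random design does produce cases
  expect_true(all(sc$impairment[clin] >= 4))
})

test_that("criterion fulfillment matches hand-computed proportions", {
  expect_equal(criterion_fulfillment(c(17, 72, 284, 296, 164), 3),
               460 / 833)
  expect_equal(criterion_fulfillment(c(218, 219, 226, 122, 48), 2),
               396 / 833)
  expect_equal(criterion_fulfillment(c(833, 0, 0, 0, 0), 1), 0)
  expect_error(criterion_fulfillment(c(0, 0, 0, 0, 0), 2), "undefined")
  expect_error(criterion_fulfillment(c(1, 2, 3), 2), "5 non-negative")
})

test_that("corrected item-total behaves under independence and duplication", {
  set.seed(303)
  n <- 4000
  theta <- rnorm(n)
  d <- tibble::tibble(s1 = rep(TRUE, n))
  cuts <- c(-Inf, -0.8, 0, 0.8, 1.6, Inf)
  for (i in c(1, 2, 4, 5, 6, 7, 8, 9, 10, 12, 13, 14, 15, 16, 18, 19, 20)) {
    d[[sprintf("q%02d", i)]] <-
      as.integer(cut(theta + 0.5 * rnorm(n), cuts)) - 1L
  }
  # item 1 replaced by pure noise: rest correlation near zero
  d$q01 <- as.integer(cut(rnorm(n), cuts)) - 1L
  expect_lt(abs(corrected_item_total(d, 1)), 0.05)
  # item 2 duplicated from item 5: strong correlation with the rest score
  d$q02 <- d$q05
  expect_gt(corrected_item_total(d, 2), 0.8)
  # two-item scale reduces to the pairwise polyserial
  two <- corrected_item_total(d, 5, rest_items = 6)
  direct <- latent_correlation(as.numeric(d$q06), d$q05, "polyserial")
  expect_equal(two, direct, tolerance = 1e-10)
})

test_that("item_analysis reproduces per-item counts and fulfillment", {
  set.seed(304)
  n <- 300
  d <- tibble::tibble(s1 = rep(TRUE, n))
  for (col in item_columns()) d[[col]] <- sample(0:4, n, replace = TRUE)
  ia <- item_analysis(d, item_total = FALSE)
  expect_equal(nrow(ia), 20)
  counts <- as.integer(ia[ia$item_id == 1, c("n0", "n1", "n2", "n3", "n4")])
  expect_equal(counts, as.integer(tabulate(d$q01 + 1, 5)))
  expect_equal(ia$pct_fulfills[ia$item_id == 1],
               round(100 * mean(d$q01 >= 3), 1))
  expect_true(is.na(ia$pct_fulfills[ia$item_id == 9])) # no criterion role
})
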