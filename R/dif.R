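# Differential item and test functioning between a reference and a focal
# group: Wald tests on between-group parameter differences, Meade-style
# effect sizes (SIDS/UIDS/ESSD for items; STDS/UETSDS/ETSSD for the test),
# Benjamini-Hochberg correction, and the iterative anchor-purification
# procedure.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# expected score and conditional variance for every item at a trait matrix
es_matrix <- function(parts, theta) {
  J <- nrow(parts$a)
  es <- matrix(0, nrow(theta), J)
  es2 <- matrix(0, nrow(theta), J)
  for (j in seq_len(J)) {
    cm <- item_cond_moments(parts, j, theta)
    es[, j] <- cm$es
    es2[, j] <- cm$es2
  }
  list(es = es, es2 = es2)
}

# model-implied variance of the total score under a latent distribution,
# from a Monte-Carlo trait sample: Var(sum ES_j(theta)) + E(sum CondVar_j).
total_score_var <- function(parts, theta) {
  m <- es_matrix(parts, theta)
  var(rowSums(m$es)) + mean(rowSums(m$es2 - m$es^2))
}

# marginal item variance by quadrature over the item's own dimensions
item_marginal_var <- function(parts, j, g_mean = 0, g_sd = 1) {
  nf <- ncol(parts$a)
  dims <- union(1L, setdiff(which(parts$a[j, ] != 0), 1L))
  nd <- length(dims)
  nn <- block_nodes(nd)
  nodes <- quad_nodes(nn)
  grid <- as.matrix(expand.grid(rep(list(nodes), nd), KEEP.OUT.ATTRS = FALSE))
  w <- quad_weights(nodes, g_mean, g_sd)[match(grid[, 1], nodes)]
  if (nd > 1) {
    ws <- quad_weights(nodes)
    for (k in 2:nd) w <- w * ws[match(grid[, k], nodes)]
  }
  theta <- matrix(0, nrow(grid), nf)
  theta[, dims] <- grid
  cm <- item_cond_moments(parts, j, theta)
  m1 <- sum(w * cm$es)
  sum(w * cm$es2) - m1^2
}

#' DIF and DTF effect sizes
#'
#' Meade-taxonomy effect sizes comparing a focal group's item parameters to a
#' reference group's at equal latent trait: per item, the signed item
#' difference in the sample (SIDS, the focal-distribution average of the
#' expected-score difference), its unsigned counterpart (UIDS), and the
#' expected score standardized difference (ESSD = SIDS / pooled model-implied
#' item SD, a Cohen's-d-like quantity); for the whole test, the signed test
#' difference (STDS), the unsigned expected test score difference (UETSDS, in
#' raw score units), and the standardized test difference (ETSSD = STDS /
#' pooled model-implied total-score SD). Expectations are taken over the
#' focal latent distribution: by deterministic quadrature per item
#' (`method = "quadrature"`, the default) or over a trait sample
#' (`method = "sample"`, matching "in the sample" semantics); the test-level
#' UETSDS and total-score SDs always use a seeded Monte-Carlo trait sample.
#'
#' @param ref_model,focal_model [bifactor_grm()] objects sharing a loading
#'   pattern.
#' @param focal_mean,focal_sd Focal general-factor distribution (specific
#'   factors are standard normal in both groups).
#' @param method `"quadrature"` or `"sample"` for the per-item expectations.
#' @param traits Optional focal trait matrix for `method = "sample"`;
#'   generated internally when absent.
#' @param n_mc Monte-Carlo sample size for the test-level quantities (and for
#'   `method = "sample"` when `traits` is absent).
#' @param mc_seed Seed for the internal Monte-Carlo draws (restores the
#'   caller's RNG state afterwards).
#' @param dtf_threshold |ETSSD| above this is judged practically meaningful
#'   DTF (0.1 by convention).
#' @return A list of class `dif_effects`: `items` (tibble with `item_id`,
#'   `sids`, `uids`, `essd`) and `dtf` (tibble with `stds`, `uetsds`,
#'   `etssd`, `practical_dtf`).
#' @export
dif_effect_sizes <- function(ref_model, focal_model, focal_mean = 0,
                             focal_sd = 1, method = c("quadrature", "sample"),
                             traits = NULL, n_mc = 100000, mc_seed = 1,
                             dtf_threshold = 0.1) {
  method <- match.arg(method)
  pr <- model_parts(ref_model)
  pf <- model_parts(focal_model)
  if (!identical(dim(pr$a), dim(pf$a))) {
    abort("Reference and focal models must share the loading pattern.")
  }
  J <- nrow(pr$a)
  nf <- ncol(pr$a)
  items <- if (inherits(ref_model, "bifactor_grm")) ref_model$items else seq_len(J)
  if (is.null(traits)) {
    traits <- with_local_seed(mc_seed, {
      t_f <- matrix(rnorm(n_mc * nf), n_mc, nf)
      t_f[, 1] <- t_f[, 1] * focal_sd + focal_mean
      t_r <- matrix(rnorm(n_mc * nf), n_mc, nf)
      list(focal = t_f, ref = t_r)
    })
  } else if (is.matrix(traits)) {
    traits <- list(focal = traits,
                   ref = with_local_seed(mc_seed, matrix(rnorm(n_mc * nf), n_mc, nf)))
  }
  sids <- uids <- essd <- numeric(J)
  pooled_sd <- numeric(J)
  for (j in seq_len(J)) {
    pooled_sd[j] <- sqrt((item_marginal_var(pr, j, 0, 1) +
                            item_marginal_var(pf, j, focal_mean, focal_sd)) / 2)
  }
  if (method == "quadrature") {
    for (j in seq_len(J)) {
      dims <- union(1L, union(setdiff(which(pr$a[j, ] != 0), 1L),
                              setdiff(which(pf$a[j, ] != 0), 1L)))
      nd <- length(dims)
      nodes <- quad_nodes(block_nodes(nd))
      grid <- as.matrix(expand.grid(rep(list(nodes), nd), KEEP.OUT.ATTRS = FALSE))
      w <- quad_weights(nodes, focal_mean, focal_sd)[match(grid[, 1], nodes)]
      if (nd > 1) {
        ws <- quad_weights(nodes)
        for (k in 2:nd) w <- w * ws[match(grid[, k], nodes)]
      }
      theta <- matrix(0, nrow(grid), nf)
      theta[, dims] <- grid
      dj <- item_cond_moments(pf, j, theta)$es - item_cond_moments(pr, j, theta)$es
      sids[j] <- sum(w * dj)
      uids[j] <- sum(w * abs(dj))
    }
  } else {
    D <- es_matrix(pf, traits$focal)$es - es_matrix(pr, traits$focal)$es
    sids <- colMeans(D)
    uids <- colMeans(abs(D))
  }
  essd <- sids / pooled_sd
  # test-level quantities over the Monte-Carlo focal sample
  D_mc <- es_matrix(pf, traits$focal)$es - es_matrix(pr, traits$focal)$es
  stds <- sum(sids)
  uetsds <- mean(abs(rowSums(D_mc)))
  vtot <- (total_score_var(pr, traits$ref) +
             total_score_var(pf, traits$focal)) / 2
  etssd <- stds / sqrt(vtot)
  structure(list(
    items = tibble::tibble(item_id = items, sids = sids, uids = uids,
                           essd = essd, pooled_sd = pooled_sd),
    dtf = tibble::tibble(stds = stds, uetsds = uetsds, etssd = etssd,
                         practical_dtf = abs(etssd) > dtf_threshold)
  ), class = "dif_effects")
}

#' @export
print.dif_effects <- function(x, ...) {
  cat("DIF effect sizes (focal minus reference):\n")
  print(x$items, n = Inf)
  cat(sprintf("DTF: STDS = %.3f, UETSDS = %.3f, ETSSD = %.3f (%s)\n",
              x$dtf$stds, x$dtf$uetsds, x$dtf$etssd,
              if (x$dtf$practical_dtf) "practically meaningful" else "ignorable"))
  invisible(x)
}

# natural parameter vector of one item in one group of a multigroup fit
item_param_vector <- function(fit, g, j) {
  fdims <- which(fit$pattern[j, ])
  c(fit$engine$a[[g]][j, fdims], fit$engine$d[[g]][[j]])
}

#' Wald test of differential item functioning
#'
#' Omnibus ("Wald-2" style) or follow-up Wald test of the between-group
#' difference in one item's parameters, using the joint cross-product
#' covariance from a multigroup fit in which the item is free in both groups.
#' Follow-up tests of slopes only or intercepts only distinguish non-uniform
#' from uniform DIF.
#'
#' @param mg_fit An `mg_grm_fit` from [fit_multigroup()] with `se = TRUE` and
#'   the tested item not equated.
#' @param item Item id to test.
#' @param which `"all"` (slopes and intercepts), `"slopes"`, or
#'   `"intercepts"`.
#' @return A one-row tibble: `item_id`, `which`, `chisq`, `df`, `p`.
#' @export
wald_dif_test <- function(mg_fit, item, which = c("all", "slopes", "intercepts")) {
  which <- match.arg(which)
  if (is.null(mg_fit$vcov)) abort("Fit the model with `se = TRUE` for Wald tests.")
  j <- match(item, mg_fit$items)
  if (is.na(j)) abort(sprintf("Item %s is not in the fit.", item))
  if (mg_fit$equated[j]) {
    abort(sprintf("Item %s is equated across groups; free it to test DIF.", item))
  }
  cols1 <- mg_fit$pmap$item_cols[[1]][[j]]
  cols2 <- mg_fit$pmap$item_cols[[2]][[j]]
  sel <- switch(which,
                all = c("a", "d"),
                slopes = "a",
                intercepts = "d")
  i1 <- unlist(cols1[sel]); i2 <- unlist(cols2[sel])
  delta <- c(item_param_vector(mg_fit, 2, j) - item_param_vector(mg_fit, 1, j))
  np_a <- length(cols1$a)
  keep <- switch(which, all = seq_along(delta), slopes = seq_len(np_a),
                 intercepts = np_a + seq_along(cols1$d))
  delta <- delta[keep]
  V <- mg_fit$vcov[i2, i2, drop = FALSE] + mg_fit$vcov[i1, i1, drop = FALSE] -
    mg_fit$vcov[i2, i1, drop = FALSE] - mg_fit$vcov[i1, i2, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e) {
    abort(sprintf("Singular covariance for item %s Wald test.", item))
  })
  chisq <- as.numeric(t(delta) %*% Vi %*% delta)
  df <- length(delta)
  tibble::tibble(item_id = item, which = which, chisq = chisq, df = df,
                 p = pchisq(chisq, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR-adjusted p-values (monotone, capped at 1).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.005, 0.04, 0.2))
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values.")
  }
  p.adjust(p, method = "BH")
}

#' Iterative anchor-purification DIF analysis
#'
#' The staged Wald-2 DIF procedure for two groups. Stage 1 fits all items
#' equated to estimate the focal group's general-factor mean and variance
#' (impact). Stage 2 fixes the group distributions at those values, frees
#' every item, and Wald-tests each. Items with non-significant DIF (p >=
#' `alpha`, uncorrected) or negligible effect size (|ESSD| < `anchor_essd`)
#' become anchors; the model is refit with anchors equated (focal
#' distribution re-estimated) and the remaining candidates retested,
#' iterating until every tested candidate shows DIF at `alpha`. The final
#' table carries Benjamini-Hochberg corrected p-values over the full item
#' set, effect sizes from the final anchored fit, a practical-DIF flag
#' (p_FDR < `alpha` and |ESSD| > `flag_essd`), and uniform/non-uniform
#' verdicts from slope-vs-intercept follow-up tests; DTF summaries come from
#' [dif_effect_sizes()] on the final fit.
#'
#' @inheritParams fit_multigroup
#' @param alpha Significance level for the Wald tests (default 0.05).
#' @param anchor_essd Items with |ESSD| below this are anchored regardless of
#'   the Wald test (default 0.2, i.e. below a "small" effect).
#' @param flag_essd |ESSD| above this, together with p_FDR < `alpha`, flags
#'   practically significant DIF (default 0.5, a "medium" effect).
#' @param ... Passed to [fit_multigroup()] (e.g. `tol`, `n_cycles`).
#' @return A list of class `dif_analysis`: `dif_table` (per-item tibble),
#'   `dtf` (tibble), `anchors` (item ids), `focal_mean`, `focal_sd`, and the
#'   final `fit`.
#' @export
iterative_anchor_dif <- function(data, pattern = NULL, items = NULL,
                                 group_col = "group", alpha = 0.05,
                                 anchor_essd = 0.2, flag_essd = 0.5, ...) {
  if (inherits(pattern, "bifactor_grm")) {
    items <- items %||% pattern$items
    pattern <- pattern$pattern
  }
  items <- items %||% sort(as.integer(sub("^q", "", grep(
    "^q[0-9]{2}$", names(data), value = TRUE))))
  J <- length(items)
  # Stage 1: impact estimation with all items anchored
  fit0 <- fit_multigroup(data, pattern, items, group_col = group_col,
                         equated = "all", se = FALSE, ...)
  mu0 <- fit0$focal_mean; sd0 <- fit0$focal_sd
  # Stage 2: all items free, group distributions fixed
  fit1 <- fit_multigroup(data, pattern, items, group_col = group_col,
                         equated = "none", focal_mean = mu0, focal_sd = sd0,
                         se = TRUE, ...)
  wald1 <- purrr::map_dfr(items, ~ wald_dif_test(fit1, .x, "all"))
  es1 <- dif_effect_sizes(fit1$ref_model, fit1$focal_model, mu0, sd0)
  p_last <- setNames(wald1$p, items)
  chisq_last <- setNames(wald1$chisq, items)
  df_last <- setNames(wald1$df, items)
  essd_last <- setNames(es1$items$essd, items)
  anchors <- items[wald1$p >= alpha | abs(es1$items$essd) < anchor_essd]
  if (length(anchors) == 0) {
    abort(paste("No anchor items found at the first iteration;",
                "specify anchors manually via fit_multigroup()."))
  }
  candidates <- setdiff(items, anchors)
  fit_final <- fit0
  mu <- mu0; sd_f <- sd0
  while (length(candidates) > 0) {
    fitk <- fit_multigroup(data, pattern, items, group_col = group_col,
                           equated = anchors, se = TRUE, ...)
    mu <- fitk$focal_mean; sd_f <- fitk$focal_sd
    # test candidates in ascending order of their previous p-values
    candidates <- candidates[order(p_last[as.character(candidates)])]
    waldk <- purrr::map_dfr(candidates, ~ wald_dif_test(fitk, .x, "all"))
    esk <- dif_effect_sizes(fitk$ref_model, fitk$focal_model, mu, sd_f)
    p_last[as.character(candidates)] <- waldk$p
    chisq_last[as.character(candidates)] <- waldk$chisq
    df_last[as.character(candidates)] <- waldk$df
    essd_cand <- setNames(
      esk$items$essd[match(candidates, esk$items$item_id)],
      candidates)
    essd_last[as.character(candidates)] <- essd_cand
    fit_final <- fitk
    new_anchors <- candidates[waldk$p >= alpha |
                                abs(essd_cand) < anchor_essd]
    if (length(new_anchors) == 0) break
    anchors <- c(anchors, new_anchors)
    candidates <- setdiff(candidates, new_anchors)
  }
  # final effect sizes and DTF from the final anchored fit
  es_final <- dif_effect_sizes(fit_final$ref_model, fit_final$focal_model,
                               fit_final$focal_mean, fit_final$focal_sd)
  essd_final <- setNames(es_final$items$essd, es_final$items$item_id)
  p_fdr <- bh_fdr(as.numeric(p_last[as.character(items)]))
  names(p_fdr) <- items
  flag <- p_fdr < alpha & abs(essd_final[as.character(items)]) > flag_essd
  # uniform / non-uniform follow-up for significant free items
  verdict <- rep(NA_character_, J)
  for (i in seq_len(J)) {
    id <- items[i]
    if (id %in% anchors || p_fdr[i] >= alpha) next
    ws <- wald_dif_test(fit_final, id, "slopes")
    wi <- wald_dif_test(fit_final, id, "intercepts")
    verdict[i] <- if (ws$p < alpha) "non-uniform" else if (wi$p < alpha) {
      "uniform"
    } else "indeterminate"
  }
  dif_table <- tibble::tibble(
    item_id = items,
    anchor = items %in% anchors,
    chisq = as.numeric(chisq_last[as.character(items)]),
    df = as.numeric(df_last[as.character(items)]),
    p = as.numeric(p_last[as.character(items)]),
    p_fdr = as.numeric(p_fdr),
    sids = es_final$items$sids[match(items, es_final$items$item_id)],
    uids = es_final$items$uids[match(items, es_final$items$item_id)],
    essd = as.numeric(essd_final[as.character(items)]),
    flag = as.logical(flag),
    dif_type = verdict
  )
  structure(list(
    dif_table = dif_table, dtf = es_final$dtf, anchors = anchors,
    focal_mean = fit_final$focal_mean, focal_sd = fit_final$focal_sd,
    fit = fit_final
  ), class = "dif_analysis")
}

#' @export
print.dif_analysis <- function(x, ...) {
  cat(sprintf("Iterative Wald DIF analysis: %d anchors, %d flagged item(s)\n",
              length(x$anchors), sum(x$dif_table$flag, na.rm = TRUE)))
  cat(sprintf("Focal general factor: mean %.3f, sd %.3f\n",
              x$focal_mean, x$focal_sd))
  print(x$dif_table, n = Inf)
  cat(sprintf("DTF: STDS = %.3f, UETSDS = %.3f, ETSSD = %.3f\n",
              x$dtf$stds, x$dtf$uetsds, x$dtf$etssd))
  invisible(x)
}

#' @method tidy dif_analysis
#' @export
tidy.dif_analysis <- function(x, ...) x$dif_table

#' @method glance dif_analysis
#' @export
glance.dif_analysis <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_anchors = length(x$anchors),
                   n_flagged = sum(x$dif_table$flag, na.rm = TRUE),
                   focal_mean = x$focal_mean, focal_sd = x$focal_sd),
    x$dtf)
}

#' @method autoplot dif_analysis
#' @export
autoplot.dif_analysis <- function(object, ...) {
  df <- object$dif_table
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$item_id), y = .data$essd,
                                   fill = .data$flag)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-0.5, 0.5), linetype = 2) +
    ggplot2::labs(x = "item", y = "ESSD (focal - reference)",
                  fill = "practical DIF",
                  title = "Expected score standardized differences") +
    ggplot2::theme_minimal()
}
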