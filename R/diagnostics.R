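# Local fit diagnostics: residual correlations (observed minus model-implied
# item-score correlations), SRMR, and Yen's Q3 computed from EAP residuals,
# with parametric-bootstrap critical values.

# Canonical parameter view: slopes matrix, per-item intercept vectors, the
# numeric values carried by each category, and the loading pattern.
model_parts <- function(x, group = 1) {
  if (inherits(x, "grm_fit")) {
    eng <- x$engine
    return(list(a = eng$a[[1]], d = eng$d[[1]],
                levels = x$levels, pattern = x$pattern))
  }
  if (inherits(x, "mg_grm_fit")) {
    eng <- x$engine
    return(list(a = eng$a[[group]], d = eng$d[[group]],
                levels = x$levels, pattern = x$pattern))
  }
  if (inherits(x, "bifactor_grm")) {
    J <- nrow(x$a)
    return(list(a = x$a, d = lapply(seq_len(J), function(j) x$d[j, ]),
                levels = rep(list(0:4), J), pattern = x$pattern))
  }
  abort("Unsupported model object.")
}

# Conditional moments of item j's score on a theta grid (M x nf).
item_cond_moments <- function(parts, j, theta) {
  P <- grm_cat_grid(parts$a[j, ], parts$d[[j]], theta)$P # K x M
  v <- parts$levels[[j]]
  list(es = as.vector(v %*% P), es2 = as.vector(v^2 %*% P))
}

# Model-implied means, variances and pairwise score correlations under an
# orthogonal normal latent distribution (general factor optionally shifted).
implied_moments <- function(parts, g_mean = 0, g_sd = 1,
                            nodes_2d = 49, nodes_3d = 15) {
  J <- nrow(parts$a)
  nf <- ncol(parts$a)
  spec_of <- lapply(seq_len(J), function(j) {
    setdiff(which(parts$a[j, ] != 0), 1L)
  })
  gq <- quad_nodes(nodes_2d)
  wg <- quad_weights(gq, g_mean, g_sd)
  # per-item conditional-on-general curves and moments
  ebar <- matrix(0, J, length(gq))
  m1 <- numeric(J); m2 <- numeric(J)
  for (j in seq_len(J)) {
    dims <- spec_of[[j]]
    nd <- 1L + length(dims)
    nn <- if (nd >= 3) nodes_3d else nodes_2d
    gq_j <- quad_nodes(nn)
    wg_j <- quad_weights(gq_j, g_mean, g_sd)
    grids <- c(list(gq_j), rep(list(quad_nodes(nn)), length(dims)))
    grid <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    theta <- matrix(0, nrow(grid), nf)
    theta[, 1] <- grid[, 1]
    if (length(dims)) theta[, dims] <- grid[, -1, drop = FALSE]
    w <- wg_j[match(grid[, 1], gq_j)]
    if (length(dims)) {
      ws <- quad_weights(quad_nodes(nn))
      for (k in seq_along(dims)) w <- w * ws[match(grid[, k + 1], quad_nodes(nn))]
    }
    cm <- item_cond_moments(parts, j, theta)
    m1[j] <- sum(w * cm$es)
    m2[j] <- sum(w * cm$es2)
    # conditional-on-general expected score, on the common general grid
    theta_g <- matrix(0, length(gq), nf)
    theta_g[, 1] <- gq
    if (length(dims)) {
      nn2 <- if (nd >= 3) nodes_3d else nodes_2d
      sq <- quad_nodes(nn2)
      wsq <- quad_weights(sq)
      sgrid <- as.matrix(expand.grid(rep(list(sq), length(dims)),
                                     KEEP.OUT.ATTRS = FALSE))
      wsg <- apply(matrix(wsq[match(sgrid, sq)], nrow(sgrid)), 1, prod)
      acc <- numeric(length(gq))
      th <- matrix(0, length(gq), nf)
      for (m in seq_len(nrow(sgrid))) {
        th[, 1] <- gq
        th[, dims] <- matrix(sgrid[m, ], length(gq), length(dims), byrow = TRUE)
        acc <- acc + wsg[m] * item_cond_moments(parts, j, th)$es
      }
      ebar[j, ] <- acc
    } else {
      ebar[j, ] <- item_cond_moments(parts, j, theta_g)$es
    }
  }
  vars <- m2 - m1^2
  # pairwise E[Xj Xk]
  R <- diag(1, J)
  for (j in seq_len(J - 1)) {
    for (k in (j + 1):J) {
      shared <- intersect(spec_of[[j]], spec_of[[k]])
      if (length(shared) == 0) {
        exjk <- sum(wg * ebar[j, ] * ebar[k, ])
      } else {
        dims <- union(spec_of[[j]], spec_of[[k]])
        nd <- 1L + length(dims)
        nn <- if (nd >= 3) nodes_3d else nodes_2d
        gq_j <- quad_nodes(nn)
        grids <- c(list(gq_j), rep(list(gq_j), length(dims)))
        grid <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
        theta <- matrix(0, nrow(grid), nf)
        theta[, 1] <- grid[, 1]
        theta[, dims] <- grid[, -1, drop = FALSE]
        w <- quad_weights(gq_j, g_mean, g_sd)[match(grid[, 1], gq_j)]
        ws <- quad_weights(gq_j)
        for (kk in seq_along(dims)) w <- w * ws[match(grid[, kk + 1], gq_j)]
        exjk <- sum(w * item_cond_moments(parts, j, theta)$es *
                      item_cond_moments(parts, k, theta)$es)
      }
      R[j, k] <- R[k, j] <- (exjk - m1[j] * m1[k]) / sqrt(vars[j] * vars[k])
    }
  }
  list(mean = m1, var = vars, cor = R)
}

#' Expected a-posteriori (EAP) latent trait estimates
#'
#' Posterior means of every latent factor given a respondent's item
#' responses, computed on the full joint quadrature grid with bifactor
#' dimension reduction.
#'
#' @param model A [bifactor_grm()] object (or a fitted `grm_fit`).
#' @param X Integer matrix of item codes 0-4, columns in model item order; or
#'   a respondent table.
#' @param g_mean,g_sd Prior mean/SD of the general factor.
#' @return Numeric matrix, respondents x factors.
#' @export
eap_scores <- function(model, X, g_mean = 0, g_sd = 1) {
  if (inherits(model, "grm_fit")) {
    parts <- model_parts(model)
    nf <- ncol(parts$a)
    facs <- colnames(parts$pattern) %||% paste0("f", seq_len(nf))
  } else {
    parts <- model_parts(model)
    nf <- ncol(parts$a)
    facs <- model$factors
  }
  if (is.data.frame(X)) {
    items <- if (inherits(model, "grm_fit")) model$items else model$items
    X <- calib_matrix(X, items)
  }
  X <- as.matrix(X)
  # recode into 1..K per item via the parts levels
  Xr <- X
  for (j in seq_len(ncol(X))) {
    Xr[, j] <- match(X[, j], parts$levels[[j]])
    if (anyNA(Xr[, j])) abort(sprintf("Unseen category for item column %d.", j))
  }
  pattern <- parts$pattern
  pattern[, 1] <- TRUE
  grid <- make_grid(pattern)
  n <- nrow(Xr)
  wg <- quad_weights(grid$gq, g_mean, g_sd)
  storage.mode(Xr) <- "integer"
  blocks_L <- list(); blocks_Lg <- list()
  for (bi in seq_along(grid$blocks)) {
    b <- grid$blocks[[bi]]
    Ps <- lapply(b$items, function(j) {
      grm_cat_grid(parts$a[j, ], parts$d[[j]], b$theta)$P
    })
    bl <- block_lik(Xr[, b$items, drop = FALSE], Ps, b$ws, b$g_of_m, grid$ng)
    blocks_L[[bi]] <- bl$L
    blocks_Lg[[bi]] <- bl$Lg
  }
  A <- Reduce(`*`, blocks_Lg)
  Li <- pmax(as.vector(A %*% wg), 1e-300)
  Pg <- A * matrix(wg, n, grid$ng, byrow = TRUE) / Li
  out <- matrix(0, n, nf)
  out[, 1] <- as.vector(Pg %*% grid$gq)
  for (bi in seq_along(grid$blocks)) {
    b <- grid$blocks[[bi]]
    if (length(b$factors) == 0) next
    outer_g <- (A / pmax(blocks_Lg[[bi]], 1e-300)) *
      matrix(wg, n, grid$ng, byrow = TRUE) / Li
    post <- block_post(blocks_L[[bi]], outer_g, b$ws, b$g_of_m)
    for (f in b$factors) out[, f] <- as.vector(post %*% b$theta[, f])
  }
  colnames(out) <- facs
  out
}

# Q3 matrix: Pearson correlations of EAP residuals x_ij - ES_j(theta_hat_i).
q3_matrix <- function(parts, Xcodes, theta_hat) {
  J <- ncol(Xcodes)
  resid <- matrix(0, nrow(Xcodes), J)
  for (j in seq_len(J)) {
    es <- item_cond_moments(parts, j, theta_hat)$es
    resid[, j] <- Xcodes[, j] - es
  }
  cor(resid)
}

#' Residual-correlation and Q3 fit diagnostics
#'
#' Computes local-misfit diagnostics for a fitted graded response model: the
#' residual correlation matrix `r_res` (observed Pearson correlations of item
#' scores minus model-implied correlations, integrated by quadrature), the
#' SRMR (root mean square of the lower-triangle residuals), the Q3 matrix of
#' EAP-residual correlations, and item pairs flagged by either criterion.
#'
#' @param fit A `grm_fit` object.
#' @param r_res_threshold Absolute residual-correlation flag threshold
#'   (0.1 by convention; 0.15 as a relaxed criterion for large models).
#' @param q3_cutoff Optional Q3 critical value, e.g. from
#'   [q3_bootstrap_cutoff()]; pairs with Q3 above it are flagged.
#' @return An object of class `fit_diagnostics`: list with `r_res`, `srmr`,
#'   `q3`, `q3_cutoff`, and a tibble `flagged` of offending pairs.
#' @export
residual_diagnostics <- function(fit, r_res_threshold = 0.1,
                                 q3_cutoff = NULL) {
  if (!inherits(fit, "grm_fit")) abort("`fit` must be a grm_fit.")
  parts <- model_parts(fit)
  J <- length(fit$items)
  # observed scores on the original category values
  obs <- vapply(seq_len(J), function(j) parts$levels[[j]][fit$X[, j]],
                numeric(nrow(fit$X)))
  obs_cor <- cor(obs)
  imp <- implied_moments(parts)
  r_res <- obs_cor - imp$cor
  diag(r_res) <- 0
  srmr <- sqrt(mean(r_res[lower.tri(r_res)]^2))
  theta_hat <- eap_scores(fit, obs)
  q3 <- q3_matrix(parts, obs, theta_hat)
  pairs <- which(lower.tri(r_res), arr.ind = TRUE)
  flagged <- tibble::tibble(
    item_i = fit$items[pairs[, 1]], item_j = fit$items[pairs[, 2]],
    r_res = r_res[pairs], q3 = q3[pairs]
  )
  flagged$flag_r_res <- abs(flagged$r_res) > r_res_threshold
  flagged$flag_q3 <- if (!is.null(q3_cutoff)) flagged$q3 > q3_cutoff else NA
  keep <- flagged$flag_r_res | (!is.na(flagged$flag_q3) & flagged$flag_q3)
  structure(list(
    r_res = r_res, srmr = srmr, q3 = q3, q3_cutoff = q3_cutoff,
    r_res_threshold = r_res_threshold,
    pairs = flagged, flagged = flagged[keep, , drop = FALSE],
    items = fit$items
  ), class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("Fit diagnostics: SRMR = %.4f; max |r_res| = %.4f; %d flagged pair(s)\n",
              x$srmr, max(abs(x$r_res)), nrow(x$flagged)))
  if (!is.null(x$q3_cutoff)) {
    cat(sprintf("  Q3 cutoff %.4f; max Q3 = %.4f\n", x$q3_cutoff,
                max(x$q3[lower.tri(x$q3)])))
  }
  invisible(x)
}

#' @method glance fit_diagnostics
#' @export
glance.fit_diagnostics <- function(x, ...) {
  lt <- lower.tri(x$r_res)
  tibble::tibble(srmr = x$srmr, max_abs_r_res = max(abs(x$r_res[lt])),
                 max_q3 = max(x$q3[lt]), mean_q3 = mean(x$q3[lt]),
                 n_flagged = nrow(x$flagged))
}

#' @method autoplot fit_diagnostics
#' @export
autoplot.fit_diagnostics <- function(object, ...) {
  df <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$item_i),
                                   y = factor(.data$item_j),
                                   fill = .data$r_res)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "item", y = "item", fill = "residual r",
                  title = "Residual item-score correlations") +
    ggplot2::theme_minimal()
}

# simulate one dataset of size n from the fitted parameters (codes on the
# original category values), traits standard normal.
simulate_from_parts <- function(parts, n) {
  nf <- ncol(parts$a)
  theta <- matrix(rnorm(n * nf), n, nf)
  J <- nrow(parts$a)
  X <- matrix(0L, n, J)
  for (j in seq_len(J)) {
    P <- t(grm_cat_grid(parts$a[j, ], parts$d[[j]], theta)$P) # n x K
    cum <- t(apply(P, 1, cumsum))
    K <- length(parts$levels[[j]])
    idx <- rowSums(runif(n) > cum[, -K, drop = FALSE]) + 1L
    X[, j] <- parts$levels[[j]][idx]
  }
  list(X = X, theta = theta)
}

#' Parametric-bootstrap critical value for Q3
#'
#' Simulates `n_reps` datasets of the original sample size from the fitted
#' model, scores each with EAP under the fitted parameters, computes all
#' pairwise Q3 values per replicate, and returns the requested percentile of
#' the pooled |Q3| distribution (or of the per-replicate maxima).
#'
#' @param fit A `grm_fit` object.
#' @param n_reps Number of bootstrap replicates (>= 10; 1000 by convention).
#' @param percentile Percentile of the null distribution (default 99).
#' @param seed Integer seed; fixed seeds give identical cutoffs.
#' @param statistic `"pooled"` pools |Q3| over all pairs and replicates;
#'   `"max"` takes each replicate's maximum |Q3|.
#' @return Length-1 numeric critical value.
#' @export
q3_bootstrap_cutoff <- function(fit, n_reps = 1000, percentile = 99,
                                seed = NULL, statistic = c("pooled", "max")) {
  statistic <- match.arg(statistic)
  if (n_reps < 10) abort("`n_reps` must be at least 10.")
  if (!is.null(seed)) set.seed(seed)
  parts <- model_parts(fit)
  n <- fit$n
  vals <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_from_parts(parts, n)
    # guard: a simulated dataset may miss a category; EAP only needs codes
    Xr <- sim$X
    ok <- TRUE
    for (j in seq_len(ncol(Xr))) {
      if (!all(Xr[, j] %in% parts$levels[[j]])) { ok <- FALSE; break }
    }
    if (!ok) next
    theta_hat <- eap_scores(fit, Xr)
    q3 <- q3_matrix(parts, Xr, theta_hat)
    off <- abs(q3[lower.tri(q3)])
    vals[[r]] <- if (statistic == "pooled") off else max(off)
  }
  pooled <- unlist(vals)
  as.numeric(quantile(pooled, percentile / 100, names = FALSE))
}
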