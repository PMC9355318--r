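#' Construct a bifactor graded response model
#'
#' A graded response model for 5-category items under an orthogonal
#' standard-normal latent structure: one general factor plus specific factors,
#' with cumulative category probabilities
#' \eqn{P(X \ge k \mid \theta) = \mathrm{logistic}(a \cdot \theta + d_k)} for
#' \eqn{k = 1, \dots, 4}. Slopes absent from the loading pattern are fixed
#' zeros; intercepts must be strictly decreasing within each item.
#'
#' @param a Numeric matrix, items x factors: slope parameters (column 1 is the
#'   general factor; zero = item does not load).
#' @param d Numeric matrix, items x 4: intercept parameters, strictly
#'   decreasing left to right.
#' @param factors Character vector of factor names (first = general).
#' @param items Integer item ids (defaults to row numbers).
#' @param pattern Optional logical matrix marking free slopes; defaults to
#'   `a != 0` with the general-factor column forced `TRUE`.
#' @return An object of class `bifactor_grm`.
#' @export
bifactor_grm <- function(a, d, factors = NULL, items = NULL, pattern = NULL) {
  a <- as.matrix(a); d <- as.matrix(d)
  if (nrow(a) != nrow(d)) abort("`a` and `d` must describe the same items.")
  if (ncol(d) != 4) abort("`d` must have 4 columns (5 response categories).")
  if (is.null(factors)) factors <- default_factor_names(ncol(a))
  if (length(factors) != ncol(a)) abort("`factors` length must match ncol(a).")
  if (is.null(items)) items <- seq_len(nrow(a))
  if (is.null(pattern)) {
    pattern <- a != 0
    pattern[, 1] <- TRUE
  }
  pattern <- as.matrix(pattern)
  if (any(rowSums(abs(a)) == 0)) abort("Every item needs at least one nonzero slope.")
  if (any(a[!pattern] != 0)) abort("Nonzero slope outside the loading pattern.")
  bad <- which(apply(d, 1, function(r) any(diff(r) >= 0)))
  if (length(bad)) {
    abort(sprintf("Intercepts must be strictly decreasing; violated for item(s) %s.",
                  paste(items[bad], collapse = ", ")))
  }
  dimnames(a) <- list(paste0("item", items), factors)
  dimnames(d) <- list(paste0("item", items), paste0("d", 1:4))
  structure(list(a = a, d = d, factors = factors, items = as.integer(items),
                 pattern = pattern),
            class = "bifactor_grm")
}

#' @export
print.bifactor_grm <- function(x, ...) {
  cat(sprintf("Bifactor graded response model: %d items, %d factors (%s)\n",
              nrow(x$a), length(x$factors),
              paste(x$factors, collapse = ", ")))
  invisible(x)
}

#' @method tidy bifactor_grm
#' @export
tidy.bifactor_grm <- function(x, ...) {
  a_tb <- tibble::as_tibble(x$a)
  names(a_tb) <- paste0("a_", x$factors)
  dplyr::bind_cols(tibble::tibble(item_id = x$items), a_tb,
                   tibble::as_tibble(x$d))
}

n_factors <- function(model) length(model$factors)

item_index <- function(model, item_id) {
  idx <- match(item_id, model$items)
  if (is.na(idx)) abort(sprintf("Item %s is not in the model.", item_id))
  idx
}

as_theta_matrix <- function(theta, nf) {
  if (is.null(dim(theta))) {
    if (length(theta) != nf) {
      abort(sprintf("`theta` must have %d coordinates (one per factor).", nf))
    }
    theta <- matrix(theta, 1, nf)
  }
  theta <- as.matrix(theta)
  if (ncol(theta) != nf) abort(sprintf("`theta` must have %d columns.", nf))
  theta
}

#' Graded-response category probabilities from raw parameters
#'
#' Low-level evaluation of the logistic graded response model for a single
#' item, without constructing a model object: cumulative probabilities
#' \eqn{P(X \ge k) = \mathrm{logistic}(a \cdot \theta + d_k)} differenced
#' into category probabilities. Slopes may all be zero (a trait-free item).
#'
#' @param a Slope vector (one entry per latent dimension).
#' @param d Strictly decreasing intercept vector (length = categories - 1).
#' @param theta Trait matrix (points x dimensions) or a single trait vector.
#' @return Matrix of category probabilities, points x categories.
#' @export
grm_probabilities <- function(a, d, theta) {
  if (any(diff(d) >= 0)) abort("Intercepts must be strictly decreasing.")
  theta <- as_theta_matrix(theta, length(a))
  z <- as.vector(theta %*% a)
  K <- length(d) + 1L
  cum <- cbind(1, plogis(matrix(z, length(z), K - 1) +
                           matrix(d, length(z), K - 1, byrow = TRUE)), 0)
  p <- cum[, 1:K, drop = FALSE] - cum[, 2:(K + 1), drop = FALSE]
  colnames(p) <- paste0("P", seq_len(K) - 1)
  p
}

# Low-level category probabilities for one item: a (length-nf slopes),
# d (length-4 decreasing intercepts), theta (n x nf). Returns n x 5.
grm_prob <- function(a, d, theta) {
  z <- theta %*% a # n x 1
  cum <- cbind(1, plogis(matrix(z, nrow(theta), 4) +
                           matrix(d, nrow(theta), 4, byrow = TRUE)), 0)
  cum[, 1:5, drop = FALSE] - cum[, 2:6, drop = FALSE]
}

#' Category response probabilities
#'
#' Probability of each response category 0-4 for one item at given latent
#' trait values, under the logistic graded response model.
#'
#' @param model A [bifactor_grm()] object.
#' @param item_id Item id within the model.
#' @param theta Latent trait values: a vector of length `n_factors` or a
#'   matrix with one row per trait point.
#' @return A numeric matrix, trait points x 5 categories; rows sum to 1.
#' @export
#' @examples
#' m <- dvmsq_model("prolific")
#' category_probabilities(m, 8, rep(0, 5))
category_probabilities <- function(model, item_id, theta) {
  j <- item_index(model, item_id)
  theta <- as_theta_matrix(theta, n_factors(model))
  p <- grm_prob(model$a[j, ], model$d[j, ], theta)
  colnames(p) <- paste0("P", 0:4)
  p
}

#' Expected item score
#'
#' Model-implied expected response \eqn{E[X \mid \theta] = \sum_{k=1}^{4}
#' P(X \ge k \mid \theta)} for a single item; lies in \[0, 4\].
#'
#' @inheritParams category_probabilities
#' @return Numeric vector, one value per trait point.
#' @export
expected_item_score <- function(model, item_id, theta) {
  j <- item_index(model, item_id)
  theta <- as_theta_matrix(theta, n_factors(model))
  grm_es(model$a[j, ], model$d[j, ], theta)
}

grm_es <- function(a, d, theta) {
  z <- as.vector(theta %*% a)
  rowSums(plogis(matrix(z, length(z), 4) +
                   matrix(d, length(z), 4, byrow = TRUE)))
}

#' Expected total score
#'
#' Sum of expected item scores over a subset of items at given latent trait
#' values.
#'
#' @inheritParams category_probabilities
#' @param items Item ids to sum over (default: all items in the model).
#' @return Numeric vector, one value per trait point.
#' @export
expected_total_score <- function(model, theta, items = NULL) {
  items <- items %||% model$items
  if (length(items) == 0) abort("`items` must be non-empty.")
  theta <- as_theta_matrix(theta, n_factors(model))
  vals <- vapply(items, function(id) expected_item_score(model, id, theta),
                 numeric(nrow(theta)))
  rowSums(matrix(vals, nrow = nrow(theta)))
}

#' Convert logistic slopes to standardized factor loadings
#'
#' Rescales logistic slopes to the normal-ogive metric by a scaling constant
#' (1.702 by default) and standardizes:
#' \eqn{\lambda_{jf} = a^*_{jf} / \sqrt{1 + \sum_f a^{*2}_{jf}}}. Residual
#' variance is \eqn{1 - h^2_j} with \eqn{h^2_j = \sum_f \lambda^2_{jf}}.
#'
#' @param model A [bifactor_grm()] object.
#' @param scaling_constant Logistic-to-probit scaling constant (> 0).
#' @return A tibble with `item_id`, one loading column per factor (named
#'   `lambda_<factor>`), `h2`, and `residual`.
#' @export
slopes_to_loadings <- function(model, scaling_constant = 1.702) {
  if (scaling_constant <= 0) abort("`scaling_constant` must be positive.")
  astar <- model$a / scaling_constant
  denom <- sqrt(1 + rowSums(astar^2))
  lambda <- astar / denom
  h2 <- rowSums(lambda^2)
  out <- tibble::as_tibble(lambda)
  names(out) <- paste0("lambda_", model$factors)
  out <- dplyr::bind_cols(tibble::tibble(item_id = model$items), out)
  out$h2 <- h2
  out$residual <- 1 - h2
  attr(out, "factors") <- model$factors
  out
}

#' Bifactor reliability indices
#'
#' Model-based reliability and dimensionality indices computed from
#' standardized loadings: omega total (\eqn{\omega_T}), omega hierarchical
#' (\eqn{\omega_H}, general-factor saturation of the total score), omega
#' hierarchical subscale (\eqn{\omega_{HS}}, per specific factor, with the
#' general loadings treated as nuisance), and the explained common variance
#' of the general factor (ECV).
#'
#' @param loadings Output of [slopes_to_loadings()], or a numeric matrix of
#'   standardized loadings with the general factor in column 1.
#' @return A one-row tibble with `omega_t`, `omega_h`, `ecv`, and one
#'   `omega_hs_<factor>` column per specific factor.
#' @export
bifactor_indices <- function(loadings) {
  if (is.data.frame(loadings)) {
    facs <- attr(loadings, "factors")
    lam_cols <- paste0("lambda_", facs)
    lambda <- as.matrix(loadings[lam_cols])
    resid <- loadings$residual
  } else {
    lambda <- as.matrix(loadings)
    facs <- colnames(lambda) %||% c("general", paste0("s", seq_len(ncol(lambda) - 1)))
    resid <- 1 - rowSums(lambda^2)
  }
  if (nrow(lambda) == 0) abort("Empty loading matrix.")
  gen <- lambda[, 1]
  spec <- lambda[, -1, drop = FALSE]
  num_g <- sum(gen)^2
  num_s <- colSums(spec)^2
  denom <- num_g + sum(num_s) + sum(resid)
  omega_t <- (num_g + sum(num_s)) / denom
  omega_h <- num_g / denom
  ecv <- sum(gen^2) / sum(lambda^2)
  out <- tibble::tibble(omega_t = omega_t, omega_h = omega_h, ecv = ecv)
  for (s in seq_len(ncol(spec))) {
    in_s <- spec[, s] != 0
    if (!any(in_s)) { out[[paste0("omega_hs_", facs[s + 1])]] <- NA_real_; next }
    num <- sum(spec[in_s, s])^2
    den <- sum(gen[in_s])^2 +
      sum(colSums(spec[in_s, , drop = FALSE])^2) + sum(resid[in_s])
    out[[paste0("omega_hs_", facs[s + 1])]] <- num / den
  }
  out
}

# --- marginal (quadrature) moments -----------------------------------------

# Marginal moments of one item's score over its own latent dimensions,
# integrating the orthogonal normal latent density by block quadrature.
# g_mean/g_sd shift the general factor only (focal-group distributions).
marginal_item_moments <- function(model, item_id, g_mean = 0, g_sd = 1,
                                  n_nodes = NULL) {
  j <- item_index(model, item_id)
  dims <- union(1L, which(model$a[j, ] != 0))
  nd <- length(dims)
  n_nodes <- n_nodes %||% block_nodes(nd)
  nodes <- quad_nodes(n_nodes)
  grids <- rep(list(nodes), nd)
  grid <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  w <- quad_weights(nodes, mean = g_mean, sd = g_sd)[match(grid[, 1], nodes)]
  if (nd > 1) {
    ws <- quad_weights(nodes)
    for (k in 2:nd) w <- w * ws[match(grid[, k], nodes)]
  }
  theta <- matrix(0, nrow(grid), n_factors(model))
  theta[, dims] <- grid
  p <- grm_prob(model$a[j, ], model$d[j, ], theta)
  scores <- 0:4
  es_theta <- as.vector(p %*% scores)
  ex <- sum(w * es_theta)
  ex2 <- sum(w * as.vector(p %*% scores^2))
  pk <- as.vector(crossprod(p, w))
  list(mean = ex, var = ex2 - ex^2, category_probs = pk / sum(w))
}

#' Marginal category probabilities
#'
#' Probability of each response category, integrated over the latent trait
#' distribution by quadrature.
#'
#' @inheritParams category_probabilities
#' @param g_mean,g_sd Mean and SD of the general factor.
#' @return Named numeric vector of 5 probabilities summing to 1.
#' @export
marginal_category_probabilities <- function(model, item_id, g_mean = 0, g_sd = 1) {
  p <- marginal_item_moments(model, item_id, g_mean, g_sd)$category_probs
  names(p) <- paste0("P", 0:4)
  p
}

#' Quadrature-marginal expected item score
#'
#' Expected item score integrated over the latent trait distribution
#' (orthogonal normal; the general factor may have a shifted mean/variance).
#'
#' @inheritParams category_probabilities
#' @param g_mean,g_sd Mean and SD of the general factor.
#' @return Length-1 numeric.
#' @export
marginal_expected_score <- function(model, item_id, g_mean = 0, g_sd = 1) {
  marginal_item_moments(model, item_id, g_mean, g_sd)$mean
}
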