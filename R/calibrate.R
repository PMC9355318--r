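# Maximum marginal likelihood estimation of graded response models by the
# Bock-Aitkin EM algorithm. The latent density is integrated on a fixed
# rectangular grid; bifactor patterns use dimension reduction: conditional on
# the general factor, blocks of specific factors (connected components of
# specifics linked by cross-loading items) are integrated independently, so
# the E-step never touches more than (1 + block size) joint dimensions.

# ---- data preparation ------------------------------------------------------

# Screen-positive complete rows -> integer code matrix (n x J) on 0..4.
calib_matrix <- function(data, items) {
  data <- validate_responses(data, items)
  cols <- item_cols(items)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Missing item columns: %s", paste(missing_cols, collapse = ", ")))
  }
  keep <- (!("s1" %in% names(data)) | (!is.na(data$s1) & data$s1)) &
    complete.cases(data[cols])
  X <- as.matrix(data[keep, cols])
  storage.mode(X) <- "integer"
  if (nrow(X) < 2) abort("Too few screen-positive complete rows for calibration.")
  X
}

# Per-item observed-category maps. Categories never observed are collapsed
# out; items must retain at least 2 categories. Returns list with recoded
# matrix (1..K_j) and the observed code levels per item.
collapse_categories <- function(X) {
  J <- ncol(X)
  levels <- vector("list", J)
  Xr <- X
  for (j in seq_len(J)) {
    lev <- sort(unique(X[, j]))
    if (length(lev) < 2) {
      abort(sprintf("Item %s shows responses in fewer than 2 categories.",
                    colnames(X)[j]))
    }
    levels[[j]] <- lev
    Xr[, j] <- match(X[, j], lev)
  }
  list(X = Xr, levels = levels, K = lengths(levels))
}

# ---- grid setup ------------------------------------------------------------

make_grid <- function(pattern, nodes_2d = 49, nodes_3d = 15) {
  blocks <- factor_blocks(pattern)
  dims <- vapply(blocks, function(b) 1L + length(b$factors), integer(1))
  ng <- if (any(dims >= 3)) nodes_3d else nodes_2d
  gq <- quad_nodes(ng)
  info <- lapply(blocks, function(b) {
    ns <- if (1L + length(b$factors) >= 3) nodes_3d else nodes_2d
    sq <- quad_nodes(ns)
    nspec <- length(b$factors)
    grids <- c(list(gq), rep(list(sq), nspec))
    grid <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    g_of_m <- match(grid[, 1], gq)
    ws <- rep(1, nrow(grid))
    if (nspec > 0) {
      wq <- quad_weights(sq)
      for (k in seq_len(nspec)) ws <- ws * wq[match(grid[, k + 1], sq)]
    }
    theta <- matrix(0, nrow(grid), ncol(pattern))
    theta[, 1] <- grid[, 1]
    if (nspec > 0) theta[, b$factors] <- grid[, -1, drop = FALSE]
    # collapse matrix onto the general grid: M x ng, entry ws at (m, g_of_m)
    W <- matrix(0, nrow(grid), ng)
    W[cbind(seq_len(nrow(grid)), g_of_m)] <- ws
    list(factors = b$factors, items = b$items, theta = theta,
         g_of_m = g_of_m, ws = ws, W = W)
  })
  list(gq = gq, ng = ng, blocks = info)
}

# ---- GRM likelihood pieces -------------------------------------------------

# Cumulative curves and category probabilities on a grid.
# a: slopes (full factor space), d: K-1 decreasing intercepts,
# theta: M x nf. Returns list(P = K x M, psi = (K-1) x M logistic densities).
grm_cat_grid <- function(a, d, theta) {
  z <- as.vector(theta %*% a)
  K <- length(d) + 1L
  cum <- plogis(outer(d, z, `+`)) # (K-1) x M
  P <- rbind(1, cum) - rbind(cum, 0)
  P <- pmax(P, 1e-12)
  list(P = P, psi = cum * (1 - cum))
}

# M-step objective/gradient for one item on its expected count table.
# par = c(a_free, d1, t_2..t_{K-1}); d_k = d1 - cumsum(exp(t)).
item_negll <- function(par, r, theta_free, K) {
  p <- ncol(theta_free)
  a <- par[seq_len(p)]
  d1 <- par[p + 1]
  d <- if (K > 2) d1 - c(0, cumsum(exp(par[(p + 2):(p + K - 1)]))) else d1
  z <- as.vector(theta_free %*% a)
  cum <- plogis(outer(d, z, `+`))
  P <- pmax(rbind(1, cum) - rbind(cum, 0), 1e-12)
  -sum(r * log(P))
}

item_negll_grad <- function(par, r, theta_free, K) {
  p <- ncol(theta_free)
  a <- par[seq_len(p)]
  d1 <- par[p + 1]
  e <- if (K > 2) exp(par[(p + 2):(p + K - 1)]) else numeric(0)
  d <- d1 - c(0, cumsum(e))
  z <- as.vector(theta_free %*% a)
  cum <- plogis(outer(d, z, `+`)) # (K-1) x M
  P <- pmax(rbind(1, cum) - rbind(cum, 0), 1e-12)
  psi <- cum * (1 - cum)
  q <- r / P # K x M
  U <- psi * (q[-1, , drop = FALSE] - q[-K, , drop = FALSE]) # (K-1) x M
  g_d <- rowSums(U) # natural intercept gradient, k = 1..K-1
  g_a <- colSums(U) %*% theta_free # 1 x p
  g_d1 <- sum(g_d)
  g_t <- if (K > 2) {
    -e * rev(cumsum(rev(g_d)))[-1]
  } else numeric(0)
  -c(as.vector(g_a), g_d1, g_t)
}

item_par_pack <- function(a_free, d) {
  K <- length(d) + 1L
  t <- if (K > 2) log(pmax(-diff(d), 1e-6)) else numeric(0)
  c(a_free, d[1], t)
}

item_par_unpack <- function(par, p, K) {
  a_free <- par[seq_len(p)]
  d1 <- par[p + 1]
  d <- if (K > 2) d1 - c(0, cumsum(exp(par[(p + 2):(p + K - 1)]))) else d1
  list(a = a_free, d = d)
}

# ---- the EM engine ---------------------------------------------------------

# X_list: list of recoded (1..K_j) matrices per group (1 or 2 groups).
# pattern: J x F logical. a0: J x F start slopes; d0: list of J vectors.
# equated: logical J (TRUE = parameters shared across groups).
# focal: list(estimate, mean, sd).
em_engine <- function(X_list, K, pattern, a0, d0, equated,
                      focal = list(estimate = FALSE, mean = 0, sd = 1),
                      control = list()) {
  ctl <- utils::modifyList(
    list(n_cycles = 500, tol = 1e-4, nodes_2d = 49, nodes_3d = 15,
         verbose = FALSE, optim_maxit = 40), control)
  G <- length(X_list)
  J <- ncol(X_list[[1]])
  grid <- make_grid(pattern, ctl$nodes_2d, ctl$nodes_3d)
  gq <- grid$gq
  # per-group parameter sets (identical storage; equated rows kept in sync)
  a_par <- rep(list(a0), G)
  d_par <- rep(list(d0), G)
  f_mean <- focal$mean %||% 0
  f_sd <- focal$sd %||% 1
  loglik_trace <- numeric(0)
  free_idx <- which(pattern, arr.ind = TRUE)

  estep_group <- function(g) {
    X <- X_list[[g]]
    n <- nrow(X)
    wg <- if (g == 1) quad_weights(gq) else quad_weights(gq, f_mean, f_sd)
    blocks_L <- vector("list", length(grid$blocks))
    blocks_Lg <- vector("list", length(grid$blocks))
    P_arr <- vector("list", J)
    for (bi in seq_along(grid$blocks)) {
      b <- grid$blocks[[bi]]
      Ps <- lapply(b$items, function(j) {
        grm_cat_grid(a_par[[g]][j, ], d_par[[g]][[j]], b$theta)$P
      })
      bl <- block_lik(X[, b$items, drop = FALSE], Ps, b$ws, b$g_of_m, grid$ng)
      blocks_L[[bi]] <- bl$L
      blocks_Lg[[bi]] <- bl$Lg
    }
    A <- Reduce(`*`, blocks_Lg)
    Li <- as.vector(A %*% wg)
    Li <- pmax(Li, 1e-300)
    Pg <- A * matrix(wg, n, grid$ng, byrow = TRUE) / Li
    list(L = blocks_L, Lg = blocks_Lg, A = A, Li = Li, Pg = Pg, wg = wg, n = n)
  }

  # expected count tables r[[g]][[j]] (K_j x M_block)
  expected_counts <- function(es, g) {
    X <- X_list[[g]]
    n <- nrow(X)
    r <- vector("list", J)
    for (bi in seq_along(grid$blocks)) {
      b <- grid$blocks[[bi]]
      outer_g <- (es$A / pmax(es$Lg[[bi]], 1e-300)) *
        matrix(es$wg, n, grid$ng, byrow = TRUE) / es$Li
      post <- block_post(es$L[[bi]], outer_g, b$ws, b$g_of_m)
      counts <- block_counts(X[, b$items, drop = FALSE], post, K[b$items])
      for (ji in seq_along(b$items)) r[[b$items[ji]]] <- counts[[ji]]
    }
    r
  }

  block_of_item <- integer(J)
  for (bi in seq_along(grid$blocks)) block_of_item[grid$blocks[[bi]]$items] <- bi

  # M-step grid collapse: expected counts over block-grid dimensions an item
  # does not load on are aggregated, shrinking the optimization grid.
  collapse_map <- vector("list", J)
  for (j in seq_len(J)) {
    b <- grid$blocks[[block_of_item[j]]]
    fdims <- which(pattern[j, ])
    key <- do.call(paste, c(as.data.frame(b$theta[, fdims, drop = FALSE]),
                            sep = "|"))
    midx <- match(key, unique(key))
    theta_item <- b$theta[!duplicated(key), fdims, drop = FALSE]
    collapse_map[[j]] <- if (max(midx) == nrow(b$theta)) {
      list(midx = NULL, theta = b$theta[, fdims, drop = FALSE])
    } else {
      list(midx = midx, theta = theta_item)
    }
  }
  collapse_counts <- function(r, j) {
    cm <- collapse_map[[j]]
    if (is.null(cm$midx)) r else t(rowsum(t(r), cm$midx))
  }

  # parameter vector packing (for the convergence check and Ramsay
  # acceleration); equated items appear once via group 1
  pack_params <- function() {
    c(unlist(lapply(seq_len(G), function(g) a_par[[g]][pattern])),
      unlist(d_par), f_mean, f_sd)
  }
  unpack_params <- function(v) {
    pos <- 0L
    for (g in seq_len(G)) {
      np <- sum(pattern)
      a_par[[g]][pattern] <<- v[pos + seq_len(np)]
      pos <- pos + np
    }
    for (g in seq_len(G)) {
      for (j in seq_len(J)) {
        nk <- K[j] - 1L
        d_par[[g]][[j]] <<- v[pos + seq_len(nk)]
        pos <- pos + nk
      }
    }
    f_mean <<- v[pos + 1L]
    f_sd <<- v[pos + 2L]
  }
  params_valid <- function(v) {
    ok <- TRUE
    pos <- G * sum(pattern)
    for (g in seq_len(G)) {
      for (j in seq_len(J)) {
        nk <- K[j] - 1L
        dj <- v[pos + seq_len(nk)]
        if (nk > 1 && any(diff(dj) >= 0)) ok <- FALSE
        pos <- pos + nk
      }
    }
    ok && v[length(v)] > 0.05
  }

  cycle <- 0L
  max_change <- Inf
  ll_prev <- -Inf
  delta_prev <- NULL
  safe_params <- NULL # plain EM iterate backing up an accelerated proposal
  accelerated <- FALSE
  cooldown <- 0L
  repeat {
    cycle <- cycle + 1L
    es <- lapply(seq_len(G), estep_group)
    ll <- sum(vapply(es, function(e) sum(log(e$Li)), numeric(1)))
    if (accelerated && ll < ll_prev - 1e-8) {
      # accelerated step overshot: fall back to the plain EM iterate
      unpack_params(safe_params)
      accelerated <- FALSE
      cooldown <- 2L
      delta_prev <- NULL
      es <- lapply(seq_len(G), estep_group)
      ll <- sum(vapply(es, function(e) sum(log(e$Li)), numeric(1)))
    }
    loglik_trace <- c(loglik_trace, ll)
    ll_prev <- ll
    r_list <- lapply(seq_len(G), function(g) expected_counts(es[[g]], g))
    old <- pack_params()
    # M-step: items
    for (j in seq_len(J)) {
      fdims <- which(pattern[j, ])
      theta_free <- collapse_map[[j]]$theta
      if (equated[j] || G == 1) {
        r <- collapse_counts(Reduce(`+`, lapply(r_list, `[[`, j)), j)
        par0 <- item_par_pack(a_par[[1]][j, fdims], d_par[[1]][[j]])
        opt <- optim(par0, item_negll, item_negll_grad, r = r,
                     theta_free = theta_free, K = K[j], method = "BFGS",
                     control = list(maxit = ctl$optim_maxit, reltol = 1e-12))
        up <- item_par_unpack(opt$par, length(fdims), K[j])
        for (g in seq_len(G)) {
          a_par[[g]][j, fdims] <- up$a
          d_par[[g]][[j]] <- up$d
        }
      } else {
        for (g in seq_len(G)) {
          par0 <- item_par_pack(a_par[[g]][j, fdims], d_par[[g]][[j]])
          opt <- optim(par0, item_negll, item_negll_grad,
                       r = collapse_counts(r_list[[g]][[j]], j),
                       theta_free = theta_free, K = K[j], method = "BFGS",
                       control = list(maxit = ctl$optim_maxit, reltol = 1e-12))
          up <- item_par_unpack(opt$par, length(fdims), K[j])
          a_par[[g]][j, fdims] <- up$a
          d_par[[g]][[j]] <- up$d
        }
      }
    }
    # M-step: focal latent distribution (general factor)
    if (G == 2 && isTRUE(focal$estimate)) {
      cg <- colSums(es[[2]]$Pg)
      obj <- function(p) {
        w <- dnorm(gq, p[1], exp(p[2]))
        w <- pmax(w / sum(w), 1e-300)
        -sum(cg * log(w))
      }
      op <- optim(c(f_mean, log(f_sd)), obj, method = "Nelder-Mead",
                  control = list(maxit = 200, reltol = 1e-10))
      f_mean <- op$par[1]
      f_sd <- exp(op$par[2])
    }
    new <- pack_params()
    delta <- new - old
    max_change <- max(abs(delta))
    if (ctl$verbose) {
      message(sprintf("cycle %d: loglik %.4f, max change %.6f%s",
                      cycle, ll, max_change,
                      if (accelerated) " (accelerated)" else ""))
    }
    if (max_change < ctl$tol || cycle >= ctl$n_cycles) break
    # Ramsay-style acceleration: when successive EM steps shrink
    # geometrically, extrapolate along the step direction; the monotonicity
    # guard at the top of the loop rejects overshoots.
    accelerated <- FALSE
    if (isTRUE(ctl$accelerate %||% TRUE) && cooldown == 0L &&
        !is.null(delta_prev) && cycle >= 3L) {
      r_ratio <- sqrt(sum(delta^2) / max(sum(delta_prev^2), 1e-300))
      if (r_ratio > 0.1 && r_ratio < 1) {
        step <- min(1 / (1 - r_ratio), 10)
        prop <- old + step * delta
        if (params_valid(prop)) {
          safe_params <- new
          unpack_params(prop)
          accelerated <- TRUE
        }
      }
    }
    if (cooldown > 0L) cooldown <- cooldown - 1L
    delta_prev <- delta
  }
  converged <- max_change < ctl$tol
  list(a = a_par, d = d_par, focal_mean = f_mean, focal_sd = f_sd,
       loglik = loglik_trace[length(loglik_trace)], trace = loglik_trace,
       cycles = cycle, max_change = max_change, converged = converged,
       grid = grid, K = K, pattern = pattern, equated = equated,
       block_of_item = block_of_item)
}

# ---- per-respondent scores (OPG information) -------------------------------

# Natural-parameter score vectors for every respondent of one group, plus
# focal-distribution scores. Returns n x P matrix given the parameter map.
engine_scores <- function(eng, X_list, pmap) {
  G <- length(X_list)
  grid <- eng$grid
  J <- ncol(X_list[[1]])
  scores <- matrix(0, sum(vapply(X_list, nrow, integer(1))), pmap$n_par)
  row_off <- 0L
  for (g in seq_len(G)) {
    X <- X_list[[g]]
    n <- nrow(X)
    wg <- if (g == 1) quad_weights(grid$gq) else {
      quad_weights(grid$gq, eng$focal_mean, eng$focal_sd)
    }
    # recompute E-step pieces
    blocks_L <- list(); blocks_Lg <- list(); P_arr <- vector("list", J)
    psi_arr <- vector("list", J)
    for (bi in seq_along(grid$blocks)) {
      b <- grid$blocks[[bi]]
      for (j in b$items) {
        cg <- grm_cat_grid(eng$a[[g]][j, ], eng$d[[g]][[j]], b$theta)
        P_arr[[j]] <- cg$P; psi_arr[[j]] <- cg$psi
      }
      bl <- block_lik(X[, b$items, drop = FALSE], P_arr[b$items], b$ws,
                      b$g_of_m, grid$ng)
      blocks_L[[bi]] <- bl$L
      blocks_Lg[[bi]] <- bl$Lg
    }
    A <- Reduce(`*`, blocks_Lg)
    Li <- pmax(as.vector(A %*% wg), 1e-300)
    for (bi in seq_along(grid$blocks)) {
      b <- grid$blocks[[bi]]
      M <- nrow(b$theta)
      outer_g <- (A / pmax(blocks_Lg[[bi]], 1e-300)) *
        matrix(wg, n, grid$ng, byrow = TRUE) / Li
      post <- block_post(blocks_L[[bi]], outer_g, b$ws, b$g_of_m)
      for (j in b$items) {
        cols <- pmap$item_cols[[g]][[j]]
        if (is.null(cols)) next
        P <- P_arr[[j]]; psi <- psi_arr[[j]]
        K <- eng$K[j]
        x <- X[, j]
        fdims <- which(eng$pattern[j, ])
        # d log P_x / d d_k = psi_k (delta_{x,k+1} - delta_{x,k}) / P_x
        Px <- P[x, , drop = FALSE] # n x M
        for (ki in seq_len(K - 1)) {
          Gk <- matrix(0, n, M)
          sel_up <- x == ki + 1L
          sel_dn <- x == ki
          if (any(sel_up)) {
            Gk[sel_up, ] <- matrix(psi[ki, ], sum(sel_up), M, byrow = TRUE) /
              Px[sel_up, , drop = FALSE]
          }
          if (any(sel_dn)) {
            Gk[sel_dn, ] <- -matrix(psi[ki, ], sum(sel_dn), M, byrow = TRUE) /
              Px[sel_dn, , drop = FALSE]
          }
          scores[row_off + seq_len(n), cols$d[ki]] <-
            scores[row_off + seq_len(n), cols$d[ki]] + rowSums(post * Gk)
        }
        # d log P_x / d a_f = theta_f (psi_{x-1} - psi_x) / P_x
        psi_pad <- rbind(0, psi, 0) # K+1 rows: psi_0..psi_K
        dz <- (psi_pad[x, , drop = FALSE] -
                 psi_pad[x + 1L, , drop = FALSE]) / Px # n x M
        for (fi in seq_along(fdims)) {
          thf <- b$theta[, fdims[fi]]
          scores[row_off + seq_len(n), cols$a[fi]] <-
            scores[row_off + seq_len(n), cols$a[fi]] +
            rowSums(post * dz * matrix(thf, n, M, byrow = TRUE))
        }
      }
    }
    if (g == 2 && !is.null(pmap$focal_cols)) {
      Pg <- A * matrix(wg, n, grid$ng, byrow = TRUE) / Li
      mu <- eng$focal_mean; sg <- eng$focal_sd
      # derivatives of log normalized weights
      lw_mu <- (grid$gq - mu) / sg^2
      lw_sg <- ((grid$gq - mu)^2 - sg^2) / sg^3
      w <- quad_weights(grid$gq, mu, sg)
      s_mu <- as.vector(Pg %*% (lw_mu - sum(w * lw_mu)))
      s_sg <- as.vector(Pg %*% (lw_sg - sum(w * lw_sg)))
      scores[row_off + seq_len(n), pmap$focal_cols[1]] <- s_mu
      scores[row_off + seq_len(n), pmap$focal_cols[2]] <- s_sg
    }
    row_off <- row_off + n
  }
  scores
}

# Parameter map: column indices for each group/item's natural parameters.
# Equated items get one shared set (listed under both groups).
make_pmap <- function(eng, n_groups, focal_free) {
  J <- length(eng$K)
  item_cols <- rep(list(vector("list", J)), n_groups)
  idx <- 0L
  labels <- character(0)
  for (j in seq_len(J)) {
    fdims <- which(eng$pattern[j, ])
    np <- length(fdims) + eng$K[j] - 1L
    if (eng$equated[j] || n_groups == 1) {
      cols <- list(a = idx + seq_along(fdims),
                   d = idx + length(fdims) + seq_len(eng$K[j] - 1L))
      idx <- idx + np
      labels <- c(labels, paste0("item", j, ".", c(paste0("a", fdims),
                                                   paste0("d", seq_len(eng$K[j] - 1L)))))
      for (g in seq_len(n_groups)) item_cols[[g]][[j]] <- cols
    } else {
      for (g in seq_len(n_groups)) {
        cols <- list(a = idx + seq_along(fdims),
                     d = idx + length(fdims) + seq_len(eng$K[j] - 1L))
        idx <- idx + np
        labels <- c(labels, paste0("g", g, ".item", j, ".",
                                   c(paste0("a", fdims),
                                     paste0("d", seq_len(eng$K[j] - 1L)))))
        item_cols[[g]][[j]] <- cols
      }
    }
  }
  focal_cols <- NULL
  if (n_groups == 2 && focal_free) {
    focal_cols <- idx + 1:2
    idx <- idx + 2L
    labels <- c(labels, "focal.mean", "focal.sd")
  }
  list(item_cols = item_cols, focal_cols = focal_cols, n_par = idx,
       labels = labels)
}

opg_vcov <- function(scores) {
  info <- crossprod(scores)
  v <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(v)) {
    ev <- eigen(info, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    v <- ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  }
  (v + t(v)) / 2
}

# ---- user-facing fitting ---------------------------------------------------

default_start <- function(Xr, K, pattern) {
  J <- ncol(Xr)
  a0 <- matrix(0, J, ncol(pattern))
  a0[pattern] <- 1
  d0 <- vector("list", J)
  for (j in seq_len(J)) {
    p_ge <- rev(cumsum(rev(tabulate(Xr[, j], K[j]) / nrow(Xr))))[-1]
    d0[[j]] <- qlogis(pmin(pmax(p_ge, 0.01), 0.99))
    # enforce strict decrease in degenerate cases
    d0[[j]] <- cummin(d0[[j]]) - (seq_len(K[j] - 1) - 1) * 1e-3
  }
  list(a = a0, d = d0)
}

#' Fit a graded response model by EM
#'
#' Maximum marginal likelihood calibration of a unidimensional or bifactor
#' graded response model on screen-positive complete respondents. The latent
#' density is integrated over a deterministic rectangular grid on \[-6, 6\]
#' (49 nodes per dimension; 15 when cross-loadings merge specific factors
#' into blocks of three or more joint dimensions), and the E-step exploits
#' bifactor dimension reduction. Standard errors, when requested, come from
#' the outer product of per-respondent score vectors (cross-product
#' information).
#'
#' @param data Respondent table (see [score_dvmsq()] for the format); only
#'   screen-positive rows with complete responses on the modeled items are
#'   used. A matrix of item codes is also accepted.
#' @param pattern Logical items x factors loading pattern (column 1 =
#'   general); `NULL` fits a unidimensional model. A [bifactor_grm()] may be
#'   given to reuse its pattern.
#' @param items Item ids to calibrate (default: inferred from `pattern` row
#'   names or all item columns present).
#' @param se Compute the parameter covariance matrix.
#' @param n_cycles,tol EM stopping rule: stop when the largest absolute
#'   parameter change falls below `tol` or after `n_cycles` cycles.
#' @param verbose Print the EM trajectory.
#' @return A `grm_fit` object: the fitted [bifactor_grm()] model, the
#'   log-likelihood trace, convergence record, and (optionally) the
#'   covariance matrix of the natural parameters.
#' @export
fit_grm <- function(data, pattern = NULL, items = NULL, se = FALSE,
                    n_cycles = 500, tol = 1e-4, verbose = FALSE) {
  if (inherits(pattern, "bifactor_grm")) {
    items <- items %||% pattern$items
    pattern <- pattern$pattern
  }
  if (is.matrix(data) && is.numeric(data)) {
    X <- data
    storage.mode(X) <- "integer"
    items <- items %||% seq_len(ncol(X))
    colnames(X) <- item_cols(items)
  } else {
    items <- items %||% sort(as.integer(sub("^q", "", grep(
      "^q[0-9]{2}$", names(data), value = TRUE))))
    X <- calib_matrix(data, items)
  }
  J <- ncol(X)
  if (is.null(pattern)) pattern <- matrix(TRUE, J, 1)
  pattern <- as.matrix(pattern)
  if (nrow(pattern) != J) abort("`pattern` rows must match the item count.")
  pattern[, 1] <- TRUE
  cc <- collapse_categories(X)
  st <- default_start(cc$X, cc$K, pattern)
  eng <- em_engine(list(cc$X), cc$K, pattern, st$a, st$d,
                   equated = rep(TRUE, J),
                   control = list(n_cycles = n_cycles, tol = tol,
                                  verbose = verbose))
  if (!eng$converged) {
    warn(sprintf("EM did not converge in %d cycles (max change %.2e).",
                 eng$cycles, eng$max_change))
  }
  fit <- structure(list(
    engine = eng, items = items, levels = cc$levels, n = nrow(X),
    X = cc$X, pattern = pattern,
    model = engine_model(eng, 1, items, cc$levels)
  ), class = "grm_fit")
  if (se) {
    pmap <- make_pmap(eng, 1, focal_free = FALSE)
    sc <- engine_scores(eng, list(cc$X), pmap)
    fit$vcov <- opg_vcov(sc)
    dimnames(fit$vcov) <- list(pmap$labels, pmap$labels)
    fit$pmap <- pmap
  }
  fit
}

# Build a bifactor_grm from engine output for one group. Items with collapsed
# categories are expanded back to the 0..4 metric only when all 5 categories
# were observed; otherwise the collapsed parameters are returned as-is with a
# `levels` attribute.
engine_model <- function(eng, g, items, levels) {
  J <- length(eng$K)
  full <- all(eng$K == 5)
  if (full) {
    d <- do.call(rbind, eng$d[[g]])
  } else {
    d <- matrix(NA_real_, J, 4)
    for (j in seq_len(J)) d[j, seq_len(eng$K[j] - 1)] <- eng$d[[g]][[j]]
    # strictly-decreasing check only applies to observed boundaries
  }
  m <- structure(list(a = eng$a[[g]], d = d,
                      factors = colnames(eng$pattern) %||%
                        default_factor_names(ncol(eng$pattern)),
                      items = as.integer(items), pattern = eng$pattern),
                 class = "bifactor_grm")
  dimnames(m$a) <- list(paste0("item", items), m$factors)
  dimnames(m$d) <- list(paste0("item", items), paste0("d", 1:4))
  attr(m, "levels") <- levels
  m
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf(
    "Graded response model fit: %d items, %d factors, n = %d\n  loglik %.2f; %d EM cycles; %s\n",
    length(x$items), ncol(x$pattern), x$n, x$engine$loglik, x$engine$cycles,
    if (x$engine$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @method tidy grm_fit
#' @export
tidy.grm_fit <- function(x, ...) tidy(x$model)

#' @method glance grm_fit
#' @export
glance.grm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$engine$loglik, n = x$n,
                 n_items = length(x$items), n_factors = ncol(x$pattern),
                 cycles = x$engine$cycles, converged = x$engine$converged,
                 max_change = x$engine$max_change)
}

#' Fit a two-group (multigroup) graded response model
#'
#' Joint calibration of two groups sharing a loading pattern. The reference
#' group's latent variables are standard normal; the focal group's general
#' factor mean and variance are estimated (or fixed), while specific-factor
#' means and variances are fixed at 0/1 in both groups. Items listed in
#' `equated` share parameters across groups; remaining items are free per
#' group. The joint covariance matrix (outer product of gradients) supports
#' Wald tests of between-group parameter differences.
#'
#' @inheritParams fit_grm
#' @param group_col Name of the grouping column; its first level (or
#'   `"reference"`) is the reference group.
#' @param equated Item ids whose parameters are constrained equal across
#'   groups, or `"all"` / `"none"`.
#' @param focal_mean,focal_sd Fixed focal general-factor moments; `NULL`
#'   (default) estimates them. Fixing both with no equated items is
#'   permitted; estimating them requires at least one equated item.
#' @return An `mg_grm_fit` object with per-group models, focal distribution
#'   estimates, and (if `se`) the joint parameter covariance.
#' @export
fit_multigroup <- function(data, pattern = NULL, items = NULL,
                           group_col = "group", equated = "all",
                           focal_mean = NULL, focal_sd = NULL, se = FALSE,
                           n_cycles = 500, tol = 1e-4, verbose = FALSE) {
  if (inherits(pattern, "bifactor_grm")) {
    items <- items %||% pattern$items
    pattern <- pattern$pattern
  }
  if (!group_col %in% names(data)) {
    abort(sprintf("Column `%s` not found.", group_col))
  }
  glev <- unique(data[[group_col]])
  if (length(glev) != 2) abort("Exactly two groups are required.")
  if ("reference" %in% glev) glev <- c("reference", setdiff(glev, "reference"))
  items <- items %||% sort(as.integer(sub("^q", "", grep(
    "^q[0-9]{2}$", names(data), value = TRUE))))
  X1 <- calib_matrix(data[data[[group_col]] == glev[1], , drop = FALSE], items)
  X2 <- calib_matrix(data[data[[group_col]] == glev[2], , drop = FALSE], items)
  J <- length(items)
  if (is.null(pattern)) pattern <- matrix(TRUE, J, 1)
  pattern <- as.matrix(pattern); pattern[, 1] <- TRUE
  # shared category collapse across groups
  cc <- collapse_categories(rbind(X1, X2))
  Xr1 <- cc$X[seq_len(nrow(X1)), , drop = FALSE]
  Xr2 <- cc$X[nrow(X1) + seq_len(nrow(X2)), , drop = FALSE]
  eq <- if (identical(equated, "all")) rep(TRUE, J) else if
  (identical(equated, "none")) rep(FALSE, J) else items %in% equated
  est_focal <- is.null(focal_mean) && is.null(focal_sd)
  if (est_focal && !any(eq)) {
    abort("Freeing every item with a free focal distribution is not identified.")
  }
  st <- default_start(cc$X, cc$K, pattern)
  eng <- em_engine(list(Xr1, Xr2), cc$K, pattern, st$a, st$d, equated = eq,
                   focal = list(estimate = est_focal,
                                mean = focal_mean %||% 0,
                                sd = focal_sd %||% 1),
                   control = list(n_cycles = n_cycles, tol = tol,
                                  verbose = verbose))
  if (!eng$converged) {
    warn(sprintf("EM did not converge in %d cycles (max change %.2e).",
                 eng$cycles, eng$max_change))
  }
  fit <- structure(list(
    engine = eng, items = items, levels = cc$levels, groups = glev,
    n = c(nrow(X1), nrow(X2)), X = list(Xr1, Xr2), pattern = pattern,
    equated = eq, focal_mean = eng$focal_mean, focal_sd = eng$focal_sd,
    ref_model = engine_model(eng, 1, items, cc$levels),
    focal_model = engine_model(eng, 2, items, cc$levels)
  ), class = "mg_grm_fit")
  if (se) {
    pmap <- make_pmap(eng, 2, focal_free = est_focal)
    sc <- engine_scores(eng, list(Xr1, Xr2), pmap)
    fit$vcov <- opg_vcov(sc)
    dimnames(fit$vcov) <- list(pmap$labels, pmap$labels)
    fit$pmap <- pmap
  }
  fit
}

#' @export
print.mg_grm_fit <- function(x, ...) {
  cat(sprintf(
    paste0("Multigroup graded response model: %d items, groups %s (n = %d) / ",
           "%s (n = %d)\n  focal general factor: mean %.3f, sd %.3f; ",
           "%d equated items; loglik %.2f (%s)\n"),
    length(x$items), x$groups[1], x$n[1], x$groups[2], x$n[2],
    x$focal_mean, x$focal_sd, sum(x$equated), x$engine$loglik,
    if (x$engine$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @method glance mg_grm_fit
#' @export
glance.mg_grm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$engine$loglik, n_reference = x$n[1],
                 n_focal = x$n[2], focal_mean = x$focal_mean,
                 focal_sd = x$focal_sd, n_equated = sum(x$equated),
                 cycles = x$engine$cycles, converged = x$engine$converged)
}
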