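# Deterministic quadrature over the latent space.
#
# Latent variables are orthogonal standard normal (optionally with a shifted
# general-factor mean/variance for focal groups). Integration uses equally
# spaced rectangles on [-6, 6]: 49 nodes per dimension for 1- or 2-dimensional
# blocks, dropping to 15 per dimension when cross-loadings merge specific
# factors into blocks of three or more joint dimensions.

quad_nodes <- function(n_nodes = 49, lower = -6, upper = 6) {
  seq(lower, upper, length.out = n_nodes)
}

quad_weights <- function(nodes, mean = 0, sd = 1) {
  w <- dnorm(nodes, mean, sd)
  w / sum(w)
}

# Connected components of specific factors linked by shared items.
# pattern: items x factors logical, column 1 = general.
# Returns a list of blocks: each has $factors (indices > 1, possibly empty)
# and $items (row indices of items whose specific loadings lie in the block).
# Items loading only on the general factor are gathered into one extra block
# with no specific factors.
factor_blocks <- function(pattern) {
  nf <- ncol(pattern)
  specifics <- seq_len(nf)[-1]
  if (length(specifics) == 0) {
    return(list(list(factors = integer(0), items = seq_len(nrow(pattern)))))
  }
  # union-find over specific factors
  parent <- seq_len(nf)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (j in seq_len(nrow(pattern))) {
    loaded <- intersect(which(pattern[j, ]), specifics)
    if (length(loaded) > 1) {
      r <- find(loaded[1])
      for (f in loaded[-1]) parent[find(f)] <- r
    }
  }
  roots <- vapply(specifics, find, integer(1))
  blocks <- lapply(unique(roots), function(r) {
    facs <- specifics[roots == r]
    its <- which(apply(pattern[, facs, drop = FALSE], 1, any))
    list(factors = facs, items = its)
  })
  g_only <- which(!apply(pattern[, specifics, drop = FALSE], 1, any))
  if (length(g_only)) {
    blocks <- c(blocks, list(list(factors = integer(0), items = g_only)))
  }
  blocks
}

# Node count rule for a block with `ndim` joint dimensions (general included).
block_nodes <- function(ndim, nodes_2d = 49, nodes_3d = 15) {
  if (ndim >= 3) nodes_3d else nodes_2d
}

# Expanded grid over the general factor and a set of specific factors.
# Returns list(theta = matrix (#points x nf), w_g = weights on the general
# grid, w_s = specific weights, g_index = index into the general grid).
block_grid <- function(nf, block_factors, g_nodes, s_nodes) {
  dims <- c(list(g = g_nodes), rep(list(s_nodes), length(block_factors)))
  grid <- as.matrix(expand.grid(dims, KEEP.OUT.ATTRS = FALSE))
  theta <- matrix(0, nrow(grid), nf)
  theta[, 1] <- grid[, 1]
  if (length(block_factors)) {
    theta[, block_factors] <- grid[, -1, drop = FALSE]
  }
  theta
}
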