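#' Draw orthogonal normal latent traits
#'
#' Independent normal draws per factor with unit variance, matching the
#' orthogonal standard-normal latent structure of the measurement model.
#'
#' @param n Number of respondents.
#' @param n_factors Number of latent factors.
#' @param mean Mean per factor (scalar or length `n_factors`).
#' @param sd SD per factor (scalar or length `n_factors`).
#' @param seed Optional integer seed for reproducibility.
#' @return An `n` x `n_factors` numeric matrix.
#' @export
draw_traits <- function(n, n_factors, mean = 0, sd = 1, seed = NULL) {
  if (n < 1) abort("`n` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  mean <- rep_len(mean, n_factors)
  sd <- rep_len(sd, n_factors)
  theta <- matrix(rnorm(n * n_factors), n, n_factors)
  sweep(sweep(theta, 2, sd, `*`), 2, mean, `+`)
}

#' Simulate DVMSQ respondents
#'
#' Generates a synthetic respondent table with the statistical structure the
#' instrument assumes: latent traits drawn from the orthogonal normal
#' distribution, item responses drawn from the graded response model, and a
#' screening gate producing the zero-inflated design (screen-negative
#' respondents skip all items). Screening is modeled either as an independent
#' Bernoulli coin (`screen = list(p = ...)`) or, by default, as a logistic
#' function of the general trait (`screen = list(slope = 1.5, intercept =
#' 0.3)`), so that screen positives are trait-enriched, mimicking how
#' zero-inflation arises in real administration.
#'
#' @param model A [bifactor_grm()] object.
#' @param n Number of respondents.
#' @param screen Screening rule: `list(p = prob)` for a fixed screen-positive
#'   probability, or `list(slope =, intercept =)` for a logistic link on the
#'   general trait. Default `list(slope = 1.5, intercept = 0.3)`.
#' @param g_mean,g_sd Mean and SD of the general trait (specific traits are
#'   standard normal).
#' @param external Optional external-scale specs: a list of
#'   `list(name =, loading =, noise_sd =)`; each scale is `loading * theta_G +
#'   N(0, noise_sd)`.
#' @param seed Optional integer seed.
#' @param group Optional group label attached to every row.
#' @return A tibble with `respondent_id`, `s1`, the model's item columns
#'   (`NA` for screen negatives), any external scales, and a `theta` attribute
#'   (matrix of the generating traits).
#' @export
#' @examples
#' m <- dvmsq_model("prolific")
#' d <- simulate_responses(m, 50, seed = 1)
simulate_responses <- function(model, n, screen = list(slope = 1.5, intercept = 0.3),
                               g_mean = 0, g_sd = 1, external = NULL,
                               seed = NULL, group = NULL) {
  if (!inherits(model, "bifactor_grm")) abort("`model` must be a bifactor_grm.")
  if (!is.null(seed)) set.seed(seed)
  nf <- n_factors(model)
  theta <- draw_traits(n, nf, mean = c(g_mean, rep(0, nf - 1)),
                       sd = c(g_sd, rep(1, nf - 1)))
  if (!is.null(screen$p)) {
    if (screen$p < 0 || screen$p > 1) abort("`screen$p` must lie in [0, 1].")
    s1 <- runif(n) < screen$p
  } else {
    s1 <- runif(n) < plogis(screen$intercept + screen$slope * theta[, 1])
  }
  out <- tibble::tibble(respondent_id = sprintf("r%05d", seq_len(n)), s1 = s1)
  u_cols <- matrix(runif(n * nrow(model$a)), n, nrow(model$a))
  for (j in seq_along(model$items)) {
    p <- grm_prob(model$a[j, ], model$d[j, ], theta)
    cum <- t(apply(p, 1, cumsum))
    x <- rowSums(u_cols[, j] > cum[, 1:4, drop = FALSE])
    x[!s1] <- NA_integer_
    out[[item_cols(model$items[j])]] <- as.integer(x)
  }
  if (!is.null(external)) {
    for (spec in external) {
      out[[spec$name]] <- spec$loading * theta[, 1] +
        rnorm(n, 0, spec$noise_sd)
    }
  }
  if (!is.null(group)) out$group <- group
  attr(out, "theta") <- theta
  out
}

#' Simulate a two-group DIF study
#'
#' Reference-group respondents are generated from the reference model with
#' standard-normal traits; focal-group respondents from the focal model with
#' the general trait mean shifted by `impact` (a true latent group difference,
#' which is not DIF). Both groups are simulated without a screening gate
#' (every row complete), as DIF analyses operate on completers.
#'
#' @param ref_model,focal_model [bifactor_grm()] objects sharing a loading
#'   pattern. Parameter differences between them constitute true DIF.
#' @param n_per_group Respondents per group (scalar or length 2).
#' @param impact Mean shift of the focal group's general trait.
#' @param seed Optional integer seed.
#' @return A tibble with a `group` column (`"reference"`, `"focal"`) and item
#'   columns.
#' @export
simulate_dif_study <- function(ref_model, focal_model = ref_model,
                               n_per_group = 1000, impact = 0, seed = NULL) {
  if (!identical(dim(ref_model$a), dim(focal_model$a)) ||
      !identical(ref_model$pattern, focal_model$pattern)) {
    abort("Reference and focal models must share the loading pattern.")
  }
  if (!is.null(seed)) set.seed(seed)
  n_per_group <- rep_len(n_per_group, 2)
  ref <- simulate_responses(ref_model, n_per_group[1], screen = list(p = 1),
                            group = "reference")
  foc <- simulate_responses(focal_model, n_per_group[2], screen = list(p = 1),
                            g_mean = impact, group = "focal")
  ref$respondent_id <- paste0("ref_", ref$respondent_id)
  foc$respondent_id <- paste0("foc_", foc$respondent_id)
  out <- dplyr::bind_rows(ref, foc)
  attr(out, "theta") <- rbind(attr(ref, "theta"), attr(foc, "theta"))
  out
}
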