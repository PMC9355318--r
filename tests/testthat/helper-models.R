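# Small models and respondent tables built in code for the tests.

# unidimensional 5-category model with J items and given slopes
unidim_model <- function(a, d = NULL, seed = 1) {
  J <- length(a)
  if (is.null(d)) {
    set.seed(seed)
    d <- t(sapply(seq_len(J), function(j) {
      base <- sort(rnorm(4, 0, 1.5), decreasing = TRUE)
      base - (0:3) * 0.4 # guarantee strictly decreasing with clear gaps
    }))
  }
  bifactor_grm(matrix(a, J, 1), d, factors = "general", items = seq_len(J))
}

# a respondent row (tibble) with all items at `fill` and named overrides
respondent_row <- function(s1 = TRUE, fill = 0L, ...) {
  d <- tibble::tibble(s1 = s1)
  d[item_columns()] <- as.list(rep(as.integer(fill), 20))
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- as.integer(over[[nm]])
  d
}

# direct transcription of the operational diagnostic table, used as an
# independent oracle for classify_misophonia (returns a character class)
oracle_classify <- function(s1, q) {
  # q: named integer vector q01..q20 (missing treated as 0)
  g <- function(i) {
    v <- q[sprintf("q%02d", i)]
    if (is.na(v)) 0L else v
  }
  if (!isTRUE(s1)) return("none")
  A <- TRUE
  B <- g(1) >= 3 || g(2) >= 3 || g(4) >= 3
  C <- g(12) >= 2 || g(5) >= 3 || g(6) >= 3
  D <- g(8) >= 2 || g(7) >= 2
  f_items <- c(13, 14, 15, 16, 18, 19, 20)
  F_ <- sum(vapply(f_items, function(i) g(i) >= 2, logical(1))) >= 2
  if (A && B && C && D && F_) "clinical" else if (A && B && C && D) "subclinical" else "none"
}
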