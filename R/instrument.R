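#' The DVMSQ item bank
#'
#' Returns the 20 Likert items of the original Duke-Vanderbilt Misophonia
#' Screening Questionnaire together with their scale membership, response
#' anchors, scoring status, and the role each item plays in the operational
#' diagnostic algorithm. Items 1-12 are symptom-frequency items (anchors
#' "Never" ... "Very often", coded 0-4); items 13-20 are impairment items
#' ("Not at all" ... "An extreme amount", coded 0-4). Items 3 (fear/panic),
#' 11 (excessive/unreasonable reactions) and 17 (impairment - concentration)
#' are administered and stored but excluded from all summary scores and from
#' the diagnostic algorithm; item 3 is retained on the form for its value in
#' differentiating misophonia from phonophobia.
#'
#' @param revised_screen logical; if `TRUE` the returned attribute
#'   `screen_text` carries the revised screening wording that clarifies the
#'   emotional (rather than loudness-related) nature of the bother. The two
#'   wordings are metadata only: scoring and classification are identical.
#'
#' @return A tibble with one row per item: `item_id`, `column` (the canonical
#'   data column `q01`...`q20`), `text`, `scale` (`"symptom"` or
#'   `"impairment"`), `scored`, `criterion` (diagnostic criterion letter or
#'   `NA`), `criterion_threshold` (minimum code fulfilling that criterion), and
#'   `anchors` (list-column of the five response labels).
#' @export
#' @examples
#' dvmsq_items()
dvmsq_items <- function(revised_screen = FALSE) {
  sym_anchors <- c("Never", "Rarely", "Sometimes", "Often", "Very often")
  imp_anchors <- c("Not at all", "A little bit", "A moderate amount",
                   "Very much", "An extreme amount")
  text <- c(
    "Intense feelings of irritation or annoyance",
    "Feelings of anger or rage",
    "Feelings of fear or panic",
    "Feelings of disgust",
    "Urges to run away from the sound",
    "Urges to cover your ears or block out the sound",
    "Urges to lash out violently at the person or object making the sound",
    "Feeling like you cannot control your response to the sound",
    "Difficulty focusing on anything except the sound",
    "Some sort of immediate physical response",
    "Emotional responses excessive, unreasonable, or out of proportion",
    "Avoidance of situations with potential trigger sounds",
    "Interference with ability to interact with other people",
    "Interference with ability to be productive at work or school",
    "Interference with ability to take care of household responsibilities",
    "Interference with ability to participate in community activities",
    "Interference with ability to concentrate",
    "Negative impact on mental or emotional health",
    "Sound sensitivities have created problems",
    "Sound sensitivities have made your entire life worse"
  )
  # diagnostic algorithm roles: criterion letter + minimum fulfilling code
  crit <- rep(NA_character_, 20)
  thr <- rep(NA_integer_, 20)
  crit[c(1, 2, 4)] <- "B"; thr[c(1, 2, 4)] <- 3L
  crit[c(12, 5, 6)] <- "C"; thr[12] <- 2L; thr[c(5, 6)] <- 3L
  crit[c(8, 7)] <- "D"; thr[c(8, 7)] <- 2L
  crit[c(13:16, 18:20)] <- "F"; thr[c(13:16, 18:20)] <- 2L
  out <- tibble::tibble(
    item_id = 1:20,
    column = item_cols(1:20),
    text = text,
    scale = rep(c("symptom", "impairment"), c(12, 8)),
    scored = !(1:20 %in% c(3L, 11L, 17L)),
    criterion = crit,
    criterion_threshold = thr,
    anchors = c(rep(list(sym_anchors), 12), rep(list(imp_anchors), 8))
  )
  attr(out, "screen_text") <- if (revised_screen) {
    paste("Are there specific sounds that you are extremely bothered by,",
          "even if they are not loud? These sounds should cause significant",
          "emotional distress (e.g., extreme irritation, anger, disgust,",
          "rage, anxiety, or panic). Do NOT count sounds that bother you",
          "only because you find them too loud or physically painful.")
  } else {
    paste("Are there specific sounds that you are extremely bothered by,",
          "even if they are not loud?")
  }
  out
}

scored_item_ids <- function() {
  items <- dvmsq_items()
  items$item_id[items$scored]
}

symptom_item_ids <- function() c(1L, 2L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 12L)
impairment_item_ids <- function() c(13L, 14L, 15L, 16L, 18L, 19L, 20L)

# Validate a respondent table: s1 logical (or Y/N), item codes integer 0-4 or
# NA, screen-negative rows item-free. Returns the data with s1 as logical and
# item columns as integer.
validate_responses <- function(data, items = 1:20) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!"s1" %in% names(data)) abort("`data` must contain an `s1` screening column.")
  data <- tibble::as_tibble(data)
  if (!"respondent_id" %in% names(data)) {
    data$respondent_id <- as.character(seq_len(nrow(data)))
  }
  s1 <- data$s1
  if (!is.logical(s1)) {
    s1_chr <- toupper(trimws(as.character(s1)))
    s1 <- dplyr::case_when(
      s1_chr %in% c("Y", "YES", "TRUE", "1") ~ TRUE,
      s1_chr %in% c("N", "NO", "FALSE", "0") ~ FALSE,
      TRUE ~ NA
    )
    if (anyNA(s1) && !all(is.na(s1) == is.na(data$s1))) {
      bad <- which(is.na(s1) & !is.na(data$s1))
      abort(sprintf("Unparseable `s1` value for respondent %s.",
                    data$respondent_id[bad[1]]))
    }
  }
  data$s1 <- s1
  present <- intersect(item_cols(items), names(data))
  for (col in present) {
    v <- data[[col]]
    if (is.character(v)) {
      v[trimws(v) == ""] <- NA
      v <- suppressWarnings(as.numeric(v))
    }
    if (is.numeric(v)) {
      nonint <- !is.na(v) & v != round(v)
      if (any(nonint)) {
        i <- which(nonint)[1]
        abort(sprintf("Non-integer response for respondent %s, item %s: %s",
                      data$respondent_id[i], col, data[[col]][i]))
      }
      v <- as.integer(round(v))
    }
    bad <- !is.na(v) & (v < 0L | v > 4L)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "Out-of-range response for respondent %s, item %s: %s (codes must be 0-4)",
        data$respondent_id[i], col, v[i]))
    }
    data[[col]] <- v
  }
  data
}

#' Score the DVMSQ
#'
#' Computes the three DVMSQ summary scores for each respondent: the total
#' score over the 17 scored items (range 0-68), the symptom score over 10
#' symptom items (0-40), and the impairment score over 7 impairment items
#' (0-28). Respondents who answered "No" to the screening item skip all
#' subsequent items by design; they are scored all-zero (`valid = TRUE`),
#' matching the convention used for full-sample analyses of the zero-inflated
#' score distribution. Screen-positive respondents with any missing scored
#' item receive `NA` scores and `valid = FALSE`; no prorating is performed.
#'
#' @param data A data frame with one row per respondent: an `s1` column
#'   (logical or "Y"/"N") and item columns `q01`...`q20` coded 0-4 (blank/`NA`
#'   = missing). A `respondent_id` column is carried through (row numbers are
#'   used if absent). Unscored items (3, 11, 17) may be present but are
#'   ignored.
#'
#' @return A tibble with columns `respondent_id`, `total`, `symptom`,
#'   `impairment`, `valid`, `n_missing` (count of missing scored items among
#'   screen positives).
#' @export
#' @examples
#' d <- tibble::tibble(s1 = c(TRUE, FALSE))
#' d[item_columns()] <- as.list(rep(2L, 20))
#' d[2, item_columns()] <- NA_integer_
#' score_dvmsq(d)
score_dvmsq <- function(data) {
  data <- validate_responses(data)
  cols_sym <- item_cols(symptom_item_ids())
  cols_imp <- item_cols(impairment_item_ids())
  missing_cols <- setdiff(c(cols_sym, cols_imp), names(data))
  for (col in missing_cols) data[[col]] <- NA_integer_
  sym_mat <- as.matrix(data[cols_sym])
  imp_mat <- as.matrix(data[cols_imp])
  n_miss <- rowSums(is.na(sym_mat)) + rowSums(is.na(imp_mat))
  symptom <- rowSums(sym_mat)
  impairment <- rowSums(imp_mat)
  screen_neg <- !is.na(data$s1) & !data$s1
  symptom[screen_neg] <- 0L
  impairment[screen_neg] <- 0L
  n_miss[screen_neg] <- 0L
  valid <- n_miss == 0L
  tibble::tibble(
    respondent_id = data$respondent_id,
    total = as.integer(symptom + impairment),
    symptom = as.integer(symptom),
    impairment = as.integer(impairment),
    valid = valid,
    n_missing = as.integer(n_miss)
  )
}

#' Canonical DVMSQ item column names
#'
#' @param ids integer item ids (default all 20).
#' @return Character vector `q01`, `q02`, ...
#' @export
item_columns <- function(ids = 1:20) item_cols(ids)

#' Apply the DVMSQ diagnostic algorithm
#'
#' Evaluates the operational diagnostic criteria for misophonia on raw item
#' codes and assigns caseness. The criteria are: A - affirmative screening
#' answer; B - intense emotional reaction (item 1, 2 or 4 at "Often" or
#' above); C - avoidance or endurance with distress (item 12 at "Sometimes"
#' or above, or item 5 or 6 at "Often" or above); D - loss of self-control
#' (item 8 or 7 at "Sometimes" or above); E - symptom duration of six months
#' or more, not assessed by the instrument and assumed true when all other
#' criteria hold; F - clinically significant impairment (at least two of
#' items 13, 14, 15, 16, 18, 19, 20 at "A moderate amount" or above).
#' Respondents meeting A-D and F are classified `clinical`; those meeting A-D
#' but not F are `subclinical`; all others `none`. Missing criterion-relevant
#' items count as non-endorsement, and the `complete` flag records whether
#' every criterion-relevant item was answered.
#'
#' @inheritParams score_dvmsq
#' @return A tibble with columns `respondent_id`, `criterion_a` ...
#'   `criterion_f`, `classification` (factor: clinical, subclinical, none) and
#'   `complete`.
#' @export
classify_misophonia <- function(data) {
  data <- validate_responses(data)
  crit_items <- c(1L, 2L, 4L, 12L, 5L, 6L, 8L, 7L, 13:16, 18:20)
  for (col in setdiff(item_cols(crit_items), names(data))) {
    data[[col]] <- NA_integer_
  }
  g <- function(id) {
    v <- data[[item_cols(id)]]
    ifelse(is.na(v), -1L, v) # missing = non-endorsement
  }
  a <- !is.na(data$s1) & data$s1
  b <- g(1) >= 3L | g(2) >= 3L | g(4) >= 3L
  cc <- g(12) >= 2L | g(5) >= 3L | g(6) >= 3L
  d <- g(8) >= 2L | g(7) >= 2L
  f_count <- Reduce(`+`, lapply(c(13:16, 18:20), function(i) as.integer(g(i) >= 2L)))
  f <- f_count >= 2L
  # screen negatives answer nothing further: all criteria false by design
  b[!a] <- FALSE; cc[!a] <- FALSE; d[!a] <- FALSE; f[!a] <- FALSE
  e <- a & b & cc & d # duration assumed true when the assessed criteria hold
  cls <- dplyr::case_when(
    a & b & cc & d & f ~ "clinical",
    a & b & cc & d ~ "subclinical",
    TRUE ~ "none"
  )
  complete_flag <- !rowSums(is.na(as.matrix(data[item_cols(crit_items)]))) > 0
  complete_flag[!a] <- TRUE
  tibble::tibble(
    respondent_id = data$respondent_id,
    criterion_a = a, criterion_b = b, criterion_c = cc,
    criterion_d = d, criterion_e = e, criterion_f = f,
    classification = factor(cls, levels = c("clinical", "subclinical", "none")),
    complete = complete_flag
  )
}

#' Proportion of respondents fulfilling an item's diagnostic criterion
#'
#' Given the category frequency distribution of a single item (counts at codes
#' 0-4) and the minimum code at which the item contributes to its diagnostic
#' criterion, returns the proportion of respondents at or above that code.
#'
#' @param category_counts Non-negative integer vector of length 5: counts at
#'   codes 0, 1, 2, 3, 4.
#' @param threshold Integer 1-4: minimum fulfilling code.
#' @return Proportion in \[0, 1\].
#' @export
#' @examples
#' criterion_fulfillment(c(17, 72, 284, 296, 164), threshold = 3) # 0.552
criterion_fulfillment <- function(category_counts, threshold) {
  if (length(category_counts) != 5 || any(category_counts < 0)) {
    abort("`category_counts` must be 5 non-negative counts (codes 0-4).")
  }
  if (length(threshold) != 1 || !threshold %in% 1:4) {
    abort("`threshold` must be a single integer between 1 and 4.")
  }
  total <- sum(category_counts)
  if (total == 0) abort("Criterion fulfillment is undefined for all-zero counts.")
  sum(category_counts[(threshold + 1):5]) / total
}

#' Corrected item-total (polyserial) correlation
#'
#' Polyserial correlation between a single item's ordinal response and the
#' rest score (the sum of the remaining scored items, treated as continuous).
#' Computed on complete screen-positive rows only, as in item analyses of the
#' completer subsample.
#'
#' @inheritParams score_dvmsq
#' @param item_id Integer id of the item of interest.
#' @param rest_items Item ids forming the rest score; defaults to all scored
#'   items other than `item_id`.
#' @return The polyserial correlation (length-1 numeric).
#' @export
corrected_item_total <- function(data, item_id,
                                 rest_items = setdiff(scored_item_ids(), item_id)) {
  data <- validate_responses(data)
  rest_items <- setdiff(rest_items, item_id)
  if (length(rest_items) < 1) abort("Need at least one rest item.")
  cols <- item_cols(c(item_id, rest_items))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Missing item columns: %s", paste(missing_cols, collapse = ", ")))
  }
  keep <- !is.na(data$s1) & data$s1 & complete.cases(data[cols])
  d <- data[keep, cols]
  y <- d[[item_cols(item_id)]]
  if (length(unique(y)) < 2) {
    abort(sprintf("Item %d has no variance among completers.", item_id))
  }
  rest <- rowSums(as.matrix(d[item_cols(rest_items)]))
  latent_correlation(rest, y, kind = "polyserial")
}

#' Item-level summary table
#'
#' Per-item category frequencies among screen-positive completers, the
#' percentage fulfilling each item's diagnostic criterion, and the corrected
#' item-total polyserial correlation for scored items.
#'
#' @inheritParams score_dvmsq
#' @param item_total logical; compute corrected item-total correlations
#'   (requires complete rows).
#' @return A tibble with one row per item: `item_id`, counts `n0`-`n4`,
#'   `pct_fulfills` (percent, 1 decimal; `NA` for items with no criterion
#'   role), and `r_item_total` when requested.
#' @export
item_analysis <- function(data, item_total = TRUE) {
  data <- validate_responses(data)
  items <- dvmsq_items()
  present <- items$item_id[items$column %in% names(data)]
  pos <- !is.na(data$s1) & data$s1
  rows <- purrr::map(present, function(id) {
    v <- data[[item_cols(id)]][pos]
    counts <- tabulate(v + 1L, nbins = 5L)
    thr <- items$criterion_threshold[items$item_id == id]
    pct <- if (is.na(thr)) NA_real_ else {
      round(100 * criterion_fulfillment(counts, thr), 1)
    }
    tibble::tibble(item_id = id, n0 = counts[1], n1 = counts[2], n2 = counts[3],
                   n3 = counts[4], n4 = counts[5], pct_fulfills = pct)
  })
  out <- dplyr::bind_rows(rows)
  if (item_total) {
    scored <- intersect(present, scored_item_ids())
    rit <- purrr::map_dbl(out$item_id, function(id) {
      if (!id %in% scored) return(NA_real_)
      tryCatch(corrected_item_total(data, id, setdiff(scored, id)),
               error = function(e) NA_real_)
    })
    out$r_item_total <- rit
  }
  dplyr::left_join(out,
                   dplyr::select(items, "item_id", "text", "scale", "scored"),
                   by = "item_id")
}
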