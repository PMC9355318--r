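#' Read a DVMSQ respondent table
#'
#' Reads the comma-separated wide respondent format: one header row; columns
#' `respondent_id`, `s1` (Y/N, case-insensitive), item columns `q01`...`q20`
#' (blank = missing), and optionally `group` and external score columns.
#' Screen-negative rows keep their items absent. Validation errors name the
#' offending respondent, item, and value.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping arbitrary input
#'   headers to canonical names, e.g. `c(item1 = "q01")` renames `item1`.
#' @return A validated tibble (see [score_dvmsq()] for the format).
#' @export
read_response_table <- function(path, column_map = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  raw <- tibble::as_tibble(raw)
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(raw))
    names(raw)[idx[!is.na(idx)]] <- column_map[!is.na(idx)]
  }
  if (!"s1" %in% names(raw)) abort("Input must have an `s1` column.")
  known <- c("respondent_id", "s1", "group", item_cols(1:20))
  qlike <- grep("^q[0-9]+$", names(raw), value = TRUE)
  bad_items <- setdiff(qlike, item_cols(1:20))
  if (length(bad_items)) {
    abort(sprintf("Unknown item column(s): %s", paste(bad_items, collapse = ", ")))
  }
  if ("respondent_id" %in% names(raw) && anyDuplicated(raw$respondent_id)) {
    dup <- raw$respondent_id[duplicated(raw$respondent_id)][1]
    abort(sprintf("Duplicate respondent_id: %s", dup))
  }
  extra <- setdiff(names(raw), known)
  for (col in extra) {
    v <- raw[[col]]
    v[trimws(v) == ""] <- NA
    suppressWarnings(num <- as.numeric(v))
    if (all(is.na(num) == is.na(v))) raw[[col]] <- num
  }
  validate_responses(raw)
}

#' Write a DVMSQ respondent table
#'
#' Serializes a respondent tibble in the format read by
#' [read_response_table()]: comma-separated, UTF-8, `s1` as Y/N, blank cells
#' for missing responses.
#'
#' @param data Respondent tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(data, path) {
  out <- as.data.frame(data)
  out$s1 <- ifelse(is.na(out$s1), "", ifelse(out$s1, "Y", "N"))
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Caseness and score summary report
#'
#' Convenience wrapper combining [score_dvmsq()] and [classify_misophonia()]:
#' per-respondent results plus a summary block of caseness counts and rates.
#'
#' @inheritParams score_dvmsq
#' @return A list with `results` (per-respondent tibble) and `summary`
#'   (caseness counts/rates tibble).
#' @export
dvmsq_report <- function(data) {
  scores <- score_dvmsq(data)
  cls <- classify_misophonia(data)
  results <- dplyr::left_join(scores, cls, by = "respondent_id")
  summary <- results |>
    dplyr::count(.data$classification, name = "n") |>
    tidyr::complete(classification = factor(c("clinical", "subclinical", "none"),
                                            levels = c("clinical", "subclinical", "none")),
                    fill = list(n = 0L)) |>
    dplyr::mutate(rate = .data$n / sum(.data$n))
  list(results = results, summary = summary)
}

#' Distribution of DVMSQ total scores
#'
#' Histogram of total scores coloured by caseness class.
#'
#' @inheritParams score_dvmsq
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(data, binwidth = 2) {
  rep <- dvmsq_report(data)
  df <- rep$results[rep$results$valid, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total, fill = .data$classification)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "DVMSQ total score (0-68)", y = "respondents",
                  fill = "caseness") +
    ggplot2::theme_minimal()
}
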