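# System Usability Scale and ITC-SOPI negative-effects scoring.

#' Score the System Usability Scale
#'
#' Standard SUS scoring: with responses on a 1-5 Likert scale, odd
#' (positively worded) items contribute `response - 1` and even
#' (negatively worded) items contribute `5 - response`; the summed
#' contributions are multiplied by 2.5, giving a score from 0 ("lack of
#' usability") to 100 ("optimal usability") in steps of 2.5.
#'
#' @param items numeric vector of exactly 10 responses, each in 1-5, in
#'   questionnaire order.
#' @return a list with `value` (0-100) and `band` (see [sus_band()]).
#' @examples
#' sus_score(rep(3, 10))$value # 50
#' @export
sus_score <- function(items) {
  if (length(items) != 10) {
    input_error("SUS requires exactly 10 item responses.")
  }
  if (anyNA(items) || !all(items %in% 1:5)) {
    input_error("SUS responses must all be integers in 1-5.")
  }
  odd <- seq(1, 9, by = 2)
  value <- 2.5 * (sum(items[odd] - 1) + sum(5 - items[-odd]))
  list(value = value, band = sus_band(value))
}

#' Adjective band of a SUS score
#'
#' Maps a 0-100 SUS value onto the seven-point adjective rating scale:
#' worst imaginable (0-25), awful (26-39), poor (40-49), OK (50-69),
#' good (70-84), excellent (85-99), best imaginable (100). The printed
#' integer ranges are applied as half-open intervals (e.g. OK is
#' \[50, 70)) so fractional scores fall in exactly one band.
#'
#' @param value numeric SUS value(s) in \[0, 100\].
#' @return character vector of band labels (ordered factor levels via
#'   [sus_band_levels()]).
#' @examples
#' sus_band(65) # "OK"
#' @export
sus_band <- function(value) {
  if (anyNA(value) || !is.numeric(value) ||
      any(value < 0) || any(value > 100)) {
    input_error("SUS value must be within [0, 100].")
  }
  cut_points <- c(0, 26, 40, 50, 70, 85, 100)
  labels <- sus_band_levels()
  idx <- findInterval(value, cut_points, rightmost.closed = FALSE)
  out <- labels[idx]
  out[value == 100] <- "best imaginable"
  out
}

#' @rdname sus_band
#' @export
sus_band_levels <- function() {
  c("worst imaginable", "awful", "poor", "OK", "good", "excellent",
    "best imaginable")
}

#' Score ITC-SOPI negative effects
#'
#' The negative-effects score is the arithmetic mean of all completed
#' items (1-5 Likert); skipped items are excluded, not imputed. The
#' instrument's item count is not fixed here: any positive number of
#' completed items is accepted.
#'
#' @param items numeric vector of responses in 1-5 (NA allowed where
#'   `completed` is FALSE).
#' @param completed logical mask of completed items (default: non-NA).
#' @return scalar mean score in \[1, 5\].
#' @examples
#' itc_ne_score(c(2, 3, 1, 2)) # 2
#' @export
itc_ne_score <- function(items, completed = !is.na(items)) {
  if (length(completed) != length(items)) {
    input_error("`completed` must match `items` in length.")
  }
  done <- items[completed]
  if (length(done) == 0) {
    input_error("ITC-SOPI NE scoring needs at least one completed item.")
  }
  if (anyNA(done) || !all(done %in% 1:5)) {
    input_error("Completed ITC-SOPI responses must be integers in 1-5.")
  }
  mean(done)
}

#' Score all questionnaires in a cohort table
#'
#' Tidy interface over [sus_score()] and [itc_ne_score()]: takes the long
#' questionnaire table of a cohort (one row per item response) and
#' returns one scored row per participant x condition x instrument.
#'
#' @param questionnaires data frame with columns `participant_id`,
#'   `condition`, `instrument` (`"SUS"` or `"ITC_SOPI_NE"`), `item`,
#'   `response` (a `nav_cohort`'s `$questionnaires` table).
#' @return tibble with columns `participant_id`, `condition`,
#'   `instrument`, `score`, `band` (`band` is NA for ITC-SOPI).
#' @export
score_questionnaires <- function(questionnaires) {
  assert_cols(questionnaires,
              c("participant_id", "condition", "instrument", "item",
                "response"), "questionnaires")
  questionnaires |>
    group_by(.data$participant_id, .data$condition, .data$instrument) |>
    arrange(.data$item, .by_group = TRUE) |>
    summarise(score = if (.data$instrument[1] == "SUS") {
      sus_score(.data$response)$value
    } else {
      itc_ne_score(.data$response)
    }, .groups = "drop") |>
    mutate(band = ifelse(.data$instrument == "SUS",
                         sus_band(pmin(pmax(.data$score, 0), 100)),
                         NA_character_))
}
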