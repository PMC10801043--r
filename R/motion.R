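# Foot-motion-pad analytics: magnitude series, encoding-recall Jaccard
# similarity, phase durations and raw tilt-density grids.
#
# Each 100 Hz sample carries two dimensionless tilts: pitch (toe-heel,
# drives forward/backward translation) and yaw (left-right, drives view
# rotation). A sample's scalar magnitude v_t = sqrt(pitch^2 + yaw^2)
# summarises mobility: v_t = 0 means the pad is neutral and the
# viewpoint is not moving.

#' Reduce motion samples to a scalar magnitude series
#'
#' Appends `v = sqrt(pitch_y^2 + yaw_z^2)` to a motion table, preserving
#' timestamps and grouping columns. Higher values mean greater lower-limb
#' mobility; zero means the pad is in its neutral position.
#'
#' @param motion data frame with columns `pitch_y`, `yaw_z` (a
#'   `nav_cohort`'s `$motion` table or any sample table).
#' @return the input tibble with a `v` column appended.
#' @examples
#' magnitude_series(tibble::tibble(t_ms = 0, pitch_y = 3, yaw_z = 4))$v # 5
#' @export
magnitude_series <- function(motion) {
  assert_cols(motion, c("pitch_y", "yaw_z"), "motion")
  motion |> as_tibble() |>
    mutate(v = sqrt(.data$pitch_y^2 + .data$yaw_z^2))
}

#' Jaccard similarity of two magnitude series
#'
#' Measures the overlap between the distributions of movement magnitude
#' during encoding and during recall. Both series are histogrammed over
#' shared bins of width `bin_width` spanning \[0, max(v)\]; the index is
#' 1 for identical movement profiles and 0 for disjoint ones.
#'
#' Variants (`method`):
#' \describe{
#'   \item{`"weighted"`}{(default) histograms are normalized to relative
#'     frequencies p and q and the index is
#'     `sum(min(p, q)) / sum(max(p, q))` — the weighted (min/max)
#'     Jaccard, robust to the two phases having different lengths.}
#'   \item{`"counts"`}{same min/max ratio on raw bin counts (length
#'     differences penalize the index).}
#'   \item{`"binary"`}{classic Jaccard on bin occupancy:
#'     `|bins in both| / |bins in either|`.}
#' }
#'
#' @param v_enc,v_rec numeric vectors of non-negative magnitudes (the `v`
#'   column of [magnitude_series()] for each phase); both non-empty.
#' @param bin_width histogram bin width in magnitude units (> 0),
#'   default 0.05.
#' @param method `"weighted"`, `"counts"` or `"binary"`.
#' @return a scalar in \[0, 1\]; symmetric in its two series.
#' @examples
#' jaccard_similarity(c(0.1, 0.2), c(0.1, 0.2)) # 1
#' @export
jaccard_similarity <- function(v_enc, v_rec, bin_width = 0.05,
                               method = c("weighted", "counts", "binary")) {
  method <- match.arg(method)
  if (length(v_enc) == 0 || length(v_rec) == 0) {
    input_error("Both magnitude series must be non-empty.")
  }
  assert_finite(v_enc, "v_enc")
  assert_finite(v_rec, "v_rec")
  if (any(v_enc < 0) || any(v_rec < 0)) {
    input_error("Magnitudes must be non-negative.")
  }
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    input_error("`bin_width` must be a single positive number.")
  }
  top <- max(v_enc, v_rec)
  breaks <- seq(0, top + bin_width, by = bin_width)
  bin <- function(v) tabulate(findInterval(v, breaks, rightmost.closed = FALSE,
                                           left.open = FALSE),
                              nbins = length(breaks))
  ce <- bin(v_enc)
  cr <- bin(v_rec)
  if (method == "binary") {
    inter <- sum(ce > 0 & cr > 0)
    union <- sum(ce > 0 | cr > 0)
    return(inter / union)
  }
  if (method == "weighted") {
    ce <- ce / sum(ce)
    cr <- cr / sum(cr)
  }
  sum(pmin(ce, cr)) / sum(pmax(ce, cr))
}

#' Encoding-recall Jaccard similarity per session
#'
#' Tidy interface over [jaccard_similarity()]: for every (participant,
#' condition) with both an encoding and a recall trace, computes the
#' similarity of the two magnitude distributions.
#'
#' @param motion a `nav_cohort`'s `$motion` table (columns
#'   `participant_id`, `condition`, `phase`, `pitch_y`, `yaw_z`).
#' @inheritParams jaccard_similarity
#' @return tibble with columns `participant_id`, `condition`, `jaccard`.
#' @export
summarize_jaccard <- function(motion, bin_width = 0.05,
                              method = c("weighted", "counts", "binary")) {
  method <- match.arg(method)
  assert_cols(motion, c("participant_id", "condition", "phase", "pitch_y",
                        "yaw_z"), "motion")
  magnitude_series(motion) |>
    group_by(.data$participant_id, .data$condition) |>
    summarise(jaccard = {
      enc <- .data$v[.data$phase == "encoding"]
      rec <- .data$v[.data$phase == "recall"]
      if (length(enc) == 0 || length(rec) == 0) NA_real_
      else jaccard_similarity(enc, rec, bin_width = bin_width,
                              method = method)
    }, .groups = "drop")
}

#' Phase duration from a motion trace
#'
#' Duration in minutes spanned by a trace's timestamps:
#' `(last t_ms - first t_ms) / 60000`.
#'
#' @param t_ms integer vector of sample timestamps (ms), length >= 2.
#' @return duration in minutes.
#' @export
phase_duration <- function(t_ms) {
  if (length(t_ms) < 2) {
    input_error("A trace needs at least 2 samples to have a duration.")
  }
  (max(t_ms) - min(t_ms)) / 60000
}

#' Phase durations for every trace in a motion table
#'
#' @param motion a `nav_cohort`'s `$motion` table.
#' @return tibble with columns `participant_id`, `condition`, `phase`,
#'   `duration_min`, `n_samples`.
#' @export
summarize_durations <- function(motion) {
  assert_cols(motion, c("participant_id", "condition", "phase", "t_ms"),
              "motion")
  motion |>
    group_by(.data$participant_id, .data$condition, .data$phase) |>
    summarise(duration_min = phase_duration(.data$t_ms),
              n_samples = dplyr::n(), .groups = "drop")
}

#' Tilt-density grid of raw pad samples
#'
#' Counts (pitch, yaw) samples in square cells of side `bin_width`
#' (default 0.1 units), the tabular counterpart of a raw-density plot of
#' the pad telemetry. Total counts equal the number of samples.
#'
#' @param motion data frame with columns `pitch_y`, `yaw_z`.
#' @param bin_width cell side length in tilt units (> 0), default 0.1.
#' @return tibble of class `nav_density_grid` with columns `pitch_bin`,
#'   `yaw_bin` (cell centres) and `count`; zero rows for an empty trace.
#' @export
density_grid <- function(motion, bin_width = 0.1) {
  assert_cols(motion, c("pitch_y", "yaw_z"), "motion")
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    input_error("`bin_width` must be a single positive number.")
  }
  grid <- motion |> as_tibble() |>
    mutate(pitch_bin = (floor(.data$pitch_y / bin_width) + 0.5) * bin_width,
           yaw_bin = (floor(.data$yaw_z / bin_width) + 0.5) * bin_width) |>
    count(.data$pitch_bin, .data$yaw_bin, name = "count")
  attr(grid, "bin_width") <- bin_width
  class(grid) <- c("nav_density_grid", class(grid))
  grid
}
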