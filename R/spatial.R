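# Recall-error metrics in polar coordinates.
#
# Each trial compares the item's encoding location with the participant's
# recalled location on the (x, z) plane of the virtual environment. The
# displacement is expressed in polar coordinates centred on the encoding
# location: r ("how far is the response from the item?") and theta ("at
# what angle?"). Convention: theta is measured from the environment +x
# axis, counter-clockwise positive, in [0, 360); it is undefined (NA)
# when the recall coincides exactly with the encoding location.

#' Per-trial recall error in polar coordinates
#'
#' Adds `r` (Euclidean distance, virtual units) and `theta_deg` (angular
#' deviation, degrees in \[0, 360), NA when `r = 0`) to a trial table.
#' By default the angle is that of the encoding-to-recall displacement;
#' `angle_direction = "recall_to_encoding"` flips it by 180 degrees.
#'
#' @param trials data frame with columns `enc_x`, `enc_z`, `rec_x`,
#'   `rec_z` (a `nav_cohort`'s `$trials` table, or any per-trial table).
#' @param angle_direction `"encoding_to_recall"` (default) or
#'   `"recall_to_encoding"`.
#' @return the input tibble with columns `r` and `theta_deg` appended.
#' @examples
#' polar_error(tibble::tibble(enc_x = 0, enc_z = 0, rec_x = 3, rec_z = 4))
#' @export
polar_error <- function(trials,
                        angle_direction = c("encoding_to_recall",
                                            "recall_to_encoding")) {
  angle_direction <- match.arg(angle_direction)
  assert_cols(trials, c("enc_x", "enc_z", "rec_x", "rec_z"), "trials")
  for (col in c("enc_x", "enc_z", "rec_x", "rec_z")) {
    assert_finite(trials[[col]], col)
  }
  dx <- trials$rec_x - trials$enc_x
  dz <- trials$rec_z - trials$enc_z
  if (angle_direction == "recall_to_encoding") {
    dx <- -dx
    dz <- -dz
  }
  r <- sqrt(dx^2 + dz^2)
  theta <- (atan2(dz, dx) * 180 / pi) %% 360
  theta[r == 0] <- NA_real_
  trials |> as_tibble() |> mutate(r = r, theta_deg = theta)
}

#' Classify recalls as correct or incorrect
#'
#' A recall is correct when its distance error is within the correctness
#' radius, boundary included (a response at exactly the radius counts:
#' "6 or lower" virtual units under the default).
#'
#' @param trials data frame with a column `r` (see [polar_error()]); the
#'   polar step is applied first if `r` is absent.
#' @param radius correctness radius in virtual units (> 0), default 6.
#' @return the input tibble with a logical `correct` column appended.
#' @export
classify_recall <- function(trials, radius = 6) {
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0) {
    input_error("`radius` must be a single positive number.")
  }
  if (!"r" %in% names(trials)) trials <- polar_error(trials)
  trials |> as_tibble() |> mutate(correct = .data$r <= radius)
}

#' Summarize recall errors per landmark x condition cell
#'
#' Aggregates per-trial polar errors into one row per (landmark,
#' condition) cell present in the data: trial count, mean and sample SD
#' (n - 1 denominator) of the distance error, and mean and SD of the
#' angular deviation. Trials with undefined angle (r = 0) contribute to
#' the distance aggregates but are excluded from the angle aggregates
#' (`n_theta` counts the angle contributors). By default angles are
#' averaged arithmetically on their degree values; `circular = TRUE`
#' uses the circular mean and circular SD instead.
#'
#' @param trials data frame with columns `landmark`, `condition` and
#'   either (`r`, `theta_deg`) or raw coordinates (then [polar_error()]
#'   is applied).
#' @param circular use circular statistics for the angle (default FALSE).
#' @return tibble with columns `landmark`, `condition`, `n_trials`,
#'   `mean_r`, `sd_r`, `n_theta`, `mean_theta`, `sd_theta`, one row per
#'   observed cell; zero rows for empty input.
#' @export
summarize_errors <- function(trials, circular = FALSE) {
  assert_cols(trials, c("landmark", "condition"), "trials")
  if (!all(c("r", "theta_deg") %in% names(trials))) {
    trials <- polar_error(trials)
  }
  if (nrow(trials) == 0) {
    return(tibble(landmark = character(0), condition = character(0),
                  n_trials = integer(0), mean_r = double(0),
                  sd_r = double(0), n_theta = integer(0),
                  mean_theta = double(0), sd_theta = double(0)))
  }
  ang_mean <- if (circular) circular_mean_deg else function(x) mean(x)
  ang_sd <- if (circular) circular_sd_deg else function(x) sd(x)
  trials |>
    group_by(.data$landmark, .data$condition) |>
    summarise(
      n_trials = dplyr::n(),
      mean_r = mean(.data$r),
      sd_r = sd(.data$r),
      n_theta = sum(!is.na(.data$theta_deg)),
      mean_theta = if (sum(!is.na(.data$theta_deg)) > 0) {
        ang_mean(.data$theta_deg[!is.na(.data$theta_deg)])
      } else NA_real_,
      sd_theta = if (sum(!is.na(.data$theta_deg)) > 0) {
        ang_sd(.data$theta_deg[!is.na(.data$theta_deg)])
      } else NA_real_,
      .groups = "drop"
    ) |>
    arrange(.data$landmark, .data$condition)
}

# Circular mean of angles in degrees, mapped to [0, 360).
circular_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}

# Circular SD in degrees: sqrt(-2 log R) on the mean resultant length.
circular_sd_deg <- function(deg) {
  rad <- deg * pi / 180
  r_bar <- sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
  sqrt(pmax(-2 * log(r_bar), 0)) * 180 / pi
}
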