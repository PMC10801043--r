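# Internal helpers shared across modules.

#' Condition and landmark factor levels
#'
#' The two display conditions and the two reference-frame labels used
#' throughout the package. Landmark labels are abstract (which physical
#' landmark — obelisk or arcade — forces which strategy is a property of the
#' environment, not of the analysis).
#' @keywords internal
#' @name levels
NULL

condition_levels <- function() c("immersive", "semi_immersive")
landmark_levels  <- function() c("allocentric", "egocentric")
phase_levels     <- function() c("encoding", "recall")

# Nominal motion-pad sampling: 100 Hz, one sample every 10 ms.
SAMPLE_MS <- 10L
SAMPLES_PER_MINUTE <- 6000L

assert_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric (no NA/NaN/Inf).", what),
          class = "navassess_input_error")
  }
  invisible(x)
}

assert_cols <- function(data, cols, what = deparse(substitute(data))) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")),
          class = "navassess_input_error")
  }
  invisible(data)
}

input_error <- function(msg) abort(msg, class = "navassess_input_error")

#' Derive a substream seed from a root seed
#'
#' Deterministic splitting rule used by the cohort generator: each
#' (participant, stream) pair gets its own seed so regenerating one
#' participant's data never perturbs another's. The rule is a fixed affine
#' hash reduced modulo 2^31 - 1.
#'
#' @param root integer root seed.
#' @param participant participant index (1-based); 0 for cohort-level streams.
#' @param stream small integer stream code (condition/phase/purpose).
#' @return an integer seed in [1, 2^31 - 2].
#' @keywords internal
substream_seed <- function(root, participant = 0L, stream = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(root %% m) * 48271 + participant * 30269 + stream * 10007) %% m
  as.integer(s %% (m - 2) + 1)
}
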