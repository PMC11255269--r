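#' @importFrom rlang %||% abort warn .data
#' @importFrom stats quantile sd median cor qnorm rnorm runif rbinom var predict
#' @importFrom utils head tail
NULL

# round half up (base round() rounds half to even; printed splits need 0.5 -> up)
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a named RNG substream seed from a master seed
#'
#' All randomness in the package flows from a single master seed through
#' named substreams, so that modules can be re-run independently without
#' coupling their random draws. The substream seed is a deterministic hash
#' of the master seed and the stream name, kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param name Character stream name (e.g. `"synthetic/trials/Stable"`).
#' @return An integer seed suitable for `set.seed()`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483587
  as.integer((abs(seed) %% 2147483587 * 48271 + h + 1) %% 2147483587)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

# frame index (1-based) of a time in seconds relative to the event at t0_frame
# windows are half-open [start, end); frame index = floor(t * rate)
frames_in_window <- function(n_frames, frame_rate, t0_frame, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  idx <- seq_len(n_frames)
  t <- (idx - t0_frame) / frame_rate
  which(t >= window[1] & t < window[2])
}

frame_times <- function(n_frames, frame_rate, t0_frame) {
  (seq_len(n_frames) - t0_frame) / frame_rate
}
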