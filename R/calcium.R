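#' Map a raw trace to [0, 1] and low-pass filter at 5 Hz
#'
#' The session-wide min-max of each neuron maps its fluorescence to
#' `[0, 1]`; the trace is then low-pass filtered with a zero-phase filter
#' whose magnitude response is a 4th-order Butterworth (applied in the
#' frequency domain, so no phase shift by construction; attenuation at
#' 10 Hz is ~24 dB for a 5 Hz cutoff at 30 frames/s).
#'
#' @param x Numeric vector (one trace) or matrix (trials x frames, filtered
#'   row-wise with a shared min-max).
#' @param frame_rate Frames per second.
#' @param cutoff_hz Cutoff frequency (default 5).
#' @param order Butterworth order (default 4).
#' @return Same shape as `x`.
#' @export
preprocess_trace <- function(x, frame_rate = 30, cutoff_hz = 5, order = 4) {
  mn <- min(x); mx <- max(x)
  if (mx == mn) {
    warn("constant trace mapped to all zeros")
    return(x * 0)
  }
  y <- (x - mn) / (mx - mn)
  if (is.matrix(y)) {
    t(apply(y, 1, lowpass_fft, frame_rate, cutoff_hz, order))
  } else {
    lowpass_fft(y, frame_rate, cutoff_hz, order)
  }
}

lowpass_fft <- function(x, frame_rate, cutoff_hz, order) {
  n <- length(x)
  stopifnot(n >= 2)
  f <- seq(0, n - 1) / n * frame_rate
  f <- pmin(f, frame_rate - f)  # two-sided frequency axis
  H <- 1 / sqrt(1 + (f / cutoff_hz)^(2 * order))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

#' Baseline fluorescence F0: interquartile-masked mean
#'
#' F0 is the mean of the baseline samples lying between the 25th and 75th
#' percentiles (inclusive; percentiles by linear interpolation between
#' order statistics).
#'
#' @param baseline Numeric vector of pre-stimulus samples.
#' @return Scalar F0.
#' @export
baseline_f0 <- function(baseline) {
  stopifnot(length(baseline) >= 1)
  q <- quantile(baseline, c(0.25, 0.75), names = FALSE, type = 7)
  mean(baseline[baseline >= q[1] & baseline <= q[2]])
}

#' Delta-F/F for one trace
#'
#' `dff = (F - F0) / F0` with F0 the interquartile-masked mean of the 2-s
#' pre-stimulus baseline (see [baseline_f0()]).
#'
#' @param F Numeric trace.
#' @param baseline The pre-stimulus samples used for F0.
#' @return List with `dff` (trace) and `f0`; `dff` is all-`NA` and the
#'   trace flagged invalid when `F0 <= 0`.
#' @export
compute_dff <- function(F, baseline) {
  f0 <- baseline_f0(baseline)
  if (!is.finite(f0) || f0 <= 0) {
    return(list(dff = rep(NA_real_, length(F)), f0 = f0, valid = FALSE))
  }
  list(dff = (F - f0) / f0, f0 = f0, valid = TRUE)
}

#' Z-score a trace against a short pre-event baseline
#'
#' Subtracts the mean of the baseline window (default the 0.5 s before the
#' event) and divides by its sample standard deviation (n - 1).
#'
#' @param dff Numeric trace.
#' @param baseline_idx Indices of the baseline frames (>= 2).
#' @return List with `z` (trace) and `valid` (`FALSE` when the baseline sd
#'   is 0; such traces are excluded downstream).
#' @export
zscore_event_aligned <- function(dff, baseline_idx) {
  stopifnot(length(baseline_idx) >= 2)
  b <- dff[baseline_idx]
  s <- sd(b)
  if (!is.finite(s) || s == 0) {
    return(list(z = rep(NA_real_, length(dff)), valid = FALSE))
  }
  list(z = (dff - mean(b)) / s, valid = TRUE)
}

#' Trial-aligned delta-F/F and z-scored tensors
#'
#' Runs the full per-trial transform for every neuron: delta-F/F against
#' the 2-s pre-stimulus interquartile-masked baseline, then a z-score
#' against the 0.5 s immediately before stimulus onset. (The 0-1 mapping
#' and 5 Hz low-pass of [preprocess_trace()] belong to raw-movie
#' extraction; the synthetic generator emits extracted traces, so they
#' are optional here.)
#'
#' @param fluo A [fluo_tensor()].
#' @param config A [run_config()] (baseline windows).
#' @param preprocess Apply [preprocess_trace()] per neuron first
#'   (default FALSE).
#' @return A `dff_tensor`: list with arrays `dff` and `zscored`
#'   (neurons x trials x frames), `valid` matrix, `f0` matrix,
#'   `frame_rate`, `t0_frame`, `neuron_ids`.
#' @export
process_calcium <- function(fluo, config = run_config(),
                            preprocess = FALSE) {
  stopifnot(inherits(fluo, "fluo_tensor"))
  F <- fluo$F
  d <- dim(F)
  n_frames <- d[3]
  bl_dff <- frames_in_window(n_frames, fluo$frame_rate, fluo$t0_frame,
                             config$baseline_dff)
  bl_z <- frames_in_window(n_frames, fluo$frame_rate, fluo$t0_frame,
                           config$baseline_z)
  if (length(bl_dff) == 0) {
    abort("recording does not contain the delta-F/F baseline window",
          class = "accvi_config_error")
  }
  dff <- array(NA_real_, d)
  zs <- array(NA_real_, d)
  valid <- matrix(TRUE, d[1], d[2])
  f0 <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    tr <- F[i, , , drop = TRUE]
    if (d[2] == 1) tr <- matrix(tr, nrow = 1)
    if (preprocess) tr <- preprocess_trace(tr, fluo$frame_rate)
    for (j in seq_len(d[2])) {
      r <- compute_dff(tr[j, ], tr[j, bl_dff])
      f0[i, j] <- r$f0
      if (!r$valid) { valid[i, j] <- FALSE; next }
      dff[i, j, ] <- r$dff
      z <- zscore_event_aligned(r$dff, bl_z)
      if (!z$valid) { valid[i, j] <- FALSE; next }
      zs[i, j, ] <- z$z
    }
  }
  structure(list(dff = dff, zscored = zs, valid = valid, f0 = f0,
                 frame_rate = fluo$frame_rate, t0_frame = fluo$t0_frame,
                 neuron_ids = fluo$neuron_ids,
                 baseline_dff = config$baseline_dff,
                 baseline_z = config$baseline_z),
            class = "dff_tensor")
}

#' @export
print.dff_tensor <- function(x, ...) {
  d <- dim(x$dff)
  cat("<dff_tensor>", d[1], "neurons x", d[2], "trials x", d[3],
      "frames;", sum(!x$valid), "invalid neuron/trials\n")
  invisible(x)
}

#' Per-neuron, per-trial window means
#'
#' Arithmetic mean over frames with `start <= t < end`. The window is
#' relative to stimulus onset, or to a per-trial event time when
#' `event_time_s` is given (e.g. the first lick for outcome responses).
#'
#' @param x A `dff_tensor` (or `fluo_tensor`).
#' @param window Length-2 seconds.
#' @param trials Optional integer selection of trials.
#' @param event_time_s Optional numeric vector (one per selected trial) of
#'   event times in seconds relative to stimulus onset; trials with `NA`
#'   event times yield `NA` means.
#' @param use Which array of a `dff_tensor` to use: `"dff"` (default) or
#'   `"zscored"`.
#' @return Matrix neurons x selected trials of window means.
#' @export
window_mean <- function(x, window, trials = NULL, event_time_s = NULL,
                        use = c("dff", "zscored")) {
  use <- match.arg(use)
  arr <- if (inherits(x, "fluo_tensor")) x$F else x[[use]]
  d <- dim(arr)
  trials <- trials %||% seq_len(d[2])
  if (is.null(event_time_s)) {
    idx <- frames_in_window(d[3], x$frame_rate, x$t0_frame, window)
    if (length(idx) == 0) {
      abort("window contains no recorded frames", class = "accvi_data_error")
    }
    out <- apply(arr[, trials, idx, drop = FALSE], c(1, 2), mean)
  } else {
    stopifnot(length(event_time_s) == length(trials))
    out <- matrix(NA_real_, d[1], length(trials))
    for (k in seq_along(trials)) {
      te <- event_time_s[k]
      if (is.na(te)) next
      idx <- frames_in_window(d[3], x$frame_rate, x$t0_frame, window + te)
      if (length(idx) == 0) {
        abort("window contains no recorded frames",
              class = "accvi_data_error")
      }
      out[, k] <- apply(arr[, trials[k], idx, drop = FALSE], 1, mean)
    }
  }
  rownames(out) <- x$neuron_ids
  out
}

#' Responsiveness screen (paired Wilcoxon signed-rank)
#'
#' Per neuron, compares per-trial stimulus-window means against per-trial
#' baseline-window means (paired signed-rank on the differences). Neurons
#' with `p < alpha` are classified activated or suppressed by the sign of
#' the median difference.
#'
#' @param dff A `dff_tensor`.
#' @param stimulus_window Seconds, default `c(0, 1)`.
#' @param baseline_window Seconds, default `c(-2, 0)`.
#' @param trials Optional trial selection.
#' @param alpha Significance level (default 0.05).
#' @return Tibble: neuron_id, p_value, direction
#'   (`activated`/`suppressed`/`none`), median_diff, n_trials.
#' @export
test_responsiveness <- function(dff, stimulus_window = c(0, 1),
                                baseline_window = c(-2, 0),
                                trials = NULL, alpha = 0.05) {
  stim <- window_mean(dff, stimulus_window, trials = trials)
  base <- window_mean(dff, baseline_window, trials = trials)
  if (ncol(stim) < 6) {
    abort("need at least 6 trials for the signed-rank screen",
          class = "accvi_data_error")
  }
  purrr::map_dfr(seq_len(nrow(stim)), function(i) {
    diffs <- stim[i, ] - base[i, ]
    diffs <- diffs[!is.na(diffs)]
    if (length(diffs) < 6 || all(diffs == 0)) {
      return(tibble::tibble(neuron_id = dff$neuron_ids[i], p_value = 1,
                            direction = "none",
                            median_diff = if (length(diffs)) median(diffs)
                                          else NA_real_,
                            n_trials = length(diffs)))
    }
    p <- suppressWarnings(
      stats::wilcox.test(diffs, mu = 0, exact = FALSE)$p.value)
    md <- median(diffs)
    dir <- if (p < alpha) { if (md > 0) "activated" else "suppressed" }
           else "none"
    tibble::tibble(neuron_id = dff$neuron_ids[i], p_value = p,
                   direction = dir, median_diff = md,
                   n_trials = length(diffs))
  })
}

#' Response onset detection
#'
#' Each trial's z-scored trace is smoothed with a 3-frame moving average;
#' at every post-onset frame inside the stimulus window, the per-trial
#' frame values are compared to the pooled per-trial baseline means with a
#' two-sided rank-sum test. The onset is the first frame with `p < 0.01`;
#' `NA` (undefined) when no frame reaches significance — latencies are not
#' fabricated by clamping.
#'
#' @param z Matrix trials x frames of z-scored responses for one neuron.
#' @param frame_rate Frames per second.
#' @param t0_frame 1-based stimulus-onset frame.
#' @param stimulus_window Seconds, default `c(0, 1)`.
#' @param baseline_window Seconds, default `c(-0.5, 0)`.
#' @param alpha Significance level (default 0.01).
#' @return Onset time in seconds, or `NA_real_`.
#' @export
detect_onset <- function(z, frame_rate = 30, t0_frame = 61,
                         stimulus_window = c(0, 1),
                         baseline_window = c(-0.5, 0), alpha = 0.01) {
  stopifnot(is.matrix(z))
  if (nrow(z) < 6) {
    abort("need at least 6 trials for onset detection",
          class = "accvi_data_error")
  }
  sm <- t(apply(z, 1, function(x) {
    stats::filter(x, rep(1 / 3, 3), sides = 2)
  }))
  bl_idx <- frames_in_window(ncol(z), frame_rate, t0_frame, baseline_window)
  stim_idx <- frames_in_window(ncol(z), frame_rate, t0_frame, stimulus_window)
  base_means <- rowMeans(z[, bl_idx, drop = FALSE])
  for (fr in stim_idx) {
    v <- sm[, fr]
    if (anyNA(v)) next
    p <- suppressWarnings(
      stats::wilcox.test(v, base_means, exact = FALSE)$p.value)
    if (is.finite(p) && p < alpha) {
      return((fr - t0_frame) / frame_rate)
    }
  }
  NA_real_
}
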