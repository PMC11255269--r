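#' Session design: trial composition and outcome rules for one task session
#'
#' The task presents a 1-s pure tone (3 kHz or 12 kHz), a 2-s response
#' window, and a 4-6 s inter-trial interval. Four canonical sessions are
#' supported:
#'
#' * `Stable`: 50/50 randomly interleaved go (3 kHz) / no-go (12 kHz) trials.
#' * `Uncertain`: 40% go, 40% no-go, 10% reward-omission (RO: go cue, correct
#'   lick, reward withheld) and 10% un-cued reward (UR: reward with no tone).
#' * `Reversal`: 50/50 with the stimulus-outcome contingency swapped
#'   (licking to 3 kHz is now punished).
#' * `Re-stable`: same contingency as Reversal, after re-learning.
#'
#' @param name One of `"Stable"`, `"Uncertain"`, `"Reversal"`, `"Re-stable"`.
#' @param n_trials Number of trials in the session (default 150, a typical
#'   daily session length).
#' @param proportions Named fractions over trial types; must sum to 1.
#'   Defaults to the canonical composition for `name`.
#' @param phase_fractions Ordered fractions splitting the session into
#'   phases T1..Tk; must sum to 1. Defaults: thirds, except Reversal
#'   (0.15/0.35/0.50).
#' @param early_phases Phase labels pooled as the "early" period for
#'   early/late comparisons. Defaults: `c("T1","T2")` (first 67%), except
#'   Reversal `"T1"` (first 15%).
#' @return A `session_design` list.
#' @export
session_design <- function(name,
                           n_trials = 150,
                           proportions = NULL,
                           phase_fractions = NULL,
                           early_phases = NULL) {
  known <- c("Stable", "Uncertain", "Reversal", "Re-stable")
  if (!name %in% known) {
    abort(paste0("unknown session name '", name, "' (expected one of ",
                 paste(known, collapse = ", "), ")"), class = "accvi_config_error")
  }
  if (is.null(proportions)) {
    proportions <- if (name == "Uncertain") {
      c(go = 0.40, nogo = 0.40, RO = 0.10, UR = 0.10)
    } else {
      c(go = 0.50, nogo = 0.50)
    }
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("session trial-type proportions must sum to 1",
          class = "accvi_config_error")
  }
  if (is.null(phase_fractions)) {
    phase_fractions <- if (name == "Reversal") {
      c(T1 = 0.15, T2 = 0.35, T3 = 0.50)
    } else {
      c(T1 = 1 / 3, T2 = 1 / 3, T3 = 1 / 3)
    }
  }
  if (abs(sum(phase_fractions) - 1) > 1e-9) {
    abort("phase fractions must sum to 1", class = "accvi_config_error")
  }
  if (is.null(early_phases)) {
    early_phases <- if (name == "Reversal") "T1" else c("T1", "T2")
  }
  # stimulus identity per trial type; in Reversal/Re-stable the go cue is 12 kHz
  stimulus_map <- if (name %in% c("Reversal", "Re-stable")) {
    c(go = "12kHz", nogo = "3kHz")
  } else {
    c(go = "3kHz", nogo = "12kHz", RO = "3kHz", UR = "none")
  }
  structure(
    list(name = name, n_trials = as.integer(n_trials),
         proportions = proportions, phase_fractions = phase_fractions,
         early_phases = early_phases, stimulus_map = stimulus_map),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  cat("<session_design> ", x$name, ": ", x$n_trials, " trials [",
      paste(sprintf("%s=%.2f", names(x$proportions), x$proportions),
            collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Run configuration for the analysis pipeline
#'
#' Holds timing conventions, analysis windows and session designs. Time is
#' measured in seconds relative to stimulus onset (frame 0 = onset); all
#' windows are half-open `[start, end)`.
#'
#' @param seed Master RNG seed; every random draw in a pipeline run is
#'   derived from it via [substream_seed()].
#' @param frame_rate Imaging frame rate, frames/s (default 30).
#' @param stimulus_window Seconds, default `c(0, 1)` (1-s tone).
#' @param response_window Seconds, default `c(1, 3)` (2-s response window).
#' @param baseline_dff Seconds used for the delta-F/F baseline F0, default
#'   `c(-2, 0)`.
#' @param baseline_z Seconds used for the z-score baseline, default
#'   `c(-0.5, 0)`.
#' @param session_designs List of [session_design()] objects keyed by name.
#' @param n_neurons Number of neurons for synthetic populations (default 300).
#' @param sarsa_repeats Simulation repeats for the SARSA stage (default 3000).
#' @param geometry_boot Bootstrap iterations for trajectory metrics in the
#'   pipeline stage (default 1000; the standalone function defaults to 5000).
#' @param decoding_repeats Decoding repeats in the pipeline stage (default 100).
#' @param output_dir Directory for pipeline outputs (default `NULL`: a
#'   temporary directory).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       frame_rate = 30,
                       stimulus_window = c(0, 1),
                       response_window = c(1, 3),
                       baseline_dff = c(-2, 0),
                       baseline_z = c(-0.5, 0),
                       session_designs = NULL,
                       n_neurons = 300L,
                       sarsa_repeats = 3000L,
                       geometry_boot = 1000L,
                       decoding_repeats = 100L,
                       output_dir = NULL) {
  for (w in list(stimulus_window, response_window, baseline_dff, baseline_z)) {
    if (length(w) != 2 || !all(is.finite(w)) || w[1] >= w[2]) {
      abort("window bounds must be finite with start < end",
            class = "accvi_config_error")
    }
  }
  if (is.null(session_designs)) {
    session_designs <- list(
      Stable      = session_design("Stable"),
      Uncertain   = session_design("Uncertain"),
      Reversal    = session_design("Reversal"),
      `Re-stable` = session_design("Re-stable")
    )
  }
  for (nm in names(session_designs)) {
    if (!inherits(session_designs[[nm]], "session_design")) {
      abort("session_designs must contain session_design objects",
            class = "accvi_config_error")
    }
  }
  structure(
    list(seed = as.integer(seed), frame_rate = frame_rate,
         stimulus_window = stimulus_window, response_window = response_window,
         baseline_dff = baseline_dff, baseline_z = baseline_z,
         session_designs = session_designs,
         n_neurons = as.integer(n_neurons),
         sarsa_repeats = as.integer(sarsa_repeats),
         geometry_boot = as.integer(geometry_boot),
         decoding_repeats = as.integer(decoding_repeats),
         output_dir = output_dir),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> seed =", x$seed, "| frame_rate =", x$frame_rate,
      "| sessions:", paste(names(x$session_designs), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_run_config()` returns a [run_config()]; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  designs <- NULL
  if (!is.null(j$session_designs)) {
    designs <- lapply(j$session_designs, function(d) {
      session_design(d$name, n_trials = d$n_trials,
                     proportions = unlist(d$proportions),
                     phase_fractions = unlist(d$phase_fractions),
                     early_phases = unlist(d$early_phases))
    })
    names(designs) <- vapply(designs, `[[`, "", "name")
  }
  run_config(
    seed = j$seed %||% 1L,
    frame_rate = j$frame_rate %||% 30,
    stimulus_window = unlist(j$stimulus_window %||% c(0, 1)),
    response_window = unlist(j$response_window %||% c(1, 3)),
    baseline_dff = unlist(j$baseline_dff %||% c(-2, 0)),
    baseline_z = unlist(j$baseline_z %||% c(-0.5, 0)),
    session_designs = designs,
    n_neurons = j$n_neurons %||% 300L,
    sarsa_repeats = j$sarsa_repeats %||% 3000L,
    geometry_boot = j$geometry_boot %||% 1000L,
    decoding_repeats = j$decoding_repeats %||% 100L,
    output_dir = j$output_dir
  )
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- config
  out$session_designs <- lapply(config$session_designs, function(d) {
    list(name = d$name, n_trials = d$n_trials,
         proportions = as.list(d$proportions),
         phase_fractions = as.list(d$phase_fractions),
         early_phases = d$early_phases)
  })
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
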