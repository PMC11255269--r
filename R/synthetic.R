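#' Deterministic trial-type counts for a session design
#'
#' Largest-remainder rounding: `count = round(fraction * n)` with any
#' remainder assigned to the largest fraction, so counts always sum to n
#' and fixtures are exactly reproducible.
#'
#' @param design A [session_design()].
#' @return Named integer vector of per-type counts.
#' @export
type_counts <- function(design) {
  p <- design$proportions
  n <- design$n_trials
  counts <- round_half_up(p * n)
  excess <- sum(counts) - n
  if (excess != 0) {
    i <- which.max(p)
    counts[i] <- counts[i] - excess
  }
  stats::setNames(as.integer(counts), names(p))
}

#' Generate the trial sequence for one session
#'
#' Trial types are drawn to match the design's proportions exactly (see
#' [type_counts()]) and uniformly shuffled; inter-trial intervals are
#' uniform on 4-6 s. Actions and outcomes are left unset.
#'
#' @param design A [session_design()].
#' @param seed Integer seed.
#' @return Trial tibble with columns session, trial_index, phase (NA),
#'   stimulus, trial_type, action (NA), outcome (NA), first_lick_s,
#'   n_licks, iti_s.
#' @export
generate_session_trials <- function(design, seed = 1L) {
  stopifnot(inherits(design, "session_design"), design$n_trials >= 1)
  counts <- type_counts(design)
  with_substream(seed, paste0("synthetic/trials/", design$name), {
    types <- sample(rep(names(counts), counts))
    tibble::tibble(
      session = design$name,
      trial_index = seq_along(types),
      phase = NA_character_,
      stimulus = unname(design$stimulus_map[types]),
      trial_type = types,
      action = NA_character_,
      outcome = NA_character_,
      first_lick_s = NA_real_,
      n_licks = 0L,
      iti_s = runif(length(types), 4, 6)
    )
  })
}

# default lick probability on trials whose tone the SARSA model does not
# track (the 12 kHz tone): proficient suppression in Stable/Uncertain,
# intermediate re-learning in Reversal, proficient licking in Re-stable
default_other_lick_prob <- function(session) {
  switch(session, Stable = 0.05, Uncertain = 0.05,
         Reversal = 0.5, `Re-stable` = 0.9, 0.05)
}

#' Simulate agent behavior through a trial sequence
#'
#' 3 kHz-tone trials are played by a SARSA agent (see [rl_params()]): the
#' action is sampled from the softmax policy and the outcome assigned by
#' the session's contingency; per-trial Q, learning rate and prediction
#' error are recorded as ground truth. Trials with other tones lick with a
#' fixed probability (`other_lick_prob`). Simulated lick times are a
#' modeling convenience (the task only constrains the response window):
#' lick onset is uniform on 0.6-1.8 s and the outcome is triggered by the
#' first lick inside the response window.
#'
#' @param trials Output of [generate_session_trials()].
#' @param params An [rl_params()]; defaults to published values with the
#'   session-appropriate beta.
#' @param seed Integer seed.
#' @param other_lick_prob Lick probability on non-3 kHz trials; default
#'   depends on the session.
#' @return The trial tibble with action, outcome, outcome_class, lick
#'   times, `outcome_time_s` and ground-truth columns q_lick, q_nolick,
#'   alpha, delta_r, p_lick.
#' @export
simulate_agent_behavior <- function(trials, params = NULL, seed = 1L,
                                    other_lick_prob = NULL) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1)
  session <- trials$session[1]
  if (is.null(params)) params <- rl_params(beta = default_beta(session))
  if (is.null(other_lick_prob)) {
    other_lick_prob <- default_other_lick_prob(session)
  }
  bad <- setdiff(unique(trials$trial_type), c("go", "nogo", "RO", "UR"))
  if (length(bad)) {
    abort(paste0("unknown trial_type '", bad[1], "'"),
          class = "accvi_data_error")
  }
  n <- nrow(trials)
  out <- tibble::as_tibble(trials)
  out$q_lick <- NA_real_; out$q_nolick <- NA_real_
  out$alpha <- NA_real_; out$delta_r <- NA_real_; out$p_lick <- NA_real_
  out$outcome_time_s <- NA_real_
  with_substream(seed, paste0("synthetic/behavior/", session), {
    ql <- params$q0_lick; qn <- params$q0_nolick
    a_prev <- params$alpha0; d_prev <- NA_real_
    for (i in seq_len(n)) {
      tt <- out$trial_type[i]
      if (tt == "UR") {
        out$action[i] <- NA_character_
        out$outcome_time_s[i] <- 1.5  # un-cued reward delivery
        out$first_lick_s[i] <- 1.6    # consumption licks follow the reward
        out$n_licks[i] <- 1L + stats::rpois(1, 3)
        next
      }
      modelled <- out$stimulus[i] == "3kHz"
      if (modelled) {
        p <- policy_probability(ql, qn, params$beta)
        lick <- runif(1) < p
        oc <- outcome_for_modelled(session, tt, lick)
        st <- sarsa_update(ql, qn, a_prev, d_prev,
                           if (lick) "lick" else "nolick", oc, params)
        out$q_lick[i] <- st$q_lick; out$q_nolick[i] <- st$q_nolick
        out$alpha[i] <- st$alpha; out$delta_r[i] <- st$delta_r
        out$p_lick[i] <- p
        ql <- st$q_lick; qn <- st$q_nolick
        a_prev <- st$alpha; d_prev <- st$delta_r
      } else {
        lick <- runif(1) < other_lick_prob
      }
      out$action[i] <- if (lick) "lick" else "nolick"
      if (lick) {
        onset <- runif(1, 0.6, 1.8)
        out$first_lick_s[i] <- onset
        out$n_licks[i] <- 1L + stats::rpois(1, 5)
        # reward/punishment/omission is triggered by the first lick in the
        # response window
        out$outcome_time_s[i] <- max(onset, 1.05)
      }
    }
  })
  design <- session_design(session, n_trials = n)
  classify_outcomes(out, design)
}

#' Plant a synthetic neural population with known functional structure
#'
#' Draws per-neuron amplitude parameters so that planted
#' outcome-monitoring neurons respond to unexpected outcomes (reward
#' omission, un-cued reward, early-Reversal air puff) with a gain of
#' `mon_gain` (well above the 2-fold classification rule), planted
#' value-updating neurons shrink their value-cue response by `upd_gain`
#' in the late period, and dual-function neurons do both. Class counts use
#' round-half-up on `class_mix`; dual neurons are a subset of both classes.
#'
#' @param n_neurons Population size.
#' @param class_mix Named fractions `c(monitoring=, updating=, dual=)`;
#'   defaults to the recorded-population mix (0.33 / 0.21 / 0.07).
#' @param effect_spec Named list overriding any default effect ranges:
#'   `amp_cue_go`, `amp_cue_nogo`, `amp_outcome` (uniform ranges),
#'   `mon_gain`, `upd_gain` (uniform gain ranges), `swap_pref_frac`,
#'   `history_base` (length-5 lag template), `history_gain` (uniform
#'   range), `noise_sd`, `kernel_tau`, `baseline_f`, `responsive_frac`.
#' @param seed Integer seed.
#' @return A `neuron_truth` tibble (one row per neuron) with the planted
#'   flags and parameters.
#' @export
generate_population <- function(n_neurons,
                                class_mix = c(monitoring = 0.33,
                                              updating = 0.21,
                                              dual = 0.07),
                                effect_spec = list(),
                                seed = 1L) {
  spec <- utils::modifyList(list(
    amp_cue_go = c(0.4, 0.8), amp_cue_nogo = c(0.1, 0.3),
    amp_outcome = c(0.3, 0.6), mon_gain = c(3, 4), upd_gain = c(3, 4),
    swap_pref_frac = 0.3, history_base = c(0.3, 0.15, 0.05, 0, 0),
    history_gain = c(0, 1), noise_sd = 0.1, kernel_tau = 0.4,
    baseline_f = 1, responsive_frac = 0.9
  ), effect_spec)
  if (any(class_mix < 0) || any(class_mix[c("monitoring", "updating")] > 1) ||
      class_mix[["dual"]] >
        min(class_mix[["monitoring"]], class_mix[["updating"]])) {
    abort("infeasible class_mix (dual must be <= min(monitoring, updating))",
          class = "accvi_config_error")
  }
  n_mon <- round_half_up(class_mix[["monitoring"]] * n_neurons)
  n_upd <- round_half_up(class_mix[["updating"]] * n_neurons)
  n_dual <- round_half_up(class_mix[["dual"]] * n_neurons)
  with_substream(seed, "synthetic/population", {
    responsive <- runif(n_neurons) < spec$responsive_frac
    resp_idx <- which(responsive)
    if (length(resp_idx) < n_mon + n_upd - n_dual) {
      abort("not enough responsive neurons for the requested class_mix",
            class = "accvi_config_error")
    }
    mon_idx <- sample(resp_idx, n_mon)
    dual_idx <- if (n_dual > 0) sample(mon_idx, n_dual) else integer(0)
    upd_only <- sample(setdiff(resp_idx, mon_idx), n_upd - n_dual)
    upd_idx <- c(dual_idx, upd_only)
    monitoring <- seq_len(n_neurons) %in% mon_idx
    updating <- seq_len(n_neurons) %in% upd_idx
    ru <- function(rg, n) runif(n, rg[1], rg[2])
    amp_go <- ru(spec$amp_cue_go, n_neurons)
    amp_nogo <- ru(spec$amp_cue_nogo, n_neurons)
    swap <- runif(n_neurons) < spec$swap_pref_frac
    tmp <- amp_go[swap]; amp_go[swap] <- amp_nogo[swap]; amp_nogo[swap] <- tmp
    w <- outer(ru(spec$history_gain, n_neurons), spec$history_base)
    colnames(w) <- paste0("w", seq_len(ncol(w)))
    out <- tibble::tibble(
      neuron_id = sprintf("n%03d", seq_len(n_neurons)),
      responsive = responsive,
      outcome_monitoring = monitoring,
      value_updating = updating,
      dual = monitoring & updating,
      amp_cue_go = ifelse(responsive, amp_go, 0),
      amp_cue_nogo = ifelse(responsive, amp_nogo, 0),
      amp_outcome = ifelse(responsive, ru(spec$amp_outcome, n_neurons), 0),
      mon_gain = ifelse(monitoring, ru(spec$mon_gain, n_neurons), 1),
      upd_gain = ifelse(updating, ru(spec$upd_gain, n_neurons), 1),
      noise_sd = rep(spec$noise_sd, n_neurons),
      kernel_tau = rep(spec$kernel_tau, n_neurons),
      baseline_f = rep(spec$baseline_f, n_neurons)
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(w * responsive))
    class(out) <- c("neuron_truth", class(out))
    out
  })
}

# lagged non-reward indicator matrix: O_t = 1 if trial t's outcome was not
# a reward, 0 if rewarded; column j holds O_(t-j), NA where history is short
outcome_history_design <- function(outcome_class, lags = 5) {
  o <- as.numeric(!outcome_class %in% c("Hit", "UR"))
  n <- length(o)
  X <- matrix(NA_real_, n, lags,
              dimnames = list(NULL, paste0("lag", seq_len(lags))))
  for (j in seq_len(lags)) {
    if (n > j) X[(j + 1):n, j] <- o[1:(n - j)]
  }
  X
}

# which tone carries the task value (the 3 kHz tone through reversal
# learning; the 12 kHz tone once the new contingency is consolidated)
value_cue <- function(session) {
  if (session == "Re-stable") "12kHz" else "3kHz"
}

#' Render a synthetic fluorescence tensor from planted ground truth
#'
#' Each neuron/trial trace is a baseline level plus calcium transients
#' (instant rise, exponential decay with time constant `kernel_tau`) at
#' stimulus onset and at outcome delivery, plus i.i.d. Gaussian noise.
#' Event amplitudes implement the planted structure: value-cue responses
#' shrink by `upd_gain` in the late period for value-updating neurons;
#' unexpected outcomes (RO, UR, early-Reversal air puff) are scaled by
#' `mon_gain` for outcome-monitoring neurons; the cue amplitude also
#' carries the planted outcome-history weights. Frames span -2 to +4 s
#' around stimulus onset.
#'
#' @param trials Trial tibble with actions/outcomes assigned and a
#'   `period` column (run [split_phases()] + [assign_periods()] first).
#' @param truth A `neuron_truth` from [generate_population()].
#' @param config A [run_config()] (frame rate, baseline windows).
#' @param seed Integer seed.
#' @return A `fluo_tensor`: list with `F` (neurons x trials x frames
#'   array), `frame_rate`, `t0_frame`, `neuron_ids`.
#' @export
render_fluorescence <- function(trials, truth, config = run_config(),
                                seed = 1L) {
  stopifnot(is.data.frame(trials), inherits(truth, "neuron_truth"))
  if (!"period" %in% names(trials) || anyNA(trials$period)) {
    abort("trials need a period column (split_phases + assign_periods)",
          class = "accvi_data_error")
  }
  span <- c(-2, 4)
  if (config$baseline_dff[1] < span[1]) {
    abort("recording window too short to contain the delta-F/F baseline",
          class = "accvi_config_error")
  }
  rate <- config$frame_rate
  n_frames <- as.integer(round((span[2] - span[1]) * rate))
  t0_frame <- as.integer(round(-span[1] * rate)) + 1L
  tt <- frame_times(n_frames, rate, t0_frame)
  n_neurons <- nrow(truth); n_trials <- nrow(trials)
  session <- trials$session[1]
  vcue <- value_cue(session)
  W <- as.matrix(truth[, paste0("w", 1:5)])
  H <- outcome_history_design(trials$outcome_class, lags = 5)
  H0 <- H; H0[is.na(H0)] <- 0
  hist_amp <- W %*% t(H0)  # neurons x trials additive cue modulation
  kern <- function(t_event, tau) {
    k <- matrix(0, length(tau), n_frames)
    u <- tt - t_event
    on <- u >= 0
    for (r in seq_along(tau)) k[r, on] <- exp(-u[on] / tau[r])
    k
  }
  with_substream(seed, paste0("synthetic/fluo/", session), {
    F <- array(rnorm(n_neurons * n_trials * n_frames) *
                 rep(truth$noise_sd, n_trials * n_frames) +
                 rep(truth$baseline_f, n_trials * n_frames),
               dim = c(n_neurons, n_trials, n_frames))
    taus <- truth$kernel_tau
    for (i in seq_len(n_trials)) {
      # cue transient
      if (trials$stimulus[i] != "none") {
        amp <- if (trials$stimulus[i] == vcue) truth$amp_cue_go
               else truth$amp_cue_nogo
        amp <- pmax(amp + hist_amp[, i] * (amp > 0), 0)
        # value updating: the whole cue response (history modulation
        # included) shrinks in the late period, but only in sessions whose
        # unexpected outcomes drive value re-assessment
        if (trials$stimulus[i] == vcue && trials$period[i] == "late" &&
            session %in% c("Uncertain", "Reversal")) {
          amp <- amp / truth$upd_gain
        }
        F[, i, ] <- F[, i, ] + amp * kern(0, taus)
      }
      # outcome transient (only when something is delivered)
      oc <- trials$outcome_class[i]
      te <- trials$outcome_time_s[i]
      if (!is.na(te) && oc %in% c("Hit", "RO", "UR", "FA")) {
        unexpected <- oc %in% c("RO", "UR") ||
          (oc == "FA" && session == "Reversal" &&
             trials$period[i] == "early")
        amp <- truth$amp_outcome * if (unexpected) truth$mon_gain else 1
        F[, i, ] <- F[, i, ] + amp * kern(te, taus)
      }
    }
    fluo_tensor(F, frame_rate = rate, t0_frame = t0_frame,
                neuron_ids = truth$neuron_id)
  })
}

#' Construct a fluorescence tensor container
#'
#' @param F Numeric array, neurons x trials x frames.
#' @param frame_rate Frames per second.
#' @param t0_frame 1-based frame index of stimulus onset (t = 0).
#' @param neuron_ids Character ids, length `dim(F)[1]`.
#' @return A `fluo_tensor` list.
#' @export
fluo_tensor <- function(F, frame_rate, t0_frame, neuron_ids = NULL) {
  stopifnot(length(dim(F)) == 3)
  if (is.null(neuron_ids)) neuron_ids <- sprintf("n%03d", seq_len(dim(F)[1]))
  stopifnot(length(neuron_ids) == dim(F)[1])
  structure(list(F = F, frame_rate = frame_rate,
                 t0_frame = as.integer(t0_frame),
                 neuron_ids = as.character(neuron_ids)),
            class = "fluo_tensor")
}

#' @export
print.fluo_tensor <- function(x, ...) {
  d <- dim(x$F)
  cat("<fluo_tensor>", d[1], "neurons x", d[2], "trials x", d[3],
      "frames @", x$frame_rate, "fps (t0 at frame", x$t0_frame, ")\n")
  invisible(x)
}

#' Assemble a complete synthetic dataset
#'
#' Generates one shared population and, for every session design in the
#' configuration, a trial sequence, SARSA-driven behavior, phase labels
#' and a rendered fluorescence tensor.
#'
#' @param config A [run_config()].
#' @param n_neurons Population size (default `config$n_neurons`).
#' @param class_mix,effect_spec Passed to [generate_population()].
#' @return An `accvi_dataset`: list with `trials` (named list of tibbles),
#'   `fluo` (named list of `fluo_tensor`), `neuron_ids`, `truth`.
#' @export
simulate_dataset <- function(config = run_config(), n_neurons = NULL,
                             class_mix = c(monitoring = 0.33,
                                           updating = 0.21, dual = 0.07),
                             effect_spec = list()) {
  n_neurons <- n_neurons %||% config$n_neurons
  truth <- generate_population(n_neurons, class_mix = class_mix,
                               effect_spec = effect_spec,
                               seed = config$seed)
  trials <- list(); fluo <- list()
  for (nm in names(config$session_designs)) {
    d <- config$session_designs[[nm]]
    tr <- generate_session_trials(d, seed = config$seed)
    tr <- simulate_agent_behavior(tr, params = rl_params(beta = default_beta(nm)),
                                  seed = config$seed)
    tr <- split_phases(tr, d$phase_fractions)
    tr <- assign_periods(tr, d$early_phases)
    trials[[nm]] <- tr
    fluo[[nm]] <- render_fluorescence(tr, truth, config, seed = config$seed)
  }
  new_dataset(trials, fluo, truth = truth)
}

new_dataset <- function(trials, fluo, truth = NULL) {
  stopifnot(identical(names(trials), names(fluo)))
  ids <- fluo[[1]]$neuron_ids
  for (nm in names(trials)) {
    if (nrow(trials[[nm]]) != dim(fluo[[nm]]$F)[2]) {
      abort(sprintf(
        "session %s: %d trials in table vs %d in fluorescence", nm,
        nrow(trials[[nm]]), dim(fluo[[nm]]$F)[2]),
        class = "accvi_alignment_error")
    }
    if (anyDuplicated(fluo[[nm]]$neuron_ids) ||
        !identical(fluo[[nm]]$neuron_ids, ids)) {
      abort("neuron ids must be unique and shared across sessions",
            class = "accvi_alignment_error")
    }
  }
  structure(list(trials = trials, fluo = fluo, neuron_ids = ids,
                 truth = truth),
            class = "accvi_dataset")
}

#' @export
print.accvi_dataset <- function(x, ...) {
  cat("<accvi_dataset>", length(x$neuron_ids), "neurons; sessions:",
      paste(sprintf("%s(%d)", names(x$trials),
                    vapply(x$trials, nrow, 1L)), collapse = ", "), "\n")
  invisible(x)
}
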