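#' Label trial outcomes (Hit / Miss / FA / CR / RO / UR)
#'
#' Applies the session's stimulus-outcome map: lick on a go cue is a Hit
#' (rewarded), lick on a no-go cue a false alarm (punished), withheld licks
#' are Miss / correct rejection. On reward-omission (RO) trials a correct
#' lick is labelled RO; for Hit/FA-rate purposes RO licks count toward the
#' Hit rate (the animal made the correct choice on a go cue). Un-cued
#' reward trials are labelled UR.
#'
#' @param trials Trial tibble with `trial_type` and `action` set.
#' @param design The session's [session_design()].
#' @return The tibble with columns `outcome_class` and `outcome` filled.
#' @export
classify_outcomes <- function(trials, design) {
  stopifnot(is.data.frame(trials), inherits(design, "session_design"))
  if (any(is.na(trials$action) & trials$trial_type != "UR")) {
    abort("actions must be set before classifying outcomes",
          class = "accvi_data_error")
  }
  cls <- character(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tt <- trials$trial_type[i]; a <- trials$action[i]
    cls[i] <- switch(tt,
      go   = if (a == "lick") "Hit" else "Miss",
      nogo = if (a == "lick") "FA" else "CR",
      RO   = if (a == "lick") "RO" else "Miss",
      UR   = "UR",
      abort(paste0("unknown trial_type '", tt, "'"),
            class = "accvi_data_error"))
  }
  outcome <- dplyr::case_match(cls,
    "Hit" ~ "reward", "UR" ~ "reward", "RO" ~ "omission",
    "FA" ~ "punishment", .default = "none")
  dplyr::mutate(tibble::as_tibble(trials),
                outcome_class = cls, outcome = outcome)
}

#' Discriminability index d-prime
#'
#' `d' = qnorm(hit_rate) - qnorm(fa_rate)`, the inverse-cumulative-Gaussian
#' difference of Hit and false-alarm rates. Degenerate rates of exactly 0
#' or 1 are clipped to `[1/(2n), 1 - 1/(2n)]` so d' stays finite. A session
#' is counted proficient at `d' >= 1.5`.
#'
#' @param hit_rate,fa_rate Fractions in `[0, 1]`.
#' @param n_go,n_nogo Trial counts behind each rate.
#' @return Tibble with `dprime` and `proficient`.
#' @export
compute_dprime <- function(hit_rate, fa_rate, n_go, n_nogo) {
  if (any(n_go == 0) || any(n_nogo == 0)) {
    abort("hit/FA rates undefined with zero go or no-go trials",
          class = "accvi_data_error")
  }
  stopifnot(all(hit_rate >= 0 & hit_rate <= 1),
            all(fa_rate >= 0 & fa_rate <= 1))
  h <- clamp(hit_rate, 1 / (2 * n_go), 1 - 1 / (2 * n_go))
  f <- clamp(fa_rate, 1 / (2 * n_nogo), 1 - 1 / (2 * n_nogo))
  d <- qnorm(h) - qnorm(f)
  tibble::tibble(dprime = d, proficient = d >= 1.5)
}

#' Hit/FA rates and d-prime for a trial table
#'
#' Go-cue trials (types `go` and `RO`) form the Hit-rate denominator, with
#' Hits and correct RO licks in the numerator; `nogo` trials form the
#' FA-rate denominator.
#'
#' @param trials Classified trial tibble (see [classify_outcomes()]).
#' @param scope Label stored in the output (e.g. session or phase name).
#' @return One-row tibble: scope, hit_rate, miss_rate, fa_rate, cr_rate,
#'   dprime, proficient, n_go, n_nogo.
#' @export
performance_summary <- function(trials, scope = "session") {
  stopifnot("outcome_class" %in% names(trials))
  go <- trials$trial_type %in% c("go", "RO")
  nogo <- trials$trial_type == "nogo"
  n_go <- sum(go); n_nogo <- sum(nogo)
  hit <- sum(trials$outcome_class %in% c("Hit", "RO") & go) / n_go
  fa <- sum(trials$outcome_class == "FA" & nogo) / n_nogo
  d <- compute_dprime(hit, fa, n_go, n_nogo)
  tibble::tibble(scope = scope, hit_rate = hit, miss_rate = 1 - hit,
                 fa_rate = fa, cr_rate = 1 - fa,
                 dprime = d$dprime, proficient = d$proficient,
                 n_go = n_go, n_nogo = n_nogo)
}

#' Split a session into contiguous ordered phases
#'
#' Phase boundary i falls after trial `round(cum_fraction_i * n)`
#' (round-half-up); the last phase absorbs any remainder. Canonical
#' splits: thirds (T1-T3) for Stable/Uncertain/Re-stable, 15/35/50% for
#' Reversal; early/late uses 67/33% (Uncertain) or 15/85% (Reversal).
#'
#' @param trials Trial tibble (ordered by `trial_index`).
#' @param fractions Ordered named fractions summing to 1; names become the
#'   phase labels (default `T1`..`Tk`).
#' @return The tibble with a `phase` column; attribute `"boundaries"` holds
#'   the last trial index of each phase.
#' @export
split_phases <- function(trials, fractions = c(T1 = 1/3, T2 = 1/3, T3 = 1/3)) {
  n <- nrow(trials)
  k <- length(fractions)
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("phase fractions must sum to 1", class = "accvi_config_error")
  }
  if (n < k) {
    abort("fewer trials than phases", class = "accvi_data_error")
  }
  if (is.null(names(fractions))) names(fractions) <- paste0("T", seq_len(k))
  bounds <- round_half_up(cumsum(fractions) * n)
  bounds[k] <- n
  if (any(diff(c(0, bounds)) < 1)) {
    abort("phase fractions give an empty phase at this n",
          class = "accvi_data_error")
  }
  out <- tibble::as_tibble(trials)
  out$phase <- names(fractions)[findInterval(seq_len(n), c(0, bounds[-k]) + 1)]
  attr(out, "boundaries") <- bounds
  out
}

#' Assign early/late period labels
#'
#' @param trials Trial tibble with a `phase` column.
#' @param early_phases Phase labels pooled as "early"; the rest are "late".
#' @return The tibble with a `period` column.
#' @export
assign_periods <- function(trials, early_phases = c("T1", "T2")) {
  stopifnot("phase" %in% names(trials))
  dplyr::mutate(tibble::as_tibble(trials),
                period = ifelse(.data$phase %in% early_phases,
                                "early", "late"))
}

#' Lick probability by stimulus and grouping
#'
#' Fraction of trials with at least one response-window lick, per stimulus
#' within each group.
#'
#' @param trials Classified trial tibble.
#' @param by Character vector of grouping columns (default `"phase"`).
#' @return Tibble: grouping columns, stimulus, lick_prob, n_trials.
#' @export
lick_probability <- function(trials, by = "phase") {
  stopifnot(all(by %in% names(trials)))
  out <- trials |>
    dplyr::filter(.data$trial_type != "UR") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "stimulus")))) |>
    dplyr::summarise(lick_prob = mean(.data$action == "lick"),
                     n_trials = dplyr::n(), .groups = "drop")
  if (any(out$n_trials == 0)) warn("empty group omitted from lick probability")
  out
}
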