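#' The 2-fold response rule
#'
#' A neuron passes when its response in the "high" context exceeds the
#' "low" one by at least 2-fold in the signed sense used throughout the
#' classification: `R_high - R_low > |R_low|` (for positive `R_low` this
#' is exactly `R_high > 2 R_low`).
#'
#' @param r_high,r_low Window-mean responses (vectorized).
#' @return Logical.
#' @export
twofold_rule <- function(r_high, r_low) {
  stopifnot(all(is.finite(r_high) | is.na(r_high)),
            all(is.finite(r_low) | is.na(r_low)))
  (r_high - r_low) > abs(r_low)
}

#' Classify outcome-monitoring, value-updating and dual-function neurons
#'
#' Session-specific contexts, all through [twofold_rule()]:
#'
#' * Uncertain — *outcome monitoring*: mean delta-F/F in a 1-s window after
#'   the first lick, reward-omission vs Hit trials; *value updating*: mean
#'   go-cue response (1-s post-onset) in the early (first 67%) vs late
#'   (last 33%) period.
#' * Reversal — *outcome monitoring*: air-puff response (1-s post-delivery)
#'   in the early (first 15%) vs late (last 85%) period; *value updating*:
#'   no-go-cue (3 kHz) response early vs late.
#'
#' Dual-function neurons satisfy both. Neurons with fewer than
#' `min_trials` trials in any required condition, or with invalid window
#' means, are skipped with a warning and excluded from denominators.
#'
#' @param dff A `dff_tensor` for the session.
#' @param trials The session's classified trial tibble (with `period`).
#' @param session `"Uncertain"` or `"Reversal"`.
#' @param window Response window length in seconds (default `c(0, 1)`).
#' @param min_trials Minimum trials per condition (default 3).
#' @param responsive_only Optionally a character vector of neuron ids to
#'   restrict classification to (e.g. responsive neurons); default all.
#' @return A `functional_labels` tibble: neuron_id, session,
#'   outcome_monitoring, value_updating, dual, and the window means that
#'   entered each rule (mon_r_high/low, upd_r_high/low).
#' @export
classify_functional <- function(dff, trials, session = c("Uncertain", "Reversal"),
                                window = c(0, 1), min_trials = 3,
                                responsive_only = NULL) {
  session <- match.arg(session)
  stopifnot(inherits(dff, "dff_tensor"), "period" %in% names(trials),
            "outcome_class" %in% names(trials))
  if (session == "Uncertain") {
    mon_hi_tr <- which(trials$outcome_class == "RO")
    mon_lo_tr <- which(trials$outcome_class == "Hit")
    mon_event <- trials$outcome_time_s
    upd_sel <- trials$trial_type %in% c("go", "RO")
    upd_hi_tr <- which(upd_sel & trials$period == "early")
    upd_lo_tr <- which(upd_sel & trials$period == "late")
  } else {
    mon_hi_tr <- which(trials$outcome_class == "FA" & trials$period == "early")
    mon_lo_tr <- which(trials$outcome_class == "FA" & trials$period == "late")
    mon_event <- trials$outcome_time_s
    upd_sel <- trials$stimulus == "3kHz"
    upd_hi_tr <- which(upd_sel & trials$period == "early")
    upd_lo_tr <- which(upd_sel & trials$period == "late")
  }
  counts <- lengths(list(mon_hi_tr, mon_lo_tr, upd_hi_tr, upd_lo_tr))
  if (any(counts < min_trials)) {
    warn(sprintf(
      "session %s: a classification condition has < %d trials; all neurons skipped",
      session, min_trials))
    return(tibble::tibble(neuron_id = dff$neuron_ids, session = session,
                          outcome_monitoring = NA, value_updating = NA,
                          dual = NA, mon_r_high = NA_real_,
                          mon_r_low = NA_real_, upd_r_high = NA_real_,
                          upd_r_low = NA_real_))
  }
  wm_event <- function(tr) {
    rowMeans(window_mean(dff, window, trials = tr,
                         event_time_s = mon_event[tr]), na.rm = TRUE)
  }
  wm_cue <- function(tr) {
    rowMeans(window_mean(dff, window, trials = tr), na.rm = TRUE)
  }
  mon_hi <- wm_event(mon_hi_tr); mon_lo <- wm_event(mon_lo_tr)
  upd_hi <- wm_cue(upd_hi_tr); upd_lo <- wm_cue(upd_lo_tr)
  keep <- is.finite(mon_hi) & is.finite(mon_lo) &
    is.finite(upd_hi) & is.finite(upd_lo)
  if (!is.null(responsive_only)) {
    keep <- keep & dff$neuron_ids %in% responsive_only
  }
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    warn(sprintf("%d neurons excluded (invalid window means or filtered)",
                 n_excluded))
  }
  mon <- ifelse(keep, twofold_rule(mon_hi, mon_lo), NA)
  upd <- ifelse(keep, twofold_rule(upd_hi, upd_lo), NA)
  out <- tibble::tibble(
    neuron_id = dff$neuron_ids, session = session,
    outcome_monitoring = mon, value_updating = upd, dual = mon & upd,
    mon_r_high = mon_hi, mon_r_low = mon_lo,
    upd_r_high = upd_hi, upd_r_low = upd_lo
  )
  class(out) <- c("functional_labels", class(out))
  out
}

#' Venn counts and percentages of functional classes
#'
#' @param labels A `functional_labels` tibble (NA-flagged neurons are
#'   excluded from counts but reported).
#' @param n_total Denominator for the percentages; default the number of
#'   classified (non-NA) neurons.
#' @return One-row tibble with counts, round-half-up integer percentages,
#'   and the exclusion count.
#' @export
venn_summary <- function(labels, n_total = NULL) {
  ok <- !is.na(labels$outcome_monitoring) & !is.na(labels$value_updating)
  n_total <- n_total %||% sum(ok)
  if (n_total == 0) {
    abort("no classified neurons to summarise", class = "accvi_data_error")
  }
  n_mon <- sum(labels$outcome_monitoring[ok])
  n_upd <- sum(labels$value_updating[ok])
  n_dual <- sum(labels$dual[ok])
  pct <- function(k) as.integer(round_half_up(100 * k / n_total))
  tibble::tibble(
    n_total = n_total, n_monitoring = n_mon, n_updating = n_upd,
    n_dual = n_dual, n_excluded = sum(!ok),
    pct_monitoring = pct(n_mon), pct_updating = pct(n_upd),
    pct_dual = pct(n_dual)
  )
}

#' Go/no-go selectivity index
#'
#' `SI = (mean_go - mean_nogo) / sigma_p` with the pooled standard
#' deviation `sigma_p = sqrt( sum_i (n_i - 1) s_i^2 / sum_i (n_i - 1) )`
#' over the two conditions. Positive SI means go-preferring.
#'
#' @param responses_go,responses_nogo Per-trial window means (>= 2 each).
#' @return Tibble: si, sigma_p, n_go, n_nogo; `si` is `NA` (flagged by
#'   `defined = FALSE`) when `sigma_p = 0`.
#' @export
selectivity_index <- function(responses_go, responses_nogo) {
  n1 <- length(responses_go); n2 <- length(responses_nogo)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(responses_go) + (n2 - 1) * var(responses_nogo)) /
    (n1 - 1 + n2 - 1)
  sp <- sqrt(sp2)
  si <- if (sp == 0) NA_real_ else
    (mean(responses_go) - mean(responses_nogo)) / sp
  tibble::tibble(si = si, sigma_p = sp, n_go = n1, n_nogo = n2,
                 defined = sp > 0)
}

#' Permutation test for the selectivity index
#'
#' Trial labels are shuffled `n_perm` times (default 1000); the neuron is
#' called significantly selective when |SI| exceeds the 95th percentile of
#' the shuffled |SI| distribution (two-sided via the absolute value, so go
#' and no-go preferences are treated symmetrically). `p_perm` is the
#' fraction of shuffles with |SI| at least the observed value.
#'
#' @inheritParams selectivity_index
#' @param n_perm Number of shuffles (default 1000).
#' @param seed Integer seed.
#' @return Tibble: si, sigma_p, n_go, n_nogo, p_perm, significant.
#' @export
si_permutation_test <- function(responses_go, responses_nogo,
                                n_perm = 1000, seed = 1L) {
  if (n_perm < 1) {
    abort("n_perm must be >= 1", class = "accvi_config_error")
  }
  base <- selectivity_index(responses_go, responses_nogo)
  n1 <- base$n_go; n2 <- base$n_nogo
  if (n1 + n2 < 10) warn("fewer than 10 trials: permutation p has low resolution")
  pooled <- c(responses_go, responses_nogo)
  n <- n1 + n2
  with_substream(seed, "functional/si_perm", {
    # vectorized shuffles: one permutation per column
    perm <- replicate(n_perm, sample.int(n))
    vals <- matrix(pooled[perm], n, n_perm)
    g <- vals[seq_len(n1), , drop = FALSE]
    ng <- vals[(n1 + 1):n, , drop = FALSE]
    m1 <- colMeans(g); m2 <- colMeans(ng)
    v1 <- (colSums(g^2) - n1 * m1^2) / (n1 - 1)
    v2 <- (colSums(ng^2) - n2 * m2^2) / (n2 - 1)
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2))
    si_sh <- (m1 - m2) / sp
    si_sh[sp == 0] <- 0
    obs <- abs(base$si)
    p_perm <- mean(abs(si_sh) >= obs)
    crit <- quantile(abs(si_sh), 0.95, names = FALSE)
    tibble::tibble(si = base$si, sigma_p = base$sigma_p,
                   n_go = n1, n_nogo = n2, p_perm = p_perm,
                   significant = is.finite(obs) && obs > crit)
  })
}
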