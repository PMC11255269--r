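#' SARSA model parameters
#'
#' The model tracks the incentive value Q of the 3 kHz tone for the two
#' actions (lick / no-lick). After each modelled trial the chosen action's
#' value is updated by the prediction error, `Q <- Q + alpha * (R - Q)`,
#' where the learning rate itself is iterated trial-by-trial from the
#' previous learning rate and the previous prediction error,
#' `alpha_t = theta' * alpha_{t-1} + theta * |dr_{t-1}|` (clamped to
#' `[0, 1]`). Actions are drawn from a softmax ("QP transformation") over
#' the two action values with inverse-temperature-like scaling `beta`.
#'
#' Defaults are the published fit: `theta' = 0.6`, `theta = 0.08`,
#' `alpha0 = 0.1`, `Q0 = (0.98, 0.02)`, `beta = 2.3` for Stable/Uncertain
#' (1.68 for Reversal), rewards Hit = 1, Miss = 0.1, RO = -0.1, FA = -2,
#' CR = 0.1.
#'
#' @param theta_prime Persistence of the learning rate (>= 0).
#' @param theta Gain converting |prediction error| into learning rate (>= 0).
#' @param alpha0 Learning rate used on the first modelled trial.
#' @param q0_lick,q0_nolick Initial action values.
#' @param beta Softmax scaling (> 0).
#' @param reward_map Named numeric: reward per outcome class.
#' @return An `rl_params` list.
#' @export
rl_params <- function(theta_prime = 0.6, theta = 0.08, alpha0 = 0.1,
                      q0_lick = 0.98, q0_nolick = 0.02, beta = 2.3,
                      reward_map = c(Hit = 1, Miss = 0.1, RO = -0.1,
                                     FA = -2, CR = 0.1)) {
  if (theta_prime < 0 || theta < 0 || beta <= 0) {
    abort("need theta_prime >= 0, theta >= 0, beta > 0",
          class = "accvi_config_error")
  }
  structure(list(theta_prime = theta_prime, theta = theta, alpha0 = alpha0,
                 q0_lick = q0_lick, q0_nolick = q0_nolick, beta = beta,
                 reward_map = reward_map),
            class = "rl_params")
}

#' Published softmax scaling per session
#' @param session Session name.
#' @return Numeric beta.
#' @export
default_beta <- function(session) {
  if (session == "Reversal") 1.68 else 2.3
}

#' Softmax (QP transformation) lick probability
#'
#' `P(lick) = exp(beta q_lick) / (exp(beta q_lick) + exp(beta q_nolick))`,
#' computed in the overflow-safe logistic form.
#'
#' @param q_lick,q_nolick Action values (vectorized).
#' @param beta Softmax scaling.
#' @return Lick probability in (0, 1).
#' @export
policy_probability <- function(q_lick, q_nolick, beta) {
  stopifnot(all(is.finite(q_lick)), all(is.finite(q_nolick)), is.finite(beta))
  1 / (1 + exp(-beta * (q_lick - q_nolick)))
}

#' One SARSA update step
#'
#' Computes the learning rate for the current trial from the previous
#' trial's learning rate and |prediction error| (the first modelled trial
#' uses `alpha0` directly, signalled by `delta_prev = NA`), then updates
#' the chosen action's value. The unchosen value persists.
#'
#' @param q_lick,q_nolick Current action values.
#' @param alpha_prev Previous trial's learning rate (or `alpha0` at t = 1).
#' @param delta_prev Previous trial's prediction error; `NA` on the first
#'   modelled trial.
#' @param action `"lick"` or `"nolick"`.
#' @param outcome Outcome class; must be a name of `params$reward_map`.
#' @param params An [rl_params()].
#' @return List with `q_lick`, `q_nolick`, `alpha` (rate used), `delta_r`.
#' @export
sarsa_update <- function(q_lick, q_nolick, alpha_prev, delta_prev,
                         action, outcome, params) {
  if (!outcome %in% names(params$reward_map)) {
    abort(paste0("unknown outcome '", outcome, "'"), class = "accvi_data_error")
  }
  alpha <- if (is.na(delta_prev)) {
    params$alpha0
  } else {
    clamp(params$theta_prime * alpha_prev + params$theta * abs(delta_prev), 0, 1)
  }
  r <- unname(params$reward_map[[outcome]])
  if (identical(action, "lick")) {
    delta <- r - q_lick
    q_lick <- q_lick + alpha * delta
  } else {
    delta <- r - q_nolick
    q_nolick <- q_nolick + alpha * delta
  }
  list(q_lick = q_lick, q_nolick = q_nolick, alpha = alpha, delta_r = delta)
}

# outcome class for a modelled (3 kHz) trial given session rule
# Stable/Uncertain: 3 kHz is the go cue; RO-type trials withhold the reward.
# Reversal/Re-stable: 3 kHz is the no-go cue; licking is punished.
outcome_for_modelled <- function(session, trial_type, lick) {
  if (session %in% c("Reversal", "Re-stable")) {
    ifelse(lick, "FA", "CR")
  } else {
    ifelse(lick, ifelse(trial_type == "RO", "RO", "Hit"), "Miss")
  }
}

#' Simulate an ensemble of SARSA agents through one session
#'
#' Only 3 kHz-tone trials are modelled (the tone whose incentive value the
#' model tracks); other trials do not update Q. Per repeat, the 3 kHz
#' trials' types and their positions within the full session are drawn
#' from the design, then each modelled trial samples an action from the
#' softmax policy, receives the rule-based outcome, and applies the
#' adaptive-learning-rate update.
#'
#' @param design A [session_design()].
#' @param params An [rl_params()]; `beta` should match the session (see
#'   [default_beta()]).
#' @param n_repeats Number of independent simulated sessions (default 3000).
#' @param seed Integer seed.
#' @return A `sarsa_sim` object holding repeat-by-trial matrices (`alpha`,
#'   `q_lick`, `q_nolick`, `delta_r`, `p_lick`, `lick`) plus the modelled
#'   trials' positions in the full session. Use [tidy()] for a long tibble.
#' @export
simulate_session <- function(design, params = NULL, n_repeats = 3000,
                             seed = 1L) {
  stopifnot(inherits(design, "session_design"))
  if (is.null(params)) {
    params <- rl_params(beta = default_beta(design$name))
  }
  counts <- type_counts(design)
  modelled_types <- intersect(
    names(design$stimulus_map)[design$stimulus_map == "3kHz"], names(counts))
  n_mod <- sum(counts[modelled_types])
  if (n_mod == 0) {
    abort("session design has no 3 kHz trials to model",
          class = "accvi_config_error")
  }
  n_total <- design$n_trials
  with_substream(seed, paste0("sarsa/", design$name), {
    # per repeat: positions of modelled trials in the session, and their types
    pos <- t(vapply(seq_len(n_repeats),
                    function(i) sort(sample.int(n_total, n_mod)),
                    integer(n_mod)))
    type_pool <- rep(modelled_types, counts[modelled_types])
    types <- t(vapply(seq_len(n_repeats),
                      function(i) sample(type_pool, n_mod),
                      character(n_mod)))
    q_lick <- matrix(NA_real_, n_repeats, n_mod)
    q_nolick <- matrix(NA_real_, n_repeats, n_mod)
    alpha <- matrix(NA_real_, n_repeats, n_mod)
    delta <- matrix(NA_real_, n_repeats, n_mod)
    p_lick <- matrix(NA_real_, n_repeats, n_mod)
    lick <- matrix(NA, n_repeats, n_mod)
    outc <- matrix(NA_character_, n_repeats, n_mod)
    ql <- rep(params$q0_lick, n_repeats)
    qn <- rep(params$q0_nolick, n_repeats)
    a_prev <- rep(params$alpha0, n_repeats)
    d_prev <- rep(NA_real_, n_repeats)
    reversal <- design$name %in% c("Reversal", "Re-stable")
    for (t in seq_len(n_mod)) {
      a_t <- ifelse(is.na(d_prev), params$alpha0,
                    clamp(params$theta_prime * a_prev +
                            params$theta * abs(d_prev), 0, 1))
      p <- policy_probability(ql, qn, params$beta)
      lk <- runif(n_repeats) < p
      oc <- if (reversal) {
        ifelse(lk, "FA", "CR")
      } else {
        ifelse(lk, ifelse(types[, t] == "RO", "RO", "Hit"), "Miss")
      }
      r <- unname(params$reward_map[oc])
      d_t <- r - ifelse(lk, ql, qn)
      ql <- ifelse(lk, ql + a_t * d_t, ql)
      qn <- ifelse(lk, qn, qn + a_t * d_t)
      q_lick[, t] <- ql; q_nolick[, t] <- qn
      alpha[, t] <- a_t; delta[, t] <- d_t
      p_lick[, t] <- p; lick[, t] <- lk; outc[, t] <- oc
      a_prev <- a_t; d_prev <- d_t
    }
    structure(list(session = design$name, design = design, params = params,
                   n_repeats = n_repeats, n_modelled = n_mod,
                   positions = pos, types = types,
                   q_lick = q_lick, q_nolick = q_nolick, alpha = alpha,
                   delta_r = delta, p_lick = p_lick, lick = lick,
                   outcome = outc),
              class = "sarsa_sim")
  })
}

#' @export
print.sarsa_sim <- function(x, ...) {
  cat("<sarsa_sim> ", x$session, ": ", x$n_repeats, " repeats x ",
      x$n_modelled, " modelled trials; mean final alpha = ",
      signif(mean(x$alpha[, x$n_modelled]), 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy sarsa_sim
#' @export
tidy.sarsa_sim <- function(x, ...) {
  n <- x$n_repeats; m <- x$n_modelled
  tibble::tibble(
    repeat_id = rep(seq_len(n), times = m),
    trial = rep(seq_len(m), each = n),
    position = as.vector(x$positions),
    q_lick = as.vector(x$q_lick),
    q_nolick = as.vector(x$q_nolick),
    alpha = as.vector(x$alpha),
    delta_r = as.vector(x$delta_r),
    p_lick = as.vector(x$p_lick),
    lick = as.vector(x$lick),
    outcome = as.vector(x$outcome)
  )
}

#' Per-phase mean learning rate across a simulation ensemble
#'
#' Phases are assigned from each modelled trial's position in the full
#' session using the design's phase fractions (boundaries at
#' `round(cum_fraction * n)`).
#'
#' @param sims A `sarsa_sim` or list of them.
#' @param conf Confidence level for the sampling CI of the mean (default 0.95).
#' @return Tibble: session, phase, mean_alpha, ci_low, ci_high, n_repeats.
#' @export
learning_rate_summary <- function(sims, conf = 0.95) {
  if (inherits(sims, "sarsa_sim")) sims <- list(sims)
  stopifnot(length(sims) >= 1)
  z <- qnorm(1 - (1 - conf) / 2)
  purrr::map_dfr(sims, function(s) {
    n_total <- s$design$n_trials
    bounds <- round_half_up(cumsum(s$design$phase_fractions) * n_total)
    bounds[length(bounds)] <- n_total
    labels <- names(s$design$phase_fractions)
    phase_of <- function(p) labels[findInterval(p, c(0, bounds[-length(bounds)]) + 1)]
    ph <- matrix(phase_of(as.vector(s$positions)), nrow = s$n_repeats)
    purrr::map_dfr(labels, function(lb) {
      # per-repeat mean alpha over trials in the phase, then across repeats
      per_rep <- vapply(seq_len(s$n_repeats), function(i) {
        sel <- ph[i, ] == lb
        if (!any(sel)) NA_real_ else mean(s$alpha[i, sel])
      }, numeric(1))
      per_rep <- per_rep[!is.na(per_rep)]
      m <- mean(per_rep)
      se <- if (length(per_rep) > 1) sd(per_rep) / sqrt(length(per_rep)) else 0
      tibble::tibble(session = s$session, phase = lb, mean_alpha = m,
                     ci_low = m - z * se, ci_high = m + z * se,
                     n_repeats = length(per_rep))
    })
  })
}

# ---- likelihood & parameter recovery -------------------------------------

# negative log-likelihood of observed actions under the model, vectorized
# over sessions. lick, outcome: matrices [sessions x trials] (outcome as
# reward values already mapped). NA entries are skipped.
sarsa_negloglik <- function(theta_prime, theta, beta, params, lick, reward) {
  ns <- nrow(lick); nt <- ncol(lick)
  ql <- rep(params$q0_lick, ns); qn <- rep(params$q0_nolick, ns)
  a_prev <- rep(params$alpha0, ns); d_prev <- rep(NA_real_, ns)
  nll <- 0
  for (t in seq_len(nt)) {
    lk <- lick[, t]
    ok <- !is.na(lk)
    a_t <- ifelse(is.na(d_prev), params$alpha0,
                  clamp(theta_prime * a_prev + theta * abs(d_prev), 0, 1))
    p <- policy_probability(ql, qn, beta)
    p <- clamp(p, 1e-12, 1 - 1e-12)
    nll <- nll - sum(ifelse(lk[ok], log(p[ok]), log(1 - p[ok])))
    d_t <- reward[, t] - ifelse(lk, ql, qn)
    ql <- ifelse(ok & lk, ql + a_t * d_t, ql)
    qn <- ifelse(ok & !lk, qn + a_t * d_t, qn)
    a_prev <- ifelse(ok, a_t, a_prev)
    d_prev <- ifelse(ok, d_t, d_prev)
  }
  nll
}

#' Recover SARSA parameters from observed choice data
#'
#' Maximizes the Bernoulli log-likelihood of the observed lick/no-lick
#' sequence on modelled (3 kHz) trials over `(theta_prime, theta, beta)`
#' by a coarse grid search followed by bounded local refinement
#' (`L-BFGS-B`). The initial state (`alpha0`, `Q0`) and the reward map are
#' held at their configured values.
#'
#' @param actions List (or matrix, sessions x trials) of logical lick
#'   indicators per session.
#' @param outcomes List (or matrix) of outcome classes (names of
#'   `params$reward_map`) aligned with `actions`.
#' @param params An [rl_params()] supplying the fixed quantities.
#' @param free Character subset of `c("theta_prime","theta","beta")` to
#'   estimate; the rest stay at `params` values.
#' @param grid Named list of candidate grids for the free parameters
#'   (sensible defaults used when `NULL`).
#' @return A `sarsa_fit` with elements `estimate` (named numeric), `logLik`,
#'   `n_trials`; has [tidy()] and [glance()] methods.
#' @export
recover_parameters <- function(actions, outcomes, params = rl_params(),
                               free = c("theta_prime", "theta", "beta"),
                               grid = NULL) {
  if (length(free) == 0) {
    abort("at least one parameter must be free", class = "accvi_config_error")
  }
  free <- match.arg(free, c("theta_prime", "theta", "beta"),
                    several.ok = TRUE)
  to_mat <- function(x, f) {
    if (is.matrix(x)) return(x)
    nt <- max(lengths(x))
    out <- matrix(NA, length(x), nt)
    for (i in seq_along(x)) out[i, seq_along(x[[i]])] <- f(x[[i]])
    out
  }
  lick <- to_mat(actions, as.logical)
  oc <- to_mat(outcomes, as.character)
  if (!all(dim(lick) == dim(oc))) {
    abort("actions and outcomes must align", class = "accvi_data_error")
  }
  n_used <- sum(!is.na(lick))
  if (n_used < 80) {
    abort("need at least 80 observed trials", class = "accvi_data_error")
  }
  if (length(unique(lick[!is.na(lick)])) < 2) {
    warn("degenerate action sequence (all identical); estimates at boundary")
  }
  reward <- matrix(NA_real_, nrow(oc), ncol(oc))
  ok <- !is.na(oc)
  reward[ok] <- unname(params$reward_map[oc[ok]])
  full <- c(theta_prime = params$theta_prime, theta = params$theta,
            beta = params$beta)
  nll_of <- function(v) {
    p <- full; p[free] <- v
    sarsa_negloglik(p[["theta_prime"]], p[["theta"]], p[["beta"]],
                    params, lick, reward)
  }
  if (is.null(grid)) {
    grid <- list(theta_prime = seq(0.1, 0.95, by = 0.17),
                 theta = c(0.01, 0.04, 0.08, 0.15, 0.3),
                 beta = c(0.5, 1, 1.7, 2.5, 4))
  }
  cand <- expand.grid(grid[free], KEEP.OUT.ATTRS = FALSE)
  nlls <- apply(as.matrix(cand), 1, nll_of)
  start <- as.numeric(cand[which.min(nlls), ])
  lower <- c(theta_prime = 0, theta = 0, beta = 0.05)[free]
  upper <- c(theta_prime = 0.999, theta = 1, beta = 10)[free]
  opt <- stats::optim(start, nll_of, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 200))
  est <- full
  est[free] <- opt$par
  structure(list(estimate = est, free = free, logLik = -opt$value,
                 n_trials = n_used, convergence = opt$convergence,
                 params = params),
            class = "sarsa_fit")
}

#' @export
print.sarsa_fit <- function(x, ...) {
  cat("<sarsa_fit> logLik =", signif(x$logLik, 6), "on", x$n_trials,
      "trials\n")
  print(signif(x$estimate, 4))
  invisible(x)
}

#' @method tidy sarsa_fit
#' @export
tidy.sarsa_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate),
                 estimate = unname(x$estimate),
                 free = names(x$estimate) %in% x$free)
}

#' @method glance sarsa_fit
#' @export
glance.sarsa_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, n_trials = x$n_trials,
                 converged = x$convergence == 0)
}
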