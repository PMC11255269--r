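#' Fit the outcome-history regression for one neuron
#'
#' Ordinary least squares of the per-trial stimulus response `f(t)` on an
#' intercept (the basic sensory response) and the outcomes of the five
#' most recent trials, `f(t) = a + sum_i w_i O_(t-i)`, with `O = 1` for a
#' non-rewarded and `0` for a rewarded outcome. The first `lags` trials
#' lack a full history and are dropped (not zero-padded, which would bias
#' the lag estimates).
#'
#' @param responses Per-trial window-mean responses (one neuron).
#' @param outcomes Per-trial outcome classes (`Hit`, `Miss`, ...) or a
#'   0/1 non-reward indicator.
#' @param lags Number of history lags (default 5).
#' @param neuron_id Optional id stored in the fit.
#' @return A `history_fit`: intercept, `weights` (w1..wlags), `se`,
#'   `rank_deficient` flag, `n_used`; has [tidy()] and [glance()] methods.
#' @export
fit_outcome_history <- function(responses, outcomes, lags = 5,
                                neuron_id = NA_character_) {
  n <- length(responses)
  stopifnot(length(outcomes) == n)
  if (n < lags + 2) {
    abort("need at least lags + 2 trials", class = "accvi_data_error")
  }
  X <- if (is.numeric(outcomes)) {
    Xm <- matrix(NA_real_, n, lags,
                 dimnames = list(NULL, paste0("lag", seq_len(lags))))
    for (j in seq_len(lags)) Xm[(j + 1):n, j] <- outcomes[1:(n - j)]
    Xm
  } else {
    outcome_history_design(outcomes, lags)
  }
  keep <- stats::complete.cases(X) & !is.na(responses)
  Xk <- cbind(`(Intercept)` = 1, X[keep, , drop = FALSE])
  yk <- responses[keep]
  qr_x <- qr(Xk)
  rank_deficient <- qr_x$rank < ncol(Xk)
  if (rank_deficient) {
    warn("design matrix rank-deficient (e.g. constant outcomes); affected weights undefined")
  }
  beta <- qr.coef(qr_x, yk)
  resid <- yk - as.vector(Xk %*% ifelse(is.na(beta), 0, beta))
  dof <- length(yk) - qr_x$rank
  sigma2 <- if (dof > 0) sum(resid^2) / dof else NA_real_
  XtXinv <- tryCatch(chol2inv(qr.R(qr_x)), error = function(e) NULL)
  se <- if (!is.null(XtXinv) && !rank_deficient) {
    sqrt(diag(XtXinv) * sigma2)
  } else rep(NA_real_, ncol(Xk))
  structure(list(neuron_id = neuron_id,
                 intercept = unname(beta[1]),
                 weights = stats::setNames(unname(beta[-1]),
                                           paste0("w", seq_len(lags))),
                 se = stats::setNames(unname(se), c("intercept",
                                                    paste0("w", seq_len(lags)))),
                 rank_deficient = rank_deficient,
                 n_used = length(yk), sigma = sqrt(sigma2)),
            class = "history_fit")
}

#' @export
print.history_fit <- function(x, ...) {
  cat("<history_fit>", if (!is.na(x$neuron_id)) x$neuron_id else "",
      "intercept =", signif(x$intercept, 4), "\n")
  print(signif(x$weights, 4))
  invisible(x)
}

#' @method tidy history_fit
#' @export
tidy.history_fit <- function(x, ...) {
  tibble::tibble(
    neuron_id = x$neuron_id,
    term = c("intercept", names(x$weights)),
    estimate = c(x$intercept, unname(x$weights)),
    std.error = unname(x$se)
  )
}

#' @method glance history_fit
#' @export
glance.history_fit <- function(x, ...) {
  tibble::tibble(neuron_id = x$neuron_id, n_used = x$n_used,
                 sigma = x$sigma, rank_deficient = x$rank_deficient)
}

# deterministic fold assignment given a seed: contiguous-free random folds
make_folds <- function(n, folds, seed) {
  with_substream(seed, "glm/folds", sample(rep(seq_len(folds),
                                               length.out = n)))
}

cv_r2 <- function(X, y, fold_id) {
  folds <- sort(unique(fold_id))
  sse <- 0; sst <- 0
  for (k in folds) {
    tr <- fold_id != k
    fit <- stats::lm.fit(X[tr, , drop = FALSE], y[tr])
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pred <- as.vector(X[!tr, , drop = FALSE] %*% beta)
    yk <- y[!tr]
    sse <- sse + sum((yk - pred)^2)
    sst <- sst + sum((yk - mean(yk))^2)  # SST from the held-out fold
  }
  if (sst == 0) return(if (sse == 0) 0 else -Inf)
  1 - sse / sst
}

#' Fit the four-task-variable model with cross-validated explained variance
#'
#' Least-squares fit of per-trial go-cue responses on the four task
#' variables (stimulus — constant 1, absorbed by the model's intercept
#' role; cumulative history — fraction of the session's unexpected trials
#' already experienced, in `[0, 1]`; previous outcome — 1 when the
#' previous trial was unexpected; licking rate — licks/s in the stimulus
#' window), with k-fold cross-validated explained variance
#' (`1 - SSE/SST` on held-out folds; negative values reported as-is).
#'
#' @param responses Per-trial responses (go trials).
#' @param design Data frame of regressors (one row per trial); a constant
#'   `stimulus` column is added when absent.
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param neuron_id Optional id.
#' @return A `taskvar_fit`: coefficients, `r2_full`, stored folds/design
#'   for [variable_contribution()], `rank_deficient` flag.
#' @export
fit_task_variables <- function(responses, design, folds = 5, seed = 1L,
                               neuron_id = NA_character_) {
  stopifnot(is.data.frame(design), nrow(design) == length(responses))
  if (!"stimulus" %in% names(design)) design$stimulus <- 1
  X <- as.matrix(design)
  keep <- stats::complete.cases(X) & !is.na(responses)
  X <- X[keep, , drop = FALSE]; y <- responses[keep]
  if (nrow(X) < folds * 2) {
    abort("too few usable trials for cross-validation",
          class = "accvi_data_error")
  }
  rank_deficient <- qr(X)$rank < ncol(X)
  if (rank_deficient) warn("task-variable design is rank-deficient")
  fold_id <- make_folds(length(y), folds, seed)
  fit <- stats::lm.fit(X, y)
  structure(list(neuron_id = neuron_id,
                 coefficients = fit$coefficients,
                 r2_full = cv_r2(X, y, fold_id),
                 X = X, y = y, fold_id = fold_id,
                 rank_deficient = rank_deficient),
            class = "taskvar_fit")
}

#' @export
print.taskvar_fit <- function(x, ...) {
  cat("<taskvar_fit> cross-validated R2 =", signif(x$r2_full, 4), "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @method tidy taskvar_fit
#' @export
tidy.taskvar_fit <- function(x, ...) {
  tibble::tibble(neuron_id = x$neuron_id,
                 term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @method glance taskvar_fit
#' @export
glance.taskvar_fit <- function(x, ...) {
  tibble::tibble(neuron_id = x$neuron_id, r2_full = x$r2_full,
                 n_used = length(x$y), rank_deficient = x$rank_deficient)
}

#' Contribution of one task variable to the explained variance
#'
#' The drop in cross-validated explained variance when the variable is
#' removed from the model, computed on the identical folds as the full
#' model.
#'
#' @param fit A `taskvar_fit`.
#' @param variable Column name to remove.
#' @return Scalar contribution `r2_full - r2_without`.
#' @export
variable_contribution <- function(fit, variable) {
  stopifnot(inherits(fit, "taskvar_fit"))
  if (!variable %in% colnames(fit$X)) {
    abort(paste0("unknown variable '", variable, "'"),
          class = "accvi_config_error")
  }
  Xr <- fit$X[, setdiff(colnames(fit$X), variable), drop = FALSE]
  fit$r2_full - cv_r2(Xr, fit$y, fit$fold_id)
}

#' Build the four task-variable regressors for go trials
#'
#' @param trials Classified trial tibble for the Uncertain session.
#' @return List: `design` tibble (stimulus, cumulative_history,
#'   previous_outcome, lick_rate) and `go_idx`, the go-cue trial indices
#'   the rows correspond to.
#' @export
task_variable_design <- function(trials) {
  stopifnot("outcome_class" %in% names(trials))
  unexpected <- trials$outcome_class %in% c("RO", "UR")
  n_unexp <- sum(unexpected)
  cum_hist <- if (n_unexp > 0) {
    dplyr::lag(cumsum(unexpected), default = 0L) / n_unexp
  } else rep(0, nrow(trials))
  prev_unexp <- dplyr::lag(as.numeric(unexpected), default = 0)
  go_idx <- which(trials$trial_type %in% c("go", "RO"))
  tibble_out <- tibble::tibble(
    stimulus = 1,
    cumulative_history = cum_hist[go_idx],
    previous_outcome = prev_unexp[go_idx],
    lick_rate = stimulus_window_lick_rate(trials)[go_idx]
  )
  list(design = tibble_out, go_idx = go_idx)
}

# licks/s inside the stimulus window [0, 1). Lick times are not stored
# individually, so licks are taken as spread at a constant rate over 1.5 s
# from the first lick; the in-window fraction of that span scales n_licks.
stimulus_window_lick_rate <- function(trials, span = 1.5) {
  fl <- trials$first_lick_s
  nl <- trials$n_licks
  rate <- ifelse(is.na(fl) | nl == 0, 0,
                 nl / span * pmax(0, pmin(1, fl + span) - pmax(0, fl)))
  as.numeric(rate)
}

#' Group-level tests on per-neuron history coefficients
#'
#' One-sample two-sided Wilcoxon signed-rank of the lag-`lag` weights
#' against zero across neurons, and (when two sessions are present) a
#' rank-sum comparison of the two sessions' weight sets.
#'
#' @param fits Tibble of tidied history fits (columns `neuron_id`,
#'   `term`, `estimate`, optionally `session`).
#' @param lag Lag index (1..5).
#' @return Tibble with the one-sample test per session and, if
#'   applicable, the between-session test (`session = "between"`).
#' @export
group_coefficient_test <- function(fits, lag = 1) {
  term_lab <- paste0("w", lag)
  w <- dplyr::filter(fits, .data$term == term_lab)
  if (!"session" %in% names(w)) w$session <- "all"
  by_ses <- split(w$estimate, w$session)
  for (v in by_ses) {
    if (length(v) < 6) {
      abort("need at least 6 neurons per group", class = "accvi_data_error")
    }
  }
  out <- purrr::map_dfr(names(by_ses), function(s) {
    v <- by_ses[[s]]
    if (length(unique(v)) == 1) {
      warn("all coefficients identical: degenerate signed-rank test")
      p <- NA_real_
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(v, mu = 0, exact = FALSE)$p.value)
    }
    tibble::tibble(session = s, lag = lag, n = length(v),
                   median_w = median(v), p_value = p,
                   test = "signed-rank vs 0")
  })
  if (length(by_ses) == 2) {
    p2 <- suppressWarnings(
      stats::wilcox.test(by_ses[[1]], by_ses[[2]], exact = FALSE)$p.value)
    out <- dplyr::bind_rows(out, tibble::tibble(
      session = "between", lag = lag, n = length(w$estimate),
      median_w = NA_real_, p_value = p2, test = "rank-sum between sessions"))
  }
  out
}
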