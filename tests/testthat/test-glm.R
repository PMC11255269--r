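test_that("history OLS matches the normal-equations oracle", {
  # tiny 8-trial example, solved independently via solve(X'X, X'y)
  set.seed(31)
  o <- c(1, 0, 0, 1, 0, 1, 1, 0)
  y <- rnorm(8)
  fit <- fit_outcome_history(y, o, lags = 2)
  X <- cbind(1, c(NA, o[1:7]), c(NA, NA, o[1:6]))
  keep <- complete.cases(X)
  beta <- solve(crossprod(X[keep, ]), crossprod(X[keep, ], y[keep]))
  expect_equal(unname(c(fit$intercept, fit$weights)), drop(beta),
               tolerance = 1e-10)
  # random small problems
  for (i in 1:15) {
    n <- sample(20:60, 1)
    o2 <- rbinom(n, 1, 0.5); y2 <- rnorm(n)
    f2 <- fit_outcome_history(y2, o2, lags = 3)
    X2 <- cbind(1, c(NA, o2[-n]), c(NA, NA, o2[1:(n - 2)]),
                c(NA, NA, NA, o2[1:(n - 3)]))
    k2 <- complete.cases(X2)
    b2 <- solve(crossprod(X2[k2, ]), crossprod(X2[k2, ], y2[k2]))
    expect_equal(unname(c(f2$intercept, f2$weights)), drop(b2),
                 tolerance = 1e-10)
  }
})

test_that("planted history weights are recovered and nulls stay null", {
  set.seed(32)
  w <- c(0.5, 0.3, 0, 0, 0)
  o <- rbinom(300, 1, 0.4)
  X <- matrix(NA_real_, 300, 5)
  for (j in 1:5) X[(j + 1):300, j] <- o[1:(300 - j)]
  lin <- X %*% w
  y <- 0.2 + ifelse(is.na(lin), 0, lin) + rnorm(300, sd = 0.1)
  fit <- fit_outcome_history(y, o)
  expect_true(all(abs(fit$weights - w) < 0.05))
  # pure-noise responses: every |w| within 2 standard errors of zero
  y0 <- rnorm(300, sd = 0.1)
  f0 <- fit_outcome_history(y0, o)
  expect_true(all(abs(f0$weights) < 2.5 * f0$se[-1]))
  # constant outcomes make the design rank-deficient
  expect_warning(fr <- fit_outcome_history(rnorm(50), rep(1, 50)),
                 "rank-deficient")
  expect_true(fr$rank_deficient)
  expect_error(fit_outcome_history(rnorm(5), rbinom(5, 1, 0.5)),
               class = "accvi_data_error")
})

test_that("task-variable contributions isolate the informative regressor", {
  set.seed(33)
  n <- 200
  design <- tibble::tibble(
    stimulus = 1,
    cumulative_history = seq(0, 1, length.out = n),
    previous_outcome = rbinom(n, 1, 0.2),
    lick_rate = runif(n, 0, 6))
  y <- 0.5 + 2 * design$cumulative_history + rnorm(n, sd = 0.1)
  fit <- fit_task_variables(y, design, seed = 2)
  c_hist <- variable_contribution(fit, "cumulative_history")
  c_lick <- variable_contribution(fit, "lick_rate")
  expect_gt(fit$r2_full, 0.9)
  expect_equal(c_hist, fit$r2_full, tolerance = 0.1)
  expect_lt(abs(c_lick), 0.02)
  expect_error(variable_contribution(fit, "weather"),
               class = "accvi_config_error")
  # contributions are fold-deterministic given the seed
  fit2 <- fit_task_variables(y, design, seed = 2)
  expect_equal(variable_contribution(fit2, "cumulative_history"), c_hist)
  # a duplicated regressor raises the rank flag
  dup <- dplyr::mutate(design, copy = .data$cumulative_history)
  expect_warning(fd <- fit_task_variables(y, dup, seed = 2),
                 "rank-deficient")
  expect_true(fd$rank_deficient)
  # an all-zero response cannot have positive held-out explained variance
  expect_lte(fit_task_variables(rep(0, n), design, seed = 2)$r2_full, 0)
})

test_that("orthogonal regressor contributions sum to about r2_full", {
  set.seed(34)
  n <- 400
  X <- qr.Q(qr(matrix(rnorm(n * 3), n)))  # orthonormal columns
  design <- tibble::tibble(a = X[, 1], b = X[, 2], c = X[, 3])
  y <- 1.5 * X[, 1] + 1.0 * X[, 2] + 0.8 * X[, 3] + rnorm(n, sd = 0.05)
  fit <- fit_task_variables(y, design, seed = 5)
  total <- sum(vapply(c("a", "b", "c"), variable_contribution,
                      numeric(1), fit = fit))
  expect_equal(total, fit$r2_full, tolerance = 0.02)
})

test_that("group coefficient tests detect planted shifts and demand n >= 6", {
  set.seed(35)
  mk_fits <- function(mu, ses, n = 30) {
    tidyr::crossing(neuron_id = sprintf("%s%02d", ses, 1:n),
                    term = paste0("w", 1:5)) |>
      dplyr::mutate(estimate = rnorm(dplyr::n(), mean = mu, sd = 0.1),
                    session = ses)
  }
  shifted <- mk_fits(0.3, "A")
  out <- group_coefficient_test(shifted, lag = 1)
  expect_lt(out$p_value[out$session == "A"], 0.05)
  both <- dplyr::bind_rows(mk_fits(0.0, "A"), mk_fits(0.4, "B"))
  out2 <- group_coefficient_test(both, lag = 2)
  expect_true("between" %in% out2$session)
  expect_lt(out2$p_value[out2$session == "between"], 0.05)
  tiny <- mk_fits(0, "A", n = 4)
  expect_error(group_coefficient_test(tiny, lag = 1),
               class = "accvi_data_error")
})

test_that("task-variable design builds the documented regressors", {
  d <- session_design("Uncertain", 60)
  tr <- generate_session_trials(d, seed = 3)
  tr <- simulate_agent_behavior(tr, seed = 3)
  tv <- task_variable_design(tr)
  expect_equal(nrow(tv$design), length(tv$go_idx))
  expect_true(all(tv$design$cumulative_history >= 0 &
                    tv$design$cumulative_history <= 1))
  expect_true(all(tv$design$previous_outcome %in% c(0, 1)))
  # cumulative history is non-decreasing in trial order
  expect_true(all(diff(tv$design$cumulative_history) >= 0))
})
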