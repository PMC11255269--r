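test_that("the 2-fold rule follows the printed inequality", {
  expect_true(twofold_rule(0.5, 0.2))    # 0.3 > 0.2
  expect_false(twofold_rule(0.3, 0.3))   # boundary: 0 > 0.3 is false
  expect_true(twofold_rule(0.1, -0.3))   # 0.4 > 0.3, negative-baseline case
  expect_false(twofold_rule(0.39, 0.2))  # just under 2-fold
  # monotone in r_high for fixed r_low
  r_lo <- 0.2
  passed <- twofold_rule(seq(0, 1, by = 0.05), r_lo)
  expect_true(all(diff(as.integer(passed)) >= 0))
})

test_that("selectivity index matches a brute-force pooled-variance oracle", {
  go <- c(1, 2, 3); ng <- c(0, 1, 2)
  r <- selectivity_index(go, ng)
  expect_equal(r$sigma_p, 1)
  expect_equal(r$si, 1)
  # identical distributions give SI = 0; swapping flips the sign
  same <- selectivity_index(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$si, 0)
  expect_equal(selectivity_index(ng, go)$si, -r$si)
  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1))
    oracle_sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                        (length(a) + length(b) - 2))
    out <- selectivity_index(a, b)
    expect_equal(out$si, (mean(a) - mean(b)) / oracle_sp, tolerance = 1e-12)
  }
  deg <- selectivity_index(c(1, 1), c(1, 1))
  expect_false(deg$defined)
})

test_that("the SI permutation test flags planted preferences", {
  set.seed(10)
  go <- rnorm(30, mean = 3); ng <- rnorm(30, mean = 0)
  r <- si_permutation_test(go, ng, n_perm = 500, seed = 2)
  expect_true(r$significant)
  expect_lt(r$p_perm, 0.05)
  expect_error(si_permutation_test(go, ng, n_perm = 0),
               class = "accvi_config_error")
  expect_warning(si_permutation_test(rnorm(4), rnorm(4), n_perm = 50,
                                     seed = 1),
                 "resolution")
})

test_that("Venn percentages recompute from counts by round-half-up", {
  lab <- tibble::tibble(
    outcome_monitoring = rep(c(TRUE, FALSE), c(179, 549 - 179)),
    value_updating = rep(c(FALSE, TRUE, FALSE), c(100, 118, 331)),
    dual = rep(FALSE, 549))
  lab$dual <- lab$outcome_monitoring & lab$value_updating
  v <- venn_summary(lab, n_total = 549)
  expect_equal(v$pct_monitoring, 33L)
  expect_equal(v$pct_updating, 21L)
  # disjoint flags give zero dual neurons
  lab2 <- tibble::tibble(outcome_monitoring = c(TRUE, FALSE),
                         value_updating = c(FALSE, TRUE),
                         dual = c(FALSE, FALSE))
  expect_equal(venn_summary(lab2)$n_dual, 0)
  expect_error(venn_summary(lab2[0, ]), class = "accvi_data_error")
  # rational-arithmetic oracle for the rounding
  for (i in 1:20) {
    k <- sample(0:500, 1); n <- sample(500:600, 1)
    lab3 <- tibble::tibble(outcome_monitoring = rep(c(TRUE, FALSE),
                                                    c(k, n - k)),
                           value_updating = FALSE, dual = FALSE)
    expect_equal(venn_summary(lab3, n_total = n)$pct_monitoring,
                 as.integer(floor(100 * k / n + 0.5)))
  }
})

test_that("classification recovers planted flags on low-noise data", {
  cfg <- run_config(seed = 6, n_neurons = 40,
                    session_designs = list(
                      Uncertain = session_design("Uncertain", 150)))
  ds <- simulate_dataset(cfg, effect_spec = list(noise_sd = 0.02))
  ca <- process_calcium(ds$fluo$Uncertain, cfg)
  rs <- test_responsiveness(ca,
                            trials = which(ds$trials$Uncertain$stimulus != "none"))
  lab <- quiet(classify_functional(ca, ds$trials$Uncertain, "Uncertain",
                                   responsive_only =
                                     rs$neuron_id[rs$direction != "none"]))
  got <- unname(!is.na(lab$outcome_monitoring) & lab$outcome_monitoring)
  expect_equal(got, ds$truth$outcome_monitoring)
  got_u <- unname(!is.na(lab$value_updating) & lab$value_updating)
  expect_equal(got_u, ds$truth$value_updating)
  expect_equal(unname(!is.na(lab$dual) & lab$dual), ds$truth$dual)
  # stored means satisfy the rule exactly as flagged
  ok <- !is.na(lab$outcome_monitoring)
  expect_equal(lab$outcome_monitoring[ok],
               twofold_rule(lab$mon_r_high[ok], lab$mon_r_low[ok]))
})

test_that("an all-flat population yields no functional flags", {
  cfg <- run_config(seed = 2, n_neurons = 10,
                    session_designs = list(
                      Uncertain = session_design("Uncertain", 120)))
  ds <- simulate_dataset(cfg,
                         class_mix = c(monitoring = 0, updating = 0, dual = 0),
                         effect_spec = list(responsive_frac = 1))
  ca <- process_calcium(ds$fluo$Uncertain, cfg)
  lab <- quiet(classify_functional(ca, ds$trials$Uncertain, "Uncertain"))
  expect_equal(sum(lab$outcome_monitoring, na.rm = TRUE), 0)
  expect_equal(sum(lab$value_updating, na.rm = TRUE), 0)
})
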