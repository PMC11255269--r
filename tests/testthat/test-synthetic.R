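test_that("trial-type counts match the session composition exactly", {
  u <- type_counts(session_design("Uncertain", 100))
  expect_equal(u, c(go = 40L, nogo = 40L, RO = 10L, UR = 10L))
  s <- type_counts(session_design("Stable", 2))
  expect_equal(s, c(go = 1L, nogo = 1L))
  # largest-remainder keeps the sum exact at awkward n
  for (n in c(7, 23, 97, 149)) {
    expect_equal(sum(type_counts(session_design("Uncertain", n))), n)
  }
  tr <- generate_session_trials(session_design("Uncertain", 100), seed = 3)
  expect_equal(sort(as.integer(table(tr$trial_type))),
               c(10L, 10L, 40L, 40L))
  expect_true(all(tr$iti_s >= 4 & tr$iti_s <= 6))
  tr2 <- generate_session_trials(session_design("Uncertain", 100), seed = 3)
  expect_identical(tr$trial_type, tr2$trial_type)
  expect_error(
    session_design("Stable", proportions = c(go = 0.6, nogo = 0.6)),
    class = "accvi_config_error")
  expect_error(session_design("Warmup"), class = "accvi_config_error")
})

test_that("agent behavior follows the SARSA policy on 3 kHz trials", {
  d <- session_design("Stable", 80)
  tr <- generate_session_trials(d, seed = 2)
  out <- simulate_agent_behavior(tr, seed = 2)
  # the first modelled trial licks with P from Q0 and beta: ~0.901
  first_p <- out$p_lick[!is.na(out$p_lick)][1]
  expect_equal(first_p, 0.9010, tolerance = 1e-4)
  # argmax limit: beta -> inf licks every 3 kHz trial
  hard <- simulate_agent_behavior(tr, rl_params(beta = 1e6), seed = 2)
  expect_true(all(hard$action[hard$stimulus == "3kHz"] == "lick"))
  # determinism
  out2 <- simulate_agent_behavior(tr, seed = 2)
  expect_identical(out$action, out2$action)
  expect_identical(out$q_lick, out2$q_lick)
  # early Stable hit rate is high (policy starts near 0.9)
  expect_gt(performance_summary(out)$hit_rate, 0.8)
})

test_that("population generation plants the documented class counts", {
  tru <- generate_population(549, seed = 8)
  expect_equal(sum(tru$outcome_monitoring), 181)
  expect_equal(sum(tru$value_updating), 115)
  expect_equal(sum(tru$dual), 38)
  expect_true(all(tru$dual == (tru$outcome_monitoring & tru$value_updating)))
  # planted gains respect the 2-fold rule with margin in expectation
  expect_true(all(tru$mon_gain[tru$outcome_monitoring] > 2))
  expect_true(all(tru$upd_gain[tru$value_updating] > 2))
  expect_identical(tru, generate_population(549, seed = 8))
  expect_error(
    generate_population(50, class_mix = c(monitoring = 0.1, updating = 0.1,
                                          dual = 0.5)),
    class = "accvi_config_error")
  one <- generate_population(1, class_mix = c(monitoring = 0, updating = 0,
                                              dual = 0),
                             effect_spec = list(responsive_frac = 0))
  expect_equal(one$amp_cue_go, 0)
})

test_that("rendered transients match the closed-form kernel", {
  cfg <- run_config()
  d <- session_design("Stable", 6)
  tr <- generate_session_trials(d, seed = 1)
  tr <- simulate_agent_behavior(tr, seed = 1)
  tr <- assign_periods(split_phases(tr, d$phase_fractions), d$early_phases)
  # zero amplitudes, zero noise -> constant traces at the baseline level
  flat <- generate_population(3, class_mix = c(monitoring = 0, updating = 0,
                                               dual = 0),
                              effect_spec = list(noise_sd = 0,
                                                 responsive_frac = 0))
  F0 <- render_fluorescence(tr, flat, cfg, seed = 1)
  expect_true(all(F0$F == 1))
  # a single cue event: peak ~ A then exponential decay with tau
  tru <- generate_population(1, class_mix = c(monitoring = 0, updating = 0,
                                              dual = 0),
                             effect_spec = list(noise_sd = 0,
                                                responsive_frac = 1,
                                                history_base = rep(0, 5),
                                                amp_cue_go = c(0.5, 0.5)))
  tr1 <- tr[tr$trial_type == "nogo" & is.na(tr$first_lick_s), ][1, ]
  tr1$stimulus <- "3kHz"  # cue event only, no outcome event
  F1 <- render_fluorescence(tr1, tru, cfg, seed = 1)
  trace <- F1$F[1, 1, ]
  t <- accvi:::frame_times(length(trace), 30, F1$t0_frame)
  expected <- 1 + 0.5 * exp(-pmax(t, 0) / 0.4) * (t >= 0)
  expect_equal(trace, expected, tolerance = 1e-12)
})

test_that("planted monitoring neurons exceed the 2-fold margin on average", {
  cfg <- run_config()
  d <- session_design("Uncertain", 150)
  tr <- generate_session_trials(d, seed = 4)
  tr <- simulate_agent_behavior(tr, seed = 4)
  tr <- assign_periods(split_phases(tr, d$phase_fractions), d$early_phases)
  tru <- generate_population(20, class_mix = c(monitoring = 0.5,
                                               updating = 0, dual = 0),
                             seed = 4)
  fl <- render_fluorescence(tr, tru, cfg, seed = 4)
  ca <- process_calcium(fl, cfg)
  ro <- which(tr$outcome_class == "RO"); hit <- which(tr$outcome_class == "Hit")
  r_ro <- rowMeans(window_mean(ca, c(0, 1), ro, tr$outcome_time_s[ro]))
  r_hit <- rowMeans(window_mean(ca, c(0, 1), hit, tr$outcome_time_s[hit]))
  mon <- tru$outcome_monitoring
  expect_true(all(r_ro[mon] - r_hit[mon] > abs(r_hit[mon])))
  expect_gt(mean(r_ro[mon] / r_hit[mon]), 2)
})
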