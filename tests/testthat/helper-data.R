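# small fixtures built in code; no stored data

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# minimal two-session dataset for I/O round trips
make_tiny_dataset <- function(n_neurons = 2, n_trials = 4, n_frames = 12,
                              seed = 1) {
  set.seed(seed)
  tr <- tibble::tibble(
    session = "Stable",
    trial_index = seq_len(n_trials),
    phase = rep("T1", n_trials),
    stimulus = rep(c("3kHz", "12kHz"), length.out = n_trials),
    trial_type = rep(c("go", "nogo"), length.out = n_trials),
    action = rep(c("lick", "nolick"), length.out = n_trials),
    outcome = rep(c("reward", "none"), length.out = n_trials),
    first_lick_s = ifelse(seq_len(n_trials) %% 2 == 1, 1.2, NA),
    n_licks = ifelse(seq_len(n_trials) %% 2 == 1, 5L, 0L)
  )
  F <- array(runif(n_neurons * n_trials * n_frames),
             dim = c(n_neurons, n_trials, n_frames))
  fl <- fluo_tensor(F, frame_rate = 30, t0_frame = 7)
  accvi:::new_dataset(list(Stable = tr), list(Stable = fl))
}

# dff_tensor built directly from an array (for geometry/decoding tests)
make_dff_tensor <- function(z, frame_rate = 30, t0_frame = NULL) {
  d <- dim(z)
  t0_frame <- t0_frame %||% (d[3] %/% 2 + 1)
  structure(list(dff = z, zscored = z,
                 valid = matrix(TRUE, d[1], d[2]),
                 f0 = matrix(1, d[1], d[2]),
                 frame_rate = frame_rate, t0_frame = t0_frame,
                 neuron_ids = sprintf("n%03d", seq_len(d[1]))),
            class = "dff_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
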