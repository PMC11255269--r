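trial_csv_columns <- c("session", "trial_index", "phase", "stimulus",
                       "trial_type", "action", "outcome", "first_lick_s",
                       "n_licks")

#' Write a dataset to disk (trial CSV + fluorescence HDF5)
#'
#' One CSV row per trial (documented columns plus any extras present) and
#' one HDF5 file with dataset `F` (neurons x trials x frames, one group
#' per session) and attributes `frame_rate`, `t0_frame`.
#'
#' @param dataset An `accvi_dataset`.
#' @param trials_path CSV path.
#' @param fluo_path HDF5 path.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, trials_path, fluo_path) {
  stopifnot(inherits(dataset, "accvi_dataset"))
  readr::write_csv(dplyr::bind_rows(dataset$trials), trials_path)
  if (file.exists(fluo_path)) file.remove(fluo_path)
  rhdf5::h5createFile(fluo_path)
  for (nm in names(dataset$fluo)) {
    fl <- dataset$fluo[[nm]]
    grp <- paste0("/", nm)
    rhdf5::h5createGroup(fluo_path, grp)
    rhdf5::h5write(fl$F, fluo_path, paste0(grp, "/F"))
    rhdf5::h5write(fl$frame_rate, fluo_path, paste0(grp, "/frame_rate"))
    rhdf5::h5write(fl$t0_frame, fluo_path, paste0(grp, "/t0_frame"))
    rhdf5::h5write(fl$neuron_ids, fluo_path, paste0(grp, "/neuron_ids"))
  }
  rhdf5::h5closeAll()
  invisible(c(trials = trials_path, fluo = fluo_path))
}

#' Load a dataset from trial CSV + fluorescence HDF5
#'
#' Validates the documented trial schema and the trial-count alignment
#' between the table and every session's fluorescence array.
#'
#' @param trials_path CSV path (documented header; see the trial-table
#'   format in the package vignette).
#' @param fluo_path HDF5 path with per-session groups holding `F`,
#'   `frame_rate`, `t0_frame`, `neuron_ids`.
#' @return An `accvi_dataset`.
#' @export
load_dataset <- function(trials_path, fluo_path) {
  tr <- readr::read_csv(trials_path, show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(trial_csv_columns, names(tr))
  if (length(missing)) {
    abort(paste0("trial CSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "accvi_schema_error")
  }
  sessions <- unique(tr$session)
  h5 <- rhdf5::h5ls(fluo_path)
  fluo <- list(); trials <- list()
  for (nm in sessions) {
    if (!nm %in% h5$name[h5$otype == "H5I_GROUP"]) {
      abort(paste0("fluorescence file lacks a group for session '", nm, "'"),
            class = "accvi_schema_error")
    }
    grp <- paste0("/", nm)
    F <- rhdf5::h5read(fluo_path, paste0(grp, "/F"))
    fr <- as.numeric(rhdf5::h5read(fluo_path, paste0(grp, "/frame_rate")))
    t0 <- as.integer(rhdf5::h5read(fluo_path, paste0(grp, "/t0_frame")))
    ids <- as.character(rhdf5::h5read(fluo_path, paste0(grp, "/neuron_ids")))
    t_ses <- dplyr::filter(tr, .data$session == nm)
    if (nrow(t_ses) != dim(F)[2]) {
      abort(sprintf(
        "session %s: %d trials in table vs %d in fluorescence",
        nm, nrow(t_ses), dim(F)[2]), class = "accvi_alignment_error")
    }
    fluo[[nm]] <- fluo_tensor(F, fr, t0, ids)
    trials[[nm]] <- t_ses
  }
  rhdf5::h5closeAll()
  new_dataset(trials, fluo)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)),
          class = "accvi_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages behavior -> calcium -> classification -> geometry
#' -> decoding -> GLM -> SARSA on a dataset (synthetic data are generated
#' from the configuration when `dataset` is `NULL`), writes per-stage
#' tabular outputs (`performance.csv`, `responsiveness.csv`,
#' `functional_labels.csv`, `geometry_metrics.csv`, `decoding.csv`,
#' `glm_history.csv`, `glm_contributions.csv`,
#' `learning_rate_summary.csv`) plus a machine-readable `summary.json`
#' into `config$output_dir`. Identical configurations give byte-identical
#' summaries.
#'
#' @param config A [run_config()].
#' @param dataset Optional `accvi_dataset`.
#' @return Invisibly, a list with all stage results and `output_dir`.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir %||% tempfile("accvi_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, file) {
    readr::write_csv(df, file.path(out_dir, file))
  }
  if (is.null(dataset)) {
    dataset <- run_stage("simulate", simulate_dataset(config))
  }
  # --- behavior ---------------------------------------------------------
  behavior <- run_stage("behavior", {
    purrr::map_dfr(names(dataset$trials), function(nm) {
      tr <- dataset$trials[[nm]]
      ses <- performance_summary(tr, scope = nm)
      phases <- purrr::map_dfr(unique(tr$phase), function(ph) {
        sub <- dplyr::filter(tr, .data$phase == ph)
        # a short phase can lack go or no-go trials; rates are undefined there
        if (!any(sub$trial_type %in% c("go", "RO")) ||
            !any(sub$trial_type == "nogo")) {
          return(tibble::tibble())
        }
        performance_summary(sub, scope = paste0(nm, "/", ph))
      })
      dplyr::bind_rows(ses, phases)
    })
  })
  emit(behavior, "performance.csv")
  # --- calcium ----------------------------------------------------------
  calcium <- run_stage("calcium", {
    purrr::map(dataset$fluo, process_calcium, config = config)
  })
  responsiveness <- run_stage("calcium", {
    purrr::map_dfr(names(calcium), function(nm) {
      go <- which(dataset$trials[[nm]]$stimulus != "none")
      dplyr::mutate(test_responsiveness(calcium[[nm]],
                                        config$stimulus_window,
                                        config$baseline_dff, trials = go),
                    session = nm, .before = 1)
    })
  })
  emit(responsiveness, "responsiveness.csv")
  # --- classification ---------------------------------------------------
  labels <- run_stage("classification", {
    purrr::map_dfr(intersect(c("Uncertain", "Reversal"), names(calcium)),
                   function(nm) {
                     resp_ids <- responsiveness$neuron_id[
                       responsiveness$session == nm &
                         responsiveness$direction != "none"]
                     classify_functional(calcium[[nm]],
                                         dataset$trials[[nm]], nm,
                                         responsive_only = resp_ids)
                   })
  })
  emit(labels, "functional_labels.csv")
  venn <- purrr::map_dfr(split(labels, labels$session), function(lb) {
    if (!any(!is.na(lb$outcome_monitoring))) return(tibble::tibble())
    venn_summary(lb)
  }, .id = "session")
  # --- geometry ---------------------------------------------------------
  geometry <- run_stage("geometry", {
    purrr::map_dfr(names(calcium), function(nm) {
      tr <- dataset$trials[[nm]]
      conds <- list(go = which(tr$trial_type == "go"),
                    nogo = which(tr$trial_type == "nogo"))
      M <- build_condition_matrix(calcium[[nm]], conds)
      traj <- embed_trajectories(M)
      tibble::tibble(
        session = nm,
        len_go = trajectory_length(traj, "go"),
        len_nogo = trajectory_length(traj, "nogo"),
        dist_go_nogo = trajectory_distance(traj, "go", "nogo"),
        ev1 = traj$explained_variance[1],
        ev_top3 = sum(traj$explained_variance)
      )
    })
  })
  boot_session <- if ("Stable" %in% names(calcium)) "Stable"
                  else names(calcium)[1]
  boot <- run_stage("geometry", {
    tr <- dataset$trials[[boot_session]]
    conds <- list(go = which(tr$trial_type == "go"),
                  nogo = which(tr$trial_type == "nogo"))
    bootstrap_trajectory_metric(calcium[[boot_session]], conds, "distance",
                                n_iter = config$geometry_boot,
                                subset_size = min(40, length(dataset$neuron_ids)),
                                seed = config$seed)
  })
  geometry$boot_dist_median <- ifelse(geometry$session == boot_session,
                                      median(boot$value), NA_real_)
  emit(geometry, "geometry_metrics.csv")
  # --- decoding ---------------------------------------------------------
  decoding <- run_stage("decoding", {
    nm <- if ("Uncertain" %in% names(calcium)) "Uncertain"
          else names(calcium)[1]
    tr <- dataset$trials[[nm]]
    keep <- tr$stimulus != "none"
    resp <- window_mean(calcium[[nm]], config$stimulus_window,
                        use = "zscored")
    scopes <- split(which(keep), tr$phase[keep])
    res <- list()
    for (a in names(scopes)) {
      for (b in names(scopes)) {
        xa <- t(resp[, scopes[[a]], drop = FALSE])
        ya <- tr$stimulus[scopes[[a]]]
        if (a == b) {
          r <- decode(xa, ya, scheme = "within",
                      n_repeats = config$decoding_repeats,
                      seed = config$seed, train_scope = a)
        } else {
          xb <- t(resp[, scopes[[b]], drop = FALSE])
          yb <- tr$stimulus[scopes[[b]]]
          r <- decode(xa, ya, xb, yb, scheme = "cross",
                      n_repeats = config$decoding_repeats,
                      seed = config$seed, train_scope = a,
                      test_scope = b)
        }
        res[[paste(a, b)]] <- glance(r)
      }
    }
    dplyr::bind_rows(res)
  })
  emit(decoding, "decoding.csv")
  # --- GLM --------------------------------------------------------------
  glm_hist <- run_stage("glm", {
    purrr::map_dfr(intersect(c("Stable", "Re-stable"), names(calcium)),
                   function(nm) {
      tr <- dataset$trials[[nm]]
      hit <- which(tr$outcome_class == "Hit")
      resp <- window_mean(calcium[[nm]], config$stimulus_window,
                          use = "zscored")
      o <- as.numeric(!tr$outcome_class %in% c("Hit", "UR"))
      purrr::map_dfr(seq_len(nrow(resp)), function(i) {
        # history over all trials, responses taken on Hit trials
        f <- fit_outcome_history(resp[i, hit], o[hit],
                                 neuron_id = rownames(resp)[i])
        dplyr::mutate(tidy(f), session = nm)
      })
    })
  })
  emit(glm_hist, "glm_history.csv")
  contrib <- run_stage("glm", {
    if (!"Uncertain" %in% names(calcium)) return(tibble::tibble())
    tr <- dataset$trials[["Uncertain"]]
    tv <- task_variable_design(tr)
    resp <- window_mean(calcium[["Uncertain"]], config$stimulus_window)
    vars <- c("cumulative_history", "previous_outcome", "lick_rate")
    purrr::map_dfr(seq_len(nrow(resp)), function(i) {
      fit <- fit_task_variables(resp[i, tv$go_idx], tv$design,
                                seed = config$seed,
                                neuron_id = rownames(resp)[i])
      tibble::tibble(neuron_id = rownames(resp)[i],
                     r2_full = fit$r2_full,
                     variable = vars,
                     contribution = vapply(vars, variable_contribution,
                                           numeric(1), fit = fit))
    })
  })
  emit(contrib, "glm_contributions.csv")
  # --- SARSA ------------------------------------------------------------
  sarsa <- run_stage("sarsa", {
    sims <- purrr::map(names(config$session_designs), function(nm) {
      simulate_session(config$session_designs[[nm]],
                       rl_params(beta = default_beta(nm)),
                       n_repeats = config$sarsa_repeats,
                       seed = config$seed)
    })
    learning_rate_summary(sims)
  })
  emit(sarsa, "learning_rate_summary.csv")
  # --- summary ----------------------------------------------------------
  summary <- list(
    seed = config$seed,
    sessions = names(dataset$trials),
    n_neurons = length(dataset$neuron_ids),
    behavior = behavior[behavior$scope %in% names(dataset$trials),
                        c("scope", "hit_rate", "fa_rate", "dprime")],
    venn = venn,
    mean_alpha = sarsa[, c("session", "phase", "mean_alpha")],
    decoding_mean = mean(decoding$mean_accuracy)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "columns")
  invisible(list(dataset = dataset, behavior = behavior,
                 responsiveness = responsiveness, labels = labels,
                 venn = venn, geometry = geometry, bootstrap = boot,
                 decoding = decoding, glm_history = glm_hist,
                 glm_contributions = contrib, sarsa = sarsa,
                 output_dir = out_dir))
}
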