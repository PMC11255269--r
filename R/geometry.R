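#' Build the condition-by-time population matrix for PCA
#'
#' For each condition, the z-scored responses are trial-averaged per
#' neuron and frame over the analysis window (default -0.5 to 1 s around
#' stimulus onset); condition blocks are stacked row-wise
#' (time x condition rows, neuron columns) and columns are centered so a
#' single PCA embeds all conditions in one shared space.
#'
#' @param dff A `dff_tensor`.
#' @param conditions Named list of integer trial selections (every
#'   condition needs >= 1 trial).
#' @param window Seconds, default `c(-0.5, 1)`.
#' @param neurons Optional integer subset of neurons.
#' @return Numeric matrix with attributes `condition` and `time_s`
#'   labelling the rows.
#' @export
build_condition_matrix <- function(dff, conditions, window = c(-0.5, 1),
                                   neurons = NULL) {
  stopifnot(inherits(dff, "dff_tensor"), length(conditions) >= 1,
            !is.null(names(conditions)))
  d <- dim(dff$zscored)
  neurons <- neurons %||% seq_len(d[1])
  idx <- frames_in_window(d[3], dff$frame_rate, dff$t0_frame, window)
  blocks <- list(); cond_lab <- c(); time_lab <- c()
  tt <- frame_times(d[3], dff$frame_rate, dff$t0_frame)[idx]
  for (nm in names(conditions)) {
    tr <- conditions[[nm]]
    if (length(tr) == 0) {
      abort(paste0("condition '", nm, "' has no trials"),
            class = "accvi_data_error")
    }
    sub <- dff$zscored[neurons, tr, idx, drop = FALSE]
    avg <- apply(sub, c(1, 3), mean, na.rm = TRUE)  # neurons x frames
    blocks[[nm]] <- t(avg)
    cond_lab <- c(cond_lab, rep(nm, length(idx)))
    time_lab <- c(time_lab, tt)
  }
  M <- do.call(rbind, blocks)
  M <- sweep(M, 2, colMeans(M))
  attr(M, "condition") <- cond_lab
  attr(M, "time_s") <- time_lab
  M
}

#' PCA embedding of population trajectories
#'
#' Singular value decomposition of the column-centered condition matrix;
#' scores are the projections of each (condition, time) row on the
#' principal components.
#'
#' @param mat Output of [build_condition_matrix()].
#' @param n_components Number of components to keep (default 3; reduced
#'   with a flag when the matrix rank is lower).
#' @return A `trajectory_result`: `scores` tibble (condition, time_s,
#'   PC1..PCk), `explained_variance`, `loadings`, `rank_deficient`.
#' @export
embed_trajectories <- function(mat, n_components = 3) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  sv <- svd(mat)
  ev <- sv$d^2 / sum(sv$d^2)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  k <- min(n_components, rank)
  rank_deficient <- k < n_components
  scores <- mat %*% sv$v[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- tibble::as_tibble(scores)
  out$condition <- attr(mat, "condition") %||% rep("all", nrow(mat))
  out$time_s <- attr(mat, "time_s") %||% seq_len(nrow(mat))
  out <- dplyr::relocate(out, "condition", "time_s")
  structure(list(scores = out,
                 explained_variance = ev[seq_len(k)],
                 loadings = sv$v[, seq_len(k), drop = FALSE],
                 rank_deficient = rank_deficient),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("<trajectory_result>", length(unique(x$scores$condition)),
      "condition(s);", nrow(x$scores), "time points; var explained:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " "),
      "\n")
  invisible(x)
}

score_matrix <- function(traj, condition = NULL, window = NULL) {
  s <- traj$scores
  if (!is.null(condition)) s <- s[s$condition == condition, , drop = FALSE]
  if (!is.null(window)) {
    s <- s[s$time_s >= window[1] & s$time_s < window[2], , drop = FALSE]
  }
  as.matrix(s[, grep("^PC", names(s)), drop = FALSE])
}

#' Trajectory path length in PC space
#'
#' Sum of Euclidean distances between consecutive time points (components
#' PC1-3 by default) over the in-window frames.
#'
#' @param traj A `trajectory_result` (or a plain time x components matrix).
#' @param condition Condition label to extract (required for
#'   multi-condition results).
#' @param window Seconds, default `c(0, 1)` (the stimulus window).
#' @return Scalar length.
#' @export
trajectory_length <- function(traj, condition = NULL, window = c(0, 1)) {
  S <- if (is.matrix(traj)) traj else score_matrix(traj, condition, window)
  if (nrow(S) < 2) {
    abort("need at least 2 in-window time points", class = "accvi_data_error")
  }
  sum(sqrt(rowSums((S[-1, , drop = FALSE] -
                      S[-nrow(S), , drop = FALSE])^2)))
}

#' Distance between two trajectories
#'
#' Sum of Euclidean distances between pairwise time points of the two
#' trajectories over the in-window frames.
#'
#' @param traj A `trajectory_result`, with `condition_a`/`condition_b`
#'   naming the two trajectories; or a matrix paired with `b`.
#' @param condition_a,condition_b Condition labels.
#' @param window Seconds, default `c(0, 1)`.
#' @param b Second matrix when `traj` is a matrix.
#' @return Scalar distance (symmetric; 0 for identical trajectories).
#' @export
trajectory_distance <- function(traj, condition_a = NULL, condition_b = NULL,
                                window = c(0, 1), b = NULL) {
  if (is.matrix(traj)) {
    A <- traj; B <- b
  } else {
    A <- score_matrix(traj, condition_a, window)
    B <- score_matrix(traj, condition_b, window)
  }
  if (!all(dim(A) == dim(B))) {
    abort("trajectories must share the same time grid",
          class = "accvi_data_error")
  }
  sum(sqrt(rowSums((A - B)^2)))
}

#' Bootstrap distribution of a trajectory metric
#'
#' Repeats `n_iter` times: sample `subset_size` neurons (without
#' replacement by default), rebuild the condition matrix, re-fit the PCA
#' (or re-use the full-population loadings with `refit = FALSE`), and
#' recompute the metric.
#'
#' @param dff A `dff_tensor`.
#' @param conditions Named list of trial selections (see
#'   [build_condition_matrix()]).
#' @param metric `"length"` (per condition) or `"distance"` (between the
#'   first two conditions).
#' @param n_iter Bootstrap iterations (default 5000).
#' @param subset_size Neurons per draw (default 40).
#' @param replace Sample neurons with replacement (default FALSE).
#' @param refit Re-fit the PCA inside each draw (default TRUE).
#' @param window Metric window, default `c(0, 1)`.
#' @param pca_window Window for the condition matrix, default `c(-0.5, 1)`.
#' @param seed Integer seed.
#' @return Tibble: iteration, condition (or pair), value.
#' @export
bootstrap_trajectory_metric <- function(dff, conditions,
                                        metric = c("length", "distance"),
                                        n_iter = 5000, subset_size = 40,
                                        replace = FALSE, refit = TRUE,
                                        window = c(0, 1),
                                        pca_window = c(-0.5, 1),
                                        seed = 1L) {
  metric <- match.arg(metric)
  n_pop <- dim(dff$zscored)[1]
  if (n_pop < subset_size) {
    abort("population smaller than the bootstrap subset size",
          class = "accvi_data_error")
  }
  full_loadings <- NULL
  if (!refit) {
    M <- build_condition_matrix(dff, conditions, pca_window)
    full_loadings <- embed_trajectories(M)$loadings
  }
  with_substream(seed, "geometry/bootstrap", {
    purrr::map_dfr(seq_len(n_iter), function(it) {
      sel <- sample.int(n_pop, subset_size, replace = replace)
      M <- build_condition_matrix(dff, conditions, pca_window, neurons = sel)
      traj <- if (refit) {
        embed_trajectories(M)
      } else {
        sc <- M %*% full_loadings[sel, , drop = FALSE]
        colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
        s <- tibble::as_tibble(sc)
        s$condition <- attr(M, "condition"); s$time_s <- attr(M, "time_s")
        structure(list(scores = s), class = "trajectory_result")
      }
      if (metric == "length") {
        tibble::tibble(iteration = it, condition = names(conditions),
                       value = vapply(names(conditions), function(nm)
                         trajectory_length(traj, nm, window), numeric(1)))
      } else {
        nms <- names(conditions)[1:2]
        tibble::tibble(iteration = it,
                       condition = paste(nms, collapse = "-"),
                       value = trajectory_distance(traj, nms[1], nms[2],
                                                   window))
      }
    })
  })
}

#' Pairwise Pearson correlation of trial-averaged population vectors
#'
#' Per group, each neuron's response is trial-averaged over the window;
#' the correlation between two groups is the Pearson r of the two
#' neuron-indexed vectors.
#'
#' @param dff A `dff_tensor`.
#' @param groups Named list of trial selections.
#' @param window Seconds, default `c(0, 1)`.
#' @param use Array to use, `"zscored"` (default) or `"dff"`.
#' @return Correlation matrix (groups x groups); zero-variance vectors
#'   give `NA` entries with a warning.
#' @export
population_correlation <- function(dff, groups, window = c(0, 1),
                                   use = "zscored") {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  vecs <- vapply(groups, function(tr) {
    rowMeans(window_mean(dff, window, trials = tr, use = use), na.rm = TRUE)
  }, numeric(dim(dff$zscored)[1]))
  sds <- apply(vecs, 2, sd)
  if (any(sds == 0)) warn("zero-variance group vector: NA correlations")
  suppressWarnings(cor(vecs))
}
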