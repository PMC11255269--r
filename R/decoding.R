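# Linear maximum-margin classifier (L1-loss SVM, dual coordinate descent,
# the liblinear algorithm), fixed C = 1, bias handled as an augmented
# constant feature. No SVM package is available in the target environment,
# so the solver lives here, behind the decoding interface.
svm_train <- function(X, y, C = 1, max_pass = 60, tol = 1e-3) {
  stopifnot(is.matrix(X), all(y %in% c(-1, 1)))
  n <- nrow(X)
  Xb <- cbind(X, 1)
  d <- ncol(Xb)
  Qd <- rowSums(Xb^2)
  alpha <- numeric(n)
  w <- numeric(d)
  for (pass in seq_len(max_pass)) {
    max_pg <- 0
    ord <- sample.int(n)
    for (i in ord) {
      G <- y[i] * sum(w * Xb[i, ]) - 1
      pg <- if (alpha[i] == 0) min(G, 0)
            else if (alpha[i] == C) max(G, 0)
            else G
      max_pg <- max(max_pg, abs(pg))
      if (abs(pg) > 1e-12) {
        a_old <- alpha[i]
        alpha[i] <- min(max(alpha[i] - G / Qd[i], 0), C)
        if (alpha[i] != a_old) {
          w <- w + (alpha[i] - a_old) * y[i] * Xb[i, ]
        }
      }
    }
    if (max_pg < tol) break
  }
  list(w = w[-d], b = w[d])
}

svm_predict <- function(model, X) {
  sign(drop(X %*% model$w) + model$b)
}

# standardize features on training statistics only
standardize_pair <- function(train, test = NULL) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  tr <- sweep(sweep(train, 2, mu), 2, sdv, "/")
  te <- if (is.null(test)) NULL else sweep(sweep(test, 2, mu), 2, sdv, "/")
  list(train = tr, test = te)
}

# subsample the majority class to balance a binary label vector
balance_classes <- function(y) {
  cls <- unique(y)
  stopifnot(length(cls) == 2)
  i1 <- which(y == cls[1]); i2 <- which(y == cls[2])
  m <- min(length(i1), length(i2))
  sort(c(sample(i1, m), sample(i2, m)))
}

#' Build pseudo-trials from non-simultaneous neurons
#'
#' Neurons pooled across animals were not recorded simultaneously, so
#' population decoding uses pseudo-trials: for each pseudo-trial of class
#' c, every neuron contributes the window-mean of one of its own class-c
#' trials, sampled with replacement. Classes are balanced by construction.
#'
#' @param responses Matrix neurons x trials of window-mean responses.
#' @param labels Trial class labels (length `ncol(responses)`, 2 classes).
#' @param n_pseudo Pseudo-trials per class.
#' @param seed Integer seed.
#' @return List: `x` (pseudo-trials x neurons), `y` (class labels).
#'   Neurons lacking trials of some class are dropped with a warning.
#' @export
build_pseudo_trials <- function(responses, labels, n_pseudo = 50, seed = 1L) {
  stopifnot(is.matrix(responses), length(labels) == ncol(responses))
  cls <- sort(unique(labels))
  stopifnot(length(cls) == 2)
  ok <- apply(responses, 1, function(r) {
    all(vapply(cls, function(c0) any(!is.na(r[labels == c0])), logical(1)))
  })
  if (any(!ok)) {
    warn(sprintf("%d neurons dropped (missing a class)", sum(!ok)))
    responses <- responses[ok, , drop = FALSE]
  }
  n_neu <- nrow(responses)
  with_substream(seed, "decoding/pseudo", {
    xs <- lapply(cls, function(c0) {
      pool <- which(labels == c0)
      m <- matrix(NA_real_, n_pseudo, n_neu)
      for (j in seq_len(n_neu)) {
        good <- pool[!is.na(responses[j, pool])]
        m[, j] <- responses[j, sample(good, n_pseudo, replace = TRUE)]
      }
      m
    })
    list(x = do.call(rbind, xs), y = rep(cls, each = n_pseudo))
  })
}

#' Linear decoding with cross-validation or cross-scope generalization
#'
#' Trains a linear maximum-margin classifier (C = 1; features
#' standardized on the training split only) and reports zero-one
#' accuracies over repeated resampling. `scheme = "within"` uses k-fold
#' cross-validation (default 3-fold: two-thirds train, one-third test);
#' `scheme = "cross"` trains on the source scope and evaluates every
#' test-scope trial, resampling the training set each repeat. Class
#' imbalance is handled by subsampling the majority class per repeat.
#'
#' @param train_x Matrix trials x features.
#' @param train_y Binary labels for `train_x`.
#' @param test_x,test_y Test scope (required for `scheme = "cross"`).
#' @param scheme `"within"` or `"cross"`.
#' @param folds Folds for within-scheme (default 3).
#' @param n_repeats Resampling repeats (default 500).
#' @param seed Integer seed.
#' @param train_scope,test_scope Labels stored in the result.
#' @return A `decode_result`: accuracy samples plus metadata; has
#'   [tidy()], [glance()] and [ggplot2::autoplot()] methods.
#' @export
decode <- function(train_x, train_y, test_x = NULL, test_y = NULL,
                   scheme = c("within", "cross"), folds = 3,
                   n_repeats = 500, seed = 1L,
                   train_scope = "train", test_scope = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(train_x), length(train_y) == nrow(train_x))
  if (length(unique(train_y)) < 2) {
    abort("training set has a single class", class = "accvi_data_error")
  }
  cls <- sort(unique(train_y))
  yn <- ifelse(train_y == cls[2], 1, -1)
  if (scheme == "cross" && (is.null(test_x) || is.null(test_y))) {
    abort("cross-scope decoding needs test data", class = "accvi_data_error")
  }
  acc <- numeric(n_repeats)
  with_substream(seed, paste0("decoding/", scheme), {
    for (r in seq_len(n_repeats)) {
      keep <- balance_classes(train_y)
      Xb <- train_x[keep, , drop = FALSE]; yb <- yn[keep]
      if (scheme == "within") {
        nb <- length(yb)
        if (nb < folds * 2) {
          abort("too few trials per class for the requested folds",
                class = "accvi_data_error")
        }
        fold <- sample(rep(seq_len(folds), length.out = nb))
        hits <- 0; tot <- 0
        for (k in seq_len(folds)) {
          tr <- fold != k
          if (length(unique(yb[tr])) < 2) next
          std <- standardize_pair(Xb[tr, , drop = FALSE],
                                  Xb[!tr, , drop = FALSE])
          m <- svm_train(std$train, yb[tr])
          pred <- svm_predict(m, std$test)
          hits <- hits + sum(pred == yb[!tr]); tot <- tot + sum(!tr)
        }
        acc[r] <- hits / tot
      } else {
        sub <- sample(seq_along(yb), ceiling(2 / 3 * length(yb)))
        if (length(unique(yb[sub])) < 2) sub <- seq_along(yb)
        yt <- ifelse(test_y == cls[2], 1, -1)
        std <- standardize_pair(Xb[sub, , drop = FALSE], test_x)
        m <- svm_train(std$train, yb[sub])
        acc[r] <- mean(svm_predict(m, std$test) == yt)
      }
    }
  })
  structure(list(accuracy_samples = acc, n_repeats = n_repeats,
                 n_neurons_used = ncol(train_x), scheme = scheme,
                 train_scope = train_scope,
                 test_scope = test_scope %||% train_scope,
                 classes = cls, seed = seed),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat("<decode_result> ", x$train_scope, " -> ", x$test_scope, " (",
      x$scheme, "): accuracy ", sprintf("%.3f", mean(x$accuracy_samples)),
      " over ", x$n_repeats, " repeats\n", sep = "")
  invisible(x)
}

#' @method tidy decode_result
#' @export
tidy.decode_result <- function(x, ...) {
  tibble::tibble(train_scope = x$train_scope, test_scope = x$test_scope,
                 scheme = x$scheme,
                 repeat_id = seq_along(x$accuracy_samples),
                 accuracy = x$accuracy_samples)
}

#' @method glance decode_result
#' @export
glance.decode_result <- function(x, ...) {
  q <- quantile(x$accuracy_samples, c(0.025, 0.975), names = FALSE)
  tibble::tibble(train_scope = x$train_scope, test_scope = x$test_scope,
                 scheme = x$scheme,
                 mean_accuracy = mean(x$accuracy_samples),
                 ci_low = q[1], ci_high = q[2],
                 n_repeats = x$n_repeats,
                 n_neurons_used = x$n_neurons_used)
}

#' Decoding with and without a neuron cohort
#'
#' Compares decoding accuracy between (a) the full population and (b) the
#' population minus an excluded set (e.g. dual-function neurons), drawing
#' the same number of neurons from each cohort per repeat so cohort size
#' cannot drive the difference. Each repeat builds fresh pseudo-trials
#' and runs k-fold cross-validation.
#'
#' @param responses Matrix neurons x trials of window-mean responses for
#'   the decoded contrast (rows named by neuron id).
#' @param labels Binary trial labels.
#' @param exclude Character neuron ids excluded from cohort (b).
#' @param n_neurons Neurons drawn per repeat (default 200).
#' @param folds Cross-validation folds (default 5).
#' @param n_repeats Repeats (default 1000).
#' @param n_pseudo Pseudo-trials per class (default 40).
#' @param seed Integer seed.
#' @return Tibble: cohort (`all` / `without_excluded`), repeat_id,
#'   accuracy.
#' @export
compare_subpopulations <- function(responses, labels, exclude,
                                   n_neurons = 200, folds = 5,
                                   n_repeats = 1000, n_pseudo = 40,
                                   seed = 1L) {
  stopifnot(is.matrix(responses), !is.null(rownames(responses)))
  ids <- rownames(responses)
  cohorts <- list(all = ids, without_excluded = setdiff(ids, exclude))
  for (nm in names(cohorts)) {
    if (length(cohorts[[nm]]) < n_neurons) {
      abort(paste0("cohort '", nm, "' smaller than n_neurons"),
            class = "accvi_data_error")
    }
  }
  cls <- sort(unique(labels))
  with_substream(seed, "decoding/subpop", {
    purrr::map_dfr(names(cohorts), function(nm) {
      pool <- cohorts[[nm]]
      accs <- vapply(seq_len(n_repeats), function(r) {
        sel <- sample(pool, n_neurons)
        ps <- build_pseudo_trials(responses[sel, , drop = FALSE], labels,
                                  n_pseudo = n_pseudo,
                                  seed = sample.int(2^30, 1))
        yn <- ifelse(ps$y == cls[2], 1, -1)
        fold <- sample(rep(seq_len(folds), length.out = length(yn)))
        hits <- 0; tot <- 0
        for (k in seq_len(folds)) {
          tr <- fold != k
          std <- standardize_pair(ps$x[tr, , drop = FALSE],
                                  ps$x[!tr, , drop = FALSE])
          m <- svm_train(std$train, yn[tr])
          hits <- hits + sum(svm_predict(m, std$test) == yn[!tr])
          tot <- tot + sum(!tr)
        }
        hits / tot
      }, numeric(1))
      tibble::tibble(cohort = nm, repeat_id = seq_len(n_repeats),
                     accuracy = accs)
    })
  })
}
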