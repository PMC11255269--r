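test_that("pseudo-trials are balanced, deterministic, and drop bad neurons", {
  set.seed(21)
  resp <- matrix(rnorm(5 * 20), 5, 20,
                 dimnames = list(sprintf("n%03d", 1:5), NULL))
  labels <- rep(c("a", "b"), each = 10)
  ps <- build_pseudo_trials(resp, labels, n_pseudo = 15, seed = 4)
  expect_equal(dim(ps$x), c(30, 5))
  expect_equal(as.integer(table(ps$y)), c(15L, 15L))
  ps2 <- build_pseudo_trials(resp, labels, n_pseudo = 15, seed = 4)
  expect_identical(ps, ps2)
  # a neuron with all-NA responses in one class is dropped
  resp[2, labels == "b"] <- NA
  expect_warning(ps3 <- build_pseudo_trials(resp, labels, n_pseudo = 5,
                                            seed = 1),
                 "dropped")
  expect_equal(ncol(ps3$x), 4)
})

test_that("the linear classifier separates what is separable", {
  set.seed(22)
  # trivially separable 2-D problem
  x <- rbind(matrix(rnorm(40, mean = -3), 20, 2),
             matrix(rnorm(40, mean = 3), 20, 2))
  y <- rep(c(-1, 1), each = 20)
  m <- accvi:::svm_train(x, y)
  expect_equal(accvi:::svm_predict(m, x), y)
  # well-separated Gaussian classes (delta = 4 sigma): accuracy >= 0.95
  n <- 200; d <- 10
  x2 <- rbind(matrix(rnorm(n / 2 * d), n / 2),
              matrix(rnorm(n / 2 * d, mean = 4 / sqrt(d)), n / 2))
  y2 <- rep(c("lo", "hi"), each = n / 2)
  r <- decode(x2, y2, scheme = "within", n_repeats = 20, seed = 7)
  expect_gte(mean(r$accuracy_samples), 0.95)
  expect_error(decode(x2, rep("lo", n), n_repeats = 2),
               class = "accvi_data_error")
})

test_that("label-shuffled decoding sits at chance", {
  set.seed(23)
  n <- 60; d <- 15
  accs <- vapply(1:20, function(k) {
    x <- matrix(rnorm(n * d), n)
    y <- sample(rep(c("a", "b"), each = n / 2))
    mean(decode(x, y, scheme = "within", n_repeats = 4,
                seed = k)$accuracy_samples)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / (20 * n)))
})

test_that("decoding results are deterministic and tidy correctly", {
  set.seed(24)
  x <- matrix(rnorm(40 * 6), 40)
  y <- rep(c("a", "b"), 20)
  r1 <- decode(x, y, n_repeats = 5, seed = 11)
  r2 <- decode(x, y, n_repeats = 5, seed = 11)
  expect_identical(r1$accuracy_samples, r2$accuracy_samples)
  td <- tidy(r1)
  expect_equal(nrow(td), 5)
  gl <- glance(r1)
  expect_true(gl$ci_low <= gl$mean_accuracy &&
                gl$mean_accuracy <= gl$ci_high)
})

test_that("cross-scope decoding degrades under planted drift", {
  set.seed(25)
  n_per <- 60; d <- 12
  base_a <- rnorm(d); base_b <- rnorm(d)
  drift <- rnorm(d, sd = 2)
  mk <- function(shift) {
    rbind(matrix(rnorm(n_per / 2 * d, sd = 1), n_per / 2, d,
                 byrow = TRUE) + matrix(base_a + shift * drift,
                                        n_per / 2, d, byrow = TRUE),
          matrix(rnorm(n_per / 2 * d, sd = 1), n_per / 2, d) +
            matrix(base_b - shift * drift, n_per / 2, d, byrow = TRUE))
  }
  y <- rep(c("go", "nogo"), each = n_per / 2)
  x_t1 <- mk(0); x_t3 <- mk(1.2)
  within <- decode(x_t1, y, scheme = "within", n_repeats = 15, seed = 3)
  cross <- decode(x_t1, y, x_t3, y, scheme = "cross", n_repeats = 15,
                  seed = 3, test_scope = "T3")
  expect_gte(mean(within$accuracy_samples), mean(cross$accuracy_samples))
})

test_that("removing an informative cohort lowers decoding accuracy", {
  set.seed(26)
  n_neu <- 30; n_tr <- 60
  labels <- rep(c("Hit", "RO"), each = n_tr / 2)
  resp <- matrix(rnorm(n_neu * n_tr, sd = 1), n_neu, n_tr,
                 dimnames = list(sprintf("n%03d", 1:n_neu), NULL))
  info <- 1:8  # only these neurons carry the outcome signal
  resp[info, labels == "RO"] <- resp[info, labels == "RO"] + 2.5
  cmp <- quiet(compare_subpopulations(resp, labels,
                                      exclude = rownames(resp)[info],
                                      n_neurons = 15, folds = 3,
                                      n_repeats = 12, n_pseudo = 20,
                                      seed = 5))
  m_all <- mean(cmp$accuracy[cmp$cohort == "all"])
  m_wo <- mean(cmp$accuracy[cmp$cohort == "without_excluded"])
  expect_gt(m_all, m_wo + 0.1)
  # an empty exclusion leaves the two cohorts statistically alike
  cmp0 <- quiet(compare_subpopulations(resp, labels, exclude = character(0),
                                       n_neurons = 15, folds = 3,
                                       n_repeats = 12, n_pseudo = 20,
                                       seed = 6))
  m1 <- mean(cmp0$accuracy[cmp0$cohort == "all"])
  m2 <- mean(cmp0$accuracy[cmp0$cohort == "without_excluded"])
  expect_lt(abs(m1 - m2), 0.1)
  expect_error(compare_subpopulations(resp, labels, exclude = character(0),
                                      n_neurons = 500),
               class = "accvi_data_error")
})
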