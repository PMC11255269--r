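test_that("condition matrices have the contracted shape and centering", {
  set.seed(5)
  z <- array(rnorm(10 * 20 * 90), dim = c(10, 20, 90))
  x <- make_dff_tensor(z, t0_frame = 61)
  conds <- list(go = 1:10, nogo = 11:20)
  M <- build_condition_matrix(x, conds)  # [-0.5, 1) at 30 fps = 45 frames
  expect_equal(dim(M), c(90, 10))
  expect_equal(unname(colMeans(M)), rep(0, 10), tolerance = 1e-12)
  # identical trial sets give identical row blocks
  M2 <- build_condition_matrix(x, list(a = 1:10, b = 1:10))
  expect_equal(M2[1:45, ], M2[46:90, ], ignore_attr = TRUE)
  expect_error(build_condition_matrix(x, list(go = 1:4, empty = integer(0))),
               class = "accvi_data_error")
})

test_that("PCA embedding handles rank-1 data and is rotation invariant", {
  set.seed(8)
  t <- seq(0, 1, length.out = 40)
  line <- outer(t, rnorm(6))  # rank-1: every neuron a multiple of t
  line <- sweep(line, 2, colMeans(line))
  attr(line, "condition") <- rep("a", 40); attr(line, "time_s") <- t
  tr <- embed_trajectories(line)
  expect_equal(tr$explained_variance[1], 1)
  expect_true(tr$rank_deficient)
  M <- matrix(rnorm(60 * 8), 60)
  M <- sweep(M, 2, colMeans(M))
  attr(M, "condition") <- rep("a", 60); attr(M, "time_s") <- seq_len(60)
  Q <- qr.Q(qr(matrix(rnorm(64), 8)))
  MR <- M %*% Q
  attr(MR, "condition") <- rep("a", 60); attr(MR, "time_s") <- seq_len(60)
  expect_equal(embed_trajectories(M)$explained_variance,
               embed_trajectories(MR)$explained_variance, tolerance = 1e-10)
})

test_that("trajectory metrics match brute-force Euclidean oracles", {
  # two points at distance 3
  expect_equal(trajectory_length(rbind(c(0, 0, 0), c(3, 0, 0))), 3)
  # static trajectory
  expect_equal(trajectory_length(matrix(1, 5, 3)), 0)
  # constant offset d over k frames -> k * d
  k <- 7; d0 <- 2.5
  A <- matrix(rnorm(k * 3), k)
  B <- A + matrix(c(d0, 0, 0), k, 3, byrow = TRUE)
  expect_equal(trajectory_distance(A, b = B), k * d0, tolerance = 1e-12)
  expect_equal(trajectory_distance(A, b = A), 0)
  expect_equal(trajectory_distance(A, b = B), trajectory_distance(B, b = A))
  # brute-force oracle on random paths
  set.seed(9)
  for (i in 1:20) {
    S <- matrix(rnorm(30), 10, 3)
    oracle <- sum(vapply(1:9, function(j) sqrt(sum((S[j + 1, ] - S[j, ])^2)),
                         numeric(1)))
    expect_equal(trajectory_length(S), oracle, tolerance = 1e-12)
  }
  # straight line equals endpoint distance; any detour is longer
  P <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_equal(trajectory_length(P), sqrt(12), tolerance = 1e-12)
  detour <- rbind(c(0, 0, 0), c(1, 3, 1), c(2, 2, 2))
  expect_gte(trajectory_length(detour), trajectory_length(P))
  expect_error(trajectory_length(matrix(1, 1, 3)), class = "accvi_data_error")
  expect_error(trajectory_distance(matrix(1, 3, 3), b = matrix(1, 4, 3)),
               class = "accvi_data_error")
})

test_that("geometry is invariant to neuron permutation", {
  set.seed(13)
  z <- array(rnorm(12 * 16 * 90, sd = 0.5), dim = c(12, 16, 90))
  z[, 1:8, 61:75] <- z[, 1:8, 61:75] + rep(runif(12), 8 * 15)
  x <- make_dff_tensor(z, t0_frame = 61)
  conds <- list(go = 1:8, nogo = 9:16)
  tr1 <- embed_trajectories(build_condition_matrix(x, conds))
  perm <- sample(12)
  xp <- make_dff_tensor(z[perm, , ], t0_frame = 61)
  tr2 <- embed_trajectories(build_condition_matrix(xp, conds))
  for (cn in c("go", "nogo")) {
    expect_equal(trajectory_length(tr1, cn), trajectory_length(tr2, cn),
                 tolerance = 1e-9)
  }
  expect_equal(trajectory_distance(tr1, "go", "nogo"),
               trajectory_distance(tr2, "go", "nogo"), tolerance = 1e-9)
})

test_that("bootstrap draws are reproducible and consistent with direct PCA", {
  set.seed(14)
  z <- array(rnorm(15 * 12 * 90, sd = 0.3), dim = c(15, 12, 90))
  z[, 1:6, 61:80] <- z[, 1:6, 61:80] + 1
  x <- make_dff_tensor(z, t0_frame = 61)
  conds <- list(go = 1:6, nogo = 7:12)
  b1 <- bootstrap_trajectory_metric(x, conds, "distance", n_iter = 20,
                                    subset_size = 8, seed = 3)
  b2 <- bootstrap_trajectory_metric(x, conds, "distance", n_iter = 20,
                                    subset_size = 8, seed = 3)
  expect_identical(b1, b2)
  expect_true(all(b1$value >= 0))
  # a full-population draw equals the direct computation (permutation
  # invariance makes the draw order irrelevant)
  bfull <- bootstrap_trajectory_metric(x, conds, "distance", n_iter = 1,
                                       subset_size = 15, seed = 5)
  direct <- embed_trajectories(build_condition_matrix(x, conds))
  expect_equal(bfull$value, trajectory_distance(direct, "go", "nogo"),
               tolerance = 1e-9)
  expect_error(bootstrap_trajectory_metric(x, conds, "length",
                                           subset_size = 99),
               class = "accvi_data_error")
})

test_that("population correlation tracks planted representational drift", {
  set.seed(15)
  n_neu <- 40; n_fr <- 90
  p1 <- runif(n_neu, 0.5, 1); p2 <- runif(n_neu, 0.5, 1)
  mix <- function(w) (1 - w) * p1 + w * p2
  z <- array(rnorm(n_neu * 30 * n_fr, sd = 0.05), dim = c(n_neu, 30, n_fr))
  for (g in 1:3) {
    tr_idx <- ((g - 1) * 10 + 1):(g * 10)
    z[, tr_idx, 61:90] <- z[, tr_idx, 61:90] + mix((g - 1) / 2)
  }
  x <- make_dff_tensor(z, t0_frame = 61)
  cm <- population_correlation(x, list(g1 = 1:10, g2 = 11:20, g3 = 21:30))
  expect_equal(diag(cm), c(g1 = 1, g2 = 1, g3 = 1))
  expect_equal(cm, t(cm))
  expect_gt(cm["g1", "g2"], cm["g1", "g3"])  # drift decorrelates with lag
  # a vector against its negation
  z2 <- z[, 1:20, ]
  z2[, 11:20, ] <- -z2[, 1:10, ]
  x2 <- make_dff_tensor(z2, t0_frame = 61)
  cm2 <- population_correlation(x2, list(a = 1:10, b = 11:20))
  expect_equal(cm2["a", "b"], -1, tolerance = 1e-12)
})
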