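test_that("feature-pair enumeration matches the distance-set rules", {
  p45 <- enumerate_feature_pairs(10, 1)
  expect_equal(nrow(p45), 45L)
  p28 <- enumerate_feature_pairs(10, 3)
  expect_equal(nrow(p28), 28L)
  expect_true(all(p28[, "j"] - p28[, "i"] >= 3))
  expect_equal(nrow(enumerate_feature_pairs(2, 2)), 0L)
  # lexicographic order
  expect_equal(p45[1:3, "j"], c(2L, 3L, 4L))
  expect_error(enumerate_feature_pairs(1), "2 sites")
})

make_single_lineage_store <- function(n_iter, S = 5, M = 1, drift = 0.01) {
  # one unbroken walker lineage: parent_seg always 1
  store <- run_store(tau = S, M = M, save_every = 1)
  cnt <- 0
  for (i in seq_len(n_iter)) {
    coords <- array(0, c(1, S, 2))
    coords[1, , 1] <- drift * (cnt + seq_len(S))
    coords[1, , 2] <- 1
    cnt <- cnt + S
    hybridwe:::store_append(store, i, coords, weight = 1,
                            parent_seg = if (i == 1) 0L else 1L,
                            lineage = 1L, bin_id = 1L, history = 0L)
  }
  store
}

test_that("lagged pairs respect lineage continuity and counts", {
  # 20 iterations x 5 frames = 100 frames on one lineage, lag 10 -> 90 pairs
  store <- make_single_lineage_store(20)
  ds <- build_lagged_pairs(store, dt = 10)
  expect_equal(nrow(ds$x), 90L)
  # every pair is exactly dt frames apart along the drifting coordinate
  expect_equal(ds$x_lag[, 1] - ds$x[, 1], rep(10 * 0.01, 90),
               tolerance = 1e-12)
  # lag >= lineage length -> no pairs
  expect_error(build_lagged_pairs(store, dt = 100), "no valid lagged pairs")
})

test_that("lagged pairs fork with splits and end at pruned branches", {
  S <- 5
  store <- run_store(tau = S, M = 2, save_every = 1)
  co1 <- array(seq_len(S * 2) / 10, c(1, S, 2))
  hybridwe:::store_append(store, 1, co1, 1, 0L, 1L, 1L, 0L)
  # iteration 2: walker split into two children, both descending from seg 1
  co2 <- array(0, c(2, S, 2)); co2[1, , ] <- 1; co2[2, , ] <- 2
  hybridwe:::store_append(store, 2, co2, c(0.5, 0.5), c(1L, 1L),
                          2:3, c(1L, 1L), c(0L, 0L))
  ds <- build_lagged_pairs(store, dt = 3)
  # per child: frames 4,5 of iter2 pair within-segment; frames 1..3 reach back
  # into the shared parent; iter1 frames 4,5 pair within iter1
  n_within1 <- S - 3            # 2 pairs in iteration 1
  n_per_child <- S              # frames 1..5 of each child all have sources
  expect_equal(nrow(ds$x), n_within1 + 2 * n_per_child)
  # a root iteration's early frames have no source (chain ends at start)
  expect_false(any(ds$x_lag[, 1] %in% (1:3 / 10)))
})

test_that("weight modes propagate or flatten the stored WE weights", {
  store <- make_single_lineage_store(4)
  store$iters[[4]]$weight <- 0.25
  use <- build_lagged_pairs(store, dt = 2, weight_mode = "use")
  ign <- build_lagged_pairs(store, dt = 2, weight_mode = "ignore")
  expect_equal(length(unique(ign$w)), 1L)
  expect_true(any(use$w == 0.25))
})

test_that("the objective is the beta-weighted bottleneck loss", {
  set.seed(1)
  x <- matrix(rnorm(200), 100, 2)
  m <- spib(x, x, init_labels = rep(1L, 100), epochs = 1, max_rounds = 1,
            hidden = c(8, 8), seed = 2)
  # K = 1: cross-entropy is exactly zero, loss = beta * KL
  y <- rep(1L, 100)
  l <- spib_objective(m, x, y, sample = FALSE)
  expect_equal(attr(l, "cross_entropy"), 0)
  expect_equal(as.numeric(l), m$beta * attr(l, "kl"))
  # rescaling all weights leaves the normalized loss unchanged
  set.seed(3); l1 <- spib_objective(m, x, y, weights = rep(1, 100))
  set.seed(3); l2 <- spib_objective(m, x, y, weights = rep(2, 100))
  expect_equal(as.numeric(l1), as.numeric(l2))
  expect_error(spib_objective(m, x[, 1, drop = FALSE], y), "dimension")
  expect_error(spib_objective(m, x[0, ], integer(0)), "empty")
})

test_that("training separates two well-separated clusters at beta = 0", {
  set.seed(7)
  n <- 400
  lab <- rep(1:2, each = n / 2)
  x <- cbind(rnorm(n, mean = c(-3, 3)[lab], sd = 0.3), rnorm(n, sd = 0.3))
  # targets equal the cluster of the (static) future frame: use x as both ends
  m <- spib(x, x, beta = 0, init_labels = lab, epochs = 30, max_rounds = 3,
            hidden = c(16, 16), seed = 4)
  l <- spib_objective(m, x, m$labels, sample = FALSE)
  expect_lt(attr(l, "cross_entropy"), 0.1)
  expect_equal(m$K, 2L)
})

test_that("decoder probabilities are a proper distribution", {
  set.seed(5)
  x <- matrix(rnorm(300), 150, 2)
  m <- spib(x, x, init_grid = 3, epochs = 3, max_rounds = 2,
            hidden = c(8, 8), seed = 6)
  P <- predict(m, x, type = "prob")
  expect_equal(rowSums(P), rep(1, 150), tolerance = 1e-6)
  expect_true(all(P >= 0))
})

test_that("latent encoding is deterministic and finite", {
  set.seed(8)
  x <- matrix(rnorm(200), 100, 2)
  m <- spib(x, x, init_grid = 2, epochs = 2, max_rounds = 1,
            hidden = c(8, 8), seed = 9)
  z1 <- predict(m, x, type = "latent")
  z2 <- predict(m, x, type = "latent")
  expect_identical(z1, z2)
  expect_true(all(is.finite(z1)))
  expect_equal(z1[3, ], predict(m, x[3, , drop = FALSE])[1, ])
  expect_error(predict(m, x[, 1, drop = FALSE]), "dimension")
})

test_that("refinement deletes sub-threshold states and is idempotent", {
  set.seed(10)
  n <- 1000
  lab <- rep(1:2, c(995, 5))
  x <- cbind(rnorm(n, mean = c(-3, 3)[lab], sd = 0.3), rnorm(n, sd = 0.3))
  m <- spib(x, x, init_labels = lab, epochs = 20, max_rounds = 2,
            hidden = c(16, 16), seed = 11, pop_threshold = 0)
  expect_equal(m$K, 2L)   # threshold off: the 0.5% state survives
  # with the 1e-3 rule a state of population 5e-4 is absorbed
  w <- rep(1, n); w[lab == 2] <- 0.1          # weighted population ~5e-4
  ref <- refine_state_labels(m, x, weights = w, pop_threshold = 1e-3)
  expect_equal(ref$model$K, 1L)
  expect_true(all(ref$labels == 1L))
  # idempotent without parameter updates
  ref2 <- refine_state_labels(ref$model, x, weights = w)
  expect_identical(ref2$labels, ref$labels)
  expect_identical(ref2$model$K, ref$model$K)
})

test_that("ground-truth states of a Markov chain are recovered", {
  dat <- markov_gauss_data(n = 3000, stay = 0.98, sep = 5, sd = 0.6)
  lag <- 5
  x <- dat$x[1:(3000 - lag), ]
  xl <- dat$x[(1 + lag):3000, ]
  truth <- dat$states[(1 + lag):3000]
  m <- spib(x, xl, init_grid = 4, epochs = 12, max_rounds = 10,
            hidden = c(32, 32), seed = 12)
  expect_equal(m$K, 3L)
  # agreement up to label permutation
  tab <- table(m$labels, truth)
  agree <- sum(apply(tab, 2, max)) / length(truth)
  expect_gte(agree, 0.95)
})

test_that("single-basin data collapses to one state", {
  set.seed(13)
  x <- matrix(rnorm(2000, sd = 0.5), 1000, 2)
  m <- spib(x[1:990, ], x[11:1000, ], init_grid = 3, epochs = 8,
            max_rounds = 10, hidden = c(16, 16), seed = 14)
  expect_equal(m$K, 1L)
})
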