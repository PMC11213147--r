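test_that("flat-run free energy is flat and normalization-invariant", {
  flat <- toy_potential("flat", domain = c(-1, 1, -1, 1))
  params <- dynamics_params(dt = 0.01, seed = 19)
  ref <- generate_reference_ensemble(
    flat, params, 4e5, list(state_def("all", c(-1, -1), c(1, 1))),
    save_every = 4, min_visits = 1)
  grid <- rect_grid(list(seq(-1, 1, by = 0.5), seq(-1, 1, by = 0.5)))
  fes <- estimate_fes(ref$traj, grid = grid, min_count = 500)
  expect_lt(max(fes$F, na.rm = TRUE), 0.1)
  # doubling every weight changes nothing
  w <- rep(2, nrow(ref$traj))
  fes2 <- estimate_fes(ref$traj, w, grid, min_count = 500)
  expect_equal(fes2$F, fes$F)
  expect_equal(min(fes$F, na.rm = TRUE), 0)
})

test_that("WE free-energy surface matches the analytic Boltzmann surface", {
  dw <- fix_double_well(3)
  g <- rect_grid(seq(-1.8, 1.8, by = 0.2), cv = function(x) x[, 1, drop = FALSE])
  run <- quick_we_run(dw, g, n_iter = 120, seed = 23, tau = 50,
                      start = c(-1, 0))
  fr <- hybridwe:::store_frames(run$store, 30:120)
  fgrid <- rect_grid(list(seq(-1.5, 1.5, by = 0.25)))
  fes <- estimate_fes(fr$x[, 1, drop = FALSE], fr$w, fgrid, min_count = 500)
  # analytic marginal over x with the transverse mode integrated out (the
  # y-marginal is bin-independent for this separable potential)
  ex <- fgrid$edges[[1]]
  probs <- vapply(seq_len(length(ex) - 1), function(i) {
    xs <- seq(ex[i], ex[i + 1], length.out = 12)
    mean(exp(-3 * (xs^2 - 1)^2))
  }, 0.0)
  f_ref <- -log(probs / sum(probs)); f_ref <- f_ref - min(f_ref)
  keep <- !is.na(fes$F)
  expect_gt(sum(keep), 3)
  diff <- fes$F[keep] - f_ref[keep]
  expect_lt(max(abs(diff - mean(diff))), 0.3)
})

test_that("averaging runs combines probabilities before the log", {
  g <- rect_grid(list(c(0, 1, 2)))
  f1 <- estimate_fes(matrix(c(0.5, 0.5, 1.5), ncol = 1), grid = g,
                     min_count = 1)
  f2 <- estimate_fes(matrix(c(0.5, 1.5, 1.5), ncol = 1), grid = g,
                     min_count = 1)
  avg <- average_fes(list(f1, f2))
  expect_equal(avg$prob, c(0.5, 0.5))
  expect_equal(avg$F, c(0, 0))
})

test_that("WE rates agree with the oracle and satisfy detailed balance", {
  dw <- fix_double_well(3)
  states <- fix_two_states()
  params <- dynamics_params(dt = 0.002, seed = 29)
  ref <- generate_reference_ensemble(dw, params, 3e6, states, save_every = 5)
  g <- rect_grid(seq(-1.8, 1.8, by = 0.2), cv = function(x) x[, 1, drop = FALSE])
  ests <- lapply(c(501, 502, 503), function(s) {
    run <- quick_we_run(dw, g, n_iter = 200, seed = s, tau = 50,
                        states = states, start = c(-1, 0))
    estimate_rates(run$store, states, burn_in = 0.3, frame_dt = 0.002 * 10)
  })
  cmb <- combine_rates(ests)
  for (pair in list(c(1, 2), c(2, 1))) {
    se <- sqrt(cmb$sem[pair[1], pair[2]]^2 + ref$rates_se[pair[1], pair[2]]^2)
    expect_lt(abs(cmb$mean[pair[1], pair[2]] - ref$rates[pair[1], pair[2]]),
              3 * se)
  }
  # symmetry of the double well
  se_sym <- sqrt(sum(cmb$sem^2))
  expect_lt(abs(cmb$mean[1, 2] - cmb$mean[2, 1]), 3 * se_sym)
  # detailed balance k(A->B) pi_A = k(B->A) pi_B with pi from occupancies
  flux_fwd <- vapply(ests, function(e)
    e$rates[1, 2] * e$occupancy[1] / sum(e$occupancy), 0.0)
  flux_bwd <- vapply(ests, function(e)
    e$rates[2, 1] * e$occupancy[2] / sum(e$occupancy), 0.0)
  d <- flux_fwd - flux_bwd
  # allow a small residual relaxation bias on top of the run-to-run error
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)) +
                          0.05 * mean(flux_fwd))
})

test_that("overlapping state predicates are rejected", {
  store <- run_store()
  expect_error(
    estimate_rates(store, list(state_def("A", c(-1, -1), c(1, 1)),
                               state_def("B", c(0, 0), c(2, 2)))),
    "overlap")
})

test_that("Bayesian bootstrap intervals behave on degenerate inputs", {
  b <- bayesian_bootstrap_ci(rep(3.5, 6), n_boot = 200, seed = 1)
  expect_equal(b$interval, c(3.5, 3.5))
  b2 <- bayesian_bootstrap_ci(c(0, 1), n_boot = 2000, seed = 2)
  expect_gte(b2$interval[1], 0)
  expect_lte(b2$interval[2], 1)
  expect_gt(b2$interval[2], 0.5)
  expect_lt(b2$interval[1], 0.5)
  expect_error(bayesian_bootstrap_ci(1), ">= 2")
})

test_that("bootstrap intervals cover a known mean at the nominal level", {
  set.seed(33)
  n_rep <- 200
  covered <- vapply(seq_len(n_rep), function(r) {
    units <- rnorm(12, mean = 2, sd = 1)
    ci <- bayesian_bootstrap_ci(units, n_boot = 300)$interval
    ci[1] <= 2 && 2 <= ci[2]
  }, TRUE)
  p <- mean(covered)
  se <- sqrt(0.95 * 0.05 / n_rep)
  expect_gt(p, 0.95 - 3 * se - 0.02)   # small-n bootstrap undercoverage slack
  expect_lte(p, 1)
})

test_that("the state-flux network matches well occupancies on the triple well", {
  tw <- fix_triple_well()
  states <- fix_three_states(tw)
  params <- dynamics_params(dt = 0.002, seed = 37)
  ref <- generate_reference_ensemble(tw, params, 3e6, states, save_every = 10)
  # train on the brute-force trajectory at an interwell-resolving lag
  n <- nrow(ref$traj)
  keep <- seq(1, n - 50, by = 15)
  m <- spib(ref$traj[keep, ], ref$traj[keep + 50, ], init_grid = 4,
            epochs = 10, max_rounds = 10, hidden = c(32, 32), seed = 38)
  expect_equal(m$K, 3L)
  # wrap the trajectory as a single-lineage store
  S <- 10
  store <- run_store(tau = S, M = 1, save_every = 1)
  nit <- floor(n / S)
  for (i in seq_len(nit)) {
    co <- array(0, c(1, S, 2))
    co[1, , ] <- ref$traj[((i - 1) * S + 1):(i * S), ]
    hybridwe:::store_append(store, i, co, 1, if (i == 1) 0L else 1L,
                            1L, 1L, 0L)
  }
  net <- build_state_network(m, store, dt = 5,
                             window = seq(1, nit, by = 3))
  expect_equal(rowSums(net$jump), rep(1, 3), tolerance = 1e-6)
  expect_true(all(diag(net$jump) > 0.5))   # metastability: heavy diagonal
  # populations match the reference well occupancies
  lab_pop <- sort(net$populations)
  ref_pop <- sort(unname(ref$populations))
  expect_lt(max(abs(lab_pop - ref_pop)), 0.1)
})

test_that("network construction handles a single-state model", {
  set.seed(39)
  x <- matrix(rnorm(2000, sd = 0.5), 1000, 2)
  m <- spib(x[1:990, ], x[11:1000, ], init_grid = 3, epochs = 8,
            max_rounds = 10, hidden = c(16, 16), seed = 40)
  expect_equal(m$K, 1L)
  store <- run_store(tau = 10, M = 1, save_every = 1)
  co <- array(rnorm(600, sd = 0.3), c(2, 10, 2))
  hybridwe:::store_append(store, 1, co, c(0.5, 0.5), c(0L, 0L), 1:2,
                          c(1L, 1L), c(0L, 0L))
  net <- build_state_network(m, store, dt = 2)
  expect_equal(net$K, 1L)
  expect_equal(net$jump, matrix(1, 1, 1))
})

test_that("rate and network tables export as plain CSV", {
  tmp1 <- tempfile(fileext = ".csv"); tmp2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmp1, tmp2)))
  cmb <- list(mean = matrix(c(0, 1, 2, 0), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B"))),
              sem = matrix(0.1, 2, 2, dimnames = list(c("A", "B"),
                                                      c("A", "B"))),
              per_run = array(1, c(2, 2, 3)))
  write_rates_csv(cmb, tmp1)
  df <- read.csv(tmp1)
  expect_equal(nrow(df), 2L)
  expect_named(df, c("source", "target", "mean", "sem",
                     "run1", "run2", "run3"))
  net <- structure(list(populations = c(0.4, 0.6),
                        jump = matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2),
                        counts = matrix(1, 2, 2), dt = 2, K = 2L),
                   class = "state_network")
  write_network_csv(net, tmp2)
  expect_equal(nrow(read.csv(tmp2)), 4L)
})
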