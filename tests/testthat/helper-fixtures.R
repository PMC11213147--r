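# shared fixtures, all generated in code

fix_double_well <- function(barrier = 2) toy_potential("double_well",
                                                       barrier = barrier)

fix_triple_well <- function(depth = 4, sigma = 0.4)
  toy_potential("triple_well", depth = depth, sigma = sigma)

fix_two_states <- function(edge = 1.6) {
  list(state_def("A", c(-edge, -edge), c(-0.6, edge)),
       state_def("B", c(0.6, -edge), c(edge, edge)))
}

fix_three_states <- function(pot, half = 0.35) {
  ctr <- pot$centers
  lapply(1:3, function(i) state_def(LETTERS[i], ctr[i, ] - half,
                                    ctr[i, ] + half))
}

# small WE run on a given potential; returns the store
quick_we_run <- function(pot, grid, n_iter = 30, seed = 1, tau = 30,
                         save_every = 10, M = 4, states = NULL,
                         start = c(0, 0)) {
  cfg <- we_config(tau = tau, M = M, save_every = save_every)
  params <- dynamics_params(dt = 0.002, seed = seed)
  prop <- make_brownian_propagator(pot, params, cfg)
  ens <- we_ensemble(matrix(rep(start, each = M), M))
  if (!is.null(states)) ens$history <- assign_states(ens$pos, states)
  store <- run_store(tau = tau, M = M, save_every = save_every)
  for (i in seq_len(n_iter)) {
    out <- run_we_iteration(ens, prop, grid, cfg, store, i, states,
                            run_seed = seed)
    ens <- out$ens
  }
  list(store = store, ens = ens)
}

# 3-state Markov chain with 2D Gaussian emissions (known ground truth)
markov_gauss_data <- function(n = 3000, stay = 0.98, sep = 4, sd = 1,
                              seed = 42) {
  set.seed(seed)
  P <- matrix((1 - stay) / 2, 3, 3); diag(P) <- stay
  centers <- rbind(c(0, 0), c(sep, 0), c(sep / 2, sep * sqrt(3) / 2))
  s <- integer(n); s[1] <- 1L
  for (t in 2:n) s[t] <- sample.int(3, 1, prob = P[s[t - 1], ])
  x <- centers[s, ] + matrix(rnorm(2 * n, sd = sd), n)
  list(x = x, states = s, P = P)
}

# a stub latent model whose "latent CVs" are the raw coordinates, letting the
# routing rule be tested against hand-computed occupancies
stub_mapper <- function(expert_edges, mask_vals, latent_h = 1,
                        latent_lo = c(0, 0), latent_hi = c(3, 3),
                        sequential = FALSE) {
  eg <- rect_grid(expert_edges, cv = function(x) x[, 1, drop = FALSE])
  lg <- hybridwe:::make_latent_grid(latent_h, latent_lo, latent_hi)
  set.seed(1)
  x0 <- matrix(rnorm(40), 20, 2)
  model <- spib(x0, x0, init_labels = rep(1L, 20), epochs = 1, max_rounds = 1,
                hidden = c(4, 4), seed = 1)
  # identity "encoder": override prediction by a passthrough class
  mask <- structure(list(mask = mask_vals, counts = rep(1L, eg$n_bins),
                         mean_count = 1, iteration = 1L),
                    class = "undersampled_mask")
  m <- hybrid_mapper(eg, lg, model, mask, sequential = sequential)
  m$model <- structure(list(passthrough = TRUE,
                            center = c(0, 0), scale = c(1, 1)),
                       class = c("latent_passthrough", "spib"))
  m
}

#' identity latent map for the stub
predict.latent_passthrough <- function(object, newdata, type = "latent", ...) {
  as.matrix(newdata)
}
registerS3method("predict", "latent_passthrough", predict.latent_passthrough,
                 envir = environment())

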