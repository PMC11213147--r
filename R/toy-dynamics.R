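#' Analytic 2D toy potentials
#'
#' Constructs a potential specification for the built-in Brownian-dynamics
#' propagator. Four families are available:
#' \describe{
#'   \item{\code{"flat"}}{\eqn{U = 0} everywhere (free diffusion).}
#'   \item{\code{"harmonic"}}{\eqn{U = k (x^2 + y^2) / 2}.}
#'   \item{\code{"double_well"}}{\eqn{U = b (x^2 - 1)^2 + k_y y^2 / 2}: two
#'     minima at \eqn{x = \pm 1} separated by a barrier of height \code{barrier}
#'     (in units of kT when kT = 1) at \eqn{x = 0}.}
#'   \item{\code{"triple_well"}}{Three Gaussian wells of depth \code{depth} and
#'     width \code{sigma} at \code{centers}; the default centers put two wells
#'     at \eqn{x = -1} (degenerate under a projection onto x) and one at
#'     \eqn{x = +1}.}
#' }
#' All potentials are finite and continuously differentiable on the domain;
#' the propagator applies reflecting boundaries at the domain edges.
#'
#' @param kind one of \code{"flat"}, \code{"harmonic"}, \code{"double_well"},
#'   \code{"triple_well"}.
#' @param k harmonic force constant (energy/length^2).
#' @param barrier double-well barrier height (energy units; >= 0).
#' @param ky transverse harmonic constant of the double well.
#' @param depth triple-well depth (energy units; >= 0); the barrier between
#'   wells is approximately \code{depth} for well-separated centers.
#' @param sigma triple-well Gaussian width (length units).
#' @param centers 3 x 2 matrix of triple-well centers.
#' @param domain simulation domain \code{c(xlo, xhi, ylo, yhi)}; reflecting.
#' @return an object of class \code{"toy_potential"}.
#' @examples
#' pot <- toy_potential("double_well", barrier = 5)
#' potential_energy(pot, c(0, 0))   # barrier top
#' potential_energy(pot, c(1, 0))   # well minimum, 0
#' @export
toy_potential <- function(kind = c("double_well", "triple_well", "flat",
                                   "harmonic"),
                          k = 1, barrier = 5, ky = 2,
                          depth = 4, sigma = 0.4,
                          centers = rbind(c(-1, 1), c(-1, -1), c(1, 0)),
                          domain = NULL) {
  kind <- match.arg(kind)
  if (barrier < 0 || depth < 0)
    stop("barrier height must be >= 0", call. = FALSE)
  if (kind == "triple_well") {
    centers <- as.matrix(centers)
    if (!identical(dim(centers), c(3L, 2L)))
      stop("triple_well needs a 3 x 2 matrix of centers", call. = FALSE)
  }
  params <- switch(kind,
    flat        = numeric(0),
    harmonic    = k,
    double_well = c(barrier, ky),
    triple_well = c(depth, sigma, as.vector(t(centers)))
  )
  if (is.null(domain)) {
    domain <- switch(kind,
      flat        = c(-3, 3, -3, 3),
      harmonic    = c(-6, 6, -6, 6),
      double_well = c(-1.8, 1.8, -1.8, 1.8),
      triple_well = c(-2.2, 2.2, -2.2, 2.2))
  }
  structure(list(kind = kind, params = params, domain = as.numeric(domain),
                 centers = if (kind == "triple_well") centers else NULL),
            class = "toy_potential")
}

pot_kind_code <- function(pot) {
  match(pot$kind, c("flat", "harmonic", "double_well", "triple_well")) - 1L
}

#' Potential energy and gradient
#'
#' @param pot a \code{\link{toy_potential}}.
#' @param x a length-2 coordinate or an n x 2 matrix of coordinates.
#' @return \code{potential_energy}: numeric vector of energies;
#'   \code{potential_gradient}: n x 2 matrix of gradients.
#' @export
potential_energy <- function(pot, x) {
  stopifnot(inherits(pot, "toy_potential"))
  x <- as_points(x)
  .pot_energy_cpp(x, pot_kind_code(pot), pot$params)
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(pot, x) {
  stopifnot(inherits(pot, "toy_potential"))
  x <- as_points(x)
  .pot_grad_cpp(x, pot_kind_code(pot), pot$params)
}

as_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 2) stop("coordinates must be 2-dimensional", call. = FALSE)
  x
}

#' Overdamped Langevin dynamics parameters
#'
#' Parameters for the first-order (Brownian) integrator
#' \deqn{x' = x - (D \Delta t / kT) \nabla U(x) + \sqrt{2 D \Delta t}\,\xi,}
#' with \eqn{\xi} standard normal per dimension. Identical seed and inputs
#' give bitwise-identical trajectories.
#'
#' @param dt integration timestep (time units; > 0).
#' @param D diffusion coefficient (length^2/time; > 0).
#' @param kT thermal energy (energy units; > 0).
#' @param seed integer RNG seed for the run.
#' @param noise_scale multiplier on the thermal noise; 0 gives deterministic
#'   gradient descent (used for zero-noise checks).
#' @export
dynamics_params <- function(dt = 0.002, D = 1, kT = 1, seed = 1,
                            noise_scale = 1) {
  if (dt <= 0 || D <= 0 || kT <= 0)
    stop("dt, D and kT must all be positive", call. = FALSE)
  structure(list(dt = dt, D = D, kT = kT, seed = as.numeric(seed),
                 noise_scale = noise_scale),
            class = "dynamics_params")
}

#' Advance walkers by Brownian dynamics
#'
#' Propagates each row of \code{x} for \code{n_steps} Euler--Maruyama steps,
#' saving a frame every \code{save_every} steps. Each walker draws from its
#' own deterministic RNG stream seeded from (run seed, lineage id, iteration),
#' so resampling never correlates sibling trajectories and runs are resumable.
#'
#' @param x n x 2 matrix of starting coordinates.
#' @param pot a \code{\link{toy_potential}}.
#' @param params a \code{\link{dynamics_params}}.
#' @param n_steps steps to advance (multiple of \code{save_every}).
#' @param save_every frame-saving stride in steps.
#' @param lineage integer vector of per-walker lineage ids (default 1..n).
#' @param iteration iteration counter entering the per-walker seed.
#' @return list with \code{frames} (n x n_save x 2 array) and \code{final}
#'   (n x 2 matrix).
#' @export
brownian_propagate <- function(x, pot, params, n_steps, save_every = n_steps,
                               lineage = seq_len(nrow(as_points(x))),
                               iteration = 0L) {
  x <- as_points(x)
  .propagate_walkers(x, as.integer(lineage), as.integer(iteration),
                     params$seed, as.integer(n_steps), as.integer(save_every),
                     pot_kind_code(pot), pot$params,
                     params$dt, params$D, params$kT, pot$domain,
                     params$noise_scale)
}

#' Single Brownian step
#'
#' Convenience wrapper advancing one walker by one integrator step.
#' @inheritParams brownian_propagate
#' @return length-2 numeric coordinate.
#' @export
brownian_step <- function(x, pot, params, lineage = 1L, iteration = 0L) {
  brownian_propagate(x, pot, params, n_steps = 1L, save_every = 1L,
                     lineage = lineage, iteration = iteration)$final[1, ]
}

#' A deliberately degenerate expert collective variable
#'
#' Projects a 2D configuration onto its first coordinate. On the default
#' triple well (wells at (-1, 1), (-1, -1), (1, 0)) this maps the two left
#' basins onto the same CV value, reproducing the classic failure mode of
#' expert CVs: distinct metastable states become indistinguishable, so any
#' 1D expert grid places them in the same bin.
#'
#' @param x a length-2 coordinate or n x 2 matrix.
#' @return numeric vector of CV values (the x coordinates).
#' @export
degenerate_expert_cv <- function(x) as_points(x)[, 1]

#' Rectangular metastable-state definition
#'
#' A named axis-aligned box over the coordinates (or over CVs produced by
#' \code{cv_fun} in the functions that accept one). Frames outside every
#' defined state carry their history label.
#'
#' @param name state name.
#' @param lo,hi numeric vectors of box bounds (same length as the CV).
#' @export
state_def <- function(name, lo, hi) {
  stopifnot(length(lo) == length(hi), all(hi > lo))
  structure(list(name = name, lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "state_def")
}

#' Assign frames to defined states
#'
#' @param x n x d matrix of coordinates/CVs.
#' @param states list of \code{\link{state_def}}; must be pairwise disjoint.
#' @return integer vector: state index per frame, 0 for "no state".
#' @export
assign_states <- function(x, states) {
  x <- as.matrix(x)
  check_states_disjoint(states)
  out <- integer(nrow(x))
  for (s in seq_along(states)) {
    st <- states[[s]]
    inside <- rep(TRUE, nrow(x))
    for (d in seq_along(st$lo))
      inside <- inside & x[, d] >= st$lo[d] & x[, d] <= st$hi[d]
    out[inside] <- s
  }
  out
}

check_states_disjoint <- function(states) {
  if (length(states) < 2) return(invisible(TRUE))
  for (i in seq_len(length(states) - 1)) for (j in (i + 1):length(states)) {
    a <- states[[i]]; b <- states[[j]]
    overlap <- all(a$lo < b$hi & b$lo < a$hi)
    if (overlap)
      stop("state definitions '", a$name, "' and '", b$name,
           "' overlap", call. = FALSE)
  }
  invisible(TRUE)
}

#' Brute-force reference ensemble and rate oracle
#'
#' Runs one long unweighted Brownian trajectory and computes state-to-state
#' rate constants with the history-labelled flux estimator (each frame carries
#' the last-visited defined state; a transition is counted when a frame enters
#' a different state). For a two-state system this equals the inverse mean
#' first-passage time. Standard errors come from contiguous time blocks. The
#' result is the oracle that weighted-ensemble estimates are tested against.
#'
#' @param pot a \code{\link{toy_potential}}.
#' @param params a \code{\link{dynamics_params}}.
#' @param n_steps total integrator steps.
#' @param states list of \code{\link{state_def}} over the coordinates.
#' @param save_every frame subsampling stride (steps).
#' @param min_visits minimum visits per state below which the oracle refuses
#'   to report ("oracle unconverged").
#' @param n_blocks number of blocks for the rate standard errors.
#' @param start starting coordinate (defaults to the domain center).
#' @return list with \code{traj} (frames), \code{labels}, \code{rates}
#'   (K x K matrix, 1/time), \code{rates_se}, \code{populations} (label
#'   occupancy fractions), \code{frame_dt}.
#' @export
generate_reference_ensemble <- function(pot, params, n_steps, states,
                                        save_every = 10L, min_visits = 20L,
                                        n_blocks = 5L, start = NULL) {
  if (is.null(start))
    start <- c(mean(pot$domain[1:2]), mean(pot$domain[3:4]))
  traj <- .simulate_trajectory(as.numeric(start), params$seed,
                               as.numeric(n_steps), as.integer(save_every),
                               pot_kind_code(pot), pot$params,
                               params$dt, params$D, params$kT, pot$domain,
                               params$noise_scale)
  st <- assign_states(traj, states)
  K <- length(states)
  # visits = genuine arrivals (history label switches), not frame counts or
  # boundary re-crossings
  lab <- history_labels(st)
  prev <- c(0L, lab[-length(lab)])
  entries <- tabulate(st[st > 0 & st != prev], nbins = K)
  if (any(entries < min_visits))
    stop("oracle unconverged: state(s) ",
         paste(vapply(states, `[[`, "", "name")[entries < min_visits],
               collapse = ", "),
         " visited fewer than ", min_visits, " times", call. = FALSE)
  frame_dt <- params$dt * save_every
  est <- flux_rates(lab, st, weight = NULL, frame_dt = frame_dt, K = K)
  # block standard errors
  idx <- cut(seq_along(st), n_blocks, labels = FALSE)
  per_block <- lapply(seq_len(n_blocks), function(b) {
    sel <- idx == b
    flux_rates(lab[sel], st[sel], NULL, frame_dt, K)$rates
  })
  arr <- array(unlist(per_block), dim = c(K, K, n_blocks))
  se <- apply(arr, c(1, 2), function(v) stats::sd(v) / sqrt(sum(is.finite(v))))
  pop <- tabulate(lab[lab > 0], nbins = K) / sum(lab > 0)
  names(pop) <- vapply(states, `[[`, "", "name")
  structure(list(traj = traj, labels = lab, rates = est$rates, rates_se = se,
                 populations = pop, frame_dt = frame_dt,
                 state_names = names(pop)),
            class = "reference_ensemble")
}

# last-visited-state label per frame (init until the first state is entered)
history_labels <- function(state_idx, init = 0L) {
  n <- length(state_idx)
  if (!n) return(integer(0))
  last <- cummax(ifelse(state_idx > 0L, seq_len(n), 0L))
  out <- rep(as.integer(init), n)
  hit <- last > 0L
  out[hit] <- state_idx[pmax(last[hit], 1L)]
  out
}

# history-labelled flux rate matrix from per-frame labels (optionally
# weighted): k(A->B) = sum of weight entering B while labelled A, divided by
# time-integrated weight labelled A.
flux_rates <- function(lab, state_idx, weight, frame_dt, K) {
  n <- length(lab)
  if (is.null(weight)) weight <- rep(1, n)
  flux <- matrix(0, K, K)
  if (n > 1) {
    prev <- lab[-n]; cur <- state_idx[-1]; w <- weight[-1]
    ev <- which(cur > 0 & prev > 0 & cur != prev)
    if (length(ev))
      for (i in ev) flux[prev[i], cur[i]] <- flux[prev[i], cur[i]] + w[i]
  }
  occ <- vapply(seq_len(K), function(s) sum(weight[lab == s]) * frame_dt,
                0.0)
  rates <- flux / ifelse(occ > 0, occ, NA_real_)
  diag(rates) <- 0
  list(rates = rates, flux = flux, occupancy = occ)
}

#' @export
print.reference_ensemble <- function(x, ...) {
  cat("Brute-force reference ensemble:", nrow(x$traj), "frames\n")
  cat("State populations:\n")
  print(round(x$populations, 4))
  cat("Rate constants (1/time):\n")
  r <- x$rates
  dimnames(r) <- list(x$state_names, x$state_names)
  print(signif(r, 3))
  invisible(x)
}
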