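#' Weighted free-energy surface on a grid
#'
#' \eqn{F_b = -\ln(\sum_b w / \sum w)} in units of kT, shifted so the
#' minimum over unmasked bins is 0. Bins holding fewer than
#' \code{min_count} unweighted samples are masked (carry NA), never
#' extrapolated. Doubling every weight leaves F unchanged.
#'
#' @param x n x d matrix of frames (or CV values), d in 1..2.
#' @param w frame weights.
#' @param grid a \code{\link{rect_grid}} over the same d CVs.
#' @param min_count unweighted sample floor per bin (default 10).
#' @return object of class \code{"we_fes"}: \code{F} (kT, NA where masked),
#'   \code{prob}, \code{counts}, the \code{grid}.
#' @export
estimate_fes <- function(x, w = NULL, grid, min_count = 10L) {
  x <- as.matrix(x)
  if (is.null(w)) w <- rep(1, nrow(x))
  b <- assign_bins(grid, x)
  counts <- tabulate(b, nbins = grid$n_bins)
  prob <- vapply(seq_len(grid$n_bins),
                 function(k) sum(w[b == k]), 0.0) / sum(w)
  f <- -log(prob)
  f[counts < min_count] <- NA_real_
  if (all(is.na(f))) stop("every bin is below the sample-count floor",
                          call. = FALSE)
  f <- f - min(f, na.rm = TRUE)
  structure(list(F = f, prob = prob, counts = counts, grid = grid,
                 min_count = min_count),
            class = "we_fes")
}

#' Average free-energy surfaces across independent runs
#'
#' Per-run probability surfaces are averaged first, then \eqn{-\ln} is
#' taken, so low-probability bins sampled in only some runs are handled
#' consistently.
#'
#' @param fes_list list of \code{"we_fes"} objects on the same grid.
#' @return a \code{"we_fes"} with the averaged surface; a bin is masked
#'   unless it meets the sample floor in at least one run.
#' @export
average_fes <- function(fes_list) {
  stopifnot(length(fes_list) >= 1)
  p <- Reduce(`+`, lapply(fes_list, `[[`, "prob")) / length(fes_list)
  counts <- Reduce(`+`, lapply(fes_list, `[[`, "counts"))
  keep <- Reduce(`|`, lapply(fes_list, function(f) !is.na(f$F)))
  f <- -log(p)
  f[!keep] <- NA_real_
  f <- f - min(f, na.rm = TRUE)
  structure(list(F = f, prob = p, counts = counts,
                 grid = fes_list[[1]]$grid,
                 min_count = fes_list[[1]]$min_count),
            class = "we_fes")
}

#' @export
print.we_fes <- function(x, ...) {
  cat("Free-energy surface:", x$grid$n_bins, "bins,",
      sum(!is.na(x$F)), "above the sample floor; range",
      signif(max(x$F, na.rm = TRUE), 3), "kT\n")
  invisible(x)
}

#' @export
plot.we_fes <- function(x, ...) {
  g <- x$grid
  if (length(g$edges) == 1) {
    mid <- (head1(g$edges[[1]]) + tail1(g$edges[[1]])) / 2
    graphics::plot(mid, x$F, type = "b", xlab = "CV", ylab = "F (kT)", ...)
  } else {
    m <- matrix(x$F, nrow = g$nbins_dim[1], byrow = TRUE)
    mx <- (head1(g$edges[[1]]) + tail1(g$edges[[1]])) / 2
    my <- (head1(g$edges[[2]]) + tail1(g$edges[[2]])) / 2
    graphics::image(mx, my, m, xlab = "CV 1", ylab = "CV 2",
                    col = grDevices::hcl.colors(32, "viridis"), ...)
    graphics::contour(mx, my, m, add = TRUE, col = "white", lwd = 0.5)
  }
  invisible(x)
}

head1 <- function(v) v[-length(v)]
tail1 <- function(v) v[-1]

#' State-to-state rate constants from a weighted-ensemble run
#'
#' History-labelled flux estimator: every saved frame carries its walker's
#' last-visited defined state, propagated along lineages through the parent
#' pointers (the same lineage rule used for SPIB training pairs). The rate
#' \eqn{k(A \to B)} is the weight flux arriving in B while labelled A, per
#' unit time, divided by the time-averaged total weight labelled A. Early
#' iterations are excluded as burn-in.
#'
#' @param store a \code{\link{run_store}}.
#' @param states list of \code{\link{state_def}} (pairwise disjoint) over
#'   the stored coordinates (or over \code{cv_fun} of them).
#' @param burn_in fraction of iterations (in [0, 1)) or an integer count of
#'   iterations to exclude; default 0.1 of aggregate time.
#' @param frame_dt physical time per saved frame (default: dt * save stride
#'   if recorded, else 1).
#' @param cv_fun optional function mapping stored coordinates to the CVs the
#'   state predicates are defined over.
#' @return object of class \code{"rate_estimate"}: \code{rates} (K x K,
#'   1/time), \code{flux}, \code{occupancy}, \code{n_events}.
#' @export
estimate_rates <- function(store, states, burn_in = 0.1, frame_dt = NULL,
                           cv_fun = NULL) {
  check_states_disjoint(states)
  K <- length(states)
  n_it <- n_iterations(store)
  skip <- if (burn_in < 1) floor(burn_in * n_it) else as.integer(burn_in)
  if (is.null(frame_dt)) frame_dt <- 1
  # per-frame labels and state hits, walked in iteration order
  labels_prev <- NULL   # per segment: label at end of previous iteration
  flux <- matrix(0, K, K)
  occ <- numeric(K)
  n_events <- 0L
  for (i in seq_len(n_it)) {
    it <- store_iter(store, i)
    n <- dim(it$coords)[1]; S <- dim(it$coords)[2]; d <- dim(it$coords)[3]
    flat <- matrix(aperm(it$coords, c(2, 1, 3)), ncol = d)
    if (!is.null(cv_fun)) flat <- as.matrix(cv_fun(flat))
    st <- matrix(assign_states(flat, states), nrow = S)
    lab0 <- if (is.null(labels_prev)) integer(n)
            else labels_prev[pmax(it$parent_seg, 1L)] *
                 (it$parent_seg >= 1L)
    lab_end <- integer(n)
    for (wk in seq_len(n)) {
      lab <- history_labels(st[, wk], init = lab0[wk])
      lab_end[wk] <- lab[S]
      if (i > skip) {
        # transitions, including one across the iteration boundary
        prev <- c(lab0[wk], lab[-S])
        cur <- st[, wk]
        ev <- which(cur > 0 & prev > 0 & cur != prev)
        for (e in ev) {
          flux[prev[e], cur[e]] <- flux[prev[e], cur[e]] + it$weight[wk]
          n_events <- n_events + 1L
        }
        # occupancy over the real frames only
        for (s in unique(lab[lab > 0]))
          occ[s] <- occ[s] + it$weight[wk] * frame_dt * sum(lab == s)
      }
    }
    labels_prev <- lab_end
  }
  rates <- flux / ifelse(occ > 0, occ, NA_real_)
  diag(rates) <- 0
  nm <- vapply(states, `[[`, "", "name")
  dimnames(rates) <- list(nm, nm)
  dimnames(flux) <- list(nm, nm)
  names(occ) <- nm
  structure(list(rates = rates, flux = flux, occupancy = occ,
                 n_iterations = n_it, burn_in_iters = skip,
                 frame_dt = frame_dt),
            class = "rate_estimate")
}

#' Combine rate estimates from independent runs
#'
#' @param estimates list of \code{"rate_estimate"} from >= 2 independent
#'   runs.
#' @return list with \code{mean}, \code{sem} (standard error of the mean
#'   across runs) and \code{per_run} (array K x K x runs).
#' @export
combine_rates <- function(estimates) {
  stopifnot(length(estimates) >= 1)
  arr <- simplify2array(lapply(estimates, `[[`, "rates"))
  m <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  sem <- if (length(estimates) >= 2)
    apply(arr, c(1, 2), function(v) stats::sd(v, na.rm = TRUE) /
            sqrt(sum(is.finite(v))))
  else array(NA_real_, dim(m), dimnames = dimnames(m))
  list(mean = m, sem = sem, per_run = arr)
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("History-labelled flux rate estimate (",
      x$n_iterations, " iterations, ", x$burn_in_iters,
      " burn-in):\n", sep = "")
  print(signif(x$rates, 3))
  invisible(x)
}

#' Bayesian-bootstrap credible interval
#'
#' Draws \code{n_boot} Dirichlet(1, ..., 1) weight vectors over the
#' resampling units (independent runs or trajectory blocks), recomputes the
#' statistic under each, and returns the equal-tailed credible interval.
#'
#' @param values per-unit statistic values (length >= 2).
#' @param statistic function of (values, weights); default the weighted
#'   mean.
#' @param n_boot bootstrap draws.
#' @param level credibility level (default 0.95).
#' @param seed RNG seed.
#' @return list \code{interval} (length 2), \code{draws}, \code{mean}.
#' @export
bayesian_bootstrap_ci <- function(values, statistic = stats::weighted.mean,
                                  n_boot = 1000L, level = 0.95, seed = NULL) {
  n <- length(values)
  if (n < 2) stop("Bayesian bootstrap needs >= 2 resampling units",
                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rexp(n_boot * n), n_boot, n)
  g <- g / rowSums(g)
  draws <- apply(g, 1, function(w) statistic(values, w))
  a <- (1 - level) / 2
  list(interval = unname(stats::quantile(draws, c(a, 1 - a))),
       draws = draws, mean = mean(draws))
}

#' SPIB state-flux network from a run store
#'
#' Nodes are the model's metastable states with their weighted stationary
#' populations; edges are the row-normalized weighted transition
#' probabilities of state labels at lag \code{dt} along walker lineages.
#' Diagonal (self-jump) entries are reported, not suppressed. A single-state
#' model yields a trivial one-node network.
#'
#' @param model a fitted \code{"spib"} model.
#' @param store a \code{\link{run_store}}.
#' @param dt lag in saved frames (default the model's training lag if
#'   recorded, else half the frames per iteration).
#' @param window iterations to use (default all).
#' @param features optional coordinate-to-feature function.
#' @return object of class \code{"state_network"}: \code{populations},
#'   \code{jump} (K x K row-stochastic), \code{counts}.
#' @export
build_state_network <- function(model, store, dt = NULL, window = NULL,
                                features = NULL) {
  if (is.null(dt)) dt <- max(1L, dim(store_iter(store, 1)$coords)[2] %/% 2L)
  pairs <- build_lagged_pairs(store, dt, window, weight_mode = "use")
  xs <- pairs$x; xt <- pairs$x_lag
  if (!is.null(features)) { xs <- features(xs); xt <- features(xt) }
  l0 <- predict(model, xs, type = "state")
  l1 <- predict(model, xt, type = "state")
  K <- model$K
  cnt <- matrix(0, K, K)
  for (i in seq_along(l0)) cnt[l0[i], l1[i]] <- cnt[l0[i], l1[i]] + pairs$w[i]
  pop <- vapply(seq_len(K), function(k) sum(pairs$w[l1 == k]), 0.0)
  pop <- pop / sum(pop)
  rs <- rowSums(cnt)
  jump <- cnt / ifelse(rs > 0, rs, 1)
  structure(list(populations = pop, jump = jump, counts = cnt, dt = dt,
                 K = K),
            class = "state_network")
}

#' @export
print.state_network <- function(x, ...) {
  cat("SPIB state network:", x$K, "states at lag", x$dt, "frames\n")
  cat("Stationary populations:\n")
  print(round(x$populations, 4))
  cat("Jump probabilities (rows sum to 1):\n")
  print(round(x$jump, 3))
  invisible(x)
}

#' Write analysis outputs as plain-text tables
#'
#' Rates/populations go to CSV (source, target, mean, sem, per-run values);
#' the state network to an edge-list CSV.
#'
#' @param combined result of \code{\link{combine_rates}}.
#' @param path output CSV path.
#' @export
write_rates_csv <- function(combined, path) {
  nm <- rownames(combined$mean)
  rows <- list()
  for (a in seq_along(nm)) for (b in seq_along(nm)) if (a != b) {
    rows[[length(rows) + 1L]] <- data.frame(
      source = nm[a], target = nm[b],
      mean = combined$mean[a, b], sem = combined$sem[a, b],
      t(combined$per_run[a, b, ]))
  }
  df <- do.call(rbind, rows)
  names(df)[-(1:4)] <- paste0("run", seq_len(ncol(df) - 4))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates_csv
#' @param network a \code{"state_network"}.
#' @export
write_network_csv <- function(network, path) {
  K <- network$K
  df <- expand.grid(source = seq_len(K), target = seq_len(K))
  df$probability <- network$jump[cbind(df$source, df$target)]
  df$source_population <- network$populations[df$source]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
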