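#' Create a weighted-ensemble walker set
#'
#' A walker ensemble is the core data structure of the resampler: positions,
#' strictly positive statistical weights summing to 1, globally unique
#' lineage ids (which also seed each walker's RNG stream), the lineage of the
#' pre-resampling ancestor, parent segment indices into the previous stored
#' iteration, and history labels (index of the last-visited defined state,
#' 0 for none).
#'
#' @param pos n x d matrix of walker configurations.
#' @param weight numeric weights; default uniform. Must be > 0 and sum to 1
#'   within 1e-12 (never silently renormalized after construction).
#' @param history integer history labels (0 = none).
#' @return an object of class \code{"we_ensemble"}.
#' @export
we_ensemble <- function(pos, weight = NULL, history = NULL) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (is.null(weight)) weight <- rep(1 / n, n)
  if (is.null(history)) history <- integer(n)
  ens <- structure(list(pos = pos, weight = as.numeric(weight),
                        lineage = seq_len(n),
                        parent_lineage = integer(n),
                        parent_seg = integer(n),
                        history = as.integer(history),
                        next_lineage = n + 1L),
                   class = "we_ensemble")
  validate_ensemble(ens)
  ens
}

validate_ensemble <- function(ens, tol = 1e-12) {
  if (any(ens$weight <= 0))
    stop("walker weights must be strictly positive", call. = FALSE)
  if (abs(sum(ens$weight) - 1) > tol * max(1, length(ens$weight)))
    stop(sprintf("ensemble weight sum %.15f drifted from 1 beyond tolerance",
                 sum(ens$weight)), call. = FALSE)
  invisible(ens)
}

#' @export
print.we_ensemble <- function(x, ...) {
  cat("WE ensemble:", nrow(x$pos), "walkers, total weight",
      format(sum(x$weight), digits = 15), "\n")
  invisible(x)
}

#' Split a walker into m children
#'
#' Children copy the parent's position, history label and stored-segment
#' pointer, receive weight \code{w/m} each, fresh lineage ids and the
#' parent's lineage as their \code{parent_lineage}. The first child replaces
#' the parent's row (so bin alignments by position survive); the rest are
#' appended. Total weight is conserved exactly.
#'
#' @param ens a \code{\link{we_ensemble}}.
#' @param i index of the walker to split.
#' @param m number of children (>= 2).
#' @return the modified ensemble (n + m - 1 walkers).
#' @export
split_walker <- function(ens, i, m) {
  if (m < 2) stop("split requires m >= 2", call. = FALSE)
  w <- ens$weight[i]
  child_w <- rep(w / m, m)
  child_w[m] <- w - sum(child_w[-m])   # exact conservation
  ids <- ens$next_lineage + seq_len(m) - 1L
  par <- ens$lineage[i]
  extra <- m - 1L
  ens$weight[i] <- child_w[1]
  ens$lineage[i] <- ids[1]
  ens$parent_lineage[i] <- par
  ens$pos <- rbind(ens$pos, ens$pos[rep(i, extra), , drop = FALSE])
  ens$weight <- c(ens$weight, child_w[-1])
  ens$lineage <- c(ens$lineage, ids[-1])
  ens$parent_lineage <- c(ens$parent_lineage, rep(par, extra))
  ens$parent_seg <- c(ens$parent_seg, rep(ens$parent_seg[i], extra))
  ens$history <- c(ens$history, rep(ens$history[i], extra))
  ens$next_lineage <- ens$next_lineage + m
  ens
}

#' Merge a group of walkers into one survivor
#'
#' The survivor is chosen with probability proportional to weight (from the
#' current R RNG stream), keeps its own position, lineage and history label,
#' and receives the group's summed weight; the other rows are deleted.
#'
#' @param ens a \code{\link{we_ensemble}}.
#' @param idx indices of the group (length >= 2; callers ensure one bin).
#' @return list \code{ens} (modified ensemble) and \code{dropped} (the
#'   original row indices removed).
#' @export
merge_walkers <- function(ens, idx) {
  if (length(idx) < 2) stop("merge requires a group of >= 2", call. = FALSE)
  w <- ens$weight[idx]
  surv <- idx[sample.int(length(idx), 1L, prob = w)]
  ens$weight[surv] <- sum(w)
  dropped <- setdiff(idx, surv)
  keep <- setdiff(seq_along(ens$weight), dropped)
  for (f in c("weight", "lineage", "parent_lineage", "parent_seg", "history"))
    ens[[f]] <- ens[[f]][keep]
  ens$pos <- ens$pos[keep, , drop = FALSE]
  list(ens = ens, dropped = dropped)
}

#' Split/merge an ensemble to the per-bin target count
#'
#' Standard weighted-ensemble resampling: in every occupied bin, while the
#' walker count is below \code{M} the currently heaviest walker is split in
#' two; while above \code{M} the two lightest walkers are merged (survivor
#' weight-proportional). Ties break by lineage id, so the result is
#' deterministic given the RNG state. Empty bins stay empty, no walker
#' changes bin, per-bin weight is preserved, and total-weight drift beyond
#' 1e-12 is a hard failure — never a silent renormalization. An ensemble
#' already at \code{M} walkers in every occupied bin is returned unchanged.
#'
#' @param ens a \code{\link{we_ensemble}}.
#' @param bins integer bin id per walker (aligned with the ensemble).
#' @param M target number of walkers per occupied bin (>= 2).
#' @return list \code{ens} and \code{bins} (updated per-walker bin ids).
#' @export
resample <- function(ens, bins, M = 4L) {
  if (M < 2) stop("target walkers per bin must be >= 2", call. = FALSE)
  if (length(bins) != length(ens$weight))
    stop("bin assignments not aligned with walkers", call. = FALSE)
  w0 <- sum(ens$weight)
  bins <- as.integer(as.vector(bins))
  for (b in sort(unique(bins))) {
    repeat {
      idx <- which(bins == b)
      if (length(idx) == M) break
      if (length(idx) < M) {
        hv <- idx[order(-ens$weight[idx], ens$lineage[idx])][1]
        ens <- split_walker(ens, hv, 2L)
        bins <- c(bins, b)           # one child appended, one replaced in place
      } else {
        lo <- idx[order(ens$weight[idx], ens$lineage[idx])][1:2]
        res <- merge_walkers(ens, lo)
        ens <- res$ens
        bins <- bins[-res$dropped]
      }
    }
  }
  drift <- abs(sum(ens$weight) - w0)
  if (drift > 1e-12)
    stop(sprintf("weight sum drifted by %.3e during resampling", drift),
         call. = FALSE)
  list(ens = ens, bins = bins)
}

#' Run one weighted-ensemble iteration
#'
#' Propagates every walker for \code{tau} integrator steps (saving frames at
#' the save stride), updates history labels from the saved frames, appends
#' the pre-resampling segment data to the run store, assigns bins with the
#' current mapper, and resamples to \code{M} walkers per occupied bin.
#' Resampling draws come from an R RNG stream seeded deterministically from
#' (run seed, iteration), so a killed run resumed at an iteration boundary
#' reproduces an uninterrupted run exactly.
#'
#' @param ens a \code{\link{we_ensemble}}.
#' @param propagator a function \code{(pos, lineage, iteration)} returning
#'   \code{list(frames = n x S x d array, final = n x d matrix)}; see
#'   \code{\link{make_brownian_propagator}}.
#' @param mapper a bin mapper.
#' @param config a \code{\link{we_config}}.
#' @param store a \code{\link{run_store}} (or NULL to skip archiving).
#' @param iteration 1-based iteration number.
#' @param states optional list of \code{\link{state_def}} used to update
#'   history labels (predicates over the raw coordinates).
#' @param run_seed seed for the iteration's resampling stream.
#' @return list \code{ens} (post-resampling ensemble) and \code{bins}.
#' @export
run_we_iteration <- function(ens, propagator, mapper, config, store = NULL,
                             iteration = 1L, states = NULL, run_seed = 1) {
  validate_ensemble(ens, tol = 1e-10)
  prop <- propagator(ens$pos, ens$lineage, iteration)
  frames <- prop$frames
  n <- nrow(ens$pos)
  S <- dim(frames)[2]
  d <- dim(frames)[3]
  # history labels walked through the saved frames
  if (!is.null(states) && length(states)) {
    flat <- matrix(aperm(frames, c(2, 1, 3)), ncol = d)  # frame-major per walker
    st <- matrix(assign_states(flat, states), nrow = S)
    for (w in seq_len(n)) {
      sw <- st[, w]
      hit <- which(sw > 0)
      if (length(hit)) ens$history[w] <- sw[hit[length(hit)]]
    }
  }
  ens$pos <- prop$final
  bins <- assign_bins(mapper, ens$pos)
  if (!is.null(store)) {
    store_append(store, iteration,
                 coords = frames, weight = ens$weight,
                 parent_seg = ens$parent_seg, lineage = ens$lineage,
                 bin_id = as.integer(bins), history = ens$history,
                 clamped = attr(bins, "clamped"),
                 routed_expert = attr(bins, "routed_expert"))
  }
  # next iteration's walkers descend from the segments just stored
  ens$parent_seg <- seq_len(n)
  set.seed(hash32(run_seed, 7919, iteration))
  out <- resample(ens, bins, config$M)
  validate_ensemble(out$ens, tol = 1e-10)
  out
}

#' Weighted-ensemble run configuration
#'
#' @param tau resampling time in integrator steps per iteration (> 0).
#' @param M target walkers per occupied bin (>= 2; default 4).
#' @param save_every frame-saving stride in steps (tau must be a multiple);
#'   defaults to saving 5 frames per iteration.
#' @export
we_config <- function(tau = 50L, M = 4L, save_every = max(1L, tau %/% 5L)) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (M < 2) stop("M must be >= 2", call. = FALSE)
  if (tau %% save_every != 0)
    stop("tau must be a multiple of save_every", call. = FALSE)
  structure(list(tau = as.integer(tau), M = as.integer(M),
                 save_every = as.integer(save_every),
                 frames_per_iter = as.integer(tau %/% save_every)),
            class = "we_config")
}

#' Brownian-dynamics propagator factory
#'
#' Wraps \code{\link{brownian_propagate}} into the propagator interface used
#' by \code{\link{run_we_iteration}}.
#'
#' @param pot a \code{\link{toy_potential}}.
#' @param params a \code{\link{dynamics_params}}.
#' @param config a \code{\link{we_config}}.
#' @return function of \code{(pos, lineage, iteration)}.
#' @export
make_brownian_propagator <- function(pot, params, config) {
  force(pot); force(params); force(config)
  function(pos, lineage, iteration) {
    brownian_propagate(pos, pot, params, n_steps = config$tau,
                       save_every = config$save_every,
                       lineage = lineage, iteration = iteration)
  }
}
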