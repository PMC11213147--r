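#' Configuration of the iterative SPIB-WE protocol
#'
#' Bundles the schedule of the hybrid workflow: \code{N0} initial
#' expert-only WE iterations, SPIB training at iteration \code{N0} and every
#' \code{Nupdate} iterations after, each training using the last
#' \code{Nlast} iterations, with walker weights ignored during the first
#' \code{weight_ignore} iterations (so newly explored low-weight states are
#' not discarded by the state-population rule).
#'
#' @param pot a \code{\link{toy_potential}} (or NULL with a custom
#'   propagator).
#' @param params a \code{\link{dynamics_params}}.
#' @param expert_grid a \code{\link{rect_grid}} over the expert CVs.
#' @param n_iterations total WE iterations to run.
#' @param N0 expert-only iterations before the first SPIB training (>= 1).
#' @param Nupdate iterations between retrainings (>= 1).
#' @param Nlast training-window length in iterations (>= Nupdate).
#' @param weight_ignore iteration horizon below which SPIB training ignores
#'   the walker weights.
#' @param B_target desired occupied latent bins.
#' @param we a \code{\link{we_config}}.
#' @param spib_dt SPIB lag in saved frames; default half the frames saved
#'   per iteration (i.e. half the resampling time).
#' @param spib_args list of extra arguments to \code{\link{spib}} (hidden
#'   sizes, epochs, ...).
#' @param states optional list of \code{\link{state_def}} for history labels.
#' @param features optional function mapping coordinates to SPIB input
#'   features (default identity).
#' @param start starting configuration (1 x d matrix or length-d vector);
#'   the initial ensemble is M copies of it.
#' @param seed run seed; every stream (propagation, resampling, training) is
#'   derived from it deterministically.
#' @param checkpoint optional file path; the run state is checkpointed there
#'   every iteration, and \code{\link{run_protocol}} can resume from it.
#' @param max_training_frames cap on SPIB training pairs (deterministic
#'   thinning keeps training time bounded on long runs).
#' @param sequential_occupancy passed to \code{\link{hybrid_mapper}}.
#' @export
protocol_config <- function(pot, params, expert_grid, n_iterations,
                            N0 = 20L, Nupdate = 20L, Nlast = 500L,
                            weight_ignore = 100L, B_target = 100L,
                            we = we_config(), spib_dt = NULL,
                            spib_args = list(), states = NULL,
                            features = NULL, start = NULL, seed = 1L,
                            checkpoint = NULL,
                            max_training_frames = 20000L,
                            sequential_occupancy = FALSE) {
  stopifnot(N0 >= 1, Nupdate >= 1, Nlast >= Nupdate)
  if (is.null(spib_dt)) spib_dt <- max(1L, we$frames_per_iter %/% 2L)
  if (is.null(start))
    start <- c(mean(pot$domain[1:2]), mean(pot$domain[3:4]))
  structure(list(pot = pot, params = params, expert_grid = expert_grid,
                 n_iterations = as.integer(n_iterations),
                 N0 = as.integer(N0), Nupdate = as.integer(Nupdate),
                 Nlast = as.integer(Nlast),
                 weight_ignore = as.integer(weight_ignore),
                 B_target = as.integer(B_target), we = we,
                 spib_dt = as.integer(spib_dt), spib_args = spib_args,
                 states = states, features = features, start = start,
                 seed = seed, checkpoint = checkpoint,
                 max_training_frames = as.integer(max_training_frames),
                 sequential_occupancy = sequential_occupancy),
            class = "protocol_config")
}

#' Run (or resume) the iterative SPIB-WE protocol
#'
#' Executes the full hybrid workflow: iterations 1..N0 use the expert
#' mapper; at every iteration i >= N0 with (i - N0) mod Nupdate = 0 a SPIB
#' model is (re)trained on the last min(i, Nlast) iterations, the latent
#' grid is refit, the undersampled mask recomputed, and the new hybrid
#' mapper swapped in for subsequent iterations. Every retraining and mapper
#' swap is logged with its iteration number in the run store, making the
#' mapper in force at any iteration reconstructible from the store. A SPIB
#' training failure logs a warning and sampling continues with the previous
#' mapper. With a checkpoint path configured the run is resumable: a killed
#' run restarted with \code{resume = TRUE} reproduces an uninterrupted run
#' bit for bit.
#'
#' @param config a \code{\link{protocol_config}}.
#' @param resume continue from the configured checkpoint if it exists.
#' @param propagator optional custom propagator (default: Brownian dynamics
#'   on \code{config$pot}).
#' @return an object of class \code{"spibwe_run"}: the \code{store}, the
#'   final \code{ensemble}, the last \code{model} (or NULL), the current
#'   \code{mapper}, \code{models} (one per training, with iteration stamps)
#'   and the \code{config}.
#' @export
run_protocol <- function(config, resume = FALSE, propagator = NULL) {
  if (is.null(propagator))
    propagator <- make_brownian_propagator(config$pot, config$params,
                                           config$we)
  state <- NULL
  if (resume && !is.null(config$checkpoint) && file.exists(config$checkpoint))
    state <- readRDS(config$checkpoint)
  if (is.null(state)) {
    pos <- matrix(rep(as.numeric(config$start), each = config$we$M),
                  nrow = config$we$M)
    hist0 <- if (!is.null(config$states))
      assign_states(pos, config$states) else NULL
    ens <- we_ensemble(pos, history = hist0)
    store <- run_store(tau = config$we$tau, M = config$we$M,
                       save_every = config$we$save_every)
    store$log$mappers[[1]] <- list(iteration = 0L, kind = "expert")
    state <- list(iter_done = 0L, ens = ens,
                  store_data = NULL, model = NULL, models = list(),
                  mapper_extra = NULL, expert_grid = config$expert_grid,
                  n_retrain = 0L)
  } else {
    store <- run_store(tau = config$we$tau, M = config$we$M,
                       save_every = config$we$save_every)
    store$iters <- state$store_data$iters
    store$attrs <- state$store_data$attrs
    store$log <- state$store_data$log
    ens <- state$ens
  }

  current_mapper <- function() {
    if (is.null(state$mapper_extra)) state$expert_grid
    else hybrid_mapper(state$expert_grid, state$mapper_extra$latent,
                       state$model, state$mapper_extra$mask,
                       sequential = config$sequential_occupancy,
                       features = config$features)
  }

  i <- state$iter_done
  while (i < config$n_iterations) {
    i <- i + 1L
    mapper <- current_mapper()
    out <- run_we_iteration(ens, propagator, mapper, config$we,
                            store = store, iteration = i,
                            states = config$states, run_seed = config$seed)
    ens <- out$ens
    st_it <- store_iter(store, i)
    store$log$routing[[i]] <- list(
      iteration = i,
      routed_expert = if (is.null(st_it$routed_expert)) NA_integer_
                      else st_it$routed_expert,
      n_walkers = length(st_it$weight))

    if (i >= config$N0 && (i - config$N0) %% config$Nupdate == 0L) {
      state$n_retrain <- state$n_retrain + 1L
      window <- seq(max(1L, i - config$Nlast + 1L), i)
      wmode <- if (i < config$weight_ignore) "ignore" else "use"
      trained <- tryCatch({
        pairs <- build_lagged_pairs(store, config$spib_dt, window, wmode)
        pairs <- thin_pairs(pairs, config$max_training_frames, config$seed)
        feats <- config$features
        if (!is.null(feats)) {
          pairs$x <- feats(pairs$x); pairs$x_lag <- feats(pairs$x_lag)
        }
        args <- c(list(x = pairs, seed = hash32(config$seed, state$n_retrain),
                       weighted_population = (wmode == "use"),
                       warm_start = state$model),
                  config$spib_args)
        model <- do.call(spib, args)
        z <- predict(model, pairs$x_lag, type = "latent")
        lg <- fit_latent_grid(z, config$B_target)
        fr <- store_frames(store, window)
        mask <- compute_undersampled_mask(fr$x, state$expert_grid,
                                          iteration = i)
        list(model = model, latent = lg, mask = mask)
      }, error = function(e) e)
      if (inherits(trained, "error")) {
        warning("SPIB training at iteration ", i, " failed (",
                conditionMessage(trained),
                "); continuing with the previous mapper", call. = FALSE)
        store$log$retrain[[length(store$log$retrain) + 1L]] <-
          list(iteration = i, ok = FALSE, msg = conditionMessage(trained))
      } else {
        state$model <- trained$model
        state$mapper_extra <- list(latent = trained$latent,
                                   mask = trained$mask)
        state$models[[length(state$models) + 1L]] <-
          list(iteration = i, model = trained$model,
               latent = trained$latent, mask = trained$mask)
        store$log$retrain[[length(store$log$retrain) + 1L]] <-
          list(iteration = i, ok = TRUE, K = trained$model$K,
               h = trained$latent$h,
               n_occupied = trained$latent$n_occupied)
        store$log$mappers[[length(store$log$mappers) + 1L]] <-
          list(iteration = i, kind = "hybrid", K = trained$model$K)
      }
    }

    state$iter_done <- i
    state$ens <- ens
    if (!is.null(config$checkpoint)) {
      state$store_data <- list(iters = store$iters, attrs = store$attrs,
                               log = store$log)
      saveRDS(state, config$checkpoint)
    }
  }

  structure(list(store = store, ensemble = ens, model = state$model,
                 mapper = current_mapper(), models = state$models,
                 expert_grid = state$expert_grid, config = config),
            class = "spibwe_run")
}

attr_or <- function(x, a, default) {
  v <- attr(x, a)
  if (is.null(v)) default else v
}

# deterministic thinning of a lagged dataset to at most n_max pairs
thin_pairs <- function(pairs, n_max, seed) {
  n <- nrow(pairs$x)
  if (n <= n_max) return(pairs)
  set.seed(hash32(seed, 65537, n))
  keep <- sort(sample.int(n, n_max))
  pairs$x <- pairs$x[keep, , drop = FALSE]
  pairs$x_lag <- pairs$x_lag[keep, , drop = FALSE]
  pairs$w <- pairs$w[keep]
  pairs
}

#' Swap the expert CV grid of a paused run
#'
#' At an iteration boundary (i.e. on a completed \code{"spibwe_run"} or a
#' checkpointed state) replaces the expert grid used for undersampled-region
#' detection and hybrid assignment in all subsequent iterations; the swap is
#' recorded with its iteration stamp in the store log. The undersampled mask
#' is recomputed against the new grid at the next SPIB training, per the
#' update rule.
#'
#' @param run a \code{"spibwe_run"}.
#' @param new_grid a \code{\link{rect_grid}}.
#' @return the modified run; continue it with \code{\link{continue_protocol}}.
#' @export
swap_expert_cvs <- function(run, new_grid) {
  stopifnot(inherits(run, "spibwe_run"), inherits(new_grid, "rect_grid"))
  it <- n_iterations(run$store)
  run$store$log$swaps[[length(run$store$log$swaps) + 1L]] <-
    list(iteration = it, n_bins = new_grid$n_bins)
  if (identical(new_grid, run$expert_grid)) return(run)   # true no-op
  run$expert_grid <- new_grid
  # the mask's indices refer to the old grid, so a changed grid forces one
  # immediate recomputation to keep the hybrid rule well-defined; scheduled
  # recomputation otherwise happens only at SPIB trainings
  if (!is.null(run$model)) {
    fr <- store_frames(run$store,
                       seq(max(1L, it - run$config$Nlast + 1L), it))
    mask <- compute_undersampled_mask(fr$x, new_grid, iteration = it)
    run$mapper <- hybrid_mapper(new_grid, run$mapper$latent, run$model, mask,
                                sequential = run$config$sequential_occupancy,
                                features = run$config$features)
  } else {
    run$mapper <- new_grid
  }
  run
}

#' Continue a finished protocol run for more iterations
#'
#' @param run a \code{"spibwe_run"}.
#' @param n_more additional WE iterations.
#' @param propagator optional custom propagator.
#' @return the extended \code{"spibwe_run"}.
#' @export
continue_protocol <- function(run, n_more, propagator = NULL) {
  config <- run$config
  config$n_iterations <- n_iterations(run$store) + as.integer(n_more)
  config$expert_grid <- run$expert_grid
  if (is.null(propagator))
    propagator <- make_brownian_propagator(config$pot, config$params,
                                           config$we)
  # rebuild a checkpoint-like state and reuse the main loop
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp), add = TRUE)
  mex <- NULL
  if (!is.null(run$model) && inherits(run$mapper, "hybrid_mapper"))
    mex <- list(latent = run$mapper$latent, mask = run$mapper$mask)
  state <- list(iter_done = n_iterations(run$store), ens = run$ensemble,
                store_data = list(iters = run$store$iters,
                                  attrs = run$store$attrs,
                                  log = run$store$log),
                model = run$model, models = run$models,
                mapper_extra = mex, expert_grid = run$expert_grid,
                n_retrain = length(run$models))
  saveRDS(state, tmp)
  config$checkpoint <- tmp
  out <- run_protocol(config, resume = TRUE, propagator = propagator)
  out$config$checkpoint <- run$config$checkpoint
  out
}

#' @export
print.spibwe_run <- function(x, ...) {
  cat("SPIB-WE run:", n_iterations(x$store), "iterations,",
      length(x$models), "SPIB trainings\n")
  if (!is.null(x$model))
    cat("Current model: K =", x$model$K, "states; latent grid h =",
        signif(x$mapper$latent$h, 3), "\n")
  cat("Final ensemble:", nrow(x$ensemble$pos), "walkers, total weight",
      format(sum(x$ensemble$weight), digits = 15), "\n")
  invisible(x)
}

#' @export
summary.spibwe_run <- function(object, ...) {
  rt <- object$store$log$retrain
  if (length(rt)) {
    cat("Retraining log:\n")
    for (r in rt)
      cat(sprintf("  iter %4d: %s%s\n", r$iteration,
                  if (isTRUE(r$ok)) paste0("K = ", r$K, ", ",
                                           r$n_occupied, " occupied bins")
                  else paste("FAILED:", r$msg), ""))
  } else cat("No SPIB trainings (expert-only run)\n")
  routed <- vapply(object$store$log$routing, function(r)
    if (is.na(r$routed_expert)) 0 else r$routed_expert / r$n_walkers, 0.0)
  cat(sprintf("Mean fraction routed to expert bins: %.3f\n", mean(routed)))
  invisible(object)
}
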