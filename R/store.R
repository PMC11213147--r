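#' Per-iteration run archive
#'
#' The run store keeps, for every WE iteration, the pre-resampling segment
#' data: saved coordinate frames (walkers x frames x dims), walker weights,
#' parent segment indices into the previous iteration, lineage ids, bin
#' assignments and history labels, plus run-level attributes (tau, M, mapper
#' descriptions, retraining and routing logs). It is an in-memory structure
#' backed by an environment, checkpointed to disk with
#' \code{\link{save_run_store}} / \code{\link{load_run_store}}; readers
#' tolerate missing optional fields.
#'
#' @param tau,M,save_every run attributes recorded for provenance.
#' @return an object of class \code{"run_store"}.
#' @export
run_store <- function(tau = NA_integer_, M = NA_integer_,
                      save_every = NA_integer_) {
  e <- new.env(parent = emptyenv())
  e$iters <- list()
  e$attrs <- list(tau = tau, M = M, save_every = save_every)
  e$log <- list(retrain = list(), routing = list(), swaps = list(),
                mappers = list())
  class(e) <- "run_store"
  e
}

store_append <- function(store, iteration, coords, weight, parent_seg,
                         lineage, bin_id, history, clamped = 0L,
                         routed_expert = NA_integer_) {
  store$iters[[iteration]] <- list(
    coords = coords, weight = weight, parent_seg = as.integer(parent_seg),
    lineage = as.integer(lineage), bin_id = as.integer(bin_id),
    history = as.integer(history), clamped = clamped,
    routed_expert = routed_expert)
  invisible(store)
}

#' @export
print.run_store <- function(x, ...) {
  n <- n_iterations(x)
  cat("Run store:", n, "iteration(s)")
  if (n) {
    nw <- vapply(x$iters, function(it) nrow(it$coords), 0L)
    cat(";", sum(nw * dim(x$iters[[1]]$coords)[2]), "stored frames,",
        "walkers per iteration", min(nw), "-", max(nw))
  }
  cat("\n")
  invisible(x)
}

#' @export
#' @rdname run_store
#' @param store a run store.
n_iterations <- function(store) length(store$iters)

store_iter <- function(store, i) {
  if (i < 1 || i > n_iterations(store))
    stop("iteration ", i, " not in store", call. = FALSE)
  store$iters[[i]]
}

# flat matrix of all saved frames of iterations in `window` (increasing),
# with per-frame weight, iteration, walker and frame indices
store_frames <- function(store, window = seq_len(n_iterations(store))) {
  parts <- lapply(window, function(i) {
    it <- store$iters[[i]]
    n <- dim(it$coords)[1]; S <- dim(it$coords)[2]; d <- dim(it$coords)[3]
    x <- matrix(aperm(it$coords, c(2, 1, 3)), ncol = d)
    list(x = x, w = rep(it$weight, each = S),
         iter = rep(i, n * S), walker = rep(seq_len(n), each = S),
         frame = rep(seq_len(S), times = n))
  })
  list(x = do.call(rbind, lapply(parts, `[[`, "x")),
       w = unlist(lapply(parts, `[[`, "w")),
       iter = unlist(lapply(parts, `[[`, "iter")),
       walker = unlist(lapply(parts, `[[`, "walker")),
       frame = unlist(lapply(parts, `[[`, "frame")))
}

#' Checkpoint a run store to disk
#'
#' Serializes the store (a runtime artifact) so long runs can be resumed and
#' analyzed later.
#' @param store a \code{\link{run_store}}.
#' @param path file path.
#' @export
save_run_store <- function(store, path) {
  saveRDS(list(iters = store$iters, attrs = store$attrs, log = store$log),
          path)
  invisible(path)
}

#' @rdname save_run_store
#' @export
load_run_store <- function(path) {
  obj <- readRDS(path)
  e <- run_store()
  e$iters <- obj$iters
  e$attrs <- obj$attrs
  if (!is.null(obj$log)) e$log <- obj$log
  e
}
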