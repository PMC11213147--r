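#' Enumerate input feature pairs
#'
#' Site-pair enumeration used to build distance feature sets: all unordered
#' pairs (i, j) with i < j and j - i >= \code{min_separation}, in
#' lexicographic order. With 10 sites and no separation constraint this
#' gives the 45 all-pair distances; requiring at least two intervening sites
#' (\code{min_separation = 3}) gives the 28 nearest-neighbour residue
#' distances of a 10-residue chain.
#'
#' @param n_sites number of sites (>= 2).
#' @param min_separation minimum index separation j - i (>= 1).
#' @return integer matrix with columns \code{i}, \code{j}.
#' @examples
#' nrow(enumerate_feature_pairs(10, 1))  # 45
#' nrow(enumerate_feature_pairs(10, 3))  # 28
#' @export
enumerate_feature_pairs <- function(n_sites, min_separation = 1L) {
  if (n_sites < 2) stop("need at least 2 sites", call. = FALSE)
  out <- list()
  for (i in seq_len(n_sites - 1))
    for (j in seq(i + 1, n_sites))
      if (j - i >= min_separation) out[[length(out) + 1L]] <- c(i, j)
  if (!length(out))
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("i", "j")
  m
}

#' Build time-lagged training pairs from a run store
#'
#' Emits every (x_t, x_{t+dt}) frame pair lying exactly \code{dt} saved
#' frames apart on one continuous walker lineage. Lineages are followed
#' backwards through the stored parent pointers across resampling: a split
#' walker's children each continue the parent's frame history (so both
#' contribute pairs), and a pruned branch ends — pairs never bridge it.
#'
#' @param store a \code{\link{run_store}}.
#' @param dt lag in saved frames (>= 1).
#' @param window iterations whose frames serve as pair *targets*; default the
#'   whole store. Source frames may reach back before the window.
#' @param weight_mode \code{"use"} takes each target frame's stored walker
#'   weight; \code{"ignore"} sets all pair weights equal.
#' @return list of class \code{"lagged_dataset"}: \code{x} (source features),
#'   \code{x_lag} (target features), \code{w} (pair weights), \code{dt}.
#' @export
build_lagged_pairs <- function(store, dt, window = NULL,
                               weight_mode = c("use", "ignore")) {
  weight_mode <- match.arg(weight_mode)
  n_it <- n_iterations(store)
  if (is.null(window)) window <- seq_len(n_it)
  window <- sort(window)
  dt <- as.integer(dt)
  if (dt < 1) stop("lag must be >= 1 frame", call. = FALSE)
  S <- dim(store_iter(store, window[1])$coords)[2]
  d <- dim(store_iter(store, window[1])$coords)[3]
  src <- list(); tgt <- list(); wts <- list()
  for (i in window) {
    it <- store_iter(store, i)
    n <- dim(it$coords)[1]
    # target frame f pairs with frame f - dt, which lies `back` iterations
    # earlier on the lineage (back = 0: within this segment)
    for (f in seq_len(S)) {
      back <- ceiling((dt - f + 1) / S)
      if (back < 0) back <- 0L
      gf <- f - dt + back * S
      if (i - back < 1) next
      # follow parent pointers `back` steps; drop walkers whose chain breaks
      gw <- seq_len(n)
      ok <- rep(TRUE, n)
      gi <- i
      for (k in seq_len(back)) {
        p <- store$iters[[gi]]$parent_seg[gw]
        p[is.na(p)] <- 0L
        ok <- ok & p >= 1L
        gw <- pmax(p, 1L)
        gi <- gi - 1L
      }
      if (!any(ok)) next
      srcm <- store$iters[[gi]]$coords[gw[ok], gf, , drop = FALSE]
      tgtm <- it$coords[which(ok), f, , drop = FALSE]
      k <- length(src) + 1L
      src[[k]] <- matrix(srcm, ncol = d)
      tgt[[k]] <- matrix(tgtm, ncol = d)
      wts[[k]] <- it$weight[ok]
    }
  }
  if (!length(src))
    stop("no valid lagged pairs: no lineage holds ", dt + 1,
         " consecutive saved frames", call. = FALSE)
  w <- unlist(wts)
  if (weight_mode == "ignore") w <- rep(1, length(w))
  structure(list(x = do.call(rbind, src), x_lag = do.call(rbind, tgt),
                 w = w, dt = dt),
            class = "lagged_dataset")
}

# ---------------------------------------------------------------------------
# small MLP machinery (base-R matrix code; Adam optimizer)

relu <- function(x) x * (x > 0)

mlp_init <- function(sizes) {
  # He-scaled init; caller controls the RNG state
  layers <- list()
  for (l in seq_len(length(sizes) - 1)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1]),
      b = rep(0, sizes[l + 1]))
  }
  layers
}

adam_new <- function(params, lr = 2e-3, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(lr = lr, b1 = b1, b2 = b2, eps = eps, t = 0, m = zeros, v = zeros)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  flat_upd <- function(p, g, m, v) {
    m <- opt$b1 * m + (1 - opt$b1) * g
    v <- opt$b2 * v + (1 - opt$b2) * g * g
    mh <- m / (1 - opt$b1^opt$t)
    vh <- v / (1 - opt$b2^opt$t)
    list(p = p - opt$lr * mh / (sqrt(vh) + opt$eps), m = m, v = v)
  }
  for (i in seq_along(params)) for (j in seq_along(params[[i]])) {
    u <- flat_upd(params[[i]][[j]], grads[[i]][[j]],
                  opt$m[[i]][[j]], opt$v[[i]][[j]])
    params[[i]][[j]] <- u$p
    opt$m[[i]][[j]] <- u$m
    opt$v[[i]][[j]] <- u$v
  }
  list(opt = opt, params = params)
}

# forward through encoder: list(h_pre..., mu, lv)
enc_forward <- function(enc, X) {
  h1p <- sweep(X %*% enc[[1]]$W, 2, enc[[1]]$b, `+`)
  h1 <- relu(h1p)
  h2p <- sweep(h1 %*% enc[[2]]$W, 2, enc[[2]]$b, `+`)
  h2 <- relu(h2p)
  mu <- sweep(h2 %*% enc[[3]]$W, 2, enc[[3]]$b, `+`)
  lv <- sweep(h2 %*% enc[[4]]$W, 2, enc[[4]]$b, `+`)
  lv <- pmin(pmax(lv, -10), 10)
  list(h1p = h1p, h1 = h1, h2p = h2p, h2 = h2, mu = mu, lv = lv)
}

dec_forward <- function(dec, Z) {
  g1p <- sweep(Z %*% dec[[1]]$W, 2, dec[[1]]$b, `+`)
  g1 <- relu(g1p)
  g2p <- sweep(g1 %*% dec[[2]]$W, 2, dec[[2]]$b, `+`)
  g2 <- relu(g2p)
  logits <- sweep(g2 %*% dec[[3]]$W, 2, dec[[3]]$b, `+`)
  list(g1p = g1p, g1 = g1, g2p = g2p, g2 = g2, logits = logits)
}

softmax_active <- function(logits, active) {
  l <- logits[, active, drop = FALSE]
  l <- l - apply(l, 1, max)
  e <- exp(l)
  e / rowSums(e)
}

# ---------------------------------------------------------------------------

#' Fit a State Predictive Information Bottleneck model
#'
#' Learns a low-dimensional continuous collective-variable space together
#' with a metastable-state labelling of the data. An encoder network maps
#' input features to a 2D latent Gaussian (mean and log-variance); a decoder
#' predicts, from a latent sample, the metastable-state label the system
#' will carry a lag time \eqn{\Delta t} in the future. The objective is the
#' weighted cross-entropy of that prediction plus \code{beta} times a
#' KL regularizer pulling the encoder posterior towards a standard-normal
#' prior, so the latent code keeps only information relevant to state-to-state
#' transitions: the lag acts as a fast-mode filter, and states with
#' lifetimes below \eqn{\Delta t} are absorbed into their neighbours.
#'
#' Training alternates gradient epochs with label refinement: every frame is
#' relabelled to the decoder's argmax at the frame's own latent mean, states
#' whose population falls below \code{pop_threshold} are deleted (their
#' frames move to the next-best state), and the loop stops when fewer than
#' \code{tol} of the (weighted) frames change label, or after
#' \code{max_rounds} rounds. The number of states K is therefore discovered,
#' not prescribed.
#'
#' @param x n x d matrix of input features at time t (pair sources).
#' @param x_lag n x d matrix of the same features at time t + lag (pair
#'   targets); labels live on these frames. Alternatively pass a
#'   \code{"lagged_dataset"} from \code{\link{build_lagged_pairs}} as
#'   \code{x} and omit \code{x_lag}.
#' @param weights optional pair weights (e.g. WE walker weights); default
#'   equal. Doubling all weights leaves the objective unchanged.
#' @param beta information-bottleneck trade-off (default 1e-3).
#' @param hidden hidden-layer widths of both networks (default c(64, 64)).
#' @param latent_dim latent dimension (default 2).
#' @param init_labels optional integer starting labels for the target
#'   frames; default: deterministic coarse-grid clustering of the features
#'   (first two principal components when d > 2) with \code{init_grid} cells
#'   per dimension.
#' @param init_grid cells per dimension of the initial grid clustering.
#' @param lr,batch_size,epochs Adam learning rate, minibatch size and
#'   gradient epochs per refinement round.
#' @param max_rounds,tol refinement rounds cap and weighted label-change
#'   fraction below which training stops.
#' @param pop_threshold state-population deletion threshold (default 1e-3).
#' @param weighted_population use weighted (TRUE) or frame-count (FALSE)
#'   populations for the deletion rule.
#' @param seed RNG seed for initialization, sampling and minibatching.
#' @param warm_start optional previous \code{"spib"} model to initialize
#'   from (used when retraining on a growing run).
#' @param verbose print per-round progress.
#' @return an object of class \code{"spib"}: network parameters, active
#'   state set, \code{K}, per-frame \code{labels}, normalization constants,
#'   \code{converged} flag and training history. Use \code{predict} to get
#'   latent CVs (\code{type = "latent"}), state labels (\code{"state"}) or
#'   decoder probabilities (\code{"prob"}).
#' @export
spib <- function(x, x_lag = NULL, weights = NULL, beta = 1e-3,
                 hidden = c(64, 64), latent_dim = 2L,
                 init_labels = NULL, init_grid = 4L,
                 lr = 2e-3, batch_size = 1024L, epochs = 15L,
                 max_rounds = 20L, tol = 0.01, pop_threshold = 1e-3,
                 weighted_population = TRUE, seed = 1L,
                 warm_start = NULL, verbose = FALSE) {
  if (inherits(x, "lagged_dataset")) {
    if (is.null(weights)) weights <- x$w
    x_lag <- x$x_lag
    x <- x$x
  }
  x <- as.matrix(x); x_lag <- as.matrix(x_lag)
  n <- nrow(x); d <- ncol(x)
  stopifnot(nrow(x_lag) == n, ncol(x_lag) == d, n > 0)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- weights / mean(weights)

  # per-feature z-scoring on the training window, stored with the model
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- scale(x, ctr, scl)
  Xt <- scale(x_lag, ctr, scl)

  if (is.null(init_labels)) init_labels <- grid_init_labels(Xt, init_grid)
  y <- match(init_labels, sort(unique(init_labels)))
  K_init <- max(y)

  set.seed(hash32(seed, 104717))
  # Warm start reuses the encoder weights (decoder and labels restart fresh:
  # relabelling under the old decoder could never grow K, since refinement
  # only merges states — newly explored basins must be able to surface).
  warm <- !is.null(warm_start) &&
    nrow(warm_start$enc[[1]]$W) == d &&
    identical(warm_start$hidden, hidden) &&
    identical(warm_start$latent_dim, as.integer(latent_dim))
  enc <- mlp_init(c(d, hidden, latent_dim))
  enc[[4]] <- list(W = matrix(0, hidden[2], latent_dim),
                   b = rep(-2, latent_dim))       # start with small variance
  if (warm) enc <- warm_start$enc
  dec <- mlp_init(c(latent_dim, hidden, K_init))
  active <- seq_len(K_init)
  y <- active[y]

  opt_e <- adam_new(enc, lr = lr)
  opt_d <- adam_new(dec, lr = lr)
  converged <- FALSE
  hist_changed <- numeric(0)

  for (round in seq_len(max_rounds)) {
    # ---- gradient epochs
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        bi <- perm[start:min(start + batch_size - 1, n)]
        g <- spib_grad(enc, dec, active, Xs[bi, , drop = FALSE], y[bi],
                       weights[bi], beta, latent_dim)
        se <- adam_step(opt_e, enc, g$enc); opt_e <- se$opt; enc <- se$params
        sd_ <- adam_step(opt_d, dec, g$dec); opt_d <- sd_$opt; dec <- sd_$params
      }
    }
    # ---- label refinement
    ref <- refine_labels_core(enc, dec, active, Xt, weights,
                              pop_threshold, weighted_population)
    changed <- sum(weights * (ref$labels != y)) / sum(weights)
    hist_changed <- c(hist_changed, changed)
    active <- ref$active
    y <- ref$labels
    if (verbose)
      message(sprintf("round %d: K = %d, changed = %.3f",
                      round, length(active), changed))
    if (changed < tol) { converged <- TRUE; break }
  }

  labels <- match(y, active)   # compact 1..K
  structure(list(enc = enc, dec = dec, active = active,
                 K = length(active), labels = labels,
                 center = ctr, scale = scl, beta = beta,
                 hidden = hidden, latent_dim = as.integer(latent_dim),
                 dt = NULL, converged = converged,
                 history = list(changed = hist_changed),
                 n_train = n, seed = seed),
            class = "spib")
}

# deterministic coarse grid clustering for initial labels
grid_init_labels <- function(X, cells = 4L) {
  if (ncol(X) > 2) {
    pc <- stats::prcomp(X, rank. = 2, center = FALSE, scale. = FALSE)
    X <- pc$x
  }
  idx <- rep(1L, nrow(X))
  for (d in seq_len(ncol(X))) {
    r <- range(X[, d])
    if (diff(r) < 1e-12) next
    e <- seq(r[1], r[2], length.out = cells + 1L)
    idx <- (idx - 1L) * cells + findInterval(X[, d], e, all.inside = TRUE)
  }
  idx
}

# single-batch loss gradient; z sampled by reparameterization
spib_grad <- function(enc, dec, active, X, y, w, beta, latent_dim) {
  nb <- nrow(X)
  ww <- w / sum(w)
  ef <- enc_forward(enc, X)
  eps <- matrix(stats::rnorm(nb * latent_dim), nb, latent_dim)
  sdv <- exp(0.5 * ef$lv)
  Z <- ef$mu + sdv * eps
  df <- dec_forward(dec, Z)
  P <- softmax_active(df$logits, active)
  ycol <- match(y, active)

  # dL/dlogits over active columns
  dl_act <- P
  dl_act[cbind(seq_len(nb), ycol)] <- dl_act[cbind(seq_len(nb), ycol)] - 1
  dl_act <- dl_act * ww
  dlogits <- matrix(0, nb, ncol(dec[[3]]$W))
  dlogits[, active] <- dl_act

  # decoder backward
  dV3 <- crossprod(df$g2, dlogits); dc3 <- colSums(dlogits)
  dg2 <- (dlogits %*% t(dec[[3]]$W)) * (df$g2p > 0)
  dV2 <- crossprod(df$g1, dg2); dc2 <- colSums(dg2)
  dg1 <- (dg2 %*% t(dec[[2]]$W)) * (df$g1p > 0)
  dV1 <- crossprod(Z, dg1); dc1 <- colSums(dg1)
  dZ <- dg1 %*% t(dec[[1]]$W)

  # encoder backward (+ KL gradients)
  dmu <- dZ + beta * ww * ef$mu
  dlv <- dZ * eps * 0.5 * sdv + beta * ww * 0.5 * (exp(ef$lv) - 1)
  dWm <- crossprod(ef$h2, dmu); dbm <- colSums(dmu)
  dWv <- crossprod(ef$h2, dlv); dbv <- colSums(dlv)
  dh2 <- (dmu %*% t(enc[[3]]$W) + dlv %*% t(enc[[4]]$W)) * (ef$h2p > 0)
  dW2 <- crossprod(ef$h1, dh2); db2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(enc[[2]]$W)) * (ef$h1p > 0)
  dW1 <- crossprod(X, dh1); db1 <- colSums(dh1)

  list(enc = list(list(W = dW1, b = db1), list(W = dW2, b = db2),
                  list(W = dWm, b = dbm), list(W = dWv, b = dbv)),
       dec = list(list(W = dV1, b = dc1), list(W = dV2, b = dc2),
                  list(W = dV3, b = dc3)))
}

refine_labels_core <- function(enc, dec, active, Xt, w,
                               pop_threshold, weighted) {
  P <- softmax_active(dec_forward(dec, enc_forward(enc, Xt)$mu)$logits, active)
  repeat {
    lab_col <- max.col(P, "first")       # index into active
    pw <- if (weighted) w else rep(1, length(w))
    pop <- vapply(seq_along(active),
                  function(k) sum(pw[lab_col == k]), 0.0) / sum(pw)
    weak <- which(pop < pop_threshold)
    if (!length(weak)) break
    if (length(weak) == length(active))
      stop("all states fell below the population threshold", call. = FALSE)
    # delete the weakest state; its frames take their next-best state
    drop <- weak[which.min(pop[weak])]
    active <- active[-drop]
    P <- P[, -drop, drop = FALSE]
    P <- P / rowSums(P)
  }
  list(labels = active[lab_col], active = active)
}

#' SPIB objective for a batch
#'
#' The training loss at the current parameters: weighted cross-entropy of
#' the decoder's prediction of the future state label from a latent sample,
#' plus \code{beta} times the KL divergence of the encoder posterior from
#' the standard-normal latent prior. Normalized by the total batch weight,
#' so rescaling all weights leaves it unchanged.
#'
#' @param model a fitted or initialized \code{"spib"} object.
#' @param x batch of source features (raw scale).
#' @param y integer target labels (1..K, compact).
#' @param weights batch weights; default equal.
#' @param sample draw the latent sample (TRUE, uses the R RNG) or evaluate
#'   at the latent mean (FALSE).
#' @return scalar loss with attributes \code{"cross_entropy"} and \code{"kl"}.
#' @export
spib_objective <- function(model, x, y, weights = NULL, sample = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    stop("feature dimension mismatch", call. = FALSE)
  n <- nrow(x)
  if (n == 0) stop("empty batch", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  ww <- weights / sum(weights)
  Xs <- scale(x, model$center, model$scale)
  ef <- enc_forward(model$enc, Xs)
  Z <- if (sample) {
    ef$mu + exp(0.5 * ef$lv) * matrix(stats::rnorm(n * model$latent_dim),
                                      n, model$latent_dim)
  } else ef$mu
  P <- softmax_active(dec_forward(model$dec, Z)$logits, model$active)
  if (max(y) > model$K || min(y) < 1)
    stop("labels must lie in 1..K", call. = FALSE)
  ce <- -sum(ww * log(pmax(P[cbind(seq_len(n), y)], 1e-300)))
  kl <- sum(ww * 0.5 * rowSums(exp(ef$lv) + ef$mu^2 - 1 - ef$lv))
  loss <- ce + model$beta * kl
  if (!is.finite(loss))
    stop("non-finite SPIB loss (ce = ", ce, ", kl = ", kl, ")", call. = FALSE)
  structure(loss, cross_entropy = ce, kl = kl)
}

#' Refine the metastable-state labelling of a fitted model
#'
#' Relabels every frame to the decoder argmax at the frame's own latent
#' mean, deletes states whose population falls below the threshold
#' (reassigning their frames to the next-best state), and compacts the
#' label indices. Applying it twice without parameter updates is a no-op.
#'
#' @param model a \code{"spib"} model.
#' @param x frames to relabel (raw feature scale).
#' @param weights optional frame weights for the population rule.
#' @param pop_threshold deletion threshold (default 1e-3).
#' @param weighted_population weighted (TRUE) or count (FALSE) populations.
#' @return list \code{labels} (compact 1..K), \code{model} (updated K and
#'   active set).
#' @export
refine_state_labels <- function(model, x, weights = NULL,
                                pop_threshold = 1e-3,
                                weighted_population = TRUE) {
  x <- as.matrix(x)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  Xs <- scale(x, model$center, model$scale)
  ref <- refine_labels_core(model$enc, model$dec, model$active, Xs, weights,
                            pop_threshold, weighted_population)
  model$active <- ref$active
  model$K <- length(ref$active)
  list(labels = match(ref$labels, ref$active), model = model)
}

#' @export
#' @param object,x a fitted \code{"spib"} model.
#' @param newdata feature matrix on the raw scale.
#' @param type \code{"latent"} (deterministic 2D latent means — the CVs used
#'   for binning), \code{"state"} (argmax labels 1..K) or \code{"prob"}
#'   (decoder probabilities over the K states).
#' @param ... unused.
#' @rdname spib
predict.spib <- function(object, newdata, type = c("latent", "state", "prob"),
                         ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$center))
    stop("feature dimension mismatch: model expects ",
         length(object$center), " features", call. = FALSE)
  Xs <- scale(x, object$center, object$scale)
  mu <- enc_forward(object$enc, Xs)$mu
  if (type == "latent") return(mu)
  P <- softmax_active(dec_forward(object$dec, mu)$logits, object$active)
  if (type == "prob") return(P)
  max.col(P, "first")
}

#' @export
print.spib <- function(x, ...) {
  cat("SPIB model: ", length(x$center), " features -> ", x$latent_dim,
      "D latent, K = ", x$K, " metastable states\n", sep = "")
  cat("beta =", x$beta, "| trained on", x$n_train, "pairs |",
      if (x$converged) "label refinement converged"
      else "label refinement NOT converged", "\n")
  invisible(x)
}

#' @export
summary.spib <- function(object, ...) {
  pop <- tabulate(object$labels, object$K) / length(object$labels)
  cat("SPIB model with K =", object$K, "states\n")
  cat("State populations (training frames):\n")
  print(round(pop, 4))
  cat("Label-change fraction by refinement round:\n")
  print(round(object$history$changed, 4))
  invisible(list(K = object$K, populations = pop,
                 converged = object$converged))
}

#' @export
plot.spib <- function(x, newdata = NULL, ...) {
  z <- if (is.null(newdata)) NULL else predict(x, newdata, type = "latent")
  if (is.null(z)) stop("supply newdata (features) to plot latents",
                       call. = FALSE)
  lab <- predict(x, newdata, type = "state")
  graphics::plot(z[, 1], z[, 2], col = lab, pch = 16, cex = 0.4,
                 xlab = "latent CV 1", ylab = "latent CV 2",
                 main = paste0("SPIB latent space (K = ", x$K, ")"), ...)
  invisible(z)
}
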