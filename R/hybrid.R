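#' Fit a uniform square grid over the learned latent space
#'
#' Rectilinear binning of the 2D SPIB latent space with a single square bin
#' edge length \code{h}, auto-adjusted so the number of *occupied* bins lands
#' within 20% of the target \code{B_target}. The bounding box is the min/max
#' of the supplied latent points padded by one bin; \code{h} is found by
#' bisection (occupied count is monotone non-increasing in \code{h} under
#' halving). When fewer distinct points than \code{0.8 * B_target} exist the
#' closest achievable count is returned and flagged.
#'
#' @param z n x 2 matrix of latent points (typically the training window's
#'   latent means).
#' @param B_target desired occupied-bin count (default 100).
#' @param max_iter bisection iterations.
#' @return an object of class \code{c("latent_grid", "bin_mapper")} with
#'   fields \code{h}, \code{box}, \code{n_occupied}, \code{target_unreachable}.
#' @export
fit_latent_grid <- function(z, B_target = 100L, max_iter = 60L) {
  z <- as.matrix(z)
  stopifnot(ncol(z) == 2)
  dup <- !duplicated(z)
  n_distinct <- sum(dup)
  if (n_distinct < 2)
    stop("degenerate latent space: all points identical", call. = FALSE)
  lo <- apply(z, 2, min); hi <- apply(z, 2, max)
  span <- max(hi - lo)
  occupied <- function(h) {
    ix <- floor((z[, 1] - lo[1]) / h)
    iy <- floor((z[, 2] - lo[2]) / h)
    length(unique(ix * 2^26 + iy))
  }
  h_hi <- span * 2          # one big bin
  h_lo <- span / 1e6        # essentially per-point bins
  band <- c(ceiling(0.8 * B_target), floor(1.2 * B_target))
  best_h <- h_hi; best_occ <- occupied(h_hi)
  for (it in seq_len(max_iter)) {
    h <- sqrt(h_lo * h_hi)  # bisect in log h
    occ <- occupied(h)
    if (abs(occ - B_target) < abs(best_occ - B_target)) {
      best_h <- h; best_occ <- occ
    }
    if (occ >= band[1] && occ <= band[2]) { best_h <- h; best_occ <- occ; break }
    if (occ > band[2]) h_lo <- h else h_hi <- h
  }
  unreachable <- best_occ < band[1] || best_occ > band[2]
  make_latent_grid(best_h, lo, hi, best_occ, unreachable)
}

make_latent_grid <- function(h, lo, hi, n_occupied = NA_integer_,
                             unreachable = FALSE) {
  # box padded by one bin on each side; walkers outside clamp to edge bins
  nx <- max(1L, ceiling((hi[1] - lo[1]) / h)) + 2L
  ny <- max(1L, ceiling((hi[2] - lo[2]) / h)) + 2L
  structure(list(h = h, origin = c(lo[1] - h, lo[2] - h),
                 nbins_dim = c(nx, ny), n_bins = nx * ny,
                 n_occupied = n_occupied,
                 target_unreachable = unreachable),
            class = c("latent_grid", "bin_mapper"))
}

#' @export
assign_bins.latent_grid <- function(mapper, x, ...) {
  z <- as.matrix(x)
  if (ncol(z) != 2)
    stop("latent grid expects 2D latent coordinates", call. = FALSE)
  bad <- which(!is.finite(z[, 1]) | !is.finite(z[, 2]))
  if (length(bad))
    stop("non-finite latent value for walker ", bad[1], call. = FALSE)
  ix <- floor((z[, 1] - mapper$origin[1]) / mapper$h)
  iy <- floor((z[, 2] - mapper$origin[2]) / mapper$h)
  clamped <- sum(ix < 0 | ix >= mapper$nbins_dim[1] |
                 iy < 0 | iy >= mapper$nbins_dim[2])
  ix <- pmin(pmax(ix, 0), mapper$nbins_dim[1] - 1)
  iy <- pmin(pmax(iy, 0), mapper$nbins_dim[2] - 1)
  structure(as.integer(ix * mapper$nbins_dim[2] + iy + 1), clamped = clamped)
}

#' @export
print.latent_grid <- function(x, ...) {
  cat("Latent grid: h =", signif(x$h, 4), "|", x$n_bins, "bins |",
      x$n_occupied, "occupied at fit",
      if (isTRUE(x$target_unreachable)) "(target unreachable)" else "", "\n")
  invisible(x)
}

#' Undersampled-region mask over the expert grid
#'
#' Maps all training frames to the expert bins *without* weights, takes the
#' mean count over occupied bins, and marks a bin undersampled iff its count
#' is strictly below that mean. Unoccupied bins (count 0) are therefore
#' always undersampled. The mask is recomputed only after each SPIB
#' training, never between.
#'
#' @param x training frames (raw coordinates; the grid's CV function is
#'   applied internally).
#' @param expert_grid a \code{\link{rect_grid}}.
#' @param iteration iteration stamp recorded on the mask.
#' @return object of class \code{"undersampled_mask"}: logical \code{mask}
#'   per expert bin, the \code{counts} vector, \code{mean_count},
#'   \code{iteration}.
#' @export
compute_undersampled_mask <- function(x, expert_grid, iteration = NA_integer_) {
  if (NROW(x) == 0) stop("no training frames", call. = FALSE)
  b <- assign_bins(expert_grid, x)
  counts <- tabulate(b, nbins = expert_grid$n_bins)
  mu <- mean(counts[counts > 0])
  structure(list(mask = counts < mu, counts = counts, mean_count = mu,
                 iteration = iteration),
            class = "undersampled_mask")
}

#' Hybrid expert/latent bin mapper
#'
#' Combines the expert rectilinear grid with the adaptive latent grid over
#' the SPIB-learned CVs. Bin ids live in a disjoint union namespace: expert
#' ids 1..Ne, latent ids Ne+1..Ne+Ns.
#'
#' @param expert_grid a \code{\link{rect_grid}} over the expert CVs.
#' @param latent_grid a \code{\link{fit_latent_grid}} result.
#' @param model the \code{"spib"} model supplying the latent CVs.
#' @param mask an \code{\link{compute_undersampled_mask}} result.
#' @param sequential update candidate occupancies walker-by-walker during
#'   assignment instead of tallying them once from the full walker set
#'   (default FALSE: two-pass, order-independent).
#' @param features optional function mapping raw coordinates to the model's
#'   input features (default identity).
#' @return object of class \code{c("hybrid_mapper", "bin_mapper")}.
#' @export
hybrid_mapper <- function(expert_grid, latent_grid, model, mask,
                          sequential = FALSE, features = NULL) {
  stopifnot(inherits(expert_grid, "rect_grid"),
            inherits(latent_grid, "latent_grid"),
            inherits(model, "spib"),
            inherits(mask, "undersampled_mask"))
  if (length(mask$mask) != expert_grid$n_bins)
    stop("mask does not match the expert grid", call. = FALSE)
  structure(list(expert = expert_grid, latent = latent_grid, model = model,
                 mask = mask, sequential = isTRUE(sequential),
                 features = features,
                 n_bins = expert_grid$n_bins + latent_grid$n_bins),
            class = c("hybrid_mapper", "bin_mapper"))
}

#' Assign walkers with the hybrid expert/latent rule
#'
#' Every walker is mapped to both its expert bin \eqn{i_e} and its latent
#' bin \eqn{i_s}; candidate occupancies \eqn{n(i_e)} and \eqn{n(i_s)} are
#' tallied over the full walker set. A walker is then routed to its expert
#' bin only when that bin lies in an undersampled region AND holds strictly
#' fewer candidates than the walker's latent bin; otherwise it goes to the
#' latent bin. Ties (\eqn{n(i_e) = n(i_s)}) therefore go to the latent bin.
#' With an empty mask the rule reduces to pure latent binning.
#'
#' @param mapper a \code{\link{hybrid_mapper}}.
#' @param x n x d matrix of raw walker coordinates.
#' @param ... unused.
#' @return integer bin ids in the union namespace, with attributes
#'   \code{"routed_expert"} (count routed to expert bins), \code{"clamped"}.
#' @export
assign_bins.hybrid_mapper <- function(mapper, x, ...) {
  x <- as.matrix(x)
  feats <- if (is.null(mapper$features)) x else mapper$features(x)
  ie <- assign_bins(mapper$expert, x)
  z <- predict(mapper$model, feats, type = "latent")
  is_ <- assign_bins(mapper$latent, z)
  n <- length(ie)
  offset <- mapper$expert$n_bins
  und <- mapper$mask$mask
  if (!mapper$sequential) {
    ne <- tabulate(ie, nbins = mapper$expert$n_bins)
    ns <- tabulate(is_, nbins = mapper$latent$n_bins)
    to_expert <- und[ie] & (ne[ie] < ns[is_])
    out <- ifelse(to_expert, ie, offset + is_)
  } else {
    cnt <- integer(mapper$n_bins)
    out <- integer(n)
    for (w in seq_len(n)) {
      e_id <- ie[w]; s_id <- offset + is_[w]
      pick <- if (und[e_id] && cnt[e_id] < cnt[s_id]) e_id else s_id
      out[w] <- pick
      cnt[pick] <- cnt[pick] + 1L
    }
    to_expert <- out <= offset
  }
  structure(as.integer(out),
            routed_expert = sum(to_expert),
            clamped = attr(ie, "clamped") + attr(is_, "clamped"))
}

#' @export
print.hybrid_mapper <- function(x, ...) {
  cat("Hybrid mapper: expert grid (", x$expert$n_bins, " bins) + latent grid (",
      x$latent$n_bins, " bins, h = ", signif(x$latent$h, 3), "), ",
      sum(x$mask$mask), " expert bins undersampled\n", sep = "")
  invisible(x)
}
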