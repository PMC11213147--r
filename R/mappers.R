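# 32-bit deterministic hash for seeding R-level RNG streams
hash32 <- function(...) {
  v <- as.numeric(c(...))
  h <- 104729
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  as.integer(h)
}

#' Rectilinear expert-CV grid
#'
#' A bin mapper over expert collective variables: per-dimension strictly
#' increasing edge vectors define half-open bins \code{[lo, hi)} (the last
#' bin closed), composed row-major into a single index. CV values beyond the
#' outermost edges clamp to the nearest edge bin; the clamp count is recorded
#' as an attribute on the assignment so frontier excursions are visible
#' without crashing a run.
#'
#' @param edges a numeric vector (1D) or list of per-dimension edge vectors.
#' @param cv function mapping an n x d coordinate matrix to an n x ncv matrix
#'   of expert CV values; default is the identity.
#' @return an object of class \code{c("rect_grid", "bin_mapper")}.
#' @examples
#' g <- rect_grid(list(c(0, 1, 2)))
#' assign_bins(g, matrix(c(0.5, 1.0, 5.0), ncol = 1))  # 1, 2, 2
#' @export
rect_grid <- function(edges, cv = NULL) {
  if (!is.list(edges)) edges <- list(edges)
  for (e in edges) {
    if (length(e) < 2 || any(diff(e) <= 0))
      stop("bin edges must be strictly increasing, length >= 2", call. = FALSE)
  }
  nb <- vapply(edges, function(e) length(e) - 1L, 0L)
  structure(list(edges = edges, nbins_dim = nb, n_bins = prod(nb), cv = cv),
            class = c("rect_grid", "bin_mapper"))
}

#' Assign configurations to bins
#'
#' Generic over bin mappers. Every in-domain configuration maps to exactly
#' one bin (1-based index); out-of-grid values clamp to the nearest edge bin.
#'
#' @param mapper a bin mapper (\code{\link{rect_grid}},
#'   \code{\link{latent_grid}} or \code{\link{hybrid_mapper}}).
#' @param x n x d matrix of configurations (raw coordinates; the mapper's own
#'   CV function, if any, is applied internally).
#' @param ... passed to methods.
#' @return integer vector of bin ids, with attribute \code{"clamped"} giving
#'   the number of out-of-grid values clamped.
#' @export
assign_bins <- function(mapper, x, ...) UseMethod("assign_bins")

#' @export
assign_bins.rect_grid <- function(mapper, x, ...) {
  x <- as.matrix(x)
  v <- if (is.null(mapper$cv)) x else as.matrix(mapper$cv(x))
  if (ncol(v) != length(mapper$edges))
    stop("mapper expects ", length(mapper$edges), " CV dimension(s), got ",
         ncol(v), call. = FALSE)
  bad <- which(!stats::complete.cases(v) | !apply(is.finite(v), 1, all))
  if (length(bad))
    stop("non-finite CV value for walker ", bad[1], call. = FALSE)
  idx <- rep(1L, nrow(v))
  clamped <- 0L
  for (d in seq_along(mapper$edges)) {
    e <- mapper$edges[[d]]
    clamped <- clamped + sum(v[, d] < e[1] | v[, d] > e[length(e)])
    i <- findInterval(v[, d], e, all.inside = TRUE)
    idx <- (idx - 1L) * mapper$nbins_dim[d] + i
  }
  structure(idx, clamped = clamped)
}

#' @export
print.rect_grid <- function(x, ...) {
  cat("Rectilinear grid:", length(x$edges), "dimension(s),",
      x$n_bins, "bins\n")
  invisible(x)
}

n_bins <- function(mapper) mapper$n_bins
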