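#' Empirical nearest-neighbour distribution function
#'
#' For a focal pattern and the pattern of one species, `D_fi(r)` is the
#' fraction of focal individuals whose nearest individual of species `i`
#' lies within distance `r`. These per-species distribution functions are the
#' building blocks of the individual species-area relationship.
#'
#' @param focals Focal `point_pattern`; must be non-empty.
#' @param species_pattern `point_pattern` of one species (may be empty, in
#'   which case `D` is identically zero).
#' @param radii Radii in metres (increasing).
#' @return Numeric vector of fractions, one per radius.
#' @export
nn_distribution <- function(focals, species_pattern, radii) {
  stopifnot(inherits(focals, "point_pattern"))
  if (npoints(focals) == 0) stop("focal pattern is empty")
  radii <- as.numeric(radii)
  if (npoints(species_pattern) == 0) return(rep(0, length(radii)))
  d <- cpp_nearest_dist(focals$x, focals$y,
                        species_pattern$x, species_pattern$y)
  vapply(radii, function(r) mean(d <= r), numeric(1))
}

#' Individual species-area relationship
#'
#' `ISAR(r)` is the expected number of species with at least one individual
#' within distance `r` of an individual of the focal class: the mean over
#' focal individuals of the distinct species count in the disc of radius `r`,
#' equivalently the sum over species of the nearest-neighbour distribution
#' functions `D_fi(r)`. (The literature formula is often printed in its
#' complement form `sum(1 - D_fi)`, which differs only by the constant species
#' total `S`; the expected-species-count convention is used throughout here,
#' so accumulator/repeller classification is unaffected.)
#'
#' Focal individuals closer than `r` to the window border are retained without
#' correction by default, matching common practice; `minus_sampling = TRUE`
#' excludes, at each radius, focals within `r` of the border (a sensitivity
#' check).
#'
#' @param focals Focal `point_pattern` (non-empty). The focal species itself
#'   should be excluded from the community.
#' @param community Marked `point_pattern`; marks are species codes.
#' @param radii Radii in metres (increasing).
#' @param minus_sampling Exclude border focals per radius (default `FALSE`).
#' @return Object of class `isar_curve` with `radii`, `isar`, `n_focal`,
#'   `s_total`, and the per-species distribution matrix `D` (species x radii).
#' @export
isar_curve <- function(focals, community, radii, minus_sampling = FALSE) {
  stopifnot(inherits(focals, "point_pattern"), inherits(community, "point_pattern"))
  if (npoints(focals) == 0) stop("focal pattern is empty")
  radii <- sort(as.numeric(radii))
  if (npoints(community) > 0 && is.null(community$marks))
    stop("community pattern must carry species marks")
  sp <- factor(community$marks)
  nsp <- nlevels(sp)
  if (npoints(community) == 0 || nsp == 0) {
    D <- matrix(0, nrow = 0, ncol = length(radii))
    return(structure(list(radii = radii, isar = rep(0, length(radii)),
                          n_focal = npoints(focals), s_total = 0L, D = D),
                     class = "isar_curve"))
  }
  if (minus_sampling) {
    w <- focals$window
    border <- pmin(focals$x, w$width - focals$x, focals$y, w$height - focals$y)
    D <- matrix(0, nrow = nsp, ncol = length(radii))
    nf <- integer(length(radii))
    for (k in seq_along(radii)) {
      keep <- border >= radii[k]
      nf[k] <- sum(keep)
      if (!nf[k]) next
      cnt <- cpp_species_nn_counts(focals$x[keep], focals$y[keep],
                                   community$x, community$y,
                                   as.integer(sp) - 1L, nsp, radii[k])
      D[, k] <- cnt[, 1] / nf[k]
    }
    isar <- colSums(D)
    n_focal <- nf
  } else {
    cnt <- cpp_species_nn_counts(focals$x, focals$y, community$x, community$y,
                                 as.integer(sp) - 1L, nsp, radii)
    D <- cnt / npoints(focals)
    isar <- colSums(D)
    n_focal <- npoints(focals)
  }
  dimnames(D) <- list(levels(sp), NULL)
  structure(list(radii = radii, isar = isar, n_focal = n_focal,
                 s_total = nsp, D = D),
            class = "isar_curve")
}

#' @export
print.isar_curve <- function(x, ...) {
  cat(sprintf("ISAR curve: %d focal individuals, %d species, radii %g-%g m\n",
              max(x$n_focal), x$s_total, min(x$radii), max(x$radii)))
  invisible(x)
}

#' ISAR analysis with Monte Carlo simulation envelopes
#'
#' Contrasts the observed ISAR curve with rank envelopes from null
#' randomisations of the focal pattern (the community is held fixed). Radii
#' where the observed curve strictly exceeds the upper envelope are classed
#' `accumulator` (the focal class carries more species in its neighbourhood
#' than expected); radii strictly below the lower envelope are `repeller`;
#' all others `neutral`.
#'
#' @inheritParams isar_curve
#' @inheritParams oring_envelope
#' @return Object of class `isar_envelope` with the observed `isar_curve`,
#'   `lower`, `upper` and per-radius `classification`.
#' @export
isar_envelope <- function(focals, community, radii, null = null_model(),
                          nsim = 199, rank = 5, seed = NULL) {
  obs <- isar_curve(focals, community, radii)
  env <- rank_envelope(focals, null,
                       function(p) isar_curve(p, community, radii)$isar,
                       obs$isar, nsim, rank, seed)
  classification <- c(attraction = "accumulator", repulsion = "repeller",
                      none = "neutral")[env$flag]
  structure(list(observed = obs, lower = env$lower, upper = env$upper,
                 classification = unname(classification),
                 nsim = nsim, rank = rank,
                 null = if (is.function(null)) NULL else null),
            class = "isar_envelope")
}

#' @export
print.isar_envelope <- function(x, ...) {
  print(x$observed)
  if (!is.null(x$null)) print(x$null)
  cat(sprintf("  %d simulations, rank-%d envelopes\n", x$nsim, x$rank))
  sig <- x$classification != "neutral"
  if (any(sig)) {
    for (i in which(sig))
      cat(sprintf("    r = %g m: diversity %s\n",
                  x$observed$radii[i], x$classification[i]))
  } else cat("  neutral at all radii\n")
  invisible(x)
}

#' @export
plot.isar_envelope <- function(x, main = "ISAR analysis", xlab = "r (m)",
                               ylab = "ISAR(r) (species)", ...) {
  r <- x$observed$radii
  ylim <- range(c(x$observed$isar, x$lower, x$upper), finite = TRUE)
  plot(r, x$observed$isar, type = "n", ylim = ylim, main = main,
       xlab = xlab, ylab = ylab, ...)
  polygon(c(r, rev(r)), c(x$lower, rev(x$upper)), col = "grey90", border = NA)
  lines(r, x$lower, lty = 2); lines(r, x$upper, lty = 2)
  lines(r, x$observed$isar)
  sig <- x$classification != "neutral"
  points(r[!sig], x$observed$isar[!sig], pch = 1)
  points(r[sig], x$observed$isar[sig], pch = 16)
  invisible(x)
}
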