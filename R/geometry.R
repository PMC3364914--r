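#' Distance to the nearest focal tree
#'
#' Euclidean distance from each query point to the closest point of a focal
#' pattern. Proximity categories used in the demographic analyses ("near"
#' within 10 m, "far" beyond) are derived from these distances; the boundary
#' itself is counted as near.
#'
#' @param x,y Query point coordinates (metres).
#' @param focals A `point_pattern` of focal trees; must be non-empty.
#' @return Numeric vector of distances (metres).
#' @seealso [near_focal()]
#' @export
nearest_focal_distance <- function(x, y, focals) {
  stopifnot(inherits(focals, "point_pattern"))
  if (npoints(focals) == 0)
    stop("focal pattern is empty: nearest distance (and the near/far flag) is undefined")
  stopifnot(length(x) == length(y))
  cpp_nearest_dist(as.numeric(x), as.numeric(y), focals$x, focals$y)
}

#' Near/far flag relative to a focal pattern
#'
#' @inheritParams nearest_focal_distance
#' @param radius Near threshold in metres (default 10); distances equal to the
#'   threshold count as near.
#' @return Logical vector.
#' @export
near_focal <- function(x, y, focals, radius = 10) {
  nearest_focal_distance(x, y, focals) <= radius
}

#' Area of a disc clipped to the window
#'
#' Exact circle-rectangle intersection area, vectorised over disc centres.
#' Used for edge correction of ring areas in the O-ring estimator.
#'
#' @param cx,cy Disc centres (metres).
#' @param r Disc radius (metres, scalar).
#' @param window A [fdp_window()].
#' @return Numeric vector of clipped areas (m^2).
#' @export
disc_window_area <- function(cx, cy, r, window) {
  stopifnot(inherits(window, "plot_window"), length(r) == 1, r >= 0)
  cpp_disc_rect_area(as.numeric(cx), as.numeric(cy), r,
                     window$width, window$height)
}

#' Area of an annulus clipped to the window
#'
#' @inheritParams disc_window_area
#' @param r_in,r_out Inner and outer ring radii, `0 <= r_in < r_out`.
#' @return Numeric vector of clipped ring areas (m^2).
#' @export
ring_window_area <- function(cx, cy, r_in, r_out, window) {
  stopifnot(r_in >= 0, r_out > r_in)
  disc_window_area(cx, cy, r_out, window) -
    disc_window_area(cx, cy, r_in, window)
}

# normalise angular intervals (matrix with columns lo, hi, possibly wrapping
# or outside [0, 2pi)) into a merged union on [0, 2pi)
merge_circular_intervals <- function(lo, hi) {
  if (!length(lo)) return(cbind(lo = numeric(0), hi = numeric(0)))
  two_pi <- 2 * pi
  lo <- lo %% two_pi
  hi2 <- hi
  # represent each interval as non-wrapping pieces
  len <- (hi - lo) %% two_pi
  len[len == 0 & hi != lo] <- two_pi  # full circle
  pieces_lo <- numeric(0); pieces_hi <- numeric(0)
  for (i in seq_along(lo)) {
    if (len[i] >= two_pi - 1e-12) return(cbind(lo = 0, hi = two_pi))
    a <- lo[i]; b <- a + len[i]
    if (b <= two_pi) {
      pieces_lo <- c(pieces_lo, a); pieces_hi <- c(pieces_hi, b)
    } else {
      pieces_lo <- c(pieces_lo, a, 0); pieces_hi <- c(pieces_hi, two_pi, b - two_pi)
    }
  }
  o <- order(pieces_lo)
  pieces_lo <- pieces_lo[o]; pieces_hi <- pieces_hi[o]
  out_lo <- pieces_lo[1]; out_hi <- pieces_hi[1]
  if (length(pieces_lo) > 1) {
    for (i in 2:length(pieces_lo)) {
      k <- length(out_lo)
      if (pieces_lo[i] <= out_hi[k]) {
        out_hi[k] <- max(out_hi[k], pieces_hi[i])
      } else {
        out_lo <- c(out_lo, pieces_lo[i]); out_hi <- c(out_hi, pieces_hi[i])
      }
    }
  }
  cbind(lo = out_lo, hi = out_hi)
}

# complement of a merged union of intervals within [0, 2pi)
complement_intervals <- function(iv) {
  two_pi <- 2 * pi
  if (!nrow(iv)) return(cbind(lo = 0, hi = two_pi))
  lo <- c(0, iv[, "hi"]); hi <- c(iv[, "lo"], two_pi)
  keep <- hi - lo > 1e-12
  cbind(lo = lo[keep], hi = hi[keep])
}

# merged union of plain (non-circular) intervals clipped to [a, b]
merge_linear_intervals <- function(lo, hi, a, b) {
  lo <- pmax(lo, a); hi <- pmin(hi, b)
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  if (!length(lo)) return(cbind(lo = numeric(0), hi = numeric(0)))
  o <- order(lo); lo <- lo[o]; hi <- hi[o]
  out_lo <- lo[1]; out_hi <- hi[1]
  if (length(lo) > 1) {
    for (i in 2:length(lo)) {
      k <- length(out_lo)
      if (lo[i] <= out_hi[k]) out_hi[k] <- max(out_hi[k], hi[i])
      else { out_lo <- c(out_lo, lo[i]); out_hi <- c(out_hi, hi[i]) }
    }
  }
  cbind(lo = out_lo, hi = out_hi)
}

#' Fraction of the plot inside the zone of influence of focal trees
#'
#' Computes the area of the union of discs of a given radius centred on the
#' focal trees, clipped to the observation window, as a fraction of the window
#' area. The computation is exact: the boundary of the clipped union is
#' decomposed into exposed circular arcs and covered window-edge segments and
#' integrated with Green's theorem, so overlap between neighbouring discs and
#' clipping at the plot edge are both handled analytically.
#'
#' @param focals A `point_pattern` of focal trees.
#' @param radius Zone-of-influence radius in metres (> 0).
#' @param window A [fdp_window()].
#' @return A single fraction in `[0, 1]`.
#' @examples
#' w <- fdp_window()
#' f <- point_pattern(250, 250, w)
#' affected_area_fraction(f, 5, w)   # pi * 25 / 250000
#' @export
affected_area_fraction <- function(focals, radius, window) {
  stopifnot(inherits(focals, "point_pattern"), inherits(window, "plot_window"),
            radius > 0)
  n <- npoints(focals)
  if (n == 0) return(0)
  xy <- unique(cbind(focals$x, focals$y))
  cx <- xy[, 1]; cy <- xy[, 2]
  n <- nrow(xy)
  r <- radius
  W <- window$width; H <- window$height
  area <- 0

  clamp1 <- function(t) pmin(1, pmax(-1, t))
  # exposed-arc contribution per circle
  for (i in seq_len(n)) {
    dx <- cx - cx[i]; dy <- cy - cy[i]
    d <- sqrt(dx^2 + dy^2)
    j <- which(d > 0 & d < 2 * r)
    lo <- numeric(0); hi <- numeric(0)
    if (length(j)) {
      alpha <- acos(clamp1(d[j] / (2 * r)))
      phi <- atan2(dy[j], dx[j])
      lo <- phi - alpha; hi <- phi + alpha
    }
    # window exclusions: arcs outside each of the four half-planes
    # "greater-than" exclusions (right x<=W, top y<=H): centre 0 / pi/2
    t_r <- (W - cx[i]) / r
    if (t_r < 1) { hw <- acos(clamp1(t_r)); lo <- c(lo, -hw); hi <- c(hi, hw) }
    t_t <- (H - cy[i]) / r
    if (t_t < 1) { hw <- acos(clamp1(t_t)); lo <- c(lo, pi / 2 - hw); hi <- c(hi, pi / 2 + hw) }
    # "less-than" exclusions (left x>=0, bottom y>=0): centre pi / 3pi/2
    t_l <- -cx[i] / r
    if (t_l > -1) { hw <- pi / 2 + asin(clamp1(t_l)); lo <- c(lo, pi - hw); hi <- c(hi, pi + hw) }
    t_b <- -cy[i] / r
    if (t_b > -1) { hw <- pi / 2 + asin(clamp1(t_b)); lo <- c(lo, 3 * pi / 2 - hw); hi <- c(hi, 3 * pi / 2 + hw) }

    kept <- complement_intervals(merge_circular_intervals(lo, hi))
    if (nrow(kept)) {
      th1 <- kept[, "lo"]; th2 <- kept[, "hi"]
      area <- area + sum(0.5 * (r^2 * (th2 - th1) +
                                  r * (cx[i] * (sin(th2) - sin(th1)) -
                                       cy[i] * (cos(th2) - cos(th1)))))
    }
  }

  # window-edge contributions: only segments inside the union lie on the
  # region boundary; with CCW traversal, bottom and left edges contribute 0
  edge_cover <- function(coord_perp, coord_par, limit) {
    # discs covering a horizontal/vertical edge at perpendicular offset
    w2 <- r^2 - coord_perp^2
    j <- which(w2 > 0)
    if (!length(j)) return(cbind(lo = numeric(0), hi = numeric(0)))
    w <- sqrt(w2[j])
    merge_linear_intervals(coord_par[j] - w, coord_par[j] + w, 0, limit)
  }
  right <- edge_cover(W - cx, cy, H)
  if (nrow(right)) area <- area + 0.5 * W * sum(right[, "hi"] - right[, "lo"])
  top <- edge_cover(H - cy, cx, W)
  if (nrow(top)) area <- area + 0.5 * H * sum(top[, "hi"] - top[, "lo"])

  min(1, max(0, area / (W * H)))
}
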