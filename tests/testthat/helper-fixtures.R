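# shared fixtures and independent oracles used across test files

csr_pattern <- function(n, window, marks = NULL) {
  point_pattern(runif(n, 0, window$width), runif(n, 0, window$height),
                window, marks = marks)
}

make_census <- function(n = 5, species = "SP01", dbh = 1.5, census = 0L,
                        width = 100, height = 100) {
  data.frame(tag = sprintf("T%03d", seq_len(n)), species = species,
             x = runif(n, 0, width), y = runif(n, 0, height), dbh = dbh,
             status = "alive", resprout = FALSE, census = census,
             date = 1996, stringsAsFactors = FALSE)
}

# numerical clipped-disc area: 1-D integration of the clipped chord length,
# split at the x-positions where the chord meets the window edges (kinks)
num_disc_area <- function(cx, cy, r, window) {
  W <- window$width; H <- window$height
  chord <- Vectorize(function(x) {
    s2 <- r^2 - (x - cx)^2
    if (s2 <= 0) return(0)
    s <- sqrt(s2)
    max(0, min(H, cy + s) - max(0, cy - s))
  })
  lo <- max(0, cx - r); hi <- min(W, cx + r)
  if (hi <= lo) return(0)
  breaks <- c(lo, hi)
  for (b2 in c(r^2 - cy^2, r^2 - (H - cy)^2))
    if (b2 > 0) breaks <- c(breaks, cx - sqrt(b2), cx + sqrt(b2))
  breaks <- sort(unique(pmin(hi, pmax(lo, breaks))))
  total <- 0
  for (i in seq_len(length(breaks) - 1)) {
    if (breaks[i + 1] - breaks[i] < 1e-12) next
    total <- total + integrate(chord, breaks[i], breaks[i + 1],
                               rel.tol = 1e-10, subdivisions = 500L)$value
  }
  total
}

# brute-force O-ring: double loop over pairs, ring areas by numerical
# integration (independent of the closed-form geometry used in the package)
brute_ring_area <- function(cx, cy, r_in, r_out, window) {
  num_disc_area(cx, cy, r_out, window) - num_disc_area(cx, cy, r_in, window)
}

brute_oring <- function(p1, p2, radii, dr) {
  window <- p1$window
  counts <- areas <- numeric(length(radii))
  for (k in seq_along(radii)) {
    r_in <- max(0, radii[k] - dr / 2); r_out <- radii[k] + dr / 2
    cnt <- 0
    for (i in seq_along(p1$x)) {
      d <- sqrt((p2$x - p1$x[i])^2 + (p2$y - p1$y[i])^2)
      cnt <- cnt + sum(d >= r_in & d < r_out)
      areas[k] <- areas[k] + brute_ring_area(p1$x[i], p1$y[i], r_in, r_out, window)
    }
    counts[k] <- cnt
  }
  list(counts = counts, o12 = counts / areas)
}

# brute-force nearest-neighbour distribution and ISAR
brute_nn_dist <- function(px, py, fx, fy) {
  vapply(seq_along(px), function(i) min(sqrt((fx - px[i])^2 + (fy - py[i])^2)),
         numeric(1))
}

brute_isar <- function(focals, community, radii) {
  sp <- unique(community$marks)
  vapply(radii, function(r) {
    per_focal <- vapply(seq_along(focals$x), function(i) {
      d <- sqrt((community$x - focals$x[i])^2 + (community$y - focals$y[i])^2)
      length(unique(community$marks[d <= r]))
    }, numeric(1))
    mean(per_focal)
  }, numeric(1))
}

# exhaustive-enumeration PERMANOVA oracle (two groups)
brute_permanova_p <- function(comm, labels) {
  d2 <- as.matrix(vegan::vegdist(comm, "bray"))^2
  n <- nrow(comm); lev <- levels(labels)
  k <- sum(labels == lev[1]); a <- 2
  fstat <- function(lab) {
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (L in lev) {
      i <- which(lab == L)
      ssw <- ssw + sum(d2[i, i][upper.tri(diag(length(i)))]) / length(i)
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  obs <- fstat(labels)
  fs <- apply(utils::combn(n, k), 2, function(i) {
    lab <- factor(rep(lev[2], n), levels = lev); lab[i] <- lev[1]
    fstat(lab)
  })
  mean(fs >= obs - 1e-12)
}

# deterministic planted-effect seedling fixture for GLM checks
expand_binary <- function(design) {
  rows <- lapply(seq_len(nrow(design)), function(i) {
    n <- design$n[i]; k <- design$k[i]
    if (n == 0) return(NULL)
    data.frame(nearA = design$nearA[i], nearB = design$nearB[i],
               survival = rep(c(1, 0), c(k, n - k)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("demog_design", "data.frame")
  out
}
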