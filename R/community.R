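#' Label quadrats by palm influence
#'
#' A quadrat is a "palm" quadrat when it contains at least one mature palm or
#' is adjacent to a quadrat that does; all other quadrats are "non-palm".
#' At the default 5 m cell size this captures the roughly 10 m reach of
#' falling fronds and rooting frugivores around a palm. Adjacency is queen
#' (8 neighbours) by default, making palm influence isotropic at the cell
#' scale; rook (4 neighbours) is available.
#'
#' @param grid A [quadrat_grid()].
#' @param mature_palms `point_pattern` of mature palms.
#' @param adjacency `"queen"` or `"rook"`.
#' @return Factor of length `nx * ny` with levels `palm`, `nonpalm`, in cell
#'   order (see [quadrat_index()]).
#' @examples
#' g <- quadrat_grid(fdp_window(25, 25))
#' lab <- label_quadrats(g, point_pattern(12, 12, fdp_window(25, 25)))
#' table(lab)   # one interior palm -> 9 palm cells
#' @export
label_quadrats <- function(grid, mature_palms, adjacency = c("queen", "rook")) {
  stopifnot(inherits(grid, "quadrat_grid"))
  adjacency <- match.arg(adjacency)
  lab <- matrix(FALSE, nrow = grid$nx, ncol = grid$ny)
  if (npoints(mature_palms) > 0) {
    ix <- pmin(floor(mature_palms$x / grid$cellsize), grid$nx - 1) + 1L
    iy <- pmin(floor(mature_palms$y / grid$cellsize), grid$ny - 1) + 1L
    occ <- unique(cbind(ix, iy))
    offs <- if (adjacency == "queen")
      expand.grid(dx = -1:1, dy = -1:1)
    else data.frame(dx = c(0, -1, 1, 0, 0), dy = c(0, 0, 0, -1, 1))
    for (k in seq_len(nrow(offs))) {
      jx <- occ[, 1] + offs$dx[k]
      jy <- occ[, 2] + offs$dy[k]
      ok <- jx >= 1 & jx <= grid$nx & jy >= 1 & jy <= grid$ny
      lab[cbind(jx[ok], jy[ok])] <- TRUE
    }
  }
  factor(ifelse(as.vector(lab), "palm", "nonpalm"),
         levels = c("palm", "nonpalm"))
}

#' Quadrat-by-species community matrix
#'
#' Tabulates individuals (typically non-palm saplings, 1-2 cm dbh) into the
#' cells of a quadrat grid, attaching the per-quadrat palm-influence label.
#'
#' @param pattern Marked `point_pattern`; marks are species codes.
#' @param grid A [quadrat_grid()].
#' @param labels Per-quadrat factor from [label_quadrats()].
#' @return Object of class `community_matrix`: integer matrix (quadrats x
#'   species) with a `labels` attribute.
#' @export
community_matrix <- function(pattern, grid, labels) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(grid, "quadrat_grid"))
  ncell <- grid$nx * grid$ny
  stopifnot(length(labels) == ncell)
  if (is.null(pattern$marks)) stop("pattern must carry species marks")
  q <- quadrat_index(grid, pattern$x, pattern$y)
  sp <- factor(pattern$marks)
  tab <- table(factor(q, levels = seq_len(ncell)), sp)
  m <- matrix(as.integer(tab), nrow = ncell, ncol = nlevels(sp),
              dimnames = list(NULL, levels(sp)))
  structure(m, labels = labels, class = c("community_matrix", "matrix"))
}

#' @export
print.community_matrix <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("Community matrix: %d quadrats (%d palm, %d nonpalm) x %d species, %d stems\n",
              nrow(x), sum(lab == "palm"), sum(lab == "nonpalm"), ncol(x),
              sum(x)))
  invisible(x)
}

#' Expected species richness in a sample of two individuals
#'
#' Hurlbert rarefaction to a sample of two: for a quadrat with total `N`
#' individuals and species abundances `N_i`, the expected number of species in
#' two draws without replacement is `sum_i [1 - C(N - N_i, 2) / C(N, 2)]`.
#' Defined only for `N >= 2`; it lies in `[1, 2]`, equals 2 exactly when every
#' species is a singleton and 1 exactly when a single species is present.
#'
#' @param counts Integer vector of species abundances (one quadrat).
#' @return The rarefied richness, or `NA` when `N < 2`.
#' @examples
#' rarefied_richness(c(2, 2))   # 5/3
#' @export
rarefied_richness <- function(counts) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 2) return(NA_real_)
  # vegan warns when the smallest count exceeds 1; genuine abundance data
  # trigger it spuriously
  as.numeric(suppressWarnings(
    vegan::rarefy(t(as.matrix(as.integer(counts))), sample = 2)))
}

#' Per-label community summaries
#'
#' Mean and standard error of stem density (individuals per quadrat), observed
#' species richness, and rarefied richness per two individuals, separately for
#' palm and non-palm quadrats. Quadrats with fewer than two individuals are
#' excluded from the rarefied summary (where it is undefined).
#'
#' @param cm A [community_matrix()].
#' @return Data frame with one row per label and columns
#'   `label, n_quadrats, density_mean, density_se, richness_mean, richness_se,
#'   rarefied_mean, rarefied_se, n_rarefied`.
#' @export
quadrat_summaries <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  lab <- attr(cm, "labels")
  N <- rowSums(cm)
  rich <- rowSums(cm > 0)
  rare <- rep(NA_real_, nrow(cm))
  ok <- N >= 2
  if (any(ok))
    rare[ok] <- as.numeric(suppressWarnings(
      vegan::rarefy(unclass(cm)[ok, , drop = FALSE], sample = 2)))
  se <- function(v) sd(v) / sqrt(length(v))
  out <- lapply(levels(lab), function(L) {
    i <- lab == L
    data.frame(label = L, n_quadrats = sum(i),
               density_mean = mean(N[i]), density_se = se(N[i]),
               richness_mean = mean(rich[i]), richness_se = se(rich[i]),
               rarefied_mean = mean(rare[i], na.rm = TRUE),
               rarefied_se = se(rare[i][!is.na(rare[i])]),
               n_rarefied = sum(!is.na(rare[i])))
  })
  do.call(rbind, out)
}

# sums of squares of a distance partition: SS_total and within-label SS
# (m2 is the full matrix of squared dissimilarities)
permanova_ss <- function(m2, labels) {
  n <- nrow(m2)
  ss_total <- sum(m2[upper.tri(m2)]) / n
  ss_within <- 0
  for (L in levels(labels)) {
    i <- which(labels == L)
    if (length(i) > 1)
      ss_within <- ss_within + sum(m2[i, i][upper.tri(diag(length(i)))]) / length(i)
  }
  c(total = ss_total, within = ss_within)
}

permanova_f <- function(m2, labels, df_b, df_w) {
  ss <- permanova_ss(m2, labels)
  ss_b <- ss["total"] - ss["within"]
  if (ss["total"] <= 0) return(c(F = 0, ss_b = 0, ss_w = 0, ss_t = 0))
  Fv <- if (ss["within"] <= 0) Inf else (ss_b / df_b) / (ss["within"] / df_w)
  c(F = unname(Fv), ss_b = unname(ss_b), ss_w = unname(ss["within"]),
    ss_t = unname(ss["total"]))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Tests whether community composition differs between palm and non-palm
#' quadrats by partitioning the Bray-Curtis dissimilarity matrix into
#' between- and within-label sums of squares. The pseudo-F statistic is
#' `(SS_between / df_between) / (SS_within / df_within)`; significance comes
#' from random relabelling of quadrats, `P = (1 + #[F* >= F]) / (1 + n_perm)`.
#' With `exact = TRUE` all distinct label assignments of the observed group
#' sizes are enumerated and `P` is the exact fraction with `F* >= F`
#' (identity included), feasible for small instances.
#'
#' Quadrats with zero individuals are dropped (Bray-Curtis is undefined for
#' empty rows). Degenerate inputs are well defined: identical rows give
#' `R^2 = 0`, `F = 0`, `P = 1`; perfectly separated internally-identical
#' groups give `R^2 = 1`, `F = Inf` and the minimum achievable `P`.
#'
#' @param cm A [community_matrix()], or a plain abundance matrix.
#' @param labels Group factor (taken from `cm` when it is a
#'   `community_matrix`). Exactly two or more groups, each with >= 2 quadrats.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @param exact Enumerate all relabellings instead of sampling.
#' @return Object of class `palm_permanova` with `df`, `ss`, `ms`,
#'   `f`, `r_squared`, `p_value`, `n_perm`.
#' @export
permanova <- function(cm, labels = attr(cm, "labels"), n_perm = 999,
                      seed = NULL, exact = FALSE) {
  m <- unclass(cm)
  labels <- factor(labels)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  if (nlevels(labels) < 2) stop("need at least two label groups")
  if (any(table(labels) < 2)) stop("each label group needs at least 2 quadrats")
  n <- nrow(m)
  a <- nlevels(labels)
  df_b <- a - 1; df_w <- n - a
  d <- vegan::vegdist(m, method = "bray")
  m2 <- as.matrix(d)^2
  obs <- permanova_f(m2, labels, df_b, df_w)
  r2 <- if (obs["ss_t"] > 0) obs["ss_b"] / obs["ss_t"] else 0

  if (obs["ss_t"] <= 0) {
    p <- 1; n_used <- 0
  } else if (exact) {
    # enumerate distinct assignments of labels to positions (multiset perms)
    perms <- enumerate_labellings(labels)
    fs <- vapply(perms, function(L) permanova_f(m2, L, df_b, df_w)["F"],
                 numeric(1))
    p <- mean(fs >= obs["F"] - 1e-12)
    n_used <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      Fp <- permanova_f(m2, sample(labels), df_b, df_w)["F"]
      if (Fp >= obs["F"] - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(df = c(between = df_b, within = df_w, total = n - 1),
                 ss = c(between = unname(obs["ss_b"]),
                        within = unname(obs["ss_w"]),
                        total = unname(obs["ss_t"])),
                 ms = c(between = unname(obs["ss_b"]) / df_b,
                        within = unname(obs["ss_w"]) / df_w),
                 f = unname(obs["F"]), r_squared = unname(r2),
                 p_value = unname(p), n_perm = n_used,
                 exact = exact),
            class = "palm_permanova")
}

# all distinct assignments of a label multiset to positions
enumerate_labellings <- function(labels) {
  n <- length(labels)
  lev <- levels(labels)
  if (length(lev) != 2) stop("exact enumeration implemented for two groups")
  k <- sum(labels == lev[1])
  sets <- combn(n, k, simplify = FALSE)
  lapply(sets, function(i) {
    L <- factor(rep(lev[2], n), levels = lev)
    L[i] <- lev[1]
    L
  })
}

#' @export
print.palm_permanova <- function(x, ...) {
  cat("PERMANOVA (Bray-Curtis, ",
      if (x$exact) "exact enumeration" else paste0(x$n_perm, " permutations"),
      ")\n", sep = "")
  tab <- data.frame(Df = x$df[1:2],
                    SumOfSqs = x$ss[1:2],
                    MeanSqs = x$ms,
                    F = c(x$f, NA),
                    R2 = c(x$r_squared, NA),
                    P = c(x$p_value, NA))
  print(format(tab, digits = 4), ...)
  invisible(x)
}

#' Per-species palm-association proportion tests
#'
#' For every species, compares the share of its individuals that fall in
#' non-palm quadrats against the null expectation `p0` (by default 0.85, the
#' fraction of all quadrats that are non-palm) with a two-sided one-sample
#' proportion test: chi-square with Yates continuity correction for
#' `n >= exact_threshold`, exact binomial below. A species significantly
#' below `p0` is over-represented near palms (`palm-associated`); one
#' significantly above is `nonpalm-associated`.
#'
#' @param cm A [community_matrix()], or a data frame with columns `species`,
#'   `n_nonpalm`, `n_palm` (e.g. a published abundance table).
#' @param p0 Null proportion in non-palm quadrats (default 0.85).
#' @param alpha Significance level for direction calls (default 0.05; no
#'   multiple-testing correction, matching conventional usage).
#' @param exact_threshold Total count below which the exact binomial test is
#'   used (default 25).
#' @return Data frame with one row per species: `species`, `n_nonpalm`,
#'   `n_palm`, `proportion_nonpalm`, `p_value`, `direction`. Species with zero
#'   total count are skipped.
#' @export
species_proportion_tests <- function(cm, p0 = 0.85, alpha = 0.05,
                                     exact_threshold = 25) {
  stopifnot(p0 > 0, p0 < 1)
  if (inherits(cm, "community_matrix")) {
    lab <- attr(cm, "labels")
    m <- unclass(cm)
    tab <- data.frame(species = colnames(m),
                      n_nonpalm = colSums(m[lab == "nonpalm", , drop = FALSE]),
                      n_palm = colSums(m[lab == "palm", , drop = FALSE]),
                      stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(cm)
    stopifnot(all(c("species", "n_nonpalm", "n_palm") %in% names(tab)))
  }
  tab <- tab[tab$n_nonpalm + tab$n_palm > 0, , drop = FALSE]
  n <- tab$n_nonpalm + tab$n_palm
  prop <- tab$n_nonpalm / n
  pv <- vapply(seq_len(nrow(tab)), function(i) {
    if (n[i] < exact_threshold)
      binom.test(tab$n_nonpalm[i], n[i], p = p0)$p.value
    else
      suppressWarnings(prop.test(tab$n_nonpalm[i], n[i], p = p0)$p.value)
  }, numeric(1))
  direction <- rep("none", nrow(tab))
  direction[pv < alpha & prop < p0] <- "palm-associated"
  direction[pv < alpha & prop > p0] <- "nonpalm-associated"
  data.frame(species = tab$species, n_nonpalm = tab$n_nonpalm,
             n_palm = tab$n_palm, proportion_nonpalm = prop,
             p_value = pv, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}
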