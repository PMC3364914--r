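#' Configuration for the synthetic forest-plot generator
#'
#' Defines the statistical structure of a simulated 25-ha forest dynamics
#' plot: a species-rich sapling layer with log-series abundances and
#' Thomas-process clustering modulated by a smooth large-scale gradient,
#' arborescent palms in three dbh classes, a dioecious large-tree family with
#' sexed adults, two censuses linked by logistic survival/growth/resprout
#' models, and annual seedling-plot cohorts. Near-palm effect sizes are
#' plantable: the defaults reproduce the disturbance signal observed around
#' mature fruiting palms (local sapling thinning, depressed seedling
#' survival, elevated negative growth and resprouting), so the analysis
#' pipeline recovers known parameters. Setting `thinning_prob = 0`,
#' `gradient_amplitude = 0` and all odds multipliers to 1 produces a fully
#' neutral plot for null calibration.
#'
#' @param width,height Window dimensions (m), default 500 x 500.
#' @param n_species Sapling species pool size (default 1000).
#' @param sad_x Log-series shape parameter in (0, 1) for species abundances
#'   (default 0.997, giving a mean of about 57 individuals per species).
#' @param offspring_mean Mean offspring per Thomas-process parent (default 25).
#' @param cluster_sd Cluster spread (s.d., m) for saplings (default 15).
#' @param gradient_amplitude Amplitude in `[0, 1)` of the smooth large-scale
#'   sapling intensity gradient (default 0.3).
#' @param palm_counts Named list of integer vectors `small`, `immature`,
#'   `mature` giving palm counts per species for the 1-10, 10-15 and >= 15 cm
#'   dbh classes. The default follows the census of a western Amazonian plot:
#'   1,673 mature, 309 immature and 508 small arborescent palms across four
#'   species, dominated by *Iriartea deltoidea*.
#' @param palm_cluster_sd Cluster spread for palms (default 30 m).
#' @param palm_gradient_coupling Strength in `[0, 1)` with which palms avoid
#'   the high-sapling-density end of the gradient (default 0.3).
#' @param thinning_radius Repulsion radius around mature palms (default 3 m).
#' @param thinning_prob Probability that a sapling within the repulsion
#'   radius of a mature palm is deleted (default 0.8).
#' @param sapling_survival,neg_growth_base,resprout_base Far-from-palm
#'   baseline probabilities of sapling survival between censuses (0.86),
#'   negative growth (0.2) and resprouting (0.05).
#' @param survival_or_mature,survival_or_immature Odds multipliers on sapling
#'   survival within 10 m of a mature/immature palm (default 1: unaffected).
#' @param neg_growth_or_mature,neg_growth_or_immature Odds multipliers on
#'   negative growth near a mature/immature palm (default 1.5).
#' @param resprout_or_mature,resprout_or_immature Odds multipliers on
#'   resprouting near a mature/immature palm (default 2).
#' @param n_myristicaceae Number of sexed adults of the dioecious family
#'   (default 200, half female).
#' @param n_seedling_plots Number of 1 m^2 seedling plots (default 339).
#' @param seedling_cohorts Cohort years (default 2003:2007).
#' @param recruit_mean Mean recruits per plot and cohort (default 7.3,
#'   about 12,400 recruits in total).
#' @param recruit_size Negative-binomial dispersion (size) of recruit counts
#'   (default 1; the plot-to-plot dispersion is unknown and configurable).
#' @param seedling_survival Far-from-palm one-year survival probability of a
#'   recruit (default 0.52).
#' @param seedling_or_mature Odds multiplier on seedling survival for plots
#'   within 10 m of a mature palm (default 0.5).
#' @param near_radius Near/far threshold (default 10 m).
#' @param date0,date1 Census dates in decimal years (1996, 2003).
#' @param seed Integer seed; every draw of the generator flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(width = 500, height = 500,
                       n_species = 1000, sad_x = 0.997,
                       offspring_mean = 25, cluster_sd = 15,
                       gradient_amplitude = 0.3,
                       palm_counts = list(
                         small = c(IRDE = 493L, ASCH = 0L, OEBA = 0L, SOEX = 15L),
                         immature = c(IRDE = 292L, ASCH = 3L, OEBA = 3L, SOEX = 11L),
                         mature = c(IRDE = 1483L, ASCH = 92L, OEBA = 95L, SOEX = 3L)),
                       palm_cluster_sd = 30, palm_gradient_coupling = 0.3,
                       thinning_radius = 3, thinning_prob = 0.8,
                       sapling_survival = 0.86,
                       survival_or_mature = 1, survival_or_immature = 1,
                       neg_growth_base = 0.2,
                       neg_growth_or_mature = 1.5, neg_growth_or_immature = 1.5,
                       resprout_base = 0.05,
                       resprout_or_mature = 2, resprout_or_immature = 2,
                       n_myristicaceae = 200,
                       n_seedling_plots = 339, seedling_cohorts = 2003:2007,
                       recruit_mean = 7.3, recruit_size = 1,
                       seedling_survival = 0.52, seedling_or_mature = 0.5,
                       near_radius = 10,
                       date0 = 1996, date1 = 2003, seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$thinning_prob, cfg$sapling_survival, cfg$neg_growth_base,
             cfg$resprout_base, cfg$seedling_survival)
  ors <- c(cfg$survival_or_mature, cfg$survival_or_immature,
           cfg$neg_growth_or_mature, cfg$neg_growth_or_immature,
           cfg$resprout_or_mature, cfg$resprout_or_immature,
           cfg$seedling_or_mature)
  stopifnot(all(probs >= 0 & probs <= 1), all(ors > 0), cfg$n_species >= 2,
            cfg$sad_x > 0, cfg$sad_x < 1,
            cfg$gradient_amplitude >= 0, cfg$gradient_amplitude < 1,
            cfg$thinning_radius > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic forest-plot configuration: %g x %g m, %d species, seed %d\n",
              x$width, x$height, x$n_species, x$seed))
  cat(sprintf("  thinning %g within %g m; seedling survival OR %g near mature palms\n",
              x$thinning_prob, x$thinning_radius, x$seedling_or_mature))
  invisible(x)
}

# log-series species-abundance draw: P(n) proportional to x^n / n,
# sampled by inversion on a truncated support
rlogseries <- function(n, x, max_n = 1e5) {
  k <- seq_len(max_n)
  p <- x^k / k
  cdf <- cumsum(p) / sum(p)
  findInterval(runif(n), cdf) + 1L
}

# smooth standardised gradient field on [-1, 1]
gradient_field <- function(x, y, width, height) {
  sin(2 * pi * x / width) * sin(2 * pi * y / height)
}

# place n points of one species cloud: Thomas process with per-point
# rejection against the window and (optionally) the gradient, preserving n
thomas_points <- function(n, width, height, cluster_sd, offspring_mean,
                          amplitude = 0, sign = 1) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  buffer <- 3 * cluster_sd
  n_par <- max(1L, as.integer(ceiling(n / offspring_mean)))
  px <- runif(n_par, -buffer, width + buffer)
  py <- runif(n_par, -buffer, height + buffer)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    par <- sample.int(n_par, m, replace = TRUE)
    cx <- px[par] + rnorm(m, 0, cluster_sd)
    cy <- py[par] + rnorm(m, 0, cluster_sd)
    ok <- cx >= 0 & cx <= width & cy >= 0 & cy <= height
    if (amplitude > 0) {
      keep_p <- (1 + sign * amplitude *
                   gradient_field(cx, cy, width, height)) / (1 + amplitude)
      ok <- ok & (runif(m) < keep_p)
    }
    x[todo[ok]] <- cx[ok]; y[todo[ok]] <- cy[ok]
    todo <- todo[!ok]
  }
  cbind(x = x, y = y)
}

# logistic helper: probability from baseline p and odds multiplier per flag
shift_odds <- function(p, or_a = 1, near_a = FALSE, or_b = 1, near_b = FALSE) {
  odds <- p / (1 - p) * or_a^near_a * or_b^near_b
  odds / (1 + odds)
}

#' Simulate a two-census forest plot
#'
#' Generates census tables for two censuses plus the reproductive-status
#' table of the dioecious family, with the structure described in
#' [sim_config()]: clustered log-series sapling communities on a smooth
#' intensity gradient, palms in three dbh classes placed preferentially at
#' the low-sapling end of the gradient, independent deletion of saplings
#' within the repulsion radius of mature palms, and census transitions
#' (survival, diameter growth, resprouting) drawn from logistic models whose
#' near-palm terms equal the configured odds multipliers. The output is fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_forest`: `census` (both censuses, stacked),
#'   `repro` (tag/sex table), `window`, `palm_species`, `config`, and the
#'   focal patterns `mature_palms`, `immature_palms`.
#' @export
simulate_forest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  w <- fdp_window(cfg$width, cfg$height)
  area_scale <- (cfg$width * cfg$height) / 25e4  # relative to the 25-ha default

  # --- sapling layer -------------------------------------------------------
  ab <- rlogseries(cfg$n_species, cfg$sad_x)
  if (area_scale < 1) ab <- rbinom(cfg$n_species, ab, area_scale)
  sp_codes <- sprintf("SP%04d", seq_len(cfg$n_species))
  pieces <- vector("list", cfg$n_species)
  for (i in seq_len(cfg$n_species)) {
    pieces[[i]] <- thomas_points(ab[i], cfg$width, cfg$height, cfg$cluster_sd,
                                 cfg$offspring_mean, cfg$gradient_amplitude, 1)
  }
  sap_xy <- do.call(rbind, pieces)
  sap_sp <- rep(sp_codes, ab)

  # --- palms ---------------------------------------------------------------
  scale_count <- function(k) {
    if (area_scale >= 1) k else rbinom(length(k), k, area_scale)
  }
  palm_species <- names(cfg$palm_counts$mature)
  palm_rows <- list()
  dbh_draw <- list(small = function(m) runif(m, 1, 10),
                   immature = function(m) runif(m, 10, 15 - 1e-6),
                   mature = function(m) runif(m, 15, 45))
  for (cls in c("small", "immature", "mature")) {
    counts <- scale_count(cfg$palm_counts[[cls]])
    for (s in seq_along(counts)) {
      m <- counts[s]
      if (m == 0) next
      xy <- thomas_points(m, cfg$width, cfg$height, cfg$palm_cluster_sd,
                          cfg$offspring_mean, cfg$palm_gradient_coupling, -1)
      palm_rows[[length(palm_rows) + 1L]] <-
        data.frame(species = palm_species[s], x = xy[, 1], y = xy[, 2],
                   dbh = dbh_draw[[cls]](m), stringsAsFactors = FALSE)
    }
  }
  palms <- do.call(rbind, palm_rows)
  mature_idx <- palms$dbh >= 15
  mature_pp <- point_pattern(palms$x[mature_idx], palms$y[mature_idx], w)
  immature_idx <- palms$dbh >= 10 & palms$dbh < 15
  immature_pp <- point_pattern(palms$x[immature_idx], palms$y[immature_idx], w)

  # --- local thinning of saplings around mature palms ----------------------
  if (cfg$thinning_prob > 0 && npoints(mature_pp) > 0 && nrow(sap_xy) > 0) {
    d <- cpp_nearest_dist(sap_xy[, 1], sap_xy[, 2], mature_pp$x, mature_pp$y)
    drop <- d <= cfg$thinning_radius & runif(nrow(sap_xy)) < cfg$thinning_prob
    sap_xy <- sap_xy[!drop, , drop = FALSE]
    sap_sp <- sap_sp[!drop]
  }

  # --- dioecious family ----------------------------------------------------
  n_myr <- if (area_scale >= 1) cfg$n_myristicaceae else
    rbinom(1, cfg$n_myristicaceae, area_scale)
  myr_xy <- thomas_points(n_myr, cfg$width, cfg$height, cfg$palm_cluster_sd,
                          cfg$offspring_mean, 0)
  myr_sex <- rep(c("F", "M"), length.out = n_myr)
  if (n_myr > 1) myr_sex <- sample(myr_sex)

  # --- census 0 ------------------------------------------------------------
  census0 <- rbind(
    data.frame(species = sap_sp, x = sap_xy[, 1], y = sap_xy[, 2],
               dbh = runif(nrow(sap_xy), 1, 2), stringsAsFactors = FALSE),
    palms[, c("species", "x", "y", "dbh")],
    if (n_myr > 0)
      data.frame(species = "MYRI", x = myr_xy[, 1], y = myr_xy[, 2],
                 dbh = runif(n_myr, 10, 60), stringsAsFactors = FALSE)
  )
  n_stems <- nrow(census0)
  census0 <- data.frame(tag = sprintf("T%06d", seq_len(n_stems)),
                        census0, status = "alive", resprout = FALSE,
                        census = 0L, date = cfg$date0,
                        stringsAsFactors = FALSE)

  repro <- data.frame(tag = census0$tag[census0$species == "MYRI"],
                      sex = myr_sex, stringsAsFactors = FALSE)

  # --- census 1 transitions ------------------------------------------------
  is_sapling <- census0$dbh >= 1 & census0$dbh <= 2 &
    !(census0$species %in% c(palm_species, "MYRI"))
  near_mat <- if (npoints(mature_pp) > 0)
    cpp_nearest_dist(census0$x, census0$y, mature_pp$x, mature_pp$y) <= cfg$near_radius
  else rep(FALSE, n_stems)
  near_imm <- if (npoints(immature_pp) > 0)
    cpp_nearest_dist(census0$x, census0$y, immature_pp$x, immature_pp$y) <= cfg$near_radius
  else rep(FALSE, n_stems)

  p_surv <- ifelse(is_sapling,
                   shift_odds(cfg$sapling_survival,
                              cfg$survival_or_mature, near_mat,
                              cfg$survival_or_immature, near_imm),
                   0.98)
  alive1 <- runif(n_stems) < p_surv
  p_neg <- shift_odds(cfg$neg_growth_base,
                      cfg$neg_growth_or_mature, near_mat,
                      cfg$neg_growth_or_immature, near_imm)
  negative <- runif(n_stems) < p_neg
  dt <- cfg$date1 - cfg$date0
  rate <- ifelse(negative, -abs(rnorm(n_stems, 0.03, 0.02)),
                 abs(rnorm(n_stems, 0.05, 0.04)))
  dbh1 <- pmax(0.1, census0$dbh + rate * dt)
  p_rsp <- shift_odds(cfg$resprout_base,
                      cfg$resprout_or_mature, near_mat,
                      cfg$resprout_or_immature, near_imm)
  resprout1 <- is_sapling & (runif(n_stems) < p_rsp)

  census1 <- data.frame(tag = census0$tag, species = census0$species,
                        x = census0$x, y = census0$y,
                        dbh = ifelse(alive1, dbh1, census0$dbh),
                        status = ifelse(alive1, "alive", "dead"),
                        resprout = resprout1, census = 1L, date = cfg$date1,
                        stringsAsFactors = FALSE)

  structure(list(census = rbind(census0, census1), repro = repro,
                 window = w, palm_species = palm_species,
                 myristicaceae_species = "MYRI",
                 mature_palms = mature_pp, immature_palms = immature_pp,
                 config = cfg),
            class = "sim_forest")
}

#' @export
print.sim_forest <- function(x, ...) {
  c0 <- x$census[x$census$census == 0, ]
  cat(sprintf("Synthetic forest plot: %d stems in census 0 (%d mature palms, %d immature)\n",
              nrow(c0), npoints(x$mature_palms), npoints(x$immature_palms)))
  invisible(x)
}

#' Write a simulated forest to census files
#'
#' Writes `census0.tsv`, `census1.tsv` and `repro.tsv` in the canonical
#' formats read by [read_census()] and [read_repro_table()]. Identical
#' configurations (including seed) produce byte-identical files.
#'
#' @param sim A [simulate_forest()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the three file paths, invisibly.
#' @export
write_forest <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_forest"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("census0.tsv", "census1.tsv", "repro.tsv"))
  write_census(sim$census[sim$census$census == 0, ], paths[1])
  write_census(sim$census[sim$census$census == 1, ], paths[2])
  write.table(sim$repro, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate seedling-plot cohorts
#'
#' Places 1 m^2 seedling plots on a jittered grid across the window, draws
#' per-plot, per-cohort recruit counts from a negative binomial, and draws
#' one-year survivors as binomial with a logit survival probability shifted
#' by the configured odds multiplier for plots within `near_radius` of a
#' mature palm. Plots with zero recruits are retained with `n = 0`.
#'
#' @param config A [sim_config()].
#' @param palms `point_pattern` of mature palms (may be empty).
#' @param seed Optional seed overriding `config$seed` (so replicate cohorts
#'   can be drawn against one fixed forest).
#' @return Data frame with columns `plot_id`, `x`, `y`, `cohort`, `recruits`,
#'   `survivors`.
#' @export
simulate_seedling_plots <- function(config, palms, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_seedling_plots
  # jittered grid: spatial spread across the plot without mapped trails
  g <- ceiling(sqrt(n))
  sx <- cfg$width / g; sy <- cfg$height / g
  cells <- sample(g * g, n)
  px <- ((cells - 1) %% g + runif(n)) * sx
  py <- ((cells - 1) %/% g + runif(n)) * sy
  near <- if (npoints(palms) > 0)
    cpp_nearest_dist(px, py, palms$x, palms$y) <= cfg$near_radius
  else rep(FALSE, n)
  p <- shift_odds(cfg$seedling_survival, cfg$seedling_or_mature, near)
  out <- do.call(rbind, lapply(seq_along(cfg$seedling_cohorts), function(k) {
    recruits <- rnbinom(n, size = cfg$recruit_size, mu = cfg$recruit_mean)
    survivors <- rbinom(n, recruits, p)
    data.frame(plot_id = sprintf("P%03d", seq_len(n)), x = px, y = py,
               cohort = cfg$seedling_cohorts[k], recruits = recruits,
               survivors = survivors, stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}

#' Write seedling plots to a delimited file
#' @param plots Data frame from [simulate_seedling_plots()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seedling_plots <- function(plots, path) {
  write.table(plots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a seedling-plot file
#' @param path Delimited file with columns `plot_id`, `x`, `y`, `cohort`,
#'   `recruits`, `survivors`.
#' @return Data frame.
#' @export
read_seedling_plots <- function(path) {
  raw <- read_delimited(path)
  need <- c("plot_id", "x", "y", "cohort", "recruits", "survivors")
  if (!all(need %in% names(raw)))
    stop("seedling-plot file must have columns: ", paste(need, collapse = ", "))
  raw[, need]
}
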