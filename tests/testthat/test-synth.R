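# a small plot keeps the generator tests fast; counts scale with area
small_cfg <- function(...) {
  sim_config(width = 125, height = 125, n_species = 150, seed = 71, ...)
}

test_that("identical configurations produce byte-identical output files", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_forest(simulate_forest(cfg), d1)
  write_forest(simulate_forest(cfg), d2)
  for (f in c("census0.tsv", "census1.tsv", "repro.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  sim <- simulate_forest(cfg)
  p1 <- simulate_seedling_plots(cfg, sim$mature_palms)
  p2 <- simulate_seedling_plots(cfg, sim$mature_palms)
  expect_identical(p1, p2)
})

test_that("simulated censuses round-trip through the census reader", {
  sim <- simulate_forest(small_cfg())
  dir <- withr::local_tempdir()
  paths <- write_forest(sim, dir)
  c0 <- read_census(file.path(dir, "census0.tsv"))
  expect_equal(nrow(c0), sum(sim$census$census == 0))
  expect_true(all(c0$dbh > 0))
  repro <- read_repro_table(file.path(dir, "repro.tsv"))
  expect_true(all(repro$sex %in% c("M", "F")))
  foc <- classify_focals(c0, sim$palm_species, repro)
  expect_equal(nrow(foc$mature_palm), npoints(sim$mature_palms))
  expect_equal(nrow(foc$immature_palm), npoints(sim$immature_palms))
})

test_that("realised species abundances follow the configured log-series", {
  # full-size window: realised abundances equal the log-series draw exactly
  # when no thinning or gradient modulation is configured
  cfg <- sim_config(n_species = 800, sad_x = 0.99,
                    thinning_prob = 0, gradient_amplitude = 0, seed = 72)
  sim <- simulate_forest(cfg)
  c0 <- sim$census[sim$census$census == 0, ]
  sap <- c0[!(c0$species %in% c(sim$palm_species, "MYRI")), ]
  ab <- table(sap$species)
  # chi-square GOF of abundance classes against the log-series pmf
  x <- 0.99
  k <- 1:5000
  p_raw <- x^k / k
  pmf <- p_raw / sum(p_raw)
  breaks <- c(1, 2, 4, 8, 16, 32, 64, Inf)
  expected_p <- vapply(seq_len(length(breaks) - 1), function(i)
    sum(pmf[k >= breaks[i] & k < breaks[i + 1]]), numeric(1))
  observed <- vapply(seq_len(length(breaks) - 1), function(i)
    sum(ab >= breaks[i] & ab < breaks[i + 1]), numeric(1))
  # drop empty abundance classes before forming the statistic
  keep <- expected_p * length(ab) >= 1
  chi2 <- sum((observed[keep] - expected_p[keep] * length(ab))^2 /
                (expected_p[keep] * length(ab)))
  expect_lt(chi2, qchisq(0.99, df = sum(keep) - 1))
})

test_that("a neutral configuration plants no bivariate signal", {
  cfg <- small_cfg(thinning_prob = 0, gradient_amplitude = 0,
                   survival_or_mature = 1, survival_or_immature = 1,
                   neg_growth_or_mature = 1, neg_growth_or_immature = 1,
                   resprout_or_mature = 1, resprout_or_immature = 1)
  sim <- simulate_forest(cfg)
  c0 <- sim$census[sim$census$census == 0, ]
  sap <- c0[c0$dbh <= 2 & !(c0$species %in% c(sim$palm_species, "MYRI")), ]
  sap_pp <- point_pattern(sap$x, sap$y, sim$window)
  env <- oring_envelope(sim$mature_palms, sap_pp, radii = 1:10, dr = 1,
                        null = null_model("heterogeneous", 30),
                        nsim = 199, rank = 5, seed = 73)
  expect_lte(mean(env$flag != "none"), 0.2)   # ~5% pointwise, one realisation
})

test_that("planted thinning produces small-scale repulsion from mature palms", {
  cfg <- small_cfg(thinning_prob = 0.8)
  sim <- simulate_forest(cfg)
  c0 <- sim$census[sim$census$census == 0, ]
  sap <- c0[c0$dbh <= 2 & !(c0$species %in% c(sim$palm_species, "MYRI")), ]
  sap_pp <- point_pattern(sap$x, sap$y, sim$window)
  env <- oring_envelope(sim$mature_palms, sap_pp, radii = 1:10, dr = 1,
                        null = null_model("heterogeneous", 30),
                        nsim = 199, rank = 5, seed = 74)
  expect_true(any(env$flag[1:3] == "repulsion"))
})

test_that("seedling plots: layout, null odds ratio, and degenerate plots", {
  cfg <- small_cfg(seedling_or_mature = 1)
  sim <- simulate_forest(cfg)
  plots <- simulate_seedling_plots(cfg, sim$mature_palms)
  expect_equal(length(unique(plots$plot_id)), cfg$n_seedling_plots)
  expect_equal(nrow(plots), cfg$n_seedling_plots * length(cfg$seedling_cohorts))
  expect_true(all(plots$survivors <= plots$recruits))
  expect_true(any(plots$recruits == 0))     # NB dispersion leaves empty plots

  # pooled near/far survival odds ratio is 1 within ~3 binomial s.e.
  near <- near_focal(plots$x, plots$y, sim$mature_palms)
  k1 <- sum(plots$survivors[near]); n1 <- sum(plots$recruits[near])
  k0 <- sum(plots$survivors[!near]); n0 <- sum(plots$recruits[!near])
  log_or <- log((k1 / (n1 - k1)) / (k0 / (n0 - k0)))
  se <- sqrt(1 / k1 + 1 / (n1 - k1) + 1 / k0 + 1 / (n0 - k0))
  expect_lt(abs(log_or), 3 * se)
})

test_that("the planted seedling survival odds multiplier shifts the fitted GLM", {
  cfg <- small_cfg(seedling_or_mature = 0.4, recruit_mean = 25)
  sim <- simulate_forest(cfg)
  plots <- simulate_seedling_plots(cfg, sim$mature_palms, seed = 75)
  fit <- seedling_survival_analysis(plots, sim$mature_palms, sim$immature_palms)
  b <- coef(fit)["nearATRUE"]
  se <- sqrt(vcov(fit)["nearATRUE", "nearATRUE"])
  expect_lt(abs(b - log(0.4)), 3.5 * se)
})
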