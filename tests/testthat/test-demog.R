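test_that("growth rate follows the census-interval formula and boundary rule", {
  g <- growth_rate(1.5, 1.4, 2000, 2005)
  expect_equal(g$rate, -0.02)
  expect_equal(g$negative, 1L)
  g0 <- growth_rate(1.2, 1.2, 2000, 2005)
  expect_equal(g0$rate, 0)
  expect_equal(g0$negative, 0L)                 # zero growth is non-negative
  gp <- growth_rate(1.0, 1.5, 2000, 2005)
  expect_equal(gp$rate, 0.1)
  expect_equal(gp$negative, 0L)
  expect_error(growth_rate(1, 1.1, 2005, 2005), "time1")
})

make_two_census <- function(n, width = 100) {
  set.seed(61)
  c0 <- data.frame(tag = sprintf("T%04d", 1:n),
                   species = sample(c("SPA", "SPB", "IRDE"), n, TRUE),
                   x = runif(n, 0, width), y = runif(n, 0, width),
                   dbh = runif(n, 0.5, 20), status = "alive",
                   resprout = FALSE, census = 0L, date = 1996,
                   stringsAsFactors = FALSE)
  c1 <- c0
  c1$census <- 1L; c1$date <- 2003
  c1$status <- ifelse(runif(n) < 0.85, "alive", "dead")
  c1$dbh <- c0$dbh + rnorm(n, 0.2, 0.5)
  c1$resprout <- runif(n) < 0.1
  rbind(c0, c1)
}

test_that("the sapling design matches a brute-force recomputation", {
  w <- fdp_window(100, 100)
  census <- make_two_census(400)
  fA <- csr_pattern(5, w); fB <- csr_pattern(4, w)
  d <- sapling_design(census, fA, fB, palm_species = "IRDE")

  c0 <- census[census$census == 0, ]
  sap <- c0[c0$dbh >= 1 & c0$dbh <= 2 & c0$species != "IRDE", ]
  expect_equal(nrow(d), nrow(sap))
  dA <- brute_nn_dist(sap$x, sap$y, fA$x, fA$y)
  dB <- brute_nn_dist(sap$x, sap$y, fB$x, fB$y)
  expect_equal(d$nearA, dA <= 10)
  expect_equal(d$nearB, dB <= 10)
  # per-cell counts equal the brute-force cross-tabulation
  expect_equal(unname(table(d$nearA, d$nearB)),
               unname(table(dA <= 10, dB <= 10)))
  # survival/resprout responses line up with the second census by tag
  c1 <- census[census$census == 1, ]
  expect_equal(d$survival,
               as.integer(c1$status[match(d$tag, c1$tag)] == "alive"))
  expect_equal(d$resprout, as.integer(c1$resprout[match(d$tag, c1$tag)]))
  # negative growth defined only for survivors
  expect_true(all(is.na(d$negative_growth[d$survival == 0])))
})

test_that("the saturated single-factor GLM reproduces the 2x2 odds ratio exactly", {
  d <- data.frame(nearA = rep(c(TRUE, FALSE), c(100, 100)), nearB = FALSE,
                  survival = c(rep(1:0, c(80, 20)), rep(1:0, c(90, 10))))
  class(d) <- c("demog_design", "data.frame")
  fit <- fit_binomial_glm(d, "survival")
  or <- odds_ratios(fit)
  near <- or[or$cell == "near-far", ]
  expect_equal(near$or, (80 * 10) / (20 * 90), tolerance = 1e-6)
  expect_equal(near$log_or_se, sqrt(1 / 80 + 1 / 20 + 1 / 90 + 1 / 10),
               tolerance = 1e-6)
  expect_equal(or$or[or$cell == "far-far"], 1)  # baseline by construction
  expect_true(all(or$or > 0, na.rm = TRUE))
})

test_that("complete separation and missing baseline raise diagnostic errors", {
  d <- data.frame(nearA = rep(c(TRUE, FALSE), each = 10), nearB = FALSE,
                  survival = 1L)
  class(d) <- c("demog_design", "data.frame")
  expect_error(fit_binomial_glm(d, "survival"), "separation")

  d2 <- data.frame(nearA = TRUE, nearB = FALSE, survival = rep(0:1, 5))
  class(d2) <- c("demog_design", "data.frame")
  expect_error(fit_binomial_glm(d2, "survival"), "far-far")
})

test_that("an empty cell leaves its contrast inestimable but the fit proceeds", {
  set.seed(62)
  d <- data.frame(nearA = rep(c(TRUE, FALSE), each = 50),
                  nearB = FALSE,
                  survival = rbinom(100, 1, 0.6))
  class(d) <- c("demog_design", "data.frame")
  fit <- fit_binomial_glm(d, "survival")
  or <- odds_ratios(fit)
  expect_true(is.na(or$or[or$cell == "far-near"]))
  expect_true(is.na(or$or[or$cell == "near-near"]))
  expect_false(is.na(or$or[or$cell == "near-far"]))
})

test_that("aggregated binomial and expanded Bernoulli fits coincide", {
  set.seed(63)
  n_plot <- 40
  design <- data.frame(plot_id = seq_len(n_plot),
                       nearA = runif(n_plot) < 0.5,
                       nearB = runif(n_plot) < 0.4,
                       n = rpois(n_plot, 20))
  design$k <- rbinom(n_plot, design$n, 0.4 + 0.2 * design$nearA)
  class(design) <- c("demog_design", "data.frame")
  agg <- fit_binomial_glm(design)
  bern <- fit_binomial_glm(expand_binary(design), "survival")
  expect_equal(coef(agg), coef(bern), tolerance = 1e-6)
  expect_equal(odds_ratios(agg)$or, odds_ratios(bern)$or, tolerance = 1e-6)
})

test_that("zero-recruit plots are retained but contribute nothing to the fit", {
  set.seed(64)
  w <- fdp_window(100, 100)
  fA <- csr_pattern(3, w); fB <- csr_pattern(3, w)
  plots <- data.frame(plot_id = sprintf("P%02d", 1:30),
                      x = runif(30, 0, 100), y = runif(30, 0, 100),
                      cohort = 2003L,
                      recruits = c(rpois(28, 10), 0L, 0L))
  plots$survivors <- rbinom(30, plots$recruits, 0.5)
  d <- seedling_design(plots, fA, fB)
  expect_equal(nrow(d), 30L)                       # zero-recruit plots retained
  fit_all <- fit_binomial_glm(d)
  d_pos <- d[d$n > 0, ]
  class(d_pos) <- c("demog_design", "data.frame")
  fit_pos <- fit_binomial_glm(d_pos)
  expect_equal(coef(fit_all), coef(fit_pos), tolerance = 1e-10)
})

test_that("a design with only far-far observations keeps just the baseline", {
  d <- data.frame(nearA = FALSE, nearB = FALSE, survival = rep(0:1, 10))
  class(d) <- c("demog_design", "data.frame")
  fit <- fit_binomial_glm(d, "survival")
  or <- odds_ratios(fit)
  expect_true(all(is.na(or$or[or$cell != "far-far"])))
  expect_equal(or$or[or$cell == "far-far"], 1)
})
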