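w <- fdp_window(100, 100)

test_that("O-ring closed-form example: three points in one ring", {
  big <- fdp_window(500, 500)
  p1 <- point_pattern(250, 250, big)
  p2 <- point_pattern(c(252.5, 247.5, 250), c(250, 250, 252.5), big)
  o <- oring(p1, p2, radii = 2.5, dr = 1)
  expect_equal(o$o12, 3 / (5 * pi))           # 3 / pi (3^2 - 2^2)
  expect_equal(o$counts, 3L)
})

test_that("degenerate patterns behave as specified", {
  p1 <- csr_pattern(5, w)
  empty <- point_pattern(numeric(0), numeric(0), w)
  o <- oring(p1, empty, radii = 1:5, dr = 1)
  expect_equal(o$o12, rep(0, 5))
  expect_error(oring(empty, p1, radii = 1:5, dr = 1), "empty")
})

test_that("O-ring equals the brute-force double loop with clipped ring areas", {
  set.seed(21)
  for (rep in 1:3) {
    p1 <- csr_pattern(15, w)
    p2 <- csr_pattern(200, w)
    radii <- c(2, 5, 9.5)
    o <- oring(p1, p2, radii = radii, dr = 2)
    b <- brute_oring(p1, p2, radii, dr = 2)
    expect_identical(as.integer(o$counts), as.integer(b$counts))
    expect_equal(o$o12, b$o12, tolerance = 1e-7)
  }
})

test_that("under independence the O-ring estimates the type-2 intensity", {
  set.seed(22)
  lambda2 <- 0.05
  radii <- c(2, 5, 10)
  reps <- 100
  est <- matrix(NA_real_, reps, length(radii))
  for (i in seq_len(reps)) {
    p1 <- csr_pattern(20, w)
    p2 <- csr_pattern(500, w)   # 500 / 1e4 = 0.05 m^-2
    est[i, ] <- oring(p1, p2, radii = radii, dr = 1)$o12
  }
  for (k in seq_along(radii)) {
    se <- sd(est[, k]) / sqrt(reps)
    expect_lt(abs(mean(est[, k]) - lambda2), 3 * se)
  }
})

test_that("g12 satisfies O12 = lambda2 * g12 identically", {
  set.seed(23)
  o <- oring(csr_pattern(10, w), csr_pattern(300, w), radii = 1:10, dr = 1)
  expect_equal(o$o12, o$lambda2 * o$g12)
})

test_that("homogeneous null draws are uniform over the window", {
  set.seed(24)
  p1 <- csr_pattern(100, w)
  counts <- matrix(0, 5, 5)
  reps <- 40
  for (i in seq_len(reps)) {
    s <- sample_null(p1, null_model("homogeneous"))
    ix <- pmin(floor(s$x / 20), 4) + 1; iy <- pmin(floor(s$y / 20), 4) + 1
    for (j in seq_along(ix)) counts[ix[j], iy[j]] <- counts[ix[j], iy[j]] + 1
  }
  n_tot <- reps * 100
  chi2 <- sum((counts - n_tot / 25)^2 / (n_tot / 25))
  expect_lt(chi2, qchisq(0.99, df = 24))
  expect_equal(npoints(sample_null(p1, null_model("homogeneous"))), 100)
})

test_that("heterogeneous null respects the displacement constraint", {
  set.seed(25)
  p1 <- csr_pattern(200, w)
  null <- null_model("heterogeneous", displacement = 7)
  for (i in 1:5) {
    s <- sample_null(p1, null)
    d <- sqrt((s$x - p1$x)^2 + (s$y - p1$y)^2)
    expect_true(all(d <= 7 + 1e-9))
    expect_true(all(s$x >= 0 & s$x <= 100 & s$y >= 0 & s$y <= 100))
  }
})

test_that("a degenerate null (identity) collapses the envelope onto the data", {
  set.seed(26)
  p1 <- csr_pattern(20, w)
  p2 <- csr_pattern(200, w)
  env <- oring_envelope(p1, p2, radii = 1:8, dr = 1,
                        null = function(p) p, nsim = 19, rank = 1)
  expect_equal(env$lower, env$observed$o12)
  expect_equal(env$upper, env$observed$o12)
  expect_true(all(env$flag == "none"))     # strict exceedance: ties stay neutral
})

test_that("the displacement null preserves a large-scale gradient that CSR destroys", {
  set.seed(27)
  # type-2 intensity increases with x; focals sit in the dense half
  n2 <- 4000
  x2 <- 100 * sqrt(runif(n2))              # density proportional to x
  p2 <- point_pattern(x2, runif(n2, 0, 100), w)
  p1 <- point_pattern(runif(40, 70, 100), runif(40, 0, 100), w)
  radii <- c(3, 5)
  obs <- oring(p1, p2, radii = radii, dr = 2)$o12
  mean_null <- function(null) {
    sims <- replicate(40, oring(sample_null(p1, null), p2,
                                radii = radii, dr = 2)$o12)
    rowMeans(sims)
  }
  het <- mean_null(null_model("heterogeneous", 15))
  csr <- mean_null(null_model("homogeneous"))
  lambda2 <- n2 / 1e4
  # CSR null collapses to the global intensity; the local null stays near the
  # locally elevated observed level
  expect_lt(abs(mean(csr) - lambda2) / lambda2, 0.15)
  expect_gt(mean(het), 1.3 * mean(csr))
  expect_lt(abs(mean(het) - mean(obs)) / mean(obs), 0.25)
})

test_that("envelope preconditions are enforced", {
  p1 <- csr_pattern(5, w); p2 <- csr_pattern(20, w)
  expect_error(oring_envelope(p1, p2, radii = 1:3, dr = 1, nsim = 5, rank = 5))
})
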