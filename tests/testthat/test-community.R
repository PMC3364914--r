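w25 <- fdp_window(25, 25)   # 5 x 5 grid of 5-m cells

test_that("palm-influence labelling follows queen adjacency with boundary clipping", {
  g <- quadrat_grid(w25, 5)
  none <- label_quadrats(g, point_pattern(numeric(0), numeric(0), w25))
  expect_true(all(none == "nonpalm"))

  interior <- label_quadrats(g, point_pattern(12, 12, w25))
  expect_equal(sum(interior == "palm"), 9L)

  corner <- label_quadrats(g, point_pattern(1, 1, w25))
  expect_equal(sum(corner == "palm"), 4L)

  edge <- label_quadrats(g, point_pattern(12, 1, w25))
  expect_equal(sum(edge == "palm"), 6L)

  rook <- label_quadrats(g, point_pattern(12, 12, w25), adjacency = "rook")
  expect_equal(sum(rook == "palm"), 5L)
})

test_that("community matrix tabulates stems into labelled quadrats", {
  g <- quadrat_grid(w25, 5)
  lab <- label_quadrats(g, point_pattern(12, 12, w25))
  pts <- point_pattern(c(1, 2, 12, 25), c(1, 1, 12, 25), w25,
                       marks = c("A", "B", "A", "C"))
  cm <- community_matrix(pts, g, lab)
  expect_equal(dim(cm), c(25L, 3L))
  expect_equal(sum(cm), 4L)
  expect_equal(unname(unclass(cm)[1, ]), c(1L, 1L, 0L))   # two stems in cell 1
  expect_equal(unname(unclass(cm)[25, "C"]), 1L)          # closed upper boundary
})

test_that("rarefied richness closed forms", {
  expect_equal(rarefied_richness(c(1, 1)), 2)
  expect_equal(rarefied_richness(c(2)), 1)
  expect_equal(rarefied_richness(c(2, 2)), 5 / 3)
  # enumeration oracle for {A:2, B:2}: distinct species over all 6 pairs
  pairs <- utils::combn(c("A", "A", "B", "B"), 2)
  expect_equal(mean(apply(pairs, 2, function(p) length(unique(p)))), 5 / 3)
  expect_true(is.na(rarefied_richness(c(1))))
  # bounds: in [1, 2] for N >= 2; 2 iff all singletons
  set.seed(51)
  for (i in 1:20) {
    counts <- rpois(4, 2)
    if (sum(counts) < 2) next
    rr <- rarefied_richness(counts)
    expect_gte(rr, 1); expect_lte(rr, 2)
    if (all(counts[counts > 0] == 1)) expect_equal(rr, 2)
  }
})

test_that("quadrat summaries compute per-label means and exclude N < 2 from rarefaction", {
  g <- quadrat_grid(fdp_window(10, 5), 5)   # two cells
  lab <- factor(c("palm", "nonpalm"), levels = c("palm", "nonpalm"))
  pts <- point_pattern(c(1, 2, 3, 7), c(1, 1, 1, 1), fdp_window(10, 5),
                       marks = c("A", "A", "B", "C"))
  cm <- community_matrix(pts, g, lab)
  s <- quadrat_summaries(cm)
  palm_row <- s[s$label == "palm", ]
  expect_equal(palm_row$density_mean, 3)
  expect_equal(palm_row$richness_mean, 2)
  expect_equal(palm_row$rarefied_mean, rarefied_richness(c(2, 1)))
  nonpalm_row <- s[s$label == "nonpalm", ]
  expect_equal(nonpalm_row$n_rarefied, 0L)   # single individual: undefined
})

test_that("PERMANOVA handles degenerate compositions as specified", {
  m <- matrix(rep(c(3L, 1L, 2L), each = 6), nrow = 6)
  lab <- factor(rep(c("palm", "nonpalm"), 3))
  res <- permanova(m, lab, n_perm = 49, seed = 1)
  expect_equal(res$r_squared, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$f, 0)

  m2 <- rbind(matrix(rep(c(5L, 0L), each = 3), 3),
              matrix(rep(c(0L, 5L), each = 3), 3))
  lab2 <- factor(rep(c("a", "b"), each = 3))
  res2 <- permanova(m2, lab2, exact = TRUE)
  expect_equal(res2$r_squared, 1)
  expect_true(is.infinite(res2$f))
  expect_equal(res2$p_value, 2 / choose(6, 3))  # both perfect splits tie at F = Inf

  expect_error(permanova(m, factor(rep("palm", 6)), n_perm = 9), "two label")
})

test_that("exact permutation P matches exhaustive enumeration", {
  set.seed(52)
  m <- matrix(rpois(6 * 4, 3), nrow = 6)
  lab <- factor(rep(c("palm", "nonpalm"), each = 3))
  res <- permanova(m, lab, exact = TRUE)
  expect_equal(res$n_perm, choose(6, 3))
  expect_equal(res$p_value, brute_permanova_p(m, lab))
  # sampled permutations approximate the exact value
  res_mc <- permanova(m, lab, n_perm = 999, seed = 53)
  expect_lt(abs(res_mc$p_value - res$p_value), 0.12)
})

test_that("sums of squares and pseudo-F agree with vegan::adonis2", {
  set.seed(54)
  m <- matrix(rpois(12 * 8, 4), nrow = 12)
  lab <- factor(rep(c("palm", "nonpalm"), each = 6))
  res <- permanova(m, lab, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(m ~ lab, method = "bray", permutations = 99)
  expect_equal(res$f, ad$F[1], tolerance = 1e-10)
  expect_equal(res$r_squared, ad$R2[1], tolerance = 1e-10)
  expect_equal(unname(res$ss["between"]), ad$SumOfSqs[1], tolerance = 1e-10)
  expect_equal(unname(res$df["between"]), ad$Df[1])
})

test_that("species proportion tests reproduce published worked examples", {
  tab <- data.frame(species = c("acalypha", "garcinia", "neutral"),
                    n_nonpalm = c(252, 40, 85),
                    n_palm = c(64, 0, 15))
  res <- species_proportion_tests(tab, p0 = 0.85)
  expect_equal(round(res$proportion_nonpalm, 2), c(0.80, 1.00, 0.85))
  expect_equal(res$direction,
               c("palm-associated", "nonpalm-associated", "none"))
  expect_true(all(res$p_value[1:2] < 0.05))
})

test_that("zero-count species are skipped and the exact test engages for small n", {
  tab <- data.frame(species = c("zero", "small"), n_nonpalm = c(0, 5),
                    n_palm = c(0, 4))
  res <- species_proportion_tests(tab, p0 = 0.85)
  expect_equal(res$species, "small")
  # with n = 9 < 25 the exact binomial is used
  expect_equal(res$p_value, binom.test(5, 9, 0.85)$p.value)
})
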