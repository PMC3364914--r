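# palmdisturb

Spatial and demographic analysis of small-scale disturbance around large
arborescent palms in fully mapped forest dynamics plots.

Large palms (in western Amazonia, chiefly *Iriartea deltoidea*) drop fronds
heavy enough to crush juvenile plants, and their fruit crops attract
peccaries that root up the ground around each stem. Either mechanism predicts
a zone of disturbance around every large palm: locally depressed seedling
survival and sapling density, more stem breakage and resprouting, and shifted
species composition. Contrasting mature fruiting palms (dbh ≥ 15 cm) with
still-large but non-fruiting palms (10–15 cm) — and, in parallel, female with
male adults of a dioecious fruiting family — separates the frond mechanism
from the frugivore mechanism. `palmdisturb` is for ecologists who want to run
that entire analysis chain on mapped census data, or to study its statistical
behaviour on synthetic plots with known effect sizes.

## What it computes

* **Bivariate O-ring statistic** `O12(r)` — the mean density of target points
  (e.g. saplings, 1–2 cm dbh) in rings of radius `r`, width `dr`, around
  focal trees; `O12(r) = λ2 · g12(r)`, with ring areas clipped to the window
  by exact circle–rectangle geometry. Monte Carlo envelopes (5th extremes of
  199 randomisations) under two nulls: homogeneous Poisson (CSR) and a
  heterogeneous Poisson implemented as local displacement of each focal
  within 30 m, which preserves large-scale habitat structure while erasing
  small-scale interaction.
* **ISAR** — the individual species–area relationship, the expected number of
  species within `r` of a focal individual, built from per-species
  nearest-neighbour distribution functions; the same envelopes classify focal
  classes as diversity *accumulators* or *repellers*.
* **Quadrat community structure** — 5 × 5 m quadrats labelled palm/non-palm
  (contains or touches a quadrat containing a mature palm); density, species
  richness and Hurlbert rarefied richness per two individuals; PERMANOVA on
  Bray–Curtis dissimilarities with an exact-enumeration mode; per-species
  proportion tests against the 85% non-palm expectation.
* **Demography** — binomial GLMs (logit link) of seedling one-year survival
  (survivors of recruits per 1 m² plot) and sapling survival, negative
  growth (`(dbh1 − dbh0)/(t1 − t0) < 0`) and resprouting, on a
  `near * far` design at 10 m for two focal classes, reported as odds ratios
  with delta-method standard errors against the far–far baseline.
* **Synthetic forest plots** — a generator producing two linked censuses,
  sexed adults of a dioecious family and seedling-plot cohorts, with
  log-series species abundances, Thomas-process clustering, a smooth density
  gradient, and *plantable* near-palm effects (sapling thinning 0.8 within
  3 m, seedling survival odds ratio 0.5, growth/resprout multipliers), so
  parameter recovery and null calibration are testable end to end.

## Worked example

```r
library(palmdisturb)

cfg <- sim_config(width = 250, height = 250, n_species = 400, seed = 42)
sim <- simulate_forest(cfg)
#> Synthetic forest plot: 5628 stems in census 0 (431 mature palms, 71 immature)

c0  <- sim$census[sim$census$census == 0, ]
sap <- c0[c0$dbh >= 1 & c0$dbh <= 2 &
            !(c0$species %in% c(sim$palm_species, "MYRI")), ]
saplings <- point_pattern(sap$x, sap$y, sim$window, marks = sap$species)

oring_envelope(sim$mature_palms, saplings, radii = 1:10, dr = 1,
               null = null_model("heterogeneous", 30),
               nsim = 199, rank = 5, seed = 43)
#> Bivariate O-ring estimate: 10 radii (1-10 m, dr = 1 m)
#>   lambda2 = 0.078944 points / m^2
#> Null model: heterogeneous Poisson (local displacement, 30 m)
#>   199 simulations, rank-5 envelopes
#>   flagged radii:
#>     r = 1 m: repulsion
#>     r = 2 m: repulsion
#>     r = 3 m: repulsion
```

Sapling density around mature palms is significantly below the
displacement-null envelope at 1–3 m — exactly the 3-m thinning the generator
planted — and consistent with the null beyond it. The community contrast
tells the same story at the quadrat scale (fewer stems and species per palm
quadrat, but near-identical rarefied richness, i.e. the richness deficit is a
density effect):

```r
grid <- quadrat_grid(sim$window, 5)
cm   <- community_matrix(saplings, grid, label_quadrats(grid, sim$mature_palms))
quadrat_summaries(cm)[, c("label", "n_quadrats", "density_mean",
                          "richness_mean", "rarefied_mean")]
#>     label n_quadrats density_mean richness_mean rarefied_mean
#> 1    palm       1670     1.657485      1.449701      1.864921
#> 2 nonpalm        830     2.609639      2.166265      1.867779

plots <- simulate_seedling_plots(cfg, sim$mature_palms, seed = 44)
seedling_survival_analysis(plots, sim$mature_palms, sim$immature_palms)
#> Binomial GLM (logit link): cbind(survivors, deaths) ~ nearA * nearB
#>       cell     or     se  p_value    n
#>    far-far 1.0000 0.0000       NA 2277
#>   near-far 0.4867 0.0234 1.18e-50 7948
#>   far-near 1.0480 0.0903 5.85e-01  710
#>  near-near 0.5312 0.0364 2.48e-20 1468
```

The fitted odds ratio of seedling survival near mature palms (0.49) recovers
the planted 0.5; proximity to immature palms alone has no effect, matching
the generator. A thin CLI wrapping these functions is installed at
`inst/cli/palmdisturb`
(`palmdisturb simulate|oring|isar|community|demog --config <yaml> --seed <int> --out <dir>`).

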