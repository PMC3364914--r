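#' Annual diameter growth rate and negative-growth flag
#'
#' Growth is the dbh increment divided by the census interval,
#' `(dbh1 - dbh0) / (time1 - time0)` in cm per year. For the demographic
#' models growth is dichotomised into negative (1) versus zero-or-positive
#' (0); a rate of exactly zero counts as non-negative.
#'
#' @param dbh0,dbh1 Diameters at the two censuses (cm).
#' @param time0,time1 Census dates (decimal years); `time1 > time0`.
#' @return Data frame with columns `rate` (cm/yr) and `negative` (0/1).
#' @examples
#' growth_rate(1.5, 1.4, 2000, 2005)   # -0.02 cm/yr, negative
#' @export
growth_rate <- function(dbh0, dbh1, time0, time1) {
  if (any(time1 <= time0))
    stop("time1 must be strictly greater than time0")
  rate <- (dbh1 - dbh0) / (time1 - time0)
  data.frame(rate = rate, negative = as.integer(rate < 0))
}

#' Build a near/far demography design for saplings
#'
#' Restricts a two-census stem table to the saplings alive in the first
#' census (1-2 cm dbh, palm species excluded), attaches the binary responses
#' (survival to the second census, negative growth among survivors,
#' resprouting), and codes proximity (within 10 m) to two focal tree classes
#' A and B computed with [nearest_focal_distance()].
#'
#' @param census Census data frame covering censuses 0 and 1 (same tags).
#' @param focalsA,focalsB Non-empty focal `point_pattern`s (e.g. mature and
#'   immature palms, or female and male trees of a dioecious family).
#' @param palm_species Species codes to exclude from the sapling community.
#' @param near_radius Near/far threshold in metres (default 10; the boundary
#'   counts as near).
#' @param dbh_range Sapling dbh limits at census 0 (default `c(1, 2)`).
#' @return Data frame of class `demog_design` with one row per sapling:
#'   `tag`, `nearA`, `nearB`, `survival`, `negative_growth` (NA for
#'   non-survivors), `resprout`.
#' @export
sapling_design <- function(census, focalsA, focalsB, palm_species = character(),
                           near_radius = 10, dbh_range = c(1, 2)) {
  stopifnot(npoints(focalsA) > 0, npoints(focalsB) > 0)
  c0 <- census[census$census == 0 & census$status == "alive", , drop = FALSE]
  c1 <- census[census$census == 1, , drop = FALSE]
  sap <- c0[c0$dbh >= dbh_range[1] & c0$dbh <= dbh_range[2] &
              !(c0$species %in% palm_species), , drop = FALSE]
  i1 <- match(sap$tag, c1$tag)
  survival <- as.integer(!is.na(i1) & c1$status[i1] == "alive")
  neg <- rep(NA_integer_, nrow(sap))
  ok <- survival == 1 & !is.na(i1) & !is.na(c1$dbh[i1])
  if (any(ok)) {
    g <- growth_rate(sap$dbh[ok], c1$dbh[i1[ok]], sap$date[ok],
                     c1$date[i1[ok]])
    neg[ok] <- g$negative
  }
  resprout <- as.integer(!is.na(i1) & c1$resprout[i1])
  out <- data.frame(tag = sap$tag,
                    nearA = nearest_focal_distance(sap$x, sap$y, focalsA) <= near_radius,
                    nearB = nearest_focal_distance(sap$x, sap$y, focalsB) <= near_radius,
                    survival = survival, negative_growth = neg,
                    resprout = resprout, stringsAsFactors = FALSE)
  class(out) <- c("demog_design", "data.frame")
  out
}

#' Build a near/far design for seedling plots
#'
#' Codes each 1 m^2 seedling plot as near/far relative to two focal classes
#' and carries the binomial response (one-year survivors `k` of recruits `n`,
#' pooled over cohorts by default). Plots with zero recruits are retained in
#' the design; with a binomial weight of zero they contribute nothing to the
#' likelihood.
#'
#' @param plots Seedling-plot data frame (`plot_id`, `x`, `y`, `cohort`,
#'   `recruits`, `survivors`).
#' @param focalsA,focalsB Non-empty focal `point_pattern`s.
#' @param near_radius Near/far threshold in metres (default 10).
#' @param pool_cohorts Sum recruits/survivors over cohorts per plot (default
#'   `TRUE`); otherwise one row per plot-cohort with a `cohort` column.
#' @return Data frame of class `demog_design` with columns `plot_id`,
#'   `nearA`, `nearB`, `k` (survivors), `n` (recruits).
#' @export
seedling_design <- function(plots, focalsA, focalsB, near_radius = 10,
                            pool_cohorts = TRUE) {
  stopifnot(npoints(focalsA) > 0, npoints(focalsB) > 0,
            all(c("plot_id", "x", "y", "recruits", "survivors") %in% names(plots)))
  if (any(plots$survivors > plots$recruits))
    stop("survivors cannot exceed recruits")
  if (pool_cohorts) {
    agg <- aggregate(cbind(recruits, survivors) ~ plot_id + x + y,
                     data = plots, FUN = sum)
  } else agg <- plots
  out <- data.frame(plot_id = agg$plot_id,
                    nearA = nearest_focal_distance(agg$x, agg$y, focalsA) <= near_radius,
                    nearB = nearest_focal_distance(agg$x, agg$y, focalsB) <= near_radius,
                    k = agg$survivors, n = agg$recruits,
                    stringsAsFactors = FALSE)
  if (!pool_cohorts) out$cohort <- agg$cohort
  class(out) <- c("demog_design", "data.frame")
  out
}

# response matrix (successes, failures) from a design and response name
design_response <- function(design, response) {
  if (!is.null(design$k)) {
    cbind(design$k, design$n - design$k)
  } else {
    y <- design[[response]]
    keep <- !is.na(y)
    cbind(y, 1 - y)[keep, , drop = FALSE]
  }
}

#' Fit the near/far binomial GLM and derive odds ratios
#'
#' Fits `response ~ nearA * nearB` with binomial errors and logit link
#' (iteratively reweighted least squares via [stats::glm()], relative
#' deviance tolerance 1e-12) under treatment coding, so the intercept is the
#' far-far
#' baseline. Per-cell odds ratios against far-far are exponentials of
#' coefficient linear combinations -- `nearA`, `nearB`, and
#' `nearA + nearB + nearA:nearB` for the near-near cell -- with delta-method
#' standard errors from the coefficient covariance and two-sided Wald tests.
#'
#' The model is saturated on the 2 x 2 design, so complete separation occurs
#' exactly when some non-empty cell has an all-0 or all-1 response; this is
#' reported as an error naming the cell. An empty cell leaves its contrast
#' inestimable (`NA` row) while the rest of the fit proceeds.
#'
#' @param design A `demog_design` (from [sapling_design()] or
#'   [seedling_design()]).
#' @param response For sapling designs, which response to model:
#'   `"survival"`, `"negative_growth"` or `"resprout"`. Ignored for binomial
#'   (k of n) seedling designs.
#' @return Object of class `focal_glm`: the underlying `glm` fit plus an
#'   odds-ratio table (`cell`, `or`, `se`, `log_or`, `log_or_se`, `p_value`,
#'   `n`).
#' @examples
#' d <- data.frame(nearA = rep(c(TRUE, FALSE), c(100, 100)),
#'                 nearB = FALSE,
#'                 survival = c(rep(1:0, c(80, 20)), rep(1:0, c(90, 10))))
#' class(d) <- c("demog_design", "data.frame")
#' fit <- fit_binomial_glm(d, "survival")
#' odds_ratios(fit)   # near-far OR = (80*10)/(20*90)
#' @export
fit_binomial_glm <- function(design, response = "survival") {
  stopifnot(inherits(design, "data.frame"))
  binomial_pair <- !is.null(design$k)
  dat <- data.frame(nearA = design$nearA, nearB = design$nearB)
  if (binomial_pair) {
    dat$k <- design$k; dat$n <- design$n
    dat <- dat[dat$n >= 0, , drop = FALSE]
    cellmean <- function(i) if (sum(dat$n[i]) > 0) sum(dat$k[i]) / sum(dat$n[i]) else NA
    has_data <- function(i) sum(dat$n[i]) > 0
  } else {
    dat$y <- design[[response]]
    dat <- dat[!is.na(dat$y), , drop = FALSE]
    cellmean <- function(i) if (any(i)) mean(dat$y[i]) else NA
    has_data <- function(i) any(i)
  }
  cells <- list("far-far" = !dat$nearA & !dat$nearB,
                "near-far" = dat$nearA & !dat$nearB,
                "far-near" = !dat$nearA & dat$nearB,
                "near-near" = dat$nearA & dat$nearB)
  if (!has_data(cells[["far-far"]]))
    stop("no observations in the far-far baseline cell")
  pbar <- vapply(cells, cellmean, numeric(1))
  degenerate <- names(cells)[!is.na(pbar) & (pbar == 0 | pbar == 1)]
  if (length(degenerate))
    stop("complete separation: all responses identical in cell(s) ",
         paste(degenerate, collapse = ", "))
  fit <- if (binomial_pair)
    glm(cbind(k, n - k) ~ nearA * nearB, family = binomial(), data = dat,
        control = list(epsilon = 1e-12, maxit = 100))
  else
    glm(y ~ nearA * nearB, family = binomial(), data = dat,
        control = list(epsilon = 1e-12, maxit = 100))
  beta <- coef(fit)
  estimable <- !is.na(beta)
  V <- vcov(fit, complete = TRUE)[estimable, estimable, drop = FALSE]
  combos <- list("near-far" = c(0, 1, 0, 0),
                 "far-near" = c(0, 0, 1, 0),
                 "near-near" = c(0, 1, 1, 1))
  ns <- vapply(cells, function(i)
    if (binomial_pair) sum(dat$n[i]) else sum(i), numeric(1))
  rows <- lapply(names(combos), function(nm) {
    L <- combos[[nm]]
    if (any(L != 0 & !estimable)) {
      return(data.frame(cell = nm, or = NA_real_, se = NA_real_,
                        log_or = NA_real_, log_or_se = NA_real_,
                        p_value = NA_real_, n = ns[[nm]]))
    }
    Lk <- L[estimable]
    est <- sum(Lk * beta[estimable])
    v <- as.numeric(t(Lk) %*% V %*% Lk)
    se_log <- sqrt(v)
    or <- exp(est)
    data.frame(cell = nm, or = or, se = or * se_log, log_or = est,
               log_or_se = se_log,
               p_value = 2 * pnorm(-abs(est / se_log)), n = ns[[nm]])
  })
  or_table <- rbind(
    data.frame(cell = "far-far", or = 1, se = 0, log_or = 0, log_or_se = 0,
               p_value = NA_real_, n = ns[["far-far"]]),
    do.call(rbind, rows))
  row.names(or_table) <- NULL
  structure(list(fit = fit, odds_ratios = or_table, response = response,
                 binomial_pair = binomial_pair),
            class = "focal_glm")
}

#' Seedling one-year survival analysis
#'
#' Convenience wrapper: builds the seedling-plot design relative to two focal
#' classes and fits the near/far binomial GLM on survivors-of-recruits.
#'
#' @inheritParams seedling_design
#' @return A `focal_glm`.
#' @export
seedling_survival_analysis <- function(plots, focalsA, focalsB,
                                       near_radius = 10) {
  design <- seedling_design(plots, focalsA, focalsB, near_radius = near_radius)
  fit_binomial_glm(design)
}

#' Odds ratios against the far-far baseline
#'
#' @param object A `focal_glm`.
#' @return The odds-ratio table (one row per proximity cell).
#' @export
odds_ratios <- function(object) {
  stopifnot(inherits(object, "focal_glm"))
  object$odds_ratios
}

#' @export
coef.focal_glm <- function(object, ...) coef(object$fit)

#' @export
vcov.focal_glm <- function(object, ...) vcov(object$fit)

#' @export
print.focal_glm <- function(x, ...) {
  cat(sprintf("Binomial GLM (logit link): %s ~ nearA * nearB\n",
              if (x$binomial_pair) "cbind(survivors, deaths)" else x$response))
  tab <- x$odds_ratios
  tab$or <- signif(tab$or, 4); tab$se <- signif(tab$se, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab[, c("cell", "or", "se", "p_value", "n")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.focal_glm <- function(object, ...) summary(object$fit, ...)

#' @export
plot.focal_glm <- function(x, main = "Odds ratios vs far-far baseline", ...) {
  tab <- x$odds_ratios
  idx <- seq_len(nrow(tab))
  plot(tab$or, idx, xlim = range(c(tab$or - tab$se, tab$or + tab$se, 1),
                                 na.rm = TRUE),
       yaxt = "n", xlab = "odds ratio", ylab = "", pch = 16, main = main, ...)
  graphics::axis(2, at = idx, labels = tab$cell, las = 1)
  graphics::segments(tab$or - tab$se, idx, tab$or + tab$se, idx)
  abline(v = 1, lty = 2)
  invisible(x)
}
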