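# Empirical-Bayes site harmonization: site-effect removal, covariate
# preservation, invariances, and agreement with an independent reference
# implementation.

sim_sites <- function(n = 60, e = 100, offset = 2, seed = 1,
                      slope = 0, b = NULL, sd = 1) {
  set.seed(seed)
  site <- rep(c("a", "b"), each = n / 2)
  if (is.null(b)) b <- rnorm(n)
  y <- matrix(rnorm(n * e, sd = sd), n, e)
  y[site == "b", ] <- y[site == "b", ] + offset
  if (slope != 0) y <- y + slope * b %o% rep(1, e)
  list(y = y, site = site, b = b)
}

test_that("single site passes through unchanged", {
  set.seed(2)
  y <- matrix(rnorm(40 * 30), 40, 30)
  out <- combat_fit_transform(y, rep("only", 40))
  expect_lt(max(abs(out$features - y)), 1e-8)
})

test_that("a pure additive site offset is removed", {
  # clean offset, negligible residual noise: removal must be essentially
  # complete per feature
  d <- sim_sites(offset = 2, seed = 3, sd = 0.05)
  gap_after <- function(mode) {
    out <- combat_fit_transform(d$y, d$site, mode = mode)
    colMeans(out$features[d$site == "b", , drop = FALSE]) -
      colMeans(out$features[d$site == "a", , drop = FALSE])
  }
  expect_lt(max(abs(gap_after("parametric"))), 0.05)
  # the nonparametric weighting is less aggressive when the offset
  # dominates the standardized scale; still >90% of the offset is gone
  expect_lt(max(abs(gap_after("nonparametric"))), 0.2)
  # at realistic noise the offset is still removed down to sampling scale
  d2 <- sim_sites(offset = 2, seed = 30, sd = 1)
  out2 <- combat_fit_transform(d2$y, d2$site)$features
  gap2 <- colMeans(out2[d2$site == "b", ]) - colMeans(out2[d2$site == "a", ])
  expect_lt(mean(abs(gap2)), 0.2)
})

test_that("multiplicative site effects are equalized", {
  set.seed(4)
  n <- 80; e <- 120
  site <- rep(c("a", "b"), each = n / 2)
  y <- matrix(rnorm(n * e), n, e)
  y[site == "b", ] <- y[site == "b", ] * 3
  out <- combat_fit_transform(y, site)
  sd_a <- apply(out$features[site == "a", ], 2, sd)
  sd_b <- apply(out$features[site == "b", ], 2, sd)
  expect_lt(median(abs(log(sd_b / sd_a))), 0.2)
  expect_gt(median(abs(log(apply(y[site == "b", ], 2, sd) /
                            apply(y[site == "a", ], 2, sd)))), 0.9)
})

test_that("a planted covariate slope survives harmonization", {
  d <- sim_sites(n = 120, e = 200, offset = 1.5, seed = 5, slope = 0.5)
  out <- combat_fit_transform(d$y, d$site, covariates = data.frame(b = d$b))
  slopes <- apply(out$features, 2, function(col) oracle_ols(d$b, col)["slope"])
  expect_lt(abs(mean(slopes) - 0.5), 0.05)
  # and the site offset (1.5 before) is reduced to sampling scale
  gap <- colMeans(out$features[d$site == "b", ]) -
    colMeans(out$features[d$site == "a", ])
  expect_lt(mean(abs(gap)), 0.15)
})

test_that("parametric and nonparametric modes agree under their priors", {
  # site effects truly Gaussian (location) / inverse-gamma (scale)
  set.seed(6)
  n <- 60; e <- 150
  site <- rep(c("a", "b"), each = n / 2)
  gam <- rbind(rnorm(e, -0.4, 0.1), rnorm(e, 0.4, 0.1))
  del <- rbind(sqrt(1 / rgamma(e, 40, 40)), sqrt(1 / rgamma(e, 40, 60)))
  y <- matrix(rnorm(n * e), n, e)
  for (s in 1:2) {
    rows <- site == c("a", "b")[s]
    y[rows, ] <- y[rows, ] * rep(del[s, ], each = sum(rows)) +
      rep(gam[s, ], each = sum(rows))
  }
  par_ <- combat_fit_transform(y, site, mode = "parametric")$features
  non_ <- combat_fit_transform(y, site, mode = "nonparametric")$features
  expect_lt(mean(abs(par_ - non_)), 0.05)
  expect_lt(max(abs(par_ - non_)), 0.5)
})

test_that("harmonization is invariant to subject order", {
  d <- sim_sites(seed = 7)
  out <- combat_fit_transform(d$y, d$site)$features
  perm <- sample(nrow(d$y))
  out_p <- combat_fit_transform(d$y[perm, ], d$site[perm])$features
  expect_lt(max(abs(out_p - out[perm, ])), 1e-8)
})

test_that("harmonizing twice is approximately idempotent", {
  d <- sim_sites(offset = 2, seed = 8)
  once <- combat_fit_transform(d$y, d$site)$features
  twice <- combat_fit_transform(once, d$site)$features
  # site effects are gone after one pass; a second pass only re-shrinks
  # within sampling noise (unit feature SD here)
  expect_lt(mean(abs(twice - once)), 0.05)
  expect_lt(max(abs(twice - once)), 0.25)
})

test_that("degenerate inputs raise informative errors", {
  d <- sim_sites(seed = 9)
  expect_error(combat_fit_transform(d$y, c("solo", d$site[-1])),
               "single subject")
  expect_warning(
    out <- combat_fit_transform(d$y, c("solo", d$site[-1]),
                                allow_singleton_sites = TRUE),
    "passing through")
  expect_identical(out$features[1, ], d$y[1, ])
  # collinear covariate (constant => collinear with site dummies)
  expect_error(combat_fit_transform(d$y, d$site,
                                    covariates = data.frame(c1 = rep(1, 60))),
               "rank deficient")
})

test_that("both modes match the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  set.seed(10)
  n <- 40; e <- 60
  site <- rep(c("a", "b"), c(18, 22))
  b <- rnorm(n)
  y <- matrix(rnorm(n * e), n, e) + 1.2 * (site == "b") + 0.4 * b
  mod <- stats::model.matrix(~ b)
  for (mode in c("parametric", "nonparametric")) {
    mine <- combat_fit_transform(y, site, covariates = data.frame(b = b),
                                 mode = mode)$features
    ref <- t(suppressMessages(sva::ComBat(t(y), batch = factor(site),
                                          mod = mod,
                                          par.prior = mode == "parametric")))
    expect_lt(max(abs(mine - ref)), 1e-6)
  }
})

test_that("generated site effects show up in ANOVA and are removed", {
  spec <- generator_spec(n_model = 120, n_validation = 10, n_control = 10,
                         n_nodes = 30)
  ds <- generate(spec, 2)
  rows <- ds$pheno$sample == "model"
  site <- factor(ds$pheno$site[rows])
  set.seed(2)
  probe <- sample.int(ncol(ds$edges), 100)
  site_f <- function(mat) {
    vapply(probe, function(e) {
      anova(lm(mat[, e] ~ site))[["F value"]][1]
    }, numeric(1))
  }
  f_before <- site_f(ds$edges[rows, ])
  harm <- combat_fit_transform(
    ds$edges[rows, ], site,
    covariates = ds$pheno[rows, c("age", "sex", "fiq", "mfd")])$features
  f_after <- site_f(harm)
  # before: median F significantly above 1; after: not above 1
  expect_lt(wilcox.test(f_before, mu = 1, alternative = "greater")$p.value,
            0.01)
  expect_gt(wilcox.test(f_after, mu = 1, alternative = "greater")$p.value,
            0.5)
  expect_lt(median(f_after), median(f_before))
})

test_that("combat_apply reproduces the fit-time transform and rejects mismatches", {
  d <- sim_sites(n = 50, e = 40, offset = 1.5, seed = 11)
  h <- combat_fit_transform(d$y, d$site, covariates = data.frame(b = d$b))
  reapplied <- combat_apply(h$model, d$y, d$site,
                            covariates = data.frame(b = d$b))
  expect_lt(max(abs(reapplied - h$features)), 1e-10)
  expect_error(combat_apply(h$model, d$y[1:2, ], c("a", "zz"),
                            covariates = data.frame(b = d$b[1:2])),
               "not seen at fit time")
  expect_error(combat_apply(h$model, d$y[1:2, ], c("a", "a")),
               "supply them")
})
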