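# Synthetic generator: determinism, planted-effect calibration, null
# behaviour, time-series round trip.

test_that("same spec and seed reproduce bit-identical datasets", {
  spec <- generator_spec(n_model = 30, n_validation = 15, n_control = 10,
                         n_nodes = 12, n_true_neg = 5)
  a <- generate(spec, 99)
  b <- generate(spec, 99)
  expect_identical(a$edges, b$edges)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth$true_edges, b$truth$true_edges)
  c <- generate(spec, 100)
  expect_false(identical(a$edges, c$edges))
})

test_that("generated datasets have the requested samples, ids, sites", {
  ds <- generate(generator_spec(n_model = 25, n_validation = 12,
                                n_control = 10, n_nodes = 10,
                                n_true_neg = 4), 5)
  expect_identical(rownames(ds$edges), ds$pheno$subject_id)
  expect_equal(as.vector(table(ds$pheno$sample)[c("model", "validation",
                                                  "control")]),
               c(25, 12, 10))
  expect_true(all(ds$pheno$group[ds$pheno$sample == "control"] == "control"))
  expect_true(all(ds$pheno$subtype[ds$pheno$group == "control"] == "HC"))
  expect_true(all(startsWith(ds$pheno$site[ds$pheno$sample == "model"], "I_")))
  expect_equal(ncol(ds$edges), n_edges(10))
})

test_that("planted edges must lie inside the matrix", {
  expect_error(generator_spec(n_nodes = 10,
                              true_edges = data.frame(i = 3, j = 11,
                                                      sign = -1)),
               "1 <= i < j")
  expect_error(generator_spec(n_nodes = 10,
                              true_edges = data.frame(i = 5, j = 3,
                                                      sign = -1)),
               "1 <= i < j")
})

test_that("under the null (beta = 0) selection hits its nominal rate", {
  spec <- generator_spec(n_model = 150, n_validation = 10, n_control = 10,
                         n_nodes = 160, n_true_neg = 0, beta = 0)
  ds <- generate(spec, 17)
  rows <- ds$pheno$sample == "model"
  sel <- select_edges(ds$edges[rows, ], ds$pheno$score_total[rows],
                      cpm_covariates(ds$pheno[rows, ]), p_threshold = 0.01)
  frac <- (length(sel$pos) + length(sel$neg)) / n_edges(160)
  # binomial sampling band around 0.01 at E = 12720 (~4.5 SD)
  expect_gt(frac, 0.006)
  expect_lt(frac, 0.014)
})

test_that("planted negative edges are recovered by selection with power", {
  hits <- vapply(1:20, function(s) {
    ds <- generate(generator_spec(n_model = 150, n_validation = 10,
                                  n_control = 10, n_nodes = 40,
                                  n_true_neg = 40, beta = 1.5,
                                  noise_sd = 1), 300 + s)
    rows <- ds$pheno$sample == "model"
    sel <- select_edges(ds$edges[rows, ], ds$pheno$score_total[rows],
                        cpm_covariates(ds$pheno[rows, ]), 0.01)
    mean(ds$truth$true_positions %in% sel$neg)
  }, numeric(1))
  expect_gte(mean(hits), 0.90)
})

test_that("controls have healthy-range scores and no edge coupling", {
  ds <- generate(generator_spec(n_model = 80, n_validation = 10,
                                n_control = 60, n_nodes = 20,
                                n_true_neg = 8, beta = 2), 23)
  ctrl <- ds$pheno$sample == "control"
  expect_lt(mean(ds$pheno$score_total[ctrl]), 4)
  # planted edges should not correlate with control scores
  r <- cor(ds$edges[ctrl, ds$truth$true_positions],
           ds$pheno$score_total[ctrl])
  expect_lt(max(abs(r)), 0.5)
  expect_lt(abs(mean(r)), 0.15)
})

test_that("time series reproduce their target connectome", {
  set.seed(31)
  z <- devectorize(rep(0, n_edges(8)), 8)
  z[1, 2] <- z[2, 1] <- atanh(0.6)
  ts <- timeseries_from_connectome(z, 5000)
  emp <- compute_connectome(ts)
  expect_lt(abs(emp[1, 2] - atanh(0.6)), 0.05)

  # identity target: all off-diagonal z small, mean near zero
  ts0 <- timeseries_from_connectome(devectorize(rep(0, n_edges(8)), 8), 5000)
  v <- vectorize(compute_connectome(ts0))
  expect_lt(max(abs(v)), 0.1)
  expect_lt(abs(mean(v)), 0.02)
})

test_that("generate_timeseries is deterministic and recovers edges", {
  spec <- generator_spec(n_model = 12, n_validation = 10, n_control = 10,
                         n_nodes = 6, n_true_neg = 2, beta = 0.3,
                         noise_sd = 0.1,
                         edge_mu_mean = 0.2, edge_mu_sd = 0.05,
                         site_gamma_sd = 0, site_gamma_tau = 0,
                         site_delta_log_sd = 0)
  a <- generate_timeseries(spec, 400, seed = 8, subjects = c("S0001", "S0002"))
  b <- generate_timeseries(spec, 400, seed = 8, subjects = c("S0001", "S0002"))
  expect_identical(a, b)
  expect_equal(dim(a$S0001), c(400, 6))

  ds <- generate(spec, 8)
  long <- generate_timeseries(spec, 8000, seed = 8, subjects = "S0001")
  emp <- vectorize(compute_connectome(long$S0001))
  target <- ds$edges["S0001", ]
  expect_lt(max(abs(emp - target)), 0.12)
})
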