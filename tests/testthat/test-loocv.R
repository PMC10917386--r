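# Leave-one-out CPM and permutation inference.

test_that("every subject is predicted from a fold excluding exactly them", {
  d <- planted_dataset(seed = 51, n_model = 30, n_nodes = 12, n_true_neg = 4)
  cov <- cpm_covariates(d$model$pheno)
  fit <- loocv_cpm(d$model$edges, d$model$pheno$score_total, cov)
  expect_length(fit$folds, 30)
  expect_length(fit$predictions$neg, 30)
  expect_false(anyNA(fit$predictions$neg))
  for (s in c(1, 13, 30)) {
    expect_identical(fit$folds[[s]]$train, setdiff(1:30, s))
  }
})

test_that("fold masks are reproducible from training subjects alone", {
  d <- planted_dataset(seed = 52, n_model = 25, n_nodes = 10, n_true_neg = 3)
  cov <- cpm_covariates(d$model$pheno)
  b <- d$model$pheno$score_total
  fit <- loocv_cpm(d$model$edges, b, cov, p_threshold = 0.05)
  for (s in c(2, 11, 25)) {
    tr <- fit$folds[[s]]$train
    sel <- select_edges(d$model$edges[tr, ], b[tr], cov[tr, ], 0.05)
    expect_identical(fit$folds[[s]]$pos, sel$pos)
    expect_identical(fit$folds[[s]]$neg, sel$neg)
  }
})

test_that("consensus is the intersection of all fold masks", {
  d <- planted_dataset(seed = 53, n_model = 24, n_nodes = 12, n_true_neg = 4)
  cov <- cpm_covariates(d$model$pheno)
  fit <- loocv_cpm(d$model$edges, d$model$pheno$score_total, cov, 0.05)
  for (tail in c("pos", "neg")) {
    inter <- Reduce(intersect, lapply(fit$folds, `[[`, tail))
    expect_identical(fit$consensus[[tail]], as.integer(sort(inter)))
    for (f in fit$folds) {
      expect_true(all(fit$consensus[[tail]] %in% f[[tail]]))
    }
  }
})

test_that("near-noiseless planted data are predicted almost perfectly", {
  d <- planted_dataset(seed = 54, n_model = 40, n_nodes = 20,
                       n_true_neg = 8, noise_sd = 0.05)
  cov <- cpm_covariates(d$model$pheno)
  fit <- loocv_cpm(d$model$edges, d$model$pheno$score_total, cov)
  expect_gt(fit$r$neg, 0.9)
  expect_setequal(fit$consensus$neg, d$truth$true_positions)
})

test_that("folds with no surviving edges predict the training mean", {
  set.seed(55)
  edges <- matrix(rnorm(20 * 30), 20, 30)
  b <- rnorm(20)
  fit <- loocv_cpm(edges, b, p_threshold = 1e-9)
  expect_equal(fit$empty_folds$neg, 20)
  expect_true(fit$invalid$neg)
  means <- vapply(1:20, function(s) mean(b[-s]), numeric(1))
  expect_equal(fit$predictions$neg, means)
  # training-mean predictions are perfectly anticorrelated with the
  # left-out score (the leave-one-out mean artifact), never positive
  expect_lt(fit$r$neg, 0)
})

test_that("permutation null is seeded, centred, and bounded below", {
  d <- planted_dataset(seed = 56, n_model = 30, n_nodes = 12,
                       n_true_neg = 5, noise_sd = 0.3)
  cov <- cpm_covariates(d$model$pheno)
  b <- d$model$pheno$score_total
  p1 <- permutation_test(d$model$edges, b, cov, tails = "neg",
                         n_perm = 100, seed = 77)
  p2 <- permutation_test(d$model$edges, b, cov, tails = "neg",
                         n_perm = 100, seed = 77)
  expect_identical(p1$neg$null_r, p2$neg$null_r)
  p3 <- permutation_test(d$model$edges, b, cov, tails = "neg",
                         n_perm = 100, seed = 78)
  expect_false(identical(p1$neg$null_r, p3$neg$null_r))
  # strong planted signal attains the add-one minimum
  expect_equal(p1$neg$p_perm, 1 / 101)
  # the null distribution sits well below the observed r; its mean skews
  # negative (training-mean predictions anticorrelate with the left-out
  # score when shuffled selections are empty)
  expect_lt(p1$neg$mean_null_r, 0.2)
  expect_gt(p1$neg$mean_null_r, -1)
  expect_lt(max(p1$neg$null_r), p1$neg$r)
  expect_length(p1$neg$null_r, 100)
})

test_that("permutation detail returns the observed LOOCV result", {
  d <- planted_dataset(seed = 57, n_model = 22, n_nodes = 10, n_true_neg = 3)
  cov <- cpm_covariates(d$model$pheno)
  b <- d$model$pheno$score_total
  pm <- permutation_test(d$model$edges, b, cov, n_perm = 100, seed = 5,
                         detail = TRUE)
  fit <- loocv_cpm(d$model$edges, b, cov)
  expect_identical(pm$observed$consensus, fit$consensus)
  expect_identical(pm$observed$predictions, fit$predictions)
  expect_equal(pm$observed$r, fit$r)
  expect_equal(pm$neg$r, fit$r$neg)
})

test_that("consensus masks render as valid masks", {
  d <- planted_dataset(seed = 58, n_model = 25, n_nodes = 10, n_true_neg = 4)
  cov <- cpm_covariates(d$model$pheno)
  fit <- loocv_cpm(d$model$edges, d$model$pheno$score_total, cov)
  m <- consensus_mask(fit, 10)
  expect_identical(m, t(m))
  expect_true(all(m %in% c(-1L, 0L, 1L)))
  idx <- edge_index(10)
  expect_identical(which(m[idx] == -1L), fit$consensus$neg)
  expect_identical(which(m[idx] == 1L), fit$consensus$pos)
})

test_that("fold-wise harmonization LOOCV stays leakage-free and predictive", {
  d <- planted_dataset(seed = 59, n_model = 40, n_nodes = 14,
                       n_true_neg = 5, n_sites_model = 2)
  ph <- d$model$pheno
  cov <- cpm_covariates(ph)
  strict <- loocv_cpm_strict(d$model$edges, ph$score_total, ph$site,
                             covariates = cov,
                             combat_covariates = data.frame(
                               age = ph$age, mfd = ph$mfd),
                             tails = "neg")
  expect_length(strict$predictions$neg, 40)
  expect_gt(strict$r$neg, 0.5)
  expect_gt(mean(d$truth$true_positions %in% strict$consensus$neg), 0.7)
  # fold masks recompute from fold-local harmonized training data
  s <- 5
  tr <- strict$folds[[s]]$train
  h <- combat_fit_transform(d$model$edges[tr, ], ph$site[tr],
                            covariates = data.frame(age = ph$age[tr],
                                                    mfd = ph$mfd[tr]))
  sel <- select_edges(h$features, ph$score_total[tr], cov[tr, ], 0.01)
  expect_identical(strict$folds[[s]]$neg, sel$neg)
})
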