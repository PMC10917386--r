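# Transfer to independent samples and network-anatomy summaries.

test_that("transfer refuses an empty consensus", {
  set.seed(61)
  edges <- matrix(rnorm(20 * 15), 20, 15)
  expect_error(transfer_model(edges, rnorm(20), integer(0)),
               "no consensus edges")
  expect_error(external_validate(list(slope = 1, intercept = 0,
                                      consensus = integer(0)),
                                 edges, rnorm(20)),
               "no consensus edges")
})

test_that("a replication sample from the same model validates", {
  d <- planted_dataset(seed = 62, n_model = 60, n_validation = 50,
                       n_nodes = 20, n_true_neg = 8)
  cov <- cpm_covariates(d$model$pheno)
  fit <- loocv_cpm(d$model$edges, d$model$pheno$score_total, cov,
                   tails = "neg")
  tm <- transfer_model(d$model$edges, d$model$pheno$score_total,
                       fit$consensus$neg)
  vr <- external_validate(tm, d$validation$edges,
                          d$validation$pheno$score_total,
                          cpm_covariates(d$validation$pheno))
  expect_s3_class(vr, "cpm_validation")
  expect_equal(vr$n, 50)
  expect_equal(vr$df, 50 - 2 - 3)
  expect_gt(vr$r, 0)
  expect_lt(vr$p, 0.05)
  # predictions follow the transferred line exactly
  expect_equal(vr$predicted, tm$intercept + tm$slope * vr$strength)
})

test_that("in-sample transfer is at least as good as honest LOOCV", {
  d <- planted_dataset(seed = 63, n_model = 50, n_nodes = 16, n_true_neg = 6)
  cov <- cpm_covariates(d$model$pheno)
  b <- d$model$pheno$score_total
  fit <- loocv_cpm(d$model$edges, b, cov, tails = "neg")
  tm <- transfer_model(d$model$edges, b, fit$consensus$neg)
  insample <- external_validate(tm, d$model$edges, b, cov, "training")
  expect_gte(insample$r, fit$r$neg - 0.02)
})

test_that("a 4-node worked example matches hand computation", {
  atl <- as_atlas(data.frame(node_id = 1:4, label = letters[1:4],
                             network = c("A", "A", "B", "B"),
                             x = 0, y = 0, z = 0))
  mask <- matrix(0L, 4, 4)
  mask[1, 3] <- mask[3, 1] <- -1L
  sm <- summarize_network(mask, atl)
  expect_equal(unname(sm$node_degree), c(1, 0, 1, 0))
  expect_equal(sm$pair_counts["A", "B"], 1L)
  expect_equal(sm$pair_counts["B", "A"], 1L)
  expect_equal(sm$pair_counts["A", "A"], 0L)
  expect_equal(sm$pair_counts["B", "B"], 0L)
  expect_equal(sm$n_edges, 1)
  expect_equal(sm$edge_list$node_i, 1)
  expect_equal(sm$edge_list$node_j, 3)
})

test_that("handshake lemma and pair-count totals hold on random masks", {
  set.seed(64)
  atl <- synthetic_atlas(24, k = 6)
  for (rep in 1:50) {
    mask <- random_mask(24, n_pos = sample(0:10, 1), n_neg = sample(0:10, 1))
    sm <- summarize_network(mask, atl)
    expect_equal(sum(sm$node_degree), 2 * sm$n_edges)
    pc <- sm$pair_counts
    expect_equal(sum(pc[upper.tri(pc)]) + sum(diag(pc)), sm$n_edges)
    expect_identical(pc, t(pc))
  }
})

test_that("pair counts are invariant to network-preserving relabelling", {
  set.seed(65)
  n <- 18
  atl <- synthetic_atlas(n, k = 3)
  mask <- random_mask(n, n_pos = 6, n_neg = 6)
  perm <- sample(n)
  # relabel nodes by perm; permuted atlas keeps each node's network
  atl2 <- as_atlas(data.frame(node_id = 1:n, label = atl$label[perm],
                              network = as.character(atl$network)[perm],
                              x = 0, y = 0, z = 0))
  inv <- integer(n); inv[perm] <- 1:n
  mask2 <- mask[perm, perm]
  sm1 <- summarize_network(mask, atl)
  sm2 <- summarize_network(mask2, atl2)
  expect_identical(sm1$pair_counts, sm2$pair_counts)
  expect_equal(unname(sm2$node_degree), unname(sm1$node_degree[perm]))
})

test_that("rank_nodes sorts by degree with node-id tie-break", {
  atl <- synthetic_atlas(3, k = 2)
  sm <- list(node_degree = c(3, 1, 3))
  class(sm) <- "cpm_network_summary"
  rk <- rank_nodes(sm, atl, top_k = 3)
  expect_equal(rk$node_id, c(1, 3, 2))
  expect_equal(rk$degree, c(3, 3, 1))
  rk_all <- rank_nodes(sm, atl, top_k = 99)
  expect_equal(nrow(rk_all), 3)
})

test_that("top-ranked nodes are endpoints of planted edges", {
  d <- planted_dataset(seed = 66, n_model = 60, n_nodes = 20, n_true_neg = 6)
  cov <- cpm_covariates(d$model$pheno)
  fit <- loocv_cpm(d$model$edges, d$model$pheno$score_total, cov,
                   tails = "neg")
  mask <- consensus_mask(fit, 20)
  sm <- summarize_network(mask, d$ds$atlas)
  rk <- rank_nodes(sm, d$ds$atlas, top_k = 5)
  endpoints <- unique(c(d$truth$true_edges$i, d$truth$true_edges$j))
  expect_true(all(rk$node_id[rk$degree > 0] %in% endpoints))
})

test_that("anatomy tables are written as plot-ready CSVs", {
  atl <- synthetic_atlas(10, k = 2)
  mask <- random_mask(10, 2, 3)
  dir <- withr::local_tempdir()
  write_network_summary(summarize_network(mask, atl), atl, dir)
  deg <- read.csv(file.path(dir, "degrees.csv"))
  expect_equal(nrow(deg), 10)
  pc <- read.csv(file.path(dir, "pair_counts.csv"), check.names = FALSE)
  expect_equal(dim(pc), c(2, 3))
  expect_equal(nrow(read.csv(file.path(dir, "edges.csv"))), 5)
})
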