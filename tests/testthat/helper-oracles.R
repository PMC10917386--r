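# Independent brute-force oracles used to check the package's vectorized
# implementations, plus small fixture builders.  The oracles deliberately
# use the most naive formulation available (explicit loops, lm(), direct
# formulas) and share no code with the implementation under test.

# Pairwise Fisher-z connectome via an explicit two-column Pearson loop.
oracle_connectome <- function(ts) {
  n <- ncol(ts)
  z <- matrix(0, n, n)
  lim <- 1 - 1e-7
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- stats::cor(ts[, i], ts[, j])
      r <- max(min(r, lim), -lim)
      z[i, j] <- z[j, i] <- atanh(r)
    }
  }
  z
}

# Partial correlation through lm() residuals.
oracle_partial_cor <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    r <- stats::cor(x, y)
    k <- 0
  } else {
    d <- as.data.frame(covariates)
    rx <- stats::resid(stats::lm(x ~ ., data = d))
    ry <- stats::resid(stats::lm(y ~ ., data = d))
    r <- stats::cor(rx, ry)
    k <- ncol(d)
  }
  n <- length(x)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE), df = df)
}

# Network strength by an explicit i<j double loop over a mask matrix.
oracle_strength <- function(z, mask, sign = 1) {
  total <- 0
  n <- nrow(mask)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (mask[i, j] == sign) total <- total + z[i, j]
    }
  }
  total
}

# Simple-regression normal equations.
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Benjamini-Hochberg step-up computed literally from its definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  ranked <- p[o] * n / seq_len(n)
  # step-up: q_i = min over j >= i of ranked_j, capped at 1
  run_min <- rev(cummin(rev(ranked)))
  q[o] <- pmin(run_min, 1)
  q
}

# Random symmetric zero-diagonal matrix.
random_connectome <- function(n_nodes) {
  v <- stats::rnorm(cpmconn::n_edges(n_nodes))
  cpmconn::devectorize(v, n_nodes)
}

# Random edge mask with given number of +1/-1 edges.
random_mask <- function(n_nodes, n_pos = 3, n_neg = 3) {
  e <- cpmconn::n_edges(n_nodes)
  pos <- sample.int(e, n_pos + n_neg)
  v <- integer(e)
  v[pos[seq_len(n_pos)]] <- 1L
  if (n_neg > 0) v[pos[n_pos + seq_len(n_neg)]] <- -1L
  m <- cpmconn::devectorize(v, n_nodes)
  storage.mode(m) <- "integer"
  m
}

# Numeric CPM covariate matrix (age, sex dummy, mean FD) for a phenotype
# subset.
cpm_covariates <- function(pheno) {
  cbind(age = pheno$age, sexM = as.numeric(pheno$sex == "M"),
        mfd = pheno$mfd)
}

# Small planted dataset split into its three samples.
planted_dataset <- function(seed, n_model = 60, n_validation = 40,
                            n_control = 20, n_nodes = 30, n_true_neg = 10,
                            ...) {
  spec <- cpmconn::generator_spec(n_model = n_model,
                                  n_validation = n_validation,
                                  n_control = n_control, n_nodes = n_nodes,
                                  n_true_neg = n_true_neg, ...)
  ds <- cpmconn::generate(spec, seed)
  split_sample <- function(sm) {
    rows <- ds$pheno$sample == sm
    list(edges = ds$edges[rows, , drop = FALSE],
         pheno = ds$pheno[rows, , drop = FALSE])
  }
  list(ds = ds, model = split_sample("model"),
       validation = split_sample("validation"),
       control = split_sample("control"),
       truth = ds$truth)
}
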