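# Leave-one-out CPM and permutation inference.
#
# The fold sweep is written so that many behaviour vectors (the observed
# one plus any number of permuted copies) are processed in one pass: per
# fold, the edge features are residualized on the training covariates
# once, and edge-behaviour correlations, edge selection, training
# strengths, tail-model fits, and the left-out prediction are obtained for
# every behaviour column with three BLAS-level matrix products.  This is
# what makes 100s-1000s of permutations of a full LOOCV affordable.

projector_Q <- function(covariates) {
  # Orthonormal basis of [1, z-scored covariates] for a training subset.
  # Columns constant within the subset are collinear with the intercept
  # and are dropped (see residualize()).
  X <- covariates$ones
  if (!is.null(covariates$cm)) {
    cm <- covariates$cm
    sds <- apply(cm, 2, stats::sd)
    cm <- cm[, sds > 0, drop = FALSE]
    if (ncol(cm)) X <- cbind(X, scale(cm))
  }
  qx <- qr(X)
  qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
}

# Core fold sweep.  edges: n x E; Bmat: n x P behaviour columns (column 1
# is the "observed" analysis whose fold details and consensus are kept).
cpm_fold_sweep <- function(edges, Bmat, covariates = NULL,
                           p_threshold = 0.01,
                           tails = c("pos", "neg"),
                           keep_fold_details = TRUE) {
  edges <- as.matrix(edges)
  dimnames(Bmat) <- NULL
  n <- nrow(edges); E <- ncol(edges); P <- ncol(Bmat)
  if (n < 10) stop("leave-one-out CPM needs at least 10 subjects")
  cm <- NULL
  if (!is.null(covariates)) {
    cm <- as.matrix(as.data.frame(covariates))
    storage.mode(cm) <- "double"
    if (anyNA(cm)) stop("covariates must be complete")
  }
  k <- if (is.null(cm)) 0L else ncol(cm)
  df_tr <- (n - 1L) - 2L - k
  if (df_tr < 1) stop("too few subjects for selection within folds")
  rc <- critical_r(p_threshold, df_tr)

  want <- list(pos = "pos" %in% tails, neg = "neg" %in% tails)
  pred <- list(pos = matrix(NA_real_, n, P), neg = matrix(NA_real_, n, P))
  nsel1 <- list(pos = integer(n), neg = integer(n))
  consensus_count <- list(pos = integer(E), neg = integer(E))
  folds <- if (keep_fold_details) vector("list", n) else NULL
  empty_folds <- list(pos = 0L, neg = 0L)

  for (s in seq_len(n)) {
    tr <- setdiff(seq_len(n), s)
    ntr <- n - 1L
    Etr <- edges[tr, , drop = FALSE]
    Btr <- Bmat[tr, , drop = FALSE]
    Q <- projector_Q(list(ones = matrix(1, ntr, 1),
                          cm = if (is.null(cm)) NULL else
                            cm[tr, , drop = FALSE]))
    RE <- Etr - Q %*% crossprod(Q, Etr)
    RB <- Btr - Q %*% crossprod(Q, Btr)
    se <- sqrt(colSums(RE^2))
    sb <- sqrt(colSums(RB^2))
    if (any(sb == 0)) stop("behaviour has zero residual variance within a fold")
    RBu <- RB / matrix(sb, ntr, P, byrow = TRUE)
    num <- crossprod(RE, RBu)           # E x P partial-correlation numerators
    thr <- rc * se                      # |r| > rc  <=>  |num| > rc * se * 1
    my <- colMeans(Btr)

    fold_rec <- if (keep_fold_details)
      list(train = tr, pos = integer(0), neg = integer(0),
           models = list()) else NULL
    for (tail in c("pos", "neg")) {
      if (!want[[tail]]) next
      M <- if (tail == "pos") num > thr else num < -thr
      mode(M) <- "double"
      nsel <- colSums(M)
      Sp <- Etr %*% M                    # training strengths, ntr x P
      ste <- as.vector(edges[s, , drop = FALSE] %*% M)
      mx <- colSums(Sp) / ntr
      sxy <- colSums(Sp * Btr) - ntr * mx * my
      sxx <- colSums(Sp^2) - ntr * mx^2
      deg <- nsel == 0 | sxx <= 1e-12 * pmax(1, mx^2) * ntr
      slope <- ifelse(deg, 0, sxy / pmax(sxx, .Machine$double.eps))
      pr <- my + slope * (ste - mx)
      pr[deg] <- my[deg]
      pred[[tail]][s, ] <- pr
      nsel1[[tail]][s] <- nsel[1]
      sel1 <- which(M[, 1] > 0)
      consensus_count[[tail]][sel1] <- consensus_count[[tail]][sel1] + 1L
      if (nsel[1] == 0) empty_folds[[tail]] <- empty_folds[[tail]] + 1L
      if (keep_fold_details) {
        fold_rec[[tail]] <- sel1
        fold_rec$models[[tail]] <- list(
          slope = slope[1], intercept = my[1] - slope[1] * mx[1],
          degenerate = deg[1])
      }
    }
    if (keep_fold_details) folds[[s]] <- fold_rec
  }

  consensus <- list(
    pos = if (want$pos) which(consensus_count$pos == n) else integer(0),
    neg = if (want$neg) which(consensus_count$neg == n) else integer(0))

  # pooled evaluation: partial correlation of LOOCV predictions with the
  # behaviour column they predict, controlling for the full-sample covariates
  RBf <- residualize(Bmat, cm)
  sbf <- sqrt(colSums(RBf^2))
  eval_r <- list(pos = NULL, neg = NULL)
  n_degenerate_eval <- list(pos = 0L, neg = 0L)
  for (tail in c("pos", "neg")) {
    if (!want[[tail]]) next
    RP <- residualize(pred[[tail]], cm)
    sp <- sqrt(colSums(RP^2))
    r <- colSums(RP * RBf) / (sp * sbf)
    bad <- !is.finite(r)
    n_degenerate_eval[[tail]] <- sum(bad)
    r[bad] <- 0
    eval_r[[tail]] <- r
  }

  list(pred = pred, eval_r = eval_r, consensus = consensus,
       consensus_count = consensus_count, folds = folds,
       nsel_observed = nsel1, empty_folds = empty_folds,
       n_degenerate_eval = n_degenerate_eval,
       df_eval = n - 2L - k, df_selection = df_tr, rc = rc, k = k)
}

#' Leave-one-out cross-validated CPM
#'
#' For each left-out subject, edges are selected (partial correlation with
#' the behaviour across the remaining `n - 1` subjects, controlling for
#' covariates, two-sided `p < p_threshold`), positive/negative network
#' strengths are computed, single-predictor linear models are fit on the
#' training subjects, and the left-out subject's behaviour is predicted.
#' Consensus networks are the edges selected in every fold.  Model
#' performance is the partial correlation (same covariates) between the
#' pooled LOOCV predictions and the observed behaviour.
#'
#' Folds in which no edge survives selection predict the training mean and
#' are flagged; a result whose folds are all empty for a tail is flagged
#' invalid for that tail.
#'
#' @param edges Numeric `n x E` subjects-by-edges matrix (canonical
#'   order).
#' @param behaviour Numeric vector of length `n`, complete.
#' @param covariates Optional `n x k` matrix/data.frame (e.g. age, sex,
#'   mean FD), z-scored within each fold's training set before
#'   residualization.
#' @param p_threshold Edge-selection threshold (two-sided), default 0.01.
#' @param tails Which tails to model: subset of `c("pos", "neg")`.
#' @return A `cpm_result` with per-subject `predictions` (per tail),
#'   per-tail evaluation `r`, `p_parametric` and `df`, consensus edge
#'   positions (`consensus$pos`, `consensus$neg`), per-fold records
#'   (`folds`: training ids, selected edges, tail models), empty-fold
#'   counts, and the configuration echo.
#' @seealso [permutation_test()] for permutation inference,
#'   [consensus_mask()] to render consensus edges as an N x N mask.
#' @export
loocv_cpm <- function(edges, behaviour, covariates = NULL,
                      p_threshold = 0.01, tails = c("pos", "neg")) {
  tails <- match.arg(tails, c("pos", "neg"), several.ok = TRUE)
  behaviour <- as.numeric(behaviour)
  if (anyNA(behaviour)) stop("behaviour must be complete (drop missing-score subjects first)")
  if (stats::sd(behaviour) == 0) stop("behaviour has zero variance")
  sw <- cpm_fold_sweep(edges, matrix(behaviour, ncol = 1), covariates,
                       p_threshold, tails, keep_fold_details = TRUE)
  assemble_cpm_result(sw, nrow(as.matrix(edges)), tails, p_threshold)
}

# Build a cpm_result from the observed (first) column of a fold sweep.
assemble_cpm_result <- function(sw, n, tails, p_threshold) {
  res <- list(n = n, tails = tails,
              predictions = lapply(sw$pred, function(m) as.vector(m[, 1])),
              r = lapply(sw$eval_r, function(r) if (is.null(r)) NULL else r[1]),
              df = sw$df_eval,
              consensus = sw$consensus,
              consensus_count = sw$consensus_count,
              folds = sw$folds,
              n_selected_per_fold = sw$nsel_observed,
              empty_folds = sw$empty_folds,
              invalid = lapply(sw$empty_folds, function(e) e >= n),
              config = list(p_threshold = p_threshold,
                            k_covariates = sw$k,
                            df_selection = sw$df_selection))
  for (tail in tails) {
    r <- res$r[[tail]]
    tval <- r * sqrt(res$df / max(1 - r^2, .Machine$double.eps))
    res[[paste0("p_parametric_", tail)]] <-
      2 * stats::pt(abs(tval), res$df, lower.tail = FALSE)
  }
  class(res) <- "cpm_result"
  res
}

#' Render consensus edges as an N x N mask
#'
#' @param result A `cpm_result` from [loocv_cpm()].
#' @param n_nodes Number of nodes `N`.
#' @return Symmetric integer matrix over {-1, 0, +1}: +1 for consensus
#'   positive-network edges, -1 for negative.
#' @export
consensus_mask <- function(result, n_nodes) {
  stopifnot(inherits(result, "cpm_result"))
  idx <- edge_index(n_nodes)
  m <- matrix(0L, n_nodes, n_nodes)
  fill <- function(m, pos, val) {
    ij <- idx[pos, , drop = FALSE]
    m[ij] <- val
    m[ij[, 2:1, drop = FALSE]] <- val
    m
  }
  m <- fill(m, result$consensus$pos, 1L)
  m <- fill(m, result$consensus$neg, -1L)
  m
}

#' Permutation test of CPM predictive performance
#'
#' Shuffles the correspondence between behaviour and connectomes
#' `n_perm` times (covariates stay paired with the connectomes), reruns
#' the full leave-one-out CPM for each shuffle, and records the evaluation
#' correlation, giving a null distribution for the observed r.  The
#' permutation p uses the add-one estimator, one-sided (greater), since
#' predictive validity is directional: `p = (1 + #{null_r >= r_obs}) /
#' (1 + n_perm)`.  Permutations whose evaluation correlation is undefined
#' (e.g. every fold degenerate) contribute r = 0 and are counted.
#'
#' @inheritParams loocv_cpm
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; the same seed reproduces the same shuffles
#'   and null distribution exactly.
#' @param detail If `TRUE`, the observed (unpermuted) analysis is
#'   returned in full as the `observed` element — the same `cpm_result`
#'   that [loocv_cpm()] would produce, obtained from the shared fold
#'   sweep at no extra cost.
#' @return A `cpm_perm` list: per requested tail, observed `r`, `p_perm`,
#'   `null_r` (length `n_perm`), `mean_null_r`, and the count of
#'   degenerate permutations.
#' @export
permutation_test <- function(edges, behaviour, covariates = NULL,
                             p_threshold = 0.01, tails = c("pos", "neg"),
                             n_perm = 1000, seed = 1, detail = FALSE) {
  tails <- match.arg(tails, c("pos", "neg"), several.ok = TRUE)
  if (n_perm < 100) stop("n_perm must be >= 100")
  behaviour <- as.numeric(behaviour)
  if (anyNA(behaviour)) stop("behaviour must be complete")
  n <- length(behaviour)
  set.seed(as.integer(seed))
  Bmat <- cbind(behaviour,
                vapply(seq_len(n_perm),
                       function(i) behaviour[sample.int(n)], numeric(n)))
  sw <- cpm_fold_sweep(edges, Bmat, covariates, p_threshold, tails,
                       keep_fold_details = detail)
  out <- list(n = n, n_perm = n_perm, seed = seed, tails = tails,
              config = list(p_threshold = p_threshold, k_covariates = sw$k))
  if (detail) out$observed <- assemble_cpm_result(sw, n, tails, p_threshold)
  for (tail in tails) {
    r_all <- sw$eval_r[[tail]]
    obs <- r_all[1]
    null_r <- r_all[-1]
    out[[tail]] <- list(
      r = obs,
      null_r = null_r,
      mean_null_r = mean(null_r),
      p_perm = (1 + sum(null_r >= obs)) / (1 + n_perm),
      n_degenerate = sw$n_degenerate_eval[[tail]])
  }
  class(out) <- "cpm_perm"
  out
}

#' @export
print.cpm_result <- function(x, ...) {
  cat("Leave-one-out CPM (n = ", x$n, ", p < ",
      x$config$p_threshold, ", k = ", x$config$k_covariates,
      " covariates)\n", sep = "")
  for (tail in x$tails) {
    cat(sprintf("  %s tail: r = %.3f (df = %d, parametric p = %.3g), %d consensus edges, %d/%d empty folds\n",
                tail, x$r[[tail]], x$df, x[[paste0("p_parametric_", tail)]],
                length(x$consensus[[tail]]), x$empty_folds[[tail]], x$n))
  }
  invisible(x)
}

#' @export
print.cpm_perm <- function(x, ...) {
  cat("CPM permutation test (", x$n_perm, " shuffles, seed ", x$seed, ")\n",
      sep = "")
  for (tail in x$tails) {
    t <- x[[tail]]
    cat(sprintf("  %s tail: r = %.3f, p_perm = %.4g, mean null r = %.4f\n",
                tail, t$r, t$p_perm, t$mean_null_r))
  }
  invisible(x)
}

#' Leave-one-out CPM with fold-wise (leakage-free) harmonization
#'
#' Methodological-comparison variant of [loocv_cpm()]: instead of
#' harmonizing the pooled sample once before cross-validation (the
#' convention of multi-site CPM studies, which leaks pooled site-effect
#' estimates across folds), each fold fits the empirical-Bayes site model
#' on its training subjects only and applies it to the held-out subject
#' via [combat_apply()].  Selection, strength computation, tail models and
#' evaluation are unchanged.  Refitting the site model n times makes this
#' markedly slower than [loocv_cpm()]; intended for moderate problem
#' sizes.
#'
#' @inheritParams loocv_cpm
#' @param site Site labels, length `n`; every site must keep >= 2 training
#'   subjects in every fold.
#' @param combat_covariates Covariates protected during harmonization
#'   (numeric matrix/data.frame), or `NULL`.
#' @param combat_mode Passed to [combat_fit_transform()].
#' @return A `cpm_result` (without fold-model details beyond masks).
#' @export
loocv_cpm_strict <- function(edges, behaviour, site, covariates = NULL,
                             combat_covariates = NULL,
                             combat_mode = "parametric",
                             p_threshold = 0.01,
                             tails = c("pos", "neg")) {
  tails <- match.arg(tails, c("pos", "neg"), several.ok = TRUE)
  edges <- as.matrix(edges)
  n <- nrow(edges)
  behaviour <- as.numeric(behaviour)
  if (anyNA(behaviour)) stop("behaviour must be complete")
  if (n < 10) stop("leave-one-out CPM needs at least 10 subjects")
  cc <- if (is.null(combat_covariates)) NULL else
    as.data.frame(combat_covariates)
  cm <- if (is.null(covariates)) NULL else as.matrix(covariates)

  pred <- list(pos = rep(NA_real_, n), neg = rep(NA_real_, n))
  consensus_count <- list(pos = integer(ncol(edges)),
                          neg = integer(ncol(edges)))
  folds <- vector("list", n)
  empty_folds <- list(pos = 0L, neg = 0L)
  for (s in seq_len(n)) {
    tr <- setdiff(seq_len(n), s)
    h <- combat_fit_transform(edges[tr, , drop = FALSE], site[tr],
                              covariates = if (is.null(cc)) NULL else
                                cc[tr, , drop = FALSE],
                              mode = combat_mode)
    test_row <- combat_apply(h$model, edges[s, , drop = FALSE], site[s],
                             if (is.null(cc)) NULL else
                               cc[s, , drop = FALSE])
    sel <- select_edges(h$features, behaviour[tr],
                        if (is.null(cm)) NULL else cm[tr, , drop = FALSE],
                        p_threshold)
    folds[[s]] <- list(train = tr, pos = sel$pos, neg = sel$neg)
    for (tail in tails) {
      idx <- sel[[tail]]
      consensus_count[[tail]][idx] <- consensus_count[[tail]][idx] + 1L
      if (length(idx) == 0) {
        empty_folds[[tail]] <- empty_folds[[tail]] + 1L
        pred[[tail]][s] <- mean(behaviour[tr])
      } else {
        fitm <- fit_tail_model(network_strength(h$features, idx),
                               behaviour[tr])
        pred[[tail]][s] <- predict_tail(
          fitm, network_strength(as.vector(test_row), idx))
      }
    }
  }
  k <- if (is.null(cm)) 0L else ncol(cm)
  res <- list(n = n, tails = tails, predictions = pred,
              r = list(pos = NULL, neg = NULL), df = n - 2L - k,
              consensus = lapply(consensus_count,
                                 function(ct) which(ct == n)),
              consensus_count = consensus_count, folds = folds,
              empty_folds = empty_folds,
              invalid = lapply(empty_folds, function(e) e >= n),
              config = list(p_threshold = p_threshold, k_covariates = k,
                            harmonization = "fold-wise"))
  for (tail in tails) {
    pc <- partial_correlation(pred[[tail]], behaviour, cm)
    res$r[[tail]] <- pc$r
    res[[paste0("p_parametric_", tail)]] <- pc$p
  }
  class(res) <- "cpm_result"
  res
}
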