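# CPM building blocks: partial correlation, edge selection, network
# strength, tail models, FDR.

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the OLS residuals of `x` and `y` after
#' regressing each on an intercept plus the covariate columns.  With no
#' covariates this is the ordinary Pearson correlation.  The two-sided p
#' uses the t distribution with `df = n - 2 - k` where `k` is the number
#' of covariate columns.
#'
#' @param x,y Numeric vectors of equal length `n >= k + 3`.
#' @param covariates Optional numeric matrix/data.frame with `n` rows and
#'   `k` full-rank columns.  Constant columns are uninformative given the
#'   intercept; they are dropped and `k` (hence `df`) adjusted.
#' @return List with `r`, `p` (two-sided), `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("x and y must be complete")
  X <- cbind(rep(1, n))
  k <- 0L
  if (!is.null(covariates)) {
    cm <- as.matrix(as.data.frame(covariates))
    if (nrow(cm) != n) stop("covariates must have one row per observation")
    storage.mode(cm) <- "double"
    if (anyNA(cm)) stop("covariates must be complete")
    # a constant covariate (e.g. a single-sex sample's sex dummy) carries
    # no information beyond the intercept; drop it and adjust df
    cm <- cm[, apply(cm, 2, stats::sd) > 0, drop = FALSE]
    X <- cbind(X, cm)
    k <- ncol(cm)
  }
  if (n < k + 3) stop("need n >= k + 3 observations (n = ", n, ", k = ", k, ")")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate design is rank deficient")
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  if (sx <= 1e-10 * sqrt(sum(x^2)) || sy <= 1e-10 * sqrt(sum(y^2))) {
    stop("zero residual variance in x or y")
  }
  r <- sum(rx * ry) / (sx * sy)
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(r = r, p = p, df = df)
}

# Critical |r| for a two-sided partial-correlation test at level p_threshold
# with df = n - 2 - k: |r| > r_crit  <=>  p < p_threshold.
critical_r <- function(p_threshold, df) {
  tcrit <- stats::qt(1 - p_threshold / 2, df)
  sqrt(tcrit^2 / (tcrit^2 + df))
}

# Residualize the columns of M on [1, covariates] (covariates z-scored
# first; this changes nothing numerically but keeps the design well
# conditioned).  A constant covariate column is collinear with the
# intercept and contributes nothing to the projection, so it is dropped —
# this matters inside LOOCV folds, where a nearly-constant covariate
# (e.g. a rare-level dummy) can become constant in a training set.
residualize <- function(M, covariates) {
  n <- nrow(M)
  X <- cbind(rep(1, n))
  if (!is.null(covariates) && ncol(as.matrix(covariates)) > 0) {
    cm <- as.matrix(covariates)
    storage.mode(cm) <- "double"
    sds <- apply(cm, 2, stats::sd)
    cm <- cm[, sds > 0, drop = FALSE]
    if (ncol(cm)) X <- cbind(X, scale(cm))
  }
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  M - Q %*% crossprod(Q, M)
}

#' Select behaviour-correlated edges
#'
#' For every edge, computes the partial correlation between edge weight
#' and behaviour across subjects (controlling for the covariates) and
#' thresholds the two-sided p value.  Edges with `p < p_threshold` enter
#' the positive mask if their partial r is positive, the negative mask if
#' negative; the masks are disjoint by construction.
#'
#' @param edges Numeric `n x E` matrix (subjects x edge features in
#'   canonical order).
#' @param behaviour Numeric vector, length `n`, complete, non-constant.
#' @param covariates Optional `n x k` matrix/data.frame.
#' @param p_threshold Two-sided selection threshold (default 0.01).
#' @return List with `pos` and `neg` (integer vectors of selected edge
#'   positions in canonical order), `r` (length-`E` partial correlations)
#'   and `df`.
#' @export
select_edges <- function(edges, behaviour, covariates = NULL,
                         p_threshold = 0.01) {
  edges <- as.matrix(edges)
  n <- nrow(edges)
  behaviour <- as.numeric(behaviour)
  if (length(behaviour) != n) stop("behaviour length must match subjects")
  if (anyNA(behaviour)) stop("behaviour must be complete")
  if (stats::sd(behaviour) == 0) stop("behaviour has zero variance")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  df <- n - 2L - k
  if (df < 1) stop("too few subjects for selection (df = ", df, ")")
  RB <- residualize(cbind(behaviour, edges), covariates)
  rb <- RB[, 1]
  RE <- RB[, -1, drop = FALSE]
  sb <- sqrt(sum(rb^2))
  se <- sqrt(colSums(RE^2))
  num <- as.vector(crossprod(RE, rb))
  r <- unname(ifelse(se > 0, num / (se * sb), 0))
  rc <- critical_r(p_threshold, df)
  list(pos = which(r > rc), neg = which(r < -rc), r = r, df = df)
}

#' Network strength: summed edge weights over a mask
#'
#' Sums each subject's edge weights over the edges of one sign of a mask,
#' each undirected edge counted once.
#'
#' @param edges Numeric `n x E` matrix, or a single length-`E` edge
#'   vector, or an `N x N` connectivity matrix.
#' @param mask An `N x N` edge-mask matrix over {-1,0,1}, or an integer
#'   vector of edge positions (canonical order).
#' @param sign Which tail of a matrix mask to sum (+1 or -1); ignored for
#'   positional masks.
#' @return Numeric vector of per-subject strengths (summed z units).
#' @export
network_strength <- function(edges, mask, sign = 1) {
  if (is.matrix(mask)) {
    validate_edge_mask(mask)
    pos <- which(mask[edge_index(nrow(mask))] == sign)
  } else {
    pos <- as.integer(mask)
  }
  if (is.matrix(edges) && nrow(edges) == ncol(edges) &&
      isTRUE(all.equal(unname(edges), unname(t(edges))))) {
    edges <- matrix(vectorize(edges), 1)
  } else if (!is.matrix(edges)) {
    edges <- matrix(edges, 1)
  }
  if (length(pos) == 0) return(rep(0, nrow(edges)))
  if (max(pos) > ncol(edges)) stop("mask refers to edges beyond E = ", ncol(edges))
  rowSums(edges[, pos, drop = FALSE])
}

#' Fit a single-tail linear predictive model
#'
#' Ordinary least squares of behaviour on network strength (one predictor
#' plus intercept).  A zero-variance strength vector yields a degenerate
#' model that predicts the training mean.
#'
#' @param strength Numeric vector of network strengths.
#' @param behaviour Numeric vector, same length, `n >= 3`.
#' @return List with `slope`, `intercept`, `degenerate` (logical).
#' @export
fit_tail_model <- function(strength, behaviour) {
  n <- length(strength)
  if (length(behaviour) != n) stop("lengths differ")
  if (n < 3) stop("need at least 3 observations")
  mx <- mean(strength); my <- mean(behaviour)
  sxx <- sum((strength - mx)^2)
  if (sxx <= .Machine$double.eps * n * max(1, mx^2)) {
    return(list(slope = 0, intercept = my, degenerate = TRUE))
  }
  slope <- sum((strength - mx) * (behaviour - my)) / sxx
  list(slope = slope, intercept = my - slope * mx, degenerate = FALSE)
}

#' Predict behaviour from a fitted tail model
#' @param model List with `slope`, `intercept` (from [fit_tail_model()]).
#' @param strength Numeric vector of strengths.
#' @return Predicted behaviour values.
#' @export
predict_tail <- function(model, strength) {
  model$intercept + model$slope * strength
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjusted p values (q values), monotone in the ranked
#' raw p values.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Numeric vector of q values, same order as the input.
#' @export
fdr_bh <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
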