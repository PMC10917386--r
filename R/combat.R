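# Empirical-Bayes multisite harmonization of edge features (ComBat).
#
# Location/scale batch model: y_se = alpha_e + X_s beta_e + gamma_ie +
# delta_ie eps_se for subject s at site i and feature (edge) e.  Per-site,
# per-feature location (gamma) and scale (delta) estimates are shrunk
# toward empirical-Bayes priors pooled across features — Gaussian for
# gamma, inverse-gamma for delta — then removed; covariate effects
# (X beta) are fit, held out of the standardization, and restored, so
# biological signal is preserved.  Both the parametric prior solution and
# the nonparametric weighted-likelihood solution are implemented.

#' Fit and apply empirical-Bayes site harmonization
#'
#' Removes additive and multiplicative site effects from a subjects x
#' features matrix while preserving variance associated with the given
#' biological covariates.  With a single site there is no between-site
#' variability to remove and the input is returned unchanged.
#'
#' @param features Numeric `n x E` matrix (subjects in rows; edge features
#'   in canonical order for connectome data, but any feature set works).
#' @param site Site/batch labels, length `n`; every site needs at least 2
#'   subjects (see `allow_singleton_sites`).
#' @param covariates Optional biological covariates to protect: numeric
#'   matrix or data frame with `n` rows (factors are expanded via
#'   `model.matrix`).  The combined design must be full rank.
#' @param mode `"parametric"` (default; Gaussian/inverse-gamma prior,
#'   iterative conditional solution) or `"nonparametric"`
#'   (weighted-likelihood integration over the other features' estimates;
#'   O(E^2), intended for moderate feature counts).
#' @param allow_singleton_sites If `TRUE`, subjects at single-subject
#'   sites are passed through unharmonized with a warning instead of
#'   raising an error.
#' @return List with `features` (harmonized `n x E` matrix, dimnames
#'   preserved) and `model` (a `cpm_combat_model`: per-site `gamma_star`,
#'   `delta_star`, grand mean, covariate coefficients, pooled variance,
#'   mode).
#' @export
combat_fit_transform <- function(features, site, covariates = NULL,
                                 mode = c("parametric", "nonparametric"),
                                 allow_singleton_sites = FALSE) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("features must be numeric")
  if (any(!is.finite(features))) stop("features contain non-finite values")
  n <- nrow(features)
  if (length(site) != n) stop("`site` length must match nrow(features)")
  site <- factor(site)

  singles <- names(which(table(site) < 2))
  pass_rows <- site %in% singles
  if (length(singles)) {
    if (!allow_singleton_sites) {
      stop("site(s) with a single subject: ", paste(singles, collapse = ", "),
           "; scale effects cannot be estimated ",
           "(set allow_singleton_sites = TRUE to pass them through)")
    }
    warning("passing through ", sum(pass_rows), " subject(s) at ",
            "single-subject site(s): ", paste(singles, collapse = ", "))
  }

  Xcov <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per subject")
    Xcov <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }

  fit_rows <- !pass_rows
  out <- features
  model <- combat_fit(features[fit_rows, , drop = FALSE],
                      droplevels(site[fit_rows]),
                      if (is.null(Xcov)) NULL else Xcov[fit_rows, , drop = FALSE],
                      mode)
  out[fit_rows, ] <- model$adjusted
  model$adjusted <- NULL
  list(features = out, model = model)
}

combat_fit <- function(Y, batch, Xcov, mode) {
  n <- nrow(Y); E <- ncol(Y)
  B <- nlevels(batch)
  n_i <- as.vector(table(batch))

  if (B == 1) {
    model <- structure(list(sites = levels(batch), n_per_site = n_i,
                            gamma_star = matrix(0, 1, E),
                            delta_star = matrix(1, 1, E),
                            grand_mean = colMeans(Y), beta_cov = NULL,
                            var_pooled = apply(Y, 2, stats::var),
                            mode = mode),
                       class = "cpm_combat_model")
    model$adjusted <- Y
    return(model)
  }

  batchmod <- stats::model.matrix(~ -1 + batch)
  design <- cbind(batchmod, Xcov)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("harmonization design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  B.hat <- solve(crossprod(design), crossprod(design, Y))
  grand.mean <- as.vector(crossprod(n_i / n, B.hat[seq_len(B), , drop = FALSE]))
  resid <- Y - design %*% B.hat
  var.pooled <- colSums(resid^2) / n
  if (any(var.pooled == 0)) {
    stop("feature(s) with zero residual variance: ",
         paste(utils::head(which(var.pooled == 0), 5), collapse = ", "))
  }
  stand.mean <- matrix(grand.mean, n, E, byrow = TRUE)
  if (!is.null(Xcov)) {
    stand.mean <- stand.mean +
      design[, -seq_len(B), drop = FALSE] %*%
        B.hat[-seq_len(B), , drop = FALSE]
  }
  Z <- (Y - stand.mean) / matrix(sqrt(var.pooled), n, E, byrow = TRUE)

  gamma.hat <- matrix(NA_real_, B, E)
  delta.hat <- matrix(NA_real_, B, E)
  for (b in seq_len(B)) {
    Zi <- Z[batch == levels(batch)[b], , drop = FALSE]
    gamma.hat[b, ] <- colMeans(Zi)
    delta.hat[b, ] <- apply(Zi, 2, stats::var)
  }

  gamma.star <- matrix(NA_real_, B, E)
  delta.star <- matrix(NA_real_, B, E)
  for (b in seq_len(B)) {
    Zi <- Z[batch == levels(batch)[b], , drop = FALSE]
    if (mode == "parametric") {
      est <- eb_parametric(Zi, gamma.hat[b, ], delta.hat[b, ])
    } else {
      est <- eb_nonparametric(Zi, gamma.hat[b, ], delta.hat[b, ])
    }
    gamma.star[b, ] <- est$gamma
    delta.star[b, ] <- est$delta
  }

  bayes <- Z - batchmod %*% gamma.star
  scale_row <- sqrt(delta.star)[as.integer(batch), , drop = FALSE]
  bayes <- bayes / scale_row
  adjusted <- bayes * matrix(sqrt(var.pooled), n, E, byrow = TRUE) + stand.mean

  model <- structure(list(sites = levels(batch), n_per_site = n_i,
                          gamma_star = gamma.star, delta_star = delta.star,
                          grand_mean = grand.mean,
                          beta_cov = if (is.null(Xcov)) NULL else
                            B.hat[-seq_len(B), , drop = FALSE],
                          var_pooled = var.pooled, mode = mode),
                     class = "cpm_combat_model")
  model$adjusted <- adjusted
  model
}

# Parametric empirical Bayes: method-of-moments hyperpriors (Gaussian on
# gamma, inverse-gamma on delta) and the standard iterative conditional
# posterior-mean solution.
eb_parametric <- function(Zi, g.hat, d.hat, conv = 1e-4, max_iter = 1000) {
  n <- nrow(Zi)
  g.bar <- mean(g.hat); t2 <- stats::var(g.hat)
  m <- mean(d.hat); s2 <- stats::var(d.hat)
  a.prior <- (2 * s2 + m^2) / s2
  b.prior <- (m * s2 + m^3) / s2
  g.old <- g.hat; d.old <- d.hat
  sum_z <- colSums(Zi); sum_z2 <- colSums(Zi^2)
  for (it in seq_len(max_iter)) {
    g.new <- (n * t2 * g.hat + d.old * g.bar) / (n * t2 + d.old)
    sum2 <- sum_z2 - 2 * g.new * sum_z + n * g.new^2
    d.new <- (0.5 * sum2 + b.prior) / (n / 2 + a.prior - 1)
    change <- max(abs(g.new - g.old) / abs(g.old),
                  abs(d.new - d.old) / abs(d.old))
    g.old <- g.new; d.old <- d.new
    if (change < conv) break
  }
  list(gamma = g.old, delta = d.old)
}

# Nonparametric empirical Bayes: each feature's posterior is the
# likelihood-weighted average of all other features' (gamma.hat,
# delta.hat) estimates.
eb_nonparametric <- function(Zi, g.hat, d.hat) {
  n <- nrow(Zi)
  E <- length(g.hat)
  gamma.star <- numeric(E); delta.star <- numeric(E)
  sum_x <- colSums(Zi); sum_x2 <- colSums(Zi^2)
  for (g in seq_len(E)) {
    gh <- g.hat[-g]; dh <- d.hat[-g]
    ss <- sum_x2[g] - 2 * gh * sum_x[g] + n * gh^2
    LH <- (2 * pi * dh)^(-n / 2) * exp(-ss / (2 * dh))
    LH[!is.finite(LH)] <- 0
    if (sum(LH) == 0) {     # degenerate weights: fall back to own estimate
      gamma.star[g] <- g.hat[g]; delta.star[g] <- d.hat[g]
    } else {
      gamma.star[g] <- sum(gh * LH) / sum(LH)
      delta.star[g] <- sum(dh * LH) / sum(LH)
    }
  }
  list(gamma = gamma.star, delta = delta.star)
}

#' @export
print.cpm_combat_model <- function(x, ...) {
  cat("Empirical-Bayes site harmonization model (", x$mode, ")\n", sep = "")
  cat("  sites:", paste(x$sites, collapse = ", "), "\n")
  cat("  subjects per site:", paste(x$n_per_site, collapse = ", "), "\n")
  cat("  features:", length(x$var_pooled), "\n")
  invisible(x)
}

#' Apply a fitted harmonization model to new subjects
#'
#' Transforms new observations with the site estimates learned by
#' [combat_fit_transform()]: standardize with the stored grand mean,
#' covariate coefficients and pooled variance, remove the subject's
#' site's shrunken location/scale estimates, and restore the biological
#' signal.  New subjects must come from sites seen at fit time.
#'
#' @param model A `cpm_combat_model`.
#' @param features Numeric `m x E` matrix of new observations.
#' @param site Site labels of the new observations (must be a subset of
#'   the model's sites).
#' @param covariates Covariates of the new observations, matching the
#'   columns used at fit time (`NULL` if none were used).
#' @return Harmonized `m x E` matrix.
#' @export
combat_apply <- function(model, features, site, covariates = NULL) {
  stopifnot(inherits(model, "cpm_combat_model"))
  features <- as.matrix(features)
  m <- nrow(features); E <- ncol(features)
  if (E != length(model$var_pooled)) {
    stop("feature count differs from the fitted model (", E, " vs ",
         length(model$var_pooled), ")")
  }
  site <- as.character(site)
  if (length(site) == 1) site <- rep(site, m)
  unknown <- setdiff(unique(site), model$sites)
  if (length(unknown)) stop("site(s) not seen at fit time: ",
                            paste(unknown, collapse = ", "))
  stand <- matrix(model$grand_mean, m, E, byrow = TRUE)
  if (!is.null(model$beta_cov)) {
    if (is.null(covariates)) stop("model was fit with covariates; supply them")
    cm <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                     drop = FALSE]
    if (!identical(colnames(cm), rownames(model$beta_cov))) {
      stop("covariate columns do not match the fit: expected ",
           paste(rownames(model$beta_cov), collapse = ", "))
    }
    stand <- stand + cm %*% model$beta_cov
  }
  sv <- matrix(sqrt(model$var_pooled), m, E, byrow = TRUE)
  z <- (features - stand) / sv
  si <- match(site, model$sites)
  z <- (z - model$gamma_star[si, , drop = FALSE]) /
    sqrt(model$delta_star[si, , drop = FALSE])
  z * sv + stand
}
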