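# Transfer of a fitted consensus network to independent samples.

#' Refit transfer coefficients on the full model sample
#'
#' The consensus network is fixed, and the tail model (slope, intercept)
#' is refit by OLS on the FULL model sample's consensus-mask strengths —
#' a deterministic summary that uses all training data, rather than an
#' average of per-fold models.
#'
#' @param edges Model-sample `n x E` edge matrix.
#' @param behaviour Model-sample behaviour vector.
#' @param consensus Integer vector of consensus edge positions (canonical
#'   order), e.g. `result$consensus$neg`.
#' @return List with `slope`, `intercept`, `degenerate`, `consensus`.
#' @export
transfer_model <- function(edges, behaviour, consensus) {
  if (length(consensus) == 0) stop("no consensus edges to transfer")
  strength <- network_strength(as.matrix(edges), consensus)
  fit <- fit_tail_model(strength, as.numeric(behaviour))
  fit$consensus <- as.integer(consensus)
  fit
}

#' Validate a consensus network on an independent sample
#'
#' Extracts the consensus edges from each new subject's connectome, sums
#' them into a network strength, applies the transferred linear model, and
#' reports the partial correlation between predicted and observed
#' behaviour controlling for the new sample's covariates.  Used both for
#' replication (independent patients; expect r > 0) and specificity
#' (controls; expect a null result).
#'
#' @param model Transferred model from [transfer_model()] (fields `slope`,
#'   `intercept`, `consensus`).
#' @param edges_new `m x E` edge matrix of the independent sample
#'   (`m >= 10`).
#' @param behaviour_new Behaviour vector of length `m`, complete.
#' @param covariates_new Optional `m x k` covariates.
#' @param sample_label Label recorded in the report.
#' @return A `cpm_validation` list: `sample`, `n`, `r`, `p` (two-sided,
#'   `df = m - 2 - k`), `df`, `predicted`, `strength`, model provenance.
#' @export
external_validate <- function(model, edges_new, behaviour_new,
                              covariates_new = NULL,
                              sample_label = "validation") {
  if (is.null(model$consensus) || length(model$consensus) == 0) {
    stop("no consensus edges to transfer")
  }
  edges_new <- as.matrix(edges_new)
  m <- nrow(edges_new)
  if (m < 10) stop("validation sample too small (n = ", m, ")")
  behaviour_new <- as.numeric(behaviour_new)
  if (anyNA(behaviour_new)) stop("behaviour must be complete")
  strength <- network_strength(edges_new, model$consensus)
  predicted <- predict_tail(model, strength)
  pc <- partial_correlation(predicted, behaviour_new, covariates_new)
  structure(list(sample = sample_label, n = m,
                 r = pc$r, p = pc$p, df = pc$df,
                 predicted = predicted, strength = strength,
                 model = model[c("slope", "intercept")],
                 n_consensus_edges = length(model$consensus)),
            class = "cpm_validation")
}

#' @export
print.cpm_validation <- function(x, ...) {
  cat(sprintf("External validation on '%s' (n = %d, %d consensus edges): r(df=%d) = %.3f, p = %.4g\n",
              x$sample, x$n, x$n_consensus_edges, x$df, x$r, x$p))
  invisible(x)
}
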