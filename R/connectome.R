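# Connectome construction and the canonical edge vectorization.

#' Fisher z-transformation of a correlation coefficient
#'
#' `fisher_z()` maps Pearson correlations to the z scale via `atanh`;
#' `inverse_fisher_z()` maps back via `tanh`.  Correlations with
#' `|r| = 1` (up to a small numerical margin) are clipped to
#' `1 - 1e-7` in magnitude before the transform so every edge stays
#' finite; the number of clipped values is reported via an attribute.
#'
#' @param r Numeric vector of correlations, `|r| <= 1` (a tolerance of
#'   `1e-12` is allowed for floating-point excess before an error is
#'   raised).
#' @param z Numeric vector of Fisher-z values.
#' @return `fisher_z()`: numeric vector of z values, with attribute
#'   `n_clipped` giving the count of inputs clipped to the open interval.
#'   `inverse_fisher_z()`: numeric vector of correlations.
#' @examples
#' fisher_z(0.5)           # atanh(0.5) = 0.5493061
#' inverse_fisher_z(fisher_z(0.3))
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r)) stop("`r` must be numeric")
  bad <- is.finite(r) & abs(r) > 1 + 1e-12
  if (any(bad)) {
    stop("correlations outside [-1, 1]: ", paste(
      format(utils::head(r[bad], 3)), collapse = ", "))
  }
  lim <- 1 - 1e-7
  clip <- is.finite(r) & abs(r) > lim
  r <- pmin(pmax(r, -lim), lim)
  z <- atanh(r)
  attr(z, "n_clipped") <- sum(clip)
  z
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Row-major upper-triangle edge index
#'
#' Enumerates the `E = N(N-1)/2` undirected edges of an `N`-node graph in
#' the package's canonical order: (1,2), (1,3), ..., (1,N), (2,3), ...,
#' (N-1,N).  This single ordering is used for every flat edge
#' representation (feature tables, masks, exports).
#'
#' @param n_nodes Number of nodes `N >= 2`.
#' @return Integer matrix with `E` rows and columns `i`, `j` (`i < j`).
#' @export
edge_index <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2) stop("`n_nodes` must be an integer >= 2")
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- sequence((n_nodes - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Number of edges for an N-node connectome
#' @param n_nodes Number of nodes.
#' @return `N(N-1)/2` as an integer.
#' @export
n_edges <- function(n_nodes) as.integer(n_nodes * (n_nodes - 1L) / 2L)

#' Flat edge position of node pairs
#'
#' Maps pairs `(i, j)`, `i < j`, to their position in the canonical
#' row-major upper-triangle order.
#'
#' @param i,j Integer node ids with `i < j`.
#' @param n_nodes Number of nodes.
#' @return Integer vector of positions in `1..E`.
#' @export
edge_position <- function(i, j, n_nodes) {
  if (any(i >= j) || any(i < 1) || any(j > n_nodes)) {
    stop("edge pairs must satisfy 1 <= i < j <= n_nodes")
  }
  as.integer((i - 1L) * n_nodes - (i - 1L) * i / 2L + (j - i))
}

#' Build a Fisher-z connectivity matrix from ROI time series
#'
#' Computes all pairwise Pearson correlations between node time courses and
#' applies the Fisher z-transformation, yielding the subject's symmetric
#' `N x N` connectivity matrix with a zero diagonal.  Perfect correlations
#' are clipped (see [fisher_z()]).
#'
#' @param ts Numeric matrix, `T` timepoints x `N` nodes, `T >= 3`, all
#'   entries finite.
#' @return Symmetric `N x N` numeric matrix of Fisher-z edge weights;
#'   diagonal exactly 0; attribute `n_clipped` counts clipped edges
#'   (each undirected edge counted once).
#' @examples
#' ts <- matrix(rnorm(200 * 5), 200, 5)
#' z <- compute_connectome(ts)
#' all(z == t(z))
#' @export
compute_connectome <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (nrow(ts) < 3) stop("need at least 3 timepoints, got ", nrow(ts))
  if (any(!is.finite(ts))) stop("time series contains non-finite values")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance time series for node(s): ",
         paste(which(sds == 0), collapse = ", "))
  }
  r <- stats::cor(ts)
  diag(r) <- 0
  z <- fisher_z(r)
  n_clip <- attr(z, "n_clipped") / 2  # symmetric matrix counts each edge twice
  z <- matrix(as.numeric(z), nrow(r), ncol(r))
  z <- (z + t(z)) / 2   # enforce exact symmetry against rounding asymmetries
  diag(z) <- 0
  dimnames(z) <- dimnames(r)
  attr(z, "n_clipped") <- n_clip
  z
}

#' Validate a connectivity matrix
#'
#' Checks the structural contract: square, symmetric, zero diagonal, all
#' off-diagonal entries finite.
#'
#' @param z Matrix to validate.
#' @param tol Symmetry tolerance.
#' @return `z`, invisibly, on success; otherwise an error.
#' @export
validate_connectome <- function(z, tol = 1e-12) {
  if (!is.matrix(z) || nrow(z) != ncol(z)) stop("connectome must be a square matrix")
  if (any(!is.finite(z))) stop("connectome contains non-finite entries")
  if (any(abs(diag(z)) > 0)) stop("connectome diagonal must be exactly 0")
  if (max(abs(z - t(z))) > tol) stop("connectome is not symmetric")
  invisible(z)
}

#' Vectorize a connectivity matrix to the canonical edge vector
#'
#' Extracts the row-major upper triangle (see [edge_index()]).  The
#' operation is the exact inverse of [devectorize()].
#'
#' @param z Symmetric `N x N` matrix (zero diagonal).
#' @return Numeric vector of length `E = N(N-1)/2`.
#' @export
vectorize <- function(z) {
  validate_connectome(z)
  idx <- edge_index(nrow(z))
  z[idx]
}

#' Rebuild a connectivity matrix from a canonical edge vector
#'
#' @param v Numeric vector of length `N(N-1)/2` in canonical edge order.
#' @param n_nodes Number of nodes `N`.
#' @return Symmetric `N x N` matrix with zero diagonal.
#' @export
devectorize <- function(v, n_nodes) {
  e <- n_edges(n_nodes)
  if (length(v) != e) {
    stop("edge vector has length ", length(v), " but N = ", n_nodes,
         " requires ", e)
  }
  idx <- edge_index(n_nodes)
  z <- matrix(0, n_nodes, n_nodes)
  z[idx] <- v
  z[idx[, 2:1, drop = FALSE]] <- v
  z
}
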