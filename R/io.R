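# Readers/writers for the package's plain-text interchange formats.
# All numeric round trips are lossless at full double precision (%.17g).

#' Read and write square connectome matrices as delimited text
#'
#' Connectomes are stored as whitespace- or comma-delimited `N x N` numeric
#' text without headers.  Writing uses 17 significant digits so a
#' write/read round trip is bit-identical.
#'
#' @param path File path.
#' @param z Symmetric `N x N` matrix to write.
#' @return `read_connectome_matrix()`: validated `N x N` matrix.
#' @export
read_connectome_matrix <- function(path) {
  z <- as.matrix(utils::read.table(path, header = FALSE,
                                   sep = "", colClasses = "numeric"))
  dimnames(z) <- NULL
  if (nrow(z) != ncol(z)) {
    stop("connectome file is not square: ", nrow(z), " x ", ncol(z),
         " (", path, ")")
  }
  validate_connectome(z)
  z
}

#' @rdname read_connectome_matrix
#' @export
write_connectome_matrix <- function(z, path) {
  validate_connectome(z)
  txt <- apply(z, 1, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(txt, path)
  invisible(path)
}

#' Read and write subject-by-edge feature tables
#'
#' Edge features (one row per subject, `E = N(N-1)/2` columns in canonical
#' edge order, see [edge_index()]) are stored as CSV with a `subject_id`
#' first column and edge columns `e1..eE`.
#'
#' @param path File path.
#' @param edges Numeric `n x E` matrix with rownames = subject ids.
#' @return `read_edge_table()`: numeric matrix with subject ids as
#'   rownames.
#' @export
read_edge_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "subject_id") stop("edge table must start with subject_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("edge table contains non-numeric values")
  if (any(!is.finite(m))) stop("edge table contains non-finite values")
  rownames(m) <- df$subject_id
  colnames(m) <- NULL
  m
}

#' @rdname read_edge_table
#' @export
write_edge_table <- function(edges, path) {
  if (is.null(rownames(edges))) stop("edge matrix needs subject ids as rownames")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("subject_id", paste0("e", seq_len(ncol(edges)))),
                   collapse = ","), con)
  for (s in seq_len(nrow(edges))) {
    writeLines(paste(c(rownames(edges)[s], sprintf("%.17g", edges[s, ])),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Phenotype CSVs carry one row per subject.  `subject_id` is required and
#' must be unique; all other columns (behavioural scores, covariates,
#' `site`, `subtype`, `group`, QC fields) are optional and validated by the
#' operations that use them.
#'
#' @param path File path.
#' @param pheno Data frame with a `subject_id` column.
#' @return `read_phenotype()`: data frame.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) stop("phenotype table must have a subject_id column")
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         df$subject_id[duplicated(df$subject_id)][1])
  }
  df
}

#' @rdname read_phenotype
#' @export
write_phenotype <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write edge masks
#'
#' An edge mask is a symmetric `N x N` integer matrix over {-1, 0, +1}
#' with a zero diagonal: +1 marks positive-network edges, -1
#' negative-network edges.  Stored as delimited text like connectomes.
#'
#' @param path File path.
#' @param mask Mask matrix.
#' @return `read_edge_mask()`: validated integer mask matrix.
#' @export
read_edge_mask <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = ""))
  dimnames(m) <- NULL
  validate_edge_mask(m)
}

#' @rdname read_edge_mask
#' @export
write_edge_mask <- function(mask, path) {
  validate_edge_mask(mask)
  writeLines(apply(mask, 1, paste, collapse = " "), path)
  invisible(path)
}

#' Convert an edge mask to/from an edge list
#'
#' The edge-list form has one row per nonzero mask entry (each undirected
#' edge once, `node_i < node_j`), sorted by `(node_i, node_j)`, with the
#' mask sign in column `sign`.  This is the export format consumed by
#' circle-plot / glass-brain tools.
#'
#' @param mask Edge mask matrix.
#' @param edge_list Data frame with columns `node_i`, `node_j`, `sign`.
#' @param n_nodes Number of nodes for the rebuilt mask.
#' @param path File path.
#' @return `mask_to_edge_list()` / `read_edge_list()`: data frame
#'   (`node_i`, `node_j`, `sign`); `edge_list_to_mask()`: mask matrix.
#' @export
mask_to_edge_list <- function(mask) {
  validate_edge_mask(mask)
  idx <- edge_index(nrow(mask))
  sgn <- mask[idx]
  keep <- sgn != 0
  out <- data.frame(node_i = idx[keep, 1], node_j = idx[keep, 2],
                    sign = as.integer(sgn[keep]))
  out[order(out$node_i, out$node_j), , drop = FALSE]
}

#' @rdname mask_to_edge_list
#' @export
edge_list_to_mask <- function(edge_list, n_nodes) {
  m <- matrix(0L, n_nodes, n_nodes)
  ij <- cbind(edge_list$node_i, edge_list$node_j)
  m[ij] <- as.integer(edge_list$sign)
  m[ij[, 2:1, drop = FALSE]] <- as.integer(edge_list$sign)
  validate_edge_mask(m)
}

#' @rdname mask_to_edge_list
#' @export
write_edge_list <- function(mask, path) {
  utils::write.csv(mask_to_edge_list(mask), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname mask_to_edge_list
#' @export
read_edge_list <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

validate_edge_mask <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("edge mask must be square")
  if (!all(m %in% c(-1L, 0L, 1L))) stop("edge mask entries must be in {-1, 0, 1}")
  if (any(diag(m) != 0)) stop("edge mask diagonal must be 0")
  if (any(m != t(m))) stop("edge mask must be symmetric")
  storage.mode(m) <- "integer"
  m
}
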