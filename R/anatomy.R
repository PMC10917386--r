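# Network anatomy: node degree and network-pair summaries of an edge mask.

#' Summarize the anatomy of a predictive network
#'
#' Computes per-node degree (number of mask edges incident to each node),
#' the K x K matrix of within/between-network edge counts (each
#' undirected edge counted once; within-network counts on the diagonal),
#' and the sorted edge list.  By the handshake lemma,
#' `sum(node_degree) == 2 * total edges`, and the upper triangle plus
#' diagonal of `pair_counts` also sums to the total edge count.
#'
#' @param mask Edge-mask matrix over {-1, 0, +1} (typically one tail of a
#'   consensus mask); all nonzero entries count.
#' @param atlas A `cpm_atlas` with the same number of nodes.
#' @return A `cpm_network_summary`: `node_degree` (integer, named by node
#'   id), `pair_counts` (K x K symmetric integer matrix with network
#'   names), `edge_list` (`node_i`, `node_j`, `sign`, sorted), `n_edges`.
#' @export
summarize_network <- function(mask, atlas) {
  mask <- validate_edge_mask(mask)
  stopifnot(inherits(atlas, "cpm_atlas"))
  if (nrow(mask) != nrow(atlas)) {
    stop("mask has ", nrow(mask), " nodes but atlas has ", nrow(atlas))
  }
  el <- mask_to_edge_list(mask)
  deg <- tabulate(c(el$node_i, el$node_j), nbins = nrow(atlas))
  names(deg) <- atlas$node_id
  nets <- levels(atlas$network)
  K <- length(nets)
  pc <- matrix(0L, K, K, dimnames = list(nets, nets))
  if (nrow(el)) {
    a <- as.integer(atlas$network[el$node_i])
    b <- as.integer(atlas$network[el$node_j])
    lo <- pmin(a, b); hi <- pmax(a, b)
    tab <- unclass(table(factor(lo, seq_len(K)), factor(hi, seq_len(K))))
    pc <- tab + t(tab) - diag(diag(tab))
    storage.mode(pc) <- "integer"
    dimnames(pc) <- list(nets, nets)
  }
  structure(list(node_degree = deg, pair_counts = pc, edge_list = el,
                 n_edges = nrow(el)),
            class = "cpm_network_summary")
}

#' Rank nodes by degree
#'
#' Orders nodes by descending degree; ties break by ascending node id.
#'
#' @param summary A `cpm_network_summary`.
#' @param atlas The atlas used to build it (for labels/networks).
#' @param top_k Number of rows to return (capped at N).
#' @return Data frame `node_id`, `label`, `network`, `degree`, sorted.
#' @export
rank_nodes <- function(summary, atlas, top_k = 10) {
  stopifnot(inherits(summary, "cpm_network_summary"), top_k >= 1)
  ord <- order(-summary$node_degree, atlas$node_id)
  out <- data.frame(node_id = atlas$node_id[ord],
                    label = atlas$label[ord],
                    network = as.character(atlas$network[ord]),
                    degree = as.integer(summary$node_degree[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, min(top_k, nrow(out)))
}

#' @export
print.cpm_network_summary <- function(x, ...) {
  cat("Network summary:", x$n_edges, "edges;",
      sum(x$node_degree > 0), "nodes involved\n")
  cat("Network-pair counts:\n")
  print(x$pair_counts)
  invisible(x)
}

#' Write the anatomy summary as plot-ready CSV tables
#'
#' Emits `degrees.csv` (node_id, label, network, degree),
#' `pair_counts.csv` (K x K table with network row names) and `edges.csv`
#' (edge list) into a directory.
#'
#' @param summary A `cpm_network_summary`.
#' @param atlas The matching `cpm_atlas`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network_summary <- function(summary, atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  deg <- data.frame(node_id = atlas$node_id, label = atlas$label,
                    network = as.character(atlas$network),
                    degree = as.integer(summary$node_degree))
  utils::write.csv(deg, file.path(dir, "degrees.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(network = rownames(summary$pair_counts),
                              summary$pair_counts, check.names = FALSE),
                   file.path(dir, "pair_counts.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(summary$edge_list, file.path(dir, "edges.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
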