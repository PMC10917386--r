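# Node atlas: node ids, anatomical labels, network assignment, MNI coordinates.

#' Read a node atlas table
#'
#' An atlas assigns every connectome node an anatomical label, a functional
#' network, and MNI coordinates (mm).  The bundled synthetic 160-node
#' fixture mirrors the layout of the six-network, 160-ROI functional atlas
#' commonly used for whole-brain CPM (default-mode, fronto-parietal,
#' cingulo-opercular, sensorimotor, occipital, cerebellum); its coordinates
#' are synthetic placeholders, not the published ROI centres.
#'
#' @param path CSV file with columns `node_id`, `label`, `network`, `x`,
#'   `y`, `z`.
#' @return A `data.frame` of class `cpm_atlas` with validated, contiguous
#'   node ids `1..N` and a factor `network` column.
#' @seealso [default_atlas()] for the bundled 160-node fixture.
#' @export
read_atlas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "label", "network", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("atlas file missing column(s): ", paste(miss, collapse = ", "))
  as_atlas(df)
}

#' @rdname read_atlas
#' @param df Data frame with the atlas columns, as from [read_atlas()].
#' @export
as_atlas <- function(df) {
  if (anyDuplicated(df$node_id)) {
    dup <- df$node_id[duplicated(df$node_id)][1]
    stop("duplicate node_id in atlas (first duplicate: row with node_id ",
         dup, ")")
  }
  if (any(is.na(df$network) | !nzchar(trimws(as.character(df$network))))) {
    bad <- which(is.na(df$network) | !nzchar(trimws(as.character(df$network))))[1]
    stop("missing network label in atlas row ", bad)
  }
  df <- df[order(df$node_id), , drop = FALSE]
  n <- nrow(df)
  if (!all(df$node_id == seq_len(n))) {
    stop("atlas node ids must be contiguous 1..N; got range ",
         min(df$node_id), "..", max(df$node_id), " over ", n, " rows")
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)) || any(!is.finite(df$z))) {
    stop("atlas coordinates must be finite")
  }
  df$node_id <- as.integer(df$node_id)
  df$network <- factor(df$network)
  rownames(df) <- NULL
  class(df) <- c("cpm_atlas", "data.frame")
  df
}

#' The bundled synthetic 160-node, six-network atlas
#'
#' @return A `cpm_atlas` with `N = 160` nodes in 6 networks.  Network sizes
#'   follow the canonical six-network split of the 160-ROI functional
#'   atlas; labels and coordinates are synthetic.
#' @export
default_atlas <- function() {
  read_atlas(system.file("extdata", "atlas160_synthetic.csv",
                         package = "cpmconn", mustWork = TRUE))
}

#' @export
print.cpm_atlas <- function(x, ...) {
  cat("Node atlas:", nrow(x), "nodes,", nlevels(x$network), "networks\n")
  print(table(x$network))
  invisible(x)
}
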