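# Differential-subnetwork export for downstream visualization.

#' Export the differential subnetwork around the top-ranked nodes
#'
#' Selects the `top_k` most significant nodes ("hubs") of a significance
#' table together with their distance-1 neighbors (any nonzero edge in
#' either layer), and tabulates the edges among this node set with the
#' signed weight difference `condition - baseline`, where the baseline is
#' the first designated layer. This is the table behind the usual
#' "differential neighborhood" network figures.
#'
#' @param net The [multiplex_network()] the table was computed from.
#' @param table A `significance_table` (rows already sorted by
#'   significance).
#' @param top_k Number of top-ranked nodes to export (1..n).
#' @param layers Optional character(2): `c(baseline, condition)`; defaults
#'   to the first two layers.
#' @param path_edges,path_nodes Optional output paths; when given, a TSV
#'   of edges (`node_a`, `node_b`, `weight_diff`) and of nodes (`node`,
#'   `role` = hub/neighbor) are written.
#' @return Invisibly, list with data frames `edges` and `nodes`.
#' @export
export_diff_subnetwork <- function(net, table, top_k, layers = NULL,
                                   path_edges = NULL, path_nodes = NULL) {
  stopifnot(inherits(net, "multiplex_network"),
            inherits(table, "significance_table"))
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1) abort_validation("top_k must be >= 1")
  if (top_k > n_nodes(net)) abort_validation("top_k exceeds the number of nodes")
  layers <- resolve_layer_pair(net, layers)
  Wa <- layer_matrix(net, layers[1])  # baseline
  Wb <- layer_matrix(net, layers[2])  # condition
  hubs <- table$node[seq_len(top_k)]
  either <- (Wa != 0) | (Wb != 0)
  nbr_mask <- rowSums(either[, hubs, drop = FALSE] == TRUE) > 0
  neighbors <- setdiff(net$node_ids[nbr_mask], hubs)
  nodes <- c(hubs, neighbors)
  idx <- match(nodes, net$node_ids)
  D <- Wb[idx, idx, drop = FALSE] - Wa[idx, idx, drop = FALSE]
  present <- either[idx, idx, drop = FALSE]
  ut <- which(upper.tri(present) & present, arr.ind = TRUE)
  edges <- data.frame(node_a = nodes[ut[, 1]], node_b = nodes[ut[, 2]],
                      weight_diff = D[ut], stringsAsFactors = FALSE)
  node_tab <- data.frame(node = nodes,
                         role = c(rep("hub", length(hubs)),
                                  rep("neighbor", length(neighbors))),
                         stringsAsFactors = FALSE)
  if (!is.null(path_edges)) {
    out <- edges
    out$weight_diff <- fmt_num(out$weight_diff)
    utils::write.table(out, path_edges, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_nodes)) {
    utils::write.table(node_tab, path_nodes, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(edges = edges, nodes = node_tab))
}
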