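# Synthetic two-layer multiplexes with planted differential-neighborhood
# nodes, plus detection-quality metrics.

#' Simulation specification
#'
#' Describes a two-layer multiplex whose layers are identical except for a
#' planted subset of nodes with perturbed neighborhoods. The perturbation
#' redraws weights on a fraction of a planted node's incident edges and
#' rewires a matching number of its edge/non-edge states (equal counts
#' removed and added), so the node's degree — and, in expectation, its
#' weighted degree — is preserved. Degree-based detectors are therefore not
#' trivially helped; the signal lives in *which* neighbors a node has, not
#' in how connected it is.
#'
#' @param n Number of nodes. Default 100.
#' @param n_planted Number of perturbed nodes. Default 10.
#' @param perturbation_strength Fraction of a planted node's incident
#'   edges affected, in \[0, 1\]. Default 0.8.
#' @param edge_density Probability that a node pair is connected in layer
#'   1, in (0, 1\]. Default 0.2.
#' @param weight_distribution `"uniform01"` or `"beta"` (shape parameters
#'   in `beta_shape`).
#' @param beta_shape Length-2 shape parameters for `"beta"` weights.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n = 100, n_planted = 10, perturbation_strength = 0.8,
                            edge_density = 0.2,
                            weight_distribution = c("uniform01", "beta"),
                            beta_shape = c(2, 2), seed = 1) {
  weight_distribution <- match.arg(weight_distribution)
  n <- as.integer(n); n_planted <- as.integer(n_planted)
  if (is.na(n) || n < 2) abort_validation("n must be >= 2")
  if (is.na(n_planted) || n_planted < 0 || n_planted >= n) {
    abort_validation("n_planted must satisfy 0 <= n_planted < n")
  }
  if (perturbation_strength < 0 || perturbation_strength > 1) {
    abort_validation("perturbation_strength must lie in [0, 1]")
  }
  if (edge_density <= 0 || edge_density > 1) abort_validation("edge_density must lie in (0, 1]")
  structure(list(n = n, n_planted = n_planted,
                 perturbation_strength = perturbation_strength,
                 edge_density = edge_density,
                 weight_distribution = weight_distribution,
                 beta_shape = beta_shape, seed = as.integer(seed)),
            class = "simulation_spec")
}

draw_weights <- function(spec, k) {
  if (k == 0) return(numeric(0))
  switch(spec$weight_distribution,
         uniform01 = runif(k),
         beta = rbeta(k, spec$beta_shape[1], spec$beta_shape[2]))
}

#' Generate a planted-perturbation multiplex
#'
#' Layer 1 is an Erdos-Renyi-style weighted graph (`edge_density`,
#' weights from `weight_distribution`); layer 2 is a copy in which each
#' planted node's neighborhood is perturbed as described in
#' [simulation_spec()]. All other edges are untouched.
#'
#' @param spec A [simulation_spec()].
#' @return List with `network` (a two-layer [multiplex_network()], layers
#'   `"layer1"` and `"layer2"`) and `planted` (character vector of
#'   perturbed node ids, sorted).
#' @export
generate_multiplex <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    ids <- sprintf("n%04d", seq_len(n))
    W1 <- matrix(0, n, n, dimnames = list(ids, ids))
    ut <- which(upper.tri(W1), arr.ind = TRUE)
    present <- runif(nrow(ut)) < spec$edge_density
    w <- draw_weights(spec, sum(present))
    W1[ut[present, , drop = FALSE]] <- w
    W1[lower.tri(W1)] <- t(W1)[lower.tri(W1)]

    planted <- sort_c(sample(ids, spec$n_planted))
    W2 <- W1
    for (v in planted) {
      vi <- match(v, ids)
      nbr <- which(W2[vi, ] > 0)
      deg <- length(nbr)
      m_v <- round(spec$perturbation_strength * deg)
      if (m_v == 0) next
      # rewire: remove t edges, add t new ones (degree preserved exactly)
      non_nbr <- setdiff(which(W2[vi, ] == 0), vi)
      t_v <- min(round(m_v / 2), deg, length(non_nbr))
      if (t_v > 0) {
        drop_idx <- nbr[sample.int(deg, t_v)]
        add_idx <- non_nbr[sample.int(length(non_nbr), t_v)]
        W2[vi, drop_idx] <- 0; W2[drop_idx, vi] <- 0
        w_new <- draw_weights(spec, t_v)
        W2[vi, add_idx] <- w_new; W2[add_idx, vi] <- w_new
        nbr <- setdiff(nbr, drop_idx)
      }
      # redraw weights on (up to) m_v surviving edges
      k_rw <- min(m_v, length(nbr))
      if (k_rw > 0) {
        rw_idx <- nbr[sample.int(length(nbr), k_rw)]
        w_rw <- draw_weights(spec, k_rw)
        W2[vi, rw_idx] <- w_rw; W2[rw_idx, vi] <- w_rw
      }
    }
    list(network = multiplex_network(list(layer1 = W1, layer2 = W2), ids),
         planted = planted)
  })
}

#' Ranking AUC of planted-node recovery
#'
#' Probability that a randomly chosen planted node scores higher than a
#' randomly chosen unplanted node (ties count 1/2), computed by exhaustive
#' pair counting. `scores` must be "larger = more likely planted" (e.g.,
#' a distance, or `-p_combined`).
#'
#' @param scores Named numeric vector (names = node ids) or plain vector
#'   aligned with `node_ids`.
#' @param planted Character vector of planted node ids.
#' @param node_ids Node ids aligned with `scores` when `scores` is unnamed.
#' @return AUC in \[0, 1\].
#' @export
ranking_auc <- function(scores, planted, node_ids = names(scores)) {
  if (is.null(node_ids)) abort_validation("node ids are required for AUC")
  is_pl <- node_ids %in% planted
  if (!any(is_pl) || all(is_pl)) abort_validation("need both planted and unplanted nodes")
  pos <- scores[is_pl]; neg <- scores[!is_pl]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

#' Detection metrics for a significance table against planted truth
#'
#' @param table A `significance_table` covering all simulated nodes.
#' @param planted Character vector of planted node ids.
#' @param alpha Rejection threshold on `p_adjusted`. Default 0.05.
#' @return List with `power` (fraction of planted nodes detected),
#'   `type_i_error` (fraction of unplanted nodes rejected) and `auc`
#'   (pair-counting AUC of the `p_combined` ranking).
#' @export
evaluate_detection <- function(table, planted, alpha = 0.05) {
  stopifnot(inherits(table, "significance_table"))
  if (!all(planted %in% table$node)) {
    abort_validation(paste0("truth/table node mismatch: ",
                            paste(setdiff(planted, table$node), collapse = ", ")))
  }
  if (alpha < 0 || alpha > 1) abort_validation("alpha must lie in [0, 1]")
  is_pl <- table$node %in% planted
  list(power = mean(table$p_adjusted[is_pl] < alpha),
       type_i_error = mean(table$p_adjusted[!is_pl] < alpha),
       auc = ranking_auc(-table$p_combined, planted, table$node))
}

#' Write a simulated multiplex and its planted truth to files
#'
#' Writes the two layers in edge-list format plus `truth.tsv` with columns
#' `node`, `planted` (0/1).
#'
#' @param sim Result of [generate_multiplex()].
#' @param dir Output directory.
#' @return Invisibly, the vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_multiplex(sim$network, dir, "edgelist_tsv")
  truth_path <- file.path(dir, "truth.tsv")
  truth <- data.frame(node = sim$network$node_ids,
                      planted = as.integer(sim$network$node_ids %in% sim$planted))
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, truth = truth_path))
}
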