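# Phase II: permutation null models, empirical p-values, phenotype
# association tests, Fisher combination across training repeats and
# multiple-testing adjustment.

#' Permute a weighted network
#'
#' Two null models: `"weight_shuffle"` permutes the upper-triangle weights
#' uniformly among all node pairs (the weight multiset is preserved
#' exactly); `"degree_preserving"` performs weighted double-edge swaps on
#' the nonzero edges (each swap exchanges endpoint pairs and carries the
#' weights along), preserving every node's binarized degree exactly.
#'
#' @param W Symmetric weight matrix with zero diagonal.
#' @param method `"weight_shuffle"` or `"degree_preserving"`.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param n_swaps Number of successful swaps for `"degree_preserving"`;
#'   default 10 per edge.
#' @return Permuted symmetric weight matrix.
#' @export
permute_network <- function(W, method = c("weight_shuffle", "degree_preserving"),
                            seed = NULL, n_swaps = NULL) {
  method <- match.arg(method)
  W <- as.matrix(W)
  if (max(abs(W - t(W))) > 1e-9) abort_validation("W must be symmetric")
  if (any(diag(W) != 0)) abort_validation("W must have a zero diagonal")
  run <- function() {
    if (method == "weight_shuffle") permute_weight_shuffle(W) else permute_degree_preserving(W, n_swaps)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

permute_weight_shuffle <- function(W) {
  ut <- upper.tri(W)
  out <- W
  out[ut] <- sample(W[ut])
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

permute_degree_preserving <- function(W, n_swaps = NULL) {
  n <- nrow(W)
  edges <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  n_edges <- nrow(edges)
  if (n_edges >= n * (n - 1) / 2) {
    abort_validation(paste0("degree-preserving rewiring is impossible on a complete graph ",
                            "(no legal swaps); use method = 'weight_shuffle'"))
  }
  if (n_edges < 2) abort_validation("degree-preserving rewiring needs >= 2 edges")
  target <- n_swaps %||% (10L * n_edges)
  adj <- W != 0
  elist <- cbind(edges[, 1], edges[, 2])
  wts <- W[edges]
  done <- 0L
  attempts <- 0L
  max_attempts <- 200L * target
  while (done < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    ij <- sample.int(n_edges, 2)
    a <- elist[ij[1], 1]; b <- elist[ij[1], 2]
    c_ <- elist[ij[2], 1]; d <- elist[ij[2], 2]
    # randomly orient the second edge so both swap patterns are reachable
    if (runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    if (length(unique(c(a, b, c_, d))) < 4) next
    if (adj[a, d] || adj[c_, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c_, d] <- adj[d, c_] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c_, b] <- adj[b, c_] <- TRUE
    elist[ij[1], ] <- c(a, d)
    elist[ij[2], ] <- c(c_, b)
    done <- done + 1L
  }
  if (done == 0L) {
    abort_validation(paste0("degree-preserving rewiring found no legal swap ",
                            "(graph too dense); use method = 'weight_shuffle'"))
  }
  out <- matrix(0, n, n, dimnames = dimnames(W))
  for (e in seq_len(n_edges)) {
    i <- elist[e, 1]; j <- elist[e, 2]
    out[i, j] <- wts[e]
    out[j, i] <- wts[e]
  }
  out
}

#' Embed a multiplex jointly with permuted copies and pool null distances
#'
#' Generates `n_perm` permuted two-layer networks (each layer permuted
#' independently), stacks their node rows with the real layers into a
#' single [train_ednn()] call so real and null instances share one
#' embedding space, then pools the between-layer node distances of all
#' permuted pairs into the null distribution. The real layers' observed
#' distances, measured in the same space, are attached as `$observed`.
#'
#' @param net A [multiplex_network()] (its first two layers, or
#'   `layers`, are compared).
#' @param n_perm Number of permuted network pairs (>= 1).
#' @param config An [embedding_config()]; `config$seed` drives training.
#' @param method Permutation null model, see [permute_network()].
#' @param seed Integer seed for the permutations.
#' @param layers Optional character(2) designating the layer pair.
#' @param per_node If `TRUE`, null distances are additionally kept per node
#'   (matrix `n_perm` x n in `$per_node`) instead of only pooled.
#' @return An object of class `null_distribution`: list with `distances`
#'   (pooled, length `n_perm * n`), `m`, `observed` (a `distance_table`)
#'   and optionally `per_node`.
#' @export
build_null <- function(net, n_perm, config = embedding_config(),
                       method = c("weight_shuffle", "degree_preserving"),
                       seed = 1, layers = NULL, per_node = FALSE) {
  stopifnot(inherits(net, "multiplex_network"))
  method <- match.arg(method)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1) abort_validation("n_perm must be >= 1")
  layers <- resolve_layer_pair(net, layers)
  Wa <- layer_matrix(net, layers[1])
  Wb <- layer_matrix(net, layers[2])

  mats <- list(Wa, Wb)
  names(mats) <- c(".real.a", ".real.b")
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      mats[[sprintf(".perm%d.a", p)]] <- permute_network(Wa, method)
      mats[[sprintf(".perm%d.b", p)]] <- permute_network(Wb, method)
    }
  })
  st <- stack_instances(mats, config)
  emb <- train_ednn(st$features, st$targets, config,
                    layers = st$layers, nodes = st$nodes)

  observed <- node_distances(emb, ".real.a", ".real.b")
  observed$node <- net$node_ids  # rows are in node order by construction
  null_mat <- matrix(NA_real_, nrow = n_perm, ncol = length(net$node_ids))
  for (p in seq_len(n_perm)) {
    dp <- node_distances(emb, sprintf(".perm%d.a", p), sprintf(".perm%d.b", p))
    null_mat[p, ] <- dp$distance
  }
  distances <- as.vector(null_mat)
  structure(list(distances = distances, m = length(distances),
                 observed = observed,
                 per_node = if (per_node) null_mat else NULL,
                 method = method, n_perm = n_perm),
            class = "null_distribution")
}

#' Empirical one-sided p-value against a null distance distribution
#'
#' Large distances indicate neighborhood variation, so the p-value is the
#' add-one-corrected upper-tail frequency
#' `(1 + #\{null >= d\}) / (1 + m)`, always in (0, 1].
#'
#' @param d Observed distance(s), finite numeric.
#' @param null A `null_distribution` or a numeric vector of null distances.
#' @return Numeric vector of p-values, same length as `d`.
#' @export
empirical_p <- function(d, null) {
  if (inherits(null, "null_distribution")) null <- null$distances
  null <- as.numeric(null)
  if (length(null) == 0) abort_validation("the null distribution is empty")
  if (any(!is.finite(d))) abort_validation("observed distances must be finite")
  vapply(d, function(x) (1 + sum(null >= x)) / (1 + length(null)), numeric(1))
}

#' Fisher's combined probability
#'
#' Combines R p-values via `X = -2 * sum(log(p))`, referred to the
#' upper tail of a chi-square distribution with `2R` degrees of freedom.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return A single combined p-value.
#' @export
fisher_combine <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (length(pvals) < 1) abort_validation("at least one p-value is required")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort_validation("all p-values must lie in (0, 1]")
  }
  X <- -2 * sum(log(pvals))
  stats::pchisq(X, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Multiple-testing adjustment
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param method `"bh"` (Benjamini-Hochberg, default), `"bonferroni"`,
#'   `"holm"` or `"none"`.
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_p <- function(pvals, method = c("bh", "bonferroni", "holm", "none")) {
  if (length(method) != 1 || !method %in% c("bh", "bonferroni", "holm", "none")) {
    abort_validation("method must be one of bh, bonferroni, holm, none")
  }
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort_validation("all p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = c(bh = "BH", bonferroni = "bonferroni",
                                    holm = "holm", none = "none")[[method]])
}

#' Wilcoxon rank-sum association test for a binary phenotype
#'
#' Two-sided test of whether per-individual distances differ between the
#' two phenotype groups; exact distribution for small tie-free samples,
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param distances Numeric vector of per-individual distances.
#' @param groups Binary group labels (factor/character/numeric, 2 levels).
#' @return Two-sided p-value.
#' @export
wilcoxon_test <- function(distances, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) abort_validation("groups must have exactly 2 levels")
  if (length(distances) != length(groups)) abort_validation("distances and groups differ in length")
  x <- distances[groups == levels(groups)[1]]
  y <- distances[groups == levels(groups)[2]]
  if (length(x) < 2 || length(y) < 2) abort_validation("each group needs >= 2 individuals")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 10
  p <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                           exact = exact, correct = TRUE)$p.value)
  # fully tied data has a degenerate rank-sum distribution: no separation
  if (is.nan(p)) p <- 1
  p
}

#' Kendall rank-correlation association test for a continuous phenotype
#'
#' Kendall's tau (tau-b under ties) between per-individual distances and
#' the phenotype, with a two-sided p-value (exact for small tie-free
#' samples, normal approximation otherwise).
#'
#' @param distances Numeric vector of per-individual distances (>= 4).
#' @param phenotype Numeric phenotype values.
#' @return List with elements `tau` and `p_value`.
#' @export
kendall_test <- function(distances, phenotype) {
  if (length(distances) != length(phenotype)) abort_validation("distances and phenotype differ in length")
  if (length(distances) < 4) abort_validation("at least 4 individuals are required")
  if (length(unique(phenotype)) < 2) abort_validation("phenotype is constant; tau is undefined")
  ties <- anyDuplicated(distances) > 0 || anyDuplicated(phenotype) > 0
  exact <- !ties && length(distances) <= 8
  ct <- suppressWarnings(stats::cor.test(distances, phenotype, method = "kendall",
                                         alternative = "two.sided", exact = exact))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}

node_rank_order <- function(p, mean_distance, node) {
  order(p, -mean_distance, match(node, sort_c(node)))
}

make_significance_table <- function(node, mean_distance, p_per_repeat,
                                    adjust_method, metadata) {
  p_combined <- apply(p_per_repeat, 1, fisher_combine)
  p_adjusted <- adjust_p(p_combined, adjust_method)
  ord <- node_rank_order(p_combined, mean_distance, node)
  tab <- data.frame(node = node[ord], mean_distance = mean_distance[ord],
                    p_combined = p_combined[ord], p_adjusted = p_adjusted[ord],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "p_per_repeat") <- p_per_repeat[ord, , drop = FALSE]
  attr(tab, "metadata") <- metadata
  class(tab) <- c("significance_table", "data.frame")
  tab
}

#' Scenario I: which nodes' neighborhoods differ between two conditions?
#'
#' For each training repeat r (seeded `seed + r - 1`), the two real layers
#' and `n_perm` permuted copies are embedded jointly, per-node observed
#' distances are referred to the pooled null distances for an empirical
#' p-value, and the R repeat p-values are combined per node with Fisher's
#' method, then adjusted across nodes. Repeats average out the randomness
#' of neural-network initialisation.
#'
#' @param net A [multiplex_network()] with (at least) two layers.
#' @param config An [embedding_config()].
#' @param n_perm Permuted network pairs per repeat. Default 100.
#' @param repeats Number of training repeats R. Default 50.
#' @param null_method Permutation null model, see [permute_network()].
#' @param adjust_method See [adjust_p()]. Default `"bh"`.
#' @param seed Master seed.
#' @param layers Optional character(2) designating the layer pair.
#' @param per_node_null If `TRUE`, each node's p-value uses only its own
#'   permuted distances instead of the pooled null.
#' @return A `significance_table`: data frame with columns `node`,
#'   `mean_distance`, `p_combined`, `p_adjusted`, sorted by `p_combined`
#'   (ties: larger mean distance, then node id); per-repeat p-values and
#'   run metadata in attributes.
#' @export
scenario1 <- function(net, config = embedding_config(), n_perm = 100,
                      repeats = 50, null_method = "weight_shuffle",
                      adjust_method = "bh", seed = 1, layers = NULL,
                      per_node_null = FALSE) {
  stopifnot(inherits(net, "multiplex_network"))
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1) abort_validation("repeats must be >= 1")
  layers <- resolve_layer_pair(net, layers)
  n <- n_nodes(net)
  p_mat <- matrix(NA_real_, nrow = n, ncol = repeats)
  d_mat <- matrix(NA_real_, nrow = n, ncol = repeats)
  m <- NA_integer_
  for (r in seq_len(repeats)) {
    rep_seed <- seed + r - 1L
    cfg <- config
    cfg$seed <- as.integer(rep_seed)
    nl <- build_null(net, n_perm, cfg, null_method, seed = rep_seed,
                     layers = layers, per_node = per_node_null)
    d_mat[, r] <- nl$observed$distance
    if (per_node_null) {
      p_mat[, r] <- vapply(seq_len(n), function(i) {
        empirical_p(nl$observed$distance[i], nl$per_node[, i])
      }, numeric(1))
    } else {
      p_mat[, r] <- empirical_p(nl$observed$distance, nl)
    }
    m <- nl$m
  }
  metadata <- list(scenario = "scenario1", layers = layers,
                   null_method = null_method, n_perm = as.integer(n_perm),
                   repeats = repeats, m = m, adjust_method = adjust_method,
                   per_node_null = per_node_null, seed = seed, config = config)
  make_significance_table(net$node_ids, rowMeans(d_mat), p_mat,
                          adjust_method, metadata)
}

#' Scenario II: which nodes' neighborhood variation tracks a phenotype?
#'
#' Takes one two-layer multiplex per individual (all over the same node
#' set). Per repeat, every individual's two layers are embedded jointly in
#' one shared space, a per-individual between-layer distance is computed
#' for each node, and each node's distances are tested for association
#' with the phenotype (Wilcoxon rank-sum for binary, Kendall's tau for
#' continuous). Repeat p-values are Fisher-combined and adjusted across
#' nodes.
#'
#' @param nets Named list of [multiplex_network()]s, one per individual;
#'   names are the individual ids matched against `phenotype`.
#' @param phenotype A [phenotype_table()] covering all individuals.
#' @param config An [embedding_config()].
#' @param repeats Number of training repeats R. Default 50.
#' @param adjust_method See [adjust_p()].
#' @param seed Master seed.
#' @param layers Optional character(2) designating the layer pair (shared
#'   by all individuals).
#' @return A `significance_table` (see [scenario1()]); `mean_distance` is
#'   the node's distance averaged over individuals and repeats. The
#'   per-individual distance matrix of the last repeat is kept in
#'   `attr(, "individual_distances")`.
#' @export
scenario2 <- function(nets, phenotype, config = embedding_config(),
                      repeats = 50, adjust_method = "bh", seed = 1,
                      layers = NULL) {
  if (!is.list(nets) || length(nets) < 4) {
    abort_validation("scenario2 needs a named list of >= 4 individual networks")
  }
  if (is.null(names(nets)) || any(!nzchar(names(nets)))) {
    abort_validation("nets must be named by individual id")
  }
  stopifnot(inherits(phenotype, "phenotype_table"))
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1) abort_validation("repeats must be >= 1")
  ref_nodes <- nets[[1]]$node_ids
  bad <- names(nets)[!vapply(nets, function(m) identical(m$node_ids, ref_nodes), logical(1))]
  if (length(bad) > 0) {
    abort_validation(paste0("individuals with mismatching node sets: ",
                            paste(bad, collapse = ", ")))
  }
  missing <- setdiff(names(nets), phenotype$sample_ids)
  if (length(missing) > 0) {
    abort_validation(paste0("phenotype is missing individuals: ",
                            paste(missing, collapse = ", ")))
  }
  pheno <- phenotype$values[match(names(nets), phenotype$sample_ids)]
  layers <- resolve_layer_pair(nets[[1]], layers)
  for (id in names(nets)) resolve_layer_pair(nets[[id]], layers)

  n <- length(ref_nodes)
  n_ind <- length(nets)
  p_mat <- matrix(NA_real_, nrow = n, ncol = repeats)
  d_accum <- matrix(0, nrow = n_ind, ncol = n)
  d_ind <- NULL
  for (r in seq_len(repeats)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r - 1L)
    mats <- list()
    for (id in names(nets)) {
      mats[[paste0(id, "\r", layers[1])]] <- layer_matrix(nets[[id]], layers[1])
      mats[[paste0(id, "\r", layers[2])]] <- layer_matrix(nets[[id]], layers[2])
    }
    st <- stack_instances(mats, cfg)
    emb <- train_ednn(st$features, st$targets, cfg,
                      layers = st$layers, nodes = st$nodes)
    d_ind <- matrix(NA_real_, nrow = n_ind, ncol = n,
                    dimnames = list(names(nets), ref_nodes))
    for (i in seq_len(n_ind)) {
      id <- names(nets)[i]
      dt <- node_distances(emb, paste0(id, "\r", layers[1]),
                           paste0(id, "\r", layers[2]))
      d_ind[i, ] <- dt$distance
    }
    d_accum <- d_accum + d_ind
    for (v in seq_len(n)) {
      p_mat[v, r] <- if (phenotype$kind == "binary") {
        wilcoxon_test(d_ind[, v], pheno)
      } else {
        kendall_test(d_ind[, v], pheno)$p_value
      }
    }
  }
  metadata <- list(scenario = "scenario2", layers = layers,
                   test = if (phenotype$kind == "binary") "wilcoxon" else "kendall",
                   repeats = repeats, n_individuals = n_ind,
                   adjust_method = adjust_method, seed = seed, config = config)
  tab <- make_significance_table(ref_nodes, colMeans(d_accum / repeats), p_mat,
                                 adjust_method, metadata)
  attr(tab, "individual_distances") <- d_ind
  tab
}

#' Write a significance table as TSV
#'
#' Columns `node`, `mean_distance`, `p_combined`, `p_adjusted`, plus one
#' `p_rep<r>` column per repeat when `verbose_repeats = TRUE`. A JSON
#' sidecar describing the run can be written with [write_run_sidecar()].
#'
#' @param tab A `significance_table`.
#' @param path Output path.
#' @param verbose_repeats Include per-repeat p-value columns.
#' @return Invisibly, `path`.
#' @export
write_significance <- function(tab, path, verbose_repeats = FALSE) {
  df <- as.data.frame(tab)
  if (verbose_repeats) {
    pr <- attr(tab, "p_per_repeat")
    colnames(pr) <- paste0("p_rep", seq_len(ncol(pr)))
    df <- cbind(df, pr)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
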