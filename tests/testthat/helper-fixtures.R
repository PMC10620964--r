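# Shared fixture builders. Everything is generated in code; no data files.

# Small embedding config for tests whose point is not convergence quality.
fast_config <- function(seed = 1, ...) {
  embedding_config(seed = seed, epochs = 40, ...)
}

# Deterministic little expression matrix.
toy_expression <- function(n_genes = 5, n_samples = 6, seed = 42) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples, mean = 5), n_genes, n_samples)
  expression_matrix(vals, paste0("g", seq_len(n_genes)),
                    paste0("s", seq_len(n_samples)))
}

# Hand-built 2-layer multiplex over nodes A..D.
toy_multiplex <- function() {
  ids <- c("A", "B", "C", "D")
  W1 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  W1["A", "B"] <- W1["B", "A"] <- 0.7
  W1["B", "C"] <- W1["C", "B"] <- 0.4
  W1["C", "D"] <- W1["D", "C"] <- 0.2
  W2 <- W1
  W2["C", "D"] <- W2["D", "C"] <- 0.9
  multiplex_network(list(base = W1, cond = W2), ids)
}

# Random symmetric weight matrix in [0,1], zero diagonal.
random_weight_matrix <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  ut <- which(upper.tri(W), arr.ind = TRUE)
  on <- runif(nrow(ut)) < density
  W[ut[on, , drop = FALSE]] <- runif(sum(on))
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

# Build a node_embedding object directly (bypassing training) for
# distance-metric unit tests.
manual_embedding <- function(coords, layers, nodes,
                             metric = "cosine") {
  structure(list(coords = coords, layers = layers, nodes = nodes,
                 loss_initial = NA_real_, loss_final = NA_real_,
                 epochs_run = 0L,
                 config = embedding_config(distance_metric = metric)),
            class = "node_embedding")
}

# Exhaustive Wilcoxon rank-sum enumeration: two-sided p for tie-free data.
wilcoxon_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  stat <- sum(rank(pooled)[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  stats <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(stat - mu))
}

# Exhaustive Kendall tau and permutation-null two-sided p.
kendall_enum <- function(x, y) {
  n <- length(x)
  tau_of <- function(a, b) {
    s <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
    }
    s / choose(n, 2)
  }
  tau <- tau_of(x, y)
  perms <- gtools_permutations(n)
  taus <- apply(perms, 1, function(p) tau_of(x, y[p]))
  list(tau = tau, p = mean(abs(taus) >= abs(tau) - 1e-12))
}

# All permutations of 1..n (tiny n only).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1
  for (k in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- setdiff(seq_len(n), k)
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1
    }
  }
  out
}
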