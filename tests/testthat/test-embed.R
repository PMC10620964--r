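# Representation learning: features, walk targets, training, distances.

test_that("node features are the adjacency rows in node order", {
  net <- toy_multiplex()
  F1 <- node_features(net, "base")
  expect_equal(F1["A", ], c(A = 0, B = 0.7, C = 0, D = 0))
  expect_equal(unname(rowSums(F1)), unname(rowSums(net$layers$base)))
  expect_error(node_features(net, "nope"), "unknown layer",
               class = "mplexvar_validation_error")

  empty <- multiplex_network(list(z = matrix(0, 3, 3,
                                             dimnames = list(letters[1:3], letters[1:3]))))
  expect_true(all(node_features(empty, "z") == 0))
})

test_that("random-walk targets match exhaustive walk enumeration", {
  # path A - B - C with unit weights
  ids <- c("A", "B", "C")
  W <- matrix(0, 3, 3, dimnames = list(ids, ids))
  W["A", "B"] <- W["B", "A"] <- 1
  W["B", "C"] <- W["C", "B"] <- 1
  P2 <- random_walk_targets(W, 2)
  # from A: A->B (p=1) then B->A or B->C (p=1/2 each)
  expect_equal(P2["A", ], c(A = 0.5, B = 0, C = 0.5))

  # two nodes, one edge: even L returns, odd L crosses
  W2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(random_walk_targets(W2, 2)["A", ], c(A = 1, B = 0))
  expect_equal(random_walk_targets(W2, 3)["A", ], c(A = 0, B = 1))

  expect_equal(random_walk_targets(W, 0), diag(3), ignore_attr = TRUE)
  expect_error(random_walk_targets(-W, 1), "nonnegative",
               class = "mplexvar_validation_error")
})

test_that("walk targets conserve probability for arbitrary graphs", {
  for (s in 1:5) {
    W <- random_weight_matrix(7, density = 0.4, seed = s)
    W[3, ] <- 0; W[, 3] <- 0   # force an isolated node
    for (L in c(0, 1, 4)) {
      P <- random_walk_targets(W, L)
      expect_equal(unname(rowSums(P)), rep(1, 7), tolerance = 1e-9)
      expect_true(all(P >= 0))
    }
    expect_equal(random_walk_targets(W, 2)[3, 3], 1)  # isolated node stays
  }
})

test_that("exact walk targets agree with sampled walk frequencies", {
  W <- random_weight_matrix(5, density = 0.8, seed = 9)
  L <- 3
  P <- random_walk_targets(W, L)
  n_walk <- 100000
  set.seed(1)
  trans <- random_walk_targets(W, 1)
  for (start in 1:5) {
    cur <- rep(start, n_walk)
    for (step in seq_len(L)) {
      nxt <- integer(n_walk)
      for (s in unique(cur)) {
        idx <- cur == s
        nxt[idx] <- sample.int(5, sum(idx), replace = TRUE, prob = trans[s, ])
      }
      cur <- nxt
    }
    counts <- tabulate(cur, 5)
    # multinomial goodness of fit of the sampled reach frequencies
    # against the exact distribution (one test per start node)
    keep <- P[start, ] > 0
    expect_true(all(counts[!keep] == 0))
    gof <- stats::chisq.test(counts[keep], p = P[start, keep] / sum(P[start, keep]))
    expect_gt(gof$p.value, 1e-3)
  }
})

test_that("training is seed-deterministic and identical rows embed identically", {
  W <- random_weight_matrix(12, density = 0.5, seed = 2)
  net <- multiplex_network(list(l1 = W, l2 = W))
  cfg <- fast_config(seed = 5)
  emb1 <- embed_multiplex(net, cfg)
  emb2 <- embed_multiplex(net, cfg)
  expect_identical(emb1$coords, emb2$coords)
  expect_lte(emb1$loss_final, emb1$loss_initial)
  # identical layers: the two instances of each node coincide exactly
  A <- emb1$coords[emb1$layers == "l1", ]
  B <- emb1$coords[emb1$layers == "l2", ]
  expect_identical(A, B)
  d <- node_distances(emb1, "l1", "l2")
  expect_identical(d$distance, rep(0, 12))
})

test_that("training inputs are validated", {
  X <- matrix(runif(20), 4, 5)
  bad <- X; bad[1, 1] <- 1.7
  expect_error(train_ednn(X, bad, fast_config()), "\\[0, 1\\]",
               class = "mplexvar_validation_error")
  expect_error(train_ednn(X[, 1:2], X[, 1:2], embedding_config(k = 2, epochs = 5)),
               "smaller than", class = "mplexvar_validation_error")
})

test_that("cosine distances match the closed form", {
  coords <- rbind(c(1, 2), c(1, 2),      # node x: identical
                  c(1, 0), c(0, 1),      # node y: orthogonal
                  c(1, 0), c(1, 1))      # node z: 45 degrees
  emb <- manual_embedding(coords, rep(c("a", "b"), 3),
                          rep(c("x", "y", "z"), each = 2))
  d <- node_distances(emb, "a", "b")
  expect_equal(d$distance[d$node == "x"], 0)
  expect_equal(d$distance[d$node == "y"], 1)
  expect_equal(d$distance[d$node == "z"], 1 - 1 / sqrt(2), tolerance = 1e-12)

  de <- node_distances(emb, "a", "b", metric = "euclidean")
  expect_equal(de$distance[de$node == "z"], 1)
})

test_that("cosine distances are invariant to positive per-layer rescaling", {
  set.seed(3)
  coords <- matrix(rnorm(20), 10, 2)
  layers <- rep(c("a", "b"), 5)
  nodes <- rep(paste0("n", 1:5), each = 2)
  emb <- manual_embedding(coords, layers, nodes)
  scaled <- coords
  scaled[layers == "a", ] <- scaled[layers == "a", ] * 37.5
  emb_s <- manual_embedding(scaled, layers, nodes)
  expect_equal(node_distances(emb, "a", "b")$distance,
               node_distances(emb_s, "a", "b")$distance, tolerance = 1e-12)
})

test_that("zero-norm vectors give cosine distance 1 with a warning", {
  emb <- manual_embedding(rbind(c(0, 0), c(1, 1)), c("a", "b"), c("n", "n"))
  expect_warning(d <- node_distances(emb, "a", "b"), "zero-norm")
  expect_equal(d$distance, 1)
})

test_that("perturbed nodes separate from unperturbed ones by distance", {
  sim <- generate_multiplex(simulation_spec(n = 60, n_planted = 6,
                                            perturbation_strength = 0.9, seed = 4))
  emb <- embed_multiplex(sim$network, embedding_config(seed = 4))
  d <- node_distances(emb, "layer1", "layer2")
  planted <- d$node %in% sim$planted
  expect_gt(mean(d$distance[planted]), mean(d$distance[!planted]))
})
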