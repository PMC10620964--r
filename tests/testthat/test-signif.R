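# Null models, p-values, combination, adjustment and the two scenarios.

test_that("weight shuffle conserves the weight multiset and is seeded", {
  W <- random_weight_matrix(15, density = 0.4, seed = 6)
  P1 <- permute_network(W, "weight_shuffle", seed = 3)
  P2 <- permute_network(W, "weight_shuffle", seed = 3)
  expect_identical(P1, P2)
  expect_equal(sort(P1[upper.tri(P1)]), sort(W[upper.tri(W)]))
  expect_identical(P1, t(P1))
  expect_true(all(diag(P1) == 0))
  expect_false(identical(P1, W))
})

test_that("degree-preserving rewiring keeps degrees and weights", {
  W <- random_weight_matrix(20, density = 0.3, seed = 8)
  P <- permute_network(W, "degree_preserving", seed = 2)
  expect_equal(rowSums(P != 0), rowSums(W != 0))
  expect_equal(sort(P[upper.tri(P) & P != 0]), sort(W[upper.tri(W) & W != 0]))
  expect_identical(P, t(P))

  complete <- matrix(0.5, 4, 4); diag(complete) <- 0
  dimnames(complete) <- list(letters[1:4], letters[1:4])
  expect_error(permute_network(complete, "degree_preserving", seed = 1),
               "weight_shuffle", class = "mplexvar_validation_error")
})

test_that("identical permutations of identical layers stay identical", {
  W <- random_weight_matrix(10, density = 0.5, seed = 10)
  expect_identical(permute_network(W, "weight_shuffle", seed = 7),
                   permute_network(W, "weight_shuffle", seed = 7))
  expect_identical(permute_network(W, "degree_preserving", seed = 7),
                   permute_network(W, "degree_preserving", seed = 7))
})

test_that("build_null pools n_perm x n distances and embeds jointly", {
  W <- random_weight_matrix(10, density = 0.5, seed = 12)
  net <- multiplex_network(list(a = W, b = permute_network(W, "weight_shuffle", seed = 1)))
  nl <- build_null(net, n_perm = 2, fast_config(seed = 2), "weight_shuffle", seed = 2)
  expect_s3_class(nl, "null_distribution")
  expect_equal(nl$m, 20)
  expect_true(all(is.finite(nl$distances)) && all(nl$distances >= 0))
  expect_equal(nrow(nl$observed), 10)

  pn <- build_null(net, n_perm = 3, fast_config(seed = 2), "weight_shuffle",
                   seed = 2, per_node = TRUE)
  expect_equal(dim(pn$per_node), c(3, 10))
  expect_equal(sort(as.vector(pn$per_node)), sort(pn$distances))
})

test_that("empirical p-values match direct counting and are monotone", {
  null <- c(1, 2, 3)
  expect_equal(empirical_p(2, null), 0.75)        # (1 + 2) / 4, tie counts
  expect_equal(empirical_p(99, rep(0.5, 99)), 0.01)
  expect_equal(empirical_p(0.1, null), 1)
  expect_error(empirical_p(1, numeric(0)), "empty",
               class = "mplexvar_validation_error")

  set.seed(4)
  null2 <- runif(57)
  d <- sort(runif(20))
  p <- empirical_p(d, null2)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("Fisher combination matches the chi-square closed form", {
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  expect_equal(fisher_combine(0.2), 0.2, tolerance = 1e-12)  # df=2 identity
  # p = (0.5, 0.5): X = 2.7726, df = 4, survival = (1 + X/2) exp(-X/2)
  X <- -2 * log(0.25)
  expect_equal(fisher_combine(c(0.5, 0.5)), (1 + X / 2) * exp(-X / 2),
               tolerance = 1e-12)
  expect_equal(round(fisher_combine(c(0.5, 0.5)), 4), 0.5966)

  set.seed(9)
  p <- runif(6)
  expect_equal(fisher_combine(p), fisher_combine(sample(p)), tolerance = 1e-15)
  p2 <- p; p2[3] <- p2[3] / 2
  expect_lte(fisher_combine(p2), fisher_combine(p))
  expect_error(fisher_combine(c(0.5, 0)), class = "mplexvar_validation_error")
})

test_that("p-value adjustment reproduces hand-computed vectors", {
  expect_equal(adjust_p(c(0.01, 0.02), "bonferroni"), c(0.02, 0.04))
  expect_equal(adjust_p(c(0.01, 0.02, 0.03, 0.04), "bh"), rep(0.04, 4))
  expect_equal(adjust_p(c(0.01, 0.04, 0.03), "holm"),
               c(0.03, 0.06, 0.06))
  expect_identical(adjust_p(c(0.2, 0.7), "none"), c(0.2, 0.7))
  expect_error(adjust_p(0.5, "fdr"), class = "mplexvar_validation_error")

  # BH: component-wise monotone, identity on constant vectors
  set.seed(2)
  p <- runif(10)
  adj <- adjust_p(p, "bh")
  p_up <- p; p_up[4] <- min(1, p_up[4] * 1.5)
  expect_true(all(adjust_p(p_up, "bh") >= adj - 1e-12))
  expect_equal(adjust_p(rep(0.3, 5), "bh"), rep(0.3, 5))
})

test_that("rank-sum test matches exhaustive enumeration on small samples", {
  expect_equal(wilcoxon_test(c(1, 2, 3, 4), c("a", "a", "b", "b")), 1 / 3,
               tolerance = 1e-12)
  expect_equal(wilcoxon_test(c(5, 5, 5, 5), c(0, 0, 1, 1)), 1)
  x <- c(1.2, 3.4, 0.7); y <- c(2.2, 5.1, 4.4, 0.1)
  g <- rep(c("A", "B"), c(3, 4))
  expect_equal(wilcoxon_test(c(x, y), g), wilcoxon_enum_p(x, y), tolerance = 1e-12)
  # label swap symmetry
  swapped <- ifelse(g == "A", "B", "A")
  expect_equal(wilcoxon_test(c(x, y), g), wilcoxon_test(c(x, y), swapped))
  expect_error(wilcoxon_test(1:3, c("a", "b", "b")), ">= 2",
               class = "mplexvar_validation_error")
})

test_that("Kendall test matches exhaustive pair counting and permutation null", {
  expect_equal(kendall_test(1:4, c(10, 20, 30, 40))$tau, 1)
  expect_equal(kendall_test(1:4, c(8, 6, 4, 2))$tau, -1)
  d <- c(1, 2, 3, 4, 5); ph <- c(1, 3, 2, 5, 4)
  oracle <- kendall_enum(d, ph)
  res <- kendall_test(d, ph)
  expect_equal(res$tau, oracle$tau, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  expect_error(kendall_test(1:4, rep(2, 4)), "constant",
               class = "mplexvar_validation_error")
  expect_error(kendall_test(1:3, 1:3), "4 individuals",
               class = "mplexvar_validation_error")
})

test_that("scenario1 on identical layers yields all-ones p-values", {
  W <- random_weight_matrix(12, density = 0.5, seed = 20)
  net <- multiplex_network(list(a = W, b = W))
  tab <- scenario1(net, fast_config(seed = 1), n_perm = 5, repeats = 2, seed = 1)
  expect_s3_class(tab, "significance_table")
  expect_equal(tab$mean_distance, rep(0, 12))
  expect_equal(tab$p_combined, rep(1, 12))
  expect_equal(tab$p_adjusted, rep(1, 12))
})

test_that("a single repeat reduces Fisher combination to the repeat p-value", {
  W <- random_weight_matrix(10, density = 0.5, seed = 21)
  net <- multiplex_network(list(a = W, b = permute_network(W, "weight_shuffle", seed = 5)))
  tab <- scenario1(net, fast_config(seed = 3), n_perm = 10, repeats = 1, seed = 3)
  pr <- attr(tab, "p_per_repeat")
  expect_equal(tab$p_combined, unname(pr[, 1]), tolerance = 1e-12)
  expect_false(is.unsorted(tab$p_combined))
})

test_that("scenario2 with identical groups returns p = 1 everywhere", {
  W <- random_weight_matrix(8, density = 0.6, seed = 22)
  W2 <- random_weight_matrix(8, density = 0.6, seed = 23)
  one <- multiplex_network(list(a = W, b = W2))
  nets <- list(i1 = one, i2 = one, i3 = one, i4 = one)
  ph <- phenotype_table(names(nets), c("x", "x", "y", "y"))
  tab <- scenario2(nets, ph, fast_config(seed = 2), repeats = 2, seed = 2)
  expect_equal(tab$p_combined, rep(1, 8))
  di <- attr(tab, "individual_distances")
  expect_equal(dim(di), c(4, 8))
  expect_true(all(apply(di, 2, function(col) length(unique(col)) == 1)))
})

test_that("scenario2 validates node sets and phenotype coverage", {
  W <- random_weight_matrix(6, density = 0.6, seed = 30)
  small <- random_weight_matrix(5, density = 0.6, seed = 31)
  good <- multiplex_network(list(a = W, b = W))
  bad <- multiplex_network(list(a = small, b = small))
  nets <- list(i1 = good, i2 = good, i3 = bad, i4 = good)
  ph <- phenotype_table(paste0("i", 1:4), c(0, 0, 1, 1))
  expect_error(scenario2(nets, ph, fast_config(), repeats = 1, seed = 1),
               "i3", class = "mplexvar_validation_error")
  nets$i3 <- good
  ph_miss <- phenotype_table(c("i1", "i2", "i3", "zz"), c(0, 0, 1, 1))
  expect_error(scenario2(nets, ph_miss, fast_config(), repeats = 1, seed = 1),
               "i4", class = "mplexvar_validation_error")
})
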