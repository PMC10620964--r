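# Phase I: node feature/target construction, encoder-decoder training and
# between-layer node distances in the shared embedding space.

#' Embedding configuration
#'
#' Bundles the tunable parameters of the representation-learning phase.
#' The encoder-decoder maps each node's n-dimensional neighborhood vector
#' through a `hidden`-unit layer to a `k`-dimensional bottleneck and back;
#' output units are logistic because reconstruction targets live in \[0, 1\].
#'
#' @param k Bottleneck (embedding) dimension. Default 2.
#' @param target_mode What the decoder reconstructs: `"adjacency"` (the
#'   input edge-weight vector itself) or `"random_walk"` (probabilities of
#'   reaching each node after a fixed-length random walk).
#' @param walk_length Number of random-walk steps when
#'   `target_mode = "random_walk"`. Default 3.
#' @param bottleneck_activation `"identity"` (default, a linear bottleneck),
#'   `"tanh"` or `"relu"`. The saturating choices compress distances near
#'   the activation bounds; the linear default trains fastest and separates
#'   perturbed from unperturbed nodes best in the bundled simulations.
#' @param epochs Maximum training epochs (early stopping applies). Default 500.
#' @param learning_rate Adam learning rate. Default 1e-3.
#' @param batch_size Minibatch size. Default 32.
#' @param seed Integer seed controlling weight initialisation and minibatch
#'   shuffling; training is bit-reproducible given the seed.
#' @param distance_metric `"cosine"` (default) or `"euclidean"`.
#' @param hidden Width of the encoder/decoder hidden layers; defaults to
#'   `max(64, 4 * k)`.
#' @param early_stop_tol Training stops once the best full-data loss has
#'   improved by less than this over `patience` consecutive epochs.
#' @param patience Epochs of sub-`early_stop_tol` improvement tolerated
#'   before stopping.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(k = 2,
                             target_mode = c("adjacency", "random_walk"),
                             walk_length = 3,
                             bottleneck_activation = c("identity", "tanh", "relu"),
                             epochs = 500,
                             learning_rate = 1e-3,
                             batch_size = 32,
                             seed = 1,
                             distance_metric = c("cosine", "euclidean"),
                             hidden = NULL, early_stop_tol = 5e-4,
                             patience = 20) {
  target_mode <- match.arg(target_mode)
  bottleneck_activation <- match.arg(bottleneck_activation)
  distance_metric <- match.arg(distance_metric)
  k <- as.integer(k)
  if (is.na(k) || k < 1) abort_validation("k must be a positive integer")
  walk_length <- as.integer(walk_length)
  if (target_mode == "random_walk" && (is.na(walk_length) || walk_length < 1)) {
    abort_validation("walk_length must be >= 1 for random-walk targets")
  }
  if (epochs < 1) abort_validation("epochs must be >= 1")
  if (learning_rate <= 0) abort_validation("learning_rate must be positive")
  if (batch_size < 1) abort_validation("batch_size must be >= 1")
  structure(list(k = k, target_mode = target_mode, walk_length = walk_length,
                 bottleneck_activation = bottleneck_activation,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 distance_metric = distance_metric,
                 hidden = as.integer(hidden %||% max(64L, 4L * k)),
                 early_stop_tol = early_stop_tol, patience = as.integer(patience)),
            class = "embedding_config")
}

#' Node feature matrix of one layer
#'
#' Row v is node v's vector of edge weights to every node of the layer —
#' the model input describing v's neighborhood.
#'
#' @param net A [multiplex_network()].
#' @param layer Layer name.
#' @return n x n numeric matrix, rows in `net$node_ids` order.
#' @export
node_features <- function(net, layer) {
  stopifnot(inherits(net, "multiplex_network"))
  layer_matrix(net, layer)
}

#' Fixed-length random-walk reach probabilities
#'
#' Row v of the result holds the probabilities of standing on each node
#' after an `L`-step random walk started at v, where one step moves to a
#' neighbor with probability proportional to edge weight. Computed exactly
#' as the L-th power of the row-normalised weight matrix; isolated nodes
#' stay put with probability 1.
#'
#' @param W Symmetric nonnegative weight matrix.
#' @param L Walk length (>= 0; `L = 0` gives the identity).
#' @return Row-stochastic matrix of the same dimension as `W`.
#' @export
random_walk_targets <- function(W, L) {
  W <- as.matrix(W)
  if (any(W < 0)) abort_validation("random-walk weights must be nonnegative")
  L <- as.integer(L)
  if (is.na(L) || L < 0) abort_validation("walk length must be >= 0")
  n <- nrow(W)
  P <- matrix(0, n, n, dimnames = dimnames(W))
  strength <- rowSums(W)
  pos <- strength > 0
  P[pos, ] <- W[pos, , drop = FALSE] / strength[pos]
  diag(P)[!pos] <- 1
  out <- diag(n)
  dimnames(out) <- dimnames(W)
  for (step in seq_len(L)) out <- out %*% P
  out
}

layer_targets <- function(W, config) {
  switch(config$target_mode,
         adjacency = W,
         random_walk = random_walk_targets(W, config$walk_length))
}

# Stack per-layer feature and target matrices into one training set with a
# (layer, node) row annotation. `mats` is a named list layer -> weight matrix.
stack_instances <- function(mats, config) {
  feats <- do.call(rbind, unname(mats))
  targs <- do.call(rbind, lapply(unname(mats), layer_targets, config = config))
  nodes <- unlist(lapply(mats, rownames), use.names = FALSE)
  layers <- rep(names(mats), vapply(mats, nrow, integer(1)))
  list(features = feats, targets = targs, layers = layers, nodes = nodes)
}

act_code <- function(a) c(identity = 0L, tanh = 1L, relu = 2L)[[a]]

#' Train the encoder-decoder and embed all (layer, node) instances
#'
#' Trains a fully connected encoder-decoder (input n, hidden layer, k-unit
#' bottleneck, hidden layer, logistic n-unit output) on all rows jointly, by
#' Adam on minibatches under binary cross-entropy, and returns each row's
#' bottleneck activation as its embedding vector. Because every layer's rows
#' pass through the same trained network, embeddings of all layers share one
#' space: identical feature rows always map to identical vectors.
#'
#' @param features Numeric matrix, one row per (layer, node) instance.
#' @param targets Numeric matrix of the same shape with entries in \[0, 1\].
#' @param config An [embedding_config()].
#' @param layers,nodes Character vectors annotating the rows; default to the
#'   `"layer"`/`"node"` attributes of `features` when present.
#' @return An object of class `node_embedding`: list with `coords` (rows x
#'   k matrix), `layers`, `nodes`, training losses and the config.
#' @export
train_ednn <- function(features, targets, config = embedding_config(),
                       layers = NULL, nodes = NULL) {
  stopifnot(inherits(config, "embedding_config"))
  features <- as.matrix(features)
  targets <- as.matrix(targets)
  if (!all(dim(features) == dim(targets))) {
    abort_validation("features and targets must have identical dimensions")
  }
  if (any(targets < 0) || any(targets > 1)) {
    abort_validation("reconstruction targets must lie in [0, 1]")
  }
  n <- ncol(features)
  if (config$k >= n) {
    abort_validation(sprintf("bottleneck dimension k = %d must be smaller than the node count n = %d",
                             config$k, n))
  }
  layers <- layers %||% attr(features, "layer") %||% rep("layer", nrow(features))
  nodes <- nodes %||% attr(features, "node") %||% as.character(seq_len(nrow(features)))

  fit <- .ednn_train_cpp(features, targets, config$k, config$hidden,
                         act_code(config$bottleneck_activation),
                         config$epochs, config$learning_rate,
                         config$batch_size, as.double(config$seed),
                         config$early_stop_tol %||% 5e-4,
                         config$patience %||% 20L)
  coords <- fit$embedding
  if (any(!is.finite(coords))) {
    stop("embedding contains non-finite values; try a smaller learning rate")
  }
  colnames(coords) <- paste0("v", seq_len(config$k))
  structure(list(coords = coords, layers = as.character(layers),
                 nodes = as.character(nodes),
                 loss_initial = fit$loss_initial, loss_final = fit$loss_final,
                 epochs_run = fit$epochs_run, config = config),
            class = "node_embedding")
}

#' @export
print.node_embedding <- function(x, ...) {
  cat(sprintf("node embedding: %d instances, k = %d, layers: %s\n",
              nrow(x$coords), ncol(x$coords),
              paste(unique(x$layers), collapse = ", ")))
  cat(sprintf("  BCE loss %.5f -> %.5f over %d epochs\n",
              x$loss_initial, x$loss_final, x$epochs_run))
  invisible(x)
}

#' Embed the layers of a multiplex network jointly
#'
#' Convenience wrapper: stacks the feature and target rows of the given
#' layers (all layers by default) and calls [train_ednn()].
#'
#' @param net A [multiplex_network()].
#' @param config An [embedding_config()].
#' @param layers Layer names to embed; default all.
#' @return A `node_embedding`.
#' @export
embed_multiplex <- function(net, config = embedding_config(), layers = NULL) {
  stopifnot(inherits(net, "multiplex_network"))
  layers <- layers %||% names(net$layers)
  mats <- net$layers[layers]
  st <- stack_instances(mats, config)
  train_ednn(st$features, st$targets, config, layers = st$layers, nodes = st$nodes)
}

embedding_coords <- function(emb, layer) {
  sel <- emb$layers == layer
  if (!any(sel)) {
    abort_validation(sprintf("layer '%s' not present in the embedding (has: %s)",
                             layer, paste(unique(emb$layers), collapse = ", ")))
  }
  M <- emb$coords[sel, , drop = FALSE]
  rownames(M) <- emb$nodes[sel]
  M
}

cosine_distance <- function(u, w) {
  if (identical(u, w)) return(0)
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) return(NA_real_)  # caller warns and maps to 1
  1 - sum(u * w) / (nu * nw)
}

#' Per-node between-layer distances in embedding space
#'
#' For each node, the distance between its embedding vectors in the two
#' layers — the package's measure of how much the node's neighborhood
#' differs between the layers. Cosine distance (default) is
#' `1 - cos(angle)`; zero-norm vectors (possible with a ReLU bottleneck)
#' yield distance 1 with a warning rather than NaN.
#'
#' @param emb A `node_embedding` containing both layers.
#' @param layer_a,layer_b Layer names.
#' @param metric `"cosine"` or `"euclidean"`; defaults to the metric in the
#'   embedding's config.
#' @return A `distance_table`: data frame with columns `node`, `distance`.
#' @export
node_distances <- function(emb, layer_a, layer_b, metric = NULL) {
  stopifnot(inherits(emb, "node_embedding"))
  metric <- metric %||% emb$config$distance_metric
  metric <- match.arg(metric, c("cosine", "euclidean"))
  A <- embedding_coords(emb, layer_a)
  B <- embedding_coords(emb, layer_b)
  nodes <- rownames(A)
  if (!identical(sort_c(nodes), sort_c(rownames(B)))) {
    abort_validation("the two layers cover different node sets")
  }
  B <- B[nodes, , drop = FALSE]
  d <- numeric(length(nodes))
  zero_norm <- FALSE
  for (i in seq_along(nodes)) {
    if (metric == "cosine") {
      di <- cosine_distance(A[i, ], B[i, ])
      if (is.na(di)) { di <- 1; zero_norm <- TRUE }
    } else {
      di <- sqrt(sum((A[i, ] - B[i, ])^2))
    }
    d[i] <- di
  }
  if (zero_norm) {
    warning("zero-norm embedding vector(s): cosine distance set to 1", call. = FALSE)
  }
  structure(data.frame(node = nodes, distance = d, stringsAsFactors = FALSE),
            class = c("distance_table", "data.frame"))
}

#' Write an embedding as TSV (columns layer, node, v1..vk)
#' @param emb A `node_embedding`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(layer = emb$layers, node = emb$nodes,
                   emb$coords, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance table as TSV (columns node, distance)
#' @param tab A `distance_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distances <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
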