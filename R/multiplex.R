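# Multiplex network container and file I/O (edge lists, adjacency CSV,
# phenotype tables).

#' Construct a multiplex network
#'
#' A multiplex network is a set of weighted edge layers over one shared,
#' ordered node set. Every layer must be a symmetric matrix with zero
#' diagonal and weights in \[0, 1\].
#'
#' @param layers Named list of n x n numeric matrices, all with the same
#'   node ids as dimnames (or none, in which case `node_ids` applies).
#' @param node_ids Character vector of node identifiers; defaults to the
#'   dimnames of the first layer.
#' @param tol Symmetry tolerance; asymmetries up to `tol` are averaged out,
#'   larger ones are an error.
#' @return An object of class `multiplex_network` with elements `node_ids`
#'   and `layers`.
#' @export
multiplex_network <- function(layers, node_ids = NULL, tol = 1e-9) {
  if (!is.list(layers) || length(layers) < 1) abort_validation("layers must be a non-empty named list")
  if (is.null(names(layers)) || any(!nzchar(names(layers))) || anyDuplicated(names(layers))) {
    abort_validation("layers must have unique non-empty names")
  }
  if (is.null(node_ids)) node_ids <- rownames(layers[[1]])
  if (is.null(node_ids)) abort_validation("node ids are required (dimnames or node_ids argument)")
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) abort_validation("duplicate node ids")
  n <- length(node_ids)
  for (nm in names(layers)) {
    W <- as.matrix(layers[[nm]])
    if (!all(dim(W) == c(n, n))) {
      abort_validation(sprintf("layer '%s' is %dx%d, expected %dx%d",
                               nm, nrow(W), ncol(W), n, n))
    }
    if (!is.null(rownames(W)) && !identical(rownames(W), node_ids)) {
      W <- W[node_ids, node_ids, drop = FALSE]
    }
    asym <- max(abs(W - t(W)))
    if (asym > tol) {
      idx <- which(abs(W - t(W)) == asym, arr.ind = TRUE)[1, ]
      abort_validation(sprintf(
        "layer '%s' is asymmetric at (%s, %s): %g vs %g",
        nm, node_ids[idx[1]], node_ids[idx[2]],
        W[idx[1], idx[2]], W[idx[2], idx[1]]))
    }
    W <- (W + t(W)) / 2
    if (any(W < 0) || any(W > 1)) {
      idx <- which(W < 0 | W > 1, arr.ind = TRUE)[1, ]
      abort_validation(sprintf("layer '%s' weight %g at edge (%s, %s) outside [0, 1]",
                               nm, W[idx[1], idx[2]], node_ids[idx[1]], node_ids[idx[2]]))
    }
    if (any(diag(W) != 0)) {
      abort_validation(sprintf("layer '%s' has a nonzero diagonal (self-loops are not allowed)", nm))
    }
    dimnames(W) <- list(node_ids, node_ids)
    layers[[nm]] <- W
  }
  structure(list(node_ids = node_ids, layers = layers),
            class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("multiplex network: %d nodes, %d layer(s): %s\n",
              length(x$node_ids), length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Number of layers / nodes of a multiplex network
#' @param net A `multiplex_network`.
#' @return Integer.
#' @export
n_nodes <- function(net) length(net$node_ids)

layer_matrix <- function(net, layer) {
  if (!layer %in% names(net$layers)) {
    abort_validation(sprintf("unknown layer '%s' (available: %s)",
                             layer, paste(names(net$layers), collapse = ", ")))
  }
  net$layers[[layer]]
}

# Pick the designated layer pair for two-layer analyses.
resolve_layer_pair <- function(net, layers = NULL) {
  if (is.null(layers)) {
    if (length(net$layers) < 2) abort_validation("at least 2 layers are required")
    layers <- names(net$layers)[1:2]
  }
  if (length(layers) != 2) abort_validation("exactly two layers must be designated")
  for (l in layers) layer_matrix(net, l)
  layers
}

read_edgelist_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(node_a = character(), node_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  has_header <- grepl("^node_a\\b", lines[1])
  df <- utils::read.table(text = lines, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) != 3) abort_validation(sprintf("edge list '%s' must have 3 columns", path))
  names(df) <- c("node_a", "node_b", "weight")
  df$node_a <- as.character(df$node_a)
  df$node_b <- as.character(df$node_b)
  df$weight <- as.numeric(df$weight)
  if (anyNA(df$weight)) abort_validation(sprintf("non-numeric weight in '%s'", path))
  df
}

edgelist_to_matrix <- function(df, node_ids, path) {
  n <- length(node_ids)
  W <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  seen <- new.env(hash = TRUE)
  for (r in seq_len(nrow(df))) {
    a <- df$node_a[r]; b <- df$node_b[r]; w <- df$weight[r]
    if (a == b) abort_validation(sprintf("self-loop on node '%s' in '%s'", a, path))
    if (w < 0 || w > 1) {
      abort_validation(sprintf("weight %g on edge (%s, %s) in '%s' outside [0, 1]",
                               w, a, b, path))
    }
    key <- paste(sort_c(c(a, b)), collapse = "\r")
    prev <- seen[[key]]
    if (!is.null(prev) && abs(prev - w) > 1e-9) {
      abort_validation(sprintf("conflicting duplicate edge (%s, %s) in '%s': %g vs %g",
                               a, b, path, prev, w))
    }
    seen[[key]] <- w
    W[a, b] <- w
    W[b, a] <- w
  }
  W
}

#' Read a multiplex network from per-layer files
#'
#' Layers are aligned to the union of node ids across all files, sorted
#' lexicographically (byte order); edges absent from a layer get weight 0.
#'
#' @param paths Character vector (>= 2) of file paths, one per layer. Names,
#'   if set, become layer names; otherwise file base names are used.
#' @param format `"edgelist_tsv"` (3 columns node_a, node_b, weight;
#'   `#` comments allowed) or `"adjacency_csv"` (node ids as header and
#'   first column).
#' @return A [multiplex_network()].
#' @export
read_multiplex <- function(paths, format = c("edgelist_tsv", "adjacency_csv")) {
  format <- match.arg(format)
  if (length(paths) < 2) abort_validation("a multiplex network needs at least 2 layer files")
  for (p in paths) if (!file.exists(p)) abort_validation(paste0("file not found: ", p))
  layer_names <- names(paths)
  if (is.null(layer_names) || any(!nzchar(layer_names))) {
    layer_names <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (anyDuplicated(layer_names)) abort_validation("layer names must be unique")

  if (format == "edgelist_tsv") {
    dfs <- lapply(paths, read_edgelist_file)
    node_ids <- sort_c(unique(unlist(lapply(dfs, function(d) c(d$node_a, d$node_b)))))
    if (length(node_ids) == 0) abort_validation("no nodes found in edge lists")
    layers <- lapply(seq_along(dfs), function(i) edgelist_to_matrix(dfs[[i]], node_ids, paths[i]))
  } else {
    mats <- lapply(paths, function(p) {
      df <- utils::read.csv(p, row.names = 1, check.names = FALSE)
      M <- as.matrix(df)
      if (!identical(rownames(M), colnames(M))) {
        abort_validation(sprintf("adjacency '%s': row and column ids differ", p))
      }
      storage.mode(M) <- "double"
      if (anyNA(M)) abort_validation(sprintf("non-numeric or missing entry in '%s'", p))
      asym <- abs(M - t(M))
      if (max(asym) > 1e-9) {
        idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
        abort_validation(sprintf("adjacency '%s' asymmetric at (%s, %s): %g vs %g",
                                 p, rownames(M)[idx[1]], colnames(M)[idx[2]],
                                 M[idx[1], idx[2]], M[idx[2], idx[1]]))
      }
      M
    })
    node_ids <- sort_c(unique(unlist(lapply(mats, rownames))))
    layers <- lapply(seq_along(mats), function(i) {
      W <- matrix(0, length(node_ids), length(node_ids),
                  dimnames = list(node_ids, node_ids))
      ids <- rownames(mats[[i]])
      W[ids, ids] <- mats[[i]]
      W
    })
  }
  names(layers) <- layer_names
  multiplex_network(layers, node_ids)
}

#' Write a multiplex network to per-layer files
#'
#' Inverse of [read_multiplex()]; weights are written at full precision so a
#' write/read round trip reproduces the network bit-exactly.
#'
#' @param net A [multiplex_network()].
#' @param dir Output directory (created if needed).
#' @param format `"edgelist_tsv"` or `"adjacency_csv"`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_multiplex <- function(net, dir, format = c("edgelist_tsv", "adjacency_csv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "multiplex_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "edgelist_tsv") ".tsv" else ".csv"
  paths <- file.path(dir, paste0(names(net$layers), ext))
  names(paths) <- names(net$layers)
  for (nm in names(net$layers)) {
    W <- net$layers[[nm]]
    if (format == "edgelist_tsv") {
      ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
      ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
      lines <- c("node_a\tnode_b\tweight",
                 sprintf("%s\t%s\t%s",
                         net$node_ids[ut[, 1]], net$node_ids[ut[, 2]],
                         fmt_num(W[ut])))
      writeLines(lines, paths[nm])
    } else {
      header <- paste0(",", paste(net$node_ids, collapse = ","))
      rows <- vapply(seq_along(net$node_ids), function(i) {
        paste0(net$node_ids[i], ",", paste(fmt_num(W[i, ]), collapse = ","))
      }, character(1))
      writeLines(c(header, rows), paths[nm])
    }
  }
  invisible(paths)
}

#' Construct a phenotype table
#'
#' @param sample_ids Character vector of unique sample/individual ids.
#' @param values Phenotype values: two groups (binary) or real numbers
#'   (continuous).
#' @param kind `"auto"` (binary when there are exactly 2 distinct values),
#'   `"binary"` or `"continuous"`.
#' @return An object of class `phenotype_table` with elements `sample_ids`,
#'   `values`, `kind`.
#' @export
phenotype_table <- function(sample_ids, values, kind = c("auto", "binary", "continuous")) {
  kind <- match.arg(kind)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    abort_validation(paste0("duplicate sample ids: ",
                            paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  if (length(sample_ids) != length(values)) abort_validation("sample_ids and values differ in length")
  n_distinct <- length(unique(values))
  if (kind == "auto") kind <- if (n_distinct == 2) "binary" else "continuous"
  if (kind == "binary") {
    if (n_distinct != 2) abort_validation("a binary phenotype needs exactly 2 distinct values")
    if (min(table(values)) < 2) abort_validation("each phenotype group needs >= 2 samples")
  } else {
    values <- as.numeric(values)
    if (anyNA(values)) abort_validation("continuous phenotype values must be numeric")
  }
  structure(list(sample_ids = sample_ids, values = values, kind = kind),
            class = "phenotype_table")
}

#' Read a phenotype table from a 2-column TSV (sample_id, value)
#'
#' @param path Path to the file (header optional).
#' @param kind See [phenotype_table()].
#' @return A [phenotype_table()].
#' @export
read_phenotype <- function(path, kind = "auto") {
  if (!file.exists(path)) abort_validation(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  has_header <- grepl("^sample_id\\b", lines[1])
  df <- utils::read.table(text = lines, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) != 2) abort_validation(sprintf("phenotype file '%s' must have 2 columns", path))
  vals <- df[[2]]
  num <- suppressWarnings(as.numeric(vals))
  if (!anyNA(num)) vals <- num
  phenotype_table(df[[1]], vals, kind)
}
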