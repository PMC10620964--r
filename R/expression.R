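# Expression-matrix handling and co-expression network construction.

#' Construct an expression matrix object
#'
#' A thin validated container for a genes x samples matrix of (typically
#' log-normalised) expression values.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param sample_ids Character vector of unique sample identifiers (columns).
#' @return An object of class `expression_matrix`: the numeric matrix with
#'   gene/sample ids as dimnames.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort_validation("gene_ids and sample_ids are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    abort_validation(sprintf("%d gene ids for %d rows", length(gene_ids), nrow(values)))
  }
  if (length(sample_ids) != ncol(values)) {
    abort_validation(sprintf("%d sample ids for %d columns", length(sample_ids), ncol(values)))
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0) {
    abort_validation(paste0("duplicate gene ids: ", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    abort_validation(paste0("duplicate sample ids: ", paste(dup_s, collapse = ", ")))
  }
  if (!is.numeric(values)) abort_validation("expression values must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort_validation(sprintf("missing/non-finite expression value at gene '%s', sample '%s'",
                             gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, class = c("expression_matrix", "matrix", "array"))
}

#' Read an expression matrix from a delimited text file
#'
#' Expects gene ids in the first column and a header row of sample ids.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter, `"\t"` (default) or `","`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) abort_validation(paste0("file not found: ", path))
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2) abort_validation("expression file needs a gene-id column plus >= 1 sample column")
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & nzchar(col))
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "non-numeric value '%s' at row %d (gene '%s'), column '%s'",
        col[bad[1]], bad[1], gene_ids[bad[1]], sample_ids[j]))
    }
    if (anyNA(num)) {
      abort_validation(sprintf("missing value for gene '%s', sample '%s'",
                               gene_ids[which(is.na(num))[1]], sample_ids[j]))
    }
    vals[, j] <- num
  }
  expression_matrix(vals, gene_ids, sample_ids)
}

#' Keep the genes with the largest expression variance
#'
#' Standard pre-filter before building a co-expression network: retain the
#' `n_top` genes with the largest across-sample variance, preserving their
#' original row order.
#'
#' @param expr An [expression_matrix()].
#' @param n_top Number of genes to keep.
#' @return An [expression_matrix()] with `n_top` rows.
#' @export
select_top_variance_genes <- function(expr, n_top) {
  stopifnot(inherits(expr, "expression_matrix"))
  n_top <- as.integer(n_top)
  if (is.na(n_top) || n_top < 1) abort_validation("n_top must be a positive integer")
  if (n_top > nrow(expr)) {
    abort_validation(sprintf("n_top (%d) exceeds the number of genes (%d)", n_top, nrow(expr)))
  }
  v <- apply(unclass(expr), 1, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(n_top)])
  expression_matrix(unclass(expr)[keep, , drop = FALSE],
                    rownames(expr)[keep], colnames(expr))
}

#' Build a gene co-expression network
#'
#' Edge weights are absolute pairwise correlations across samples, so they
#' live in \[0, 1\] and can serve directly as reconstruction targets for the
#' logistic-output embedding model. Zero-variance genes have undefined
#' correlations; those edges are set to 0 with a warning.
#'
#' @param expr An [expression_matrix()] with at least 2 genes and 3 samples.
#' @param method Correlation estimator, `"pearson"` (default) or `"spearman"`.
#' @return Symmetric weight matrix (genes x genes) with zero diagonal and
#'   gene ids as dimnames.
#' @export
build_gcn <- function(expr, method = c("pearson", "spearman")) {
  stopifnot(inherits(expr, "expression_matrix"))
  method <- match.arg(method)
  if (ncol(expr) < 3) abort_validation("at least 3 samples are required to estimate correlations")
  if (nrow(expr) < 2) abort_validation("at least 2 genes are required")
  vals <- unclass(expr)
  W <- abs(suppressWarnings(stats::cor(t(vals), method = method)))
  if (anyNA(W)) {
    const <- rownames(expr)[apply(vals, 1, stats::var) == 0]
    warning(sprintf("zero-variance gene(s) %s: undefined correlations set to 0",
                    paste(const, collapse = ", ")), call. = FALSE)
    W[is.na(W)] <- 0
  }
  W <- (W + t(W)) / 2
  W[W > 1] <- 1
  diag(W) <- 0
  W
}

#' LIONESS linear interpolation for a single edge (or matrix of edges)
#'
#' The individual-specific weight implied by an aggregate network over `N`
#' samples and the leave-one-out network without sample q:
#' `N * agg - (N - 1) * loo`. Values can fall outside \[0, 1\]; see
#' [build_isns()] for clipping at the embedding interface.
#'
#' @param n_samples Total sample count N.
#' @param agg Aggregate-network weight(s).
#' @param loo Leave-one-out-network weight(s).
#' @return Un-clipped individual-specific weight(s).
#' @export
lioness_edge <- function(n_samples, agg, loo) {
  if (n_samples < 2) abort_validation("n_samples must be >= 2")
  n_samples * agg - (n_samples - 1) * loo
}

#' Build LIONESS individual-specific networks
#'
#' For each sample q, the individual-specific network (ISN) is the LIONESS
#' linear interpolation `N * agg - (N - 1) * agg_minus_q`, where `agg` is the
#' co-expression network over all N samples and `agg_minus_q` leaves sample q
#' out. Raw interpolated weights can fall outside \[0, 1\]; the returned
#' networks are clipped for downstream embedding, with the raw matrices
#' attached when `keep_raw = TRUE`.
#'
#' @param expr An [expression_matrix()] with at least 4 samples.
#' @param method Correlation estimator passed to [build_gcn()].
#' @param keep_raw If `TRUE`, each returned matrix carries the un-clipped
#'   LIONESS weights in `attr(, "raw")`.
#' @return Named list (one element per sample) of symmetric weight matrices.
#' @export
build_isns <- function(expr, method = c("pearson", "spearman"), keep_raw = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  method <- match.arg(method)
  N <- ncol(expr)
  if (N < 4) abort_validation("at least 4 samples are required for leave-one-out networks")
  agg <- build_gcn(expr, method)
  out <- vector("list", N)
  names(out) <- colnames(expr)
  for (q in seq_len(N)) {
    sub <- expression_matrix(unclass(expr)[, -q, drop = FALSE],
                             rownames(expr), colnames(expr)[-q])
    raw <- lioness_edge(N, agg, build_gcn(sub, method))
    isn <- pmin(pmax(raw, 0), 1)
    diag(isn) <- 0
    if (keep_raw) attr(isn, "raw") <- raw
    out[[q]] <- isn
  }
  out
}

#' Number of edges of a complete undirected network
#'
#' The number of unordered node pairs, `n * (n - 1) / 2` — the edge count of
#' a fully dense co-expression network on `n` genes.
#'
#' @param n Number of nodes (positive integer).
#' @return Integer-valued numeric.
#' @export
complete_edge_count <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    abort_validation("n must be a positive integer")
  }
  n * (n - 1) / 2
}
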