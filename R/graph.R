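# Hybrid graph construction: PCA / reciprocal-PCA projections, mutual
# nearest neighbors within and across datasets, and the voting filter that
# removes unreliable cross-dataset connections.

new_bipartite_adjacency <- function(pairs, n_ref, n_query) {
  pairs <- unique(pairs)
  if (nrow(pairs) > 0) {
    stopifnot(all(pairs[, 1] >= 1L & pairs[, 1] <= n_ref),
              all(pairs[, 2] >= 1L & pairs[, 2] <= n_query))
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  dimnames(pairs) <- list(NULL, c("ref", "query"))
  structure(list(pairs = pairs, n_ref = n_ref, n_query = n_query),
            class = "bipartite_adjacency")
}

#' @export
print.bipartite_adjacency <- function(x, ...) {
  cat(sprintf("bipartite_adjacency: %d connections (%d ref x %d query cells)\n",
              nrow(x$pairs), x$n_ref, x$n_query))
  invisible(x)
}

new_intra_adjacency <- function(pairs, n_cells) {
  if (nrow(pairs) > 0) {
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, c(2, 1)]
    pairs <- unique(pairs)
    stopifnot(all(pairs[, 1] != pairs[, 2]),
              all(pairs >= 1L & pairs <= n_cells))
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  dimnames(pairs) <- list(NULL, c("i", "j"))
  structure(list(pairs = pairs, n_cells = n_cells),
            class = "intra_adjacency")
}

#' @export
print.intra_adjacency <- function(x, ...) {
  cat(sprintf("intra_adjacency: %d edges over %d cells\n",
              nrow(x$pairs), x$n_cells))
  invisible(x)
}

#' Principal-component projection of cells
#'
#' Truncated PCA of the cells of a standardized genes x cells matrix,
#' used before within-dataset neighbor search. Deterministic: exact SVD with
#' a fixed sign convention (the largest-magnitude loading of each component
#' is made positive).
#'
#' @param X A `"standardized_matrix"` or a plain genes x cells matrix.
#' @param n_components Number of components (must not exceed `min(m, n)`).
#' @return cells x `n_components` score matrix.
#' @export
pca_project <- function(X, n_components = 30) {
  m <- if (inherits(X, "standardized_matrix")) X$matrix else as.matrix(X)
  if (n_components > min(dim(m)))
    stop_usage("n_components = ", n_components, " exceeds min(genes, cells) = ",
               min(dim(m)))
  V <- pca_loadings(m, n_components)
  crossprod(m, V)  # cells x k
}

# Gene-space loadings (m x k) of a standardized genes x cells matrix, sign
# fixed for reproducibility.
pca_loadings <- function(m, k) {
  sv <- svd(m, nu = k, nv = 0)
  V <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    piv <- which.max(abs(V[, j]))
    if (V[piv, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Reciprocal-PCA projection of a reference/query pair
#'
#' Projects both datasets into the PCA gene-space of the reference and,
#' reciprocally, into the PCA gene-space of the query, yielding two shared
#' coordinate systems for cross-dataset neighbor search.
#'
#' @param Xr,Xq `"standardized_matrix"` objects sharing the same gene order.
#' @param n_components Components per space (default 30).
#' @return List of two coordinate systems, `ref_space` and `query_space`,
#'   each a list with cells x k score matrices `ref` and `query`.
#' @export
rpca_project <- function(Xr, Xq, n_components = 30) {
  mr <- Xr$matrix; mq <- Xq$matrix
  if (nrow(mr) != nrow(mq))
    stop_data("reference and query must share the same genes")
  if (!is.null(Xr$gene_ids) && !is.null(Xq$gene_ids) &&
      !identical(Xr$gene_ids, Xq$gene_ids))
    stop_data("gene order differs between reference and query")
  lim <- min(nrow(mr), ncol(mr), ncol(mq))
  if (n_components > lim)
    stop_usage("n_components = ", n_components,
               " exceeds min(genes, n_ref, n_query) = ", lim)
  Vr <- pca_loadings(mr, n_components)
  Vq <- pca_loadings(mq, n_components)
  list(
    ref_space   = list(ref = crossprod(mr, Vr), query = crossprod(mq, Vr)),
    query_space = list(ref = crossprod(mr, Vq), query = crossprod(mq, Vq))
  )
}

# indices (rows of b) of the K nearest neighbors of each row of a
knn_index <- function(a, b, K, exclude_self = FALSE) {
  d2 <- cross_dist2(a, b)
  if (exclude_self) diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(K)]))
}

#' Mutual nearest neighbors across two embeddings
#'
#' A connection (i, j) is kept when j is among the K nearest neighbors of i
#' in `emb_b` and i is among the K nearest neighbors of j in `emb_a`
#' (Euclidean distance in the shared coordinate system).
#'
#' @param emb_a,emb_b cells x d coordinate matrices in a common space
#'   (reference first).
#' @param K Neighborhood size; clipped with a warning if it reaches the size
#'   of the opposing set.
#' @return A `"bipartite_adjacency"` with the mutual pairs.
#' @export
mnn_pairs <- function(emb_a, emb_b, K = 5) {
  emb_a <- as.matrix(emb_a); emb_b <- as.matrix(emb_b)
  na <- nrow(emb_a); nb <- nrow(emb_b)
  stopifnot(K >= 1)
  if (K > nb || K > na) {
    K <- min(K, na, nb)
    warning("K clipped to ", K, " (opposing set size)")
  }
  nn_ab <- knn_index(emb_a, emb_b, K)  # na x K, entries in 1..nb
  nn_ba <- knn_index(emb_b, emb_a, K)  # nb x K, entries in 1..na
  in_ba <- Matrix::sparseMatrix(i = rep(seq_len(nb), K), j = as.vector(nn_ba),
                                x = TRUE, dims = c(nb, na))
  cand_i <- rep(seq_len(na), K)
  cand_j <- as.vector(nn_ab)
  mutual <- in_ba[cbind(cand_j, cand_i)]
  new_bipartite_adjacency(cbind(cand_i[mutual], cand_j[mutual]), na, nb)
}

#' Mutual nearest neighbors within one embedding
#'
#' Undirected mutual-KNN graph over the cells of a single dataset; each
#' cell's neighbor list excludes itself.
#'
#' @param emb cells x d coordinate matrix.
#' @param K Neighborhood size; clipped with a warning when `K >= n`.
#' @return An `"intra_adjacency"`.
#' @export
intra_mnn <- function(emb, K = 10) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  stopifnot(K >= 1)
  if (n < 2) {
    warning("fewer than 2 cells; returning an empty adjacency")
    return(new_intra_adjacency(matrix(integer(), 0, 2), n))
  }
  if (K >= n) {
    K <- n - 1L
    warning("K clipped to ", K)
  }
  nn <- knn_index(emb, emb, K, exclude_self = TRUE)
  memb <- Matrix::sparseMatrix(i = rep(seq_len(n), K), j = as.vector(nn),
                               x = TRUE, dims = c(n, n))
  cand_i <- rep(seq_len(n), K)
  cand_j <- as.vector(nn)
  mutual <- memb[cbind(cand_j, cand_i)]
  keep <- mutual & (cand_i < cand_j)
  new_intra_adjacency(cbind(cand_i[keep], cand_j[keep]), n)
}

#' Score reference cells by neighborhood label purity
#'
#' For each reference cell r, the score u_r is the fraction of its neighbors
#' in the within-reference graph that carry the same type label as r; cells
#' with no neighbors score 0. These scores weight the votes that estimate
#' query cell types.
#'
#' @param arr `"intra_adjacency"` over the reference cells.
#' @param labels Character vector of reference cell types.
#' @return Numeric vector `u` in `[0, 1]`, one entry per reference cell.
#' @export
score_reference_cells <- function(arr, labels) {
  n <- arr$n_cells
  stopifnot(length(labels) == n)
  same <- numeric(n)
  deg <- numeric(n)
  p <- arr$pairs
  if (nrow(p) > 0) {
    agree <- labels[p[, 1]] == labels[p[, 2]]
    deg <- tabulate(p[, 1], n) + tabulate(p[, 2], n)
    same <- tabulate(p[agree, 1], n) + tabulate(p[agree, 2], n)
  }
  u <- ifelse(deg > 0, same / pmax(deg, 1), 0)
  u
}

#' Estimate query cell types from cross-dataset connections
#'
#' Each query cell accumulates, per reference type, the purity scores of its
#' reference neighbors of that type; the highest-scoring type wins. Cells
#' whose maximal score is 0 (including isolated cells) are labeled
#' `"Unknown"`. Ties break to the lexicographically smallest type.
#'
#' @param arq `"bipartite_adjacency"` between reference and query cells.
#' @param labels Reference cell types.
#' @param u Reference purity scores from [score_reference_cells()].
#' @return Character vector of estimated types, one per query cell.
#' @export
estimate_query_types <- function(arq, labels, u) {
  types <- sort(unique(labels))
  scores <- matrix(0, arq$n_query, length(types),
                   dimnames = list(NULL, types))
  p <- arq$pairs
  if (nrow(p) > 0) {
    ti <- match(labels[p[, 1]], types)
    acc <- Matrix::sparseMatrix(i = p[, 2], j = ti, x = u[p[, 1]],
                                dims = dim(scores))
    scores <- as.matrix(acc)
    colnames(scores) <- types
  }
  best <- max.col(scores, ties.method = "first")
  kq <- types[best]
  kq[apply(scores, 1, max) <= 0] <- "Unknown"
  kq
}

#' Refine query type estimates by multi-hop neighborhood voting
#'
#' Re-estimates each query cell's type as the plurality of the estimated
#' types in its h-hop neighborhood of the within-query graph (default 4
#' hops, the cell itself excluded). `"Unknown"` estimates do not vote; a
#' cell with no countable votes keeps its own estimate. Ties break to the
#' lexicographically smallest type.
#'
#' @param aqq `"intra_adjacency"` over the query cells.
#' @param kq Estimated types from [estimate_query_types()].
#' @param hops Neighborhood radius in edges; `hops = 0` returns `kq`
#'   unchanged.
#' @return Character vector of refined types.
#' @export
refine_query_types <- function(aqq, kq, hops = 4) {
  n <- aqq$n_cells
  stopifnot(length(kq) == n, hops >= 0)
  if (hops == 0 || nrow(aqq$pairs) == 0) return(kq)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(aqq$pairs))
  hood <- igraph::ego(g, order = hops, nodes = seq_len(n), mindist = 1)
  out <- kq
  for (q in seq_len(n)) {
    votes <- kq[as.integer(hood[[q]])]
    votes <- votes[votes != "Unknown"]
    if (length(votes) == 0) next
    tab <- table(votes)
    out[q] <- names(tab)[which.max(tab)]  # ties: first = smallest type name
  }
  out
}

#' Filter cross-dataset connections by type agreement
#'
#' A connection (i, j) is kept only when the reference label of i equals the
#' refined estimated type of query cell j; connections to `"Unknown"` query
#' cells are always removed. Warns when nothing survives.
#'
#' @param arq `"bipartite_adjacency"` to filter.
#' @param ref_labels Reference cell types.
#' @param kq_prime Refined query types from [refine_query_types()].
#' @return The filtered `"bipartite_adjacency"` (a subset of the input).
#' @export
filter_inter_connections <- function(arq, ref_labels, kq_prime) {
  p <- arq$pairs
  keep <- if (nrow(p) > 0) {
    ref_labels[p[, 1]] == kq_prime[p[, 2]] & kq_prime[p[, 2]] != "Unknown"
  } else logical(0)
  if (nrow(p) > 0 && !any(keep))
    warning("all cross-dataset connections were filtered out; training will ",
            "proceed without the hard regularization term")
  new_bipartite_adjacency(p[keep, , drop = FALSE], arq$n_ref, arq$n_query)
}

#' Assemble the hybrid graph
#'
#' Union of the filtered cross-dataset connections and both within-dataset
#' graphs over `n_ref + n_query` nodes (reference block first; query indices
#' offset by `n_ref`). Every edge carries a provenance tag.
#'
#' @param arq_f Filtered `"bipartite_adjacency"`.
#' @param arr,aqq `"intra_adjacency"` for reference and query.
#' @return An object of class `"hybrid_graph"`: list with `n_nodes`, `n_ref`,
#'   `n_query` and an `edges` data frame (`from`, `to`, `provenance`).
#' @export
assemble_hybrid_graph <- function(arq_f, arr, aqq) {
  n_ref <- arr$n_cells
  n_query <- aqq$n_cells
  if (arq_f$n_ref != n_ref || arq_f$n_query != n_query)
    stop("index spaces disagree between the adjacency inputs")
  inter <- cbind(arq_f$pairs[, 1], arq_f$pairs[, 2] + n_ref)
  intra_r <- arr$pairs
  intra_q <- aqq$pairs + n_ref
  edges <- data.frame(
    from = c(inter[, 1], intra_r[, 1], intra_q[, 1]),
    to = c(inter[, 2], intra_r[, 2], intra_q[, 2]),
    provenance = rep(c("inter", "intra_ref", "intra_query"),
                     c(nrow(inter), nrow(intra_r), nrow(intra_q))),
    stringsAsFactors = FALSE
  )
  structure(list(n_nodes = n_ref + n_query, n_ref = n_ref, n_query = n_query,
                 edges = edges),
            class = "hybrid_graph")
}

#' @export
print.hybrid_graph <- function(x, ...) {
  tab <- table(x$edges$provenance)
  cat(sprintf("hybrid_graph: %d nodes (%d ref + %d query), %d edges\n",
              x$n_nodes, x$n_ref, x$n_query, nrow(x$edges)))
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(x)
}

# Symmetric sparse 0/1 adjacency of the hybrid graph.
hybrid_adjacency <- function(graph) {
  e <- graph$edges
  n <- graph$n_nodes
  if (nrow(e) == 0)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  A <- Matrix::sparseMatrix(i = c(e$from, e$to), j = c(e$to, e$from),
                            x = 1, dims = c(n, n), use.last.ij = TRUE)
  A
}

#' Write a hybrid graph as an edge-list TSV
#'
#' Columns `node_a`, `node_b`, `provenance`; node indices are 1-based over
#' the joint reference-then-query ordering.
#'
#' @param graph A `"hybrid_graph"`.
#' @param path Output path.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  utils::write.table(
    data.frame(node_a = e$from, node_b = e$to, provenance = e$provenance),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build and filter the full hybrid graph from standardized matrices
#'
#' Runs the complete graph stage: reciprocal-PCA projection and mutual-KNN
#' search across datasets, PCA and mutual-KNN within each dataset, reference
#' purity scoring, query type estimation and multi-hop refinement, connection
#' filtering, and final assembly.
#'
#' @param Xr,Xq `"standardized_matrix"` objects on common genes.
#' @param ref_labels Reference cell types.
#' @param k_inter,k_intra Neighborhood sizes for cross- and within-dataset
#'   mutual-KNN (defaults 5 and 10).
#' @param n_pcs Components for both PCA and reciprocal PCA (default 30).
#' @param hops Refinement neighborhood radius (default 4).
#' @param rpca_combine `"union"` (default) or `"intersection"` of the mutual
#'   pair sets found in the two reciprocal-PCA coordinate systems.
#' @return List with the raw and filtered cross-dataset adjacencies
#'   (`arq`, `arq_filtered`), the within-dataset adjacencies (`arr`, `aqq`),
#'   reference scores `u`, estimated and refined query types (`kq`,
#'   `kq_prime`), and the assembled `graph`.
#' @export
build_hybrid_graph <- function(Xr, Xq, ref_labels,
                               k_inter = 5, k_intra = 10, n_pcs = 30,
                               hops = 4,
                               rpca_combine = c("union", "intersection")) {
  rpca_combine <- match.arg(rpca_combine)
  n_ref <- ncol(Xr$matrix); n_query <- ncol(Xq$matrix)
  stopifnot(length(ref_labels) == n_ref)

  proj <- rpca_project(Xr, Xq, n_components = min(n_pcs, nrow(Xr$matrix),
                                                  n_ref, n_query))
  p1 <- mnn_pairs(proj$ref_space$ref, proj$ref_space$query, K = k_inter)
  p2 <- mnn_pairs(proj$query_space$ref, proj$query_space$query, K = k_inter)
  pairs <- if (rpca_combine == "union") {
    rbind(p1$pairs, p2$pairs)
  } else {
    key1 <- paste(p1$pairs[, 1], p1$pairs[, 2])
    key2 <- paste(p2$pairs[, 1], p2$pairs[, 2])
    p1$pairs[key1 %in% key2, , drop = FALSE]
  }
  arq <- new_bipartite_adjacency(pairs, n_ref, n_query)

  arr <- intra_mnn(pca_project(Xr, min(n_pcs, nrow(Xr$matrix), n_ref)),
                   K = k_intra)
  aqq <- intra_mnn(pca_project(Xq, min(n_pcs, nrow(Xq$matrix), n_query)),
                   K = k_intra)

  u <- score_reference_cells(arr, ref_labels)
  kq <- estimate_query_types(arq, ref_labels, u)
  kq_prime <- refine_query_types(aqq, kq, hops = hops)
  arq_f <- filter_inter_connections(arq, ref_labels, kq_prime)

  list(arq = arq, arq_filtered = arq_f, arr = arr, aqq = aqq,
       u = u, kq = kq, kq_prime = kq_prime,
       graph = assemble_hybrid_graph(arq_f, arr, aqq))
}
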