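# The three loss terms of the composite training objective, with their
# gradients. Values follow the printed formulas exactly; the query-graph
# term additionally carries a differentiable surrogate, because the printed
# indicator has zero gradient almost everywhere.

#' Hard regularization loss
#'
#' Penalizes embedding distance across the filtered cross-dataset
#' connections:
#' `max(mean over pairs of ||H_i^R - H_j^Q||^2 / d - eps, 0)`.
#' Zero by definition when no connections survive the filter.
#'
#' @param H d x (nR+nQ) joint embedding, reference columns first.
#' @param arq_f Filtered `"bipartite_adjacency"`.
#' @param eps Relaxation parameter (default 0.1).
#' @return Nonnegative scalar.
#' @export
hard_regularization_loss <- function(H, arq_f, eps = 0.1) {
  p <- arq_f$pairs
  if (nrow(p) == 0) return(0)
  d <- nrow(H)
  diff <- H[, p[, 1], drop = FALSE] - H[, arq_f$n_ref + p[, 2], drop = FALSE]
  max(mean(colSums(diff^2)) / d - eps, 0)
}

# Gradient of the hard loss with respect to H (zero matrix when inactive).
hard_regularization_grad <- function(H, arq_f, eps = 0.1) {
  d <- nrow(H); n <- ncol(H)
  p <- arq_f$pairs
  if (nrow(p) == 0 || hard_regularization_loss(H, arq_f, eps) <= 0)
    return(NULL)
  ri <- p[, 1]
  qi <- arq_f$n_ref + p[, 2]
  diff <- H[, ri, drop = FALSE] - H[, qi, drop = FALSE]
  scale <- 2 / (d * nrow(p))
  col_accumulate(scale * diff, ri, n) - col_accumulate(scale * diff, qi, n)
}

#' Cross-entropy loss over the supervised set
#'
#' Mean negative log-probability of the working label, over the reference
#' cells plus any promoted query cells.
#'
#' @param P Probability matrix (types x cells).
#' @param sup Supervised set: list with integer `indices` (columns of `P`)
#'   and integer `labels` (type row indices).
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(P, sup) {
  if (length(sup$indices) == 0)
    stop_data("empty supervised set: cannot train without labeled cells")
  -mean(log(pmax(P[cbind(sup$labels, sup$indices)], 1e-12)))
}

#' Query-graph regularization
#'
#' Encourages adjacent query cells to receive the same predicted type:
#' `max(1 - mean over edges of I[pred(i) == pred(j)] - eps, 0)`.
#' Because the indicator is piecewise constant, training uses a
#' differentiable surrogate in which the indicator is replaced by the
#' agreement probability `sum_t P_ti P_tj`; both values are returned (the
#' indicator for reporting, the surrogate for backpropagation).
#'
#' @param P Probability matrix (types x cells).
#' @param aqq `"intra_adjacency"` over the query cells.
#' @param eps Relaxation parameter (default 0.1).
#' @param query_offset Column of `P` preceding the first query cell
#'   (i.e. nR for a joint matrix; 0 if `P` holds query cells only).
#' @return List with elements `indicator` and `surrogate`.
#' @export
query_graph_regularization <- function(P, aqq, eps = 0.1, query_offset = 0) {
  p <- aqq$pairs
  if (nrow(p) == 0) return(list(indicator = 0, surrogate = 0))
  ci <- query_offset + p[, 1]
  cj <- query_offset + p[, 2]
  pred <- apply(P, 2, which.max)
  agree_ind <- mean(pred[ci] == pred[cj])
  agree_sur <- mean(colSums(P[, ci, drop = FALSE] * P[, cj, drop = FALSE]))
  list(indicator = max(1 - agree_ind - eps, 0),
       surrogate = max(1 - agree_sur - eps, 0))
}

# Gradient of the query surrogate with respect to P (NULL when inactive).
query_graph_grad <- function(P, aqq, eps = 0.1, query_offset = 0) {
  p <- aqq$pairs
  if (nrow(p) == 0) return(NULL)
  if (query_graph_regularization(P, aqq, eps, query_offset)$surrogate <= 0)
    return(NULL)
  n <- ncol(P)
  ci <- query_offset + p[, 1]
  cj <- query_offset + p[, 2]
  scale <- -1 / nrow(p)
  col_accumulate(scale * P[, cj, drop = FALSE], ci, n) +
    col_accumulate(scale * P[, ci, drop = FALSE], cj, n)
}

#' Total training loss
#'
#' Unweighted sum of the hard regularization, cross-entropy and query-graph
#' terms.
#'
#' @param hard,entropy,query Scalar loss terms.
#' @return Their sum.
#' @export
total_loss <- function(hard, entropy, query) hard + entropy + query
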