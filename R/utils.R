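# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

elu <- function(x) ifelse(x > 0, x, expm1(x))

# derivative of ELU, expressed through the pre-activation
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

# standard Gumbel(0, 1) draws
rgumbel <- function(n) -log(-log(stats::runif(n)))

# Accumulate columns of M (d x k) into an d x n matrix by target index:
# out[, j] = sum over {l : idx[l] == j} of M[, l].
col_accumulate <- function(M, idx, n) {
  k <- length(idx)
  stopifnot(ncol(M) == k)
  if (k == 0L) return(matrix(0, nrow(M), n))
  Tm <- Matrix::sparseMatrix(i = seq_len(k), j = idx, x = 1, dims = c(k, n))
  as.matrix(M %*% Tm)
}

# Squared Euclidean cross-distances between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("scgt_data_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("scgt_usage_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("scgt_numeric_error", "error")))
}
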