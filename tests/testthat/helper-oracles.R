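# Independent brute-force oracles used across the test files. These are
# deliberately written with plain loops, separate from any package code
# path they check.

# K nearest rows of b for one point x (Euclidean), as an index set.
oracle_knn_one <- function(x, b, K) {
  d <- sqrt(colSums((t(b) - x)^2))
  order(d)[seq_len(K)]
}

# All mutual-KNN pairs across two point sets, O(n^2).
oracle_mutual_pairs <- function(a, b, K) {
  pairs <- matrix(integer(), 0, 2)
  nn_a <- lapply(seq_len(nrow(a)), function(i) oracle_knn_one(a[i, ], b, K))
  nn_b <- lapply(seq_len(nrow(b)), function(j) oracle_knn_one(b[j, ], a, K))
  for (i in seq_len(nrow(a)))
    for (j in nn_a[[i]])
      if (i %in% nn_b[[j]]) pairs <- rbind(pairs, c(i, j))
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

# Mutual-KNN edges within one point set (self excluded), rows i < j.
oracle_mutual_intra <- function(a, K) {
  n <- nrow(a)
  nn <- lapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(a) - a[i, ])^2))
    d[i] <- Inf
    order(d)[seq_len(K)]
  })
  pairs <- matrix(integer(), 0, 2)
  for (i in seq_len(n))
    for (j in nn[[i]])
      if (i < j && i %in% nn[[j]]) pairs <- rbind(pairs, c(i, j))
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

# Mean silhouette by the textbook a(i)/b(i) definition.
oracle_silhouette <- function(emb, labels) {
  n <- nrow(emb)
  labels <- as.character(labels)
  d <- as.matrix(stats::dist(emb))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Average precision for one cell by exhaustive neighbor ranking.
oracle_ap <- function(emb, labels, i, W) {
  d <- sqrt(colSums((t(emb) - emb[i, ])^2))
  d[i] <- Inf
  nb <- order(d)[seq_len(W)]
  hits <- labels[nb] == labels[i]
  if (sum(hits) == 0) return(0)
  total <- 0
  for (s in seq_len(W))
    if (hits[s]) total <- total + sum(hits[seq_len(s)]) / s
  total / sum(hits)
}

# Dense quadratic-cost kernel attention with the gated local term; the
# oracle the linear-cost implementation must match.
oracle_dense_attention <- function(h, A, layer, tau, g) {
  q <- layer$W_Q %*% h
  k <- layer$W_K %*% h
  v <- layer$W_V %*% h
  n <- ncol(h)
  phi <- function(x) {
    exp(-sum(x^2) / 2) / sqrt(nrow(layer$W_rf)) * exp(drop(layer$W_rf %*% x))
  }
  out <- matrix(0, nrow(v), n)
  A <- as.matrix(A)
  for (i in seq_len(n)) {
    w <- numeric(n)
    for (j in seq_len(n))
      w[j] <- exp(g[j] / tau) * sum(phi(q[, i] / tau) * phi(k[, j] / tau))
    glob <- (v %*% w) / sum(w)
    loc <- v %*% (A[i, ] * scgt:::sigmoid(layer$beta))
    out[, i] <- glob + loc
  }
  out
}

# small convenience wrapper for fast end-to-end fits in unit tests
tiny_control <- function(...) {
  scgt_control(d_enc = 64, d_attn = 32, n_pcs = 15, ...)
}
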