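# The graph-transformer network: a one-layer encoder, kernelized
# Gumbel-Softmax attention layers with a gated local edge term, and a linear
# classifier. Forward and backward passes are written directly against BLAS
# matrix operations; every layer caches what its gradient needs.
#
# Layout convention throughout: columns are cells (reference block first),
# rows are features.

glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Initialize graph-transformer parameters
#'
#' Weights are Glorot-uniform; the local-gate parameter beta starts at 0 so
#' the edge gate opens at sigmoid(0) = 0.5; each attention layer draws its
#' own random-feature matrix with i.i.d. standard normal rows, fixed for the
#' life of the model.
#'
#' @param m_genes Number of common genes (encoder input width).
#' @param n_types Number of reference cell types (classifier output width).
#' @param d_enc Encoder output width (default 256).
#' @param d_attn Attention width (default 64).
#' @param n_layers Number of attention layers (default 2).
#' @param m_rf Number of positive random features (default 35).
#' @param tau Softmax temperature (default 0.25).
#' @param encoder_activation `"elu"` (default) or `"identity"`.
#' @param local_normalize Divide the local edge term by node degree
#'   (default `TRUE`; `FALSE` gives the plain unnormalized sum, which makes
#'   the embedding magnitude scale with node degree).
#' @return An object of class `"gt_params"`.
#' @export
gt_params <- function(m_genes, n_types, d_enc = 256, d_attn = 64,
                      n_layers = 2, m_rf = 35, tau = 0.25,
                      encoder_activation = c("elu", "identity"),
                      local_normalize = TRUE) {
  encoder_activation <- match.arg(encoder_activation)
  stopifnot(tau > 0, n_layers >= 1, m_rf >= 1)
  layers <- vector("list", n_layers)
  d_in <- d_enc
  for (l in seq_len(n_layers)) {
    layers[[l]] <- list(
      W_Q = glorot(d_attn, d_in), W_K = glorot(d_attn, d_in),
      W_V = glorot(d_attn, d_in), beta = 0,
      W_rf = matrix(stats::rnorm(m_rf * d_attn), m_rf, d_attn)
    )
    d_in <- d_attn
  }
  structure(
    list(W_enc = glorot(d_enc, m_genes), b_enc = numeric(d_enc),
         layers = layers,
         W_cls = glorot(n_types, d_attn), b_cls = numeric(n_types),
         d_enc = d_enc, d_attn = d_attn, n_layers = n_layers,
         m_rf = m_rf, tau = tau, m_genes = m_genes, n_types = n_types,
         encoder_activation = encoder_activation,
         local_normalize = local_normalize),
    class = "gt_params"
  )
}

#' Positive random feature map
#'
#' The softmax-kernel feature map
#' `phi(x) = exp(-||x||^2 / 2) / sqrt(m_rf) * exp(W_rf x)` (elementwise
#' exponential), so that `E[phi(x)' phi(y)] = exp(x'y)` when the rows of
#' `W_rf` are i.i.d. standard normal. All entries are strictly positive.
#'
#' @param x A d-vector or d x n matrix of column vectors.
#' @param W_rf m_rf x d random projection matrix.
#' @return m_rf-vector, or m_rf x n matrix for matrix input.
#' @export
random_feature_map <- function(x, W_rf) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(W_rf) && ncol(x) == ncol(W_rf)) x <- t(x)
  m_rf <- nrow(W_rf)
  E <- W_rf %*% x
  out <- exp(sweep(E, 2, colSums(x^2) / 2, "-")) / sqrt(m_rf)
  if (ncol(out) == 1) drop(out) else out
}

encoder_activation_fun <- function(params, Z, deriv = FALSE) {
  if (params$encoder_activation == "identity") {
    if (deriv) return(matrix(1, nrow(Z), ncol(Z))) else return(Z)
  }
  if (deriv) elu_grad(Z) else elu(Z)
}

#' Encoder forward pass
#'
#' One fully connected layer mapping the column-concatenated standardized
#' matrices of both datasets from gene space down to `d_enc` dimensions,
#' followed by the encoder nonlinearity.
#'
#' @param X m x (nR+nQ) matrix, reference columns first.
#' @param params A `"gt_params"` object.
#' @return List with the activation `h` (d_enc x n) and the pre-activation
#'   `Z` (cached for the backward pass).
#' @export
encoder_forward <- function(X, params) {
  if (nrow(X) != ncol(params$W_enc))
    stop_data("encoder expects ", ncol(params$W_enc), " genes, got ", nrow(X))
  Z <- params$W_enc %*% X + params$b_enc
  list(h = encoder_activation_fun(params, Z), Z = Z)
}

# Stabilized phi exponents for the attention layer. Per-query-column shifts
# and one global key-side shift cancel exactly in the attention ratio (it is
# scale-invariant in phi(q_i) and jointly in all weighted phi(k_j)), so
# values and gradients are unaffected while exp() stays in range.
attention_phis <- function(q, k, W_rf, tau, g) {
  xq <- q / tau
  xk <- k / tau
  m_rf <- nrow(W_rf)
  Eq <- sweep(W_rf %*% xq, 2, colSums(xq^2) / 2, "-")
  Phi_q <- exp(sweep(Eq, 2, apply(Eq, 2, max), "-"))
  Ek <- sweep(W_rf %*% xk, 2, colSums(xk^2) / 2 - g / tau, "-")
  Phi_ka <- exp(Ek - max(Ek))  # Gumbel weights folded into the exponent
  list(xq = xq, xk = xk, Phi_q = Phi_q, Phi_ka = Phi_ka)
}

#' Kernelized Gumbel-Softmax attention layer (forward)
#'
#' Computes, for every node i, the global attention term
#' `phi(q_i/tau)' sum_j e^{g_j/tau} phi(k_j/tau) v_j' /
#'  phi(q_i/tau)' sum_w e^{g_w/tau} phi(k_w/tau)`
#' plus the gated local term `sum_{j : A_ij = 1} sigmoid(beta) v_j`, using
#' the two cached key-side sums so the cost is linear in the number of nodes
#' (no n x n matrix is ever formed).
#'
#' @param h d_in x n input columns.
#' @param A Sparse symmetric n x n adjacency of the hybrid graph (0/1).
#' @param layer One element of `params$layers`.
#' @param tau Temperature.
#' @param g Length-n Gumbel draw (one shared draw per source node); use
#'   zeros at inference.
#' @param local_normalize Divide the local sum by node degree.
#' @return List with the output `out` (d x n) and a `cache` for the backward
#'   pass.
#' @export
attention_layer <- function(h, A, layer, tau, g = NULL,
                            local_normalize = FALSE) {
  n <- ncol(h)
  if (is.null(g)) g <- numeric(n)
  q <- layer$W_Q %*% h
  k <- layer$W_K %*% h
  v <- layer$W_V %*% h
  ph <- attention_phis(q, k, layer$W_rf, tau, g)

  S <- tcrossprod(ph$Phi_ka, v)        # m_rf x d
  z <- rowSums(ph$Phi_ka)              # m_rf
  Num <- crossprod(S, ph$Phi_q)        # d x n
  D <- drop(crossprod(ph$Phi_q, z))    # n
  bad <- D <= 0  # shifts keep the ratio exact, so only true underflow matters
  if (any(bad)) {
    warning("attention normalizer underflow for ", sum(bad),
            " node(s); adding eps")
    D[bad] <- D[bad] + 1e-8
  }
  G <- sweep(Num, 2, D, "/")

  sb <- sigmoid(layer$beta)
  M <- as.matrix(v %*% A)              # sum of neighbor values per node
  deg <- NULL
  if (local_normalize) {
    deg <- pmax(Matrix::colSums(A), 1)
    M <- sweep(M, 2, deg, "/")
  }
  out <- G + sb * M

  list(out = out,
       cache = list(h = h, q = q, k = k, v = v, ph = ph, S = S, z = z,
                    D = D, G = G, M = M, deg = deg, A = A, g = g,
                    sb = sb, tau = tau, layer = layer,
                    local_normalize = local_normalize))
}

# Backward pass of attention_layer. Returns gradients for the layer weights
# and for the input h.
attention_backward <- function(cache, dOut) {
  layer <- cache$layer
  tau <- cache$tau
  Phi_q <- cache$ph$Phi_q
  Phi_ka <- cache$ph$Phi_ka
  xq <- cache$ph$xq
  xk <- cache$ph$xk

  # local gated term
  dbeta <- cache$sb * (1 - cache$sb) * sum(cache$M * dOut)
  dM <- cache$sb * dOut
  if (cache$local_normalize) dM <- sweep(dM, 2, cache$deg, "/")
  dv <- as.matrix(dM %*% cache$A)      # A symmetric

  # global term: G = Num / D columnwise
  dNum <- sweep(dOut, 2, cache$D, "/")
  dD <- -colSums(cache$G * dOut) / cache$D
  dPhi_q <- cache$S %*% dNum + outer(cache$z, dD)
  dS <- tcrossprod(Phi_q, dNum)        # m_rf x d
  dz <- drop(Phi_q %*% dD)
  dPhi_ka <- dS %*% cache$v + dz       # dz recycles down columns
  dv <- dv + crossprod(dS, Phi_ka)

  # through the (stabilized) feature maps; the Jacobian of
  # phi(x) = c(x) exp(Wx) gives dx = W'(phi o dphi) - (phi . dphi) x,
  # a formula that holds verbatim for any constant rescaling of phi.
  T1 <- Phi_q * dPhi_q
  dxq <- crossprod(layer$W_rf, T1) - sweep(xq, 2, colSums(T1), "*")
  T2 <- Phi_ka * dPhi_ka
  dxk <- crossprod(layer$W_rf, T2) - sweep(xk, 2, colSums(T2), "*")
  dq <- dxq / tau
  dk <- dxk / tau

  h <- cache$h
  list(
    W_Q = tcrossprod(dq, h), W_K = tcrossprod(dk, h),
    W_V = tcrossprod(dv, h), beta = dbeta,
    dh = crossprod(layer$W_Q, dq) + crossprod(layer$W_K, dk) +
      crossprod(layer$W_V, dv)
  )
}

#' Classifier forward pass
#'
#' Single affine layer projecting the joint embedding into per-type logit
#' space.
#'
#' @param H d x n embedding.
#' @param params A `"gt_params"`.
#' @return `|T_R|` x n logit matrix C.
#' @export
classifier_forward <- function(H, params) {
  params$W_cls %*% H + params$b_cls
}

#' Column-wise softmax probabilities
#'
#' Numerically stabilized by per-column max subtraction; each column of the
#' result sums to one.
#'
#' @param C Logit matrix (types x cells).
#' @return Probability matrix of the same shape.
#' @export
softmax_probabilities <- function(C) {
  E <- exp(sweep(C, 2, apply(C, 2, max), "-"))
  sweep(E, 2, colSums(E), "/")
}

#' Full network forward pass
#'
#' Encoder, all attention layers over the hybrid graph, classifier, softmax.
#'
#' @param X m x (nR+nQ) standardized input, reference columns first.
#' @param A Sparse hybrid-graph adjacency over all nodes.
#' @param params A `"gt_params"`.
#' @param gumbel List of length-n Gumbel draws, one per layer, or `NULL`
#'   for deterministic inference (all zeros).
#' @return List with `H` (joint embedding, d x n), `C` (logits), `P`
#'   (probabilities) and `caches` for the backward pass.
#' @export
gt_forward <- function(X, A, params, gumbel = NULL) {
  enc <- encoder_forward(X, params)
  h <- enc$h
  caches <- vector("list", params$n_layers)
  for (l in seq_len(params$n_layers)) {
    g <- if (is.null(gumbel)) NULL else gumbel[[l]]
    at <- attention_layer(h, A, params$layers[[l]], params$tau, g,
                          params$local_normalize)
    caches[[l]] <- at$cache
    h <- at$out
  }
  H <- h
  C <- classifier_forward(H, params)
  P <- softmax_probabilities(C)
  list(H = H, C = C, P = P, enc = enc, caches = caches, X = X)
}

# Backward through the whole network given dL/dC and an extra dL/dH term
# (from losses acting on the embedding directly). Returns a gradient list
# shaped like the parameters.
gt_backward <- function(fwd, params, dC, dH_extra = NULL) {
  H <- fwd$H
  dW_cls <- tcrossprod(dC, H)
  db_cls <- rowSums(dC)
  dh <- crossprod(params$W_cls, dC)
  if (!is.null(dH_extra)) dh <- dh + dH_extra

  glayers <- vector("list", params$n_layers)
  for (l in rev(seq_len(params$n_layers))) {
    gr <- attention_backward(fwd$caches[[l]], dh)
    glayers[[l]] <- gr[c("W_Q", "W_K", "W_V", "beta")]
    dh <- gr$dh
  }
  dZ <- dh * encoder_activation_fun(params, fwd$enc$Z, deriv = TRUE)
  list(W_enc = tcrossprod(dZ, fwd$X), b_enc = rowSums(dZ),
       layers = glayers,
       W_cls = dW_cls, b_cls = db_cls)
}

#' Save or load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the named weight tensors
#' together with a JSON block of the hyperparameters, so a trained model
#' can be inspected or re-attached to data later.
#'
#' @param params A `"gt_params"` object (trained or freshly initialized);
#'   `scgt_save_model()` also accepts a fitted `"scgt"` object.
#' @param path File path for the checkpoint.
#' @return `scgt_save_model()` returns `path` invisibly;
#'   `scgt_load_model()` returns the `"gt_params"` object.
#' @export
scgt_save_model <- function(params, path) {
  if (inherits(params, "scgt")) params <- params$params
  stopifnot(inherits(params, "gt_params"))
  hyper <- params[c("d_enc", "d_attn", "n_layers", "m_rf", "tau",
                    "m_genes", "n_types", "encoder_activation",
                    "local_normalize")]
  tensors <- c(
    list(W_enc = params$W_enc, b_enc = params$b_enc,
         W_cls = params$W_cls, b_cls = params$b_cls),
    stats::setNames(
      unlist(lapply(seq_along(params$layers), function(l)
        params$layers[[l]][c("W_Q", "W_K", "W_V", "beta", "W_rf")]),
        recursive = FALSE),
      unlist(lapply(seq_along(params$layers), function(l)
        paste0("layer", l, ".", c("W_Q", "W_K", "W_V", "beta", "W_rf"))))))
  saveRDS(list(tensors = tensors,
               hyperparameters_json = jsonlite::toJSON(hyper,
                                                       auto_unbox = TRUE)),
          path)
  invisible(path)
}

#' @rdname scgt_save_model
#' @export
scgt_load_model <- function(path) {
  ar <- readRDS(path)
  hyper <- jsonlite::fromJSON(ar$hyperparameters_json)
  tn <- ar$tensors
  layers <- lapply(seq_len(hyper$n_layers), function(l) {
    pre <- paste0("layer", l, ".")
    list(W_Q = tn[[paste0(pre, "W_Q")]], W_K = tn[[paste0(pre, "W_K")]],
         W_V = tn[[paste0(pre, "W_V")]], beta = tn[[paste0(pre, "beta")]],
         W_rf = tn[[paste0(pre, "W_rf")]])
  })
  structure(
    c(list(W_enc = tn$W_enc, b_enc = tn$b_enc, layers = layers,
           W_cls = tn$W_cls, b_cls = tn$b_cls),
      hyper),
    class = "gt_params")
}

#' Predicted types and confidences for query cells
#'
#' Each query cell gets the argmax type of its probability column and the
#' maximum probability as its confidence. With an `unknown_threshold`, cells
#' whose confidence falls below the threshold are labeled `"Unknown"`. Ties
#' resolve to the smallest type index.
#'
#' @param P Probability matrix (types x cells) with type rownames.
#' @param query_indices Columns of `P` holding query cells.
#' @param unknown_threshold Confidence threshold in (0, 1], or `NULL` to
#'   disable rejection.
#' @return Data frame with `index`, `predicted_type`, `confidence`.
#' @export
predict_with_confidence <- function(P, query_indices,
                                    unknown_threshold = NULL) {
  sub <- P[, query_indices, drop = FALSE]
  best <- apply(sub, 2, which.max)  # first maximum = smallest type index
  conf <- sub[cbind(best, seq_len(ncol(sub)))]
  types <- rownames(P) %||% as.character(seq_len(nrow(P)))
  pred <- types[best]
  if (!is.null(unknown_threshold)) {
    stopifnot(unknown_threshold > 0, unknown_threshold <= 1)
    pred[conf < unknown_threshold] <- "Unknown"
  }
  data.frame(index = query_indices, predicted_type = pred,
             confidence = conf, stringsAsFactors = FALSE)
}
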