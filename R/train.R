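# Training loop: Adam on the full graph, per-epoch loss logging, optional
# promotion of confident query cells into the supervised set.

#' Training and model configuration
#'
#' Collects every tunable of the pipeline in one list. Defaults: Adam with
#' learning rate 1e-3 and weight decay 5e-4 for 300 epochs; relaxation
#' eps = 0.1 for both regularizers; promotion of query cells whose
#' confidence exceeds 0.95, checked once per epoch.
#'
#' @param epochs Number of full-graph gradient steps.
#' @param lr Adam learning rate.
#' @param weight_decay L2 weight decay applied to all weight matrices.
#' @param eps_hard,eps_query Relaxation parameters of the two regularizers.
#' @param promotion Enable confident-cell promotion.
#' @param promotion_threshold Confidence needed for promotion.
#' @param promotion_every Epoch cadence of the promotion check.
#' @param unknown_threshold Confidence below which query predictions are
#'   reported `"Unknown"` (`NULL` disables rejection).
#' @param k_inter,k_intra,n_pcs,hops,rpca_combine Graph-stage settings, see
#'   [build_hybrid_graph()].
#' @param d_enc,d_attn,n_layers,m_rf,tau,encoder_activation,local_normalize
#'   Network settings, see [gt_params()].
#' @param scale_factor LogNormalize scale factor.
#' @param seed Integer seed for all randomness (initialization, Gumbel
#'   noise, any randomized solver).
#' @param verbose Print a progress line every 50 epochs.
#' @return List of class `"scgt_control"`.
#' @export
scgt_control <- function(epochs = 300, lr = 1e-3, weight_decay = 5e-4,
                         eps_hard = 0.1, eps_query = 0.1,
                         promotion = TRUE, promotion_threshold = 0.95,
                         promotion_every = 1,
                         unknown_threshold = NULL,
                         k_inter = 5, k_intra = 10, n_pcs = 30, hops = 4,
                         rpca_combine = "union",
                         d_enc = 256, d_attn = 64, n_layers = 2, m_rf = 35,
                         tau = 0.25, encoder_activation = "elu",
                         local_normalize = TRUE,
                         scale_factor = 1e4, seed = 0, verbose = FALSE) {
  stopifnot(promotion_threshold > 0, promotion_threshold <= 1,
            eps_hard >= 0, eps_query >= 0, epochs >= 0)
  structure(as.list(environment()), class = "scgt_control")
}

adam_state <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else 0 * x
  walk <- function(p) {
    list(W_enc = zero_like(p$W_enc), b_enc = zero_like(p$b_enc),
         layers = lapply(p$layers, function(l)
           list(W_Q = zero_like(l$W_Q), W_K = zero_like(l$W_K),
                W_V = zero_like(l$W_V), beta = 0)),
         W_cls = zero_like(p$W_cls), b_cls = zero_like(p$b_cls))
  }
  list(m = walk(params), v = walk(params), t = 0)
}

# One Adam step; weight decay on weight matrices only (not biases/beta).
adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v, decay) {
    if (decay) g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  fields <- list(c("W_enc", TRUE), c("b_enc", FALSE),
                 c("W_cls", TRUE), c("b_cls", FALSE))
  for (f in fields) {
    nm <- f[1]; dec <- as.logical(f[2])
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]], dec)
    params[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  for (l in seq_along(params$layers)) {
    for (nm in c("W_Q", "W_K", "W_V")) {
      r <- upd(params$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               state$m$layers[[l]][[nm]], state$v$layers[[l]][[nm]], TRUE)
      params$layers[[l]][[nm]] <- r$p
      state$m$layers[[l]][[nm]] <- r$m
      state$v$layers[[l]][[nm]] <- r$v
    }
    r <- upd(params$layers[[l]]$beta, grads$layers[[l]]$beta,
             state$m$layers[[l]]$beta, state$v$layers[[l]]$beta, FALSE)
    params$layers[[l]]$beta <- r$p
    state$m$layers[[l]]$beta <- r$m
    state$v$layers[[l]]$beta <- r$v
  }
  list(params = params, state = state)
}

#' Promote confident query cells into the supervised set
#'
#' Query cells whose prediction confidence exceeds the threshold are added
#' to the supervised set with their predicted label; cells promoted earlier
#' have their working label refreshed to the current prediction. Reference
#' cells are never re-labeled, and the set never shrinks.
#'
#' @param P Probability matrix (types x cells, joint ordering).
#' @param sup Supervised set: list with `indices`, `labels` (integer type
#'   rows) and `n_ref` (count of reference cells, which occupy the first
#'   `n_ref` entries).
#' @param threshold Promotion confidence threshold (default 0.95).
#' @param query_indices Columns of `P` that are query cells.
#' @return The updated supervised set.
#' @export
promote_confident_cells <- function(P, sup, threshold = 0.95,
                                    query_indices = NULL) {
  if (is.null(query_indices))
    query_indices <- setdiff(seq_len(ncol(P)), sup$indices[seq_len(sup$n_ref)])
  sub <- P[, query_indices, drop = FALSE]
  best <- apply(sub, 2, which.max)
  conf <- sub[cbind(best, seq_len(ncol(sub)))]
  hot <- query_indices[conf > threshold]
  promoted <- sup$indices[-seq_len(sup$n_ref)]
  new_idx <- c(promoted, setdiff(hot, promoted))
  # every promoted cell tracks the current prediction, not a stale one
  new_lab <- best[match(new_idx, query_indices)]
  sup$indices <- c(sup$indices[seq_len(sup$n_ref)], new_idx)
  sup$labels <- c(sup$labels[seq_len(sup$n_ref)], new_lab)
  sup
}

#' Train the graph-transformer
#'
#' Full-graph Adam training of the composite objective
#' `L = L_hard + L_entropy + L_query`. Gumbel noise is resampled at every
#' epoch and zeroed for the final inference pass, so the returned embedding
#' and predictions are deterministic given the seed.
#'
#' @param X m x (nR+nQ) standardized input (reference columns first).
#' @param graphs Output of [build_hybrid_graph()].
#' @param ref_label_idx Integer vector: reference labels as type indices.
#' @param types Character vector of type names (rownames of the logits).
#' @param params A `"gt_params"` (initialized by the caller so the seed
#'   covers it).
#' @param control A [scgt_control()].
#' @param true_query_idx Optional integer vector of true query type indices
#'   (evaluation logging only; never trains).
#' @return List with the trained `params`, final deterministic forward
#'   output (`H`, `C`, `P`), the training `log` data frame and the final
#'   supervised set.
#' @export
gt_train <- function(X, graphs, ref_label_idx, types, params, control,
                     true_query_idx = NULL) {
  n_ref <- graphs$arq_filtered$n_ref
  n_query <- graphs$arq_filtered$n_query
  n <- n_ref + n_query
  stopifnot(ncol(X) == n)
  A <- hybrid_adjacency(graphs$graph)
  query_cols <- n_ref + seq_len(n_query)

  sup <- list(indices = seq_len(n_ref), labels = ref_label_idx, n_ref = n_ref)
  state <- adam_state(params)
  log_rows <- vector("list", control$epochs)

  for (epoch in seq_len(control$epochs)) {
    gumbel <- lapply(seq_len(params$n_layers), function(l) rgumbel(n))
    fwd <- gt_forward(X, A, params, gumbel)

    l_hard <- hard_regularization_loss(fwd$H, graphs$arq_filtered,
                                       control$eps_hard)
    l_ent <- cross_entropy_loss(fwd$P, sup)
    l_query <- query_graph_regularization(fwd$P, graphs$aqq,
                                          control$eps_query,
                                          query_offset = n_ref)
    for (nm in c("l_hard", "l_ent")) {
      if (!is.finite(get(nm)))
        stop_numeric("non-finite ", sub("l_", "", nm), " loss at epoch ",
                     epoch)
    }
    if (!is.finite(l_query$surrogate))
      stop_numeric("non-finite query loss at epoch ", epoch)

    # dL/dC: cross-entropy through softmax, plus the query surrogate on P
    dC <- matrix(0, nrow(fwd$P), n)
    Y <- matrix(0, nrow(fwd$P), length(sup$indices))
    Y[cbind(sup$labels, seq_along(sup$indices))] <- 1
    dC_sup <- (fwd$P[, sup$indices, drop = FALSE] - Y) / length(sup$indices)
    dC <- dC + col_accumulate(dC_sup, sup$indices, n)
    dP <- query_graph_grad(fwd$P, graphs$aqq, control$eps_query,
                           query_offset = n_ref)
    if (!is.null(dP)) {
      # softmax backward: dC_i = P_i * (dP_i - <P_i, dP_i>)
      inner <- colSums(fwd$P * dP)
      dC <- dC + fwd$P * sweep(dP, 2, inner, "-")
    }
    dH <- hard_regularization_grad(fwd$H, graphs$arq_filtered,
                                   control$eps_hard)

    grads <- gt_backward(fwd, params, dC, dH)
    st <- adam_step(params, grads, state, control$lr, control$weight_decay)
    params <- st$params
    state <- st$state

    if (control$promotion && epoch %% control$promotion_every == 0)
      sup <- promote_confident_cells(fwd$P, sup,
                                     control$promotion_threshold,
                                     query_indices = query_cols)

    acc <- NA_real_
    if (!is.null(true_query_idx)) {
      pred <- apply(fwd$P[, query_cols, drop = FALSE], 2, which.max)
      acc <- mean(pred == true_query_idx)
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, l_hard = l_hard, l_entropy = l_ent,
      l_query = l_query$indicator, l_query_surrogate = l_query$surrogate,
      l_total = total_loss(l_hard, l_ent, l_query$indicator),
      n_promoted = length(sup$indices) - n_ref, accuracy = acc)
    if (control$verbose && epoch %% 50 == 0)
      message(sprintf("epoch %d: hard %.4f entropy %.4f query %.4f (%d promoted)",
                      epoch, l_hard, l_ent, l_query$indicator,
                      length(sup$indices) - n_ref))
  }

  fwd <- gt_forward(X, A, params, gumbel = NULL)  # deterministic inference
  rownames(fwd$C) <- rownames(fwd$P) <- types
  list(params = params, H = fwd$H, C = fwd$C, P = fwd$P,
       log = if (control$epochs > 0) do.call(rbind, log_rows) else
         data.frame(),
       sup = sup)
}
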