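#' Integrate a labeled reference with an unlabeled query
#'
#' The main fitting function. Runs the full pipeline on a labeled scRNA-seq
#' reference and an unlabeled scATAC-seq query (gene activity matrix):
#' restriction to common genes, LogNormalize and per-gene standardization
#' (each dataset over its own cells), hybrid-graph construction with
#' mutual-nearest-neighbor connections and voting-based filtering of the
#' cross-dataset connections, then semi-supervised training of the
#' kernelized Gumbel-Softmax graph transformer under the composite loss
#' `L = L_hard + L_entropy + L_query`.
#'
#' @param reference [omics_dataset()] with per-cell labels
#'   (modality `"reference"`).
#' @param query [omics_dataset()] without labels (modality `"query"`).
#' @param control A [scgt_control()] holding every tunable, including the
#'   seed.
#' @param true_query_labels Optional ground-truth query labels, used only to
#'   log per-epoch transfer accuracy; they never influence training.
#'
#' @return An object of class `"scgt"` with components:
#' \describe{
#'   \item{embedding}{cells x d joint embedding (reference rows first).}
#'   \item{predictions}{data frame `cell_id`, `predicted_type`,
#'     `confidence` for the query cells (thresholded if
#'     `control$unknown_threshold` is set).}
#'   \item{probabilities}{types x cells posterior matrix over all cells.}
#'   \item{graphs}{the hybrid-graph stage output, including the raw and
#'     filtered cross-dataset adjacencies.}
#'   \item{log}{per-epoch training log.}
#'   \item{params}{trained network parameters.}
#' }
#' @examples
#' sim <- simulate_multiomics(n_ref = 60, n_query = 60, n_genes = 40,
#'                            n_types = 2, seed = 1)
#' fit <- scgt(sim$reference, sim$query,
#'             control = scgt_control(epochs = 5, n_pcs = 10, d_enc = 32,
#'                                    d_attn = 16, seed = 1))
#' head(predict(fit))
#' @export
scgt <- function(reference, query, control = scgt_control(),
                 true_query_labels = NULL) {
  stopifnot(inherits(reference, "omics_dataset"),
            inherits(query, "omics_dataset"))
  if (is.null(reference$labels))
    stop_data("the reference dataset must carry cell type labels")
  cl <- match.call()
  set.seed(control$seed)

  aligned <- align_common_genes(reference, query)
  Xr <- standardize_genes(lognormalize(aligned$reference,
                                       control$scale_factor))
  Xq <- standardize_genes(lognormalize(aligned$query, control$scale_factor))

  graphs <- build_hybrid_graph(Xr, Xq, reference$labels,
                               k_inter = control$k_inter,
                               k_intra = control$k_intra,
                               n_pcs = control$n_pcs, hops = control$hops,
                               rpca_combine = control$rpca_combine)

  types <- sort(unique(reference$labels))
  ref_idx <- match(reference$labels, types)
  true_idx <- NULL
  if (!is.null(true_query_labels))
    true_idx <- match(true_query_labels, types)  # NA for query-only types

  X <- cbind(Xr$matrix, Xq$matrix)
  params <- gt_params(nrow(X), length(types),
                      d_enc = control$d_enc, d_attn = control$d_attn,
                      n_layers = control$n_layers, m_rf = control$m_rf,
                      tau = control$tau,
                      encoder_activation = control$encoder_activation,
                      local_normalize = control$local_normalize)
  trained <- gt_train(X, graphs, ref_idx, types, params, control,
                      true_query_idx = true_idx)

  n_ref <- ncol(Xr$matrix); n_query <- ncol(Xq$matrix)
  query_cols <- n_ref + seq_len(n_query)
  pred <- predict_with_confidence(trained$P, query_cols,
                                  control$unknown_threshold)
  predictions <- data.frame(cell_id = query$cell_ids,
                            predicted_type = pred$predicted_type,
                            confidence = pred$confidence,
                            stringsAsFactors = FALSE)

  emb <- t(trained$H)
  rownames(emb) <- c(paste0("ref:", reference$cell_ids),
                     paste0("query:", query$cell_ids))
  structure(
    list(call = cl, control = control, types = types,
         n_ref = n_ref, n_query = n_query,
         cell_ids = list(reference = reference$cell_ids,
                         query = query$cell_ids),
         ref_labels = reference$labels,
         embedding = emb, probabilities = trained$P,
         predictions = predictions, graphs = graphs,
         log = trained$log, params = trained$params, sup = trained$sup),
    class = "scgt"
  )
}

#' @export
print.scgt <- function(x, ...) {
  cat("scGT integration fit\n")
  cat(sprintf("  %d reference + %d query cells, %d genes, %d types\n",
              x$n_ref, x$n_query, x$params$m_genes, length(x$types)))
  cat(sprintf("  hybrid graph: %d cross-dataset (of %d before filtering), %d + %d within-dataset edges\n",
              nrow(x$graphs$arq_filtered$pairs), nrow(x$graphs$arq$pairs),
              nrow(x$graphs$arr$pairs), nrow(x$graphs$aqq$pairs)))
  if (nrow(x$log) > 0) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  after %d epochs: L_hard %.4f, L_entropy %.4f, L_query %.4f\n",
                last$epoch, last$l_hard, last$l_entropy, last$l_query))
  }
  invisible(x)
}

#' @export
summary.scgt <- function(object, ...) {
  tab <- table(object$predictions$predicted_type)
  out <- list(fit = object, type_counts = tab,
              mean_confidence = mean(object$predictions$confidence),
              n_promoted = length(object$sup$indices) - object$sup$n_ref)
  class(out) <- "summary.scgt"
  out
}

#' @export
print.summary.scgt <- function(x, ...) {
  print(x$fit)
  cat("  predicted query type counts:\n")
  for (nm in names(x$type_counts))
    cat(sprintf("    %-16s %d\n", nm, x$type_counts[[nm]]))
  cat(sprintf("  mean prediction confidence: %.3f\n", x$mean_confidence))
  cat(sprintf("  query cells promoted to supervision: %d\n", x$n_promoted))
  invisible(x)
}

#' Query-cell predictions from a fitted integration
#'
#' Returns the per-query-cell predicted type and confidence, optionally
#' re-thresholded: with `unknown_threshold` set, cells below the threshold
#' are reported as `"Unknown"` without refitting.
#'
#' @param object A fitted `"scgt"` object.
#' @param unknown_threshold Confidence threshold in (0, 1], or `NULL` to
#'   keep the argmax type for every cell.
#' @param ... Unused.
#' @return Data frame `cell_id`, `predicted_type`, `confidence`.
#' @export
predict.scgt <- function(object, unknown_threshold = NULL, ...) {
  query_cols <- object$n_ref + seq_len(object$n_query)
  pred <- predict_with_confidence(object$probabilities, query_cols,
                                  unknown_threshold)
  data.frame(cell_id = object$cell_ids$query,
             predicted_type = pred$predicted_type,
             confidence = pred$confidence, stringsAsFactors = FALSE)
}

#' @export
fitted.scgt <- function(object, ...) object$embedding

#' Plot a fitted integration
#'
#' Scatter of the first two principal components of the joint embedding,
#' colored by cell type (reference labels and query predictions), with
#' plotting symbol distinguishing the modalities.
#'
#' @param x A fitted `"scgt"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scgt <- function(x, ...) {
  emb <- x$embedding
  emb <- sweep(emb, 2, colMeans(emb))
  sv <- svd(emb, nu = 2, nv = 0)
  pcs <- sv$u %*% diag(sv$d[1:2], 2)
  types <- c(x$ref_labels, x$predictions$predicted_type)
  all_types <- sort(unique(types))
  cols <- grDevices::hcl.colors(max(3, length(all_types)), "Dark 3")
  modality <- rep(c(1, 2), c(x$n_ref, x$n_query))
  graphics::plot(pcs, col = cols[match(types, all_types)],
                 pch = c(1, 3)[modality],
                 xlab = "PC1 of joint embedding",
                 ylab = "PC2 of joint embedding", ...)
  graphics::legend("topright", legend = all_types,
                   col = cols[seq_along(all_types)], pch = 16, cex = 0.7)
  invisible(x)
}
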