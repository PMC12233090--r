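# Evaluation suite: silhouette F1 (biology vs. modality mixing), mean
# average precision, cell-type ASW, label-transfer accuracy and the
# normalized confusion matrix.

mean_silhouette <- function(embedding, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    warning("silhouette undefined with a single class; returning NA")
    return(NA_real_)
  }
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(embedding))
  mean(sil[, "sil_width"])
}

#' Silhouette F1 of an integrated embedding
#'
#' Computes the mean silhouette coefficient under the cell-type labeling
#' (`sil_celltype`, larger is better) and under the omics labeling
#' (`sil_omics`, smaller is better), then their harmonic-mean combination
#' `F1 = 2 a b / (a + b)` with `a = 1 - (1 + sil_omics)/2` and
#' `b = (1 + sil_celltype)/2`. Euclidean distances on the embedding.
#'
#' @param embedding cells x d matrix.
#' @param celltype_labels,omics_labels Per-cell labelings; each needs at
#'   least two classes (otherwise `NA` with a warning).
#' @return List with `sil_celltype`, `sil_omics`, `sil_f1`.
#' @export
silhouette_f1 <- function(embedding, celltype_labels, omics_labels) {
  sc <- mean_silhouette(embedding, celltype_labels)
  so <- mean_silhouette(embedding, omics_labels)
  a <- 1 - (1 + so) / 2
  b <- (1 + sc) / 2
  f1 <- if (is.na(a) || is.na(b) || a + b == 0) {
    if (!is.na(a) && !is.na(b)) 0 else NA_real_
  } else 2 * a * b / (a + b)
  list(sil_celltype = sc, sil_omics = so, sil_f1 = f1)
}

#' Mean average precision of cell-type neighborhoods
#'
#' For each cell, the W nearest neighbors (Euclidean, self excluded) are
#' ranked; average precision is the mean, over the type-matched neighbors,
#' of the precision at their ranks, and 0 for cells with no type-matched
#' neighbor among the W. MAP is the mean over cells.
#'
#' @param embedding cells x d matrix.
#' @param celltype_labels Per-cell type labels.
#' @param W Neighborhood size (default 30; must be < number of cells).
#' @return Scalar in `[0, 1]`.
#' @export
mean_average_precision <- function(embedding, celltype_labels, W = 30) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  stopifnot(W >= 1, W < n)
  labels <- as.character(celltype_labels)
  d2 <- cross_dist2(embedding, embedding)
  diag(d2) <- Inf
  ap <- vapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[seq_len(W)]
    match_flag <- labels[nb] == labels[i]
    k <- sum(match_flag)
    if (k == 0) return(0)
    prec_at <- cumsum(match_flag) / seq_len(W)
    sum(prec_at[match_flag]) / k
  }, numeric(1))
  mean(ap)
}

#' Cell-type average silhouette width
#'
#' The mean silhouette under the cell-type labeling, affinely mapped from
#' `[-1, 1]` to `[0, 1]`: `(mean silhouette + 1) / 2`.
#'
#' @inheritParams silhouette_f1
#' @return Scalar in `[0, 1]`.
#' @export
cell_type_asw <- function(embedding, celltype_labels) {
  (mean_silhouette(embedding, celltype_labels) + 1) / 2
}

#' Label-transfer accuracy
#'
#' Fraction of query cells whose predicted type matches the ground truth.
#' In corrected mode (used when the query holds types absent from the
#' reference), an `"Unknown"` prediction counts as correct exactly when the
#' true label is one of the designated unknown types.
#'
#' @param true_labels,predicted_labels Per-query-cell labels.
#' @param unknown_true_labels Character vector of ground-truth types that
#'   an `"Unknown"` prediction should match (default none).
#' @return Scalar in `[0, 1]`.
#' @export
label_transfer_accuracy <- function(true_labels, predicted_labels,
                                    unknown_true_labels = NULL) {
  stopifnot(length(true_labels) == length(predicted_labels))
  ok <- predicted_labels == true_labels
  if (!is.null(unknown_true_labels))
    ok <- ok | (predicted_labels == "Unknown" &
                  true_labels %in% unknown_true_labels)
  mean(ok)
}

#' Row-normalized confusion matrix
#'
#' Rows are true types, columns predicted types (including `"Unknown"` when
#' present); every nonempty row is divided by its row sum.
#'
#' @param true_labels,predicted_labels Per-cell labels.
#' @return Numeric matrix with labeled dimnames.
#' @export
confusion_matrix_normalized <- function(true_labels, predicted_labels) {
  tab <- table(true = true_labels, predicted = predicted_labels)
  m <- unclass(tab)
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  m / rs
}

#' Full metrics report for an integrated embedding
#'
#' Bundles the silhouette F1, MAP, cell-type ASW and, when predictions and
#' ground truth are supplied, the label-transfer accuracy and normalized
#' confusion matrix.
#'
#' @param embedding cells x d joint embedding.
#' @param celltype_labels Per-cell ground-truth types (both modalities).
#' @param omics_labels Per-cell modality labels.
#' @param true_query_labels,predicted_query_labels Optional query-cell
#'   labels for the accuracy/confusion entries.
#' @param unknown_true_labels Passed to [label_transfer_accuracy()].
#' @param W MAP neighborhood size.
#' @return List of class `"scgt_metrics"`.
#' @export
integration_metrics <- function(embedding, celltype_labels, omics_labels,
                                true_query_labels = NULL,
                                predicted_query_labels = NULL,
                                unknown_true_labels = NULL, W = 30) {
  sil <- silhouette_f1(embedding, celltype_labels, omics_labels)
  out <- list(
    sil_celltype = sil$sil_celltype, sil_omics = sil$sil_omics,
    sil_f1 = sil$sil_f1,
    map_score = mean_average_precision(embedding, celltype_labels,
                                       W = min(W, nrow(embedding) - 1)),
    celltype_asw = cell_type_asw(embedding, celltype_labels)
  )
  if (!is.null(true_query_labels) && !is.null(predicted_query_labels)) {
    out$accuracy <- label_transfer_accuracy(true_query_labels,
                                            predicted_query_labels,
                                            unknown_true_labels)
    out$confusion <- confusion_matrix_normalized(true_query_labels,
                                                 predicted_query_labels)
  }
  class(out) <- "scgt_metrics"
  out
}

#' @export
print.scgt_metrics <- function(x, ...) {
  cat("integration metrics\n")
  for (nm in c("sil_celltype", "sil_omics", "sil_f1", "map_score",
               "celltype_asw", "accuracy"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-14s %.4f\n", nm, x[[nm]]))
  if (!is.null(x$confusion)) {
    cat("  confusion (rows = true, row-normalized):\n")
    print(round(x$confusion, 3))
  }
  invisible(x)
}
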