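# Synthetic paired-modality generator. Emulates the structure the
# integration task assumes: two count-like matrices whose cells share a
# latent cluster structure, with a modality-specific per-gene shift, count
# overdispersion, dropout sparsity, and optionally types present in only
# one of the datasets.

#' Generate paired synthetic reference/query datasets
#'
#' Cell types are defined by latent per-gene log-mean vectors shared across
#' the two modalities; the query additionally receives a per-gene modality
#' offset (constant across its cells). Counts are negative-binomial around
#' `exp(latent mean)` with fixed dispersion, then randomly thinned until
#' the requested fraction of zero entries is reached. The reference carries
#' its labels; query labels are returned separately for evaluation only.
#'
#' @param n_ref,n_query Cell counts (defaults 800 each).
#' @param n_genes Number of genes (default 300).
#' @param n_types Number of distinct types overall (default 4).
#' @param type_proportions Sampling weights over the types (default equal);
#'   renormalized within each dataset over the types it contains.
#' @param cluster_separation Expected Euclidean distance between the latent
#'   log-mean vectors of two types (default 16, giving clearly separated
#'   clusters).
#' @param omics_shift_scale Standard deviation of the per-gene modality
#'   offset added to the query latent means (default 0.5).
#' @param noise_sd Per-cell, per-gene latent noise standard deviation
#'   (default 0.3).
#' @param sparsity Target fraction of zero entries per modality, reached by
#'   thinning (default 0.6); a warning is issued if the counts are already
#'   sparser than requested.
#' @param ref_only_types,query_only_types Types (names like `"Type3"` or
#'   integer indices) present only in the respective dataset; must be
#'   disjoint.
#' @param dispersion Negative-binomial dispersion (default 0.5, i.e.
#'   `size = 2`).
#' @param seed Optional seed set before generation; a fixed seed makes the
#'   output byte-identical across runs.
#' @return List with `reference` (labeled [omics_dataset()]), `query`
#'   (unlabeled) and `query_labels` (ground truth, evaluation only).
#' @export
simulate_multiomics <- function(n_ref = 800, n_query = 800, n_genes = 300,
                                n_types = 4, type_proportions = NULL,
                                cluster_separation = 16,
                                omics_shift_scale = 0.5, noise_sd = 0.3,
                                sparsity = 0.6,
                                ref_only_types = character(),
                                query_only_types = character(),
                                dispersion = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sparsity >= 0, sparsity < 1, dispersion > 0, n_types >= 1)
  types <- paste0("Type", seq_len(n_types))
  as_type <- function(x) if (is.numeric(x)) types[x] else as.character(x)
  ref_only_types <- as_type(ref_only_types)
  query_only_types <- as_type(query_only_types)
  if (!all(c(ref_only_types, query_only_types) %in% types))
    stop_usage("only-lists must name types among ",
               paste(types, collapse = ", "))
  if (length(intersect(ref_only_types, query_only_types)) > 0)
    stop_usage("a type cannot be exclusive to both datasets")
  props <- type_proportions %||% rep(1 / n_types, n_types)
  if (length(props) != n_types || abs(sum(props) - 1) > 1e-8)
    stop_usage("type_proportions must have one entry per type and sum to 1")
  names(props) <- types
  ref_types <- setdiff(types, query_only_types)
  query_types <- setdiff(types, ref_only_types)
  if (length(ref_types) == 0 || length(query_types) == 0)
    stop_usage("each dataset must contain at least one type")

  genes <- sprintf("Gene%03d", seq_len(n_genes))
  base_mean <- stats::rnorm(n_genes, 0, 1)
  # per-type deviations with E||mu_s - mu_t|| = cluster_separation
  type_effect <- matrix(stats::rnorm(n_genes * n_types, 0,
                                     cluster_separation / sqrt(2 * n_genes)),
                        n_genes, n_types, dimnames = list(genes, types))
  omics_offset <- stats::rnorm(n_genes, 0, omics_shift_scale)

  draw_modality <- function(n_cells, avail, offset, prefix) {
    p <- props[avail] / sum(props[avail])
    labels <- sample(avail, n_cells, replace = TRUE, prob = p)
    latent <- base_mean + type_effect[, labels, drop = FALSE] + offset +
      matrix(stats::rnorm(n_genes * n_cells, 0, noise_sd), n_genes, n_cells)
    counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = exp(latent),
                                    size = 1 / dispersion),
                     n_genes, n_cells)
    counts <- thin_to_sparsity(counts, sparsity)
    colnames(counts) <- paste0(prefix, seq_len(n_cells))
    rownames(counts) <- genes
    list(counts = counts, labels = labels)
  }
  ref <- draw_modality(n_ref, ref_types, 0, "refcell")
  qry <- draw_modality(n_query, query_types, omics_offset, "querycell")

  list(
    reference = omics_dataset(ref$counts, genes, colnames(ref$counts),
                              labels = ref$labels, modality = "reference"),
    query = omics_dataset(qry$counts, genes, colnames(qry$counts),
                          modality = "query"),
    query_labels = qry$labels
  )
}

# Zero out uniformly chosen nonzero entries until the matrix reaches the
# target fraction of zeros.
thin_to_sparsity <- function(counts, sparsity) {
  n_total <- length(counts)
  nz <- which(counts != 0)
  target_zero <- round(sparsity * n_total)
  extra <- target_zero - (n_total - length(nz))
  if (extra > 0) {
    counts[sample(nz, extra)] <- 0
  } else if (extra < 0 && sparsity > 0) {
    warning(sprintf("counts already sparser (%.1f%%) than requested (%.1f%%)",
                    100 * (1 - length(nz) / n_total), 100 * sparsity))
  }
  counts
}

#' Plant type-violating connections into a bipartite adjacency
#'
#' Test harness for the connection filter: replaces a stated fraction of
#' the cross-dataset pairs with uniformly drawn pairs whose endpoints carry
#' different true types, so filter precision/recall can be measured against
#' ground truth.
#'
#' @param arq A `"bipartite_adjacency"`.
#' @param flip_fraction Fraction of pairs to replace, in `[0, 1]`.
#' @param ref_labels,query_labels True types of the reference and query
#'   cells.
#' @return The corrupted `"bipartite_adjacency"` (same number of pairs).
#' @export
plant_connection_noise <- function(arq, flip_fraction, ref_labels,
                                   query_labels) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 1)
  p <- arq$pairs
  n_flip <- round(flip_fraction * nrow(p))
  if (n_flip == 0) return(arq)
  flip <- sample(nrow(p), n_flip)
  for (k in flip) {
    repeat {
      i <- sample(arq$n_ref, 1)
      j <- sample(arq$n_query, 1)
      if (ref_labels[i] != query_labels[j]) break
    }
    p[k, ] <- c(i, j)
  }
  new_bipartite_adjacency(p, arq$n_ref, arq$n_query)
}

#' Connection correctness rate
#'
#' Fraction of cross-dataset pairs whose endpoints carry the same true
#' type; the quantity the filter is designed to raise.
#'
#' @inheritParams plant_connection_noise
#' @return Scalar in `[0, 1]` (`NaN` for an empty adjacency).
#' @export
connection_correctness <- function(arq, ref_labels, query_labels) {
  p <- arq$pairs
  if (nrow(p) == 0) return(NaN)
  mean(ref_labels[p[, 1]] == query_labels[p[, 2]])
}
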