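#' Construct a single-cell omics dataset
#'
#' Container for a genes x cells matrix (raw counts for scRNA-seq, gene
#' activity scores for scATAC-seq) together with gene/cell identifiers, an
#' optional per-cell label vector and a modality tag.
#'
#' @param matrix Numeric matrix (base or [Matrix::Matrix]) with genes in rows
#'   and cells in columns.
#' @param gene_ids Character vector of gene identifiers, one per row. No
#'   duplicates allowed.
#' @param cell_ids Character vector of cell identifiers, one per column.
#' @param labels Optional character vector of per-cell type labels. Required
#'   for the reference modality, absent for the query.
#' @param modality Either `"reference"` (labeled scRNA-seq) or `"query"`
#'   (unlabeled scATAC-seq gene activity).
#'
#' @return An object of class `"omics_dataset"`: a list with elements
#'   `matrix`, `gene_ids`, `cell_ids`, `labels`, `modality`.
#' @examples
#' m <- matrix(rpois(6, 2), nrow = 3,
#'             dimnames = list(c("G1", "G2", "G3"), c("c1", "c2")))
#' ds <- omics_dataset(m, rownames(m), colnames(m),
#'                     labels = c("T", "B"), modality = "reference")
#' ds
#' @export
omics_dataset <- function(matrix, gene_ids, cell_ids, labels = NULL,
                          modality = c("reference", "query")) {
  modality <- match.arg(modality)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(matrix) != length(gene_ids))
    stop_data("matrix has ", nrow(matrix), " rows but ", length(gene_ids),
              " gene ids")
  if (ncol(matrix) != length(cell_ids))
    stop_data("matrix has ", ncol(matrix), " columns but ", length(cell_ids),
              " cell ids")
  if (anyDuplicated(gene_ids))
    stop_data("duplicate gene ids: ",
              paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 3),
                    collapse = ", "))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(cell_ids))
      stop_data("got ", length(labels), " labels for ", length(cell_ids),
                " cells")
  }
  if (modality == "reference" && is.null(labels))
    stop_data("reference datasets require per-cell labels")
  if (modality == "query" && !is.null(labels))
    stop_data("query datasets are unlabeled; keep ground-truth labels ",
              "outside the dataset for evaluation")
  structure(
    list(matrix = matrix, gene_ids = gene_ids, cell_ids = cell_ids,
         labels = labels, modality = modality),
    class = "omics_dataset"
  )
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset (%s): %d genes x %d cells\n",
              x$modality, length(x$gene_ids), length(x$cell_ids)))
  if (!is.null(x$labels))
    cat("  cell types:", paste(sort(unique(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) dim(x$matrix)

#' Load a dataset from disk
#'
#' Reads a genes x cells matrix in one of three dialects:
#' \describe{
#'   \item{mtx}{Matrix Market file plus sidecar text files with one gene id
#'     per line and one cell id per line. By default these are looked up next
#'     to the matrix as `genes.tsv`/`barcodes.tsv`; override with
#'     `genes_path`/`cells_path`.}
#'   \item{csv}{Delimited text with gene identifiers in the first column and
#'     a header row of cell identifiers.}
#'   \item{h5ad}{AnnData container, converted through the `python` `anndata`
#'     package found on the PATH. Cells x genes on disk (the AnnData
#'     convention), transposed on load; labels are read from the `obs` column
#'     named by `label_key`.}
#' }
#' For `mtx` and `csv` the on-disk orientation must be declared through
#' `orientation`; `h5ad` is always cells x genes on disk.
#'
#' @param path Path to the matrix file.
#' @param format One of `"mtx"`, `"csv"`, `"h5ad"`.
#' @param labels_path Optional path to a label file with one type per line
#'   (ignored for `h5ad`; use `label_key`).
#' @param modality `"reference"` or `"query"`.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`,
#'   describing the on-disk layout for `mtx`/`csv`.
#' @param genes_path,cells_path Sidecar id files for `mtx`.
#' @param label_key `obs` column holding cell types in an `h5ad` file.
#' @param sep Field separator for `csv` (default `","`; use `"\t"` for TSV).
#'
#' @return An [omics_dataset()].
#' @export
load_dataset <- function(path, format = c("mtx", "csv", "h5ad"),
                         labels_path = NULL,
                         modality = c("reference", "query"),
                         orientation = c("genes_by_cells", "cells_by_genes"),
                         genes_path = NULL, cells_path = NULL,
                         label_key = "cell_type", sep = ",") {
  format <- match.arg(format)
  modality <- match.arg(modality)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_data("file not found: ", path)

  loaded <- switch(format,
    mtx = read_mtx_triplet(path, genes_path, cells_path),
    csv = read_dense_table(path, sep),
    h5ad = read_h5ad_via_python(path, label_key)
  )
  mat <- loaded$matrix
  genes <- loaded$genes
  cells <- loaded$cells
  labels <- loaded$labels

  if (format != "h5ad" && orientation == "cells_by_genes") {
    mat <- Matrix::t(mat)
    tmp <- genes; genes <- cells; cells <- tmp
  }
  if (!is.null(labels_path)) {
    if (!file.exists(labels_path)) stop_data("label file not found: ", labels_path)
    labels <- readLines(labels_path)
    labels <- labels[nzchar(labels)]
  }
  if (!is.null(labels) && length(labels) != ncol(mat))
    stop_data("label file has ", length(labels), " entries for ", ncol(mat),
              " cells")
  if (modality == "query") labels <- NULL
  omics_dataset(mat, genes, cells, labels = labels, modality = modality)
}

read_mtx_triplet <- function(path, genes_path, cells_path) {
  dir <- dirname(path)
  genes_path <- genes_path %||% file.path(dir, "genes.tsv")
  cells_path <- cells_path %||% file.path(dir, "barcodes.tsv")
  mat <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop_data("failed to parse ", path, ": ",
                                                conditionMessage(e)))
  for (p in c(genes_path, cells_path))
    if (!file.exists(p)) stop_data("sidecar id file not found: ", p)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  list(matrix = mat, genes = genes, cells = cells, labels = NULL)
}

read_dense_table <- function(path, sep) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, comment.char = ""),
    error = function(e) stop_data("failed to parse ", path, ": ",
                                  conditionMessage(e)))
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop_data("non-numeric entries in ", path)
  list(matrix = mat, genes = rownames(df), cells = colnames(df), labels = NULL)
}

# Convert an AnnData .h5ad container to Matrix Market + sidecars through the
# python anndata package, then read those. Avoids requiring an R HDF5 binding.
read_h5ad_via_python <- function(path, label_key) {
  py <- Sys.which("python")
  if (py == "") stop_data("h5ad input requires a `python` with anndata on PATH")
  out <- tempfile("h5ad_dump_")
  dir.create(out)
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  script <- sprintf('
import sys, scipy.io, scipy.sparse, anndata
ad = anndata.read_h5ad(sys.argv[1])
out = sys.argv[2]
X = scipy.sparse.csr_matrix(ad.X)
scipy.io.mmwrite(out + "/matrix.mtx", X)
open(out + "/obs.txt", "w").write("\\n".join(map(str, ad.obs_names)) + "\\n")
open(out + "/var.txt", "w").write("\\n".join(map(str, ad.var_names)) + "\\n")
key = sys.argv[3]
if key in ad.obs.columns:
    open(out + "/labels.txt", "w").write("\\n".join(map(str, ad.obs[key])) + "\\n")
')
  status <- system2(py, c("-c", shQuote(script), shQuote(path), shQuote(out),
                          shQuote(label_key)), stdout = FALSE, stderr = FALSE)
  if (status != 0)
    stop_data("failed to convert h5ad file ", path)
  mat <- Matrix::readMM(file.path(out, "matrix.mtx"))  # cells x genes
  cells <- readLines(file.path(out, "obs.txt"))
  genes <- readLines(file.path(out, "var.txt"))
  labels <- NULL
  lf <- file.path(out, "labels.txt")
  if (file.exists(lf)) labels <- readLines(lf)
  list(matrix = Matrix::t(mat), genes = genes, cells = cells, labels = labels)
}

#' Restrict two datasets to their common genes
#'
#' Diagonal integration operates on the genes shared by the reference
#' expression matrix and the query gene activity matrix. Both outputs carry
#' the intersection, sorted lexicographically, in identical order.
#'
#' @param ref,query [omics_dataset()] objects.
#' @param case_insensitive Lowercase identifiers on both sides before
#'   matching (default exact, case-sensitive matching).
#' @return List with elements `reference` and `query`.
#' @export
align_common_genes <- function(ref, query, case_insensitive = FALSE) {
  gr <- ref$gene_ids
  gq <- query$gene_ids
  if (case_insensitive) {
    gr <- tolower(gr); gq <- tolower(gq)
  }
  common <- sort(intersect(gr, gq))
  if (length(common) == 0L)
    stop_data("no genes shared between reference and query; harmonize gene ",
              "identifiers (species, case, symbol vs. ensembl) and retry")
  ir <- match(common, gr)
  iq <- match(common, gq)
  sub <- function(ds, idx) {
    omics_dataset(ds$matrix[idx, , drop = FALSE], ds$gene_ids[idx],
                  ds$cell_ids, labels = ds$labels, modality = ds$modality)
  }
  list(reference = sub(ref, ir), query = sub(query, iq))
}

#' Log-normalize a dataset
#'
#' Library-size normalization: each entry becomes
#' `log(1 + scale_factor * x / colsum)`, the standard LogNormalize transform.
#' Columns that sum to zero pass through as zeros with a warning.
#'
#' @param ds An [omics_dataset()] with nonnegative entries.
#' @param scale_factor Positive scale applied after depth normalization
#'   (default `1e4`).
#' @return The dataset with the transformed matrix.
#' @export
lognormalize <- function(ds, scale_factor = 1e4) {
  stopifnot(scale_factor > 0)
  m <- as.matrix(ds$matrix)
  if (any(m < 0)) stop_data("negative entries; lognormalize expects counts ",
                            "or activity scores >= 0")
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell column(s) passed through unchanged")
    cs[zero] <- 1
  }
  m <- log1p(sweep(m, 2, cs / scale_factor, "/"))
  ds$matrix <- m
  ds
}

#' Standardize each gene to zero mean and unit variance
#'
#' Per-gene z-scoring within one dataset: `(x - mu_i) / theta_i`, with the
#' population (divide by n) standard deviation. Genes with zero variance are
#' set to all-zero rows. Reference and query are standardized independently,
#' each over its own cells.
#'
#' @param ds An [omics_dataset()], normally log-normalized first.
#' @return An object of class `"standardized_matrix"`: list with the dense
#'   `matrix`, `per_gene_mean`, `per_gene_sd`, plus `gene_ids`, `cell_ids`,
#'   `labels`, `modality` carried over.
#' @export
standardize_genes <- function(ds) {
  m <- as.matrix(ds$matrix)
  n <- ncol(m)
  mu <- rowMeans(m)
  centered <- m - mu
  theta <- sqrt(rowSums(centered^2) / n)
  ok <- theta > 0
  out <- centered
  out[ok, ] <- centered[ok, , drop = FALSE] / theta[ok]
  out[!ok, ] <- 0
  structure(
    list(matrix = out, per_gene_mean = mu, per_gene_sd = theta,
         gene_ids = ds$gene_ids, cell_ids = ds$cell_ids,
         labels = ds$labels, modality = ds$modality),
    class = "standardized_matrix"
  )
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat(sprintf("standardized_matrix: %d genes x %d cells (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$modality))
  invisible(x)
}

#' Write per-cell predictions to a TSV file
#'
#' Three columns: `cell_id`, `predicted_type`, `confidence`. Confidence is
#' written with six decimals so repeated runs with the same seed produce
#' byte-identical files.
#'
#' @param predictions Data frame with columns `cell_id`, `predicted_type`,
#'   `confidence`.
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  df <- data.frame(cell_id = predictions$cell_id,
                   predicted_type = predictions$predicted_type,
                   confidence = sprintf("%.6f", predictions$confidence))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
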