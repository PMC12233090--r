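# Projections, mutual-nearest-neighbor graphs, reference scoring, query
# type estimation/refinement, connection filtering and graph assembly.

std_mat <- function(m) {
  ds <- omics_dataset(m, paste0("G", seq_len(nrow(m))),
                      paste0("c", seq_len(ncol(m))), modality = "query")
  st <- standardize_genes(ds)
  st
}

test_that("pca_project matches direct SVD scores and explained variance", {
  set.seed(3)
  m <- matrix(rnorm(100 * 80), 100, 80)
  st <- std_mat(m)
  emb <- pca_project(st, 5)
  sv <- svd(st$matrix)
  scores <- t(st$matrix) %*% sv$u[, 1:5]
  # per-component equality up to sign
  for (j in 1:5)
    expect_true(max(abs(emb[, j] - scores[, j])) < 1e-8 ||
                max(abs(emb[, j] + scores[, j])) < 1e-8)
  expect_equal(colSums(emb^2), sv$d[1:5]^2, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("identical cells receive identical PCA embeddings", {
  m <- matrix(rnorm(40), 10, 4)
  m <- cbind(m, m[, 1])  # duplicate a cell
  emb <- pca_project(m, 3)
  expect_equal(emb[1, ], emb[5, ], tolerance = 1e-10)
  expect_error(pca_project(m, 50), "exceeds")
})

test_that("full-rank PCA of orthogonal one-hot cells preserves distances", {
  m <- diag(4)
  emb <- pca_project(m, 4)
  expect_equal(as.matrix(stats::dist(emb)), as.matrix(stats::dist(t(m))),
               tolerance = 1e-8)
})

test_that("rpca on identical datasets collapses to one space up to sign", {
  set.seed(4)
  m <- matrix(rnorm(50 * 30), 50, 30)
  st <- std_mat(m)
  pr <- rpca_project(st, st, 5)
  for (j in 1:5)
    expect_true(max(abs(pr$ref_space$ref[, j] - pr$query_space$ref[, j])) < 1e-8 ||
                max(abs(pr$ref_space$ref[, j] + pr$query_space$ref[, j])) < 1e-8)
})

test_that("rpca projection of ref onto its own PCs equals standard PCA scores", {
  set.seed(5)
  mr <- matrix(rnorm(50 * 40), 50, 40)
  mq <- matrix(rnorm(50 * 35), 50, 35)
  str <- std_mat(mr); stq <- std_mat(mq)
  pr <- rpca_project(str, stq, 10)
  expect_equal(pr$ref_space$ref, pca_project(str, 10), tolerance = 1e-10)
  expect_equal(pr$query_space$query, pca_project(stq, 10), tolerance = 1e-10)
  expect_error(rpca_project(str, stq, 100), "exceeds")
})

test_that("rank-1 rpca coordinates reproduce distances along the axis", {
  v <- c(1, -1, 0.5)
  coef_r <- c(-2, 1, 3, 0)
  m <- outer(v, coef_r)
  st <- list(matrix = m, gene_ids = NULL)
  class(st) <- "standardized_matrix"
  pr <- rpca_project(st, st, 1)
  d <- as.matrix(stats::dist(pr$ref_space$ref))
  expect_equal(d, as.matrix(stats::dist(coef_r * sqrt(sum(v^2)))),
               tolerance = 1e-8)
})

test_that("mnn_pairs handles forced and geometric toy cases", {
  a <- matrix(0, 1, 1)
  b <- matrix(0, 1, 1)
  expect_equal(mnn_pairs(a, b, K = 1)$pairs,
               matrix(c(1L, 1L), 1, dimnames = list(NULL, c("ref", "query"))))

  a2 <- matrix(c(0, 100), 2, 1)   # two reference points
  b2 <- matrix(1, 1, 1)           # one query point near the first
  got <- mnn_pairs(a2, b2, K = 1)
  expect_equal(unname(got$pairs), matrix(c(1L, 1L), 1))

  expect_warning(mnn_pairs(a2, b2, K = 5), "clipped")
})

test_that("mnn_pairs equals the brute-force mutual-KNN oracle", {
  set.seed(21)
  a <- matrix(rnorm(60), 30, 2)
  b <- matrix(rnorm(60), 30, 2)
  got <- mnn_pairs(a, b, K = 3)
  expect_equal(unname(got$pairs), unname(oracle_mutual_pairs(a, b, 3)))
})

test_that("intra_mnn equals its oracle and handles degenerate sets", {
  set.seed(22)
  a <- matrix(rnorm(80), 40, 2)
  got <- intra_mnn(a, K = 3)
  expect_equal(unname(got$pairs), unname(oracle_mutual_intra(a, 3)))

  expect_warning(e <- intra_mnn(matrix(0, 1, 2), K = 1), "fewer than 2")
  expect_equal(nrow(e$pairs), 0L)
  two <- intra_mnn(matrix(c(0, 1), 2, 1), K = 1)
  expect_equal(unname(two$pairs), matrix(c(1L, 2L), 1))
})

test_that("reference purity scores count same-type neighbors", {
  # cell 1 neighbors {2,3} same type; cell 4 neighbors {5,6} mixed with 2
  # same and 2 other across its edges; cell 7 isolated
  pairs <- rbind(c(1, 2), c(1, 3), c(4, 5), c(4, 6), c(4, 2), c(4, 3))
  arr <- scgt:::new_intra_adjacency(pairs, 7L)
  labels <- c("A", "A", "A", "B", "B", "B", "C")
  u <- score_reference_cells(arr, labels)
  expect_equal(u[1], 1)
  expect_equal(u[4], 0.5)  # neighbors 5,6 are B; 2,3 are A
  expect_equal(u[7], 0)
})

test_that("query type estimation takes the purity-weighted argmax", {
  arq <- scgt:::new_bipartite_adjacency(
    rbind(c(1L, 1L), c(2L, 2L), c(3L, 2L), c(4L, 3L)), 4L, 3L)
  labels <- c("T", "A", "B", "A")
  u <- c(0.8, 0.9, 0.4, 0)
  kq <- estimate_query_types(arq, labels, u)
  expect_equal(kq[1], "T")            # one neighbor with u = 0.8
  expect_equal(kq[2], "A")            # A mass 0.9 beats B mass 0.4
  expect_equal(kq[3], "Unknown")      # only neighbor has u = 0
})

test_that("isolated query cells and zero-score ties become Unknown", {
  arq <- scgt:::new_bipartite_adjacency(matrix(integer(), 0, 2), 2L, 2L)
  kq <- estimate_query_types(arq, c("A", "B"), c(1, 1))
  expect_equal(kq, c("Unknown", "Unknown"))
})

test_that("refinement votes over multi-hop neighborhoods", {
  # chain 1-2-3-4-5; all estimated T except cell 1
  chain <- scgt:::new_intra_adjacency(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)), 5L)
  kq <- c("X", "T", "T", "T", "T")
  expect_equal(refine_query_types(chain, kq, hops = 4)[1], "T")

  # star: center 1 with 3 votes A, 2 votes B
  star <- scgt:::new_intra_adjacency(cbind(1L, 2:6), 6L)
  kq2 <- c("B", "A", "A", "A", "B", "B")
  expect_equal(refine_query_types(star, kq2, hops = 1)[1], "A")

  # isolated cell falls back to its own estimate
  iso <- scgt:::new_intra_adjacency(rbind(c(2L, 3L)), 3L)
  expect_equal(refine_query_types(iso, c("T", "A", "A"), hops = 4)[1], "T")

  # Unknown votes are ignored
  star2 <- scgt:::new_intra_adjacency(cbind(1L, 2:4), 4L)
  expect_equal(refine_query_types(star2, c("A", "Unknown", "Unknown", "B"),
                                  hops = 1)[1], "B")
})

test_that("hops = 0 reduces refinement to the raw estimate", {
  set.seed(8)
  pairs <- oracle_mutual_intra(matrix(rnorm(40), 20, 2), 3)
  aqq <- scgt:::new_intra_adjacency(pairs, 20L)
  kq <- sample(c("A", "B", "Unknown"), 20, replace = TRUE)
  expect_equal(refine_query_types(aqq, kq, hops = 0), kq)
})

test_that("filtering keeps exactly the type-consistent connections", {
  arq <- scgt:::new_bipartite_adjacency(
    rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(2L, 3L), c(3L, 3L)), 3L, 3L)
  ref_labels <- c("A", "B", "C")
  kqp <- c("A", "B", "Unknown")
  out <- filter_inter_connections(arq, ref_labels, kqp)
  expect_equal(unname(out$pairs), rbind(c(1L, 1L), c(2L, 2L)))

  same <- filter_inter_connections(arq, c("A", "A", "A"),
                                   c("A", "A", "A"))
  expect_equal(same$pairs, arq$pairs)

  expect_warning(
    none <- filter_inter_connections(arq, ref_labels, c("B", "C", "A")),
    "filtered out")
  expect_equal(nrow(none$pairs), 0L)
})

test_that("hybrid graph assembly offsets query indices and tags provenance", {
  arq_f <- scgt:::new_bipartite_adjacency(rbind(c(1L, 1L)), 2L, 3L)
  arr <- scgt:::new_intra_adjacency(rbind(c(1L, 2L)), 2L)
  aqq <- scgt:::new_intra_adjacency(rbind(c(2L, 3L)), 3L)
  g <- assemble_hybrid_graph(arq_f, arr, aqq)
  expect_equal(g$n_nodes, 5L)
  expect_equal(nrow(g$edges), 3L)
  inter <- g$edges[g$edges$provenance == "inter", ]
  expect_equal(c(inter$from, inter$to), c(1L, 3L))  # query node 1 -> 2+1
  intra_q <- g$edges[g$edges$provenance == "intra_query", ]
  expect_equal(c(intra_q$from, intra_q$to), c(4L, 5L))

  empty <- assemble_hybrid_graph(
    scgt:::new_bipartite_adjacency(matrix(integer(), 0, 2), 2L, 3L),
    scgt:::new_intra_adjacency(matrix(integer(), 0, 2), 2L),
    scgt:::new_intra_adjacency(matrix(integer(), 0, 2), 3L))
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(empty$n_nodes, 5L)
})

test_that("filtering never adds connections and the full stage runs", {
  sim <- simulate_multiomics(n_ref = 120, n_query = 120, n_genes = 80,
                             n_types = 3, seed = 31)
  Xr <- standardize_genes(lognormalize(sim$reference))
  Xq <- standardize_genes(lognormalize(sim$query))
  g <- build_hybrid_graph(Xr, Xq, sim$reference$labels, n_pcs = 15)
  expect_lte(nrow(g$arq_filtered$pairs), nrow(g$arq$pairs))
  expect_true(all(g$u >= 0 & g$u <= 1))
  expect_true(all(g$kq_prime[g$kq_prime != "Unknown"] %in%
                    sim$reference$labels))
  # every surviving pair is type-consistent with the refined estimate
  p <- g$arq_filtered$pairs
  expect_true(all(sim$reference$labels[p[, 1]] == g$kq_prime[p[, 2]]))
})
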