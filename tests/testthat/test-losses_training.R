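# Loss terms, promotion of confident cells, gradient correctness, and the
# training loop.

bip <- function(pairs, n_ref, n_query)
  scgt:::new_bipartite_adjacency(pairs, n_ref, n_query)
intra <- function(pairs, n) scgt:::new_intra_adjacency(pairs, n)

test_that("hard regularization matches closed forms", {
  # identical embeddings at the paired endpoints -> inside the relaxation
  H <- matrix(rnorm(12), 2, 6)
  arq <- bip(rbind(c(1L, 1L), c(2L, 2L)), 3L, 3L)
  H[, 4] <- H[, 1]; H[, 5] <- H[, 2]
  expect_equal(hard_regularization_loss(H, arq, eps = 0.1), 0)

  # one pair, d = 2, difference (2, 0): max(4/2 - 0.1, 0) = 1.9
  H2 <- matrix(0, 2, 2)
  H2[, 1] <- c(2, 0)
  expect_equal(hard_regularization_loss(H2, bip(rbind(c(1L, 1L)), 1L, 1L),
                                        eps = 0.1), 1.9)

  # empty connection set contributes nothing
  expect_equal(hard_regularization_loss(H2, bip(matrix(integer(), 0, 2),
                                                1L, 1L)), 0)
})

test_that("hard regularization equals a naive pairwise loop", {
  set.seed(13)
  d <- 5; n_ref <- 6; n_query <- 7
  H <- matrix(rnorm(d * (n_ref + n_query)), d)
  pairs <- cbind(sample(n_ref, 10, TRUE), sample(n_query, 10, TRUE))
  arq <- bip(pairs, n_ref, n_query)
  acc <- 0
  for (k in seq_len(nrow(arq$pairs)))
    acc <- acc + sum((H[, arq$pairs[k, 1]] -
                        H[, n_ref + arq$pairs[k, 2]])^2)
  want <- max(acc / nrow(arq$pairs) / d - 0.1, 0)
  expect_equal(hard_regularization_loss(H, arq, 0.1), want)
})

test_that("cross-entropy matches closed forms and a direct loop", {
  P <- matrix(c(1, 0, 0.5, 0.5), 2, 2)
  expect_equal(cross_entropy_loss(P, list(indices = 1L, labels = 1L)), 0)
  expect_equal(cross_entropy_loss(P, list(indices = 2L, labels = 1L)), log(2))

  set.seed(14)
  C <- matrix(rnorm(30), 3, 10)
  P2 <- softmax_probabilities(C)
  lab <- sample(3, 10, TRUE)
  want <- -mean(sapply(1:10, function(i) log(P2[lab[i], i])))
  expect_equal(cross_entropy_loss(P2, list(indices = 1:10, labels = lab)),
               want)
  expect_error(cross_entropy_loss(P2, list(indices = integer(), labels = integer())),
               "empty supervised set")
})

test_that("query-graph regularization follows the printed indicator", {
  # all adjacent predictions agree -> 1 - 1 - eps < 0 -> 0
  P <- cbind(c(0.9, 0.1), c(0.8, 0.2), c(0.7, 0.3))
  aqq <- intra(rbind(c(1L, 2L), c(2L, 3L)), 3L)
  r <- query_graph_regularization(P, aqq, eps = 0.1)
  expect_equal(r$indicator, 0)

  # no adjacent pair agrees: 1 - 0 - 0.1 = 0.9
  P2 <- cbind(c(0.9, 0.1), c(0.1, 0.9))
  r2 <- query_graph_regularization(P2, intra(rbind(c(1L, 2L)), 2L), eps = 0.1)
  expect_equal(r2$indicator, 0.9)

  # one-hot columns: surrogate equals indicator exactly
  P3 <- cbind(c(1, 0), c(0, 1), c(0, 1))
  aqq3 <- intra(rbind(c(1L, 2L), c(2L, 3L)), 3L)
  r3 <- query_graph_regularization(P3, aqq3, eps = 0.1)
  expect_equal(r3$surrogate, r3$indicator)
  expect_equal(r3$indicator, max(1 - 0.5 - 0.1, 0))

  # empty graph contributes nothing
  r4 <- query_graph_regularization(P3, intra(matrix(integer(), 0, 2), 3L))
  expect_equal(r4$indicator, 0)
  expect_equal(r4$surrogate, 0)
})

test_that("the total loss is the unweighted sum of its terms", {
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(1, 2, 3), 6)
})

test_that("loss terms are always nonnegative", {
  set.seed(15)
  for (rep in 1:5) {
    d <- 3; n <- 8
    H <- matrix(rnorm(d * n), d, n)
    P <- softmax_probabilities(matrix(rnorm(2 * n), 2, n))
    arq <- bip(cbind(sample(4, 5, TRUE), sample(4, 5, TRUE)), 4L, 4L)
    aqq <- intra(rbind(c(1L, 2L), c(3L, 4L)), 4L)
    expect_gte(hard_regularization_loss(H, arq, 0.1), 0)
    expect_gte(cross_entropy_loss(P, list(indices = 1:4,
                                          labels = sample(2, 4, TRUE))), 0)
    q <- query_graph_regularization(P, aqq, 0.1, query_offset = 4)
    expect_gte(q$indicator, 0)
    expect_gte(q$surrogate, 0)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(16)
  n <- 8; m <- 6; ntypes <- 3
  X <- matrix(rnorm(m * n), m, n)
  A <- Matrix::sparseMatrix(i = c(1, 2, 3, 7), j = c(2, 3, 4, 8), x = 1,
                            dims = c(n, n))
  A <- A + Matrix::t(A)
  params <- gt_params(m, ntypes, d_enc = 5, d_attn = 4, n_layers = 2,
                      m_rf = 7, tau = 0.25)
  g <- lapply(1:2, function(l) scgt:::rgumbel(n))
  arqf <- bip(cbind(c(1L, 2L), c(1L, 3L)), 4L, 4L)
  aqq <- intra(cbind(c(1L, 2L), c(2L, 3L)), 4L)
  sup <- list(indices = 1:4, labels = c(1L, 2L, 3L, 1L), n_ref = 4L)

  loss_fn <- function(p) {
    fwd <- gt_forward(X, A, p, g)
    hard_regularization_loss(fwd$H, arqf, 0.01) +
      cross_entropy_loss(fwd$P, sup) +
      query_graph_regularization(fwd$P, aqq, 0.01,
                                 query_offset = 4)$surrogate
  }
  fwd <- gt_forward(X, A, params, g)
  dC <- matrix(0, ntypes, n)
  Y <- matrix(0, ntypes, 4); Y[cbind(sup$labels, 1:4)] <- 1
  dC[, 1:4] <- (fwd$P[, 1:4] - Y) / 4
  dP <- scgt:::query_graph_grad(fwd$P, aqq, 0.01, query_offset = 4)
  if (!is.null(dP)) {
    inner <- colSums(fwd$P * dP)
    dC <- dC + fwd$P * sweep(dP, 2, inner, "-")
  }
  dH <- scgt:::hard_regularization_grad(fwd$H, arqf, 0.01)
  gr <- scgt:::gt_backward(fwd, params, dC, dH)

  check <- function(ana, get, set) {
    w <- get(params)
    idx <- sample(length(w), min(5, length(w)))
    num <- vapply(idx, function(i) {
      e <- 1e-6
      (loss_fn(set(params, replace(w, i, w[i] + e))) -
         loss_fn(set(params, replace(w, i, w[i] - e)))) / (2 * e)
    }, numeric(1))
    expect_equal(as.numeric(ana)[idx], num, tolerance = 1e-5)
  }
  check(gr$W_enc, function(p) p$W_enc, function(p, w) { p$W_enc <- w; p })
  check(gr$W_cls, function(p) p$W_cls, function(p, w) { p$W_cls <- w; p })
  for (l in 1:2) {
    check(gr$layers[[l]]$W_Q, function(p) p$layers[[l]]$W_Q,
          function(p, w) { p$layers[[l]]$W_Q <- w; p })
    check(gr$layers[[l]]$W_K, function(p) p$layers[[l]]$W_K,
          function(p, w) { p$layers[[l]]$W_K <- w; p })
    check(gr$layers[[l]]$W_V, function(p) p$layers[[l]]$W_V,
          function(p, w) { p$layers[[l]]$W_V <- w; p })
    check(gr$layers[[l]]$beta, function(p) p$layers[[l]]$beta,
          function(p, w) { p$layers[[l]]$beta <- w; p })
  }
})

test_that("promotion adds confident cells, refreshes them, never shrinks", {
  P <- cbind(c(1, 0), c(0, 1),               # reference cells
             c(0.96, 0.04), c(0.6, 0.4))     # query cells
  sup <- list(indices = 1:2, labels = c(1L, 2L), n_ref = 2L)
  s1 <- promote_confident_cells(P, sup, 0.95, query_indices = 3:4)
  expect_equal(s1$indices, c(1L, 2L, 3L))
  expect_equal(s1$labels, c(1L, 2L, 1L))

  # nothing above the threshold: unchanged
  P2 <- P; P2[, 3] <- c(0.9, 0.1)
  expect_equal(promote_confident_cells(P2, sup, 0.95, query_indices = 3:4),
               sup)

  # a promoted cell flips its working label with the prediction
  P3 <- P; P3[, 3] <- c(0.01, 0.99)
  s2 <- promote_confident_cells(P3, s1, 0.95, query_indices = 3:4)
  expect_equal(s2$indices, c(1L, 2L, 3L))
  expect_equal(s2$labels, c(1L, 2L, 2L))
  # reference entries are untouched in every case
  expect_equal(s2$labels[1:2], sup$labels)
  expect_gte(length(s2$indices), length(s1$indices))
})

test_that("zero-epoch training returns the initial model", {
  sim <- simulate_multiomics(n_ref = 30, n_query = 30, n_genes = 25,
                             n_types = 2, seed = 17)
  fit <- suppressWarnings(
    scgt(sim$reference, sim$query,
         control = tiny_control(epochs = 0, seed = 17)))
  expect_equal(nrow(fit$log), 0L)
  set.seed(17)  # reproduce the initialization path
  expect_s3_class(fit, "scgt")
  expect_equal(ncol(fit$probabilities), 60L)
})

test_that("training recovers labels on well-separated two-type data", {
  sim <- simulate_multiomics(n_ref = 150, n_query = 150, n_genes = 120,
                             n_types = 2, seed = 18)
  fit <- suppressWarnings(
    scgt(sim$reference, sim$query,
         control = tiny_control(epochs = 200, seed = 18),
         true_query_labels = sim$query_labels))
  acc <- label_transfer_accuracy(sim$query_labels,
                                 fit$predictions$predicted_type)
  expect_gte(acc, 0.95)
  # the loss sequence is finite and logged every epoch
  expect_equal(nrow(fit$log), 200L)
  expect_true(all(is.finite(fit$log$l_total)))
  # promotion is monotone across epochs
  expect_true(all(diff(fit$log$n_promoted) >= 0))
})

test_that("fit methods expose predictions, embedding and summaries", {
  sim <- simulate_multiomics(n_ref = 40, n_query = 40, n_genes = 30,
                             n_types = 2, seed = 19)
  fit <- suppressWarnings(
    scgt(sim$reference, sim$query,
         control = tiny_control(epochs = 10, seed = 19)))
  expect_output(print(fit), "scGT integration fit")
  expect_output(print(summary(fit)), "mean prediction confidence")
  pr <- predict(fit)
  expect_equal(nrow(pr), 40L)
  pr9 <- predict(fit, unknown_threshold = 0.999)
  expect_true(any(pr9$predicted_type == "Unknown"))
  expect_equal(dim(fitted(fit)), c(80L, 32L))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
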