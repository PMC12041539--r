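# Dual-branch classifier: isomorphic layer, fusion, pooling, head, training.

test_that("isomorphic aggregation is the injective sum update", {
  set.seed(1)
  p <- init_iso_layer(3, 4)
  # isolated node with eps = 0: the aggregated message is the node itself
  X <- matrix(c(1, 2, 3), 1, 3)
  A0 <- matrix(0, 1, 1)
  fw <- molgraphnn:::iso_forward(X, A0, p, training = FALSE)
  expect_equal(fw$cache$M, X)

  # sum aggregation separates multisets {a, a} vs {a}: star centre with two
  # identical leaves differs from a pair centre, unlike a mean aggregator
  a <- c(1, 0.5, -1)
  ctr <- c(0.2, 0.2, 0.2)
  Xstar <- rbind(ctr, a, a)
  Astar <- rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0))
  Xpair <- rbind(ctr, a)
  Apair <- rbind(c(0, 1), c(1, 0))
  Mstar <- molgraphnn:::iso_forward(Xstar, Astar, p, FALSE)$cache$M
  Mpair <- molgraphnn:::iso_forward(Xpair, Apair, p, FALSE)$cache$M
  expect_equal(Mstar[1, ], ctr + 2 * a)
  expect_equal(Mpair[1, ], ctr + a)
  expect_false(isTRUE(all.equal(Mstar[1, ], Mpair[1, ])))

  # permutation equivariance of the full layer
  set.seed(2)
  X <- matrix(rnorm(15), 5, 3)
  A <- matrix(0, 5, 5)
  A[upper.tri(A)] <- rbinom(10, 1, 0.5)
  A <- A + t(A)
  perm <- sample(5)
  P <- diag(5)[perm, ]
  Y <- iso_layer(X, A, p)
  Yp <- iso_layer(P %*% X, P %*% A %*% t(P), p)
  expect_equal(Yp, P %*% Y, tolerance = 1e-10)

  expect_error(iso_layer(matrix(0, 2, 7), diag(2), p), "dimension")
})

test_that("fusion is a commutative elementwise sum feeding the next layers", {
  a <- matrix(rnorm(6), 2, 3)
  b <- matrix(rnorm(6), 2, 3)
  expect_equal(fuse_layers(a, matrix(0, 2, 3)), a)
  expect_equal(fuse_layers(a, b), fuse_layers(b, a))
  expect_error(fuse_layers(a, matrix(0, 3, 2)), "mismatch")
})

test_that("global mean pool averages nodes and ignores node order", {
  x <- matrix(c(1, 2, 3, 4), 1, 4)
  expect_equal(global_mean_pool(x), as.numeric(x))
  v <- rnorm(4)
  expect_equal(global_mean_pool(rbind(v, -v)), rep(0, 4))
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(global_mean_pool(X), global_mean_pool(X[5:1, ]))
})

test_that("prediction head outputs calibrated probabilities", {
  set.seed(3)
  m <- init_dual_branch(k = 2)
  # zero logits map to probability one half
  m0 <- m
  m0$out$W[] <- 0
  m0$out$b[] <- 0
  p <- predict_head(rnorm(512), m0)
  expect_equal(as.numeric(p), c(0.5, 0.5))
  # finite logits stay strictly inside (0, 1)
  p2 <- predict_head(matrix(rnorm(5 * 512), 5, 512), m)
  expect_true(all(p2 > 0 & p2 < 1))
  # regression head returns unbounded reals
  mr <- init_dual_branch(k = 1, task_mode = "regression")
  mr$out$b[] <- 5
  mr$out$W[] <- 0
  expect_equal(as.numeric(predict_head(rnorm(512), mr)), 5)
})

test_that("masked loss ignores missing labels exactly", {
  probs <- matrix(c(0.9, 0.5, 0.2, 0.8), 2, 2)
  y <- matrix(c(1, 1, NA, 0), 2, 2)
  expect_equal(classification_loss(matrix(1 - 1e-9, 1, 1), matrix(1)), 0,
               tolerance = 1e-6)
  expect_equal(classification_loss(matrix(0.5), matrix(1)), log(2))
  # removing the missing entry changes neither the sum nor the divisor
  manual <- mean(c(-log(0.9), -log(0.5), -log(1 - 0.8)))
  expect_equal(classification_loss(probs, y), manual)
  expect_error(classification_loss(matrix(0.5), matrix(NA_real_)), "missing")
  # regression substitutes squared error
  expect_equal(classification_loss(matrix(c(1, 2)), matrix(c(0, NA)),
                                   task_mode = "regression"), 1)
})

test_that("parameter count matches hand arithmetic and the stated budget", {
  set.seed(4)
  layer1 <- init_cheb_layer(56, 128)
  expect_identical(molgraphnn:::n_param_leaves(layer1), 3L * 56L * 128L + 128L)
  expect_identical(molgraphnn:::n_param_leaves(layer1), 21632L)

  for (k in c(1L, 2L, 12L)) {
    m <- init_dual_branch(k = k)
    expect_lt(count_parameters(m), 1e6)
  }
  # doubling every width quadruples the weight-matrix sizes
  w1 <- length(init_cheb_layer(56, 128)$theta[[1]])
  w2 <- length(init_cheb_layer(112, 256)$theta[[1]])
  expect_identical(w2, 4L * w1)
})

test_that("backbone transfer validates layer shapes", {
  set.seed(5)
  bad <- init_encoder(dims = c(56L, 64L, 256L, 512L))
  expect_error(init_dual_branch(k = 1, backbone = bad), "layer 1")
  good <- init_encoder()
  m <- init_dual_branch(k = 1, backbone = good)
  expect_identical(m$spectral[[2]]$theta[[1]], good$layers[[2]]$theta[[1]])
})

test_that("zeroing the isomorphic branch reduces the model to the spectral path", {
  set.seed(6)
  m <- init_dual_branch(k = 1)
  for (l in seq_along(m$iso)) {
    m$iso[[l]]$W[] <- 0
    m$iso[[l]]$b[] <- 0
    m$iso[[l]]$gamma[] <- 0
    m$iso[[l]]$beta[] <- 0
  }
  g <- fixture_graphs(1)[[1]]
  emb <- molgraphnn:::branch_forward(g, m)$embedding
  # spectral-only stack: cheb conv + ReLU chain on the same Laplacian
  Lhat <- molgraphnn:::graph_scaled_laplacian(g, m$laplacian, m$fixed_lambda)
  X <- g$node_features
  for (l in seq_along(m$spectral)) {
    X <- molgraphnn:::relu(cheb_conv(X, Lhat, m$spectral[[l]]))
  }
  expect_equal(emb, global_mean_pool(X), tolerance = 1e-10)
})

test_that("end-to-end prediction is invariant to node reordering", {
  set.seed(7)
  m <- init_dual_branch(k = 1)
  for (g in fixture_graphs(5)) {
    perm <- sample(n_nodes(g))
    gp <- permute_graph(g, perm)
    expect_equal(predict(m, list(gp)), predict(m, list(g)), tolerance = 1e-5)
  }
})

test_that("training is reproducible and can overfit a small set", {
  ds <- synthetic_classification_dataset(10, seed = 9)
  gs <- smiles_to_graphs(ds$smiles)
  lab <- matrix(ds$label)
  f1 <- train_classifier(gs, labels = lab, k = 1, epochs = 3, batch_size = 5,
                         seed = 4)
  f2 <- train_classifier(gs, labels = lab, k = 1, epochs = 3, batch_size = 5,
                         seed = 4)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$model$iso[[1]]$W, f2$model$iso[[1]]$W)
  expect_identical(f1$model$out$W, f2$model$out$W)

  f <- train_classifier(gs, labels = lab, k = 1, epochs = 40, batch_size = 5,
                        seed = 4)
  expect_lt(tail(f$trace$loss, 1), 0.05)
})
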