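# Contrastive pre-training: perturbation, losses, sampling, optimisation.

test_that("latent perturbation follows the Gaussian unit-direction scheme", {
  # constant embedding: zero variance, no perturbation
  zc <- matrix(2, 3, 4)
  d <- perturb_embedding(zc)
  expect_identical(d$z1, zc)
  expect_identical(d$z2, zc)
  expect_equal(d$sigma2, 0)

  set.seed(10)
  z <- matrix(rnorm(20), 4, 5)
  d <- perturb_embedding(z)
  expect_equal(sqrt(sum(d$k1^2)), 1, tolerance = 1e-6)
  expect_equal(sqrt(sum(d$k2^2)), 1, tolerance = 1e-6)
  # displacement magnitude equals the drawn amplitude
  expect_equal(sqrt(sum((d$z1 - z)^2)), abs(d$eps1), tolerance = 1e-10)
  expect_equal(d$sigma2, mean((z - mean(z))^2))

  # Monte-Carlo: E[|z1 - z|^2] = sigma^2 (population variance of z)
  set.seed(77)
  sq <- replicate(10000, {
    dd <- perturb_embedding(z)
    sum((dd$z1 - z)^2)
  })
  expect_equal(mean(sq), d$sigma2, tolerance = 0.05)
})

test_that("cosine link matches its closed forms", {
  v <- c(1, 2, 3)
  expect_equal(cosine_link(v, v), 1)
  expect_equal(cosine_link(v, -v), -1)
  expect_equal(cosine_link(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_link(c(0, 0), v[1:2]), "all-zero")
})

test_that("information loss has the symmetric closed form and is monotone", {
  x <- adjacency_matrix(path3_graph())
  p <- sigmoid(x - 0.5)
  expect_equal(information_loss(x, p, p, p, eps_num = 0), log(2))
  expect_equal(information_loss(x, x, x, x, eps_num = 0), log(2))
  # eps_num -> 0 limit with all three reconstructions equal
  expect_equal(information_loss(x, p, p, p, eps_num = 1e-12), log(2),
               tolerance = 1e-10)

  # loss decreases as the true reconstruction aligns better with x,
  # perturbed reconstructions held fixed
  set.seed(3)
  B <- matrix(runif(9), 3, 3); B <- (B + t(B)) / 2
  p1 <- sigmoid(B); p2 <- sigmoid(-B)
  losses <- vapply(c(0.5, 1, 2, 4), function(t) {
    information_loss(x, sigmoid(t * (2 * x - 1)), p1, p2)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("negative sampling returns distinct absent edges", {
  # complete triangle: no negatives exist
  tri <- molecular_graph(matrix(runif(3 * 4), 3, 4),
                         rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2),
                               c(1, 3), c(3, 1)),
                         matrix(0, 6, 9))
  expect_error(negative_sample(tri, 1), "complete")

  # 3-path: the single non-edge is (1, 3)
  set.seed(4)
  ns <- negative_sample(path3_graph(), 1)
  expect_equal(sort(as.integer(ns)), c(1L, 3L))

  benz <- smiles_to_graph("c1ccccc1")
  set.seed(5)
  ns <- negative_sample(benz, 6)
  expect_equal(nrow(ns), 6)
  expect_equal(nrow(unique(ns)), 6)
  A <- adjacency_matrix(benz)
  expect_true(all(A[ns] == 0))
  expect_true(all(ns[, 1] != ns[, 2]))
})

test_that("reconstruction loss matches hand-computed values", {
  n <- 3
  pos <- rbind(c(1, 2), c(2, 3))
  neg <- rbind(c(1, 3))
  p_half <- matrix(0.5, n, n)
  expect_equal(reconstruction_loss(p_half, pos, neg), log(2))
  p_good <- matrix(1e-7, n, n)
  p_good[1, 2] <- 1 - 1e-7
  p_good[2, 3] <- 1 - 1e-7
  expect_lt(reconstruction_loss(p_good, pos, neg), 1e-5)
  # hand-summed oracle on arbitrary probabilities
  set.seed(6)
  p <- matrix(runif(9, 0.1, 0.9), 3, 3)
  expected <- -(log(p[1, 2]) + log(p[2, 3]) + log(1 - p[1, 3])) / 3
  expect_equal(reconstruction_loss(p, pos, neg), expected)
})

test_that("the composite loss decomposes exactly with lambda = 0.4", {
  pl <- pretrain_loss(1.25, 0.5)
  expect_identical(pl$penalty_lambda, 0.4)
  expect_identical(pl$total, 1.25 + 0.4 * 0.5)
  pl2 <- pretrain_loss(0.3, -0.2, penalty_lambda = 0.1)
  expect_identical(pl2$total, 0.3 + 0.1 * (-0.2))
})

test_that("contrastive gradient w.r.t. the embedding matches finite differences", {
  set.seed(13)
  g <- random_graph(4, in_dim = 3)
  x <- adjacency_matrix(g)
  pos <- undirected_edges(g)
  set.seed(14)
  neg <- negative_sample(g, nrow(pos))
  z <- matrix(rnorm(4 * 5), 4, 5)
  set.seed(15)
  draw <- perturb_embedding(z)
  res <- contrastive_loss_dz(z, draw, x, pos, neg)
  lossfn <- function(zz) {
    dd <- list(z1 = zz + draw$eps1 * draw$k1, z2 = zz + draw$eps2 * draw$k2)
    contrastive_loss_dz(zz, dd, x, pos, neg)$loss$total
  }
  h <- 1e-6
  for (idx in list(c(1, 1), c(2, 3), c(4, 5))) {
    zp <- z; zp[idx[1], idx[2]] <- zp[idx[1], idx[2]] + h
    zm <- z; zm[idx[1], idx[2]] <- zm[idx[1], idx[2]] - h
    fd <- (lossfn(zp) - lossfn(zm)) / (2 * h)
    expect_equal(res$dz[idx[1], idx[2]], fd, tolerance = 1e-4)
  }
})

test_that("perturbation leaves the input embedding untouched", {
  set.seed(21)
  z <- matrix(rnorm(12), 3, 4)
  z_copy <- z + 0
  invisible(perturb_embedding(z))
  expect_identical(z, z_copy)
})

test_that("pre-training is reproducible and reduces the loss on one graph", {
  set.seed(8)
  feats <- matrix(runif(4 * 6), 4, 6)
  edges <- rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(3, 4), c(4, 3))
  g <- molecular_graph(feats, edges, matrix(0, 6, 9), smiles = "path4")

  enc <- init_encoder(dims = c(6L, 8L, 8L, 8L))
  r1 <- pretrain(list(g), epochs = 30, batch_size = 1, seed = 2, encoder = enc)
  r2 <- pretrain(list(g), epochs = 30, batch_size = 1, seed = 2, encoder = enc)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$encoder$layers[[3]]$theta[[2]],
                   r2$encoder$layers[[3]]$theta[[2]])

  # overfit sanity: 500 steps drive the reconstruction loss below the log 2
  # chance baseline (its analytic floor with nonnegative latents is
  # #neg * log 2 / (#pos + #neg) ~= 0.35 here)
  set.seed(8)
  enc <- init_encoder(dims = c(6L, 8L, 8L, 8L))
  r <- pretrain(list(g), epochs = 500, batch_size = 1, seed = 2, encoder = enc)
  expect_lt(tail(r$trace$reconstruction, 1), log(2))
  expect_lt(tail(r$trace$reconstruction, 1), r$trace$reconstruction[1])
})
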