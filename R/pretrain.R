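# Contrastive self-supervised pre-training of the spectral backbone.
#
# Per graph: z = encode(graph); z1, z2 = z perturbed along random unit
# directions with N(0, sigma^2) amplitudes (sigma^2 = variance of z's
# entries); A = z z^T, A1 = z1 z1^T, A2 = z2 z2^T; p = sigmoid(A) etc.
# Loss (composite) = reconstruction BCE (true edges as positives, sampled
# non-edges as negatives) + lambda * information loss, lambda = 0.4.

#' Perturb a latent embedding with Gaussian noise along unit directions
#'
#' Draws two unit directions `k1`, `k2` (standard-normal draws, normalized to
#' unit Frobenius norm) and amplitudes `eps1`, `eps2 ~ N(0, sigma^2)` where
#' `sigma^2` is the population variance of all entries of `z`, and returns
#' `z1 = z + eps1 k1`, `z2 = z + eps2 k2`. A constant `z` (zero variance)
#' returns `z1 = z2 = z`.
#'
#' Uses the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param z numeric embedding matrix.
#' @return list with `z1`, `z2`, `k1`, `k2`, `eps1`, `eps2`, `sigma2`.
#' @export
perturb_embedding <- function(z) {
  z <- as.matrix(z)
  stopifnot(length(z) >= 1)
  sigma2 <- mean((z - mean(z))^2)
  if (sigma2 == 0) {
    k <- matrix(0, nrow(z), ncol(z))
    return(list(z1 = z, z2 = z, k1 = k, k2 = k,
                eps1 = 0, eps2 = 0, sigma2 = 0))
  }
  draw_unit <- function() {
    k <- matrix(stats::rnorm(length(z)), nrow(z), ncol(z))
    k / sqrt(sum(k^2))
  }
  k1 <- draw_unit()
  k2 <- draw_unit()
  eps1 <- stats::rnorm(1, 0, sqrt(sigma2))
  eps2 <- stats::rnorm(1, 0, sqrt(sigma2))
  list(z1 = z + eps1 * k1, z2 = z + eps2 * k2,
       k1 = k1, k2 = k2, eps1 = eps1, eps2 = eps2, sigma2 = sigma2)
}

#' Cosine similarity link function
#'
#' `x . p / (||x|| ||p||)` over flattened matrices or vectors.
#'
#' @param x,p numeric arrays of equal length.
#' @return real in `[-1, 1]`.
#' @export
cosine_link <- function(x, p) {
  x <- as.numeric(x)
  p <- as.numeric(p)
  stopifnot(length(x) == length(p))
  nx <- sqrt(sum(x^2))
  np <- sqrt(sum(p^2))
  if (nx == 0 || np == 0) {
    stop("cosine similarity is undefined for an all-zero vector",
         call. = FALSE)
  }
  sum(x * p) / (nx * np)
}

#' Contrastive information loss
#'
#' `-log( exp(g(x, p)) / (exp(g(x, p1)) + exp(g(x, p2)) + eps_num) )` with
#' `g` the cosine link on flattened matrices: the reconstruction of the true
#' embedding is scored against the two perturbed reconstructions. Equal
#' similarities give `log 2` (at `eps_num = 0`).
#'
#' @param x true 0/1 adjacency matrix.
#' @param p,p1,p2 edge probability matrices from [decode()].
#' @param eps_num small stabiliser in the denominator.
#' @return scalar loss.
#' @export
information_loss <- function(x, p, p1, p2, eps_num = 1e-8) {
  s <- cosine_link(x, p)
  s1 <- cosine_link(x, p1)
  s2 <- cosine_link(x, p2)
  -(s - log(exp(s1) + exp(s2) + eps_num))
}

# gradient of cosine_link(x, p) with respect to p (same shape as p)
cosine_link_grad_p <- function(x, p) {
  xv <- as.numeric(x)
  pv <- as.numeric(p)
  nx <- sqrt(sum(xv^2))
  np <- sqrt(sum(pv^2))
  s <- sum(xv * pv) / (nx * np)
  g <- xv / (nx * np) - s * pv / np^2
  matrix(g, nrow(p), ncol(p))
}

# information loss together with its gradients with respect to the raw
# adjacency reconstructions A, A1, A2 (p = sigmoid(A) etc.)
information_loss_grads <- function(x, A, A1, A2, eps_num = 1e-8) {
  p <- sigmoid(A); p1 <- sigmoid(A1); p2 <- sigmoid(A2)
  s <- cosine_link(x, p)
  s1 <- cosine_link(x, p1)
  s2 <- cosine_link(x, p2)
  denom <- exp(s1) + exp(s2) + eps_num
  loss <- -(s - log(denom))
  dL_ds <- -1
  dL_ds1 <- exp(s1) / denom
  dL_ds2 <- exp(s2) / denom
  dA <- dL_ds * cosine_link_grad_p(x, p) * p * (1 - p)
  dA1 <- dL_ds1 * cosine_link_grad_p(x, p1) * p1 * (1 - p1)
  dA2 <- dL_ds2 * cosine_link_grad_p(x, p2) * p2 * (1 - p2)
  list(loss = loss, dA = dA, dA1 = dA1, dA2 = dA2)
}

#' Sample non-edges of a molecular graph
#'
#' Draws up to `count` distinct unordered node pairs that are neither edges
#' nor self-loops, for use as negatives in the reconstruction loss. If fewer
#' non-edges exist than requested, all of them are returned.
#'
#' Uses the session RNG; seed with [set.seed()].
#'
#' @param graph a [molecular_graph()].
#' @param count number of pairs requested.
#' @return k x 2 integer matrix of pairs (i < j).
#' @export
negative_sample <- function(graph, count) {
  n <- n_nodes(graph)
  A <- adjacency_matrix(graph)
  cand <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    stop("Graph is complete: no absent edges to sample.", call. = FALSE)
  }
  k <- min(count, nrow(cand))
  idx <- if (nrow(cand) == 1) 1L else sample.int(nrow(cand), k)
  cand[idx, , drop = FALSE]
}

#' Edge reconstruction loss
#'
#' Mean binary cross-entropy of decoded edge probabilities: `-log p` over
#' positive (true) edges and `-log(1 - p)` over sampled negative pairs, with
#' probabilities clipped away from 0 and 1 by 1e-7.
#'
#' @param p edge probability matrix from [decode()].
#' @param positive_edges k x 2 matrix of true edge pairs.
#' @param negative_pairs k' x 2 matrix of non-edge pairs.
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(p, positive_edges, negative_pairs) {
  positive_edges <- matrix(as.integer(positive_edges), ncol = 2)
  negative_pairs <- matrix(as.integer(negative_pairs), ncol = 2)
  stopifnot(nrow(positive_edges) > 0, nrow(negative_pairs) > 0)
  pp <- pmin(pmax(p[positive_edges], 1e-7), 1 - 1e-7)
  pn <- pmin(pmax(p[negative_pairs], 1e-7), 1 - 1e-7)
  -(sum(log(pp)) + sum(log(1 - pn))) / (length(pp) + length(pn))
}

# reconstruction loss plus its gradient with respect to A (p = sigmoid(A)).
# The loss reads one directed entry per listed pair, so the gradient lives
# exactly at those entries; symmetrization is the caller's concern.
reconstruction_loss_grads <- function(A, positive_edges, negative_pairs) {
  p <- sigmoid(A)
  loss <- reconstruction_loss(p, positive_edges, negative_pairs)
  m <- nrow(positive_edges) + nrow(negative_pairs)
  dA <- matrix(0, nrow(A), ncol(A))
  # d/dA of -log(sigmoid(A)) is (p - 1); of -log(1 - sigmoid(A)) is p
  for (r in seq_len(nrow(positive_edges))) {
    i <- positive_edges[r, 1]; j <- positive_edges[r, 2]
    dA[i, j] <- dA[i, j] + (p[i, j] - 1) / m
  }
  for (r in seq_len(nrow(negative_pairs))) {
    i <- negative_pairs[r, 1]; j <- negative_pairs[r, 2]
    dA[i, j] <- dA[i, j] + p[i, j] / m
  }
  list(loss = loss, dA = dA)
}

#' Composite pre-training loss
#'
#' `total = reconstruction + lambda * information` (lambda defaults to 0.4).
#'
#' @param reconstruction,information component losses.
#' @param penalty_lambda weight of the information term.
#' @return list with `reconstruction`, `information`, `penalty_lambda`,
#'   `total`.
#' @export
pretrain_loss <- function(reconstruction, information, penalty_lambda = 0.4) {
  list(reconstruction = reconstruction, information = information,
       penalty_lambda = penalty_lambda,
       total = reconstruction + penalty_lambda * information)
}

# full contrastive loss for one graph plus its gradient with respect to z.
# `draw` is a perturbation from perturb_embedding(); `negatives` a pair
# matrix. Returns components and dz.
contrastive_loss_dz <- function(z, draw, x, positives, negatives,
                                penalty_lambda = 0.4, eps_num = 1e-8) {
  A <- tcrossprod(z)
  A1 <- tcrossprod(draw$z1)
  A2 <- tcrossprod(draw$z2)
  rec <- reconstruction_loss_grads(A, positives, negatives)
  inf <- information_loss_grads(x, A, A1, A2, eps_num)
  loss <- pretrain_loss(rec$loss, inf$loss, penalty_lambda)
  GA <- rec$dA + penalty_lambda * inf$dA
  G1 <- penalty_lambda * inf$dA1
  G2 <- penalty_lambda * inf$dA2
  # A = z z^T => dz = (G + G^T) z ; z1, z2 shift z by constants => chain is I
  dz <- (GA + t(GA)) %*% z +
    (G1 + t(G1)) %*% draw$z1 +
    (G2 + t(G2)) %*% draw$z2
  list(loss = loss, dz = dz, A = A, A1 = A1, A2 = A2)
}

#' Pre-train the spectral backbone contrastively
#'
#' Iterates epochs of encode / perturb / decode / composite loss /
#' Adam step (`beta1 = 0.5`, `beta2 = 0.999`, `lr = 2e-4`). Negatives are
#' re-sampled each epoch, one per positive edge. Fully reproducible for a
#' fixed `seed`.
#'
#' @param graphs list of [molecular_graph()] objects (each with at least one
#'   edge).
#' @param epochs number of passes over the data.
#' @param batch_size graphs per optimiser step.
#' @param lr,beta1,beta2 Adam hyper-parameters.
#' @param penalty_lambda weight of the information term in the composite
#'   loss.
#' @param init weight initialisation (`"scaled"` or `"unit"`).
#' @param seed integer seed controlling initialisation, shuffling,
#'   perturbation draws and negative sampling.
#' @param encoder optionally, a pre-built encoder to continue training.
#' @param verbose print per-epoch losses.
#' @return list with `encoder` (trained), `trace` (data.frame of per-epoch
#'   reconstruction / information / total losses), `config`, `seed`.
#' @export
pretrain <- function(graphs, epochs = 30L, batch_size = 32L, lr = 2e-4,
                     beta1 = 0.5, beta2 = 0.999, penalty_lambda = 0.4,
                     init = c("scaled", "unit"), seed = 1L,
                     encoder = NULL, verbose = FALSE) {
  init <- match.arg(init)
  stopifnot(length(graphs) > 0)
  set.seed(seed)
  if (is.null(encoder)) encoder <- init_encoder(init = init)
  # static per-graph quantities
  prep <- lapply(graphs, function(g) {
    pos <- undirected_edges(g)
    if (nrow(pos) == 0) {
      stop("Pre-training requires every graph to have at least one edge ",
           "(offending SMILES: ", g$smiles, ")", call. = FALSE)
    }
    list(graph = g, x = adjacency_matrix(g), positives = pos,
         Lhat = graph_scaled_laplacian(g, encoder$laplacian,
                                       encoder$fixed_lambda))
  })
  opt <- adam_init(list(layers = encoder$layers))
  trace <- data.frame(epoch = integer(0), reconstruction = numeric(0),
                      information = numeric(0), total = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(prep))
    ep_rec <- 0; ep_inf <- 0; ep_tot <- 0
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (bt in batches) {
      bgrad <- NULL
      for (gi in bt) {
        pg <- prep[[gi]]
        fw <- encode_forward(pg$graph, encoder, Lhat = pg$Lhat)
        draw <- perturb_embedding(fw$z)
        negs <- negative_sample(pg$graph, nrow(pg$positives))
        res <- contrastive_loss_dz(fw$z, draw, pg$x, pg$positives, negs,
                                   penalty_lambda = penalty_lambda)
        if (!is.finite(res$loss$total)) {
          stop("Non-finite pre-training loss at epoch ", ep,
               " on graph '", pg$graph$smiles, "'", call. = FALSE)
        }
        g <- encode_backward(fw, encoder, res$dz)
        bgrad <- if (is.null(bgrad)) g else grad_add(bgrad, g)
        ep_rec <- ep_rec + res$loss$reconstruction
        ep_inf <- ep_inf + res$loss$information
        ep_tot <- ep_tot + res$loss$total
      }
      bgrad <- grad_scale(bgrad, 1 / length(bt))
      step <- adam_step(list(layers = encoder$layers), bgrad, opt,
                        lr = lr, beta1 = beta1, beta2 = beta2)
      encoder$layers <- step$params$layers
      opt <- step$state
    }
    ng <- length(prep)
    trace <- rbind(trace, data.frame(
      epoch = ep, reconstruction = ep_rec / ng,
      information = ep_inf / ng, total = ep_tot / ng))
    if (verbose) {
      message(sprintf("epoch %3d  recon %.4f  info %.4f  total %.4f",
                      ep, ep_rec / ng, ep_inf / ng, ep_tot / ng))
    }
  }
  list(encoder = encoder, trace = trace,
       config = list(epochs = epochs, batch_size = batch_size, lr = lr,
                     beta1 = beta1, beta2 = beta2,
                     penalty_lambda = penalty_lambda, init = init),
       seed = seed)
}

#' Reconstruction loss of an encoder on a set of graphs
#'
#' Mean edge-reconstruction BCE over graphs, with seeded 1:1 negative
#' sampling; the all-0.5 chance baseline is `log 2`.
#'
#' @param encoder a trained (or fresh) encoder.
#' @param graphs list of molecular graphs.
#' @param seed seed for negative sampling.
#' @return scalar mean loss.
#' @export
evaluate_reconstruction <- function(encoder, graphs, seed = 1L) {
  set.seed(seed)
  losses <- vapply(graphs, function(g) {
    z <- encode(g, encoder)
    p <- decode(z)
    pos <- undirected_edges(g)
    negs <- negative_sample(g, nrow(pos))
    reconstruction_loss(p, pos, negs)
  }, numeric(1))
  mean(losses)
}
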