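# Dual-branch victim model: a spectral (Chebyshev) branch whose weights are
# transferred from pre-training and a graph-isomorphic branch (GIN-style
# injective sum aggregation with an affine + batch-norm + ReLU link), fused
# additively after every layer; global mean pooling and a 512 -> 256 -> k
# prediction head.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# ---- batch normalization (feature-wise over rows) ---------------------------

init_batchnorm <- function(dim) {
  list(gamma = rep(1, dim), beta = numeric(dim),
       running_mean = numeric(dim), running_var = rep(1, dim))
}

# forward over rows of X. `use_batch_stats` selects normalization by the
# current rows (population variance) versus the stored running statistics;
# running stats are only updated while training.
batchnorm_forward <- function(X, bn, training, use_batch_stats = training) {
  if (use_batch_stats) {
    mu <- colMeans(X)
    va <- colMeans(sweep(X, 2, mu)^2)
    if (training) {
      bn$running_mean <- (1 - BN_MOMENTUM) * bn$running_mean + BN_MOMENTUM * mu
      bn$running_var <- (1 - BN_MOMENTUM) * bn$running_var + BN_MOMENTUM * va
    }
  } else {
    mu <- bn$running_mean
    va <- bn$running_var
  }
  invstd <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(sweep(X, 2, mu), 2, invstd, "*")
  Y <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(Y = Y, bn = bn, cache = list(xhat = xhat, invstd = invstd,
                                    use_batch_stats = use_batch_stats))
}

batchnorm_backward <- function(dY, bn, cache) {
  xhat <- cache$xhat
  invstd <- cache$invstd
  N <- nrow(xhat)
  dbeta <- colSums(dY)
  dgamma <- colSums(dY * xhat)
  dxhat <- sweep(dY, 2, bn$gamma, "*")
  if (cache$use_batch_stats) {
    sum_dxhat <- colSums(dxhat)
    sum_dxhat_xhat <- colSums(dxhat * xhat)
    dX <- sweep(N * dxhat, 2, sum_dxhat) -
      xhat * matrix(sum_dxhat_xhat, N, length(sum_dxhat), byrow = TRUE)
    dX <- sweep(dX, 2, invstd / N, "*")
  } else {
    dX <- sweep(dxhat, 2, invstd, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- graph-isomorphic layer -------------------------------------------------

#' Initialise one graph-isomorphic layer
#'
#' @param in_dim,out_dim layer dimensions.
#' @param init weight initialisation scheme.
#' @param eps_self self-weight of the isomorphic update (fixed, default 0).
#' @return parameter list with affine link weights and batch-norm state.
#' @export
init_iso_layer <- function(in_dim, out_dim, init = c("scaled", "unit"),
                           eps_self = 0) {
  init <- match.arg(init)
  sd <- if (init == "unit") 1 else sqrt(2 / in_dim)
  c(list(W = matrix(stats::rnorm(in_dim * out_dim, 0, sd), in_dim, out_dim),
         b = numeric(out_dim), eps_self = eps_self),
    init_batchnorm(out_dim))
}

#' Graph-isomorphic convolution layer
#'
#' For each node v: `h'_v = ReLU(BatchNorm(Linear((1 + eps) h_v +
#' sum_{u in N(v)} h_u)))`. Sum aggregation keeps the multiset of neighbour
#' features injective (Weisfeiler-Lehman expressiveness).
#'
#' @param X n x in_dim node feature matrix.
#' @param A n x n symmetric adjacency matrix.
#' @param params a layer from [init_iso_layer()].
#' @param training use batch statistics (TRUE) or running statistics.
#' @return n x out_dim matrix (invisibly also available with caches via the
#'   internal forward).
#' @export
iso_layer <- function(X, A, params, training = FALSE) {
  iso_forward(X, A, params, training)$Y
}

iso_forward <- function(X, A, params, training) {
  X <- as.matrix(X)
  if (nrow(A) != nrow(X)) {
    stop("Adjacency size ", nrow(A), " does not match node count ",
         nrow(X), call. = FALSE)
  }
  if (ncol(X) != nrow(params$W)) {
    stop("Feature dimension ", ncol(X), " does not match layer input ",
         nrow(params$W), call. = FALSE)
  }
  M <- (1 + params$eps_self) * X + A %*% X
  pre <- sweep(M %*% params$W, 2, params$b, "+")
  # normalization over the graph's own nodes in both modes (graph instance
  # normalization): keeps train and eval forward passes consistent and the
  # layer permutation-equivariant
  bnf <- batchnorm_forward(pre, params, training, use_batch_stats = TRUE)
  Y <- relu(bnf$Y)
  list(Y = Y, params = bnf$bn,
       cache = list(M = M, bn_cache = bnf$cache, bn_out = bnf$Y))
}

iso_backward <- function(dY, X, A, params, cache) {
  dbn_out <- dY * (cache$bn_out > 0)
  bnb <- batchnorm_backward(dbn_out, params, cache$bn_cache)
  dpre <- bnb$dX
  dW <- crossprod(cache$M, dpre)
  db <- colSums(dpre)
  dM <- dpre %*% t(params$W)
  dX <- (1 + params$eps_self) * dM + t(A) %*% dM
  list(dX = dX, grads = list(W = dW, b = db,
                             gamma = bnb$dgamma, beta = bnb$dbeta))
}

#' Fuse spectral and isomorphic layer outputs
#'
#' Elementwise sum; the fused tensor feeds both branches' next layers, and
#' the final-layer fusion is the aggregated 512-d representation that is
#' pooled.
#'
#' @param spectral_out,iso_out equally shaped matrices.
#' @export
fuse_layers <- function(spectral_out, iso_out) {
  if (!identical(dim(spectral_out), dim(iso_out))) {
    stop("Branch outputs have mismatched shapes.", call. = FALSE)
  }
  spectral_out + iso_out
}

#' Global mean pooling
#'
#' Arithmetic mean of node features; permutation invariant.
#'
#' @param X n x d node feature matrix with n >= 1.
#' @return length-d vector.
#' @export
global_mean_pool <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("Cannot pool an empty graph.", call. = FALSE)
  colMeans(X)
}

# ---- model ------------------------------------------------------------------

#' Initialise the dual-branch model
#'
#' @param k number of output tasks.
#' @param task_mode `"classification"` (sigmoid outputs) or `"regression"`
#'   (identity outputs).
#' @param dims branch widths including the 56-d input.
#' @param init weight initialisation scheme for randomly initialised parts.
#' @param backbone optional pre-trained encoder from [pretrain()]; its
#'   Chebyshev layers are copied into the spectral branch (shapes must
#'   match).
#' @param laplacian,fixed_lambda spectral configuration (see
#'   [init_encoder()]); inherited from `backbone` when one is given.
#' @return a `dual_branch_model` object.
#' @export
init_dual_branch <- function(k = 1L, task_mode = c("classification", "regression"),
                             dims = c(56L, 128L, 256L, 512L),
                             init = c("scaled", "unit"), backbone = NULL,
                             laplacian = "sym", fixed_lambda = NULL) {
  task_mode <- match.arg(task_mode)
  init <- match.arg(init)
  nl <- length(dims) - 1
  spectral <- lapply(seq_len(nl), function(l) {
    init_cheb_layer(dims[l], dims[l + 1], init = init)
  })
  if (!is.null(backbone)) {
    for (l in seq_len(nl)) {
      bl <- backbone$layers[[l]]
      if (!identical(dim(bl$theta[[1]]), dim(spectral[[l]]$theta[[1]]))) {
        stop("Backbone layer ", l, " has shape ",
             paste(dim(bl$theta[[1]]), collapse = "x"),
             ", expected ",
             paste(dim(spectral[[l]]$theta[[1]]), collapse = "x"),
             call. = FALSE)
      }
      spectral[[l]] <- bl
    }
    laplacian <- backbone$laplacian
    fixed_lambda <- backbone$fixed_lambda
  }
  iso <- lapply(seq_len(nl), function(l) {
    init_iso_layer(dims[l], dims[l + 1], init = init)
  })
  d_embed <- dims[length(dims)]
  sd1 <- if (init == "unit") 1 else sqrt(2 / d_embed)
  sd2 <- if (init == "unit") 1 else sqrt(2 / 256)
  head <- c(list(W = matrix(stats::rnorm(d_embed * 256, 0, sd1), d_embed, 256),
                 b = numeric(256)),
            init_batchnorm(256))
  out <- list(W = matrix(stats::rnorm(256 * k, 0, sd2), 256, k),
              b = numeric(k))
  structure(list(spectral = spectral, iso = iso, head = head, out = out,
                 dims = dims, k = as.integer(k), task_mode = task_mode,
                 laplacian = laplacian, fixed_lambda = fixed_lambda),
            class = "dual_branch_model")
}

#' Count trainable parameters of a dual-branch model
#'
#' Trainable scalars across both branches, links, head and output layer;
#' batch-norm running statistics and the fixed isomorphic self-weight are
#' excluded.
#'
#' @param model a `dual_branch_model`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  n_param_leaves(list(spectral = model$spectral, iso = model$iso,
                      head = model$head, out = model$out))
}

# per-graph forward through both branches up to the pooled 512-d embedding
branch_forward <- function(graph, model, training = FALSE, Lhat = NULL) {
  if (is.null(Lhat)) {
    Lhat <- graph_scaled_laplacian(graph, model$laplacian, model$fixed_lambda)
  }
  Lm <- Lhat$matrix
  A <- adjacency_matrix(graph)
  X <- graph$node_features
  nl <- length(model$spectral)
  caches <- vector("list", nl)
  for (l in seq_len(nl)) {
    sp <- model$spectral[[l]]
    Z1 <- X
    Z2 <- Lm %*% X
    Z3 <- 2 * Lm %*% Z2 - Z1
    spre <- sweep(Z1 %*% sp$theta[[1]] + Z2 %*% sp$theta[[2]] +
                    Z3 %*% sp$theta[[3]], 2, sp$bias, "+")
    S <- relu(spre)
    isf <- iso_forward(X, A, model$iso[[l]], training)
    model$iso[[l]] <- isf$params  # running-stat updates
    Fused <- fuse_layers(S, isf$Y)
    caches[[l]] <- list(X = X, Z1 = Z1, Z2 = Z2, Z3 = Z3, spre = spre,
                        iso = isf$cache)
    X <- Fused
  }
  emb <- global_mean_pool(X)
  list(embedding = emb, model = model,
       cache = list(layers = caches, Lm = Lm, A = A, n = nrow(A)))
}

# backward from d(embedding) to branch parameter gradients
branch_backward <- function(demb, model, cache) {
  n <- cache$n
  Lm <- cache$Lm
  A <- cache$A
  nl <- length(model$spectral)
  dX <- matrix(demb, n, length(demb), byrow = TRUE) / n
  sgrads <- vector("list", nl)
  igrads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    cc <- cache$layers[[l]]
    sp <- model$spectral[[l]]
    # fusion: identical gradient into both branch outputs
    dspre <- dX * (cc$spre > 0)
    sgrads[[l]] <- list(theta = list(crossprod(cc$Z1, dspre),
                                     crossprod(cc$Z2, dspre),
                                     crossprod(cc$Z3, dspre)),
                        bias = colSums(dspre))
    dZ3 <- dspre %*% t(sp$theta[[3]])
    dZ2 <- dspre %*% t(sp$theta[[2]]) + 2 * Lm %*% dZ3
    dZ1 <- dspre %*% t(sp$theta[[1]]) - dZ3
    dX_sp <- dZ1 + Lm %*% dZ2
    isb <- iso_backward(dX, cc$X, A, model$iso[[l]], cc$iso)
    igrads[[l]] <- isb$grads
    dX <- dX_sp + isb$dX
  }
  list(spectral = sgrads, iso = igrads)
}

# head forward over a batch of embeddings (B x 512)
head_forward <- function(E, model, training = FALSE) {
  pre1 <- sweep(E %*% model$head$W, 2, model$head$b, "+")
  bnf <- batchnorm_forward(pre1, model$head, training)
  model$head <- utils::modifyList(model$head,
                                  bnf$bn[c("running_mean", "running_var")])
  H <- relu(bnf$Y)
  logits <- sweep(H %*% model$out$W, 2, model$out$b, "+")
  list(logits = logits, model = model,
       cache = list(E = E, bn_cache = bnf$cache, bn_out = bnf$Y, H = H))
}

head_backward <- function(dlogits, model, cache) {
  dW2 <- crossprod(cache$H, dlogits)
  db2 <- colSums(dlogits)
  dH <- dlogits %*% t(model$out$W)
  dbn_out <- dH * (cache$bn_out > 0)
  bnb <- batchnorm_backward(dbn_out, model$head, cache$bn_cache)
  dpre1 <- bnb$dX
  dW1 <- crossprod(cache$E, dpre1)
  db1 <- colSums(dpre1)
  dE <- dpre1 %*% t(model$head$W)
  list(dE = dE,
       grads = list(head = list(W = dW1, b = db1, gamma = bnb$dgamma,
                                beta = bnb$dbeta),
                    out = list(W = dW2, b = db2)))
}

#' Predict from pooled graph embeddings
#'
#' Applies the prediction head (512 -> 256 affine + batch norm + ReLU, then
#' 256 -> k affine) and, in classification mode, an elementwise sigmoid.
#'
#' @param graph_embedding a 512-d vector or a B x 512 matrix.
#' @param model a `dual_branch_model`.
#' @return B x k matrix of probabilities (classification) or reals
#'   (regression).
#' @export
predict_head <- function(graph_embedding, model) {
  E <- if (is.matrix(graph_embedding)) graph_embedding
       else matrix(graph_embedding, nrow = 1)
  hf <- head_forward(E, model, training = FALSE)
  if (model$task_mode == "classification") sigmoid(hf$logits) else hf$logits
}

#' Predict properties for molecular graphs
#'
#' Full forward pass (both branches, pooling, head) in evaluation mode.
#'
#' @param object a `dual_branch_model`.
#' @param graphs list of [molecular_graph()] objects.
#' @param ... unused.
#' @return length(graphs) x k matrix of predictions.
#' @export
predict.dual_branch_model <- function(object, graphs, ...) {
  E <- t(vapply(graphs, function(g) branch_forward(g, object)$embedding,
                numeric(object$dims[length(object$dims)])))
  predict_head(E, object)
}

#' Masked negative log-likelihood / regression loss
#'
#' Classification: mean over observed (non-missing) label entries of
#' `-y log p - (1 - y) log(1 - p)`. Regression: mean squared error over
#' observed entries.
#'
#' @param probs B x k probabilities (classification) or predictions
#'   (regression).
#' @param labels B x k labels with NA marking missing entries.
#' @param task_mode `"classification"` or `"regression"`.
#' @return scalar loss.
#' @export
classification_loss <- function(probs, labels,
                                task_mode = c("classification", "regression")) {
  task_mode <- match.arg(task_mode)
  probs <- as.matrix(probs)
  labels <- as.matrix(labels)
  mask <- !is.na(labels)
  if (!any(mask)) stop("All labels are missing.", call. = FALSE)
  if (task_mode == "classification") {
    p <- pmin(pmax(probs[mask], 1e-7), 1 - 1e-7)
    y <- labels[mask]
    mean(-y * log(p) - (1 - y) * log(1 - p))
  } else {
    mean((probs[mask] - labels[mask])^2)
  }
}

#' Train the dual-branch classifier
#'
#' Loads the pre-trained spectral backbone (if given), then trains all
#' parameters of both branches, links and head end-to-end with Adam
#' (`beta1 = 0.9`, `beta2 = 0.999`, `lr = 2e-4`) on the masked
#' negative log-likelihood (classification) or MSE (regression). Tracks a
#' validation metric per epoch and returns the weights of the best epoch.
#'
#' @param graphs list of labelled [molecular_graph()] objects.
#' @param labels B x k label matrix (NA = missing); if `NULL`, taken from
#'   the graphs' `labels` fields.
#' @param backbone optional pre-trained encoder ([pretrain()]`$encoder`).
#' @param k number of tasks.
#' @param task_mode `"classification"` or `"regression"`.
#' @param epochs maximum epochs (the reference protocol allows up to 1000;
#'   synthetic tasks converge in far fewer).
#' @param batch_size graphs per optimiser step.
#' @param lr,beta1,beta2 Adam hyper-parameters.
#' @param val_graphs,val_labels optional validation split for model
#'   selection (best ROC-AUC for classification, lowest MSE for regression).
#' @param target_val_metric optional early-stopping target: training stops at
#'   the end of the first epoch whose validation ROC-AUC reaches this value
#'   (classification only). Useful to obtain a victim at a prescribed
#'   operating point rather than at saturation, where ranking metrics become
#'   insensitive to perturbations.
#' @param init initialisation for randomly initialised parts.
#' @param seed integer seed.
#' @param verbose print progress.
#' @return list with `model` (best weights), `final_model` (last epoch),
#'   `trace` (per-epoch loss and validation metric), `seed`.
#' @export
train_classifier <- function(graphs, labels = NULL, backbone = NULL, k = 1L,
                             task_mode = c("classification", "regression"),
                             epochs = 50L, batch_size = 32L, lr = 2e-4,
                             beta1 = 0.9, beta2 = 0.999,
                             val_graphs = NULL, val_labels = NULL,
                             target_val_metric = NULL,
                             init = c("scaled", "unit"), seed = 1L,
                             verbose = FALSE) {
  task_mode <- match.arg(task_mode)
  init <- match.arg(init)
  stopifnot(length(graphs) > 0)
  if (is.null(labels)) {
    labels <- do.call(rbind, lapply(graphs, function(g) {
      if (is.null(g$labels)) rep(NA_real_, k) else as.numeric(g$labels)
    }))
  }
  labels <- matrix(as.numeric(labels), nrow = length(graphs))
  stopifnot(ncol(labels) == k)
  set.seed(seed)
  model <- init_dual_branch(k = k, task_mode = task_mode, init = init,
                            backbone = backbone)
  trainable <- list(spectral = model$spectral, iso = model$iso,
                    head = model$head, out = model$out)
  opt <- adam_init(trainable)
  Lhats <- lapply(graphs, function(g) {
    graph_scaled_laplacian(g, model$laplacian, model$fixed_lambda)
  })
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      val_metric = numeric(0))
  best_metric <- if (task_mode == "classification") -Inf else Inf
  best_model <- model
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(graphs))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0; ep_nobs <- 0
    for (bt in batches) {
      bfw <- vector("list", length(bt))
      E <- matrix(0, length(bt), model$dims[length(model$dims)])
      for (bi in seq_along(bt)) {
        bfw[[bi]] <- branch_forward(graphs[[bt[bi]]], model, training = TRUE,
                                    Lhat = Lhats[[bt[bi]]])
        model <- bfw[[bi]]$model
        E[bi, ] <- bfw[[bi]]$embedding
      }
      hf <- head_forward(E, model, training = TRUE)
      model <- hf$model
      y <- labels[bt, , drop = FALSE]
      mask <- !is.na(y)
      nobs <- sum(mask)
      if (nobs == 0) next
      if (task_mode == "classification") {
        p <- sigmoid(hf$logits)
        loss <- classification_loss(p, y, task_mode)
        dlogits <- matrix(0, nrow(p), ncol(p))
        dlogits[mask] <- (p[mask] - y[mask]) / nobs
      } else {
        loss <- classification_loss(hf$logits, y, task_mode)
        dlogits <- matrix(0, nrow(hf$logits), ncol(hf$logits))
        dlogits[mask] <- 2 * (hf$logits[mask] - y[mask]) / nobs
      }
      if (!is.finite(loss)) {
        stop("Non-finite training loss at epoch ", ep, call. = FALSE)
      }
      hb <- head_backward(dlogits, model, hf$cache)
      bgrad <- list(spectral = NULL, iso = NULL,
                    head = hb$grads$head, out = hb$grads$out)
      acc <- NULL
      for (bi in seq_along(bt)) {
        bg <- branch_backward(hb$dE[bi, ], model, bfw[[bi]]$cache)
        acc <- if (is.null(acc)) bg else
          list(spectral = mapply(grad_add, acc$spectral, bg$spectral,
                                 SIMPLIFY = FALSE),
               iso = mapply(grad_add, acc$iso, bg$iso, SIMPLIFY = FALSE))
      }
      bgrad$spectral <- acc$spectral
      bgrad$iso <- acc$iso
      trainable <- list(spectral = model$spectral, iso = model$iso,
                        head = model$head, out = model$out)
      step <- adam_step(trainable, bgrad, opt, lr = lr,
                        beta1 = beta1, beta2 = beta2)
      opt <- step$state
      model$spectral <- step$params$spectral
      model$iso <- step$params$iso
      model$head <- utils::modifyList(model$head,
                                      step$params$head[c("W", "b", "gamma", "beta")])
      model$out <- step$params$out
      ep_loss <- ep_loss + loss * nobs
      ep_nobs <- ep_nobs + nobs
    }
    val_metric <- NA_real_
    if (!is.null(val_graphs)) {
      vp <- predict(model, val_graphs)
      if (task_mode == "classification") {
        val_metric <- tryCatch(roc_auc(val_labels, vp), error = function(e) NA)
        if (!is.na(val_metric) && val_metric > best_metric) {
          best_metric <- val_metric
          best_model <- model
        }
      } else {
        val_metric <- mean((vp - val_labels)^2, na.rm = TRUE)
        if (val_metric < best_metric) {
          best_metric <- val_metric
          best_model <- model
        }
      }
    } else {
      best_model <- model
    }
    trace <- rbind(trace, data.frame(epoch = ep, loss = ep_loss / max(ep_nobs, 1),
                                     val_metric = val_metric))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.4f", ep,
                      ep_loss / max(ep_nobs, 1), val_metric))
    }
    if (!is.null(target_val_metric) && task_mode == "classification" &&
        !is.na(val_metric) && val_metric >= target_val_metric) {
      break
    }
  }
  list(model = best_model, final_model = model, trace = trace, seed = seed)
}
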