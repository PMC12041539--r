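# Chebyshev spectral graph-convolution backbone: 3 layers (56 -> 128 -> 256
# -> 512), each a K = 3 Chebyshev filter on the scaled graph Laplacian,
# followed by ReLU; plus the parameter-free inner-product edge decoder.

#' Combinatorial graph Laplacian
#'
#' `L = D - A` on the simple undirected adjacency of the graph.
#'
#' @param graph a [molecular_graph()].
#' @return symmetric n x n matrix with zero row sums.
#' @export
build_laplacian <- function(graph) {
  A <- adjacency_matrix(graph)
  diag(rowSums(A), nrow(A)) - A
}

#' Symmetric-normalized graph Laplacian
#'
#' `L_sym = I - D^{-1/2} A D^{-1/2}`; rows and diagonal entries of isolated
#' (degree-0) nodes are zero, so an edgeless graph has the zero Laplacian.
#' Eigenvalues lie in `[0, 2]`.
#'
#' @param graph a [molecular_graph()].
#' @export
normalized_laplacian <- function(graph) {
  A <- adjacency_matrix(graph)
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  # isolated nodes get a zero diagonal (so an edgeless graph has L = 0)
  diag(as.numeric(d > 0), nrow(A)) - (dinv * A) %*% diag(dinv, nrow(A))
}

#' Largest Laplacian eigenvalue by power iteration
#'
#' @param L symmetric nonnegative-definite matrix.
#' @param tol convergence tolerance on the Rayleigh quotient.
#' @param max_iter iteration cap.
#' @return the dominant eigenvalue (0 for the zero matrix).
#' @export
lambda_max <- function(L, tol = 1e-6, max_iter = 200) {
  n <- nrow(L)
  if (n == 1) return(abs(L[1, 1]))
  # deterministic unstructured start: a constant vector would be orthogonal
  # to the dominant eigenspace of D - A (whose null vector is constant)
  v <- sin(seq_len(n) * 1.23) + 0.1
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (it in seq_len(max_iter)) {
    w <- as.vector(L %*% v)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) return(0)
    v <- w / nw
    lam_new <- sum(v * (L %*% v))
    if (abs(lam_new - lam) < tol) {
      lam <- lam_new
      break
    }
    lam <- lam_new
  }
  lam
}

#' Scale a Laplacian to the Chebyshev domain
#'
#' `Lhat = 2 L / lambda_max - I`, mapping the Laplacian spectrum into
#' `[-1, 1]`.
#'
#' @param L Laplacian matrix.
#' @param lambda_max its largest eigenvalue (must be positive).
#' @return list with `matrix` and `lambda_max` (class `scaled_laplacian`).
#' @export
scale_laplacian <- function(L, lambda_max) {
  if (lambda_max <= 0) {
    stop("lambda_max must be positive; got ", lambda_max, call. = FALSE)
  }
  structure(list(matrix = 2 * L / lambda_max - diag(nrow(L)),
                 lambda_max = lambda_max),
            class = "scaled_laplacian")
}

# scaled Laplacian for a graph under the encoder's configuration; edgeless
# graphs (zero Laplacian) fall back to the L_sym spectral bound lambda = 2,
# giving Lhat = -I
graph_scaled_laplacian <- function(graph, laplacian = c("sym", "comb"),
                                   fixed_lambda = NULL) {
  laplacian <- match.arg(laplacian)
  L <- if (laplacian == "sym") normalized_laplacian(graph)
       else build_laplacian(graph)
  lam <- if (!is.null(fixed_lambda)) {
    fixed_lambda
  } else if (nrow(L) <= 128) {
    # exact for the molecule-sized graphs this package works on; power
    # iteration can underestimate lambda_max when the top eigenvalues are
    # nearly degenerate, which would push the scaled spectrum outside [-1, 1]
    max(abs(eigen(L, symmetric = TRUE, only.values = TRUE)$values))
  } else {
    lambda_max(L)
  }
  if (lam <= 1e-8) lam <- 2
  scale_laplacian(L, lam)
}

#' Initialise one Chebyshev layer
#'
#' @param in_dim,out_dim layer dimensions.
#' @param K Chebyshev filter size (number of polynomial terms).
#' @param init `"scaled"` for variance-scaled normal draws (default) or
#'   `"unit"` for unit-variance normal draws; biases start at zero.
#' @return list with `theta` (K matrices) and `bias`.
#' @export
init_cheb_layer <- function(in_dim, out_dim, K = 3L, init = c("scaled", "unit")) {
  init <- match.arg(init)
  sd <- if (init == "unit") 1 else sqrt(1 / (K * in_dim))
  theta <- lapply(seq_len(K), function(k) {
    matrix(stats::rnorm(in_dim * out_dim, 0, sd), in_dim, out_dim)
  })
  list(theta = theta, bias = numeric(out_dim))
}

#' Chebyshev spectral graph convolution
#'
#' Computes `X' = sum_k Z^k Theta^k + bias` with the Chebyshev recursion
#' `Z^1 = X`, `Z^2 = Lhat X`, `Z^k = 2 Lhat Z^{k-1} - Z^{k-2}`.
#'
#' @param X n x in_dim node feature matrix.
#' @param Lhat a `scaled_laplacian` (or plain matrix).
#' @param params a Chebyshev layer from [init_cheb_layer()].
#' @return n x out_dim matrix.
#' @export
cheb_conv <- function(X, Lhat, params) {
  Lm <- if (inherits(Lhat, "scaled_laplacian")) Lhat$matrix else Lhat
  X <- as.matrix(X)
  if (nrow(Lm) != nrow(X)) {
    stop("Laplacian size ", nrow(Lm), " does not match node count ",
         nrow(X), call. = FALSE)
  }
  if (ncol(X) != nrow(params$theta[[1]])) {
    stop("Feature dimension ", ncol(X), " does not match layer input ",
         nrow(params$theta[[1]]), call. = FALSE)
  }
  K <- length(params$theta)
  Zprev2 <- X
  out <- X %*% params$theta[[1]]
  if (K >= 2) {
    Zprev1 <- Lm %*% X
    out <- out + Zprev1 %*% params$theta[[2]]
    if (K >= 3) {
      for (k in 3:K) {
        Zk <- 2 * Lm %*% Zprev1 - Zprev2
        out <- out + Zk %*% params$theta[[k]]
        Zprev2 <- Zprev1
        Zprev1 <- Zk
      }
    }
  }
  sweep(out, 2, params$bias, "+")
}

#' Initialise the spectral encoder
#'
#' Three Chebyshev layers with widths 56 -> 128 -> 256 -> 512, ReLU after
#' each.
#'
#' @param dims layer widths including the input width.
#' @param K Chebyshev filter size.
#' @param init weight initialisation scheme (see [init_cheb_layer()]).
#' @param laplacian `"sym"` (symmetric-normalized, default) or `"comb"`
#'   (combinatorial `D - A`).
#' @param fixed_lambda optional fixed `lambda_max` (e.g. 2 for `L_sym`);
#'   `NULL` computes it per graph (exactly for molecule-sized graphs, by
#'   power iteration beyond that).
#' @return an `encoder` parameter object.
#' @export
init_encoder <- function(dims = c(56L, 128L, 256L, 512L), K = 3L,
                         init = c("scaled", "unit"),
                         laplacian = c("sym", "comb"), fixed_lambda = NULL) {
  init <- match.arg(init)
  laplacian <- match.arg(laplacian)
  layers <- lapply(seq_len(length(dims) - 1), function(l) {
    init_cheb_layer(dims[l], dims[l + 1], K = K, init = init)
  })
  structure(list(layers = layers, dims = dims, K = K, laplacian = laplacian,
                 fixed_lambda = fixed_lambda),
            class = "encoder")
}

# forward pass through the cheb stack; returns caches needed for backprop
encode_forward <- function(graph, encoder, Lhat = NULL) {
  if (is.null(Lhat)) {
    Lhat <- graph_scaled_laplacian(graph, encoder$laplacian,
                                   encoder$fixed_lambda)
  }
  Lm <- Lhat$matrix
  X <- graph$node_features
  caches <- vector("list", length(encoder$layers))
  for (l in seq_along(encoder$layers)) {
    p <- encoder$layers[[l]]
    Z1 <- X
    Z2 <- Lm %*% X
    Z3 <- 2 * Lm %*% Z2 - Z1
    pre <- Z1 %*% p$theta[[1]] + Z2 %*% p$theta[[2]] + Z3 %*% p$theta[[3]]
    pre <- sweep(pre, 2, p$bias, "+")
    out <- relu(pre)
    caches[[l]] <- list(Z1 = Z1, Z2 = Z2, Z3 = Z3, pre = pre)
    X <- out
  }
  list(z = X, caches = caches, Lhat = Lhat)
}

#' Encode a molecular graph into per-node latent embeddings
#'
#' @param graph a [molecular_graph()] with 56-d node features.
#' @param encoder an encoder from [init_encoder()].
#' @return n x 512 embedding matrix.
#' @export
encode <- function(graph, encoder) {
  if (ncol(graph$node_features) != encoder$dims[1]) {
    stop("Node features have ", ncol(graph$node_features),
         " dimensions; encoder expects ", encoder$dims[1], call. = FALSE)
  }
  encode_forward(graph, encoder)$z
}

# backprop through the cheb stack; dZ is the gradient at the encoder output.
# Relies on Lhat being symmetric. Returns gradients mirroring encoder$layers.
encode_backward <- function(fw, encoder, dZ) {
  Lm <- fw$Lhat$matrix
  grads <- vector("list", length(encoder$layers))
  for (l in rev(seq_along(encoder$layers))) {
    cache <- fw$caches[[l]]
    p <- encoder$layers[[l]]
    dpre <- dZ * (cache$pre > 0)
    g <- list(theta = list(crossprod(cache$Z1, dpre),
                           crossprod(cache$Z2, dpre),
                           crossprod(cache$Z3, dpre)),
              bias = colSums(dpre))
    grads[[l]] <- g
    dZ3 <- dpre %*% t(p$theta[[3]])
    dZ2 <- dpre %*% t(p$theta[[2]]) + 2 * Lm %*% dZ3
    dZ1 <- dpre %*% t(p$theta[[1]]) - dZ3
    dZ <- dZ1 + Lm %*% dZ2
  }
  list(layers = grads)
}

#' Inner-product edge decoder
#'
#' Edge probabilities `p = sigmoid(z z^T)`; symmetric by construction with
#' entries strictly inside (0, 1). The decoder has no parameters.
#'
#' @param z n x d latent embedding matrix.
#' @return symmetric n x n probability matrix.
#' @export
decode <- function(z) {
  z <- as.matrix(z)
  stopifnot(all(is.finite(z)))
  sigmoid(tcrossprod(z))
}
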