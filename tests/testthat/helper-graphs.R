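# Shared fixtures for the test suite. All graphs are built in code; RDKit
# parses are memoised inside the package, so repeated helpers are cheap.

# a hand-built molecular graph: path 1-2-3 with arbitrary 56-d features
path3_graph <- function(features = NULL) {
  if (is.null(features)) {
    set.seed(42)
    features <- matrix(stats::runif(3 * 56), 3, 56)
  }
  edges <- rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L))
  efeat <- matrix(rep(featurize_bond("single", FALSE), 4),
                  nrow = 4, byrow = TRUE)
  molecular_graph(features, edges, efeat, smiles = "synthetic-path3")
}

# a random undirected graph as a molecular_graph with random features;
# guaranteed connected enough for spectral tests (at least one edge)
random_graph <- function(n, in_dim = 4, p_edge = 0.5) {
  repeat {
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p_edge)
    A <- A + t(A)
    if (sum(A) > 0 || n == 1) break
  }
  idx <- which(A == 1, arr.ind = TRUE)
  efeat <- matrix(rep(featurize_bond("single", FALSE), nrow(idx)),
                  nrow = nrow(idx), byrow = TRUE)
  molecular_graph(matrix(stats::rnorm(n * in_dim), n, in_dim),
                  idx, efeat, smiles = "synthetic-random")
}

# small cached set of featurized fixture molecules
fixture_graphs <- local({
  cache <- NULL
  function(n = 30) {
    if (is.null(cache)) {
      fx <- fixture_molecules()
      cache <<- smiles_to_graphs(fx$smiles[seq_len(min(60, nrow(fx)))])
    }
    cache[seq_len(min(n, length(cache)))]
  }
})

# tiny encoder working on low-dimensional inputs, for fast spectral tests
tiny_encoder <- function(dims = c(4L, 5L, 6L, 7L), seed = 1) {
  set.seed(seed)
  init_encoder(dims = dims)
}

# permute the nodes of a molecular_graph
permute_graph <- function(graph, perm) {
  inv <- order(perm)
  edges <- cbind(perm[graph$edges[, 1]], perm[graph$edges[, 2]])
  molecular_graph(graph$node_features[inv, , drop = FALSE],
                  edges, graph$edge_features,
                  labels = graph$labels, smiles = graph$smiles)
}
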