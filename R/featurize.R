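# Atom/bond featurization: 56-d node vectors and 9-d edge vectors.
#
# Node layout (56 slots):
#   1-7    formal charge one-hot over {-3..+3}
#   8-19   heavy-atom degree one-hot over {0..10, >=11}
#   20-25  hybridization one-hot over {sp, sp2, sp3, sp3d, sp3d2, other}
#   26     in-ring flag
#   27     aromatic flag
#   28-30  scaled atomic mass, van der Waals radius, covalent radius
#   31-56  element one-hot over 26 drug-like elements
#
# Edge layout (9 slots): bond type one-hot {single, double, triple, aromatic},
# conjugation flag, stereo one-hot {none, any, E, Z}.

#' Supported elements
#'
#' The 26 drug-like elements recognised by the atom featurizer, in one-hot
#' slot order.
#' @export
ELEMENTS <- c("B", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P", "S",
              "Cl", "K", "Ca", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
              "As", "Se", "Br", "Sn", "I")

#' Hybridization classes
#'
#' One-hot slot order of the hybridization block.
#' @export
HYBRIDIZATIONS <- c("sp", "sp2", "sp3", "sp3d", "sp3d2", "other")

#' Bond order vocabulary
#'
#' One-hot slot order of the bond-type block.
#' @export
BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' Bond stereo vocabulary
#'
#' One-hot slot order of the E/Z stereo block.
#' @export
STEREO_LABELS <- c("none", "any", "E", "Z")

#' Atom feature vector length
#' @export
ATOM_FEATURE_DIM <- 56L

#' Bond feature vector length
#' @export
BOND_FEATURE_DIM <- 9L

#' Formal charge of an atom
#'
#' Computes the formal charge from electron counts as
#' `V - N - B/2` (valence minus non-bonding minus half the bonding
#' electrons), clamped to `[-3, 3]`, the range covered by the charge one-hot.
#'
#' @param valence_electrons number of valence electrons of the free atom.
#' @param nonbonding_electrons number of non-bonding valence electrons.
#' @param bonding_electrons total electrons shared in bonds (must be even).
#' @return integer formal charge in `[-3, 3]`.
#' @examples
#' compute_formal_charge(4, 0, 8) # methane carbon: 0
#' compute_formal_charge(6, 2, 6) # hydronium oxygen: +1
#' @export
compute_formal_charge <- function(valence_electrons, nonbonding_electrons,
                                  bonding_electrons) {
  stopifnot(valence_electrons >= 0, nonbonding_electrons >= 0,
            bonding_electrons >= 0)
  if (bonding_electrons %% 2 != 0) {
    stop("bonding_electrons must be even; got ", bonding_electrons,
         call. = FALSE)
  }
  fc <- valence_electrons - nonbonding_electrons - bonding_electrons / 2
  as.integer(max(-3, min(3, fc)))
}

#' Hybrid-orbital count
#'
#' `H = (V + M - C + A) / 2`, rounded to the nearest integer: valence
#' electrons of the central atom plus monovalent neighbours, adjusted for
#' cationic/anionic charge.
#'
#' @param valence valence electrons of the central atom.
#' @param monovalent_neighbors number of surrounding monovalent atoms.
#' @param cation_charge magnitude of positive charge.
#' @param anion_charge magnitude of negative charge.
#' @return integer orbital count.
#' @export
count_hybrid_orbitals <- function(valence, monovalent_neighbors,
                                  cation_charge = 0, anion_charge = 0) {
  stopifnot(valence >= 0, monovalent_neighbors >= 0,
            cation_charge >= 0, anion_charge >= 0)
  as.integer(round((valence + monovalent_neighbors - cation_charge +
                      anion_charge) / 2))
}

#' Map a hybrid-orbital count to a hybridization class
#'
#' 2 -> sp, 3 -> sp2, 4 -> sp3, 5 -> sp3d, 6 -> sp3d2; anything else falls in
#' the "other" class.
#'
#' @param H hybrid-orbital count (nonnegative integer).
#' @return one of `"sp"`, `"sp2"`, `"sp3"`, `"sp3d"`, `"sp3d2"`, `"other"`.
#' @export
map_hybridization <- function(H) {
  stopifnot(H >= 0)
  switch(as.character(H),
         "2" = "sp", "3" = "sp2", "4" = "sp3",
         "5" = "sp3d", "6" = "sp3d2", "other")
}

#' Scale an atomic mass
#'
#' Affine rescaling `(mass - 10.812) / 116.092` mapping boron's mass to 0 and
#' iodine's to 1 over the supported element range.
#' @param mass atomic mass in unified atomic mass units.
#' @export
scale_atomic_mass <- function(mass) {
  stopifnot(mass > 0)
  (mass - 10.812) / 116.092
}

#' Scale a van der Waals radius
#'
#' Affine rescaling `(radius - 1.5) / 0.6` (radius in Angstrom).
#' @param radius van der Waals radius in Angstrom.
#' @export
scale_vdw_radius <- function(radius) {
  stopifnot(radius > 0)
  (radius - 1.5) / 0.6
}

#' Scale a covalent radius
#'
#' Affine rescaling `(radius - 0.64) / 0.76` (radius in Angstrom).
#' @param radius covalent radius in Angstrom.
#' @export
scale_covalent_radius <- function(radius) {
  stopifnot(radius > 0)
  (radius - 0.64) / 0.76
}

one_hot <- function(index, n) {
  v <- numeric(n)
  v[index] <- 1
  v
}

#' Build a 56-d atom feature vector
#'
#' Concatenates the charge, degree and hybridization one-hots, ring and
#' aromatic flags, the three scaled scalars and the element one-hot.
#'
#' @param element element symbol; must be one of [ELEMENTS].
#' @param formal_charge integer charge, clamped to `[-3, 3]`.
#' @param degree heavy-atom degree (capped at the `>=11` bucket).
#' @param hybridization one of [HYBRIDIZATIONS].
#' @param in_ring,aromatic logical or 0/1 flags.
#' @param mass,vdw_radius,covalent_radius raw (unscaled) atom properties.
#' @return numeric vector of length 56.
#' @export
featurize_atom <- function(element, formal_charge, degree, hybridization,
                           in_ring, aromatic, mass, vdw_radius,
                           covalent_radius) {
  el_idx <- match(element, ELEMENTS)
  if (is.na(el_idx)) {
    stop("Unsupported element: '", element, "'", call. = FALSE)
  }
  fc <- max(-3L, min(3L, as.integer(formal_charge)))
  deg <- min(as.integer(degree), 11L)
  hyb_idx <- match(hybridization, HYBRIDIZATIONS)
  if (is.na(hyb_idx)) hyb_idx <- match("other", HYBRIDIZATIONS)
  c(one_hot(fc + 4L, 7L),
    one_hot(deg + 1L, 12L),
    one_hot(hyb_idx, 6L),
    as.numeric(as.logical(in_ring)),
    as.numeric(as.logical(aromatic)),
    scale_atomic_mass(mass),
    scale_vdw_radius(vdw_radius),
    scale_covalent_radius(covalent_radius),
    one_hot(el_idx, 26L))
}

#' Build a 9-d bond feature vector
#'
#' @param order one of [BOND_ORDERS].
#' @param conjugated logical or 0/1 flag.
#' @param stereo one of [STEREO_LABELS]; defaults to `"none"`.
#' @return numeric vector of length 9.
#' @export
featurize_bond <- function(order, conjugated, stereo = "none") {
  o_idx <- match(order, BOND_ORDERS)
  if (is.na(o_idx)) {
    stop("Unknown bond order: '", order, "'", call. = FALSE)
  }
  s_idx <- match(stereo, STEREO_LABELS)
  if (is.na(s_idx)) s_idx <- 1L
  c(one_hot(o_idx, 4L),
    as.numeric(as.logical(conjugated)),
    one_hot(s_idx, 4L))
}

#' Construct a molecular graph object
#'
#' Low-level constructor; [smiles_to_graph()] is the usual entry point.
#' Edges are stored directed both ways with mirrored edge features.
#'
#' @param node_features n x 56 numeric matrix.
#' @param edges m x 2 integer matrix of 1-based node indices (both
#'   directions of every bond).
#' @param edge_features m x 9 numeric matrix aligned with `edges`.
#' @param labels optional label vector (NA = missing).
#' @param smiles provenance SMILES string.
#' @return an object of class `molecular_graph`.
#' @export
molecular_graph <- function(node_features, edges, edge_features,
                            labels = NULL, smiles = NA_character_) {
  node_features <- as.matrix(node_features)
  n <- nrow(node_features)
  stopifnot(n >= 1)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    stopifnot(all(edges >= 1), all(edges <= n), all(edges[, 1] != edges[, 2]))
  }
  edge_features <- matrix(as.numeric(edge_features), nrow = nrow(edges))
  structure(
    list(node_features = node_features, edges = edges,
         edge_features = edge_features, labels = labels, smiles = smiles),
    class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$smiles, "\n",
      "  nodes: ", nrow(x$node_features),
      "  directed edges: ", nrow(x$edges),
      if (!is.null(x$labels)) paste0("  labels: ", length(x$labels)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Number of nodes in a molecular graph
#' @param graph a `molecular_graph`.
#' @export
n_nodes <- function(graph) nrow(graph$node_features)

#' Dense adjacency matrix of a molecular graph
#'
#' @param graph a `molecular_graph`.
#' @return symmetric n x n 0/1 matrix without self-loops.
#' @export
adjacency_matrix <- function(graph) {
  n <- n_nodes(graph)
  A <- matrix(0, n, n)
  if (nrow(graph$edges) > 0) A[graph$edges] <- 1
  A
}

#' Undirected edge pairs of a molecular graph
#'
#' @param graph a `molecular_graph`.
#' @return m/2 x 2 matrix with i < j, one row per bond.
#' @export
undirected_edges <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0) return(matrix(integer(0), ncol = 2))
  keep <- e[, 1] < e[, 2]
  e[keep, , drop = FALSE]
}

graph_from_parsed <- function(parsed, labels = NULL, smiles = NA_character_) {
  atoms <- parsed$atoms
  n <- length(atoms)
  X <- matrix(0, n, ATOM_FEATURE_DIM)
  for (i in seq_len(n)) {
    a <- atoms[[i]]
    X[i, ] <- featurize_atom(a$element, a$formal_charge, a$degree,
                             a$hybridization, a$in_ring, a$aromatic,
                             a$mass, a$vdw_radius, a$covalent_radius)
  }
  bonds <- parsed$bonds
  m <- length(bonds)
  edges <- matrix(integer(0), ncol = 2)
  efeat <- matrix(numeric(0), ncol = BOND_FEATURE_DIM)
  if (m > 0) {
    edges <- matrix(0L, 2L * m, 2L)
    efeat <- matrix(0, 2L * m, BOND_FEATURE_DIM)
    for (b in seq_len(m)) {
      bd <- bonds[[b]]
      fv <- featurize_bond(bd$order, bd$conjugated, bd$stereo)
      edges[2L * b - 1L, ] <- c(bd$i, bd$j)
      edges[2L * b, ] <- c(bd$j, bd$i)
      efeat[2L * b - 1L, ] <- fv
      efeat[2L * b, ] <- fv
    }
  }
  molecular_graph(X, edges, efeat, labels = labels, smiles = smiles)
}

#' Convert a SMILES string to a featurized molecular graph
#'
#' Parses the SMILES with RDKit (heavy atoms only; hydrogens implicit) and
#' assembles the 56-d node and 9-d edge feature matrices. Every bond is stored
#' as two directed edges with identical features.
#'
#' @param smiles a single SMILES string.
#' @param labels optional label vector attached unchanged (NA = missing).
#' @return a [molecular_graph()].
#' @examples
#' \dontrun{
#' g <- smiles_to_graph("c1ccccc1")  # benzene: 6 nodes, 12 directed edges
#' }
#' @export
smiles_to_graph <- function(smiles, labels = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  parsed <- parse_smiles(smiles)[[1]]
  if (is.null(parsed)) {
    stop("Unparsable SMILES: '", smiles, "'", call. = FALSE)
  }
  graph_from_parsed(parsed, labels = labels, smiles = smiles)
}

#' Convert many SMILES strings to molecular graphs
#'
#' Batch variant of [smiles_to_graph()]; one RDKit subprocess for the whole
#' vector. Unparsable entries yield `NULL` with a warning.
#'
#' @param smiles character vector.
#' @param labels optional list or matrix of per-molecule labels.
#' @return list of [molecular_graph()] (or `NULL` for failures).
#' @export
smiles_to_graphs <- function(smiles, labels = NULL) {
  parsed <- parse_smiles(smiles)
  out <- vector("list", length(smiles))
  bad <- 0L
  for (i in seq_along(smiles)) {
    if (is.null(parsed[[i]])) {
      bad <- bad + 1L
      next
    }
    lab <- if (is.null(labels)) NULL
           else if (is.matrix(labels)) labels[i, ]
           else if (is.list(labels)) labels[[i]]
           else labels[i]
    out[[i]] <- graph_from_parsed(parsed[[i]], labels = lab,
                                  smiles = smiles[i])
  }
  if (bad > 0) {
    warning(bad, " SMILES string(s) could not be parsed and were dropped.",
            call. = FALSE)
  }
  out
}
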