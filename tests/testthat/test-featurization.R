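# Atom/bond featurization and SMILES-to-graph conversion.

test_that("formal charge follows the electron-count oracle", {
  # methane C, hydronium O, hydroxide O: textbook formal-charge cases
  expect_identical(compute_formal_charge(4, 0, 8), 0L)
  expect_identical(compute_formal_charge(6, 2, 6), 1L)
  expect_identical(compute_formal_charge(6, 6, 2), -1L)
  # clamped to the one-hot range
  expect_identical(compute_formal_charge(8, 0, 0), 3L)
  expect_error(compute_formal_charge(4, 0, 7), "even")
})

test_that("hybrid-orbital count and hybridization mapping follow the table", {
  expect_identical(count_hybrid_orbitals(4, 4), 4L)   # CH4
  expect_identical(count_hybrid_orbitals(5, 5), 5L)   # PCl5
  expect_identical(count_hybrid_orbitals(6, 6), 6L)   # SF6
  expect_identical(map_hybridization(2), "sp")
  expect_identical(map_hybridization(3), "sp2")
  expect_identical(map_hybridization(4), "sp3")
  expect_identical(map_hybridization(5), "sp3d")
  expect_identical(map_hybridization(6), "sp3d2")
  expect_identical(map_hybridization(1), "other")
  expect_identical(map_hybridization(7), "other")
})

test_that("property scalings are the stated affine maps", {
  expect_equal(scale_atomic_mass(10.812), 0)
  expect_equal(scale_atomic_mass(126.904), 1)
  expect_equal(scale_atomic_mass(12.011), 0.010328, tolerance = 1e-4)
  expect_equal(scale_vdw_radius(1.5), 0)
  expect_equal(scale_vdw_radius(2.1), 1)
  expect_equal(scale_vdw_radius(1.7), 1 / 3, tolerance = 1e-10)
  expect_equal(scale_vdw_radius(1.2), -0.5)
  expect_equal(scale_covalent_radius(0.64), 0)
  expect_equal(scale_covalent_radius(1.40), 1)
  expect_equal(scale_covalent_radius(0.76), 0.15789, tolerance = 1e-4)
})

test_that("the scaling maps satisfy the affine identity f(x)+f(y)=f(x+y)+f(0)", {
  fns <- list(scale_atomic_mass, scale_vdw_radius, scale_covalent_radius)
  set.seed(1)
  for (f in fns) {
    x <- runif(20, 0.5, 150)
    y <- runif(20, 0.5, 150)
    expect_equal(f(x) + f(y), f(x + y) + f(1e-12 + 0 * x), tolerance = 1e-8)
  }
})

test_that("atom feature vectors have the documented 56-slot layout", {
  v <- featurize_atom("C", 0, 3, "sp2", TRUE, TRUE, 12.011, 1.7, 0.76)
  expect_length(v, 56)
  expect_equal(v[4], 1)              # charge 0 slot
  expect_equal(sum(v[1:7]), 1)       # charge one-hot
  expect_equal(sum(v[8:19]), 1)      # degree one-hot
  expect_equal(v[8 + 3], 1)          # degree 3 slot
  expect_equal(sum(v[20:25]), 1)     # hybridization one-hot
  expect_equal(v[21], 1)             # sp2 slot
  expect_equal(v[26], 1)             # in ring
  expect_equal(v[27], 1)             # aromatic
  expect_equal(sum(v[31:56]), 1)     # element one-hot
  expect_equal(v[30 + match("C", ELEMENTS)], 1)

  # degenerate isolated atom
  v0 <- featurize_atom("N", 0, 0, "other", FALSE, FALSE, 14.007, 1.6, 0.71)
  expect_equal(v0[8], 1)
  expect_equal(v0[26], 0)
  expect_equal(v0[27], 0)

  # exactly three non-indicator real slots
  idx_real <- which(!(v %in% c(0, 1)))
  expect_true(all(idx_real %in% 28:30))

  expect_error(featurize_atom("Xx", 0, 0, "sp3", FALSE, FALSE, 1, 1, 1),
               "Xx")
})

test_that("bond feature vectors have the documented 9-slot layout", {
  v <- featurize_bond("double", TRUE, "E")
  expect_length(v, 9)
  expect_equal(v[2], 1)
  expect_equal(v[5], 1)
  expect_equal(v[5 + match("E", STEREO_LABELS)], 1)
  v2 <- featurize_bond("single", FALSE)
  expect_equal(v2[1], 1)
  expect_equal(v2[5], 0)
  expect_equal(v2[6], 1)  # stereo none
  v3 <- featurize_bond("aromatic", TRUE)
  expect_equal(v3[4], 1)
  expect_error(featurize_bond("quadruple", FALSE), "bond order")
})

test_that("smiles_to_graph builds the expected structures", {
  g1 <- smiles_to_graph("C")
  expect_equal(n_nodes(g1), 1)
  expect_equal(nrow(g1$edges), 0)

  g2 <- smiles_to_graph("CC")
  expect_equal(n_nodes(g2), 2)
  expect_equal(nrow(g2$edges), 2)
  expect_equal(g2$edge_features[1, ], g2$edge_features[2, ])

  g6 <- smiles_to_graph("c1ccccc1")
  expect_equal(n_nodes(g6), 6)
  expect_equal(nrow(g6$edges), 12)
  expect_true(all(g6$node_features[, 26] == 1))  # in ring
  expect_true(all(g6$node_features[, 27] == 1))  # aromatic

  expect_error(smiles_to_graph("not-a-molecule"), "not-a-molecule")
})

test_that("labels are attached unchanged", {
  g <- smiles_to_graph("CCO", labels = c(1, NA, 0))
  expect_identical(g$labels, c(1, NA, 0))
})

test_that("featurization invariants hold over the fixture set", {
  for (g in fixture_graphs(30)) {
    X <- g$node_features
    expect_equal(ncol(X), 56)
    expect_true(all(abs(rowSums(X[, 1:7, drop = FALSE]) - 1) < 1e-12))
    expect_true(all(abs(rowSums(X[, 8:19, drop = FALSE]) - 1) < 1e-12))
    expect_true(all(abs(rowSums(X[, 20:25, drop = FALSE]) - 1) < 1e-12))
    expect_true(all(abs(rowSums(X[, 31:56, drop = FALSE]) - 1) < 1e-12))
    expect_true(all(X[, 26:27] %in% c(0, 1)))
    if (nrow(g$edges) > 0) {
      E <- g$edge_features
      expect_equal(ncol(E), 9)
      expect_true(all(abs(rowSums(E[, 1:4, drop = FALSE]) - 1) < 1e-12))
      expect_true(all(abs(rowSums(E[, 6:9, drop = FALSE]) - 1) < 1e-12))
      # symmetric, self-loop-free edge set
      expect_true(all(g$edges[, 1] != g$edges[, 2]))
      key <- paste(g$edges[, 1], g$edges[, 2])
      rkey <- paste(g$edges[, 2], g$edges[, 1])
      expect_setequal(key, rkey)
      A <- adjacency_matrix(g)
      expect_true(isSymmetric(A))
      expect_true(all(diag(A) == 0))
    }
  }
})
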