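test_that("conformer generation relaxes sensible geometries deterministically", {
  h2 <- generate_conformer("[H][H]")
  expect_equal(nrow(h2), 2)
  blen <- sqrt(sum((h2[1, ] - h2[2, ])^2))
  expect_gt(blen, 0.5)
  expect_lt(blen, 1.1)

  ch4 <- generate_conformer("C")
  expect_equal(nrow(ch4), 5)
  expect_equal(attr(ch4, "elements")[1], "C")
  ch_d <- apply(ch4[2:5, ], 1, function(h) sqrt(sum((h - ch4[1, ])^2)))
  expect_lt(max(ch_d) - min(ch_d), 0.05)  # tetrahedral symmetry

  again <- generate_conformer("C")
  expect_identical(unclass(ch4)[seq_along(ch4)], unclass(again)[seq_along(again)])
})

test_that("radius edges match the brute-force pairwise oracle", {
  two <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_edges(two, 4)$edges,
               matrix(c(1L, 2L, 2L, 1L), 2, 2, byrow = TRUE,
                      dimnames = list(NULL, c("i", "j"))))
  far <- matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(nrow(radius_edges(far, 4)$edges), 0)

  set.seed(99)
  for (cutoff in c(1.5, 3, 6)) {
    pts <- matrix(stats::rnorm(60, sd = 2), 20, 3)
    got <- radius_edges(pts, cutoff)
    # brute force O(n^2) oracle
    oracle <- NULL
    for (i in 1:20) for (j in 1:20) {
      if (i != j && sqrt(sum((pts[i, ] - pts[j, ])^2)) <= cutoff) {
        oracle <- rbind(oracle, c(i, j))
      }
    }
    o <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
    expect_equal(unname(got$edges), o)
    # symmetry of the edge set
    key <- paste(got$edges[, 1], got$edges[, 2])
    rev <- paste(got$edges[, 2], got$edges[, 1])
    expect_setequal(key, rev)
  }
})

test_that("Fourier distance features obey the encoding identities", {
  z <- fourier_distance_features(0, K = 5, r_max = 4)
  expect_equal(as.vector(z), c(rep(0, 5), rep(1, 5)))
  e <- fourier_distance_features(4, K = 3, r_max = 4)
  expect_equal(e[1, 1], sin(pi), tolerance = 1e-12)
  expect_equal(e[1, 4], cos(pi))
  r <- stats::runif(50, 0, 20)
  f <- fourier_distance_features(r, K = 16, r_max = 4)
  expect_true(all(f >= -1 & f <= 1))
  expect_equal(dim(f), c(50, 32))
  expect_error(fourier_distance_features(1, K = 4, r_max = 0), "r_max")
})

test_that("graph construction perceives structure and enforces the atom vocabulary", {
  pyr <- build_graph("c1ccncc1", mode = "2d")
  expect_equal(pyr$n_atoms, 11)  # 6 heavy + 5 explicit H
  expect_equal(sum(pyr$aromatic), 6)
  expect_equal(sum(pyr$in_ring), 6)
  expect_equal(sum(pyr$elements == "H"), 5)
  # ring atoms sp2, hydrogens s
  expect_true(all(pyr$hybridization_idx[pyr$aromatic] == 2))
  expect_true(all(pyr$hybridization_idx[pyr$elements == "H"] == 4))

  ch4 <- build_graph("C", mode = "3d", cutoff_A = 4)
  expect_equal(ch4$n_atoms, 5)
  expect_equal(nrow(ch4$edges), 20)  # complete graph on 5 atoms
  expect_true(all(ch4$edge_dist <= 4))

  # selenium is in the vocabulary, boron is not
  expect_s3_class(build_graph("C[Se]C", mode = "2d"), "mol_graph")
  expect_error(build_graph("B(O)(O)c1ccccc1", mode = "2d"), "unsupported")
})

test_that("2D and 3D graphs of one molecule share node features", {
  g2 <- build_graph("Cc1ccncc1", mode = "2d")
  g3 <- build_graph("Cc1ccncc1", mode = "3d")
  expect_identical(g2$features, g3$features)
  expect_null(g2$coords)
  expect_false(is.null(g3$coords))
})

test_that("node features are invariant to the SMILES atom ordering", {
  a <- build_graph("c1ccncc1", mode = "2d")
  b <- build_graph("n1ccccc1", mode = "2d")
  expect_equal(a$n_atoms, b$n_atoms)
  # same multiset of atom feature rows
  key <- function(g) sort(apply(g$features, 1, paste, collapse = ""))
  expect_identical(key(a), key(b))
})
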