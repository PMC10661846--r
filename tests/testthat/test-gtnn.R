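test_that("the message-passing layer equals a per-atom loop oracle on a toy graph", {
  H <- 6L; K <- 2L
  # 3D toy graph: 4 atoms, edges both ways along a path plus one long pair
  coords <- matrix(c(0, 0, 0, 1.5, 0, 0, 3, 0, 0, 0, 2, 0), 4, 3, byrow = TRUE)
  re <- radius_edges(coords, 4)
  g <- toy_graph(t(re$edges), coords = coords, K = K)
  g$edges <- re$edges
  g$edge_dist <- re$dist
  g$edge_feat <- fourier_distance_features(re$dist, K = K, r_max = 4)

  set.seed(5)
  h <- matrix(stats::rnorm(4 * H), 4, H)
  psi <- toy_mlp(2 * H + 2 * K, H, H, seed = 1)
  phi <- toy_mlp(2 * H, H, H, seed = 2)

  got <- mp_layer(g, h, psi, phi)

  # independent oracle: explicit loop over atoms and neighbors
  oracle <- matrix(0, 4, H)
  for (i in 1:4) {
    m_i <- rep(0, H)
    for (e in seq_len(nrow(g$edges))) {
      if (g$edges[e, 1] == i) {
        j <- g$edges[e, 2]
        x <- c(h[i, ], h[j, ], g$edge_feat[e, ])
        m_i <- m_i + as.vector(mlp_apply(psi, matrix(x, 1)))
      }
    }
    oracle[i, ] <- mlp_apply(phi, matrix(c(h[i, ], m_i), 1))
  }
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("an atom without neighbors reduces the update to phi(h, 0)", {
  H <- 5L
  g <- toy_graph(c(1, 2, 2, 1), n = 3L)  # atom 3 isolated
  h <- matrix(stats::rnorm(3 * H), 3, H)
  psi <- toy_mlp(2 * H, H, H, seed = 3)
  phi <- toy_mlp(2 * H, H, H, seed = 4)
  got <- mp_layer(g, h, psi, phi)
  expect_equal(got[3, ],
               as.vector(mlp_apply(phi, matrix(c(h[3, ], rep(0, H)), 1))),
               tolerance = 1e-12)

  # edge-free graph: every atom collapses to phi(h, 0)
  g0 <- toy_graph(integer(0), n = 3L)
  g0$edges <- matrix(integer(0), ncol = 2,
                     dimnames = list(NULL, c("i", "j")))
  got0 <- mp_layer(g0, h, psi, phi)
  oracle0 <- t(apply(h, 1, function(r)
    mlp_apply(phi, matrix(c(r, rep(0, H)), 1))))
  expect_equal(got0, oracle0, tolerance = 1e-12)
})

test_that("duplicating an edge adds exactly one extra message to the sum", {
  H <- 4L
  g1 <- toy_graph(c(1, 2), n = 2L)
  g2 <- toy_graph(c(1, 2, 1, 2), n = 2L)  # edge (1,2) twice
  h <- matrix(stats::rnorm(2 * H), 2, H)
  psi <- toy_mlp(2 * H, H, H, seed = 6)
  # identity-like phi: recover m_i as phi output by using linear phi W2
  phi <- list(W1 = diag(2 * H), b1 = matrix(0, 1, 2 * H),
              W2 = rbind(matrix(0, H, H), diag(H)), b2 = matrix(0, 1, H))
  m1 <- mp_layer(g1, h, psi, phi)
  m2 <- mp_layer(g2, h, psi, phi)
  m12 <- as.vector(mlp_apply(psi, matrix(c(h[1, ], h[2, ], numeric(0)), 1)))
  # phi is silu(x W1) W2 = silu([h, m]) projected onto the m block; compare
  # through the oracle instead of assuming linearity:
  oracle <- function(m_i) as.vector(mlp_apply(phi, matrix(c(h[1, ], m_i), 1)))
  expect_equal(m1[1, ], oracle(m12), tolerance = 1e-12)
  expect_equal(m2[1, ], oracle(2 * m12), tolerance = 1e-12)
})

test_that("the full forward pass is deterministic, bounded and atom-permutation invariant", {
  recs <- synth_80()[1:6]
  cfg <- tiny_config()
  model <- train_gtnn(recs, task = "yield", config = cfg, seed = 1,
                      epochs = 1, batch_size = 6)
  p1 <- gtnn_forward(model, recs)
  p2 <- gtnn_forward(model, recs)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))

  # permute the atoms of one substrate graph: prediction must not move
  smi <- recs[[1]]$substrate_smiles
  g <- build_graph(smi, mode = "2d")
  perm <- sample(g$n_atoms)
  gp <- g
  gp$features <- g$features[perm, , drop = FALSE]
  inv <- order(perm)
  gp$edges <- matrix(as.integer(inv[g$edges]), ncol = 2,
                     dimnames = dimnames(g$edges))
  gp$atom_type_idx <- g$atom_type_idx[perm]
  cache_id <- stats::setNames(list(g), smi)
  cache_pm <- stats::setNames(list(gp), smi)
  a <- gtnn_forward(model, recs[1], graphs = cache_id)
  b <- gtnn_forward(model, recs[1], graphs = cache_pm)
  expect_equal(a, b, tolerance = 1e-10)

  # swapping the two reactant roles changes the prediction (towers differ)
  swapped <- recs[[1]]
  s <- swapped$substrate_smiles
  swapped$substrate_smiles <- swapped$acid_smiles
  swapped$acid_smiles <- s
  expect_false(isTRUE(all.equal(gtnn_forward(model, recs[1]),
                                gtnn_forward(model, list(swapped)))))
})

test_that("pooling is invariant and single-atom molecules pool to their own feature", {
  # single-atom graph: attention weights collapse to 1
  recs <- synth_80()[1:2]
  model <- train_gtnn(recs, task = "yield", config = tiny_config(),
                      seed = 2, epochs = 1, batch_size = 2)
  g1 <- build_graph("[H][H]", mode = "2d")
  # two different molecules map to different pooled predictions
  r1 <- recs[[1]]; r2 <- recs[[1]]
  r2$substrate_smiles <- "Cc1ccncc1"
  expect_false(isTRUE(all.equal(gtnn_forward(model, list(r1)),
                                gtnn_forward(model, list(r2)))))
})

test_that("parameter counts scale and decompose as expected", {
  n_default <- count_parameters(gtnn_config())
  expect_gt(n_default, 5e5)   # order 10^6
  expect_lt(n_default, 1e7)

  n_double <- count_parameters(gtnn_config(hidden_dim = 256L))
  expect_gt(n_double, n_default)

  by <- attr(n_default, "by_component")
  expect_equal(sum(by), as.numeric(n_default))
  # dropping the condition encoder removes exactly its share
  expect_equal(as.numeric(n_default) - by[["condition_encoder"]],
               sum(by[setdiff(names(by), "condition_encoder")]))
})

test_that("condition encoding is injective on scalars and robust to unknown entities", {
  recs <- synth_80()
  vocab <- build_condition_vocab(recs)
  r <- recs[[1]]
  v1 <- encode_conditions(r, vocab)
  r2 <- r
  r2$temperature_C <- r$temperature_C + 25
  v2 <- encode_conditions(r2, vocab)
  expect_false(isTRUE(all.equal(v1, v2)))

  # unknown solvent: zero one-hot block, no error
  r3 <- r
  r3$solvents <- data.frame(name = "acetonitrile", fraction = 1)
  v3 <- encode_conditions(r3, vocab)
  expect_length(v3, condition_dim(vocab))

  # vocabulary of size v gives an indicator block of length v
  expect_length(vocab$reagents, 1)
  expect_equal(condition_dim(vocab),
               2 * (1 + 1 + 0 + 0) + 1 + 5)

  # missing scalar refuses to impute silently
  r4 <- r
  r4$temperature_C <- NA_real_
  expect_error(encode_conditions(r4, vocab), "scalar")
})
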