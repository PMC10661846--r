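test_that("Jaccard similarity matches the set-arithmetic oracle", {
  # direct formula on tiny bit sets: {1,2} vs {2,3} -> 1/3
  fp <- rbind(c(1, 1, 0), c(0, 1, 1))
  J <- jaccard_matrix(fp)
  expect_equal(J[1, 2], 1 / 3)
  expect_equal(diag(J), c(1, 1))

  # identical molecules -> 1
  fps <- ecfp4_fingerprints(c("c1ccncc1", "c1ccncc1", "CC(O)=O"))
  J2 <- jaccard_matrix(fps)
  expect_equal(J2[1, 2], 1)
  expect_lt(J2[1, 3], 1)

  # random 10-molecule set against per-pair set operations
  smi <- c(SUBSTRATE_TEMPLATES$meta_unsub_pyridine[1:5],
           make_acid_panel()$smiles[c(1, 7, 15, 19, 23)])
  fpm <- ecfp4_fingerprints(smi)
  got <- jaccard_matrix(fpm)
  for (i in 1:10) for (j in 1:10) {
    A <- which(fpm[i, ] > 0); B <- which(fpm[j, ] > 0)
    expect_equal(got[i, j], length(intersect(A, B)) / length(union(A, B)),
                 tolerance = 1e-12)
  }
  expect_equal(got, t(got))

  # empty fingerprints give similarity 0 with a warning
  expect_warning(J3 <- jaccard_matrix(rbind(c(0, 0), c(1, 0))), "empty")
  expect_equal(J3[1, 2], 0)
})

test_that("agglomerative clustering recovers separable blocks deterministically", {
  fpA <- ecfp4_fingerprints("c1ccncc1")
  fpB <- ecfp4_fingerprints("CC(C)(C)OC(=O)N1CCCCC1")
  fp <- rbind(fpA, fpA, fpA, fpB, fpB, fpB)
  J <- jaccard_matrix(fp)
  lab <- agglomerative_clusters(J, 2)
  expect_length(unique(lab[1:3]), 1)
  expect_length(unique(lab[4:6]), 1)
  expect_false(lab[1] == lab[4])

  # eight distinct molecules, eight clusters: all singletons
  smi8 <- SUBSTRATE_TEMPLATES$meta_unsub_pyridine[1:8]
  J8 <- jaccard_matrix(ecfp4_fingerprints(smi8))
  lab8 <- agglomerative_clusters(J8, 8)
  expect_equal(sort(unique(lab8)), 1:8)

  expect_identical(agglomerative_clusters(J8, 3),
                   agglomerative_clusters(J8, 3))
  expect_error(agglomerative_clusters(J8[1:4, 1:4], 8), "cannot form")
})

test_that("sphere exclusion honors the Tanimoto cutoff invariant", {
  fpA <- ecfp4_fingerprints("c1ccncc1")
  same <- rbind(fpA, fpA, fpA)
  expect_equal(max(sphere_exclusion(same, 0.6)), 1)

  two <- ecfp4_fingerprints(c("c1ccncc1", "CC(C)(C)OC(=O)N1CCCCC1"))
  expect_equal(max(sphere_exclusion(two, 0.6)), 2)

  # every member is within the cutoff of its own centroid
  smi <- c(SUBSTRATE_TEMPLATES$meta_sub_pyridine,
           SUBSTRATE_TEMPLATES$five_membered)
  fp <- ecfp4_fingerprints(smi)
  cutoff <- 0.4
  lab <- sphere_exclusion(fp, cutoff)
  cents <- attr(lab, "centroids")
  J <- jaccard_matrix(fp)
  for (i in seq_along(smi)) {
    expect_gte(J[i, cents[lab[i]]], ifelse(i %in% cents, 1, cutoff))
  }
})

test_that("ensemble scores aggregate the six models exactly", {
  recs <- synth_80()
  cfg <- tiny_config()
  one_y <- train_gtnn(recs[1:30], task = "yield", config = cfg, seed = 1,
                      epochs = 2, batch_size = 30)
  one_b <- train_gtnn(recs[1:30], task = "binary", config = cfg, seed = 1,
                      epochs = 2, batch_size = 30)
  models <- list(yield = list(one_y, one_y, one_y),
                 binary = list(one_b, one_b, one_b))
  subs <- c("c1ccncc1", "Cc1cccnc1")
  acids <- make_acid_panel()$smiles[c(1, 7, 19)]
  sc <- ensemble_score(subs, acids, standard_conditions(), models)
  expect_equal(nrow(sc), 6)  # 2 x 3 grid
  expect_equal(sc$yield_sd, rep(0, 6))   # identical members
  expect_equal(sc$outcome_sd, rep(0, 6))
  expect_equal(sc$combined, (sc$yield_mean + sc$outcome_mean) / 2)
  expect_true(all(sc$yield_mean >= 0 & sc$yield_mean <= 1))

  # brute-force recomputation from the individual members
  r <- standard_conditions()
  r$substrate_smiles <- subs[1]
  r$acid_smiles <- acids[1]
  direct <- gtnn_forward(one_y, list(r))
  expect_equal(sc$yield_mean[sc$substrate_smiles == subs[1] &
                               sc$acid_smiles == acids[1]],
               direct, tolerance = 1e-10)
})

test_that("substrate selection takes top scorers per kept cluster", {
  set.seed(8)
  ranking <- data.frame(
    substrate_smiles = sprintf("C%dCC", 1:40),
    score = stats::runif(40),
    cluster_id = rep(1:8, each = 5))
  sel <- select_substrates(ranking, k_per_cluster = 3,
                           excluded_clusters = c(2, 7))
  expect_equal(nrow(sel), 18)  # 6 clusters x 3
  expect_false(any(sel$cluster_id %in% c(2, 7)))
  for (cl in unique(sel$cluster_id)) {
    top <- sort(ranking$score[ranking$cluster_id == cl], decreasing = TRUE)[1:3]
    expect_equal(sort(sel$score[sel$cluster_id == cl], decreasing = TRUE), top)
  }

  expect_equal(nrow(select_substrates(ranking, 0)), 0)

  # raising a score pulls the substrate into the selection
  ranking2 <- ranking
  out_row <- which(!(ranking$substrate_smiles %in% sel$substrate_smiles) &
                     ranking$cluster_id == 1)[1]
  ranking2$score[out_row] <- 2
  sel2 <- select_substrates(ranking2, 3)
  expect_true(ranking2$substrate_smiles[out_row] %in% sel2$substrate_smiles)

  # short cluster: take all members, warn
  short <- ranking[c(1:2, 6:10), ]
  expect_warning(sel3 <- select_substrates(short, 3), "only")
  expect_equal(sum(sel3$cluster_id == 1), 2)
})

test_that("decoy generation spans the grid and rejects aromatic substrates", {
  panel <- make_acid_panel()
  decoys <- generate_decoys(SUBSTRATE_TEMPLATES$decoy, panel$smiles)
  expect_length(decoys, 16 * 23)
  expect_true(all(vapply(decoys, `[[`, integer(1), "outcome") == 0L))
  expect_true(all(vapply(decoys, `[[`, numeric(1), "combined_yield_pct") == 0))
  expect_true(all(vapply(decoys, `[[`, character(1), "provenance") == "decoy"))

  expect_error(generate_decoys(c("C1CCCCC1", "c1ccccc1"), panel$smiles[1]),
               "c1ccccc1")
})
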