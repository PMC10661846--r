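test_that("combined yield is the capped sum of product yields", {
  expect_equal(combined_yield(numeric(0)), 0)
  expect_equal(combined_yield(c(10, 5, 2)), 17)
  expect_equal(combined_yield(c(60, 55)), 100)
  expect_error(combined_yield(c(10, -1)), "negative")
  expect_error(combined_yield(c(10, 101)), "above 100")
})

test_that("records derive the binary outcome from the 5% threshold and enforce invariants", {
  r <- rich_record(yields = c(3, 1.5))
  expect_equal(r$combined_yield_pct, 4.5)
  expect_equal(r$outcome, 0L)
  r2 <- rich_record(yields = c(3, 2))
  expect_equal(r2$outcome, 1L)

  # stored outcome contradicting the yield is reported, not fixed
  bad <- r
  bad$outcome <- 1L
  probs <- validate_record(bad)
  expect_match(probs, "contradicts", all = FALSE)

  # solvent fractions must sum to one
  expect_error(
    reaction_record("x", "experimental", "c1ccncc1", "CC(O)=O",
                    solvents = data.frame(name = c("DMSO", "water"),
                                          fraction = c(0.6, 0.6))),
    "sum to 1")

  # decoys must carry zero yield and outcome
  expect_error(
    reaction_record("d", "decoy", "C1CCCCC1", "CC(O)=O",
                    products = data.frame(product_smiles = "CC",
                                          yield_pct = 12)),
    "decoy")
})

test_that("write_surf / read_surf round-trips records losslessly", {
  recs <- list(rich_record("rx-1"), rich_record("rx-2", yields = c(50, 60)),
               rich_record("rx-3", yields = numeric(0)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_surf(recs, path)
  back <- read_surf(path, check_smiles = FALSE)
  expect_length(back, 3)
  for (i in 1:3) {
    for (nm in setdiff(names(recs[[i]]), "smiles_ok")) {
      expect_identical(back[[i]][[nm]], recs[[i]][[nm]],
                       label = paste("field", nm, "record", i))
    }
  }
  # two solvents with 0.5/0.5 fractions survive
  expect_equal(back[[1]]$solvents$fraction, c(0.5, 0.5))
  # unknown extra columns survive as opaque payload
  expect_equal(unname(back[[2]]$extra["plate"]), "P1")

  # empty table: header only in, empty list out
  write_surf(list(), path)
  expect_length(read_surf(path), 0)
})

test_that("read_surf reports schema and row-level errors precisely", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("reaction_id\tstartingmat_1_smiles", path)
  expect_error(read_surf(path), "startingmat_2_smiles")

  writeLines(c(
    "reaction_id\tstartingmat_1_smiles\tstartingmat_2_smiles\tcombined_yield_pct",
    "r1\tc1ccncc1\tCC(O)=O\tnot_a_number"), path)
  expect_error(read_surf(path), "row.*1")

  # malformed SMILES are flagged, never dropped
  writeLines(c(
    "reaction_id\tstartingmat_1_smiles\tstartingmat_2_smiles\tcombined_yield_pct",
    "r1\tc1ccncc1\tCC(O)=O\t50",
    "r2\tnot_a_smiles(((\tCC(O)=O\t10"), path)
  recs <- read_surf(path)
  expect_length(recs, 2)
  expect_false(recs[[2]]$smiles_ok)
  expect_match(attr(recs, "problems"), "malformed SMILES", all = FALSE)
})

test_that("dataset_summary counts are additive and permutation-invariant", {
  recs <- synth_80()
  s <- dataset_summary(recs)
  expect_equal(s$n_total, 80)
  expect_equal(s$n_successful + s$n_unsuccessful, s$n_total)

  perm <- dataset_summary(recs[sample.int(80)])
  expect_equal(perm$n_successful, s$n_successful)

  a <- dataset_summary(recs[1:30])
  b <- dataset_summary(recs[31:80])
  expect_equal(a$n_total + b$n_total, s$n_total)
  expect_equal(a$n_successful + b$n_successful, s$n_successful)
  expect_equal(as.vector(a$by_provenance + b$by_provenance),
               as.vector(s$by_provenance))

  decoys <- generate_decoys(c("C1CCCCC1", "CCCCC"), c("CC(O)=O"))
  expect_equal(dataset_summary(decoys)$n_successful, 0)
})
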