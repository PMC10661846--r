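test_that("random splits are disjoint, exhaustive and seed-reproducible", {
  recs <- synth_80()[1:10]
  sp <- random_split(recs, 0.2, seed = 4)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  ids <- function(x) sort(vapply(x, `[[`, character(1), "reaction_id"))
  expect_identical(ids(c(sp$train, sp$test)), ids(recs))

  sp2 <- random_split(recs, 0.2, seed = 4)
  expect_identical(ids(sp2$test), ids(sp$test))

  big <- synth_300()
  a <- random_split(big, 0.2, seed = 1)
  b <- random_split(big, 0.2, seed = 2)
  expect_false(identical(ids(a$test), ids(b$test)))

  expect_error(random_split(list(), 0.2), "empty")
})

test_that("yield bins follow the printed edges with boundaries in the lower bin", {
  expect_equal(as.character(yield_bin(c(0, 0.5, 1))),
               rep("no_reaction", 3))
  expect_equal(as.character(yield_bin(c(1.01, 11))), c("poor", "poor"))
  expect_equal(as.character(yield_bin(c(11.01, 26, 35))),
               c("medium", "medium", "medium"))
  expect_equal(as.character(yield_bin(c(35.01, 99, 100))),
               c("high", "high", "high"))
  expect_error(yield_bin(-0.1), "0, 100")
  expect_error(yield_bin(101), "0, 100")
})

test_that("evaluation metrics match brute-force oracles", {
  # perfect predictions
  y <- c(0, 3, 20, 50, 80, 12)
  ev <- evaluate_predictions(y, y, task = "yield")
  expect_equal(ev$mae_pct, 0)
  expect_equal(ev$bin_accuracy_pct, 100)
  evb <- evaluate_predictions(c(0, 0, 1, 1), c(0, 0, 1, 1), task = "binary")
  expect_equal(evb$binary_accuracy_pct, 100)
  expect_equal(evb$f_score_pct, 100)

  # direct F1 identity: tp=1, fp=1, fn=1 -> 50%
  ev1 <- evaluate_predictions(c(0.9, 0.9, 0.1, 0.1),
                              c(1, 0, 1, 0), task = "binary")
  expect_equal(ev1$tp, 1); expect_equal(ev1$fp, 1); expect_equal(ev1$fn, 1)
  expect_equal(ev1$f_score_pct, 50)
  expect_equal(f_score(1, 1, 1), 0.5)

  # random vectors against exhaustive pair counting
  set.seed(21)
  for (rep in 1:5) {
    n <- 40
    truths <- stats::runif(n, 0, 100)
    preds <- pmin(pmax(truths + stats::rnorm(n, 0, 25), 0), 100)
    ev <- evaluate_predictions(preds, truths, task = "yield")
    lv <- c("no_reaction", "poor", "medium", "high")
    conf <- matrix(0L, 4, 4, dimnames = list(truth = lv, prediction = lv))
    for (i in seq_len(n)) {
      conf[as.character(yield_bin(truths[i])),
           as.character(yield_bin(preds[i]))] <-
        conf[as.character(yield_bin(truths[i])),
             as.character(yield_bin(preds[i]))] + 1L
    }
    expect_equal(unclass(ev$bin_confusion), unclass(as.table(conf)),
                 ignore_attr = TRUE)
    expect_equal(ev$mae_pct, mean(abs(preds - truths)))
    expect_equal(ev$pearson_r, stats::cor(preds, truths))

    labs <- stats::rbinom(n, 1, 0.5)
    props <- stats::runif(n)
    evb <- evaluate_predictions(props, labs, task = "binary")
    hard <- as.integer(props >= 0.5)
    tp <- sum(hard & labs); fp <- sum(hard & !labs); fn <- sum(!hard & labs)
    expect_equal(evb$f_score_pct, 100 * 2 * tp / (2 * tp + fp + fn))
    expect_equal(evb$binary_accuracy_pct, 100 * mean(hard == labs))
  }

  # degenerate variance: Pearson r is NA, not 0
  expect_warning(
    ev0 <- evaluate_predictions(rep(10, 5), c(1, 2, 3, 4, 5), task = "yield"),
    "variance")
  expect_true(is.na(ev0$pearson_r))
})

test_that("adding a constant offset inflates the MAE towards the offset", {
  set.seed(3)
  truths <- stats::runif(30, 20, 60)
  preds <- truths + stats::rnorm(30, 0, 2)
  base <- evaluate_predictions(preds, truths, task = "yield")$mae_pct
  shifted <- evaluate_predictions(pmin(preds + 20, 100), truths,
                                  task = "yield")$mae_pct
  expect_gt(shifted, base)
  expect_gt(shifted, 15)
})

test_that("training reduces the loss and fits a constant-target set", {
  recs <- synth_80()[1:50]
  m <- train_gtnn(recs, task = "yield", config = tiny_config(), seed = 1,
                  epochs = 5, batch_size = 25)
  expect_lt(m$log$final_loss, m$log$initial_loss)
  expect_equal(m$log$seed, 1)
  expect_equal(m$log$epochs, 5)

  # decoys only: binary predictions must sit near zero on the training data
  decoys <- generate_decoys(SUBSTRATE_TEMPLATES$decoy[1:4],
                            make_acid_panel()$smiles[1:5])
  mb <- train_gtnn(decoys, task = "binary", config = tiny_config(), seed = 1,
                   epochs = 6, batch_size = 20)
  preds <- gtnn_forward(mb, decoys)
  expect_lt(max(preds), 0.2)
})
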