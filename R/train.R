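# Featurize every molecule referenced by `records`, isolating failures
# per-molecule when the batch call fails.
.featurize_robust <- function(records, config, graphs = NULL) {
  smi <- unique(unlist(lapply(records, function(r)
    c(r$substrate_smiles, r$acid_smiles))))
  missing <- setdiff(smi, names(graphs))
  failed <- character(0)
  if (length(missing)) {
    got <- tryCatch(
      featurize_smiles(missing, mode = config$mode, cutoff_A = config$cutoff_A,
                       K = config$K, r_max = config$r_max),
      error = function(e) NULL)
    if (is.null(got)) {
      got <- list()
      for (s in missing) {
        g <- tryCatch(featurize_smiles(s, mode = config$mode,
                                       cutoff_A = config$cutoff_A,
                                       K = config$K, r_max = config$r_max),
                      error = function(e) NULL)
        if (is.null(g)) failed <- c(failed, s) else got <- c(got, g)
      }
    }
    graphs <- c(graphs, got)
  }
  list(graphs = graphs, failed = failed)
}

#' Random train/test split
#'
#' Disjoint, exhaustive and reproducible given the seed.
#'
#' @param records list of reaction records.
#' @param test_fraction fraction held out, in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
random_split <- function(records, test_fraction = 0.2, seed = 1L) {
  if (length(records) == 0) stop("empty input", call. = FALSE)
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- length(records)
  n_test <- max(1L, round(n * test_fraction))
  if (n_test >= n) stop("split leaves no training data", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n, n_test)
  list(train = records[-idx], test = records[idx])
}

#' Train a dual-graph network on reaction records
#'
#' Both tasks are fit as regression problems on the sigmoid output: mean
#' absolute error (L1) on the yield fraction for `task = "yield"`, binary
#' cross-entropy on the success label for `task = "binary"`. Optimization is
#' Adam on minibatches; molecules failing graph construction are listed,
#' excluded with a warning and counted in the run log, never silently
#' dropped.
#'
#' @param records training records.
#' @param task `"yield"` or `"binary"` (overrides `config$task`).
#' @param config a [gtnn_config()].
#' @param seed seed for init and batching.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param graphs optional featurization cache (shared across ensemble
#'   members to avoid recomputing conformers).
#' @param vocab optional prebuilt condition vocabulary.
#' @param verbose print per-epoch losses.
#' @return object of class `gtnn_model`: config, vocabulary, parameters and
#'   a run log (seed, epochs, initial/final loss, excluded molecules).
#' @export
train_gtnn <- function(records, task = config$task, config = gtnn_config(),
                       seed = 1L, epochs = 30L, batch_size = 32L,
                       lr = 1e-3, graphs = NULL, vocab = NULL,
                       verbose = FALSE) {
  stopifnot(length(records) >= 2)
  config$task <- match.arg(task, c("yield", "binary"))
  fz <- .featurize_robust(records, config, graphs)
  graphs <- fz$graphs
  failed <- fz$failed
  usable <- vapply(records, function(r) {
    r$substrate_smiles %in% names(graphs) && r$acid_smiles %in% names(graphs)
  }, logical(1))
  if (any(!usable)) {
    warning(sum(!usable), " record(s) excluded: graph construction failed ",
            "for ", paste(unique(failed), collapse = ", "), call. = FALSE)
    records <- records[usable]
  }
  if (is.null(vocab)) vocab <- build_condition_vocab(records)
  batch_all <- assemble_batch(records, vocab, graphs, config)
  graphs <- batch_all$graphs
  target <- if (config$task == "yield") batch_all$y_yield else batch_all$y_bin

  base_rate <- min(max(mean(target), 0.02), 0.98)
  params <- gtnn_init_params(config, condition_dim(vocab), seed = seed,
                             out_bias = stats::qlogis(base_rate))
  opt <- adam_init(params)
  n <- length(records)
  set.seed(seed + 1L)
  loss_of_epoch <- numeric(epochs)
  initial_loss <- NA_real_
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      take <- ord[s:min(s + batch_size - 1L, n)]
      recs <- records[take]
      batch <- assemble_batch(recs, vocab, graphs, config)
      ag_tape_start()
      pn <- lapply(params, ag_param)
      out <- .gtnn_forward_nodes(pn, batch, config)
      y <- matrix(target[take], ncol = 1)
      loss <- if (config$task == "yield") {
        ag_l1_loss(out$pred, y)
      } else {
        ag_bce_logits(out$logit, y)
      }
      ag_backward(loss)
      grads <- lapply(pn, function(p) p$grad)
      ag_tape_stop()
      step <- adam_step(params, grads, opt, lr = lr)
      params <- step$params
      opt <- step$state
      ep_loss <- ep_loss + loss$val[1] * length(take)
      if (is.na(initial_loss)) initial_loss <- loss$val[1]
    }
    loss_of_epoch[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, loss_of_epoch[ep]))
  }
  structure(list(
    config = config, vocab = vocab, params = params,
    log = list(seed = seed, epochs = epochs, lr = lr,
               batch_size = batch_size, n_records = n,
               n_excluded = sum(!usable), failed_smiles = failed,
               initial_loss = initial_loss,
               final_loss = loss_of_epoch[epochs],
               loss_by_epoch = loss_of_epoch)
  ), class = "gtnn_model")
}

#' Train the 3 + 3 screening ensemble
#'
#' Three independently seeded yield models and three binary-outcome models,
#' the ensemble used for in silico screening.
#'
#' @inheritParams train_gtnn
#' @param seeds integer vector of length 3 (one per ensemble member).
#' @return list with elements `yield` and `binary`, each a list of 3
#'   `gtnn_model`s, plus the shared featurization cache as attribute
#'   `graphs`.
#' @export
train_ensemble <- function(records, config = gtnn_config(), seeds = 1:3,
                           epochs = 30L, batch_size = 32L, lr = 1e-3,
                           graphs = NULL, verbose = FALSE) {
  stopifnot(length(seeds) == 3)
  vocab <- build_condition_vocab(records)
  graphs <- .featurize_robust(records, config, graphs)$graphs
  models <- list(yield = list(), binary = list())
  for (task in c("yield", "binary")) {
    cfg <- config
    cfg$task <- task
    for (k in 1:3) {
      models[[task]][[k]] <- train_gtnn(
        records, task = task, config = cfg, seed = seeds[k],
        epochs = epochs, batch_size = batch_size, lr = lr,
        graphs = graphs, vocab = vocab, verbose = verbose)
    }
  }
  attr(models, "graphs") <- graphs
  models
}
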