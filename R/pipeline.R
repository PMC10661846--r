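.pipeline_defaults <- function() {
  list(
    seed = 1L,
    data = list(source = "synthetic", n_reactions = 300L, surf_path = NULL),
    split = list(test_fraction = 0.2),
    model = list(hidden_dim = 32L, embed_dim = 16L, post_pool_dim = 64L,
                 pool_attention_heads = 4L, mode = "3d", epochs = 15L,
                 batch_size = 48L, lr = 1e-3),
    screen = list(library = NULL, n_clusters = 8L, k_per_cluster = 3L,
                  excluded_clusters = integer(0))
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      .merge_config(base[[nm]], override[[nm]])
    } else override[[nm]]
  }
  base
}

#' Run the full screening pipeline
#'
#' validate -> train the 3 + 3 ensemble -> evaluate on a held-out split ->
#' score the screening library against the 23-acid panel -> cluster ->
#' select substrates. Every artifact-producing run writes exactly one
#' manifest (command, config and input hashes, seeds, package version,
#' timestamps). On a stage failure, partial artifacts are preserved
#' together with a `FAILED_<stage>` marker file.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Unset keys fall back to documented defaults.
#' @param out_dir output directory (defaults to `config$out_dir`).
#' @return invisibly, a list with the artifacts (models, reports, tables)
#'   and their paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(.pipeline_defaults(), config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("out_dir required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  stage <- "setup"
  marker <- function() file.path(out_dir, paste0("FAILED_", stage))
  result <- tryCatch({
    t_start <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

    stage <- "data"
    input_hash <- NULL
    if (identical(cfg$data$source, "surf")) {
      if (is.null(cfg$data$surf_path) || !file.exists(cfg$data$surf_path)) {
        stop("SURF input not found: ", cfg$data$surf_path)
      }
      records <- read_surf(cfg$data$surf_path)
      input_hash <- unname(tools::md5sum(cfg$data$surf_path))
    } else {
      records <- generate_dataset(synth_spec(
        n_reactions = cfg$data$n_reactions, seed = cfg$seed))
      write_surf(records, file.path(out_dir, "dataset.tsv"))
    }
    probs <- attr(records, "problems")
    if (length(probs)) {
      writeLines(probs, file.path(out_dir, "validation_problems.txt"))
    }

    stage <- "train"
    mcfg <- gtnn_config(hidden_dim = cfg$model$hidden_dim,
                        embed_dim = cfg$model$embed_dim,
                        post_pool_dim = cfg$model$post_pool_dim,
                        pool_attention_heads = cfg$model$pool_attention_heads,
                        mode = cfg$model$mode)
    sp <- random_split(records, cfg$split$test_fraction, seed = cfg$seed)
    ens <- train_ensemble(sp$train, config = mcfg,
                          seeds = cfg$seed + 0:2,
                          epochs = cfg$model$epochs,
                          batch_size = cfg$model$batch_size,
                          lr = cfg$model$lr)
    graphs <- attr(ens, "graphs")
    for (task in c("yield", "binary")) {
      for (k in 1:3) {
        save_gtnn(ens[[task]][[k]],
                  file.path(out_dir, "models",
                            sprintf("%s_%d.rds", task, k)))
      }
    }

    stage <- "evaluate"
    reports <- list(
      yield = lapply(ens$yield, evaluate_model, records = sp$test),
      binary = lapply(ens$binary, evaluate_model, records = sp$test))
    summarize <- function(task, field) {
      v <- vapply(reports[[task]], `[[`, numeric(1), field)
      list(mean = mean(v), sd = stats::sd(v))
    }
    eval_json <- list(
      n_test = length(sp$test),
      yield = list(mae_pct = summarize("yield", "mae_pct"),
                   pearson_r = summarize("yield", "pearson_r"),
                   bin_accuracy_pct = summarize("yield", "bin_accuracy_pct")),
      binary = list(accuracy_pct = summarize("binary", "binary_accuracy_pct"),
                    f_score_pct = summarize("binary", "f_score_pct")))
    jsonlite::write_json(eval_json, file.path(out_dir, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(as.data.frame.matrix(reports$yield[[1]]$bin_confusion),
                       file.path(out_dir, "bin_confusion.tsv"),
                       sep = "\t", quote = FALSE)

    stage <- "screen"
    library_smiles <- if (!is.null(cfg$screen$library)) {
      if (!file.exists(cfg$screen$library)) {
        stop("library file not found: ", cfg$screen$library)
      }
      readLines(cfg$screen$library)
    } else {
      screening_library()
    }
    panel <- make_acid_panel()
    scores <- ensemble_score(library_smiles, panel$smiles,
                             standard_conditions(), ens, graphs)
    utils::write.table(scores, file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "select"
    ranking <- rank_substrates(scores, n_clusters = cfg$screen$n_clusters)
    selection <- select_substrates(ranking, cfg$screen$k_per_cluster,
                                   cfg$screen$excluded_clusters)
    utils::write.table(ranking, file.path(out_dir, "ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(selection, file.path(out_dir, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "manifest"
    manifest <- list(
      command = "run_pipeline",
      config = cfg,
      config_hash = if (!is.null(config_path)) {
        unname(tools::md5sum(config_path))
      } else NA,
      input_hash = input_hash,
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("miniscreen")),
      started = t_start,
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    list(records = records, models = ens, reports = reports,
         scores = scores, ranking = ranking, selection = selection,
         out_dir = out_dir)
  }, error = function(e) {
    file.create(marker())
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
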