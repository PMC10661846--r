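#' Pairwise Jaccard (Tanimoto) similarity matrix
#'
#' `J(A, B) = |A intersect B| / |A union B|` over fingerprint bit sets.
#' Symmetric with unit diagonal; a pair in which either fingerprint is
#' empty gets similarity 0 (with a warning).
#'
#' @param fp numeric 0/1 matrix, one fingerprint per row (e.g. from
#'   [ecfp4_fingerprints()]).
#' @return `N x N` numeric similarity matrix.
#' @export
jaccard_matrix <- function(fp) {
  fp <- as.matrix(fp)
  if (nrow(fp) < 2) stop("need at least two fingerprints", call. = FALSE)
  inter <- tcrossprod(fp)
  sizes <- rowSums(fp)
  un <- outer(sizes, sizes, "+") - inter
  if (any(sizes == 0)) {
    warning("empty fingerprint(s): similarities involving them set to 0",
            call. = FALSE)
  }
  J <- ifelse(un > 0, inter / un, 0)
  diag(J) <- ifelse(sizes > 0, 1, 0)
  dimnames(J) <- list(rownames(fp), rownames(fp))
  J
}

#' Agglomerative clustering of a similarity matrix
#'
#' Average-linkage hierarchical clustering on distance `1 - similarity`,
#' cut into `n_clusters` groups. Deterministic given the input.
#'
#' @param sim square symmetric similarity matrix.
#' @param n_clusters number of clusters (default 8).
#' @return integer vector of cluster labels in `1..n_clusters`.
#' @export
agglomerative_clusters <- function(sim, n_clusters = 8L) {
  sim <- as.matrix(sim)
  stopifnot(nrow(sim) == ncol(sim))
  if (max(abs(sim - t(sim))) > 1e-8) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  if (nrow(sim) < n_clusters) {
    stop("cannot form ", n_clusters, " clusters from ", nrow(sim),
         " molecules", call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  unname(stats::cutree(hc, k = n_clusters))
}

#' Sphere-exclusion clustering of fingerprints
#'
#' Greedy centroid selection in input order: each molecule joins the most
#' similar existing centroid if that similarity reaches the Tanimoto
#' cutoff, otherwise it founds a new cluster. By construction every member
#' has similarity >= cutoff to its own centroid. Deterministic given input
#' order.
#'
#' @param fp fingerprint matrix, one row per molecule.
#' @param tanimoto_cutoff similarity cutoff (default 0.6).
#' @return integer labels; attribute `centroids` gives the row index of
#'   each cluster's centroid.
#' @export
sphere_exclusion <- function(fp, tanimoto_cutoff = 0.6) {
  fp <- as.matrix(fp)
  n <- nrow(fp)
  stopifnot(n >= 1)
  tan1 <- function(a, b) {
    un <- sum(a | b)
    if (un == 0) 0 else sum(a & b) / un
  }
  centroids <- 1L
  labels <- integer(n)
  labels[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      sims <- vapply(centroids, function(c) tan1(fp[i, ] > 0, fp[c, ] > 0),
                     numeric(1))
      best <- which.max(sims)
      if (sims[best] >= tanimoto_cutoff) {
        labels[i] <- best
      } else {
        centroids <- c(centroids, i)
        labels[i] <- length(centroids)
      }
    }
  }
  structure(labels, centroids = centroids)
}

#' Ensemble screening scores for substrate x acid combinations
#'
#' Scores every (substrate, acid) pair with the 3 + 3 model ensemble: the
#' mean and standard deviation over the three yield models and over the
#' three binary models, and the combined score `(yield_mean +
#' outcome_mean) / 2`. Pairs whose featurization fails are kept as rows
#' flagged `failed` with NA scores, never dropped silently.
#'
#' @param substrates character vector of substrate SMILES.
#' @param acids character vector of acid SMILES.
#' @param conditions a template `reaction_record` carrying the reaction
#'   conditions applied to every pair (its reactants are ignored), e.g.
#'   [standard_conditions()].
#' @param models result of [train_ensemble()], or a list with elements
#'   `yield` and `binary` of three `gtnn_model`s each.
#' @param graphs optional featurization cache.
#' @return data.frame with one row per pair: `substrate_smiles`,
#'   `acid_smiles`, `yield_mean`, `yield_sd`, `outcome_mean`, `outcome_sd`,
#'   `combined`, `failed`.
#' @export
ensemble_score <- function(substrates, acids, conditions, models,
                           graphs = NULL) {
  stopifnot(length(models$yield) == 3, length(models$binary) == 3)
  modes <- unique(c(vapply(models$yield, function(m) m$config$mode, ""),
                    vapply(models$binary, function(m) m$config$mode, "")))
  if (length(modes) != 1) {
    stop("ensemble members disagree on featurization mode", call. = FALSE)
  }
  grid <- expand.grid(substrate_smiles = substrates, acid_smiles = acids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    r <- conditions
    r$reaction_id <- sprintf("screen-%05d", i)
    r$substrate_smiles <- grid$substrate_smiles[i]
    r$acid_smiles <- grid$acid_smiles[i]
    r
  })
  cfg <- models$yield[[1]]$config
  fz <- .featurize_robust(recs, cfg, graphs)
  graphs <- fz$graphs
  ok <- vapply(recs, function(r) {
    r$substrate_smiles %in% names(graphs) && r$acid_smiles %in% names(graphs)
  }, logical(1))
  preds <- matrix(NA_real_, nrow(grid), 6)
  if (any(ok)) {
    for (k in 1:3) {
      preds[ok, k] <- gtnn_forward(models$yield[[k]], recs[ok], graphs)
      preds[ok, 3 + k] <- gtnn_forward(models$binary[[k]], recs[ok], graphs)
    }
  }
  ym <- rowMeans(preds[, 1:3, drop = FALSE])
  om <- rowMeans(preds[, 4:6, drop = FALSE])
  data.frame(
    grid,
    yield_mean = ym,
    yield_sd = apply(preds[, 1:3, drop = FALSE], 1, stats::sd),
    outcome_mean = om,
    outcome_sd = apply(preds[, 4:6, drop = FALSE], 1, stats::sd),
    combined = (ym + om) / 2,
    failed = !ok,
    stringsAsFactors = FALSE
  )
}

#' Rank substrates by mean screening score and cluster them
#'
#' Aggregates an [ensemble_score()] table to one score per substrate (the
#' mean of the combined score over the acid panel) and attaches
#' agglomerative ECFP4/Jaccard cluster labels.
#'
#' @param score_table result of [ensemble_score()].
#' @param n_clusters number of structural clusters (default 8).
#' @return data.frame `substrate_smiles`, `score`, `cluster_id`, sorted by
#'   decreasing score.
#' @export
rank_substrates <- function(score_table, n_clusters = 8L) {
  ok <- !score_table$failed
  sc <- stats::aggregate(combined ~ substrate_smiles,
                         data = score_table[ok, ], FUN = mean)
  names(sc)[2] <- "score"
  fp <- ecfp4_fingerprints(sc$substrate_smiles)
  sc$cluster_id <- agglomerative_clusters(jaccard_matrix(fp), n_clusters)
  sc[order(-sc$score), ]
}

#' Diversity-aware substrate selection
#'
#' Picks the `k_per_cluster` top-scoring substrates from every non-excluded
#' cluster. Ties break lexicographically on canonical SMILES (logged via
#' message); clusters with fewer members than `k_per_cluster` contribute
#' all members with a warning.
#'
#' @param ranking data.frame from [rank_substrates()] (columns
#'   `substrate_smiles`, `score`, `cluster_id`).
#' @param k_per_cluster selections per cluster (default 3).
#' @param excluded_clusters integer cluster ids to skip (e.g. clusters
#'   dominated by heterocycles lacking free C-H bonds; exclusion is a
#'   manual/config decision, not an automated structural filter).
#' @return data.frame of selected rows, ordered by cluster then score.
#' @export
select_substrates <- function(ranking, k_per_cluster = 3L,
                              excluded_clusters = integer(0)) {
  stopifnot(all(c("substrate_smiles", "score", "cluster_id") %in%
                  names(ranking)))
  if (k_per_cluster == 0) return(ranking[0, ])
  kept <- ranking[!(ranking$cluster_id %in% excluded_clusters), ]
  out <- list()
  for (cl in sort(unique(kept$cluster_id))) {
    part <- kept[kept$cluster_id == cl, ]
    if (anyDuplicated(part$score)) {
      canon <- canonical_smiles(part$substrate_smiles)
      part <- part[order(-part$score, canon), ]
      message("cluster ", cl, ": score ties broken by canonical SMILES")
    } else {
      part <- part[order(-part$score), ]
    }
    if (nrow(part) < k_per_cluster) {
      warning("cluster ", cl, " has only ", nrow(part), " member(s); taking all",
              call. = FALSE)
    }
    out[[as.character(cl)]] <- utils::head(part, k_per_cluster)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate decoy reactions from non-reactive substrates
#'
#' Builds the full substrate x acid grid of guaranteed-unsuccessful
#' records (combined yield 0, outcome 0, provenance `"decoy"`). Every
#' substrate is checked to contain no aromatic or heteroaromatic ring --
#' the structural reason it cannot undergo Minisci alkylation -- and
#' aromatic substrates are rejected by name.
#'
#' @param substrates character vector of decoy substrate SMILES.
#' @param acids character vector of acid SMILES.
#' @param base_conditions template `reaction_record` for the condition
#'   fields (default [standard_conditions()]).
#' @return list of `reaction_record`s of length
#'   `length(substrates) * length(acids)`.
#' @export
generate_decoys <- function(substrates, acids,
                            base_conditions = standard_conditions()) {
  arom <- has_aromatic_ring(substrates)
  if (any(arom)) {
    stop("substrate(s) with (hetero)aromatic rings cannot be decoys: ",
         paste(substrates[arom], collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(substrate = substrates, acid = acids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    r <- base_conditions
    r$reaction_id <- sprintf("decoy-%04d", i)
    r$provenance <- "decoy"
    r$substrate_smiles <- grid$substrate[i]
    r$acid_smiles <- grid$acid[i]
    r$products <- r$products[0, ]
    r$combined_yield_pct <- 0
    r$outcome <- 0L
    r
  })
}

#' Standard Minisci screening-plate conditions
#'
#' The optimized plate condition: ammonium persulfate oxidant (6 eq), acid
#' at 20 eq, DMSO, 40 deg C under nitrogen at 16 mmol/L. Returned as a
#' template record whose reactants are placeholders.
#'
#' @return a `reaction_record` template.
#' @export
standard_conditions <- function() {
  reaction_record(
    reaction_id = "template", provenance = "experimental",
    substrate_smiles = "c1ccncc1", acid_smiles = "OC(=O)C1CCOCC1",
    reagents = data.frame(name = "ammonium persulfate", equivalents = 6),
    solvents = data.frame(name = "DMSO", fraction = 1),
    atmosphere = "nitrogen", temperature_C = 40, time_h = 16,
    scale_mmol_per_L = 16, substrate_equiv = 1, acid_equiv = 20)
}
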