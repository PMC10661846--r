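#' Atom-type and hybridization vocabularies
#'
#' The featurization supports 12 elements (H, C, N, O, F, P, S, Cl, Br, I,
#' Si, Se) and 4 hybridization states (sp3, sp2, sp, s). Molecules containing
#' anything else are rejected at graph construction.
#'
#' @name vocabularies
#' @keywords internal
ATOM_VOCAB <- c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "Si", "Se")
HYBRID_VOCAB <- c("sp3", "sp2", "sp", "s")

#' Generate a 3D conformer for a SMILES string
#'
#' Embeds one conformer by distance geometry and relaxes it with the
#' universal force field (UFF). Deterministic given the seed: the same
#' (SMILES, seed) pair yields identical coordinates on every call.
#'
#' @param smiles single SMILES string.
#' @param seed integer seed for the distance-geometry embedding.
#' @return numeric matrix `n_atoms x 3` of coordinates in Angstrom, with
#'   attribute `elements` (character vector) and `seed`.
#' @export
generate_conformer <- function(smiles, seed = 1L) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  set <- .mol_sdf(smiles, gen3d = TRUE, seed = seed)
  mol <- .parse_sdf_mol(set[[1]], smiles)
  if (nrow(mol$coords) < 1) stop("no atoms for '", smiles, "'", call. = FALSE)
  structure(mol$coords, elements = mol$elements, seed = as.integer(seed))
}

#' Radius-graph edges from coordinates
#'
#' Returns every ordered pair (i, j), i != j, whose Euclidean distance is at
#' most `cutoff_A`. Both directions are listed, so the edge set is symmetric.
#'
#' @param coords numeric matrix `n x 3` (Angstrom).
#' @param cutoff_A positive cutoff radius in Angstrom.
#' @return list with `edges` (integer matrix, columns `i`, `j`) and `dist`
#'   (numeric vector of edge lengths).
#' @export
radius_edges <- function(coords, cutoff_A = 4) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("at least one atom required", call. = FALSE)
  stopifnot(cutoff_A > 0)
  d <- as.matrix(stats::dist(coords))
  keep <- which(d <= cutoff_A & row(d) != col(d), arr.ind = TRUE)
  ord <- order(keep[, 1], keep[, 2])
  keep <- keep[ord, , drop = FALSE]
  list(edges = matrix(as.integer(keep), ncol = 2,
                      dimnames = list(NULL, c("i", "j"))),
       dist = d[keep])
}

#' Fourier features of an inter-atomic distance
#'
#' Sine/cosine positional encoding of a distance r:
#' `[sin(k pi r / r_max), cos(k pi r / r_max)]` for k = 1..K. All components
#' lie in `[-1, 1]`; at r = 0 the sine block is 0 and the cosine block is 1.
#'
#' @param r numeric vector of distances (Angstrom), all >= 0.
#' @param K number of frequencies (default 16).
#' @param r_max period scale in Angstrom (default 4, the radius cutoff).
#' @return numeric matrix `length(r) x 2K`: K sine columns then K cosine
#'   columns.
#' @export
fourier_distance_features <- function(r, K = 16L, r_max = 4) {
  if (r_max <= 0) stop("r_max must be positive", call. = FALSE)
  stopifnot(K >= 1, all(r >= 0))
  ang <- outer(r, seq_len(K)) * pi / r_max
  cbind(sin(ang), cos(ang))
}

.hybridization <- function(elements, bonds, aromatic) {
  n <- length(elements)
  n_double <- n_triple <- integer(n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]; o <- bonds[b, 3]
      if (o == 2) { n_double[i] <- n_double[i] + 1L; n_double[j] <- n_double[j] + 1L }
      if (o == 3) { n_triple[i] <- n_triple[i] + 1L; n_triple[j] <- n_triple[j] + 1L }
    }
  }
  hy <- rep("sp3", n)
  hy[n_double >= 1 | aromatic] <- "sp2"
  hy[n_triple >= 1 | n_double >= 2] <- "sp"
  hy[elements == "H"] <- "s"
  hy
}

.atom_feature_matrix <- function(graph) {
  n <- graph$n_atoms
  X <- matrix(0, n, length(ATOM_VOCAB) + 2 + length(HYBRID_VOCAB))
  X[cbind(seq_len(n), graph$atom_type_idx)] <- 1
  X[, length(ATOM_VOCAB) + 1] <- as.numeric(graph$in_ring)
  X[, length(ATOM_VOCAB) + 2] <- as.numeric(graph$aromatic)
  X[cbind(seq_len(n), length(ATOM_VOCAB) + 2 + graph$hybridization_idx)] <- 1
  X
}

.graph_from_mol <- function(mol, mode, cutoff_A, K, r_max, seed) {
  bad <- setdiff(unique(mol$elements), ATOM_VOCAB)
  if (length(bad)) {
    stop("unsupported element(s) ", paste(bad, collapse = ", "), " in '",
         mol$smiles, "': supported types are ",
         paste(ATOM_VOCAB, collapse = ", "), call. = FALSE)
  }
  hy <- .hybridization(mol$elements, mol$bonds, mol$aromatic)
  g <- list(
    smiles = mol$smiles,
    mode = mode,
    n_atoms = length(mol$elements),
    elements = mol$elements,
    atom_type_idx = match(mol$elements, ATOM_VOCAB),
    in_ring = mol$in_ring,
    aromatic = mol$aromatic,
    hybridization_idx = match(hy, HYBRID_VOCAB),
    seed = as.integer(seed)
  )
  if (mode == "3d") {
    g$coords <- mol$coords
    re <- radius_edges(mol$coords, cutoff_A)
    g$edges <- re$edges
    g$edge_dist <- re$dist
    g$edge_feat <- fourier_distance_features(re$dist, K = K, r_max = r_max)
  } else {
    e <- mol$bonds[, 1:2, drop = FALSE]
    both <- rbind(e, e[, 2:1, drop = FALSE])
    ord <- order(both[, 1], both[, 2])
    g$edges <- matrix(as.integer(both[ord, , drop = FALSE]), ncol = 2,
                      dimnames = list(NULL, c("i", "j")))
    g$coords <- NULL
    g$edge_dist <- NULL
    g$edge_feat <- NULL
  }
  g$features <- .atom_feature_matrix(g)
  class(g) <- "mol_graph"
  g
}

#' Build a featurized molecular graph from SMILES
#'
#' In 3D mode a UFF-relaxed conformer is embedded, edges connect every atom
#' pair within `cutoff_A` Angstrom, and each edge carries Fourier distance
#' features. In 2D mode edges are the covalent bonds (both directions) and no
#' coordinates or distance features are attached. Node features are identical
#' between modes: one-hot atom type (12 symbols), ring flag, aromaticity
#' flag, one-hot hybridization (sp3/sp2/sp/s). Hydrogens are explicit atoms.
#'
#' @param smiles single SMILES string.
#' @param mode `"3d"` (default) or `"2d"`.
#' @param cutoff_A radius cutoff in Angstrom (3D mode).
#' @param K,r_max Fourier encoding parameters, see
#'   [fourier_distance_features()].
#' @param seed conformer seed, logged with the graph.
#' @return object of class `mol_graph`.
#' @export
build_graph <- function(smiles, mode = c("3d", "2d"), cutoff_A = 4,
                        K = 16L, r_max = cutoff_A, seed = 1L) {
  mode <- match.arg(mode)
  featurize_smiles(smiles, mode = mode, cutoff_A = cutoff_A, K = K,
                   r_max = r_max, seed = seed)[[1]]
}

#' Featurize a batch of SMILES into molecular graphs
#'
#' Vectorized companion of [build_graph()]: one conformer-generation call for
#' the whole batch, returning a named list keyed by the input SMILES.
#'
#' @inheritParams build_graph
#' @param smiles character vector of SMILES (duplicates allowed; computed
#'   once each).
#' @return named list of `mol_graph` objects, one entry per unique SMILES.
#' @export
featurize_smiles <- function(smiles, mode = c("3d", "2d"), cutoff_A = 4,
                             K = 16L, r_max = cutoff_A, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.character(smiles), length(smiles) >= 1)
  uniq <- unique(smiles)
  set <- .mol_sdf(uniq, gen3d = (mode == "3d"), seed = seed)
  out <- vector("list", length(uniq))
  names(out) <- uniq
  for (k in seq_along(uniq)) {
    mol <- .parse_sdf_mol(set[[k]], uniq[k])
    out[[k]] <- .graph_from_mol(mol, mode, cutoff_A, K, r_max, seed)
  }
  out
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, "\n  mode: ", x$mode,
      ", atoms: ", x$n_atoms, ", edges: ", nrow(x$edges),
      if (!is.null(x$coords)) ", 3D coordinates present", "\n", sep = "")
  invisible(x)
}
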