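#' @importFrom ChemmineOB forEachMol fingerprint_OB smartsSearch_OB convertFormat
#' @importFrom ChemmineR read.SDFset atomblock bondblock rings validSDF
NULL

# One tab-separated "SMILES\ttitle" block per molecule, as OpenBabel expects.
.smi_block <- function(smiles, titles = seq_along(smiles)) {
  paste(paste(smiles, titles, sep = "\t"), collapse = "\n")
}

.with_obmol <- function(smiles, f) {
  res <- tryCatch(
    ChemmineOB::forEachMol("SMILES", .smi_block(smiles[1], "m"), f),
    error = function(e) stop("SMILES could not be processed: '", smiles[1],
                             "' (", conditionMessage(e), ")", call. = FALSE)
  )
  res[[1]]
}

#' Canonicalize SMILES strings
#'
#' Converts each input SMILES to its canonical form, used as the stable
#' dictionary key for featurization caches, screening tables and tie-breaks.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, same length.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  out <- ChemmineOB::convertFormat("SMI", "CAN", .smi_block(smiles))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(smiles)) {
    stop("canonicalization failed: ", length(smiles), " molecules in, ",
         length(lines), " out; check SMILES validity", call. = FALSE)
  }
  vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
}

#' Count SMARTS pattern matches in a molecule
#'
#' @param smiles single SMILES string.
#' @param smarts SMARTS pattern.
#' @return integer match count.
#' @export
count_smarts <- function(smiles, smarts) {
  n <- .with_obmol(smiles, function(m) ChemmineOB::smartsSearch_OB(list(m), smarts))
  as.integer(n)
}

#' Test molecules for (hetero)aromatic content
#'
#' A molecule qualifies as a Minisci decoy substrate only if it contains no
#' aromatic or heteroaromatic ring; this is the structural check behind decoy
#' generation.
#'
#' @param smiles character vector of SMILES.
#' @return logical vector, `TRUE` where the molecule has at least one
#'   aromatic atom.
#' @export
has_aromatic_ring <- function(smiles) {
  vapply(smiles, function(s) count_smarts(s, "a") > 0, logical(1),
         USE.NAMES = FALSE)
}

#' Check for a carboxylic acid group
#'
#' @param smiles character vector of SMILES.
#' @return logical vector, `TRUE` where a `-C(=O)OH` group is present.
#' @export
has_carboxylic_acid <- function(smiles) {
  vapply(smiles, function(s) count_smarts(s, "[CX3](=O)[OX2H1]") > 0,
         logical(1), USE.NAMES = FALSE)
}

#' ECFP4 fingerprints
#'
#' Extended-connectivity fingerprints of diameter 4 (radius 2) as binary bit
#' vectors, the descriptor used for substrate clustering and diversity
#' selection. The installed fingerprint backend folds ECFP4 to 4096 bits;
#' the length is reported in the result's columns rather than configurable.
#'
#' @param smiles character vector of SMILES.
#' @return a numeric 0/1 matrix with one row per molecule (rownames = input
#'   SMILES) and one column per bit.
#' @export
ecfp4_fingerprints <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  rows <- lapply(smiles, function(s) {
    as.numeric(.with_obmol(s, function(m) ChemmineOB::fingerprint_OB(list(m), "ECFP4")))
  })
  fp <- do.call(rbind, rows)
  rownames(fp) <- smiles
  fp
}

# Turn a batch of SMILES into an SDFset in input order.
#
# 3D mode runs the seeded embedding helper (distance-geometry conformer +
# UFF relaxation via RDKit): deterministic given (SMILES, seed). 2D mode
# runs obabel for the covalent bond table only (zeroed coordinates).
.mol_sdf <- function(smiles, gen3d = TRUE, seed = 1L) {
  stopifnot(length(smiles) >= 1)
  smi <- tempfile(fileext = ".smi")
  sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(smi, sdf)), add = TRUE)
  writeLines(.smi_block(smiles), smi)
  if (gen3d) {
    helper <- system.file("python", "embed3d.py", package = "miniscreen")
    suppressWarnings(
      system2("python", c(helper, smi, sdf, as.integer(seed)),
              stdout = FALSE, stderr = TRUE))
  } else {
    suppressWarnings(
      system2("obabel", c(smi, "-osdf", "-O", sdf, "-h"),
              stdout = FALSE, stderr = TRUE))
  }
  if (!file.exists(sdf) || file.size(sdf) == 0) {
    stop("conformer generation failed for batch starting with '",
         smiles[1], "'", call. = FALSE)
  }
  set <- ChemmineR::read.SDFset(sdf, skipErrors = TRUE)
  if (length(set) != length(smiles)) {
    titles <- ChemmineR::sdfid(set)
    missing <- setdiff(as.character(seq_along(smiles)), titles)
    stop("embedding failed for molecule(s): ",
         paste(smiles[as.integer(missing)], collapse = ", "), call. = FALSE)
  }
  set
}

# Parse one ChemmineR SDF into a plain structure: elements, coords (Angstrom),
# bonds (from, to, order), ring and aromaticity flags.
.parse_sdf_mol <- function(sdfobj, smiles) {
  ab <- ChemmineR::atomblock(sdfobj)
  bb <- ChemmineR::bondblock(sdfobj)
  labels <- rownames(ab)
  elements <- vapply(strsplit(labels, "_", fixed = TRUE), `[`, character(1), 1)
  n <- length(elements)
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(integer(0), ncol = 3)
  } else {
    unname(as.matrix(bb[, 1:3, drop = FALSE]))
  }
  in_ring <- rep(FALSE, n)
  aromatic <- rep(FALSE, n)
  rng <- tryCatch(ChemmineR::rings(sdfobj, type = "all", arom = TRUE),
                  error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
  if (length(rng$RINGS)) {
    idx_of <- function(lab) match(lab, labels)
    for (k in seq_along(rng$RINGS)) {
      idx <- idx_of(rng$RINGS[[k]])
      in_ring[idx] <- TRUE
      if (isTRUE(rng$AROMATIC[[k]])) aromatic[idx] <- TRUE
    }
  }
  list(smiles = smiles, elements = elements, coords = coords,
       bonds = bonds, in_ring = in_ring, aromatic = aromatic)
}
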