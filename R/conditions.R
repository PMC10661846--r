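#' Build the reaction-condition vocabulary from training records
#'
#' Collects the categorical vocabularies (reagents, solvents, catalysts,
#' additives, atmosphere) and the standardization statistics for the scalar
#' block (equivalents, temperature, time, concentration) from a training
#' set. The same vocabulary object must be reused at prediction time;
#' entities unseen in training encode as all-zero blocks.
#'
#' @param records list of reaction records (see [reaction_record()]).
#' @return object of class `condition_vocab`.
#' @export
build_condition_vocab <- function(records) {
  stopifnot(length(records) >= 1)
  pull_names <- function(field) {
    sort(unique(unlist(lapply(records, function(r) r[[field]]$name))))
  }
  scalars <- t(vapply(records, function(r) {
    c(substrate_equiv = r$substrate_equiv, acid_equiv = r$acid_equiv,
      temperature_C = r$temperature_C, time_h = r$time_h,
      scale_mmol_per_L = r$scale_mmol_per_L)
  }, numeric(5)))
  mu <- colMeans(scalars)
  sd <- apply(scalars, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  structure(list(
    reagents = pull_names("reagents"),
    solvents = pull_names("solvents"),
    catalysts = pull_names("catalysts"),
    additives = pull_names("additives"),
    atmosphere = sort(unique(vapply(records, `[[`, character(1), "atmosphere"))),
    scalar_mean = mu, scalar_sd = sd
  ), class = "condition_vocab")
}

.entity_blocks <- function(tab, vocab_names) {
  ind <- amt <- numeric(length(vocab_names))
  if (!is.null(tab) && nrow(tab)) {
    pos <- match(tab$name, vocab_names)
    known <- !is.na(pos)
    ind[pos[known]] <- 1
    amt[pos[known]] <- tab[[2]][known]
  }
  c(ind, amt)
}

#' Encode one reaction's conditions as a numeric vector
#'
#' Concatenates, per entity category, a presence indicator block over the
#' vocabulary and a parallel amount block (equivalents, or fractions for
#' solvents), a one-hot atmosphere block, and a standardized scalar block
#' (substrate and acid equivalents, temperature in deg C, time in h, scale
#' in mmol/L). This raw vector is what the model's condition MLP consumes.
#'
#' @param record a reaction record.
#' @param vocab a [build_condition_vocab()] result.
#' @return numeric vector of length [condition_dim()].
#' @export
encode_conditions <- function(record, vocab) {
  stopifnot(inherits(vocab, "condition_vocab"))
  sc <- c(record$substrate_equiv, record$acid_equiv, record$temperature_C,
          record$time_h, record$scale_mmol_per_L)
  if (anyNA(sc) || !all(is.finite(sc))) {
    stop("record '", record$reaction_id,
         "': missing scalar condition (no silent imputation); scalars = [",
         paste(sc, collapse = ", "), "]", call. = FALSE)
  }
  atm <- numeric(length(vocab$atmosphere))
  pos <- match(record$atmosphere, vocab$atmosphere)
  if (!is.na(pos)) atm[pos] <- 1
  c(.entity_blocks(record$reagents, vocab$reagents),
    .entity_blocks(record$solvents, vocab$solvents),
    .entity_blocks(record$catalysts, vocab$catalysts),
    .entity_blocks(record$additives, vocab$additives),
    atm,
    (sc - vocab$scalar_mean) / vocab$scalar_sd)
}

#' Length of the raw condition vector for a vocabulary
#' @param vocab a `condition_vocab`.
#' @return integer vector length.
#' @export
condition_dim <- function(vocab) {
  2L * (length(vocab$reagents) + length(vocab$solvents) +
        length(vocab$catalysts) + length(vocab$additives)) +
    length(vocab$atmosphere) + 5L
}

#' Condition matrix for a set of records
#' @param records list of reaction records.
#' @param vocab a `condition_vocab`.
#' @return numeric matrix, one row per record.
#' @export
condition_matrix <- function(records, vocab) {
  t(vapply(records, encode_conditions, numeric(condition_dim(vocab)),
           vocab = vocab))
}
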