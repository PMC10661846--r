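#' Success threshold for the binary reaction outcome
#'
#' A reaction counts as successful when the combined yield of all alkylation
#' products reaches the LCMS detection criterion of 5%.
#' @keywords internal
SUCCESS_THRESHOLD_PCT <- 5

.entity_df <- function(x, value_col) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(stats::setNames(data.frame(character(0), numeric(0)),
                           c("name", value_col)))
  }
  if (!is.data.frame(x)) x <- as.data.frame(x)
  stopifnot(ncol(x) == 2)
  names(x) <- c("name", value_col)
  x$name <- as.character(x$name)
  x[[value_col]] <- as.numeric(x[[value_col]])
  x
}

#' Construct a single SURF reaction record
#'
#' One row of a SURF (Simple User-friendly Reaction Format) table: the two
#' reactants as SMILES, the full reaction conditions, the per-product yields
#' and the derived learning targets. The combined yield is the capped sum of
#' the product yields (all listed products are productive alkylation
#' outcomes); the binary outcome is 1 iff the combined yield reaches the 5%
#' LCMS threshold. Decoy records must carry zero yield and outcome 0.
#'
#' @param reaction_id identifier string.
#' @param provenance one of `"literature"`, `"experimental"`, `"decoy"`.
#' @param substrate_smiles,acid_smiles reactant SMILES.
#' @param products data.frame (`product_smiles`, `yield_pct`), possibly
#'   empty.
#' @param reagents,catalysts,additives data.frames (`name`, `equivalents`).
#' @param solvents data.frame (`name`, `fraction`); fractions must sum to 1
#'   when any solvent is present.
#' @param atmosphere free-text atmosphere label.
#' @param temperature_C,time_h,scale_mmol_per_L scalar conditions.
#' @param substrate_equiv,acid_equiv reactant equivalents.
#' @param combined_yield_pct optional; computed from `products` when `NULL`.
#' @param outcome optional 0/1; derived from the combined yield when `NULL`.
#' @param extra named character vector of unknown columns carried through
#'   I/O untouched.
#' @param threshold_pct success threshold (default 5).
#' @return object of class `reaction_record`.
#' @export
reaction_record <- function(reaction_id, provenance, substrate_smiles,
                            acid_smiles, products = NULL,
                            reagents = NULL, solvents = NULL,
                            catalysts = NULL, additives = NULL,
                            atmosphere = "nitrogen", temperature_C = 40,
                            time_h = 16, scale_mmol_per_L = 16,
                            substrate_equiv = 1, acid_equiv = 20,
                            combined_yield_pct = NULL, outcome = NULL,
                            extra = character(0),
                            threshold_pct = SUCCESS_THRESHOLD_PCT) {
  provenance <- match.arg(provenance, c("literature", "experimental", "decoy"))
  products <- .entity_df(products, "yield_pct")
  names(products)[1] <- "product_smiles"
  if (any(products$yield_pct < 0 | products$yield_pct > 100)) {
    stop("product yields must lie in [0, 100]", call. = FALSE)
  }
  solvents <- .entity_df(solvents, "fraction")
  if (nrow(solvents) && abs(sum(solvents$fraction) - 1) > 1e-6) {
    stop("solvent fractions must sum to 1 (got ",
         sum(solvents$fraction), ")", call. = FALSE)
  }
  if (is.null(combined_yield_pct)) {
    combined_yield_pct <- combined_yield(products$yield_pct)
  }
  if (is.null(outcome)) {
    outcome <- as.integer(combined_yield_pct >= threshold_pct)
  }
  rec <- structure(list(
    reaction_id = as.character(reaction_id), provenance = provenance,
    substrate_smiles = substrate_smiles, acid_smiles = acid_smiles,
    substrate_equiv = as.numeric(substrate_equiv),
    acid_equiv = as.numeric(acid_equiv),
    reagents = .entity_df(reagents, "equivalents"),
    solvents = solvents,
    catalysts = .entity_df(catalysts, "equivalents"),
    additives = .entity_df(additives, "equivalents"),
    atmosphere = as.character(atmosphere),
    temperature_C = as.numeric(temperature_C),
    time_h = as.numeric(time_h),
    scale_mmol_per_L = as.numeric(scale_mmol_per_L),
    products = products,
    combined_yield_pct = as.numeric(combined_yield_pct),
    outcome = as.integer(outcome),
    extra = extra
  ), class = "reaction_record")
  probs <- validate_record(rec, threshold_pct)
  if (length(probs)) stop(paste(probs, collapse = "; "), call. = FALSE)
  rec
}

#' Validate a reaction record
#'
#' Returns a character vector of problems (empty when valid). Inconsistency
#' between a stored outcome flag and the outcome re-derived from the
#' combined yield is reported, never silently fixed.
#'
#' @param rec a `reaction_record`.
#' @param threshold_pct success threshold.
#' @return character vector of problem descriptions.
#' @export
validate_record <- function(rec, threshold_pct = SUCCESS_THRESHOLD_PCT) {
  probs <- character(0)
  who <- rec$reaction_id
  if (is.na(rec$combined_yield_pct)) {
    return(paste0(who, ": missing combined yield"))
  }
  if (rec$combined_yield_pct < 0 || rec$combined_yield_pct > 100) {
    probs <- c(probs, paste0(who, ": combined yield outside [0, 100]"))
  }
  # missing condition scalars stay NA here; encode_conditions() refuses them
  if (isTRUE(rec$time_h < 0)) {
    probs <- c(probs, paste0(who, ": negative time"))
  }
  if (isTRUE(rec$scale_mmol_per_L <= 0)) {
    probs <- c(probs, paste0(who, ": non-positive scale"))
  }
  derived <- as.integer(rec$combined_yield_pct >= threshold_pct)
  if (!is.na(rec$outcome) && rec$outcome != derived) {
    probs <- c(probs, paste0(who, ": stored outcome ", rec$outcome,
                             " contradicts combined yield ",
                             rec$combined_yield_pct, "% (threshold ",
                             threshold_pct, "%)"))
  }
  if (rec$provenance == "decoy" &&
      (rec$combined_yield_pct != 0 || rec$outcome != 0)) {
    probs <- c(probs, paste0(who, ": decoy record with non-zero yield/outcome"))
  }
  probs
}

#' Combined yield from per-product yields
#'
#' All observed alkylation products (the two mono-alkylation regioisomers
#' and the di-alkylation product) are productive outcomes, so their yields
#' are summed; the sum is capped at 100%.
#'
#' @param product_yields numeric vector of per-product yields in \[0, 100\].
#' @return single numeric in \[0, 100\].
#' @export
combined_yield <- function(product_yields) {
  y <- as.numeric(product_yields)
  if (length(y) == 0) return(0)
  if (any(is.na(y))) stop("missing product yield", call. = FALSE)
  if (any(y < 0)) stop("negative product yield", call. = FALSE)
  if (any(y > 100)) stop("product yield above 100%", call. = FALSE)
  min(sum(y), 100)
}

#' Summarize a reaction data set
#'
#' @param records list of `reaction_record`s.
#' @return object of class `dataset_summary` with `n_total`, `n_successful`,
#'   `n_unsuccessful` and per-provenance counts.
#' @export
dataset_summary <- function(records) {
  outcomes <- vapply(records, `[[`, integer(1), "outcome")
  prov <- vapply(records, `[[`, character(1), "provenance")
  structure(list(
    n_total = length(records),
    n_successful = sum(outcomes == 1L),
    n_unsuccessful = sum(outcomes == 0L),
    by_provenance = table(factor(prov, levels = c("literature",
                                                  "experimental", "decoy")))
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("Reactions:", x$n_total, "(", x$n_successful, "successful /",
      x$n_unsuccessful, "unsuccessful )\n")
  print(x$by_provenance)
  invisible(x)
}

#' Column dialect for SURF tables
#'
#' The public SURF schema is adapted via this mapping layer, so tables whose
#' headers differ from the package's native names can be read by supplying a
#' modified dialect instead of editing code. Scalar entries map internal
#' field -> file column name; the `families` entries give the prefixes of
#' numbered column groups (e.g. `reagent_1_name`, `reagent_1_equivalents`).
#'
#' @param ... scalar overrides, e.g. `reaction_id = "rxn_id"`.
#' @return named list dialect.
#' @export
surf_dialect <- function(...) {
  d <- list(reaction_id = "reaction_id", provenance = "provenance",
            substrate_smiles = "startingmat_1_smiles",
            substrate_equiv = "startingmat_1_eq",
            acid_smiles = "startingmat_2_smiles",
            acid_equiv = "startingmat_2_eq",
            atmosphere = "atmosphere", temperature_C = "temperature_deg_c",
            time_h = "time_h", scale_mmol_per_L = "concentration_mol_l",
            combined_yield_pct = "combined_yield_pct", outcome = "binary_outcome",
            families = list(reagent = c("name", "equivalents"),
                            solvent = c("name", "fraction"),
                            catalyst = c("name", "equivalents"),
                            additive = c("name", "equivalents"),
                            product = c("smiles", "yield_pct")))
  ov <- list(...)
  d[names(ov)] <- ov
  d
}

.family_cols <- function(header, family, parts) {
  pat <- paste0("^", family, "_([0-9]+)_(", paste(parts, collapse = "|"), ")$")
  hits <- grep(pat, header, value = TRUE)
  if (!length(hits)) return(integer(0))
  ks <- unique(as.integer(sub(pat, "\\1", hits)))
  sort(ks)
}

.num_or_stop <- function(x, what, rows) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad)) {
    stop("unparsable ", what, " at data row(s) ",
         paste(rows[bad], collapse = ", "), ": '",
         paste(x[bad], collapse = "', '"), "'", call. = FALSE)
  }
  out
}

#' Read a SURF tab-separated reaction table
#'
#' Parses one record per data row. Yields are percentages. SMILES that fail
#' canonicalization are flagged in the `problems` attribute (and in each
#' record's `smiles_ok`), never silently dropped. Rows whose stored outcome
#' contradicts the outcome re-derived from the combined yield are likewise
#' reported in `problems`.
#'
#' @param path TSV file path (UTF-8, header row).
#' @param provenance optional provenance forced onto all rows; when `NULL`
#'   the file's provenance column is used.
#' @param dialect column mapping, see [surf_dialect()].
#' @param threshold_pct success threshold.
#' @param check_smiles validate SMILES by canonicalization (default TRUE).
#' @return list of `reaction_record`s with attribute `problems`.
#' @export
read_surf <- function(path, provenance = NULL, dialect = surf_dialect(),
                      threshold_pct = SUCCESS_THRESHOLD_PCT,
                      check_smiles = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  header <- names(df)
  mandatory <- c("reaction_id", "substrate_smiles", "acid_smiles")
  for (f in mandatory) {
    if (!(dialect[[f]] %in% header)) {
      stop("missing mandatory column '", dialect[[f]], "' (field ", f, ")",
           call. = FALSE)
    }
  }
  n <- nrow(df)
  if (n == 0) return(structure(list(), problems = character(0)))
  rows <- seq_len(n)
  col <- function(f, default = NA_character_) {
    nm <- dialect[[f]]
    if (!is.null(nm) && nm %in% header) df[[nm]] else rep(default, n)
  }
  fam_tabs <- lapply(names(dialect$families), function(fn) {
    parts <- dialect$families[[fn]]
    ks <- .family_cols(header, fn, parts)
    lapply(ks, function(k) {
      list(a = df[[paste0(fn, "_", k, "_", parts[1])]],
           b = df[[paste0(fn, "_", k, "_", parts[2])]])
    })
  })
  names(fam_tabs) <- names(dialect$families)
  known <- unlist(dialect[setdiff(names(dialect), "families")],
                  use.names = FALSE)
  for (fn in names(dialect$families)) {
    parts <- dialect$families[[fn]]
    ks <- .family_cols(header, fn, parts)
    known <- c(known, as.vector(outer(paste0(fn, "_", ks, "_"), parts, paste0)))
  }
  extra_cols <- setdiff(header, known)

  prov_col <- if (!is.null(provenance)) rep(provenance, n) else col("provenance")
  cy <- .num_or_stop(col("combined_yield_pct"), "combined yield", rows)
  oc <- .num_or_stop(col("outcome"), "outcome", rows)
  te <- .num_or_stop(col("temperature_C"), "temperature", rows)
  th <- .num_or_stop(col("time_h"), "time", rows)
  sc <- .num_or_stop(col("scale_mmol_per_L"), "scale", rows)
  se <- .num_or_stop(col("substrate_equiv"), "substrate equivalents", rows)
  ae <- .num_or_stop(col("acid_equiv"), "acid equivalents", rows)

  fam_df <- function(fn, i, nm2) {
    tabs <- fam_tabs[[fn]]
    if (!length(tabs)) return(NULL)
    a <- vapply(tabs, function(t) t$a[i], character(1))
    b <- vapply(tabs, function(t) t$b[i], character(1))
    keep <- nzchar(a) & !is.na(a)
    if (!any(keep)) return(NULL)
    bn <- .num_or_stop(b[keep], paste(fn, "value"), rep(i, sum(keep)))
    stats::setNames(data.frame(a[keep], bn, stringsAsFactors = FALSE),
                    c("name", nm2))
  }

  problems <- character(0)
  records <- vector("list", n)
  for (i in rows) {
    prods <- fam_df("product", i, "yield_pct")
    rec <- list(
      reaction_id = df[[dialect$reaction_id]][i],
      provenance = {
        pv <- prov_col[i]
        if (is.na(pv) || !nzchar(pv)) pv <- "experimental"
        match.arg(pv, c("literature", "experimental", "decoy"))
      },
      substrate_smiles = df[[dialect$substrate_smiles]][i],
      acid_smiles = df[[dialect$acid_smiles]][i],
      substrate_equiv = if (is.na(se[i])) 1 else se[i],
      acid_equiv = if (is.na(ae[i])) 20 else ae[i],
      reagents = .entity_df(fam_df("reagent", i, "equivalents"), "equivalents"),
      solvents = .entity_df(fam_df("solvent", i, "fraction"), "fraction"),
      catalysts = .entity_df(fam_df("catalyst", i, "equivalents"), "equivalents"),
      additives = .entity_df(fam_df("additive", i, "equivalents"), "equivalents"),
      atmosphere = {a <- col("atmosphere")[i]; if (is.na(a) || !nzchar(a)) "unknown" else a},
      temperature_C = te[i], time_h = th[i], scale_mmol_per_L = sc[i],
      products = {
        p <- .entity_df(prods, "yield_pct"); names(p)[1] <- "product_smiles"; p
      },
      combined_yield_pct = if (is.na(cy[i])) {
        combined_yield(if (is.null(prods)) numeric(0) else prods$yield_pct)
      } else cy[i],
      extra = if (!length(extra_cols)) character(0) else {
        stats::setNames(vapply(extra_cols, function(cc) df[[cc]][i],
                               character(1)), extra_cols)
      }
    )
    rec$outcome <- if (is.na(oc[i])) {
      as.integer(rec$combined_yield_pct >= threshold_pct)
    } else as.integer(oc[i])
    class(rec) <- "reaction_record"
    problems <- c(problems, validate_record(rec, threshold_pct))
    records[[i]] <- rec
  }
  if (check_smiles) {
    smi <- unique(unlist(lapply(records, function(r)
      c(r$substrate_smiles, r$acid_smiles))))
    ok <- .smiles_parse_ok(smi)
    bad <- smi[!ok]
    for (i in rows) {
      r <- records[[i]]
      records[[i]]$smiles_ok <- !(r$substrate_smiles %in% bad ||
                                    r$acid_smiles %in% bad)
      if (!records[[i]]$smiles_ok) {
        problems <- c(problems, paste0(r$reaction_id,
                                       ": malformed SMILES (row ", i, ")"))
      }
    }
  }
  structure(records, problems = problems)
}

.smiles_parse_ok <- function(smiles) {
  vapply(smiles, function(s) {
    !inherits(tryCatch(canonical_smiles(s), error = function(e) e), "error")
  }, logical(1), USE.NAMES = FALSE)
}

#' Write reaction records as a SURF tab-separated table
#'
#' Lossless counterpart of [read_surf()]: entity lists expand into numbered
#' column families sized for the widest record, unknown extra columns are
#' restored, and numeric fields are printed with full precision so a
#' write/read round trip is the identity on validated records.
#'
#' @param records list of `reaction_record`s.
#' @param path output file path.
#' @param dialect column mapping, see [surf_dialect()].
#' @return `path`, invisibly.
#' @export
write_surf <- function(records, path, dialect = surf_dialect()) {
  fmt <- function(x) {
    ifelse(is.na(x), "", vapply(x, format, character(1), digits = 12))
  }
  fams <- list(reagent = "reagents", solvent = "solvents",
               catalyst = "catalysts", additive = "additives",
               product = "products")
  widths <- lapply(fams, function(f)
    max(0L, vapply(records, function(r) nrow(r[[f]]), integer(1))))
  header <- c(dialect$reaction_id, dialect$provenance,
              dialect$substrate_smiles, dialect$substrate_equiv,
              dialect$acid_smiles, dialect$acid_equiv)
  for (fn in names(fams)) {
    parts <- dialect$families[[fn]]
    w <- widths[[fn]]
    if (w > 0) {
      for (k in seq_len(w)) {
        header <- c(header, paste0(fn, "_", k, "_", parts))
      }
    }
  }
  header <- c(header, dialect$atmosphere, dialect$temperature_C,
              dialect$time_h, dialect$scale_mmol_per_L,
              dialect$combined_yield_pct, dialect$outcome)
  extra_cols <- unique(unlist(lapply(records, function(r) names(r$extra))))
  header <- c(header, extra_cols)

  lines <- vapply(records, function(r) {
    row <- c(r$reaction_id, r$provenance, r$substrate_smiles,
             fmt(r$substrate_equiv), r$acid_smiles, fmt(r$acid_equiv))
    for (fn in names(fams)) {
      tab <- r[[fams[[fn]]]]
      w <- widths[[fn]]
      if (w > 0) {
        for (k in seq_len(w)) {
          if (k <= nrow(tab)) {
            row <- c(row, tab[[1]][k], fmt(tab[[2]][k]))
          } else row <- c(row, "", "")
        }
      }
    }
    row <- c(row, r$atmosphere, fmt(r$temperature_C), fmt(r$time_h),
             fmt(r$scale_mmol_per_L), fmt(r$combined_yield_pct),
             as.character(r$outcome))
    ex <- if (length(extra_cols)) {
      vapply(extra_cols, function(cc) {
        v <- r$extra[cc]; if (is.na(v)) "" else unname(v)
      }, character(1))
    } else character(0)
    paste(c(row, ex), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), lines), con)
  invisible(path)
}
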