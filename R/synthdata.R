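# Curated SMILES template sets for the four substrate classes and the acid
# panel. Representative structures of each reactivity class, not a copy of
# any proprietary library.
SUBSTRATE_TEMPLATES <- list(
  meta_unsub_pyridine = c(
    "c1ccncc1",               # pyridine
    "Cc1ccncc1",              # 4-methylpyridine
    "Cc1ccccn1",              # 2-methylpyridine
    "COc1ccncc1",             # 4-methoxypyridine
    "CC(C)(C)c1ccncc1",       # 4-tert-butylpyridine
    "c1ccc(-c2ccncc2)cc1",    # 4-phenylpyridine
    "c1ccc2ncccc2c1",         # quinoline
    "c1ccc2cnccc2c1",         # isoquinoline
    "Cc1cccc(C)n1",           # 2,6-lutidine
    "N#Cc1ccncc1"             # 4-cyanopyridine
  ),
  meta_sub_pyridine = c(
    "Cc1cccnc1",              # 3-methylpyridine
    "COc1cccnc1",             # 3-methoxypyridine
    "Clc1cccnc1",             # 3-chloropyridine
    "Fc1cccnc1",              # 3-fluoropyridine
    "N#Cc1cccnc1",            # nicotinonitrile
    "Nc1cccnc1",              # 3-aminopyridine
    "Cc1cncc(C)c1",           # 3,5-dimethylpyridine
    "CCOC(=O)c1cccnc1",       # ethyl nicotinate
    "Brc1cccnc1",             # 3-bromopyridine
    "c1ccc(-c2cccnc2)cc1"     # 3-phenylpyridine
  ),
  five_membered = c(
    "c1cc[nH]n1",             # pyrazole
    "c1c[nH]cn1",             # imidazole
    "c1cscn1",                # thiazole
    "c1cocn1",                # oxazole
    "Cn1cccn1",               # 1-methylpyrazole
    "Cn1ccnc1",               # 1-methylimidazole
    "c1cc[nH]c1",             # pyrrole
    "c1ccc2[nH]cnc2c1",       # benzimidazole
    "Cc1cscn1",               # 4-methylthiazole
    "Cc1ccn(C)n1"             # 1,3-dimethylpyrazole
  ),
  decoy = c(
    "C1CCCCC1",               # cyclohexane
    "CC1CCCCC1",              # methylcyclohexane
    "O=C1CCCCC1",             # cyclohexanone
    "OC1CCCCC1",              # cyclohexanol
    "C1CCOC1",                # tetrahydrofuran
    "C1CCOCC1",               # tetrahydropyran
    "C1COCCO1",               # 1,4-dioxane
    "C1CCNCC1",               # piperidine
    "C1COCCN1",               # morpholine
    "CC(C)(C)OC(=O)N1CCCCC1", # N-Boc-piperidine
    "CCCCCC",                 # n-hexane
    "CC(C)(C)O",              # tert-butanol
    "O=C1CCCC1",              # cyclopentanone
    "CCOCC",                  # diethyl ether
    "C1CC2CCC1C2",            # norbornane
    "CC(C)CC(C)(C)C"          # 2,2,4-trimethylpentane
  )
)

# Curated in silico screening library: 64 N-heteroarene building blocks
# spanning pyridines, diazines, fused bicyclics and five-membered azoles.
SCREENING_LIBRARY <- c(
  "c1ccncc1", "Cc1ccncc1", "Cc1ccccn1", "Cc1cccnc1", "COc1ccncc1",
  "COc1cccnc1", "CC(C)(C)c1ccncc1", "Fc1ccncc1", "Fc1cccnc1",
  "Clc1ccncc1", "Clc1cccnc1", "Brc1cccnc1", "N#Cc1ccncc1", "N#Cc1cccnc1",
  "CC(=O)c1ccncc1", "CCOC(=O)c1cccnc1", "c1ccc(-c2ccncc2)cc1",
  "c1ccc(-c2cccnc2)cc1", "Cc1cncc(C)c1", "Cc1cccc(C)n1", "Nc1cccnc1",
  "Nc1ccncc1", "OCc1ccncc1", "CN(C)c1ccncc1", "FC(F)(F)c1ccncc1",
  "FC(F)(F)c1cccnc1", "c1ccnnc1", "c1cncnc1", "Cc1ncccn1", "c1cnccn1",
  "Cc1cnccn1", "c1ccc2ncccc2c1", "Cc1ccnc2ccccc12", "c1ccc2cnccc2c1",
  "c1ccc2nccnc2c1", "c1ccc2ncncc2c1", "c1ccc2cccnc2n1", "c1cc2cc[nH]c2nc1",
  "c1ccc2[nH]cnc2c1", "c1ccc2scnc2c1", "c1ccc2ocnc2c1", "Cn1ccnc1",
  "Cn1cccn1", "c1cscn1", "Cc1cscn1", "c1cocn1", "c1cc[nH]n1",
  "Cc1ccn(C)n1", "c1c[nH]cn1", "Cn1cnc2ccccc21", "Cc1nccs1",
  "c1ccc(-c2nccs2)cc1", "COc1ccc2ncccc2c1", "c1ccn2ccnc2c1",
  "Cc1cc(C)nc(C)c1", "OCCc1ccncc1", "CCc1ccncc1", "CCc1cccnc1",
  "COC(=O)c1ccncc1", "CC(=O)Nc1cccnc1", "Fc1ccc2ncccc2c1",
  "c1ccc(-n2cccn2)cc1", "Cn1ccc2ccccc21", "Cc1cnc2ccccc2n1")

#' Example N-heteroarene screening library
#'
#' 64 curated heteroaromatic building blocks (pyridines, diazines, fused
#' bicyclics, five-membered azoles) used as the default in silico screening
#' library. Representative drug-like ring systems, large enough for
#' eight-cluster diversity selection.
#'
#' @return character vector of SMILES.
#' @export
screening_library <- function() SCREENING_LIBRARY

ACID_PANEL <- data.frame(
  label = letters[1:23],
  class = c(rep("cyclic_ether", 6), rep("cyclic_alkane", 8),
            rep("boc_amine", 4), rep("n_alkyl", 5)),
  name = c("tetrahydropyran-4-carboxylic acid",
           "tetrahydrofuran-3-carboxylic acid",
           "oxetane-3-carboxylic acid",
           "tetrahydrofuran-2-carboxylic acid",
           "oxane-2-carboxylic acid",
           "1,4-dioxane-2-carboxylic acid",
           "cyclopropanecarboxylic acid",
           "cyclobutanecarboxylic acid",
           "cyclopentanecarboxylic acid",
           "cyclohexanecarboxylic acid",
           "1-methylcyclopropane-1-carboxylic acid",
           "4,4-difluorocyclohexane-1-carboxylic acid",
           "bicyclo[1.1.1]pentane-1-carboxylic acid",
           "2-methylcyclohexane-1-carboxylic acid",
           "1-Boc-azetidine-3-carboxylic acid",
           "1-Boc-piperidine-4-carboxylic acid",
           "1-Boc-pyrrolidine-3-carboxylic acid",
           "1-Boc-pyrrolidine-2-carboxylic acid",
           "acetic acid", "propionic acid", "isobutyric acid",
           "pivalic acid", "3-methylbutanoic acid"),
  smiles = c("OC(=O)C1CCOCC1", "OC(=O)C1CCOC1", "OC(=O)C1COC1",
             "OC(=O)C1CCCO1", "OC(=O)C1CCCCO1", "OC(=O)C1COCCO1",
             "OC(=O)C1CC1", "OC(=O)C1CCC1", "OC(=O)C1CCCC1",
             "OC(=O)C1CCCCC1", "CC1(CC1)C(O)=O", "OC(=O)C1CCC(F)(F)CC1",
             "OC(=O)C12CC(C1)C2", "CC1CCCCC1C(O)=O",
             "CC(C)(C)OC(=O)N1CC(C1)C(O)=O",
             "CC(C)(C)OC(=O)N1CCC(CC1)C(O)=O",
             "CC(C)(C)OC(=O)N1CCC(C1)C(O)=O",
             "CC(C)(C)OC(=O)N1CCCC1C(O)=O",
             "CC(O)=O", "CCC(O)=O", "CC(C)C(O)=O", "CC(C)(C)C(O)=O",
             "CC(C)CC(O)=O"),
  stringsAsFactors = FALSE
)

#' The 23-acid screening panel
#'
#' The sp3-rich alkyl carboxylic acids of the screening plate, labeled
#' a-w with their 24-well plate positions (B4 is reserved for the
#' reference reaction and carries no panel acid). The four reactivity
#' classes are cyclic ethers, cyclic alkanes, Boc-protected cyclic amines
#' and n-alkyl acids. The structures are representative members of each
#' class.
#'
#' @return data.frame with columns `label`, `position`, `class`, `name`,
#'   `smiles` (23 rows).
#' @export
make_acid_panel <- function() {
  wells <- paste0(rep(LETTERS[1:4], each = 6), rep(1:6, times = 4))
  panel <- ACID_PANEL
  panel$position <- setdiff(wells, "B4")
  panel[, c("label", "position", "class", "name", "smiles")]
}

#' Specification for a synthetic Minisci reaction data set
#'
#' Defines the statistical structure of generated SURF data: the substrate
#' and acid class mixes, the planted class mean yields, and the noise
#' level. The default class means are the observed reactivity trends:
#' meta-unsubstituted pyridines 44%, meta-substituted 20%, five-membered
#' N-heterocycles 2% (decoy substrates 0); cyclic ethers 40%, cyclic
#' alkanes 42%, Boc-amines 8%, n-alkyl acids 30%.
#'
#' @param n_reactions number of records to generate.
#' @param substrate_mix named probabilities over the four substrate
#'   classes; must sum to 1.
#' @param acid_mix named probabilities over the four acid classes; the
#'   default follows the panel composition (6/8/4/5 of 23).
#' @param substrate_means,acid_means planted class mean yields in percent.
#' @param noise_sd_pct Gaussian noise standard deviation in percent.
#' @param seed integer seed.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_reactions = 691L,
                       substrate_mix = c(meta_unsub_pyridine = 0.35,
                                         meta_sub_pyridine = 0.35,
                                         five_membered = 0.10,
                                         decoy = 0.20),
                       acid_mix = c(cyclic_ether = 6 / 23,
                                    cyclic_alkane = 8 / 23,
                                    boc_amine = 4 / 23,
                                    n_alkyl = 5 / 23),
                       substrate_means = c(meta_unsub_pyridine = 44,
                                           meta_sub_pyridine = 20,
                                           five_membered = 2,
                                           decoy = 0),
                       acid_means = c(cyclic_ether = 40,
                                      cyclic_alkane = 42,
                                      boc_amine = 8,
                                      n_alkyl = 30),
                       noise_sd_pct = 10, seed = 1L) {
  stopifnot(n_reactions >= 1,
            abs(sum(substrate_mix) - 1) < 1e-8,
            abs(sum(acid_mix) - 1) < 1e-8,
            all(substrate_means >= 0 & substrate_means <= 100),
            all(acid_means >= 0 & acid_means <= 100),
            noise_sd_pct >= 0)
  structure(list(n_reactions = as.integer(n_reactions),
                 substrate_mix = substrate_mix, acid_mix = acid_mix,
                 substrate_means = substrate_means, acid_means = acid_means,
                 noise_sd_pct = noise_sd_pct, seed = as.integer(seed)),
            class = "synth_spec")
}

# Mean of clip(N(m, s), 0, 100) in closed form.
.clipped_normal_mean <- function(m, s) {
  if (s == 0) return(pmin(pmax(m, 0), 100))
  a <- (0 - m) / s
  b <- (100 - m) / s
  m + s * (stats::dnorm(a) - stats::dnorm(b)) +
    (0 - m) * stats::pnorm(a) + (100 - m) * (1 - stats::pnorm(b))
}

#' Expected class-mean yields of the generator
#'
#' Closed-form marginal mean yields implied by a [synth_spec()], including
#' the truncation of the noisy yield to \[0, 100\]: the analytic oracle
#' against which group-wise averages of generated data are tested.
#'
#' @param spec a `synth_spec`.
#' @return list with numeric vectors `substrate` and `acid` of expected
#'   mean yields (percent) per class.
#' @export
expected_class_means <- function(spec) {
  norm <- sum(spec$acid_mix * spec$acid_means)
  mean_sub <- function(cls) {
    if (cls == "decoy") return(0)
    mus <- spec$substrate_means[[cls]] * spec$acid_means / norm
    sum(spec$acid_mix *
          vapply(mus, .clipped_normal_mean, numeric(1), s = spec$noise_sd_pct))
  }
  reactive <- names(spec$substrate_mix)[names(spec$substrate_mix) != "decoy"]
  w <- spec$substrate_mix[reactive] / sum(spec$substrate_mix[reactive])
  mean_acid <- function(cls) {
    mus <- spec$substrate_means[reactive] * spec$acid_means[[cls]] / norm
    sum(w * vapply(mus, .clipped_normal_mean, numeric(1),
                   s = spec$noise_sd_pct))
  }
  list(substrate = vapply(stats::setNames(nm = names(spec$substrate_mix)),
                          mean_sub, numeric(1)),
       acid = vapply(stats::setNames(nm = names(spec$acid_mix)), mean_acid,
                     numeric(1)))
}

#' Generate a synthetic SURF reaction data set
#'
#' Draws, per record, a substrate class from the class mix (and a template
#' SMILES uniformly within the class) and an acid from the panel members of
#' a drawn acid class. The true yield is
#' `clip(mu_substrate * mu_acid / mu_bar + noise, 0, 100)` with Gaussian
#' noise, where `mu_bar` is the acid-mix-weighted mean acid effect, so the
#' substrate-class marginals match the planted means; decoy substrates get
#' yield 0 exactly. The outcome is 1 iff the yield reaches the 5% LCMS
#' threshold. Byte-identical output for equal seeds.
#'
#' @param spec a [synth_spec()].
#' @return list of `reaction_record`s; attribute `truth` is a data.frame
#'   with the drawn classes per record.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  for (cls in names(spec$substrate_mix)) {
    if (spec$substrate_mix[[cls]] > 0 &&
        length(SUBSTRATE_TEMPLATES[[cls]]) == 0) {
      stop("no substrate templates for class ", cls, call. = FALSE)
    }
  }
  panel <- make_acid_panel()
  set.seed(spec$seed)
  n <- spec$n_reactions
  sub_cls <- sample(names(spec$substrate_mix), n, replace = TRUE,
                    prob = spec$substrate_mix)
  acid_cls <- sample(names(spec$acid_mix), n, replace = TRUE,
                     prob = spec$acid_mix)
  norm <- sum(spec$acid_mix * spec$acid_means)
  base <- standard_conditions()
  records <- vector("list", n)
  sub_smi <- character(n)
  acid_smi <- character(n)
  for (i in seq_len(n)) {
    tpl <- SUBSTRATE_TEMPLATES[[sub_cls[i]]]
    sub_smi[i] <- tpl[sample.int(length(tpl), 1)]
    members <- panel$smiles[panel$class == acid_cls[i]]
    acid_smi[i] <- members[sample.int(length(members), 1)]
  }
  noise <- stats::rnorm(n, 0, spec$noise_sd_pct)
  mu <- spec$substrate_means[sub_cls] * spec$acid_means[acid_cls] / norm
  y <- round(pmin(pmax(unname(mu) + noise, 0), 100), 2)
  y[sub_cls == "decoy"] <- 0
  for (i in seq_len(n)) {
    r <- base
    r$reaction_id <- sprintf("synth-%05d", i)
    r$provenance <- if (sub_cls[i] == "decoy") "decoy" else "experimental"
    r$substrate_smiles <- sub_smi[i]
    r$acid_smiles <- acid_smi[i]
    r$products <- data.frame(product_smiles = character(0),
                             yield_pct = numeric(0))
    r$combined_yield_pct <- y[i]
    r$outcome <- as.integer(y[i] >= SUCCESS_THRESHOLD_PCT)
    records[[i]] <- r
  }
  attr(records, "truth") <- data.frame(substrate_class = sub_cls,
                                       acid_class = acid_cls,
                                       stringsAsFactors = FALSE)
  records
}
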