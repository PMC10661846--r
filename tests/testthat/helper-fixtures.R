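# Shared fixtures, memoized so expensive objects (conformers, trained
# models, synthetic datasets) are built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixtures)) assign(name, fn(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small architecture used wherever the test only needs "a working model".
tiny_config <- function(mode = "2d") {
  gtnn_config(hidden_dim = 16L, embed_dim = 8L, post_pool_dim = 16L,
              pool_attention_heads = 2L, mode = mode, K = 4L)
}

# Screening-scale architecture (matches the pipeline defaults).
small_config <- function() {
  gtnn_config(hidden_dim = 32L, embed_dim = 16L, post_pool_dim = 64L,
              pool_attention_heads = 4L, mode = "3d")
}

synth_80 <- function() {
  fixture("synth_80", function() generate_dataset(synth_spec(80, seed = 7)))
}

synth_300 <- function() {
  fixture("synth_300", function() generate_dataset(synth_spec(300, seed = 11)))
}

# A record with full condition/product structure for SURF round trips.
rich_record <- function(id = "rx-1", yields = c(10, 5, 2)) {
  prods <- if (length(yields)) {
    data.frame(product_smiles = paste0("CCC", seq_along(yields)),
               yield_pct = yields)
  }
  reaction_record(
    reaction_id = id, provenance = "experimental",
    substrate_smiles = "c1ccncc1", acid_smiles = "OC(=O)C1CCOCC1",
    products = prods,
    reagents = data.frame(name = "ammonium persulfate", equivalents = 6),
    solvents = data.frame(name = c("DMSO", "water"), fraction = c(0.5, 0.5)),
    catalysts = data.frame(name = "silver nitrate", equivalents = 0.2),
    atmosphere = "nitrogen", temperature_C = 40, time_h = 16,
    scale_mmol_per_L = 16, extra = c(plate = "P1", well = "A1"))
}

# Hand-built 4-atom toy graph (no chemistry) for message-passing oracles.
toy_graph <- function(edges, n = 4L, coords = NULL, K = 2L, r_max = 4) {
  g <- list(smiles = "toy", mode = if (is.null(coords)) "2d" else "3d",
            n_atoms = n, elements = rep("C", n),
            atom_type_idx = rep(2L, n), in_ring = rep(FALSE, n),
            aromatic = rep(FALSE, n), hybridization_idx = rep(1L, n),
            seed = 1L,
            edges = matrix(as.integer(edges), ncol = 2, byrow = TRUE,
                           dimnames = list(NULL, c("i", "j"))))
  if (!is.null(coords)) {
    g$coords <- coords
    d <- sqrt(rowSums((coords[g$edges[, 1], , drop = FALSE] -
                         coords[g$edges[, 2], , drop = FALSE])^2))
    g$edge_dist <- d
    g$edge_feat <- fourier_distance_features(d, K = K, r_max = r_max)
  }
  g$features <- miniscreen:::.atom_feature_matrix(g)
  class(g) <- "mol_graph"
  g
}

# Fixed small MLP parameters for oracle checks.
toy_mlp <- function(nin, nhid, nout, scale = 0.3, seed = 42) {
  set.seed(seed)
  list(W1 = matrix(stats::runif(nin * nhid, -scale, scale), nin, nhid),
       b1 = matrix(stats::runif(nhid, -scale, scale), 1),
       W2 = matrix(stats::runif(nhid * nout, -scale, scale), nhid, nout),
       b2 = matrix(stats::runif(nout, -scale, scale), 1))
}

silu <- function(x) x / (1 + exp(-x))

mlp_apply <- function(p, x) {
  h <- silu(x %*% p$W1 + matrix(p$b1, nrow(x), ncol(p$W1), byrow = TRUE))
  h %*% p$W2 + matrix(p$b2, nrow(x), ncol(p$W2), byrow = TRUE)
}
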