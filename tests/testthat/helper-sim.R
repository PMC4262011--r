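# Simulation helpers shared across test files.

# Constructed-truth tree: k clusters of `tips` samples each, cluster crowns
# on the order of `crown` and all between-species divergences at least
# `stem_min` (the youngest species split is rescaled to stem_min), so the
# separation regime stem >= 10 x crown holds by construction.
make_clustered_tree <- function(k, tips, stem_min = 10, crown = 0.1,
                                seed = 1) {
  set.seed(seed)
  sp <- ape::rcoal(k, tip.label = paste0("c", seq_len(k)))
  bt <- ape::branching.times(sp)
  sp$edge.length <- sp$edge.length * stem_min / min(bt)
  suppressWarnings(
    simulate_gene_tree(sp, coalescent_depth = crown, tips, seed = seed + 1))
}

# Neutral constant-size coalescent alignment: n sequences, Jukes-Cantor on
# a standard coalescent tree; theta ~ 2 * rate * sites in rcoal time units.
sim_neutral_alignment <- function(n, sites = 600, rate = 0.004, seed = 1) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  evolve_sequences(tr, subst_rate = rate, seq_length = sites, seed = seed + 1)
}

# Random small alignment over A/C/G/T (optionally with gaps/N) for oracle
# comparisons.
random_alignment <- function(n, sites, seed, missing = 0) {
  set.seed(seed)
  alphabet <- c("A", "C", "G", "T")
  m <- matrix(sample(alphabet, n * sites, replace = TRUE), nrow = n)
  # make columns mostly monomorphic so S is moderate
  base <- sample(alphabet, sites, replace = TRUE)
  keep <- runif(n * sites) < 0.85
  m[keep] <- rep(base, each = n)[keep]
  if (missing > 0) {
    idx <- runif(n * sites) < missing
    m[idx] <- sample(c("-", "N"), sum(idx), replace = TRUE)
  }
  setNames(apply(m, 1, paste0, collapse = ""), paste0("s", seq_len(n)))
}
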