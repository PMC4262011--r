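## Synthetic data with the statistical structure the analysis assumes:
## constant-rate birth-death species trees, independent single-population
## coalescents within species grafted onto the species tree, Jukes-Cantor
## sequence evolution, and two sampling presets emulating a clonal
## ("asexual_like") and a sexual ("sexual_like") sampling regime.

#' Simulate a reconstructed constant-rate birth-death tree
#'
#' Conditioned on the number of extant species; extinct lineages removed.
#' Branch lengths share the time unit of the rates (Myr throughout).
#'
#' @param r Net diversification rate lambda - mu (> 0).
#' @param eps Extinction fraction mu / lambda in `[0, 1)`.
#' @param n_species Number of tips.
#' @param seed Integer seed (fixed seed gives an identical Newick string).
#' @return Ultrametric binary `phylo`.
#' @export
simulate_bd_tree <- function(r, eps, n_species, seed) {
  if (r <= 0 || eps < 0 || eps >= 1)
    stop_discretus("domain_error", "need r > 0 and 0 <= eps < 1")
  lambda <- r / (1 - eps)
  set.seed(seed)
  ape::rphylo(n_species, birth = lambda, death = lambda * eps)
}

## plain recursive Newick builder allowing per-tip substitution of subtree
## text and pendant length (used to hang coalescent trees off species tips)
build_newick <- function(tr, tip_text, tip_len) {
  nt <- ape::Ntip(tr)
  kids <- vector("list", nt + tr$Nnode)
  for (e in seq_len(nrow(tr$edge)))
    kids[[tr$edge[e, 1L]]] <-
      c(kids[[tr$edge[e, 1L]]], list(c(tr$edge[e, 2L], tr$edge.length[e])))
  rec <- function(v) {
    if (v <= nt)
      return(sprintf("%s:%.12g", tip_text[v], tip_len[v]))
    parts <- vapply(kids[[v]], function(kd) {
      ch <- kd[1L]
      if (ch <= nt) rec(ch)
      else sprintf("%s:%.12g", rec(ch), kd[2L])
    }, character(1))
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  paste0(rec(nt + 1L), ";")
}

#' Simulate a gene tree by coalescents within a species tree
#'
#' Each species receives an independent single-population coalescent whose
#' time scale is set so that the expected TMRCA of k samples equals
#' `coalescent_depth * (1 - 1/k)` (Kingman scaling).  The within-species
#' genealogies are grafted onto the species tree at the species tips.  A
#' coalescent deeper than the species' stem attachment would break
#' ultrametric grafting, so it is rescaled below the stem with a warning
#' (constructed-truth regimes should never trigger this).
#'
#' @param species_tree Ultrametric binary `phylo`.
#' @param coalescent_depth Expected within-species TMRCA scale (Myr).
#' @param samples_per_species Integer vector (recycled) of samples per
#'   species (>= 1).
#' @param seed Integer seed.
#' @return List with `tree` (gene tree, tips `<species>_<i>`), `partition`
#'   (data.frame `tip`, `species`: the truth) and `species_tree`.
#' @export
simulate_gene_tree <- function(species_tree, coalescent_depth,
                               samples_per_species, seed) {
  nt <- ape::Ntip(species_tree)
  k <- rep_len(as.integer(samples_per_species), nt)
  if (any(k < 1L))
    stop_discretus("domain_error", "need >= 1 sample per species")
  ages <- ape::branching.times(species_tree)
  node_age <- numeric(nt + species_tree$Nnode)
  node_age[as.integer(names(ages))] <- as.numeric(ages)
  parent_age <- node_age[species_tree$edge[, 1L]][
    match(seq_len(nt), species_tree$edge[, 2L])]
  seeds <- derive_seeds(seed, nt)
  tip_text <- character(nt)
  tip_len <- numeric(nt)
  labs <- species_tree$tip.label
  for (i in seq_len(nt)) {
    if (k[i] == 1L) {
      tip_text[i] <- paste0(labs[i], "_1")
      tip_len[i] <- parent_age[i]
      next
    }
    set.seed(seeds[i])
    ct <- ape::rcoal(k[i], tip.label = paste0(labs[i], "_", seq_len(k[i])))
    ct$edge.length <- ct$edge.length * coalescent_depth / 2
    h <- max(ape::branching.times(ct))
    if (h >= parent_age[i]) {
      warn_discretus("coalescent_depth_warning",
                     sprintf("coalescent of %s deeper than its stem; rescaled",
                             labs[i]))
      ct$edge.length <- ct$edge.length * 0.95 * parent_age[i] / h
      h <- 0.95 * parent_age[i]
    }
    txt <- ape::write.tree(ct)
    tip_text[i] <- sub(";$", "", txt)
    tip_len[i] <- parent_age[i] - h
  }
  gene <- ape::read.tree(text = build_newick(species_tree, tip_text, tip_len))
  partition <- data.frame(tip = gene$tip.label,
                          species = sub("_[0-9]+$", "", gene$tip.label))
  list(tree = gene, partition = partition, species_tree = species_tree)
}

#' Evolve sequences along a gene tree under Jukes-Cantor
#'
#' Branch lengths (time) are multiplied by `subst_rate` to obtain expected
#' substitutions per site.
#'
#' @param gene_tree `phylo`.
#' @param subst_rate Substitutions per site per Myr.
#' @param seq_length Number of sites.
#' @param seed Integer seed (fixed seed gives bit-identical sequences).
#' @return Named character vector of aligned sequences.
#' @export
evolve_sequences <- function(gene_tree, subst_rate, seq_length, seed) {
  set.seed(seed)
  sim <- phangorn::simSeq(gene_tree, l = seq_length, rate = subst_rate)
  m <- toupper(as.character(sim))
  setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
}

scenario_presets <- function() {
  list(
    asexual_like = list(
      n_datasets = 6L, r = 0.072, eps = 0, n_species = 12L,
      coalescent_depth = 0.8, samples_mean = 5.63, samples_dispersion = 0.5,
      seq_length = 600L, subst_rate = 0.0176,
      clade = "asexual", habitat = "limnoterrestrial"),
    sexual_like = list(
      n_datasets = 7L, r = 0.048, eps = 0, n_species = 12L,
      coalescent_depth = 0.8, samples_mean = 16.4, samples_dispersion = 0.5,
      seq_length = 600L, subst_rate = 0.0176,
      clade = "sexual", habitat = "aquatic"))
}

#' Generate a full scenario bundle
#'
#' `asexual_like` emulates the clonal sampling regime: faster net
#' diversification (r = 0.072/Myr), few sequences per species (mean 5.63)
#' and consequently many singletons; `sexual_like` the sexual regime:
#' slower diversification (r = 0.048/Myr) and dense sampling (mean 16.4
#' sequences per species), with 6 and 7 datasets respectively.  Per-species
#' sample counts are drawn as `1 + NegBin(mu = mean - 1, size = dispersion)`.
#' Both presets share the within-species coalescent depth, so intraspecific
#' diversity is comparable between groups while between-species divergence
#' differs through the diversification rate alone.
#'
#' @param preset `"asexual_like"` or `"sexual_like"`.
#' @param overrides Named list overriding preset fields.
#' @param seed Integer master seed; everything downstream is derived from it.
#' @return Object of class `scenario_bundle`: `config` plus a `datasets`
#'   list, each with `species_tree`, `gene_tree`, `alignment`, `meta`,
#'   `truth` (tip-to-species map, r, eps, sample counts).
#' @export
make_scenario <- function(preset = c("asexual_like", "sexual_like"),
                          overrides = list(), seed = 1L) {
  preset <- match.arg(preset)
  cfg <- utils::modifyList(scenario_presets()[[preset]], overrides)
  cfg$preset <- preset
  nd <- cfg$n_datasets
  seeds <- matrix(derive_seeds(seed, nd * 5L), nrow = nd)
  datasets <- vector("list", nd)
  for (d in seq_len(nd)) {
    sp <- simulate_bd_tree(cfg$r, cfg$eps, cfg$n_species, seeds[d, 1L])
    sp$tip.label <- sprintf("d%02ds%02d", d, seq_len(cfg$n_species))
    set.seed(seeds[d, 2L])
    k <- 1L + rnbinom(cfg$n_species, mu = cfg$samples_mean - 1,
                      size = cfg$samples_dispersion)
    gene <- simulate_gene_tree(sp, cfg$coalescent_depth, k, seeds[d, 3L])
    aln <- evolve_sequences(gene$tree, cfg$subst_rate, cfg$seq_length,
                            seeds[d, 4L])
    set.seed(seeds[d, 5L])
    obs_len <- sample(seq(480L, 658L), length(aln), replace = TRUE)
    meta <- data.frame(id = names(aln),
                       dataset = sprintf("%s_%02d", cfg$clade, d),
                       clade = cfg$clade, habitat = cfg$habitat,
                       seq_length = obs_len)
    datasets[[d]] <- list(species_tree = sp, gene_tree = gene$tree,
                          alignment = aln, meta = meta,
                          truth = list(partition = gene$partition,
                                       r = cfg$r, eps = cfg$eps,
                                       samples_per_species = k))
  }
  names(datasets) <- vapply(datasets, function(x) x$meta$dataset[1L], "")
  structure(list(config = cfg, datasets = datasets),
            class = "scenario_bundle")
}

#' Write a scenario bundle to disk
#'
#' Layout: `<dir>/<dataset>/gene_tree.nwk`, `alignment.fasta`, `meta.tsv`,
#' `truth.json`.
#'
#' @param bundle A `scenario_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  for (nm in names(bundle$datasets)) {
    ds <- bundle$datasets[[nm]]
    sub <- file.path(dir, nm)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    ape::write.tree(ds$gene_tree, file.path(sub, "gene_tree.nwk"))
    write_fasta(ds$alignment, file.path(sub, "alignment.fasta"))
    utils::write.table(ds$meta, file.path(sub, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(ds$truth, file.path(sub, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
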