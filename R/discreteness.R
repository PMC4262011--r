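## Per-cluster discreteness metrics: intraspecific nucleotide diversity and
## TMRCA, interspecific nearest-neighbour raw and phylogenetic distances,
## and dataset-level sampling summaries.  Undefined quantities (singletons,
## single-species datasets) propagate as NA sentinels and are excluded from
## group statistics downstream.

species_sets <- function(partition) {
  attr(partition, "species_tips")
}

#' Within-cluster nucleotide diversity (pi)
#'
#' Unweighted mean of all within-cluster pairwise p-distances between unique
#' haplotypes.  With `weighted = TRUE` pairs are weighted by the product of
#' haplotype multiplicities (sequence-level pi).  Singletons are `NA`.
#'
#' @param partition A `species_partition`.
#' @param dm p-distance matrix whose labels cover the partition's tips.
#' @param multiplicity Optional named multiplicities (needed if `weighted`).
#' @param weighted Weight pairs by multiplicity products (default `FALSE`).
#' @return Named numeric vector, one value per species.
#' @export
cluster_pi <- function(partition, dm, multiplicity = NULL, weighted = FALSE) {
  sets <- species_sets(partition)
  miss <- setdiff(unlist(sets), rownames(dm))
  if (length(miss))
    stop_discretus("lookup_error",
                   sprintf("tips missing from distance matrix: %s",
                           paste(head(miss, 5L), collapse = ", ")))
  if (weighted && is.null(multiplicity))
    stop_discretus("domain_error", "weighted pi needs multiplicities")
  vapply(sets, function(tips) {
    k <- length(tips)
    if (k < 2L) return(NA_real_)
    sub <- dm[tips, tips, drop = FALSE]
    pairs <- sub[upper.tri(sub)]
    if (!weighted) return(mean(pairs))
    w <- outer(multiplicity[tips], multiplicity[tips])
    sum(w[upper.tri(w)] * pairs) / sum(w[upper.tri(w)])
  }, numeric(1))
}

#' Within-cluster TMRCA (basal node age)
#'
#' Age of the most recent common ancestor of the cluster's tips on the
#' ultrametric tree.  Singletons are `NA`.
#'
#' @param partition A `species_partition`.
#' @param tr The gene tree the partition was extracted from.
#' @return Named numeric vector of ages.
#' @export
cluster_tmrca <- function(partition, tr) {
  sets <- species_sets(partition)
  ages <- ape::branching.times(tr)
  vapply(sets, function(tips) {
    if (length(tips) < 2L) return(NA_real_)
    mrca <- ape::getMRCA(tr, tips)
    unname(ages[as.character(mrca)])
  }, numeric(1))
}

#' Nearest heterospecific neighbour distances
#'
#' For every species, the minimum raw p-distance to any tip of another
#' species (`nn_raw`) and the minimum patristic distance to such a tip
#' halved, i.e. the divergence time (`nn_phylo`).
#'
#' @param partition A `species_partition` with >= 2 species (otherwise `NA`
#'   with a warning).
#' @param dm p-distance matrix.
#' @param tr Gene tree (for patristic distances).
#' @return data.frame (`species`, `nn_raw`, `nn_phylo`).
#' @export
nearest_neighbor <- function(partition, dm, tr) {
  sets <- species_sets(partition)
  ids <- names(sets)
  if (length(sets) < 2L) {
    warn_discretus("single_species_warning",
                   "only one species: nearest-neighbour distances undefined")
    return(data.frame(species = ids, nn_raw = NA_real_, nn_phylo = NA_real_))
  }
  pm <- patristic_matrix(tr)
  res <- lapply(ids, function(id) {
    own <- sets[[id]]
    other <- setdiff(unlist(sets), own)
    data.frame(species = id,
               nn_raw = min(dm[own, other]),
               nn_phylo = min(pm[own, other]) / 2)
  })
  do.call(rbind, res)
}

#' Dataset-level sampling summary
#'
#' Per-dataset means of sequences and haplotypes per delimited species, the
#' proportion of singleton species, and the proportion of singletons that
#' are genuine single-sample specimens (multiplicity one) rather than
#' collapsed clones.
#'
#' @param partition A `species_partition`.
#' @param multiplicity Named integer vector of haplotype multiplicities.
#' @param meta Optional one-row metadata (list/data.frame with `dataset`,
#'   `clade`, `habitat`).
#' @return One-row data.frame.
#' @export
dataset_summary <- function(partition, multiplicity, meta = NULL) {
  sets <- species_sets(partition)
  n_haps <- lengths(sets)
  n_seqs <- vapply(sets, function(t) sum(multiplicity[t]), numeric(1))
  singles <- n_haps == 1L
  single_sample <- singles & n_seqs == 1L
  out <- data.frame(
    dataset = if (!is.null(meta)) meta$dataset[1L] else NA_character_,
    clade = if (!is.null(meta)) meta$clade[1L] else NA_character_,
    habitat = if (!is.null(meta)) meta$habitat[1L] else NA_character_,
    n_entities = length(sets),
    mean_sequences = mean(n_seqs),
    mean_haplotypes = mean(n_haps),
    singleton_prop = mean(singles),
    single_sample_singleton_prop =
      if (any(singles)) sum(single_sample) / sum(singles) else NA_real_)
  out
}

#' Tidy per-species discreteness table
#'
#' Assembles pi, TMRCA and nearest-neighbour metrics into one row per
#' species, annotated with dataset metadata when supplied.
#'
#' @param partition A `species_partition`.
#' @param dm p-distance matrix over the haplotypes.
#' @param tr Gene tree.
#' @param multiplicity Named multiplicities.
#' @param meta Optional metadata (as in [dataset_summary()]).
#' @return data.frame, one row per species.
#' @export
species_metrics <- function(partition, dm, tr, multiplicity, meta = NULL) {
  sets <- species_sets(partition)
  pi <- cluster_pi(partition, dm)
  tmrca <- cluster_tmrca(partition, tr)
  nn <- nearest_neighbor(partition, dm, tr)
  data.frame(
    dataset = if (!is.null(meta)) meta$dataset[1L] else NA_character_,
    clade = if (!is.null(meta)) meta$clade[1L] else NA_character_,
    habitat = if (!is.null(meta)) meta$habitat[1L] else NA_character_,
    species = names(sets),
    n_haplotypes = lengths(sets),
    n_sequences = vapply(sets, function(t) sum(multiplicity[t]), numeric(1)),
    pi = unname(pi),
    tmrca = unname(tmrca),
    nn_raw = nn$nn_raw[match(names(sets), nn$species)],
    nn_phylo = nn$nn_phylo[match(names(sets), nn$species)],
    row.names = NULL)
}
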