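## End-to-end convenience wrappers: one dataset (alignment + gene tree +
## metadata) through haplotype collapsing, GMYC delimitation, discreteness
## metrics and neutrality statistics; and the same over a whole scenario
## bundle.

#' Analyse one dataset end to end
#'
#' Collapses the alignment to unique haplotypes, prunes the gene tree to
#' the retained haplotypes, fits the GMYC, and computes per-species
#' discreteness metrics, the dataset sampling summary and (optionally)
#' neutrality statistics.
#'
#' @param gene_tree Ultrametric binary `phylo` over the sequence ids.
#' @param alignment Named character vector of aligned sequences.
#' @param meta Optional metadata data.frame (`dataset`, `clade`, `habitat`).
#' @param df LR-test df convention, passed to [fit_gmyc()].
#' @param neutrality Also compute per-species neutrality statistics.
#' @return List: `haplotypes`, `tree` (pruned), `fit`, `partition`,
#'   `metrics`, `summary`, and `neutrality` (or `NULL`).
#' @export
analyze_dataset <- function(gene_tree, alignment, meta = NULL, df = 3L,
                            neutrality = TRUE) {
  check_tip_join(gene_tree, alignment)
  haps <- collapse_haplotypes(alignment[gene_tree$tip.label])
  tr <- if (length(haps$seqs) < ape::Ntip(gene_tree))
    ape::keep.tip(gene_tree, names(haps$seqs)) else gene_tree
  fit <- fit_gmyc(tr, df = df)
  dm <- p_distance_matrix(haps$seqs)
  metrics <- species_metrics(fit$partition, dm, tr, haps$multiplicity, meta)
  summ <- dataset_summary(fit$partition, haps$multiplicity, meta)
  neut <- if (neutrality) neutrality_by_species(fit$partition, haps) else NULL
  list(haplotypes = haps, tree = tr, fit = fit, partition = fit$partition,
       metrics = metrics, summary = summ, neutrality = neut)
}

#' Analyse every dataset of a scenario bundle
#'
#' @param bundle A `scenario_bundle` from [make_scenario()].
#' @param df LR-test df convention.
#' @param neutrality Compute neutrality statistics per species.
#' @return List with `results` (per dataset), `metrics` (row-bound, with a
#'   `group` column = clade) and `summaries`.
#' @export
run_pipeline <- function(bundle, df = 3L, neutrality = FALSE) {
  results <- lapply(bundle$datasets, function(ds)
    analyze_dataset(ds$gene_tree, ds$alignment, ds$meta, df = df,
                    neutrality = neutrality))
  metrics <- do.call(rbind, lapply(results, `[[`, "metrics"))
  metrics$group <- metrics$clade
  summaries <- do.call(rbind, lapply(results, `[[`, "summary"))
  rownames(metrics) <- rownames(summaries) <- NULL
  list(results = results, metrics = metrics, summaries = summaries)
}
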