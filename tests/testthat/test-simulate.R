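test_that("birth-death simulation meets its structural contract", {
  for (seed in 1:5) {
    tr <- simulate_bd_tree(0.072, 0, 20, seed)
    expect_identical(ape::Ntip(tr), 20L)
    expect_true(ape::is.binary(tr))
    expect_true(ape::is.ultrametric(tr))
  }
  expect_identical(ape::write.tree(simulate_bd_tree(0.05, 0.3, 15, 7)),
                   ape::write.tree(simulate_bd_tree(0.05, 0.3, 15, 7)))
  expect_error(simulate_bd_tree(-1, 0, 5, 1), class = "domain_error")
})

test_that("one sample per species returns the species tree itself", {
  sp <- simulate_bd_tree(0.1, 0, 6, seed = 3)
  sp$tip.label <- paste0("sp", 1:6)
  g <- simulate_gene_tree(sp, 0.5, 1, seed = 4)
  expect_identical(ape::Ntip(g$tree), 6L)
  expect_identical(sort(g$tree$tip.label), sort(paste0(sp$tip.label, "_1")))
  # identical branching structure
  expect_equal(sort(as.numeric(ape::branching.times(g$tree))),
               sort(as.numeric(ape::branching.times(sp))), tolerance = 1e-9)
  expect_identical(g$partition$species, sub("_1$", "", g$partition$tip))
})

test_that("within-species TMRCA follows the Kingman expectation", {
  # species tree with one deep split so stems never bind at depth 0.05
  sp <- read_newick(text = "(A:60,B:60);")
  k <- 10
  depth <- 0.05
  tm <- sapply(1:400, function(i) {
    g <- simulate_gene_tree(sp, depth, c(k, 1), seed = 5000 + i)
    tips <- g$partition$tip[g$partition$species == "A"]
    max(patristic_matrix(ape::keep.tip(g$tree, tips))) / 2
  })
  expect_equal(mean(tm) / depth, 1 - 1 / k, tolerance = 0.05)
})

test_that("gene trees stay valid and carry the true partition", {
  sp <- simulate_bd_tree(0.08, 0.1, 8, seed = 10)
  sp$tip.label <- paste0("sp", 1:8)
  g <- suppressWarnings(simulate_gene_tree(sp, 0.3, c(3, 1, 5, 2, 1, 4, 2, 6),
                                           seed = 11))
  expect_silent(validate_ultrametric(g$tree))
  expect_identical(ape::Ntip(g$tree), 24L)
  expect_identical(nrow(g$partition), 24L)
  expect_setequal(unique(g$partition$species), sp$tip.label)
})

test_that("sequence evolution honours rate limits and determinism", {
  g <- make_clustered_tree(3, 4, seed = 20)
  a0 <- evolve_sequences(g$tree, 1e-9, 100, seed = 21)
  expect_identical(length(unique(a0)), 1L)  # rate -> 0: all identical
  a1 <- evolve_sequences(g$tree, 0.01, 200, seed = 22)
  a2 <- evolve_sequences(g$tree, 0.01, 200, seed = 22)
  expect_identical(a1, a2)
  expect_identical(unique(nchar(a1)), 200L)
})

test_that("mean p-distance follows the Jukes-Cantor closed form", {
  two <- read_newick(text = "(x:5,y:5);")
  rate <- 0.004
  d_pat <- 10
  expected <- 0.75 * (1 - exp(-4 / 3 * rate * d_pat))
  obs <- sapply(1:400, function(i) {
    a <- evolve_sequences(two, rate, 300, seed = 7000 + i)
    p_distance_matrix(a)["x", "y"]
  })
  expect_equal(mean(obs), expected, tolerance = 0.01)
})

test_that("scenario bundles are deterministic and self-consistent", {
  b1 <- make_scenario("asexual_like", overrides = list(n_datasets = 2L),
                      seed = 5)
  b2 <- make_scenario("asexual_like", overrides = list(n_datasets = 2L),
                      seed = 5)
  expect_identical(lapply(b1$datasets, `[[`, "alignment"),
                   lapply(b2$datasets, `[[`, "alignment"))
  expect_identical(ape::write.tree(b1$datasets[[1]]$gene_tree),
                   ape::write.tree(b2$datasets[[1]]$gene_tree))
  for (ds in b1$datasets) {
    expect_silent(validate_ultrametric(ds$gene_tree))
    expect_true(check_tip_join(ds$gene_tree, ds$alignment))
    expect_identical(nrow(ds$meta), length(ds$alignment))
  }
})

test_that("generated sampling matches the preset targets", {
  # truth-level samples per species, pooled over datasets
  # 30 datasets give ~360 negative-binomial draws, enough to hold the
  # ensemble mean within the 15% self-consistency band
  mean_k <- function(preset, target, seed) {
    b <- suppressWarnings(
      make_scenario(preset, overrides = list(n_datasets = 30L), seed = seed))
    ks <- unlist(lapply(b$datasets,
                        function(d) d$truth$samples_per_species))
    mean(ks) / target
  }
  expect_lt(abs(mean_k("asexual_like", 5.63, 31) - 1), 0.15)
  expect_lt(abs(mean_k("sexual_like", 16.4, 32) - 1), 0.15)
})

test_that("the clonal preset yields more singletons than the sexual one", {
  pa <- suppressWarnings(run_pipeline(
    make_scenario("asexual_like", overrides = list(n_datasets = 3L),
                  seed = 41)))
  ps <- suppressWarnings(run_pipeline(
    make_scenario("sexual_like", overrides = list(n_datasets = 3L),
                  seed = 42)))
  expect_gt(mean(pa$summaries$singleton_prop),
            mean(ps$summaries$singleton_prop))
})

test_that("scenario bundles round-trip through the disk layout", {
  b <- make_scenario("sexual_like",
                     overrides = list(n_datasets = 1L, n_species = 6L),
                     seed = 77)
  dir <- withr::local_tempdir()
  write_scenario(b, dir)
  ds <- names(b$datasets)[1]
  tr <- read_newick(file.path(dir, ds, "gene_tree.nwk"))
  aln <- read_fasta(file.path(dir, ds, "alignment.fasta"))
  meta <- read_metadata(file.path(dir, ds, "meta.tsv"))
  expect_true(check_tip_join(tr, aln))
  expect_setequal(meta$id, names(aln))
  truth <- jsonlite::read_json(file.path(dir, ds, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$r, 0.048)
})
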