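# Shared fixture: a clustered gene tree with haplotype-level alignment.
local_discreteness_fixture <- function(seed = 77) {
  g <- make_clustered_tree(5, 6, stem_min = 8, crown = 0.2, seed = seed)
  aln <- evolve_sequences(g$tree, subst_rate = 0.01, seq_length = 500,
                          seed = seed + 2)
  fit <- fit_gmyc(g$tree)
  list(tree = g$tree, truth = g$partition, fit = fit,
       partition = fit$partition, dm = p_distance_matrix(aln),
       mult = setNames(rep(1L, length(aln)), names(aln)))
}

test_that("cluster pi is the unweighted mean of within-cluster distances", {
  dm <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dm["a", "b"] <- dm["b", "a"] <- 0.01
  dm["a", "c"] <- dm["c", "a"] <- 0.01
  dm["b", "c"] <- dm["c", "b"] <- 0.02
  part <- structure(data.frame(), species_tips = list(sp1 = c("a", "b", "c")))
  expect_equal(unname(cluster_pi(part, dm)), mean(c(0.01, 0.01, 0.02)))

  part2 <- structure(data.frame(),
                     species_tips = list(sp1 = c("a", "b"), sp2 = "c"))
  pi2 <- cluster_pi(part2, dm)
  expect_true(is.na(pi2["sp2"]))  # singleton -> undefined sentinel
  expect_error(cluster_pi(structure(data.frame(),
                                    species_tips = list(sp1 = "zz")), dm),
               class = "lookup_error")
})

test_that("cluster pi equals a brute-force double loop", {
  fx <- local_discreteness_fixture()
  pi <- cluster_pi(fx$partition, fx$dm)
  for (id in names(attr(fx$partition, "species_tips"))) {
    tips <- attr(fx$partition, "species_tips")[[id]]
    if (length(tips) < 2) next
    acc <- c()
    for (i in seq_along(tips)) for (j in seq_along(tips))
      if (i < j) acc <- c(acc, fx$dm[tips[i], tips[j]])
    expect_equal(unname(pi[id]), mean(acc))
  }
  expect_true(all(pi[!is.na(pi)] <= max(fx$dm)))
})

test_that("cluster TMRCA is the basal node age", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  part <- structure(data.frame(),
                    species_tips = list(sp1 = c("A", "B"), sp2 = "C"))
  tm <- cluster_tmrca(part, tr)
  expect_equal(unname(tm["sp1"]), 1)
  expect_true(is.na(tm["sp2"]))
  whole <- structure(data.frame(),
                     species_tips = list(sp1 = c("A", "B", "C")))
  expect_equal(unname(cluster_tmrca(whole, tr)), 2)

  # brute-force oracle on a simulated fixture
  fx <- local_discreteness_fixture(81)
  tm <- cluster_tmrca(fx$partition, fx$tree)
  pm <- patristic_matrix(fx$tree)
  for (id in names(tm)) {
    tips <- attr(fx$partition, "species_tips")[[id]]
    if (length(tips) < 2) next
    expect_equal(unname(tm[id]), max(pm[tips, tips]) / 2, tolerance = 1e-8)
  }
})

test_that("TMRCA is monotone under cluster merging", {
  fx <- local_discreteness_fixture(83)
  sets <- attr(fx$partition, "species_tips")
  multi <- names(sets)[lengths(sets) >= 2]
  a <- multi[1]; b <- multi[2]
  merged <- structure(data.frame(),
                      species_tips = list(ab = c(sets[[a]], sets[[b]])))
  tm <- cluster_tmrca(fx$partition, fx$tree)
  expect_gte(unname(cluster_tmrca(merged, fx$tree)),
             max(tm[a], tm[b]))
})

test_that("nearest neighbours use tip-level minima and halved patristics", {
  tr <- read_newick(text = "((A:1,B:1):4,(C:2,D:2):3);")
  dm <- p_distance_matrix(c(A = "AAAA", B = "AAAT", C = "TTTT", D = "TTTA"))
  part <- structure(data.frame(),
                    species_tips = list(sp1 = c("A", "B"), sp2 = c("C", "D")))
  nn <- nearest_neighbor(part, dm, tr)
  expect_equal(nn$nn_phylo, c(5, 5))  # MRCA age of the two clusters
  expect_equal(nn$nn_raw[1], nn$nn_raw[2])  # same minimizing pair

  single <- structure(data.frame(), species_tips = list(sp1 = c("A", "B")))
  expect_warning(nn1 <- nearest_neighbor(single, dm, tr),
                 class = "single_species_warning")
  expect_true(all(is.na(nn1$nn_raw)))
})

test_that("nearest neighbours match an exhaustive pair scan", {
  fx <- local_discreteness_fixture(85)
  nn <- nearest_neighbor(fx$partition, fx$dm, fx$tree)
  pm <- patristic_matrix(fx$tree)
  sets <- attr(fx$partition, "species_tips")
  ages <- ape::branching.times(fx$tree)
  for (k in seq_along(sets)) {
    own <- sets[[k]]
    other <- setdiff(unlist(sets), own)
    best_raw <- Inf; best_ph <- Inf; best_mrca <- Inf
    for (i in own) for (j in other) {
      best_raw <- min(best_raw, fx$dm[i, j])
      best_ph <- min(best_ph, pm[i, j] / 2)
      best_mrca <- min(best_mrca,
                       ages[as.character(ape::getMRCA(fx$tree, c(i, j)))])
    }
    row <- nn[nn$species == names(sets)[k], ]
    expect_equal(row$nn_raw, best_raw)
    expect_equal(row$nn_phylo, best_ph)
    # ultrametric identity: halved patristic = MRCA age
    expect_equal(row$nn_phylo, unname(best_mrca), tolerance = 1e-8)
  }
})

test_that("dataset summaries count singletons and clones correctly", {
  mult <- c(a = 1L, b = 1L, c = 1L)
  all_single <- structure(data.frame(),
                          species_tips = list(s1 = "a", s2 = "b", s3 = "c"))
  ds <- dataset_summary(all_single, mult)
  expect_equal(ds$singleton_prop, 1)
  expect_equal(ds$single_sample_singleton_prop, 1)

  one_cluster <- structure(data.frame(),
                           species_tips = list(s1 = c("a", "b", "c")))
  expect_equal(dataset_summary(one_cluster, mult)$singleton_prop, 0)

  # a clonal singleton (multiplicity > 1) is not a single-sample singleton
  mult2 <- c(a = 5L, b = 1L)
  two <- structure(data.frame(), species_tips = list(s1 = "a", s2 = "b"))
  ds2 <- dataset_summary(two, mult2)
  expect_equal(ds2$singleton_prop, 1)
  expect_equal(ds2$single_sample_singleton_prop, 0.5)
  expect_equal(ds2$mean_sequences, 3)
})

test_that("species_metrics assembles one coherent row per species", {
  fx <- local_discreteness_fixture(87)
  tab <- species_metrics(fx$partition, fx$dm, fx$tree, fx$mult,
                         meta = data.frame(dataset = "d1", clade = "asexual",
                                           habitat = "limnoterrestrial"))
  expect_identical(nrow(tab), length(attr(fx$partition, "species_tips")))
  expect_true(all(is.na(tab$pi) == (tab$n_haplotypes == 1)))
  expect_true(all(tab$nn_phylo > 0))
  expect_identical(unique(tab$dataset), "d1")
})
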