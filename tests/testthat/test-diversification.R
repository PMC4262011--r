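test_that("pruning keeps the longest sequence per species", {
  g <- make_clustered_tree(4, 5, seed = 11)
  fit <- fit_gmyc(g$tree)
  tips <- g$tree$tip.label
  set.seed(1)
  lens <- setNames(sample(400:650, length(tips)), tips)
  sp <- prune_to_species(g$tree, fit$partition, lens)
  expect_identical(ape::Ntip(sp), fit$n_entities)
  expect_true(ape::is.ultrametric(sp))
  expect_true(ape::is.binary(sp))
  prov <- attr(sp, "provenance")
  for (id in names(prov)) {
    members <- attr(fit$partition, "species_tips")[[id]]
    expect_identical(unname(lens[prov[id]]), max(lens[members]))
  }
  # between-cluster node ages survive pruning
  full_ages <- sort(ape::branching.times(g$tree), decreasing = TRUE)[1:3]
  pruned_ages <- sort(ape::branching.times(sp), decreasing = TRUE)[1:3]
  expect_equal(unname(pruned_ages), unname(full_ages), tolerance = 1e-8)

  # all-singleton partition: tree unchanged except tip renaming
  part1 <- extract_partition(g$tree, min(ape::branching.times(g$tree)) / 2)
  sp1 <- prune_to_species(g$tree, part1, lens)
  expect_identical(ape::Ntip(sp1), length(tips))

  # ties resolve to the lexicographically smallest id, stably
  lens2 <- setNames(rep(500, length(tips)), tips)
  a <- attr(prune_to_species(g$tree, fit$partition, lens2), "provenance")
  b <- attr(prune_to_species(g$tree, fit$partition, lens2), "provenance")
  expect_identical(a, b)
  expect_identical(unname(a),
                   unname(vapply(attr(fit$partition, "species_tips"),
                                 function(t) sort(t)[1], "")))
  expect_error(prune_to_species(g$tree, fit$partition, lens[-1]),
               class = "metadata_error")
})

test_that("birth-death log-likelihood matches oracles and pools additively", {
  set.seed(5)
  t1 <- ape::rphylo(25, 0.15, 0.05)
  t2 <- ape::rphylo(15, 0.1, 0)
  for (par in list(c(0.1, 0), c(0.08, 0.3), c(0.2, 0.7))) {
    expect_equal(bd_loglik(t1, par[1], par[2]),
                 naive_bd_loglik(t1, par[1], par[2]), tolerance = 1e-10)
  }
  expect_equal(bd_loglik(list(t1), 0.1, 0.2), bd_loglik(t1, 0.1, 0.2))
  expect_equal(bd_loglik(list(t1, t2), 0.1, 0.2),
               bd_loglik(t1, 0.1, 0.2) + bd_loglik(t2, 0.1, 0.2))
  expect_error(bd_loglik(t1, -1, 0), class = "domain_error")
  expect_error(bd_loglik(ape::rcoal(2), 1, 0),
               class = "insufficient_data_error")
})

test_that("bd_fit agrees with the reference implementation", {
  set.seed(9)
  tr <- ape::rphylo(40, 0.15, 0.05)
  ours <- bd_fit(tr)
  ref <- ape::birthdeath(tr)
  expect_equal(ours$r_hat, unname(ref$para[2]), tolerance = 1e-4)
  expect_equal(-2 * ours$loglik, unname(ref$dev), tolerance = 1e-6)
  expect_equal(ours$deviance, -2 * ours$loglik)
  # pure-birth data pushed to the eps boundary
  set.seed(10)
  yule <- ape::rphylo(60, 0.1, 0)
  fy <- bd_fit(yule)
  expect_lt(fy$eps_hat, 0.2)
})

test_that("the pooled-vs-separate LR test reproduces the worked example", {
  lr <- lr_pooled_vs_separate(loglik_separate = c(-84.35, -164.53),
                              loglik_global = -254.51)
  expect_equal(lr$chi2, 11.26, tolerance = 1e-10)
  expect_identical(lr$df, 2L)
  one <- lr_pooled_vs_separate(loglik_separate = -10, loglik_global = -10)
  expect_identical(one$df, 0L)
  expect_equal(one$chi2, 0)
})

test_that("gamma matches the reference and its own closed form", {
  # 3-tip worked example, evaluated through the internal kernel since the
  # public function guards n >= 4: g2 = g3 = 1 gives gamma = -0.3464
  expect_equal(discretus:::gamma_from_times(c(2, 1)),
               (2 - 2.5) / (5 * sqrt(1 / 12)), tolerance = 1e-10)
  expect_error(gamma_statistic(ape::rcoal(3)),
               class = "insufficient_data_error")
  set.seed(12)
  for (i in 1:5) {
    tr <- ape::rphylo(sample(8:60, 1), 1, 0)
    expect_equal(gamma_statistic(tr), ape::gammaStat(tr), tolerance = 1e-10)
    sc <- tr
    sc$edge.length <- sc$edge.length * runif(1, 0.1, 30)
    expect_equal(gamma_statistic(sc), gamma_statistic(tr), tolerance = 1e-8)
  }
})

test_that("MCCR test is deterministic and reacts to pruning", {
  m1 <- mccr_test(-1, n_sampled = 20, n_total = 20, reps = 150, seed = 42)
  m2 <- mccr_test(-1, n_sampled = 20, n_total = 20, reps = 150, seed = 42)
  expect_identical(m1$mccr_p, m2$mccr_p)
  expect_identical(m1$null_gamma, m2$null_gamma)
  m3 <- mccr_test(-1, n_sampled = 20, n_total = 40, reps = 150, seed = 42)
  expect_lt(mean(m3$null_gamma), 0)  # undersampling biases gamma down
  expect_lt(mean(m3$null_gamma), mean(m1$null_gamma))
  expect_error(mccr_test(-1, 10, 5), class = "domain_error")
  expect_error(mccr_test(-1, 10, 20, reps = 10), class = "domain_error")
})

test_that("missing-species imputation is structurally sound", {
  set.seed(30)
  tr <- ape::rphylo(20, 1, 0)
  id <- corsim_impute(tr, 0, reps = 5, seed = 1)
  expect_equal(id$corsim_gamma_mean, gamma_statistic(tr))
  ci <- corsim_impute(tr, 7, reps = 8, seed = 2)
  for (ct in ci$trees) {
    expect_identical(ape::Ntip(ct), 27L)
    expect_true(ape::is.ultrametric(ct, tol = 1e-6))
    expect_true(ape::is.binary(ct))
    # crown age unchanged by grafting
    expect_equal(max(ape::branching.times(ct)),
                 max(ape::branching.times(tr)), tolerance = 1e-8)
  }
  expect_error(corsim_impute(tr, -1), class = "domain_error")
})

test_that("imputation pulls the pruning artefact in gamma towards zero", {
  set.seed(31)
  res <- t(sapply(1:8, function(i) {
    tr <- ape::rphylo(50, 1, 0)
    pr <- ape::keep.tip(tr, sample(tr$tip.label, 25))
    ci <- corsim_impute(pr, 25, reps = 15, seed = 100 + i)
    c(pruned = gamma_statistic(pr), corsim = ci$corsim_gamma_mean)
  }))
  expect_gt(mean(res[, "corsim"]), mean(res[, "pruned"]))
})

test_that("ltt table tracks lineage counts", {
  set.seed(3)
  tr <- ape::rphylo(12, 1, 0)
  lt <- ltt_table(tr)
  expect_identical(nrow(lt), 11L)
  expect_identical(lt$n_lineages, 2:12)
  expect_true(all(diff(lt$time_before_present) <= 0))
})
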