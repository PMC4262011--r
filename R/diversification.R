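## Species-tree macroevolution: pruning gene trees to one tip per delimited
## species, birth-death maximum likelihood on pooled branching times with a
## likelihood-ratio comparison of separate vs. global rates, the gamma
## statistic, and two under-sampling corrections (MCCR post hoc, and a
## missing-species imputation in the spirit of CorSiM a priori).

#' Prune a gene tree to one tip per delimited species
#'
#' The retained tip is the one with the longest sequence; ties resolve to
#' the lexicographically smallest tip id.  Tips are renamed to species ids
#' and the provenance map is kept as an attribute.
#'
#' @param tr Gene tree (`phylo`).
#' @param partition A `species_partition` extracted from `tr`.
#' @param seq_lengths Named numeric vector of sequence lengths per tip.
#' @return `phylo` with one tip per species; attribute `provenance` maps
#'   species id to the retained haplotype id.
#' @export
prune_to_species <- function(tr, partition, seq_lengths) {
  sets <- attr(partition, "species_tips")
  miss <- setdiff(unlist(sets), names(seq_lengths))
  if (length(miss))
    stop_discretus("metadata_error",
                   sprintf("sequence length missing for tip(s): %s",
                           paste(head(miss, 5L), collapse = ", ")))
  keep <- vapply(sets, function(tips) {
    tips <- sort(tips)  # lexicographic tie-break
    tips[which.max(seq_lengths[tips])]
  }, character(1))
  out <- ape::keep.tip(tr, unname(keep))
  out$tip.label <- names(keep)[match(out$tip.label, keep)]
  attr(out, "provenance") <- keep
  out
}

## Nee et al. reconstructed-process log-likelihood of one tree's branching
## times, conditioned on the crown age and survival of both crown lineages.
## t = branching times sorted decreasing, t[1] = crown age; r = lambda - mu,
## a = mu / lambda.
bd_loglik_one <- function(t, r, a) {
  N <- length(t) + 1L  # tips
  lfactorial(N - 1L) + (N - 2L) * log(r) + r * sum(t[-1L]) +
    N * log(1 - a) - 2 * sum(log(exp(r * t) - a))
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) list(trees)
  else if (inherits(trees, "multiPhylo") || is.list(trees)) trees
  else stop_discretus("type_error", "expected a phylo or a list of them")
}

#' Pooled birth-death log-likelihood
#'
#' Sum over trees of the reconstructed-process likelihood of branching
#' times, conditioned on each tree's crown age and survival of both crown
#' lineages, at shared net diversification `r = lambda - mu` and extinction
#' fraction `eps = mu / lambda`.
#'
#' @param trees A `phylo` or list of them (each >= 3 tips).
#' @param r Net diversification rate (> 0).
#' @param eps Extinction fraction in `[0, 1)`.
#' @return Log-likelihood.
#' @export
bd_loglik <- function(trees, r, eps) {
  if (r <= 0 || eps < 0 || eps >= 1)
    stop_discretus("domain_error", "need r > 0 and 0 <= eps < 1")
  trees <- as_tree_list(trees)
  if (any(vapply(trees, ape::Ntip, integer(1)) < 3L))
    stop_discretus("insufficient_data_error",
                   "each tree needs >= 3 tips for a birth-death fit")
  sum(vapply(trees, function(tr) {
    t <- sort(as.numeric(ape::branching.times(tr)), decreasing = TRUE)
    bd_loglik_one(t, r, eps)
  }, numeric(1)))
}

#' Maximum-likelihood birth-death fit
#'
#' Optimizes `(log r, logit eps)` by bounded quasi-Newton from three
#' deterministic starts; the standard error of `r_hat` comes from the
#' numerical observed information.  An optimum with `eps` at the zero
#' boundary is reported as pure birth (`pure_birth = TRUE`).
#'
#' @param trees A `phylo` or list of them.
#' @param pooled If `TRUE` (default) one `(r, eps)` is fitted to all trees
#'   jointly; if `FALSE` a list of single-tree fits is returned.
#' @return Object of class `bd_fit` (or list of them): `r_hat`, `eps_hat`,
#'   `loglik`, `deviance` (= -2 loglik), `se_r`, `n_tips`, `n_trees`,
#'   `pure_birth`.
#' @export
bd_fit <- function(trees, pooled = TRUE) {
  trees <- as_tree_list(trees)
  if (!pooled && length(trees) > 1L)
    return(lapply(trees, bd_fit, pooled = TRUE))
  bts <- lapply(trees, function(tr)
    sort(as.numeric(ape::branching.times(tr)), decreasing = TRUE))
  if (any(lengths(bts) < 2L))
    stop_discretus("insufficient_data_error",
                   "each tree needs >= 3 tips for a birth-death fit")
  nll <- function(par) {
    r <- exp(par[1L]); a <- plogis(par[2L])
    v <- -sum(vapply(bts, bd_loglik_one, numeric(1), r = r, a = a))
    if (!is.finite(v)) 1e10 else v
  }
  ## crude pure-birth rate to centre the starts
  r0 <- sum(lengths(bts) - 1L) / sum(vapply(bts, sum, numeric(1)))
  starts <- list(c(log(r0), qlogis(1e-4)),
                 c(log(r0), qlogis(0.5)),
                 c(log(r0 / 4), qlogis(0.9)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, nll, method = "L-BFGS-B",
            lower = c(log(r0) - 10, -16), upper = c(log(r0) + 10, 6),
            control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    stop_discretus("fit_error", "birth-death optimization failed to converge")
  r_hat <- exp(best$par[1L])
  eps_hat <- plogis(best$par[2L])
  pure_birth <- eps_hat < 1e-5
  ll <- -best$value
  se_r <- bd_se_r(bts, r_hat, eps_hat, pure_birth)
  structure(list(r_hat = r_hat, eps_hat = eps_hat, loglik = ll,
                 deviance = -2 * ll, se_r = se_r,
                 n_tips = sum(lengths(bts) + 1L), n_trees = length(bts),
                 pure_birth = pure_birth),
            class = "bd_fit")
}

## observed-information standard error of r; drops to a 1-D curvature when
## eps sits on the boundary
bd_se_r <- function(bts, r, a, boundary) {
  f <- function(r_, a_) sum(vapply(bts, bd_loglik_one, numeric(1),
                                   r = r_, a = a_))
  hr <- r * 1e-4
  if (boundary || a < 1e-5) {
    d2 <- (f(r + hr, a) - 2 * f(r, a) + f(r - hr, a)) / hr^2
    return(if (d2 < 0) sqrt(-1 / d2) else NA_real_)
  }
  ha <- min(a, 1 - a) * 1e-4
  H <- matrix(NA_real_, 2L, 2L)
  H[1L, 1L] <- (f(r + hr, a) - 2 * f(r, a) + f(r - hr, a)) / hr^2
  H[2L, 2L] <- (f(r, a + ha) - 2 * f(r, a) + f(r, a - ha)) / ha^2
  H[1L, 2L] <- H[2L, 1L] <-
    (f(r + hr, a + ha) - f(r + hr, a - ha) -
       f(r - hr, a + ha) + f(r - hr, a - ha)) / (4 * hr * ha)
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V) || V[1L, 1L] <= 0) NA_real_ else sqrt(V[1L, 1L])
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf(
    "birth-death fit: r = %.4g (se %.3g), eps = %.3g%s, loglik = %.4f (%d trees, %d tips)\n",
    x$r_hat, x$se_r, x$eps_hat, if (x$pure_birth) " [pure birth]" else "",
    x$loglik, x$n_trees, x$n_tips))
  invisible(x)
}

#' Likelihood-ratio test of separate vs. global diversification rates
#'
#' Compares separately parameterized `(r, eps)` per group against a single
#' global pair fitted to all trees: `chi2 = 2 (sum of separate logliks -
#' global loglik)`, `df = 2 (n_groups - 1)`.  Alternatively the test can be
#' computed directly from known log-likelihoods.
#'
#' @param group_trees Named list: group -> tree or list of trees.  Ignored
#'   when `loglik_separate` is given.
#' @param loglik_separate Optional numeric vector of per-group logliks.
#' @param loglik_global Optional global loglik.
#' @return List with `chi2`, `df`, `p`, and (when fitted from trees) the
#'   per-group and global `bd_fit` objects.
#' @export
lr_pooled_vs_separate <- function(group_trees = NULL,
                                  loglik_separate = NULL,
                                  loglik_global = NULL) {
  fits <- NULL
  if (is.null(loglik_separate)) {
    if (length(group_trees) < 1L)
      stop_discretus("domain_error", "need at least one group")
    fits <- lapply(group_trees, bd_fit)
    global <- bd_fit(unlist(lapply(group_trees, as_tree_list),
                            recursive = FALSE))
    loglik_separate <- vapply(fits, `[[`, numeric(1), "loglik")
    loglik_global <- global$loglik
  }
  g <- length(loglik_separate)
  chi2 <- 2 * (sum(loglik_separate) - loglik_global)
  if (g == 1L) chi2 <- 0
  if (chi2 < -1e-6)
    stop_discretus("fit_error",
                   "separate fits worse than global: optimizer failure")
  chi2 <- max(chi2, 0)
  df <- 2L * (g - 1L)
  out <- list(chi2 = chi2, df = df,
              p = if (df > 0L) pchisq(chi2, df, lower.tail = FALSE)
                  else NA_real_)
  if (!is.null(fits)) {
    out$separate <- fits
    out$global <- global
  }
  out
}

#' The gamma statistic of node-time constancy
#'
#' Standardized contrast between observed internal node positions and those
#' expected under a constant-rate model; negative values indicate an early
#' burst / slowdown (or under-sampling), positive values a late
#' acceleration or high background extinction.
#'
#' @param tr Ultrametric `phylo` with >= 4 tips.
#' @return gamma (numeric scalar).
#' @export
gamma_statistic <- function(tr) {
  if (ape::Ntip(tr) < 4L)
    stop_discretus("insufficient_data_error",
                   "gamma needs >= 4 tips")
  gamma_from_times(sort(as.numeric(ape::branching.times(tr)),
                        decreasing = TRUE))
}

## t: branching times sorted decreasing (t[1] = crown age); n tips = len + 1
gamma_from_times <- function(t) {
  n <- length(t) + 1L
  bounds <- c(t, 0)
  g <- bounds[-length(bounds)] - bounds[-1L]   # g_k, k = 2..n lineages
  Tk <- cumsum((2:n) * g)                      # T_2 .. T_n
  Ttot <- Tk[n - 1L]
  (mean(Tk[1:(n - 2L)]) - Ttot / 2) / (Ttot * sqrt(1 / (12 * (n - 2L))))
}

#' Monte Carlo constant-rates (MCCR) test for incomplete sampling
#'
#' Simulates complete pure-birth trees of the true richness `n_total`,
#' prunes each to a uniform random subset of `n_sampled` tips, and compares
#' the observed gamma with the resulting null distribution.
#'
#' @param gamma_obs Observed gamma.
#' @param n_sampled Number of sampled species (>= 4).
#' @param n_total True species richness (`>= n_sampled`).  Ideally supplied
#'   from an external richness estimate; the default is the documented
#'   fallback of twice the sampled richness.
#' @param reps Null replicates (>= 100).
#' @param seed Integer seed.
#' @return List with `mccr_p` (one-tailed: proportion of null gamma <=
#'   observed), `mccr_crit` (5th percentile of the null) and `null_gamma`.
#' @export
mccr_test <- function(gamma_obs, n_sampled, n_total = 2L * n_sampled,
                      reps = 1000L, seed = 1L) {
  if (n_sampled < 4L || n_total < n_sampled)
    stop_discretus("domain_error", "need n_total >= n_sampled >= 4")
  if (reps < 100L)
    stop_discretus("domain_error", "need reps >= 100")
  seeds <- derive_seeds(seed, reps)
  null_gamma <- vapply(seq_len(reps), function(i) {
    set.seed(seeds[i])
    tr <- ape::rphylo(n_total, birth = 1, death = 0)
    if (n_sampled < n_total)
      tr <- ape::keep.tip(tr, sample(tr$tip.label, n_sampled))
    gamma_statistic(tr)
  }, numeric(1))
  list(mccr_p = mean(null_gamma <= gamma_obs),
       mccr_crit = unname(quantile(null_gamma, 0.05)),
       null_gamma = null_gamma)
}

## Branching times of a rho-sampled reconstructed birth-death tree form a
## coalescent point process whose node-depth CDF is
##   H(t) = c (1 - e^{-rt}) / (c (1 - e^{-rt}) + r e^{-rt}),  c = rho * lambda,
## with density h(t) = c r^2 e^{-rt} / (c (1 - e^{-rt}) + r e^{-rt})^2.
## Fitting (r, c) under the known sampling fraction gives rate estimates
## that are unbiased by the missing species - essential before imputing
## their speciation times.
cpp_sampled_fit <- function(bt, rho) {
  Tc <- bt[1L]
  xs <- bt[-1L]
  ll <- function(r, cc) {
    H <- function(t) {
      em <- exp(-r * t)
      cc * (1 - em) / (cc * (1 - em) + r * em)
    }
    em <- exp(-r * xs)
    den <- cc * (1 - em) + r * em
    sum(log(cc) + 2 * log(r) - r * xs - 2 * log(den)) -
      length(xs) * log(H(Tc))
  }
  r0 <- (length(bt) - 1L) / sum(bt)
  obj <- function(par) {
    v <- ll(exp(par[1L]), exp(par[2L]))
    if (!is.finite(v)) -1e10 else v
  }
  best <- NULL
  for (s in list(c(log(r0), log(r0 * rho)),
                 c(log(r0 * 3), log(r0)),
                 c(log(r0 / 3), log(r0 * rho / 3)))) {
    o <- tryCatch(optim(s, obj, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value > best$value)) best <- o
  }
  if (is.null(best))
    stop_discretus("fit_error", "sampled birth-death fit failed")
  r <- exp(best$par[1L])
  lambda <- exp(best$par[2L]) / rho
  eps <- max(0, min(0.95, 1 - r / lambda))
  list(r = r, eps = eps, lambda = lambda)
}

## Attach a new pendant tip at age `t` on a uniformly chosen lineage alive
## at that time.  Pure edge surgery; the result is re-validated by callers.
graft_tip <- function(tr, t, label) {
  nt <- ape::Ntip(tr)
  nn <- tr$Nnode
  age <- numeric(nt + nn)
  age[as.integer(names(ape::branching.times(tr)))] <-
    as.numeric(ape::branching.times(tr))
  pa <- age[tr$edge[, 1L]]
  ca <- age[tr$edge[, 2L]]
  cand <- which(pa > t & ca <= t)
  if (!length(cand))
    stop_discretus("domain_error", "no lineage alive at graft age")
  e <- if (length(cand) == 1L) cand else sample(cand, 1L)
  u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
  ## renumber: tips 1..nt keep, new tip nt+1, old internal j -> j+1,
  ## new internal node last
  remap <- function(x) ifelse(x > nt, x + 1L, x)
  w <- nt + nn + 2L
  edge <- cbind(remap(tr$edge[, 1L]), remap(tr$edge[, 2L]))
  len <- tr$edge.length
  edge[e, ] <- c(remap(u), w)          # upper part of split edge
  len[e] <- pa[e] - t
  edge <- rbind(edge, c(w, remap(v)), c(w, nt + 1L))
  len <- c(len, t - ca[e], t)
  out <- list(edge = edge, edge.length = len,
              tip.label = c(tr$tip.label, label), Nnode = nn + 1L)
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' Missing-species imputation for gamma (CorSiM-style a priori correction)
#'
#' Estimates `(r, eps)` from the observed tree, then per replicate draws
#' `n_missing` additional speciation times from the constant-rate
#' reconstructed birth-death density conditioned on the observed crown age,
#' grafts each onto a uniformly chosen contemporary lineage (oldest first,
#' so later grafts may land on earlier ones), and recomputes gamma on every
#' completed tree.
#'
#' @param tr Observed species tree (`phylo`, >= 4 tips).
#' @param n_missing Number of unsampled species to impute (>= 0).
#' @param reps Imputation replicates.
#' @param seed Integer seed.
#' @param r,eps Optional known rates; when `NULL` they are estimated from
#'   the observed tree under the sampled birth-death likelihood with
#'   sampling fraction `n / (n + n_missing)`, so the estimates are not
#'   biased by the species that are about to be imputed.
#' @return List with `trees` (completed trees), `gammas`,
#'   `corsim_gamma_mean`, and the rates used.
#' @export
corsim_impute <- function(tr, n_missing, reps = 100L, seed = 1L,
                          r = NULL, eps = NULL) {
  if (n_missing < 0L)
    stop_discretus("domain_error", "n_missing must be >= 0")
  g_obs <- gamma_statistic(tr)
  if (n_missing == 0L)
    return(list(trees = list(tr), gammas = g_obs,
                corsim_gamma_mean = g_obs, r = r, eps = eps))
  if (is.null(r) || is.null(eps)) {
    n <- ape::Ntip(tr)
    fit <- cpp_sampled_fit(sort(as.numeric(ape::branching.times(tr)),
                                decreasing = TRUE),
                           rho = n / (n + n_missing))
    r <- fit$r
    eps <- fit$eps
  }
  Tcrown <- max(ape::branching.times(tr))
  cfac <- (1 - exp(-r * Tcrown)) / (1 - eps * exp(-r * Tcrown))
  seeds <- derive_seeds(seed, reps)
  trees <- vector("list", reps)
  gammas <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    u <- runif(n_missing)
    y <- (1 - u * cfac) / (1 - u * cfac * eps)  # inverse CDF, y = exp(-r t)
    ts <- sort(-log(y) / r, decreasing = TRUE)
    cur <- tr
    for (k in seq_len(n_missing))
      cur <- graft_tip(cur, ts[k], sprintf("imputed_%d_%d", i, k))
    trees[[i]] <- cur
    gammas[i] <- gamma_statistic(cur)
  }
  list(trees = trees, gammas = gammas, corsim_gamma_mean = mean(gammas),
       r = r, eps = eps)
}

#' Lineage-through-time table
#'
#' @param tr Ultrametric `phylo`.
#' @return data.frame (`time_before_present`, `n_lineages`) with one row per
#'   branching event, ordered from the root (oldest) to the youngest event.
#' @export
ltt_table <- function(tr) {
  bt <- sort(as.numeric(ape::branching.times(tr)), decreasing = TRUE)
  data.frame(time_before_present = bt,
             n_lineages = seq_along(bt) + 1L)
}
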