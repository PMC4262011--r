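## Single-threshold Generalized Mixed Yule Coalescent (GMYC) model.
##
## Branching events are ordered from the root.  Events older than a
## threshold T are diversification (Yule-like) events; events younger than T
## are coalescences inside the clusters founded by the branches crossing T.
## During the waiting interval with i+1 lineages the total branching rate is
##
##   b_i = lambda_div * nd_i^p_div + lambda_coal * sum_j (n_ij (n_ij-1))^p_coal
##
## where nd_i counts species-level lineages (all lineages above T, the
## number of crossing branches below T) and n_ij the lineages of cluster j.
## Waiting times between successive events are modelled as independent
## exponentials with rate b_i, and each observed event contributes the
## *total* rate b_i as its density term (the convention of the source
## delimitation method; it keeps the null and GMYC models likelihoods of the
## same waiting-time data).  The interval running from the youngest event to
## the present contributes exposure only.  The null model is a single
## branching class over the whole tree with rate lambda * (n(n-1))^p.
##
## The overall rate scale profiles out in closed form, so each candidate
## threshold needs only a bounded 3-parameter search over (mixing weight,
## p_div, p_coal); the null is a concave 1-D profile in p.

## ---- internal precomputation ------------------------------------------

gmyc_tree_data <- function(tr) {
  nt <- ape::Ntip(tr)
  nn <- tr$Nnode
  ages_raw <- ape::branching.times(tr)
  node_age <- numeric(nt + nn)
  node_age[as.integer(names(ages_raw))] <- as.numeric(ages_raw)
  po <- ape::reorder.phylo(tr, "postorder")
  tipsets <- vector("list", nt + nn)
  for (i in seq_len(nt)) tipsets[[i]] <- i
  desc_ids <- vector("list", nt + nn)  # internal descendants incl. self
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
    if (ch > nt)  # NB: [[<- with NULL would delete the element
      desc_ids[p] <- list(c(desc_ids[[p]], ch, desc_ids[[ch]]))
  }
  for (v in (nt + 1L):(nt + nn)) desc_ids[[v]] <- c(v, desc_ids[[v]])
  ord <- order(node_age[(nt + 1L):(nt + nn)], decreasing = TRUE) + nt
  list(tr = tr, nt = nt, node_age = node_age,
       ord_ids = ord, ages_desc = node_age[ord],
       rootage = node_age[nt + 1L], edge = tr$edge,
       tipsets = tipsets, desc_ids = desc_ids)
}

## Interval bookkeeping for a given threshold: interval i runs from the i-th
## oldest event down to the next boundary and holds i+1 lineages; following
## the backward (coalescent) convention, the event at its older boundary
## takes its density from this interval's rate, so counts are those just
## *after* (younger than) each event.
gmyc_threshold_stats <- function(td, T) {
  n <- td$nt
  a <- c(td$ages_desc, 0)
  w <- a[-n] - a[-1L]                    # widths of intervals 1..n-1
  if (T >= td$rootage) {                 # degenerate: one cluster = null
    m <- 0L
  } else m <- sum(td$ages_desc > T)
  K <- m + 1L
  nd <- pmin(seq_len(n - 1L) + 1L, K)
  ev_old <- integer(0)
  if (m < n - 1L) {
    ## map each sub-threshold event to its cluster and track sizes
    clus <- integer(length(td$node_age))
    if (m == 0L) {
      clus[td$desc_ids[[td$nt + 1L]]] <- 1L
      nclus <- 1L
    } else {
      pa <- td$node_age[td$edge[, 1L]]
      ca <- td$node_age[td$edge[, 2L]]
      cross <- which(pa > T & ca <= T & td$edge[, 2L] > td$nt)
      nclus <- 0L
      for (ch in td$edge[cross, 2L]) {
        nclus <- nclus + 1L
        clus[td$desc_ids[[ch]]] <- nclus
      }
    }
    sizes <- rep(1L, nclus)
    ev_old <- integer(n - 1L - m)
    for (k in seq_along(ev_old)) {
      j <- clus[td$ord_ids[m + k]]
      ev_old[k] <- sizes[j]
      sizes[j] <- sizes[j] + 1L
    }
  }
  list(n = n, m = m, K = K, n_entities = K, w = w, nd = nd,
       ev_old = ev_old, smax = if (length(ev_old)) max(ev_old) + 1L else 1L)
}

## per-interval coalescent rate factor sum_j (n_j (n_j - 1))^p_coal
gmyc_coal_profile <- function(st, p_coal) {
  n <- st$n
  C <- numeric(n - 1L)
  if (length(st$ev_old)) {
    qv <- (2:st$smax) * (1:(st$smax - 1L))
    qp <- qv^p_coal
    old <- st$ev_old
    prev <- qp[pmax(old - 1L, 1L)]
    prev[old < 2L] <- 0
    delta <- qp[old] - prev
    C[(st$m + 1L):(n - 1L)] <- cumsum(delta)
  }
  C
}

## log-likelihood with the overall scale sigma profiled out; shape_i is the
## per-interval rate divided by sigma.  Every interval i ends (at its older
## boundary) in the event whose density it supplies, so all n-1 events have
## a rate term and all n-1 intervals contribute exposure.
gmyc_ll_profiled <- function(shape, w) {
  ne <- length(shape)
  if (any(shape <= 0)) return(-Inf)
  I <- sum(w * shape)
  ne * log(ne / I) + sum(log(shape)) - ne
}

gmyc_shape <- function(st, rho, p_div, p_coal) {
  rho * st$nd^p_div + (1 - rho) * gmyc_coal_profile(st, p_coal)
}

## null model: single class, rate lambda * (n(n-1))^p; concave 1-D profile
gmyc_null_profile <- function(w, tol = 1e-8) {
  n <- length(w) + 1L
  q <- as.numeric(2:n) * as.numeric(1:(n - 1L))
  f <- function(p) gmyc_ll_profiled(q^p, w)
  opt <- optimize(f, c(0, 2), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, 2)
  lls <- c(opt$objective, f(0), f(2))
  i <- which.max(lls)
  I <- sum(w * q^cand[i])
  list(ll = lls[i], p = cand[i], lambda = (n - 1L) / I)
}

gmyc_fit_threshold <- function(st, coarse = FALSE, warm = NULL) {
  ne <- st$n - 1L
  if (st$m == st$n - 1L) {
    ## all events diversification (every tip a singleton): 1-D in p_div
    f <- function(p) gmyc_ll_profiled(st$nd^p, st$w)
    opt <- optimize(f, c(0, 2), maximum = TRUE, tol = 1e-8)
    cand <- c(opt$maximum, 0, 2)
    lls <- c(opt$objective, f(0), f(2))
    i <- which.max(lls)
    sigma <- ne / sum(st$w * st$nd^cand[i])
    return(list(ll = lls[i], lambda_div = sigma, p_div = cand[i],
                lambda_coal = 0, p_coal = NA_real_))
  }
  obj <- function(par) {
    v <- gmyc_ll_profiled(gmyc_shape(st, par[1L], par[2L], par[3L]), st$w)
    if (!is.finite(v)) -1e10 else v
  }
  starts <- if (coarse) list(c(0.5, 1, 1))
            else list(c(0.5, 1, 1), c(0.05, 0.5, 1.5), c(0.95, 1.5, 0.5))
  if (!is.null(warm)) starts <- c(list(warm), starts)
  ctrl <- list(fnscale = -1, factr = 1e7,
               maxit = if (coarse) 30L else 100L)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, obj, method = "L-BFGS-B",
            lower = c(1e-9, 0, 0), upper = c(1, 2, 2), control = ctrl),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value > best$value)) best <- o
  }
  if (is.null(best))
    stop_discretus("fit_error", "GMYC threshold optimization failed")
  rho <- best$par[1L]; pd <- best$par[2L]; pc <- best$par[3L]
  sigma <- (st$n - 1L) / sum(st$w * gmyc_shape(st, rho, pd, pc))
  list(ll = best$value, lambda_div = sigma * rho, p_div = pd,
       lambda_coal = sigma * (1 - rho), p_coal = pc)
}

## ---- exported operations ----------------------------------------------

#' GMYC log-likelihood at fixed threshold and parameters
#'
#' Direct evaluation of the mixed Yule-coalescent likelihood described
#' above, without any optimization.
#'
#' @param tr Validated ultrametric binary `phylo`.
#' @param threshold Threshold time before present, strictly inside
#'   `(0, root age)`.
#' @param params List with `lambda_div`, `p_div`, `lambda_coal`, `p_coal`
#'   (rates > 0 wherever their class has events).
#' @return Log-likelihood (numeric scalar).
#' @export
gmyc_likelihood <- function(tr, threshold, params) {
  td <- gmyc_tree_data(tr)
  if (threshold <= 0 || threshold >= td$rootage)
    stop_discretus("domain_error",
                   "threshold must lie strictly between 0 and the root age")
  st <- gmyc_threshold_stats(td, threshold)
  b <- params$lambda_div * st$nd^params$p_div +
    params$lambda_coal * gmyc_coal_profile(st, params$p_coal)
  if (any(b <= 0)) return(-Inf)
  sum(log(b)) - sum(st$w * b)
}

#' Null (single branching class) log-likelihood at fixed parameters
#'
#' One rate class across the whole tree with total rate
#' `lambda * (n(n-1))^p`.
#'
#' @param tr Ultrametric binary `phylo`.
#' @param lambda Rate parameter (> 0).
#' @param p Scaling exponent.
#' @return Log-likelihood.
#' @export
gmyc_null_likelihood <- function(tr, lambda, p) {
  td <- gmyc_tree_data(tr)
  st <- gmyc_threshold_stats(td, td$rootage)
  b <- lambda * gmyc_coal_profile(st, p)
  if (any(b <= 0)) return(-Inf)
  sum(log(b)) - sum(st$w * b)
}

#' Fit the single-threshold GMYC model
#'
#' Candidate thresholds are the midpoints between consecutive distinct node
#' ages, plus one below the youngest node (every tip a singleton) and the
#' degenerate all-coalescent configuration, which coincides with the null
#' model and therefore guarantees a non-negative likelihood ratio.  Per
#' threshold the overall rate scale is profiled out in closed form and the
#' remaining mixing weight and scaling exponents (bounded to `[0, 2]`) are
#' maximized by bounded quasi-Newton from three deterministic starts.  Ties
#' between equal-likelihood thresholds resolve to the youngest threshold
#' (most clusters).
#'
#' @param tr Ultrametric binary `phylo` with >= 4 tips.
#' @param df Degrees of freedom for the chi-square LR test.  The default 3
#'   (two extra rate-class parameters plus the profiled threshold) is the
#'   convention under which the test's type-I error calibrates to its
#'   nominal level in this implementation; `df = 2` (threshold not counted,
#'   the source method's convention) is available but anticonservative.
#' @return Object of class `gmyc_fit` with the threshold, both rate classes,
#'   log-likelihoods, the LR test, the entity count and the extracted
#'   `partition`.
#' @export
fit_gmyc <- function(tr, df = 3L) {
  validate_ultrametric(tr)
  if (ape::Ntip(tr) < 4L)
    stop_discretus("insufficient_data_error", "GMYC fit needs >= 4 tips")
  if (!df %in% c(2L, 3L))
    stop_discretus("domain_error", "df must be 2 or 3")
  td <- gmyc_tree_data(tr)
  n <- td$nt
  distinct <- unique(td$ages_desc)
  cand <- c((distinct[-length(distinct)] + distinct[-1L]) / 2,
            distinct[length(distinct)] / 2)

  null <- gmyc_null_profile(gmyc_threshold_stats(td, td$rootage)$w)
  ## coarse screen of every candidate, then full multi-start refinement of
  ## the leading thresholds (deterministic two-stage search)
  stats <- lapply(cand, function(T) gmyc_threshold_stats(td, T))
  fits <- lapply(stats, gmyc_fit_threshold, coarse = TRUE)
  refine <- order(vapply(fits, `[[`, numeric(1), "ll"),
                  decreasing = TRUE)[seq_len(min(8L, length(fits)))]
  for (i in refine) {
    w0 <- fits[[i]]
    warm <- if (is.na(w0$p_coal)) NULL
            else c(w0$lambda_div / (w0$lambda_div + w0$lambda_coal),
                   w0$p_div, w0$p_coal)
    fits[[i]] <- gmyc_fit_threshold(stats[[i]], warm = warm)
  }
  for (i in seq_along(fits))
    fits[[i]] <- c(fits[[i]], list(T = cand[i],
                                   n_entities = stats[[i]]$n_entities))
  ## degenerate all-coalescent configuration == the null model
  fits <- c(fits, list(list(ll = null$ll, lambda_div = 0, p_div = NA_real_,
                            lambda_coal = null$lambda, p_coal = null$p,
                            T = td$rootage, n_entities = 1L)))
  cand <- c(cand, td$rootage)
  ll <- vapply(fits, `[[`, numeric(1), "ll")
  top <- which(ll >= max(ll) - 1e-9 * max(1, abs(max(ll))))
  best <- fits[[top[which.min(cand[top])]]]

  lr <- max(2 * (best$ll - null$ll), 0)
  partition <- extract_partition(tr, best$T)
  structure(list(
    threshold_T = best$T,
    lambda_div = best$lambda_div, p_div = best$p_div,
    lambda_coal = best$lambda_coal, p_coal = best$p_coal,
    loglik_null = null$ll, loglik_gmyc = best$ll,
    lr_chi2 = lr, df = as.integer(df),
    p_value = pchisq(lr, df, lower.tail = FALSE),
    n_entities = best$n_entities,
    partition = partition,
    profile = data.frame(threshold = cand, loglik = ll,
                         n_entities = vapply(fits, `[[`, integer(1),
                                             "n_entities")),
    rootage = td$rootage, n_tips = n), class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("GMYC fit\n")
  cat(sprintf("  tips: %d   entities: %d (%d clusters + %d singletons)\n",
              x$n_tips, x$n_entities,
              sum(!attr(x$partition, "singleton_species")),
              sum(attr(x$partition, "singleton_species"))))
  cat(sprintf("  threshold: %.4g (root age %.4g)\n", x$threshold_T, x$rootage))
  cat(sprintf("  loglik: null %.4f  gmyc %.4f  LR chi2 = %.4f (df %d), p = %.4g\n",
              x$loglik_null, x$loglik_gmyc, x$lr_chi2, x$df, x$p_value))
  invisible(x)
}

#' Delimit species from a threshold on the gene tree
#'
#' Every branch that crosses the threshold founds one species: the tips
#' descending from it.  A crossing branch with no internal node younger than
#' the threshold (in particular any pendant branch) yields a singleton.
#'
#' @param tr Ultrametric binary `phylo`.
#' @param threshold Either a `gmyc_fit` or a numeric threshold time.
#' @return data.frame (`tip`, `species`, `is_singleton`) of class
#'   `species_partition`, with attributes `threshold`, `species_tips`
#'   (named list) and `singleton_species` (named logical).
#' @export
extract_partition <- function(tr, threshold) {
  if (inherits(threshold, "gmyc_fit")) threshold <- threshold$threshold_T
  td <- gmyc_tree_data(tr)
  if (threshold >= td$rootage) {
    sets <- list(td$tipsets[[td$nt + 1L]])
  } else {
    pa <- td$node_age[td$edge[, 1L]]
    ca <- td$node_age[td$edge[, 2L]]
    cross <- which(pa > threshold & ca <= threshold)
    sets <- lapply(td$edge[cross, 2L], function(v) td$tipsets[[v]])
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  wid <- max(2L, nchar(length(sets)))
  ids <- sprintf(paste0("sp%0", wid, "d"), seq_along(sets))
  tips <- tr$tip.label[unlist(sets)]
  species <- rep(ids, lengths(sets))
  singleton <- setNames(lengths(sets) == 1L, ids)
  out <- data.frame(tip = tips, species = species,
                    is_singleton = unname(singleton[species]),
                    row.names = NULL)
  out <- out[order(match(out$tip, tr$tip.label)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("species_partition", "data.frame"),
            threshold = threshold,
            species_tips = setNames(
              lapply(sets, function(s) tr$tip.label[s]), ids),
            singleton_species = singleton)
}

#' Sensitivity of the GMYC fit to sample size
#'
#' Randomly deletes tips (without replacement), prunes the tree and refits
#' the GMYC per replicate, summarizing how model support and the entity
#' count degrade under subsampling.
#'
#' @param tr Ultrametric binary `phylo`.
#' @param fraction Proportion of tips retained per replicate (0 < f < 1).
#' @param reps Number of replicates; `0` returns an empty summary.
#' @param seed Integer seed.
#' @param df Passed to [fit_gmyc()].
#' @return data.frame (`rep`, `n_tips`, `p_value`, `n_entities`) with
#'   attribute `skipped` counting replicates whose pruned tree had < 4 tips.
#' @export
subsample_refit <- function(tr, fraction, reps, seed, df = 3L) {
  if (fraction <= 0 || fraction >= 1)
    stop_discretus("domain_error", "fraction must be in (0, 1)")
  n <- ape::Ntip(tr)
  keep_n <- round(fraction * n)
  out <- vector("list", reps)
  skipped <- 0L
  seeds <- if (reps > 0) derive_seeds(seed, reps) else integer(0)
  for (r in seq_len(reps)) {
    if (keep_n < 4L) { skipped <- skipped + 1L; next }
    set.seed(seeds[r])
    keep <- sample(tr$tip.label, keep_n)
    fit <- fit_gmyc(ape::keep.tip(tr, keep), df = df)
    out[[r]] <- data.frame(rep = r, n_tips = keep_n,
                           p_value = fit$p_value,
                           n_entities = fit$n_entities)
  }
  keep_rows <- !vapply(out, is.null, TRUE)
  res <- if (any(keep_rows)) do.call(rbind, out[keep_rows])
         else data.frame(rep = integer(0), n_tips = integer(0),
                         p_value = numeric(0), n_entities = integer(0))
  structure(res, skipped = skipped)
}
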