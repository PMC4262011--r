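## Group comparison utilities: Wilcoxon rank-sum with the Mann-Whitney W
## convention, Cohen's d, retrospective power of the two-sample t-test, and
## a dataset-blocked permutation test that stands in for mixed-effects
## modelling of per-species metrics.  The permutation test is NOT equivalent
## to a mixed model; it only respects the dataset blocking structure.

#' Wilcoxon rank-sum test
#'
#' `W` follows the Mann-Whitney convention: sum of ranks of `x` minus
#' `n_x (n_x + 1) / 2`.  The two-sided p-value is exact (by enumeration of
#' the rank-sum distribution) when there are no ties and
#' `n_x * n_y <= 10^4`, otherwise a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with `W`, `p_value`, and `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y))
    stop_discretus("empty_input_error", "both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && nx * ny <= 1e4
  if (exact) {
    ## two-sided doubling of the smaller tail, capped at 1
    if (W > nx * ny / 2) {
      p <- 2 * stats::pwilcox(W - 1, nx, ny, lower.tail = FALSE)
    } else if (W < nx * ny / 2) {
      p <- 2 * stats::pwilcox(W, nx, ny)
    } else p <- 1
    p <- min(1, p)
  } else {
    nties <- table(rk)
    mu <- nx * ny / 2
    sigma2 <- (nx * ny / 12) *
      ((nx + ny + 1) - sum(nties^3 - nties) / ((nx + ny) * (nx + ny - 1)))
    z <- W - mu
    z <- z - sign(z) * 0.5  # continuity correction
    z <- z / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(W = W, p_value = p, exact = exact)
}

#' Cohen's d effect size
#'
#' Difference of group means divided by the pooled (n - 1 weighted)
#' standard deviation.
#'
#' @param x,y Numeric samples with >= 2 values each.
#' @return d, or `NA` with a warning when the pooled SD is zero.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop_discretus("insufficient_data_error", "need >= 2 values per group")
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) {
    warn_discretus("zero_sd_warning", "pooled SD is zero; d undefined")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Power of the two-sided two-sample t-test
#'
#' Computed from the noncentral t distribution with noncentrality
#' `d * sqrt(n_x n_y / (n_x + n_y))` and `n_x + n_y - 2` degrees of freedom.
#'
#' @param n_x,n_y Sample sizes (>= 2).
#' @param d Cohen's d effect size.
#' @param alpha Two-sided significance level, default 0.05.
#' @return Power in `[alpha, 1]`.
#' @export
power_two_sample <- function(n_x, n_y, d, alpha = 0.05) {
  if (n_x < 2L || n_y < 2L)
    stop_discretus("insufficient_data_error", "need n >= 2 per group")
  if (alpha <= 0 || alpha >= 1)
    stop_discretus("domain_error", "alpha must be in (0, 1)")
  df <- n_x + n_y - 2
  ncp <- d * sqrt(n_x * n_y / (n_x + n_y))
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp = ncp) + pt(tc, df, ncp = ncp, lower.tail = FALSE)
}

#' Dataset-blocked permutation test of a group difference
#'
#' Observed statistic: difference between the two groups of the mean over
#' their datasets of per-dataset mean metric values.  The null is built by
#' permuting group labels at the dataset (block) level, which respects
#' non-independence of species within a dataset.  When the number of
#' distinct label assignments is at most `reps`, exact enumeration is used
#' (with a message); otherwise `reps` random permutations.
#'
#' This is a documented stand-in for mixed-effects modelling and is not
#' equivalent to it.
#'
#' @param table data.frame of per-species metrics with at least the columns
#'   named by `metric`, plus `dataset` and `group`.
#' @param metric Column name of the metric to compare.
#' @param reps Maximum number of permutations.
#' @param seed Integer seed.
#' @return List with `observed`, `p_value`, `n_perm`, `exact`.
#' @export
blocked_permutation_test <- function(table, metric, reps = 2000L, seed = 1L) {
  stopifnot(all(c(metric, "dataset", "group") %in% names(table)))
  vals <- table[[metric]]
  ok <- is.finite(vals)
  block_means <- tapply(vals[ok], table$dataset[ok], mean)
  block_group <- tapply(as.character(table$group), table$dataset, `[`, 1L)
  block_group <- block_group[names(block_means)]
  groups <- sort(unique(block_group))
  if (length(groups) != 2L)
    stop_discretus("domain_error", "need exactly two groups")
  if (min(table(block_group)) < 2L)
    stop_discretus("domain_error", "need >= 2 datasets per group")
  nb <- length(block_means)
  na <- sum(block_group == groups[1L])
  stat <- function(lab) mean(block_means[lab == groups[1L]]) -
    mean(block_means[lab != groups[1L]])
  obs <- stat(block_group)
  n_distinct <- choose(nb, na)
  if (n_distinct <= reps) {
    message(sprintf("exact enumeration of %d label assignments", n_distinct))
    idx <- combn(nb, na)
    null <- apply(idx, 2L, function(i) {
      lab <- rep(groups[2L], nb)
      lab[i] <- groups[1L]
      stat(lab)
    })
    exact <- TRUE
  } else {
    seeds <- derive_seeds(seed, 1L)
    set.seed(seeds)
    null <- replicate(reps, stat(sample(block_group)))
    exact <- FALSE
  }
  list(observed = obs,
       p_value = mean(abs(null) >= abs(obs) - 1e-12),
       n_perm = length(null), exact = exact)
}

#' Full comparison report for one metric
#'
#' Wilcoxon rank-sum on per-dataset means, Cohen's d, and retrospective
#' power at the observed effect size.
#'
#' @param table Per-species metric table with `dataset`, `group` columns.
#' @param metric Metric column name.
#' @param alpha Significance level for the power computation.
#' @return One-row data.frame of class `group_comparison`.
#' @export
compare_groups <- function(table, metric, alpha = 0.05) {
  vals <- table[[metric]]
  ok <- is.finite(vals)
  bm <- tapply(vals[ok], table$dataset[ok], mean)
  bg <- tapply(as.character(table$group), table$dataset, `[`, 1L)[names(bm)]
  groups <- sort(unique(bg))
  x <- bm[bg == groups[1L]]
  y <- bm[bg == groups[2L]]
  w <- wilcoxon_rank_sum(x, y)
  d <- cohens_d(x, y)
  structure(data.frame(
    statistic_name = metric, group_a = groups[1L], group_b = groups[2L],
    n_a = length(x), n_b = length(y),
    W = w$W, p_value = w$p_value, d = d,
    power = if (is.na(d)) NA_real_
            else power_two_sample(length(x), length(y), d, alpha)),
    class = c("group_comparison", "data.frame"))
}
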