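## Neutrality statistics computed per delimited species from its sequences
## (haplotypes expanded back by multiplicity, since clone sampling affects
## the site-frequency spectrum).  Alignment columns containing a gap, N or ?
## in any sequence are excluded alignment-wide (complete deletion) before
## anything is counted.  Sites with more than two alleles count as one
## segregating site but contribute (alleles - 1) mutations to eta.

#' Expand haplotypes to the sampled sequence set
#'
#' @param haps A `haplotype_alignment` (or named character vector) to expand.
#' @param multiplicity Named multiplicities (ignored when `haps` carries its
#'   own).
#' @return Named character vector with one entry per original sequence
#'   (names suffixed `.k` for copies beyond the first).
#' @export
expand_haplotypes <- function(haps, multiplicity = NULL) {
  if (inherits(haps, "haplotype_alignment")) {
    multiplicity <- haps$multiplicity
    haps <- haps$seqs
  }
  if (is.null(multiplicity)) multiplicity <- setNames(
    rep(1L, length(haps)), names(haps))
  idx <- rep(seq_along(haps), multiplicity[names(haps)])
  out <- haps[idx]
  names(out) <- make.unique(names(haps)[idx], sep = ".")
  out
}

## complete-deletion integer matrix (rows = sequences, cols = kept sites)
popgen_matrix <- function(seqs) {
  code <- encode_alignment(seqs)
  keep <- colSums(code == 0L) == 0L
  code[, keep, drop = FALSE]
}

#' Site summaries underlying the neutrality statistics
#'
#' @param seqs Named character vector: the expanded (per-sequence) alignment.
#' @return List with `n`, `S` (segregating sites), `k_bar` (mean pairwise
#'   differences, in sites), `theta_W` (Watterson, differences scale), `eta`
#'   (total mutations), `eta_s` (singleton mutations), `K` (haplotype count),
#'   `sites` (sites retained after complete deletion).
#' @export
site_summaries <- function(seqs) {
  if (length(seqs) < 2L)
    stop_discretus("insufficient_data_error", "need >= 2 sequences")
  m <- popgen_matrix(seqs)
  n <- nrow(m)
  L <- ncol(m)
  S <- 0L; eta <- 0L; eta_s <- 0L
  diff_sum <- 0
  npairs <- n * (n - 1) / 2
  for (j in seq_len(L)) {
    cnt <- tabulate(m[, j])
    cnt <- cnt[cnt > 0L]
    if (length(cnt) > 1L) {
      S <- S + 1L
      eta <- eta + length(cnt) - 1L
      eta_s <- eta_s + sum(cnt == 1L)
      diff_sum <- diff_sum + (npairs - sum(cnt * (cnt - 1) / 2)) / npairs
    }
  }
  a1 <- sum(1 / seq_len(n - 1L))
  ## diff_sum sums, over sites, the fraction of pairs differing there, so it
  ## equals the mean pairwise difference count (in sites, not per site)
  list(n = n, S = S, k_bar = diff_sum, theta_W = S / a1,
       eta = eta, eta_s = eta_s,
       K = length(unique(apply(m, 1L, paste, collapse = ""))),
       sites = L)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' @param summ Output of [site_summaries()].
#' @return D, or `NA` when `S = 0` or `n < 4`.
#' @export
tajimas_d <- function(summ) {
  if (summ$S == 0L || summ$n < 4L) return(NA_real_)
  cst <- tajima_constants(summ$n)
  S <- summ$S
  (summ$k_bar - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Fu and Li's D* and F* (no-outgroup versions)
#'
#' Uses total mutation count eta and singleton count eta_s with the
#' corrected variance constants of the starred statistics.
#'
#' @param summ Output of [site_summaries()].
#' @return List with `D_star` and `F_star` (`NA` when `S = 0` or `n < 4`).
#' @export
fu_li <- function(summ) {
  if (summ$S == 0L || summ$n < 4L)
    return(list(D_star = NA_real_, F_star = NA_real_))
  n <- summ$n
  eta <- summ$eta
  eta_s <- summ$eta_s
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  an1 <- a1 + 1 / n  # harmonic number of order n (i.e. a_{n+1})
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
           2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
  uD <- (n / (n - 1)) * (a1 - n / (n - 1)) - vD
  D_star <- ((n / (n - 1)) * eta - a1 * eta_s) /
    sqrt(uD * eta + vD * eta^2)
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           2 * (n - 1) * a1 / n^2 - 8 * a2 / n) / (a1^2 + a2)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / a1 - vF
  F_star <- (summ$k_bar - ((n - 1) / n) * eta_s) /
    sqrt(uF * eta + vF * eta^2)
  list(D_star = D_star, F_star = F_star)
}

## log unsigned Stirling numbers of the first kind, row n (k = 1..n),
## by the stable log-space recurrence.
log_stirling_row <- function(n) {
  row <- 0  # n = 1: |S(1,1)| = 1
  for (m in seq_len(n - 1L)) {
    prev <- row
    row <- numeric(m + 1L)
    row[1L] <- log(m) + prev[1L]
    row[m + 1L] <- prev[m]
    if (m > 1L) {
      a <- prev[1:(m - 1L)]
      b <- log(m) + prev[2:m]
      hi <- pmax(a, b)
      row[2:m] <- hi + log1p(exp(pmin(a, b) - hi))
    }
  }
  row
}

#' Fu's Fs
#'
#' `S' = P(K >= K_obs | theta = k_bar)` under the Ewens sampling
#' distribution (computed with log-space Stirling numbers), and
#' `Fs = ln(S' / (1 - S'))`.
#'
#' @param summ Output of [site_summaries()].
#' @return Fs; `NA` when `k_bar = 0`; `+-Inf` with a warning when `S'`
#'   underflows to 0 or 1.
#' @export
fu_fs <- function(summ) {
  if (summ$k_bar <= 0) return(NA_real_)
  n <- summ$n
  theta <- summ$k_bar
  lst <- log_stirling_row(n)
  lnorm <- sum(log(theta + 0:(n - 1L)))  # log rising factorial
  lp <- lst + seq_len(n) * log(theta) - lnorm
  lSp <- log(sum(exp(lp[summ$K:n] - max(lp[summ$K:n])))) + max(lp[summ$K:n])
  Sp <- exp(lSp)
  if (Sp >= 1 || Sp <= 0) {
    warn_discretus("fs_overflow_warning",
                   "Fu's Fs: S' is numerically 0 or 1; returning infinite Fs")
    return(if (Sp >= 1) -Inf else Inf)
  }
  ## log(S'/(1-S')) computed stably from the log of S'
  lSp - log(-expm1(lSp))
}

#' Ramos-Onsins and Rozas' R2
#'
#' `R2 = sqrt(mean((U_i - k_bar/2)^2)) / S`, where `U_i` counts singleton
#' mutations carried by sequence i.
#'
#' @param seqs Expanded alignment (named character vector).
#' @param summ Output of [site_summaries()] on the same alignment (computed
#'   if missing).
#' @return R2, or `NA` when `S = 0`.
#' @export
r2_stat <- function(seqs, summ = site_summaries(seqs)) {
  if (summ$S == 0L) return(NA_real_)
  m <- popgen_matrix(seqs)
  n <- nrow(m)
  U <- numeric(n)
  for (j in seq_len(ncol(m))) {
    cnt <- tabulate(m[, j], nbins = max(m[, j]))
    sing <- which(cnt == 1L)
    for (al in sing) U[m[, j] == al] <- U[m[, j] == al] + 1
  }
  sqrt(mean((U - summ$k_bar / 2)^2)) / summ$S
}

#' All five neutrality statistics for one alignment
#'
#' @param seqs Expanded per-sequence alignment, or a `haplotype_alignment`
#'   (expanded internally).
#' @return One-row data.frame with `n`, `S`, `k_bar`, `theta_W`, `eta_s`,
#'   `K`, `D`, `D_star`, `F_star`, `Fs`, `R2`.
#' @export
neutrality_stats <- function(seqs) {
  if (inherits(seqs, "haplotype_alignment")) seqs <- expand_haplotypes(seqs)
  summ <- site_summaries(seqs)
  fl <- fu_li(summ)
  data.frame(n = summ$n, S = summ$S, k_bar = summ$k_bar,
             theta_W = summ$theta_W, eta_s = summ$eta_s, K = summ$K,
             D = tajimas_d(summ), D_star = fl$D_star, F_star = fl$F_star,
             Fs = fu_fs(summ), R2 = r2_stat(seqs, summ))
}

#' Neutrality statistics per delimited species
#'
#' Expands each species' haplotypes by multiplicity and computes
#' [neutrality_stats()]; species with fewer than two sequences are reported
#' as all-`NA` rows.
#'
#' @param partition A `species_partition`.
#' @param haps A `haplotype_alignment` covering the partition's tips.
#' @return data.frame, one row per species.
#' @export
neutrality_by_species <- function(partition, haps) {
  sets <- species_sets(partition)
  rows <- lapply(names(sets), function(id) {
    tips <- sets[[id]]
    seqs <- expand_haplotypes(haps$seqs[tips], haps$multiplicity[tips])
    if (length(seqs) < 2L) {
      out <- data.frame(n = length(seqs), S = NA_integer_, k_bar = NA_real_,
                        theta_W = NA_real_, eta_s = NA_integer_,
                        K = NA_integer_, D = NA_real_, D_star = NA_real_,
                        F_star = NA_real_, Fs = NA_real_, R2 = NA_real_)
    } else out <- neutrality_stats(seqs)
    cbind(species = id, out)
  })
  do.call(rbind, rows)
}
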