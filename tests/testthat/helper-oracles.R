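# Independent, deliberately naive reference implementations.  These share no
# code with the package internals: everything is recomputed from first
# principles (character loops, explicit interval scans, textbook formulas).

# --- p-distance by explicit double loop over characters ------------------
naive_p_distance <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  miss <- c("-", "N", "?")
  comp <- 0L
  diff <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% miss || b[i] %in% miss) next
    comp <- comp + 1L
    if (a[i] != b[i]) diff <- diff + 1L
  }
  if (comp == 0L) NA_real_ else diff / comp
}

# --- GMYC likelihood by direct interval-by-interval summation ------------
# Walks a fine event grid, counts lineages and per-cluster lineages at the
# midpoint of every inter-event slice by scanning edges, and accumulates
# event-density and exposure terms directly.  The event at the older end of
# each slice takes the total rate prevailing in that slice (the convention
# of the package, arrived at independently here).
naive_gmyc_loglik <- function(tr, T, ld, pd, lc, pc) {
  nt <- ape::Ntip(tr)
  bt <- ape::branching.times(tr)
  age <- numeric(nt + tr$Nnode)
  age[as.integer(names(bt))] <- as.numeric(bt)
  pa <- age[tr$edge[, 1]]
  ca <- age[tr$edge[, 2]]
  tips_below <- function(v) {
    if (v <= nt) return(v)
    unlist(lapply(tr$edge[tr$edge[, 1] == v, 2], tips_below))
  }
  cross <- which(pa > T & ca <= T)
  cluster_of_tip <- integer(nt)
  for (j in seq_along(cross))
    cluster_of_tip[tips_below(tr$edge[cross[j], 2])] <- j
  K <- length(cross)
  rate_at <- function(t) {
    alive <- which(pa > t & ca <= t)
    if (t > T) {
      nd <- length(alive)
      qsum <- 0
    } else {
      nd <- K
      sizes <- table(vapply(alive, function(e)
        cluster_of_tip[tips_below(tr$edge[e, 2])[1]], integer(1)))
      qsum <- sum((sizes * (sizes - 1))^pc)
    }
    ld * nd^pd + lc * qsum
  }
  ev <- sort(as.numeric(bt), decreasing = TRUE)
  bounds <- c(ev, 0)
  ll <- 0
  for (i in seq_along(ev)) {
    hi <- bounds[i]
    lo <- bounds[i + 1]
    b <- rate_at((hi + lo) / 2)
    ll <- ll + log(b) - b * (hi - lo)
  }
  ll
}

# --- neutrality statistics, textbook route -------------------------------
# Complete deletion, then direct pairwise/sitewise scans and the published
# formulas transcribed independently of R/popgen.R.
naive_neutrality <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  # pairwise differences
  ks <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    ks <- c(ks, sum(m[i, ] != m[j, ]))
  k_bar <- mean(ks)
  S <- 0L; eta <- 0L; eta_s <- 0L
  U <- numeric(n)
  for (col in seq_len(ncol(m))) {
    tab <- table(m[, col])
    if (length(tab) > 1) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      for (al in names(tab)[tab == 1]) {
        eta_s <- eta_s + 1L
        U[which(m[, col] == al)] <- U[which(m[, col] == al)] + 1
      }
    }
  }
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  D <- if (S == 0) NA_real_ else {
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (k_bar - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
  }
  if (S == 0) {
    Dst <- Fst <- NA_real_
  } else {
    an1 <- a1 + 1 / n
    cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
    dn <- cn + (n - 2) / (n - 1)^2 +
      2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
    vD <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
             2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
    uD <- n / (n - 1) * (a1 - n / (n - 1)) - vD
    Dst <- (n / (n - 1) * eta - a1 * eta_s) / sqrt(uD * eta + vD * eta^2)
    vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
             2 * (n - 1) * a1 / n^2 - 8 * a2 / n) / (a1^2 + a2)
    uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
             (3 * n * (n - 1))) / a1 - vF
    Fst <- (k_bar - (n - 1) / n * eta_s) / sqrt(uF * eta + vF * eta^2)
  }
  # Fu's Fs with exact rational Stirling numbers (feasible for small n)
  Fs <- if (k_bar <= 0) NA_real_ else {
    st <- matrix(0, n, n)   # |S(i, j)|
    st[1, 1] <- 1
    if (n > 1) for (i in 2:n) for (j in 1:i)
      st[i, j] <- (if (j > 1) st[i - 1, j - 1] else 0) + (i - 1) * st[i - 1, j]
    theta <- k_bar
    probs <- st[n, ] * theta^(1:n) / prod(theta + 0:(n - 1))
    K <- length(unique(apply(m, 1, paste0, collapse = "")))
    Sp <- sum(probs[K:n])
    log(Sp / (1 - Sp))
  }
  R2 <- if (S == 0) NA_real_ else sqrt(sum((U - k_bar / 2)^2) / n) / S
  list(n = n, S = S, k_bar = k_bar, theta_W = S / a1, eta = eta,
       eta_s = eta_s, D = D, D_star = Dst, F_star = Fst, Fs = Fs, R2 = R2)
}

# --- birth-death likelihood as a plain term-by-term sum ------------------
# Nee et al. reconstructed process conditioned on crown age and survival:
#   ln L = ln((N-1)!) + sum_{i=3}^N [ln r + r t_i] + N ln(1-a)
#          - 2 sum_{i=2}^N ln(e^{r t_i} - a)
naive_bd_loglik <- function(tr, r, a) {
  t <- sort(as.numeric(ape::branching.times(tr)), decreasing = TRUE)
  N <- length(t) + 1
  ll <- lfactorial(N - 1) + N * log(1 - a)
  for (i in 2:N) {
    ti <- t[i - 1]
    ll <- ll - 2 * log(exp(r * ti) - a)
    if (i >= 3) ll <- ll + log(r) + r * ti
  }
  ll
}
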