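# Independent brute-force oracles and small fixtures shared across tests.
# The oracles deliberately use naive loops / enumeration so they share no code
# path with the package implementations they check.

brute_tanimoto <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1L && b[i] == 1L) inter <- inter + 1L
    if (a[i] == 1L || b[i] == 1L) uni <- uni + 1L
  }
  if (uni == 0L) 0 else inter / uni
}

brute_auroc <- function(labels, scores) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# AUROC via the trapezoid rule on the full ROC step curve (second independent
# route, distinct from both the rank identity and the pairwise count).
trapezoid_auroc <- function(labels, scores) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(labels == 1 & scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(labels == 0 & scores >= t) / n0, numeric(1))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (tie-free samples only).
enumerate_mw_p <- function(a, b) {
  nA <- length(a); nB <- length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  combos <- utils::combn(nA + nB, nA)
  Us <- apply(combos, 2L, function(idx) sum(idx) - nA * (nA + 1) / 2)
  lower <- mean(Us <= U_obs)
  upper <- mean(Us >= U_obs)
  min(1, 2 * min(lower, upper))
}

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in (m - 1):1) if (m > 1) adj[o[i]] <- min(adj[o[i]], adj[o[i + 1]])
  pmin(adj, 1)
}

# Small fast benchmark + training config for functional tests.
mini_benchmark <- function(seed = 1L) {
  make_benchmark("strong_signal", seed = seed,
                 sizes = list(n_cells = 24L, n_genes = 30L, n_drugs = 4L,
                              n_refs = 3L, n_bits = 64L, k_support = 4L,
                              n_types = 2L))
}

mini_control <- function(seed = 1L, ...) {
  refdnn_control(batch_size = 16L, max_epochs = 15L, patience = 5L,
                 seed = seed, ...)
}

# Study configuration used for benchmark-scale fits (documented in the
# methods vignette).
bench_control <- function(seed = 1L) {
  refdnn_control(max_epochs = 150L, patience = 30L, seed = seed)
}

random_fingerprint <- function(width, density = 0.3) {
  f <- stats::rbinom(width, 1L, density)
  if (sum(f) == 0L) f[sample.int(width, 1L)] <- 1L
  f
}
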