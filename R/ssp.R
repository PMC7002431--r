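#' Tanimoto coefficient between two binary fingerprints
#'
#' The ratio of shared on-bits to the union of on-bits, `|a AND b| / |a OR b|`,
#' the standard 2D chemical similarity on substructure fingerprints. Lies in
#' \[0, 1\]; 1 for identical non-empty fingerprints, 0 for disjoint ones. The
#' degenerate all-zero vs all-zero case is defined as 0 (with a warning): an
#' empty fingerprint shares no feature with anything.
#'
#' @param a,b Binary 0/1 vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0), c(1, 0, 1))  # 1/3
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stopf("fingerprint width mismatch: %d vs %d", length(a), length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) {
    warnf("Tanimoto of two all-zero fingerprints defined as 0")
    return(0)
  }
  inter / uni
}

#' Structure similarity profile of one drug against a reference panel
#'
#' @param d Binary fingerprint of the target drug.
#' @param refs Reference panel: a [fingerprint_table()] (or 0/1 matrix with
#'   drug-id rownames) whose row order fixes the profile order.
#' @return Numeric vector of length `nrow(refs)`: entry j is the Tanimoto
#'   coefficient between `d` and reference drug j, named by reference id.
#' @export
compute_ssp <- function(d, refs) {
  refs <- as_ref_matrix(refs)
  if (length(d) != ncol(refs))
    stopf("fingerprint width mismatch: drug has %d bits, references have %d",
          length(d), ncol(refs))
  ssp_matrix(matrix(as.integer(d), nrow = 1L, dimnames = list("d", NULL)), refs)[1L, ]
}

#' Structure-similarity-profile matrix for a set of drugs
#'
#' Vectorized Tanimoto: `|a AND b| = a . b` and
#' `|a OR b| = |a| + |b| - a . b` for 0/1 vectors, so the whole drugs x
#' references block is two matrix products.
#'
#' @param fps Drugs to profile: [fingerprint_table()] or 0/1 matrix with
#'   rownames.
#' @param refs Reference panel, same width.
#' @return Numeric matrix, drugs x references, entries in \[0, 1\].
#' @export
ssp_matrix <- function(fps, refs) {
  fps <- as_ref_matrix(fps)
  refs <- as_ref_matrix(refs)
  if (ncol(fps) != ncol(refs))
    stopf("fingerprint width mismatch: %d vs %d", ncol(fps), ncol(refs))
  A <- matrix(as.double(fps), nrow(fps))
  B <- matrix(as.double(refs), nrow(refs))
  inter <- A %*% t(B)
  uni <- outer(rowSums(A), rowSums(B), `+`) - inter
  if (any(uni == 0)) warnf("Tanimoto of two all-zero fingerprints defined as 0")
  s <- ifelse(uni == 0, 0, inter / uni)
  dimnames(s) <- list(rownames(fps), rownames(refs))
  s
}

as_ref_matrix <- function(x) {
  m <- unclass(x)
  if (!is.matrix(m)) stopf("expected a fingerprint matrix")
  m
}

#' Select a maximally diverse reference-drug panel
#'
#' Greedy max-min selection on Tanimoto distance (1 - Tc): seed with the pair
#' at maximal distance, then repeatedly add the drug whose minimum distance to
#' the chosen set is largest. Ties are broken by drug-id sort order, making the
#' procedure fully deterministic; `seed` is accepted for interface uniformity
#' but unused. Exhaustive search over all subsets is exponential and only used
#' as a test oracle at tiny sizes.
#'
#' @param fps [fingerprint_table()] of candidate drugs.
#' @param m Panel size, between 1 and `nrow(fps)`.
#' @param seed Unused; the tie rule makes selection deterministic.
#' @return A [fingerprint_table()] with `m` rows, in selection order.
#' @export
select_diverse_references <- function(fps, m, seed = NULL) {
  fpm <- as_ref_matrix(fps)
  n <- nrow(fpm)
  if (m < 1L || m > n) stopf("m must be in [1, %d], got %s", n, m)
  ids <- rownames(fpm)
  ord <- order(ids)
  if (m == 1L) return(fingerprint_table(fpm[ord[1L], , drop = FALSE]))
  D <- 1 - ssp_matrix(fps, fps)
  # seed pair: maximal distance, ties by lexicographically smallest sorted id pair
  best <- NULL; best_d <- -Inf
  for (i in ord) for (j in ord) {
    if (i == j) next
    pr <- sort(c(i, j))
    if (D[pr[1L], pr[2L]] > best_d + 1e-15) { best_d <- D[pr[1L], pr[2L]]; best <- pr }
  }
  chosen <- best
  while (length(chosen) < m) {
    remaining <- setdiff(ord, chosen)
    mind <- vapply(remaining, function(i) min(D[i, chosen]), numeric(1))
    # ties by id order: remaining is already id-sorted, take first argmax
    chosen <- c(chosen, remaining[which.max(mind + 0)])
  }
  fingerprint_table(fpm[chosen, , drop = FALSE])
}
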