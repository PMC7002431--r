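# Biomarker extraction from trained bank coefficients and the two validation
# analyses: differential expression between resistant and sensitive cell
# lines, and IC50 comparison across a median split of a gene's expression.

#' Top-ranked genes of one reference drug's classifier
#'
#' Ranks genes by the absolute value of the trained sparse-logistic
#' coefficients of the chosen reference drug, descending; ties break by gene
#' id. Exact-zero coefficients (the ones FTRL's l1 pruned) never outrank
#' nonzero ones and are excluded from the result.
#'
#' @param model A fitted [refdnn()] model.
#' @param ref_drug Reference drug identifier.
#' @param k How many genes (default 10). `k > G` is truncated with a warning.
#' @return Data.frame with `gene_id`, `coefficient`, `abs_coefficient`,
#'   `rank`; zero rows (with a warning) if the classifier is entirely pruned.
#' @export
top_k_genes <- function(model, ref_drug, k = 10L) {
  w <- coef(model, ref_drug = ref_drug)
  if (k > length(w)) {
    warnf("k = %d exceeds the %d available genes; truncating", k, length(w))
    k <- length(w)
  }
  nz <- which(w != 0)
  if (!length(nz)) {
    warnf("reference drug '%s' has no informative genes (all coefficients zero)",
          ref_drug)
    return(data.frame(gene_id = character(0), coefficient = numeric(0),
                      abs_coefficient = numeric(0), rank = integer(0)))
  }
  ord <- nz[order(-abs(w[nz]), names(w)[nz])]
  ord <- utils::head(ord, k)
  data.frame(gene_id = names(w)[ord], coefficient = unname(w[ord]),
             abs_coefficient = unname(abs(w[ord])),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midrank ties. The p-value is exact (enumeration
#' distribution) for small tie-free samples (`nA + nB <= 12`), otherwise the
#' normal approximation with tie correction and continuity correction is used.
#'
#' @param groupA,groupB Numeric samples, both non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `U` (statistic of group A), `p`, and the method used.
#' @export
mann_whitney_u <- function(groupA, groupB, alternative = "two.sided") {
  if (!length(groupA) || !length(groupB)) stopf("both groups must be non-empty")
  nA <- length(groupA); nB <- length(groupB)
  r <- rank(c(groupA, groupB))
  U_A <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- any(duplicated(c(groupA, groupB)))
  exact <- (nA + nB) <= 12L && !ties
  if (exact) {
    # stats::pwilcox is the exact enumeration distribution of U
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::pwilcox(U_A, nA, nB),
                                 1 - stats::pwilcox(U_A - 1, nA, nB))),
      less = stats::pwilcox(U_A, nA, nB),
      greater = 1 - stats::pwilcox(U_A - 1, nA, nB))
  } else {
    mu <- nA * nB / 2
    tie_tab <- table(r)
    n <- nA + nB
    sig2 <- nA * nB / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = U_A, p = 1, method = "normal"))
    cc <- 0.5  # continuity correction
    zstat <- switch(alternative,
      two.sided = (U_A - mu - sign(U_A - mu) * cc) / sqrt(sig2),
      less = (U_A - mu + cc) / sqrt(sig2),
      greater = (U_A - mu - cc) / sqrt(sig2))
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(zstat)),
      less = stats::pnorm(zstat),
      greater = 1 - stats::pnorm(zstat))
    p <- min(1, max(0, p))
  }
  list(U = U_A, p = p, method = if (exact) "exact" else "normal")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: `p.adjust(method = "BH")` behind a
#' stable interface.
#'
#' @param pvals Numeric vector of raw p-values.
#' @return Adjusted p-values in \[0, 1\], same order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Differential expression between resistant and sensitive cell lines
#'
#' Splits the cell lines by their binary response to one drug and tests each
#' candidate gene with the Mann-Whitney U test; BH adjustment is applied
#' across the tested gene set only (the candidate family, not the genome).
#' Direction is the sign of (median resistant - median sensitive).
#'
#' @param expression An [expression_matrix()].
#' @param records Response data.frame (`cell_id`, `drug_id`, `label`).
#' @param drug Drug identifier whose response defines the two groups.
#' @param genes Character vector of genes to test.
#' @return Data.frame with `gene_id`, `U`, `p`, `p_adj`, `direction`.
#' @export
de_by_response <- function(expression, records, drug, genes) {
  rec <- records[records$drug_id == drug, , drop = FALSE]
  if (!nrow(rec)) stopf("no records for drug '%s'", drug)
  res_cells <- rec$cell_id[rec$label == 1L]
  sen_cells <- rec$cell_id[rec$label == 0L]
  if (!length(res_cells) || !length(sen_cells))
    stopf("drug '%s' lacks one response class", drug)
  miss <- setdiff(genes, colnames(expression))
  if (length(miss)) stopf("unknown gene(s): %s", paste(miss, collapse = ", "))
  expr <- unclass(expression)
  rows <- lapply(genes, function(g) {
    a <- expr[res_cells, g]; b <- expr[sen_cells, g]
    mw <- mann_whitney_u(a, b)
    data.frame(gene_id = g, U = mw$U, p = mw$p,
               direction = sign(stats::median(a) - stats::median(b)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p)
  out[, c("gene_id", "U", "p", "p_adj", "direction")]
}

#' IC50 comparison across a median split of one gene's expression
#'
#' Divides cell lines into high- and low-expression groups at the gene's
#' median (ties at the median go to the low group) and compares their log-IC50
#' values for one drug with the Mann-Whitney U test. A consistent biomarker
#' shows higher log-IC50 (more resistance) in the group matching its
#' coefficient's direction.
#'
#' @param expression An [expression_matrix()].
#' @param ic50_records Data.frame with `cell_id`, `drug_id`, `ln_ic50`.
#' @param drug Drug identifier.
#' @param gene Gene identifier.
#' @param split_quantile Where to split the expression distribution (default
#'   0.5, the median).
#' @return List with `U`, `p`, `median_high`, `median_low` (log-IC50 medians),
#'   and the group sizes.
#' @export
ic50_by_median_split <- function(expression, ic50_records, drug, gene,
                                 split_quantile = 0.5) {
  rec <- ic50_records[ic50_records$drug_id == drug, , drop = FALSE]
  if (!nrow(rec)) stopf("no IC50 records for drug '%s'", drug)
  if (!gene %in% colnames(expression)) stopf("unknown gene '%s'", gene)
  cells <- intersect(rec$cell_id, rownames(expression))
  rec <- rec[rec$cell_id %in% cells, , drop = FALSE]
  x <- unclass(expression)[rec$cell_id, gene]
  cut <- stats::quantile(x, split_quantile, names = FALSE)
  high <- x > cut   # ties at the split value go to the low group
  if (sum(high) < 2L || sum(!high) < 2L)
    stopf("degenerate split for gene '%s': need >= 2 cell lines per group", gene)
  mw <- mann_whitney_u(rec$ln_ic50[high], rec$ln_ic50[!high])
  list(U = mw$U, p = mw$p,
       median_high = stats::median(rec$ln_ic50[high]),
       median_low = stats::median(rec$ln_ic50[!high]),
       n_high = sum(high), n_low = sum(!high))
}

#' Full biomarker report for one reference drug
#'
#' Combines [top_k_genes()] with [de_by_response()] on the same dataset:
#' candidate genes ranked by coefficient magnitude, each annotated with its
#' resistant-vs-sensitive differential-expression test.
#'
#' @param model A fitted [refdnn()] model.
#' @param ref_drug Reference drug identifier.
#' @param dataset The `refdnn_dataset` to validate against.
#' @param k Candidate count (default 10).
#' @return Data.frame merging the ranking and the test results.
#' @export
biomarker_report <- function(model, ref_drug, dataset, k = 10L) {
  top <- top_k_genes(model, ref_drug, k = k)
  if (!nrow(top)) return(top)
  de <- de_by_response(dataset$expression, dataset$records, ref_drug, top$gene_id)
  merge(top, de, by = "gene_id", sort = FALSE)[order(top$rank), ]
}
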