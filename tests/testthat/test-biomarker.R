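# Coefficient ranking, rank tests, FDR adjustment and the validation analyses.

toy_model <- function(W, ref_ids = paste0("r", seq_len(nrow(W))),
                      gene_ids = paste0("g", seq_len(ncol(W)))) {
  M <- nrow(W); G <- ncol(W)
  refs <- fingerprint_table(matrix(1L, M, 4, dimnames = list(ref_ids, NULL)))
  dnn <- refdnn:::new_dnn_params(M, 2, seed = 1)
  refdnn:::new_refdnn(refs = refs, gene_ids = gene_ids,
                      bank = list(W = W, b = rep(0, M)), dnn = dnn,
                      hp = list(hidden_units = 2))
}

test_that("top genes rank by absolute coefficient with zeros excluded", {
  m <- toy_model(matrix(c(0, -3, 1), 1, 3))
  top <- top_k_genes(m, "r1", k = 2)
  expect_equal(top$gene_id, c("g2", "g3"))
  expect_equal(top$coefficient, c(-3, 1))
  expect_equal(top$rank, 1:2)

  full <- top_k_genes(m, "r1", k = 3)
  expect_equal(nrow(full), 2L)                   # the zero never makes the list

  expect_warning(empty <- top_k_genes(toy_model(matrix(0, 1, 3)), "r1", k = 3),
                 "no informative genes")
  expect_equal(nrow(empty), 0L)
  expect_warning(top_k_genes(m, "r1", k = 10), "truncating")
  expect_error(top_k_genes(m, "rX"), "unknown")

  # ties break by gene id; ranking is invariant to gene permutation
  m2 <- toy_model(matrix(c(2, -2, 1), 1, 3))
  expect_equal(top_k_genes(m2, "r1", k = 2)$gene_id, c("g1", "g2"))
  m3 <- toy_model(matrix(c(1, -2, 2), 1, 3), gene_ids = c("g3", "g2", "g1"))
  expect_equal(top_k_genes(m3, "r1", k = 2)$gene_id, c("g1", "g2"))
})

test_that("Mann-Whitney exact p matches full enumeration on small tie-free samples", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)                        # 2/20 extreme orderings
  expect_equal(mw$method, "exact")

  set.seed(404)
  for (i in 1:40) {
    nA <- sample(2:5, 1); nB <- sample(2:5, 1)
    a <- rnorm(nA); b <- rnorm(nB)
    mw <- mann_whitney_u(a, b)
    expect_equal(mw$p, enumerate_mw_p(a, b), tolerance = 1e-12)
    # U_A + U_B identity
    expect_equal(mw$U + mann_whitney_u(b, a)$U, nA * nB)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("identical samples give p = 1 and large samples use the corrected normal", {
  mw_same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw_same$p, 1)

  set.seed(405)
  a <- rnorm(10); b <- rnorm(10)
  mw <- mann_whitney_u(a, b)
  expect_equal(mw$method, "normal")
  # exact enumeration distribution (pwilcox) as oracle: agreement within 0.02
  U <- mw$U
  p_exact <- min(1, 2 * min(pwilcox(U, 10, 10), 1 - pwilcox(U - 1, 10, 10)))
  expect_lt(abs(mw$p - p_exact), 0.02)
  # and against the standard implementation with the same corrections
  wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
})

test_that("Benjamini-Hochberg adjustment is the hand step-up", {
  expect_equal(benjamini_hochberg(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.07, 5)), rep(0.07, 5))
  set.seed(406)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= 0 & adj <= 1))
  }
  # appending an uninformative p = 1 never removes rejections
  p <- c(0.001, 0.02, 0.8)
  expect_gte(sum(benjamini_hochberg(c(p, 1)) < 0.05),
             sum(benjamini_hochberg(p) < 0.05))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_de_fixture <- function(n = 40, shift = 3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", 1:12)
  cells <- sprintf("c%02d", 1:n)
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(cells, genes))
  lab <- rep(c(0L, 1L), each = n / 2)
  X[lab == 1L, "g01"] <- X[lab == 1L, "g01"] + shift   # planted DE gene
  list(expr = expression_matrix(X),
       rec = data.frame(cell_id = cells, drug_id = "dA", label = lab))
}

test_that("differential expression flags the planted gene and reports direction", {
  fx <- make_de_fixture()
  de <- de_by_response(fx$expr, fx$rec, "dA", sprintf("g%02d", 1:12))
  planted <- de[de$gene_id == "g01", ]
  expect_lt(planted$p_adj, 0.05)
  expect_equal(planted$direction, 1)               # higher in resistant
  expect_lt(sum(de$p_adj[de$gene_id != "g01"] < 0.05), 3)
  # direction equals the sign of the median difference for every gene
  expr <- unclass(fx$expr)
  for (g in de$gene_id) {
    d <- sign(median(expr[fx$rec$label == 1, g]) - median(expr[fx$rec$label == 0, g]))
    expect_equal(de$direction[de$gene_id == g], d)
  }
  expect_error(de_by_response(fx$expr, fx$rec[fx$rec$label == 1, ], "dA", "g01"),
               "lacks one response class")
  expect_error(de_by_response(fx$expr, fx$rec, "dA", "nope"), "unknown gene")
})

test_that("null genes reject at roughly the nominal rate", {
  set.seed(77)
  n <- 30
  cells <- sprintf("c%02d", 1:n)
  genes <- sprintf("g%03d", 1:300)
  X <- matrix(rnorm(n * 300), n, 300, dimnames = list(cells, genes))
  rec <- data.frame(cell_id = cells, drug_id = "dA",
                    label = rep(c(0L, 1L), each = n / 2))
  de <- de_by_response(expression_matrix(X), rec, "dA", genes)
  rate <- mean(de$p < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("the median-split IC50 analysis detects a monotone gene-response link", {
  set.seed(55)
  n <- 40
  cells <- sprintf("c%02d", 1:n)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(cells, c("gA", "gB", "gConst")))
  X[, "gConst"] <- 1
  ic50 <- data.frame(cell_id = cells, drug_id = "dA",
                     ln_ic50 = 2 * X[, "gA"] + rnorm(n, sd = 0.3))
  res <- ic50_by_median_split(expression_matrix(X), ic50, "dA", "gA")
  expect_lt(res$p, 0.001)
  expect_gt(res$median_high, res$median_low)
  # balanced split when no ties at the median
  expect_lte(abs(res$n_high - res$n_low), 1L)
  expect_error(ic50_by_median_split(expression_matrix(X), ic50, "dA", "gConst"),
               "degenerate")
})

test_that("the combined biomarker report merges ranking with the response tests", {
  bench <- mini_benchmark(seed = 30)
  fit <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
                l1 = 0.02, control = mini_control(seed = 12))
  rep <- biomarker_report(fit, bench$ref_ids[1], bench$dataset, k = 5)
  if (nrow(rep)) {
    expect_true(all(c("gene_id", "coefficient", "U", "p", "p_adj", "direction")
                    %in% names(rep)))
    expect_true(all(rep$p_adj >= rep$p - 1e-12))
  }
  expect_true(nrow(rep) <= 5)
})
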