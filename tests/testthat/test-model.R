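# Forward-pass algebra, prediction invariances, and model persistence.

bn_identity <- function(dnn) {
  # running stats such that infer-mode normalization is exactly the identity
  dnn$rm1 <- rep(0, dnn$H); dnn$rv1 <- rep(1 - dnn$eps, dnn$H)
  dnn$rm2 <- rep(0, dnn$H); dnn$rv2 <- rep(1 - dnn$eps, dnn$H)
  dnn
}

test_that("the ElasticNet bank computes per-reference sigmoid probabilities", {
  bank0 <- list(W = matrix(0, 3, 4), b = rep(0, 3))
  expect_equal(unname(elasticnet_forward(rnorm(4), bank0)[1, ]), rep(0.5, 3))
  bank1 <- list(W = matrix(1, 1, 1), b = 0)
  expect_equal(elasticnet_forward(0, bank1)[1, 1], 0.5)
  bank2 <- list(W = matrix(c(1, -1), 1, 2), b = 0)
  expect_equal(elasticnet_forward(c(log(2), 0), bank2)[1, 1], 2 / 3)
  expect_error(elasticnet_forward(rnorm(3), bank0), "does not match")
})

test_that("similarity weighting is the element-wise product", {
  z <- c(0.8, 0.6)
  expect_identical(weight_by_ssp(z, c(1, 1)), z)
  expect_identical(weight_by_ssp(z, c(0, 0)), c(0, 0))
  expect_equal(weight_by_ssp(z, c(0.5, 0)), c(0.4, 0))
  expect_error(weight_by_ssp(z, c(1, 1, 1)), "length mismatch")
})

test_that("the network forward pass reproduces hand-chained sigmoid values", {
  d <- refdnn:::new_dnn_params(1, 1, seed = 1)
  d$W1 <- matrix(0, 1, 1); d$W2 <- matrix(0, 1, 1); d$w_out <- 0; d$b_out <- 0
  d <- bn_identity(d)
  expect_equal(dnn_forward(1.23, d, "infer")$p, 0.5)  # all-zero weights

  d$W1 <- matrix(1, 1, 1); d$W2 <- matrix(1, 1, 1); d$w_out <- 1
  # independent scalar chain: sigma(sigma(sigma(1)))
  oracle <- 1 / (1 + exp(-(1 / (1 + exp(-(1 / (1 + exp(-1))))))))
  expect_equal(dnn_forward(1, d, "infer")$p, oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 4), 0.6626)

  # w_out = 0 pins the output at 0.5 regardless of input
  d$w_out <- 0
  expect_equal(dnn_forward(rnorm(1), d, "infer")$p, 0.5)
})

test_that("train-mode batch norm needs >= 2 samples and updates running stats", {
  d <- refdnn:::new_dnn_params(3, 2, seed = 2)
  expect_error(dnn_forward(matrix(rnorm(3), 1, 3), d, "train"), ">= 2")
  Z <- matrix(rnorm(12), 4, 3)
  out <- dnn_forward(Z, d, "train")
  expect_false(identical(out$dnn$rm1, d$rm1))
  expect_true(all(out$dnn$rv1 >= 0) && all(out$dnn$rv2 >= 0))
  expect_true(all(out$p > 0 & out$p < 1))
})

test_that("inference is independent of batch composition", {
  set.seed(5)
  d <- refdnn:::new_dnn_params(4, 3, seed = 3)
  d$rm1 <- rnorm(3); d$rv1 <- runif(3, 0.5, 2)
  d$rm2 <- rnorm(3); d$rv2 <- runif(3, 0.5, 2)
  Z <- matrix(rnorm(40), 10, 4)
  p_batch <- dnn_forward(Z, d, "infer")$p
  p_solo <- vapply(1:10, function(i) dnn_forward(Z[i, ], d, "infer")$p, numeric(1))
  expect_equal(p_batch, p_solo, tolerance = 1e-12)
})

test_that("the forward pass stays finite and bounded at extreme logits", {
  bank <- list(W = matrix(500, 1, 1), b = 0)
  expect_true(all(is.finite(elasticnet_forward(matrix(c(-1, 1), 2, 1), bank))))
  expect_true(is.finite(loss_dnn(c(0, 1), c(1 - 1e-16, 1e-16))))
  expect_true(loss_dnn(1, 0.5) > 0)
})

test_that("prediction composes the pipeline and respects gene identity, not order", {
  bench <- mini_benchmark(seed = 3)
  fit <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
                control = mini_control(seed = 1))
  pred <- predict(fit, bench$dataset)
  expect_equal(nrow(pred), nrow(bench$dataset$records))
  expect_true(all(pred$p_resistance > 0 & pred$p_resistance < 1))
  expect_equal(pred$p_sensitivity, 1 - pred$p_resistance)

  # jointly permuting input genes leaves predictions bit-identical
  expr <- unclass(bench$dataset$expression)
  perm <- sample(ncol(expr))
  pred2 <- predict(fit, expr[, perm], bench$dataset$fingerprints,
                   bench$dataset$records)
  expect_identical(pred$p_resistance, pred2$p_resistance)

  # missing genes are a hard error naming offenders
  expect_error(predict(fit, expr[, -1], bench$dataset$fingerprints,
                       bench$dataset$records), colnames(expr)[1])
  # fingerprint width mismatch
  expect_error(predict(fit, expr, fingerprint_table(
    matrix(1L, 1, 3, dimnames = list("dX", NULL)))), "width")
})

test_that("predictions are invariant under joint permutation of the reference panel", {
  bench <- mini_benchmark(seed = 4)
  fit <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
                control = mini_control(seed = 2))
  perm <- c(3, 1, 2)
  fit2 <- fit
  fit2$refs <- fingerprint_table(unclass(fit$refs)[perm, ])
  fit2$bank$W <- fit$bank$W[perm, ]
  fit2$bank$b <- fit$bank$b[perm]
  fit2$dnn$W1 <- fit$dnn$W1[perm, ]
  p1 <- predict(fit, bench$dataset)$p_resistance
  p2 <- predict(fit2, bench$dataset)$p_resistance
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("a drug sharing no substructure with the panel gets the constant cold-start floor", {
  bench <- mini_benchmark(seed = 5)
  fit <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
                control = mini_control(seed = 3))
  # fingerprint disjoint from every reference: on-bits where all refs are 0
  refbits <- unclass(fit$refs)
  free <- which(colSums(refbits) == 0)
  d_new <- integer(ncol(refbits)); d_new[free[1:2]] <- 1L
  fps <- fingerprint_table(rbind(unclass(bench$dataset$fingerprints),
                                 novel = d_new))
  pred <- predict(fit, bench$dataset$expression, fps,
                  data.frame(cell_id = rownames(bench$dataset$expression),
                             drug_id = "novel"))
  expect_equal(length(unique(round(pred$p_resistance, 12))), 1L)
})

test_that("models round-trip bit-exactly through the plain-text directory format", {
  bench <- mini_benchmark(seed = 6)
  fit <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
                control = mini_control(seed = 4))
  dir <- file.path(tempdir(), "model_roundtrip")
  save_refdnn(fit, dir)
  fit2 <- load_refdnn(dir)
  expect_identical(fit$bank$W, fit2$bank$W)
  expect_identical(fit$bank$b, fit2$bank$b)
  for (nm in c("W1", "g1", "b1", "W2", "g2", "b2", "w_out", "b_out",
               "rm1", "rv1", "rm2", "rv2"))
    expect_identical(unname(as.matrix(fit$dnn[[nm]])),
                     unname(as.matrix(fit2$dnn[[nm]])), label = nm)
  p1 <- predict(fit, bench$dataset)$p_resistance
  p2 <- predict(fit2, bench$dataset)$p_resistance
  expect_identical(p1, p2)

  # manifest damage is detected
  mf <- file.path(dir, "manifest.json")
  manifest <- jsonlite::read_json(mf)
  manifest$gene_ids <- NULL
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  expect_error(load_refdnn(dir), "truncated")

  manifest$gene_ids <- fit$gene_ids
  manifest$M <- manifest$M + 1L
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  expect_error(load_refdnn(dir), "does not match")
  unlink(dir, recursive = TRUE)
})

test_that("fitted-model methods expose coefficients, residuals and history", {
  bench <- mini_benchmark(seed = 8)
  fit <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
                control = mini_control(seed = 5))
  W <- coef(fit)
  expect_equal(dim(W), c(3L, 30L))
  expect_equal(rownames(W), bench$ref_ids)
  expect_equal(coef(fit, ref_drug = bench$ref_ids[2]), W[bench$ref_ids[2], ])
  expect_error(coef(fit, ref_drug = "nope"), "unknown")
  expect_equal(residuals(fit), fit$labels - fitted(fit))
  expect_output(print(fit), "reference drugs")
  s <- summary(fit)
  expect_s3_class(s, "summary.refdnn")
  expect_length(s$nonzero_coefficients, 3L)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
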