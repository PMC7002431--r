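# Losses, optimizers, initialization, gradients, and the training loop.

test_that("cross-entropy losses match closed forms", {
  expect_lt(loss_dnn(1, 1 - 1e-12), 1e-6)           # perfect prediction (clip floor)
  expect_equal(loss_dnn(1, 0.5), log(2))
  expect_equal(loss_dnn(c(1, 0), c(0.5, 0.5)), 2 * log(2))
  expect_error(loss_dnn(1, 1.2), "\\[0, 1\\]")

  z <- matrix(0.5, 2, 2)
  ind0 <- matrix(0, 2, 2)
  expect_identical(loss_elasticnet(c(1, 0), z, ind0), 0)  # no reference drugs
  ind1 <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(loss_elasticnet(c(1, 0), z, ind1), log(2))
  # an indicator firing twice counts both terms (degenerate duplicate refs)
  ind2 <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(loss_elasticnet(c(1, 0), z, ind2), 2 * log(2))

  expect_equal(total_loss(c(1, 0), c(0.5, 0.5), z, ind1), 3 * log(2))
})

test_that("the reference indicator compares drug identifiers", {
  ind <- reference_indicator(c("a", "b", "a"), c("a", "c"))
  expect_equal(ind, matrix(c(1, 0, 1, 0, 0, 0), 3, 2))
})

test_that("one FTRL-Proximal step reproduces the per-coordinate closed form", {
  st <- ftrl_state(1, alpha = 0.5, beta = 1, lambda1 = 0.1, lambda2 = 0)
  up <- ftrl_step(st, grad = 1, w = 0)
  expect_identical(up$w, -0.225)            # -(1 - 0.1) / ((1 + 1)/0.5)
  expect_identical(up$state$z, 1)
  expect_identical(up$state$n, 1)

  # zero gradient at zero weight is a fixed point
  st0 <- ftrl_state(c(2, 2), alpha = 0.1, lambda1 = 0.05)
  up0 <- ftrl_step(st0, matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(all(up0$w == 0))

  # overwhelming l1 pins every weight at exactly zero
  sth <- ftrl_state(c(3, 4), alpha = 0.1, lambda1 = 1e6)
  w <- matrix(rnorm(12), 3, 4)
  for (i in 1:5) {
    u <- ftrl_step(sth, matrix(rnorm(12), 3, 4), w)
    w <- u$w; sth <- u$state
  }
  expect_true(all(w == 0))
  expect_error(ftrl_step(st, NaN, 0), "non-finite")
})

test_that("one Adam step matches the bias-corrected closed form", {
  st <- adam_state(1, alpha = 0.001)
  up <- adam_step(st, grad = 1, params = 0)
  expect_equal(up$params, -0.001 / (1 + 1e-8), tolerance = 1e-12)

  # zero gradients never move parameters
  st2 <- adam_state(c(2, 2), alpha = 0.01)
  p0 <- matrix(rnorm(4), 2, 2); p <- p0
  for (i in 1:3) { u <- adam_step(st2, matrix(0, 2, 2), p); p <- u$params; st2 <- u$state }
  expect_identical(p, p0)

  # first step moves opposite the gradient, coordinate-wise
  st3 <- adam_state(c(5), alpha = 0.1)
  g <- c(3, -2, 0.5, -0.1, 10)
  u3 <- adam_step(st3, g, rep(0, 5))
  expect_true(all(sign(u3$params) == -sign(g)))
})

test_that("Glorot initialization respects its support bound, seed and zero mean", {
  W <- glorot_init(c(10, 10), seed = 42)
  lim <- sqrt(6 / 20)
  expect_true(all(abs(W) <= lim))
  expect_identical(W, glorot_init(c(10, 10), seed = 42))
  expect_false(identical(W, glorot_init(c(10, 10), seed = 43)))

  big <- glorot_init(c(500, 200), seed = 7)     # 1e5 draws
  se <- (2 * sqrt(6 / 700)) / sqrt(12) / sqrt(length(big))
  expect_lt(abs(mean(big)), 3 * se)
})

test_that("analytic gradients of the composite loss match central finite differences", {
  set.seed(9)
  G <- 3; M <- 2; H <- 2; B <- 6
  X <- matrix(rnorm(B * G), B, G)
  S <- matrix(runif(B * M), B, M)
  y <- rbinom(B, 1, 0.5)
  ind <- matrix(rbinom(B * M, 1, 0.4), B, M)
  bank <- list(W = matrix(rnorm(M * G) * 0.5, M, G), b = rnorm(M) * 0.2)
  dnn <- refdnn:::new_dnn_params(M, H, seed = 17)
  dnn$g1 <- runif(H, 0.5, 1.5); dnn$b1 <- rnorm(H) * 0.2
  dnn$g2 <- runif(H, 0.5, 1.5); dnn$b2 <- rnorm(H) * 0.2
  dnn$b_out <- 0.1

  lg <- refdnn:::refdnn_loss_grad(X, S, y, ind, bank, dnn)
  loss_at <- function(bank, dnn) {
    z <- plogis(sweep(X %*% t(bank$W), 2, bank$b, `+`))
    total_loss(y, dnn_forward(z * S, dnn, "train")$p, z, ind)
  }
  eps <- 1e-6
  check_block <- function(holder, field, analytic) {
    v <- holder[[field]]
    for (i in seq_along(v)) {
      vp <- v; vp[i] <- vp[i] + eps
      vm <- v; vm[i] <- vm[i] - eps
      hp <- holder; hp[[field]] <- vp
      hm <- holder; hm[[field]] <- vm
      num <- if (identical(names(holder)[1], "W"))
        (loss_at(hp, dnn) - loss_at(hm, dnn)) / (2 * eps)
      else (loss_at(bank, hp) - loss_at(bank, hm)) / (2 * eps)
      expect_equal(as.numeric(analytic)[i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", field, i))
    }
  }
  check_block(bank, "W", lg$grads$bank_W)
  check_block(bank, "b", lg$grads$bank_b)
  for (nm in refdnn:::DNN_TRAINABLE) check_block(dnn, nm, lg$grads[[nm]])
})

test_that("FTRL l1 strength controls exact sparsity of the trained bank", {
  bench <- mini_benchmark(seed = 10)
  fit_l1 <- function(l1) refdnn(bench$dataset, refs = bench$ref_ids,
                                hidden_units = 4, l1 = l1,
                                control = mini_control(seed = 6))
  f0 <- fit_l1(0)
  f1 <- fit_l1(1.0)
  expect_identical(sum(f0$bank$W == 0), 0L)            # no exact zeros at l1 = 0
  expect_lte(sum(f1$bank$W != 0), sum(f0$bank$W != 0)) # monotone in l1
  expect_gt(sum(f1$bank$W == 0), 0L)
})

test_that("training on a separable planted dataset reduces loss and stops early", {
  bench <- mini_benchmark(seed = 12)
  fit <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
                control = refdnn_control(batch_size = 16, max_epochs = 200,
                                         patience = 10, seed = 7))
  h <- fit$history
  expect_lt(nrow(h), 200L)                              # early stopping fired
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1L])
  expect_lt(min(h$val_loss), h$val_loss[1L])
  # stopping-rule arithmetic: epochs run = best epoch + patience when early
  expect_identical(nrow(h), fit$best_epoch + 10L)
})

test_that("the returned parameters are those of the best validation epoch", {
  bench <- mini_benchmark(seed = 13)
  ctrl <- mini_control(seed = 8)
  fit <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
                control = ctrl)
  # reconstruct the validation split and recompute the prediction loss
  rec <- bench$dataset$records
  sp <- refdnn:::stratified_split(as.numeric(rec$label), ctrl$val_fraction,
                                  refdnn:::substream_seed(ctrl$seed, "split"))
  va <- sp$val
  X <- unclass(bench$dataset$expression)[rec$cell_id[va], , drop = FALSE]
  S <- ssp_matrix(bench$dataset$fingerprints, fit$refs)[rec$drug_id[va], , drop = FALSE]
  z <- elasticnet_forward(X, fit$bank)
  p <- dnn_forward(weight_by_ssp(z, S), fit$dnn, "infer")$p
  expect_equal(loss_dnn(rec$label[va], p) / length(va),
               min(fit$history$val_loss), tolerance = 1e-12)
})

test_that("training is bit-reproducible for identical seeds and configs", {
  bench <- mini_benchmark(seed = 14)
  f1 <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
               control = mini_control(seed = 9))
  f2 <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
               control = mini_control(seed = 9))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$bank$W, f2$bank$W)
  expect_identical(f1$fitted, f2$fitted)
  f3 <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
               control = mini_control(seed = 10))
  expect_false(identical(f1$fitted, f3$fitted))
})

test_that("degenerate training inputs are rejected", {
  bench <- mini_benchmark(seed = 15)
  ds <- bench$dataset
  ds$records$label <- 1L
  expect_error(refdnn(ds, refs = bench$ref_ids), "both response classes")
  expect_error(refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 0),
               "positive")
  expect_error(refdnn(bench$dataset, refs = bench$ref_ids, lr_ftrl = -1),
               "positive")
  expect_error(refdnn(bench$dataset, refs = c(bench$ref_ids, "ghost")),
               "ghost")
})
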