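# Composite loss, optimizers, and the refdnn() fitting function.
#
# The model minimizes the sum of two cross-entropies: the network's loss on
# every (cell, drug) pair, plus the bank's loss restricted to pairs whose drug
# IS one of the reference drugs (each such pair supervises exactly that
# reference's classifier directly). The bank is updated with FTRL-Proximal so
# the l1 strength produces exact zeros; the network is updated with Adam.

#' Binary cross-entropy loss of the network
#'
#' `-sum(y log p + (1 - y) log(1 - p))`, summed (not averaged) over the batch.
#' Probabilities are clipped to `[1e-7, 1 - 1e-7]` before the logarithm as a
#' numerical guard.
#'
#' @param y 0/1 labels.
#' @param p Predicted resistance probabilities in (0, 1).
#' @return Non-negative scalar.
#' @export
loss_dnn <- function(y, p) {
  if (length(y) != length(p)) stopf("label/prediction length mismatch")
  if (any(p < 0 | p > 1)) stopf("predictions must lie in [0, 1]")
  p <- clip_prob(p)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Cross-entropy loss of the ElasticNet bank
#'
#' Only pairs whose target drug is itself a reference drug contribute: pair i
#' with drug equal to reference j adds the cross-entropy between its label and
#' the bank probability `z[i, j]`. A batch containing no reference drug has
#' loss exactly 0. Drug/reference equality is by identifier, and duplicate
#' identical references (rejected upstream) would each contribute a term.
#'
#' @param y 0/1 labels, length N.
#' @param z Bank probability matrix, N x M (rows follow `y`).
#' @param indicator N x M 0/1 matrix: `indicator[i, j] = 1` iff pair i's drug
#'   is reference j. See [reference_indicator()].
#' @return Non-negative scalar.
#' @export
loss_elasticnet <- function(y, z, indicator) {
  if (any(z < 0 | z > 1)) stopf("bank probabilities must lie in [0, 1]")
  if (!all(dim(z) == dim(indicator))) stopf("z / indicator shape mismatch")
  zc <- clip_prob(z)
  ll <- y * log(zc) + (1 - y) * log(1 - zc)
  -sum(indicator * ll)
}

#' @rdname loss_elasticnet
#' @param drug_ids Drug identifier per pair.
#' @param ref_ids Reference drug identifiers (canonical order).
#' @export
reference_indicator <- function(drug_ids, ref_ids) {
  outer(drug_ids, ref_ids, `==`) * 1
}

#' Total training loss
#'
#' Sum of [loss_dnn()] and [loss_elasticnet()]; every parameter of the model,
#' bank and network alike, receives gradients of this total.
#'
#' @inheritParams loss_dnn
#' @inheritParams loss_elasticnet
#' @return Non-negative scalar.
#' @export
total_loss <- function(y, p, z, indicator) {
  loss_dnn(y, p) + loss_elasticnet(y, z, indicator)
}

#' Glorot (Xavier) uniform initialization
#'
#' Draws uniformly on `[-limit, limit]` with `limit = sqrt(6 / (fan_in +
#' fan_out))`, the variance-preserving choice for layers between units of
#' comparable scale. Deterministic per seed.
#'
#' @param shape Integer vector `c(fan_in, fan_out)`.
#' @param seed Integer seed.
#' @return `fan_in` x `fan_out` matrix.
#' @export
glorot_init <- function(shape, seed) {
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  limit <- sqrt(6 / (shape[1L] + shape[2L]))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(stats::runif(prod(shape), -limit, limit), shape[1L], shape[2L])
}

#' One FTRL-Proximal update
#'
#' Per-coordinate Follow-The-Regularized-Leader with l1/l2 regularization: the
#' accumulator update is `sigma = (sqrt(n + g^2) - sqrt(n)) / alpha`,
#' `z <- z + g - sigma * w`, `n <- n + g^2`, and the new weight is exactly 0
#' when `|z| <= lambda1`, otherwise
#' `w = -(z - sign(z) * lambda1) / ((beta + sqrt(n)) / alpha + lambda2)`.
#' Unlike plain gradient descent this drives coefficients to exact zeros,
#' which is what makes the bank's coefficients usable for biomarker selection.
#'
#' @param state List with accumulators `z`, `n` (same shape as `w`) and scalars
#'   `alpha` (learning rate), `beta` (default 1), `lambda1`, `lambda2`. Create
#'   with [ftrl_state()].
#' @param grad Gradient, same shape as `w`.
#' @param w Current weights.
#' @return List with updated `w` and `state`.
#' @export
ftrl_step <- function(state, grad, w) {
  if (any(!is.finite(grad))) stopf("non-finite gradient passed to ftrl_step")
  g2 <- grad * grad
  sigma <- (sqrt(state$n + g2) - sqrt(state$n)) / state$alpha
  state$z <- state$z + grad - sigma * w
  state$n <- state$n + g2
  shrink <- abs(state$z) <= state$lambda1
  denom <- (state$beta + sqrt(state$n)) / state$alpha + state$lambda2
  w_new <- -(state$z - sign(state$z) * state$lambda1) / denom
  w_new[shrink] <- 0
  list(w = w_new, state = state)
}

#' @rdname ftrl_step
#' @param shape Dimensions of the weight block.
#' @param alpha,beta,lambda1,lambda2 FTRL constants.
#' @export
ftrl_state <- function(shape, alpha, beta = 1, lambda1 = 0, lambda2 = 0) {
  z <- array(0, dim = shape); n <- array(0, dim = shape)
  if (length(shape) == 1L) { z <- as.numeric(z); n <- as.numeric(n) }
  list(z = z, n = n, alpha = alpha, beta = beta,
       lambda1 = lambda1, lambda2 = lambda2)
}

#' One Adam update
#'
#' Standard bias-corrected Adam: `m <- b1 m + (1 - b1) g`,
#' `v <- b2 v + (1 - b2) g^2`, `p <- p - alpha * mhat / (sqrt(vhat) + eps)`.
#'
#' @param state List from [adam_state()] (`m`, `v`, step counter `t`, and the
#'   constants `alpha`, `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`).
#' @param grad Gradient, shaped like `params`.
#' @param params Current parameter values.
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(state, grad, params) {
  if (any(!is.finite(grad))) stopf("non-finite gradient passed to adam_step")
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad * grad
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(params = params - state$alpha * mhat / (sqrt(vhat) + state$eps),
       state = state)
}

#' @rdname adam_step
#' @param shape Dimensions of the parameter block.
#' @param alpha Learning rate.
#' @export
adam_state <- function(shape, alpha) {
  z <- array(0, dim = shape)
  if (length(shape) == 1L) z <- as.numeric(z)
  list(m = z, v = z, t = 0L, alpha = alpha, beta1 = 0.9, beta2 = 0.999,
       eps = 1e-8)
}

# Forward + analytic gradient of the summed total loss for one batch, using
# train-mode batch statistics. Returns the loss, gradients for every trainable
# block, and the DNN list with updated running statistics.
refdnn_loss_grad <- function(X, S, y, indicator, bank, dnn) {
  B <- nrow(X)
  t_bank <- sweep(X %*% t(bank$W), 2L, bank$b, `+`)
  z <- sigmoid(t_bank)
  zhat <- z * S
  fwd <- dnn_forward(zhat, dnn, mode = "train")
  p <- fwd$p
  cache <- fwd$cache
  loss <- total_loss(y, p, z, indicator)

  dlogit <- p - y                                    # d(sum BCE)/d logit
  dw_out <- drop(t(cache$h2) %*% dlogit)
  db_out <- sum(dlogit)
  dh2 <- outer(dlogit, dnn$w_out)
  du2 <- dh2 * cache$h2 * (1 - cache$h2)
  bb2 <- bn_backward(du2, dnn$g2, cache$bn2)
  dW2 <- t(cache$h1) %*% bb2$da
  dh1 <- bb2$da %*% t(dnn$W2)
  du1 <- dh1 * cache$h1 * (1 - cache$h1)
  bb1 <- bn_backward(du1, dnn$g1, cache$bn1)
  dW1 <- t(zhat) %*% bb1$da
  dzhat <- bb1$da %*% t(dnn$W1)

  dz <- dzhat * S                                    # network path into z
  dt_bank <- dz * z * (1 - z) + indicator * (z - y)  # + direct bank loss path
  dbank_W <- t(dt_bank) %*% X
  dbank_b <- colSums(dt_bank)

  list(loss = loss, dnn = fwd$dnn, p = p,
       grads = list(bank_W = dbank_W, bank_b = dbank_b,
                    W1 = dW1, g1 = bb1$dg, b1 = bb1$db,
                    W2 = dW2, g2 = bb2$dg, b2 = bb2$db,
                    w_out = dw_out, b_out = db_out))
}

#' Training control parameters
#'
#' @param batch_size Mini-batch size (default 64).
#' @param max_epochs Epoch cap (default 1000).
#' @param patience Epochs without validation improvement before stopping
#'   (default 10).
#' @param val_fraction Fraction held out (stratified by label) for early
#'   stopping (default 0.2).
#' @param seed Integer seed governing the split, initialization and batch
#'   shuffling, via named substreams.
#' @param verbose Print per-epoch losses.
#' @return List of class `refdnn_control`.
#' @export
refdnn_control <- function(batch_size = 64L, max_epochs = 1000L, patience = 10L,
                           val_fraction = 0.2, seed = 1L, verbose = FALSE) {
  stopifnot(batch_size >= 2L, max_epochs >= 1L, patience >= 1L,
            val_fraction > 0, val_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "refdnn_control")
}

# Stratified index split: returns list(train, val).
stratified_split <- function(labels, val_fraction, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  val <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(length(idx) * val_fraction))
    val <- c(val, sample(idx, n_val))
  }
  list(train = setdiff(seq_along(labels), val), val = sort(val))
}

#' Fit the reference-drug resistance model
#'
#' Trains the joint model on an aligned dataset: per-reference-drug sparse
#' logistic classifiers (the bank) over gene expression, fused with the target
#' drug's Tanimoto similarity profile and passed through a two-hidden-layer
#' batch-normalized sigmoid network. The bank is optimized with FTRL-Proximal
#' (so `l1 > 0` yields exact zero coefficients), the network with Adam, both
#' on the batch-mean gradient of the composite cross-entropy loss. Training
#' holds out a stratified `val_fraction` of the records and keeps the
#' parameters of the epoch with the lowest validation loss (early stopping).
#'
#' @param dataset A `refdnn_dataset` from [align_dataset()] (or
#'   [make_benchmark()]).
#' @param refs Reference panel: a [fingerprint_table()], or a character vector
#'   of drug ids selecting rows of `dataset$fingerprints`. Default: all drugs
#'   in the dataset, in id order.
#' @param hidden_units Width of both hidden layers.
#' @param lr_ftrl FTRL learning rate for the bank.
#' @param lr_adam Adam learning rate for the network.
#' @param l1,l2 FTRL regularization strengths (bank weights only; biases are
#'   unpenalized, and the network carries no l1/l2).
#' @param control A [refdnn_control()] list.
#' @return An object of class `refdnn`; see [predict.refdnn()],
#'   [coef.refdnn()], [save_refdnn()].
#' @examples
#' bench <- make_benchmark("strong_signal", seed = 1,
#'                         sizes = list(n_cells = 20, n_genes = 30, n_drugs = 4,
#'                                      n_refs = 3, k_support = 3))
#' fit <- refdnn(bench$dataset, refs = bench$ref_ids, hidden_units = 4,
#'               control = refdnn_control(max_epochs = 3, seed = 1))
#' fit
#' @export
refdnn <- function(dataset, refs = NULL, hidden_units = 16L,
                   lr_ftrl = 0.5, lr_adam = 0.003, l1 = 0.02, l2 = 0.01,
                   control = refdnn_control()) {
  if (!inherits(dataset, "refdnn_dataset")) stopf("dataset must be a refdnn_dataset")
  if (hidden_units < 1L) stopf("hidden_units must be positive")
  if (lr_ftrl <= 0 || lr_adam <= 0) stopf("learning rates must be positive")
  if (l1 < 0 || l2 < 0) stopf("regularization strengths must be non-negative")
  records <- dataset$records
  if (length(unique(records$label)) < 2L)
    stopf("training needs both response classes present")

  if (is.null(refs)) {
    refs <- dataset$fingerprints[sort(rownames(dataset$fingerprints)), , drop = FALSE]
    refs <- fingerprint_table(unclass(refs))
  } else if (is.character(refs)) {
    miss <- setdiff(refs, rownames(dataset$fingerprints))
    if (length(miss)) stopf("unknown reference drug(s): %s", paste(miss, collapse = ", "))
    refs <- fingerprint_table(unclass(dataset$fingerprints)[refs, , drop = FALSE])
  }
  M <- nrow(refs); H <- as.integer(hidden_units)
  gene_ids <- colnames(dataset$expression)
  G <- length(gene_ids)

  X_all <- unclass(dataset$expression)[records$cell_id, , drop = FALSE]
  S_all <- ssp_matrix(dataset$fingerprints, refs)[records$drug_id, , drop = FALSE]
  I_all <- reference_indicator(records$drug_id, rownames(refs))
  y_all <- as.numeric(records$label)

  bank <- new_bank(M, G, seed = substream_seed(control$seed, "init_bank"))
  dnn <- new_dnn_params(M, H, seed = substream_seed(control$seed, "init_dnn"))

  sp <- stratified_split(y_all, control$val_fraction,
                         seed = substream_seed(control$seed, "split"))
  tr <- sp$train; va <- sp$val

  st_bank_W <- ftrl_state(dim(bank$W), alpha = lr_ftrl, lambda1 = l1, lambda2 = l2)
  st_bank_b <- ftrl_state(M, alpha = lr_ftrl, lambda1 = 0, lambda2 = 0)
  st_dnn <- lapply(DNN_TRAINABLE, function(nm)
    adam_state(if (is.matrix(dnn[[nm]])) dim(dnn[[nm]]) else length(dnn[[nm]]),
               alpha = lr_adam))
  names(st_dnn) <- DNN_TRAINABLE

  # Early stopping monitors the network's prediction loss on the held-out
  # split. The bank's own cross-entropy is deliberately excluded: it is
  # auxiliary supervision for representation learning and its validation value
  # rises as the bank tightens, which would halt training long before the
  # classifier converges.
  val_loss_of <- function(bank, dnn) {
    z <- elasticnet_forward(X_all[va, , drop = FALSE], bank)
    p <- dnn_forward(weight_by_ssp(z, S_all[va, , drop = FALSE]), dnn, "infer")$p
    loss_dnn(y_all[va], p) / length(va)
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, bank = bank, dnn = dnn, epoch = 0L)
  wait <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(control$seed, "batches"))

  for (epoch in seq_len(control$max_epochs)) {
    idx <- sample(tr)
    n_batch <- ceiling(length(idx) / control$batch_size)
    ep_loss <- 0
    for (b in seq_len(n_batch)) {
      bi <- idx[(((b - 1L) * control$batch_size + 1L)):min(b * control$batch_size, length(idx))]
      if (length(bi) < 2L) next  # batch norm needs >= 2 samples
      lg <- refdnn_loss_grad(X_all[bi, , drop = FALSE], S_all[bi, , drop = FALSE],
                             y_all[bi], I_all[bi, , drop = FALSE], bank, dnn)
      dnn <- lg$dnn
      ep_loss <- ep_loss + lg$loss
      scale <- 1 / length(bi)  # optimizers consume the batch-mean gradient
      up_w <- ftrl_step(st_bank_W, lg$grads$bank_W * scale, bank$W)
      bank$W <- up_w$w; st_bank_W <- up_w$state
      up_b <- ftrl_step(st_bank_b, lg$grads$bank_b * scale, bank$b)
      bank$b <- up_b$w; st_bank_b <- up_b$state
      for (nm in DNN_TRAINABLE) {
        up <- adam_step(st_dnn[[nm]], lg$grads[[nm]] * scale, dnn[[nm]])
        dnn[[nm]] <- up$params; st_dnn[[nm]] <- up$state
      }
    }
    vl <- val_loss_of(bank, dnn)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / length(tr),
                                         val_loss = vl))
    if (control$verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      ep_loss / length(tr), vl))
    if (vl < best$val - 1e-12) {
      best <- list(val = vl, bank = bank, dnn = dnn, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }

  model <- new_refdnn(refs = refs, gene_ids = gene_ids,
                      bank = best$bank, dnn = best$dnn,
                      hp = list(hidden_units = H, lr_ftrl = lr_ftrl,
                                lr_adam = lr_adam, l1 = l1, l2 = l2),
                      history = history, control = control,
                      call = match.call())
  z_fit <- elasticnet_forward(X_all, model$bank)
  model$fitted <- drop(dnn_forward(weight_by_ssp(z_fit, S_all), model$dnn, "infer")$p)
  model$labels <- y_all
  model$best_epoch <- best$epoch
  model
}
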