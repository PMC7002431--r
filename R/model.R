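# Model containers and the forward pass.
#
# A fitted model (class "refdnn") bundles:
#   refs     - reference-drug fingerprint table (row order is canonical M order)
#   gene_ids - gene order the bank was trained on (length G)
#   bank     - list(W: M x G, b: M): one sparse logistic classifier per reference
#   dnn      - list(W1: M x H, g1, b1, W2: H x H, g2, b2, w_out: H, b_out,
#              rm1, rv1, rm2, rv2, momentum, eps, H): two equal-width
#              batch-normalized sigmoid hidden layers and a sigmoid output unit
#   hp       - the five tunables (hidden_units, lr_ftrl, lr_adam, l1, l2)

#' ElasticNet-bank forward pass
#'
#' Applies every reference drug's logistic classifier to each cell line:
#' entry (i, j) is the predicted probability that cell line i is resistant to
#' reference drug j, `sigmoid(w_j . x_i + b_j)`.
#'
#' @param x Expression matrix (cells x genes) or a single expression vector.
#' @param bank List with `W` (references x genes) and `b` (per-reference bias).
#' @return Probability matrix, cells x references, entries in (0, 1).
#' @export
elasticnet_forward <- function(x, bank) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != ncol(bank$W))
    stopf("expression length %d does not match bank gene dimension %d",
          ncol(X), ncol(bank$W))
  sigmoid(sweep(X %*% t(bank$W), 2L, bank$b, `+`))
}

#' Weight bank probabilities by a structure similarity profile
#'
#' The Hadamard (element-wise) product of the per-reference resistance
#' probabilities with the target drug's Tanimoto similarities: information from
#' a reference drug contributes in proportion to how structurally similar the
#' target drug is to it.
#'
#' @param z Probability vector/matrix from [elasticnet_forward()].
#' @param s Similarity profile of matching length (rows of [ssp_matrix()]).
#' @return Element-wise product, same shape as `z`.
#' @export
weight_by_ssp <- function(z, s) {
  if (is.matrix(z)) {
    s <- if (is.matrix(s)) s else matrix(s, nrow(z), length(s), byrow = TRUE)
    if (!all(dim(z) == dim(s))) stopf("length mismatch between z and SSP")
  } else if (length(z) != length(s)) {
    stopf("length mismatch: z has %d entries, SSP has %d", length(z), length(s))
  }
  z * s
}

# Fresh DNN parameter set. Pre-BN linear layers carry no additive bias (the BN
# shift beta plays that role); the output unit has a bias and no batch norm.
new_dnn_params <- function(M, H, seed, eps = 1e-3, momentum = 0.99) {
  list(
    W1 = glorot_init(c(M, H), seed = substream_seed(seed, "W1")),
    g1 = rep(1, H), b1 = rep(0, H),
    W2 = glorot_init(c(H, H), seed = substream_seed(seed, "W2")),
    g2 = rep(1, H), b2 = rep(0, H),
    w_out = drop(glorot_init(c(H, 1L), seed = substream_seed(seed, "w_out"))),
    b_out = 0,
    rm1 = rep(0, H), rv1 = rep(1, H),
    rm2 = rep(0, H), rv2 = rep(1, H),
    momentum = momentum, eps = eps, H = H
  )
}

new_bank <- function(M, G, seed) {
  W <- t(vapply(seq_len(M), function(j)
    drop(glorot_init(c(G, 1L), seed = substream_seed(seed, paste0("bank", j)))),
    numeric(G)))
  list(W = matrix(W, M, G), b = rep(0, M))
}

DNN_TRAINABLE <- c("W1", "g1", "b1", "W2", "g2", "b2", "w_out", "b_out")

#' Feedforward-network forward pass
#'
#' Two equal-width hidden layers, each linear transform -> batch normalization
#' -> sigmoid, then a sigmoid output unit giving the probability of resistance.
#' In `"train"` mode batch statistics (mean, biased variance) normalize each
#' unit and the running statistics are updated with momentum; `"infer"` mode
#' uses the stored running statistics, so a sample's prediction does not depend
#' on what it is batched with.
#'
#' @param zhat Similarity-weighted probability matrix (batch x references) or a
#'   single vector.
#' @param dnn DNN parameter list (see [refdnn()]).
#' @param mode `"infer"` (default) or `"train"`; train mode needs a batch of at
#'   least 2 rows for batch statistics.
#' @return List with `p` (probability vector, one per row), `dnn` (parameters,
#'   with updated running statistics in train mode) and `cache` (intermediate
#'   activations for backpropagation).
#' @export
dnn_forward <- function(zhat, dnn, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  Z <- if (is.matrix(zhat)) zhat else matrix(zhat, nrow = 1L)
  if (ncol(Z) != nrow(dnn$W1))
    stopf("input width %d does not match W1 rows %d", ncol(Z), nrow(dnn$W1))
  if (mode == "train" && nrow(Z) < 2L)
    stopf("train-mode batch normalization needs a batch of >= 2 samples")

  bn <- function(a, gamma, beta, rm, rv) {
    if (mode == "train") {
      mu <- colMeans(a)
      v <- colMeans(a * a) - mu * mu
      v <- pmax(v, 0)
    } else {
      mu <- rm; v <- rv
    }
    istd <- 1 / sqrt(v + dnn$eps)
    xh <- sweep(sweep(a, 2L, mu, `-`), 2L, istd, `*`)
    u <- sweep(sweep(xh, 2L, gamma, `*`), 2L, beta, `+`)
    list(u = u, xh = xh, istd = istd, mu = mu, v = v)
  }

  a1 <- Z %*% dnn$W1
  bn1 <- bn(a1, dnn$g1, dnn$b1, dnn$rm1, dnn$rv1)
  h1 <- sigmoid(bn1$u)
  a2 <- h1 %*% dnn$W2
  bn2 <- bn(a2, dnn$g2, dnn$b2, dnn$rm2, dnn$rv2)
  h2 <- sigmoid(bn2$u)
  logit <- drop(h2 %*% dnn$w_out) + dnn$b_out
  p <- sigmoid(logit)

  if (mode == "train") {
    m <- dnn$momentum
    dnn$rm1 <- m * dnn$rm1 + (1 - m) * bn1$mu
    dnn$rv1 <- m * dnn$rv1 + (1 - m) * bn1$v
    dnn$rm2 <- m * dnn$rm2 + (1 - m) * bn2$mu
    dnn$rv2 <- m * dnn$rv2 + (1 - m) * bn2$v
  }
  list(p = p, dnn = dnn,
       cache = list(Z = Z, h1 = h1, h2 = h2, bn1 = bn1, bn2 = bn2, mode = mode))
}

# Backward pass through one batch-norm layer (train-mode batch statistics).
bn_backward <- function(du, gamma, cache) {
  B <- nrow(du)
  dg <- colSums(du * cache$xh)
  db <- colSums(du)
  dxh <- sweep(du, 2L, gamma, `*`)
  s1 <- colSums(dxh)
  s2 <- colSums(dxh * cache$xh)
  da <- sweep(B * dxh - matrix(s1, B, length(s1), byrow = TRUE) -
                cache$xh * matrix(s2, B, length(s2), byrow = TRUE),
              2L, cache$istd / B, `*`)
  list(da = da, dg = dg, db = db)
}

#' Predict drug resistance for new (cell line, drug) pairs
#'
#' Composes the full model: similarity profile of each drug against the
#' reference panel, ElasticNet-bank probabilities for each cell line,
#' similarity weighting, and the network in inference mode. Genes are matched
#' by identifier and reordered to the training order; missing genes or a
#' fingerprint width mismatch are errors.
#'
#' @param object A fitted [refdnn()] model.
#' @param expression Expression matrix (cells x genes, identifier dimnames) or
#'   a `refdnn_dataset` (in which case `fingerprints`/`records` default to its
#'   components).
#' @param fingerprints Fingerprint table for the drugs to score.
#' @param records Data.frame with `cell_id`, `drug_id` naming the pairs to
#'   score; defaults to the full cross of cells and drugs.
#' @param ... Unused.
#' @return Data.frame with `cell_id`, `drug_id`, `p_resistance`,
#'   `p_sensitivity` (`= 1 - p_resistance`).
#' @export
predict.refdnn <- function(object, expression, fingerprints = NULL,
                           records = NULL, ...) {
  if (inherits(expression, "refdnn_dataset")) {
    ds <- expression
    expression <- ds$expression
    fingerprints <- fingerprints %||% ds$fingerprints
    records <- records %||% ds$records
  }
  if (is.null(fingerprints)) stopf("fingerprints are required")
  expr <- as.matrix(unclass(expression))
  missing_genes <- setdiff(object$gene_ids, colnames(expr))
  if (length(missing_genes))
    stopf("expression data lacks %d model gene(s): %s%s",
          length(missing_genes),
          paste(utils::head(missing_genes, 5L), collapse = ", "),
          if (length(missing_genes) > 5L) ", ..." else "")
  expr <- expr[, object$gene_ids, drop = FALSE]
  fpm <- as_ref_matrix(fingerprints)
  if (ncol(fpm) != ncol(object$refs))
    stopf("fingerprint width %d does not match model width %d",
          ncol(fpm), ncol(object$refs))
  if (is.null(records))
    records <- expand.grid(cell_id = rownames(expr), drug_id = rownames(fpm),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bad_cell <- setdiff(records$cell_id, rownames(expr))
  bad_drug <- setdiff(records$drug_id, rownames(fpm))
  if (length(bad_cell) || length(bad_drug))
    stopf("records reference unknown identifiers: %s",
          paste(c(bad_cell, bad_drug), collapse = ", "))

  S_drug <- ssp_matrix(fingerprints, object$refs)       # drugs x M
  Z_cell <- elasticnet_forward(expr, object$bank)       # cells x M
  Z <- Z_cell[records$cell_id, , drop = FALSE]
  S <- S_drug[records$drug_id, , drop = FALSE]
  p <- dnn_forward(weight_by_ssp(Z, S), object$dnn, mode = "infer")$p
  data.frame(cell_id = records$cell_id, drug_id = records$drug_id,
             p_resistance = as.numeric(p), p_sensitivity = 1 - as.numeric(p),
             stringsAsFactors = FALSE)
}

#' Save / load a fitted model as a plain-text directory
#'
#' All numeric arrays are written with 17 significant digits, which round-trips
#' IEEE doubles exactly, alongside a JSON manifest recording dimensions,
#' identifiers, hyperparameters and a format version.
#'
#' @param model A fitted [refdnn()] model.
#' @param path Directory to write (created if needed).
#' @return `path` invisibly (`save_refdnn`); the model (`load_refdnn`).
#' @export
save_refdnn <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  arrays <- c(list(bank_W = model$bank$W, bank_b = model$bank$b),
              model$dnn[c("W1", "g1", "b1", "W2", "g2", "b2", "w_out", "b_out",
                          "rm1", "rv1", "rm2", "rv2")])
  for (nm in names(arrays))
    write_numeric_matrix(as.matrix(arrays[[nm]]), file.path(path, paste0(nm, ".txt")))
  writeLines(paste(rownames(model$refs),
                   apply(unclass(model$refs), 1L, paste, collapse = "")),
             file.path(path, "references.tsv"))
  manifest <- list(
    format = "refdnn-model-v1",
    M = nrow(model$refs), G = length(model$gene_ids), H = model$dnn$H,
    F = ncol(model$refs),
    momentum = model$dnn$momentum, eps = model$dnn$eps,
    output_bias = TRUE,
    reference_ids = rownames(model$refs),
    gene_ids = model$gene_ids,
    hyperparameters = model$hp,
    history_epochs = if (!is.null(model$history)) nrow(model$history) else 0L
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history))
    utils::write.table(model$history, file.path(path, "history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_refdnn
#' @export
load_refdnn <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stopf("no manifest.json under %s", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "refdnn-model-v1"))
    stopf("unsupported model format '%s'", manifest$format %||% "<missing>")
  need <- c("M", "G", "H", "reference_ids", "gene_ids", "hyperparameters")
  miss <- need[!need %in% names(manifest)]
  if (length(miss)) stopf("truncated manifest: missing field(s) %s",
                          paste(miss, collapse = ", "))
  rd <- function(nm) {
    f <- file.path(path, paste0(nm, ".txt"))
    if (!file.exists(f)) stopf("model directory is missing array '%s'", nm)
    read_numeric_matrix(f)
  }
  refs_lines <- strsplit(readLines(file.path(path, "references.tsv")), " ")
  refs <- do.call(rbind, lapply(refs_lines, function(p) as.integer(strsplit(p[2L], "")[[1L]])))
  rownames(refs) <- vapply(refs_lines, `[`, "", 1L)
  refs <- fingerprint_table(refs)
  bank <- list(W = rd("bank_W"), b = drop(rd("bank_b")))
  if (nrow(bank$W) != manifest$M)
    stopf("manifest reference count (%d) does not match bank rows (%d)",
          manifest$M, nrow(bank$W))
  if (nrow(refs) != manifest$M)
    stopf("manifest reference count (%d) does not match reference table (%d)",
          manifest$M, nrow(refs))
  dnn <- list(W1 = rd("W1"), g1 = drop(rd("g1")), b1 = drop(rd("b1")),
              W2 = rd("W2"), g2 = drop(rd("g2")), b2 = drop(rd("b2")),
              w_out = drop(rd("w_out")), b_out = drop(rd("b_out")),
              rm1 = drop(rd("rm1")), rv1 = drop(rd("rv1")),
              rm2 = drop(rd("rm2")), rv2 = drop(rd("rv2")),
              momentum = manifest$momentum, eps = manifest$eps,
              H = manifest$H)
  history <- if (file.exists(file.path(path, "history.tsv")))
    utils::read.table(file.path(path, "history.tsv"), header = TRUE, sep = "\t")
  new_refdnn(refs = refs, gene_ids = manifest$gene_ids, bank = bank, dnn = dnn,
             hp = as.list(manifest$hyperparameters), history = history)
}

new_refdnn <- function(refs, gene_ids, bank, dnn, hp, history = NULL,
                       control = NULL, fitted = NULL, call = NULL) {
  # canonical storage is unnamed arrays; coef() re-attaches identifiers
  bank$W <- unname(as.matrix(bank$W)); bank$b <- unname(as.numeric(bank$b))
  stopifnot(nrow(bank$W) == nrow(refs), ncol(bank$W) == length(gene_ids),
            nrow(dnn$W1) == nrow(refs), ncol(dnn$W1) == dnn$H)
  structure(list(refs = refs, gene_ids = gene_ids, bank = bank, dnn = dnn,
                 hp = hp, history = history, control = control,
                 fitted = fitted, call = call),
            class = "refdnn")
}
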