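# S3 methods for fitted models.

#' @export
print.refdnn <- function(x, ...) {
  cat("Reference-drug resistance model (refdnn)\n")
  cat(sprintf("  %d reference drugs x %d genes, hidden width %d\n",
              nrow(x$refs), length(x$gene_ids), x$dnn$H))
  cat(sprintf("  hyperparameters: lr_ftrl = %g, lr_adam = %g, l1 = %g, l2 = %g\n",
              x$hp$lr_ftrl, x$hp$lr_adam, x$hp$l1, x$hp$l2))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  trained %d epoch(s); best validation loss %.4f at epoch %d\n",
                max(x$history$epoch), min(x$history$val_loss),
                x$best_epoch %||% which.min(x$history$val_loss)))
  nz <- mean(x$bank$W != 0)
  cat(sprintf("  bank sparsity: %.1f%% of coefficients are exactly zero\n",
              100 * (1 - nz)))
  invisible(x)
}

#' Summarize a fitted resistance model
#'
#' @param object A fitted [refdnn()] model.
#' @param ... Unused.
#' @return A list with per-reference nonzero coefficient counts, training
#'   history and (when available) in-sample threshold metrics.
#' @export
summary.refdnn <- function(object, ...) {
  nonzero <- rowSums(object$bank$W != 0)
  names(nonzero) <- rownames(object$refs)
  out <- list(
    n_references = nrow(object$refs),
    n_genes = length(object$gene_ids),
    hidden_units = object$dnn$H,
    hyperparameters = object$hp,
    nonzero_coefficients = nonzero,
    history = object$history
  )
  if (!is.null(object$fitted))
    out$train_metrics <- threshold_metrics(object$labels, object$fitted)
  class(out) <- "summary.refdnn"
  out
}

#' @export
print.summary.refdnn <- function(x, ...) {
  cat(sprintf("refdnn model: %d references, %d genes, hidden width %d\n",
              x$n_references, x$n_genes, x$hidden_units))
  cat("nonzero bank coefficients per reference drug:\n")
  print(x$nonzero_coefficients)
  if (!is.null(x$train_metrics)) {
    cat(sprintf("in-sample: accuracy %.3f, AUROC %.3f, AUCPR %.3f\n",
                x$train_metrics$accuracy, x$train_metrics$auroc,
                x$train_metrics$aucpr))
  }
  invisible(x)
}

#' Extract ElasticNet-bank coefficients
#'
#' @param object A fitted [refdnn()] model.
#' @param ref_drug Optional reference drug id; default returns the full
#'   references x genes coefficient matrix.
#' @param ... Unused.
#' @return Coefficient matrix (dimnames: reference ids x gene ids) or a named
#'   vector for one reference.
#' @export
coef.refdnn <- function(object, ref_drug = NULL, ...) {
  W <- object$bank$W
  dimnames(W) <- list(rownames(object$refs), object$gene_ids)
  if (is.null(ref_drug)) return(W)
  if (!ref_drug %in% rownames(W)) stopf("unknown reference drug '%s'", ref_drug)
  W[ref_drug, ]
}

#' @export
fitted.refdnn <- function(object, ...) object$fitted

#' @export
residuals.refdnn <- function(object, ...) {
  if (is.null(object$fitted)) stopf("model carries no fitted values")
  object$labels - object$fitted
}

#' Plot the training history
#'
#' Training and validation loss per epoch, with the early-stopping epoch marked.
#'
#' @param x A fitted [refdnn()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.refdnn <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stopf("model carries no training history")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "mean loss per record", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
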