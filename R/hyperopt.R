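# Bayesian optimization of the five hyperparameters.
#
# Small self-contained Gaussian-process machinery: a Matern 5/2 kernel on the
# unit hypercube (integer dimensions snapped, positive-real dimensions mapped
# through log10), hyperparameters of the surrogate (lengthscale, signal and
# noise variance) fit by maximum marginal likelihood, and Expected Improvement
# with exploration offset xi as the acquisition.

#' Hyperparameter search space
#'
#' Five dimensions: the hidden width as an integer range, and the two learning
#' rates plus the two regularization strengths as positive ranges sampled on a
#' log scale. The default ranges are this package's choices.
#'
#' @param hidden_units Integer c(lower, upper).
#' @param lr_ftrl,lr_adam,l1,l2 Positive c(lower, upper), explored
#'   log-uniformly.
#' @return A `search_space` list of dimension descriptors.
#' @export
search_space <- function(hidden_units = c(2L, 128L),
                         lr_ftrl = c(1e-5, 1e-1), lr_adam = c(1e-5, 1e-1),
                         l1 = c(1e-5, 10), l2 = c(1e-5, 10)) {
  dims <- list(
    hidden_units = list(type = "integer", lower = hidden_units[1L], upper = hidden_units[2L]),
    lr_ftrl = list(type = "log", lower = lr_ftrl[1L], upper = lr_ftrl[2L]),
    lr_adam = list(type = "log", lower = lr_adam[1L], upper = lr_adam[2L]),
    l1 = list(type = "log", lower = l1[1L], upper = l1[2L]),
    l2 = list(type = "log", lower = l2[1L], upper = l2[2L])
  )
  for (nm in names(dims))
    if (dims[[nm]]$lower > dims[[nm]]$upper)
      stopf("search space dimension '%s' has lower > upper", nm)
  structure(dims, class = "search_space")
}

#' Build a custom search space from dimension descriptors
#'
#' @param dims Named list; each element is `list(type, lower, upper)` with type
#'   one of `"integer"`, `"real"`, `"log"`.
#' @return A `search_space`.
#' @export
as_search_space <- function(dims) {
  for (nm in names(dims)) {
    d <- dims[[nm]]
    if (!d$type %in% c("integer", "real", "log")) stopf("bad dimension type '%s'", d$type)
    if (d$lower > d$upper) stopf("dimension '%s' has lower > upper", nm)
  }
  structure(dims, class = "search_space")
}

# Map a point between the unit hypercube and natural units.
space_decode <- function(space, u) {
  out <- list()
  for (i in seq_along(space)) {
    d <- space[[i]]
    out[[names(space)[i]]] <- switch(d$type,
      integer = as.integer(round(d$lower + u[i] * (d$upper - d$lower))),
      real = d$lower + u[i] * (d$upper - d$lower),
      log = 10^(log10(d$lower) + u[i] * (log10(d$upper) - log10(d$lower))))
  }
  out
}

space_encode <- function(space, x) {
  vapply(seq_along(space), function(i) {
    d <- space[[i]]
    v <- x[[names(space)[i]]]
    switch(d$type,
      integer = if (d$upper == d$lower) 0.5 else (v - d$lower) / (d$upper - d$lower),
      real = if (d$upper == d$lower) 0.5 else (v - d$lower) / (d$upper - d$lower),
      log = if (d$upper == d$lower) 0.5 else
        (log10(v) - log10(d$lower)) / (log10(d$upper) - log10(d$lower)))
  }, numeric(1))
}

# Matern 5/2 kernel on scaled distances.
matern52 <- function(D, lengthscale) {
  r <- sqrt(5) * D / lengthscale
  (1 + r + r^2 / 3) * exp(-r)
}

gp_fit <- function(U, y) {
  D <- as.matrix(stats::dist(U))
  y_mu <- mean(y); y_sd <- stats::sd(y); if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mu) / y_sd
  nll <- function(par) {
    ls <- exp(par[1L]); noise <- exp(par[2L])
    K <- matern52(D, ls) + diag(noise + 1e-8, nrow(U))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    0.5 * sum(ys * alpha) + sum(log(diag(ch)))
  }
  best <- NULL
  for (start in list(c(log(0.5), log(0.1)), c(log(1.5), log(0.01)), c(log(0.2), log(0.5)))) {
    op <- tryCatch(stats::optim(start, nll, method = "L-BFGS-B",
                                lower = c(log(0.05), log(1e-6)),
                                upper = c(log(10), log(1))),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  ls <- exp(best$par[1L]); noise <- exp(best$par[2L])
  K <- matern52(D, ls) + diag(noise + 1e-8, nrow(U))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(U = U, ch = ch, alpha = alpha, ls = ls, noise = noise,
       y_mu = y_mu, y_sd = y_sd)
}

gp_predict <- function(gp, Unew) {
  D2 <- outer(rowSums(Unew^2), rowSums(gp$U^2), `+`) - 2 * Unew %*% t(gp$U)
  Ks <- matern52(sqrt(pmax(D2, 0)), gp$ls)
  mu <- drop(Ks %*% gp$alpha)
  var <- pmax(1 - colSums(forwardsolve(t(gp$ch), t(Ks))^2), 1e-12)
  list(mu = mu * gp$y_sd + gp$y_mu, sd = sqrt(var) * gp$y_sd)
}

expected_improvement <- function(mu, sd, best, xi = 0.01) {
  imp <- mu - best - xi
  z <- imp / sd
  ei <- imp * stats::pnorm(z) + sd * stats::dnorm(z)
  ei[sd <= 0] <- 0
  ei
}

#' Mean inner-CV accuracy for one hyperparameter setting
#'
#' The hyperparameter-search objective: mean test accuracy over a stratified
#' k-fold CV (default k = 3), training a fresh model per fold with seeds
#' derived from `seed`.
#'
#' @param dataset A `refdnn_dataset`.
#' @param refs Reference panel.
#' @param hp Named hyperparameter list (missing entries take defaults).
#' @param k Fold count (default 3).
#' @param seed Integer seed.
#' @param control A [refdnn_control()].
#' @return Mean accuracy in \[0, 1\].
#' @export
cv_objective <- function(dataset, refs, hp, k = 3L, seed = 1L,
                         control = refdnn_control()) {
  hp <- fill_hp(hp)
  plan <- kfold_splits(dataset$records, k, seed = substream_seed(seed, "cvobj"))
  accs <- vapply(seq_along(plan), function(i) {
    ctrl <- control
    ctrl$seed <- substream_seed(seed, paste0("cvobj_fold", i))
    fs <- fit_and_score(dataset, refs, hp, ctrl, plan[[i]]$train, plan[[i]]$test)
    mean(as.integer(fs$probabilities > 0.5) == fs$labels)
  }, numeric(1))
  mean(accs)
}

#' Bayesian optimization over a search space
#'
#' Maximizes `objective` with a Gaussian-process surrogate (Matern 5/2
#' covariance, surrogate hyperparameters by maximum marginal likelihood) and
#' Expected Improvement acquisition with exploration offset `xi = 0.01`.
#' Starts from `n_initial` seeded random points, then proposes the EI argmax
#' over a seeded candidate set each iteration. The returned optimum is always
#' the best *evaluated* trial, never a surrogate prediction. A uniform random
#' search fallback is selectable with `method = "random"`.
#'
#' @param objective Function taking a named hyperparameter list, returning a
#'   scalar to maximize.
#' @param space A [search_space()] / [as_search_space()].
#' @param n_calls Total objective evaluations (default 20).
#' @param n_initial Random initial points (default 5).
#' @param xi EI exploration offset.
#' @param seed Integer seed.
#' @param method `"gp"` (default) or `"random"`.
#' @return List with `best` (hyperparameter list), `best_value`, and `trials`
#'   (data.frame of all evaluated points and objective values).
#' @export
bayes_optimize <- function(objective, space, n_calls = 20L, n_initial = 5L,
                           xi = 0.01, seed = 1L, method = c("gp", "random")) {
  method <- match.arg(method)
  if (n_calls < n_initial) stopf("n_calls (%d) must be >= n_initial (%d)", n_calls, n_initial)
  degenerate <- vapply(space, function(d) d$lower == d$upper, logical(1))
  if (any(degenerate))
    warnf("degenerate search dimension(s) collapsed to a point: %s",
          paste(names(space)[degenerate], collapse = ", "))
  if (all(degenerate)) {
    x <- space_decode(space, rep(0.5, length(space)))
    val <- objective(x)
    trials <- cbind(as.data.frame(x), data.frame(objective = val, trial = 1L))
    return(list(best = x, best_value = val, trials = trials))
  }
  d <- length(space)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  U <- matrix(stats::runif(n_initial * d), n_initial, d)
  U[, degenerate] <- 0.5
  xs <- list(); ys <- numeric(0)
  for (i in seq_len(n_initial)) {
    xs[[i]] <- space_decode(space, U[i, ])
    ys[i] <- objective(xs[[i]])
  }
  while (length(ys) < n_calls) {
    if (method == "random") {
      u <- stats::runif(d); u[degenerate] <- 0.5
    } else {
      cand <- matrix(stats::runif(512 * d), 512, d)
      cand[, degenerate] <- 0.5
      # snap integer dimensions so the surrogate sees the evaluable lattice
      for (j in seq_len(d)) if (space[[j]]$type == "integer") {
        rng <- space[[j]]$upper - space[[j]]$lower
        if (rng > 0) cand[, j] <- round(cand[, j] * rng) / rng
      }
      gp <- tryCatch(gp_fit(U, ys), error = function(e) NULL)
      if (is.null(gp)) {
        u <- stats::runif(d); u[degenerate] <- 0.5
      } else {
        pr <- gp_predict(gp, cand)
        ei <- expected_improvement(pr$mu, pr$sd, max(ys), xi = xi)
        u <- cand[which.max(ei), ]
      }
    }
    i <- length(ys) + 1L
    xs[[i]] <- space_decode(space, u)
    ys[i] <- objective(xs[[i]])
    U <- rbind(U, u)
  }
  best_i <- which.max(ys)
  trials <- do.call(rbind, lapply(seq_along(xs), function(i)
    cbind(as.data.frame(xs[[i]]), data.frame(objective = ys[i], trial = i))))
  list(best = xs[[best_i]], best_value = ys[best_i], trials = trials)
}
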