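# Internal numeric helpers shared across the package.

# Numerically stable logistic function. plogis() never overflows and returns
# values in [0, 1]; callers that need strict (0, 1) clip afterwards.
sigmoid <- function(x) stats::plogis(x)

# Clip probabilities away from {0, 1} before taking logs. The guard is applied
# inside the losses only; forward-pass outputs are reported unclipped.
PROB_EPS <- 1e-7

clip_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

# Derive a reproducible sub-seed (< 2^31) for a named random substream so that
# changing the draws of one component never shifts another's.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Full-precision text serialization for doubles: 17 significant digits
# round-trip IEEE doubles exactly through decimal.
format_full <- function(x) sprintf("%.17g", x)

write_numeric_matrix <- function(m, path) {
  stopifnot(is.matrix(m) || is.numeric(m))
  m <- as.matrix(m)
  lines <- apply(m, 1L, function(r) paste(format_full(r), collapse = "\t"))
  writeLines(c(sprintf("# %d %d", nrow(m), ncol(m)), lines), path)
}

read_numeric_matrix <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(sub("^# ", "", lines[1L]), " ")[[1L]])
  vals <- lapply(lines[-1L], function(l) as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]]))
  m <- do.call(rbind, vals)
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  if (nrow(m) != dims[1L] || ncol(m) != dims[2L])
    stopf("corrupt array file '%s': header says %dx%d, found %dx%d",
          path, dims[1L], dims[2L], nrow(m), ncol(m))
  m
}
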