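#' Read a gene-expression matrix from delimited text
#'
#' Reads a genes-by-cell-lines (or cell-lines-by-genes) table with identifier
#' header row and column, and returns it oriented cell lines x genes, which is
#' the orientation every downstream function expects.
#'
#' @param path Path to a TSV/CSV file. The delimiter is auto-detected from the
#'   extension (`.csv` means comma, anything else tab) unless `sep` is given.
#' @param orientation Either `"cells_by_genes"` (rows are cell lines) or
#'   `"genes_by_cells"` (rows are genes; the matrix is transposed on read).
#' @param sep Field delimiter override.
#' @return An object of class `expression_matrix`: a numeric matrix, cell lines
#'   in rows, genes in columns, with identifier dimnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(matrix(rnorm(6), 2, dimnames = list(c("c1", "c2"), c("g1", "g2", "g3"))),
#'             f, sep = "\t", quote = FALSE)
#' x <- read_expression(f)
#' dim(x)
#' @export
read_expression <- function(path, orientation = c("cells_by_genes", "genes_by_cells"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    nonnum <- colnames(tab)[vapply(tab, function(col)
      any(is.na(suppressWarnings(as.numeric(as.character(col))))), logical(1))]
    stopf("non-numeric expression values in column(s): %s",
          paste(nonnum, collapse = ", "))
  }
  if (orientation == "genes_by_cells") m <- t(m)
  expression_matrix(m)
}

#' Construct and validate an expression matrix
#'
#' @param values Numeric matrix, cell lines in rows, genes in columns, with
#'   identifier dimnames.
#' @return The validated matrix with class `expression_matrix`.
#' @export
expression_matrix <- function(values) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs cell-line rownames and gene colnames")
  dup_g <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_g)) stopf("duplicate gene identifier(s): %s", paste(dup_g, collapse = ", "))
  dup_c <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_c)) stopf("duplicate cell-line identifier(s): %s", paste(dup_c, collapse = ", "))
  if (!all(is.finite(values))) stopf("expression matrix contains non-finite values")
  if (nrow(values) < 1L || ncol(values) < 1L) stopf("expression matrix is empty")
  storage.mode(values) <- "double"
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Read drug fingerprints from delimited text
#'
#' Accepts either rows of `id<sep>bitstring` (e.g. `"drugA\t10110"`), rows of
#' `id` followed by one 0/1 column per bit, or FPS-style `hexstring<TAB>id`
#' lines (leading-`#` header lines are skipped).
#'
#' @param path Path to the fingerprint file.
#' @param format `"auto"` (default), `"bits"` or `"fps"`.
#' @return A `fingerprint_table`: integer 0/1 matrix, drugs in rows (rownames
#'   are drug identifiers), one column per fingerprint bit.
#' @export
read_fingerprints <- function(path, format = c("auto", "bits", "fps")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("fingerprint file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "auto") {
    body <- lines[!startsWith(lines, "#")]
    first <- strsplit(trimws(body[1L]), "[\t ,]+")[[1L]]
    # id + 0/1 payload means the plain bits format; a leading hex token with a
    # non-binary second field means FPS ("hexstring<TAB>id") lines
    payload_binary <- length(first) >= 2L && all(grepl("^[01]+$", first[-1L]))
    looks_hex <- grepl("^[0-9a-fA-F]+$", first[1L]) && nchar(first[1L]) %% 2L == 0L
    format <- if (!payload_binary && length(first) == 2L && looks_hex) "fps" else "bits"
  }
  if (format == "fps") {
    body <- lines[!startsWith(lines, "#")]
    parts <- strsplit(trimws(body), "[\t ]+")
    ids <- vapply(parts, `[`, "", 2L)
    bits <- lapply(parts, function(p) hex_to_bits(p[1L]))
  } else {
    parts <- strsplit(trimws(lines[!startsWith(lines, "#")]), "[\t ,]+")
    ids <- vapply(parts, `[`, "", 1L)
    bits <- lapply(parts, function(p) {
      rest <- p[-1L]
      if (length(rest) == 1L) {
        chars <- strsplit(rest, "")[[1L]]
        bad <- setdiff(unique(chars), c("0", "1"))
        if (length(bad)) stopf("invalid fingerprint bit character(s) %s in row '%s'",
                               paste(sQuote(bad), collapse = ", "), p[1L])
        as.integer(chars)
      } else {
        v <- suppressWarnings(as.integer(rest))
        if (any(is.na(v)) || any(!v %in% c(0L, 1L)))
          stopf("invalid fingerprint bit value in row '%s'", p[1L])
        v
      }
    })
  }
  widths <- lengths(bits)
  if (length(unique(widths)) != 1L)
    stopf("ragged fingerprint widths: found %s", paste(unique(widths), collapse = ", "))
  m <- do.call(rbind, bits)
  rownames(m) <- ids
  fingerprint_table(m)
}

hex_to_bits <- function(hex) {
  nib <- strtoi(strsplit(hex, "")[[1L]], base = 16L)
  if (any(is.na(nib))) stopf("invalid hex fingerprint: %s", hex)
  as.integer(unlist(lapply(nib, function(n) bitwAnd(bitwShiftR(n, 3:0), 1L))))
}

#' Construct and validate a fingerprint table
#'
#' @param bits Integer/numeric 0-1 matrix, drugs in rows; rownames are drug ids.
#' @return Validated matrix of class `fingerprint_table`.
#' @export
fingerprint_table <- function(bits) {
  if (is.null(rownames(bits))) stopf("fingerprint table needs drug-id rownames")
  dup <- unique(rownames(bits)[duplicated(rownames(bits))])
  if (length(dup)) stopf("duplicate drug identifier(s): %s", paste(dup, collapse = ", "))
  if (ncol(bits) < 1L) stopf("fingerprint width must be >= 1")
  if (!all(bits %in% c(0L, 1L))) stopf("fingerprint entries must be 0 or 1")
  storage.mode(bits) <- "integer"
  class(bits) <- c("fingerprint_table", class(bits))
  bits
}

#' Binarize a drug response from log IC50 and the maximum screening concentration
#'
#' A (cell line, drug) pair is called resistant (label 1) when its IC50 exceeds
#' the highest concentration actually screened, i.e. the drug failed to reach
#' half-maximal inhibition within the tested range; otherwise sensitive (0).
#' Both arguments must be on the same (natural-log) scale. The inequality is
#' strict: a pair exactly at the maximum screening concentration is sensitive.
#'
#' @param ln_ic50 Numeric vector of natural-log IC50 values.
#' @param ln_max_conc Numeric vector (recycled) of natural-log maximum screening
#'   concentrations.
#' @return Integer vector of labels: 1 = resistant, 0 = sensitive.
#' @examples
#' binarize_response(c(2, 0.5, 1), 1)   # 1 0 0
#' @export
binarize_response <- function(ln_ic50, ln_max_conc) {
  if (any(!is.finite(ln_ic50)) || any(!is.finite(ln_max_conc)))
    stopf("binarize_response requires finite inputs")
  as.integer(ln_ic50 > ln_max_conc)
}

#' Assemble an aligned modelling dataset
#'
#' Joins the expression matrix, fingerprint table and response records into a
#' single validated dataset. Records whose cell line or drug has no data are
#' either dropped with a message (`drop_unmatched = TRUE`) or cause an error.
#'
#' @param expression An [expression_matrix()].
#' @param fingerprints A [fingerprint_table()].
#' @param responses A data.frame with columns `cell_id`, `drug_id`, `label`
#'   (0/1), and optionally `ln_ic50`, `ln_max_conc`, `cancer_type`. If `label`
#'   is absent but `ln_ic50`/`ln_max_conc` are present, labels are derived with
#'   [binarize_response()].
#' @param drop_unmatched Drop records lacking expression or fingerprint data
#'   instead of erroring.
#' @param keep_first How to handle duplicated (cell, drug) pairs: by default
#'   conflicting duplicates are an error; `keep_first = TRUE` keeps the first
#'   occurrence.
#' @return A `refdnn_dataset`: list with elements `expression`, `fingerprints`,
#'   `records` (the kept response data.frame) and `log` (alignment counts).
#' @export
align_dataset <- function(expression, fingerprints, responses,
                          drop_unmatched = FALSE, keep_first = FALSE) {
  responses <- as.data.frame(responses, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "drug_id") %in% names(responses)))
    stopf("responses need cell_id and drug_id columns")
  if (!"label" %in% names(responses)) {
    if (!all(c("ln_ic50", "ln_max_conc") %in% names(responses)))
      stopf("responses need either a label column or ln_ic50 + ln_max_conc")
    responses$label <- binarize_response(responses$ln_ic50, responses$ln_max_conc)
  }
  if (!all(responses$label %in% c(0L, 1L))) stopf("labels must be 0 or 1")
  if (all(c("ln_ic50", "ln_max_conc") %in% names(responses))) {
    ok <- is.finite(responses$ln_ic50) & is.finite(responses$ln_max_conc)
    bad <- which(ok & responses$label != binarize_response(
      ifelse(ok, responses$ln_ic50, 0), ifelse(ok, responses$ln_max_conc, 0)))
    if (length(bad))
      stopf("label inconsistent with IC50 binarization in %d record(s), first at row %d",
            length(bad), bad[1L])
  }

  key <- paste(responses$cell_id, responses$drug_id, sep = "\r")
  if (anyDuplicated(key)) {
    split_labels <- split(responses$label, key)
    conflicting <- names(split_labels)[vapply(split_labels, function(l)
      length(unique(l)) > 1L, logical(1))]
    if (length(conflicting) && !keep_first)
      stopf("%d (cell, drug) pair(s) have conflicting duplicate labels; set keep_first = TRUE to keep the first occurrence",
            length(conflicting))
    responses <- responses[!duplicated(key), , drop = FALSE]
  }

  have_cell <- responses$cell_id %in% rownames(expression)
  have_drug <- responses$drug_id %in% rownames(fingerprints)
  matched <- have_cell & have_drug
  n_drop <- sum(!matched)
  if (n_drop > 0L && !drop_unmatched)
    stopf("%d record(s) reference unknown cell lines or drugs (set drop_unmatched = TRUE to drop them)",
          n_drop)
  if (!any(matched)) stopf("no response record matches both the expression and fingerprint data")
  if (n_drop > 0L)
    message(sprintf("align_dataset: dropped %d unmatched record(s) (%d missing cell, %d missing drug); kept %d",
                    n_drop, sum(!have_cell), sum(!have_drug), sum(matched)))
  records <- responses[matched, , drop = FALSE]
  rownames(records) <- NULL

  ds <- structure(list(
    expression = expression,
    fingerprints = fingerprints,
    records = records,
    log = list(input = length(matched), kept = sum(matched), dropped = n_drop)
  ), class = "refdnn_dataset")
  ds
}

#' @export
print.refdnn_dataset <- function(x, ...) {
  cat(sprintf("refdnn dataset: %d records (%d resistant / %d sensitive)\n",
              nrow(x$records), sum(x$records$label == 1L), sum(x$records$label == 0L)))
  cat(sprintf("  expression:   %d cell lines x %d genes\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  fingerprints: %d drugs x %d bits\n",
              nrow(x$fingerprints), ncol(x$fingerprints)))
  invisible(x)
}

#' Serialize / restore a dataset as a directory of delimited tables
#'
#' Writes three tables (expression, fingerprints, responses) plus a JSON
#' metadata file; [read_dataset()] restores an identical `refdnn_dataset`.
#'
#' @param dataset A `refdnn_dataset` from [align_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly (`write_dataset`); the dataset (`read_dataset`).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- unclass(dataset$expression)
  # 17 significant digits round-trip doubles exactly through the text format
  expr_chr <- matrix(format_full(expr), nrow(expr), ncol(expr),
                     dimnames = dimnames(expr))
  utils::write.table(
    data.frame(cell_id = rownames(expr), expr_chr, check.names = FALSE),
    file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  fp <- dataset$fingerprints
  writeLines(paste(rownames(fp), apply(unclass(fp), 1L, paste, collapse = "")),
             file.path(dir, "fingerprints.tsv"))
  utils::write.table(dataset$records, file.path(dir, "responses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(format = "refdnn-dataset-v1",
                            orientation = "cells_by_genes",
                            log = dataset$log),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  if (!identical(meta$format, "refdnn-dataset-v1"))
    stopf("unrecognized dataset format in %s", dir)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  fp <- read_fingerprints(file.path(dir, "fingerprints.tsv"))
  resp <- utils::read.table(file.path(dir, "responses.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE,
                            colClasses = NA, check.names = FALSE)
  resp$cell_id <- as.character(resp$cell_id)
  resp$drug_id <- as.character(resp$drug_id)
  align_dataset(expr, fp, resp)
}
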