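#' Construct a drug x cell-line response matrix
#'
#' The central data container of the package: a real-valued matrix of drug
#' sensitivity measurements (rows = drugs, columns = cell lines) together with
#' a binary observation mask. Missing measurements are stored as `NA` and
#' flagged as 0 in the mask; the mask is always derivable from finiteness of
#' the values and is kept explicit because the fitting code treats the index
#' set of observed entries (and its complement, the entries to be completed)
#' as first-class objects.
#'
#' @param values numeric matrix, drugs in rows, cell lines in columns.
#'   Non-finite entries (`NA`, `NaN`, `Inf`) are treated as missing.
#' @param drug_ids character vector of unique row identifiers. Defaults to
#'   existing rownames, else `"drug1"..`.
#' @param cellline_ids character vector of unique column identifiers.
#' @param unit_label free-text unit of measurement, e.g. `"activity_area"`
#'   (higher = sensitive) or `"ln_IC50"` (lower = sensitive).
#' @return An object of class `response_matrix` with elements `values`
#'   (numeric matrix, `NA` at unobserved cells), `mask` (0/1 integer matrix),
#'   `drug_ids`, `cellline_ids`, `unit_label`.
#' @examples
#' rm <- response_matrix(matrix(c(1, 2, NA, 4), 2, 2))
#' sparsity_percent(rm)
#' @export
response_matrix <- function(values, drug_ids = NULL, cellline_ids = NULL,
                            unit_label = "") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  m <- nrow(values)
  n <- ncol(values)
  if (m < 1L || n < 1L) stopf("response matrix must have at least one row and one column")
  if (is.null(drug_ids)) {
    drug_ids <- if (!is.null(rownames(values))) rownames(values) else paste0("drug", seq_len(m))
  }
  if (is.null(cellline_ids)) {
    cellline_ids <- if (!is.null(colnames(values))) colnames(values) else paste0("cell", seq_len(n))
  }
  drug_ids <- as.character(drug_ids)
  cellline_ids <- as.character(cellline_ids)
  if (length(drug_ids) != m) stopf("length(drug_ids) (%d) != nrow(values) (%d)", length(drug_ids), m)
  if (length(cellline_ids) != n) stopf("length(cellline_ids) (%d) != ncol(values) (%d)", length(cellline_ids), n)
  if (anyDuplicated(drug_ids)) stopf("duplicate drug id: '%s'", drug_ids[duplicated(drug_ids)][1L])
  if (anyDuplicated(cellline_ids)) stopf("duplicate cell-line id: '%s'", cellline_ids[duplicated(cellline_ids)][1L])
  mask <- ifelse(is.finite(values), 1L, 0L)
  storage.mode(mask) <- "integer"
  if (sum(mask) == 0L) stopf("response matrix has no observed entries")
  vals <- values
  vals[mask == 0L] <- NA_real_
  dimnames(vals) <- list(drug_ids, cellline_ids)
  dimnames(mask) <- dimnames(vals)
  structure(
    list(values = vals, mask = mask, drug_ids = drug_ids,
         cellline_ids = cellline_ids, unit_label = unit_label),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d drugs x %d cell lines, %d observed (%.2f%% missing)%s\n",
              nrow(x$values), ncol(x$values), sum(x$mask), sparsity_percent(x),
              if (nzchar(x$unit_label)) paste0(", unit: ", x$unit_label) else ""))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

assert_response_matrix <- function(rm) {
  if (!inherits(rm, "response_matrix")) stopf("expected a `response_matrix` object")
  invisible(rm)
}

infer_delim <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

is_missing_token <- function(x) {
  x <- trimws(x)
  is.na(x) | x == "" | tolower(x) %in% c("na", "nan")
}

#' Read a response matrix from CSV/TSV
#'
#' The file must have cell identifiers in the first row and first column.
#' Empty cells and the tokens `NA`/`NaN` (case-insensitive) are read as
#' missing. The delimiter is inferred from the extension (`.tsv`/`.txt` =>
#' tab, otherwise comma) unless given.
#'
#' @param path file to read.
#' @param orientation `"drugs_as_rows"` (default) if the file's rows are
#'   drugs, `"celllines_as_rows"` if rows are cell lines (the matrix is
#'   transposed on read so the returned object always has drugs as rows).
#' @param delimiter optional field separator overriding the inference.
#' @param unit_label passed to [response_matrix()].
#' @return a [response_matrix()].
#' @export
read_response_csv <- function(path, orientation = c("drugs_as_rows", "celllines_as_rows"),
                              delimiter = NULL, unit_label = "") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- infer_delim(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stopf("matrix in %s is empty", path)
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  vals <- matrix(NA_real_, nrow(cells), ncol(cells))
  miss <- is_missing_token(cells)
  parsed <- suppressWarnings(as.numeric(cells[!miss]))
  bad <- which(is.na(parsed))
  if (length(bad)) {
    pos <- which(!miss)[bad[1L]]
    i <- (pos - 1L) %% nrow(cells) + 1L
    j <- (pos - 1L) %/% nrow(cells) + 1L
    stopf("non-numeric cell at row '%s', column '%s': '%s'",
          row_ids[i], col_ids[j], cells[pos])
  }
  vals[!miss] <- parsed
  rm <- response_matrix(vals, drug_ids = row_ids, cellline_ids = col_ids,
                        unit_label = unit_label)
  if (orientation == "celllines_as_rows") rm <- transpose_response(rm)
  rm
}

# Swap the two axes (drugs <-> cell lines); used internally for the
# row-factor network and by read_response_csv.
transpose_response <- function(rm) {
  assert_response_matrix(rm)
  response_matrix(t(rm$values), drug_ids = rm$cellline_ids,
                  cellline_ids = rm$drug_ids, unit_label = rm$unit_label)
}

#' Write a response matrix to CSV/TSV
#'
#' Missing entries are written as empty cells. Values are formatted with
#' `%.17g` so that a write/read round trip reproduces them bit-exactly.
#'
#' @param rm a [response_matrix()].
#' @param path destination; delimiter inferred from extension as in
#'   [read_response_csv()].
#' @param delimiter optional separator override.
#' @export
write_response_csv <- function(rm, path, delimiter = NULL) {
  assert_response_matrix(rm)
  sep <- infer_delim(path, delimiter)
  cells <- matrix("", nrow(rm$values), ncol(rm$values))
  obs <- rm$mask == 1L
  cells[obs] <- sprintf("%.17g", rm$values[obs])
  quote_field <- function(x) {
    needs <- grepl(paste0("[\"\n", sep, "]"), x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  header <- paste(c("id", quote_field(rm$cellline_ids)), collapse = sep)
  rows <- vapply(seq_len(nrow(cells)), function(i) {
    paste(c(quote_field(rm$drug_ids[i]), cells[i, ]), collapse = sep)
  }, character(1L))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Percentage of missing entries
#'
#' Reports `100 * n_missing / (m * n)`, the fraction of the matrix that is
#' unobserved (the usual "sparsity" figure quoted for pharmacogenomic
#' response panels).
#'
#' @param rm a [response_matrix()].
#' @return scalar percentage in `[0, 100)`.
#' @export
sparsity_percent <- function(rm) {
  assert_response_matrix(rm)
  100 * sum(rm$mask == 0L) / length(rm$mask)
}

#' Random k-fold partition of the observed entries
#'
#' Shuffles the coordinates of the observed entries with a seeded PRNG and
#' deals them round-robin into `k` folds, so fold sizes differ by at most one
#' and the assignment is reproducible.
#'
#' @param rm a [response_matrix()].
#' @param k number of folds, `>= 2`.
#' @param seed integer seed.
#' @return an object of class `fold_assignment`: a list with `fold` (integer
#'   matrix of the same shape as `rm$values`, entries `0..k-1` at observed
#'   cells and `NA` elsewhere), `k` and `seed`.
#' @export
assign_folds <- function(rm, k, seed) {
  assert_response_matrix(rm)
  k <- as.integer(k)
  if (k < 2L) stopf("`k` must be >= 2")
  obs <- which(rm$mask == 1L)
  if (k > length(obs)) stopf("k = %d exceeds the number of observed entries (%d)", k, length(obs))
  shuffled <- with_seed(seed, sample(obs))
  fold <- matrix(NA_integer_, nrow(rm$values), ncol(rm$values),
                 dimnames = dimnames(rm$values))
  fold[shuffled] <- rep_len(0:(k - 1L), length(obs))
  structure(list(fold = fold, k = k, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Leave-one-unit-out (cold-start) splits
#'
#' Yields one split per drug (row) or per cell line (column): the held-out
#' unit's observed entries form the test set and every other observed entry
#' is available for training. Units with no observed entries are skipped with
#' a warning.
#'
#' @param rm a [response_matrix()].
#' @param axis `"drug"` to hold out rows, `"cellline"` to hold out columns.
#' @return list of splits, each a list with `train_mask` (0/1 matrix),
#'   `held_out_index`, `held_out_id` and `axis`.
#' @export
cold_start_splits <- function(rm, axis = c("drug", "cellline")) {
  assert_response_matrix(rm)
  axis <- match.arg(axis)
  n_units <- if (axis == "drug") nrow(rm$values) else ncol(rm$values)
  ids <- if (axis == "drug") rm$drug_ids else rm$cellline_ids
  if (n_units < 2L) stopf("need at least 2 %ss for cold-start splits", axis)
  splits <- list()
  for (u in seq_len(n_units)) {
    unit_mask <- if (axis == "drug") rm$mask[u, ] else rm$mask[, u]
    if (sum(unit_mask) == 0L) {
      warning(sprintf("%s '%s' has no observed entries; split skipped", axis, ids[u]),
              call. = FALSE)
      next
    }
    train_mask <- rm$mask
    if (axis == "drug") train_mask[u, ] <- 0L else train_mask[, u] <- 0L
    splits[[length(splits) + 1L]] <- list(train_mask = train_mask,
                                          held_out_index = u,
                                          held_out_id = ids[u], axis = axis)
  }
  splits
}

# Return a copy of rm with the given cells (linear indices or logical/0-1
# matrix) hidden, i.e. turned into missing entries.
mask_out_entries <- function(rm, idx) {
  assert_response_matrix(rm)
  vals <- rm$values
  if (is.matrix(idx)) idx <- which(idx != 0)
  vals[idx] <- NA_real_
  response_matrix(vals, rm$drug_ids, rm$cellline_ids, rm$unit_label)
}
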