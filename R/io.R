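#' Read a named numeric matrix from a TSV file
#'
#' All pipeline matrices (drug doses, TF activities, prior drug-target masks)
#' are plain tab-separated files with named rows and columns. Row and column
#' names are preserved exactly; parsing is locale-independent (decimal point
#' is always `.`).
#'
#' @param path Path to a TSV file with a header row and row names in the first
#'   column.
#' @param orientation Either `"as_is"` (default) or `"transpose"`; the latter
#'   returns the transposed matrix, convenient when a file stores features in
#'   rows but the pipeline wants samples in rows.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path, orientation = c("as_is", "transpose")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL,
                          colClasses = "character")
  if (ncol(df) < 2) stop_fmt("%s: expected at least one data column", path)
  rn <- df[[1]]
  if (anyDuplicated(rn)) {
    stop_fmt("%s: duplicate row name(s): %s", path,
             paste(unique(rn[duplicated(rn)]), collapse = ", "))
  }
  cn <- colnames(df)[-1]
  if (anyDuplicated(cn)) {
    stop_fmt("%s: duplicate column name(s): %s", path,
             paste(unique(cn[duplicated(cn)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num) ) {
    bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop_fmt("%s: non-numeric cell at row '%s', column '%s' (value '%s')",
               path, rn[bad[1, 1]], cn[bad[1, 2]], vals[bad[1, 1], bad[1, 2]])
    }
  }
  dimnames(num) <- list(rn, cn)
  if (orientation == "transpose") num <- t(num)
  num
}

#' Write a named numeric matrix to a TSV file
#'
#' Inverse of [read_matrix_tsv()]; the first column holds row names under the
#' header `id`.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Header for the row-name column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  check_named_matrix(m, "matrix")
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Convert a binary drug-target matrix to long format
#'
#' The long format lists one `(drug_smiles, target_uniprot)` record per prior
#' interaction (entries equal to 1); the network-connection step consumes this
#' form.
#'
#' @param mask Binary matrix, drugs in rows (SMILES), targets in columns
#'   (UniProt identifiers).
#' @return A data.frame with columns `drug_smiles` and `target_uniprot`.
#' @export
matrix_to_long <- function(mask) {
  check_named_matrix(mask, "mask")
  if (!all(mask %in% c(0, 1))) stop_fmt("mask must be binary (0/1)")
  idx <- which(mask == 1, arr.ind = TRUE)
  out <- data.frame(
    drug_smiles = rownames(mask)[idx[, 1]],
    target_uniprot = colnames(mask)[idx[, 2]],
    stringsAsFactors = FALSE
  )
  out[order(match(out$drug_smiles, rownames(mask)),
            match(out$target_uniprot, colnames(mask))), , drop = FALSE]
}

#' Convert a long drug-target table back to a binary matrix
#'
#' @param table data.frame with columns `drug_smiles` and `target_uniprot`.
#'   Duplicate pairs are collapsed with a warning. Rows with a missing/empty
#'   target (control conditions such as DMSO) contribute a drug row of zeros.
#' @param drugs,targets Optional row/column universes; defaults to the names
#'   mentioned in the table, in order of first appearance.
#' @return Binary matrix drugs x targets.
#' @export
long_to_matrix <- function(table, drugs = NULL, targets = NULL) {
  stopifnot(is.data.frame(table))
  if (!all(c("drug_smiles", "target_uniprot") %in% colnames(table))) {
    stop_fmt("long table needs columns drug_smiles and target_uniprot")
  }
  has_target <- !is.na(table$target_uniprot) & table$target_uniprot != ""
  pairs <- table[has_target, c("drug_smiles", "target_uniprot"), drop = FALSE]
  if (anyDuplicated(pairs)) {
    warn_fmt("long table contains duplicate drug-target pairs; deduplicating")
    pairs <- unique(pairs)
  }
  drugs <- drugs %||% unique(table$drug_smiles)
  targets <- targets %||% unique(pairs$target_uniprot)
  m <- matrix(0, length(drugs), length(targets), dimnames = list(drugs, targets))
  if (nrow(pairs) > 0) {
    keep <- pairs$drug_smiles %in% drugs & pairs$target_uniprot %in% targets
    m[cbind(match(pairs$drug_smiles[keep], drugs),
            match(pairs$target_uniprot[keep], targets))] <- 1
  }
  m
}

#' Save / load prediction tensors in a portable self-describing container
#'
#' Ensemble predictions (`[models, samples, TFs]`) and masked predictions
#' (`[models, thresholds, samples, TFs]`) are stored as JSON holding the
#' dimension vector, optional dimension names, and the flattened values
#' (column-major), so any language can re-read them.
#'
#' @param tensor A numeric array.
#' @param path Output (input) path.
#' @param expected_rank For loading: if given, the stored rank must match.
#' @return `load_prediction_tensor` returns the array.
#' @export
save_prediction_tensor <- function(tensor, path) {
  if (!is.array(tensor)) stop_fmt("tensor must be an array")
  obj <- list(
    dim = dim(tensor),
    dimnames = dimnames(tensor),
    values = as.vector(tensor)
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_prediction_tensor
#' @export
load_prediction_tensor <- function(path, expected_rank = NULL) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(obj$dim)
  if (!is.null(expected_rank) && length(dims) != expected_rank) {
    stop_fmt("%s: stored tensor has rank %d, expected %d",
             path, length(dims), expected_rank)
  }
  if (length(obj$values) != prod(dims)) {
    stop_fmt("%s: value count %d does not match declared dims (%s)",
             path, length(obj$values), paste(dims, collapse = "x"))
  }
  arr <- array(as.numeric(obj$values), dim = dims)
  if (!is.null(obj$dimnames) && length(obj$dimnames) == length(dims)) {
    dn <- lapply(obj$dimnames, function(x) if (length(x) == 0) NULL else x)
    if (!all(vapply(dn, is.null, logical(1)))) dimnames(arr) <- dn
  }
  arr
}
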