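#' ECFP4 fingerprint of a molecule
#'
#' Computes the extended-connectivity fingerprint of radius 2 (ECFP4) for one
#' or more SMILES strings through OpenBabel (via ChemmineOB), folded to 2048
#' binary bits. The fingerprint is deterministic and invariant to SMILES
#' canonicalization of the same molecule.
#'
#' @param smiles Character vector of SMILES strings.
#' @param n_bits Folded fingerprint length (default 2048).
#' @return Logical matrix, one row per molecule, `n_bits` columns.
#' @export
fingerprint <- function(smiles, n_bits = 2048) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  bad <- which(is.na(smiles) | trimws(smiles) == "")
  if (length(bad) > 0) {
    stop_fmt("invalid SMILES at position %d: empty string", bad[1])
  }
  fps <- matrix(FALSE, length(smiles), n_bits)
  for (i in seq_along(smiles)) {
    raw <- tryCatch(
      ChemmineOB::fingerprint_OB(
        ChemmineOB::forEachMol("SMILES", smiles[i], identity), "ECFP4"),
      error = function(e) NULL)
    if (is.null(raw)) stop_fmt("unparseable SMILES: '%s'", smiles[i])
    v <- as.logical(if (is.matrix(raw)) raw[1, ] else raw)
    # fold the native width down to n_bits by OR-ing segments
    if (length(v) %% n_bits != 0) {
      stop_fmt("native fingerprint width %d is not a multiple of n_bits %d",
               length(v), n_bits)
    }
    folded <- rep(FALSE, n_bits)
    for (seg in seq_len(length(v) / n_bits)) {
      folded <- folded | v[((seg - 1) * n_bits + 1):(seg * n_bits)]
    }
    fps[i, ] <- folded
  }
  rownames(fps) <- smiles
  fps
}

#' Pairwise Tanimoto chemical-similarity matrix
#'
#' Builds the drugs x drugs similarity matrix `S` used by the drug layer:
#' `S[i, j]` is the Tanimoto (Jaccard) coefficient between the ECFP4 bit sets
#' of drugs i and j. The diagonal is exactly 1; the matrix is symmetric with
#' entries in \[0, 1\].
#'
#' @param smiles Character vector of SMILES (duplicates allowed; duplicate
#'   molecules get off-diagonal similarity 1).
#' @param n_bits Fingerprint length passed to [fingerprint()].
#' @return Numeric matrix with `smiles` as row and column names.
#' @export
tanimoto_matrix <- function(smiles, n_bits = 2048) {
  fps <- fingerprint(smiles, n_bits = n_bits)
  n <- nrow(fps)
  S <- matrix(1, n, n, dimnames = list(smiles, smiles))
  fpn <- rowSums(fps)
  inter <- fps %*% t(fps) # bit-set intersections
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      uni <- fpn[i] + fpn[j] - inter[i, j]
      S[i, j] <- if (uni == 0) 0 else inter[i, j] / uni
    }
  }
  S
}

#' Compute and save chemical similarities for a drug list CSV
#'
#' Reads a CSV with one column named `smiles`, computes the pairwise
#' Tanimoto matrix and writes it as a CSV matrix with SMILES row/column
#' names — the `ChemicalSims` file the training step consumes.
#'
#' @param smiles_csv Input CSV path (single column `smiles`).
#' @param out_csv Output CSV path.
#' @return The similarity matrix, invisibly.
#' @export
chemical_sims_file <- function(smiles_csv, out_csv) {
  df <- utils::read.csv(smiles_csv, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!"smiles" %in% colnames(df)) stop_fmt("%s must have a 'smiles' column", smiles_csv)
  S <- tanimoto_matrix(df$smiles)
  utils::write.csv(S, out_csv, quote = FALSE)
  invisible(S)
}
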