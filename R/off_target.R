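#' Ensemble off-target effect on TF activities
#'
#' For each model the full prediction `Yhat` is compared with a prediction
#' `Yhat_prime` in which the drug layer's effective drug-to-target map is
#' restricted to the prior mask's support (every beyond-prior drug-target
#' pair contributes zero signal). The restriction acts on the map, keeping
#' dose information, so a model whose learned interactions are confined to
#' the prior mask gives exactly zero difference. Ensemble means are taken
#' before differencing: `DeltaY = mean(Yhat_prime) - mean(Yhat)`. Control
#' samples (no active drug) have `DeltaY = 0` by construction and are
#' flagged.
#'
#' @param bundles `model_ensemble` (or list of bundles).
#' @param X Samples x drugs dose matrix.
#' @param prior_mask Binary drugs x targets prior matrix.
#' @return List of class `off_target_delta`: `delta` (samples x TFs),
#'   `Y_hat`, `Y_hat_prime` (ensemble means), `controls` (logical per
#'   sample).
#' @export
delta_tf <- function(bundles, X, prior_mask) {
  stopifnot(length(bundles) >= 1)
  check_named_matrix(prior_mask, "prior_mask")
  b1 <- bundles[[1]]
  targets <- b1$drug$targets
  drugs <- b1$drug$drugs
  stopifnot(identical(colnames(X), drugs))
  pm <- prior_mask[drugs, targets, drop = FALSE]
  active <- X != 0
  controls <- rowSums(active) == 0
  acc_full <- acc_masked <- NULL
  for (b in bundles) {
    yin <- drug_layer_forward(X, b$drug, b$S, FALSE)
    pred_full <- predict_model(b, X, yin_override = yin)$tf_activity
    # restrict the effective drug-to-target map to the prior support
    Z <- bn_transform(X, b$drug, FALSE)$Z
    M <- (b$S * b$drug$W_drug) %*% t(b$drug$A * b$drug$mask)
    yin_masked <- Z %*% (M * pm)
    dimnames(yin_masked) <- dimnames(yin)
    pred_masked <- predict_model(b, X, yin_override = yin_masked)$tf_activity
    # controls carry no drug signal to restrict
    pred_masked[controls, ] <- pred_full[controls, ]
    acc_full <- if (is.null(acc_full)) pred_full else acc_full + pred_full
    acc_masked <- if (is.null(acc_masked)) pred_masked else acc_masked + pred_masked
  }
  Y_hat <- acc_full / length(bundles)
  Y_hat_prime <- acc_masked / length(bundles)
  delta <- Y_hat_prime - Y_hat
  delta[controls, ] <- 0
  structure(list(delta = delta, Y_hat = Y_hat, Y_hat_prime = Y_hat_prime,
                 controls = controls), class = "off_target_delta")
}

#' Build the per-pair off-target record table
#'
#' One record per (sample, TF): the off-target delta, the TF's ensemble
#' training correlation, the induced (predicted) activity, and the active
#' drug of the sample.
#'
#' @param ot `off_target_delta`.
#' @param performance data.frame from [ensemble_train_performance()].
#' @param X Dose matrix (to name the active drug per sample).
#' @return data.frame with columns `sample`, `drug`, `tf`, `delta`, `r`,
#'   `activity`.
#' @export
off_target_records <- function(ot, performance, X) {
  tfs <- colnames(ot$delta)
  samples <- rownames(ot$delta) %||% as.character(seq_len(nrow(ot$delta)))
  drug_of <- apply(X != 0, 1, function(a) {
    if (!any(a)) "control" else paste(colnames(X)[a], collapse = "+")
  })
  rec <- expand.grid(sample = samples, tf = tfs, stringsAsFactors = FALSE)
  rec$drug <- drug_of[rec$sample]
  rec$delta <- as.vector(ot$delta)
  rec$activity <- as.vector(ot$Y_hat)
  rec$r <- performance$r[match(rec$tf, performance$tf)]
  rec[, c("sample", "drug", "tf", "delta", "r", "activity")]
}

#' Select candidate off-target drug-TF pairs
#'
#' Flags records with a large estimated off-target effect
#' (`|delta| >= delta_cut`, default 0.25, relaxed band at 0.2), marks as
#' interesting those whose induced TF activity is saturated high
#' (`> act_hi`) or low (`< act_lo`), and labels trust from the training
#' correlation bands (trusted above 0.4, untrusted below 0.2). Also returns
#' the per-TF maximum-|delta| record.
#'
#' @param records data.frame from [off_target_records()].
#' @param delta_cut,relaxed Absolute-delta cutoffs for `large` and
#'   `large_relaxed`.
#' @param act_hi,act_lo Induced-activity saturation cutoffs.
#' @param r_bands Length-2 vector `(trusted_above, untrusted_below)`.
#' @return List with `table` (records plus flag columns, ranked by |delta|)
#'   and `per_tf_max` (one row per TF).
#' @export
select_candidates <- function(records, delta_cut = 0.25, relaxed = 0.2,
                              act_hi = 0.75, act_lo = 0.25,
                              r_bands = c(0.4, 0.2)) {
  tb <- records
  tb$large <- abs(tb$delta) >= delta_cut
  tb$large_relaxed <- abs(tb$delta) >= relaxed
  tb$interesting <- tb$large & (tb$activity > act_hi | tb$activity < act_lo)
  tb$trust <- ifelse(is.na(tb$r), "undefined",
                     ifelse(tb$r > r_bands[1], "trusted",
                            ifelse(tb$r < r_bands[2], "untrusted",
                                   "intermediate")))
  tb <- tb[order(-abs(tb$delta)), , drop = FALSE]
  per_tf <- do.call(rbind, lapply(split(tb, tb$tf), function(d) {
    d[which.max(abs(d$delta)), , drop = FALSE]
  }))
  rownames(per_tf) <- NULL
  rownames(tb) <- NULL
  list(table = tb, per_tf_max = per_tf)
}

#' Write the off-target result files
#'
#' Emits `DeltaTF1.csv` (samples x TFs off-target deltas) and
#' `TrainEnsemblePerformance.csv` (per-TF ensemble training correlation)
#' into `res_dir`.
#'
#' @param ot `off_target_delta`.
#' @param performance data.frame from [ensemble_train_performance()].
#' @param res_dir Output directory.
#' @export
write_off_target <- function(ot, performance, res_dir) {
  dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ot$delta, file.path(res_dir, "DeltaTF1.csv"), quote = FALSE)
  utils::write.csv(performance,
                   file.path(res_dir, "TrainEnsemblePerformance.csv"),
                   quote = FALSE, row.names = FALSE)
  invisible(res_dir)
}
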