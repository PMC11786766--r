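#' Run the full synthetic recovery study
#'
#' End-to-end exercise of the pipeline on one synthetic ground truth:
#' generate the study ([make_ground_truth()] + [simulate_dataset()] at the
#' default 30-node / 20-drug / 150-condition scale), aggregate replicates,
#' train an ensemble (1500 epochs, the point at which the similarity-mixing
#' weights have converged on this problem size), infer drug-target
#' interactions, and score the consensus beyond-prior calls against the
#' planted off-target interactions.
#'
#' @param seed Generator seed (training seeds are derived from it).
#' @param n_models Ensemble size (default 5).
#' @param epochs Training epochs per member.
#' @param consensus_freq Consensus call frequency for a beyond-prior DTI.
#' @param ... Passed to [make_ground_truth()].
#' @return List: `precision`, `recall`, `called` (beyond-prior call table),
#'   `planted`, plus the intermediate `ensemble`, `dti`, `gt`, `X`, `Y`.
#' @export
run_recovery_study <- function(seed, n_models = 5, epochs = 1500,
                               consensus_freq = 0.6, ...) {
  gt <- make_ground_truth(seed = seed, ...)
  ds <- simulate_dataset(gt, seed = seed)
  Y <- aggregate_replicates(ds$Y_rep, ds$replicate_map)
  X <- ds$X[rownames(Y), , drop = FALSE]
  cfg <- training_config(epochs = epochs, n_models = n_models,
                         seed = derive_seed(seed * 100, 0))
  ens <- train_ensemble(X, Y, gt$mask, gt$S, gt$scaffold, cfg)
  res <- infer_dti(ens, X, Y)
  beyond <- res$frequency * (gt$mask == 0)
  called_idx <- which(beyond >= consensus_freq, arr.ind = TRUE)
  called <- data.frame(
    drug = rownames(beyond)[called_idx[, 1]],
    target = colnames(beyond)[called_idx[, 2]],
    frequency = beyond[called_idx],
    stringsAsFactors = FALSE
  )
  key <- function(d, t) paste(d, t, sep = "\r")
  tp <- sum(key(called$drug, called$target) %in%
              key(gt$planted$drug, gt$planted$target))
  list(
    precision = if (nrow(called) > 0) tp / nrow(called) else NA_real_,
    recall = tp / nrow(gt$planted),
    called = called, planted = gt$planted,
    ensemble = ens, dti = res, gt = gt, X = X, Y = Y
  )
}
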