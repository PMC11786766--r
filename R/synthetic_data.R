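# Built-in small-molecule SMILES used to name synthetic drug columns; the
# similarity structure of a synthetic study is planted explicitly, so these
# serve as realistic unique identifiers.
synthetic_smiles <- c(
  "CCO", "CCCO", "CCCCO", "CC(C)O", "CCN", "CCCN", "CC(C)N", "CCOC",
  "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
  "COc1ccccc1", "CC(=O)O", "CCC(=O)O", "CC(=O)N", "CC(=O)OC", "CCOC(=O)C",
  "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "CC(C)C(=O)O", "OCCO"
)

#' Generate a random trim-stable signaling scaffold
#'
#' Builds a random directed signed graph in which every node lies on a
#' directed path from some input (drug-target) node to some output (TF)
#' node, so the scaffold survives [trim_network()] unchanged. Nodes are
#' ordered inputs, intermediates, TFs; a backbone guarantees connectivity
#' (every non-input draws an edge from an earlier node, every non-TF sends
#' one to a later node) and the remaining edges are random forward edges
#' plus occasional feedback. About 70% of edges are stimulating.
#'
#' @param n_nodes,n_edges Graph size (`n_edges >= n_nodes - 1`).
#' @param n_inputs,n_tfs Numbers of input and output nodes.
#' @param seed Seed; the same seed yields the identical graph.
#' @param p_stim Probability of a stimulating sign.
#' @return A `scaffold_network` with node names `T<i>` (targets), `N<i>`
#'   (intermediates), `TF<i>` (transcription factors).
#' @export
make_scaffold <- function(n_nodes, n_edges, n_inputs, n_tfs, seed = 1,
                          p_stim = 0.7) {
  if (n_inputs + n_tfs > n_nodes) stop_fmt("n_inputs + n_tfs exceeds n_nodes")
  if (n_edges < n_nodes - 1) stop_fmt("need n_edges >= n_nodes - 1")
  set.seed(seed)
  n_mid <- n_nodes - n_inputs - n_tfs
  nodes <- c(paste0("T", seq_len(n_inputs)),
             if (n_mid > 0) paste0("N", seq_len(n_mid)) else character(0),
             paste0("TF", seq_len(n_tfs)))
  is_input <- seq_len(n_nodes) <= n_inputs
  is_tf <- seq_len(n_nodes) > n_inputs + n_mid
  edges <- matrix(NA_integer_, 0, 2)
  # backbone: each non-input receives from an earlier node; each non-TF sends
  # to a later node
  for (v in which(!is_input)) {
    u <- if (v == n_inputs + 1 || stats::runif(1) < 0.5) {
      sample(which(is_input), 1)
    } else sample(seq_len(v - 1), 1)
    edges <- rbind(edges, c(u, v))
  }
  for (u in which(!is_tf)) {
    v <- sample((u + 1):n_nodes, 1)
    edges <- rbind(edges, c(u, v))
  }
  edges <- unique(edges)
  # fill with random forward edges (10% feedback among intermediates)
  guard <- 0
  while (nrow(edges) < n_edges && guard < 50 * n_edges) {
    guard <- guard + 1
    feedback <- stats::runif(1) < 0.1 && n_mid > 1
    if (feedback) {
      uv <- sort(sample(which(!is_input & !is_tf), 2), decreasing = TRUE)
    } else {
      uv <- sort(sample(n_nodes, 2))
      if (is_tf[uv[1]]) next
      if (is_input[uv[2]]) next
    }
    cand <- rbind(edges, uv)
    if (nrow(unique(cand)) > nrow(edges)) edges <- unique(cand)
  }
  signs <- ifelse(stats::runif(nrow(edges)) < p_stim, 1, -1)
  edf <- data.frame(source = nodes[edges[, 1]], target = nodes[edges[, 2]],
                    stimulation = as.integer(signs > 0),
                    inhibition = as.integer(signs < 0),
                    provenance = "synthetic", sign = signs, flagged = FALSE,
                    stringsAsFactors = FALSE)
  scaffold_network(nodes = nodes, edges = edf,
                   input_nodes = nodes[is_input],
                   output_nodes = nodes[is_tf],
                   annotation = data.frame(node = nodes, gene = nodes,
                                           stringsAsFactors = FALSE))
}

#' Generate a synthetic ground truth with planted off-target interactions
#'
#' Builds the complete generative model a study assumes: a scaffold, a
#' prior drug-target mask (each drug one prior target, cycled over the
#' input nodes), a chemical-similarity matrix with planted high-similarity
#' drug pairs, and true model parameters in which each planted pair's first
#' drug additionally hits the second drug's prior target through the
#' similarity-mixing path — an off-target interaction absent from the prior
#' mask. Signaling weights are rescaled for a contractive (convergent)
#' steady-state iteration; node biases give a nonzero baseline so
#' inhibition is observable.
#'
#' @param n_nodes,n_edges,n_inputs,n_tfs Scaffold size.
#' @param n_drugs Number of drugs (at most `length(synthetic_smiles)`).
#' @param n_offtargets Number of planted off-target pairs.
#' @param seed Seed.
#' @param sim_planted Similarity of planted drug pairs (default 0.7).
#' @param w_off True mixing weight of the planted interaction; the default
#'   `1 / sim_planted` makes the planted off-target's dose sensitivity equal
#'   to a prior interaction's — an off-target as potent as the on-target,
#'   the regime in which off-target inference is meaningful (multi-kinase
#'   inhibitors being the canonical example).
#' @return List of class `ground_truth`: `scaffold`, `mask` (drugs x
#'   targets), `S`, `drug` (true `drug_layer_params`), `sig` (true
#'   `signaling_params`), `planted` (data.frame `drug`, `target`, `via`,
#'   `sign`).
#' @export
make_ground_truth <- function(n_nodes = 30, n_edges = 80, n_inputs = 5,
                              n_tfs = 8, n_drugs = 20, n_offtargets = 4,
                              seed = 1, sim_planted = 0.7,
                              w_off = 1 / sim_planted) {
  if (n_drugs > length(synthetic_smiles)) {
    stop_fmt("at most %d synthetic drugs available", length(synthetic_smiles))
  }
  scaffold <- make_scaffold(n_nodes, n_edges, n_inputs, n_tfs, seed = seed)
  set.seed(seed + 1000)
  drugs <- synthetic_smiles[seq_len(n_drugs)]
  targets <- scaffold$input_nodes
  mask <- matrix(0, n_drugs, length(targets), dimnames = list(drugs, targets))
  mask[cbind(seq_len(n_drugs), rep_len(seq_along(targets), n_drugs))] <- 1

  # synthetic similarity: weak random background, planted similar pairs
  S <- matrix(stats::runif(n_drugs^2, 0, 0.15), n_drugs, n_drugs)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(drugs, drugs)
  prior_target_idx <- apply(mask, 1, which.max)

  # gain chosen so target-node inputs stay mostly inside the activation's
  # graded range over the dose grid (u = bias + A * dose < 2 for most doses)
  drug <- drug_layer_params(mask, seed = seed + 2000)
  drug$A <- drug$mask * 0.6

  sig <- signaling_params(scaffold, seed = seed + 3000)
  # rescale for contraction at baseline
  W <- weight_matrix(sig)
  rho <- max(abs(eigen(W * activation_grad(0.3, sig$leak),
                       only.values = TRUE)$values))
  if (rho > 0.85) {
    sig$raw_weights <- log(expm1(softplus(sig$raw_weights) * 0.85 / rho))
  }
  sig$bias <- stats::runif(length(sig$nodes), 0.05, 0.35)
  # mid-range baseline at the drug-target nodes so inhibitory interactions
  # produce graded (not silenced) responses
  sig$bias[sig$input_idx] <- stats::runif(length(sig$input_idx), 0.4, 0.6)

  # downstream influence of each target node: mean absolute TF shift of a
  # unit perturbation, used to plant only off-targets whose effect is
  # observable at the TF layer (an unobservable planting tests nothing)
  zero_yin <- matrix(0, 1, length(targets), dimnames = list("s", targets))
  base_tf <- steady_state(sig, embed_input(zero_yin, scaffold))$tf_activity
  influence <- vapply(seq_along(targets), function(k) {
    yin <- zero_yin
    yin[1, k] <- 1
    mean(abs(steady_state(sig, embed_input(yin, scaffold))$tf_activity -
               base_tf))
  }, numeric(1))

  planted <- NULL
  cand_pairs <- which(outer(prior_target_idx, prior_target_idx, `!=`),
                      arr.ind = TRUE)
  cand_pairs <- cand_pairs[cand_pairs[, 1] != cand_pairs[, 2], , drop = FALSE]
  # planted target must carry at least half the influence of the drug's own
  # prior target, so its masking share stays detectable
  ratio <- influence[prior_target_idx[cand_pairs[, 2]]] /
    pmax(influence[prior_target_idx[cand_pairs[, 1]]], 1e-9)
  qualified <- which(ratio >= 0.5)
  ord <- if (length(qualified) >= n_offtargets) {
    sample(qualified, n_offtargets)
  } else {
    order(ratio, decreasing = TRUE)[seq_len(n_offtargets)]
  }
  pick <- cand_pairs[ord, , drop = FALSE]

  W_true <- diag(1, n_drugs)
  for (r in seq_len(nrow(pick))) {
    i <- pick[r, 1]; j <- pick[r, 2]
    S[i, j] <- S[j, i] <- sim_planted
    sgn <- sample(c(-1, 1), 1)
    W_true[i, j] <- sgn * w_off
    planted <- rbind(planted, data.frame(
      drug = drugs[i], target = targets[prior_target_idx[j]],
      via = drugs[j], sign = sgn, stringsAsFactors = FALSE))
  }
  # keep planted pairs disjoint from the prior mask
  keep <- mask[cbind(match(planted$drug, drugs),
                     match(planted$target, targets))] == 0
  planted <- planted[keep, , drop = FALSE]
  planted <- planted[!duplicated(planted[, c("drug", "target")]), , drop = FALSE]
  drug$W_drug <- W_true

  structure(list(scaffold = scaffold, mask = mask, S = S, drug = drug,
                 sig = sig, planted = planted, drugs = drugs,
                 targets = targets, seed = seed),
            class = "ground_truth")
}

#' Simulate a dose-response study from a ground truth
#'
#' Each non-control condition applies one drug at a log-dose drawn from a
#' grid spanning two orders of magnitude below to one above 1 micromolar
#' (log10 dose in \[-2, 1\], stored shifted so 0 still means "absent"); a
#' fraction of conditions are DMSO-like controls with all-zero dose rows.
#' True TF activities are the ground-truth model's steady state; each
#' replicate adds independent Gaussian noise and is clipped to (0, 1).
#'
#' @param gt `ground_truth`.
#' @param n_conditions Number of conditions (including controls).
#' @param n_replicates Replicates per condition (default 3, the usual
#'   perturbational-screen design).
#' @param noise_sd Replicate noise standard deviation (default 0.03).
#' @param control_frac Fraction of control conditions (default 0.08).
#' @param seed Seed; fixed seed gives identical output.
#' @return List: `X` (conditions x drugs doses), `Y` (conditions x TFs
#'   noise-free truth), `Y_rep` (replicates x TFs), `replicate_map`
#'   (data.frame `sample_id`, `condition_id`), `conditions` (data.frame of
#'   the design).
#' @export
simulate_dataset <- function(gt, n_conditions = 150, n_replicates = 3,
                             noise_sd = 0.03, control_frac = 0.08, seed = 1) {
  stopifnot(n_conditions >= 1)
  set.seed(seed)
  n_drugs <- length(gt$drugs)
  n_ctrl <- max(1, round(control_frac * n_conditions))
  n_trt <- n_conditions - n_ctrl
  cond_drug <- c(rep_len(seq_len(n_drugs), n_trt), rep(NA, n_ctrl))
  log_dose <- c(stats::runif(n_trt, -2, 1), rep(NA, n_ctrl))
  cond_ids <- sprintf("cond_%03d", seq_len(n_conditions))
  X <- matrix(0, n_conditions, n_drugs, dimnames = list(cond_ids, gt$drugs))
  trt <- !is.na(cond_drug)
  X[cbind(which(trt), cond_drug[trt])] <- log_dose[trt] + 2.1 # 0 keeps meaning absent

  yin <- X %*% (gt$S * gt$drug$W_drug) %*% t(gt$drug$A * gt$drug$mask)
  colnames(yin) <- gt$targets
  emb <- embed_input(yin, gt$scaffold)
  st <- steady_state(gt$sig, emb)
  if (!all(st$converged)) {
    # damp the generative weights until the steady state converges
    warn_fmt("ground-truth steady state not converged; damping weights")
    gt$sig$raw_weights <- log(expm1(softplus(gt$sig$raw_weights) * 0.8))
    st <- steady_state(gt$sig, emb)
  }
  Y <- st$tf_activity
  colnames(Y) <- gt$scaffold$output_nodes
  rownames(Y) <- cond_ids

  rep_ids <- as.vector(vapply(cond_ids, function(cc) {
    sprintf("%s_rep%d", cc, seq_len(n_replicates))
  }, character(n_replicates)))
  Y_rep <- Y[rep(seq_len(n_conditions), each = n_replicates), , drop = FALSE]
  if (noise_sd > 0) {
    Y_rep <- Y_rep + matrix(stats::rnorm(length(Y_rep), 0, noise_sd),
                            nrow(Y_rep))
  }
  Y_rep <- pmin(pmax(Y_rep, 1e-3), 1 - 1e-3)
  rownames(Y_rep) <- rep_ids
  list(
    X = X, Y = Y, Y_rep = Y_rep,
    replicate_map = data.frame(sample_id = rep_ids,
                               condition_id = rep(cond_ids,
                                                  each = n_replicates),
                               stringsAsFactors = FALSE),
    conditions = data.frame(condition_id = cond_ids,
                            drug = ifelse(trt, gt$drugs[cond_drug], "control"),
                            log10_dose = log_dose,
                            stringsAsFactors = FALSE)
  )
}

#' Write a synthetic study to the pipeline's file formats
#'
#' Emits the exact TSV/CSV files the pipeline consumes: `DrugsIn` (doses),
#' `TargetsIn` (prior mask), `TFsOut` (replicate-aggregated TF activities),
#' `ChemicalSims`, `PKN` and `PknAnnotation`.
#'
#' @param gt `ground_truth`.
#' @param ds [simulate_dataset()] output.
#' @param dir Output directory.
#' @return Named list of written paths.
#' @export
write_synthetic_study <- function(gt, ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    DrugsIn = file.path(dir, "conditions_drugs.tsv"),
    TargetsIn = file.path(dir, "drugs_targets.tsv"),
    TFsOut = file.path(dir, "tf_activities.tsv"),
    ChemicalSims = file.path(dir, "chemical_sims.csv"),
    PKN = file.path(dir, "pkn.tsv"),
    PknAnnotation = file.path(dir, "pkn_annotation.tsv"),
    planted = file.path(dir, "planted_offtargets.tsv")
  )
  write_matrix_tsv(ds$X, paths$DrugsIn, id_col = "sample")
  write_matrix_tsv(gt$mask, paths$TargetsIn, id_col = "smiles")
  write_matrix_tsv(aggregate_replicates(ds$Y_rep, ds$replicate_map),
                   paths$TFsOut, id_col = "sample")
  utils::write.csv(gt$S, paths$ChemicalSims, quote = FALSE)
  write_scaffold(gt$scaffold, paths$PKN, paths$PknAnnotation)
  utils::write.table(gt$planted, paths$planted, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
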