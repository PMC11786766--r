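# Shared fixtures, generated in code.

# tiny signed interaction table: input -> a -> TF plus a dangling node d
tiny_edges <- function() {
  data.frame(
    source = c("in1", "a", "a"),
    target = c("a", "tf1", "d"),
    stimulation = c(1, 1, 1),
    inhibition = c(0, 0, 0),
    provenance = "fixture",
    sign = c(1, 1, 1),
    flagged = FALSE,
    stringsAsFactors = FALSE
  )
}

random_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  uv <- unique(t(replicate(n_edges * 2, sample(n_nodes, 2))))
  uv <- uv[seq_len(min(n_edges, nrow(uv))), , drop = FALSE]
  data.frame(source = nodes[uv[, 1]], target = nodes[uv[, 2]],
             stimulation = 1, inhibition = 0, provenance = "rand",
             sign = 1, flagged = FALSE, stringsAsFactors = FALSE)
}

# brute-force reachability filter: nodes on some input->output path via
# transitive closure of the adjacency matrix (the oracle trim)
closure_trim_oracle <- function(edges, inputs, outputs) {
  nodes <- unique(c(edges$source, edges$target, inputs, outputs))
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(match(edges$source, nodes), match(edges$target, nodes))] <- TRUE
  R <- A | diag(TRUE, n)
  for (k in seq_len(n)) R <- R | (R %*% R) > 0
  from_in <- apply(R[intersect(inputs, nodes), , drop = FALSE], 2, any)
  to_out <- apply(R[, intersect(outputs, nodes), drop = FALSE], 1, any)
  nodes[from_in & to_out]
}

# small trained fixture shared by the heavier tests; cached per session
small_trained_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gt <- make_ground_truth(n_nodes = 20, n_edges = 50, n_inputs = 4,
                            n_tfs = 5, n_drugs = 8, n_offtargets = 2,
                            seed = 11)
    ds <- simulate_dataset(gt, n_conditions = 120, seed = 11)
    Y <- aggregate_replicates(ds$Y_rep, ds$replicate_map)
    X <- ds$X[rownames(Y), , drop = FALSE]
    cfg <- training_config(epochs = 400, n_models = 3, seed = 500)
    ens <- suppressWarnings(train_ensemble(X, Y, gt$mask, gt$S, gt$scaffold, cfg))
    cache <<- list(gt = gt, ds = ds, X = X, Y = Y, ens = ens)
    cache
  }
})

# random drug-layer parameters for Jacobian-equivalence checks
random_drug_layer <- function(n_drugs = 5, n_targets = 3, seed = 1) {
  set.seed(seed)
  drugs <- paste0("d", seq_len(n_drugs))
  targets <- paste0("t", seq_len(n_targets))
  mask <- matrix(rbinom(n_drugs * n_targets, 1, 0.4), n_drugs, n_targets,
                 dimnames = list(drugs, targets))
  mask[1, 1] <- 1
  p <- drug_layer_params(mask, seed = seed)
  p$W_drug <- matrix(rnorm(n_drugs^2, 0, 0.5), n_drugs) + diag(n_drugs)
  p$A <- p$mask * matrix(rnorm(n_targets * n_drugs, 1, 0.5), n_targets)
  p$w_bn <- runif(n_drugs, 0.5, 1.5)
  p$b_bn <- rnorm(n_drugs, 0, 0.2)
  p$mu_bn <- rnorm(n_drugs, 0, 0.3)
  p$var_bn <- runif(n_drugs, 0.5, 2)
  S <- matrix(runif(n_drugs^2, 0, 0.5), n_drugs)
  S <- (S + t(S)) / 2; diag(S) <- 1
  dimnames(S) <- list(drugs, drugs)
  list(params = p, S = S, drugs = drugs, targets = targets)
}
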