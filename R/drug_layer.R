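#' Construct drug-layer parameters
#'
#' The drug layer maps log-dose inputs to perturbation signals on target
#' proteins in three stages: per-drug batch normalization, chemical-similarity
#' scaled drug mixing (`S` elementwise `W_drug`), and a masked drug-target
#' weight map (`A` elementwise the binary prior `mask`). `W_drug` is
#' initialized at the identity so prior interactions dominate at the start of
#' training; `A` starts from the mask with small positive values.
#'
#' @param mask Binary prior drug-target matrix, **drugs x targets** (the
#'   canonical orientation; the layer stores the targets x drugs transpose).
#' @param eps Batch-normalization stabilizer (default 1e-5).
#' @param init_a Initial magnitude for prior interaction weights.
#' @param seed Optional seed for the small random jitter on `A`.
#' @return Object of class `drug_layer_params`.
#' @export
drug_layer_params <- function(mask, eps = 1e-5, init_a = 1, seed = NULL) {
  check_named_matrix(mask, "mask")
  if (!all(mask %in% c(0, 1))) stop_fmt("mask must be binary")
  drugs <- rownames(mask)
  targets <- colnames(mask)
  d <- length(drugs)
  if (!is.null(seed)) set.seed(seed)
  A <- t(mask) * (init_a + stats::runif(length(mask), -0.1, 0.1))
  structure(list(
    drugs = drugs,
    targets = targets,
    W_drug = diag(1, d, d),
    A = A,                      # targets x drugs
    mask = t(mask),             # targets x drugs
    w_bn = rep(1, d),
    b_bn = rep(0, d),
    mu_bn = rep(0, d),
    var_bn = rep(1, d),
    eps = eps
  ), class = "drug_layer_params")
}

# batch-normalized doses: training mode uses batch statistics, inference mode
# the running statistics stored in the parameters
bn_transform <- function(X, params, training_mode = FALSE) {
  if (training_mode) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
  } else {
    mu <- params$mu_bn
    v <- params$var_bn
  }
  Z <- sweep(sweep(X, 2, mu), 2, sqrt(v + params$eps), "/")
  Z <- sweep(sweep(Z, 2, params$w_bn, "*"), 2, params$b_bn, "+")
  list(Z = Z, mu = mu, var = v)
}

#' Drug-layer forward pass
#'
#' Computes the perturbation signal `Yin = BN(X) (S * W_drug) (A * mask)^T`
#' (samples x targets). In training mode the normalization uses batch
#' statistics; otherwise the stored running statistics.
#'
#' @param X Samples x drugs dose matrix (0 = drug absent); columns must align
#'   with `params$drugs` and `S`.
#' @param params `drug_layer_params`.
#' @param S Drugs x drugs chemical-similarity matrix.
#' @param training_mode Logical; use batch statistics when `TRUE`.
#' @return Samples x targets signal matrix.
#' @export
drug_layer_forward <- function(X, params, S, training_mode = FALSE) {
  if (!identical(colnames(X), params$drugs)) {
    stop_fmt("drug ordering of X does not match the drug-layer parameters")
  }
  if (!identical(rownames(S), params$drugs) ||
      !identical(colnames(S), params$drugs)) {
    stop_fmt("drug ordering of S does not match the drug-layer parameters")
  }
  Z <- bn_transform(X, params, training_mode)$Z
  H <- Z %*% (S * params$W_drug)
  Yin <- H %*% t(params$A * params$mask)
  colnames(Yin) <- params$targets
  rownames(Yin) <- rownames(X)
  Yin
}

#' Closed-form drug-target interaction scores for the linear drug layer
#'
#' The exact Jacobian of the drug layer's output with respect to its dose
#' inputs, computed in closed form:
#' `K = w_bn / sqrt(var_bn + eps)`, `W = S * W_drug`, `A = A * mask`,
#' `scores[i, t] = K[i] * sum_j W[i, j] * A[t, j]`.
#' `K` scales the row of `W` indexed by the *input* drug, so each score chain
#' ends at that drug's normalization slope. Running (inference) statistics
#' are used, and the result equals the integrated-gradients attribution of
#' the same layer (see [ig_scores()]).
#'
#' @param params `drug_layer_params`.
#' @param S Drugs x drugs similarity matrix.
#' @return Drugs x targets score matrix.
#' @export
closed_form_scores <- function(params, S) {
  K <- params$w_bn / sqrt(params$var_bn + params$eps)
  W <- S * params$W_drug
  A <- params$A * params$mask               # targets x drugs
  scores <- t(A %*% t(K * W))               # (K*W) scales row i by K[i]
  dimnames(scores) <- list(params$drugs, params$targets)
  scores
}
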