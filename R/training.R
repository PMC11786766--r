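#' Training configuration
#'
#' Collects every training hyperparameter with its default: 500 epochs,
#' batch size 25, adaptive-moment (Adam) steps at learning rate 1e-3 under a
#' cosine schedule with one warm restart at mid-training, input noise scale
#' `noise_lambda` (default 0.01) annealed linearly to zero, and the
#' regularization coefficients of [regularization_terms()].
#'
#' @param epochs,batch_size,learning_rate,noise_lambda Scalars as described.
#' @param lambda Regularization coefficient list (see
#'   [regularization_terms()]).
#' @param n_models Ensemble size (default 50, as the protocol's ensembles);
#'   member `i` trains with seed `base_seed + i`.
#' @param seed Base seed.
#' @return List of class `training_config`.
#' @export
training_config <- function(epochs = 500, batch_size = 25,
                            learning_rate = 1e-3, noise_lambda = 0.01,
                            lambda = list(l2_sig = 1e-4, spectral = 1e-2,
                                          l2_wdrug = 1e-5, l2_a = 1e-5,
                                          rho_max = 0.95),
                            n_models = 50, seed = 1) {
  stopifnot(n_models >= 1, epochs >= 1, batch_size >= 1)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, noise_lambda = noise_lambda,
                 lambda = lambda, n_models = n_models, seed = seed),
            class = "training_config")
}

# one Adam state per parameter block
adam_init <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, dim = s), v = array(0, dim = s)))
}

adam_step <- function(state, grad, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  state$delta <- lr * mhat / (sqrt(vhat) + eps)
  state
}

# cosine learning-rate schedule with a warm restart at mid-training
lr_schedule <- function(epoch, epochs, lr_base) {
  half <- ceiling(epochs / 2)
  pos <- if (epoch <= half) (epoch - 1) / half else (epoch - half - 1) / max(1, epochs - half)
  lr_base * (0.1 + 0.9 * 0.5 * (1 + cos(pi * pos)))
}

# full forward + adjoint backward pass on one batch; returns loss pieces and
# gradients for every trainable block
model_batch_grad <- function(Xb, Yb, drug, sig, S, training_mode, noise_sd,
                             lambda) {
  bn <- bn_transform(Xb, drug, training_mode)
  Z <- bn$Z
  P <- S * drug$W_drug
  AM <- drug$A * drug$mask           # targets x drugs
  H <- Z %*% P
  Yin <- H %*% t(AM)
  colnames(Yin) <- drug$targets
  C <- matrix(0, nrow(Xb), length(sig$nodes))
  pos <- match(drug$targets, sig$nodes)
  C[, pos] <- Yin
  if (noise_sd > 0) C <- C + matrix(stats::rnorm(length(C), 0, noise_sd),
                                    nrow(C))
  W <- weight_matrix(sig)
  dimnames(W) <- NULL # keep the iteration loop free of attribute copying
  tW <- t(W)
  off <- sweep(C, 2, sig$bias, "+")
  a <- matrix(0, nrow(Xb), ncol(C))
  u <- off
  for (it in seq_len(sig$max_iters)) {
    u <- a %*% tW + off
    a_new <- activation(u, sig$leak)
    if (max(abs(a_new - a)) < sig$tol) { a <- a_new; break }
    a <- a_new
  }
  Yhat <- a[, sig$output_idx, drop = FALSE]
  err <- mean((Yb - Yhat)^2)

  # adjoint fixed point: Lam = f'(u) * (G + Lam W)
  G <- matrix(0, nrow(Xb), ncol(a))
  G[, sig$output_idx] <- 2 * (Yhat - Yb) / length(Yb)
  Fp <- activation_grad(u, sig$leak)
  Lam <- Fp * G
  for (it in seq_len(sig$max_iters)) {
    Lam_new <- Fp * (G + Lam %*% W)
    if (max(abs(Lam_new - Lam)) < sig$tol * 1e-2) { Lam <- Lam_new; break }
    Lam <- Lam_new
  }

  g_bias <- colSums(Lam)
  dW <- crossprod(Lam, a)            # dL/dW[i, j]
  g_edge <- dW[cbind(sig$tgt_idx, sig$src_idx)]
  # chain through the sign constraint weight = sign * softplus(raw)
  dwdraw <- ifelse(sig$signs == 0, 1, sig$signs * sigmoid(sig$raw_weights))
  g_raw <- g_edge * dwdraw

  G_yin <- Lam[, pos, drop = FALSE]
  G_H <- G_yin %*% AM
  g_AM <- crossprod(G_yin, H)        # targets x drugs
  g_A <- g_AM * drug$mask
  g_P <- crossprod(Z, G_H)
  g_Wdrug <- S * g_P
  G_Z <- G_H %*% t(P)
  Zhat <- sweep(sweep(Xb, 2, bn$mu), 2, sqrt(bn$var + drug$eps), "/")
  g_wbn <- colSums(G_Z * Zhat)
  g_bbn <- colSums(G_Z)

  # regularization gradients
  w <- softplus(sig$raw_weights) * sig$signs
  w[sig$signs == 0] <- sig$raw_weights[sig$signs == 0]
  reg_sig <- lambda$l2_sig * sum(w^2)
  g_raw <- g_raw + 2 * lambda$l2_sig * w * dwdraw
  fp_mean <- colMeans(Fp)
  sp <- spectral_surrogate(W, fp_mean, n_iter = 25)
  reg_spec <- lambda$spectral * max(0, sp$rho - lambda$rho_max)^2
  if (sp$rho > lambda$rho_max) {
    uv <- sum(sp$u * sp$v)
    if (abs(uv) > 1e-8) {
      drho_dW <- outer(sp$u, sp$v * fp_mean) / uv
      lam_num <- sum(sp$u * ((W * rep(fp_mean, each = nrow(W))) %*% sp$v))
      s_ <- sign(lam_num / uv)
      coef <- 2 * lambda$spectral * (sp$rho - lambda$rho_max) * s_
      g_spec_edge <- coef * drho_dW[cbind(sig$tgt_idx, sig$src_idx)]
      g_raw <- g_raw + g_spec_edge * dwdraw
    }
  }
  d <- length(drug$drugs)
  g_Wdrug <- g_Wdrug + 2 * lambda$l2_wdrug * (drug$W_drug - diag(1, d, d))
  reg_wd <- lambda$l2_wdrug * sum((drug$W_drug - diag(1, d, d))^2)
  g_A <- g_A + 2 * lambda$l2_a * AM * drug$mask
  reg_a <- lambda$l2_a * sum(AM^2)

  list(mse = err,
       loss = err + reg_sig + reg_spec + reg_wd + reg_a,
       rho = sp$rho,
       bn_mu = bn$mu, bn_var = bn$var,
       grads = list(raw_weights = g_raw, bias = g_bias, W_drug = g_Wdrug,
                    A = g_A, w_bn = g_wbn, b_bn = g_bbn))
}

#' Train one interactome-constrained model
#'
#' Minimizes the mean squared error between measured and predicted TF
#' activities plus the regularization penalties by stochastic
#' adaptive-moment gradient steps. Gaussian noise of scale
#' `config$noise_lambda` (annealed linearly to zero) is added to the
#' embedded drug-layer signal during training only. Batch-normalization
#' running statistics are tracked with momentum 0.1 and used for all
#' inference-time computations.
#'
#' @param X Samples x drugs dose matrix.
#' @param Y Samples x TFs measured activity matrix, values in (0, 1); rows
#'   aligned with `X`.
#' @param mask Binary drugs x targets prior interaction matrix.
#' @param S Drugs x drugs chemical-similarity matrix.
#' @param scaffold `scaffold_network` whose input nodes cover the mask's
#'   targets and whose output nodes cover `colnames(Y)`.
#' @param config `training_config`.
#' @param seed Seed fixing initialization, batching, and noise.
#' @return A `model_bundle`: learned `drug` and `sig` parameters, `S`,
#'   `scaffold`, the per-epoch `diagnostics`, and the seed.
#' @export
train_model <- function(X, Y, mask, S, scaffold, config = training_config(),
                        seed = config$seed) {
  check_named_matrix(X, "X"); check_named_matrix(Y, "Y")
  stopifnot(identical(rownames(X), rownames(Y)))
  if (nrow(X) < 100) {
    warn_fmt("only %d conditions; at least 100-120 are recommended for a predictive model",
             nrow(X))
  }
  if (!all(colnames(Y) %in% scaffold$output_nodes)) {
    stop_fmt("TF column(s) of Y missing from the scaffold's output nodes")
  }
  set.seed(seed)
  drug <- drug_layer_params(mask, seed = seed)
  sig <- signaling_params(scaffold, seed = seed + 1)
  # restrict the readout to the TFs actually present in Y, in Y's order
  sig$output_idx <- match(colnames(Y), sig$nodes)

  blocks <- c("raw_weights", "bias", "W_drug", "A", "w_bn", "b_bn")
  shapes <- list(length(sig$raw_weights), length(sig$bias),
                 dim(drug$W_drug), dim(drug$A),
                 length(drug$w_bn), length(drug$b_bn))
  names(shapes) <- blocks
  adam <- adam_init(shapes)
  t_step <- 0
  n <- nrow(X)
  momentum <- 0.1
  loss_trace <- mse_trace <- rho_trace <- numeric(config$epochs)

  # reference error before any update (batch statistics over the full set)
  bn0 <- bn_transform(X, drug, TRUE)
  drug$mu_bn <- bn0$mu
  drug$var_bn <- bn0$var
  yin0 <- drug_layer_forward(X, drug, S, FALSE)
  st0 <- steady_state(sig, embed_input(yin0, scaffold))
  mse0 <- mean((Y - st0$node_activity[, sig$output_idx, drop = FALSE])^2)

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config$epochs, config$learning_rate)
    noise_sd <- config$noise_lambda * (1 - (epoch - 1) / config$epochs)
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    ep_loss <- ep_mse <- ep_rho <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + config$batch_size - 1, n)]
      if (length(idx) < 2) next # batch statistics need >= 2 samples
      res <- model_batch_grad(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                              drug, sig, S, TRUE, noise_sd, config$lambda)
      if (!is.finite(res$loss)) {
        stop_fmt("NaN/Inf loss at epoch %d (batch starting at sample %d)",
                 epoch, s0)
      }
      t_step <- t_step + 1
      for (b in blocks) {
        adam[[b]] <- adam_step(adam[[b]], res$grads[[b]], lr, t_step)
      }
      sig$raw_weights <- sig$raw_weights - as.vector(adam$raw_weights$delta)
      sig$bias <- sig$bias - as.vector(adam$bias$delta)
      drug$W_drug <- drug$W_drug - adam$W_drug$delta
      drug$A <- drug$A - adam$A$delta
      drug$w_bn <- drug$w_bn - as.vector(adam$w_bn$delta)
      drug$b_bn <- drug$b_bn - as.vector(adam$b_bn$delta)
      drug$mu_bn <- (1 - momentum) * drug$mu_bn + momentum * res$bn_mu
      drug$var_bn <- (1 - momentum) * drug$var_bn + momentum * res$bn_var
      frac <- length(idx) / n
      ep_loss <- ep_loss + res$loss * frac
      ep_mse <- ep_mse + res$mse * frac
      ep_rho <- max(ep_rho, res$rho)
    }
    loss_trace[epoch] <- ep_loss
    mse_trace[epoch] <- ep_mse
    rho_trace[epoch] <- ep_rho
  }

  bundle <- structure(list(
    drug = drug, sig = sig, S = S, scaffold = scaffold,
    tf_names = colnames(Y),
    diagnostics = list(loss = loss_trace, mse = mse_trace, rho = rho_trace,
                       mse_initial = mse0),
    config = config, seed = seed
  ), class = "model_bundle")
  bundle
}

#' Predict with a trained model
#'
#' Inference-mode forward pass: drug layer with running batch statistics,
#' then the recurrent signaling network to steady state.
#'
#' @param bundle `model_bundle`.
#' @param X Samples x drugs dose matrix.
#' @param yin_override Optional samples x targets matrix replacing the drug
#'   layer's output (used by masking-based attribution and off-target
#'   estimation).
#' @return List with `tf_activity` (samples x TFs), `node_activity`,
#'   `yin`, and `converged`.
#' @export
predict_model <- function(bundle, X, yin_override = NULL) {
  yin <- yin_override %||% drug_layer_forward(X, bundle$drug, bundle$S, FALSE)
  emb <- embed_input(yin, bundle$scaffold)
  st <- steady_state(bundle$sig, emb)
  colnames(st$tf_activity) <- bundle$sig$nodes[bundle$sig$output_idx]
  list(tf_activity = st$tf_activity, node_activity = st$node_activity,
       yin = yin, converged = st$converged)
}

#' Train an ensemble of models
#'
#' Trains `config$n_models` models with member seeds `config$seed + i`.
#' Member failures are recorded and the ensemble continues; fewer than two
#' surviving members (when more were requested) is an error.
#'
#' @inheritParams train_model
#' @param res_dir Optional directory; each member bundle is serialized there
#'   as `<out_pattern><i>.json`.
#' @param out_pattern File-name pattern for saved members.
#' @return List of `model_bundle`s (class `model_ensemble`) with a
#'   `failures` attribute.
#' @export
train_ensemble <- function(X, Y, mask, S, scaffold,
                           config = training_config(), res_dir = NULL,
                           out_pattern = "model") {
  bundles <- list()
  failures <- list()
  for (i in seq_len(config$n_models)) {
    member_seed <- derive_seed(config$seed, i)
    b <- tryCatch(
      train_model(X, Y, mask, S, scaffold, config, seed = member_seed),
      error = function(e) e)
    if (inherits(b, "error")) {
      failures[[length(failures) + 1]] <- list(member = i,
                                               message = conditionMessage(b))
      warn_fmt("ensemble member %d failed: %s", i, conditionMessage(b))
    } else {
      bundles[[length(bundles) + 1]] <- b
      if (!is.null(res_dir)) {
        save_model_bundle(b, file.path(res_dir,
                                       sprintf("%s%d.json", out_pattern, i)))
      }
    }
  }
  if (config$n_models >= 2 && length(bundles) < 2) {
    stop_fmt("fewer than 2 ensemble members survived training")
  }
  if (length(bundles) == 0) stop_fmt("all ensemble members failed")
  structure(bundles, class = "model_ensemble", failures = failures)
}

#' Per-TF training performance of an ensemble
#'
#' The ensemble-mean prediction is compared per TF with the measured
#' activity by Pearson correlation. Each TF is labelled `trusted`
#' (r > 0.4), `intermediate`, or `untrusted` (r < 0.2), the bands used to
#' decide which fitted TFs to interpret.
#'
#' @param bundles `model_ensemble` (or list of `model_bundle`s).
#' @param X,Y Dose and measured-activity matrices (rows aligned).
#' @return data.frame with columns `tf`, `r`, `label`.
#' @export
ensemble_train_performance <- function(bundles, X, Y) {
  stopifnot(length(bundles) >= 1)
  preds <- lapply(bundles, function(b) predict_model(b, X)$tf_activity)
  Ybar <- Reduce(`+`, preds) / length(preds)
  r <- vapply(seq_len(ncol(Y)), function(j) {
    yj <- Y[, j]; pj <- Ybar[, j]
    if (stats::sd(yj) == 0 || stats::sd(pj) == 0) return(NA_real_)
    stats::cor(yj, pj)
  }, numeric(1))
  if (anyNA(r)) {
    message(sprintf("%d TF(s) with constant profiles; correlation undefined",
                    sum(is.na(r))))
  }
  data.frame(
    tf = colnames(Y),
    r = r,
    label = ifelse(is.na(r), "undefined",
                   ifelse(r > 0.4, "trusted",
                          ifelse(r < 0.2, "untrusted", "intermediate"))),
    stringsAsFactors = FALSE
  )
}

#' Serialize / restore a model bundle
#'
#' Stores every parameter block and the scaffold in the portable JSON
#' container so trained members round-trip losslessly across sessions.
#'
#' @param bundle `model_bundle`.
#' @param path File path.
#' @export
save_model_bundle <- function(bundle, path) {
  obj <- list(
    drugs = bundle$drug$drugs, targets = bundle$drug$targets,
    W_drug = bundle$drug$W_drug, A = bundle$drug$A, mask = bundle$drug$mask,
    w_bn = bundle$drug$w_bn, b_bn = bundle$drug$b_bn,
    mu_bn = bundle$drug$mu_bn, var_bn = bundle$drug$var_bn,
    eps = bundle$drug$eps,
    nodes = bundle$sig$nodes,
    edges = bundle$scaffold$edges,
    raw_weights = bundle$sig$raw_weights, bias = bundle$sig$bias,
    signs = bundle$sig$signs,
    leak = bundle$sig$leak, max_iters = bundle$sig$max_iters,
    tol = bundle$sig$tol,
    input_nodes = bundle$scaffold$input_nodes,
    output_nodes = bundle$scaffold$output_nodes,
    tf_names = bundle$tf_names,
    S = bundle$S, seed = bundle$seed,
    diagnostics = bundle$diagnostics
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_named <- function(m, rn, cn) {
    m <- as.matrix(m); dimnames(m) <- list(rn, cn); m
  }
  scaffold <- scaffold_network(
    nodes = o$nodes, edges = as.data.frame(o$edges),
    input_nodes = o$input_nodes, output_nodes = o$output_nodes)
  drug <- structure(list(
    drugs = o$drugs, targets = o$targets,
    W_drug = as_named(o$W_drug, o$drugs, o$drugs),
    A = as_named(o$A, o$targets, o$drugs),
    mask = as_named(o$mask, o$targets, o$drugs),
    w_bn = as.numeric(o$w_bn), b_bn = as.numeric(o$b_bn),
    mu_bn = as.numeric(o$mu_bn), var_bn = as.numeric(o$var_bn),
    eps = as.numeric(o$eps)
  ), class = "drug_layer_params")
  sig <- structure(list(
    nodes = o$nodes,
    src_idx = match(scaffold$edges$source, o$nodes),
    tgt_idx = match(scaffold$edges$target, o$nodes),
    signs = as.numeric(o$signs),
    raw_weights = as.numeric(o$raw_weights), bias = as.numeric(o$bias),
    output_idx = match(o$tf_names, o$nodes),
    input_idx = match(o$input_nodes, o$nodes),
    leak = as.numeric(o$leak), max_iters = as.integer(o$max_iters),
    tol = as.numeric(o$tol)
  ), class = "signaling_params")
  structure(list(
    drug = drug, sig = sig,
    S = as_named(o$S, o$drugs, o$drugs), scaffold = scaffold,
    tf_names = o$tf_names, diagnostics = o$diagnostics, seed = o$seed
  ), class = "model_bundle")
}
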