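#' Bounded activation for signaling nodes
#'
#' Piecewise Michaelis-Menten-like activation with a small leak for negative
#' inputs: `f(x) = leak * x` for `x < 0`, `f(x) = x - x^2 / 4` on `[0, 2]`,
#' and `f(x) = 1` for `x > 2`. It satisfies `f(0) = 0`, saturates at 1, and
#' has Lipschitz constant at most 1, which keeps the recurrent iteration
#' well behaved.
#'
#' @param x Numeric input.
#' @param leak Slope for negative inputs (default 0.01).
#' @return `f(x)`, same shape as `x`.
#' @export
activation <- function(x, leak = 0.01) {
  # arithmetic clamps (no pmin/pmax) keep this allocation-light in the
  # fixed-point loops: pos = max(x, 0), z = min(pos, 2)
  pos <- (x + abs(x)) * 0.5
  d <- 2 - pos
  z <- 2 - (d + abs(d)) * 0.5
  leak * (x - abs(x)) * 0.5 + z - z * z * 0.25
}

# derivative of the activation; sub-derivative 1 taken at x = 0, 0 at x = 2
activation_grad <- function(x, leak = 0.01) {
  neg <- x < 0
  pos <- (x + abs(x)) * 0.5
  d <- 2 - pos
  z <- 2 - (d + abs(d)) * 0.5
  neg * leak + (!neg) * (1 - z * 0.5)
}

#' Construct signaling parameters on a scaffold
#'
#' One trainable weight per scaffold edge, sign-constrained to the edge's
#' prior sign via `weight = sign * softplus(raw)` (unsigned edges, sign 0,
#' are left unconstrained), plus one bias per node.
#'
#' @param scaffold A `scaffold_network`.
#' @param leak Activation leak slope.
#' @param max_iters Maximum steady-state iterations (default 120).
#' @param tol Convergence tolerance on the max-abs iterate change.
#' @param init_weight Initial softplus-scale weight magnitude.
#' @param seed Optional seed for the random initialization.
#' @return Object of class `signaling_params`.
#' @export
signaling_params <- function(scaffold, leak = 0.01, max_iters = 120,
                             tol = 1e-6, init_weight = 0.5, seed = NULL) {
  stopifnot(inherits(scaffold, "scaffold_network"), max_iters >= 1, tol > 0)
  if (!is.null(seed)) set.seed(seed)
  nodes <- scaffold$nodes
  e <- scaffold$edges
  signs <- e$sign
  n_e <- nrow(e)
  # softplus^{-1} of |w| jittered around init_weight
  w0 <- pmax(init_weight + stats::runif(n_e, -0.2, 0.2), 0.05)
  raw <- log(expm1(w0))
  structure(list(
    nodes = nodes,
    src_idx = match(e$source, nodes),
    tgt_idx = match(e$target, nodes),
    signs = signs,
    raw_weights = raw,
    bias = rep(0, length(nodes)),
    output_idx = match(scaffold$output_nodes, nodes),
    input_idx = match(scaffold$input_nodes, nodes),
    leak = leak,
    max_iters = max_iters,
    tol = tol
  ), class = "signaling_params")
}

# edge weights from raw parameters under the sign constraint
edge_weights <- function(params) {
  w <- softplus(params$raw_weights) * params$signs
  w[params$signs == 0] <- params$raw_weights[params$signs == 0]
  w
}

# dense connectivity matrix W with W[i, j] = weight of edge j -> i
weight_matrix <- function(params) {
  n <- length(params$nodes)
  W <- matrix(0, n, n, dimnames = list(params$nodes, params$nodes))
  W[cbind(params$tgt_idx, params$src_idx)] <- edge_weights(params)
  W
}

#' Embed drug-layer output into the full node space
#'
#' Places each target column of `yin` at its node position; all other node
#' columns are zero.
#'
#' @param yin Samples x targets signal matrix (named columns).
#' @param scaffold A `scaffold_network` (or `signaling_params`).
#' @return Samples x nodes matrix.
#' @export
embed_input <- function(yin, scaffold) {
  nodes <- scaffold$nodes
  pos <- match(colnames(yin), nodes)
  if (anyNA(pos)) {
    stop_fmt("target(s) not in scaffold: %s",
             paste(colnames(yin)[is.na(pos)], collapse = ", "))
  }
  out <- matrix(0, nrow(yin), length(nodes),
                dimnames = list(rownames(yin), nodes))
  out[, pos] <- yin
  out
}

#' Iterate the recurrent signaling network to steady state
#'
#' Starting from zero activity, iterates
#' `a_{k+1} = f(W a_k + bias + input)` per sample until the max-abs change
#' drops below `tol` or `max_iters` is reached. The TF readout restricts the
#' node activities to the scaffold's output nodes. Samples are decoupled:
#' the steady state does not depend on batch composition.
#'
#' @param params `signaling_params`.
#' @param input Samples x nodes embedded input ([embed_input()]).
#' @return List of class `steady_state`: `node_activity` (samples x nodes),
#'   `tf_activity` (samples x TFs), `converged` (per sample), `residual`,
#'   `n_iters`, and `pre_activation` (samples x nodes, for gradients).
#' @export
steady_state <- function(params, input) {
  W <- weight_matrix(params)
  dimnames(W) <- NULL # avoid attribute copying inside the iteration
  tW <- t(W)
  n <- length(params$nodes)
  rn <- rownames(input)
  a <- matrix(0, nrow(input), n)
  off <- sweep(unname(input), 2, params$bias, "+")
  it <- 0
  u <- off
  a_prev <- a
  while (it < params$max_iters) {
    it <- it + 1
    u <- a %*% tW + off
    a_new <- activation(u, params$leak)
    delta <- max(abs(a_new - a))
    a_prev <- a
    a <- a_new
    if (delta < params$tol) break
  }
  resid <- apply(abs(a - a_prev), 1, max)
  converged <- resid < params$tol
  if (!all(converged)) {
    warn_fmt("steady_state: %d sample(s) not converged after %d iterations",
             sum(!converged), params$max_iters)
  }
  tf <- a[, params$output_idx, drop = FALSE]
  colnames(tf) <- params$nodes[params$output_idx]
  rownames(tf) <- rownames(input)
  dimnames(a) <- list(rownames(input), params$nodes)
  structure(list(node_activity = a, tf_activity = tf, converged = converged,
                 residual = resid, n_iters = it, pre_activation = u),
            class = "steady_state")
}

# spectral-radius surrogate: power-iteration estimate of |lambda_max| of the
# mean steady-state Jacobian W * diag(mean f'(u)). Signed networks often have
# a complex dominant pair, where plain power iteration oscillates, so the
# radius is the geometric mean of the post-burn-in growth factors; the final
# left/right iterates feed the gradient surrogate.
spectral_surrogate <- function(W, fprime_mean, n_iter = 60, seed_vec = NULL) {
  n <- nrow(W)
  J <- W * rep(fprime_mean, each = n) # scales column j by fprime_mean[j]
  v0 <- seed_vec %||% (1 + seq_len(n) / n)
  v <- v0 / sqrt(sum(v0^2))
  u <- v
  burn <- n_iter %/% 2
  logs <- numeric(0)
  for (k in seq_len(n_iter)) {
    v_new <- J %*% v
    nv <- sqrt(sum(v_new^2))
    if (nv < 1e-14) return(list(rho = 0, u = u, v = v))
    v <- as.vector(v_new) / nv
    if (k > burn) logs <- c(logs, log(nv))
    u_new <- t(J) %*% u
    nu <- sqrt(sum(u_new^2))
    if (nu < 1e-14) return(list(rho = 0, u = u, v = v))
    u <- as.vector(u_new) / nu
  }
  list(rho = exp(mean(logs)), u = u, v = v)
}

#' Regularization penalties for a model
#'
#' Signaling part: L2 on the edge weights plus a spectral-radius surrogate (a
#' power-iteration estimate of the dominant eigenvalue magnitude of the
#' steady-state Jacobian, penalized quadratically above `rho_max`), which
#' keeps the recurrent iteration contractive. Drug-layer part: L2 pulling
#' `W_drug` toward the identity (off-diagonal mixing is how off-target
#' interactions arise, so it must be earned from data) and a small L2 on the
#' prior interaction weights.
#'
#' @param sig `signaling_params`.
#' @param drug `drug_layer_params`.
#' @param state Optional `steady_state` for the spectral term; when missing
#'   the Jacobian is evaluated at zero activity.
#' @param lambda List of coefficients: `l2_sig`, `spectral`, `l2_wdrug`,
#'   `l2_a`, and threshold `rho_max` (default 0.95).
#' @return List with `total` and the individual penalty values.
#' @export
regularization_terms <- function(sig, drug, state = NULL,
                                 lambda = list(l2_sig = 1e-4, spectral = 1e-2,
                                               l2_wdrug = 1e-5, l2_a = 1e-5,
                                               rho_max = 0.95)) {
  w <- edge_weights(sig)
  l2_sig <- lambda$l2_sig * sum(w^2)
  W <- weight_matrix(sig)
  fp <- if (is.null(state)) {
    rep(activation_grad(0, sig$leak), length(sig$nodes))
  } else {
    colMeans(activation_grad(state$pre_activation, sig$leak))
  }
  sp <- spectral_surrogate(W, fp)
  spec_pen <- lambda$spectral * max(0, sp$rho - lambda$rho_max)^2
  d <- length(drug$drugs)
  l2_wd <- lambda$l2_wdrug * sum((drug$W_drug - diag(1, d, d))^2)
  l2_a <- lambda$l2_a * sum((drug$A * drug$mask)^2)
  list(total = l2_sig + spec_pen + l2_wd + l2_a,
       l2_signaling = l2_sig, spectral = spec_pen, rho = sp$rho,
       l2_wdrug = l2_wd, l2_a = l2_a)
}
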