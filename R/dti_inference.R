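#' Logarithmic threshold grid for interaction-score binarization
#'
#' By default 50 values logarithmically spaced from `10^-3.5` to `10^3.5`
#' inclusive — the grid swept when masking interactions by attribution
#' score.
#'
#' @param n Number of grid points (>= 2).
#' @param lo_exp,hi_exp Decadic exponents of the endpoints.
#' @return Ascending numeric vector of length `n`.
#' @export
threshold_grid <- function(n = 50, lo_exp = -3.5, hi_exp = 3.5) {
  stopifnot(n >= 2)
  if (lo_exp >= hi_exp) stop_fmt("lo_exp must be < hi_exp")
  10^seq(lo_exp, hi_exp, length.out = n)
}

#' Integrated-gradients attribution of an arbitrary map
#'
#' Midpoint-rule path integral of the numerical gradient along the straight
#' line from `baseline` to `x`: the average Jacobian over `n_steps`
#' interpolation points, each gradient obtained by central finite
#' differences. For a linear map this equals the Jacobian exactly for any
#' number of steps.
#'
#' @param f Function taking a row vector (length `length(x)`) and returning
#'   a numeric output vector.
#' @param x Input point.
#' @param baseline Integration baseline (default zero vector).
#' @param n_steps Number of path points.
#' @param h Finite-difference step.
#' @return Matrix `length(x)` x `length(f(x))` of averaged gradients.
#' @export
ig_attribution <- function(f, x, baseline = NULL, n_steps = 10, h = 1e-4) {
  baseline <- baseline %||% numeric(length(x))
  acc <- NULL
  for (s in seq_len(n_steps)) {
    xs <- baseline + (s - 0.5) / n_steps * (x - baseline)
    gs <- vapply(seq_along(x), function(i) {
      xp <- xs; xp[i] <- xp[i] + h
      xm <- xs; xm[i] <- xm[i] - h
      (f(xp) - f(xm)) / (2 * h)
    }, f(xs))
    g <- if (is.matrix(gs)) t(gs) else matrix(gs, nrow = length(x))
    acc <- if (is.null(acc)) g else acc + g
  }
  acc / n_steps
}

#' Integrated-gradients drug-target interaction scores
#'
#' Attributes each target's drug-layer output to each drug input by
#' integrated gradients with a zero baseline, averaged over the samples in
#' which the drug is active. For the linear drug layer this equals
#' [closed_form_scores()] — the cheap linear-algebra route — up to numeric
#' quadrature error; both are exposed so either can validate the other.
#' Drugs active in no sample fall back to the closed-form row and are
#' flagged via the `fallback_drugs` attribute.
#'
#' @param bundle `model_bundle`.
#' @param X Samples x drugs dose matrix.
#' @param n_steps Integration steps (default 10; a warning is issued below
#'   that, where quadrature error for nonlinear layers becomes material).
#' @return Drugs x targets score matrix.
#' @export
ig_scores <- function(bundle, X, n_steps = 10) {
  stopifnot(n_steps >= 1)
  if (n_steps < 10) warn_fmt("n_steps below 10 is not recommended")
  drug <- bundle$drug
  S <- bundle$S
  f <- function(xrow) {
    Xr <- matrix(xrow, 1, dimnames = list("s", drug$drugs))
    as.vector(drug_layer_forward(Xr, drug, S, FALSE))
  }
  d <- length(drug$drugs)
  tg <- length(drug$targets)
  scores <- matrix(0, d, tg, dimnames = list(drug$drugs, drug$targets))
  counts <- integer(d)
  cf <- closed_form_scores(drug, S)
  active <- X != 0
  for (n in seq_len(nrow(X))) {
    act <- which(active[n, ])
    if (length(act) == 0) next
    att <- ig_attribution(f, X[n, ], n_steps = n_steps)
    scores[act, ] <- scores[act, , drop = FALSE] + att[act, , drop = FALSE]
    counts[act] <- counts[act] + 1L
  }
  fallback <- counts == 0
  scores[counts > 0, ] <- scores[counts > 0, , drop = FALSE] / counts[counts > 0]
  if (any(fallback)) {
    scores[fallback, ] <- cf[fallback, , drop = FALSE]
  }
  attr(scores, "fallback_drugs") <- drug$drugs[fallback]
  scores
}

#' Masked ensemble predictions over the threshold grid
#'
#' For each threshold `t`, drug-target interactions with `|score| <= t` are
#' removed from the drug layer's effective map for the drugs active in each
#' sample (contributions of inactive drugs — the batch-normalization offsets
#' — are untouched), and the signaling network is re-run to steady state.
#'
#' @param bundle `model_bundle`.
#' @param X Samples x drugs dose matrix.
#' @param scores Drugs x targets score matrix for this model.
#' @param grid Ascending threshold vector ([threshold_grid()]).
#' @return Array `[thresholds, samples, TFs]`.
#' @export
masked_predictions <- function(bundle, X, scores, grid = threshold_grid()) {
  drug <- bundle$drug
  stopifnot(identical(rownames(scores), drug$drugs),
            identical(colnames(scores), drug$targets))
  Z <- bn_transform(X, drug, FALSE)$Z
  P <- S_eff <- bundle$S * drug$W_drug
  AM <- drug$A * drug$mask
  M <- P %*% t(AM)                       # drugs x targets effective map
  act <- X != 0
  Z_act <- Z * act
  Z_inact <- Z * (!act)
  n_tf <- length(bundle$sig$output_idx)
  out <- array(NA_real_, c(length(grid), nrow(X), n_tf))
  base_inact <- Z_inact %*% M
  for (j in seq_along(grid)) {
    keep <- abs(scores) > grid[j]
    yin <- base_inact + Z_act %*% (M * keep)
    colnames(yin) <- drug$targets
    rownames(yin) <- rownames(X)
    pred <- predict_model(bundle, X, yin_override = yin)
    out[j, , ] <- pred$tf_activity
  }
  dimnames(out) <- list(NULL, rownames(X),
                        bundle$sig$nodes[bundle$sig$output_idx])
  out
}

#' Per-drug global interaction-score thresholds
#'
#' For every model and every sample in which a drug is active, the unmasked
#' reference error `err0` is the mean absolute error of the prediction
#' against the measured TF activities, and `err1(t)` the same under masking
#' at threshold `t`. The normalized error
#' `(err1(t) - err0) / (err1(t_max) - err0)` runs from 0 at the unmasked
#' reference to 1 at the maximal-masking end of the grid. `error_threshold`
#' (default 0.25) is the maximum allowable normalized error increase: the
#' member threshold snaps to the largest grid value whose masking still
#' keeps the normalized error below the allowance, so the interactions
#' whose removal first pushes the error past it sit above the threshold and
#' are the ones called by [binarize_dti()]. Duplicate instances of
#' a drug are averaged, then member thresholds are averaged over models into
#' the per-drug global threshold. Flat error curves yield the grid maximum,
#' flagged uninformative.
#'
#' @param Y Samples x TFs measured activities.
#' @param Y_hat Array `[models, samples, TFs]` of unmasked predictions.
#' @param Y_masked Array `[models, thresholds, samples, TFs]`.
#' @param X Samples x drugs dose matrix (defines drug instances).
#' @param grid Threshold grid used to build `Y_masked`.
#' @param error_threshold Normalized-error crossing level in (0, 1).
#' @return List of class `global_thresholds`: `global` (named per-drug
#'   vector), `members` (drugs x models matrix), `uninformative` (logical
#'   per-drug vector).
#' @export
per_drug_threshold <- function(Y, Y_hat, Y_masked, X, grid = threshold_grid(),
                               error_threshold = 0.25) {
  stopifnot(error_threshold > 0, error_threshold < 1)
  n_models <- dim(Y_hat)[1]
  drugs <- colnames(X)
  members <- matrix(NA_real_, length(drugs), n_models,
                    dimnames = list(drugs, NULL))
  uninfo <- rep(FALSE, length(drugs))
  names(uninfo) <- drugs
  n_grid <- length(grid)
  for (m in seq_len(n_models)) {
    for (k in seq_along(drugs)) {
      inst <- which(X[, k] != 0)
      if (length(inst) == 0) next
      th_inst <- numeric(length(inst))
      flat <- logical(length(inst))
      for (q in seq_along(inst)) {
        nidx <- inst[q]
        err0 <- mean(abs(Y_hat[m, nidx, ] - Y[nidx, ]))
        err1 <- vapply(seq_len(n_grid), function(j) {
          mean(abs(Y_masked[m, j, nidx, ] - Y[nidx, ]))
        }, numeric(1))
        span <- err1[n_grid] - err0
        if (abs(span) < 1e-12) {
          th_inst[q] <- grid[n_grid]
          flat[q] <- TRUE
        } else {
          norm_err <- (err1 - err0) / span
          hit <- which(norm_err >= error_threshold)
          if (length(hit) == 0) {
            th_inst[q] <- grid[n_grid]
            flat[q] <- TRUE
          } else {
            # the largest threshold whose masking stays within the allowable
            # error increase; interactions above it are the consequential ones
            th_inst[q] <- grid[max(hit[1] - 1, 1)]
          }
        }
      }
      members[k, m] <- mean(th_inst)
      if (all(flat)) uninfo[k] <- TRUE
    }
  }
  global <- rowMeans(members)
  never_active <- is.na(global)
  if (any(never_active)) {
    # drugs absent from every sample carry no masking signal; default to the
    # most conservative (maximal) threshold and flag them
    global[never_active] <- grid[n_grid]
    uninfo[never_active] <- TRUE
  }
  structure(list(global = global, members = members,
                 uninformative = uninfo, grid = grid,
                 error_threshold = error_threshold),
            class = "global_thresholds")
}

#' Binarize drug-target interactions and build the ensemble consensus
#'
#' An interaction `(drug, target)` is called in a model when its absolute
#' attribution score exceeds the drug's global threshold; the consensus
#' frequency is the fraction of models calling it.
#'
#' @param score_list List (one per model) of drugs x targets score matrices.
#' @param thresholds `global_thresholds` (or named per-drug vector).
#' @return List with `calls` (list of binary matrices per model) and
#'   `frequency` (drugs x targets consensus matrix).
#' @export
binarize_dti <- function(score_list, thresholds) {
  thr <- if (inherits(thresholds, "global_thresholds")) thresholds$global else thresholds
  calls <- lapply(score_list, function(sc) {
    th <- thr[rownames(sc)]
    if (anyNA(th)) stop_fmt("missing threshold for drug(s): %s",
                            paste(rownames(sc)[is.na(th)], collapse = ", "))
    (abs(sc) > th) * 1
  })
  freq <- Reduce(`+`, calls) / length(calls)
  list(calls = calls, frequency = freq)
}

#' Full DTI inference across an ensemble
#'
#' Convenience wrapper running score extraction (closed form by default, the
#' exact route for the linear drug layer), masked predictions over the
#' grid, per-drug threshold selection and consensus binarization.
#'
#' @param bundles `model_ensemble`.
#' @param X,Y Dose and measured TF-activity matrices.
#' @param grid Threshold grid.
#' @param error_threshold Crossing level for [per_drug_threshold()].
#' @param method `"closed_form"` or `"ig"`.
#' @param n_steps Integration steps when `method = "ig"`.
#' @return List: `scores` (per model), `Y_hat`, `Y_masked`, `thresholds`,
#'   `calls`, `frequency`.
#' @export
infer_dti <- function(bundles, X, Y, grid = threshold_grid(),
                      error_threshold = 0.25,
                      method = c("closed_form", "ig"), n_steps = 10) {
  method <- match.arg(method)
  n_models <- length(bundles)
  scores <- lapply(bundles, function(b) {
    if (method == "closed_form") closed_form_scores(b$drug, b$S)
    else ig_scores(b, X, n_steps)
  })
  n_tf <- length(bundles[[1]]$sig$output_idx)
  Y_hat <- array(NA_real_, c(n_models, nrow(X), n_tf))
  Y_masked <- array(NA_real_, c(n_models, length(grid), nrow(X), n_tf))
  for (m in seq_len(n_models)) {
    Y_hat[m, , ] <- predict_model(bundles[[m]], X)$tf_activity
    Y_masked[m, , , ] <- masked_predictions(bundles[[m]], X, scores[[m]], grid)
  }
  thr <- per_drug_threshold(Y, Y_hat, Y_masked, X, grid, error_threshold)
  bin <- binarize_dti(scores, thr)
  list(scores = scores, Y_hat = Y_hat, Y_masked = Y_masked,
       thresholds = thr, calls = bin$calls, frequency = bin$frequency)
}
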