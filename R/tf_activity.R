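#' Regulon enrichment scores for transcription-factor activity
#'
#' Scores each TF in each sample by a rank-normal weighted enrichment of its
#' regulon: within a sample, gene expression values are rank-transformed to
#' standard-normal scores, and the TF's normalized enrichment score (NES) is
#' the confidence-weighted, mode-signed sum of its targets' scores divided by
#' the root of the summed squared weights. Under a permuted-gene null the NES
#' is approximately standard normal, the contract the downstream sigmoid
#' squashing relies on. The enrichment is rank-based, hence invariant to any
#' within-sample monotone transform of the expression values.
#'
#' @param expr Numeric matrix, genes (symbols) in rows, samples in columns.
#' @param regulons List of regulons; each element is a list with fields `tf`
#'   (name) and `targets` (data.frame with columns `gene`, `mode` in
#'   \[-1, 1\], `weight` in \[0, 1\]).
#' @param min_targets TFs with fewer usable (measured) targets are skipped
#'   with a message (default 5).
#' @return Numeric matrix samples x TFs of NES values; skipped TFs are
#'   reported via the `skipped` attribute.
#' @export
enrichment_scores <- function(expr, regulons, min_targets = 5) {
  check_named_matrix(expr, "expression matrix")
  genes <- rownames(expr)
  n_genes <- nrow(expr)
  # per-sample rank -> standard normal scores
  z <- apply(expr, 2, function(x) {
    stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
  })
  rownames(z) <- genes
  tf_names <- vapply(regulons, function(r) r$tf, character(1))
  nes <- matrix(NA_real_, ncol(expr), length(regulons),
                dimnames = list(colnames(expr), tf_names))
  skipped <- character(0)
  for (k in seq_along(regulons)) {
    tg <- regulons[[k]]$targets
    tg <- tg[tg$gene %in% genes, , drop = FALSE]
    if (nrow(tg) < min_targets) {
      skipped <- c(skipped, tf_names[k])
      next
    }
    w <- tg$weight * tg$mode
    denom <- sqrt(sum(tg$weight^2))
    nes[, k] <- as.vector(t(z[tg$gene, , drop = FALSE]) %*% w) / denom
  }
  if (length(skipped) > 0) {
    message(sprintf("skipped %d TF(s) with < %d usable targets: %s",
                    length(skipped), min_targets,
                    paste(skipped, collapse = ", ")))
    nes <- nes[, !(colnames(nes) %in% skipped), drop = FALSE]
  }
  attr(nes, "skipped") <- skipped
  nes
}

#' Squash enrichment scores to the open unit interval
#'
#' Elementwise logistic transform `1 / (1 + exp(-x))`, mapping the
#' normal-like NES scale onto (0, 1) as the recurrent model's output range
#' requires. Strictly monotone; 0 maps to 0.5.
#'
#' @param nes Numeric matrix (or vector) of finite enrichment scores.
#' @return Object of the same shape with values in (0, 1).
#' @export
squash <- function(nes) {
  if (any(!is.finite(nes))) stop_fmt("squash requires finite inputs")
  sigmoid(nes)
}

#' Aggregate replicate TF-activity profiles by condition
#'
#' Averages the replicates of each condition; the plain aggregation used
#' when the replicate-correlation filter is not applied.
#'
#' @param tf_activity Samples x TFs matrix.
#' @param replicate_map data.frame (`sample_id`, `condition_id`) or named
#'   vector mapping samples to conditions.
#' @return Conditions x TFs matrix (condition order of first appearance).
#' @export
aggregate_replicates <- function(tf_activity, replicate_map) {
  if (is.data.frame(replicate_map)) {
    cmap <- stats::setNames(as.character(replicate_map$condition_id),
                            as.character(replicate_map$sample_id))
  } else cmap <- replicate_map
  cond <- cmap[rownames(tf_activity)]
  conds <- unique(cond)
  agg <- t(vapply(conds, function(cc) {
    colMeans(tf_activity[cond == cc, , drop = FALSE])
  }, numeric(ncol(tf_activity))))
  dimnames(agg) <- list(conds, colnames(tf_activity))
  agg
}

#' Filter conditions by replicate correlation against a null
#'
#' For every condition with two or more replicates the statistic is the mean
#' pairwise Spearman correlation of the replicates' TF-activity profiles. The
#' null distribution is built from correlations of randomly drawn profile
#' pairs belonging to different conditions; a condition is kept when its
#' statistic exceeds the `1 - alpha` null quantile. Kept conditions are
#' aggregated by averaging replicates. Single-replicate conditions cannot be
#' validated and pass the filter flagged as `unvalidated`.
#'
#' @param tf_activity Samples x TFs matrix of (squashed) activities.
#' @param replicate_map Named character vector or data.frame (`sample_id`,
#'   `condition_id`) mapping every row of `tf_activity` to a condition.
#' @param n_null Number of null cross-condition pairs (>= 1000).
#' @param alpha Null-quantile level (default 0.05).
#' @param seed Seed for the null draws; fixing it fixes the kept set.
#' @param method Correlation method for the replicate statistic
#'   (default `"spearman"`).
#' @return List with `kept` (condition ids), `activity` (condition x TF
#'   aggregated matrix over kept conditions), and `report` (per-condition
#'   data.frame: statistic, null quantile, kept flag, n_replicates,
#'   unvalidated flag).
#' @export
filter_replicates <- function(tf_activity, replicate_map, n_null = 1000,
                              alpha = 0.05, seed = 1, method = "spearman") {
  if (n_null < 1000) stop_fmt("n_null must be >= 1000")
  if (is.data.frame(replicate_map)) {
    cmap <- stats::setNames(as.character(replicate_map$condition_id),
                            as.character(replicate_map$sample_id))
  } else {
    cmap <- replicate_map
  }
  samples <- rownames(tf_activity)
  if (!all(samples %in% names(cmap))) stop_fmt("every sample must be mapped to a condition")
  cond <- cmap[samples]
  conds <- unique(cond)

  # null: correlations between profiles from distinct conditions
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    expr
  }
  null_cors <- withr_seed({
    n <- nrow(tf_activity)
    out <- numeric(n_null)
    for (b in seq_len(n_null)) {
      repeat {
        ij <- sample.int(n, 2)
        if (cond[ij[1]] != cond[ij[2]]) break
      }
      out[b] <- stats::cor(tf_activity[ij[1], ], tf_activity[ij[2], ],
                           method = method)
    }
    out
  })
  cutoff <- stats::quantile(null_cors, 1 - alpha, names = FALSE)

  rows <- lapply(conds, function(cc) {
    idx <- which(cond == cc)
    if (length(idx) < 2) {
      data.frame(condition = cc, statistic = NA_real_, null_quantile = cutoff,
                 kept = TRUE, n_replicates = length(idx), unvalidated = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      cm <- stats::cor(t(tf_activity[idx, , drop = FALSE]), method = method)
      stat <- mean(cm[upper.tri(cm)])
      data.frame(condition = cc, statistic = stat, null_quantile = cutoff,
                 kept = stat > cutoff, n_replicates = length(idx),
                 unvalidated = FALSE, stringsAsFactors = FALSE)
    }
  })
  report <- do.call(rbind, rows)
  kept <- report$condition[report$kept]
  agg <- t(vapply(kept, function(cc) {
    colMeans(tf_activity[cond == cc, , drop = FALSE])
  }, numeric(ncol(tf_activity))))
  rownames(agg) <- kept
  colnames(agg) <- colnames(tf_activity)
  list(kept = kept, activity = agg, report = report)
}
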