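#' Consensus inferred targets of a drug
#'
#' Targets called for the drug by at least `source_freq_thresh` of the
#' ensemble's models (inclusive comparison). With `moa_off_target` set to
#' `"inhibit"` or `"activate"`, targets are additionally filtered by the
#' sign of the ensemble-mean interaction score. An empty result is an error,
#' matching the pipeline's behaviour when the frequency threshold is set too
#' high.
#'
#' @param calls List of per-model binary drugs x targets call matrices
#'   ([binarize_dti()] output `calls`).
#' @param drug Drug identifier (SMILES, a row name of the call matrices).
#' @param source_freq_thresh Minimum call frequency (default 0.6).
#' @param moa_off_target `"any"`, `"inhibit"` or `"activate"`.
#' @param score_list Per-model score matrices, required for sign filtering.
#' @return Named numeric vector of call frequencies for the kept targets.
#' @export
consensus_targets <- function(calls, drug, source_freq_thresh = 0.6,
                              moa_off_target = c("any", "inhibit", "activate"),
                              score_list = NULL) {
  moa_off_target <- match.arg(moa_off_target)
  stopifnot(length(calls) >= 2)
  freq <- Reduce(`+`, lapply(calls, function(m) m[drug, ])) / length(calls)
  kept <- freq[freq >= source_freq_thresh]
  if (moa_off_target != "any") {
    if (is.null(score_list)) stop_fmt("score_list required for sign filtering")
    mean_score <- Reduce(`+`, lapply(score_list, function(m) m[drug, ])) /
      length(score_list)
    sgn <- mean_score[names(kept)]
    kept <- if (moa_off_target == "inhibit") kept[sgn < 0] else kept[sgn > 0]
  }
  if (length(kept) == 0) stop("No inferred drug`s targets kept!", call. = FALSE)
  kept
}

#' Per-edge ensemble activity frequencies
#'
#' An edge is active in a model, for the chosen sample, when the absolute
#' signal it carries — the steady-state activity of its source node times
#' its learned weight — exceeds `activity_eps`. The frequency is the active
#' fraction across models.
#'
#' @param bundles `model_ensemble`.
#' @param X Dose matrix.
#' @param sample Row name (or index) of the sample of interest.
#' @param activity_eps Signal-magnitude cutoff (default 1e-3).
#' @return data.frame `source`, `target`, `sign`, `frequency`, plus the
#'   ensemble-mean node activities as the `node_activity` attribute.
#' @export
edge_frequencies <- function(bundles, X, sample, activity_eps = 1e-3) {
  stopifnot(length(bundles) >= 1)
  if (is.character(sample) && !(sample %in% rownames(X))) {
    stop_fmt("sample '%s' not found in X", sample)
  }
  Xs <- X[sample, , drop = FALSE]
  sc <- bundles[[1]]$scaffold
  n_e <- nrow(sc$edges)
  cnt <- numeric(n_e)
  act_sum <- numeric(length(sc$nodes))
  for (b in bundles) {
    pred <- predict_model(b, Xs)
    a <- pred$node_activity[1, ]
    w <- edge_weights(b$sig)
    flux <- abs(a[b$sig$src_idx] * w)
    cnt <- cnt + (flux > activity_eps)
    act_sum <- act_sum + a
  }
  out <- data.frame(source = sc$edges$source, target = sc$edges$target,
                    sign = sc$edges$sign, frequency = cnt / length(bundles),
                    stringsAsFactors = FALSE)
  attr(out, "node_activity") <- stats::setNames(act_sum / length(bundles),
                                                sc$nodes)
  out
}

# best connecting path: maximizes the summed edge frequency over simple
# paths (depth-first search over the scaffold), ties broken by fewer edges,
# then by lexicographic node sequence. `max_expansions` bounds the search on
# large graphs; the fixtures and trimmed scaffolds this runs on are small.
best_path <- function(edges_df, freq, from, to, max_hops = 12,
                      max_expansions = 2e5) {
  nodes <- unique(c(edges_df$source, edges_df$target, from, to))
  adj <- split(seq_len(nrow(edges_df)), edges_df$source)
  best <- NULL
  best_key <- c(-Inf, Inf)  # (sum, hops)
  best_pstr <- ""
  expansions <- 0L
  visit <- function(node, path_edges, path_sum, on_path) {
    if (expansions > max_expansions) return(invisible())
    expansions <<- expansions + 1L
    if (node == to) {
      hops <- length(path_edges)
      pstr <- paste(c(from, edges_df$target[path_edges]), collapse = "\r")
      better <- path_sum > best_key[1] + 1e-12 ||
        (abs(path_sum - best_key[1]) <= 1e-12 &&
           (hops < best_key[2] ||
              (hops == best_key[2] && pstr < best_pstr)))
      if (better) {
        best <<- path_edges
        best_key <<- c(path_sum, hops)
        best_pstr <<- pstr
      }
      return(invisible())
    }
    if (length(path_edges) >= max_hops) return(invisible())
    for (e in adj[[node]] %||% integer(0)) {
      nxt <- edges_df$target[e]
      if (nxt %in% on_path) next
      visit(nxt, c(path_edges, e), path_sum + freq[e], c(on_path, nxt))
    }
    invisible()
  }
  visit(from, integer(0), 0, from)
  if (is.null(best) && from != to) return(NULL)
  list(edges = best %||% integer(0), sum = best_key[1])
}

#' Build the consensus mechanism-of-action subnetwork
#'
#' Edges with ensemble frequency at least `edge_thresh_init` (and above
#' zero) form the initial filtered network. Every consensus drug target that
#' cannot reach the TF there is reconnected by the simple path over the full
#' scaffold with the highest possible sum of edge frequencies; ties prefer
#' fewer edges, then the lexicographically smallest node sequence. Added
#' edges are flagged. The
#' shortest-path variant contains only the union of these optimal
#' target-to-TF paths (computed for every kept target). Node roles are
#' `source` (drug targets), `target` (the TF), `mid_node` (everything
#' else).
#'
#' @param scaffold `scaffold_network`.
#' @param targets Named frequency vector from [consensus_targets()].
#' @param tf TF node identifier.
#' @param edge_freqs data.frame from [edge_frequencies()].
#' @param edge_thresh_init Initial edge-frequency filter (default 0.5).
#' @return List of class `moa_subnetwork` with elements `full` and `short`,
#'   each a list of `edges` (`source`, `target`, `sign`, `frequency`,
#'   `added_by_path`) and `nodes` (`node`, `gene`, `role`, `activity`);
#'   plus `dropped_targets`.
#' @export
build_subnetwork <- function(scaffold, targets, tf, edge_freqs,
                             edge_thresh_init = 0.5) {
  stopifnot(tf %in% scaffold$nodes)
  ef <- edge_freqs
  kept <- ef$frequency >= edge_thresh_init & ef$frequency > 0
  node_act <- attr(edge_freqs, "node_activity")

  reach_tf <- function(edge_idx, from) {
    if (from == tf) return(TRUE)
    if (length(edge_idx) == 0) return(FALSE)
    g <- igraph::graph_from_data_frame(
      ef[edge_idx, c("source", "target")], directed = TRUE,
      vertices = data.frame(name = unique(c(ef$source[edge_idx],
                                            ef$target[edge_idx], from, tf))))
    tf %in% names(igraph::subcomponent(g, from, mode = "out"))
  }

  added <- integer(0)
  short_edges <- integer(0)
  dropped <- character(0)
  kept_targets <- character(0)
  for (tg in names(targets)) {
    if (!(tg %in% scaffold$nodes)) {
      warn_fmt("target %s absent from the scaffold; dropped", tg)
      dropped <- c(dropped, tg)
      next
    }
    bp <- best_path(ef, ef$frequency, tg, tf)
    if (is.null(bp)) {
      warn_fmt("no path from target %s to TF %s; target dropped", tg, tf)
      dropped <- c(dropped, tg)
      next
    }
    kept_targets <- c(kept_targets, tg)
    short_edges <- union(short_edges, bp$edges)
    if (!reach_tf(which(kept), tg)) {
      added <- union(added, setdiff(bp$edges, which(kept)))
    }
  }
  if (length(kept_targets) == 0) {
    stop("No inferred drug`s targets kept!", call. = FALSE)
  }

  make_net <- function(edge_idx, added_idx) {
    e <- ef[edge_idx, c("source", "target", "sign", "frequency"), drop = FALSE]
    e$added_by_path <- edge_idx %in% added_idx
    nodes <- unique(c(e$source, e$target, kept_targets, tf))
    role <- ifelse(nodes %in% kept_targets, "source",
                   ifelse(nodes == tf, "target", "mid_node"))
    # the TF of interest takes the target role even if it is also a drug target
    role[nodes == tf] <- "target"
    gene <- if (!is.null(scaffold$annotation)) {
      g <- scaffold$annotation$gene[match(nodes, scaffold$annotation$node)]
      ifelse(is.na(g), nodes, g)
    } else nodes
    nd <- data.frame(node = nodes, gene = gene, role = role,
                     activity = if (!is.null(node_act)) node_act[nodes] else NA_real_,
                     stringsAsFactors = FALSE)
    rownames(nd) <- NULL
    rownames(e) <- NULL
    list(edges = e, nodes = nd)
  }
  full_idx <- union(which(kept), added)
  out <- list(full = make_net(full_idx, added),
              short = make_net(short_edges, integer(0)),
              dropped_targets = dropped,
              targets = targets[kept_targets], tf = tf)
  class(out) <- "moa_subnetwork"
  out
}

#' Drug-target interaction sign report for a signaling node
#'
#' Reports the ensemble-mean steady-state activity of the node in the chosen
#' sample, the ensemble-mean attribution score of the drug on the node, and
#' the inferred interaction sign (the score mean's sign; zero means the
#' ensemble is ambiguous and is flagged).
#'
#' @param bundles `model_ensemble`.
#' @param X Dose matrix.
#' @param sample Sample identifier (row of `X`).
#' @param drug Drug identifier (SMILES).
#' @param node Scaffold node identifier.
#' @return List: `activity`, `score`, `sign`, `flagged` (TRUE when the node
#'   is not a modelled target or the ensemble scores cancel).
#' @export
sign_report <- function(bundles, X, sample, drug, node) {
  b1 <- bundles[[1]]
  stopifnot(node %in% b1$scaffold$nodes)
  acts <- scs <- numeric(length(bundles))
  is_target <- node %in% b1$drug$targets
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    pred <- predict_model(b, X[sample, , drop = FALSE])
    acts[i] <- pred$node_activity[1, node]
    scs[i] <- if (is_target) closed_form_scores(b$drug, b$S)[drug, node] else 0
  }
  mean_score <- mean(scs)
  sgn <- sign(mean_score)
  flagged <- !is_target || sgn == 0
  if (!is_target) warn_fmt("node %s is not in the modelled target space; score 0", node)
  list(activity = mean(acts), score = mean_score, sign = sgn,
       flagged = flagged)
}

#' Write MoA subnetwork CSV exports
#'
#' Two-file export per variant, importable by Cytoscape's table reader:
#' `<prefix>_<drug_name>_<tf_gene>_moa_model_ensembleFiltered.csv` (full
#' network), `..._moa_short_model_ensembled.csv` (shortest-path variant)
#' and `..._moa_nodes.csv` (node roles and activities).
#'
#' @param moa `moa_subnetwork`.
#' @param res_dir Output directory.
#' @param prefix,drug_name,tf_gene Naming components.
#' @return Named list of written paths.
#' @export
write_moa_network <- function(moa, res_dir, prefix, drug_name, tf_gene) {
  dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)
  base <- sprintf("%s_%s_%s", prefix, drug_name, tf_gene)
  paths <- list(
    full = file.path(res_dir, paste0(base, "_moa_model_ensembleFiltered.csv")),
    short = file.path(res_dir, paste0(base, "_moa_short_model_ensembled.csv")),
    nodes = file.path(res_dir, paste0(base, "_moa_nodes.csv"))
  )
  utils::write.csv(moa$full$edges, paths$full, row.names = FALSE, quote = FALSE)
  utils::write.csv(moa$short$edges, paths$short, row.names = FALSE, quote = FALSE)
  utils::write.csv(moa$full$nodes, paths$nodes, row.names = FALSE, quote = FALSE)
  invisible(paths)
}
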