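#' Parse a signed prior-knowledge signaling network
#'
#' Reads a PKN stored as TSV (or an equivalent data.frame) with the columns
#' `source`, `target`, `direction`, `stimulation`, `inhibition`, `sources`
#' (provenance, `;`-separated) and optionally `references`. Undirected rows
#' (`direction == 0`) are dropped: the recurrent model requires directed,
#' signed edges. Rows flagged both stimulating and inhibiting are resolved
#' conservatively to inhibition and flagged; rows with neither flag are kept
#' with sign 0 and flagged. Self-loops are retained.
#'
#' @param pkn Path to a TSV file or a data.frame with the columns above.
#' @param allowed_sources Character vector of accepted provenance labels; an
#'   interaction is kept when its provenance intersects this set. `NULL` or
#'   empty keeps everything.
#' @return A data.frame of interactions with columns `source`, `target`,
#'   `sign` (+1, -1 or 0), `stimulation`, `inhibition`, `provenance`, and a
#'   logical `flagged` column marking resolved conflicts / unsigned rows.
#' @export
parse_pkn <- function(pkn, allowed_sources = NULL) {
  if (is.character(pkn)) {
    pkn <- utils::read.delim(pkn, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE)
  }
  need <- c("source", "target", "direction", "stimulation", "inhibition")
  miss <- setdiff(need, colnames(pkn))
  if (length(miss) > 0) stop_fmt("PKN is missing column(s): %s",
                                 paste(miss, collapse = ", "))
  prov <- if ("sources" %in% colnames(pkn)) as.character(pkn$sources) else ""
  keep <- as.numeric(pkn$direction) == 1
  if (length(allowed_sources) > 0) {
    hit <- vapply(strsplit(prov, ";", fixed = TRUE), function(s) {
      any(trimws(s) %in% allowed_sources)
    }, logical(1))
    keep <- keep & hit
  }
  out <- data.frame(
    source = as.character(pkn$source)[keep],
    target = as.character(pkn$target)[keep],
    stimulation = as.numeric(pkn$stimulation)[keep],
    inhibition = as.numeric(pkn$inhibition)[keep],
    provenance = prov[keep],
    stringsAsFactors = FALSE
  )
  both <- out$stimulation == 1 & out$inhibition == 1
  neither <- out$stimulation == 0 & out$inhibition == 0
  if (any(both)) {
    warn_fmt("%d interaction(s) flagged both stimulating and inhibiting; resolved to inhibition",
             sum(both))
    out$stimulation[both] <- 0
  }
  out$sign <- ifelse(out$inhibition == 1, -1, ifelse(out$stimulation == 1, 1, 0))
  if (any(neither)) {
    warn_fmt("%d interaction(s) carry neither stimulation nor inhibition; kept with sign 0",
             sum(neither))
  }
  out$flagged <- both | neither
  rownames(out) <- NULL
  out
}

#' Apply a manual curation set to an interaction list
#'
#' Removals and edits are applied first, additions last; additions that
#' duplicate an existing `(source, target)` pair replace it so the result has
#' no duplicate pairs. Edits or removals that reference an absent edge are
#' warned about and skipped.
#'
#' @param edges Interaction data.frame as returned by [parse_pkn()].
#' @param curation List with optional elements `add` (interaction data.frame),
#'   `remove` (data.frame with `source`, `target`), `edit` (interaction
#'   data.frame whose rows replace the matching pair's fields).
#' @return Curated interaction data.frame.
#' @export
apply_curation <- function(edges, curation) {
  key <- function(df) paste(df$source, df$target, sep = "\r")
  norm <- function(df) {
    df$sign <- ifelse(as.numeric(df$inhibition) == 1, -1,
                      ifelse(as.numeric(df$stimulation) == 1, 1, 0))
    if (is.null(df$provenance)) df$provenance <- "curated"
    if (is.null(df$flagged)) df$flagged <- FALSE
    df[, c("source", "target", "stimulation", "inhibition",
           "provenance", "sign", "flagged")]
  }
  if (!is.null(curation$remove) && nrow(curation$remove) > 0) {
    hit <- key(edges) %in% key(curation$remove)
    absent <- !(key(curation$remove) %in% key(edges))
    if (any(absent)) warn_fmt("%d removal(s) reference absent edges; ignored", sum(absent))
    edges <- edges[!hit, , drop = FALSE]
  }
  if (!is.null(curation$edit) && nrow(curation$edit) > 0) {
    ed <- norm(curation$edit)
    pos <- match(key(ed), key(edges))
    if (anyNA(pos)) {
      warn_fmt("%d edit(s) reference absent edges; ignored", sum(is.na(pos)))
      ed <- ed[!is.na(pos), , drop = FALSE]
      pos <- pos[!is.na(pos)]
    }
    if (length(pos) > 0) edges[pos, colnames(ed)] <- ed
  }
  if (!is.null(curation$add) && nrow(curation$add) > 0) {
    ad <- norm(curation$add)
    edges <- edges[!(key(edges) %in% key(ad)), , drop = FALSE]
    edges <- rbind(edges[, colnames(ad)], ad)
  }
  edges <- edges[!duplicated(key(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Connect drug-target and TF data to the network
#'
#' Drops drugs none of whose prior targets appear in the network and TFs that
#' are not network nodes; records TFs that are themselves direct drug targets
#' and marks them (with their incident edges) to be forcefully kept by
#' [trim_network()].
#'
#' @param edges Interaction data.frame ([parse_pkn()] output).
#' @param dti Long drug-target table ([matrix_to_long()] format); rows with an
#'   empty target are treated as control conditions and always retained.
#' @param tf_names Character vector of TF node identifiers.
#' @return List with `dti` (trimmed long table), `tf_names` (trimmed),
#'   `targeted_tfs` (TFs that are direct drug targets), `forced_keep` (node
#'   set), and `forced_edges` (edges incident to targeted TFs).
#' @export
connect_data_to_pkn <- function(edges, dti, tf_names) {
  nodes <- unique(c(edges$source, edges$target))
  is_ctrl <- is.na(dti$target_uniprot) | dti$target_uniprot == ""
  in_net <- dti$target_uniprot %in% nodes
  connectable_drugs <- unique(dti$drug_smiles[in_net & !is_ctrl])
  keep_row <- is_ctrl | (dti$drug_smiles %in% connectable_drugs & in_net)
  dti_out <- dti[keep_row, , drop = FALSE]
  if (!any(!is_ctrl[keep_row])) stop_fmt("no connectable drugs")
  tf_keep <- tf_names[tf_names %in% nodes]
  targeted_tfs <- intersect(tf_keep, dti_out$target_uniprot)
  forced_edges <- edges[edges$source %in% targeted_tfs |
                          edges$target %in% targeted_tfs, , drop = FALSE]
  forced_keep <- unique(c(targeted_tfs))
  list(dti = dti_out, tf_names = tf_keep, targeted_tfs = targeted_tfs,
       forced_keep = forced_keep, forced_edges = forced_edges)
}

#' Trim a network to the input-to-output connected core
#'
#' Iteratively removes nodes that do not lie on any directed path from an
#' input node (drug target) to an output node (TF): a node survives when it is
#' reachable from some input and can itself reach some output, or when it
#' belongs to `forced_keep`. Edges between two retained nodes are kept,
#' including edges joining two forced-keep nodes that are otherwise
#' unreachable. Reachability uses directed edges and ignores signs.
#'
#' @param edges Interaction data.frame.
#' @param input_nodes Drug-target node identifiers (nonempty).
#' @param output_nodes TF node identifiers (nonempty).
#' @param forced_keep Nodes never removed.
#' @return A `scaffold_network` object: list with `nodes`, `edges`,
#'   `input_nodes`, `output_nodes`, `forced_keep`.
#' @export
trim_network <- function(edges, input_nodes, output_nodes,
                         forced_keep = character(0)) {
  stopifnot(length(input_nodes) > 0, length(output_nodes) > 0)
  cur <- edges
  repeat {
    nodes <- unique(c(cur$source, cur$target, input_nodes, output_nodes,
                      forced_keep))
    g <- igraph::graph_from_data_frame(
      cur[, c("source", "target")], directed = TRUE,
      vertices = data.frame(name = nodes))
    ins <- intersect(input_nodes, nodes)
    outs <- intersect(output_nodes, nodes)
    fwd <- unique(unlist(lapply(ins, function(v) {
      names(igraph::subcomponent(g, v, mode = "out"))
    })))
    bwd <- unique(unlist(lapply(outs, function(v) {
      names(igraph::subcomponent(g, v, mode = "in"))
    })))
    if (length(intersect(fwd, bwd)) == 0) stop_fmt("disconnected scaffold")
    keep_nodes <- union(intersect(fwd, bwd), forced_keep)
    nxt <- cur[cur$source %in% keep_nodes & cur$target %in% keep_nodes, ,
               drop = FALSE]
    if (nrow(nxt) == nrow(cur)) {
      cur <- nxt
      break
    }
    cur <- nxt
  }
  nodes <- unique(c(cur$source, cur$target, forced_keep))
  scaffold_network(
    nodes = nodes,
    edges = cur,
    input_nodes = intersect(input_nodes, nodes),
    output_nodes = intersect(output_nodes, nodes),
    forced_keep = forced_keep
  )
}

#' Construct a scaffold network object
#'
#' @param nodes Node identifier vector.
#' @param edges Interaction data.frame (`source`, `target`, `sign`, ...).
#' @param input_nodes,output_nodes Drug-target and TF node sets.
#' @param forced_keep Nodes protected from trimming.
#' @param annotation Optional data.frame mapping node ids to display names
#'   (columns `node`, `gene`).
#' @return Object of class `scaffold_network`.
#' @export
scaffold_network <- function(nodes, edges, input_nodes, output_nodes,
                             forced_keep = character(0), annotation = NULL) {
  nodes <- unique(c(nodes, forced_keep))
  stopifnot(all(edges$source %in% nodes), all(edges$target %in% nodes))
  out <- structure(list(
    nodes = nodes,
    edges = edges,
    input_nodes = intersect(input_nodes, nodes),
    output_nodes = intersect(output_nodes, nodes),
    forced_keep = forced_keep,
    annotation = annotation
  ), class = "scaffold_network")
  out
}

#' @export
print.scaffold_network <- function(x, ...) {
  cat(sprintf("scaffold_network: %d nodes, %d edges (%d inputs, %d outputs, %d forced)\n",
              length(x$nodes), nrow(x$edges), length(x$input_nodes),
              length(x$output_nodes), length(x$forced_keep)))
  invisible(x)
}

#' Write a trimmed scaffold and its node annotation to TSV
#'
#' Produces the two files the training step consumes: the final PKN (one row
#' per signed edge) and a node annotation table with role flags.
#'
#' @param scaffold A `scaffold_network`.
#' @param pkn_path,annotation_path Output paths.
#' @export
write_scaffold <- function(scaffold, pkn_path, annotation_path) {
  e <- scaffold$edges
  out <- data.frame(source = e$source, target = e$target, direction = 1,
                    stimulation = as.integer(e$sign > 0),
                    inhibition = as.integer(e$sign < 0),
                    sources = e$provenance %||% "",
                    stringsAsFactors = FALSE)
  utils::write.table(out, pkn_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(
    node = scaffold$nodes,
    gene = if (!is.null(scaffold$annotation)) {
      scaffold$annotation$gene[match(scaffold$nodes, scaffold$annotation$node)]
    } else scaffold$nodes,
    is_input = as.integer(scaffold$nodes %in% scaffold$input_nodes),
    is_output = as.integer(scaffold$nodes %in% scaffold$output_nodes),
    forced = as.integer(scaffold$nodes %in% scaffold$forced_keep),
    stringsAsFactors = FALSE
  )
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(pkn = pkn_path, annotation = annotation_path))
}

#' Read a scaffold written by [write_scaffold()]
#'
#' @param pkn_path,annotation_path Paths produced by [write_scaffold()].
#' @return A `scaffold_network`.
#' @export
read_scaffold <- function(pkn_path, annotation_path) {
  edges <- parse_pkn(pkn_path)
  ann <- utils::read.delim(annotation_path, sep = "\t",
                           stringsAsFactors = FALSE)
  scaffold_network(
    nodes = ann$node,
    edges = edges,
    input_nodes = ann$node[ann$is_input == 1],
    output_nodes = ann$node[ann$is_output == 1],
    forced_keep = ann$node[ann$forced == 1],
    annotation = ann[, c("node", "gene")]
  )
}
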