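# Assembly of the predicted TF networks from enrichment output.
#
# Node types: pattern (the query list), GO term, motif, TF.
# Edge types and directions:
#   TF-motif       TF -> motif        (no p-value)
#   motif-pattern  motif -> pattern   (whole-list motif enrichment p)
#   pattern-GOterm pattern -> GO term (whole-list GO enrichment p)
#   motif-GOterm   motif -> GO term   (subanalysis p)

NODE_TYPES <- c("pattern", "GO term", "motif", "TF")

EDGE_RULES <- list(
  "TF-motif"       = c(source = "TF",      target = "motif"),
  "motif-pattern"  = c(source = "motif",   target = "pattern"),
  "pattern-GOterm" = c(source = "pattern", target = "GO term"),
  "motif-GOterm"   = c(source = "motif",   target = "GO term")
)

#' Construct a typed TF network
#'
#' Validates that edge endpoints exist, that edge types are consistent
#' with their endpoint node types, and that only `TF-motif` edges lack a
#' p-value.  Nodes and edges are stored lexicographically sorted so that
#' serialization is deterministic.
#'
#' @param nodes Data frame with columns `node`, `type` (type one of
#'   `pattern`, `GO term`, `motif`, `TF`).
#' @param edges Data frame with columns `source`, `edge_type`, `target`,
#'   `p_value` (NA allowed only for `TF-motif`).
#' @return An object of class `tf_network`.
#' @export
tf_network <- function(nodes = data.frame(node = character(),
                                          type = character(),
                                          stringsAsFactors = FALSE),
                       edges = data.frame(source = character(),
                                          edge_type = character(),
                                          target = character(),
                                          p_value = numeric(),
                                          stringsAsFactors = FALSE)) {
  stopifnot(all(c("node", "type") %in% names(nodes)),
            all(c("source", "edge_type", "target", "p_value") %in% names(edges)))
  nodes <- unique(nodes[, c("node", "type"), drop = FALSE])
  if (anyDuplicated(nodes$node)) {
    stop("node with more than one type: ",
         nodes$node[duplicated(nodes$node)][1])
  }
  if (!all(nodes$type %in% NODE_TYPES)) {
    stop("invalid node type: ",
         setdiff(unique(nodes$type), NODE_TYPES)[1])
  }
  type_of <- setNames(nodes$type, nodes$node)
  edges <- unique(edges[, c("source", "edge_type", "target", "p_value"),
                        drop = FALSE])
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    rule <- EDGE_RULES[[e$edge_type]]
    if (is.null(rule)) stop("invalid edge type: ", e$edge_type)
    if (!e$source %in% nodes$node || !e$target %in% nodes$node) {
      stop("edge endpoint missing from nodes: ", e$source, " -> ", e$target)
    }
    if (type_of[[e$source]] != rule[["source"]] ||
        type_of[[e$target]] != rule[["target"]]) {
      stop("edge type ", e$edge_type, " inconsistent with endpoint types (",
           e$source, " -> ", e$target, ")")
    }
    if (e$edge_type == "TF-motif" && !is.na(e$p_value)) {
      stop("TF-motif edges carry no p-value")
    }
    if (e$edge_type != "TF-motif" && is.na(e$p_value)) {
      stop(e$edge_type, " edges must carry the enrichment p-value")
    }
  }
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  edges <- edges[order(edges$source, edges$edge_type, edges$target), ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  tab <- table(factor(x$nodes$type, levels = NODE_TYPES))
  cat(sprintf("tf_network: %d nodes (%s), %d edges\n", nrow(x$nodes),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Associate enriched motifs with query-list TFs able to bind them
#'
#' A pair `(tf, motif)` is returned when the motif is among the supplied
#' (significantly enriched) motifs, the TF binds that motif according to
#' the TF-motif map, and the TF itself is a member of the query list.
#' TFs outside the query never appear.
#'
#' @param enriched_motifs Character vector of significant motif ids, or
#'   an enrichment result data frame (its `item_id` column is used).
#' @param query A [query_list].
#' @param tf_map A [tf_motif_map].
#' @return Data frame with columns `tf_id`, `motif_id`.
#' @export
associate_tfs <- function(enriched_motifs, query, tf_map) {
  motif_ids <- if (is.data.frame(enriched_motifs)) {
    enriched_motifs$item_id
  } else as.character(enriched_motifs)
  keep <- tf_map$motif_id %in% motif_ids & tf_map$tf_id %in% query$gene_ids
  pairs <- unique(as.data.frame(tf_map)[keep, c("tf_id", "motif_id"),
                                        drop = FALSE])
  pairs <- pairs[order(pairs$tf_id, pairs$motif_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Build the whole-query-list (analysis) network
#'
#' One pattern node represents the query list.  Every significant motif
#' connects to the pattern (edge carries that motif's p-value), every
#' significant GO term connects from the pattern (edge carries that
#' term's p-value), and every `(tf, motif)` pair connects TF to motif.
#' Motifs with no bound TF in the query remain as nodes.
#'
#' @param query A [query_list].
#' @param go_sig Significant GO results (rows of [enrich_go()] output
#'   with `significant == TRUE`).
#' @param motif_sig Significant motif results.
#' @param tf_pairs Data frame `tf_id`, `motif_id` from [associate_tfs()].
#' @param pattern_label Pattern node label; defaults to `query$name`.
#' @return A [tf_network].
#' @export
build_analysis_network <- function(query, go_sig, motif_sig, tf_pairs,
                                   pattern_label = NULL) {
  pattern_label <- pattern_label %||% query$name
  nodes <- data.frame(node = pattern_label, type = "pattern",
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = character(), edge_type = character(),
                      target = character(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(motif_sig)) {
    nodes <- rbind(nodes, data.frame(node = motif_sig$item_id,
                                     type = "motif", stringsAsFactors = FALSE))
    edges <- rbind(edges, data.frame(source = motif_sig$item_id,
                                     edge_type = "motif-pattern",
                                     target = pattern_label,
                                     p_value = motif_sig$p_value,
                                     stringsAsFactors = FALSE))
  }
  if (nrow(go_sig)) {
    nodes <- rbind(nodes, data.frame(node = go_sig$item_id, type = "GO term",
                                     stringsAsFactors = FALSE))
    edges <- rbind(edges, data.frame(source = pattern_label,
                                     edge_type = "pattern-GOterm",
                                     target = go_sig$item_id,
                                     p_value = go_sig$p_value,
                                     stringsAsFactors = FALSE))
  }
  if (nrow(tf_pairs)) {
    nodes <- rbind(nodes, data.frame(node = unique(tf_pairs$tf_id),
                                     type = "TF", stringsAsFactors = FALSE))
    edges <- rbind(edges, data.frame(source = tf_pairs$tf_id,
                                     edge_type = "TF-motif",
                                     target = tf_pairs$motif_id,
                                     p_value = NA_real_,
                                     stringsAsFactors = FALSE))
  }
  tf_network(nodes, edges)
}

#' Build the per-GO-term (subanalysis) network
#'
#' For every significant `(term, motif)` pair from the subanalysis, a
#' `motif-GOterm` edge carries that subanalysis p-value; TFs from the
#' query list able to bind each per-term significant motif connect via
#' `TF-motif` edges.  A motif significant under several terms keeps a
#' single node with one edge per term.
#'
#' @param sub_results Named list (term -> motif result data frame) with
#'   only significant rows retained, e.g.
#'   `lapply(subanalysis_motifs(...), function(df) df[df$significant, ])`.
#' @param query A [query_list].
#' @param tf_map A [tf_motif_map].
#' @return A [tf_network].
#' @export
build_subanalysis_network <- function(sub_results, query, tf_map) {
  nodes <- data.frame(node = character(), type = character(),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = character(), edge_type = character(),
                      target = character(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  for (term in names(sub_results)) {
    df <- sub_results[[term]]
    if (!nrow(df)) next
    nodes <- rbind(nodes,
                   data.frame(node = term, type = "GO term",
                              stringsAsFactors = FALSE),
                   data.frame(node = df$item_id, type = "motif",
                              stringsAsFactors = FALSE))
    edges <- rbind(edges, data.frame(source = df$item_id,
                                     edge_type = "motif-GOterm",
                                     target = term, p_value = df$p_value,
                                     stringsAsFactors = FALSE))
    pairs <- associate_tfs(df, query, tf_map)
    if (nrow(pairs)) {
      nodes <- rbind(nodes, data.frame(node = unique(pairs$tf_id),
                                       type = "TF", stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(source = pairs$tf_id,
                                       edge_type = "TF-motif",
                                       target = pairs$motif_id,
                                       p_value = NA_real_,
                                       stringsAsFactors = FALSE))
    }
  }
  tf_network(nodes, edges)
}
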