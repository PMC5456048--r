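# Hypergeometric over-representation tests for GO terms and promoter
# motifs over the genome-wide background, and the per-GO-term motif
# subanalysis.
#
# The test statistic follows the classic a/b/c/d contingency layout:
#   a = query genes belonging to the item,
#   b = genome genes belonging to the item,
#   c = query size, d = genome (universe) size,
# and the p-value is the exact upper tail P(X >= a) with
# X ~ Hypergeometric(population d, successes b, draws c).

#' Upper-tail hypergeometric p-value
#'
#' Exact `P(X >= a)` for `X ~ Hypergeometric(d, b, c)` (population `d`,
#' `b` marked genes, `c` draws).  One-sided over-representation only.
#' Vectorized over all four arguments.
#'
#' @param a Query genes carrying the item.
#' @param b Genome genes carrying the item.
#' @param c Query size.
#' @param d Universe size.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_upper_tail(3, 5, 4, 20)  # 155/4845
hypergeom_upper_tail <- function(a, b, c, d) {
  if (any(a < 0 | b < 0 | c < 0 | d <= 0)) {
    stop("counts must be non-negative and d > 0")
  }
  if (any(b > d | c > d)) stop("b and c must not exceed d")
  if (any(a > pmin(b, c))) stop("a must not exceed min(b, c)")
  phyper(a - 1, m = b, n = d - b, k = c, lower.tail = FALSE)
}

make_results_df <- function(item_id, item_label, a, b, c, d, alpha) {
  p <- if (length(item_id)) hypergeom_upper_tail(a, b, c, d) else numeric()
  q <- p.adjust(p, method = "BH")
  res <- data.frame(item_id = as.character(item_id),
                    item_label = as.character(item_label),
                    a = as.integer(a), b = as.integer(b),
                    c = as.integer(c), d = as.integer(d),
                    p_value = p, q_value = q,
                    significant = p < alpha,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$item_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' GO term over-representation in a query gene list
#'
#' Tests every GO term with at least one annotated gene in `universe`.
#' The universe is the full set of annotated genes (the "genome");
#' `c` is the number of query genes inside the universe.  Results are
#' sorted by ascending p-value (ties broken by term id); `significant`
#' flags raw `p < alpha`.  Benjamini-Hochberg q-values are attached for
#' reporting but never drive the flag.
#'
#' @param query A [query_list].
#' @param go A [go_annotation].
#' @param universe Character vector of all genome gene ids.
#' @param alpha Significance threshold (default 0.001).
#' @return Data frame with columns `item_id`, `item_label`, `a`, `b`,
#'   `c`, `d`, `p_value`, `q_value`, `significant`.
#' @export
enrich_go <- function(query, go, universe, alpha = 0.001) {
  stopifnot(inherits(query, "query_list"), inherits(go, "go_annotation"),
            alpha > 0, alpha < 1)
  universe <- unique(as.character(universe))
  d <- length(universe)
  if (!d) stop("empty universe")
  qry <- intersect(query$gene_ids, universe)
  cc <- length(qry)
  term_genes <- lapply(go$term_to_genes, intersect, y = universe)
  keep <- lengths(term_genes) > 0
  term_genes <- term_genes[keep]
  a <- vapply(term_genes, function(g) length(intersect(g, qry)), integer(1))
  b <- lengths(term_genes)
  ids <- names(term_genes)
  make_results_df(ids, unname(go$term_names[ids]), a, b,
                  rep(cc, length(ids)), rep(d, length(ids)), alpha)
}

#' Promoter motif over-representation in a query gene list
#'
#' For each motif in the index, `a` is the number of query genes whose
#' promoter carries the motif, `b` the number of such genes genome-wide,
#' `c` the query size and `d` the number of genes with a promoter.
#'
#' @param query A [query_list] whose gene ids all have promoters
#'   (i.e. are contained in `index$universe`).
#' @param index A `motif_index` from [build_motif_index()].
#' @param alpha Significance threshold (default 0.001).
#' @param labels Optional named character vector motif id -> label
#'   (defaults to the motif id itself).
#' @return Data frame as in [enrich_go()].
#' @export
enrich_motifs <- function(query, index, alpha = 0.001, labels = NULL) {
  stopifnot(inherits(query, "query_list"), inherits(index, "motif_index"),
            alpha > 0, alpha < 1)
  d <- length(index$universe)
  if (!d) stop("empty universe")
  if (!all(query$gene_ids %in% index$universe)) {
    stop("query contains genes without promoters; restrict to index$universe")
  }
  qry <- query$gene_ids
  ids <- names(index$motif_to_genes)
  a <- vapply(index$motif_to_genes, function(g) length(intersect(g, qry)),
              integer(1))
  b <- lengths(index$motif_to_genes)
  lab <- if (is.null(labels)) ids else {
    ifelse(ids %in% names(labels), labels[ids], ids)
  }
  make_results_df(ids, lab, a, b, rep(length(qry), length(ids)),
                  rep(d, length(ids)), alpha)
}

#' Per-GO-term motif subanalysis
#'
#' For every significantly enriched GO term (raw `p < alpha` in
#' `go_results`), motif enrichment is rerun with the query restricted to
#' the query genes annotated to that term: `c` becomes the subset size
#' and `a` the subset genes carrying each motif, while the genome-wide
#' background `b` and `d` are unchanged.  Terms whose subset is empty are
#' omitted.
#'
#' @param query A [query_list].
#' @param go_results GO enrichment results from [enrich_go()] computed on
#'   the same query.
#' @param go The [go_annotation] used for `go_results`.
#' @param index A `motif_index`.
#' @param alpha Significance threshold (default 0.001).
#' @param labels Optional motif labels, as in [enrich_motifs()].
#' @return Named list: GO term id -> motif enrichment data frame.
#' @export
subanalysis_motifs <- function(query, go_results, go, index, alpha = 0.001,
                               labels = NULL) {
  stopifnot(inherits(query, "query_list"), inherits(go, "go_annotation"),
            inherits(index, "motif_index"))
  sig_terms <- go_results$item_id[go_results$p_value < alpha]
  out <- list()
  for (term in sig_terms) {
    sub_ids <- intersect(intersect(query$gene_ids, index$universe),
                         go$term_to_genes[[term]] %||% character())
    if (!length(sub_ids)) next
    sub_query <- query_list(sub_ids, species = query$species,
                            name = paste0(query$name, ":", term))
    out[[term]] <- enrich_motifs(sub_query, index, alpha = alpha,
                                 labels = labels)
  }
  out
}
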