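# Readers and writers for every external format the tool touches.  All
# parsing dialects are pinned here; computational modules only see the
# domain objects constructed below.

#' Construct a query list object
#'
#' A query list is the ordered, deduplicated set of gene identifiers a user
#' submits (typically a co-expression cluster or a differential-expression
#' gene set), together with any identifiers that could not be resolved
#' against the annotation.
#'
#' @param gene_ids Character vector of resolved gene identifiers (no
#'   duplicates).
#' @param dropped_ids Identifiers present in the input but absent from the
#'   annotation.
#' @param species One of `"arabidopsis"`, `"bnapus"`, `"custom"`.
#' @param name Label used for the pattern node in output networks.
#' @return An object of class `query_list`.
#' @export
query_list <- function(gene_ids, dropped_ids = character(),
                       species = c("custom", "arabidopsis", "bnapus"),
                       name = "query") {
  species <- match.arg(species)
  gene_ids <- as.character(gene_ids)
  dropped_ids <- as.character(dropped_ids)
  if (anyDuplicated(gene_ids)) stop("query gene_ids contain duplicates")
  if (length(intersect(gene_ids, dropped_ids))) {
    stop("gene_ids and dropped_ids overlap")
  }
  structure(list(species = species, gene_ids = gene_ids,
                 dropped_ids = dropped_ids, name = name),
            class = "query_list")
}

#' @export
print.query_list <- function(x, ...) {
  cat(sprintf("query_list '%s' (%s): %d genes, %d dropped\n",
              x$name, x$species, length(x$gene_ids), length(x$dropped_ids)))
  invisible(x)
}

#' Read a plain-text query gene list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored.  Identifiers are uppercased and deduplicated preserving first
#' occurrence.  Identifiers absent from `annotation` are moved to
#' `dropped_ids` with a warning; if more than half the identifiers are
#' unknown a second, escalated warning is emitted but the run continues.
#'
#' @param path Path to the query `.txt` file.
#' @param annotation Character vector of known gene identifiers.
#' @param species Species tag stored on the result.
#' @return A [query_list].
#' @export
read_query_list <- function(path, annotation,
                            species = c("custom", "arabidopsis", "bnapus")) {
  species <- match.arg(species)
  if (!file.exists(path)) stop("query file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (!length(ids)) stop("empty query list")
  ids <- toupper(ids)
  ids <- ids[!duplicated(ids)]
  known <- ids %in% annotation
  dropped <- ids[!known]
  if (length(dropped)) {
    warning(sprintf("%d query identifier(s) not found in annotation: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
    if (length(dropped) > length(ids) / 2) {
      warning("more than 50% of query identifiers are unknown; ",
              "check that the query matches the annotation's identifier scheme",
              call. = FALSE)
    }
  }
  if (!any(known)) stop("empty query list")
  query_list(ids[known], dropped_ids = dropped, species = species,
             name = tools::file_path_sans_ext(basename(path)))
}

#' Write a query list to a plain-text file
#'
#' @param query A [query_list] or character vector of gene ids.
#' @param path Output path.
#' @export
write_query_list <- function(query, path) {
  ids <- if (inherits(query, "query_list")) query$gene_ids else as.character(query)
  writeLines(ids, path)
  invisible(path)
}

#' Read a gene annotation
#'
#' Two dialects are supported.  `tsv`: four whitespace-separated columns
#' `gene_id`, `contig`, `strand`, `tss` (1-based transcription start).
#' `gff3`: standard GFF3 parsed with \pkg{rtracklayer}; only `gene`
#' features are used and the TSS is the feature start on the `+` strand
#' and the feature end on the `-` strand.
#'
#' @param path Annotation file path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @return A data frame with columns `gene_id`, `contig`, `strand`, `tss`.
#' @export
read_annotation <- function(path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  genes <- switch(dialect,
                  tsv = read_annotation_tsv(path),
                  gff3 = read_annotation_gff3(path))
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) stop("duplicate gene id: ", paste(unique(dup), collapse = ", "))
  if (any(genes$tss < 1)) stop("tss must be >= 1")
  rownames(genes) <- NULL
  genes
}

read_annotation_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("annotation file is empty: ", path)
  parts <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stop(sprintf("malformed annotation line %d: expected 4 columns", lineno[bad[1]]))
  }
  m <- do.call(rbind, parts)
  strand <- m[, 3]
  badstrand <- which(!strand %in% c("+", "-"))
  if (length(badstrand)) {
    stop(sprintf("unknown strand symbol '%s' at line %d",
                 strand[badstrand[1]], lineno[badstrand[1]]))
  }
  tss <- suppressWarnings(as.integer(m[, 4]))
  badtss <- which(is.na(tss))
  if (length(badtss)) {
    stop(sprintf("malformed annotation line %d: tss is not an integer",
                 lineno[badtss[1]]))
  }
  data.frame(gene_id = m[, 1], contig = m[, 2], strand = strand, tss = tss,
             stringsAsFactors = FALSE)
}

read_annotation_gff3 <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene", , drop = FALSE]
  if (!nrow(gr)) stop("no gene features in GFF3 file: ", path)
  ids <- as.character(if (!is.null(gr$ID)) gr$ID else gr$Name)
  if (is.null(ids) || anyNA(ids)) stop("gene feature without an ID attribute")
  ids <- sub("^gene:", "", ids)
  strand <- as.character(gr$strand)
  if (any(strand == "*")) stop("unknown strand symbol '*' on gene ",
                               ids[which(strand == "*")[1]])
  tss <- ifelse(strand == "+", gr$start, gr$end)
  data.frame(gene_id = ids, contig = as.character(gr$seqnames),
             strand = strand, tss = as.integer(tss), stringsAsFactors = FALSE)
}

#' Write an annotation in the 4-column TSV dialect
#'
#' @param genes Annotation data frame (`gene_id`, `contig`, `strand`, `tss`).
#' @param path Output path.
#' @export
write_annotation_tsv <- function(genes, path) {
  write.table(genes[, c("gene_id", "contig", "strand", "tss")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' Wrapper over [Biostrings::readDNAStringSet()]; contig names are the
#' first whitespace-separated token of each FASTA header and sequences
#' are uppercased.
#'
#' @param path FASTA path.
#' @return Named character vector, one element per contig.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  seqs
}

#' Write a genome FASTA
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Construct a GO annotation table
#'
#' @param gene_to_terms Named list mapping gene id to a character vector of
#'   term ids.
#' @param term_names Named character vector mapping term id to a label.
#'   Terms appearing in `gene_to_terms` without a label get their id as
#'   label.
#' @return An object of class `go_annotation`.
#' @export
go_annotation <- function(gene_to_terms, term_names = character()) {
  gene_to_terms <- lapply(gene_to_terms, function(x) unique(as.character(x)))
  all_terms <- unique(unlist(gene_to_terms, use.names = FALSE)) %||% character()
  missing <- setdiff(all_terms, names(term_names))
  if (length(missing)) term_names[missing] <- missing
  # invert once; enrichment iterates terms, not genes
  term_to_genes <- list()
  if (length(gene_to_terms)) {
    df <- data.frame(
      gene = rep(names(gene_to_terms), lengths(gene_to_terms)),
      term = unlist(gene_to_terms, use.names = FALSE),
      stringsAsFactors = FALSE)
    term_to_genes <- split(df$gene, df$term)
  }
  structure(list(gene_to_terms = gene_to_terms,
                 term_to_genes = term_to_genes,
                 term_names = term_names),
            class = "go_annotation")
}

#' Read a gene-to-GO-term table
#'
#' TSV with header columns `gene_id`, `term_id`, `term_label` (one row per
#' gene/term pair; the annotation is used exactly as provided, without
#' ancestor propagation).
#'
#' @param path TSV path.
#' @return A [go_annotation] object.
#' @export
read_go_table <- function(path) {
  if (!file.exists(path)) stop("GO table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "term_id", "term_label")
  if (!all(need %in% names(df))) {
    stop("GO table must have columns: ", paste(need, collapse = ", "))
  }
  labels <- df$term_label[!duplicated(df$term_id)]
  names(labels) <- df$term_id[!duplicated(df$term_id)]
  go_annotation(split(df$term_id, df$gene_id), labels)
}

#' Write a GO annotation table as TSV
#' @param go A [go_annotation] object.
#' @param path Output path.
#' @export
write_go_table <- function(go, path) {
  genes <- rep(names(go$gene_to_terms), lengths(go$gene_to_terms))
  terms <- unlist(go$gene_to_terms, use.names = FALSE) %||% character()
  df <- data.frame(gene_id = genes %||% character(), term_id = terms,
                   term_label = unname(go$term_names[terms]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse motifs from a MEME minimal-format file
#'
#' Supports the minimal MEME text format: optional version/alphabet
#' header lines, then `MOTIF` blocks each carrying a
#' `letter-probability matrix:` with `A C G T` column order.  Each matrix
#' row must sum to within `[0.99, 1.01]` and is renormalized to 1.
#'
#' @param path MEME file path.
#' @return List of [pwm] objects, in file order.
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) stop("MEME file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  al <- grep("^ALPHABET", lines, value = TRUE)
  if (length(al)) {
    alpha <- gsub("[=[:space:]]", "", sub("^ALPHABET", "", al[1]))
    if (alpha != "ACGT") stop("unsupported alphabet: ", alpha)
  }
  starts <- grep("^MOTIF([[:space:]]|$)", lines)
  if (!length(starts)) stop("no MOTIF blocks in MEME file: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    toks <- strsplit(trimws(block[1]), "[[:space:]]+")[[1]]
    if (length(toks) < 2) stop("MOTIF line without an identifier")
    motif_id <- toks[2]
    hdr <- grep("letter-probability matrix", block)
    if (!length(hdr)) stop("motif ", motif_id, ": no letter-probability matrix")
    hline <- block[hdr[1]]
    alen <- as.integer(sub(".*alength=[[:space:]]*([0-9]+).*", "\\1", hline))
    if (grepl("alength=", hline) && !is.na(alen) && alen != 4L) {
      stop("unsupported alphabet: alength=", alen)
    }
    w <- if (grepl("w=", hline)) {
      as.integer(sub(".*\\bw=[[:space:]]*([0-9]+).*", "\\1", hline))
    } else NA_integer_
    body <- block[-seq_len(hdr[1])]
    body <- trimws(body)
    body <- body[nzchar(body)]
    rows <- list()
    for (bl in body) {
      vals <- suppressWarnings(as.numeric(strsplit(bl, "[[:space:]]+")[[1]]))
      if (anyNA(vals)) break  # next section (URL, etc.)
      if (length(vals) != 4) {
        stop("motif ", motif_id, ": matrix row with ", length(vals),
             " values (expected 4)")
      }
      rows[[length(rows) + 1L]] <- vals
    }
    if (!is.na(w) && length(rows) != w) {
      stop("motif ", motif_id, ": width mismatch (w=", w, ", rows=",
           length(rows), ")")
    }
    probs <- do.call(rbind, rows)
    sums <- rowSums(probs)
    bad <- which(sums < 0.99 | sums > 1.01)
    if (length(bad)) {
      stop("motif ", motif_id, ": probability row ", bad[1], " sums to ",
           format(sums[bad[1]]), " (outside [0.99, 1.01])")
    }
    pwm(motif_id, probs / sums)
  })
}

#' Read / write the degenerate IUPAC motif table
#'
#' TSV with header columns `motif_id`, `pattern`, `source`, `tf_ids`
#' (semicolon-joined; empty when no TF is associated).
#'
#' @param path TSV path.
#' @return List of [iupac_motif] objects.
#' @export
read_motif_table <- function(path) {
  if (!file.exists(path)) stop("motif table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                   colClasses = "character")
  need <- c("motif_id", "pattern", "source", "tf_ids")
  if (!all(need %in% names(df))) {
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    tfs <- strsplit(df$tf_ids[i], ";", fixed = TRUE)[[1]]
    iupac_motif(df$motif_id[i], df$pattern[i], source = df$source[i],
                tf_ids = tfs[nzchar(tfs)])
  })
}

#' @rdname read_motif_table
#' @param motifs List of [iupac_motif] objects.
#' @export
write_motif_table <- function(motifs, path) {
  df <- data.frame(
    motif_id = vapply(motifs, `[[`, character(1), "motif_id"),
    pattern = vapply(motifs, `[[`, character(1), "pattern"),
    source = vapply(motifs, `[[`, character(1), "source"),
    tf_ids = vapply(motifs, function(m) paste(m$tf_ids, collapse = ";"),
                    character(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the TF-motif interaction map
#'
#' TSV with header columns `tf_id`, `motif_id`, `provenance` where
#' provenance is one of `experimental`, `family_transfer`,
#' `ortholog_transfer`.
#'
#' @param path TSV path.
#' @return A [tf_motif_map] data frame.
#' @export
read_tf_map <- function(path) {
  if (!file.exists(path)) stop("TF map not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  tf_motif_map(df)
}

#' @rdname read_tf_map
#' @param map A [tf_motif_map].
#' @export
write_tf_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a TF family (cluster) assignment table
#'
#' TSV with header columns `tf_id`, `cluster_id`; each TF maps to exactly
#' one cluster.
#'
#' @param path TSV path.
#' @return Named character vector: TF id -> cluster id.
#' @export
read_family_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("tf_id", "cluster_id") %in% names(df))) {
    stop("family table must have columns tf_id, cluster_id")
  }
  if (anyDuplicated(df$tf_id)) stop("TF assigned to more than one cluster")
  setNames(df$cluster_id, df$tf_id)
}

#' Read a TF orthology table
#'
#' TSV with header columns `source_tf`, `target_tf`; many-to-many pairs.
#'
#' @param path TSV path.
#' @return Data frame with columns `source_tf`, `target_tf`.
#' @export
read_ortholog_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("source_tf", "target_tf") %in% names(df))) {
    stop("ortholog table must have columns source_tf, target_tf")
  }
  unique(df[, c("source_tf", "target_tf")])
}

#' Write full and summary enrichment reports
#'
#' The full report contains every tested item sorted by ascending p-value;
#' the summary contains the subset with `p_value < alpha` (strict
#' inequality).  Both are TSVs with columns `item_id`, `item_label`, `a`,
#' `b`, `c`, `d`, `p_value`, `q_value`; p/q-values are written in
#' scientific notation with six significant digits.  Benjamini-Hochberg
#' q-values are informational only: significance and the summary cut use
#' the raw p-value.
#'
#' @param results Enrichment result data frame (see [enrich_go()]).
#' @param path_full,path_summary Output paths.
#' @param alpha Summary threshold, default `0.001`.
#' @export
write_enrichment_report <- function(results, path_full, path_summary,
                                    alpha = 0.001) {
  stopifnot(alpha > 0, alpha < 1)
  results <- results[order(results$p_value, results$item_id), , drop = FALSE]
  emit <- function(df, path) {
    header <- c("item_id", "item_label", "a", "b", "c", "d", "p_value",
                "q_value")
    lines <- paste(header, collapse = "\t")
    if (nrow(df)) {
      lines <- c(lines, paste(df$item_id, df$item_label, df$a, df$b, df$c,
                              df$d, format_pvalue(df$p_value),
                              format_pvalue(df$q_value), sep = "\t"))
    }
    writeLines(lines, path)
  }
  emit(results, path_full)
  emit(results[results$p_value < alpha, , drop = FALSE], path_summary)
  invisible(c(path_full, path_summary))
}

#' Write the per-GO-term motif subanalysis report
#'
#' Same layout as [write_enrichment_report()] with a leading `go_term_id`
#' column; rows are grouped by term and sorted by ascending p-value within
#' each term.
#'
#' @param sub_results Named list of enrichment result data frames, one per
#'   GO term (as returned by [subanalysis_motifs()]).
#' @param path_full,path_summary Output paths.
#' @param alpha Summary threshold.
#' @export
write_subanalysis_report <- function(sub_results, path_full, path_summary,
                                     alpha = 0.001) {
  stopifnot(alpha > 0, alpha < 1)
  header <- c("go_term_id", "item_id", "item_label", "a", "b", "c", "d",
              "p_value", "q_value")
  rows_for <- function(only_sig) {
    out <- character()
    for (term in names(sub_results)) {
      df <- sub_results[[term]]
      df <- df[order(df$p_value, df$item_id), , drop = FALSE]
      if (only_sig) df <- df[df$p_value < alpha, , drop = FALSE]
      if (nrow(df)) {
        out <- c(out, paste(term, df$item_id, df$item_label, df$a, df$b,
                            df$c, df$d, format_pvalue(df$p_value),
                            format_pvalue(df$q_value), sep = "\t"))
      }
    }
    out
  }
  writeLines(c(paste(header, collapse = "\t"), rows_for(FALSE)), path_full)
  writeLines(c(paste(header, collapse = "\t"), rows_for(TRUE)), path_summary)
  invisible(c(path_full, path_summary))
}

#' Write Cytoscape-compatible network and attribute files
#'
#' Produces `<prefix>.analysis.networks.txt` and
#' `<prefix>.subanalysis.networks.txt` as edge tables (TSV columns
#' `source`, `edge_type`, `target`, `p_value`; p-value empty when absent)
#' plus `<prefix>.attributes.txt` (TSV columns `node`, `type`) labelling
#' every node of either network exactly once as `pattern`, `GO term`,
#' `motif` or `TF`.
#'
#' @param analysis,subanalysis [tf_network] objects.
#' @param prefix Path stem for the three output files.
#' @param attributes Optional named character vector node -> type; derived
#'   from the two graphs when `NULL`.
#' @return Invisibly, the three file paths.
#' @export
write_network_files <- function(analysis, subanalysis, prefix,
                                attributes = NULL) {
  stopifnot(inherits(analysis, "tf_network"), inherits(subanalysis, "tf_network"))
  if (is.null(attributes)) {
    both <- rbind(analysis$nodes, subanalysis$nodes)
    nodes <- both[!duplicated(both$node), , drop = FALSE]
    conflict <- tapply(both$type, both$node, function(t) length(unique(t)))
    if (any(conflict > 1)) {
      stop("node with conflicting types across networks: ",
           names(conflict)[conflict > 1][1])
    }
    attributes <- setNames(nodes$type, nodes$node)
  }
  all_nodes <- unique(c(analysis$nodes$node, subanalysis$nodes$node))
  missing <- setdiff(all_nodes, names(attributes))
  if (length(missing)) stop("node missing a type: ", missing[1])
  emit_net <- function(net, path) {
    e <- net$edges
    e <- e[order(e$source, e$edge_type, e$target), , drop = FALSE]
    lines <- "source\tedge_type\ttarget\tp_value"
    if (nrow(e)) {
      lines <- c(lines, paste(e$source, e$edge_type, e$target,
                              format_pvalue(e$p_value), sep = "\t"))
    }
    writeLines(lines, path)
  }
  paths <- paste0(prefix, c(".analysis.networks.txt",
                            ".subanalysis.networks.txt", ".attributes.txt"))
  emit_net(analysis, paths[1])
  emit_net(subanalysis, paths[2])
  keep <- names(attributes) %in% all_nodes
  attributes <- attributes[keep]
  ord <- order(names(attributes))
  writeLines(c("node\ttype",
               if (length(attributes)) paste(names(attributes)[ord],
                                             attributes[ord], sep = "\t")),
             paths[3])
  invisible(paths)
}
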