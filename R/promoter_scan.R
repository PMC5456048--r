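# Promoter extraction and the genome-wide motif "lookup" index
# (motif -> set of genes whose 1 kb upstream region contains a match),
# which supplies both query counts and the background for enrichment.

#' Extract upstream promoter regions
#'
#' For a `+` strand gene with 1-based TSS `t`, the promoter is the 1-based
#' interval `[max(1, t - window), t - 1]` in forward orientation; for a
#' `-` strand gene it is `[t + 1, min(contig_end, t + window)]`
#' reverse-complemented, so every returned sequence reads 5'->3' relative
#' to its gene.  Promoters clipped to zero length by a contig boundary
#' are dropped with a warning.  Sequences are uppercased and characters
#' outside A/C/G/T are mapped to `N`.
#'
#' @param genes Annotation data frame (`gene_id`, `contig`, `strand`,
#'   `tss`), e.g. from [read_annotation()].
#' @param sequences Named character vector of contig sequences (e.g. from
#'   [read_genome_fasta()]).
#' @param window Promoter length in bp upstream of the TSS (default 1000).
#' @return Data frame with columns `gene_id`, `contig`, `strand`,
#'   `start`, `end` (0-based half-open genomic interval) and `sequence`.
#' @export
extract_promoters <- function(genes, sequences, window = 1000) {
  stopifnot(window >= 1)
  missing_contig <- setdiff(unique(genes$contig), names(sequences))
  if (length(missing_contig)) {
    stop("contig(s) absent from genome: ", paste(missing_contig, collapse = ", "))
  }
  clen <- nchar(sequences)
  out <- vector("list", nrow(genes))
  dropped <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    L <- clen[[g$contig]]
    if (g$tss < 1 || g$tss > L) {
      stop("tss outside contig bounds for gene ", g$gene_id)
    }
    if (g$strand == "+") {
      s <- max(1, g$tss - window); e <- g$tss - 1
    } else {
      s <- g$tss + 1; e <- min(L, g$tss + window)
    }
    if (s > e) {
      dropped <- c(dropped, g$gene_id)
      next
    }
    seq <- toupper(substr(sequences[[g$contig]], s, e))
    seq <- gsub("[^ACGT]", "N", seq)
    if (g$strand == "-") seq <- revcomp_dna(seq)
    out[[i]] <- data.frame(gene_id = g$gene_id, contig = g$contig,
                           strand = g$strand, start = as.integer(s - 1),
                           end = as.integer(e), sequence = seq,
                           stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped),
            " gene(s) with empty promoter at contig boundary: ",
            paste(utils::head(dropped, 5), collapse = ", "), call. = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

# Forward-strand scan of encoded sequence against per-position allowances.
match_offsets <- function(allow, codes) {
  n <- length(codes); w <- length(allow)
  if (w > n) return(integer())
  ok <- allow[[1]][codes[seq_len(n - w + 1L)]]
  if (w > 1) {
    for (i in 2:w) ok <- ok & allow[[i]][codes[i:(n - w + i)]]
  }
  which(ok) - 1L
}

#' Find degenerate-consensus matches of a motif in a promoter
#'
#' Exact IUPAC consensus matching: offset `o` matches when every motif
#' position's identity set contains the promoter base at `o + i`.  With
#' `strand_policy = "both"` (the default) the reverse complement of the
#' motif is also scanned against the same sequence, and those matches are
#' reported on strand `-` at their forward-coordinate offsets.  A genomic
#' `N` satisfies only a motif `N` position.
#'
#' @param motif An [iupac_motif].
#' @param promoter A single promoter (one row of the data frame returned
#'   by [extract_promoters()], or any list with a `sequence` element).
#' @param strand_policy `"both"` or `"given"` (forward scan only).
#' @return Data frame with columns `offset` (0-based) and `strand`.
#' @export
#' @examples
#' p <- list(sequence = "AATTGACT")
#' find_matches(iupac_motif("m", "TTGACY"), p)
find_matches <- function(motif, promoter, strand_policy = c("both", "given")) {
  strand_policy <- match.arg(strand_policy)
  seq <- promoter$sequence
  stopifnot(is.character(seq), length(seq) == 1)
  codes <- encode_seq(seq)
  fwd <- match_offsets(motif_allowance(motif$pattern), codes)
  res <- data.frame(offset = fwd,
                    strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (strand_policy == "both") {
    rev <- match_offsets(motif_allowance(revcomp_iupac(motif$pattern)), codes)
    res <- rbind(res, data.frame(offset = rev,
                                 strand = rep("-", length(rev)),
                                 stringsAsFactors = FALSE))
  }
  res <- res[order(res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the genome-wide motif lookup index
#'
#' Scans every promoter for every motif and records, per motif, the set of
#' genes whose promoter contains at least one match.  Gene-level presence
#' (not occurrence counts) defines both query and background counts for
#' the enrichment tests.
#'
#' @param motifs List of [iupac_motif] objects.
#' @param promoters Promoter data frame from [extract_promoters()].
#' @param strand_policy `"both"` (default) or `"given"`.
#' @return An object of class `motif_index` with elements
#'   `motif_to_genes` (named list) and `universe` (all promoter gene ids).
#' @export
build_motif_index <- function(motifs, promoters,
                              strand_policy = c("both", "given")) {
  strand_policy <- match.arg(strand_policy)
  if (!nrow(promoters)) stop("no promoters supplied")
  if (anyDuplicated(promoters$gene_id)) {
    stop("duplicate promoter for gene: ",
         promoters$gene_id[duplicated(promoters$gene_id)][1])
  }
  codes <- lapply(promoters$sequence, encode_seq)
  motif_ids <- vapply(motifs, `[[`, character(1), "motif_id")
  if (anyDuplicated(motif_ids)) stop("duplicate motif ids in motif list")
  motif_to_genes <- setNames(vector("list", length(motifs)), motif_ids)
  for (k in seq_along(motifs)) {
    allows <- list(motif_allowance(motifs[[k]]$pattern))
    if (strand_policy == "both") {
      allows <- c(allows,
                  list(motif_allowance(revcomp_iupac(motifs[[k]]$pattern))))
    }
    hit <- vapply(codes, function(cd) {
      for (al in allows) if (length(match_offsets(al, cd))) return(TRUE)
      FALSE
    }, logical(1))
    motif_to_genes[[k]] <- promoters$gene_id[hit]
  }
  structure(list(motif_to_genes = motif_to_genes,
                 universe = promoters$gene_id),
            class = "motif_index")
}

#' @export
print.motif_index <- function(x, ...) {
  cat(sprintf("motif_index: %d motifs over %d genes\n",
              length(x$motif_to_genes), length(x$universe)))
  invisible(x)
}

#' Write promoter intervals as BED
#'
#' 0-based half-open intervals, name column = gene id, strand column from
#' the gene.
#'
#' @param promoters Promoter data frame from [extract_promoters()].
#' @param path Output BED path.
#' @export
write_promoter_bed <- function(promoters, path) {
  df <- data.frame(promoters$contig, promoters$start, promoters$end,
                   promoters$gene_id, 0L, promoters$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Dump a motif index as a two-column TSV
#'
#' One `(motif_id, gene_id)` row per gene-level match, with header.
#'
#' @param index A `motif_index`.
#' @param path Output path.
#' @export
write_motif_index <- function(index, path) {
  df <- data.frame(
    motif_id = rep(names(index$motif_to_genes),
                   lengths(index$motif_to_genes)),
    gene_id = unlist(index$motif_to_genes, use.names = FALSE) %||% character(),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
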