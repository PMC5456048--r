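# Deterministic synthetic fixture generator: a toy genome, annotation,
# GO table, motif/TF database and query list with planted enrichment
# signal plus machine-readable ground truth, so every stage and the full
# pipeline are testable offline.
#
# Layout: one contig divided into non-overlapping slots of
# promoter_len + 200 bp, one gene per slot with alternating strands, so
# promoters never overlap and strand handling is exercised on both sides.

#' Describe one planted enrichment signal
#'
#' @param pattern IUPAC motif pattern planted verbatim (one concrete
#'   instantiation per carrier promoter).
#' @param term GO term id whose membership is tied to the motif carriers.
#' @param query_frac Fraction of query genes carrying the motif; must
#'   exceed `background_frac`.
#' @param background_frac Fraction of non-query genes carrying the motif.
#' @param n_tfs Number of query genes declared TFs bound to the motif.
#' @return A list describing the planted signal.
#' @export
planted_signal <- function(pattern, term, query_frac = 0.8,
                           background_frac = 0.05, n_tfs = 2) {
  stopifnot(query_frac >= 0, query_frac <= 1,
            background_frac >= 0, background_frac <= 1,
            query_frac > background_frac, n_tfs >= 0)
  list(pattern = toupper(pattern), term = term, query_frac = query_frac,
       background_frac = background_frac, n_tfs = as.integer(n_tfs))
}

#' Specify a synthetic fixture
#'
#' Defaults model a scaled-down plant genome: AT-rich promoters
#' (A/T 0.30, C/G 0.20), a query list of about 10% of the genes, decoy
#' motifs wide enough (6 bp) and decoy GO terms large enough (50-150
#' genes) that null hypergeometric counts are not dominated by
#' discreteness.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_genes Number of genes in the toy genome.
#' @param n_query Query list size.
#' @param promoter_len Promoter window in bp.
#' @param planted List of [planted_signal()] descriptions (may be empty
#'   for null fixtures).
#' @param n_decoy_motifs,decoy_motif_len Unplanted concrete motifs that
#'   only match by chance.
#' @param n_decoy_terms,decoy_term_range Unplanted GO terms annotating
#'   random gene sets of size uniform in `decoy_term_range`.
#' @param base_composition Named A/C/G/T probability vector for the
#'   background sequence.
#' @param term_noise_frac Fraction of the genome added as noise genes to
#'   each planted GO term.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_genes = 500, n_query = 50,
                         promoter_len = 1000, planted = list(),
                         n_decoy_motifs = 10, decoy_motif_len = 6,
                         n_decoy_terms = 30, decoy_term_range = c(50, 150),
                         base_composition = c(A = 0.3, C = 0.2,
                                              G = 0.2, T = 0.3),
                         term_noise_frac = 0.04) {
  stopifnot(n_genes >= 2, n_query >= 1, n_query <= n_genes,
            promoter_len >= 10, length(base_composition) == 4,
            abs(sum(base_composition) - 1) < 1e-6,
            decoy_term_range[1] <= decoy_term_range[2],
            decoy_term_range[2] <= n_genes)
  names(base_composition) <- c("A", "C", "G", "T")
  for (p in planted) {
    if (nchar(p$pattern) > promoter_len) {
      stop("planted motif longer than promoter")
    }
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_query = as.integer(n_query),
                 promoter_len = as.integer(promoter_len), planted = planted,
                 n_decoy_motifs = as.integer(n_decoy_motifs),
                 decoy_motif_len = as.integer(decoy_motif_len),
                 n_decoy_terms = as.integer(n_decoy_terms),
                 decoy_term_range = as.integer(decoy_term_range),
                 base_composition = base_composition,
                 term_noise_frac = term_noise_frac),
            class = "fixture_spec")
}

# Concrete instantiation of a degenerate pattern (one base per position).
instantiate_pattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1) s else sample(s, 1)
  }, character(1)), collapse = "")
}

#' Generate a complete synthetic input bundle
#'
#' Builds the toy genome, annotation, GO table, motif/TF database and
#' query list described by `spec`, plants the configured signals, writes
#' every input file in the formats of the I/O module plus a
#' `truth.json` ground-truth manifest, and returns everything in memory.
#' Regenerating with the same spec reproduces the bundle byte-identically.
#'
#' @param spec A [fixture_spec].
#' @param dir Output directory (created if needed).
#' @return An object of class `fixture_bundle` with elements `spec`,
#'   `dir`, `paths`, `genome`, `annotation`, `promoters`, `go`, `motifs`,
#'   `tf_map`, `query` and `truth`.
#' @export
make_fixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_preserved_seed(spec$seed, {
    n <- spec$n_genes
    W <- spec$promoter_len
    slot <- W + 200L
    contig_len <- n * slot + 100L
    gene_id <- sprintf("G%04d", seq_len(n))
    strand <- rep(c("+", "-"), length.out = n)
    slot0 <- (seq_len(n) - 1L) * slot            # 0-based slot starts
    tss <- ifelse(strand == "+", slot0 + W + 1L, slot0 + 100L)
    annotation <- data.frame(gene_id = gene_id, contig = "chr1",
                             strand = strand, tss = as.integer(tss),
                             stringsAsFactors = FALSE)
    # genomic promoter bounds, 1-based inclusive
    pstart <- ifelse(strand == "+", tss - W, tss + 1L)
    pend <- ifelse(strand == "+", tss - 1L, tss + W)

    contig <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE,
                     prob = spec$base_composition)

    query_ids <- sample(gene_id, spec$n_query)
    nonquery <- setdiff(gene_id, query_ids)

    plant_instance <- function(gene, pattern) {
      i <- match(gene, gene_id)
      w <- nchar(pattern)
      inst <- instantiate_pattern(pattern)
      o <- sample.int(W - w + 1L, 1L) - 1L       # 0-based promoter offset
      if (strand[i] == "+") {
        gstart <- pstart[i] + o
        contig[gstart:(gstart + w - 1L)] <<-
          strsplit(inst, "", fixed = TRUE)[[1]]
      } else {
        gend <- pend[i] - o
        contig[(gend - w + 1L):gend] <<-
          strsplit(revcomp_dna(inst), "", fixed = TRUE)[[1]]
      }
    }

    truth_planted <- list()
    planted_motifs <- list()
    term_to_genes <- list()
    tf_rows <- list()
    for (k in seq_along(spec$planted)) {
      p <- spec$planted[[k]]
      motif_id <- sprintf("PLANTED_M%02d", k)
      n_qc <- round(p$query_frac * length(query_ids))
      n_bc <- round(p$background_frac * length(nonquery))
      carriers_q <- sample(query_ids, n_qc)
      carriers_b <- sample(nonquery, n_bc)
      for (g in c(carriers_q, carriers_b)) plant_instance(g, p$pattern)
      noise <- sample(nonquery, round(spec$term_noise_frac * n))
      term_to_genes[[p$term]] <- unique(c(carriers_q, noise))
      tfs <- if (p$n_tfs > 0) sample(query_ids, p$n_tfs) else character()
      if (length(tfs)) {
        tf_rows[[length(tf_rows) + 1L]] <- data.frame(
          tf_id = tfs, motif_id = motif_id, provenance = "experimental",
          stringsAsFactors = FALSE)
      }
      planted_motifs[[k]] <- iupac_motif(motif_id, p$pattern,
                                         source = "planted", tf_ids = tfs)
      truth_planted[[k]] <- list(motif_id = motif_id, pattern = p$pattern,
                                 term = p$term, tfs = tfs,
                                 query_carriers = sort(carriers_q),
                                 background_carriers = sort(carriers_b))
    }

    decoy_patterns <- character()
    while (length(decoy_patterns) < spec$n_decoy_motifs) {
      cand <- paste(sample(c("A", "C", "G", "T"), spec$decoy_motif_len,
                           replace = TRUE), collapse = "")
      known <- c(decoy_patterns,
                 vapply(spec$planted, `[[`, character(1), "pattern"))
      if (!cand %in% known) decoy_patterns <- c(decoy_patterns, cand)
    }
    decoy_motifs <- lapply(seq_along(decoy_patterns), function(j) {
      tf <- sample(nonquery, 1)
      tf_rows[[length(tf_rows) + 1L]] <<- data.frame(
        tf_id = tf, motif_id = sprintf("M%03d", j),
        provenance = "experimental", stringsAsFactors = FALSE)
      iupac_motif(sprintf("M%03d", j), decoy_patterns[j], source = "decoy",
                  tf_ids = tf)
    })

    for (j in seq_len(spec$n_decoy_terms)) {
      size <- sample(spec$decoy_term_range[1]:spec$decoy_term_range[2], 1)
      term_to_genes[[sprintf("GO:%07d", j)]] <- sample(gene_id, size)
    }

    motifs <- c(planted_motifs, decoy_motifs)
    tf_map <- tf_motif_map(do.call(rbind, c(tf_rows, list(
      data.frame(tf_id = character(), motif_id = character(),
                 provenance = character(), stringsAsFactors = FALSE)))))

    # invert term -> genes into the annotation table shape
    go_df <- data.frame(
      gene_id = unlist(term_to_genes, use.names = FALSE) %||% character(),
      term_id = rep(names(term_to_genes), lengths(term_to_genes)),
      stringsAsFactors = FALSE)
    go <- go_annotation(split(go_df$term_id, go_df$gene_id))

    genome <- setNames(paste(contig, collapse = ""), "chr1")
    prom_seq <- substring(genome[[1]], pstart, pend)
    prom_seq <- ifelse(strand == "-", revcomp_dna(prom_seq), prom_seq)
    promoters <- data.frame(gene_id = gene_id, contig = "chr1",
                            strand = strand, start = pstart - 1L,
                            end = as.integer(pend), sequence = prom_seq,
                            stringsAsFactors = FALSE)

    query <- query_list(query_ids, species = "custom", name = "query")
    truth <- list(planted = truth_planted, query = query_ids,
                  decoy_motif_ids = vapply(decoy_motifs, `[[`, character(1),
                                           "motif_id"),
                  decoy_term_ids = setdiff(names(term_to_genes),
                                           vapply(spec$planted, `[[`,
                                                  character(1), "term")))

    paths <- c(genome = file.path(dir, "genome.fa"),
               annotation = file.path(dir, "annotation.tsv"),
               go = file.path(dir, "go.tsv"),
               motifs = file.path(dir, "motifs.tsv"),
               tf_map = file.path(dir, "tf_map.tsv"),
               query = file.path(dir, "query.txt"),
               truth = file.path(dir, "truth.json"))
    write_genome_fasta(genome, paths[["genome"]])
    write_annotation_tsv(annotation, paths[["annotation"]])
    write_go_table(go, paths[["go"]])
    write_motif_table(motifs, paths[["motifs"]])
    write_tf_map(tf_map, paths[["tf_map"]])
    write_query_list(query, paths[["query"]])
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = FALSE,
                         pretty = TRUE)

    structure(list(spec = spec, dir = dir, paths = paths, genome = genome,
                   annotation = annotation, promoters = promoters, go = go,
                   motifs = motifs, tf_map = tf_map, query = query,
                   truth = truth),
              class = "fixture_bundle")
  })
}

# IUPAC pattern -> regex character classes; genomic N only matches motif N.
iupac_regex <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    if (ch == "N") return("[ACGTN]")
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Recompute contingency counts for planted items by direct counting
#'
#' The independent oracle used to validate pipeline reports: motif
#' presence is re-derived by regular-expression scanning (both strands)
#' of the bundle's promoter sequences, and GO counts by direct set
#' operations on the bundle's tables.  Chance background matches of a
#' planted motif are therefore included, exactly as the pipeline sees
#' them.
#'
#' @param bundle A `fixture_bundle` from [make_fixture()].
#' @param items Item ids to count; defaults to every planted motif and
#'   term.  Unknown ids raise an error.
#' @return Data frame with columns `item_id`, `item_type`, `a`, `b`,
#'   `c`, `d`.
#' @export
realized_counts <- function(bundle, items = NULL) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  motif_ids <- vapply(bundle$motifs, `[[`, character(1), "motif_id")
  term_ids <- names(bundle$go$term_to_genes)
  if (is.null(items)) {
    items <- unlist(lapply(bundle$truth$planted,
                           function(p) c(p$motif_id, p$term)))
    if (is.null(items)) items <- character()
  }
  qry <- bundle$query$gene_ids
  seqs <- bundle$promoters$sequence
  genes <- bundle$promoters$gene_id
  rows <- lapply(items, function(it) {
    if (it %in% motif_ids) {
      pat <- bundle$motifs[[match(it, motif_ids)]]$pattern
      present <- grepl(iupac_regex(pat), seqs) |
        grepl(iupac_regex(revcomp_iupac(pat)), seqs)
      data.frame(item_id = it, item_type = "motif",
                 a = sum(present & genes %in% qry), b = sum(present),
                 c = length(intersect(qry, genes)), d = length(genes),
                 stringsAsFactors = FALSE)
    } else if (it %in% term_ids) {
      universe <- bundle$annotation$gene_id
      members <- intersect(bundle$go$term_to_genes[[it]], universe)
      data.frame(item_id = it, item_type = "GO term",
                 a = length(intersect(members, qry)), b = length(members),
                 c = length(intersect(qry, universe)), d = length(universe),
                 stringsAsFactors = FALSE)
    } else {
      stop("unknown item: ", it)
    }
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(item_id = character(), item_type = character(),
               a = integer(), b = integer(), c = integer(), d = integer(),
               stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}
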