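# End-to-end orchestration: the full enrichment/network run and the
# motif database build.

#' Configure a full analysis run
#'
#' @param query Path to the plain-text query gene list.
#' @param genome Path to the genome FASTA.
#' @param annotation Path to the gene annotation.
#' @param go_table Path to the gene/GO-term TSV.
#' @param motif_table Path to the IUPAC motif TSV.
#' @param tf_map Path to the TF-motif map TSV (optional; without it no
#'   TF nodes are produced).
#' @param out_prefix Path stem for all output files.
#' @param alpha Significance threshold for summaries and networks
#'   (default 0.001).
#' @param window Promoter length in bp (default 1000).
#' @param strand_policy Motif scanning policy, `"both"` or `"given"`.
#' @param annotation_dialect `"tsv"` or `"gff3"`.
#' @param species Species tag for the query list.
#' @param pattern_label Label of the pattern node; defaults to the query
#'   file stem.
#' @return An object of class `run_config`.
#' @export
run_config <- function(query, genome, annotation, go_table, motif_table,
                       out_prefix, tf_map = NULL, alpha = 0.001,
                       window = 1000, strand_policy = c("both", "given"),
                       annotation_dialect = c("tsv", "gff3"),
                       species = c("custom", "arabidopsis", "bnapus"),
                       pattern_label = NULL) {
  stopifnot(alpha > 0, alpha < 1, window >= 1)
  structure(list(query = query, genome = genome, annotation = annotation,
                 go_table = go_table, motif_table = motif_table,
                 tf_map = tf_map, out_prefix = out_prefix, alpha = alpha,
                 window = window, strand_policy = match.arg(strand_policy),
                 annotation_dialect = match.arg(annotation_dialect),
                 species = match.arg(species),
                 pattern_label = pattern_label),
            class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full enrichment and network-prediction pipeline
#'
#' Reads every input, extracts promoters, builds the motif index, runs
#' GO and motif enrichment plus the per-term subanalysis, assembles the
#' analysis and subanalysis networks, and writes the reports
#' (`<prefix>.go.full.tsv`, `.go.summary.tsv`, `.motifs.full.tsv`,
#' `.motifs.summary.tsv`, `.subanalysis.full.tsv`,
#' `.subanalysis.summary.tsv`) and the Cytoscape files
#' (`<prefix>.analysis.networks.txt`, `.subanalysis.networks.txt`,
#' `.attributes.txt`).  Progress is logged with [message()]; any stage
#' failure aborts with a stage-named error.  Deterministic for fixed
#' inputs.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with the in-memory results (`query`,
#'   `promoters`, `index`, `go_results`, `motif_results`, `sub_results`,
#'   `analysis_network`, `subanalysis_network`, `files`).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- c(query = config$query, genome = config$genome,
              annotation = config$annotation, go_table = config$go_table,
              motif_table = config$motif_table)
  if (!is.null(config$tf_map)) inputs <- c(inputs, tf_map = config$tf_map)
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      stop("stage input-check: missing ", nm, " file: ", inputs[[nm]],
           call. = FALSE)
    }
  }
  alpha <- config$alpha

  annotation <- run_stage("read-annotation",
                          read_annotation(config$annotation,
                                          config$annotation_dialect))
  message("annotation: ", nrow(annotation), " genes")
  genome <- run_stage("read-genome", read_genome_fasta(config$genome))
  message("genome: ", length(genome), " contig(s)")
  query <- run_stage("read-query",
                     read_query_list(config$query, annotation$gene_id,
                                     species = config$species))
  message("query: ", length(query$gene_ids), " genes (",
          length(query$dropped_ids), " dropped)")
  go <- run_stage("read-go", read_go_table(config$go_table))
  message("GO table: ", length(go$term_to_genes), " terms")
  motifs <- run_stage("read-motifs", read_motif_table(config$motif_table))
  message("motif table: ", length(motifs), " motifs")
  tf_map <- if (is.null(config$tf_map)) tf_motif_map() else {
    run_stage("read-tf-map", read_tf_map(config$tf_map))
  }

  promoters <- run_stage("extract-promoters",
                         extract_promoters(annotation, genome,
                                           window = config$window))
  message("promoters: ", nrow(promoters), " extracted")
  index <- run_stage("build-index",
                     build_motif_index(motifs, promoters,
                                       strand_policy = config$strand_policy))

  go_universe <- annotation$gene_id
  go_results <- run_stage("enrich-go",
                          enrich_go(query, go, go_universe, alpha = alpha))
  message("GO enrichment: ", sum(go_results$significant), " of ",
          nrow(go_results), " terms significant at p < ", alpha)

  motif_query_ids <- intersect(query$gene_ids, index$universe)
  if (length(motif_query_ids) < length(query$gene_ids)) {
    message("motif enrichment: ",
            length(query$gene_ids) - length(motif_query_ids),
            " query gene(s) without promoters excluded")
  }
  motif_query <- query_list(motif_query_ids, species = query$species,
                            name = query$name)
  motif_labels <- setNames(vapply(motifs, `[[`, character(1), "pattern"),
                           vapply(motifs, `[[`, character(1), "motif_id"))
  motif_results <- run_stage("enrich-motifs",
                             enrich_motifs(motif_query, index, alpha = alpha,
                                           labels = motif_labels))
  message("motif enrichment: ", sum(motif_results$significant), " of ",
          nrow(motif_results), " motifs significant at p < ", alpha)

  sub_results <- run_stage("subanalysis",
                           subanalysis_motifs(motif_query, go_results, go,
                                              index, alpha = alpha,
                                              labels = motif_labels))
  message("subanalysis: ", length(sub_results), " enriched term(s)")

  go_sig <- go_results[go_results$significant, , drop = FALSE]
  motif_sig <- motif_results[motif_results$significant, , drop = FALSE]
  tf_pairs <- run_stage("associate-tfs",
                        associate_tfs(motif_sig, query, tf_map))
  analysis_net <- run_stage(
    "analysis-network",
    build_analysis_network(query, go_sig, motif_sig, tf_pairs,
                           pattern_label = config$pattern_label))
  sub_sig <- lapply(sub_results,
                    function(df) df[df$significant, , drop = FALSE])
  sub_sig <- sub_sig[vapply(sub_sig, nrow, integer(1)) > 0]
  sub_net <- run_stage("subanalysis-network",
                       build_subanalysis_network(sub_sig, query, tf_map))

  prefix <- config$out_prefix
  files <- run_stage("write-outputs", {
    f1 <- write_enrichment_report(
      go_results, paste0(prefix, ".go.full.tsv"),
      paste0(prefix, ".go.summary.tsv"), alpha = alpha)
    f2 <- write_enrichment_report(
      motif_results, paste0(prefix, ".motifs.full.tsv"),
      paste0(prefix, ".motifs.summary.tsv"), alpha = alpha)
    f3 <- write_subanalysis_report(
      sub_results, paste0(prefix, ".subanalysis.full.tsv"),
      paste0(prefix, ".subanalysis.summary.tsv"), alpha = alpha)
    f4 <- write_network_files(analysis_net, sub_net, prefix)
    c(f1, f2, f3, f4)
  })
  message("wrote ", length(files), " output files under ", prefix, ".*")

  invisible(list(query = query, promoters = promoters, index = index,
                 go_results = go_results, motif_results = motif_results,
                 sub_results = sub_results, analysis_network = analysis_net,
                 subanalysis_network = sub_net, tf_pairs = tf_pairs,
                 files = files))
}

#' Build the curated motif/TF database
#'
#' Converts PWMs (MEME files) to degenerate IUPAC motifs, merges them
#' with any pre-converted IUPAC tables, removes duplicate patterns and
#' non-informative motifs, applies family-based then orthology-based
#' TF-motif transfer, and writes the motif table, TF map and a build log
#' recording the counts removed or added at each step.
#'
#' @param meme_paths Character vector of MEME minimal-format files.
#' @param iupac_paths Character vector of IUPAC motif TSVs.
#' @param tf_map_path Optional TSV of experimental TF-motif pairs.
#' @param family_path Optional TF family table (`tf_id`, `cluster_id`).
#' @param ortholog_path Optional ortholog table (`source_tf`,
#'   `target_tf`).
#' @param out_dir Output directory.
#' @param inclusion_threshold Per-base probability below which a base is
#'   not recorded during IUPAC conversion (default 0.10).
#' @param chance_threshold Per-locus chance probability at or above which
#'   a motif is discarded as non-informative (default 0.02).
#' @return Invisibly, a list with `motifs`, `tf_map` and the named
#'   integer `log`.
#' @export
build_motif_db <- function(meme_paths = character(),
                           iupac_paths = character(), tf_map_path = NULL,
                           family_path = NULL, ortholog_path = NULL,
                           out_dir = ".", inclusion_threshold = 0.10,
                           chance_threshold = 0.02) {
  if (!length(meme_paths) && !length(iupac_paths)) {
    stop("at least one motif source (MEME or IUPAC table) is required")
  }
  stopifnot(inclusion_threshold > 0, inclusion_threshold < 1,
            chance_threshold > 0, chance_threshold < 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pwms <- unlist(lapply(meme_paths, read_meme_motifs), recursive = FALSE)
  converted <- lapply(pwms, pwm_to_iupac,
                      inclusion_threshold = inclusion_threshold)
  loaded <- unlist(lapply(iupac_paths, read_motif_table), recursive = FALSE)
  motifs <- c(converted, loaded %||% list())

  deduped <- dedupe_motifs(motifs)
  filt <- filter_non_informative(deduped, chance_threshold = chance_threshold)
  kept <- filt$retained
  if (!length(kept)) stop("zero motifs survive the filters")

  # experimental map: supplied pairs plus the motifs' own tf_ids
  kept_ids <- vapply(kept, `[[`, character(1), "motif_id")
  own_rows <- do.call(rbind, c(lapply(kept, function(m) {
    if (!length(m$tf_ids)) return(NULL)
    data.frame(tf_id = m$tf_ids, motif_id = m$motif_id,
               provenance = "experimental", stringsAsFactors = FALSE)
  }), list(data.frame(tf_id = character(), motif_id = character(),
                      provenance = character(), stringsAsFactors = FALSE))))
  map_df <- own_rows
  if (!is.null(tf_map_path)) {
    ext <- as.data.frame(read_tf_map(tf_map_path))
    ext <- ext[ext$motif_id %in% kept_ids, , drop = FALSE]
    map_df <- unique(rbind(map_df, ext))
  }
  map <- tf_motif_map(map_df)

  n_family <- 0L
  if (!is.null(family_path)) {
    families <- read_family_table(family_path)
    before <- nrow(map)
    map <- transfer_by_family(map, families)
    n_family <- nrow(map) - before
  }
  n_ortholog <- 0L
  if (!is.null(ortholog_path)) {
    orthologs <- read_ortholog_table(ortholog_path)
    target_map <- transfer_by_orthology(map, orthologs)
    n_ortholog <- nrow(target_map)
    map <- tf_motif_map(rbind(as.data.frame(map),
                              as.data.frame(target_map)))
  }

  # reflect final map back onto the motifs' tf_ids
  final <- lapply(kept, function(m) {
    m$tf_ids <- sort(unique(c(m$tf_ids,
                              map$tf_id[map$motif_id == m$motif_id])))
    m
  })

  log <- c(n_pwm_converted = length(converted),
           n_iupac_loaded = length(loaded %||% list()),
           n_duplicates_removed = length(motifs) - length(deduped),
           n_noninformative_removed = length(filt$removed),
           n_family_transfers = n_family,
           n_ortholog_transfers = n_ortholog,
           n_motifs_final = length(final),
           n_map_entries_final = nrow(map))
  write_motif_table(final, file.path(out_dir, "motifs.tsv"))
  write_tf_map(map, file.path(out_dir, "tf_map.tsv"))
  writeLines(paste(names(log), log, sep = "\t"),
             file.path(out_dir, "build_log.txt"))
  for (nm in names(log)) message(nm, ": ", log[[nm]])
  invisible(list(motifs = final, tf_map = map, log = log))
}
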