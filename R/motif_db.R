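# Motif/TF database construction: PWM -> degenerate IUPAC conversion,
# deduplication, informativeness filtering, and transfer of binding sites
# to TFs lacking experimental data via family and orthology tables.

#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param probs Numeric matrix, one row per position, four columns in
#'   A, C, G, T order; every row must sum to 1 within `1e-6`.
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, probs) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1) stop("PWM must have width >= 1")
  if (any(probs < 0 | probs > 1)) stop("PWM probabilities must lie in [0, 1]")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("PWM rows must each sum to 1 (within 1e-6)")
  }
  colnames(probs) <- c("A", "C", "G", "T")
  rownames(probs) <- NULL
  structure(list(motif_id = as.character(motif_id), probs = probs),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (width %d)\n", x$motif_id, nrow(x$probs)))
  print(round(x$probs, 3))
  invisible(x)
}

#' Construct a degenerate IUPAC motif
#'
#' @param motif_id Motif identifier.
#' @param pattern Non-empty string over the 15-letter IUPAC nucleotide
#'   alphabet `ACGTRYSWKMBDHVN`.
#' @param source Provenance tag (e.g. name of the source database).
#' @param tf_ids Character vector of TF identifiers known to bind the motif.
#' @return An object of class `iupac_motif`.
#' @export
iupac_motif <- function(motif_id, pattern, source = "unknown",
                        tf_ids = character()) {
  pattern <- toupper(as.character(pattern))
  if (!nzchar(pattern)) stop("motif pattern must be non-empty")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (!all(chars %in% IUPAC_CODES)) {
    stop("motif pattern contains non-IUPAC characters: ", pattern)
  }
  structure(list(motif_id = as.character(motif_id), pattern = pattern,
                 source = as.character(source),
                 tf_ids = unique(as.character(tf_ids))),
            class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("iupac_motif '%s' %s [%s] tfs: %s\n", x$motif_id, x$pattern,
              x$source, paste(x$tf_ids, collapse = ",")))
  invisible(x)
}

#' Construct a TF-motif interaction map
#'
#' A data frame of `(tf_id, motif_id, provenance)` triples; each
#' `(tf_id, motif_id)` pair appears at most once and provenance is one of
#' `experimental`, `family_transfer`, `ortholog_transfer`.
#'
#' @param df Data frame with columns `tf_id`, `motif_id`, `provenance`.
#' @return The validated map, classed `tf_motif_map`.
#' @export
tf_motif_map <- function(df = data.frame(tf_id = character(),
                                         motif_id = character(),
                                         provenance = character(),
                                         stringsAsFactors = FALSE)) {
  need <- c("tf_id", "motif_id", "provenance")
  if (!all(need %in% names(df))) {
    stop("TF map must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need, drop = FALSE]
  ok <- df$provenance %in% c("experimental", "family_transfer",
                             "ortholog_transfer")
  if (!all(ok)) stop("invalid provenance: ", df$provenance[!ok][1])
  df <- df[!duplicated(df), , drop = FALSE]
  key <- paste(df$tf_id, df$motif_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(tf_id, motif_id) pair with conflicting provenance: ",
         sub("\r", "/", key[duplicated(key)][1]))
  }
  rownames(df) <- NULL
  class(df) <- c("tf_motif_map", "data.frame")
  df
}

#' Convert a PWM to a degenerate IUPAC motif
#'
#' At each position, the set of bases whose probability is at least
#' `inclusion_threshold` (default 0.10; bases below the threshold are not
#' recorded) is mapped to the unique IUPAC code with that identity set;
#' all four bases passing yields `N`.
#'
#' @param pwm A [pwm] object.
#' @param inclusion_threshold Minimum per-base probability for a base to
#'   be recorded, in `(0, 1)`.
#' @return An [iupac_motif] with `source = "pwm"`.
#' @export
#' @examples
#' p <- pwm("m1", rbind(c(0.45, 0.05, 0.45, 0.05), c(0, 0, 0, 1)))
#' pwm_to_iupac(p)$pattern  # "RT"
pwm_to_iupac <- function(pwm, inclusion_threshold = 0.10) {
  stopifnot(inherits(pwm, "pwm"),
            inclusion_threshold > 0, inclusion_threshold < 1)
  bases <- colnames(pwm$probs)
  codes <- vapply(seq_len(nrow(pwm$probs)), function(i) {
    S <- bases[pwm$probs[i, ] >= inclusion_threshold]
    if (!length(S)) {
      stop("no base reaches threshold at position ", i, " of motif ",
           pwm$motif_id)
    }
    iupac_code_for_bases(S)
  }, character(1))
  iupac_motif(pwm$motif_id, paste(codes, collapse = ""), source = "pwm")
}

#' Probability of a motif match at a single promoter position by chance
#'
#' Under an i.i.d. background base model, the chance that a fixed locus
#' (one start position, one strand) matches the motif is the product over
#' positions of the total background probability of the bases each
#' position accepts.
#'
#' @param motif An [iupac_motif].
#' @param background Length-4 probability vector (A, C, G, T), summing
#'   to 1; default uniform.
#' @return A probability in `(0, 1]`.
#' @export
#' @examples
#' per_locus_probability(iupac_motif("m", "RY"))  # 0.25
per_locus_probability <- function(motif, background = rep(0.25, 4)) {
  stopifnot(inherits(motif, "iupac_motif"), length(background) == 4,
            abs(sum(background) - 1) < 1e-6, all(background >= 0))
  names(background) <- c("A", "C", "G", "T")
  chars <- strsplit(motif$pattern, "", fixed = TRUE)[[1]]
  prod(vapply(chars, function(ch) sum(background[IUPAC_SETS[[ch]]]),
              numeric(1)))
}

#' Remove non-informative motifs
#'
#' A motif is non-informative when it lacks sequence specificity, i.e. its
#' chance of matching any individual promoter locus reaches
#' `chance_threshold` (default 0.02).  Motifs with
#' `per_locus_probability >= chance_threshold` are removed.
#'
#' @param motifs List of [iupac_motif] objects.
#' @param chance_threshold Removal threshold in `(0, 1)`.
#' @param background Background base probabilities passed to
#'   [per_locus_probability()].
#' @return List with components `retained` and `removed`, each preserving
#'   input order.
#' @export
filter_non_informative <- function(motifs, chance_threshold = 0.02,
                                   background = rep(0.25, 4)) {
  stopifnot(chance_threshold > 0, chance_threshold < 1)
  p <- vapply(motifs, per_locus_probability, numeric(1),
              background = background)
  list(retained = motifs[p < chance_threshold],
       removed = motifs[p >= chance_threshold])
}

#' Merge motifs with identical patterns
#'
#' Motifs sharing an identical pattern string are merged into one record
#' that keeps the first motif's id, unions the associated TF ids, and
#' joins the provenance tags.  Output order is first-occurrence order.
#'
#' @param motifs List of [iupac_motif] objects.
#' @return Deduplicated list of [iupac_motif] objects.
#' @export
dedupe_motifs <- function(motifs) {
  out <- list()
  idx <- integer()  # position of each pattern in `out`
  patterns <- character()
  for (m in motifs) {
    j <- match(m$pattern, patterns)
    if (is.na(j)) {
      patterns <- c(patterns, m$pattern)
      out[[length(out) + 1L]] <- m
    } else {
      kept <- out[[j]]
      kept$tf_ids <- unique(c(kept$tf_ids, m$tf_ids))
      kept$source <- paste(unique(c(strsplit(kept$source, ";")[[1]],
                                    strsplit(m$source, ";")[[1]])),
                           collapse = ";")
      out[[j]] <- kept
    }
  }
  out
}

#' Transfer motifs to uncharacterized TFs within phylogenetic clusters
#'
#' Every TF in `tf_universe` that has no experimental motif but shares a
#' cluster with at least one experimentally characterized TF receives the
#' union of that cluster's experimental motifs, tagged
#' `family_transfer`.  Experimental entries are never modified; TFs
#' without a cluster assignment are left unchanged (and logged).
#'
#' @param map A [tf_motif_map].
#' @param families Named character vector: TF id -> cluster id.
#' @param tf_universe Character vector of all TF ids under consideration;
#'   defaults to the union of the map's TFs and the family table's TFs.
#' @return The augmented [tf_motif_map].
#' @export
transfer_by_family <- function(map, families,
                               tf_universe = union(map$tf_id, names(families))) {
  map <- tf_motif_map(as.data.frame(map))
  if (!all(map$tf_id %in% tf_universe)) {
    stop("TF in map missing from tf_universe")
  }
  exper <- map[map$provenance == "experimental", , drop = FALSE]
  tfs_with_exp <- unique(exper$tf_id)
  candidates <- setdiff(tf_universe, tfs_with_exp)
  new_rows <- list()
  unassigned <- character()
  for (tf in candidates) {
    cl <- if (tf %in% names(families)) families[[tf]] else NA_character_
    if (is.na(cl)) {
      unassigned <- c(unassigned, tf)
      next
    }
    donors <- intersect(names(families)[families == cl], tfs_with_exp)
    if (!length(donors)) next
    motifs <- sort(unique(exper$motif_id[exper$tf_id %in% donors]))
    # never overwrite an existing pair, whatever its provenance
    have <- map$motif_id[map$tf_id == tf]
    motifs <- setdiff(motifs, have)
    if (length(motifs)) {
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        tf_id = tf, motif_id = motifs, provenance = "family_transfer",
        stringsAsFactors = FALSE)
    }
  }
  if (length(unassigned)) {
    message(length(unassigned), " TF(s) without cluster assignment left unchanged")
  }
  if (length(new_rows)) {
    add <- do.call(rbind, new_rows)
    add <- add[order(add$tf_id, add$motif_id), , drop = FALSE]
    map <- tf_motif_map(rbind(as.data.frame(map), add))
  }
  map
}

#' Transfer motifs across species via orthology
#'
#' Each target TF receives all motifs of its source orthologs, tagged
#' `ortholog_transfer`; many-to-many ortholog relations union their
#' motif sets.
#'
#' @param source_map [tf_motif_map] for the source species.
#' @param orthologs Data frame with columns `source_tf`, `target_tf`.
#' @return A [tf_motif_map] for the target TFs only.
#' @export
transfer_by_orthology <- function(source_map, orthologs) {
  source_map <- tf_motif_map(as.data.frame(source_map))
  if (!nrow(orthologs)) return(tf_motif_map())
  merged <- merge(as.data.frame(source_map), orthologs,
                  by.x = "tf_id", by.y = "source_tf")
  if (!nrow(merged)) return(tf_motif_map())
  out <- unique(data.frame(tf_id = merged$target_tf,
                           motif_id = merged$motif_id,
                           provenance = "ortholog_transfer",
                           stringsAsFactors = FALSE))
  out <- out[order(out$tf_id, out$motif_id), , drop = FALSE]
  tf_motif_map(out)
}
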