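# Independent oracles, coded from first principles and kept free of the
# package's own lookup tables and scanner.

# Degenerate nucleotide code table, written out literally: identity set
# (sorted, collapsed) -> code.
ORACLE_CODE_FOR_SET <- c(
  A = "A", C = "C", G = "G", T = "T",
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
  CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")

oracle_revcomp <- function(pattern) {
  paste(rev(unname(ORACLE_COMP[strsplit(pattern, "")[[1]]])), collapse = "")
}

# Naive O(n*w) sliding-window matcher; a sequence 'N' matches only a
# pattern 'N'.
naive_matches <- function(pattern, seq, both = TRUE) {
  seq_chars <- strsplit(seq, "")[[1]]
  n <- length(seq_chars)
  pats <- list(`+` = pattern)
  if (both) pats[["-"]] <- oracle_revcomp(pattern)
  rows <- list()
  for (st in names(pats)) {
    pc <- strsplit(pats[[st]], "")[[1]]
    w <- length(pc)
    if (w > n) next
    for (o in 0:(n - w)) {
      hit <- TRUE
      for (i in seq_len(w)) {
        sc <- seq_chars[o + i]
        ok <- if (sc == "N") pc[i] == "N" else sc %in% ORACLE_SETS[[pc[i]]]
        if (!ok) { hit <- FALSE; break }
      }
      if (hit) rows[[length(rows) + 1L]] <- data.frame(
        offset = o, strand = st, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(offset = integer(),
                                                strand = character(),
                                                stringsAsFactors = FALSE))))
  out[order(out$offset, out$strand), , drop = FALSE]
}

# Brute-force upper-tail hypergeometric probability by direct summation
# of binomial-coefficient terms.
brute_upper_tail <- function(a, b, c, d) {
  ks <- seq(a, min(b, c))
  sum(exp(lchoose(b, ks) + lchoose(d - b, c - ks) - lchoose(d, c)))
}

random_iupac_pattern <- function(len, codes = names(ORACLE_SETS)) {
  paste(sample(codes, len, replace = TRUE), collapse = "")
}

random_dna <- function(len, with_n = FALSE) {
  ab <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(ab, len, replace = TRUE), collapse = "")
}

# Small fixture shared by several test files.
small_planted_spec <- function(seed = 11) {
  fixture_spec(seed = seed, n_genes = 80, n_query = 16, promoter_len = 250,
               planted = list(planted_signal("TTGACY", "GO:2000001",
                                             query_frac = 0.8,
                                             background_frac = 0.05,
                                             n_tfs = 2)),
               n_decoy_motifs = 4, n_decoy_terms = 6,
               decoy_term_range = c(15, 40))
}

# Write a MEME minimal-format file for the given named probability
# matrices (rows = positions, columns A C G T).
write_meme_file <- function(motifs, path) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "")
  for (nm in names(motifs)) {
    m <- motifs[[nm]]
    lines <- c(lines, paste("MOTIF", nm),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(m)),
               apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  path
}
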