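# Degenerate IUPAC nucleotide alphabet and small shared helpers.

#' @importFrom stats setNames p.adjust phyper
#' @importFrom utils read.delim write.table
NULL

# Identity set of each IUPAC code (15 codes: 4 bases + 11 degenerate).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

# Reverse lookup: sorted base set (collapsed string) -> code, e.g. "AG" -> "R".
IUPAC_CODE_FOR_SET <- local({
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), character(1))
  setNames(names(keys), keys)
})

iupac_code_for_bases <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  if (!key %in% names(IUPAC_CODE_FOR_SET)) {
    stop("no IUPAC code for base set {", key, "}")
  }
  unname(IUPAC_CODE_FOR_SET[key])
}

# Complement preserves degeneracy: R(A/G) -> Y(T/C), B -> V, etc.
complement_iupac <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
}

#' Reverse complement of a degenerate IUPAC pattern
#'
#' @param x Character vector of IUPAC patterns.
#' @return Character vector of reverse-complemented patterns.
#' @export
#' @examples
#' revcomp_iupac("TTGACY")  # "RGTCAA"
revcomp_iupac <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complement_iupac(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Plain-DNA reverse complement (A/C/G/T/N sequences).
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Promoter/genome sequences are restricted to this alphabet after cleanup.
SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

encode_seq <- function(s) {
  codes <- match(strsplit(s, "", fixed = TRUE)[[1]], SEQ_ALPHABET)
  if (anyNA(codes)) stop("sequence contains characters outside {A,C,G,T,N}")
  codes
}

# Per-position allowance vectors over SEQ_ALPHABET for a motif pattern.
# A genomic 'N' satisfies only a motif 'N' position (conservative rule).
motif_allowance <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (!length(chars)) stop("empty motif pattern")
  if (!all(chars %in% IUPAC_CODES)) {
    stop("motif pattern contains non-IUPAC characters: ", pattern)
  }
  lapply(chars, function(ch) {
    c(SEQ_ALPHABET[1:4] %in% IUPAC_SETS[[ch]], ch == "N")
  })
}

# p-values serialize in scientific notation, 6 significant digits; missing as "".
format_pvalue <- function(p) {
  out <- ifelse(is.na(p), "", formatC(p, format = "e", digits = 5))
  as.character(out)
}

# Run code under a fixed RNG state without touching the caller's stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
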