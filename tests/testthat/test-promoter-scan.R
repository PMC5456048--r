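# Promoter extraction, IUPAC consensus matching and the motif index.

make_contig <- function(len, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

test_that("promoters cover the 1 kb upstream window with strand-aware orientation", {
  contig <- make_contig(7000)
  genes <- data.frame(gene_id = c("P1", "P2", "M1"), contig = "c1",
                      strand = c("+", "+", "-"), tss = c(5001L, 300L, 5000L))
  prom <- extract_promoters(genes, c(c1 = contig), window = 1000)
  # '+' tss=5001: 1-based 4001..5000, forward
  p1 <- prom[prom$gene_id == "P1", ]
  expect_identical(c(p1$start, p1$end), c(4000L, 5000L))
  expect_identical(p1$sequence, substr(contig, 4001, 5000))
  expect_identical(nchar(p1$sequence), 1000L)
  # '+' tss=300: clipped to 1..299
  p2 <- prom[prom$gene_id == "P2", ]
  expect_identical(c(p2$start, p2$end), c(0L, 299L))
  expect_identical(nchar(p2$sequence), 299L)
  # '-' tss=5000: 5001..6000 reverse-complemented
  m1 <- prom[prom$gene_id == "M1", ]
  expect_identical(c(m1$start, m1$end), c(5000L, 6000L))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 5001, 6000))))
  expect_identical(m1$sequence, rc)
})

test_that("boundary genes drop with a warning and out-of-bounds TSS errors", {
  contig <- make_contig(2000)
  genes <- data.frame(gene_id = c("E1", "OK"), contig = "c1",
                      strand = c("+", "+"), tss = c(1L, 500L))
  expect_warning(prom <- extract_promoters(genes, c(c1 = contig)),
                 "empty promoter")
  expect_identical(prom$gene_id, "OK")
  bad <- data.frame(gene_id = "B1", contig = "c1", strand = "+", tss = 4000L)
  expect_error(extract_promoters(bad, c(c1 = contig)),
               "tss outside contig bounds for gene B1")
})

test_that("ambiguous genome characters become N in promoter sequences", {
  genes <- data.frame(gene_id = "G1", contig = "c1", strand = "+", tss = 9L)
  prom <- extract_promoters(genes, c(c1 = "acgtRyWnACGT"), window = 8)
  expect_identical(prom$sequence, "ACGTNNNN")
})

test_that("consensus matching finds the worked examples", {
  m <- find_matches(iupac_motif("m", "TTGACY"), list(sequence = "AATTGACT"))
  expect_identical(m$offset, 2L)
  expect_identical(m$strand, "+")
  m2 <- find_matches(iupac_motif("m", "RY"), list(sequence = "AAGT"))
  expect_identical(unique(m2$offset), 2L)
  expect_true("+" %in% m2$strand)
  # motif longer than the sequence: no matches
  m3 <- find_matches(iupac_motif("m", "ACGTACGT"), list(sequence = "ACG"))
  expect_identical(nrow(m3), 0L)
})

test_that("a genomic N satisfies only a motif N position", {
  hits <- find_matches(iupac_motif("m", "ANT"), list(sequence = "ANTANT"),
                       strand_policy = "given")
  expect_identical(hits$offset, c(0L, 3L))
  none <- find_matches(iupac_motif("m", "AAT"), list(sequence = "ANT"),
                       strand_policy = "given")
  expect_identical(nrow(none), 0L)
  # motif N still matches a real base
  real <- find_matches(iupac_motif("m", "ANT"), list(sequence = "ACT"),
                       strand_policy = "given")
  expect_identical(real$offset, 0L)
})

test_that("matching agrees with the naive sliding-window oracle on random inputs", {
  set.seed(101)
  for (i in 1:80) {
    pat <- random_iupac_pattern(sample(2:7, 1))
    seq <- random_dna(sample(15:50, 1), with_n = (i %% 4 == 0))
    got <- find_matches(iupac_motif("m", pat), list(sequence = seq))
    want <- naive_matches(pat, seq, both = TRUE)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("both-strand matching is the union of forward scans of motif and its reverse complement", {
  set.seed(55)
  for (i in 1:30) {
    pat <- random_iupac_pattern(sample(2:6, 1))
    seq <- random_dna(40)
    both <- find_matches(iupac_motif("m", pat), list(sequence = seq))
    fwd <- find_matches(iupac_motif("m", pat), list(sequence = seq), "given")
    rev <- find_matches(iupac_motif("m", oracle_revcomp(pat)),
                        list(sequence = seq), "given")
    expect_setequal(both$offset[both$strand == "+"], fwd$offset)
    expect_setequal(both$offset[both$strand == "-"], rev$offset)
  }
})

test_that("shrinking a motif position's identity set never gains matches", {
  set.seed(77)
  for (i in 1:30) {
    pat <- random_iupac_pattern(sample(2:5, 1))
    chars <- strsplit(pat, "")[[1]]
    j <- sample(length(chars), 1)
    chars[j] <- sample(ORACLE_SETS[[chars[j]]], 1)
    shrunk <- paste(chars, collapse = "")
    seq <- random_dna(60)
    big <- find_matches(iupac_motif("m", pat), list(sequence = seq))
    small <- find_matches(iupac_motif("m", shrunk), list(sequence = seq))
    key <- function(df) paste(df$offset, df$strand)
    expect_true(all(key(small) %in% key(big)))
  }
})

test_that("the motif index records gene-level presence over the promoter universe", {
  prom <- data.frame(gene_id = sprintf("G%02d", 1:10), contig = "c1",
                     strand = "+", start = 0L, end = 20L,
                     sequence = replicate(10, random_dna(20)),
                     stringsAsFactors = FALSE)
  set.seed(3)
  # plant a verbatim motif in 3 promoters; pattern avoids chance hits
  planted <- c(1, 4, 9)
  for (i in planted) {
    s <- prom$sequence[i]
    substr(s, 5, 12) <- "TTGACTTG"
    prom$sequence[i] <- s
  }
  idx <- build_motif_index(list(iupac_motif("w", "TTGACTTG"),
                                iupac_motif("n", "N")), prom)
  expect_setequal(idx$motif_to_genes[["w"]], prom$gene_id[planted])
  expect_identical(idx$motif_to_genes[["n"]], prom$gene_id)  # width-1 N matches all
  expect_identical(idx$universe, prom$gene_id)

  empty <- build_motif_index(list(), prom)
  expect_length(empty$motif_to_genes, 0)
  expect_identical(empty$universe, prom$gene_id)
})

test_that("index gene sets are invariant to promoter order and reject duplicates", {
  set.seed(9)
  prom <- data.frame(gene_id = sprintf("G%02d", 1:8), contig = "c1",
                     strand = "+", start = 0L, end = 30L,
                     sequence = replicate(8, random_dna(30)),
                     stringsAsFactors = FALSE)
  motifs <- list(iupac_motif("m1", "RYS"), iupac_motif("m2", "TGA"))
  idx1 <- build_motif_index(motifs, prom)
  idx2 <- build_motif_index(motifs, prom[sample(8), ])
  for (m in names(idx1$motif_to_genes)) {
    expect_setequal(idx1$motif_to_genes[[m]], idx2$motif_to_genes[[m]])
  }
  expect_error(build_motif_index(motifs, prom[c(1, 1, 2), ]),
               "duplicate promoter")
})
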