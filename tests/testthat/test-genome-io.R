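# Readers, writers and their parsing dialects.

test_that("query lists are uppercased, deduplicated and filtered against the annotation", {
  f <- withr::local_tempfile(lines = c("AT1G01010", "", "# a comment",
                                       "at1g01010", "AT1G01020", "FAKE01"))
  q <- suppressWarnings(read_query_list(f, c("AT1G01010", "AT1G01020")))
  expect_identical(q$gene_ids, c("AT1G01010", "AT1G01020"))
  expect_identical(q$dropped_ids, "FAKE01")
  expect_warning(read_query_list(f, c("AT1G01010", "AT1G01020")),
                 "not found in annotation")
})

test_that("a query list with only comments or only unknown ids is an error", {
  f <- withr::local_tempfile(lines = c("# comment", "", "#x"))
  expect_error(read_query_list(f, "AT1G01010"), "empty query list")
  f2 <- withr::local_tempfile(lines = c("FAKE01", "FAKE02"))
  expect_error(suppressWarnings(read_query_list(f2, "AT1G01010")),
               "empty query list")
})

test_that("majority-unknown queries escalate but continue", {
  f <- withr::local_tempfile(lines = c("AT1G01010", "FAKE01", "FAKE02"))
  w <- capture_warnings(q <- read_query_list(f, "AT1G01010"))
  expect_true(any(grepl("50%", w)))
  expect_identical(q$gene_ids, "AT1G01010")
})

test_that("TSV annotation parses, validates strand and rejects duplicates", {
  f <- withr::local_tempfile(lines = c("G1\tc1\t+\t5001", "G2\tc1\t-\t800"))
  ann <- read_annotation(f, "tsv")
  expect_identical(ann$gene_id, c("G1", "G2"))
  expect_identical(ann$tss, c(5001L, 800L))

  bad <- withr::local_tempfile(lines = c("G1\tc1\t+\t5001", "G2\tc1\t*\t10"))
  expect_error(read_annotation(bad, "tsv"), "unknown strand symbol '\\*' at line 2")
  mal <- withr::local_tempfile(lines = c("G1\tc1\t+"))
  expect_error(read_annotation(mal, "tsv"), "line 1")
  dup <- withr::local_tempfile(lines = c("G1\tc1\t+\t10", "G1\tc1\t+\t20"))
  expect_error(read_annotation(dup, "tsv"), "duplicate gene id")
})

test_that("GFF3 genes use start as TSS on + and end on -", {
  f <- withr::local_tempfile(lines = c(
    "##gff-version 3",
    "c1\tsrc\tgene\t100\t900\t.\t-\t.\tID=gene:GM1",
    "c1\tsrc\tgene\t2000\t2500\t.\t+\t.\tID=GP1",
    "c1\tsrc\tmRNA\t2000\t2500\t.\t+\t.\tID=GP1.1;Parent=GP1"))
  ann <- read_annotation(f, "gff3")
  expect_setequal(ann$gene_id, c("GM1", "GP1"))
  expect_identical(ann$tss[ann$gene_id == "GM1"], 900L)
  expect_identical(ann$tss[ann$gene_id == "GP1"], 2000L)
})

test_that("MEME minimal files parse into normalized PWMs in file order", {
  f <- write_meme_file(list(
    m1 = rbind(c(0.25, 0.25, 0.25, 0.25), c(0.994, 0.002, 0.002, 0.002),
               c(0.5, 0.5, 0, 0)),
    m2 = rbind(c(0, 0, 0, 1), c(1, 0, 0, 0))), tempfile(fileext = ".meme"))
  on.exit(unlink(f))
  pwms <- read_meme_motifs(f)
  expect_length(pwms, 2)
  expect_identical(vapply(pwms, `[[`, character(1), "motif_id"),
                   c("m1", "m2"))
  expect_equal(nrow(pwms[[1]]$probs), 3)
  expect_true(all(abs(rowSums(pwms[[1]]$probs) - 1) < 1e-6))
})

test_that("MEME validation rejects bad row sums, width mismatch and non-ACGT alphabets", {
  f <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "ALPHABET= ACGT", "MOTIF bad",
               "letter-probability matrix: alength= 4 w= 1",
               "0.5 0.5 0.5 0.5"), f)
  expect_error(read_meme_motifs(f), "outside \\[0.99, 1.01\\]")
  writeLines(c("MEME version 4", "ALPHABET= ACGT", "MOTIF short",
               "letter-probability matrix: alength= 4 w= 3",
               "0.25 0.25 0.25 0.25"), f)
  expect_error(read_meme_motifs(f), "width mismatch")
  writeLines(c("MEME version 4", "ALPHABET= ACGU", "MOTIF rna",
               "letter-probability matrix: alength= 4 w= 1",
               "1 0 0 0"), f)
  expect_error(read_meme_motifs(f), "unsupported alphabet")
  unlink(f)
})

test_that("enrichment reports: summary holds exactly the rows with p < alpha, strictly", {
  res <- data.frame(item_id = c("i1", "i2", "i3"),
                    item_label = c("l1", "l2", "l3"),
                    a = 1:3, b = 2:4, c = 5L, d = 50L,
                    p_value = c(5e-4, 1e-3, 5e-3),
                    q_value = c(1.5e-3, 1.5e-3, 5e-3),
                    significant = c(TRUE, FALSE, FALSE))
  fp <- tempfile(); fs <- tempfile()
  write_enrichment_report(res, fp, fs, alpha = 0.001)
  full <- read.delim(fp)
  summ <- read.delim(fs)
  expect_identical(nrow(full), 3L)
  expect_identical(nrow(summ), 1L)            # p == 0.001 excluded
  expect_identical(summ$item_id, "i1")
  # summary rows are exactly the full rows below alpha
  expect_equal(summ, full[full$p_value < 0.001, ], ignore_attr = TRUE)
  unlink(c(fp, fs))
})

test_that("empty enrichment results produce header-only reports", {
  res <- data.frame(item_id = character(), item_label = character(),
                    a = integer(), b = integer(), c = integer(),
                    d = integer(), p_value = numeric(), q_value = numeric(),
                    significant = logical())
  fp <- tempfile(); fs <- tempfile()
  write_enrichment_report(res, fp, fs)
  expect_identical(readLines(fp),
                   "item_id\titem_label\ta\tb\tc\td\tp_value\tq_value")
  expect_identical(readLines(fp), readLines(fs))
  unlink(c(fp, fs))
})

test_that("network files serialize edges with empty p for TF-motif and cover all nodes once", {
  nodes <- data.frame(node = c("TF1", "motifM", "pat", "GO:1"),
                      type = c("TF", "motif", "pattern", "GO term"))
  edges <- data.frame(source = c("TF1", "motifM", "pat"),
                      edge_type = c("TF-motif", "motif-pattern", "pattern-GOterm"),
                      target = c("motifM", "pat", "GO:1"),
                      p_value = c(NA, 1e-5, 2e-4))
  net <- tf_network(nodes, edges)
  prefix <- tempfile()
  paths <- write_network_files(net, tf_network(), prefix)
  lines <- readLines(paths[1])
  expect_true("TF1\tTF-motif\tmotifM\t" %in% lines)
  expect_true(any(grepl("^motifM\tmotif-pattern\tpat\t1\\.00000e-05$", lines)))
  attrs <- read.delim(paths[3])
  expect_setequal(attrs$node, nodes$node)
  expect_identical(anyDuplicated(attrs$node), 0L)
  expect_setequal(unique(attrs$type), c("pattern", "GO term", "motif", "TF"))
  unlink(paths)
})

test_that("empty networks give three header-only files", {
  prefix <- tempfile()
  paths <- write_network_files(tf_network(), tf_network(), prefix)
  expect_identical(readLines(paths[1]), "source\tedge_type\ttarget\tp_value")
  expect_identical(readLines(paths[2]), "source\tedge_type\ttarget\tp_value")
  expect_identical(readLines(paths[3]), "node\ttype")
  unlink(paths)
})

test_that("motif, TF-map, GO, annotation and query tables round-trip exactly", {
  motifs <- list(iupac_motif("M1", "TTGACY", "dbA", c("T1", "T2")),
                 iupac_motif("M2", "CACGTG", "dbB", character()))
  f <- tempfile()
  write_motif_table(motifs, f)
  back <- read_motif_table(f)
  expect_equal(back, motifs)

  map <- tf_motif_map(data.frame(tf_id = c("T1", "T2"),
                                 motif_id = c("M1", "M1"),
                                 provenance = c("experimental", "family_transfer")))
  write_tf_map(map, f)
  expect_equal(as.data.frame(read_tf_map(f)), as.data.frame(map))

  ann <- data.frame(gene_id = c("G1", "G2"), contig = "c1",
                    strand = c("+", "-"), tss = c(100L, 900L))
  write_annotation_tsv(ann, f)
  expect_equal(read_annotation(f, "tsv"), ann)

  go <- go_annotation(list(G1 = c("GO:1", "GO:2"), G2 = "GO:1"),
                      c("GO:1" = "proc one", "GO:2" = "proc two"))
  write_go_table(go, f)
  back_go <- read_go_table(f)
  expect_equal(back_go$gene_to_terms, go$gene_to_terms)
  expect_equal(sort(back_go$term_names), sort(go$term_names))

  q <- query_list(c("G2", "G1"))
  write_query_list(q, f)
  expect_identical(read_query_list(f, c("G1", "G2"))$gene_ids, c("G2", "G1"))
  unlink(f)
})
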