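# PWM -> IUPAC conversion, informativeness filtering, deduplication and
# TF-motif transfer.

test_that("pwm_to_iupac records bases at or above the inclusion threshold", {
  p <- pwm("m", rbind(c(0.45, 0.05, 0.45, 0.05),   # A/G -> R
                      c(0.09, 0.09, 0.09, 0.73),   # T
                      c(0.25, 0.25, 0.25, 0.25),   # all four -> N
                      c(1, 0, 0, 0),               # A
                      c(0, 0, 0, 1)))              # T
  expect_identical(pwm_to_iupac(p)$pattern, "RTNAT")
})

test_that("the 0.10 inclusion boundary itself is included", {
  p <- pwm("m", rbind(c(0.10, 0.05, 0.05, 0.80),
                      c(0.0999, 0.0501, 0.05, 0.80)))
  expect_identical(pwm_to_iupac(p)$pattern, "WT")
})

test_that("a column where no base reaches the threshold is an error", {
  p <- pwm("m", matrix(0.25, 1, 4))
  expect_error(pwm_to_iupac(p, inclusion_threshold = 0.3),
               "no base reaches threshold")
})

test_that("conversion agrees with an independent code table over all 15 base subsets", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  subsets <- Filter(length, unlist(lapply(1:4, function(k)
    combn(bases, k, simplify = FALSE)), recursive = FALSE))
  expect_length(subsets, 15)
  for (S in subsets) {
    for (rep in 1:20) {
      # members >= 0.1, non-members < 0.1, column sums to 1
      col <- setNames(numeric(4), bases)
      out <- setdiff(bases, S)
      if (length(out)) col[out] <- runif(length(out), 0, 0.0999)
      rem <- 1 - sum(col)
      shares <- runif(length(S)); shares <- shares / sum(shares)
      col[S] <- 0.1 + (rem - 0.1 * length(S)) * shares
      expect_gte(min(col[S]), 0.1)
      expected <- unname(ORACLE_CODE_FOR_SET[paste(sort(S), collapse = "")])
      got <- pwm_to_iupac(pwm("m", matrix(col, 1, 4)))$pattern
      expect_identical(got, expected)
    }
  }
})

test_that("per-locus chance probability follows the identity-set widths", {
  expect_equal(per_locus_probability(iupac_motif("m", "N")), 1.0)
  expect_equal(per_locus_probability(iupac_motif("m", "ACGT")), 0.00390625)
  expect_equal(per_locus_probability(iupac_motif("m", "RY")), 0.25)
  # non-uniform background
  bg <- c(0.4, 0.1, 0.1, 0.4)
  expect_equal(per_locus_probability(iupac_motif("m", "W"), bg), 0.8)
})

test_that("per-locus probability is multiplicative and monotone under set shrinkage", {
  set.seed(7)
  for (i in 1:25) {
    p1 <- random_iupac_pattern(sample(1:5, 1))
    p2 <- random_iupac_pattern(sample(1:5, 1))
    expect_equal(per_locus_probability(iupac_motif("a", paste0(p1, p2))),
                 per_locus_probability(iupac_motif("b", p1)) *
                   per_locus_probability(iupac_motif("c", p2)))
    # shrinking one position's identity set never increases the probability
    chars <- strsplit(p1, "")[[1]]
    j <- sample(length(chars), 1)
    sub <- sample(ORACLE_SETS[[chars[j]]], 1)  # single base subset
    chars[j] <- sub
    expect_lte(per_locus_probability(iupac_motif("d", paste(chars, collapse = ""))),
               per_locus_probability(iupac_motif("b", p1)))
  }
})

test_that("non-informative motifs (chance >= threshold) are removed, order preserved", {
  ms <- list(iupac_motif("m1", "NNWN"),     # p = 0.5    -> removed
             iupac_motif("m2", "TTGACY"),   # p = 4.88e-4 -> retained
             iupac_motif("m3", "SSS"),      # p = 0.125  -> removed
             iupac_motif("m4", "ACGTA"))    # p = 9.77e-4 -> retained
  out <- filter_non_informative(ms)
  expect_identical(vapply(out$retained, `[[`, "", "motif_id"), c("m2", "m4"))
  expect_identical(vapply(out$removed, `[[`, "", "motif_id"), c("m1", "m3"))
  expect_identical(filter_non_informative(list()),
                   list(retained = list(), removed = list()))
})

test_that("lowering the chance threshold never rescues a removed motif", {
  set.seed(13)
  ms <- lapply(1:30, function(i)
    iupac_motif(paste0("m", i), random_iupac_pattern(sample(2:6, 1))))
  thresholds <- c(0.5, 0.1, 0.02, 0.004)
  removed_prev <- character()
  for (t in thresholds) {
    out <- filter_non_informative(ms, chance_threshold = t)
    removed_now <- vapply(out$removed, `[[`, "", "motif_id")
    expect_true(all(removed_prev %in% removed_now))
    expect_length(c(out$retained, out$removed), length(ms))
    removed_prev <- removed_now
  }
})

test_that("identical patterns merge keeping first id and uniting TFs", {
  ms <- list(iupac_motif("a", "CACGTG", "db1", "T1"),
             iupac_motif("b", "CACGTC", "db1", "T9"),
             iupac_motif("c", "CACGTG", "db2", "T2"),
             iupac_motif("d", "CACGTG", "db1", "T1"))
  out <- dedupe_motifs(ms)
  expect_length(out, 2)
  expect_identical(out[[1]]$motif_id, "a")
  expect_setequal(out[[1]]$tf_ids, c("T1", "T2"))
  expect_identical(out[[1]]$source, "db1;db2")
  expect_identical(out[[2]]$motif_id, "b")
})

test_that("family transfer fills only TFs without experimental data", {
  map <- tf_motif_map(data.frame(
    tf_id = c("T1", "T3"), motif_id = c("M1", "M2"),
    provenance = "experimental"))
  fams <- c(T1 = "c1", T2 = "c1", T3 = "c1", T4 = "c2", T5 = "c3")
  out <- suppressMessages(
    transfer_by_family(map, fams, tf_universe = c(paste0("T", 1:5), "T6")))
  # T2 (empty, cluster c1) gains the union of c1's experimental motifs
  got <- out[out$tf_id == "T2", ]
  expect_setequal(got$motif_id, c("M1", "M2"))
  expect_true(all(got$provenance == "family_transfer"))
  # experimental entries untouched; characterized TFs gain nothing
  expect_identical(out$motif_id[out$tf_id == "T1"], "M1")
  expect_identical(out$motif_id[out$tf_id == "T3"], "M2")
  # singleton cluster without data, and TF without cluster: unchanged
  expect_false("T4" %in% out$tf_id)
  expect_false("T6" %in% out$tf_id)
})

test_that("family transfer is idempotent", {
  map <- tf_motif_map(data.frame(tf_id = "T1", motif_id = "M1",
                                 provenance = "experimental"))
  fams <- c(T1 = "c1", T2 = "c1", T3 = "c1")
  once <- transfer_by_family(map, fams)
  twice <- transfer_by_family(once, fams)
  expect_equal(as.data.frame(once), as.data.frame(twice))
})

test_that("orthology transfer fans out and unions across sources", {
  src <- tf_motif_map(data.frame(
    tf_id = c("AT1", "AT1", "AT2"), motif_id = c("M1", "M3", "M2"),
    provenance = c("experimental", "family_transfer", "experimental")))
  orth <- data.frame(source_tf = c("AT1", "AT1", "AT2"),
                     target_tf = c("BN1", "BN2", "BN1"))
  out <- transfer_by_orthology(src, orth)
  expect_setequal(out$motif_id[out$tf_id == "BN1"], c("M1", "M2", "M3"))
  expect_setequal(out$motif_id[out$tf_id == "BN2"], c("M1", "M3"))
  expect_true(all(out$provenance == "ortholog_transfer"))
  empty <- transfer_by_orthology(src, data.frame(source_tf = character(),
                                                 target_tf = character()))
  expect_identical(nrow(empty), 0L)
})
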