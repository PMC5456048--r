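---
title: "Methods: promoter enrichment and TF network prediction in cisenrich"
author: "cisenrich authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter enrichment and TF network prediction in cisenrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisenrich)
```

## The model

`cisenrich` treats a co-expressed gene list (the *query*, or *pattern*)
as a draw without replacement from the genome and asks, for each GO term
and each promoter motif, whether the query is enriched for genes
carrying that item. With `a` query carriers, `b` genome carriers, query
size `c` and universe size `d`, the p-value is the exact one-sided upper
tail

$$P(X \ge a), \qquad X \sim \mathrm{Hypergeometric}(d,\, b,\, c),$$

computed with `stats::phyper` (the test suite cross-checks it against
direct summation of binomial-coefficient terms). Only
over-representation is tested; a depleted item is simply not
interesting for network building. No multiple-testing correction enters
the core decision path: items enter summaries and networks at raw
`p < 0.001` (strict), which is deliberately stringent for a raw
threshold. Benjamini–Hochberg q-values are written as an extra report
column so users can judge the survey-wide error rate, but they never
drive the `significant` flag.

Two universes coexist and each result records its own `d`: GO tests run
over all annotated genes, motif tests over all genes that have a
promoter. The two sets usually coincide but can differ when a TSS sits
at a contig edge.

### Promoters and matching

A promoter is the 1 kb immediately upstream of the transcription start
site: 1-based `[max(1, t−w), t−1]` on the `+` strand and `[t+1,
min(L, t+w)]` reverse-complemented on `−`, clipped only by contig
boundaries (neighbouring genes do not truncate; internal coordinates
are 0-based half-open, everything user-facing is 1-based). Motifs are
degenerate IUPAC strings matched as exact consensus — a position
matches when the promoter base is in the code's identity set — on both
strands by default, since TF binding is double-stranded and a database
of IUPAC consensi carries no score model to threshold. Gene-level
presence (≥ 1 match) rather than site counts defines both query and
background, because the hypergeometric draw is over genes. An `N` in
the genome satisfies only a motif `N`: this conservative rule prevents
assembly gaps from inflating the background.

### The subanalysis

For each GO term enriched at `p < alpha`, the motif test is rerun with
the query restricted to the query genes annotated to that term (`c`
shrinks, `a` is recounted; the genome background `b`, `d` is
unchanged). This localises motifs to the biological process they may
regulate and is what gives the second network its motif → GO-term
edges.

### Networks

Two typed graphs are exported as Cytoscape edge tables plus one node
attributes file. The *analysis* network has one pattern node for the
query; each significant motif points at the pattern (edge holds its
p-value), the pattern points at each significant GO term, and each
TF → motif edge (no p-value) connects query-member TFs able to bind a
significant motif. The *subanalysis* network holds motif → GO-term
edges with the per-term p-values plus the corresponding TF → motif
edges. Where the original description leaves open whether whole-list GO
terms attach to the pattern or to motifs, we attach them to the
pattern: whole-list GO enrichment carries no motif pairing, and
motif–term pairing is exactly what the subanalysis defines
statistically. TFs never enter a network unless they are themselves in
the query list; an enriched motif with no bound query TF stays in the
graph so a database gap cannot hide a motif-level discovery.

## Database construction

PWMs (MEME minimal format; rows renormalized when they sum to within
[0.99, 1.01], rejected otherwise) become IUPAC strings by recording, at
each position, the set of bases with probability ≥ 0.10 — the boundary
value is included, i.e. exclusion applies to probabilities strictly
below 0.10 — and mapping that set to its unique code. A column where
all four bases pass yields `N`; with the default threshold ≤ 0.25 an
empty set is impossible, and a higher threshold that empties a column
is an error. Duplicate patterns are merged (first id kept, TF sets
united). A motif is *non-informative* and removed when its chance of
matching one promoter locus — the product over positions of the
background mass of each identity set, under a uniform background by
default — is at least 0.02: `N` contributes factor 1, a two-base code
0.5, a specific base 0.25, so e.g. `TTGACY` survives at
$(1/4)^5 \cdot (1/2) \approx 4.9\times10^{-4}$ while `NNWN` (0.5) is
discarded. The wording that motivated this filter ties the 0.02 number
to motifs *lacking* specificity, so removal is on the
high-chance side; we resolve the direction in favour of the specificity
rationale. The single-locus, single-strand uniform-background chance
model is the simplest one consistent with "occurring at any individual
locus"; a genome-derived background can be supplied where promoter
composition deviates strongly.

Family transfer gives a TF with *zero* experimental motifs the union of
the experimental motifs in its phylogenetic cluster, tagged
`family_transfer`; experimentally characterized TFs are never touched
(how conflicting experimental evidence should be overridden is not
operationalized, so we do not). Orthology transfer fans every source
TF's motifs out to its target-species orthologs (`ortholog_transfer`),
unions across many-to-many relations, and both transfers are idempotent
because `(tf, motif)` pairs are unique with immutable provenance.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| promoter window | 1000 | bp | captures the large majority of plant TF binding sites near the TSS |
| summary / network alpha | 0.001 | raw p | stringent raw threshold used for all summaries and network membership (strict `<`) |
| IUPAC inclusion | 0.10 | probability | balance between overly general and overly exclusive consensus strings; boundary included |
| non-informative chance | 0.02 | probability per locus | removes patterns likely to match by chance at any given position |
| strand policy | both | — | binding is double-stranded; `given` retained for testing |

## The synthetic fixture generator

`make_fixture` builds one contig divided into slots of
`promoter_len + 200` bp, one gene per slot with alternating strands, so
promoters never overlap (overlap would confound counts) and both
orientation code paths are exercised. Sequence is i.i.d. with A/T 0.30
and C/G 0.20 — plant promoters are AT-rich. Planted motifs are inserted
*verbatim* (one concrete instantiation of the degenerate pattern per
carrier, at a uniform random offset), so ground-truth presence is
exact; chance matches elsewhere are not suppressed but recovered by an
independent regular-expression scan in `realized_counts`, which is the
oracle the pipeline's a/b/c/d reports are validated against. Planted GO
terms annotate exactly the query carriers plus 4% of the genome as
noise; a designated subset of query genes is declared TFs bound to the
planted motif, which is what makes the TF → motif → GO-term chain
recoverable. All randomness flows through one seeded Mersenne-Twister
stream that is saved and restored around generation, so bundles are
byte-identical per seed and the caller's RNG is untouched.

Default sizes — 500 genes, 50-gene query, 10 decoy 6-mers, 30 decoy
terms of 50–150 genes — were chosen once, at design time: queries of a
few hundred genes against ~30k-gene genomes scale to ~10% here, and the
decoy widths/sizes keep null counts large enough (`b` in the dozens to
hundreds) that the discreteness of the hypergeometric does not dominate
its null behaviour. On unplanted fixtures the fraction of items below
p = 0.05 runs slightly *under* 5% — the test is discrete and therefore
conservative — which the calibration check allows for.

What the generator does **not** emulate: real base composition beyond
AT-richness, gene-density variation, promoter overlap, the GO DAG
(annotations are flat, as the pipeline consumes them), PWM-sampled
binding-site degeneracy, or linkage between terms. Passing tests
therefore demonstrate correctness of counting, testing and assembly —
not biological performance on real genomes.

## Numerical and degenerate-input choices

* `phyper` supplies the exact tail; reported p-values serialize in
  scientific notation with six significant digits, and absent edge
  p-values serialize as the empty string (never `"NA"`) for Cytoscape
  column-type inference.
* Ties in p are broken lexicographically by item id, and nodes/edges
  are stored sorted, so every output file is deterministic for fixed
  inputs.
* Empty query after comment/blank filtering is an error; unknown
  identifiers are dropped with a warning (escalated when they are the
  majority, since that usually means an annotation mismatch). Query ids
  are uppercased on read — gene identifiers in the target
  nomenclatures are conventionally uppercase.
* A gene whose promoter is fully clipped (TSS at position 1 on `+`) is
  dropped with a warning; a TSS outside its contig is an error naming
  the gene.
* Terms with no annotated gene in the universe, and subanalysis terms
  whose query subset is empty, are omitted rather than reported at
  p = 1.

## Problem sizes used in the checks

The bundled validation runs use 500-gene fixtures for planted-signal
recovery (five seeds; planted motif at query fraction 0.8 vs background
0.05), twenty 500-gene unplanted fixtures for null calibration (~800
null items), an exhaustive sweep of all contingency tables with
`d ≤ 60` against brute-force tail enumeration, 1000 random
motif/sequence pairs against a naive scanner, and randomized
probability columns for all 15 base subsets of the code table.

## Known limitations

* Exact consensus matching cannot rank partial matches; a PWM log-odds
  scanner is out of scope because the curated database is
  consensus-based.
* No GO ancestor propagation: enrichment is only as complete as the
  annotation table supplied.
* Raw-p thresholds at 0.001 control per-item error, not FDR; consult
  the q-value column for large motif databases.
* Promoters ignore upstream neighbouring genes, which can double-count
  intergenic sequence in compact genomes.
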