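# cisenrich

Plant RNA-seq experiments routinely end with a list of co-expressed genes
— a cluster from a time course, or the genes induced in one tissue or
treatment — and the question of *which transcription factors drive them*.
`cisenrich` answers that question the classic way: it tests which Gene
Ontology (GO) terms and which degenerate promoter motifs are
over-represented in the list relative to the whole genome, then joins the
significant motifs to the transcription factors (TFs) *inside the same
list* that are able to bind them, producing a predicted
TF → motif → biological-process network ready for Cytoscape.

It is aimed at bench biologists and bioinformaticians analysing
co-expression clusters in Arabidopsis-like genomes, and at database
curators who need to build the motif/TF tables such an analysis runs on.

## The statistic

Every test is a one-sided (over-representation) exact hypergeometric
test on the a/b/c/d contingency layout:

* `a` — query genes carrying the item (GO term, or ≥ 1 promoter match of
  the motif),
* `b` — genome genes carrying the item,
* `c` — query size, `d` — genome (universe) size,

with p-value `P(X ≥ a)` for `X ~ Hypergeometric(d, b, c)`:

```
P(X ≥ a) = Σ_{k=a}^{min(b,c)}  C(b, k) · C(d − b, c − k) / C(d, c)
```

Promoters are the 1 kb upstream of each annotated transcription start
site; motifs are degenerate IUPAC consensus strings matched exactly on
both strands (gene-level presence, not occurrence counts, feeds the
test). Summaries and networks keep items with raw `p < 0.001`;
Benjamini–Hochberg q-values are reported alongside but do not drive
significance. A *subanalysis* reruns the motif test inside each enriched
GO term (query restricted to that term's query genes, background
unchanged) and is the basis of the second network file.

The database toolkit converts position weight matrices (MEME minimal
format) to IUPAC strings — a base is recorded where its probability is
≥ 0.10 — removes duplicate patterns, discards non-informative motifs
(chance of matching a single promoter locus ≥ 0.02), and extends
TF–motif pairs to uncharacterized TFs via phylogenetic-family clusters
and cross-species orthology.

## Worked example

The package ships a deterministic fixture generator, so a complete run
needs no downloads. Below, a 500-gene toy genome is generated with a
planted signal: the W-box-like motif `TTGACY` is inserted into the
promoters of 80% of a 50-gene query (vs 5% of the background), the GO
term `GO:2000001` annotates exactly those carriers, and two query genes
are declared TFs binding the motif.

```r
library(cisenrich)

spec <- fixture_spec(seed = 42,
  planted = list(planted_signal("TTGACY", "GO:2000001",
                                query_frac = 0.8, background_frac = 0.05,
                                n_tfs = 2)))
b <- make_fixture(spec, "demo")

cfg <- run_config(query = b$paths[["query"]], genome = b$paths[["genome"]],
                  annotation = b$paths[["annotation"]],
                  go_table = b$paths[["go"]],
                  motif_table = b$paths[["motifs"]],
                  tf_map = b$paths[["tf_map"]], out_prefix = "demo/out")
res <- run_analysis(cfg)
#> annotation: 500 genes
#> query: 50 genes (0 dropped)
#> promoters: 500 extracted
#> GO enrichment: 2 of 31 terms significant at p < 0.001
#> motif enrichment: 1 of 11 motifs significant at p < 0.001
#> subanalysis: 2 enriched term(s)
#> wrote 9 output files under demo/out.*

head(res$motif_results, 3)
#>      item_id item_label  a   b  c   d      p_value
#>  PLANTED_M01     TTGACY 49 367 50 500 1.610225e-06
#>         M007     TGACCT 25 203 50 500 1.017930e-01
#>         M010     ATCATT 36 323 50 500 1.592489e-01
```

The planted motif ranks first: 49 of the 50 query promoters carry it
(the 40 planted copies plus chance matches — a 6-mer with one
two-base-degenerate position is common in a 1 kb window, hence
`b = 367`), and the genome-wide imbalance still yields `p ≈ 1.6e-06`.
The planted GO term is recovered at `p ≈ 1.2e-34` (`a = 40` of `b = 60`).
The subanalysis network file contains exactly the planted circuit:

```
source       edge_type      target       p_value
G0069        TF-motif       PLANTED_M01
G0269        TF-motif       PLANTED_M01
PLANTED_M01  motif-GOterm   GO:2000001   2.32209e-06
```

`demo/out.analysis.networks.txt`, `demo/out.subanalysis.networks.txt`
and `demo/out.attributes.txt` import directly into Cytoscape (edge table
+ node attributes); the six `*.tsv` reports hold the full and
`p < 0.001` summary tables for GO terms, motifs and the subanalysis.

A database build from the bundled example PWMs:

```r
build_motif_db(meme_paths = system.file("extdata", "example_motifs.meme",
                                        package = "cisenrich"),
               out_dir = "db")
#> n_pwm_converted: 3
#> n_noninformative_removed: 1   # the low-information PWM converts to NNN
#> n_motifs_final: 2
```

A command-line wrapper with `run`, `build-db` and `make-fixture`
subcommands is installed at
`system.file("scripts", "cisenrich", package = "cisenrich")`.

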