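Package: cisenrich
Title: Promoter Motif and GO Term Enrichment with Transcription Factor
    Network Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies Gene Ontology terms and degenerate IUPAC promoter
    motifs over-represented in a co-expressed gene list relative to a
    genome-wide background using exact hypergeometric tests, and assembles
    the significant transcription factors, motifs and terms into typed
    networks exportable to Cytoscape.  Promoters are the 1 kb regions
    upstream of annotated transcription start sites.  Includes a motif
    database construction toolkit (position weight matrix to IUPAC
    conversion, informativeness filtering, family- and orthology-based
    transfer of binding sites to uncharacterized transcription factors)
    and a deterministic synthetic fixture generator with planted
    enrichment signal for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
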