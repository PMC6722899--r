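Package: splicesleuth
Title: Noncanonical Splice Junctions and circRNA Back-Splices in Lepidopteran APN Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of noncanonical splicing in
    lepidopteran aminopeptidase N (APN) transcripts. Calls internal-deletion
    (exon-skipping) junctions in linear transcripts and head-to-tail
    back-splice junctions in circular RNA by exact split decomposition
    against a reference, normalizes repeat-induced breakpoint ambiguity,
    annotates short co-directional repeats and GT/AG versus noncanonical
    splice signals, searches flanking windows for reverse-complement
    (complementary) sequence pairs, predicts frame and premature-stop
    consequences of deletion isoforms, and tests whether circular splice
    sites cluster near linear splice sites with a permutation test. Ships
    the published isoform and splice-site tables for Helicoverpa armigera
    HaAPN1/HaAPN3 as validated fixtures and includes a synthetic-data
    generator with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
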