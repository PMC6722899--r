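---
title: "Methods: noncanonical splice junctions and circRNA back-splices in APN genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noncanonical splice junctions and circRNA back-splices in APN genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicesleuth)
```

## The biological problem

Aminopeptidase N (APN) proteins line the midgut brush border of
lepidopteran larvae and serve as receptors for *Bacillus thuringiensis*
Cry toxins. In the cotton bollworm *Helicoverpa armigera*, cloning of the
ten clustered APN cDNAs revealed two unusual phenomena concentrated in
*HaAPN1* and *HaAPN3*: dozens of truncated linear transcripts whose
internal segments are cleanly deleted (exon skipping at non-standard
sites), and families of exonic circular RNAs (circRNAs) whose
head-to-tail (back-splice) junctions fall inside exons. Neither class of
junction uses the canonical GT/AG intron signal. Instead, short
co-directional repeats — direct, same-strand duplications of 4–8 nt
present on both sides of a junction — mark the splice sites, and the
splice sites of the circular isoforms cluster tightly in the same regions
used by the linear deletion isoforms.

This package implements the complete downstream analysis as reusable,
tested code: junction calling by exact split decomposition, repeat and
splice-signal annotation, reverse-complement (complementary) flank
search, frame/premature-stop consequence prediction, a permutation test
formalizing the clustering claim, and a generator of synthetic genes with
known ground truth. The published isoform tables for HaAPN1/HaAPN3 (and
HaAPN4/6/9) ship as validated fixtures.

## Coordinates and conventions

All coordinates are 1-based and inclusive, matching the printed tables.
Analyses run on the coding strand; reverse-strand genes are expected to
be flipped at load time. A junction is a pair (donor, acceptor) where the
**donor is the last retained base** on the 5′ side and the **acceptor is
the first retained base** on the 3′ side. For a linear deletion,
`acceptor = donor + deletion_len + 1`; for a back-splice,
`acceptor < donor` (the read runs off the 3′ end of the circle and
re-enters at its 5′ end).

## Junction calling and repeat-induced ambiguity

A deletion variant must equal a reference prefix plus a reference suffix.
With `p` the longest common prefix and `s` the longest common suffix of
reference and variant, the variant is accepted as a single contiguous
deletion iff `p + s >= nchar(variant)`; the excess `p + s - nchar(variant)`
is the number of alternative breakpoint placements, and it equals the
length of the co-directional repeat spanning the junction. Back-splice
reads are decomposed as `R1 + R2` with both arms matching exactly and the
acceptor at or upstream of the donor; placements reachable by sliding the
junction across a repeat are one junction, while decompositions at
genuinely different loci raise an error rather than being resolved
silently.

**Canonical placement.** Every ambiguous junction is reported once, at
the placement that **maximizes the donor position**. Equivalently: the
retained copy of the junction repeat is the 5′-most copy, and
`repeat_seq` is the reference substring ending at the canonical donor.
The choice is arbitrary in the same way indel normalization conventions
are; what matters is that it is deterministic, applied identically to
linear and circular calls, and recovered bit-for-bit by
`find_codirectional_repeat()`, whose bidirectional extension around any
placement of the junction returns the same repeat string and length
(`ambiguity_len`).

**Anchors.** Both sides of a junction must match the reference exactly
over at least `min_anchor` bases (default 8). The default exceeds the
longest commonly observed junction repeats (4–8 nt), so an anchor can
never be absorbed entirely by a repeat copy; shorter anchors make split
placement statistically unreliable on multi-kilobase genes. Matching is
exact by design: the data this pipeline targets are Sanger-sequenced
clones, not error-prone short reads.

## Splice-signal classification

`classify_splice_signal()` reads the two bases immediately 3′ of the
donor and immediately 5′ of the acceptor on the genomic sequence — the
positions where a canonical intron shows GT and AG. Junctions whose
breakpoints lie inside exons (the dominant case in these APN genes) are
therefore always noncanonical under this rule, which is exactly the
point: the analysis separates spliceosomal GT/AG junctions from the
repeat-guided class. Generated genes from the simulator carry genuine
GT…AG introns, and their annotated exon/intron boundaries classify as
canonical in the test suite.

## Complementary flank search

For each circRNA splice site, a window of `w = 10` nt on each side of the
junction is extracted (20 nt total; donor-style windows end at the donor
base, acceptor-style windows start at the acceptor base). Complementarity
between the two windows of a circle is defined as **exact
reverse-complement substring matching** with a minimum length of 4 nt:
`find_rc_matches()` reports every maximal pair `(m1, m2)` with
`m2 == reverse_complement(m1)`. The published analysis used an RNA-folding
web service; an exhaustive reverse-complement search is deterministic,
reproducible offline, and recovers all eight printed complementary pairs
(4–5 nt) on the packaged windows. It can also find pairs the folding
heuristic did not report (e.g. a 4-nt pair in a window whose printed
entry is blank), so counts from this search are an upper bound on the
folding-based counts. Whether a pair must straddle the junction point is
not constrained; the whole windows are searched.

## Frame and premature-stop consequences

A deletion is frameshifting iff its length is not a multiple of 3.
`scan_orf()` translates from the start codon to the first in-frame stop
and flags the stop as premature when it falls strictly before the codon
index homologous to the wild-type stop (supplied by the caller; for an
in-frame deletion of *d* codons that index is the wild-type stop minus
*d*). When no reference index is available, a stop more than 10 codons
before the end of the reconstructed ORF is flagged — a heuristic,
documented as such. Molecular weights use the conventional average
residue masses plus one water, reported in kDa; the printed wild-type
values (e.g. 112.8 kDa) are fixture data for display since the full
coding sequences are not part of the tables.

The audit across the packaged tables confirms the expected consistency:
all 24 frameshift variant rows are printed with a premature stop, and a
single in-frame row (HaAPN3 V3, 2466 bp deleted) is printed "Yes" — it is
reported as an exception (a junction-generated stop codon or a
transcription error cannot be distinguished without the cDNA sequence).

## Splice-site clustering test

The qualitative claim that circular splice sites sit in the splice-site-
rich regions of the linear variants is formalized as a one-sided
permutation test. The statistic is the mean nearest-neighbor distance
from each circular site to the set of linear sites.
`proximity_permutation_test()` resamples the circular site positions
uniformly over a stated domain (`n_perm` times, default domain = the span
of the observed sites; an exonic-only domain can be supplied when a gene
model is available) and reports the add-one p-value
`(1 + #[null <= obs]) / (n_perm + 1)`, which is never zero and is exactly
calibrated under exchangeability. Because the analyzed tables print
splice positions but not the full gene structure, fixture-based domains
are approximate gene spans; this is flagged in the report object. Under a
uniform null the rejection rate at α = 0.05 sits inside its binomial
confidence band over 500 replicates in the test suite, and all results
are bit-reproducible for a fixed seed (the caller's RNG state is never
disturbed).

qPCR copy-number arithmetic (the 2^−ΔΔCt rule) is provided as an exact
analytic operation; no raw Ct values are published, so the printed mean
copy number is not a recomputation target.

## The synthetic-data generator

`generate_gene()` builds a gene of 14 exons by default (exons 150–300 bp,
introns 80–250 bp with GT…AG ends, uniform base composition with an
optional GC knob) and plants the events the analysis must recover:

* **Linear events** — a repeat of 4–8 nt written at two cDNA loci; the
  variant deletes the intervening segment plus one copy, so the junction
  carries the repeat.
* **Circular events** — a repeat written across the back-splice contexts
  in gDNA, plus (with probability 0.5) a 4–5 nt reverse-complement motif
  pair planted just inside the two circle ends, inside the 10-nt flank
  windows.

The bases immediately outside every planted copy are forced to mismatch
their counterparts. This pins the common-prefix/suffix arithmetic
exactly: each event's ambiguity equals its planted repeat length and the
canonical call equals the recorded truth, making 100% parameter recovery
a meaningful correctness criterion rather than a statistical accident.
Planted loci are kept disjoint with margins and re-drawn on collision
(bounded retries). Junction reads carry arms of 12–18 nt; when an arm
happens to match a second locus by chance (a duplicated k-mer), the read
would not identify its junction uniquely, so the generator grows the arms
in 6-nt steps — the in-silico analogue of discarding non-uniquely-mapping
junction reads. A per-base substitution `error_rate` (default 0,
Sanger-grade) perturbs emitted sequences only, never the reference.

What the simulator does **not** emulate: codon structure or realistic
base composition, expression levels, sequencing quality strings,
fragmentation, or intron-pairing secondary structure. Passing recovery
tests therefore demonstrates the correctness of the string algorithms
under the stated event model, not performance on noisy high-throughput
data.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence properties on inputs up to
60 bp (junction callers) and 25 nt (reverse-complement search) against
brute-force enumeration, parameter recovery on 50 genes × (4 linear + 2
circular) events — 400 calls — and the calibration experiment with 500
replicates of a 99-permutation test; these sizes keep the default suite
in the tens of seconds while exercising every code path. Ties between
equally long candidate substrings are broken by smallest start positions;
ties between non-equivalent back-splice decompositions are errors;
permutation p-values use the add-one correction; degenerate inputs
(empty site lists, out-of-range windows, non-ACGT characters, missing
ATG) raise typed errors rather than silent NA propagation.

## Known limitations

* Donor/acceptor positions in the packaged splice-site tables are carried
  as printed; the underlying genome sequence is not distributed, so those
  positions are not re-derived from alignments here.
* Whether printed positions mean last-retained or first-skipped base is
  not stated in the source tables; this package fixes last-retained /
  first-retained and documents it.
* The complementarity search is exact-match; wobble pairing and
  thermodynamics are out of scope (an external folding tool can be
  layered on top of the window extraction).
* Multi-deletion isoforms are rejected, not decomposed: every analyzed
  isoform shows a single contiguous deletion.
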