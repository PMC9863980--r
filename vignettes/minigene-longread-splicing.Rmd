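---
title: "Methods: minigene splicing assays with long-read amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minigene splicing assays with long-read amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minisplice)
```

# The analysis in one paragraph

A minigene splicing assay couples an exon-trapping vector with a cloned
genomic fragment (exons plus flanking introns), so that splicing of the
insert can be read out from vector-primed transcripts. Sequencing the
RT-PCR amplicon with long reads turns every transcript into a full-length
observation of its exon chain. `minisplice` models the construct in two
coordinate systems (construct positions and HGVS-style coding positions
with intronic offsets), aligns reads to the construct with a splice-aware
anchor-chaining aligner, derives consensus exon coordinates from breakpoint
frequencies, snaps each read to those coordinates, defines isoforms as
equivalence classes of snapped chains, names each isoform by its splicing
events, aggregates events across isoforms, predicts protein consequences
with an NMD heuristic, and converts the wild-type/mutant comparison into
ACMG PS3/BS3 functional evidence and a five-class interpretation.

# The construct model

A `minigene_construct` holds the amplicon reference sequence (transcription
orientation, 1-based inclusive), an ordered exon annotation in three
classes (vector trap exons, constitutive insert exons with coding
coordinates, alternative exons excluded from the canonical chain), a CDS
frame anchor `(construct position, c. position, phase)` and the insert
region. BED input (0-based half-open) is converted once on ingestion;
GFF3 and the internal representation are 1-based inclusive, which minimises
off-by-one risk because HGVS is also 1-based.

Intronic positions use the standard HGVS convention: `c.357+136` is the
136th base of the intron downstream of the exon ending at c.357, and
`c.1033-275` counts upstream of the exon starting at c.1033;
`construct_to_c()` labels an intronic base from the nearer boundary.
Negative-offset positions are normalised against the upstream boundary when
intron-local arithmetic needs a single convention.

One convention deserves emphasis because it differs from the common habit
of labelling a 3'SS by its intronic AG dinucleotide: **the printed position
of a cryptic site is the first (acceptor) or last (donor) included
nucleotide of the pseudoexon**. The inclusive length is therefore
`donor_offset − acceptor_offset + 1`, which is what ties the intron-6 site
pairs (+138, +331), (+235, +331) and (+319, +331) to pseudoexons of 194,
97 and 13 nt. All three pseudoexons share the same cryptic donor, so each
size is set purely by which acceptor is used.

# The synthetic assay

The simulator is first-class code, not a test fixture: it defines the study
conditions under which every downstream claim is evaluated.

* **Isoform mixtures.** Reads are drawn multinomially from declared
  `(label, chain, abundance)` specs. The built-in mixtures use the
  abundances reported for the four deep-intronic variants and the two
  wild-type constructs verbatim where they were printed; isoforms that were
  only summarised in aggregate (sub-threshold annex rows) are completed
  with plausible natural minors so each mixture closes to 100%. For
  example, the c.357+334G>A mixture carries a 2.6% `∆5+PSE13` annex row so
  the PSE13 event total equals its reported 44.4%.
* **Errors.** Substitutions 2%, insertions 2%, deletions 4% per base,
  i.i.d. — a deliberately simple indel-dominated surrogate for nanopore
  behaviour. Internal junction edges are perturbed by rounded Gaussian
  jitter (SD 2 nt), emulating basecalling-induced junction ambiguity.
  Half of the reads are emitted reverse-complemented to force orientation
  handling. Default depth is 5000 reads per sample, mirroring the assay's
  sequencing stop rule.
* **Barcoding.** `attach_barcodes()` ligates a barcode at the 5' end and
  its reverse complement at the 3' end (the native-barcoding layout),
  passing both copies through the same error model.
* **Synthetic constructs.** `pax6_construct_5_7()` and
  `pax6_construct_10_13()` reproduce the coordinate geometry of the two
  assay constructs — exon 6 spanning c.142–c.357 with the natural
  alternative donor after c.156, the 42-nt alternative exon 5a, complete
  introns 6 and 11 carrying the variant reference alleles and cryptic-site
  motifs — but their sequences are generated, not the real locus. Coding
  regions are built from sense codons so the canonical frame is stop-free,
  and every donor/acceptor used by any isoform carries a canonical GT/AG
  with deliberately mismatched adjacent bases, which besides being the
  biological motif removes microhomology at spliced junctions so noiseless
  alignment is exactly invertible.

What the simulator does **not** emulate: signal-level artefacts, realistic
per-base quality values, chimeric reads, PCR amplification bias, or
reverse-transcription template switching. A green test suite therefore
shows the pipeline is correct under multinomial sampling, indel-dominated
noise and junction wobble — not that it is robust to every artefact of a
real flow cell.

# Read processing

`demultiplex()` fuzzy-matches each barcode (and its reverse complement)
inside 60-nt terminal windows using generalised Levenshtein distance
(`utils::adist`, best infix match); a read is assigned iff exactly one
barcode comes within `max_edits` (default 3, i.e. 12.5% of a 24-nt
barcode); ties go to the unassigned bin.

Alignment has two front ends with one output type. `ingest_sam()` accepts
any external spliced aligner's SAM/BAM: CIGAR `N` operations become intron
gaps, `D` operations of at least `intron_min` (default 30 nt) are promoted
to introns, smaller ones are absorbed, clips count into the unaligned
fraction. `chain_align()` is the internal aligner:

1. exact k-mer anchors (default k = 11) between read and construct are
   merged along diagonals into maximal blocks;
2. blocks are chained collinearly to maximise anchored bases, trying both
   orientations;
3. between consecutive blocks, a gap is a junction only when the reference
   advances at least `intron_min` more than the read — co-diagonal "error
   deserts" merge into one block;
4. each junction gap is split between its flanking blocks by a banded,
   indel-tolerant extension score (+1 match, −1 mismatch, −2 indel, lanes
   tracking net ref/read offset), with a small bonus for split points that
   restore a GT donor / AG acceptor;
5. read chunks that neither side wants, spanning an intron-sized gap, are
   placed by (near-)exact search inside the gap — this is how a pseudoexon
   shorter than the anchor length is recovered; k = 11 (rather than a
   longer anchor) was chosen so that a 13-nt pseudoexon can also carry
   anchors of its own;
6. terminal read bases attach at their best-scoring extension with a small
   length bonus, since amplicon reads run to the construct ends.

Reads whose chain covers less than half of the read fail alignment and are
reported in QC, never silently dropped.

# Consensus, snapping and quantification

Junction placement on noisy long reads wobbles by a few nucleotides, both
from simulated jitter and from chance sequence homology near junctions.
The pipeline absorbs this downstream rather than pretending per-read
precision: `detect_breakpoints()` tallies every distinct segment start/end
over all aligned reads, keeps positions supported by at least
`read_threshold` (default 3%) of reads, and collapses candidates within
`collapse_window` (default 21 nt) onto the strongest (modal) position, so
each true junction is represented once; the reported support sums the whole
wobble cluster. `assign_reads()` snaps each edge to the nearest
consensus site of its side within `snap_window` (default ±10 nt), with the
window auto-capped at `floor((d_min − 1)/2)` for the closest same-side site
pair so close sites can never be merged. The ±10/21 pairing was sized
empirically for the default error model, where junction wobble reaches
~8 nt at homology-afflicted junctions; the auto-cap keeps the behaviour
safe for constructs with nearby alternative sites.

`curate_breakpoints()` applies a deterministic edit list (add / remove /
move), the programmatic stand-in for the manual curation step of the assay
workflow. Two situations need it under the default noise model: the
sub-threshold natural partial exons of the exon 10–13 construct, and the
PSE13 acceptor (c.357+319) in the c.357+136G>A sample, where the
pseudoexon rides on a 4.6% isoform and its site support falls below the 3%
threshold. Adding a predicted site is exactly what an analyst does with
the in silico predictions in hand.

`quantify()` defines isoforms as equivalence classes of identical snapped
chains; abundance is `100 × class count / assigned reads` (unassigned reads
are excluded from the denominator, matching the relative-abundance
semantics of the assay figures). `filter_report()` moves rows at or below
the reporting threshold (default 5%) into a minor-isoform annex that stays
available for event aggregation. `qc_depth()` flags samples under 5000
assigned reads, report-only.

# Event annotation and aberrance

`classify_isoform()` diffs a chain against the canonical annotation into
the field's taxonomy — exon skip (`∆5`), partial exon (`∆'6`), alternative
exon (`5a`), pseudoexon (`PSE13`), elongation (`Ins331`), intron retention
(`IR(6)`) — with deterministic tokens that round-trip to class and size.
Combined tokens are ordered 5'→3' and joined with `+`.

"Aberrant" is registry-driven, not hard-coded: an event is aberrant iff its
token is absent from the construct's wild-type repertoire. This was a
genuinely open design point: full exon-6 skipping appears in a mutant assay
at 5.9% and could be argued either way, but the assay's own event count for
that variant is three (Ins331, PSE97, PSE13), which the registry reproduces
by treating `∆6` as part of the wild-type repertoire (it is in frame —
216 nt — unlike every intron-6 exonization event, all of which are ≢ 0
mod 3 and frameshift). Event-level totals
(`aggregate_event_abundance()`) sum reported **and** annexed isoforms,
because sub-5% isoforms carry a substantial share of an event's total
(e.g. 26.2 + 4.9 + 1.1 = 32.2% for the 331-nt retention).

# Consequences and clinical logic

`translate_consequence()` splices the chain, locates the reading frame from
the CDS anchor, translates from the first complete codon of the coding
ladder (vector exon sequence upstream of the anchor is never translated)
and diffs against the canonical translation. A frameshift is called iff
the net spliced-length change is not a multiple of three; the HGVS p.
shorthand covers the first affected residue and `fs*N` (N counting the
first changed residue as 1), plus stop-gains. Complex in-frame delins
naming is out of scope (`p.?`). The engine is checked against an
independent brute-force codon walk on 1000 seeded random constructs.

`predict_nmd()` applies the 50-nt rule: NMD iff the premature stop lies at
least 50 nt upstream of the last exon–exon junction; the threshold is
configurable because the biology is a heuristic.

`splice_functional_evidence()` turns an assay comparison into PS3
(mutant aberrant fraction ≥ 20% with a clean wild type), BS3 (mutant
aberrant fraction ≤ 5% and reported repertoire within 10 total-variation
points of the wild type) or inconclusive. The 20/5/10 thresholds are
package decisions — the assay literature states the qualitative rule only —
chosen so clearly aberrant assays (aberrant fractions above 50%) and
clearly wild-type-like assays sit far from the boundaries; the verdict is
monotone in the aberrant fraction and PS3/BS3 are mutually exclusive.

`combine_acmg()` evaluates evidence tags against a rule table that is data,
not code; the default table implements the standard combining rules.
Population/predictor tags (PM2, PP3, BS1, BP7, …) are carried as opaque
annotations, never computed. One documented discrepancy: a variant
annotated with two Strong criteria (PS2 and PS3) classifies as pathogenic
(class 5) under the standard table, whereas the assay study's platform
reported likely pathogenic (class 4); passing a modified rule table
reproduces the platform's behaviour, and the default pipeline fixture
annotates that variant with its non-segregation criteria only.

# Numerical choices and degenerate inputs

* Ties in snapping break toward the smaller coordinate; ties in consensus
  collapse break toward higher support, then smaller position — all
  deterministic.
* All randomness flows through explicit seeds; a pipeline rerun with the
  same config is byte-identical.
* Empty chains, zero intronic offsets, offsets beyond the intron,
  reference-allele mismatches, overlapping exons, invalid phases and
  unknown event tokens are errors; degenerate snapped chains and
  unsnappable edges unassign the read with a recorded reason.
* `apply_variant` changes exactly one base (Hamming distance 1) and is an
  involution with the reverse substitution.

# Problem sizes

The shipped analyses and tests run at: 5000 reads for the end-to-end
recovery demonstration (the assay's per-sample depth), 1500 reads per
sample for the four-variant clinical reproduction, and a few hundred reads
for unit-level properties; the translation oracle uses 1000 random cases
and the coordinate round-trip is exhaustive over a ~1 kb toy construct.

# Known limitations

* The built-in constructs are synthetic surrogates with authentic
  geometry; real-locus protein strings (e.g. the exact fsTer lengths of the
  published variants) require the user to supply the RefSeq sequence and
  build the construct from it via `load_construct()`.
* Recovery of isoforms whose discriminating segment is much shorter than
  the anchor length degrades with noise (the 13-nt pseudoexon riding on a
  15-nt partial exon is the worst case); chunk placement recovers the
  clean majority, and event-level calls remain robust, but per-isoform
  abundances involving such segments carry extra error.
* Junction microhomology makes per-read junction placement ambiguous by a
  few nucleotides in any aligner; claims should be made at the consensus
  level (where coordinates are exact), not per read.
* No transcript-level error correction, UMIs, chimera handling or
  differential-expression statistics; splice-site strength scores are
  carried as annotations only, never recomputed.
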