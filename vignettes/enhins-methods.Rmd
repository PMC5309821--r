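---
title: "Methods: discovering small enhancer insertions from ChIP-seq reads"
author: "enhins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering small enhancer insertions from ChIP-seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhins)
```

## The problem

H3K27ac ChIP-seq enriches DNA from active enhancers, concentrating the
variant-discovery search space on the few percent of a tumour genome most
likely to matter for gene regulation.  Short reads carrying a small
insertion relative to the reference genome, however, usually fail gapless
alignment and are silently discarded by standard pipelines.  `enhins`
implements a rescue pipeline for exactly these reads: it identifies the
reads a gapless aligner cannot place, realigns them (and contigs
assembled from them) with an insertion-aware aligner, verifies each
candidate with an independent exhaustive realignment, and reduces the
survivors to a catalogue of coordinate+allele keys that downstream
stages annotate (germline likelihood, allele-specific coverage bias,
insulated-neighbourhood target genes).

All coordinates in the package are 0-based with half-open intervals.  An
insertion's anchor is the index of the reference base immediately to the
left of the insertion point, and its key serializes as
`chrom:position:sequence`.

## Discovery model

**Gapless pass.** Each read is placed full length on both strands with at
most 2 mismatches.  Only a unique placement in the best (minimal)
mismatch stratum counts as mapped; ties are "ambiguous".  Both ambiguous
and no-hit reads feed the rescue path — the conservative reading of
"initially unalignable", exposed as `include_ambiguous`.

**Assembly.** Unmapped reads are assembled by greedy exact-overlap
merging (minimum overlap 20 bases, either orientation, containments
absorbed), extending the effective read length so insertions too large
for one 40-base read to bridge become callable.  Merging order is
longest-overlap first with ties broken by the lexicographically smallest
member read id, which makes assembly deterministic.  Contigs are trimmed
so every retained base has read depth at least 5; a contig with an
interior dip below that depth is discarded rather than split, since a
clean tiling never produces one.  Overlaps are exact: the verification
stage demands zero mismatches anyway, so error-tolerant overlaps would
add reach the rest of the pipeline cannot use.

**Rescue alignment.** `map_gapped()` performs seeded single-indel
alignment: exact 11-mer seeds propose candidate windows, and within each
window every full-length placement of the query with either no gap, one
insertion (up to 31 bases), or one deletion is enumerated.  Scoring is
match +1, mismatch −1, gap open −2, gap extend −1 (a length-k gap costs
k+1).  The single best placement wins; distinct placements tied at the
best score make the query ambiguous and it is dropped.

The restriction to one contiguous gap is a deliberate design choice, not
a shortcut.  Under these scores a free multi-gap aligner will sometimes
split a genuine insertion into an I/D mosaic whose pieces re-match the
reference (a planted 6-base insertion can score 64 as
`63M1I4M4D4M1D4M` against 63 as `63M6I7M`), producing alignments that
no downstream stage can consume: verification accepts only a single
clean insertion or deletion with zero mismatches.  A 40–80-base query is
interpreted as carrying at most one small event; within seeded windows
the aligner is then *exactly* equivalent to an exhaustive split-point
enumeration, and the test suite asserts that equivalence against an
independently written oracle on 500 planted cases.

**Gap placement and keys.** Shifting a gap left across equal characters
leaves the aligned sequence pair unchanged, so every equivalent placement
is rotated to its leftmost representation before anything is compared.
Keys are additionally left-normalized against the full reference
(VCF-style), so identical events inside repeats collapse onto one
canonical key; without this, recurrence counting and dbSNP matching
would silently fragment.  dbSNP input is normalized with the same
function, which is what makes key matching meaningful.

**Verification.** `verify_hit()` re-derives the alignment around the
reported locus by independent exhaustive enumeration of zero-mismatch
single-insertion placements (prefix/suffix exact-match arrays, both
orientations).  A hit is accepted only if a single best placement
consumes the whole query, contains exactly one insertion shorter than
the query, has zero mismatches, and the insertion is within the cap.
The cap is 20 bases on the read route — a BLAT-style whole-query
filter — and 31 bases on the contig route, the upper end of the targeted
1-31-base size range; a single 20-base cap would make 25-base
insertions unreachable even through contigs, contradicting their stated
purpose of capturing 14–31-base events.  The gapped hit and the
verification hit must also agree positionally within 100 bases.  A
minimum aligned flank of 5 bases on each side of the insertion (measured
over all equivalent placements) guards against soft-clip-like end
insertions; the threshold is configurable.

When verification rejects a hit it reports why: `too_long` only when the
aligner's own CIGAR insertion exceeds the cap; a flank mismatch that
forces the zero-mismatch realignment to absorb extra bases into a larger
gap reports `mismatch`.  Accepted calls are extracted from the verified
canonical placement (identical to the aligner's CIGAR on error-free
data).

**Peaks.** The built-in peak caller is a declared stand-in for MACS:
read starts are deduplicated per position up to an expected maximum
(Poisson 1e−5 tail, the keep-dup analogue), counted in 500-base windows
stepping by 250, and windows with Poisson tail probability below 1e−9
against the local rate (the genome-wide rate, or the depth-scaled
control count when input DNA is provided) are merged into peaks.  Any
serious use at published scale should supply externally called peaks as
BED, which the pipeline accepts directly.

**Deletions.** Contigs only.  A contig is accepted as a deletion iff its
best alignment is exactly M,D,M with zero insertions and zero
mismatches, confirmed by the same kind of exhaustive zero-mismatch scan,
and the deleted interval is left-normalized.

## Germline deprioritization

An insertion is flagged as likely germline if its exact key is present
in the dbSNP key set, or if it recurs in more than 2 samples — recurrence
across unrelated individuals is more parsimonious with inheritance than
with independent somatic events, and the threshold of 2 is chosen so
that a genuine somatic event shared by a pair of samples is not flagged.  The union
obeys inclusion–exclusion and is asserted on every run.  Flags are
reported, never a somatic verdict: flagged sets may still mix germline
and somatic variants, and the package does not pretend otherwise.

## Allele-specific coverage bias

For each catalogue entry two mini-genomes are built: the reference
window of twice the read length centred on the insertion locus, and the
same window with the insertion spliced in.  Every read of the sample is
aligned gaplessly (both strands, ≤2 mismatches, unique within each mini)
against both; a read is informative only if it aligns to exactly one —
reads that do not span the insertion junction align to both and are
ignored.  The bias ratio is `(alt + 1) / (ref + 1)`: the single
pseudocount keeps the ratio defined when a heterozygous site has zero
reference-supporting reads, and raw counts are reported alongside so
users can apply their own rule.  The twofold-or-greater filter keeps the
boundary value 2.0.  At published scale one would pre-enumerate all
mappable reads for efficiency; aligning the sample's actual reads
directly is the same contract at desk scale.

## Insulated neighbourhoods

Loops (cohesin ChIA-PET interactions) are filtered to FDR < 0.2 with
CTCF-enriched regions at both anchors.  Containment uses the outer span
`[anchor1.start, anchor2.end)`; since loops nest, the smallest
containing span is used, with deterministic tie-breaking (leftmost span
start, then input order).  An insertion's candidate target genes are the
active genes whose TSS lies in the same span; "active" is a
caller-supplied flag, with a helper that marks a gene active iff an
H3K27ac peak overlaps ±1 kb around its TSS (the criterion is otherwise
unspecified upstream, so it is explicit here).

The oncogene-enrichment permutation test is this package's own
construction: the observed statistic is the number of insertions whose
neighbourhood contains a catalogued oncogene; each permutation re-places
every insertion uniformly at random within the collapsed enhancer union
and recomputes it, and `p = (1 + #{perm ≥ obs}) / (1 + n_perm)`, so the
estimate is never below `1/(n_perm + 1)` and is bit-reproducible given
the seed.  Under uniform placement the null mean equals the key count
times the oncogene-neighbourhood fraction of the union, which the tests
check against a binomial oracle.

## Confirmation by amplicon sequencing

Per-allele custom genomes cover 250 bases up- and downstream of the
anchor (reference window length 2×250; the anchor base itself sits at
offset 249, which is the "+1 anchor base accounting" of our 0-based
convention).  Amplicon reads are assembled with the same assembler at
minimum 5× coverage; contigs must align gaplessly with **zero**
mismatches and uniquely to a custom genome, and count as evidence only
if the alignment strictly contains the anchor (reference allele) or the
full inserted span (insertion allele) — "contacted the position" made
precise.  Zygosity follows from the two presence flags; with no
informative contigs the result is `undetermined`.  Paired-end amplicon
reads are treated as independent single reads: pairing adds nothing to a
zero-mismatch contig contract.

## The synthetic world

The generator is first-class, tested code and states one world:

* genomes are i.i.d. base draws at GC 0.45 (typical mammalian bulk GC);
* enhancer peaks are 500-base non-overlapping windows;
* insertions are planted inside peaks (≥60 bases from the peak edge so
  reads can span), sizes 1–31 skewed to 1 base by a truncated geometric
  with ratio 0.5 (small-insertion size spectra are dominated by 1-bp
  events), random inserted sequence;
* zygosity is heterozygous with probability 0.75 (sequencing-confirmed
  enhancer insertions in this setting are heterozygous about three
  quarters of the time); haplotype 1
  carries every insertion, haplotype 2 only the homozygous ones;
* ChIP-like reads are error-free 40-base draws, uniform within peaks at
  the stated depth split evenly across haplotypes, random strand, with
  optional genome-wide background and an optional uniform substitution
  error rate (default 0: the pipeline's zero-mismatch verification makes
  error modelling a separate concern, and the knob exists to probe
  robustness);
* amplicon reads are 150-base draws at ≥10× from the allele genomes per
  zygosity.

Everything is bit-reproducible from the seed.  What a green test
establishes is recovery and calibration in this idealized world — real
data add sequencing errors, PCR duplicates, mappability structure,
repeat-driven ambiguity far beyond a random genome's, and copy-number
distortion of allelic ratios, none of which are emulated.  Catalogue
sizes and confirmation rates observed on real hundred-dataset corpora
depend on inputs this package does not ship and are deliberately not
asserted.

## Numerical and degenerate-input choices

* Aligner equivalence is asserted on sequences of length 50–80 carrying
  planted insertions of 0–20 bases with flanks of at least 12: a seeded
  aligner cannot (and should not) reproduce the exhaustive optimum of a
  sequence with no seedable exact match, and observed disagreements
  outside this regime are confined to garbage optima scoring a small
  fraction of the sequence length.
* Empty inputs return empty results (assembly, catalogue, peak calling
  with no reads); an empty enhancer union is an error for the
  permutation test because the null is undefined.
* Mini-genome windows clipped at one chromosome end record their actual
  extent; clipped at both ends is an error.
* `NA`-free integer arithmetic throughout the accounting helpers;
  inclusion–exclusion is asserted, not assumed.

## Known limitations

* The peak caller is a coarse MACS surrogate; peak boundary effects
  differ from MACS output, which is why external peak BEDs are
  first-class inputs.
* Multi-gap events (an insertion near a deletion) are outside the
  single-indel model and are dropped at rescue rather than called.
* Recurrence-based germline flagging depends on sample count; with few
  samples it flags almost nothing, as in the underlying method.
* The permutation scheme fixes the loop and gene structure and
  randomizes insertion positions only; alternative nulls (shuffling
  neighbourhood labels) would answer slightly different questions.
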