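---
title: "Single-nucleotide CLIP site calling: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-nucleotide CLIP site calling: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipnucleo)
```

# The biological signal and its statistical model

CLIP protocols cross-link protein (or an anti-m6A antibody) to RNA with
UV light. Two artefacts of reverse transcription then mark the cross-link
at single-nucleotide resolution:

* **read-through misincorporation** — for m6A-miCLIP, a C>T transition at
  the +1 position of the methylated adenosine (the antibody cross-links
  to the base 3′ of the m6A);
* **cDNA truncation** — synthesis stops at the cross-linked adduct, so
  the read's 5′ end sits at cross-link + 1. Throughout the package the
  cross-link position of a read is *read start − 1 on the transcript
  strand*. This geometry has a consequence worth stating: a truncated
  read cannot also display the +1 substitution, because truncation
  removes that base from the read.

## Tallies

`tally_alignments()` produces, per (contig, strand, position):
`k` = unique-tag coverage, `m[type]` = unique tags carrying a given
substitution (transcript-strand sense; minus-strand alignments are
complemented into transcript space), and `t` = unique tags whose inferred
cross-link is the position. Every read contributes exactly one cross-link
event, so `sum(t)` equals the number of reads minus those whose
cross-link falls off the contig (dropped with a warning).

## CIMS: permutation FDR on substitution counts

Candidates are positions with at least one substitution of the tested
type. The null preserves everything about the library except *where*
within each read its substitutions sit: each observed event is relocated
uniformly within its own read's aligned span, keeping read placement and
per-read mutation counts fixed. This conditions on the coverage profile
`k`, which is exactly the quantity the statistic is stratified by. For a
site with coverage `k` and count `m`,

FDR(k, m) = mean over rounds of N_null(k, ≥m) / N_obs(k, ≥m),

capped at 1 and monotonized (cumulative minimum over increasing `m`
within each `k` stratum), so more extreme counts never receive larger
FDRs. Stratification uses exact `k`; in very sparse strata (a single
candidate at an outlier coverage) the estimate is noisy and can
occasionally under-estimate — with the default ten rounds we observed
null candidate fractions at FDR ≤ 0.1 of well under 2%, i.e. conservative
control in aggregate. The permutation is deterministic given `seed`.

## CITS: cluster binomial test on truncation pileups

Clusters are maximal runs of positions with `k ≥ 1` per contig and
strand — a deliberately literal definition. Within a cluster of covered
length `L` containing `n` truncation events, a position with `t ≥ 1` gets
the exact tail p = P[X ≥ t] for X ~ Binomial(n, 1/L), and q-values are
Benjamini–Hochberg over all tested positions genome-wide (ties resolved
by position order, so output order is deterministic). Two degenerate
cases follow from the definition: a single-position cluster always has
p = 1, and truncation events landing one base 5′ of a cluster's first
covered position belong to no cluster and are untested. At realistic
coverage the cross-link position of a genuine site is covered by the
non-truncated reads crossing it, so this loses only boundary artefacts.

Whether the retention threshold applies to raw p or adjusted values is
genuinely ambiguous in the protocols this follows; the package defaults
to BH-adjusted q ≤ 0.05 and exposes `use_raw_p` as an escape hatch.

## From candidate sites to residues

* miCLIP m6A, CIMS branch: keep C>T candidates with m/k ≤ 0.5 (boundary
  inclusive) whose transcript −1 base is A; emit the residue at that A.
  The bare quoted rule carries no significance filter, but a single
  background C>T error 3′ of any adenosine would then become a residue
  call; since the upstream protocol applies CIMS significance filtering,
  `call_m6a_from_cims()` takes an optional `fdr` argument (off by
  default, so the bare rule is testable) and the pipeline enables
  FDR ≤ 0.1. Both filters are independent flags.
* miCLIP m6A, CITS branch: significant truncation sites at or adjacent
  to an A. "Adjacent" is interpreted as the ±1 window, with assignment
  preference self, then −1, then +1 — the narrowest reading; the window
  is deliberately not widened.
* Reader footprints: CIMS branch keeps any substitution position with
  FDR ≤ 0.1, with no base-context restriction; the CITS branch reuses the
  adenosine-neighbor procedure (the protocols describe it as "the same
  way"), with `cits_require_a = FALSE` available since a binding
  footprint has no intrinsic reason to sit near adenosines.
* SNP masking runs before residue filters and ignores strand: a genomic
  SNP confounds either strand's mutation calls.

Every emitted m6A position is hard-asserted to be a reference adenosine
(transcript sense). Footprints are the site ±5 nt, stored half-open.

# Integrative analyses

* `overlap_sites()` pairs sites greedily nearest-first, one-to-one,
  within a tolerance defaulting to 5 nt — the footprint flank. The
  pairing rule is a package choice (the underlying figure legend does not
  state one); `tolerance = 0` gives exact matching.
* `metagene_profile()` averages strand-oriented coverage over
  [−W, W], W = 100 nt by default (matching the 100-nt proximity scale
  used elsewhere in the analysis); intensity is deduplicated unique-tag
  coverage scaled to counts per million unique tags, with raw and
  per-anchor normalizations available. Edge anchors are dropped with a
  warning.
* `splice_proximity_test()` labels a splice site "near" iff an m6A lies
  within 100 nt (inclusive at exactly 100), takes mean coverage over
  ±10 nt as the site's intensity — a point estimate would be too noisy,
  a wider window would blur neighboring sites — and compares groups with
  a two-sided rank-sum test. An empty group yields p = NA with a warning
  rather than an error.
* `motif_enrichment()` scores 21-nt windows ([−10, 10] around footprint
  centers, transcript sense) by IUPAC motif match count and tests
  foreground > background by rank-sum. The default background is ten
  dinucleotide-preserving shuffles per window (Altschul–Erikson
  algorithm: exact dinucleotide multiset, first and last base preserved);
  `bg_mode = "genome"` samples random genome windows instead. With the
  shuffle background the pooled rank-sum is conservative under the null
  (heavily tied small counts; observed rejection ≈ 1% at α = 0.05), which
  trades a little power for never inflating type-I error; the genome
  background is exactly exchangeable and rejects at the nominal 5%.
* `wilcoxon_rank_sum()` uses exact enumeration for combined n ≤ 12
  without ties, otherwise the normal approximation with tie and
  continuity correction; an all-tied comparison returns p = 1.

# The synthetic-data generator

The generator is the package's study-conditions oracle, not a tuning
knob. Defaults: two 50-kb contigs at GC 0.5, two genes per contig (three
exons each, alternating strands), 200 m6A residues planted on RGACT
motifs written into gene bodies on a jittered ~100-nt grid (so planted
sites are ≥ 50 nt apart and a read crosses at most one), one residue
written exactly at a splice junction, 200 reader footprints of which 70%
fall within 5 nt of an m6A and the rest at motif loci ≥ 50 nt from any
m6A, 20 heterozygous (allele fraction 0.5) C>T SNPs planted at AC
dinucleotides — the exact context a cross-link mutation mimics — 30×
unique coverage with threefold IP enrichment of reads crossing a
cross-link site, read lengths uniform on 30–50 nt, per-read cross-link
mutation probability 0.3 and truncation probability 0.2, uniform
background substitution rate 10⁻³, 30% PCR duplication, and 5-nt sample
barcodes. Where the underlying protocols state no value (enrichment,
duplication, overlap fraction, gene layout) the defaults are one-time
choices of what a CLIP analyst would call a clean library, set for test
power and documented here; they were not revisited per test.

What the simulator deliberately does not model: sequencing quality
scores, adapter contamination, spliced reads, indels, multi-mapping, or
UMI structure. Reads are emitted pre-aligned (a truth SAM) because
external aligner behavior is not the inference under test. Passing tests
therefore demonstrate correctness of the inference chain under this
event model, not robustness to alignment artefacts in real libraries.

Minus-strand genes run the identical event model in transcript
coordinates; the genomic representation (G>A at the complementary
position, truncation at the alignment's right edge) is derived, and a
dedicated test checks that a mirrored gene yields identical calls in
transcript space.

# Numerical and testing choices

Problem sizes were chosen so the full suite runs in well under a minute
of simulation time: the recovery scenario uses the default 100-kb genome
(~75k unique tags per library), null calibration uses 20 background-only
replicates of the same size, the splice-null uniformity check uses 30
replicates of a 30-kb six-gene model at 10× depth with
Kolmogorov–Smirnov distance < 0.25 as the uniformity bound, and the
motif type-I check uses 100 replicates of 60 random windows. All
randomness flows through explicit seeds; reruns are bit-identical, and
the pipeline manifest records per-file checksums to make that checkable.

Known limitations: the CIMS permutation FDR is an estimate whose sparse
strata are noisy at small `B` (raise `n_perm` for final analyses); CITS
power is bounded by the whole-gene cluster length under continuous
coverage, so low-truncation sites lean on the CIMS branch; footprint
recall is structurally limited for anchors whose substitution type is
not the tested one; and the greedy overlap pairing is not globally
optimal (it is, however, symmetric in its counts).
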