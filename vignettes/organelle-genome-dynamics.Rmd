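---
title: "Methods: comparative organelle-genome dynamics with orgdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative organelle-genome dynamics with orgdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgdyn)
```

## Scope and model of the data

orgdyn analyses plant organelle genomes — a mitogenome and its companion
plastome — as circular (or linear) DNA molecules with interval-based
feature annotations, and asks five families of questions about them:

1. what repetitive content they carry (microsatellites and dispersed
   forward/palindromic repeats);
2. how their protein-coding genes use synonymous codons (RSCU);
3. which fragments moved from the plastome into the mitogenome (MTPTs),
   where those transfers cluster (hotspots), and how the two genomes and
   different species align at the block level (synteny);
4. which transcriptome positions are post-transcriptionally edited
   (C>T and T>C), at what efficiency, and how that varies across tissues;
5. how informative a multi-species alignment matrix is
   (variable / singleton / parsimony-informative site classes).

All internal coordinates are 0-based half-open; every external table is
1-based inclusive except BED, which stays 0-based half-open.  This single
conversion site is asserted by tests on both conventions.  Features that
wrap the origin of a circular molecule are stored as two intervals flagged
as one wrapped feature, which keeps all downstream interval arithmetic
standard.

## Repeat scanning

`find_ssrs()` reports maximal tandem runs of 1–6-bp motifs with minimum
repeat numbers 8, 5, 4, 3, 3, 3 (mono- through hexanucleotide), the
thresholds conventionally used for organellar microsatellite surveys.  A
run is reported once under its first-occurring phase, and motifs that are
whole repetitions of a shorter motif are rejected, so an (AT)~n~ run is
never double-reported as (ATAT)~m~.  Compound (interrupted) runs are
deliberately *not* merged: each perfect run is one record, since plain
run counts are what downstream summaries consume.  N truncates runs.  On
circular molecules the scan runs on the doubled sequence; a run is kept
when its start lies in the first copy and its circular left extension
fails, which yields exactly one wrapped record for an origin-spanning run.

`find_dispersed_repeats()` reports repeated segment pairs — forward and
palindromic — of at least 30 bp with at most 3 substitutions (Hamming
distance; no gaps).  A *maximal* pair cannot be extended on either side
without exceeding the mismatch budget; on a given diagonal those windows
are exactly the stretches between the *q*-th and (*q*+4)-th mismatch once
sequence-edge sentinels are appended.  Because one repeated locus
generally admits several maximal windows (the budget spent on different
flanks), overlapping windows on one diagonal are reduced to the
best-scoring one (matches − 2·mismatches, ties to the longest then
leftmost), so a planted exact copy is reported once at its exact extent.
The implementation finds candidate diagonals from exact 7-mer seeds
(pigeonhole: any 30-bp window with ≤ 3 mismatches contains an exact
7-mer) and walks outward collecting the bounding mismatches; the test
suite checks it against an exhaustive all-diagonal oracle.

Pair significance uses the match–mismatch expectation for a random
sequence of the genome's length: E = n² · C(ℓ, e) · 3^e / 4^ℓ for a
length-ℓ window with e mismatches; pairs with E > 10⁻⁵ are dropped and at
most 5000 pairs are reported (length-descending, ties by position).  The
tool this mirrors states the cutoff but not the formula; this is the
standard expectation for the match/mismatch model and is documented here
as the package's choice.

## Codon usage

`extract_cds()` concatenates exon intervals in feature order and
reverse-complements the concatenation for minus-strand features;
sequences with length not divisible by three or internal stop codons are
flagged and excluded by default.  ATG starts are *not* enforced, because
organellar CDSs may acquire their start by RNA editing.  `compute_rscu()`
uses the standard genetic code (NCBI table 1, the plant mitochondrial
convention) with the three stop codons treated as one synonymous family,
so a stop codon can be reported as preferred (RSCU > 1) like any sense
codon.  RSCU(c) = count(c) × family size / family total; within every
observed family the values sum to the family size, an invariant asserted
on every random table the tests draw.  All CDSs of a genome are pooled
(not averaged per gene), matching the default behaviour of the usual
codon-usage tools.

## Homology search and transfer detection

`homology_search()` is a seed-and-extend local aligner: exact 15-mer
seeds on both strands (encoded as exact base-4 integers), clustered per
diagonal, extended in both directions with X-drop termination (drop 20)
under match +1 / mismatch −2 scoring; collinear fragments separated by a
small diagonal shift (an indel) are chained with affine penalties (open
−5, extend −2 per shifted base).  Significance is the ungapped
Karlin–Altschul e-value for these scores over the m×n search space, with
λ solved numerically from the score distribution and K = 0.62, the
standard tabulated value for +1/−2 nucleotide scoring.  Fragments shorter
than 100 bp, below 80% identity, or above e-value 10⁻⁵ are discarded —
the three cutoffs that define a homologous fragment here.  Circular
molecules are scanned with a 10-kb origin pad and folded coordinates, so
origin-spanning fragments up to the pad length are found; the pad (rather
than full doubling) keeps the search linear-time at these genome sizes,
and transfers longer than 10 kb that *also* span the origin would be the
only blind spot.

`collapse_inverted_repeat()` removes the second copy of the plastome's
large inverted repeat (the longest self-palindromic pair ≥ 1 kb,
substitutions tolerated) before transfer analysis, so IR-borne transfers
are not double-counted.  `detect_transfers()` then runs one search and
merges fragment intervals on each side separately: the plastome union is
"transferred from", the mitogenome union "integrated into"; the two
counts legitimately differ when rearrangement splits or fuses fragments
on one side.  Window profiles attribute transferred bases per base (not
per fragment midpoint), so window sums conserve the merged total — an
invariant the tests assert against a per-base mask.  A hotspot is a
window whose transferred total strictly exceeds 2000 bp (5000-bp windows
for mitogenomes, 3000-bp for plastomes), and a hotspot "contains" a tRNA
when any tRNA feature overlaps it by at least one base — complete or
partial, matching how tRNA co-occurrence at integration sites is usually
scored.  `synteny_blocks()` reuses the same search; in self mode the
trivial self-diagonal is dropped and each pair reported once, and a
display subset keeps blocks ≥ 5 kb, the scale at which interspecific
synteny is drawn.

## RNA-editing sites

`call_editing_sites()` evaluates C>T and T>C evidence on the reference
plus strand, exactly as the filter set is stated: minimum depth 10 reads
on mitogenomes and 20 on plastomes, base quality ≥ 10, and exclusion of
sites within 5 bp of an indel (strictly greater than 5 passes).  Quality
is taken as the mean base quality of the variant-supporting reads — the
closest testable reading of a variant-caller site quality without
re-implementing a caller.  Two additional guards are the package's own,
documented choice: at least 2 supporting reads and at least 5% of the
depth, to suppress singleton sequencing errors that depth-only filters
would admit; both are configurable.  An optional strand-aware mode remaps
G>A/A>G evidence through the coding strand of an overlapping gene but is
off by default, following the letter of the stated site types.
Efficiency is the edited-read fraction; the five reporting bins are
lower-closed with a closed top bin, so 0.8 falls in 0.8–1.  Location is
`cds` only for positions inside CDS *exonic* intervals.

## Windowed transcription and ORFs

`window_counts()` slides windows of 100 bp by 50 bp (transcription) or
500 bp by 200 bp (sequencing depth); a read counts in every window it
overlaps by one base, the coverage-tool semantics that keep calls robust
at window edges.  "Relatively high" intergenic transcription is
operationalised — the package's own choice, made once — as intergenic
windows exceeding the intergenic mean + 2 SD, merged when adjacent;
windows touching any annotation are never reported.  `find_orfs()` scans
both strands in three frames for ATG-to-stop ORFs of ≥ 150 bp by default
(the ORF-finder setting is not standardised; 150 bp is a common floor for
calling an IGS product an ORF), reporting nested ORFs sharing a stop once
(longest).

## Alignment site classes

`classify_sites()` counts a column as gap/missing when it contains any
gap or ambiguity code (ambiguities are treated as missing), and excludes
such columns from the variability classes; percentages are computed over
the *total* alignment length, the bookkeeping that reproduces published
matrix summaries.  Among clean columns: variable = ≥ 2 distinct bases;
parsimony-informative = ≥ 2 bases each in ≥ 2 sequences; singleton =
variable but not informative; the variant number is the count of distinct
bases.  total = gap + invariant + singleton + informative holds on every
input, and the summary is invariant under row and column permutation.

## The synthetic-data generator

`simulate_organelle_pair()` is first-class, tested code, not a fixture:
its defaults *are* the study regime the pipeline targets — a 60-kb
plastome with one 15-kb exact inverted repeat, a 120-kb mitogenome at 45%
GC, ten transfers of 150–3000 bp at 85–100% identity, tRNA annotations
enriched within ~500 bp of insertion sites, planted SSRs, dispersed
repeats and CDSs with known coding sequences.  Identity targets are hit
with substitutions only, so planted identity is exact and recovery
arithmetic is clean; an indel mode is deliberately out of scope for the
truth tables.  Features are placed by rejection sampling with a retry cap
and an explicit "infeasible packing" error.  `simulate_pileup()` draws
binomial edited-read counts and deliberately plants sub-threshold sites
(depth one below the cutoff, quality 9, 0–5 bp from an indel) to exercise
every filter; planted sites are kept > 12 bp apart so one site's indel
can never contaminate another's exclusion zone.  `simulate_alignment()`
builds every column to an assigned site class and records realized
counts.  All generators are deterministic functions of their seed
(R's default Mersenne–Twister), and every truth table serialises to JSON
byte-identically.

What the generator does **not** emulate: real covariance structure
(GC gradients, repeat families, editing-site clustering in codon
position 2), gapped transfer evolution, mapping artefacts in pileups, or
phylogenetic signal in alignments.  Passing tests therefore demonstrate
algorithmic correctness under the stated regime, not end-to-end accuracy
on real sequencing data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the regime above: 20
simulated organelle pairs for transfer recovery; 100 random 10-kb
sequences (SSR oracle), 30 random 2-kb sequences (dispersed-repeat
oracle) and 50 random interval sets (window masks); 10 seeded pileup
simulations for filter exactness and 1000 sites per efficiency level
0.1–0.9 at depth 30; 100 random matrices for site-class conservation.
These sizes were chosen so the whole acceptance run completes in a few
minutes on one CPU while keeping every check exact rather than sampled.

Deterministic tie-breaks are stated next to each rule: repeat truncation
orders by length descending then position; locus reduction by score,
length, then leftmost start; chained fragments keep the query span as the
aligned length.  At efficiency 0.1 and depth 30 the ≥ 2-read evidence
filter induces a small upward conditioning bias in mean recovered
efficiency (≈ 0.017, within the ±0.02 recovery check); this is a property
of any minimum-evidence filter, not of the estimator, which is exact
binomial otherwise.

## Known limitations

- The aligner is substitution-oriented; long gapped homologies are
  chained rather than globally realigned, so identities across large
  indels are approximate.
- Origin-spanning homologous fragments longer than the 10-kb circular pad
  are truncated.
- Editing calls are reference-plus-strand by default; minus-strand gene
  editing appears as G>A/A>G and needs the strand-aware mode.
- Accession-based reproduction of published repeat counts depends on
  compound-SSR and maximality conventions of the original tools; the SSR
  scanner reports each perfect run separately, which is logged as a known
  divergence risk for such comparisons.
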