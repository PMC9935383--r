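---
title: "Quantifying sense and antisense transcription on vector constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sense and antisense transcription on vector constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandquant)
```

## The problem

Self-inactivating lentiviral transfer vectors terminate transcription at a
weak poly(A) signal in the U3-deleted 3' LTR. On a linear, covalently
closed DNA template there is little or no template downstream of the
cassette, and two failure modes become visible in RNA-seq of producer
cells: RNA polymerase II drops off prematurely, so sense read abundance
falls across the 3' LTR; and polymerase can track around the closed 3' end
and initiate antisense transcription near the 3' stuffer. Both degrade the
full-length vector genomic RNA available for packaging. This package
quantifies both signatures at single-nucleotide resolution and provides
the surrounding arithmetic (titres, copy numbers, construct ratios) needed
to interpret production experiments.

## The counting model

The input is a coordinate-sorted SAM/BAM of stranded paired-end reads
aligned to a reference set that contains the construct sequences plus a
host "decoy" (the full host genome in production; a small random sequence
in tests). The decoy exists so background transcription has somewhere to
align other than the constructs; decoy reads are discarded at the parsing
boundary and never enter memory.

For each sample and construct, every primary mapped segment is classified
by the orientation of the **first mate** of its pair:

* first mate, reverse-aligned → **sense** (under the default `reverse`
  library convention);
* first mate, forward-aligned → **antisense**;
* second mate → the class its first mate would receive, looked up by read
  name;
* unpaired segments, or second mates whose first mate is unmapped or
  absent → **skip**.

Under the `forward` convention the two classes swap; the correct setting
is a property of the library chemistry and is deliberately a run
parameter, not a constant.

Every aligned base of a classified segment increments the classified
array at its position. Three consequences of this definition are worth
stating explicitly:

* both mates are counted independently, so bases where the mates overlap
  count twice — the counter reproduces the per-read increment rule
  exactly rather than collapsing to fragment coverage;
* "covers a position" means an aligned (CIGAR M/=/X) base; positions
  spanned by deletions or introns are not counted;
* skipped segments contribute to neither array, but they remain in the
  normalisation denominator, which is defined as the number of *aligned*
  reads (each mate one read), not classified reads. Skip tallies are
  reported in the run log because this is a policy choice.

The production counter accumulates read-major (one pass over segments
after a first pass that records first-mate orientations by name — this
avoids requiring name-sorted input). Its equivalence to the literal
position-major reading of the counting rule — for each position, for each
read, test coverage and classify — is enforced by a test against an
independent naive implementation rather than assumed.

## Normalisation, integration, region metrics

Counts are normalised per position by the total aligned reads on the
construct, making tracks comparable across samples with different
sequencing depth. Group integration takes the positionwise arithmetic
mean of the normalised tracks and records the across-sample minimum and
maximum, which are plotted as an envelope around the mean. Min and max
are computed on normalised values, consistent with normalisation
preceding integration.

Two region summaries operationalise the biology:

* `retention_ratio` — mean normalised sense coverage over a query
  interval divided by that over a baseline interval. With the query
  placed downstream and the baseline upstream of a termination anchor, a
  value near 1 means read-through; a value near 0 means hard drop-off.
* `antisense_fraction` — summed antisense over (sense + antisense) within
  the interval. Summing before dividing avoids the instability of
  averaging per-position fractions at zero-coverage positions.

Metrics that are undefined (zero coverage; zero baseline) are reported as
`NA` with a reason string, never as 0, since "no antisense detected" and
"nothing aligned here" are different findings.

## The simulator and what it does (not) emulate

`simulate_sample()` writes alignments directly — the quantification under
test begins downstream of the aligner, so tests need no external aligner
and no reference download. A `transcription_program` is a set of
intervals with relative rates per strand; a fragment is assigned to an
interval with probability proportional to rate × length (so per-base
fragment density is proportional to rate), its length is drawn from a
normal distribution truncated to `[read_length, interval length]`, its
start is uniform, and it lies entirely within its interval. Each fragment
emits one error-free, all-M proper pair whose flags encode its strand
under the active convention. A fixed seed gives byte-identical output;
the exact per-fragment truth is returned alongside.

The default study conditions: a 5 kb random-sequence construct with a
SIN-LV-like feature layout (5' LTR 0–600, payload 600–3200, 3' LTR
3200–3800 with the weak poly(A) anchor at 3500, strong poly(A) 3800–3850,
stuffer 3850–5000), a 2 kb decoy, fragments of 300 ± 30 bases, 100-base
reads, and 5 % background routed to the decoy. Three presets encode the
vector architectures of interest: `dropoff` (sense rate falls from 1 to
0.1 at the anchor, antisense at rate 0.05 over the stuffer), `strong_pA`
(full sense through the 3' LTR, halved residuals), and `spacer` (no
antisense at all). The 0.1 residual and 0.05 antisense rates are free
parameters of the simulation — chosen as a clear but not extreme
termination defect — not measured quantities; recovery tests check the
pipeline returns whatever was programmed, not a particular biological
value.

What the simulator does **not** model: sequencing errors, indels (except
an optional deletion-injection switch used to exercise CIGAR block
handling), PCR duplicates, splicing, real LTR sequence content, or
mappability structure. Passing recovery tests therefore demonstrates the
correctness of the counting and aggregation arithmetic on ideal
alignments, not robustness to alignment artefacts on real libraries.

## Titres and construct ratios

`infectious_titre()` implements `TU/mL = (F × C / V) × D` (F = fraction
of transgene-positive cells, C = cells seeded, V = inoculum volume in mL,
D = dilution factor). Only dilutions yielding 5–25 % positive cells are in
the assay's linear range; the gate bounds are treated as inclusive and
multiple valid dilutions are averaged arithmetically — both policy
choices, as is returning an explicit no-valid-dilution result instead
of 0. `copies_per_cell()` infers cell number from a reference gene
assayed in the same reaction (RNase P, 2 copies per diploid cell by
default). `genome_particle_titre()` divides genome copies by 2 genomes
per particle, reflecting the dimeric lentiviral genome; the divisor is
explicit because titration kits do not always disclose their convention.
`convert_ratio()` moves between mass and molar construct ratios (molar ∝
mass / length), rescales so the smallest element is 1, and always reports
per-construct mass concentrations that sum to the configured total.

## Numerical and design notes

* All internal coordinates are 0-based half-open (BED convention); SAM's
  1-based POS is converted once at the parse boundary.
* "Reference concatenation" for alignment means a multi-record FASTA
  (set union), never joining sequences end-to-end.
* Duplicate-marked records are kept by default (no duplicate marking is
  assumed upstream) and no mapping-quality filter is applied by default;
  both are exposed switches, and multi-mapper handling beyond
  primary-record selection is a known divergence risk between aligners.
* Normalisation is exactly invertible: multiplying the normalised track
  by its stored denominator and rounding recovers the integer counts
  bit-exactly, since the round-trip error is far below 0.5.
* The normalisation denominator counts mates, not fragments; the
  alternative reading would halve all normalised values uniformly and
  leave every ratio-type metric unchanged.
* Determinism: counting is independent of record order; the simulator and
  pipeline are byte-stable under fixed seeds and inputs.
* Problem sizes in the test suite (500–50,000 fragments per sample,
  10-seed replication for stochastic recovery) were chosen so binomial
  sampling error is small against the tested tolerances while the full
  suite stays fast on a laptop.

## Limitations

Fragment-level (template-length-based) coverage, UMI handling, spliced
reconstruction, and statistical testing of coverage differences between
groups are out of scope. The plots are linear-axis by convention;
antisense is drawn below zero purely for visual separation.
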