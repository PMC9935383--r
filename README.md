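# strandquant

Strand-aware per-nucleotide quantification of transcription on viral vector
constructs, for people characterising lentiviral vector (LVV) production —
in particular transfer vectors on linear, covalently closed DNA templates,
where weak termination at the self-inactivating 3' LTR can cause RNA
polymerase drop-off (falling sense read abundance across the 3' LTR) and
antisense transcription initiating near the 3' end.

## What it computes

From stranded paired-end RNA-seq alignments against a reference set of
construct sequences plus a host decoy, the package builds, for every sample
and construct, two integer arrays indexed by nucleotide position `p`:

- `sense[p]` — aligned bases at `p` from fragments transcribed in the
  cassette orientation,
- `antisense[p]` — aligned bases at `p` from the opposite orientation.

Strand is assigned per read from the **first-mate alignment orientation**
under a library convention: with the default `reverse` (dUTP-style)
convention, a reverse-aligned first mate means sense, and a second mate
inherits the class of its first mate. Counts are then normalised per
position by the total number of reads aligned to that construct,

    sense_norm[p] = sense[p] / N_aligned,

integrated across the samples of a group (positionwise mean with min–max
envelope), and summarised per annotated region:

- **retention ratio** = mean sense coverage downstream of a termination
  anchor / mean sense coverage upstream — a value well below 1 is the
  drop-off signature;
- **antisense fraction** = Σ antisense / (Σ sense + Σ antisense) over the
  region.

A built-in simulator generates stranded paired-end alignments (SAM) over a
toy ~5 kb transfer vector with programmable sense/antisense initiation and
exact per-fragment ground truth, so the whole pipeline is testable without
an external aligner. A separate module implements the titration arithmetic
used alongside the sequencing: infectious titre `TU/mL = (F × C / V) × D`
with 5–25 % flow-cytometry gating, genome-particle titre, qPCR vector
copies per cell against a diploid RNase P reference, and mass ↔ molar
construct-ratio conversion for multi-construct transfections.

## Worked example

```r
library(strandquant)

toy <- toy_references(seed = 3)          # 5 kb construct + 2 kb host decoy
sc  <- scenario_library()                # dropoff / strong_pA / spacer
sim <- simulate_sample(sc$dropoff, fragment_model(20000, seed = 42),
                       references = toy$references, dir = tempdir(),
                       sample_id = "demo")

segs <- read_alignments(sim$sam, ref_ids = "transfer_vector")
tr   <- count_sample(segs, toy$references["transfer_vector"],
                     sample_id = "demo")$transfer_vector
prof <- integrate_group(list(normalize_track(tr)), "demo_group")

f <- toy$features
region_metrics(prof, f[f$name == "downstream_pA", ],
               baseline = f[f$name == "upstream_pA", ])
```

which prints (seed 42):

```
     construct_id   group_id          name start  end sense_mean_cov
1 transfer_vector demo_group downstream_pA  3500 5000    0.002666667
  antisense_mean_cov antisense_fraction retention_ratio note
1        0.001066667          0.2857143      0.09887006

```

The `dropoff` scenario programs sense transcription at rate 1 upstream of
the weak poly(A) anchor (position 3500) and 0.1 downstream: the recovered
`retention_ratio` of ≈ 0.099 matches the programmed 10 % read-through, and
the non-zero `antisense_fraction` reflects the antisense initiation
programmed over the 3' stuffer. Running the same metrics on the `spacer`
scenario gives `antisense_fraction` exactly 0.

Titre arithmetic:

```r
infectious_titre(titre_observation(percent_positive = 10,
                                   cells_seeded = 1e5,
                                   volume_ml = 0.1, dilution = 100))
#> [1] 1e+07          # TU/mL
copies_per_cell(target_copies = 8000, reference_copies = 4000)
#> [1] 4
convert_ratio(construct_set(c("a","b"), c(8000, 4000), c(1, 1), "mass"),
              "molar")$ratio
#> [1] 1 2
```

A thin command-line wrapper for the simulator, pipeline, and titre
calculator is installed at `inst/scripts/strandquant-cli.R`.

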