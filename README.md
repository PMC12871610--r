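# bivalink

Calling bivalent chromatin domains — promoters simultaneously marked by
activating H3K4me3 and repressive H3K27me3 — from binned FPKM coverage
tracks, and classifying how bivalency changes across developmental stages.

Bivalency poises developmental genes for later activation, and mapping when
it is established during early development requires comparing promoter
signal across samples whose global depth and efficiency differ. `bivalink`
is for epigenomics analysts who have per-stage coverage tracks (bedGraph,
FPKM, fixed bins), H3K4me3 peak calls and a TSS annotation, and want
reproducible per-stage bivalent gene sets and transition classes without
hand-picking cutoffs.

## The method

For gene *g*, mark *m* and stage *s*, the promoter signal is the
length-weighted mean FPKM over a window around the TSS (±1 kb for calling;
−1 kb/+500 bp for normalization), taking the **maximum over a gene's TSSs**.
Cross-stage comparability comes from saturation normalization: with
*S<sub>s</sub>* the median FPKM of the top 3,000 promoters at stage *s*,
each stage's values are multiplied by *f<sub>s</sub> = S<sub>ref</sub> /
S<sub>s</sub>* so every stage's saturated value matches the reference
stage's (*f<sub>ref</sub>* = 1).

The unified cutoff θ is calibrated, not chosen: at the calibration stage,
regions of ±2 kb around H3K4me3 peak centers with mean **raw** H3K27me3
FPKM ≥ 3 define a reference count *N<sub>ref</sub>*, and θ is set so that
the number of genes with

&nbsp;&nbsp;&nbsp;&nbsp;normK27<sub>g</sub> ≥ θ **and** normK4<sub>g</sub> ≥ θ
&nbsp;&nbsp;(equivalently *b<sub>g</sub>* = min(normK27, normK4) ≥ θ)

equals *N<sub>ref</sub>*. The same θ then calls bivalent genes at every
stage; between consecutive stages the bivalent sets are partitioned into
stage-specific and shared groups, with count timelines, fold changes and
expression summaries per group. A synthetic-data generator with planted
truth (`scenario_two_waves()`) makes the whole pipeline testable end to end.

## Worked example

```r
library(bivalink)

# four developmental stages, two waves of bivalency gain, planted truth
cfg <- scenario_two_waves(n_genes = 1000, seed = 42, genes_per_chrom = 250)
paths <- write_dataset(generate_dataset(cfg), "demo")

stages <- lapply(seq_len(nrow(paths$stages)), function(i)
  list(name = paths$stages$name[i], k27_track = paths$stages$k27_track[i],
       k4_track = paths$stages$k4_track[i], k4_peaks = paths$stages$k4_peaks[i]))
res <- run_pipeline(list(stages = stages, annotation = paths$annotation,
                         calibration_stage = "S3", top_n = 100,
                         output_dir = "demo_out"))

res$threshold
#> <bivalency_threshold> theta=11.1821 (stage S3): target 250, achieved 250
res$timeline
#>    stage n_bivalent fold_change
#> S1    S1        150          NA
#> S2    S2        149   0.9933333
#> S3    S3        250   1.6778523
#> S4    S4        397   1.5880000
res$partitions[["S3->S4"]]
#> <transition_partition> S3 -> S4: 2 S3-specific | 248 shared | 149 S4-specific
#>   shared / bivalent(S4) = 248/397 = 62.5%
```

Reading the output: 250 reference regions were derived from the calibration
stage's H3K4me3 peaks (K27-marked promoters), and θ = 11.18 reproduces
exactly that many bivalent genes there. Counts are flat across the first two
stages, then rise in two waves (~1.7× and ~1.6×) as planted; after the
second wave 62.5% of stage-4 bivalent genes were inherited from stage 3,
and the 149 newly bivalent genes are the planted "K4 gained on pre-existing
K27" block. `demo_out/` holds the call table, per-mark scale-factor audit
tables, the transition table and a JSON run report with every parameter and
input checksum.

The same functions run on real data: point the stage table at your bedGraph
tracks and peak BEDs, supply your TSS annotation, and keep the defaults
(100 bp bins, −1000/+500 and ±1000 bp windows, top 3,000 promoters, ±2 kb
regions, min mean 3) for as-published behavior. A thin command-line wrapper
lives at `inst/scripts/bivalink.R` (`simulate` and `run` subcommands).

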