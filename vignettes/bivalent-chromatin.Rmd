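---
title: "Calling bivalent chromatin domains across developmental stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling bivalent chromatin domains across developmental stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalink)
```

## The problem

Bivalent promoters carry the activating H3K4me3 and the repressive H3K27me3
mark at the same time, poising developmental genes for later activation.
Deciding *which* promoters are bivalent, and *when* bivalency appears during
development, runs into two practical obstacles:

1. CUT&RUN / ChIP coverage in FPKM is not comparable across stages — global
   efficiency and depth differ sample to sample, so a fixed FPKM cutoff means
   something different at every stage.
2. Any cutoff on promoter signal is arbitrary unless it is anchored to an
   independent observable.

`bivalink` implements a pipeline that addresses both: promoter signals are put
on a common scale by **saturation normalization**, and the single bivalency
cutoff $\theta$ is **calibrated against a peak-derived region count** rather
than chosen by eye. The same $\theta$ is then applied to every stage, which is
what makes per-stage bivalent counts and stage-to-stage transition classes
("stage-A-specific", "shared", "stage-B-specific") interpretable.

## The procedure

**Promoter quantification.** For each gene and mark, the promoter signal is
the length-weighted mean of the binned FPKM track over a window around the
TSS. Genes with several TSSs get the *highest* value among their TSSs — a
gene is bivalent if any of its promoters is. Windows at chromosome edges are
truncated and renormalized by the covered length. Two windows are in play,
both configurable:

* the *normalization window*, −1,000/+500 bp around the TSS, on which scale
  factors are computed;
* the *calling window*, ±1,000 bp, which produces the matrix that calls are
  made on.

The two defaults reflect the two roles: the asymmetric window concentrates on
the region where promoter marks are steepest, the symmetric one is the
conventional promoter definition. Which window feeds the final matrix is a
configuration choice; the default applies the factors to the ±1,000 bp
matrix.

**Saturation normalization.** Promoter marks saturate at their strongest
targets, so the top of the per-stage promoter distribution tracks global
depth rather than biology. For stage $s$ the *saturated value* $S_s$ is the
median FPKM of the top `top_n` promoters (3,000 by default; scale it down
with the gene universe — we use 10% of the universe for synthetic runs so the
median still falls inside the signal-carrying class). Each stage's column is
multiplied by a factor $f_s$ anchored at a reference stage with $f_{ref} = 1$
exactly.

A deliberate design decision lives here. Dividing each stage's saturated
value by the reference's and multiplying by that ratio ($f_s = S_s/S_{ref}$,
the `literal` convention) *amplifies* depth differences instead of removing
them. Because the stated purpose of this step is to make stages comparable,
the default convention is `equalize`: $f_s = S_{ref}/S_s$, after which every
stage's saturated value equals $S_{ref}$ (asserted to 1e-9 in the tests).
`literal` remains available behind a switch for comparison; on depth-skewed
data the two conventions produce visibly different per-stage calls, and the
convention used is always recorded in the run report.

Two consequences of anchoring worth knowing:

* multiplying any *non-reference* stage's raw tracks by a constant changes no
  normalized value (to 1e-9 relative) and no call;
* multiplying the *reference* stage's tracks by $c$ co-scales every
  normalized column and the calibrated $\theta$ by the same $c$ — ratios,
  ranks and calls are untouched, only the nominal scale moves.

**Threshold calibration.** The cutoff is anchored to an independent region
count: around the center of every H3K4me3 peak at the calibration stage a
±2 kb window is placed, and windows whose mean *raw* H3K27me3 FPKM is ≥ 3
(inclusive) count as strong-H3K27me3 domains overlapping an H3K4me3 peak.
Their number $N_{ref}$ is the target. Writing $b_g = \min(\mathrm{normK27}_g,
\mathrm{normK4}_g)$ for the limiting signal, the count
$|\{g : b_g \ge \theta\}|$ is a non-increasing step function of $\theta$
whose attainable values sit at the distinct $b_g$; $\theta$ is the
$N_{ref}$-th largest $b_g$ when the target is attainable, otherwise the
candidate minimizing the count gap, ties broken toward the larger (more
inclusive) count. Regions are counted one per peak — overlapping peaks are
not merged, matching the peak-count semantics of the target. Because the
region filter is defined on *raw* FPKM, it is intentionally depth-sensitive;
depth-invariance of the calls is a statement about everything downstream of
the target count.

**Calling and transitions.** A gene is bivalent at a stage iff both
normalized marks are ≥ θ (inclusive — a gene at exactly $(\theta,\theta)$ is
in). Between two stages the union of bivalent sets is partitioned into
A-specific, shared and B-specific; fractions are reported against both
stages' counts (the "shared out of the later stage's total" convention is the
one used for statements like "194 of 1,457 inherited"). Expression of the
groups is summarized by quartiles of FPKM or of
$\log_2\!\frac{FPKM_B + c}{FPKM_A + c}$ with pseudocount $c = 1$ by default
(configurable); no significance testing is attached to these descriptive
summaries.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 100 bp | track bin width |
| `norm_window` | −1000/+500 bp | window for scale factors |
| `call_window` | ±1000 bp | window for the called matrix |
| `strand_aware` | TRUE | orient asymmetric windows by transcription direction |
| `top_n` | 3000 | promoters behind the saturated value |
| `convention` | equalize | scale-factor direction (see above) |
| `half_width` | 2000 bp | reference region half-width around peak centers |
| `min_mean` | 3 FPKM | inclusive raw-K27 floor for reference regions |
| `target_count` | — | optional override of $N_{ref}$ |
| `pseudocount` | 1 | fold-change offset in expression summaries |

The minus-strand window is the exact mirror of the plus-strand one around the
TSS base: $[t+1-\mathrm{down},\, t+1+\mathrm{up})$ versus
$[t-\mathrm{up},\, t+\mathrm{down})$. `strand_aware = FALSE` reproduces a
strand-naive reading; for symmetric windows the difference is a single base
of placement.

## Numerical choices and degenerate inputs

* Intervals are 0-based half-open everywhere; bin $i$ covers
  $[i \cdot \mathrm{bin\_size}, (i+1) \cdot \mathrm{bin\_size})$. Peak
  centers use the floor midpoint.
* bedGraph intervals off the bin grid are rasterized length-weighted; total
  signal mass is conserved to float rounding and tested to 1e-9.
* An all-zero promoter column makes the saturated value 0 and normalization
  undefined; this raises an error rather than producing NaNs.
* An empty peak set yields $N_{ref} = 0$ with a warning. A target of 0 sets
  $\theta$ just above the largest limiting signal across *all* stages, so a
  degenerate run is silent everywhere, not only at the calibration stage.
* Tie-breaking at repeated $b_g$: when the exact target is unattainable the
  more inclusive count wins. This rule is asserted by tests against an
  exhaustive sweep; it is a package convention, not a claim about how the
  original analysis resolved ties.
* A TSS on a chromosome absent from a track scores 0; a window entirely
  outside the covered extent is an error naming the gene.

## What the synthetic data does and does not emulate

`generate_dataset()` plants, per gene and stage, one of four promoter
classes (bivalent / K4-only / K27-only / silent), draws a log-normal
promoter FPKM per mark, paints it as a plateau around the TSS over a low
uniform background, and multiplies each stage's track by a planted depth
multiplier. H3K4me3 peaks are emitted per TSS whose pre-depth K4 draw clears
a floor — peak truth deliberately does not depend on the depth nuisance the
normalization exists to remove. A fraction of genes carries a secondary,
weaker TSS; expression is drawn per class with bivalent and silent genes
low. Background noise is piecewise-constant over 10-bin blocks, which keeps
generated bedGraphs compact while remaining non-trivial.

`scenario_two_waves()` encodes the two waves of bivalency gain seen across
early development as exact-count trajectories: a block of genes gains both
marks at once between stages 2 and 3, and a block of K27-only genes gains
H3K4me3 between stages 3 and 4, alongside constitutive, early-lost, and
never-bivalent genes, with per-stage depth multipliers between 0.5× and 2×.

What this emulates well: class mixtures and their separation, multi-TSS
genes, cross-stage depth differences, peak-anchored calibration, transition
ground truth. What it does not emulate: read-level sampling noise and
count overdispersion, fragment-length and GC biases, replicate structure and
IDR peak reproducibility, signal spreading beyond promoters, and genes whose
promoter signal sits genuinely *on* the decision boundary. Passing the
planted-truth tests therefore demonstrates that the machinery is correct and
well-calibrated under separation, not that real borderline promoters are
classified with this accuracy.

Problem sizes: the full test suite and the acceptance run use 5,000 genes in
blocks of 500 per chromosome (100 bp bins, 8 kb TSS spacing) for the
end-to-end scenario and 400–1,000 genes for the invariance checks, with
`top_n` scaled to 10% of the universe.

## Known limitations

* The gene universe is whatever annotation is supplied; the run report
  records its size but the package takes no position on filtering to
  expressed genes.
* The reference-region count is raw-FPKM-based and therefore
  depth-sensitive by design; comparing $N_{ref}$ across datasets of very
  different depth requires a target override or identical processing.
* A single unified $\theta$ is applied to both marks; per-mark thresholds
  are intentionally not implemented.
* Heatmap-style clustering of transition groups is out of scope; the
  partition is pure set algebra on the calls.
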