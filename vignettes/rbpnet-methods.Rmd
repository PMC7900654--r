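---
title: "Predicting protein-RNA binding from sequence and in vivo structure: models and methods"
author: "rbpnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-RNA binding from sequence and in vivo structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA-binding proteins (RBPs) recognize their targets through a combination of
short sequence motifs and the local structural state of the RNA — many RBPs
only bind their motif when it sits in a single-stranded (unpaired) region.
CLIP-seq experiments give genome-wide binding peaks; icSHAPE-style chemical
probing gives a per-nucleotide reactivity score in [0, 1] where high values
mark flexible, unpaired nucleotides and low values mark paired ones. `rbpnet`
trains a convolutional neural network on both inputs jointly, then interprets
the trained model (saliency maps, high-attention regions, integrative
sequence-and-structure motifs) and quantifies structural differences between
cellular conditions (structurally variable sites, riboSNitches, enrichment
statistics).

## The model

Each binding site is a 101-nt window encoded as a 101 x 5 matrix: four
one-hot sequence channels (A, C, G, U; all-zero for N) and one reactivity
channel in [0, 1] with missing scores encoded as exactly -1. The network is

    y = sigmoid(FC(f_R(f_S(f_C(X)))))

* `f_C`: a 2d convolution over the length x depth plane (default kernel
  7 x 5, C = 8 feature maps) with "same" padding ((l-1)/2, (d-1)/2), batch
  normalization and ReLU.
* `f_S`: a squeeze-excitation block — global average pooling per channel,
  two fully connected layers (reduction ratio r = 2) and a sigmoid gate that
  rescales each channel, acting as channel-wise attention.
* `f_R`: a 2d residual block, average pooling over the depth axis (pooling
  the 2d feature maps into 1d vectors), and a 1d residual block. Each
  residual block is `ReLU(x + B3(ReLU(B2(ReLU(B1(x))))))` with
  `B_j = BN(Conv_j)`. Dropout (0.5, then 0.3) follows each residual block.
* a fully connected head (hidden width configurable, ReLU) and a sigmoid
  output.

The identity shortcut `x + I(x)` requires the channel width to be constant
along the residual path; we therefore keep all convolutional widths at C
(configurable) rather than widening the 1d block, since the residual
equations contain no projection shortcut. Batch-norm running estimates use
momentum 0.1; eval-mode forward passes are fully deterministic.

The loss is weighted binary cross-entropy with L2 weight decay,

    Loss = -(1/N) * sum( p_c * t * log y + (1 - t) * log(1 - y) ) + lambda * sum(w^2)

with positive weight `p_c = 2` (datasets are imbalanced at 1 positive : 2
negatives) and `lambda = 1e-6`. Predictions are clipped to
[1e-7, 1 - 1e-7] inside the loss so `log` stays finite; we read the penalty
`|W|_2` as the conventional squared-norm weight-decay term (its gradient is
`2 * lambda * w`). All forward and backward passes are implemented in R on
top of BLAS matrix products (im2col convolutions); gradients of every layer
are verified against central finite differences in the test suite.

## Training

Adam (beta = 0.9/0.999, eps = 1e-8) with base learning rate 0.001, linear
warmup from 0 over `warmup_steps` optimizer steps, and per-step global
gradient-norm clipping at 5.0. After every epoch the validation AUROC
(rank-based, midrank ties) is computed in eval mode; only the best-AUROC
parameters are kept, and training stops after 20 epochs without improvement
or at 200 epochs. Defaults (base LR 0.001, batch 64, warmup 500) are sized
for datasets of a few thousand sites; the synthetic benchmark
configurations in this package use batch 16, warmup 20 and base LR 0.003,
because a ~300-sample dataset otherwise provides too few optimizer steps
for the schedule to leave the warmup ramp or for Adam to traverse the early
plateau within the 20-epoch benchmark budget.

Data preparation mirrors standard CLIP processing: per-replicate min-max
normalization of peak signals to [0, 1] (all-equal signals map to 1),
merging of peaks overlapping by at least 1 nt with summed signals,
unification of every site to 101 nt (center-preserving; excess trimmed
floor/ceil left/right, deficits expanded the same way, clamped at transcript
ends with the shortfall carried over), a >= 40% reactivity-coverage filter,
the top 5000 sites by signal as positives, and 10000 random coverage-matched
windows avoiding all positives as negatives, subsampled to 1:2
positive:negative and split 4:1 into training and validation. The split is
stratified per class — the source procedure says only "randomly split", but
stratification stabilizes AUROC at small n and is the only deviation.

## Interpretation

SmoothGrad saliency: `M(x) = x ⊙ (1/n) Σ g(x + N(0, σ²))` with
`g(x) = ∂y/∂x` computed by backpropagation in eval mode. Defaults n = 10,
σ = 0.15 (about 15% of the one-hot dynamic range); both are exposed because
no canonical values exist. Plain gradients are the default so that the
finite-difference oracle remains valid; guided backpropagation
(positive-gradient gating at every ReLU) is available via `guided = TRUE`.
The L x 5 attribution is reduced to two tracks: the sequence response is the
sum of the positive parts of the four one-hot channels, the structure
response the absolute reactivity-channel attribution. This reduction is our
own definition — the two heat-map tracks it mimics were never given a
formula.

High-attention regions (HARs) are 20-nt windows (step 1) with the highest
mean response: the argmax window (leftmost on ties) in `single` mode, or the
top 20% of windows (count rounded up) merged into disjoint intervals in
`top20pct` mode. Sequence and structure HARs overlapping by >= 1 nt are
classified SequenceAndStructure, the rest SequenceOnly / StructureOnly.

Integrative motifs are built from the top-20% attention windows of sites
with predicted probability > 0.8. Reactivity is binarized at 0.233 (the
median of the original transcriptome-wide score distribution; recomputable
per dataset) into U (unpaired, >= 0.233) and P (paired). All 6-mers are
clustered greedily, seeded by descending frequency; a 6-mer joins a cluster
when, at the best offset in {-1, 0, +1} with overhangs ignored, its sequence
Hamming distance is <= 1 and its structure Hamming distance <= 2. Cluster
members are tallied into a 4 x 6 sequence PWM and a 2 x 6 structure PWM with
pseudocount 0.01 per cell (so scan scores stay finite), the motif weight is
the member k-mer frequency over all k-mers, and near-duplicate PWMs
(stacked-PWM Pearson correlation > 0.8 at the best offset) are merged — an
internal replacement for an external motif-comparison tool. Weights are
tested against a uniform 10% baseline with one-sided Fisher tests.

Scanning computes `R = Σ log10 p_seq + Σ log10 p_struct` at every position
whose 6-nt window is fully reactivity-covered, and converts R to an
empirical p-value against 200,000 positions sampled uniformly from the
covered positions, with the +1 rank correction `(#null >= R + 1)/(n+1)` so p
is never zero. The null is drawn per motif from a per-motif seed offset.
Motif similarity for clustering is the Euclidean distance over all PWM
cells; trees use average-linkage agglomeration (the linkage was left open by
the source; average linkage is the common choice for profile distances) and
export to newick.

## Comparative structure statistics

Replicate noise is calibrated as the nearest-rank 95th percentile of pooled
per-nucleotide |s1 - s2| between replicates (ΔS_noise); this fixes the
binomial success rate at p = 0.05. For two conditions, 20-nt windows (step
1) count structurally variable nucleotides (cross-condition L1 above
ΔS_noise) among the jointly covered positions m (windows with m < 10 are
skipped; the binomial n is m, our documented choice for partial coverage).
A window is called when the exact binomial tail P(K >= k) is < 0.05 *and*
its mean L1 exceeds ΔL1, the nearest-rank 90th percentile of all window
means; called windows merge into disjoint structurally variable sites.
Per-window raw p-values mirror the source procedure; an optional
Benjamini-Hochberg flag is provided but off by default. A differing-allele
variant inside such a site is a putative riboSNitch; a differing-allele
variant outside every site is a variation of stable structure (VSS);
same-allele variants are excluded.

Enrichment machinery: permutation tests resample length-matched region sets
uniformly from a user-supplied universe (1000 draws, rank p with the +1
correction, mirrored for depletion); odds ratios use the Haldane-Anscombe
0.5 correction on zero cells and one-sided hypergeometric-tail p-values
(verified against `fisher.test`); group comparisons are one-sided Welch
t-tests.

## The synthetic generator

The generator emulates the statistical structure the pipeline assumes, with
every planted feature recorded as ground truth: i.i.d. uniform ACGU
background; a block-wise paired/unpaired architecture (block lengths 15-40
nt); one planted consensus (default GCAUG) per transcript, placed in an
unpaired context with probability 0.5 and otherwise in a paired context as a
decoy; binding requires motif AND required context, and only bound sites
emit peaks (two replicates, jittered intervals, logistic-scale signals).
Chance occurrences of the consensus in the background are mutated away so
that ground truth and sequences stay exactly consistent. Reactivity follows
a two-state model — unpaired mean 0.7, paired mean 0.1, Gaussian sd 0.1,
clipped to [0, 1] — chosen so the 0.233 binarization threshold separates the
states; replicates add sd-0.05 noise; 10% of positions are missing.
Condition B shares condition A's biological base profile except at planted
20-nt structure flips (and allele changes at planted variants), so
cross-condition differences outside planted changes reflect technical noise
alone — exactly the premise of the ΔS_noise calibration. What the generator
does *not* emulate: realistic transcript-length and expression
distributions, thermodynamic folding, position-dependent coverage, or
sequence composition bias; passing tests therefore demonstrate correctness
of the algorithms under their stated assumptions, not performance on real
transcriptomes.

The standard benchmark (200 transcripts x 500 nt) yields roughly 100
positives and 200 negatives (planted decoys plus random windows, 1:2), on
which sequence alone cannot separate the classes: a motif-presence oracle
tops out near AUROC 0.83 while the full rule is perfectly separable. The
compact model (C = 8, hidden 32) reaches validation AUROC >= 0.95 within 20
epochs on one CPU; these problem sizes were chosen so the whole suite runs
comfortably on a laptop.

## Numerical choices and degenerate inputs

* Probability clipping 1e-7 in the loss and in the reverse-sigmoid score
  `S = -ln(1/P - 1)`.
* Min-max normalization maps an all-equal replicate to 1.0.
* Nearest-rank quantiles (`sorted[ceiling(p * n)]`) for both structure
  thresholds.
* Argmax ties: leftmost window; k-mer cluster seeding ties: lexicographic.
* Empirical and permutation p-values always use the +1 correction.
* All RNG flows from one seed per entry point; derived child seeds stay
  below 2^31.

## Known limitations

The network is CPU-bound R; it is sized for the synthetic benchmark and
for moderate real datasets, not for training 250+ models on full eCLIP
compendia. The motif-merging step replaces an external comparison tool with
a PWM-correlation heuristic. Conservation-score analyses are supported only
as generic position/score comparisons. Peak calling, variant calling and
read processing are out of scope; the package consumes their tabular
outputs.
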