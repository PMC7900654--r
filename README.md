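# rbpnet

Predicting RNA-binding-protein (RBP) binding sites from RNA sequence plus
per-nucleotide in vivo structure reactivity, and interpreting what the model
learned.

Many RBPs recognize a short sequence motif *in a particular structural
context* — typically single-stranded RNA. CLIP-seq gives binding peaks;
icSHAPE-style probing gives a reactivity score per nucleotide (high =
flexible/unpaired, low = paired). `rbpnet` joins the two:

* **Model.** A convolutional network over 101-nt sites encoded as 101 × 5
  matrices (one-hot A/C/G/U + reactivity, missing = −1):
  `y = σ(FC(f_R(f_S(f_C(X)))))` with a batch-normalized convolution block
  `f_C`, a squeeze-excitation channel-attention block `f_S` (reduction
  r = 2), and `f_R` = 2d residual block → average pooling over depth → 1d
  residual block, each residual block `ReLU(x + BN(Conv(⋯)))` with dropout
  0.5/0.3. Training minimizes weighted binary cross-entropy
  (positive weight p_c = 2) with L2 weight decay (λ = 1e−6) under Adam,
  linear warmup, gradient clipping at norm 5, and best-validation-AUROC
  early stopping. Forward *and* backward passes are implemented in R on BLAS
  matrix products and verified against finite differences.
* **Interpretation.** SmoothGrad saliency maps
  `M(x) = x ⊙ (1/n) Σ g(x + N(0, σ²))`, high-attention regions (20-nt
  windows, merged), and integrative motifs: paired 4 × 6 sequence and 2 × 6
  structure PWMs (structure binarized at reactivity 0.233) with
  log₁₀-likelihood-ratio scanning against an empirical null and
  average-linkage clustering.
* **Comparative structure.** Structurally variable sites between two
  conditions via a sliding-window exact binomial test (noise threshold =
  95th percentile of replicate L1 distances, window threshold = 90th
  percentile of window mean L1), riboSNitch vs VSS classification of
  differing-allele variants, and permutation / odds-ratio enrichment
  statistics.
* **Synthetic benchmark.** A seeded generator plants a consensus motif
  (default GCAUG) in unpaired or paired (decoy) contexts, emits peaks,
  two-replicate reactivity with calibrated noise, condition pairs with
  planted 20-nt structure flips, and variants — all with exact ground truth.

## Worked example

The demo chains the whole pipeline on a small seeded benchmark
(60 transcripts × 400 nt): simulate → prepare → train → predict → saliency →
motifs → variable sites → riboSNitches.

```r
library(rbpnet)
metrics <- run_demo(seed = 1)
str(metrics)
#> List of 9
#>  $ val_auroc          : num 1
#>  $ n_predicted_sites  : int 176
#>  $ mean_har_response  : num 0.00899
#>  $ n_motifs           : int 27
#>  $ top_motif_consensus: chr "GCAUGC"
#>  $ n_svs_called       : int 6
#>  $ n_ribosnitch       : int 3
#>  $ n_vss              : int 2
#>  $ seed               : num 1
```

Reading the numbers: the compact model separates bound from unbound windows
perfectly on the held-out validation split — the planted rule (GCAUG in an
unpaired context) is learnable only when the reactivity channel is present,
since decoy GCAUGs in paired contexts are labeled negative. The top-weight
integrative motif, `GCAUGC`, is the planted consensus plus one flanking
base, and its structure PWM is strongly unpaired. All 6 planted structure
flips between the two conditions are recovered as structurally variable
sites, and the planted variants classify exactly as 3 riboSNitches
(differing alleles inside a variable site) and 2 VSSs (differing alleles,
stable structure), with the same-allele control excluded. Rerunning with
the same seed reproduces every number exactly.

The step-by-step API (`make_benchmark()`, `train_model()`,
`predict_transcriptome()`, `smoothgrad()`, `find_hars()`, `build_motifs()`,
`scan_motif()`, `call_svs()`, `classify_variants()`,
`permutation_enrichment()`, …) is documented in the help pages and the
methods vignette (`vignettes/rbpnet-methods.Rmd`). A thin command-line
wrapper lives at `inst/scripts/rbpnet-cli.R`.

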