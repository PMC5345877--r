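---
title: "Imputing cell-specific TF binding with gated convolutional embedding networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing cell-specific TF binding with gated convolutional embedding networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

ChIP-seq measures where a transcription factor (TF) binds in one cell
line, but the matrix of (TF, cell line) combinations is profiled only very
sparsely: a few hundred combinations out of tens of thousands of possible
ones.  `tfgate` implements a multi-task model that trains on *all*
available combinations at once and can then predict binding for a
combination that was never profiled, as long as the TF and the cell line
each appear somewhere in the training data.  The mechanism is a
convolutional motif scanner whose per-filter outputs are multiplied by
*gates* computed from learned TF and cell-line embeddings: a filter that
detects a motif irrelevant to the queried condition can be switched off by
the gate.

## The model

An input is a triple (sequence $S$, TF, cell line); the target is a 0/1
binding label.  The forward pass is:

1. **One-hot encoding.** $S$ of length $N$ becomes an $N \times 4$ binary
   matrix $X$ under the fixed column order (A, C, G, T).  An ambiguous
   base N becomes an all-zero row — it contributes nothing to the linear
   convolution.  (This convention is ours; the source model never
   discusses ambiguous bases.)
2. **Convolution.** $Y_{r,k} = \sum_{i=1}^{F}\sum_{j=1}^{4}
   W^{(k)}_{i,j}\,X_{r+i-1,j}$, a valid convolution with $K$ filters of
   length $F$, giving an $(N{-}F{+}1)\times K$ map.
3. **Thresholded rectifier.** $\mathrm{ReLU}(x, b) = x$ if $x > b$, else
   $0$, with one threshold $b_k$ per filter (different motifs have
   different affinities).  Taken literally this passes *negative* values
   whenever $b < 0$ — and $b$ is initialized at $-4$.  The default
   (`relu_mode = "literal"`) honors the printed formula; a conventional
   shifted rectifier $\max(0, x - b)$ is available as
   `relu_mode = "shifted"`.  Note that under the literal form
   $\partial z/\partial b = 0$ almost everywhere, so the thresholds never
   train; that is a consequence of the formula as printed.
4. **Max-pooling** over non-overlapping windows of `pool_window`
   convolution positions (last window truncated).  With the
   open-chromatin configuration ($N{=}300$, $F{=}20$, window 100) each
   filter yields exactly 3 pooled values; with the 100 bp configuration,
   exactly 1.
5. **Gates.** The TF and cell-line embeddings (50 dimensions each) are
   concatenated — TF half first, 100 values total — and passed through a
   one-layer sigmoid network: $G = \sigma(W_1\,e + b_1)$, one gate per
   filter, strictly in $(0,1)$.  The same gate multiplies all pooled
   windows of its filter, *after* pooling.
6. **Output.** $F(S) = \max(W_2\,\mathrm{vec}(M) + b_2)$ where
   $M = G \odot \mathrm{Pooling}(\cdot)$ — the maximum over the
   fully-connected layer's outputs, exactly as printed; no extra output
   weight vector is introduced.
7. **Strand symmetry.** The final score is
   $\max(F(S), F(\mathrm{revcomp}(S)))$, so predictions are *exactly*
   invariant under reverse complementation (tested to floating-point
   equality).

The score-to-probability mapping (logistic) and the loss (binary
cross-entropy) are our choices; the source describes only "comparing the
prediction with the target".  TF and cell-line embeddings live in two
separate tables; a single shared table would be equivalent, two are
clearer.

A long-sequence variant (`multi_tf_config()` / `train_multi_tf()`)
predicts all TFs at once for one cell line: the cell-line embedding has
length $K$ and is squashed directly into gates, the gated pooled signal
(windows of 50) is fed as a sequence into a GRU, and the last hidden state
maps linearly to one output per TF.  Production scale (1,000 bp, 2,000
filters, hidden size 1,000) is reachable by configuration; the tests run
it scaled down.

## Training

Optimization is AdaDelta (accumulator decay $\rho = 0.95$,
$\epsilon = 10^{-6}$ — the original AdaDelta constants; the source names
the method but not the constants).  "Learning-rate decay 0.03 per 50,000
instances" is read multiplicatively: the computed update is scaled by
$(1 - 0.03)^{\lfloor \mathrm{seen}/50000 \rfloor}$.  AdaDelta has no base
learning rate, so this is the only sensible attachment point; with decay 0
the schedule is identically 1.  Mini-batch size (64) and uniform shuffling
are our choices; neither is stated.

Weights start at $\mathcal{N}(0, 0.01^2)$, rectifier thresholds at $-4$,
all other biases at 0.

Checkpointing follows the dual-validation protocol: every 50,000 instances
the pooled AUC is computed on two validation sets — one drawn from
combinations present in training (selects the model used on
within-combination test sets) and one of held-out combinations (selects
the model used for imputation).  `merge_and_retrain()` reproduces the
final-model protocol for downstream analyses: find the early-stop point on
the held-out-combination validation set, then retrain on everything
including that validation set for exactly that many instances.

### Implementation note

The fused convolution + rectifier + max-pool forward and its backward pass
are compiled (Rcpp), with the inner accumulation laid out contiguously
over filters; everything else (gates, fully connected layer, AdaDelta) is
plain R linear algebra.  Pure-R reference implementations of every
operation (`convolve_onehot()`, `thresholded_relu()`, `max_pool()`,
`strand_score()`) remain the package's spec surface and are compared
against the batched compiled path exactly in the tests.  All gradients are
verified against central finite differences (relative error $\le 10^{-4}$,
in practice $\sim 10^{-6}$) for both rectifier modes and for the GRU
variant.

## Dataset construction

Two negative-set constructions are provided:

* **Dinucleotide-preserving shuffles** (`dinucleotide_shuffle()`): the
  Eulerian-path (Altschul–Erickson) algorithm, which preserves the exact
  multiset of overlapping dinucleotides (hence mononucleotide counts and
  both end bases) and samples uniformly among valid shuffles.  Swap-based
  approximations were rejected because exact preservation is the
  requirement.  Positives containing N are dropped before shuffling — the
  shuffle is undefined over N.
* **Union-DHS negatives** (`build_union_dhs()`, `build_dhs_negatives()`):
  every DNase peak trimmed to 300 bp around its summit, merged across
  datasets (`GenomicRanges::reduce`), and negatives sampled uniformly from
  union regions with zero overlap against the TF's peaks, each matched
  1:1 with a positive.

Peaks are ranked by narrowPeak column 7 (signalValue) — the source says
only "top" peaks — with ties broken by (chrom, start).  Windows are
summit-centered: $[\,s - \lfloor w/2 \rfloor,\ s - \lfloor w/2 \rfloor + w)$,
0-based half-open throughout.  For the random-background protocol,
1-based odd ranks of the top 1,000 peaks feed training and even ranks the
test pool (500 + 500).

### Combination partitioning

The imputation benchmark needs the largest possible holdout of
combinations such that every TF and cell line in the holdout still occurs
in the remaining base set.  Maximizing the holdout is *exactly* equivalent
to minimizing the base subject to covering all TFs and cell lines — a
minimum edge cover of the bipartite combination graph, solved exactly via
maximum bipartite matching (Gallai's identity: minimum cover = vertices −
maximum matching).  We implement the exact algorithm rather than a greedy
heuristic; a single-pass greedy provably stalls at 5 on the fully crossed
3×3 toy whose optimum is 6, and the exact solution is verified against
exhaustive enumeration on random small grids in the tests.  From the
holdout, 20 combinations (configurable) are sampled as the
held-out-combination validation set and the rest form the imputation test
set; base combinations with ≥ 2 replicate experiments form the replicate
test set.

## Evaluation

* `roc_auc()`: rank (Mann–Whitney) formulation, ties counted 1/2;
  single-class input is `NA` with a warning.
* `grouped_auc()`: per-TF or per-combination AUCs; single-class groups
  dropped with a warning.
* `recall_at_fdr()`: the smallest threshold whose calling set has
  FDR ≤ q, ties included in the calling set.  The threshold is chosen on
  the test data itself, exactly following the original protocol — this is
  optimistic by construction but uniform across methods that have no
  training set.
* `shuffle_field()`: the wrong-TF / wrong-cell-line negative controls.
* `bin_and_label()`: genome tiling with peak-center labels (summit when
  present, else midpoint; half-open bin membership).
* `compare_grouped_auc()`: a paired Wilcoxon signed-rank test; the test
  behind the published grouped p-values is unstated, so we provide this
  without targeting those numbers.

## Downstream analyses

* `snp_delta()`: probability(allele A) − probability(allele B) for every
  (TF, cell line); antisymmetric under allele swap, exactly 0 for
  identical alleles, bounded in (−1, 1).
* `enhancer_signature()`: first principal component of the
  column-centered (not scaled — unstated in the source, centering is the
  minimal choice) sequences × TFs affinity matrix.  A PC's sign is
  arbitrary and genuinely flips between cell lines in the original
  analysis, so we fix it to correlate non-negatively with the
  per-sequence mean affinity.
* `top_bottom_test()`: Welch's t-test (the pooled-vs-Welch choice is
  unstated; Welch is the safer default) between signatures of the top and
  bottom 100 sequences ranked by measured activity.
* `cluster_embeddings()`: average-linkage clustering under 1 − Pearson
  distance (both unstated; this pairing is the common choice for
  expression-style profiles), serializable to Newick via `ape`.

## The synthetic world

`make_world()` defines the ground truth every test runs against: one PWM
per TF with a sharp consensus, a binary TF × cell-line activity matrix
(Bernoulli 0.7, repaired so every TF and cell line is active somewhere),
and an order-1 Markov background (GC 0.41, human-like; persistence 0.1 so
that dinucleotide shuffling is a non-trivial control).  Two TFs share one
PWM on purpose, to make embedding clustering testable.

Calibration: per-position consensus probabilities are drawn from
U(0.85, 0.97) and planted instances are rejection-sampled to at most 2
consensus mismatches.  Both choices exist to make the world satisfy its
own stated invariants — planted motifs within Hamming distance 2 of the
consensus, and a PWM log-odds scanner that separates active combinations
at AUC ≥ 0.95 (with the softer U(0.8, 0.95) draw the scanner sat at
~0.947).  The scanner (`pwm_scan_score()`) is also the *Bayes-style
ceiling*: tests assert the trained model never beats it by more than 0.03
on any combination, which guards against label leakage.

Instances: active combinations emit background sequences with one PWM draw
planted at a uniform position and strand (positives) and pure background
(negatives), balanced 1:1.  Inactive combinations emit pure background for
*both* labels — binding is absent, so their labels are irreducible coin
flips.  Those uninformative instances are not waste: they are the only
training signal that activity is combination-specific, and without them
the model never learns any cell-line dependence.

What a green test does *not* establish: the world is motif-driven and
cell-gated only.  Real ChIP-seq has cooperative binding, chromatin
context, GC and mappability artifacts, and graded binding strength, none
of which are emulated; accuracy numbers on this world say nothing
quantitative about accuracy on ENCODE-scale data.

## The scaled-down imputation benchmark

`run_imputation_benchmark()` is the package's core end-to-end experiment
(8 TFs × 5 cell lines, activity density 0.7, 2,000 instances per
combination, model K = 64, F = 12, N = 100, 5 epochs): hold out 4 active
combinations whose TF and cell line each appear elsewhere, train on
everything else, and measure mean per-combination AUC on the held-out
combinations, plus the shuffled-TF and shuffled-cell controls and the
oracle ceiling.  Design choices:

* Two *additional* active combinations are held out as the
  imputation-validation set — the dual-checkpoint protocol requires one,
  and using the graded test combinations for checkpoint selection would
  leak.
* The 4 test combinations use distinct TFs and distinct cell lines, and
  never include both members of the shared-PWM pair: two TFs with
  identical PWMs are sequence-indistinguishable, so swapping one for the
  other in the shuffled-TF control is not a "wrong TF" at all.
* Only the test combinations must be active — an inactive combination has
  no binding to detect and its AUC is 0.5 by construction.

At this scale the 5-epoch protocol is still convergence-limited (the
original model trained on ~60× more instances per epoch): held-out AUC
reaches ≈ 0.84–0.91 against an oracle ceiling of ≈ 0.93–0.99, the
TF-shuffle control drops AUC by ≈ 0.14–0.21, and the cell-line-shuffle
control barely moves it — the qualitative ordering (sequence/TF identity
dominates, cell line is secondary) that motivates the whole design.
Cell-line-specific gating emerges more slowly than motif detection,
because the gate path is a product of three small learned factors; by
20 epochs the gates visibly encode the activity matrix, which is the
regime the downstream analyses (SNP deltas, enhancer signature) assume —
they therefore run on a 20-epoch model, mirroring the original work's use
of its final fully-trained network for those analyses.

## Numerical conventions

* Coordinates: 0-based half-open everywhere on disk; `GRanges` used
  internally for interval arithmetic (1-based closed, converted at the
  boundary).
* Pooling and strand ties break toward the first position / forward
  strand deterministically.
* Model files are versioned JSON with full-precision arrays (round-trip
  agreement to ~1e-15 relative; bit-exactness is not guaranteed through
  decimal text).
* All stochastic steps consume the R session RNG: `set.seed()` makes any
  pipeline bit-reproducible, and identical seeds give identical training
  checkpoints (single-threaded).

## Known limitations

* The literal rectifier never trains its thresholds (zero gradient); the
  shifted mode does, but is not the printed formula.
* `recall_at_fdr()` thresholds on test data (as specified) and is
  therefore optimistic.
* The exact minimum-edge-cover partition is optimal for the holdout-size
  objective but, like the original, does not balance instance counts
  across subsets.
* Training is single-threaded by design (determinism); an ENCODE-scale
  run would need the production-scale configuration and hardware this
  package does not target.
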