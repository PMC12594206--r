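---
title: "Models and methods behind spliceppi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliceppi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spliceppi packages, at desk scale, the quantitative machinery used to
study how NAD⁺ precursors influence neuronal alternative splicing and the
protein interactions of a splicing-linked membrane protein: a
prompt-guided multi-task protein encoder for protein–protein-interaction
(PPI) screening, percent-spliced-in (PSI) statistics for alternative
splicing events (ASEs), and the bespoke assay statistics (reporter
splicing index, chemotaxis index, Manders colocalization). Everything
runs on seeded synthetic data so that each statistical claim in the test
suite is checkable end to end. This vignette explains the models, the
defaults, and what the synthetic conditions do and do not show.

## The prompt-guided multi-task encoder

The encoder maps an amino-acid sequence to per-residue representations
$h_p \in \mathbb{R}^{L \times d}$. Three pretraining tasks share it, each
steered by its own learned prompt token prepended to the sequence:

* **Masked-residue modelling (MLM).** With $Y$ the masked positions and
  $V$ the 20-residue vocabulary, the loss is
  $L_{\mathrm{MLM}} = \sum_{y \in Y} -\log q(y \mid h_p)$ with $q$ a
  softmax over $V$. Masking is exact-count: `round(rate * L)` distinct
  positions (default rate 0.15 for the standalone operation, 0.2 during
  pretraining), sampled without replacement. The softmax is taken over
  the vocabulary; uniform scores therefore cost exactly $\ln 20$ nats
  per masked residue, which the tests pin down.
* **Cα-coordinate prediction (CRD).** A two-layer perceptron κ predicts
  an $L \times 3$ coordinate matrix; the loss is the mean squared error
  after optimal rigid (Kabsch) superposition of the prediction onto the
  ground truth $Z$, so neither global rotation nor translation is
  penalized. The gradient holds the optimal transform fixed, which is
  exact at the optimum (envelope argument) and is verified against
  finite differences.
* **Pair interaction (PPI).** For proteins $m, n$ the pair-aware
  representation is built from
  $\mathrm{Attn}_{m,n} = \sigma\!\big((H_m W)(H_n W)^\top / d_W\big)$
  and the concatenation of the row-means of
  $\mathrm{Attn}^\top H_m$ and $\mathrm{Attn}\, H_n$; a
  classification head turns it into an interaction probability scored
  by binary cross-entropy, summed over the batch.

The multitask objective is
$L = \alpha_1 L_{\mathrm{MLM}} + \alpha_2 L_{\mathrm{CRD}} +
\alpha_3 L_{\mathrm{PPI}}$ with three independent weights defaulting to
1 (the printed form of the objective reuses one symbol for two weights;
we expose three). For downstream use, a linear prompt-tuning module
$\tau_\theta$ maps the concatenated task prompts to a single tuned
prompt $p'$; fine-tuning optimizes $\tau_\theta$ and the pair head on
training edges only, with the encoder frozen.

### Reading conventions adopted

Three details of the printed equations are ambiguous and were resolved
as follows (each is a config option where meaningful):

* The MLM softmax denominator is taken over the vocabulary $V$, not over
  the masked set; summing over the masked set would make the loss depend
  on which other positions happen to be masked.
* The pair-attention logits are divided by $d_W$ before the sigmoid
  (scaled-attention convention; `scale_attn = FALSE` disables it).
* "mean" in the pair representation is the row-mean, giving two
  $d$-vectors whose concatenation swaps halves when the two proteins are
  swapped — a property test exercises this.

### Architecture and training choices

The encoder is deliberately small (defaults: width $d = 16$, one
attention + feed-forward block, feed-forward width 32) so that a full
pretraining run takes about a minute of one CPU. Two additions matter:

* **Local-context embeddings.** Each residue's input embedding mixes in
  a learned linear map of the embeddings within ±2 positions. Interaction
  signal in the planted corpora (and in real interfaces) lives in short
  sequence patterns; without local context, per-residue representations
  can only reflect single letters plus a global summary, and no amount of
  training recovers motif identity. A fixed sinusoidal positional
  encoding (amplitude 0.1) supplies the absolute positions that the
  coordinate task needs.
* **A one-hidden-layer pair head.** "Both proteins carry the *same*
  latent pattern" is not linearly decodable from the concatenated pair
  representation (it is an exclusive-or across pattern classes); a
  single hidden layer makes it decodable. The head is fitted first on
  frozen representations (cheap, thousands of Adam steps on cached
  features), then refined jointly with the prompt-tuning module. Its
  decision threshold is calibrated on training pairs at their natural
  class ratio, because the head is trained on balanced batches.

Training uses Adam with global-norm gradient clipping (norm 25), small
batches for the residue tasks, and a per-epoch protein *clique* for the
pair task so that one epoch's pair gradients reuse a few dozen encodings.
A two-phase schedule spends the first ~55% of epochs building features
(masked-residue-heavy) and the remainder interaction-heavy. All
randomness flows from one root seed through named substreams, so every
run is bit-reproducible on one thread.

### Kabsch superposition

`kabsch_superpose` computes the SVD of the cross-covariance of the
centered point sets and corrects the sign so the rotation is always
proper (determinant +1); coincident-point input returns the identity by
convention. The acceptance tests compare it on random 4–8-point
instances against a brute-force rotation search (a 6° Euler-angle grid
refined locally at 0.5°) and against `bio3d::fit.xyz`.

## PPI screening

Networks are split three ways. BFS and DFS splits traverse the
positive-edge graph from a seeded-random root (restarting across
components) and accumulate visited proteins as held-out proteins until
the fraction of pairs incident to them reaches the target; *every* pair
touching a held-out protein is a test pair, the stricter convention that
avoids leakage. The random split samples pairs uniformly. A hub root in
a dense graph can legitimately pull all pairs into the test set; the
split is still a valid partition and downstream fitting refuses the
empty training set. Binary, positive-class F1 is the comparison metric.

Candidate screening ranks partners of a query protein by predicted
probability, removes candidates carrying user-supplied exclusion tags
*before* truncating to the cap (default 100, mirroring a manually
curated top-100 shortlist), and breaks score ties lexicographically.
The consensus over per-isoform rankings keeps candidates present in all
rankings, ordered by best worst-rank (minimax), ties by mean rank then
identifier — the rule that elevates a partner ranked highly against
every isoform.

## Splicing metrics

Gene models use 0-based half-open exon intervals internally (GTF input
is converted on read). Pairwise transcript comparison yields five event
classes — exon skipping (ES), multiple exon skipping (MES), intron
retention (IR), and alternative 5'/3' splice sites (A5SS/A3SS, oriented
by transcription strand) — de-duplicated by type and defining
coordinates. Composite differences are reported as multiple atomic
events. The classifier is held equal, event for event, to a brute-force
enumeration oracle on random toy gene models, and flipping the strand
annotation must swap A5SS↔A3SS exactly.

The inclusion level (PSI) of an event is the length-normalized fraction
$(I/l_I) / (I/l_I + S/l_S)$ with $I$, $S$ the inclusion and skipping
junction reads and $l_I$, $l_S$ effective lengths; zero-coverage events
are flagged missing rather than zero. For differential inclusion we pool
replicates per group and use a binomial likelihood-ratio test of equal
versus free inclusion probabilities (the binomial success probability is
the effective-length-weighted inclusion probability, so equal rates mean
equal PSI). This is a deliberate, documented simplification of the
rMATS paired model — the tool the source analysis ran — and equivalence
with rMATS is not claimed; at depth 500 with three replicates its type-I
error sits at the nominal 5% and power against ΔPSI = 0.3 exceeds 95%,
which the acceptance suite measures. Benjamini–Hochberg adjustment is
applied across all events in a run. The reporting filter keeps events
with |ΔPSI| > 0.1 and adjusted p < 0.05, both strict.

Condition-set logic is UpSet-style: exclusive membership patterns over
named event sets (their counts must sum to the union size), plus a rule
language `in(A) & in(B) & !in(C) & !in(D)` evaluated per event — the
four-comparison rule used to isolate treatment-specific events is
expressed this way and is user-overridable, since the final exclusion
clause in the published selection is itself a judgment call.

## Assay statistics

* **Reporter splicing index**: GFP/mCherry per worm (inclusion vs
  skipping reporter); group summaries are mean ± SEM with the sample
  (n−1) standard deviation. Worms with zero mCherry are excluded with a
  warning rather than silently scored.
* **Chemotaxis index**: (#IA − #T)/(#IA + #T + #S) over gradient, trap
  and start region counts; in [−1, 1], antisymmetric under swapping
  gradient and trap. Lower values indicate better memory performance
  under the assay's convention.
* **Manders coefficients**: the intensity-weighted originals with
  explicit per-channel thresholds defaulting to 0 — M1 is red intensity
  where green is above threshold over red intensity where red is above
  threshold, M2 symmetric. The thresholded variants are the same
  operations with nonzero thresholds; which variant a given commercial
  "Coloc" tool reports is not documented, so both are exposed through
  one interface. ROI percentages divide white (colocalized), red-only
  and green-only ROI counts by their total, ×100; drawing ROIs was a
  manual step on real slides, so the operation consumes pre-labelled
  ROIs and a tiling helper labels synthetic images for tests.

## The synthetic-data generators

The generators define the conditions under which every statistical claim
is tested; their defaults are fixed once:

* **Proteins**: 200 uniform-random sequences of 50–100 residues, each
  carrying one of 4 planted 8-residue motifs at a random position.
  Motif-sharing pairs interact with probability 0.9, others with 0.05 —
  a strong planted signal with realistic family sizes. Under these
  rates a motif-aware baseline tops out near the positive-class Bayes
  F1 of ≈ 0.88 (precision is capped at 0.9 and recall by the
  cross-family positives), which is why the end-to-end learnability
  bar is held-out F1 ≥ 0.8 against a label-shuffled control.
* **Structures**: an ideal α-helix Cα trace (rise 1.5 Å, radius 2.3 Å,
  100°/residue — consecutive-Cα spacing 3.83 Å) plus isotropic Gaussian
  noise; any rigid template suffices as ground truth for a loss that is
  superposition-invariant by construction.
* **Junction reads**: totals Poisson at the configured depth; inclusion
  reads binomial with the effective-length-weighted inclusion
  probability, making the PSI estimator calibration-consistent by
  construction (|bias| < 0.01 at depth 2000).
* **Reporter worms**: log-normal per-worm channel intensities around the
  designed group means with a common coefficient of variation (default
  0.3; per-worm index noise is then ≈ 44%, so designed group ratios are
  recovered within 5% only on averages over replicate assays).
* **Images**: a designed fraction of red-support pixels also carries
  green signal, chosen independently of intensity, so Manders M1
  estimates that fraction (±0.02 at 256²); fractions 1 and 0 give
  identical and disjoint supports exactly.
* **Chemotaxis counts**: multinomial over the three regions.

What passing these tests shows is that the *computations* are correct
and the statistical machinery is calibrated under known generative
models. It does not show that the encoder scale, the binomial splicing
test, or the planted-motif interaction model transfer to real corpora:
real interaction signal is not a literal shared substring, real junction
reads are overdispersed relative to Poisson–binomial sampling, and real
fluorescence has structured (not log-normal i.i.d.) variation.

## Numerical and degenerate-input conventions

Sequences are uppercased and non-canonical residues map to a dedicated
unknown token. Softmax and binary cross-entropy are computed with
max-shifting / probability clamping at 1e−12. Coincident-point
superposition returns the identity rotation; reflection cases are
sign-corrected. Zero-coverage splicing events and below-threshold
channels are flagged, never coerced to 0. Score ties in rankings break
lexicographically so output is deterministic. Problem sizes in the test
suite (200-protein corpora, 1000–2000 simulated events, 256² images,
4–8-point superposition instances) were chosen so the full suite
exercises every claim in minutes on one CPU.
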