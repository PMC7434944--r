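---
title: "Signal-guided revision of basecalled nanopore reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-guided revision of basecalled nanopore reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanorevise)
```

## The problem

Nanopore sequencers report a raw current trace; a basecaller segments that
trace into *events* (one pore state each) and translates them into bases.
Basecalls retain a substantial error load — deletions, insertions and
mismatches at a few percent each — yet the raw signal still carries
information the basecaller discarded. `nanorevise` is a post-basecalling
*reviser*: it keeps the basecaller's segmentation as a scaffold, re-reads the
raw signal underneath each called base, and edits the read where two
independent neural predictors agree the call was wrong. No consensus across
reads is built; each read is corrected on its own.

## From events to training examples

**Re-segmentation.** Basecaller events carry a `move` field: 0 means the DNA
did not advance between events, 1 and 2 mean it advanced one or two bases.
`resegment_events()` converts the event stream into exactly one event per
called base: stay events merge into their predecessor (a leading stay merges
forward), and a double-move event's samples are split at the interval
midpoint, with `ceiling(length/2)` samples to the first base. The midpoint is
a deliberate neutral choice — the event table carries no dwell information
that would justify an uneven split. Means and standard deviations are
recomputed from the raw samples of each final interval, and the union of
sample intervals is exactly preserved.

**Normalization.** Raw currents are normalized per read by median/MAD scaling
(`(x - median) / (1.4826 MAD)`), falling back to the standard deviation when
the MAD is zero. Median/MAD is robust to current spikes, and per-read scaling
absorbs pore-to-pore offset and gain differences. Per-event normalization was
considered and rejected: events are short (a handful of samples), so
per-event statistics would be dominated by noise.

**Labels.** Reads are aligned to a reference and each base-level event gets
two labels: an error-type label in {A, C, G, T, I, D} and a true-base label
in {A, C, G, T}. Matches and mismatches carry the reference base in both
labels; an inserted read base is labeled `I` with the called base as its
true-base label; a reference deletion attaches `D` to the event immediately
*preceding* the deleted bases, with the first deleted base as the true-base
label. Attaching to the preceding event mirrors the physical situation — the
pore had traversed the missing base while that event was still open — and
the first-base-only convention matches the one-label-per-event output space:
of a multi-base deletion only the first base is recoverable in one pass,
which is a documented limitation. Minus-strand alignments are handled by
reverse-complementing the reference into read (basecall) orientation before
labeling, so events never leave basecall orientation. Soft-clipped events
are flagged and excluded from training.

**Windows.** Each event becomes the center of a 13-event window (the window
size at which the error-type model performed best; configurable). Per
position the feature vector is the one-hot called base (4), the event mean
and standard deviation on the normalized-current scale, and the event length
relative to the read's median event length (3) — plus a one-hot methylation
type (3) when the methylation channel is enabled. Positions beyond the read
ends are all-zero padding. The window's signal input concatenates the member
events' normalized samples, each padded or tail-truncated to a fixed per-event
cap (40 samples by default).

## The model

Two networks share one architecture and differ only in their output space:
model 1 predicts the six error-type classes, model 2 the four true bases.

* **Signal branch**: a stem 1×3 convolution (8 filters, stride 1) followed by
  an identity block of three residual blocks, each
  conv → batch-norm → ReLU → conv → batch-norm plus the shortcut connection,
  then mean-pooling per event back to the 13 window positions.
* **Feature branch**: two Bi-LSTM layers (state 16, tanh) with batch
  normalization.
* **Trunk**: the concatenated branches feed Bi-LSTM layers of state 64 with
  dropout 0.2, then two dense layers (64 units with ReLU, then the class
  logits) and a softmax.

The loss is `L = Ls + lambda * Lc`: softmax cross-entropy plus a center loss
`Lc = 1/2 sum_i ||x_i - c_{y_i}||^2` on the penultimate dense features, with
`lambda = 0.2`. The center loss pulls same-class features together, which
matters because the error-type classes are heavily imbalanced (most events
are correct calls). Class centers are updated after each mini-batch by the
standard rule `c_j <- c_j - alpha * sum_{y_i = j}(c_j - x_i) / (1 + n_j)`
with `alpha = 0.5`; the published description cites this center-loss scheme
without restating the update, so the canonical one is used. Optimization is
Adam (initial learning rate 0.002, beta1 0.9, beta2 0.999) for 50 epochs at
batch size 256, shuffling the training windows at the start of every epoch.
The "decay 0.05" hyper-parameter is interpreted as learning-rate decay
`lr_t = lr_0 / (1 + 0.05 t)` per epoch — the conventional reading when a
decay rate is listed next to an initial learning rate. Trunk depth (two
layers) and the dense widths are stated as one state size each in the source
configuration; two trunk layers of state 64 and a 64-unit first dense layer
are used. Weights are Glorot-uniform from the configuration seed, LSTM
forget-gate biases start at 1, and model 1 and model 2 are trained
independently with identical hyper-parameters.

During training, reported per-epoch losses satisfy
`total = Ls + lambda * Lc` exactly, and the analytic gradients are verified
against central finite differences in the test suite (worst relative error
around 1e-7 at double precision).

### Numerical engine

No deep-learning framework ships with the supporting R stack, so the
forward/backward passes are implemented in RcppArmadillo, templated on the
floating type: double precision for loss verification and gradient checks,
single precision for training throughput. Matrix work goes through BLAS;
bandwidth-bound steps (gate nonlinearities, batch-norm, the 8-filter
convolutions) have vectorized kernels with a runtime CPU check and portable
scalar fallbacks. Inference uses running batch-norm statistics and no
dropout, so per-event distributions are deterministic and independent of
batch composition.

## Merging predictions into a revised read

Per event, with argmax classes `p1` (error type) and `p2` (true base) and
original base `b`:

1. if `p1` is a base and either prediction equals `b`: keep;
2. if `p1 == p2 != b`: substitute;
3. if `p1 == I` and `p2 == b`: delete the base;
4. if `p1 == D`: keep the base and insert `p2` after it;
5. otherwise keep.

Rule 4 outranks rule 1 even when `p2 == b`: a deletion prediction concerns a
*missing neighbor*, not the event's own base, so agreement on the original
base is no evidence against it. Insertion after the D-labeled event matches
the label attachment side. Decoding is argmax-only — no probability
thresholds — and the default action is always to keep the original base,
which bounds how much damage an uncertain model can do. The decision table
is pinned exhaustively (96 cells) in the tests.

## Evaluation metrics

With `Alignlength = readlength + deletionlength`,

```
XRate     = Xlength / Alignlength            X in {deletion, insertion, mismatch}
ErrorRate = (del + ins + mm) / Alignlength
```

so the error rate decomposes exactly into the three component rates. Across
read sets, lengths are pooled before dividing (micro-average), which keeps
the shared denominator consistent. On methylated areas the per-type rates
are `XRate_k = Xbases_k / methylated_bases_k`, and the pooled
methylated-area rate is reproduced literally as the *sum* of the per-type
rates; a base-weighted alternative (total errors over total annotated bases)
is available behind `weighted = TRUE` and is what the end-to-end tests use,
since it is the direct "error rate restricted to annotated positions".
Two alignment routes feed these formulas: CIGAR walks over SAM/BAM records
(`stats_from_alignment()`), and a global pairwise alignment against a known
reference window (`stats_vs_reference()`), which is the route of choice for
short, error-dense simulated reads that seed-based mappers drop.

## The synthetic data generator

Every stage is testable without downloads because the generator emulates the
full input stack with known ground truth:

* **Pore model**: Gaussian currents per 5-mer whose level is a weighted sum
  of per-base codes with the central base dominant (±18 pA span, 1.5 pA
  noise), shifted-geometric dwell (mean 8 samples/base, minimum 2), and an
  additive current offset (default 6 pA) at annotated methylated positions.
  This is the minimal generative model consistent with event
  mean/stdv/length semantics — it makes no attempt to mimic real pore
  chemistry, homopolymer dwell behavior, or chemistry versions.
* **Errors**: single-base mismatches, insertions and deletions injected
  along the reference with a minimum spacing of 2 between error events, at
  rates calibrated so the *realized* alignment-length rates match the
  requested targets (default 15% split 6:5:8 deletion:insertion:mismatch).
  The spacing and single-base restrictions make every injected error
  recoverable by single-pass per-event labeling, which is what the
  round-trip tests rely on; real nanopore errors do cluster, so passing
  those tests bounds correctness of the machinery, not real-data accuracy.
* **Error physics**: a mismatch keeps the *true* k-mer's signal under the
  wrong called base; an inserted base reuses the previous position's k-mer
  (a stay miscalled as a move); a deleted base's dwell samples fold into the
  preceding called base's event. These choices are what make the three error
  types learnable from signal at all.
* **Event stream**: stays split events (probability 0.15) and fusions merge
  neighbors into move-2 events (probability 0.05); the truth record logs the
  canonical base-level intervals after the midpoint convention, every
  injected error, the expected labels, and the exact alignment, which is
  written straight to SAM — never re-aligned — so labeling tests are
  independent of any aligner.
* Reads are drawn from both strands (30% minus by default), exercising the
  orientation handling end to end.

## Problem sizes and the reduced profile

The full-profile defaults above match the published configuration. For
desk-scale experiments the package ships `nr_reduced_config()`: one residual
block, one feature-branch Bi-LSTM of state 16, one trunk Bi-LSTM of state
32, dense width 32, 8 signal samples per event, batch 64, 10 epochs,
single-precision arithmetic. The acceptance experiments train on 200
simulated reads of 500 bp (about 100,000 windows) and evaluate on 50
held-out reads, for three model seeds, with and without the methylation
channel; under the reduced profile this reliably more than halves the
held-out error rate. The per-event signal cap of 8 truncates roughly half of
each event's dwell; the event mean/stdv features retain the full-event
summary, so the information loss is modest.

## Degenerate inputs and tie-breaks

Constant signals normalize to all zeros; zero-length intervals, windows
larger than `2n + 1`, moves outside {0, 1, 2}, non-finite losses, label/event
count mismatches and checkpoint geometry mismatches are all hard errors.
Argmax ties in decoding resolve to the first (alphabetically first) class.
A deletion before the first alignable event has no host and is dropped with
a counter. Methylation types overlapping one position resolve by the fixed
priority m6A > m4C > modified.

## Known limitations

* Only the first base of a multi-base deletion can be recovered per pass.
* The reviser never changes the basecaller's segmentation itself; an event
  boundary error that fuses two bases survives unless the move field saw it.
* Methylation-aware revision requires an annotation and alignments at
  inference time; it cannot call methylation de novo.
* The synthetic generator's independence assumptions (uncorrelated errors,
  context-free dwell) are idealizations; performance on it does not certify
  performance on real flowcell data.

## A short worked example

```{r example, eval = FALSE}
library(nanorevise)

ds <- generate_dataset(60, read_length = 500, seed = 42,
                       methyl_density = 0.02, reference_length = 20000)
sam <- tempfile(fileext = ".sam")
write_truth_sam(ds$reads, ds$reference, sam)
refv <- setNames(ds$reference$sequence, ds$reference$ref_name)

prep <- nr_prepare_windows(ds$reads[1:50], parse_alignment(sam), refv,
                           window = 13, signal_cap = 8)
m1 <- nr_train(nr_init_model(nr_reduced_config(num_classes = 6, seed = 1)),
               prep$windows, which_label = 1)
m2 <- nr_train(nr_init_model(nr_reduced_config(num_classes = 4, seed = 2)),
               prep$windows, which_label = 2)
revised <- nr_revise_pipeline(ds$reads[51:60], m1, m2)
```
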