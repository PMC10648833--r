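---
title: "Adaptive individual cat identification: model, memory and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive individual cat identification: model, memory and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(catdrift)
```

# The problem

In a multi-cat household, attributing each litter-box visit to the right cat
turns a cheap camera into a health monitor: changes in urination or
defecation frequency are early signs of urinary-tract and digestive disease.
Identification from body crops is harder than face recognition — a body
crop may not contain the face at all — and, crucially, the data distribution
does not stand still. Cats grow from kittens to adults within months, coats
mature, lighting changes, and the cat population itself changes as animals
are adopted, rehomed or lost. A classifier trained once will silently decay.
`catdrift` implements an identification architecture designed around that
decay, together with a synthetic world that lets every mechanism be tested
end to end without animal data.

# The identification model

A feature extractor `f` maps a body-crop image to a 128-dimensional
embedding, L2-normalized to the unit hypersphere. Identity assignment is
delegated to a classical classifier operating on embeddings (KNN, random
forest, or SVM), so that retraining the *classifier* is cheap and frequent
while retraining the *extractor* is expensive and rare.

## Triplet curriculum

The extractor is trained with triplet loss on squared Euclidean distances,

$$ L(a,p,n) = \max\!\big(0,\; d^2(a,p) - d^2(a,n) + \alpha\big), \qquad \alpha = 0.2, $$

where `p` shares the anchor's identity and `n` does not. Training proceeds
through three stages that differ only in which triplets are mined from each
batch:

* **semi-hard** — negatives inside the margin window,
  $d^2(a,p) < d^2(a,n) < d^2(a,p) + \alpha$;
* **hard** — negatives closer than the positive, $d^2(a,n) < d^2(a,p)$;
* **hardest** — for each anchor–positive pair, only the globally closest
  negative in the batch (ties broken by lowest index).

The semi-hard and hard sets are disjoint by construction, which the test
suite asserts against an $O(n^3)$ brute-force enumeration. "Hardest" has no
universally agreed definition; this package fixes it as the batch-hardest
negative per anchor–positive pair.

A global orthogonal regularization term is added with weight
`gor_weight` (default 1): over all different-identity pairs in the batch
with mean dot product $M_1$ and mean squared dot product $M_2$,

$$ L_{gor} = M_1^2 + \max(0,\; M_2 - 1/d), \qquad d = 128 .$$

For uniformly spread unit vectors $M_1 \to 0$ and $M_2 \to 1/d$, so the
penalty drives embeddings of different cats toward maximal spread. It is
zero when the batch holds a single identity, and invariant under batch
permutation and global rotation (both property-tested).

## Optimization and early stopping

Adam with learning rate 0.001, $\beta_1 = 0.9$, $\beta_2 = 0.999$. Batches
are composed as P identities × K images (defaults 4 × 4) so every anchor has
positives. Each stage runs at most 100 epochs and stops early once the
validation loss has not strictly improved for 5 consecutive epochs; the
weights of the best-validation epoch are restored. The train/validation
split is stratified 8:2 by identity.

## The backbone

The embedding network is a compact strided convolutional network: 3×3
valid convolutions with stride 2 (channels 16 then 32), ReLU, global
average pooling, a dense layer to 128 dimensions and L2 normalization.
Forward and backward passes are explicit matrix algebra (im2col), verified
against finite differences in the test suite. Two blocks at a 32×32 input
give a receptive field covering most of the frame while training in
seconds on one CPU; both the block structure and the input size are
configuration parameters, and any network honoring the unit-norm 128-d
contract can stand in. Embeddings are normalized because the $1/d$ limit in
the regularizer assumes unit vectors, and distances on the sphere make the
margin scale-free.

## Fine-tuning

Adaptation-triggered fine-tuning is a single hardest-mode stage at one
tenth of the base learning rate: by that point the embedding space is
already organized, so the gentle rate preserves it while absorbing drifted
appearances. With an epoch budget of zero, fine-tuning is exactly the
identity.

# The adaptive memory

Each registered identity owns a bounded set of at most `N` embedding
records (default 200). The adaptation loop, governed by a `retrain_policy`:

1. **Session relabeling.** Users label whole sessions — one litter-box
   visit, one label for all frames. Ingested frames are embedded and staged.
2. **Selection (M-triggered).** Once an identity has `M` staged embeddings
   (default 20), the arithmetic mean of its bounded ∪ staged vectors is
   computed and the `N` vectors closest to that mean (Euclidean distance,
   ties by input order) are retained; the rest are discarded. This removes
   outliers — mislabeled or atypical frames far from the identity's center —
   and bounds server memory. The mean is a reference point only and is not
   renormalized to the sphere.
3. **Classifier refit.** After any selection event the classifier is refit
   on all bounded records. Refitting per event (rather than on a timer) is
   this package's reading of a deliberately sequenced design: selection
   first, then retraining.
4. **Fine-tune (C-triggered).** When *every* registered identity has
   accumulated `C` litter-box images since the last fine-tune (default
   500), a fine-tune action is emitted; the pipeline then fine-tunes the
   extractor on the store's images, re-embeds every bounded record with
   the new weights, and refits the classifier. `C` counts raw ingested
   images per identity, and the all-identities condition is the literal
   reading of "a sufficient number of images for all cats".

Registration embeds user-supplied photos as bounded records (trimmed by the
same mean-vector rule if they exceed `N`, so the capacity invariant holds
at every observable point); deregistration deletes an identity's vectors
entirely, and the next refit removes it from the class set — after which no
input can ever be predicted as that identity.

# Classifiers and evaluation

The comparison bank holds KNN with K ∈ {3, 5, 7}, a 100-tree random
forest, and SVMs with linear and RBF kernels. Choices the underlying
libraries do not fix are declared here: KNN uses Euclidean distance on the
unit-normalized embeddings with vote-fraction scores, and a vote tie falls
back to the single nearest neighbour's label; SVM scores come from
pairwise-coupling probability calibration with cost 1 and RBF
$\gamma = 1/(d \cdot \mathrm{var})$; the forest is seeded for determinism.

Evaluation is per frame. Accuracy is correct-over-total; confusion matrices
are reported raw and row-normalized. Per class (one-vs-rest), the ROC curve
sweeps every distinct score threshold computing TPR = TP/(TP+FN) and
FPR = FP/(FP+TN), with AUC by the trapezoid rule — equal, as the tests
verify to $10^{-9}$, to the Mann–Whitney pair-counting statistic. The PR
curve sweeps the same thresholds computing recall and precision, summarized
by step-interpolated average precision $\sum_i (R_i - R_{i-1}) P_i$.
The stratified splitter assigns each class
$\min(n-1, \max(1, \mathrm{round}(f \cdot n)))$ test samples, so every class
appears in both partitions. A per-session majority-vote view is available
via `majority_label()` but all reported numbers are per frame.

# The synthetic world

Because no public dataset of labeled multi-cat litter-box sessions exists,
the simulator stands in for one. It emulates the *structure* of such data:

* **Identity signatures.** Each cat is a genotype — RGB coat color, a
  sinusoidal stripe pattern (frequency and phase), a body scale and a growth
  rate — rendered as a striped ellipse over a plain background with seeded
  Gaussian pixel noise. Distinct genotypes are visually separable at low
  noise (asserted in pixel space), which is the property the metric learner
  needs to exercise the whole pipeline.
* **Lighting.** Frames pass through one of four color-temperature filters —
  2700, 4100, 6500 and 10,000 K — implemented as per-channel blackbody
  gains normalized at 6500 K, so the capture temperature is exactly the
  identity map. Training corpora cycle the four temperatures 1:1:1:1.
* **Drift.** Age grows as `tick × morph_rate`. Body scale follows logistic
  growth saturating at an adult value of 0.9 of the frame; coat color
  darkens by the maturation factor $0.55 + 0.45 e^{-0.15\,\mathrm{age}}$.
  Both are deterministic in age, so drift is gradual and reproducible.
* **Population churn.** Scenario events add cats (fresh genotypes derived
  from a shared seed, so ingest and evaluation streams agree on who the new
  cat is) or remove them; sessions are only ever drawn from cats alive at
  their tick.

What it does **not** model: photorealistic cats, pose and articulation,
occlusion by litter-box geometry, detector localization error (crops are
ground truth by construction), background clutter, or motion blur. Passing
tests therefore demonstrate that the *mechanisms* — curriculum, selection,
triggers, lifecycle, evaluation — behave as specified and that adaptation
beats a frozen model under controlled drift; they do not certify any
particular accuracy on real animals.

# Study conditions and numerical choices

The desk-scale conditions used throughout the tests and the acceptance
script, chosen once as a realistic small household: 5 identities, 32×32
frames, pixel noise 0.02, 24 training frames per identity, and for drift
runs 10 ticks with 15 ingest and 10 evaluation sessions per tick (8 frames
each). The strong-drift scenario uses `morph_rate = 2`, which carries a
kitten most of the way to adult size and coat over the run. Policy defaults
are `T = 1` tick, `M = 20`, `N = 200`, `C = 500`; with these stream rates
`C` does not fire within a 10-tick run, so the adaptive arm's gains there
come from selection plus classifier refits — the fine-tune path is
exercised separately with small `C` in targeted tests. The simulated
relabeler returns ground-truth session labels (an optional error rate is
available); per-tick evaluation uses sessions excluded from ingestion to
avoid leakage.

Numerical details: embedding norms are floored at $10^{-12}$ before
division; selection ties and KNN distance ties break by input order,
keeping results deterministic; every stochastic step (genotype sampling,
rendering noise, batch composition, splits, classifier fitting) flows from
an explicit seed through a hash-derived child-seed scheme, so any run is
bit-reproducible from its master seed.

# Known limitations

* The appearance model is deliberately minimal; classifiers saturate on it
  at low noise, so comparisons between classifiers are about protocol, not
  ranking power.
* Fine-tuning quality is only lightly exercised at desk scale, since the
  selection + refit path already tracks the simulator's drift.
* Drift *detection* is out of scope by design: the architecture retrains on
  policy triggers, not on detected distribution change.
* The CLI stores models as RDS files; interoperability with other
  frameworks is limited to the CSV embedding exports.
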