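---
title: "Extracting symbolic rules and region concepts from a convolutional classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting symbolic rules and region concepts from a convolutional classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A convolutional network trained to detect pleural effusion on chest
radiographs is accurate but opaque: a clinician cannot see *which*
image structures a prediction rests on, and cannot intervene when the
model leans on clinically irrelevant ones. `cnnrules` implements a
decompositional knowledge-extraction workflow around such a classifier:

1. **Quantization.** At a designated feature-extraction layer $l$ with
   $k_l$ kernels, each kernel's activation map on image $i$ is summarized
   by its L1 norm $a_{i,k} = \lVert A_{i,k} \rVert_1$. A per-kernel
   threshold $\theta_k$, the arithmetic mean of $a_{i,k}$ over the
   training set, binarizes the norm into a logical literal:
   $b_{i,k} = +1$ if $a_{i,k} > \theta_k$ (strictly), else $-1$.
2. **Rule extraction.** A depth-capped decision tree over the literals is
   induced against the *network's own predictions* $h(g(x_i))$, so the
   tree is a surrogate whose quality is measured by *fidelity* — the
   fraction of images on which rule and network agree — alongside
   accuracy, sensitivity and specificity against ground truth. Each
   root-to-leaf path is one conjunctive rule, e.g.
   $\neg\mathrm{AG} \wedge \mathrm{AK} \rightarrow \text{Effusion}$.
3. **Concept assignment.** Each kernel's activation map is upsampled to
   image resolution, thresholded at its own 95th percentile, and boxed.
   A per-image *hit* on an anatomical region is an intersection-over-union
   above 0.5 between that box and the region's bounding box. A kernel is
   assigned the region it hits in more than 70% of the images (at most
   two regions may exceed the threshold, otherwise the kernel is
   *uninterpretable*).
4. **Intervention.** Rules can be re-induced under an expert-constrained
   vocabulary (allow/deny kernel lists) and compared side by side — the
   "what if this kernel were excluded" workflow.
5. **Ablation.** The causal relevance of kernel groups is measured by
   muting (zeroing feature maps before the classifier head) and
   activating groups, against random baselines of equal size drawn from
   the uninterpretable kernels (100 repetitions by default).
6. **Radiomics grounding.** Texture features computed on region crops —
   GLCM joint entropy, GLRLM gray-level and run-length non-uniformities,
   first-order mean absolute deviation and root mean square — are
   correlated with kernel norms, giving the literals a quantitative
   texture reading (e.g. "this kernel's norm falls as the region becomes
   more homogeneous").

Everything runs end-to-end on synthetic phantoms with a built-in CNN, so
the full workflow is testable on one CPU with no external data.

## The phantom study

`phantom_config()` defines a balanced two-class study of square
grayscale images in $[0,1]$ containing nine named rectangular regions in
a 3×3 grid, labelled after the anatomical regions used for frontal chest
X-rays (T, UM, CS, LC, RC, LH, RH, LCA, RCA). Every region carries a
persistent sinusoidal texture signature: a region-specific orientation
and period. The default *signal regions* are the upper mediastinum (UM)
and cardiac silhouette (CS) — the regions whose obscuring ("silhouette
sign") radiologists associate with effusion.

In the negative class every region shows its full-amplitude signature
(signal regions: amplitude 0.32, period 3 px, oblique orientations 80°
and 145°; decoys: amplitude 0.10, periods 5–6 px, at angles at least 15°
from the signal orientations). In the positive class the signal regions
are *homogenized*: texture amplitude is damped by 0.6, the mean
intensity is raised from 0.45 to 0.65, and pixel noise is unchanged
(sd 0.03). Each region's amplitude additionally jitters by ±15% and its
mean by sd 0.02 per image, emulating acquisition-to-acquisition
variation. These defaults give a within-region variance ratio above 2
between the classes — large enough that a texture-energy reading
separates the classes, while the damped grating keeps each signal
region detectable by the same oriented kernels in both classes. The
choices that matter:

* **Class signal as amplitude damping, not texture removal.** If the
  positive class removed the signal texture entirely, a kernel tuned to
  it would fall silent on half the dataset and could never reach the 70%
  dataset-wide hit rate that concept assignment requires. Partial
  damping with a raised mean keeps the region the most salient thing at
  its location in both classes, which is how persistent anatomy behaves
  in real radiographs.
* **Oblique, frequency-separated signatures.** Axis-aligned fine
  gratings interact badly with 2×2 max-pooling; signal signatures use
  oblique orientations. Decoy regions use coarser periods and weaker
  amplitudes so that kernels tuned to the fine signal textures respond
  weakly elsewhere.
* **Per-region exposure jitter.** Without it, even microscopic
  class-dependent leakage into off-orientation kernels is statistically
  reliable (pixel noise averages out over a region), and any classifier
  readout will exploit it; the jitter drowns those micro-signals while
  the macroscopic signal-region contrast survives.
* **Jitter off by default.** Box jitter (±2 px, clipped) emulates
  detection noise from an upstream localizer and is enabled only in
  robustness tests; jitter perturbs the reported boxes, not the texture.

What the phantom does *not* emulate: anatomical shape variation,
projection physics, intensity calibration differences, co-morbid
findings, or label noise. Passing the end-to-end tests therefore shows
the *machinery* recovers planted structure under controlled conditions —
not that a real radiological deployment would behave as well.

## The built-in CNN

`train_tiny_cnn()` fits a three-block convolutional network: a fixed
bank of 7×7 oriented grating filters (Gabor-style with a Gaussian
envelope, orientations evenly spaced over 180°, periods alternating 5
and 3 px) as block 1, then two trainable depthwise 3×3 blocks with ReLU
and 2×2 max-pooling, a 2×2 max-pool, global average pooling and a
linear two-class head. The post-ReLU maps of block 3 (side
`input_size/4`, 16 kernels by default) are the designated
feature-extraction layer; masking applies between this layer and the
head. The 7×7 support gives the bank sharp angular tuning, so a kernel
responds to its own orientation and only weakly to neighbours.

Two design choices deserve justification, because a fully generic tiny
CNN trained from random initialization does not support the workflow:

* **Fixed oriented front end, depthwise refinement.** Kernel-level
  concept attribution presupposes kernels that respond to a specific
  visual structure wherever it occurs — the specialization large
  pretrained classifiers exhibit. A three-block network trained from
  scratch on a desk-scale phantom classifies perfectly, but its kernels
  fire on one class's appearance only and never localize one region
  across both classes. Giving block 1 a deterministic oriented filter
  bank and keeping blocks 2–3 depthwise (each designated-layer kernel
  refines one oriented energy channel; the depthwise weights are
  constrained nonnegative, so maps remain local averages of that
  channel) makes the designated layer texture-selective by construction
  while the network remains a trained CNN: the depthwise blocks and the
  head are fit by mini-batch Adam on softmax cross-entropy.
* **Sparse readout refit.** After backprop, the linear head is refit
  as a thresholded diagonal-LDA readout of the pooled per-kernel
  energies (shrunken-centroid style): a kernel is read out only when
  its between-class energy contrast exceeds `head_min_effect` (default
  0.25) and its absolute separation is at least 5% of the largest;
  kept kernels are weighted by separation over within-class variance
  with the intercept at the balanced midpoint. All other kernels get
  exactly-zero head weights. This supplies the class-wise activation
  sparsity that muting experiments presuppose: muting a zero-weight
  kernel provably cannot move a prediction, while muting a weighted
  kernel removes its full logit contribution. The refit is
  deterministic given the training data; penalized logistic readouts
  chosen by cross-validation were rejected because their selection is
  unstable on (near-)separable data and, with standardized features,
  they hang enormous coefficients on near-constant kernels, which
  breaks the muting experiments' calibration.

Training is deterministic given `(dataset, arch, seed)`: the seed
drives initialization and batch order; the filter bank is
seed-independent and the readout refit is a deterministic function of
the trained features. Defaults (20 epochs, batch 32, learning rate
3e-3, Adam, decoupled decay 0.1 on the head before refit, depthwise
weights projected nonnegative after every step) reach validation
accuracy 1.0 on the default 400-image phantom in about a minute on one
CPU; training aborts with diagnostics if validation accuracy ends
below 0.7.

## Quantization and rule induction

Thresholds are always computed on the training split and frozen —
validation literals reuse training thresholds, and the threshold vector
records that provenance. The strict inequality means a norm exactly at
the threshold yields a negative literal. Norms are not normalized by map
size.

Tree induction is greedy: at each node the allowed kernel minimizing the
weighted Gini impurity of the two children is chosen, ties broken by
lowest kernel index so builds are deterministic. The best split is taken
even at zero Gini gain (an XOR-structured target has no first split with
positive gain); growth stops at purity, the depth cap (default 3
literals per rule body, which suffices for high-fidelity surrogates),
or the minimum child size (default 2). Leaf ties predict class 0
(healthy) — a deterministic, conservative default. Pruning is
reduced-error pruning on a held-out fold (default 20% of the training
rows): bottom-up, a subtree collapses to its training-majority leaf
whenever validation misclassifications do not increase, so sibling
leaves predicting the same class always merge. The pruning method and
minimum node size are this package's choices; they favor determinism
and testability.

`apply_rules()` evaluates rule bodies by direct conjunction matching,
independently of tree traversal; the two paths agreeing everywhere is a
standing property test.

## Concept assignment choices

The mapping from a continuous activation map to a region box is the one
genuinely open design point: maps are bilinearly upsampled to image
resolution (nearest-neighbour available), thresholded at their own 95th
percentile, and the tight bounding box of the positive supra-threshold
pixels is taken. The percentile rule is scale-free — multiplying a map
by a constant does not move its box — and parameter-light. An all-zero
map has no box and counts as a miss; the hit-rate denominator is all
images of the split, so silent kernels are penalized, matching a
dataset-wide reading of the 70% criterion. When two regions exceed the
hit threshold the maximum-rate region is assigned (ties break by region
name order) and both are recorded; more than two qualifying regions mark
the kernel uninterpretable.

## Ablation conventions

Accuracy is measured against ground-truth labels on the training split
by default (configurable), matching how kernel-relevance curves are
usually reported. Random baselines draw without replacement from the
uninterpretable kernels only, with 100 repetitions for incremental
activation and 20 for the random muting curve. Combination search is
exhaustive with a 5,000-evaluation cap. All experiments reuse one
extracted activation set, so each condition costs one pass of the
classifier head; every reported number is reproducible bit-for-bit from
(seed, config, checkpoint).

## Radiomics conventions

Crops are discretized per crop by min–max scaling into 32 equal bins
(configurable); first-order features use raw intensities. The GLCM uses
distance 1, four angles (0°, 45°, 90°, 135°), symmetric accumulation,
features averaged over angles; the GLRLM averages over the four
standard directions. Correlations are Pearson on raw values (Spearman
available); zero-variance inputs are reported as undefined rather than
silently dropped. On the default phantom the joint entropy of a signal
region correlates strongly and negatively with the norms of the kernels
assigned to it — homogenized (effusion-like) crops have low entropy and
low kernel norms — which is the quantitative texture reading the kernel
norm plots are meant to convey.

## Problem sizes and determinism

The default study uses 400 training and 80 validation images (200/40
per class) at 64×64 px with 16 kernels; the whole pipeline runs in
roughly two minutes on one CPU. Unit tests use smaller phantoms (tens of
images, a shared 8-epoch model fixture); the end-to-end recovery test
runs the full default study over three seeds and requires two of three
to pass every sub-check, reflecting the honest run-to-run variability of
CNN training. All randomness flows through explicit integer seeds;
identical configs reproduce byte-identical artifacts.

## Known limitations

* The phantom's class signal is a single texture contrast; it cannot
  probe multi-finding interactions or label noise.
* The concept vocabulary is rectangular boxes; non-box regions (lung
  fields with curved borders) would need mask-based IOU.
* The built-in CNN's interpretability is partly architectural (oriented
  channels); a generic user-supplied model may have far fewer
  interpretable kernels, and the workflow then reports exactly that
  rather than failing.
* Fidelity is measured against hard predictions, not probabilities; a
  soft-fidelity extension would need calibrated scores.
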