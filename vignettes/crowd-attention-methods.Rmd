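---
title: "Learning from crowds with cross-attention pseudo-labels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning from crowds with cross-attention pseudo-labels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In many applied classification settings — medical image triage, perceptual
voice rating, crowd-labelled natural images — no single trustworthy label
exists per instance. Instead each instance $x_n$ carries labels
$o_n^{(w)} \in \{0,1\}^K$ (one-hot over $K$ classes) from a subset
$W_n$ of $W$ annotators of unknown and heterogeneous competence, and the
true label $y_n$ is latent. `crowdattn` trains a classifier directly on
such data, while estimating, for every single annotation, how much it
should be trusted.

## The model

Two coupled components share one set of parameters:

1. **Classification network.** A feed-forward encoder with ReLU hidden
   layers and a softmax head maps features to a predicted class
   distribution $\hat y_n \in [0,1]^K$. At inference time this network
   acts alone; annotations are never an input to prediction.

2. **Crowd aggregation by cross-attention.** The current prediction
   $\hat y_n$ is used as a *query* against the one-hot annotations, which
   serve as both *keys* and *values*. With a plain dot-product score,

   $$p_n^{(w)} = \hat y_n^\top o_n^{(w)},$$

   the reliability of annotator $w$ on instance $n$ is simply the model's
   predicted probability of the class that annotator chose. Because the
   query lies on the simplex and the keys are one-hot, the scores are
   already in $[0,1]$; no softmax is applied across annotators, so an
   annotator's weight does not depend on how many colleagues labelled the
   same instance. The pseudo-label is the normalized, score-weighted
   consensus

   $$\tilde y_n = \frac{\sum_{w \in W_n} p_n^{(w)} o_n^{(w)}}
                        {\sum_{w \in W_n} p_n^{(w)}},$$

   a valid distribution on the simplex. Per instance the whole
   aggregation costs $O(WK)$ operations.

3. **Loss.** Training minimizes the mean cross-entropy of the prediction
   against the pseudo-label,
   $L(\theta) = -\tfrac1N \sum_n \sum_k \tilde y_{n,k} \log \hat y_{n,k}$,
   jointly updating the classifier and, through it, the attention scores.
   No gold labels are consumed.

The intuition: early in training the predictions are near-uniform, so the
pseudo-labels are close to a soft majority vote and the model learns the
broad structure of the task; as predictions sharpen, annotators who agree
with the emerging decision function are up-weighted *per instance*, which
suppresses locally unreliable annotators without ever allocating
per-annotator parameters.

## Numerical and design choices

* **Gradient through the pseudo-label.** The loss as written makes
  $\tilde y_n$ depend on $\theta$ via the query. By default
  (`detach_pseudo_label = TRUE`) we treat $\tilde y_n$ as a constant
  target in each step — the standard pseudo-labelling convention, which
  avoids a self-confirmation term that rewards the model for making its
  own targets easy. Setting the flag to `FALSE` follows the literal
  composite gradient (the extra term
  $m_j(\langle \tilde y, \log \hat y\rangle - \log \hat y_j)/\sigma$
  per class $j$ with $m_j$ annotators, plus the softmax Jacobian); both
  paths are implemented and tested.
* **Zero-denominator fallback.** If $\sum_w p_n^{(w)} \le \varepsilon$
  (default $10^{-8}$; a query orthogonal to every annotation), the
  pseudo-label falls back to equal weights over the observed annotators,
  i.e. the soft majority vote — the natural prior when the model has no
  opinion.
* **Initialization.** Hidden layers use uniform fan-in scaling,
  $U(\pm 1/\sqrt{\text{fan-in}})$; the output layer starts at exactly
  zero. The zero head makes the initial predictions exactly uniform, so
  the first pseudo-labels are exactly the soft majority vote: training
  warm-starts from the naive consensus and departs from it only as
  evidence accumulates. Symmetry is broken by the first gradient step on
  the head.
* **Optimization.** Adam with learning rate 0.005, full-batch gradient
  descent (every instance in every step), 500 epochs, no early stopping.
  The epoch count is a package default chosen because the synthetic task
  (below) saturates well before it while a run stays in the
  tens-of-seconds range on one CPU; it is fully configurable.
  Mini-batching (`batch_size`) exists for larger datasets.
* **Log clamping.** Predictions are clamped at $10^{-12}$ before any
  logarithm.
* **Ties.** Argmax predictions, majority votes and zero-support F1
  classes all resolve deterministically (lowest class index / F1 = 0),
  so repeated runs are bit-reproducible given seeds.

## The synthetic benchmark

The bundled generator emulates a fully controlled study. Inputs are
scalar, uniform on $[0,1]$; the true class is the index of the largest of
$\sin(2\pi x)$, $-\sin(2\pi x)$ and $0.5-\sin(2\pi(x+0.25))$; 300
instances form the training split and 200 the test split.

Five annotators are simulated with *input-dependent* reliability: each
has a reliable set, a finite union of half-open subintervals of $[0,1]$.
Inside it the annotator reports the true label; outside it draws
uniformly among the $K-1$ wrong labels ("uniform-wrong"), which permits
deliberately adversarial, below-chance annotators. The interval lengths
are calibrated so the expected accuracies are exactly
84.66, 59.66, 66.33, 55.66 and 27.66 percent, and the layouts realize
four archetypes: long plateaus with sharp transitions (a1, a3),
alternating bumps, i.e. non-monotonic reliability (a2, a4), and a single
sparse reliable window (a5, the adversarial one). The generator also
emits, for every annotation, the binary indicator of whether it was
correct — the ground truth for reliability-recovery evaluation.

What the generator does *not* model: correlation between annotators'
errors (draws are independent given $x$), per-annotator class confusion
structure, and instance difficulty. Reliability is deterministic in $x$
rather than stochastic. Consequently the simulated crowd is somewhat
cleaner than a real one: the weighted consensus of five such annotators
identifies the true label almost everywhere, and a well-trained crowd
model can approach the gold-trained upper bound on this task. Passing
the synthetic suite therefore demonstrates correct mechanics and
reliability recovery, not performance on real crowds with structured,
correlated noise.

## Baselines

Two aggregation-first baselines train the *same* backbone on fixed
targets:

* **Majority vote** (`train_mv`): plurality label per instance, ties to
  the lowest class index.
* **Dawid–Skene** (`train_ds`): EM jointly estimating latent class
  posteriors and per-annotator $K \times K$ confusion matrices.
  Initialization is the majority-vote proportion posterior; priors and
  confusion rows get additive smoothing $10^{-6}$ to avoid
  zero-probability lock-in; the E-step runs in log space; iteration stops
  when the largest posterior change drops below $10^{-6}$ or after 100
  iterations (then flagged `converged = FALSE` with a warning). The
  observed-data log-likelihood is recorded per iteration and is
  non-decreasing. The backbone is trained on the *soft* posteriors
  rather than their argmax — strictly more information, a package choice.
* **Gold** (`train_gold`): the upper bound, trained on true labels.

## Evaluation utilities

* `classification_report()`: accuracy, per-class and macro F1 in
  percent. Classes without true or predicted support score F1 = 0 (kept
  in the macro average — conservative and deterministic).
* `reliability_recovery_f1()`: estimated reliabilities are binarized at
  0.5 (a probability-scale midpoint, the only parameter-free threshold
  given binary ground truth) and compared per annotator to the
  correctness indicators with "reliable" as the positive class;
  the summary is the unweighted annotator mean. We evaluate on the test
  inputs.
* `friedman_test()`: the classical rank statistic
  $\chi^2 = \tfrac{12}{Nk(k+1)}\sum_j R_j^2 - 3N(k+1)$ with average
  ranks for ties and no tie-correction factor, referred to
  $\chi^2_{k-1}$.
* `annotator_sweep()`: the cumulative protocol — annotators sorted by
  descending label count (ties by id), subsets of sizes $1, 1+s, 1+2s,
  \dots$ capped at $W$ (step $s = 4$ by default, $W$ always included),
  one retraining per subset, method and seed; training instances left
  unlabelled under a subset are dropped for that run.

## Problem sizes and determinism

All shipped experiments run at the study scale: 300/200 train/test
instances, five annotators, 512/256 hidden units, 500 full-batch epochs;
a single training run takes roughly ten seconds on one CPU and the full
10-initialization protocol a few minutes. Every stochastic step —
input draw, annotator errors, weight initialization, batch shuffling —
flows from explicit integer seeds, and all generators restore the
caller's RNG state, so `(data, config, seed)` fully determines every
result in this package.

## Known limitations

* The annotator simulator is deterministic-in-$x$ and uncorrelated; see
  above for what that implies about external validity.
* The backbone is a plain MLP; convolutional or pretrained encoders are
  out of scope, so image-scale tasks need externally extracted feature
  vectors (the CSV interfaces accept any numeric feature table).
* Reliability scores inherit the classifier's errors near decision
  boundaries: where $\hat y$ is uncertain, scores fluctuate, a known
  behavior of prediction-as-query attention.
* The crowd model does not represent systematic per-annotator biases or
  class-dependent confusion; the Dawid–Skene baseline covers the
  instance-independent version of that structure.
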