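---
title: "Discriminant RBMs for personalized pain-state classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant RBMs for personalized pain-state classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painrbm)
```

This vignette is the package's own account of the method: the probabilistic
model and its assumptions, the preprocessing that makes flowsheet data fit
it, the decisions taken where the design was genuinely open, the numerical
choices, and — importantly — what the synthetic testbed can and cannot show
about real clinical data.

## The model

A binary restricted Boltzmann machine (RBM) places an energy on each joint
configuration of $m$ visible and $n$ hidden binary units,

$$E(\mathbf v, \mathbf h) = -\mathbf b^\top \mathbf v - \mathbf c^\top \mathbf h - \mathbf v^\top W \mathbf h,
\qquad p(\mathbf v, \mathbf h) = \frac{e^{-E(\mathbf v, \mathbf h)}}{Z}.$$

The bipartite structure (no within-layer connections) makes both layer
conditionals factorize into independent logistic units, which is what makes
Gibbs sampling and contrastive divergence practical. Marginalizing the
hidden layer yields the free energy; for binary hidden units it collapses to
a sum of softplus terms,

$$f(\mathbf v) = -\mathbf b^\top \mathbf v - \sum_j \log\!\left(1 + e^{c_j + W_{\cdot j}^\top \mathbf v}\right),
\qquad p(\mathbf v) = \frac{e^{-f(\mathbf v)}}{Z}.$$

**Classification.** The pain label $c \in \{0,1\}$ is included as one more
visible unit — by package convention the *last* one (the convention is
arbitrary but must be fixed; every function that consumes feature-only
vectors documents it). The intractable partition function cancels in the
odds of the two label completions:

$$\frac{p(c=0 \mid \mathbf x)}{p(c=1 \mid \mathbf x)} = \frac{p(\mathbf x, 0)}{p(\mathbf x, 1)}
 = e^{f(\mathbf x \oplus 1) - f(\mathbf x \oplus 0)},$$

so `rbm_class_posterior()` computes
$p(c=1 \mid \mathbf x) = \sigma(f(\mathbf x \oplus 0) - f(\mathbf x \oplus 1))$
through a single logistic — overflow-safe and algebraically identical to
exponentiating both free energies. The complement is constructed as
$1 - p_1$, so the two columns sum to one exactly rather than up to a
normalization. Since either the posterior or the raw free-energy gap can
serve as an ROC score (they are monotone transforms of each other and AUC is
invariant under monotone transforms), the package uses the posterior
everywhere and exposes the gap via `predict(type = "score")`.

An alternative route — feeding the hidden activation probabilities to any
downstream classifier — is provided by `rbm_hidden_features()`. The label
unit is unknown at feature-extraction time; it is clamped to 0, a documented
convention the model itself does not dictate. Note that generatively trained
hidden units carry no guarantee of label relevance; the package's tests
include a single-hidden-unit experiment showing the unit is statistically
unrelated to labels when the data carry no label signal.

## Training

Learning is stochastic gradient ascent on the mean training log-likelihood
with the CD-$k$ estimate (default $k = 1$): positive statistics are clamped
to the data, negative statistics come from $k$ alternating Gibbs steps
started at the data. Two standard variance-reduction choices are baked in:
the chain uses *sampled* hidden states, but the final visible reconstruction
and the final hidden statistics use *probabilities* rather than samples.
CD-1 is biased; the suite therefore asserts only directional agreement
(positive cosine similarity of the seed-averaged estimate with the exact
enumeration gradient on a $4 \times 3$ model) plus a strict likelihood
improvement over initialization on data sampled from a known enumerable RBM
— not unbiasedness.

Tunable parameters, defaults, and why:

| Parameter | Default | Rationale |
|---|---|---|
| `n_hidden` | 20 | midpoint of the 15–30 range that works at flowsheet scale; more units = richer representation but more overfitting |
| `k` | 1 | classic CD-1; higher `k` trades time for lower bias |
| `learning_rate` | 0.05 | conventional for CD on ~25-dimensional binary data (dimensionless energy units) |
| `epochs` | 200 | enough passes for ~1000-row patients; training cost is linear in it |
| `batch_size` | 32 | conventional minibatch size |
| `init_scale` | 0.01 | small Normal weight init, zero biases; breaks symmetry without saturating units |

The whole trajectory — initialization, epoch shuffles, Gibbs noise — is a
pure function of the `seed` argument, and identical calls return
bit-identical parameters. Trained models serialize to plain JSON at 17
significant digits, which round-trips doubles exactly.

## Personalized binarization

Baseline physiology differs across individuals, so "abnormal" is defined
per patient: `fit_normalizer()` estimates each item's mean and sample
standard deviation (denominator $n-1$) from that patient's non-missing
readings only. The probability that reading $t$ is abnormal is taken as the
two-sided central coverage of its z-score,

$$p(x = 1) = 2\,\Phi\!\left(\frac{|t - \mu|}{\sigma}\right) - 1,$$

thresholded at 0.5, equivalently $|t - \mu| > z_0\sigma$ with
$z_0 = \Phi^{-1}(0.75) \approx 0.6745$. Mapping a Gaussian fit to an
*abnormality probability* admits several readings; this one was chosen
because it is the unique symmetric choice that is continuous, zero at the
mean, strictly increasing in $|z|$, affine-invariant, and gives the 0.5
cutoff a concrete meaning: exactly half of in-distribution draws fall
outside the band. That last property is a double-edged sword and is analyzed
below. Missing cells are imputed as 0 ("normal") and flagged in a mask;
features with fewer than two observations or zero variance are dropped with
a warning, mirroring the reality that no patient has every flowsheet item.

## Evaluation

`roc_curve()` sweeps the decision threshold over every distinct score (ties
grouped), yielding a curve from (0,0) to (1,1) whose trapezoidal area equals
the Mann–Whitney statistic with ties counted ½ — the estimator the tests
verify against an exhaustive pairwise count. The operating point is the
curve point minimizing $\sqrt{\mathrm{FPR}^2 + (1-\mathrm{TPR})^2}$, i.e.
closest to the ideal corner; ties break toward higher TPR (favouring
sensitivity in a pain-detection context), then toward the lower threshold.
At that threshold the report gives sensitivity, specificity and accuracy;
a rate whose reference class is absent is reported as `NA`, never silently 0.

By default `run_experiment()` selects the operating threshold on the *test*
ROC it reports — the conventional presentation for this kind of study, but
an optimistic protocol, since the threshold is tuned on the evaluation data.
A cleaner `threshold_selection = "train"` mode is provided and recommended
for any comparative claims. The 20 % split is uniform random without
stratification by default (stratified splitting is an opt-in flag), and a
split that loses a class in either part is resampled a bounded number of
times from derived seeds.

The two comparators are deliberately standard: the pooled-covariance linear
discriminant $\Sigma^{-1}(\mu_1 - \mu_0)$ (with an optional ridge on
$\Sigma$ — binary feature matrices are routinely collinear; the pipeline
default is $10^{-6}$), and PCA onto 4 components followed by a linear SVM
with cost 1. Kernel and cost for the margin classifier are fixed, documented
stand-ins; no hyperparameter search is performed for any model.

## The synthetic testbed

`generate_patient()` emulates the structure the method assumes: per-patient
item baselines $\mu_i \sim U(40, 160)$, $\sigma_i \sim U(2, 25)$
(vital-sign-like scales), latent per-cell abnormality bits
$z \sim \mathrm{Bernoulli}(\rho)$ with $\rho = 0.25$ by default (a
clinically plausible per-item abnormal fraction), readings drawn from the
baseline displaced by `shift` $\sigma$ (default 2) in a per-feature fixed
direction, labels computed from the latent bits by a configurable rule
(weighted linear cut, XOR of a designated pair, or total count threshold)
with 5 % flip noise by default, and 2 % missing cells. Scale defaults — 25
items, 1200 labelled rows — mirror realistic per-patient charting volumes.
The generator returns the full ground truth (latent bits, baselines, shift
directions, clean labels), so every pipeline stage is measurable.

What the generator does *not* emulate: temporal autocorrelation (the method
treats rows as exchangeable, and so does the generator), cross-item
correlation beyond what the label rule induces, drifting baselines,
non-Gaussian heavy-tailed readings, and informative missingness. Passing
tests therefore demonstrate correctness of the machinery and behaviour under
the model's own assumptions — not clinical performance.

### The information floor of 0.5-threshold binarization

One structural property deserves emphasis because it governs every
end-to-end number the package produces. The 0.5 cutoff on the two-sided
coverage probability flags **half of all in-regime readings** as abnormal by
construction (the acceptance suite computes this rate on 10,000 draws).
Consequently a binarized feature is a noisy channel for its latent
abnormality bit: at shift $2\sigma$ a truly abnormal cell is recovered with
probability $\approx 0.91$ against the generating baseline, but a normal
cell still reads "abnormal" roughly half the time. Two consequences follow.

First, end-to-end AUCs on synthetic cohorts plateau well below 1 even when
the latent rule is deterministic — the per-feature channel caps what any
classifier downstream of binarization can achieve. Second, and less
obviously, an XOR rule on two latent bits is *not* a clean nonlinear
showcase after this binarization: when the two designated items have
abnormality rate exactly 0.5 the fitted baseline sits mid-mixture and the
coverage band becomes symmetric between the two regimes, making the
binarized bit exactly independent of the latent bit at any shift; at any
other rate the XOR leaks a linear margin into the observed bits, and with
two binary features the Bayes posterior induces the same score ordering as a
linear function, so the discriminant RBM has no attainable ROC advantage
over the linear discriminant in this regime. The model-separation
experiment in the acceptance suite runs exactly as designed and reports what
it measures; readers should interpret modest, closely-spaced AUCs there as a
property of the binarization floor, not of the RBM machinery. Richer visible
units (softmax or Gaussian) that retain the direction and magnitude of a
deviation are the natural remedy and are out of scope here.

## Numerical choices

* Softplus terms in the free energy are computed as
  $\max(x, 0) + \log(1 + e^{-|x|})$; the naive $\log(1+e^x)$ overflows past
  $x \approx 710$, and activations of that size occur in saturated models.
* All enumeration-based quantities (`rbm_log_partition()`,
  `rbm_exact_gradient()`, `rbm_log_likelihood()`) use log-sum-exp reductions
  and refuse models beyond 20 visible or 20 hidden units: they are oracles
  for testing and diagnostics, not production paths, and the cap keeps them
  honest.
* Posterior complements are constructed (`1 - p1`), not renormalized.
* Exact ties at a decision threshold classify as positive — the conservative
  direction for pain detection.
* All randomness flows from one root seed through a documented sub-stream
  derivation (`derive_seed()`), keeping every experiment a pure function of
  its configuration; seeds stay below $2^{31}$.

## Problem sizes used by the test suite

The oracle suites run hundreds of random models at enumerable sizes
($m, n \le 10$); CD-1 diagnostics average 1000 seeded estimates on a
$4 \times 3$ model; coverage and recovery use $10^4$ draws and a
1200-row patient; the model-separation experiments run the full pipeline on
1200-row, 25-item cohorts; determinism checks use 400-row cohorts with 60
training epochs. These sizes were chosen so the complete suite exercises
every claim at full statistical strength while remaining comfortable on a
single CPU.

## Known limitations

* Rows are treated as exchangeable; no temporal structure is modelled, and
  a chronological train/test split would be the harder, more honest protocol
  for deployment claims.
* Binary visible units discard the direction and magnitude of a deviation
  (the floor analyzed above).
* CD-1 is a biased gradient estimator; no persistent chains, momentum or
  weight decay are implemented.
* Posteriors are not calibrated; they are intended as ranking scores.
* The default operating-point protocol tunes the threshold on the test ROC;
  use `threshold_selection = "train"` for conservative reporting.
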