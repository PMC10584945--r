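---
title: "Methods: wavelet sub-band features, dragonfly selection, and MLP classification of EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet sub-band features, dragonfly selection, and MLP classification of EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and numerical choices behind
**eegseizure**: what each stage of the pipeline computes, which parameters
matter and why they hold their default values, what the synthetic generator
does and does not emulate, and where the design was genuinely open.

## The detection problem

Scalp EEG during an epileptic seizure (the *ictal* state) shows a sudden
transition to high-amplitude rhythmic activity, classically 3–5 Hz
spike-and-wave discharge. Between seizures (*interictal*), the record of an
epilepsy patient shows sporadic sharp transients over otherwise ordinary
background; a healthy (*normal*) record shows low-amplitude mixed rhythms.
The pipeline classifies single-channel records into these three states from
a fixed-length feature representation.

The record geometry follows the public Bonn convention: one channel,
173.61 Hz sampling, 23.6 s per record (4097 samples), amplitudes in
microvolts, one value per ASCII line.

## Preprocessing

Records are checked for missing samples (strict mode refuses them; lenient
mode linearly interpolates interior gaps and reports the count), band-limited
to 0–40 Hz, and rescaled to $[-1, 1]$.

* **Filter** — an order-4 Butterworth low-pass applied forward and backward
  (zero phase), with odd-symmetric edge extension to suppress startup
  transients. Zero phase matters because the Hjorth descriptors are built
  from discrete derivatives: a phase-distorting filter would change waveform
  slopes, not just spectral content. The 40 Hz cutoff keeps the clinical
  delta-to-gamma range and removes line noise and EMG residue.
* **Normalization** — division by the maximum absolute amplitude. A max-abs
  map (rather than min–max affine) preserves the zero line and waveform
  symmetry. Note that it deliberately discards *absolute* amplitude, one of
  the strongest ictal cues; class information then rides on waveform shape
  and relative band energies. The switch `normalize_before_features` in
  `pipeline_config()` exposes both conventions, because published per-band
  feature magnitudes in this literature are sometimes only consistent with
  unnormalized inputs while pipeline diagrams place normalization first.
  The default keeps normalization on.

## Undecimated wavelet-packet decomposition

Each record is truncated to a multiple of $2^4$ (4097 → 4096) and passed
through a **full undecimated wavelet-packet tree** of depth 4 with the db4
filter pair: at level $j$ every node is circularly filtered with the
analysis low-pass and high-pass filters upsampled à-trous by $2^{j-1}$, and
*both* branches are split further. This yields $2^4 = 16$ terminal
sub-bands, each of the input length.

Why a packet tree and not the plain stationary wavelet transform? The
feature contract is $16 \times 9 - 1 = 143$ values over 16 sub-bands, and a
depth-4 plain SWT produces only 8 coefficient sets (cA1–4, cD1–4); the full
binary tree is the only depth-4 undecimated decomposition with 16 leaves.
The plain transform remains available as `tree = "swt8"` for comparison.

Numerical conventions, all chosen to make properties exactly testable:

* **Circular (periodic) boundary handling.** With orthonormal filters this
  makes the bank a tight frame: the leaf energies sum to exactly
  $2^{\text{depth}}$ times the signal energy, and circularly shifting the
  input shifts every leaf by the same amount to machine precision. Both are
  asserted in the test suite.
* **Frequency ordering.** The natural (filter-path) leaf order is not
  frequency-sorted; ascending nominal frequency visits the leaves in
  Gray-code order. Per-leaf features and the "adjacent band" ratios use this
  sequency ordering, since adjacency is a frequency notion.
* **db4 taps** are frozen at 17 significant digits; the high-pass is the
  quadrature mirror $g_k = (-1)^k l_{N-1-k}$.

## The 143-element feature vector

Eight descriptors per sub-band — mean absolute value, population standard
deviation, skewness, kurtosis, RMS power, and the Hjorth triple
(activity $= \operatorname{var} y$, mobility
$= \sqrt{\operatorname{var}\Delta y / \operatorname{var} y}$, complexity
$= \text{mobility}(\Delta y)/\text{mobility}(y)$) — plus 15 ratios of mean
absolute values between frequency-adjacent sub-bands:
$16 \times 8 + 15 = 143$.

Conventions worth stating:

* All moments use the population divisor $M$. Skewness and kurtosis are the
  standard standardized third and fourth moments (kurtosis non-excess, so a
  Gaussian sub-band scores ≈ 3). Formulations that wrap these in an outer
  square root appear in print but are undefined for negative skewness —
  which real EEG sub-bands routinely have — so the standard forms are the
  default and `moments = "as_printed"` reproduces the literal formulas
  (with a 0 guard) for auditability.
* The Hjorth derivative is the first difference without sampling-interval
  scaling; the $\Delta t$ cancels in complexity and mobility is reported in
  radians/sample.
* Band ratios are oriented lower-frequency over next-higher; the orientation
  is arbitrary but fixed and documented.
* Zero-variance and zero-denominator guards return 0 (flagged) rather than
  NaN, so constant sub-bands from degenerate inputs cannot crash selection.

## Dragonfly wrapper selection

The selection problem is binary: a mask over the 143 features. Each of 10
dragonflies carries a mask and a real step vector; per iteration the step is
updated from five behaviors (separation, alignment, cohesion, attraction to
the best-so-far solution, distraction from the current worst) as

$$\Delta X_{t+1} = s S + a A + c C + f F + e E + w \Delta X_t,$$

componentwise clamped to $[-6, 6]$, and each bit is redrawn with probability
$T(\Delta x, \tau) = |\tanh(\Delta x / \tau)|$, with $\tau$ annealed
linearly from 4 to 0.01 over the 100 iterations. Defaults are the published
settings ($s{=}0.1, a{=}0.1, c{=}0.7, f{=}1, e{=}1, w{=}0.85,
\alpha{=}0.99, \beta{=}0.01$, population 10).

The wrapper fitness is
$\alpha\,\gamma_R(D) + \beta\,|C|/|N|$, where $\gamma_R(D)$ is the
misclassification rate of a 5-nearest-neighbour classifier under stratified
seeded 10-fold cross-validation restricted to the masked columns. The
neighbour count is a package choice (the source protocol fixes the
classifier and folds but not $k$). Folds are drawn once per optimizer run
and reused for every mask: evaluations are deterministic, comparable across
masks, and an order of magnitude cheaper; the cost is that masks can adapt
to one fold split, which matters only on near-zero-error plateaus (see
Limitations). An all-zero candidate scores the worst fitness 1 and is never
repaired mid-run; only the final returned mask is repaired (one uniform
random bit) to guarantee a non-empty selection.

Choices the printed pseudocode leaves open, resolved as follows:

* **Inertia** acts on the previous *step*, the standard dragonfly recursion;
  the literal reading (inertia on the position) is available as
  `inertia = "position_literal"`.
* **Separation** uses the standard orientation $-\sum_j (X_i - X_j)$; the
  printed operand order is available as `separation = "literal"`.
* **Position rule**: the bit is *set* with probability $T$ exactly as the
  update rule is printed; the common binary-swarm variant that *flips* the
  bit is available as `position_rule = "flip"`. Empirically the two reach
  similar fitness on the planted benchmarks.
* **Neighborhood** is the whole swarm minus self (no radius is defined in
  the source protocol); the food source is elitist best-so-far, which makes
  the reported convergence history monotone by construction; the enemy is
  the worst member of the current iteration.

## Classifier

A fully connected MLP with three hidden layers of ten sigmoid units and a
softmax output, trained by full-batch BFGS on cross-entropy with a small L2
penalty ($10^{-4}$), inputs standardized by training-set statistics, weights
initialized Glorot-uniform from a seed. A quasi-Newton full-batch fit is
deterministic given the seed and reliable at these problem sizes (≈ 240
training rows, ≤ 1000 parameters); with so few rows a held-out
early-stopping slice would add variance for little benefit, so weight decay
carries the regularization instead. The source protocol names the
architecture and activation but no optimizer, loss, or epoch budget.

Evaluation uses a stratified 80/20 split. Feature selection runs on the
training split only — selection is part of the fitted model, and letting it
see test rows would leak. Metrics are computed from the held-out confusion
matrix; for three classes, sensitivity/specificity/precision/F1 are
one-vs-rest with macro averaging (the averaging rule is a package choice).
The Fisher score of the selected subset is the standard
between/within-class variance ratio
$F_i = \sum_c n_c(\mu_{ci} - \mu_i)^2 / \sum_c n_c \sigma^2_{ci}$, averaged
over the subset; it is data-dependent and reported, not asserted against
any external value.

## The synthetic corpus

The generator emulates the three classes at Bonn geometry (173.61 Hz,
23.6 s, 4097 samples):

* **normal** — Gaussian background ($\sigma_{bg} = 20\,\mu V$) plus a 10 Hz
  alpha sinusoid (30 μV, random phase);
* **interictal** — normal plus sporadic biphasic sharp transients
  (Poisson rate 0.4/s thinned to ≥ 200 ms spacing, amplitude
  $6\sigma_{bg}$, width ≈ 60 ms);
* **ictal** — background plus rhythmic spike-and-wave (fundamental drawn
  from 3–5 Hz with two harmonics at 1 : 0.5 : 0.25), peak amplitude 6× the
  typical normal peak.

Amplitudes sit in the range a clinician would call plausible for scalp EEG,
and the class contrasts (transient sparsity vs rhythmicity vs amplitude) are
the ones the clinical taxonomy names. Per-record seeds are spawned from the
master seed by counter, so any record is reproducible in isolation and
independent of generation order.

What the generator does **not** model: volume conduction, electrode
artifacts (EOG/EMG), non-stationary background drift, patient-to-patient
variability, or the continuum between interictal and ictal activity. Passing
tests on this corpus therefore demonstrate that the pipeline's machinery is
correct and that it separates classes whose differences resemble the
clinical ones — not that the reported accuracies transfer to clinical data.
The planted-feature tables serve the complementary role for the optimizer:
known informative columns with exact effect sizes.

## Problem sizes and numerical tolerances

The packaged experiments run at 100 records per class (300 records,
matching the three-set protocol), 100 optimizer iterations with population
10, and an 80/20 split; tests that only exercise orchestration use smaller
swarms and shorter records. Tight-frame and shift-invariance identities are
asserted at $10^{-8}$ relative or better; descriptor implementations agree
with independent definitional oracles at $10^{-10}$; the transfer function
matches its closed form at $10^{-12}$.

## Known limitations

* On benchmarks where a small feature subset already achieves zero
  cross-validated error, the wrapper objective is flat over everything that
  keeps the error at zero: only the (feature-agnostic) size penalty acts,
  so the identity of the returned subset is not fully determined and
  "recovery" of all informative columns cannot be forced by this objective.
  The packaged recovery benchmark shows exactly this plateau behavior.
* The selected-feature ratio is data- and seed-dependent; on the synthetic
  corpus it is typically 0.2–0.4, larger than ratios reported on real EEG,
  again because near-zero error leaves the size penalty as the only
  pressure.
* KNN tie-breaking inside the fitness is randomized by `class::knn`; the
  fitness seeds that draw, so results are reproducible, but a different k
  or distance metric would change selected subsets more than it changes
  accuracy.
* The max-abs normalization removes absolute amplitude before feature
  extraction (see above); pipelines that need the amplitude cue should set
  `normalize_before_features = FALSE`.
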