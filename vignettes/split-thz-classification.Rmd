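---
title: "Methods: split-learning classification of THz-style hyperspectral tissue images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-learning classification of THz-style hyperspectral tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitthz)
```

## Scope and pipeline

`splitthz` classifies individual pixels of terahertz-style hyperspectral
reflectance cubes into fat, muscle and cancer. The pipeline is

phantom generation → spectral preprocessing → PCA → EM reliability
selection → split-learning training of an ordinal probit head → evaluation,

and `run_pipeline()` executes it end to end with every stage seeded from
one global seed (`derive_seed()` maps the global seed to fixed per-stage
seeds, so a stage rerun in isolation reproduces its in-pipeline draw).

## The synthetic phantom

No real mouse-tumor THz cubes are publicly available, so all testing runs
on phantoms. A phantom is an H×W×B array with disjoint labeled regions
(axis-aligned rectangles and discs, chosen because exact pixel membership
is computable in tests) on a background. Each class has an isotropic
Gaussian spectrum in band space. The class means are collinear: fat,
muscle and cancer sit at increasing offsets along one spectral direction,
mirroring the water-content ordering that drives THz tissue contrast and
making the ordinal latent-scale model scientifically appropriate rather
than merely convenient.

Defaults (the conditions used throughout the tests): 64×64 pixels, 16
bands, adjacent-class mean separation of 5 noise standard deviations
(Euclidean, in band space), unit noise SD per class. Fresh-vs-FFPE
degradation is emulated by `corrupt_labels()`: a seeded random subset of
labeled pixels receives a constant additive spectral shift (default
magnitude 5 SDs spread evenly across bands) and is flagged in a corruption
mask; 10% of labeled pixels are corrupted in the default pipeline.

What the phantom does **not** emulate: spatial correlation of noise,
instrument point-spread functions, band-dependent noise, partial-volume
mixing at region boundaries, or any THz wave physics. Tests passing on
phantoms therefore demonstrate the *algorithmic* properties (recovery,
filtering, equivalence, calibration of the evaluation battery), not
instrument-level performance on real tissue.

## Preprocessing

- **Nyquist guard.** `check_nyquist()` passes iff the sampling interval is
  at most half the reciprocal of the highest frequency component.
  `resample_signal()` decimates by an integer factor without an anti-alias
  pre-filter; the guard is the user's responsibility after decimation.
- **Min–max normalization** maps each feature column onto [0, 1]. A
  constant column makes the transform undefined and raises an error naming
  the column — silent mapping to 0 would corrupt downstream distances.
  Parameters are fitted on the training split only and re-applied to
  held-out data, avoiding leakage.
- **Low-pass filtering** is discrete FIR convolution of each pixel
  spectrum ("same" output length). The continuous convolution integral is
  replaced by its discrete analogue because pixel spectra are discrete.
  Boundaries use edge replication, avoiding artificial dips at the
  spectrum ends; the index convention is documented in `?lowpass` and
  fixed for reproducibility. The default kernel is the 3-tap binomial
  smoother `[0.25, 0.5, 0.25]` (unity DC gain); high-pass filtering is out
  of scope.

## PCA features

`pca_fit()` eigendecomposes the unbiased (1/(n−1)) sample covariance.
Loadings are column-orthonormal with a deterministic sign rule (the
largest-magnitude entry of each column is positive), and eigenvalue ties
keep the eigendecomposition's order — both choices exist purely so that
repeated fits are bit-identical and tests can compare loadings directly.
When neither `k` nor a variance fraction is given, 95% retained variance
is the default; the pipeline default is `k = 3`, which is enough to
separate three collinear class means plus a corruption direction. Tiny
negative eigenvalues from round-off are clipped at zero.

## EM reliability selection

The corruption model motivates a per-class two-component isotropic
Gaussian mixture in PCA space: one component for reliable pixels, one for
the shifted population. EM is run per class (running it globally would
confound class structure with corruption structure). Initialization is
deterministic: the reliable component starts at the class median, the
unreliable one at the point farthest from the median, mixing weight 0.8 —
biased toward the majority being reliable, which matches the sampling
design (corruption fractions well below one half). A variance floor of
1e-6 times the class's total variance prevents the classical
single-point collapse. Convergence is declared when the relative
log-likelihood change falls below 1e-8 (default) or after 200 iterations;
the trace is stored and is nondecreasing, which the test suite asserts on
every run.

The reliability score of a pixel is the posterior responsibility of its
class's reliable component; `select_reliable()` keeps scores strictly
above τ. τ = 0.8 is the package default: with well-separated components
responsibilities saturate near 0 or 1, so any threshold in (0.2, 0.95)
behaves similarly, and 0.8 errs toward discarding doubtful pixels —
training data are plentiful relative to the 5-parameter head. The
component designated "reliable" is the heavier one; if EM ends with the
shifted component heavier (possible only when corruption exceeds half the
class), the designation follows the weight, which is the defensible
behaviour without external information.

## The ordinal probit head

Classes are ordered fat < muscle < cancer. A latent score `β'z + ε`,
`ε ~ N(0, 1)` (scale fixed for identification), is cut by `γ₁ < γ₂`. The
phrase "multinomial ordinal" admits two readings; the ordinal one (single
β, shared cutpoints) is implemented because it minimizes parameters —
`d + C − 1` in total — which is the design goal; an unordered multinomial
probit with per-class weights is a non-goal. The class order is a fixed
convention exposed through the `classes` argument.

**MAP fitting** is plain gradient descent on the penalized negative
log-likelihood (independent normal(0, 10²) prior on β, flat on ordered
cutpoints), because the same first-order update is what the split protocol
distributes. The default learning rate is `1/n`: the Hessian of a summed
likelihood scales linearly with n, so `α = 1/n` keeps the effective step
size constant across problem sizes. Defaults `max_iter = 2000`,
`tol = 1e-8` (relative loss change). Cutpoint ordering is enforced after
every step with a minimum gap of 1e-8; per-observation likelihoods are
floored at 1e-300 with a warning under extreme linear predictors, and a
loss above 1e10 raises a divergence error suggesting a smaller α.
Initialization is deterministic: β = 0, cutpoints (−0.5, 0.5).

**Gibbs sampling** uses the classical latent-variable augmentation:
truncated-normal latents given the observed class (drawn by inverse-CDF,
with the truncation interval kept numerically non-empty and latents
clamped to ±8 SDs of the linear predictor), a conjugate normal draw for β,
and uniform conditional draws for each cutpoint on the interval pinned by
the neighbouring classes' latents — so every retained draw is ordered by
construction. Cutpoint updates require every class present in the data.
Defaults: 1500 draws, 500 burn-in. The reported point estimate of a
`method = "gibbs"` fit is the posterior mean.

An independent cross-check in the test suite confirms the MAP coordinates
against the ordinal probit MLE of `MASS::polr` (the prior's shrinkage is
negligible at the test's n), and a finite-difference oracle validates
every analytic gradient.

## The split-learning protocol

The client model is a single linear layer (optional tanh), d_out = 3 by
default — deliberately small, matching the head's parameter budget. Client
weights initialize from a seeded normal with variance 0.01; the server
head starts at β = 0, cutpoints (−0.5, 0.5).

Each round: the client sends representations and labels; the server
computes class probabilities, the NLL loss, the head gradient, and the
gradient with respect to the representations, which it returns; the server
updates first, then the client pulls the representation gradient back
through the chain rule — both from the same round's loss. The update
equations for client and server are formally simultaneous; sequential
execution with the same round's gradients reproduces exactly one joint
gradient-descent step on the composed model, which is the package's key
structural property: the test suite verifies the split and joint
trajectories agree round-by-round (to 1e-9; in this implementation they
are bit-identical) over 100 rounds on a 200-pixel task.

Labels travel to the server (the label-sharing variant): the server's
update needs the loss, and the privacy claim protected — and audited — is
the confidentiality of the raw feature rows. `audit_transcript()` checks
that no payload equals or contains (as a contiguous column block) any raw
feature row; payloads narrower than the raw dimension pass dimensionally.
Transport, encryption, and gradient-inversion attacks are out of scope.

Multi-client mode is sequential round-robin with weight hand-off: within
each round the clients run, in fixed order, one update each on their own
partition (IID by default, seeded). Convergence is declared when the
relative change in the full-data loss between consecutive rounds falls
below `tol` (default 1e-6; `tol = 0` disables early stopping for
fixed-round experiments); `max_rounds` defaults to 500.

## Evaluation battery

- **Pooled t-test** on the first principal component of cancer vs
  non-cancer pixels. The pooled (Student) rather than Welch form is used
  so the degrees of freedom are `n₁ + n₂ − 2`, the convention matched by
  the reported two-group results in this literature. `log10_p` is computed
  via `pt(log.p = TRUE)` so extreme statistics remain informative instead
  of underflowing. Zero pooled variance with equal means yields t = 0,
  p = 1; with unequal means it is a degenerate-input error.
- **AUC** is the rank-based Mann–Whitney statistic with half credit for
  ties, computed one-vs-rest per region from the probit class
  probabilities. **Segmentation thresholds** maximize Youden's J over all
  score midpoints; ties break toward higher sensitivity, prioritizing
  cancer detection.
- **Classification report**: per-class one-vs-rest TP/TN/FP/FN counts and
  accuracy, precision, recall, F1. Zero-denominator metrics surface as
  `NA` with a warning — silent zeros would corrupt model comparisons.
- **Learning curves**: per-round training/validation loss and accuracy
  (recorded when `train_split()` receives a validation set), the argmax
  epoch of validation accuracy, and a plateau flag (no improvement beyond
  1e-4 over 10 epochs).

## Problem sizes and numerical tolerances

The test and acceptance workloads use phantoms between 24×24×8 and
64×64×16 (roughly 200–1600 labeled pixels), parameter-recovery samples of
n = 2000, Gibbs chains of ~1200 draws, and up to 500 communication
rounds — sizes at which every statistical property under test (recovery
within the stated bands, EM exclusion rates, AUC levels) is comfortably
resolved while the full suite runs in well under a minute. Equivalence
checks run at 1e-9, linear-algebra identities at 1e-8, gradient checks at
1e-5 relative, and exact combinatorial oracles (AUC pair counting,
convolution double sums) at equality.

## Storage formats

Cubes serialize to a plain-text JSON format (`write_cube()`): the
flattened cube, the label map (0 = background, 1 = fat, 2 = muscle,
3 = cancer), the corruption mask, and the seed and full configuration as
attributes, written at 17 significant digits so round trips are lossless.
Models serialize to JSON, label maps and pixel tables to CSV, session
transcripts to JSON lines, and run directories carry an MD5 manifest of
every artifact.

## Known limitations

- The phantom's isotropic, spatially independent noise makes the task
  easier than real THz cubes; reliability filtering and AUC levels on real
  data will be worse.
- The ordinal assumption (single latent direction) is right for
  water-content-ordered tissue but would mis-specify tissues that are not
  ordered; the multinomial extension is deliberately excluded.
- The corruption model is a constant shift; FFPE artifacts with
  class-dependent or nonlinear structure would need a richer mixture.
- The split protocol shares labels with the server and does not defend
  against representation-inversion adversaries; it guarantees only that
  raw rows never cross the boundary, which the audit enforces.
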