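---
title: "Simulating federated training of glioblastoma segmentation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating federated training of glioblastoma segmentation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedsegsim)
```

## The problem and the model

Glioblastoma delineation on multi-parametric MRI (T1, T1Gd, T2, T2-FLAIR)
distinguishes three *nested* tumor sub-compartments: the enhancing tumor
(ET), the tumor core (TC = ET plus necrotic core), and the whole tumor
(WT = TC plus peritumoral edema).  Segmentation reference labels follow the
BraTS convention — integer codes 0 (background), 1 (necrosis, NCR),
2 (edema, ED) and 4 (enhancing tumor, ET) — and the three regions a model
predicts are unions of those codes, nested as ET ⊆ TC ⊆ WT.

Training an accurate model requires data from many hospitals, but patient
volumes rarely leave their institutions.  Federated learning (FL) solves
this by moving the model instead of the data: each collaborating site
trains the shared network on its local cases for one epoch per *federated
round*, sends only parameter updates to an aggregation server, and
receives back a consensus model formed by federated averaging (FedAvg) —
the elementwise mean of site parameters weighted by each site's
contributing training data.

`fedsegsim` re-creates this whole workflow at desk scale, replacing
hospital data with synthetic mpMRI phantoms so that every mechanism —
label algebra, loss, round protocol, aggregation weighting, consensus-model
selection, and data-quality monitoring — is exercised and testable on one
CPU.

## The segmentation network and its loss

The network is a configurable 3D U-Net with residual connections.  Each
encoder level is a residual block (two 3×3×3 convolutions with instance
normalization and leaky-ReLU activations, plus an identity or 1×1×1
projection shortcut); levels are connected by 2×2×2 max-pooling, the
decoder mirrors them with kernel-2, stride-2 transposed-convolution
upsampling and concatenation skip connections, and a final 1×1×1
convolution with a sigmoid produces three output channels per voxel, one
per region in the fixed order (ET, TC, WT).  Published descriptions of
such architectures typically leave the exact block composition to a
diagram; the composition above is this package's own fixed choice of a
standard 3D-ResUNet and is configurable in code if an alternative is
needed.

Training minimizes the *mirrored* generalized Dice (DSC) loss.  The
generalized DSC between reference values RL and predicted values PM is

$$\mathrm{DSC} = \frac{2\,\lVert \mathrm{RL} \odot \mathrm{PM} \rVert_1}
{\lVert \mathrm{RL} \rVert_1 + \lVert \mathrm{PM} \rVert_1},$$

with ⊙ the elementwise product.  The loss averages, over the three
regions, one minus the *soft* DSC evaluated on the absolute complement of
each region (reference complement vs. one-minus-sigmoid).  Scoring the
complement keeps small structures such as a thin enhancing rim from being
swamped by their size, so no per-region penalty weights are used.  Final
predictions binarize each sigmoid channel with a strict `> 0.5`
comparison; evaluation uses the binary generalized DSC per region, with
the both-empty convention DSC = 1.

Two conventions worth noting, both fixed for determinism:

* exactly-0.5 activations map to 0 (strict threshold; ties are
  measure-zero in practice);
* a loss channel whose reference and predicted complements are both empty
  contributes 0 — no smoothing epsilon is added, since the complement of a
  sub-compartment inside a patch is never empty in practice.

## Data pipeline

Per case, in order: (1) all-zero border planes are cropped on each axis
(only leading/trailing planes — interior removal would break spatial
contiguity); (2) each channel's non-zero intensities are z-scored to mean
0, population SD 1, leaving background exactly zero (a constant channel is
zeroed); (3) during each training epoch a single random cubic patch is
drawn per case (volumes smaller than the patch are first zero-padded
symmetrically); (4) augmentation applies, in fixed order, a flip
(probability 1, axis uniform), a 90° and a 180° rotation (probability 0.5
each, rotation axis re-drawn uniformly per event), and additive Gaussian
noise (μ = 0, σ = 0.1, probability 0.2) on the image channels only.  The
fixed ordering (geometric, then intensity) is a package choice where the
protocol lists the augmentations without an order; it keeps the noise
un-rotated and the pipeline deterministic to test.  Whole-volume
z-scoring happens once per case rather than per patch, the cheaper and
deterministic of the two readings of the protocol.

Each site's cases are split 4:1 into training and validation using
`n_val = floor(n/5)` (at least 1), by a seeded shuffle.  The floor rule is
forced by the canonical bookkeeping: 231 cases split into 185 training
and 46 validation.  Splits derive from per-site seeds hashed out of the
global seed, so they are preserved for the entire federation and
reproducible regardless of site iteration order.

## The federated round protocol

One round: broadcast the consensus parameters to every participating
site; each site runs one local epoch (one Adam step per case, batch size
1, one fresh augmented random patch per case); the server forms the new
consensus by FedAvg with weights equal to the sites' *training-split* case
counts ("contributing data" is read as the data the update was computed
from, not total contributed cases); the new consensus is evaluated on
every site's local validation cases.  Optimizer moments are never
aggregated; by default each site also starts every round with a fresh
Adam state.  Persisting local moments across rounds sounds attractive
(no re-warm-up), but after a broadcast the persisted momentum describes
the site's *previous* trajectory, not the new consensus point, and with
the short local epochs of a desk-scale federation (≤ ~12 steps) that
stale momentum measurably drags the consensus below what centralized
training reaches — in the bundled homogeneous-federation simulation,
persistence plateaus the pooled validation DSC roughly 0.1 lower than
per-round resets under identical budgets.  A `reset_optimizer = FALSE`
flag restores persistence for studying exactly this effect.  Rounds are
synchronous; a site failure
aborts the round rather than aggregating partially.  Sites tagged
`public_initial` (the data behind a pre-trained starting model) rejoin
training as ordinary collaborator nodes; `out_of_sample` sites never
train and serve only for generalizability evaluation.

Every round's consensus is checkpointed, because model selection operates
over the whole round sequence: the *singlet* is the round whose validation
collective score (per-case mean over the three regions, then mean across
all cases of all sites) is highest, and the *triplet* picks one
specialist round per region by that region's pooled score.  Ties break
toward the earlier round (cheaper to trust, and determinism requires a
rule).  Triplet inference runs exactly three forward passes and assembles
region r from specialist r's sigmoid output before a single thresholding
pass; ensembles average member sigmoids voxelwise before thresholding.
Stopping is a fixed round budget by default, with optional plateau
detection (no improvement above ε across a trailing window) mirroring how
a long federation is halted in practice after validation flattens.

## Monitoring and evaluation

Per-round, per-site validation curves are the federation's quality
monitor.  A site whose reference annotations are wrong scores
consistently below the federation mean; `site_anomaly_scan()` formalizes
this by pairing, per region, the site's round-wise mean with the pooled
federation mean across rounds and applying a two-sided Wilcoxon
signed-rank test (exact null distribution up to 25 ties-free pairs,
normal approximation with continuity and tie corrections otherwise; zero
differences dropped).  A site is flagged when p < α (default 0.05) *and*
its mean lies at least a minimum effect (default 0.05 DSC) below the
federation's — the test is two-sided but the flag is one-sided-in-effect,
since only low scores indicate a problem.  The minimum-effect guard is
essential: the paired rank test is magnitude-blind, and a site whose
fixed validation cases are marginally harder than average sits below the
federation mean in *every* round, driving p to its floor at a deficit of
a few hundredths of a DSC point.  In the bundled corrupted-federation
simulation, clean sites show significant deficits of at most ≈ 0.03 DSC
(ordinary case-difficulty spread) while the label-corrupted site's ET/TC
deficits exceed 0.5 — the guard separates the two regimes by an order of
magnitude.  Whether such tests should be one- or two-sided is not fixed
by convention in this setting; two-sided is implemented and documented.
P-values are reported raw across sites (an optional Bonferroni column is
available).

Model comparisons (`compare_models_paired()`) report per-region means for
both models, the *relative* improvement (Δ/mean of the baseline × 100 —
a 0.62 → 0.82 change in TC reads as ≈ +33%), and paired Wilcoxon
p-values per region, with an undefined (not infinite) improvement when
the baseline mean is zero.

## The phantom generator

Phantoms stand in for the multi-site patient data.  Each case is an
ellipsoid "brain" of non-zero intensity on a zero background with, by
default always, a concentric three-compartment tumor: an NCR core inside
an ET shell inside an ED envelope (radii strictly increasing), the
simplest geometry that satisfies the nesting the annotation protocol
defines while remaining learnable by a small network.  Mean intensity per
(channel × tissue) encodes the expected radiology — ET enhances on T1Gd,
NCR is dark on T1Gd, ED is brightest on T2-FLAIR — and sites perturb
these with per-channel affine effects (shift/scale), emulating scanner
heterogeneity.  Gaussian noise (default σ = 5 intensity units against
tissue contrasts of ~40–80) keeps classes clearly separable, which is
deliberate: the phantoms are designed so that federation behaviors
(aggregation, weighting, corruption effects) dominate the signal, not raw
task difficulty.  Site case-counts in the bundled fixtures are skewed,
mimicking the heavy imbalance of real federations, and per-site seeds
derive from a stable hash of the site id so a federation is bit-identical
under the same seed regardless of iteration order.

Annotation corruption is injectable per site: `label_swap` (ET↔ED codes
exchanged — the classic mislabeled-protocol site), morphological `dilate`
/ `erode` of the whole tumor, or `random_flip` of tumor codes.  Images
are untouched; corrupted maps remain valid label maps.

What the phantoms do *not* emulate: MR physics (bias fields, partial
volume, anisotropic voxels), deformable anatomy, registration error, or
realistic tumor shape.  Passing tests therefore demonstrate that the
federated machinery is correct and robust under controlled heterogeneity
and label noise — not that any particular DSC level transfers to real
patient data.

## Numerical and scale choices

* **Problem sizes.**  The bundled simulations use 48³-voxel volumes, a
  4-filter depth-2 network and 32³ patches (`tiny_model_config()`), with
  federations of 5–6 sites and 2–14 cases per site trained for 10–20
  rounds — sizes chosen so a full multi-federation study runs in minutes
  on a single CPU core while exercising every architectural element.  The
  paper-scale regime (30 base filters, depth 4, 128³ patches, lr 5 × 10⁻⁵)
  remains expressible via `model_config()` defaults.
* **Learning rate.**  The tiny configuration trains with Adam at 5e-3
  rather than the large-scale 5 × 10⁻⁵: desk-scale runs take on the order
  of 10³ optimizer steps rather than several 10⁵, and the rate is
  calibrated so both centralized and federated training *converge* on the
  phantom task within that budget — comparisons between the two are then
  about their converged behavior, not about transient optimization speed.
* **Determinism.**  All stochastic stages (case geometry, splits, patch
  corners, augmentation, initialization, epoch shuffling) draw from
  streams derived by a stable FNV-style hash of a global seed plus
  context tags, so runs are bit-reproducible and independent of site
  ordering; a 1-site federation reproduces centralized training
  bit-exactly.
* **FedAvg normalization.**  Aggregation weights are normalized to sum to
  one before averaging, making aggregation invariant to weight rescaling
  and a single-site aggregation exactly the identity in floating point.
* **Degenerate inputs.**  Entirely-zero images are rejected at cropping;
  constant non-zero channels z-score to zero; empty-region DSC follows
  the both-empty = 1 convention; all-zero-difference Wilcoxon samples
  report p = 1 with a degenerate flag.
* **Label code 3.**  The legacy BraTS "non-enhancing" code is rejected,
  not remapped — the annotation protocol modeled here defines only
  1/2/4, and silently remapping would hide upstream data errors.

## A small worked federation

```{r federation, eval = FALSE}
sites <- list(
  site_spec("A", 8), site_spec("B", 6), site_spec("C", 6),
  site_spec("BAD", 2, corruption = corruption_spec("label_swap", fraction = 1))
)
ds <- generate_federation(sites, phantom_config(), seed = 1)
run <- run_federation(
  federation_config(max_rounds = 25, seed = 1),
  ds, init_model(tiny_model_config())
)
glance(run)
select_models(run$case_scores, k = 3)
scan_all_sites(run)
autoplot(run)
```

The corrupted two-case site trains on (and validates against) swapped
ET/ED labels; because it holds a small fraction of the total data its
weighted contribution barely moves the consensus, while its own
validation curve sits far below the federation mean and is flagged by the
anomaly scan — the robustness-plus-detectability behavior the round
protocol is designed to surface.

## Known limitations

* The residual-block composition stands in for an unpublished diagram;
  conclusions about exact parameter counts or layer-level behavior are
  specific to this package's choice.
* Whole-volume validation inference is used each round (phantom volumes
  are small); patch-wise validation of large volumes is not implemented.
* Phantom realism is intentionally limited (see above); DSC levels
  reached here do not predict clinical performance.
* No network transport, encryption, or trusted-execution machinery is
  simulated — the federation is an in-process loop over sites.
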