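---
title: "NN-FDK reconstruction: model, training and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NN-FDK reconstruction: model, training and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nnfdk)
```

This vignette is the package's own account of the science it implements:
what is computed, under which assumptions, which knobs matter, and where the
design was genuinely open and a choice had to be made.

## 1. The reconstruction problem and FDK

A circular cone-beam scan is modelled as a linear system `W x = y`: `x` is
the N×N×N volume of attenuation values (1/cm), `y` the stack of `Na` cone
projections of N×N detector pixels (dimensionless `-ln(I/I0)` line
integrals), and `W` the discretized cone-beam transform. The FDK algorithm
approximately inverts this system in three steps,

`FDK(y, h) = W' ( h * r(y) )_1D`,

where `r` multiplies each detector sample at physical position (u, v) by
`D / sqrt(D² + u² + v²)` (D the source-to-detector distance), `(h * ·)_1D`
convolves every detector row with a one-dimensional filter `h` of 2N spatial
taps, and `W'` is a voxel-driven backprojection with bilinear detector
interpolation carrying the Feldkamp distance weight `(Rs/(Rs+s))²` (`s` the
voxel coordinate along the source-to-centre axis). FDK is exact only in the
midplane and degrades with cone angle, noise and angular undersampling —
this is the gap the learned filters close.

### Coordinates, units, normalization

* The volume is centred on the rotation axis, sample points at cell
  centres; detector rows are axial, columns transaxial, u = v = 0 at the
  detector centre. Lengths are mm; attenuation is 1/cm, so the projectors
  integrate path length in cm. This makes `exp(-y)` a physical transmission
  and keeps Beer–Lambert noise simulation consistent.
* Standard filters (Ram-Lak, Hann) are built by sampling the ideal
  frequency response `|f|` (times the Hann window) on the 2N-point DFT grid
  in cycles per cm of the *virtual* detector pitch (detector pitch divided
  by the magnification), then inverse-transforming. Sampling the exact
  response rather than truncating the closed-form taps gives an exactly
  zero DC response, a Hann response exactly zero at Nyquist, and exactly
  vanishing even-offset taps (the sampled taps are the aliased closed-form
  coefficients, and aliasing preserves parity).
* The angular normalization `pi / Na` (the full-circle angular step over
  its two-fold redundancy) lives in the backprojection, not the filter, so
  learned filter coefficients remain comparable across angle counts. The
  pitch factor of the convolution integral is carried by the
  frequency-sampled taps themselves (which scale as 1/pitch).
* Convolution uses FFT multiplication with zero padding to at least 3N−1
  (linear, zero-boundary). A consequence visible in tests: applying Ram-Lak
  to a *finite* constant row leaves a ~2–3% residue because the tap tails
  are truncated at the row ends; this is a property of any linear
  convolution implementation, not an error.

### Projector discretizations

The forward projector is ray-driven (trilinear sampling along each
source-to-pixel ray, step = half a voxel). Its *exact transpose* — the same
samples applied in scatter form — is `backProject(method = "matched")`; the
pair passes adjoint dot-product tests at machine precision, which is what
SIRT's convergence theory needs, so SIRT uses it. The FDK backprojector is
the standard voxel-driven bilinear one: faster and smoother, but not the
exact transpose. A reference GPU implementation would make the same split;
absolute grey values of FDK reconstructions therefore agree with other
implementations only up to discretization, which is harmless for NN-FDK
because the network learns the scale.

## 2. The NN-FDK network and its equivalence to the reconstruction

Filters are compressed by exponential binning `h ≈ E h_e`: the 2N taps are
partitioned into `Ne` bins, symmetric about the centre tap, with radial
widths 1, 1, 1, 1, 2, 4, 8, … truncated at radius N, and mirror bins at the
same distance merged (learned FDK filters are treated as symmetric). The
precise width sequence of the historical scheme is not published; this
sequence was chosen because it satisfies the two published constraints —
`Ne` grows like log₂N, and an Nh = 4 network at N = 1024 has exactly
(13 + 2)·4 + 1 = 61 trainable parameters — and it is exported as plain bin
boundaries (`binningDescription()`) for reproducibility. Columns of `E` are
0/1 indicators without width normalization; conditioning is handled by
input scaling during training instead.

The network applies `Nh` sigmoid perceptrons with weights `h_e^k` and biases
`b_k` to the `Ne` feature values of a voxel, then one output perceptron
(ξ, b₀). Because FDK is bilinear, the v-th voxel of the full reconstruction
equals the network applied to the v-th row of the feature matrix
`F_y E` — whose j-th column is simply `FDK(y, E e_j)`. `nnfdkReconstruct()`
exploits this: it runs exactly `Nh` FDK reconstructions with the expanded
filters and combines them pointwise. The equivalence is the module's central
correctness property and is asserted to 1e-5 relative error at N = 16 and
N = 32 in the test suite.

### Scalings (a design decision)

The output perceptron is sigmoidal, so raw grey values (≈0–0.33 1/cm here)
must be mapped into (0, 1) for Eq.-style least squares to make sense. Two
affine maps are stored inside the parameter object:

* **target scaling**: the pooled ROI value range of the high-quality
  targets is mapped to [0.05, 0.95] before training; the inverse map is
  applied after reconstruction. The 5% margin keeps targets away from the
  saturated sigmoid tails.
* **input scaling**: each of the `Ne` feature channels is normalized to
  zero mean, unit standard deviation over the training pairs (LMA
  conditioning — the outer bins have systematically smaller dynamic range).
  At reconstruction time the scaling is *fused* into the filter
  coefficients and hidden biases, so the voxelwise equivalence holds
  exactly rather than approximately.

Neither map is part of the published method description (its appendix is
not available); both are standard practice for sigmoid-output regression
and are serialized with the parameters.

## 3. Training

Training pairs are (feature row, scaled HQ voxel). To avoid fitting empty
background, pairs are drawn only from a region of interest: the HQ volume
thresholded by Otsu's method, dilated by a cubic structuring element of
radius `round(0.2 N)` voxels. Draws are uniform without replacement, unique,
disjoint between training and validation, and balanced across datasets.
Defaults follow the published recipe — Nh = 4 hidden nodes, 10⁶ training and
10⁶ validation voxels — but the pair counts scale down automatically (with a
message) when the ROI is smaller, as it always is at test sizes N = 16–64.

The loss is `L(θ) = ½ Σ (O_j − Nθ(Z_j))²`, minimized by full-batch
Levenberg–Marquardt with the analytic Jacobian (checked against central
finite differences to 1e-5): each epoch solves `(J'J + λ D) δ = J'r`,
accepts the step only if the training loss decreases, divides λ by 10 on
acceptance and multiplies by 10 on rejection (λ₀ = 1e-2). `D` is the
identity by default; damping by `diag(J'J)` is available behind a config
switch since the historical variant is unspecified. Validation loss is
tracked every epoch; the returned parameters are those with the lowest
validation loss seen (initialized with θ₀ itself, so training can never
return something that validates worse than its start), with ties resolved
toward the earliest epoch for determinism. Early stopping after 100 epochs
without validation improvement, at most 500 epochs. Since the loss is
nonconvex, `trainNNFDK(config = lmaConfig(restarts = k))` trains from `k`
seeded random initializations and keeps the best validation loss;
single-start training occasionally lands in a local minimum (one seed in the
planted-recovery experiments does), and multi-start is the package's
standard remedy.

LMA is a batch method, so an "epoch" is one LMA iteration over all pairs;
with fewer than ~60 parameters the normal equations are trivially cheap and
the quasi-Newton convergence rate is what makes training take seconds.

## 4. What the synthetic data emulates — and what it does not

`fourshapeRandom()` draws three occurrences each of four primitive types —
ellipsoid, cuboid, Gaussian blob, Siemens star (8 bright wedges) — with
random sizes, orientations (Haar-random rotations), centres and relative
intensities in [0.5, 1.5]. The published description names the families and
the randomization axes but not the distributions; the ranges used here
(half-extents 2.5–15% of the cube width, all config-exposed) produce scenes
with the same qualitative variability and are stated once, not tuned. The
2D names "ellipse, rectangle" are read as their 3D solids, since the method
reconstructs volumes. `defriseRandom()`/`defriseStandard()` build the
classic stack of thin disks that exposes cone-angle artifacts; the random
variant varies radius, thickness, tilt (≤5°) and intensity under a
non-overlap constraint with bounded retries.

Phantoms live in a 10 cm cube, intensity 1 maps to μ = 0.22 1/cm (common
plastics at ~40 keV), and primitives are additionally confined to the
inscribed sphere of radius 0.475 — the physical field of view of the default
geometry (`simGeometry()`: source at 1 m, detector at 0.5 m behind the
centre, magnification 1.5, detector pitch 1.25× the magnified voxel) — so no
projection is ever truncated. Voxelization samples at 2× per axis and
block-averages (partial-volume handling).

Noise follows Beer–Lambert: detected counts `c ~ Poisson(I0 · exp(−ȳ))`,
converted back through `−ln(max(c, 1)/I0)`; the clamp keeps fully absorbed
rays finite and is noted here because it slightly biases the very darkest
rays. The high-quality target recipe is a dense 1500-angle scan at
`I0 = 2²⁰` reconstructed with Hann-filtered FDK. The printed source value
"I0 = 220" is read as 2²⁰ (the literal 220 would be *noisier* than the
low-quality scans it is meant to supervise); this reading is config-exposed
and never used as an acceptance number.

What the generator does **not** emulate: scatter, beam hardening, detector
blur and afterglow, ring artifacts, mechanical jitter — all present in real
scanner data. A green end-to-end test therefore establishes that the
pipeline learns and generalizes within the stated noise/undersampling model,
not that it reproduces experimental-scanner error tables.

## 5. Evaluation

* **TSE** is the average training loss over the ROI,
  `TSE = ‖mask ⊙ (x_hq − x_r)‖² / (2 N_ROI)` — note the factor ½ inherited
  from the loss; the tests assert the exact consistency between the two
  code paths.
* **SSIM** uses a uniform 19-pixel window with the default stabilization
  constants, computed in 2D per axial slice over the ROI bounding box and
  averaged (the published competitors are 2D slice-based networks, which
  motivates slice-wise evaluation); whether the original computation masked
  to the ROI is unstated, so ROI-masked is the default and full-slice is
  available. Valid-window (no padding) semantics with sample covariance
  normalization match the common scikit-image implementation.
* **Segmentation metrics**: signed volume error `(|S_rec| − |S_gs|)/|S_gs|`
  (tables elsewhere report magnitudes; the sign is informative, so it is
  kept and `abs()` is left to the caller), mislabelled fraction
  `|S_rec − S_gs|/|S_gs|`, and Dice `2|S_rec ∩ S_gs|/(|S_rec| + |S_gs|)`.
  The watershed pipeline that *produces* masks on real data is out of
  scope; only mask comparison is implemented.

## 6. Baseline

SIRT⁺ iterates `x ← max(0, x + C W' R (y − W x))` from zero, with `R`, `C`
the inverse row/column sums of `W` (zeroed where undefined), using the
matched projector pair. It converges to the row-sum-weighted least-squares
solution (the tests verify this on an explicit small system), and the
nonnegativity projection is applied after every update. Default iteration
counts mirror common practice: 200 (few-angle/high-dose) and 20 (low-dose).

## 7. Degenerate inputs, tolerances, determinism

* All randomized operations take explicit seeds and run on a private RNG
  stream that never disturbs the caller's `.Random.seed`.
* Singular LMA normal equations are handled by λ escalation, never failure;
  non-finite losses abort with an error.
* Constant volumes are rejected by `roiMask()` (no object), empty masks by
  `tse()`, empty gold standards by the segmentation metrics; the SSIM of
  two constant images is 1 through the stabilized formula.
* Adjointness holds at ~1e-16 for the matched pair; the voxelwise network
  equivalence at ≤1e-5 relative (float accumulation across `Nh` FDK runs);
  filter/convolution oracles at 1e-10.
* End-to-end experiments in the test suite scale the published world down
  (N = 64, Na = 32, I₀ = 256, pair counts 2×10⁴) to fit a single-CPU
  budget; the SIRT⁺ monotonicity check runs at 200 iterations on the same
  data. The headline N = 1024 tables of the source study are not
  reproducible at desk scale and are deliberately not targeted.

## 8. Known limitations

* The native projectors are single-threaded CPU code; N beyond ~256 is
  impractical. The projector interface is narrow (three functions), so a
  GPU backend could replace it, but none ships here.
* Short-scan (Parker) weighting, detector offsets/tilts, helical
  trajectories and polychromatic physics are out of scope.
* The exponential binning scheme is *a* faithful reconstruction of the
  published constraints, not a byte-level reimplementation of the
  historical code; learned coefficients are therefore not interchangeable
  with other implementations, though reconstructions are.
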