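---
title: "Quantifying multi-site MRI reproducibility: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-site MRI reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrirepro)
```

## The problem

Multi-site MRI studies pool quantitative measurements — brain-structure
volumes, diffusion metrics — made on different scanners, from different
vendors, over years. Before scanner effects can be separated from biology,
the measurement system itself has to be characterised: how much does the
same quantity vary when the same object is scanned repeatedly on one
scanner (intra-scanner), across all scanners (inter-scanner), or within one
vendor's scanners (intra-vendor)?

`mrirepro` implements the standard quality-assurance chain used for this
purpose: ACR-phantom signal metrics, single-tensor diffusion fitting,
consensus label fusion, ROI measurement extraction, and
coefficient-of-variation (CV) reporting. Because scanner data from such
studies are rarely shareable, a synthetic-data module generates every input
with known ground truth, and the bundled reference tables from a published
seven-scanner study provide printed worked examples for the reporting
layer.

## Phantom quality metrics

The ACR accreditation phantom is a uniform fluid-filled acrylic cylinder.
On its 11-slice axial T1-weighted protocol (256 × 256 matrix, 250 mm FOV,
5 mm slices at 10 mm centres) two metrics are computed:

* **SNR** = mean(signal ROI) / SD(background ROI). The signal ROI is a
  centred disc of 400 mm² per slice on slices 6–10; the background ROI is
  182 mm² per slice on slices 2–10, outside the phantom. The printed
  formula is implemented literally: the background SD on a magnitude image
  is Rayleigh-distributed and *no* Rayleigh correction is applied, matching
  field practice for this metric.
* **Integral uniformity** IU = 100 × (1 − (high − low)/(high + low)), where
  high/low are the nearest-rank 95th/5th percentile intensities over a
  large (default 200 cm²) centred region on slice 7. The source tables
  print a uniformity-ROI "volume" and "area" that are mutually inconsistent
  as units, so the disc area is an explicit configuration parameter rather
  than a guess.

Two geometric decisions deserve note. Slice indices are 1-based throughout
configuration ("slices 6 through 10") and converted internally once. And
because the package's contract requires the three masks to be pairwise
disjoint while both the signal and uniformity ROIs are centred, the
uniformity region is built from the voxels nearest the centre *excluding*
the signal disc — an annulus-completed disc of the full configured area.
The excluded 400 mm² is 2% of the region and lies where the bias field is
flattest, so the percentile statistics are essentially unchanged.

Sample standard deviations (n − 1) are used everywhere; the convention is
not stated by the sources this package emulates, and the choice is visible
only at small n.

## The synthetic phantom and its bias field

`gen_acr_phantom()` draws magnitude data from the physically correct
model: |N(S·b(x), σ) + i·N(0, σ)| inside the cylinder (Rician) and the
same expression with S = 0 outside (Rayleigh, SD = σ√((4−π)/2)). With
σ = 0 the image is exactly the noiseless signal, which makes closed-form
tests exact.

The multiplicative bias field b(x) is radial and smooth, and is scaled so
that (max − min)/(max + min) — over the *cylinder* — equals the requested
`bias_amplitude`. A plain quadratic profile cannot simultaneously satisfy
that contract and let IU recover `100·(1 − amplitude)`: the 5th/95th
percentiles taken over the uniformity disc (radius ≈ 0.84 R) see only
about two thirds of the cylinder-wide range. The profile used is a
smoothstep in normalised squared radius that saturates at r ≈ 0.81 R,
i.e. the full bias range is realised *inside* the uniformity disc and the
nearest-rank percentiles capture almost all of it. With σ ≪ S, measured IU
tracks 100·(1 − amplitude) to a fraction of a percentage point across
amplitudes 0–0.2, and decreases strictly monotonically in the amplitude.

## Diffusion tensor estimation

The single-tensor model S_k = S0 · exp(−b_k g_kᵀ D g_k) is fitted in its
log-linear form: ln S_k is linear in (ln S0, Dxx, Dxy, Dxz, Dyy, Dyz,
Dzz). The scheme must contain at least one b = 0 measurement and six
independent directions; rank deficiency of the design matrix is an error,
not a warning.

The fit is robust in the IRLS sense:

1. an ordinary least-squares fit on the log signals initialises the
   parameters — deliberately *unweighted*, because weighting by the
   observed squared signal hands a gross outlier enough leverage to hide
   its own residual;
2. each iteration reweights by `fitted_signal² × Huber(r; c·MAD)` with
   c = 1.345, where the first factor is the first-order variance
   correction for log-transformed data and the second caps the influence
   of outliers;
3. iteration stops when the largest parameter change falls below 1e-10,
   at 50 iterations, or immediately when the residual MAD is numerically
   zero (the noiseless case, which is then exact to machine precision).

The plain weighted-LS path is kept accessible (`robust = FALSE`) so tests
can demonstrate the robustness gap on the same voxel: a single measurement
multiplied by 10 moves the plain fit by > 100% and the robust fit by
< 1e-6 %.

Signals are floored at 1e-6 × max before the log. After eigendecomposition
the eigenvalues are sorted descending and negative values (a noise
phenomenon) are clamped to zero, with the clamp count logged and carried
in the result. FA uses the standard normalised-dispersion form
√(3/2 · Σ(λᵢ − λ̄)² / Σλᵢ²) — the printed expression in the source
literature is typographically ambiguous about root placement and the
variance denominator, and the standard reading is adopted and documented
rather than asserted as the authors' literal formula. MD is the eigenvalue
mean. An all-zero triple returns FA = 0 by convention.

The default gradient scheme is 5 × b = 0 plus 30 directions at
b = 1000 s/mm² on a deterministic golden-angle hemisphere spiral; the
6 × b = 0 variant that appears in some protocol descriptions is available
via `n_b0`.

## Consensus label fusion

Template-propagated segmentations disagree voxelwise; STAPLE estimates a
consensus and per-rater K × K performance matrices θ_r by EM on the
multilabel generative model. The E-step computes the posterior over true
labels, W(v, l) ∝ π_l Π_r θ_r[l, d_r(v)]; the M-step sets θ_r[l, m] to the
posterior-weighted emission frequency. Because the sources are silent on
the algorithm's settings, the following are package decisions: diagonal
0.99 initialisation, a stationary global prior defaulting to the raters'
pooled label frequencies, tol 1e-6 on the largest θ change, 100 iterations
maximum, no spatial regularisation. Posterior argmax ties break toward the
smaller label index, as do majority-vote ties. Voxels where every rater
emits background can optionally be excluded from the E/M computation —
the exclusion region strongly affects θ estimates, so it is an explicit
flag (default: include). The observed-data log-likelihood is recorded per
iteration and is non-decreasing, which the tests assert; a brute-force
looped EM oracle in the test helpers verifies the vectorised
implementation on a 4 × 4 grid.

The intensity-augmented fusion variants used by some pipelines for
anatomical parcellation are out of scope; classic multilabel STAPLE is
used for both the parcellation and white-matter-ROI roles here.

## Measurement panels and the CV engine

Per-scan measurements (label volumes in mm³, mean FA/MD per ROI) are
assembled into a long panel keyed by (scanner, vendor, session, rescan
flag, label, metric). FA is reported dimensionless and MD in mm²/s; the
published tables print FA × 10⁻¹ and MD in units of 10⁻⁴ mm²/s, and that
scaling stays in the display layer.

For every (label, metric): the **inter-scanner** CV pools every scan on
every scanner, rescans included; each **intra-scanner** CV uses one
scanner's scans (fewer than two scans contributes no row); **intra-vendor**
CVs pool a vendor's scanners — including single-scanner vendors, for which
the vendor CV equals that scanner's intra CV. The **mean intra-scanner**
CV per label is the unweighted mean of per-scanner CVs, and the
inter : intra ratio divides the full-precision inter CV by it. The
"mean intra-scanner" *headline* averages each scanner's across-label mean
CV over scanners — the reading that reproduces the published overview
table — which is deliberately not the same number as averaging the
per-label mean-intra column. Rounding (half-even, 1 decimal) is confined
to the report CSVs; every internal comparison runs at full precision.
Whether published ratio columns were computed before or after rounding is
unknowable from the tables; full precision is used here.

## The synthetic multi-site panel

`gen_multisite_panel()` draws value(i, s, j) = μ_j (1 + δ_i + ε_is): a
scanner offset δ_i shared across that scanner's sessions and per-session
noise ε_is, both multiplicative so that CVs are scale-free. Because the
measured inter-scanner CV pools both components, the generator derives the
between-scanner SD as √(max(inter² − intra², 0)); requesting intra > inter
is allowed but logged, and clamps the between-scanner variance to zero.
Nonpositive draws (possible only at absurd CVs) are resampled with a log
message. Defaults mirror the published study's world: seven scanners from
three vendors, that study's session counts (26 scans, ~35% rescans), an
inter-scanner volume CV of 3.3% and intra-scanner 1.1%.

What a green test establishes — and what it does not: the generator
produces exchangeable Gaussian scanner/session effects with no drift,
no label-correlation structure beyond the shared session factor, and no
heavy tails. Recovery tests therefore validate the estimator arithmetic
and its sampling behaviour, not robustness to real scanner upgrades or
physiological trends. One statistical subtlety is honoured rather than
hidden: with seven scanners the between-scanner SD carries six degrees of
freedom, so a single panel estimates the inter CV with a ~30% relative
standard error; recovery tests average replicate panels and use 3-SE
margins, and the expectation-level claim that inter CV exceeds intra CV is
asserted over 200 replicates, not per panel (it is not a per-sample
mathematical truth).

## Numerical and degenerate-input policy

* CV requires ≥ 2 values and a nonzero mean; both violations are errors.
* SNR errors on a zero-variance background; IU errors when high + low = 0.
* The phantom aligner is integer-voxel centre-of-mass translation only —
  full rigid/affine registration is deliberately out of scope — and it
  refuses unimodal (no-phantom) images using Otsu separability.
* NIfTI I/O is a minimal purpose-built NIfTI-1 codec (no NIfTI R package
  is available in the supported toolchain): single-file `.nii`/`.nii.gz`,
  3D/4D, both endiannesses on read, float64/int32 on write so round trips
  are bit-exact. Label maps are stored as int32.
* All generators restore the caller's RNG state; identical specs (seed
  included) produce bit-identical outputs, and the demo pipeline's CSVs
  are byte-identical across reruns.

## Known limitations

Registration, susceptibility/motion correction, multi-shell diffusion
models, intensity-augmented fusion and mixed-effects reliability
coefficients are out of scope by design. The synthetic phantom has no
k-space artefacts, no coil-profile anisotropy (its bias field is radial),
and identical slices along z. The bundled reference tables carry printed
(rounded) precision; one column of the ACR summary (the IU CV column) is
internally inconsistent with its own mean/SD columns and is not used in
consistency checks.
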