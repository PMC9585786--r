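---
title: "Quantitative sodium MRI of calf muscle: models, corrections, and repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative sodium MRI of calf muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natriq)
```

## The quantification problem

Tissue sodium concentration (TSC, mmol/L) in skeletal muscle is estimated
from ²³Na images by comparing corrected muscle signal intensities against
calibration phantoms of known concentration:

$$[\mathrm{Na}_{tissue}] \;=\;
  \frac{I_{tissue}^{corr}/f_{tissue}}{I_{phan}^{corr}/f_{phan}}\,
  [\mathrm{Na}_{ref}],$$

where $I^{corr}$ are intensities corrected for field inhomogeneity and
partial-volume effects, $f$ are relaxation-attenuation factors
($f = (1-e^{-TR/T_1})\,[F_s e^{-TE/T_{2s}^*} + F_l e^{-TE/T_{2l}^*}]$,
`relaxation_factor()`), and $[\mathrm{Na}_{ref}] = 25$ mmol/L is the
reference concentration at which the calibration line is evaluated. The
calibration line is an ordinary least-squares fit of corrected tube
intensity versus concentration over four agarose tubes at 15.4, 30.8, 46.2
and 61.6 mmol/L; we do not force it through the origin, because the
intercept absorbs the residual noise floor of magnitude images (a
single-tube proportional mode exists for comparison).

Because sodium relaxes fast and bi-exponentially ($T_{2s}^*$ of a few ms,
$T_{2l}^*$ around 13 ms, fractions $F_s/F_l \approx 60/40$), every stage —
acquisition, point-spread function, relaxometry and the relaxation
correction — is built around that bi-exponential envelope. Relaxation
parameters enter the correction as cohort means
(`cohort_relaxation_defaults()`), mirroring the practice of deriving them
once from healthy subjects; a per-subject override is available.

No public raw data exist for this kind of acquisition, so the package
ships a synthetic-data generator that reproduces the statistical and
physical structure the analysis assumes; all acceptance-style checks run
end to end on the synthetic calf.

## Acquisition model

### DA-3DPR trajectory

`build_da3dpr_trajectory()` constructs the density-adapted 3D radial
(center-out) sampling geometry. Spoke directions follow a deterministic
golden-means spiral (quasi-uniform, reproducible; the sequence literature
does not mandate a particular distribution). Along each spoke the radius
grows linearly up to the transition radius $k_0 = t_0 \cdot k_{max}$
(default `t0_fraction = 0.25`, exposed in the configuration since the
pulse-ramp details are hardware-specific) and then follows the cube-root
law $k(t) = (k_0^3 + 3k_0^2 c\,(t-t_0))^{1/3}$, which makes the sample
density per unit k-space volume constant beyond $k_0$. The default radial
sampling is four points per nominal k-space increment: the constant-
gradient ramp occupies only a few percent of the readout, and coarser
radial sampling of that portion aliases the edges of FOV-filling objects
into rings.

Density-compensation weights are the exact per-sample shell volumes
(`diff(k_edges^3)/3`). For reconstruction these analytic weights are
additionally refined by a few Pipe–Menon iterations
(`refine_density_weights()`): gridding the weights and re-sampling them at
the trajectory estimates the local kernel-smoothed sampling density, and
dividing by it flattens the reconstruction's transfer function. Without
this step the near-DC response is several-fold too high and large objects
acquire a smooth dome, which would corrupt the cylinder-derived intensity
correction below.

### Gridding and the imaging operator

`grid_reconstruct()` implements density-compensated Kaiser–Bessel gridding
(kernel width 4, two-fold oversampling, Beatty's shape parameter,
sinh-form deapodization), and `forward_sample()` the adjoint-consistent
forward interpolation. Both are validated against direct discrete-Fourier
oracles on small problems (relative RMS error below 1%; the direct-sum PSF
path is exact to 1e-6).

`psf_operator()` composes forward sampling, optional bi-exponential decay
along the readout (the PSF is simulated with cohort-mean $T_2^*$ values,
as the quantification practice prescribes), and the gridding adjoint into
one linear operator, normalized so a large object's interior keeps its
level. This operator *is* the package's blur model: applied to a delta it
yields the PSF; applied to a compartment mask it yields that compartment's
region-spread function. We deliberately do not approximate it by
convolution with an FOV-cropped PSF kernel — the DA-3DPR PSF has
long-range tails, and kernel truncation biases compartment means by up to
~10%, which we verified against an exact brute-force operator.

### Synthetic calf

`make_digital_phantom()` builds a schematic extruded-2D calf: an elliptical
cross-section holding gastrocnemius medialis (GM), tibialis anterior (TA)
and soleus (S) sub-ellipses inside "other muscle", four peripheral
calibration tubes, and, as a separate scenario, the homogeneous
61.6 mmol/L cylinder used for field mapping. Healthy-state concentrations
are GM 19.9, TA 13.8, S 12.6 mmol/L ("other" is set to a mid-muscle
15 mmol/L); the Addison scenario uses 10.2/8.4/7.2 mmol/L. Relaxation
parameters are the cohort means; the agarose tubes are $T_1$-matched to
muscle, as the physical tubes are by doping. B0 is a smooth low-order
polynomial within ±50 Hz; B1⁺ varies quadratically from 1.2 at the coil
centre to 0.8 at the FOV edge; each receive channel has a smooth
centre-weighted magnitude profile with a gentle lateral lobe and a smooth
phase. Geometry is schematic, not anatomical — only region statistics
matter downstream — and the compartment volume fractions are roughly
GM 20%, TA 13%, S 24% of the calf.

`simulate_series()` produces multi-echo (20 TEs) or inversion-recovery
(5 TIs, signed $1 - 2e^{-TI/T_1}$ factor before magnitude) series. In the
default `image_psf` mode the imaging operator is applied once per shaded
compartment indicator, and each contrast is a closed-form linear
combination of those basis volumes — exactly equal (by linearity) to the
per-contrast `kspace` mode, which forward-samples the full ideal image and
is kept as the reference path, optionally with per-voxel B0 phase
accumulation. Complex Gaussian noise is added per channel; its standard
deviation is calibrated so that the mean muscle SNR of the sodium-protocol
image is 16, the value this simulator emulates for the healthy calf (the
Addison scans in the emulated study were slightly noisier, ~13, but we
keep one calibration for comparability). Noise-only volumes accompany
every series; magnitude images are therefore Rician, and relaxometry's
free offset absorbs the noise floor.

## Corrections

* **Coil combination** (`adaptive_combine()`): blockwise dominant-
  eigenvector (Walsh-style) sensitivity estimation on a coarse lattice
  (defaults mirror the protocol: interpolation factor 2, overlap 8),
  neighbour-aligned phases, smooth interpolation, matched-filter
  combination. Zero-signal blocks inherit the nearest signal-bearing
  block's estimate.
* **SNR** (`multiple_replica_snr()`): pseudo-replica — synthetic noise
  matched to the measured noise-only statistics is repeatedly added, and
  per-voxel SNR is the replica mean over standard deviation.
* **B0** (`b0_map_dual_echo()`): inter-echo phase at 0.60/1.60 ms; the
  map is single-wrap with an unambiguous band of ±500 Hz at 1 ms spacing.
* **B1⁺** (`b1_map_phase_sensitive()`): the phase of a composite
  $2\alpha_x,\alpha_y$ preparation relative to a plain excitation is
  tabulated from the rotation model and inverted; the relation is strictly
  monotone for actual flips in (10°, 170°) and voxels outside that domain
  are flagged invalid.
* **Off-resonance** (`correct_off_resonance()`): multi-frequency
  conjugate-phase reconstruction, 20 demodulation bins by default
  (the count is a configuration choice), nearest-bin assembly.
* **Intensity** (`derive_and_apply_correction()`): the homogeneous
  cylinder fills the coil, so any structure in its image is instrumental
  shading. The gain is nominal level over the smoothed observed cylinder
  (normalized convolution, Gaussian sd 2 voxels, both exposed), derived
  from a central axial slab and replicated along z — the shading fields
  are axially smooth, and this keeps the cylinder's own end-of-volume
  partial-volume drop out of the gain. Near-zero voxels get gain 1 and a
  flag. Deriving the correction from the cylinder and transferring it to
  the subject scan mirrors the acquisition practice ("same geometry");
  nothing is estimated from the in-vivo-like data themselves.

## Partial-volume correction

`gtm_correct()` implements the geometric-transfer-matrix method: region-
spread functions $RSF_i$ (imaging operator applied to each compartment
mask, or FFT convolution with an explicit kernel), weights
$\omega_{ji} = \langle RSF_i\rangle_{ROI_j}$, observed ROI means $b$, and
a least-squares solve $\omega c = b$ with the condition number reported
(systems beyond 1e6 are rejected with advice to merge compartments). On
noiseless piecewise-constant images the solve is exact for any full-rank
$\omega$ — a property the tests exercise at 0.5% tolerance.

The pipeline's compartment set is GM, TA, S, "other muscle", and the four
calibration tubes. The tubes are bright and blur into everything, so they
must be part of the model even though their own concentrations are read
from eroded interior ROIs that bypass the GTM (the emulated study did not
segment its tubes, and flags that as a limitation). The zero-concentration
background is deliberately *not* a compartment: it contributes nothing to
the model (its true mean is zero), while its observed magnitude mean is a
rectified mixture of noise and ringing that cannot legitimately enter a
linear solve. Masks are used in 3D; a three-slice mode can be emulated by
passing cropped masks.

## Relaxometry

`fit_t2star()` fits the five-parameter bi-exponential
$SI = C_{0s}e^{-TE/T_{2s}^*} + C_{0l}e^{-TE/T_{2l}^*} + \mathrm{offset}$
with non-negative amplitudes, $T_2^*$ bounded to [0.1, 100] ms and the
components ordered after fitting; fractions are
$F_s = 100\,C_{0s}/(C_{0s}+C_{0l})$, so $F_s + F_l = 100$ by construction.
`fit_t1_ir()` fits the magnitude inversion-recovery model
$SI = |M_m(1-2e^{-TI/T_1})| + \mathrm{offset}$. Both use bounded
Levenberg–Marquardt with eight jittered multi-starts (fixed sub-seed),
relative function tolerance 1e-10, at most 500 iterations; $T_1$ starts at
the signed-signal null-point estimate $TI_{null}/\ln 2$ and $T_2^*$ at
3/13 ms. Degenerate outcomes (flat curves, collapsed components, bounds)
are flagged rather than silently reported. ROI-level fitting is the
primary path, with the ROI fixed on the lowest-TE image and reused across
contrasts.

Recovery behaviour: noiseless fits are exact to better than 0.1%, and
$T_1$ recovers with median error well under 5% already at curve SNR 30
(five TIs). The bi-exponential long component is a different matter: with
a free offset, $T_{2l}^*$ and the offset trade against each other in the
long-TE tail, and the median recovery error over cohort-like ROIs scales
roughly as $15/\mathrm{SNR}$ of the fitted curve (about 30% at curve SNR
30, 5% only near curve SNR 400). Fitted ROI-mean curves from a high-SNR
relaxometry acquisition do reach that effective level, which is why
ROI-by-ROI fitting (rather than voxelwise mapping) is the primary path;
at low curve SNR no optimizer can do better, since the fitted solutions
already attain lower residuals than the generating truth. On the
simulated calf the pipeline's $T_2^*$ table additionally runs slightly
low for $T_{2l}^*$ (~5–10%): those ROI curves are partial-volume mixtures
whose long-TE tail carries a Rician floor that the offset only partly
absorbs — a limitation shared with the in-vivo procedure this emulates.

## Repeatability statistics

`icc_twoway()` computes all four two-way ICC variants from the ANOVA mean
squares, with F-based 95% intervals. The reporting default is Ck —
average-measures consistency — because on the packaged reference cohort
table it reproduces the published repeatability coefficients exactly
(0.784/0.818/0.807 for GM/TA/S) even though the emulated analysis is
described as "absolute agreement"; the absolute-agreement variants are
always computed alongside. `bland_altman()` gives session-pair limits of
agreement $\bar d \pm 1.96\,s_d$ and the fraction of subjects within.

The exact nonparametric tests avoid asymptotic approximations at the
cohort's sample sizes: `friedman_test()` enumerates (by dynamic
programming over subjects, equivalent to all $k!^n$ permutations) the
distribution of the classic rank statistic with midranks;
`wilcoxon_signed_rank()` convolves the positive-rank-sum distribution
over all $2^n$ sign assignments (n ≤ 25 by default) with optional
Bonferroni correction; `wilcoxon_rank_sum()` enumerates group assignments
up to 1e6 combinations and falls back to the tie-corrected normal
approximation beyond. The per-subject value entering the across-muscle
and between-group tests is the mean over sessions (the emulated analysis
does not state its choice; a single-session mode is a one-line filter on
the table). All exact paths are verified against brute-force enumeration
for every n ≤ 8.

## Numerical choices and scales

The full pipeline (`run_pipeline()`) runs at matrix 64 with 5,000
projections by default — the acquisition-scale 128/10,000 is available via
the configuration but is not needed to exercise any model component. The
study conditions are: SNR 16 sodium images, two receive channels, B1 range
0.8–1.2, B0 within ±50 Hz, seed 20220719 for every stochastic stage
(stage seeds are small offsets of the master seed). A healthy-scenario run
takes on the order of two minutes on one CPU.

## What the synthetic tests do and do not show

The generator reproduces: piecewise-constant compartments with the
published concentrations and relaxation values, bi-exponential decay,
IR sign structure, DA-3DPR blur including readout decay, smooth transmit/
receive shading, Rician magnitude statistics at calibrated SNR, and
noise-only scans. It does not reproduce: anatomical geometry, motion,
susceptibility-induced B0 from tissue interfaces, quadrupolar spin-3/2
dynamics beyond the bi-exponential envelope, vessel signal, or
registration error between proton-derived masks and sodium images (inputs
are assumed co-registered, as in the emulated workflow). Passing the
recovery tests therefore demonstrates that the *estimation chain* is
unbiased under its own assumptions at realistic noise — not that those
assumptions hold in vivo.

## Known limitations

* The adjoint-with-density-compensation reconstruction is not an exact
  inverse; residual few-percent ripple on large uniform objects remains
  after Pipe–Menon refinement and is absorbed by the GTM/calibration
  consistency rather than removed.
* $T_{2l}^*$ from simulated-calf ROI curves is biased low by the Rician
  tail (see above).
* The B1-intensity translation for a 90° excitation uses the
  $\sin(\alpha)$ model inside the cylinder-derived gain; more elaborate
  transmit/receive separations are out of scope.
* Exact Friedman/pairwise p-values printed by the emulated study
  (P = 0.0005, P = 0.018) are not derivable from its printed table under
  standard conventions; the package asserts significance levels, not those
  literal values.
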