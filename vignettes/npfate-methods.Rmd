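---
title: "Methods: models, parameters and design choices in npfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in npfate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npfate)
```

# Scope

`npfate` analyses three co-registered X-ray modalities — scanning SAXS,
micro-CT, and micro-XRF — measured on nanoparticle-infiltrated leaf tissue
over a multi-day time course, and classifies the joint signal trends into one
of four nanoparticle processes (aggregation, dispersion, dissolution,
translocation). This vignette documents the underlying models, every tunable
parameter that matters, the synthetic phantoms used for validation, and the
numerical choices made where the design was genuinely open.

Upstream steps are consumed, not performed: tomographic phase retrieval and
cone-beam reconstruction (we read reconstructed volumes), XRF spectral
fitting (we read fitted element maps), and detector calibration beyond the
geometric pixel-to-q mapping.

# SAXS reduction

## Geometry and regrouping

A pixel at radial distance $r$ from the beam center on a detector at distance
$D$ maps to
$$q = \frac{4\pi}{\lambda}\,\sin\!\Big(\tfrac12\arctan\frac{r}{D}\Big),
\qquad \lambda[\mathrm{\AA}] = \frac{12.398}{E[\mathrm{keV}]},$$
with azimuth $\theta$ measured counterclockwise from the detector $+x$ axis
(increasing column), $+y$ along increasing row, on $[-\pi, \pi)$. The beam
center pixel has no defined azimuth and is excluded from regrouping.

Azimuthal regrouping assigns each unmasked pixel to a $(q, \theta)$ cell and
stores the **mean** of the contributing pixel counts together with the number
of contributing pixels. Means (rather than sums) keep partially filled cells
at the frame corners comparable; retaining the pixel counts makes sums
well-defined downstream — the invariant
$\sum_\text{cells} \text{mean} \times \text{count} = \sum_\text{pixels}$
holds exactly and is asserted in the tests. The implementation is verified
cell-by-cell against a brute-force double loop over pixels for random
geometries and masks.

Radial curves report the pixel-weighted mean $q$ of each bin rather than the
geometric bin center. Where the curve is steep (the Guinier regime of large
particles) the bin-center abscissa introduces a bias of order
$(\partial \ln I/\partial q)\,\delta q$; the mean-$q$ abscissa removes it to
second order.

## The azimuthal first moment

The anisotropy statistic is the trapezoidal first moment
$M_1 = \int \theta\, I(\theta)\, d\theta$ over a $\theta$ grid whose bin
centers are symmetric about zero. On such a grid an isotropic profile gives
exactly zero, and oriented cellulose scattering (concentrated near a
preferred azimuth $\theta_0 \ne 0$) pulls the moment toward $\theta_0$. The
literal moment is origin-dependent on a non-centered grid — it then measures
total intensity, not anisotropy — so a non-centered grid triggers a warning,
and feature maps default to the **normalized** moment
$M_1 / \int I\, d\theta$, an intensity-independent orientation statistic.
Both variants are tested against adaptive quadrature to $10^{-6}$.

## Analysis window and corrections

The default analysis q-window is **0.004–0.022 Å⁻¹**, the range in which the
nanoparticles of interest dominate the signal; it is a parameter everywhere
it appears. No polarization, solid-angle, flat-field or dark-current
corrections are applied, and intensities are relative throughout (no
absolute calibration to, e.g., water scattering) — a deliberate calibration
limitation, as the downstream statistics are ratios and trends.
Solution background subtraction (`subtract_background`) supports a scale
factor (default 1; whether a transmission scaling is appropriate depends on
the measurement) and retains negative results with a warning count rather
than clipping, since over-subtraction is diagnostic information.

# Guinier analysis

The low-q Guinier law $I(q) = I_0 \exp(-q^2 R_g^2/3)$ is fitted by weighted
linear least squares of $\ln I$ on $q^2$ with weights $(I/\sigma)^2$ (the
delta-method variance of $\ln I$). Points with $I \le 0$ are dropped and
counted. When no window is supplied, the fit iterates with the restriction
$q_{\max} R_g \le 1.3$ — the standard validity limit for globular
scatterers — until the window stabilizes (at most 50 iterations). A fit is
flagged *degenerate* when the slope is non-negative or when
$q_{\max} R_g < 0.01$, i.e. the curve decays by less than $10^{-4}$ across
the window and carries no size information; degenerate fits report
$R_g = 0$.

Dilution-series analysis reports $I_0(\text{baseline})/I_0(\text{entry})$,
which tracks the dilution factor when particles neither aggregate nor
interact, and an $R_g$-stability measure,
$\max_i |R_{g,i} - \tilde{R}_g| / \tilde{R}_g$ with $\tilde{R}_g$ the median
(stable below a default 5% tolerance). Ratios are reported at full precision;
the conventional table rounds to 2 decimals.

# Micro-CT quantification

Leaf segmentation applies Otsu's threshold to the full volume, closes the
foreground with a radius-1 (6-connected) morphological closing, and keeps
the largest 6-connected component, so debris and noise specks never enter
the denominator. A guard rejects volumes with no real air/sample contrast:
if the two Otsu classes' means are closer than 1.5 times the sum of their
standard deviations, the "foreground" is just split noise and an error is
raised.

Nanoparticle segmentation is *semi-automated*: Otsu's threshold computed on
the gray values **restricted to the leaf** by default, a caller-supplied
threshold (recorded as `manual`) otherwise. The volume fraction is NP voxels
over *leaf* voxels — the sample, not its bounding box. Otsu is computed via
`EBImage::otsu` on values affinely rescaled to $[0,1]$ at 256 levels, which
makes the segmentation exactly invariant under gray-level shifts and scales
(tested). The NP mask is not smoothed: cluster boundaries stay sharp.

Interpretation of time-series reports: denser packing yields a higher
segmentation threshold and a smaller volume fraction; as clusters disperse,
the threshold falls and the fraction rises, and NP-region histograms shift
left. These trend directions — not absolute thresholds, which depend on
reconstruction scaling — are the reproducible content.

# XRF maps

Co-registration is translation-only (the acquisition protocol crops to a
common region; rotation and scale are out of scope and must be handled
upstream), estimated by integer-shift normalized cross-correlation of
Otsu-binarized maps; a correlation peak below 0.2 is rejected and a manual
offset required. Constructed integer shifts are recovered exactly (tested).
Histogram comparisons use common bin edges across the series, and the
control-group **maximum** as the reference marker: the fraction of pixels
above it isolates NP-attributable signal from the native tissue background.
Bin count is a parameter (default 64).

# Multimodal classification

Each modality's time series of region statistics is reduced to a trend by
the first-to-last relative change $r = (x_\text{last} - x_\text{first}) /
x_\text{first}$, with $|r| \le 0.10$ (boundary inclusive) classed as stable.
First-to-last is used rather than a regression slope: the framework compares
the initial and final states and, with 2–3 timepoints, a slope adds noise,
not information. The band is configurable; the four process signatures are
matched exactly, every matching rule is returned (the signatures do not
partition all $3^3$ triplets; an empty result is reported as "inconsistent
with framework").

The XRF trend is that of the **immobile tracer** (e.g. Ce). The mobile
nutrient (P) declines under dissolution as ions translocate away; that
decline is reported separately and never used to veto a dissolution call.
The CT statistic is the mean gray inside each day's own NP segmentation.

# Dosimetry

Dose per exposure is $D = \Phi E t / A \cdot (\mu/\rho)$ in gray, with keV →
J ($1.602176634\times10^{-16}$), µm² → m², and cm²/g → m²/kg conversions —
a thin-sample surface-dose approximation with no transmission or thickness
factor, exactly as the quantity is conventionally quoted. $\mu/\rho$ is a
user input; no internal attenuation tables are bundled. Cone-beam helpers:
magnification $M = \mathrm{SDD}/\mathrm{SOD}$, effective voxel
$= \text{pixel}/M$, effective propagation
$z_\text{eff} = \mathrm{SOD}(\mathrm{SDD}-\mathrm{SOD})/\mathrm{SDD}$,
reported at full precision with a display layer rounding to the conventional
printed precisions.

# The synthetic phantoms

The phantom generator is first-class, tested code: it defines the study
conditions under which the pipeline is validated.

**SAXS frames.** Each pixel is an isotropic particle term plus an anisotropic
cellulose background:
$$I(q, \theta) = c \cdot I_\text{model}(q) +
A\Big(\frac{q}{0.01}\Big)^{-p}\big[1 - f + f\cos^2(\theta - \theta_0)\big],$$
optionally Poisson-sampled. The particle term uses orientation-averaged
analytic form factors, normalized so $I(0) = \text{concentration} \times
\text{contrast}^2$: sphere ($\Phi(x) = 3(\sin x - x\cos x)/x^3$), cylinder
(Gauss–Legendre orientation average, 128 nodes — the crystalline
hydroxyapatite rods, length 280 Å, radius 80 Å), core–shell sphere (ZnO in
mesoporous silica), and a pure Guinier scatterer. Closed-form gyration
radii: sphere $R_g^2 = 3R^2/5$, cylinder $R_g^2 = L^2/12 + R^2/2$. No
polydispersity and no structure factor are modelled (dilution experiments
show minimal interparticle interference), and none of the solution
$R_g \approx 297$ Å is imposed on the rod geometry: aggregation in solution
makes the two legitimately different, and the package never asserts their
equality. The cellulose exponent $p$ (default 2.5) is a free simulator
parameter — the q-dependence of real leaf background is not characterized
here — and the background amplitude is quoted at the reference
$q = 0.01$ Å⁻¹ so that changing $p$ does not silently rescale it. The
default phantom beam (20.129 keV, 2250 mm, 172 µm pixels, 64 × 64 frame)
spans q up to ≈ 0.025 Å⁻¹, covering the analysis window.

**CT volumes.** A leaf slab (gray 0.35 ± 0.03) in air (0.08 ± 0.02) with
Gaussian NP clusters ($\sigma$ = 2.5 voxels, peak amplitude 0.6) placed with
a minimum mutual distance of 4.2 $\sigma$ so blobs never merge; the default
cluster count scales with the volume so the NP-labelled fraction of the leaf
is size-independent. Dispersion is modelled as *fragmentation* — the cluster
count grows while the peak amplitude falls — rather than as blob widening:
widening makes overlapping tails raise the mean gray, the opposite of the
dispersion signature. Cluster sites are fixed across a day series; only
amplitudes, counts and noise streams evolve.

**XRF maps.** Tissue texture (gamma, mean 1, cv ≈ 0.22) plus the infiltrated
region's signal: a per-pixel lognormal deposition pattern (sd 0.5 in log
space) that is *fixed in time* — infiltration heterogeneity does not
fluctuate day to day — modulated by the element's overall level and 5%
temporal noise. The spatial spread is what lets the fraction-above-control
statistic decay gradually as the level falls through the control maximum;
the fixed pattern is what keeps the region mean stable enough for the ±10%
band when the element does not move.

**Per-mode evolution.** Day multipliers (day $d$): dissolution — SAXS
$e^{-0.55d}$, CT stable, P $e^{-0.8d}$, Ce stable; aggregation — SAXS
$e^{-0.4d}$, CT amplitude $1 + 0.25d$; translocation — SAXS $e^{-0.6d}$, CT
$e^{-0.35d}$, both elements $e^{-0.4d}$; dispersion — SAXS $1 + 0.3d$, CT
amplitude $1/(1+0.4d)$ with count $\times(1+0.6d)$. The rates are chosen
once so each trending modality moves several times the stability band by
day 3 (strong, unambiguous courses) while stable modalities stay well
inside it; they are simulator conditions, not measurements of barley.

**Determinism.** All randomness threads through the spec seed: Poisson
frame noise is seeded per scan point (so a single rendered frame is
bit-identical to the same point inside a full mesh render), cluster sites
and deposition patterns from per-role offsets of the base seed. Identical
specs give bit-identical outputs, asserted in the tests.

## What phantom validation does and does not show

Passing the phantom suites shows the *analysis* is correct: regrouping
agrees with brute force, fits recover generating parameters, segmentation
recovers known fractions, and each generated process maps to its own label.
It does **not** show that real leaf data satisfy the generators'
assumptions: real cellulose background is not a clean power law, real
cluster shapes are not Gaussian, reconstruction artifacts (rings, beam
hardening) are absent from the phantoms, XRF self-absorption is ignored,
and real inter-sample variability (different leaves per timepoint) is not
modelled. Absolute beamline intensities are therefore out of desk reach;
the package reproduces printed reference quantities that are pure
arithmetic (dose, geometry, dilution ratios) and the qualitative trend
structure, which is what the classification framework consumes.

# Problem sizes and runtime

The shipped tests run mesh scans of 6×6–24×24 points with 16–64 px frames,
CT volumes of 36³–48³ voxels for unit tests and 128³ for the dispersion
trend check, and 20 seeded classification replicates per mode; the full
suite completes in under two minutes on one core. `scripts/acceptance.R`
uses 100 Guinier replicates. All sizes are package choices made to keep the
validation loop fast while leaving every statistic well inside its
asymptotic regime.

# Known limitations

* Relative intensities only; no absolute calibration, polarization or
  solid-angle corrections.
* Translation-only XRF registration; rotation/scale must be handled
  upstream.
* The hierarchical interchange container is a directory layout
  (YAML manifest + float TIFFs with plain-text sidecars), chosen for
  dependency-free portability; TIFF floats are stored normalized with the
  affine scale in the sidecar.
* The stability band (±10%) discretizes trends sharply; series hovering at
  the band edge flip labels under noise. The band is a parameter, and the
  relative changes are always reported alongside the call.
* The classifier is rule-based and hard: no soft/probabilistic calls, no
  kinetics. Mixed processes that produce intermediate triplets return every
  matching rule, or none.
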