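# npfate

Correlative X-ray imaging analysis of nanoparticle fate in plant leaves.

Foliar nano-fertilization delivers nutrients as nanoparticles (NPs) infiltrated
directly into leaf tissue. Whether those particles then **aggregate**,
**disperse**, **dissolve**, or **translocate** decides whether the nutrient is
actually released where the plant can use it — and no single imaging modality
can tell these processes apart. `npfate` implements the analysis chain for
three complementary X-ray modalities measured on the same samples over a
multi-day time course:

* **scanning SAXS** — small-angle X-ray scattering mesh scans, sensitive to
  nanoscale particulate structure;
* **micro-CT** — 3D gray-value tomograms in which NP-densified regions appear
  as bright clusters;
* **micro-XRF** — fitted elemental intensity maps (mobile nutrients such as P,
  immobile tracers such as Ce).

The package is aimed at beamline users and image-analysis scientists working on
nanoparticle–plant interactions. A synthetic phantom generator reproduces the
statistical structure of all three modalities, so every stage of the pipeline
is testable without beamline data.

## What it computes

**SAXS reduction.** Detector pixels are mapped to the scattering vector
q = (4π/λ) sin(½ atan(r/D)) and azimuth θ, and frames are regrouped onto a
polar (q, θ) cake (verified cell-by-cell against a brute-force per-pixel
oracle). Radial integration gives I(q); azimuthal integration over an analysis
window (default 0.004–0.022 Å⁻¹) gives I(θ). Two per-scan-point statistics form
the mesh-scan feature maps:

* total scattering — summed counts in the q-window (NP concentration proxy);
* scattering anisotropy — the first moment M₁ = ∫ θ·I(θ) dθ on a θ-grid
  centered on zero (optionally normalized by ∫ I dθ), which separates oriented
  cellulose scattering from isotropic NP scattering.

**Guinier analysis.** Solution curves are fitted with the Guinier law
I(q) = I₀ exp(−q²R_g²/3) by weighted least squares of ln I on q², with an
automatic low-q window satisfying q_max·R_g ≤ 1.3. Dilution series yield I₀
reduction ratios (which track the dilution factor for non-interacting
particles) and an R_g-stability report.

**Micro-CT quantification.** Otsu's threshold segments leaf from air (largest
connected component, radius-1 closing); a second Otsu threshold *within the
leaf* — overridable by hand, hence "semi-automated" — labels NP-densified
voxels. The volume fraction is NP voxels over leaf voxels; time-series reports
track threshold, fraction, and NP-region histograms.

**XRF maps.** Translation-only co-registration by normalized cross-correlation
of Otsu-binarized maps, and common-bin histograms against the *control-group
maximum*: the fraction of pixels above that marker isolates the NP-attributable
signal.

**Multimodal classification.** Each modality's region statistic is reduced to
an up/down/stable trend (first-to-last relative change, ±10% stability band)
and matched against the process signatures:

| process | SAXS | CT | XRF (immobile tracer) |
|---|---|---|---|
| aggregation | down | up | stable |
| dispersion | up | down | stable |
| dissolution | down | stable | stable |
| translocation | down | down | down |

**Dosimetry.** Dose per exposure D = Φ·E·t/A · (µ/ρ) with strict unit
handling, plus cone-beam geometry helpers (magnification SDD/SOD, effective
voxel, effective propagation distance).

## Worked example

```r
library(npfate)

# dose per 50 ms exposure of a 50x50 um^2 focused 20.129 keV beam at 1e13 ph/s
beam <- beam_geometry(20.129, 2250, 172, c(32.5, 32.5),
                      photon_flux = 1e13, exposure_time = 0.05,
                      spot_area_um2 = 2500, mass_attenuation_cm2g = 0.56)
dose_per_exposure(beam)     # 36120 Gy ~ 36 kGy, far above the ~4 kGy damage onset

# a simulated nHAP-like dilution series, Guinier-fitted
p <- particle_model("cylinder", length = 280, radius = 80, concentration = 2000)
dilution_table(simulate_dilution_series(p, c(5, 9), noise = 0.01, seed = 17))
#>      label dilution_factor       rg    rg_err    i_zero i_zero_err reduction_ratio
#> 1 baseline               1 99.75122 0.4623019 2013.3418  5.3137234            1.00
#> 2   5-fold               5 99.83433 0.5507075  402.8071  1.2675976            5.00
#> 3   9-fold               9 97.62594 0.4725582  221.5665  0.6114287            9.09
```

R_g is stable under dilution while the fitted I₀ ratios track the true
dilution factors (5.00 and 9.09 vs 5 and 9, inside the 10% band) — the
concentration sensitivity that makes SAXS useful for tracking dissolution.

```r
# end-to-end phantom round trip: a dissolving-NP time course
ts <- render_timeseries_phantoms(c(0, 1, 3), mode = "dissolution", seed = 1)
res <- classify_timeseries(ts)
writeLines(report_case(res))
#> multimodal nanoparticle-fate classification
#> trends: SAXS down (-0.772), CT stable (+0.004), XRF stable (-0.009)
#> call: dissolution
#> matches the dissolution signature
#>
#> evidence:
#>  time      saxs        ct      xrf
#>     0 141288.44 0.6183360 5.134329
#>     1  84237.81 0.6230743 5.314361
#>     3  32257.75 0.6210528 5.090257
```

The SAXS total scattering collapses by 77% over three days while the CT
NP-region gray level and the immobile-tracer XRF signal stay inside the ±10%
band: the joint pattern is dissolution, not translocation (which would drag
all three down) or dispersion (which would raise SAXS).

A command-line front end covering the same stages
(`simulate | reduce | maps | guinier | ct | xrf | classify | dose`) is in
`inst/cli/npfate.R`:

```sh
Rscript inst/cli/npfate.R dose flux=1e13 energy_kev=20.129 time_s=0.05 area_um2=2500 mu_rho=0.56
```

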