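---
title: "Multiscale bone-quality analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale bone-quality analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoquant)
```

# Scope

`osteoquant` re-implements, as a tested pipeline, the analysis chain of a
two-group (control vs. diet/streptozotocin-induced type-2-diabetic) rat
bone-quality study: whole-bone mechanics from three-point bending traces,
tissue-level mechanics from cyclic reference-point indentation (cRPI) and
Oliver–Pharr nanoindentation, bone composition from FTIR spectra (including
amide I sub-band deconvolution for the non-enzymatic cross-link ratio,
NE-xLR), mineral crystallite size from XRD via the Scherrer equation,
fluorescent advanced glycation end products (fAGEs) normalized to collagen,
cortical/trabecular voxel morphometry, and the group-statistics layer that
turns per-animal measurements into a comparison table.

Because the original raw data are not deposited, every stage is fed by a
forward-modelling synthetic-cohort generator whose latent per-animal
parameters are drawn from the study's published group summaries. The
generator is first-class, tested code: each forward model attaches its
closed-form ground truth, so each analyzer is validated by exact
forward–inverse round-trips, not merely by plausibility.

# The synthetic cohort: the stated world

`default_parameter_table()` holds one row per latent parameter (control
mean/SD, diabetic mean/SD). Three provenance classes exist:

* **Verbatim group summaries** — endpoint metabolic covariates (body
  weight, fasting glucose, HbA1c, plasma insulin, triglycerides,
  cholesterol) and all micro-CT parameters are the published mean ± SD
  values, bit-for-bit. The week-4 insulin excursion (1.72 → 2.61 mIU/L) is
  deliberately not a default: the endpoint values are, since those are the
  covariates analysed against bone outcomes.
* **Printed modality means** — nanoindentation modulus and hardness
  (20.6 ± 1.04 / 16.22 ± 0.78 GPa and 0.577 ± 0.039 / 0.387 ± 0.039 GPa),
  crystallite length and width (18.29 ± 0.73 / 16.67 ± 0.85 nm and
  4.64 ± 0.11 / 5.18 ± 0.19 nm) and fAGE content (288.6 ± 33.5 /
  412.4 ± 36.6 ng quinine/mg collagen).
* **Anchored contrasts** — three-point bending, cRPI and FTIR outcomes are
  published only as percent group differences. The control anchors were
  chosen once from typical values for mature female Sprague-Dawley rat
  femora (F_max 120 N, stiffness 250 N/mm, work-to-failure 45 N·mm, PYD
  0.25 mm; ID-1st 85 µm, IDI 10 µm, US-1st 0.55 N/µm, Avg-ED 25 µJ;
  mineral/matrix 4.0, carbonate/phosphate 0.009, crystallinity 1.25, acid
  phosphate 0.72, NE-xLR 1.55, collagen maturity 3.0), and the diabetic
  means are the anchors scaled by the published percent differences
  (e.g. stiffness −57%, NE-xLR +85.65%). Group SDs keep roughly the control
  coefficient of variation.

Latents are independent truncated-at-zero normals — matching the mean ± SD
reporting of the source — with one exception: a per-animal standard-normal
"glycation severity" factor, with loadings +0.835 on NE-xLR and −0.835 on
PYD in the diabetic group only, induces the within-diabetic-group
correlation r(NE-xLR, PYD) ≈ −0.835² ≈ −0.697 without asserting any
mechanism. Control-group loadings are zero because the study found no
significant glycation correlations there.

Measurement noise defaults are small relative to the biological SDs
(load-cell 0.2% of F_max, cRPI force 0.2%, FTIR absorbance 5·10⁻⁴, XRD 0.5%
of peak counts, plate readings 0.2%): the published group SDs are treated
as biological spread and live in the latent draws, not in the instrument
models. The plate-reading default deserves a note: the quinine standards
span 0–10 µg/mL while diluted bone hydrolysates read near 0.07 µg/mL, so
relative reading noise is amplified roughly thirty-fold into the
back-calculated concentration; 0.2% reading noise keeps the per-animal fAGE
measurement CV near 3%, well below the 12% biological CV.

Two published values cannot be honoured simultaneously and are handled as
follows:

* The printed polar moment of inertia (0.34 mm⁴) is geometrically
  impossible alongside the printed cortical area (6.76 mm²): any planar
  section satisfies J ≥ A²/2π ≈ 7.3 mm⁴. The cortical forward model
  therefore derives an annulus from (Ct.Ar, Ct.Th); J is emergent
  (≈ 16.8 mm⁴ for the control geometry) and the printed J is retained only
  as a recorded covariate. The percent group difference in J still emerges
  (≈ 21%) because it is driven by the same area/thickness contrast.
* The trabecular plate-stack model can honour BV/TV and Tb.Th exactly, but
  then Tb.Sp is fixed by them (t(1−f)/f); the published BV/TV, Tb.Th and
  Tb.Sp triplet is itself mutually inconsistent for any plate geometry.
  BV/TV and Tb.Th are honoured; Tb.Sp and Tb.N are emergent. A smoothed
  Gaussian random-field generator (`method = "field"`) is available when a
  more trabecular-looking topology matters more than exact thickness.

# Forward models built for exact inversion

**Bending.** The trace is linear at the nominal stiffness up to a
proportional limit, then follows an exponential-saturation hardening arc
`F(d) = F_sat − kτ·exp(−(d−d_p)/τ)`. The pair (d_p, τ) is solved (1-D
root-find) so that the 0.2%-offset construction used by `analyze_bending()`
intersects the curve exactly at the requested yield load, and the curve
reaches F_max exactly at `D_fx = D_yield + PYD`. This makes the generator's
(stiffness, F_yield, F_max, PYD) the *offset-derived* quantities — the ones
the analysis reports — so zero-noise round-trips close to better than 1%.
The request is infeasible when `F_max − F_yield ≥ stiffness × PYD` (the
secant would have to exceed the elastic slope); the generator then warns
and falls back to a purely elastic ramp. Work-to-failure truth is the
closed-form area (the arc integrates analytically); it is reported in N·mm,
reading the source's "N/mm" units as a typo for an area under a
load–displacement curve.

**cRPI.** Cycles are force triangles at 8 N and 2 Hz. Peak-force depth of
cycle c is `ID_1st + (c−1)·creep`; the unloading branch is linear at the
requested slope. Loop area is decoupled from creep by repositioning the
loading start point at zero force between cycles, so *every* cycle's
hysteresis area equals the requested energy; without this, triangle
geometry forces loop area = 4·creep. Avg-ED averages all ten cycles
(`exclude_first_ed` flips the convention; the source does not say).

**Nanoindentation.** The load–depth curve is built from the Oliver–Pharr
equations themselves (A = P_max/H, h_c = √(A/24.5), S = (2/√π)·Er·√A,
h_max = h_c + εP_max/S, unloading P = α(h−h_f)^m with
h_f = h_max − mP_max/S), so the analysis — power-law fit over 40–95% of
the unloading force, S at h_max, ideal Berkovich area function, ε = 0.75,
β = 1 — inverts it to machine precision. The power-law fit profiles α out
and optimizes (h_f, m) with an analytic envelope-theorem gradient; m is
constrained to [1, 3].

**Spectra.** FTIR spectra are sums of Gaussians on a 2 cm⁻¹ grid
(400–1800 cm⁻¹): a phosphate ν1ν3 envelope whose 1020/1030 and 1096/1127
amplitudes are solved from a small linear system so the *summed-envelope*
intensity ratios equal the configured crystallinity and acid-phosphate
values; a carbonate ν2 band; and six amide I sub-bands at 1610–1692 cm⁻¹
(σ = 5.5 cm⁻¹) whose 1678/1692 and 1660/1692 areas encode NE-xLR and
collagen maturity. XRD patterns place Gaussian peaks at 2θ = 26° and 40°
(0.0334° steps, 20–45°) whose FWHMs invert the Scherrer relation
`B = λ/(L·cosθ)` at λ = 0.15406 nm, so sizing is a strict round-trip.

# Analysis conventions and numerical choices

* **Linear region (bending):** all sliding windows between the 10 N
  preload crossing and 80% of F_max (minimum 20 samples) are scored by
  linear-fit R² via cumulative sums; the kept threshold is
  `max(0.98, 1 − 4(1 − R²_best))` and the *longest* window above it wins.
  On noise-free data R²_best = 1 up to rounding, so only exactly-linear
  windows qualify and the elastic slope is recovered exactly; on noisy data
  the rule degrades gracefully toward the plain R² ≥ 0.98 criterion.
* **Offset basis:** the 0.2% offset is expressed as a displacement of
  `offset_fraction × span` (0.038 mm at the 19 mm span), a strain-equivalent
  convention, configurable. The fracture point is the last sample before
  the load drops below 50% of F_max.
* **Local baselines:** every spectral window (band integration, amide I,
  diffraction peaks) uses a straight line through the window endpoints, as
  interactive baseline correction would. For *fits* this is refined by a
  free linear term in the model: the endpoint line inevitably rides on the
  peaks' own tails, and the refinement removes that bias exactly for
  in-model (Gaussian) data. Window-endpoint effects do remain in the plain
  band *integrals*: the carbonate/phosphate ratio, whose 852–890 cm⁻¹
  window is only ±2.7σ wide, reads ≈ 6% below its configured value. Group
  percent differences are unaffected (the bias is multiplicative and equal
  in both groups), and this mirrors what windowed integration does to real
  spectra.
* **Amide I fit:** amplitudes are initialised from second-derivative
  minima, centers are bounded to ±4 cm⁻¹, widths (σ) to [4, 30] cm⁻¹;
  L-BFGS-B with analytic gradients and per-parameter scaling (`parscale`)
  is run to a tight tolerance — without the scaling the mixed
  absorbance/wavenumber parameterisation stalls short of the optimum and
  biases the area ratios by ~0.5%. One flat-amplitude restart precedes a
  hard error.
* **Scherrer constant:** K = 1 exactly as the source equation is written
  (the conventional 0.9 is available as an argument).
* **XRD windows:** peak windows auto-widen to ≈ 8× the estimated FWHM
  (clipped to the scan range) so the endpoint baseline sits on true
  background even for nanometre-scale (broad-peak) crystallites.
* **Local thickness:** inscribed-sphere (distance-ridge) definition,
  computed by a compiled Euclidean distance transform plus sphere painting.
  Thickness is `2·EDT` at the ridge — the BoneJ-style convention with no
  half-voxel correction, which is exact for curved interfaces sampled
  finely but can overestimate slab thickness by up to one voxel
  (odd-thickness slabs); tests assert plate fixtures at a one-voxel
  tolerance and the annulus at 2%. Ct.Th uses the ridge mean directly;
  Tb.Th/Tb.Sp use the sphere-painted map over each phase; Tb.N is computed
  as (BV/TV)/Tb.Th (one of several literature estimators — documented,
  configurable in spirit by computing from the returned pieces).
* **Morphometry:** Ct.Ar is voxel-count area per slice; J is Σr²·dA about
  the per-slice centroid, averaged over slices; both converge to the
  closed-form annulus values as the voxel shrinks (tested).
* **Statistics:** normality is a one-sample Kolmogorov–Smirnov test
  against a normal with the sample's own mean/SD (Lilliefors-style — which
  exact variant the original toolchain used is unknowable, and this choice
  is flagged here); variance homogeneity is Levene's test (mean-centered);
  the decision rule is Student t (both normal, homogeneous), Welch t (both
  normal, heterogeneous), otherwise Mann–Whitney U with exact enumeration
  whenever `choose(n1+n2, n1)` is affordable and a tie-corrected normal
  approximation beyond. Outlier removal is single-pass (mean/SD computed
  once), per parameter, k = 2 SD. Percent differences are signed and
  control-referenced. Stepwise regression is pure-forward with a
  partial-F entry criterion at p < 0.05 and no removal step.

# What a green test establishes — and what it does not

The synthetic world is deliberately idealised: bending arcs are smooth and
single-peaked (no micro-fracture load drops), cRPI loops are polygonal,
nanoindentation has no thermal drift or tip defects, spectra are exact
Gaussian mixtures, plates are parallel and volumes noise-free binary
masks. Green round-trips therefore establish that the *analysis chain is
internally consistent and implements the stated conventions exactly* — not
that it is robust to every artifact of real instruments. Conversely, the
property suites (scale invariances, enumeration equivalence for the U
statistic, closed-form annulus geometry, Scherrer inversion across
2–50 nm) hold independently of the generator's idealisations.

Runtime scaling: tests and the bundled study runner use reduced cohort
sizes and coarser trabecular voxels than the 5 µm protocol default purely
to keep suite runtime small; the generator defaults themselves follow the
study protocol (20 µm cortical / 5 µm trabecular, 1.5 mm trabecular cube,
six cRPI sites, eight nanoindents).

# Known limitations

* Percent differences for bending, cRPI and FTIR depend on the chosen
  control anchors only through rounding; the anchors themselves are
  conventions, not measurements.
* The fracture-pattern classification, SMI, degree of anisotropy and
  connectivity density are out of scope, as is reconstruction from
  projections and any beam-physics simulation.
* The Mann–Whitney exact enumeration defines the two-sided p as the tail
  probability of |U − n₁n₂/2|; with heavy ties other two-sided conventions
  can differ slightly.
* `ks.test` with estimated parameters is anti-conservative as a normality
  gate; it is used because it is the closest executable reading of the
  source's stated procedure.
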