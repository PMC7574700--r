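# osteoquant

Multiscale bone-quality analysis for two-group (control vs. type-2-diabetic)
rodent studies, built as a tested, reusable R pipeline.

Diabetic bone fractures more readily than its density alone predicts: the
deficit lives in bone *quality* — matrix composition, collagen cross-linking,
mineral crystal size, tissue-level mechanics — as much as in structure.
Characterising it takes a battery of instruments whose raw outputs each need
non-trivial numerical analysis. `osteoquant` implements that analysis chain
end to end for the measurements typical of a rat femur study:

| Modality | Raw input | Parameters extracted |
|---|---|---|
| Three-point bending | load–displacement trace | F_max, stiffness (best linear region), work-to-failure, 0.2%-offset yield, post-yield displacement (PYD) |
| Cyclic reference-point indentation | cyclic force–depth record | ID-1st, TID, IDI, first-cycle unloading slope, average energy dissipation |
| Nanoindentation | load–depth curve | reduced modulus E_r and hardness H by the Oliver–Pharr method (power-law unloading fit, S = dP/dh, h_c = h_max − εP_max/S, A = 24.5 h_c², E_r = (√π/2)·S/√A) |
| FTIR | absorbance spectrum, 400–1800 cm⁻¹ | mineral/matrix, carbonate/phosphate, crystallinity, acid phosphate; amide I six-Gaussian deconvolution → NE-xLR (A₁₆₇₈/A₁₆₉₂) and collagen maturity |
| XRD | powder pattern, 20–45° 2θ | crystallite length (002) and width (310) via the Scherrer equation B = λ/(L·cos θ) |
| fAGE assay | plate-reader standards + samples | ng quinine-equivalents per mg collagen (collagen = hydroxyproline/0.14) |
| micro-CT | voxel volume | BV/TV, Tb.Th, Tb.Sp, Tb.N, Ct.Ar, Ct.Th, polar moment J, phantom-calibrated TMD |
| Statistics | per-animal table | 2-SD outlier screen, KS/Levene-guided Student/Welch/Mann–Whitney selection, Pearson correlation, forward stepwise regression |

Because the original study's raw data are not deposited, the package ships a
forward-modelling **synthetic-cohort generator**: latent per-animal parameters
are drawn from the published group summaries (means ± SD, or published
percent differences anchored at typical control values) and rendered into
raw-format instrument files with known ground truth. Every analyzer is
validated by exact forward–inverse round-trips against that truth. See the
methods vignette (`vignettes/bone-quality-pipeline.Rmd`) for the models,
conventions and design decisions.

## Worked example

```r
library(osteoquant)

# whole-bone mechanics: generate a noise-free trace and invert it
trace <- forward_bending(stiffness = 250, F_yield = 96, F_max = 120, PYD = 0.25)
analyze_bending(trace)
#> <bending_result> F_max 120.00 N, stiffness 250.0 N/mm, work 49.15 N*mm, PYD 0.2500 mm

# Oliver-Pharr at the diabetic group's printed means
analyze_nanoindentation(forward_nano(Er = 16.22, H = 0.387))
#> <nano_result> Er 16.22 GPa, H 0.387 GPa (S 29.421 uN/nm, h_c 324.8 nm, m 1.500, R2 1.00000)

# crystallite sizing round-trip at the control means
analyze_xrd(forward_xrd(length_nm = 18.29, width_nm = 4.64))
#> <xrd_result> length 18.29 nm (002), width 4.64 nm (310)

# a small two-modality study: generate, analyze, compare
cohort <- cohort_config(n_per_group = 10, seed = 1,
                        modalities = c("bending", "nano"), n_nano_indents = 2)
run_study(study_config(cohort = cohort, out_dir = tempfile("demo")))
#> <study_report> seed 1, 6 parameters compared (0 failed)
#> significant group differences (control-referenced):
#>   F_max_N                    +32.9%  p = 4.89e-07 ***
#>   stiffness_N_mm             +54.8%  p = 2.105e-09 ***
#>   work_N_mm                  +41.6%  p = 0.00058 ***
#>   PYD_mm                     +49.1%  p = 2.316e-07 ***
#>   Er_GPa                     +23.2%  p = 1.142e-08 ***
#>   H_GPa                      +32.3%  p = 4.037e-08 ***
```

The percent differences are signed and referenced to the control group: at
n = 10 per group the recovered contrasts scatter around the calibrated
targets (e.g. stiffness −57%, maximum load −36.9% in the diabetic group)
with group-mean sampling error of a few percentage points.

A thin command-line wrapper over the same functions is installed at
`inst/cli/osteoquant` (`osteoquant bending --in trace.csv --out result.json`,
plus `rpi`, `nano`, `ftir`, `xrd`, `fage`, `microct`, `generate`, `run-all`).

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the acceptance quantities: it forward-models zero-noise inputs at
the study's printed parameter values (the diabetic-group nanoindentation
modulus/hardness, the diabetic-mean crystallite length, and a pair of amide I
envelopes whose sub-band area ratios differ by the reported NE-xLR
contrast), runs the corresponding analysis stages, and writes the recovered
values as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
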