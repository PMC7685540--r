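# spineshare

Simulation and analysis of intervertebral **motion sharing** biomarkers
from passive recumbent lumbar flexion, as measured with quantitative
fluoroscopy (QF), together with the intra-/inter-investigator
repeatability statistics used to validate them.

## The problem and who this is for

In QF, a motorised table passively flexes a side-lying subject's trunk
(6°/s² for 1 s, then 6°/s to 40° and back) while a fluoroscope images the
lumbar spine at 15 Hz.  Tracking each vertebral body through the sequence
yields per-frame intervertebral rotations at L2-L3, L3-L4, L4-L5 and
L5-S1.  Two composite biomarkers — candidates for mechanical markers of
chronic nonspecific low back pain — summarise how the four levels share
the gross L2-S1 rotation.  With the proportional contribution
`p_l(i) = θ_l(i) / G(i)` and its per-frame range
`fRC_i = max_l p_l(i) − min_l p_l(i)` over the middle 80% of movement:

    MSI = (1/N) Σ fRC_i                  (Motion Sharing Inequality)
    MSV = sqrt( (1/N) Σ (fRC_i − MSI)² ) (Motion Sharing Variability)

Both require manual first-image registration to seed automated tracking,
so investigator input is a potential error source.  The package is aimed
at spine-biomechanics researchers who want to (a) compute MSI/MSV from
intervertebral angle time series, (b) quantify investigator repeatability
— ICC(2,1) with 95% CI, standard error of measurement (SEM), minimal
difference (MD = SEM × 1.96 × √2) — and (c) test the whole chain on
synthetic data with known ground truth, since the underlying clinical
image archives are not public.

Five building blocks, each usable on its own:

| stage | functions |
|---|---|
| protocol simulation | `table_profile()`, `generate_table_motion()`, `generate_subject()`, `generate_cohort()`, `generate_observation_matrix()` |
| image rendering | `vertebral_geometry()`, `render_frames()`, `write_image_sequence()` |
| template tracking | `register_first_image()`, `track_sequence()`, `retrack_failures()`, `extract_intervertebral_angles()` |
| biomarkers | `trim_middle80()`, `to_proportional()`, `frame_range()`, `compute_msi()`, `compute_msv()`, `motion_share()` |
| repeatability | `icc_two_way_random_single()`, `sem_from_anova()`, `minimal_difference()`, `categorize_icc()`, `repeatability_report()` |

`run_pipeline()` and the `inst/cli/spineshare` script bind them into an
end-to-end, seed-deterministic pipeline.  See the vignette
(`vignettes/motion-sharing-repeatability.Rmd`) for the model details and
design decisions.

## Worked example

Simulate one subject under the default protocol and derive the
biomarkers:

```r
library(spineshare)
subj <- generate_subject(table_profile(), sharing_profile(), seed = 11)
motion_share(subj)
#> <motion_share_result>
#>   MSI = 0.239   MSV = 0.071   (N = 160 retained frames)
#>   trim = amplitude, phases = both
```

231 frames are simulated (116 outward, 115 return); the middle-80% trim
retains the 160 frames whose gross angle lies in [4°, 36°].  MSI = 0.239
means the most- and least-contributing levels differ by about 24% of the
gross angle on a typical frame; MSV = 0.071 is the frame-to-frame spread
of that inequality.

A full 30-subject repeatability study with three simulated reading sets
(investigator 1, and investigator 2 at two occasions):

```r
run <- run_pipeline(default_config(), outdir = "demo", seed = 1)
run$report$table
#>   biomarker      pairing     raters  icc ci_lower ci_upper    category   sem sem_pct    md
#> 1       msi        intra DT1 vs DT2 0.89     0.78     0.95 substantial 0.025      10 0.070
#> 2       msi        inter AxB vs DT1 0.93     0.85     0.96 substantial 0.021       8 0.057
#> 3       msi completeness AxB vs DT2 0.94     0.89     0.97 substantial 0.018       7 0.051
#> 4       msv        intra DT1 vs DT2 0.32    -0.04     0.61      slight 0.017      27 0.047
#> 5       msv        inter AxB vs DT1 0.25    -0.13     0.56      slight 0.020      31 0.056
#> 6       msv completeness AxB vs DT2 0.25    -0.12     0.56      slight 0.020      32 0.055
```

The pattern mirrors the published repeatability study of these
biomarkers: MSI reliability is substantial (ICC ≈ 0.9, SEM ≈ 10% of the
group mean of ≈ 0.24) while MSV — an order of magnitude smaller (group
mean ≈ 0.07) at the same absolute error — fares much worse.  `demo/`
receives the per-subject sequence CSVs, the readings, a Markdown report,
identity-line scatterplots and a `results.json` with provenance (package
version, config hash, seed); the same config and seed reproduce it
byte-identically.

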