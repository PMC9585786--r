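# natriq

Quantitative sodium (²³Na) MRI of human calf muscle at ultra-high field,
as a tested, reusable R package plus a reproducible analysis workflow.
It is aimed at MR physicists and image-analysis researchers who want to
exercise, validate, or extend a complete tissue-sodium-concentration
(TSC) estimation chain without scanner data.

The package implements:

* **DA-3DPR acquisition geometry** — density-adapted 3D radial
  projection-reconstruction trajectories (cube-root radial law, golden-
  means spoke spiral), point-spread-function simulation with
  bi-exponential readout decay, Kaiser–Bessel gridding reconstruction and
  the matching forward model, plus Pipe–Menon density-compensation
  refinement.
* **Synthetic digital calf** — a multi-compartment phantom
  (gastrocnemius medialis / tibialis anterior / soleus / other muscle,
  four calibration tubes at 15.4–61.6 mmol/L, a homogeneous 61.6 mmol/L
  cylinder) with smooth B0/B1⁺ fields, complex coil profiles, and
  multi-echo / inversion-recovery series at calibrated SNR.
* **Corrections** — adaptive (Walsh-type) coil combination,
  multiple-replica SNR maps, dual-echo B0 mapping, phase-sensitive B1⁺
  mapping, multi-frequency off-resonance correction, and
  cylinder-derived intensity correction.
* **Relaxometry** — ROI-based bi-exponential T2* and magnitude
  inversion-recovery T1 fitting with bounded multi-start
  Levenberg–Marquardt.
* **Partial-volume correction** — the geometric transfer matrix (GTM)
  method with region-spread functions from the simulated imaging
  operator.
* **Quantification** — calibration-curve construction and
  TSC = (I_tissue/f_tissue)/(I_phan/f_phan) · 25 mmol/L with
  relaxation-difference correction.
* **Repeatability statistics** — two-way ICC (all four variants, F-based
  CIs), Bland–Altman limits of agreement, and exact (enumeration-based)
  Friedman, Wilcoxon signed-rank and rank-sum tests.

A reference cohort measurement table (10 healthy subjects × 3 sessions
and 5 Addison's-disease patients, per muscle; plus a 4-subject
relaxometry subgroup) ships in `inst/extdata/` and drives the statistics.

## Worked example

Run the full pipeline on the synthetic healthy calf (matrix 64,
5,000 projections, muscle SNR calibrated to 16):

```r
library(natriq)
res <- run_pipeline(default_config(matrix = 64, scenario = "healthy"))
print(res)
#> pipeline result: scenario 'healthy', matrix 64, SNR 16.3
#>   muscle      tsc truth   rel_error
#> 1     GM 20.04104  19.9 0.007087612
#> 2     TA 13.94910  13.8 0.010804508
#> 3      S 12.68595  12.6 0.006821801
#> correction gap (%): GM 12.3, TA 10.5, S 15.6
```

The corrected concentrations recover the generative truths
(19.9/13.8/12.6 mmol/L) to about 1%; without the intensity and
partial-volume corrections the estimates run 10–16% high, matching the
magnitude of correction reported for this kind of protocol.

Repeatability statistics on the reference cohort table:

```r
rep <- analyze_repeatability(reference_tsc_table())
rep$icc$GM
#> ICC(Ck) = 0.784 (95% CI 0.368-0.942); n=10, k=3
round(rep$means$healthy, 2)
#>    GM    TA     S
#> 19.89 13.84 12.57
rep$group_comparison$GM$p_exact   # healthy vs Addison, exact rank-sum
#> [1] 0.000666000666000666
```

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (phantoms → pipeline → field maps → relaxometry →
TSC → statistics) and write tables and figures under `results/`.

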