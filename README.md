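# lumbarqmri

Level-by-level quantification of lumbar paraspinal muscle structure from
multiparametric MRI, for researchers studying muscle health in the
lumbar spine (aging, low back pain, deconditioning). The package
implements the full measurement chain for the two posterior muscle
groups — multifidus and erector spinae — at each vertebral level L1–S1,
and ships a digital phantom so the whole chain is testable as a
parameter-recovery problem without any patient data.

## What it computes

* **Dixon fat–water separation.** From an in-phase/out-of-phase pair,
  `S_w = (IP + OP)/2`, `S_f = IP − S_w`, and the fat signal fraction
  `FF = S_f / (S_f + S_w) ∈ [0, 1]` (`dixonDecompose()`,
  `fractionAbove()`).
* **Diffusion tensor metrics.** Per-voxel log-linear least squares on
  `ln(S_i/S_0) = −b gᵢᵀ D gᵢ` (`fitTensor()`), then sorted eigenvalues
  λ₁ ≥ λ₂ ≥ λ₃, `MD = (λ₁+λ₂+λ₃)/3`, `RD = (λ₂+λ₃)/2` and
  `FA = √(3/2)·√Σ(λᵢ−MD)² / √Σλᵢ²` (`eigenMetrics()`).
* **Vertebral-level ROIs.** Half-open axial slabs cut midway between
  adjacent vertebrae (`sliceLevels()`), nearest-neighbor mask transfer
  between acquisition grids (`resampleMask()`), and per-muscle/per-level
  aggregation into a tidy level table (`aggregateLevels()`).
* **Tractography.** Deterministic interpolated-streamline integration of
  the principal eigenvector field with a 15° angular termination
  threshold, per-track length/pennation metrics, and TrackVis `.trk`
  export (`trackStreamlines()`, `writeTrk()`).
* **Statistics.** Two-way repeated-measures ANOVA (muscle × level,
  within-subject error strata), Sidak-adjusted per-level paired
  comparisons, and a repeated-measures ANCOVA with fat fraction as
  covariate (`rmAnova()`, `sidakPosthoc()`, `ancovaFatCovariate()`).
* **Digital phantom.** Multi-subject anatomy/Dixon/DWI datasets with
  exact ground truth, Rician noise and between-subject variability
  (`phantomConfig()`, `simulateSubject()`, `writeDataset()`), plus the
  end-to-end driver `phantomRecoveryStudy()` and pipeline runner
  `runPipeline()` (NIfTI, bvec/bval, `.trk`, CSV outputs). A
  command-line wrapper lives at `inst/scripts/run_pipeline.R`.

## Worked example

```r
library(lumbarqmri)

cfg <- phantomConfig(nSubjects = 10, betweenSubjectCV = 0, snr = 40,
                     seed = 0)
run <- phantomRecoveryStudy(cfg, withDti = FALSE)
lt <- run$levelTable
round(c(es_volume  = mean(lt$volume_ml[lt$muscle == "erector_spinae"]),
        mf_volume  = mean(lt$volume_ml[lt$muscle == "multifidus"]),
        es_ff      = mean(lt$fat_fraction[lt$muscle == "erector_spinae"]),
        mf_ff      = mean(lt$fat_fraction[lt$muscle == "multifidus"]),
        highfat_pct = 100 * run$highFat[["fraction"]]), 4)
#>   es_volume   mf_volume       es_ff       mf_ff highfat_pct
#>    125.8000     54.0000      0.2285      0.2051     12.6046
```

The ten-subject study recovers the phantom's ground-truth aggregates:
mean erector spinae volume 125.8 mL versus 54.0 mL for the multifidus,
overall fat signal fractions of ~0.228 and ~0.205, and ~12.6% of labeled
voxels with a fat fraction above 0.45 — fatty voxels concentrated in the
epimuscular shell rather than spread through the muscle.

The statistics stage works on the same level table (here from the fast
table-level simulator with 10% between-subject variability):

```r
tab <- simulateLevelTable(defaultTruthTable(), nSubjects = 10, cv = 0.1,
                          seed = 1)
rmAnova(tab, "volume_ml")
#> Two-way repeated-measures ANOVA of 'volume_ml' (n = 10 subjects)
#>   muscle         F(1, 9) = 1828.538, p = 1.044e-11
#>   level          F(5, 45) =   71.061, p = 3.23e-20
#>   muscle:level   F(5, 45) =  342.622, p = 1.281e-34
#>   Sidak post hoc (alpha = 0.05): significant at L1, L2, L3, L4, L5, S1
```

Both muscle and level matter, they interact (the muscles' size ranking
flips in the lower spine), and every per-level paired comparison
survives the Sidak adjustment.

See `vignettes/lumbar-muscle-quantification.Rmd` for the model, the
phantom's design and its limitations.

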