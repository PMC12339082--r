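# osteoquant

Quantification pipeline for **quantitative backscattered electron imaging
(qBEI)** of longitudinal bone sections, as used to characterize bone
matrix mineralization, osteocyte lacunae and trabecular structure in
mouse models of skeletal disease — here tuned to the *Lmna*^G609G^
progeria mouse study design (femora at 8 weeks, humeri at 15 weeks,
wild-type vs. mutant littermates).

The package implements the full measurement chain:

* **Calibration** — raw 8-bit gray levels → calcium weight-percent via a
  two-point carbon/aluminum standards model (canonical slope
  0.17 wt%Ca per gray step);
* **BMDD** — the bone mineralization density distribution with its five
  descriptors: CaMean, CaPeak, CaWidth (FWHM), and CaLow/CaHigh, the area
  fractions below the 5th / above the 95th percentile of a pooled
  wild-type metaphyseal reference;
* **Histomorphometry** — BV/TV, Tb.Th (distance-transform local
  thickness) and Tb.N (plate model) in the primary spongiosa (first
  500 µm below the metaphyseal mineralization front) and secondary
  spongiosa (the following 1 mm), plus the thickness of the unmineralized
  growth-plate zone (resting + proliferative cartilage);
* **OLS** — osteocyte lacuna sections: enclosed unmineralized voids,
  8-connected, gated to 5–200 µm², with Crofton perimeters; porosity,
  density, median area/perimeter, and the empty-lacuna fraction from
  histology counts;
* **Statistics** — Shapiro–Wilk-gated t / Mann–Whitney two-group tests,
  type-II two-way ANOVA (site × genotype) with Tukey HSD, percent group
  differences;
* **Synthetic phantoms** — a generator for qBEI-like sections and whole
  cohorts with planted, recorded ground truth (zone calcium gradients,
  dashed-rod trabecular texture, elliptical cortical lacunae, imaging
  noise, per-age genotype effect profiles shipped in
  `inst/extdata/effect_profiles.yaml`).

## Worked example

```r
library(osteoquant)

img <- generate_bone_image(synthetic_config(), seed = 42)
rec <- run_sample(img)
rec
#> sample_record 'synthetic' (config 963c53ed)
#>   site ca_mean ca_peak ca_width
#> 1   Ct   24.09   24.06    3.320
#> 2   Es   22.59   22.36    3.197
#> 3   Ms   21.08   21.00    3.327
#>      region bv_tv tb_th   tb_n bone_area tissue_area
#> 1   primary 35.49 29.43 12.058    152522      429742
#> 2 secondary 19.80 43.60  4.541    170141      859485
#> growth plate: 149.6 um (977 columns)
#> OLS: n = 185, porosity 1.49%
```

Reading the output: the three sites show the planted tissue-age gradient
(cortex 24 → epiphysis 22.5 → metaphysis 21 wt%Ca) with CaWidth ≈ 3.3
(the planted σ = 1.3 wt%Ca broadened by detector noise, FWHM = 2.3548 σ);
the spongiosa BV/TV values recover the planted 35% / 20% targets; the
growth plate reads 149.6 µm for a planted 150 µm band (170 px at
0.88 µm/px); all 185 in-gate planted lacunae are found.

Cohort-level comparison with a planted genotype effect:

```r
coh <- generate_cohort(synthetic_config(), n_wt = 19, n_mut = 18,
                       age_group = "8W", seed = 11)
m <- measure_cohort(coh, "gp_thickness")
cohort_percent_difference(m, "gp_thickness")   # ~ -18 (%)
```

`run_cohort()` produces the full report (per-sample BMDD/OLS/
histomorphometry tables, the wild-type metaphyseal reference, CaLow/CaHigh
per sample, and the genotype comparisons per measure). A thin CLI wrapper
lives in `inst/cli/osteoquant.R` (`simulate`, `run-sample`,
`run-cohort`).

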