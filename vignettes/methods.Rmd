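---
title: "Methods: quantitative backscattered electron imaging of bone sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative backscattered electron imaging of bone sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoquant)
```

## The measurement chain

In quantitative backscattered electron imaging (qBEI), the backscatter
signal of a polished, carbon-coated bone section grows with the local mean
atomic number, so the gray level of an 8-bit SEM image encodes the local
calcium content of the mineralized matrix. `osteoquant` implements the
downstream quantification chain for longitudinal sections of long bones:

1. **Calibration** — gray level to calcium weight-percent via carbon and
   aluminum standards;
2. **BMDD** — the bone mineralization density distribution and its five
   scalar descriptors;
3. **Histomorphometry** — BV/TV, Tb.Th and Tb.N in the primary- and
   secondary-spongiosa bands below the metaphyseal mineralization front,
   and the thickness of the unmineralized growth-plate zone;
4. **OLS** — osteocyte lacuna sections in the cortex;
5. **Cohort statistics** — normality-gated two-group tests, two-way
   factorial analysis and percent group differences.

A synthetic image generator with planted, recorded ground truth makes the
whole chain testable without access to instrument data.

## Calibration model

The backscatter detector and beam current drift between sessions, so each
image carries the measured gray levels of pure carbon and aluminum
standards. The model is a two-stage affine map: measured gray is first
rescaled so the standards land on configurable canonical positions
(defaults 25 and 225, common qBEI practice), then canonical gray maps to
calcium as

$$\mathrm{Ca}(g) = s\,\big(g_\mathrm{canon}(g) - z\big),$$

with a fixed slope $s = 0.17$ wt%Ca per canonical step and a zero-calcium
offset $z = 25$ by default. One canonical gray step therefore equals one
BMDD bin — the native resolution of the calcium measurement. The exact
canonical anchor positions used by any given laboratory are an instrument
convention; all four constants are configurable through
`qbei_constants()`. Gray levels below the zero-calcium offset are organic
matrix or embedding resin and are clipped to 0 rather than erred, since
they fall below the mineralization threshold anyway. Sample/background
separation is delegated to an optional mask input; absent one, the
5.2 wt%Ca threshold performs the separation downstream.

## BMDD

The BMDD is the histogram of calcium content over mineralized pixels
(Ca ≥ 5.2 wt%Ca, the same boundary the OLS segmentation uses, since no
separate inclusion threshold is part of the method), normalized to percent
of bone area. Bins are half-open $[lo, lo + 0.17)$ starting at 0 wt%Ca and
kept on the full fixed grid to 45 wt%Ca (pure hydroxyapatite) so all
curves share identical binning. Because calibrated gray levels are exact
multiples of the bin width, the bin index is computed with a small epsilon
so that values sitting on a bin edge up to floating-point error land in
the correct bin; without it, quantized maps alias into double-height
spikes and empty bins.

Descriptors:

* **CaMean** — frequency-weighted mean;
* **CaPeak** — the maximal bin's center; exact ties are resolved as the
  arithmetic mean of tied centers (no smoothing is applied — determinism
  is preferred over cosmetic smoothness);
* **CaWidth** — full width at half the peak frequency, linearly
  interpolated at the outermost half-maximum crossings around the global
  peak (robust to multiple crossings on noisy curves);
* **CaLow / CaHigh** — percent of bone area below the 5th / above the
  95th percentile of a *reference* BMDD. The reference pools the
  wild-type metaphyseal curves of each age group by unweighted mean
  (each animal counts equally regardless of bone area, matching the
  per-animal statistics), and its percentiles are linearly interpolated on
  the pooled cumulative distribution. Partial bins are apportioned
  linearly rather than counted whole, which makes the self-reference
  identity CaLow = CaHigh = 5% hold to interpolation accuracy.

## Histomorphometry

The mineral mask is the pixel-wise comparison Ca ≥ 5.2 wt%Ca. Band and
front search run on a copy opened with a 3×3 box (one pass by default) so
single-pixel noise can neither fabricate nor pierce the growth-plate band.

**Band detection.** Columns that are almost fully mineralized top to
bottom (fill ≥ 0.85) are treated as cortex and excluded. On the remaining
columns, candidate bands are interior runs of rows whose mineralized
fraction is ≤ 0.05 and whose length is ≥ 8 px. Among candidates, the run
whose boundary rows are most densely mineralized wins (ties broken by
length): the growth plate is bounded by the subchondral plate and the
chondro-osseous junction on either side, whereas chance alignments of
inter-trabecular marrow are bounded by sparse rows. This scoring is what
keeps band detection stable in low-BV/TV metaphyses.

**Front and bands.** The mineralization front is, per column, the first
mineralized pixel on the metaphyseal side of the band; columns occluded by
a mineralized bridge through the band center, or whose band runs into the
image border, are invalid. The primary spongiosa is the per-column band
[front, front + 500 µm), the secondary spongiosa the following 1000 µm;
depths are rounded to the nearest integer pixel count (568 and 1136 px at
0.88 µm/px) and clipped to the image with a warning. Pixel coordinates
are 1-based row/column indices, intervals half-open.

**BV/TV** is the mineralized area fraction of the band. **Tb.Th** is the
area-weighted mean of the 2D local thickness field: each mineralized pixel
receives the diameter of the largest inscribed disc that contains it,
computed from the exact Euclidean distance transform with disc centers
pruned to the distance ridge. The convention is `2·dt − 1` pixels (an
isolated pixel has thickness one pixel; a slab of width $w$ px reads $w$
for odd and $w - 1$ for even widths, a sub-pixel discretization bias).
Structures touching the evaluation window border are treated as
continuing, and the window pads the band by 64 px so discs anchored just
outside are seen. **Tb.N** is the plate-model quantity
(BV/TV/100)/Tb.Th, reported per millimeter; no intercept counting is
attempted, so Tb.N is exactly reproducible from the two measured
quantities. **Growth-plate thickness** is, per valid column, the distance
between the last epiphyseal and first metaphyseal mineralized pixels,
averaged over valid columns.

## Osteocyte lacuna sections

Lacunae are connected components of unmineralized pixels using
8-connectivity for the voids (and 4-connectivity implicitly for the
mineralized complement — the standard digital-topology pairing). A
component is a lacuna candidate only if it is fully enclosed: touching the
raster border or being 8-adjacent to an off-sample pixel disqualifies it,
which removes marrow space and vascular canals connected to the outside.
Candidates are gated by section area with inclusive bounds 5–200 µm².
Perimeters use the Crofton 4-direction estimator,
$P = \tfrac{\pi}{8}\,(n_0 + n_{90} + (n_{45} + n_{135})/\sqrt{2})$
with $n_\theta$ the count of foreground/background transitions along the
line family in direction $\theta$ — smoother convergence for small objects
than boundary-pixel counting. Summary statistics use mineralized area plus
total lacunar area as the evaluated-bone denominator (the sectioned tissue
including its voids); the denominator is configurable since either
convention appears in practice. The empty-lacuna fraction is a pure ratio
statistic over upstream manual counts from decalcified histology; no
nucleus detection is attempted.

## Cohort statistics

Each group is gated by the Shapiro–Wilk test at α = 0.05; if either group
fails (constant samples count as failing), the two-sided Mann–Whitney test
replaces the two-sided Student t-test (equal-variance form). The
Mann–Whitney branch uses the exact null distribution when the smaller
group has at most 8 untied observations and the tie-corrected normal
approximation otherwise. The two-way site × genotype analysis uses type-II
sums of squares — appropriate for the unbalanced cohorts (19/18 and 7/7)
without an interaction emphasis — with Tukey HSD over the site levels by
default (over all site × genotype cells on request). Percent differences
are reported as 100·(mean(MUT) − mean(WT))/mean(WT). Following the study
design, no multiple-testing adjustment is applied across measures.

## The synthetic phantom

`generate_bone_image()` lays out, along the vertical bone axis: an
epiphyseal trabecular compartment, the unmineralized growth-plate band
(resting + proliferative cartilage), a metaphyseal compartment split into
primary- and secondary-spongiosa texture bands, and flanking cortical
bands. Thin (≈ 3.5 µm) mineralized seam plates border the growth plate on
both sides — the subchondral plate and the chondro-osseous junction — so
the planted band thickness is exactly defined and front detection has a
physical anchor. Their area is budgeted into the band BV/TV targets so
achieved fractions equal the targets.

Trabeculae are dashed vertical rods of controlled width. Per rod line, the
band is split into height cells and one gap of length (1 − λ)·cell is
placed uniformly inside each cell, so the covered fraction equals the
target λ per cell up to rasterization; gaps that would leave a fragment
shorter than the rod width are snapped to the cell boundary (fragments
depress the local-thickness mean). Rod widths jitter by ±2 px around the
target — natural variation that also averages out the odd/even parity of
the rasterized width. Per-zone calcium values are drawn from Gaussians
whose means decrease from cortex (24 wt%Ca) to epiphysis (22.5) to
metaphysis (21) — the tissue-age gradient of growing bone — with
σ = 1.3 wt%Ca; elliptical lacunae (log-normal section areas with median
30 µm², truncated to the 5–200 µm² gate; aspect ratio 1.6–3, long axis
near the bone axis; ≈ 600/mm²) are carved into the cortex on a jittered
grid whose clearance scales with each lacuna's own size, so lacunae
neither overlap nor touch compartment boundaries. Calcium maps to gray
through the inverse calibration, and Gaussian detector noise (σ = 3 gray
levels) is added last. Ground truth records quantities of the *rasterized*
image (achieved area fractions, per-column band height, rasterized lacuna
areas), not the continuous parameters.

`generate_cohort()` draws per-animal multiplicative parameter jitter
(truncated normal, CV 3%) and applies the per-age effect profile to mutant
animals. The profiles live in `extdata/effect_profiles.yaml`, transcribed
from the group differences measured in the *Lmna* G609G progeria mouse
cohorts this pipeline targets: growth plate ×0.82 (8 weeks) / ×0.75
(15 weeks), primary BV/TV ×0.77 / ×0.62, secondary BV/TV ×0.64 / ×0.51,
secondary Tb.Th ×0.79 / ×0.76, calcium unchanged; code carries no effect
numbers. The empty-lacuna scaling (×2) is directional only — the increase
is established but its magnitude is not published as a number. The
between-animal CV of 3% reflects inbred littermates and keeps the sampling
error of group-mean percent differences at the smallest study group size
(7 vs 7) within the ±3-percentage-point recovery band used in validation,
while leaving all planted large effects highly significant at the study's
group sizes and null measures null. Sex is assigned alternately and
carries no planted effect.

**What the phantom does not emulate:** Poisson electron statistics,
charging artifacts and detector shading; curved or branching trabecular
networks (rods are axis-aligned, so anisotropy measures would be
meaningless); realistic marrow texture; canalicular porosity; partially
mineralized osteoid seams. Passing the validation suite therefore
demonstrates correctness of the measurement chain on known geometry and
calibrated statistics — not robustness to every artifact of real
micrographs.

## Validation problem sizes

The test suite exercises: full-resolution phantoms (≈ 1200 × 2400 px at
0.88 µm/px) for cohort-level effect recovery at the study's group sizes
(19/18 at 8 weeks, 7/7 at 15 weeks, one cohort per quantity);
reduced-width phantoms (≈ 450 × 1100 px) for per-stage recovery tests; a
10⁶-pixel Gaussian map for the BMDD limit (CaMean → µ,
CaWidth → 2.3548 σ); stripe, disc and ellipse phantoms against closed-form
geometry and a brute-force inscribed-disc oracle; and 2000-replicate null
simulations for the type-I error of the gated two-group test and the
ANOVA genotype factor.

## Known limitations

* Tb.Th carries a ≈ −1 px discretization bias from the even-width slab
  convention and a small downward pull from thin seam plates inside the
  primary band; both are shared by wild-type and mutant groups and cancel
  to first order in percent differences.
* CaMean of heavily quantized maps sits half a bin (0.085 wt%Ca) above
  the underlying continuous mean, since each gray level occupies the bin
  starting at its own value; the offset is common to all groups.
* Band detection assumes one transverse growth plate roughly perpendicular
  to the image columns; oblique sections should be rotated upstream.
* The automatic compartment segmentation (cortex by column fill, zones by
  band position) is tailored to longitudinal metaphyseal sections and is
  not a general-purpose bone segmenter.
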