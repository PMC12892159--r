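---
title: "Quantifying cochlear mosaic order: methods and design choices"
author: "cortiStar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cochlear mosaic order: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortiStar)
```

## The assay and its model

The organ of Corti packs its outer hair cells (OHCs) into three rows of
near-hexagonal, crystal-like order. `cortiStar` quantifies that order with a
nearest-neighbor angular statistic: for each focal cell of a chosen row, arms
are drawn to its six closest same-type neighbors; each arm's direction,
measured counter-clockwise from the longitudinal axis of the epithelium, is
assigned to one of 16 radial sectors of 22.5°; and the per-sample sector
occupancy frequencies form the profile that is plotted as a radar and
compared between genotypes. The statistic presumes only that cell centroids
are available in a locally flat 2D field in µm — the cochlear spiral is
treated as straight at the scale of one confocal image, and no curvature
correction is applied.

Two further analyses sit on top: per-sector two-sample t-tests on the
per-sample frequencies (unit of replication = cochlea), and cell density,
defined as count / epithelium length × 100 (cells per 100 µm), compared by
two-way fixed-effects ANOVA (genotype × region) with Tukey HSD contrasts of
genotype within region.

## Reference axis and sector numbering

A radial map needs an orientation, and mounting orientation varies between
images. Sector 1 therefore begins at the longitudinal axis direction, with
sectors numbered counter-clockwise; the axis is either supplied
(`axisMode = "given"`) or estimated as the principal axis (direction of
maximal variance) of the focal-row centroids. The estimated axis is defined
modulo 180°; because cell mosaics are approximately centro-symmetric, a
half-turn maps sector *s* to *s* + 8 and the occupied sector set onto itself,
so profiles are insensitive to the residual ambiguity. Co-rotating a mosaic
and a given axis leaves the profile exactly unchanged (up to arms lying
within floating-point distance of a sector boundary, which are absent for
generic data).

Sectors are half-open, [(s−1)·22.5°, s·22.5°): every angle maps to exactly
one sector, with boundary angles going to the higher-numbered sector (0° →
sector 1, 22.5° → sector 2, 359.9° → sector 16).

## Nearest neighbors, ties, edges, degeneracies

- Neighbor search is exhaustive Euclidean over the candidate set (cells of
  the focal row's type by default; `candidateTypes` widens this, e.g. to
  include ectopic hair cells). Ordering and ties are resolved by
  (distance, cell id) ascending — deterministic and checkable against a
  brute-force oracle; real digitized data essentially never ties.
- Edge handling defaults to `include`: every target-row cell with at least
  six candidates is a focal cell, which matches counting "a minimum of 10
  cells per sample" on small fields. `exclude_margin` instead drops focal
  cells within `margin` µm of the field's bounding box; with
  `margin = 0.6 d_c` on a noiseless lattice it isolates interior cells,
  whose stars are all identical.
- Coincident focal/neighbor coordinates raise an error rather than being
  dropped: they indicate a corrupted centroid table.
- At least `minFocalCells = 10` eligible focal cells are required per
  sample; fewer is an error reporting found vs required.

## The synthetic epithelium generator

The generator is the package's study-condition definition, not a fixture: it
builds an offset-row lattice (row *i*, column *j*: x = j·d_c + (i mod 2)·½·d_c,
y = i·d_r), removes each site independently with `missingRate`, inserts
ectopic cells (one candidate per column, midway between row 1 and the
pillar-cell position, included with `ectopicRate`), then jitters every cell
with isotropic Gaussian noise of sd `jitterSD`. All draws run under one
explicit seed with a fixed RNG, so identical configurations are bit-identical.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `nRows` | 3 | the three OHC rows |
| `cellsPerRow` | 20 | a plausible field of ~10–20 focal cells per row |
| `colSpacing` d_c | 8 µm | placeholder — embryonic inter-OHC spacing is not established; user-settable |
| `rowSpacing` d_r | d_c·√3/2 | makes the noiseless lattice hexagonal: six equidistant neighbors, the idealized control |
| `rowOffsetFraction` | 0.5 | offset-row (near-hexagonal) packing |
| control preset | jitter 0.05·d_c, no missing/ectopic | ordered control mosaic with the small residual variability real images show |
| `etv_tko` preset | jitter 0.25·d_c, missing 0.05, ectopic 0.1 | produces visibly disrupted profiles and a partial fourth row at n = 3 samples — calibrated to the qualitative knockout contrast, not measured from tissue |

What the generator does *not* emulate: cell-size and cell-shape variation,
the gradual base→apex maturation gradient within one field, curvature of the
cochlear duct, segmentation error structure of real images, and any
biological mechanism of patterning. Passing tests therefore demonstrate the
correctness and calibration of the *statistics* under controlled disorder,
not that real knockout tissue has these particular parameter values.

## Statistical choices

- **Sector tests.** Two-sided two-sample t-tests per sector on per-sample
  frequencies: pooled-variance Student by default, Welch by flag. Raw p
  drives the significance labels (`*` p < 0.05, `**` p < 0.01 —
  configurable), and Benjamini–Hochberg-adjusted p across the 16 sectors is
  always reported alongside, since the per-sector convention of radar-plot
  asterisks carries a multiplicity burden. Sectors with zero variance in
  both groups have an undefined t; they are flagged `degenerate`, reported
  not-significant, and never silently dropped.
- **Density ANOVA.** Fixed effects with interaction, type-II sums of squares
  (identical to the classical balanced decomposition on balanced designs),
  Tukey HSD on genotype-within-region contrasts. The design requires ≥ 2
  genotypes × ≥ 2 regions with ≥ 2 replicates per cell; all-zero
  within-cell variance is rejected as degenerate. Ectopic hair cells count
  toward OHC density by default (they are hair cells in the field), with an
  explicit `ectopicAs` switch.
- **Entropy.** Shannon entropy (base 2, 0·log 0 := 0) of the frequency
  vector summarizes disorder on a 0–4 bit scale for 16 sectors; the perfect
  lattice in interior view scores log₂ 6 ≈ 2.585 bits, and with edge cells
  included about 3.1–3.2 bits.

## Calibration results and their problem sizes

The test suite validates, on one CPU:

- the analytic six-sector profile of the noiseless lattice (15×3 cells);
- exact agreement of the k-NN search with a brute-force oracle on 200 random
  point sets (n ≤ 100) plus square-lattice tie cases;
- rigid-motion invariance over 10 random rotations and translations;
- arm conservation (Σcounts = 6·n_focal) and normalization over 500 random
  generator configurations;
- monotone non-decreasing mean entropy over jitter σ ∈ {0, 0.05, 0.1, 0.2,
  0.3}·d_c with 50 replicates per level;
- type-I calibration of the sector t-test over 2000 null experiments (3 vs 3
  samples from the identical disordered preset), pooled raw rejection rate
  within 0.05 ± 0.02;
- ≥ 80% of 100 simulated 3-vs-3 control-vs-knockout experiments detecting at
  least one significant sector;
- ANOVA F statistics equal to an explicit sums-of-squares oracle on all
  balanced designs up to 3 genotypes × 3 regions × 5 replicates;
- byte-identical end-to-end reruns of `simulate-experiment` under a fixed
  seed.

The null calibration deliberately draws both groups from the *disordered*
preset: it occupies all 16 sectors with continuous per-sample frequencies,
so every sector's test is exercised under conditions where the t-test's
assumptions approximately hold. Under the ordered control preset the
in-between sectors are empty or nearly so; their per-sample frequencies are
discrete, and the n = 3 t-test there is conservative (empirically ~0.02–0.03
pooled). This is a known small-sample property of t-tests on sparse
compositional data, worth remembering when reading radar asterisks for
sectors with tiny frequencies.

## Known limitations

- The statistic treats fields as locally straight; strongly curved apical
  whole-mount fields would need re-orientation or curvature correction
  upstream.
- With n = 3 samples per group, the Student t-test leans on approximate
  normality of per-sample frequencies; it is well calibrated for
  well-occupied sectors and conservative for sparse ones (see above).
- The epithelium length L is taken as digitized (or defaulted to the
  longitudinal extent of the field); no arc-length measurement along a
  curved row is attempted.
- Strong jitter can displace cells slightly beyond the nominal field length;
  the constructor warns rather than errors, keeping L as the imaged-field
  length.
- PROX1⁺ supporting-cell analysis reuses the same machinery with
  `targetRow = 4` and the appropriate candidate type; the choice of "fourth
  row" vs "second-most-lateral row" coincides for five rows but is the
  user's to set.
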