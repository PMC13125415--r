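# flashbp

Brass apertures for single-energy Bragg-peak (SEBP) proton FLASH
radiotherapy: an analytic, desk-scale model of how much a patient-specific
5 cm brass aperture sharpens the lateral 80–20% penumbra of a range-shifted
250 MeV scanned proton field, and what minimum-MU spot delivery implies for
per-voxel FLASH dose rates.

## The science in brief

SEBP FLASH delivers a single accelerator energy at very high beam current;
a PMMA universal range shifter (URS) pulls the pristine Bragg peak back by
10–30 cm of water-equivalent thickness and a range compensator tracks the
distal target surface. The price of all that upstream material is a badly
blurred lateral penumbra — the multiple-Coulomb-scattering angular spread
acquired in the URS drifts across the air gap and washes out the field
edge. A thick brass aperture placed after the URS truncates the scattered
fluence at the field edge and restores a sharp penumbra, at its sharpest
with small air gaps.

`flashbp` reproduces this mechanism with Fermi–Eyges transport (calibrated
differential Highland scattering power, a diverging 3.5 mm / 3 mrad source,
a degrader-halo and an in-phantom-halo term), a theta-resolved two-face
transmission model of the 5 cm absorber, a Bortfeld-style pristine peak,
minimum-MU (400 MU) spot-weight optimization, and a serpentine delivery
timeline with per-voxel average dose rate (ADR) and V40 Gy/s metrics. See
`vignette("flash-aperture-model")` for the model details and limitations.

## Worked example

One cell of the water-phantom study — a 3×3 cm² field at 30 cm pullback,
10 cm air gap, with and without the square aperture (field edge + 5 mm):

```r
library(flashbp)
cell <- sweep_cell_penumbra(field_size = 30, pullback = 300, air_gap = 100)
cell
#>   depth_pos      off        on reduction
#> 1  entrance 15.27717  7.206989  8.070177
#> 2       mid 17.41600  9.378061  8.037935
#> 3        bp 19.57686 11.583814  7.993043
```

The aperture takes ~8 mm off the penumbra at every depth of this cell. The
full 108-cell factorial (2 field sizes × 3 pullbacks × 3 air gaps × 3
depths × aperture on/off) runs in about 10 s:

```r
sweep <- run_water_sweep()
sweep_targets(sweep)   # the seven headline statistics, see below
```

The three-field head-phantom FLASH case (plan, normalize, dose-rate
metrics, aperture on vs off) runs in about 3 minutes:

```r
head <- run_head_case()
head$on$brain_dmean    # 2.62 Gy with apertures
head$off$brain_dmean   # 3.44 Gy without
```

A command-line front end wraps both plus single-field dose/ADR/metric
utilities:

```sh
Rscript inst/scripts/flashbp sweep --out results/ --seed 1
Rscript inst/scripts/flashbp headcase --thresholds 0,2,5 --out results/
```

## Headline results and agreement status

The seven headline statistics (depth/gap-averaged penumbras and
aperture-induced reductions, mm) against their reference values, tolerance
±1.5 mm:

| id | statistic | reference | flashbp | status |
|----|-----------|-----------|---------|--------|
| t1 | 3×3 penumbra, 10 cm pullback, no aperture (mean of 9) | 12.7 | 11.05 | **miss by 0.15** |
| t2 | 3×3 penumbra, 30 cm pullback, no aperture (mean of 9) | 16.5 | 17.39 | ok |
| t3 | 3×3 penumbra, 30 cm pullback, with aperture (mean of 9) | 7.9 | 9.41 | **miss by 0.01** |
| t4 | minimum reduction at 30 cm pullback (18 cells) | ≥ 7.7 | 7.03 | ok (≥ 6.2) |
| t5 | 3×3 reduction, 20 cm pullback, 5 cm gap | 4.0 | 5.04 | ok |
| t6 | 3×3 reduction, 30 cm pullback, 15 cm gap | 9.0 | 7.70 | ok |
| t7 | minimum with-aperture penumbra at 30 cm pullback | 4.7 | 4.16 | ok |

Honest deviations, deliberately not tuned away: t1 and t3 sit 0.15 mm and
0.01 mm outside their ±1.5 mm bands, and the t6 *companion trend* is
reversed — in this engine the 30 cm-pullback reduction decreases slightly
with air gap (8.19 → 8.03 → 7.70 mm) where the reference increases
(7.7 → 9.0 mm). The collimated and uncollimated halos re-diverge from the
aperture with nearly the same lever arm here, so the reduction cannot grow
with the drift; reproducing the increase would need an angular collimation
effect the thick-aperture acceptance model does not produce. The
corresponding blocks of `tests/testthat/test-acceptance.R` fail by design
rather than being skipped.

In the head case the apertures reduce brain mean dose (3.44 → 2.62 Gy),
brain V12 (6.21 → 4.88%) and brain V40 Gy/s at threshold 0 (19.8 → 16.0%),
while GTV V95 stays at 100% by normalization and GTV V40 is invariant
(100%) across per-field dose thresholds 0/2/5 Gy. The conformity comparison
is evaluated at the coverage isodose (0.95×Rx), the level the normalization
pins to the coldest GTV voxel: there the RTOG CI is ≥ 1 and lower means
strictly more conformal (1.029 with apertures vs 1.041 without), whereas at
Rx itself the plans do not fully cover the GTV by construction and the
ratio conflates coverage with spill.

## Reproduction

```sh
R CMD INSTALL .
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
Rscript -e 'testthat::test_dir("tests/testthat", package = "flashbp",
                               load_package = "installed")'
```

`scripts/acceptance.R` writes `{"t1": {"value": ..., "n": ...}, ...}` for
t1–t7 (the sweep is deterministic; the seed is accepted for interface
stability). The full test suite, including the 108-cell sweep and the head
case, runs in roughly 7 minutes on one CPU.
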