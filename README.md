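# bollmark

Detection and classification of stink bug puncture marks on cotton bolls
from LED-induced fluorescence photographs.

Stink bugs (*Nezara viridula* and relatives) pierce developing cotton bolls
with their proboscis to feed on the seeds. The standard way to assess
infestation is to crack bolls open — slow, destructive, and operator
dependent. Under blue LED excitation, intact boll tissue fluoresces red
(chlorophyll) while puncture-damaged tissue fluoresces green, so feeding
marks can be detected on the closed boll from a photograph. The catch is
that non-feeding damage also fluoresces green, so the image analysis has to
separate true puncture marks from look-alike false positives.

`bollmark` implements the full analysis chain for people working on optical
pest-damage screening:

1. **Ratiometric imaging** — center-weighted median filter, 2×2 binning
   (raw 36 px/mm → working 18 px/mm), boll mask from a
   Butterworth-blurred channel with a fixed threshold (black backdrop), and
   the masked pixel-wise G/R ratio image.
2. **Mark detection** — local-maximum filter (minimum peak distance 15 px,
   minimum prominence 10 counts over the mean in a 15-px disc) and
   segmentation with a greedy-snake active contour (32 vertices, energy
   `E = α Σ|vᵢ₊₁−vᵢ| + β Σ|vᵢ₊₁−2vᵢ+vᵢ₋₁| − γ Σ g(vᵢ)`).
3. **Mark filtering** — minimum area 28 px (0.09 mm²), minimum integrated
   intensity 0.04 mm⁻², aspect ratio ≤ 2, solidity ≥ 0.9.
4. **The donut statistic** — each mark's boundary is converted to its
   equal-area circle; `I2` is the mean ratio inside it and `I1` the mean
   inside a concentric 4-px circle. Punctures have a dark center
   (`I1/I2 < 1`); false positives are center-bright (`I1/I2 > 1`).
5. **Classification** — the rectangle criterion `A < 0.6 mm²` and
   `I1/I2 < 1.2`, contingency tables, and an ROC sweep over six rectangle
   corners on the diagonal through (0.6, 1.2).
6. **Statistics** — Kruskal–Wallis, Dunn's post test, Wilcoxon signed rank
   (α = 0.05).
7. **Synthetic data** — a scene generator (elliptical boll, donut-shaped
   punctures, center-bright false-positive blobs, needle marks) and a
   feature-table generator calibrated to the published group medians
   (area 0.35 / 0.6 / 0.27 mm², I1/I2 0.96 / 1.2 / 0.86 for
   infested / control / needle marks), so everything is testable without
   the original photographs, which were never deposited.

## Worked example

```r
library(bollmark)

# a synthetic boll photograph: two punctures and one false-positive blob
spec   <- random_scene_spec(n_tp = 2, n_fp = 1, seed = 42)
scene  <- generate_boll_image(spec)
report <- run_pipeline(list(boll = scene$image))
report
#> <run_report> 1 image(s), 15 mark(s), 2 positive; infested: TRUE

subset(report$marks, kept)[, c("area_mm2", "I1", "I2", "ratio", "positive")]
#>  area_mm2    I1    I2 ratio positive
#>     0.395 1.019 1.087 0.937     TRUE
#>     1.210 1.158 0.993 1.166    FALSE
#>     0.386 0.905 0.993 0.911     TRUE
```

Fifteen candidate peaks were found; twelve were noise candidates whose
snakes collapsed below the 28-px area floor and were rejected. The three
surviving marks match the planted ground truth (areas 0.414, 0.400,
1.345 mm²; I1/I2 0.911, 0.925, 1.190): the two punctures fall inside the
rectangle (area < 0.6 mm², ratio < 1.2) and classify positive, the large
center-bright blob falls outside on both axes and is (correctly) negative.

Classification and statistics work on any labeled mark table — here the
calibrated generator at the published group sizes (169 infested, 49
control):

```r
mt <- sample_mark_table(seed = 1)   # 169 infested / 49 control / 81 needle
contingency(mt)
#> Contingency table (A < 0.6 mm^2, I1/I2 < 1.2), n = 218
#> Percent of pooled total:
#>          area_pass area_fail ratio_pass ratio_fail both_pass both_fail
#> infested      76.1       1.4       60.1       17.4      59.2      18.3
#> control       12.8       9.6       12.8        9.6       7.3      15.1

roc_sweep(mt)      # six-corner rectangle sweep: sens 0.92 -> 0.35,
                   # spec 0.27 -> 0.96 from the largest to smallest rectangle

compare_groups(mt, "ratio")$medians
#> infested  control   needle
#>    0.984    1.142    0.855
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
BM=$(Rscript -e 'cat(system.file("exec", "bollmark", package = "bollmark"))')
Rscript $BM simulate --n-scenes 4 --n-tp 3 --seed 7 --out-dir scenes
Rscript $BM process scenes/scene_*.tif --out-dir run --save-intermediates
Rscript $BM simulate-table --out-dir tab
Rscript $BM classify tab/mark_table.csv --out-dir out
Rscript $BM roc tab/mark_table.csv --out-dir out
Rscript $BM stats tab/mark_table.csv --out-dir out
```

Configuration is a YAML file passed with `--config`; every threshold named
above is a key (see `pipeline_config()`), unknown keys are rejected, and the
MD5 of the configuration is recorded in every output artifact.

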