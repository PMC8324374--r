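# LeukoLobes

Counting white blood cells in a stained smear micrograph sounds like
counting connected blobs — until a neutrophil shows up. Neutrophil and
eosinophil nuclei are *polylobar*: split into 2–5 lobes that may be
joined by thin chromatin filaments, overlap each other, or appear
completely disconnected under the microscope. A naive count then reports
one cell as three, which skews the differential count that clinicians
read. LeukoLobes implements a morphology-based pipeline that segments
leukocyte nuclei, recognises when separate regions are lobes of one
nucleus, re-joins them, and counts cells correctly.

## Method

For an RGB micrograph of a Wright-stained smear:

1. **Channel difference.** Nuclei (and platelets) stain blue-purple, so
   their blue channel exceeds their green channel; background and
   erythrocytes have `B ≈ G`. The image `clamp(B − G, 0, 255)` carries
   nuclei and platelets as the bright class.
2. **Otsu threshold.** The gray level `T1` maximising the between-class
   variance `ω₀ω₁(μ₀ − μ₁)²` binarizes the difference image.
3. **Area filter.** Every platelet is far smaller than any nucleus, so
   connected regions with area `< S` are dropped (`S` defaults to 150 px
   and can be calibrated as the minimum training-nucleus area).
4. **Shape cascade.** Each remaining region gets five descriptors —
   area `A`, bounding-box plumpness `P1 = A/(a1·b1)`, aspect ratio
   `s = b1/a1`, moment-ellipse plumpness `P2 = A/(π·a2·b2)` and
   eccentricity `e = √(a2² − b2²)/a2` — and is flagged as a polylobar
   candidate when `e > X1 ∧ P2 < X2`, else `P1 < X3 ∧ s < X4`, else
   `A < X5`.
5. **Minimal-distance merge.** The nearest pair of Canny edge pixels
   between a candidate and its closest region is bridged and the result
   filled, provided the gap is within a distance cap, the partner is
   itself a candidate (unilobar nuclei are never absorbed) and the
   merged area stays plausible for one nucleus. Features and verdicts
   are recomputed after every merge; the loop repeats until nothing
   changes.
6. **Count.** The leukocyte count `T` is the number of regions after
   merging, with polylobar/unilobar tallies and optional per-type
   counters `T_N, T_E, T_B, T_M, T_L`.

Because no image corpus is distributed with this method, the package
ships a synthetic smear generator with exact ground truth (light
background, pink erythrocytes invisible to `B − G`, platelets, and
nuclei in all three connection modes), including presets for the four
scene archetypes that historically cause miscounts and a
differential-mix dataset builder for evaluation.

## Worked example

```r
library(LeukoLobes)

spec <- casePreset(1, seed = 7)   # one 3-lobed nucleus, lobes disconnected
res  <- analyzeSmear(spec)
res
#> SmearAnalysis: 256 x 256 px, Otsu threshold 10
#>   regions: 3 before merging, 1 after
#> CountReport: T = 1 (1 polylobar, 0 unilobar)

round(shapeTable(res)[, c("label", "A", "P1", "s", "P2", "e")], 3)
#>   label   A    P1     s    P2     e
#> 1     1 201 0.785 1.000 1.000 0.133
#> 2     2 217 0.798 0.941 1.001 0.257
#> 3     3 225 0.779 1.000 1.000 0.163

lobeDecisions(res)
#>   label   verdict      rule
#> 1     1 polylobar rule2_ecc
```

The three pre-merge regions are the lobes: disk-like (`P1 ≈ π/4`,
`P2 ≈ 1`, low `e`) but individually too small to be whole nuclei, so the
cascade flags them and the minimal-distance rule joins them; the final
single region is counted once. `totalCount(countReport(res))` returns
`1`. The same call on `casePreset(2, ...)` (two nearby unilobar cells)
returns 2 with zero merges.

A shell interface wraps the same functions:

```sh
Rscript inst/cli/leukolobes synth --case 1 --seed 7 --out-dir scene
Rscript inst/cli/leukolobes count scene/img_001.png
Rscript inst/cli/leukolobes evaluate --dir scene
```

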