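# fins — Fluorescence Imaging of Nuclear Staining

Automated per-nucleus counting of immunofluorescently stained nuclear
proteins in multi-channel microscopy images of cultured cells. Typical use:
you have DAPI + Ki67 + γH2AX images from a coverslip experiment and want,
per image, the number of nuclei and the number of nuclei positive for each
marker — reproducibly, without manual counting.

## Method

Nuclear regions are computed from the counterstain channel
`z_δ(x) ∈ [0,1]` by minimising the convex relaxation of a two-phase
segmentation energy,

    min_{u ∈ [0,1]}  ∫ |∇u| dx + λ ∫ f(x) u(x) dx ,    f(x) = t_δ − z_δ(x),

where `t_δ` is a 256-bin Otsu threshold and `λ = 20`. The total-variation
term removes noise and speckle that defeat plain thresholding, while the
global minimiser is still essentially binary; binarizing at `β = 0.5` gives
the foreground `Ω_D`, whose 8-connected components `Ω_D^i` are the nuclei.
Each marker channel gets one global Otsu threshold floored at `t_f = 0.1`;
nucleus `i` is positive for a marker iff any of its pixels strictly exceeds
that threshold. The energy is minimised by Split Bregman iteration
(Gauss–Seidel u-step with clipping, vector shrinkage, Bregman update),
implemented in C++.

The package also provides the validation metrics used to compare automated
counts with a panel of human raters (centroid distances, percentage
concordance, percent-over-range), a synthetic multi-channel image generator
with known ground truth, and a batch driver with timestamped CSV output and
review overlays. See `vignettes/fins-methods.Rmd` for assumptions, numerical
choices and limitations.

## Worked example

```r
library(fins)

fx  <- generate_fixture(fixture_spec(n_nuclei = 10, seed = 42))  # known truth
res <- fins(fx$channels, image_name = "demo")
res
#> FINS counts for 'demo'
#>   nuclei (counterstain): 10
#>   Ki67 positive: 4 / 10
#>   gH2AX positive: 6 / 10
summary(res)
#> FINS analysis of 'demo'
#>   counterstain threshold t = 0.3730; 10 nuclei
#>   Ki67: 4 positive (t = 0.4082)
#>   gH2AX: 6 positive (t = 0.4121)
#>   solver: 35 iterations, converged; energy -15307.6701; 0.13% non-binary pixels
as.data.frame(res)
#>   image_name DAPI Ki67 gH2AX
#> 1       demo   10    4     6
```

The fixture's ground truth (`fx$truth$positive_ids`) has exactly 4
Ki67-positive and 6 γH2AX-positive nuclei — the counts above are exact
recoveries, and the per-nucleus ids match. `plot(res)` shows the review
overlay (white nuclear regions, red/green contours around positive nuclei).

Batch processing from R:

```r
mapping <- channel_mapping(counterstain = 3, markers = c(Ki67 = 1, gH2AX = 2))
run_batch("images/", "results/", mapping)   # CSV + overlays + log
```

or from the shell via the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fins_count.R", package = "fins"))')" \
    count images/ --out results/ --dapi-channel 3 --marker Ki67:1,gH2AX:2
```

Comparing algorithm counts with human raters:

```r
sets <- read_rater_counts("raters.csv", marker_channel = "Ki67")
percentage_concordance(sets)                 # algorithm vs all raters
percentage_concordance(sets, leave_out = "R1")  # rater R1 vs the rest
percent_over_range(62, c(55, 51, 54, 51, 39))   # 12.73 (% above the range)
```

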