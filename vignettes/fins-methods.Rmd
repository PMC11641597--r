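---
title: "Counting stained nuclei with convex TV segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting stained nuclei with convex TV segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fins)
```

## The problem

Immunofluorescence experiments on cultured cells routinely ask a binary
question per cell: does this nucleus contain signal for a nuclear protein of
interest (Ki67 for proliferation, phosphorylated H2AX for a DNA damage-repair
response)? The readout is a pair of counts per image — nuclei in the
counterstain (DAPI) channel, and nuclei containing any supra-threshold marker
signal. Manual counting is slow and subjective; this package automates it
while deliberately mimicking what a careful human counter does: threshold the
counterstain, but regularise away noise before counting, then look for marker
signal only *inside* counted nuclei.

## The segmentation model

All channels are normalised to $[0,1]$ (integer data by dtype full scale, see
"Design choices"). Write $z_\delta(x)$ for the counterstain intensity on the
image domain $\Omega$. A global threshold $t_\delta$ is chosen by Otsu's
method (256-bin histogram, intra-class variance minimised). Rather than using
the raw threshold set $\{z_\delta > t_\delta\}$, the nuclear foreground is the
minimiser of the convex two-phase segmentation energy

$$\min_{u \in [0,1]} \int_\Omega |\nabla u|\,dx
  \;+\; \lambda \int_\Omega f(x)\,u(x)\,dx,
  \qquad f(x) = t_\delta - z_\delta(x).$$

The total-variation term charges interface length, so isolated bright pixels
and ragged noise are smoothed away; the fidelity term pulls $u$ towards 1
where the image exceeds the threshold and towards 0 elsewhere. An edge
weight on the TV term is supported in principle but fixed to 1: edges are not
well defined in this image class. Because the binary constraint $u \in
\{0,1\}$ is relaxed to the interval, the problem is convex and a global
minimiser $u^*$ is computable; $u^*$ is approximately binary, and
thresholding it at any level $\beta \in (0,1)$ yields a minimiser of the
original binary problem. The foreground is $\Omega_D = \{u^* > \beta\}$,
and its connected components $\Omega_D^1,\dots,\Omega_D^n$ are the nuclei.

Marker channels are then scored per nucleus: a single global Otsu threshold
$t_\chi$ is computed on the whole marker channel, floored at $t_f = 0.1$, and
nucleus $i$ is positive when $z_\chi(x) > t_\chi$ (strictly) for *any*
$x \in \Omega_D^i$. Focus multiplicity is deliberately not quantified; the
count is presence/absence, bounded by $n$.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `lambda` | 20 | fidelity weight; large enough that nucleus-sized regions are kept intact (fidelity scales with area, interface cost with perimeter), small enough that single-pixel impulses cost more interface than they pay in fidelity |
| `beta` | 0.5 | binarization level on $u^*$; the solution is near-binary so the choice is immaterial in effect (see "Numerical behaviour") |
| `mu` | 1 | Split Bregman penalty weight; affects the iteration path, not the minimiser |
| `tol` | 1e-4 | relative-change stopping rule $\|u_{k+1}-u_k\|/\|u_k\|$ |
| `max_iter` | 200 | iteration cap; hitting it is reported (`converged = FALSE`), never an error |
| `min_area` | 0 (off) | optional small-component filter. Off by default: small debris is tolerated and left to reviewer judgement, because stringency that removes debris also removes condensed mitotic nuclei |
| `connectivity` | 8 | merges corner-touching fragments of one nucleus |
| marker floor | 0.1 | lower bound on every marker threshold, never applied to the counterstain; makes blank or histogram-degenerate marker channels count zero (positivity needs intensity *strictly above* the floor) |

## The solver

The minimiser is computed by Split Bregman iteration with an auxiliary field
$d \approx \nabla u$ and Bregman variable $b$:

1. **u-step** — one Gauss–Seidel sweep of
   $\mu \Delta u = \lambda f + \mu\,\mathrm{div}(d - b)$,
   followed by clipping $u$ into $[0,1]$;
2. **d-step** — vector shrinkage
   $d = \max(|g| - 1/\mu, 0)\, g/|g|$ with $g = \nabla u + b$;
3. **b-step** — $b \leftarrow b + \nabla u - d$.

Discretisation: forward differences with replicate (Neumann) boundary,
isotropic gradient magnitude $\sqrt{u_x^2 + u_y^2}$; the divergence is the
negative adjoint of the gradient (backward differences). The solver starts at
the indicator of $\{f < 0\}$ — the raw thresholded image — which is close to
the minimiser and saves iterations; the converged labelling is independent of
the start (this is tested by also starting from all-zeros). The discrete
energy at the solution never exceeds the energy of the initial labelling
(asserted to within $10^{-9}$ relative slack in the tests).

## Numerical behaviour worth knowing

* **Near-binariness.** The solver reports the fraction of pixels with
  $u^* \in (0.05, 0.95)$; on the synthetic suite it is on the order of
  0.1%. On noiseless piecewise-constant images the solution is exactly
  binary and $\Omega_D$ coincides with the raw threshold set
  $\{z_\delta > t_\delta\}$ pixel for pixel — the regulariser only matters
  when there is something to regularise.
* **Fractional pixels under noise.** Where noise puts pixels essentially on
  the threshold at a region interface, the relaxed minimiser can be genuinely
  fractional: by the co-area argument every threshold of $u^*$ is an optimal
  binary solution, but different levels may pick different (equally optimal)
  boundary pixels. Binarization levels 0.25/0.5/0.75 therefore agree exactly
  on noiseless fields, while under noise they may differ on a handful of
  interface pixels — never changing the nucleus count in the test suite. This
  is a property of the relaxation, not of the iteration: it persists at any
  stopping tolerance.
* **Otsu plateaus.** For a cleanly bimodal histogram the between-class
  variance is constant across the empty bins between the modes; the
  implementation (EBImage's) returns the plateau midpoint, so thresholds land
  mid-gap rather than hugging one mode. A constant image has no two-class
  split: the counterstain path signals a classed degenerate-histogram
  condition (the batch driver records a zero-count row and flags the image in
  the log); marker channels fall back to the floor.
* **Stopping.** `tol = 1e-4` with one Gauss–Seidel sweep per outer iteration
  converges in 20–130 iterations on 256²–1024² synthetic fields; a
  1024×1024 three-channel image processes in a few seconds on one CPU
  (measured, not contractual — see the acceptance script's
  `seconds_per_1024px_image`).

## Design choices

* **Normalisation by dtype full scale.** Integer images are divided by
  $2^b - 1$, *not* min-max rescaled: the marker floor 0.1 is only meaningful
  on an absolute scale tied to acquisition gain/exposure. Per-image min-max
  would force every image to reach 1.0 and silently change what the floor
  means. Real-valued input already in $[0,1]$ passes through; real input
  outside it is min-max rescaled as a last resort.
* **Floor semantics.** The floor is applied unconditionally as
  $t_\chi \leftarrow \max(t_\chi^{\mathrm{Otsu}}, 0.1)$, per marker channel,
  never to the counterstain. This is the most conservative reading of "when
  Otsu does not provide an adequate threshold": an adequate Otsu value is
  above the floor and unaffected; an inadequate one is replaced by it.
* **Strict positivity.** Positivity requires $z > t$ strictly, so an
  all-background channel (everything at or below the floor) counts zero.
* **No border exclusion, no default size filter.** Nuclei cropped by the
  image border are counted when they exceed threshold, matching how the
  method behaves on real data; whether to count them is left to review.
* **Review overlays instead of a GUI.** Each processed image can be rendered
  as a white-on-black region mask with one contour colour per marker around
  positive nuclei — the static equivalent of an interactive review window.
* **Concordance asymmetry.** The concordance metric compares a counter
  against the centroid of the *other* raters; the algorithm is compared
  against all raters while a left-out rater is compared against one fewer.
  This asymmetry slightly flatters the algorithm and is reproduced
  deliberately, not corrected. Ties at the maximum distance count as
  non-concordant under the strict "below the maximum" rule.

## What the synthetic generator does and does not emulate

The generator renders fields of non-overlapping elliptical nuclei with
heterogeneous sizes (7–14 px semi-axes by default, eccentricity up to 0.7,
per-nucleus brightness ±8%), smooth cosine-taper edges, dim background
(0.05), additive Gaussian noise, moderate-contrast impulse speckle on the
counterstain, sub-threshold cell detritus, and optionally border-cropped
nuclei. Marker channels carry punctate foci planted strictly inside a known
subset of nuclei: broad regions for Ki67 (3 foci of radius 6 at intensity
0.85), many small foci for gamma-H2AX (8 of radius 3). These masses are
chosen so the marker Otsu threshold sits between the focus and background
modes — well above the 0.1 floor — across the modelled noise range
($\sigma \le 0.05$); with vanishingly sparse foreground, Otsu's criterion
would collapse into the background mode, which is a property of Otsu, not of
the counting rule. Speckle impulses are drawn 0.35–0.45 above background:
bright enough that plain thresholding counts them as spurious objects, while
their single-pixel fidelity gain $\lambda|f|$ stays below the interface cost
$2+\sqrt{2}$ of an isolated pixel, so the TV energy removes them — this is
precisely the regime in which regularised segmentation improves on plain
thresholding, and the suite asserts that improvement fixture by fixture.

Not emulated: overlapping post-mitotic nuclei (the method itself merges
touching nuclei — simulating them would only re-assert a known limitation),
optical point-spread, vignetting, chromatic shift, and supra-threshold
autofluorescence artefacts in marker channels. Passing tests on these
fixtures therefore demonstrate correctness of the algorithmic pipeline under
controlled conditions, not robustness to every pathology of real microscopy.

Problem sizes used by the test and acceptance suites: 20 noiseless fields
(256²–adaptive, 5–60 nuclei), 15 noisy fields (256², 12 nuclei, 5 replicates
at $\sigma \in \{0.01, 0.03, 0.05\}$), and one 1024×1024 three-channel field
with 120 nuclei.

## Known limitations

* Touching or overlapping nuclei merge into one component (no watershed or
  shape prior); condensed doublets undercount.
* One global threshold per marker channel: strong spatially varying
  autofluorescence can defeat it — review overlays exist for exactly that
  case.
* LIF containers are not read; acquisitions must be exported to TIFF/OME-TIFF
  (multi-plane grayscale, 8/12/16-bit).
* The concordance metrics require at least two raters after any leave-out and
  are undefined below a rater count of zero maximum (percent-over-range
  against an all-zero range is refused).
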