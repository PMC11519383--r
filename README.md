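# fibralign

Collagen fiber alignment and wound-healing kinetics from Masson's trichrome
histology.

Scarring and fibrosis reorganise dermal collagen from a near-random
basket-weave into parallel bundles. `fibralign` quantifies that organisation
from ordinary RGB images of trichrome-stained sections, and pairs the image
metrics with wound-closure kinetics and group statistics, for studies that
compare matched biopsy sites (e.g. previously irradiated vs non-irradiated
skin of the same donor) or track healing over days.

## What it computes

**Image chain** (per section):

1. sRGB → CIELAB (standard D65 conversion). Aniline-blue collagen has
   strongly negative b\*; red cytoplasm has positive a\*.
2. Collagen isolation: the a\* channel superimposed onto the rectified
   negative b\* channel, `C = max(a* + max(−b*, 0), 0)` (two alternative
   modes are configurable).
3. Enhancement: Gaussian smoothing, 1st/99th-percentile contrast stretch,
   and a zero floor so background pixels are exactly 0.
4. Fourier-domain orientation analysis: Hann-windowed 2-D FFT, power
   accumulated into 180 orientation bins over [0, π) within a radial
   frequency band. The **alignment coefficient** is the energy-weighted
   circular resultant on doubled angles,

   R = |Σₖ Eₖ e^(2iθₖ)| / Σₖ Eₖ ∈ [0, 1],

   0 for a random fiber distribution, 1 for perfect alignment, plus the
   dominant orientation θ̂ = ½ Arg Σₖ Eₖ e^(2iθₖ) and the **density**
   (fraction of non-zero enhanced pixels).

**Kinetics**: wound contraction `(IW_D0 − IW_t)/IW_D0 × 100%`, wound closure
`A_t/A_D0 × 100%`, and one-phase decay fits
`Y(t) = plateau + (Y0 − plateau)·e^(−kt)` (bounded Levenberg–Marquardt, with
half-life ln2/k).

**Statistics**: paired two-tailed t-tests between matched sites and Pearson
correlation of any metric with months since radiotherapy.

**Simulator**: trichrome-like fiber fields with axial von Mises orientations
and known ground truth, and noisy exponential wound-closure series — every
stage is testable without any external data.

## Worked example

```r
library(fibralign)

# a simulated section: 300 fibers concentrated around 60 degrees
params <- fiber_field_params(kappa = 20, mean_orientation = pi/3, seed = 42)
sim <- generate_fiber_image(params)

analyze_image(sim$image)
#> alignment coefficient: 0.934
#> dominant orientation:  59.6 deg
#> collagen density:      0.515  (262144 pixels)

true_alignment(sim$truth$orientations)  # ground truth of the sampled angles
#> 0.974
```

The coefficient (0.934) tracks the ground-truth circular resultant of the
sampled fiber angles (0.974); the dominant orientation recovers the 60° mean
axis; about half the canvas is covered by fibrous signal.

```r
# a healing curve: days 0-5, Y0 = 10, plateau = 2, k = 0.8/day, 2% noise
ws <- generate_wound_series(wound_series_params(seed = 42))
fit_one_phase_decay(ws)
#> one-phase decay fit (area, n = 6)
#>   Y0 = 10.25, plateau = 2.121, k = 0.8505 /day (half-life 0.815 days)
#>   rss = 0.04221, converged: TRUE

wound_contraction(ws$area[6], ws$area[1])  # day-5 contraction
#> 79.3
```

Batches run from a CSV manifest (`path, donor, group, months_since_rt`):

```r
run <- run_pipeline("manifest.csv", pipeline_config())
run$results  # per-image coefficient / orientation / density + config hash
run$stats    # paired t-tests and Pearson correlations the manifest supports
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/fibralign simulate --out img.png --truth truth.json --kappa 8 --seed 1
Rscript inst/cli/fibralign analyze --in img.png --out result.json
Rscript inst/cli/fibralign batch --manifest manifest.csv --out results.csv
Rscript inst/cli/fibralign kinetics --in series.csv --out fits.csv
```

See `vignettes/fibralign-methods.Rmd` for the model, parameter defaults, and
numerical choices.

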