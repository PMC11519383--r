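---
title: "Quantifying collagen alignment and wound-healing kinetics with fibralign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collagen alignment and wound-healing kinetics with fibralign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibralign)
```

## The measurement problem

Dermal scarring reorganises collagen: healthy reticular dermis shows a
basket-weave of fibers in near-random orientations, while fibrotic or scarred
tissue shows bundles running in parallel. On Masson's trichrome sections the
collagen is stained aniline blue, which makes its organisation measurable from
ordinary brightfield RGB images. `fibralign` reduces each section to three
numbers — an alignment coefficient in $[0,1]$, a dominant fiber orientation,
and a collagen area-density fraction — and provides companion tools for
wound-closure kinetics and group statistics, so that a batch of
irradiated/non-irradiated (RT$^+$/RT$^-$) biopsy pairs can be processed into
per-donor comparisons in one pass.

## The image-analysis chain

### 1. Colour: isolating the collagen stain in CIELAB

RGB values are converted to CIELAB (standard sRGB companding, D65 white
point). The conversion is implemented directly from the standard — the same
matrices and white point used by the reference colorimetric libraries — so
that channel thresholds are portable. In CIELAB, $a^*$ is the green–red
opponent axis and $b^*$ the blue–yellow axis; aniline-blue collagen carries
strongly negative $b^*$, red cytoplasm carries positive $a^*$, and the pale
section background is near-neutral in both.

The collagen intensity map superimposes the full $a^*$ channel onto the
rectified negative $b^*$ channel by pixel-wise addition:

$$C(x) = \max\bigl(a^*(x) + \max(-b^*(x), 0),\ 0\bigr).$$

This is the default `a_plus_negb` mode; it reads "superimposed onto" as
addition, the most literal arithmetic. Because the phrase admits other
readings, two alternatives are selectable through the configuration:
`negb_only` ($\max(-b^*,0)$, blueness alone) and `negb_minus_posa`
($\max(\max(-b^*,0)-\max(a^*,0),0)$, blueness penalised by redness, which
suppresses red cytoplasm). All three are monotone in blueness at fixed $a^*$
and map neutral background to zero, which is the property the rest of the
chain relies on.

### 2. Enhancement: a grayscale map with an exact-zero background

The collagen map is Gaussian-smoothed ($\sigma = 1$ px by default), linearly
stretched so the 1st/99th percentiles map to 0/1 (clipped), and finally
floored: values below `zero_floor = 0.1` are set to exactly zero. The exact
zeros are not cosmetic — the density metric is *the fraction of the image
with non-zero pixel values*, so enhancement must decide which pixels count
as background. The floor of 0.1 (10% of the stretched range) removes
residual background texture while leaving anti-aliased fiber edges intact;
a constant input has no contrast to stretch and maps to an all-zero image,
which downstream stages report as degenerate rather than silently analysing
noise.

### 3. Fourier domain: the alignment coefficient

A field of co-oriented fibers concentrates its spectral power along the axis
*perpendicular* to the fiber direction. The enhanced image is center-cropped
to the largest square, mean-subtracted, tapered with a 2-D Hann window
(suppressing edge-discontinuity leakage), and transformed with a 2-D FFT.
The power $|F|^2$ at spatial frequencies with radius $r \in [r_{\min},
r_{\max}]$ cycles/pixel is accumulated into 180 orientation bins over
$[0, \pi)$ after folding modulo $\pi$ and rotating by $90°$ into the spatial
fiber convention (counterclockwise from the image $x$-axis). Defaults
$r_{\min} = 0.05$, $r_{\max} = 0.45$ (Nyquist is $0.5$) exclude
illumination-scale gradients below and pixel-scale noise at the extreme
corner frequencies above; both bounds and the bin count are configurable.

Fibers are undirected axes — $\theta$ and $\theta + \pi$ are the same fiber —
so the angular energy distribution $E(\theta_k)$ is summarised with the
standard *axial* (doubled-angle) statistic, the energy-weighted circular
resultant length:

$$R \;=\; \frac{\bigl|\sum_k E_k\, e^{\,2i\theta_k}\bigr|}{\sum_k E_k}.$$

This is the unique standard dispersion statistic whose extremes match the
metric's stated calibration exactly: $R = 0$ for uniform energy over evenly
spaced bins (a random fiber distribution; the doubled bin angles cancel by
symmetry) and $R = 1$ when all energy lies in a single bin (perfect
alignment). The dominant orientation is the halved argument of the same
resultant, $\hat\theta = \tfrac{1}{2}\operatorname{Arg}\sum_k E_k
e^{2i\theta_k} \bmod \pi$; when opposing axes balance exactly the resultant
vanishes and the orientation is reported as undefined.

The coefficient is computed once per image (a single global index per
section); tiled or per-region maps are out of scope.

### 4. Density

`fiber_density()` is simply `mean(values > 0)` on the enhanced image: the
pixel-area fraction of fibrous signal. It is exact by construction given the
enhancement output, and monotone under union of fibrous signal.

## The synthetic fiber-field generator

There is no deposited image set to validate against, so the package carries
its own simulator with known ground truth. `generate_fiber_image()` draws
straight anti-aliased segments (sub-pixel endpoints; a linear one-pixel
coverage ramp at the edges avoids the axis-aligned raster artifacts that
would otherwise bias the spectrum) with centres uniform in the frame.
Orientations are axial von Mises: $\varphi_j \sim \mathrm{vM}(2\mu, \kappa)$
on the doubled angle, $\theta_j = (\varphi_j/2) \bmod \pi$, so $\kappa = 0$
is isotropic and large $\kappa$ is near-perfect alignment. Fibers are
composited in a trichrome-like blue (default sRGB (60, 90, 200), $b^*
\approx -61$) over a pale background ((240, 238, 242), $|a^*|, |b^*| < 2$),
optionally with red cytoplasm-like disks ((200, 60, 80), positive $a^*$),
then clipped Gaussian noise is added and the raster quantised to 8 bits.
Colours are validated at construction against the CIELAB contract the
isolation stage assumes. All randomness flows from one seed; identical
parameters give byte-identical images.

Default study conditions, chosen once as a realistic desk-scale section:
512$^2$ canvas, 300 fibers of length 120 px (about a quarter of the frame)
and width 3 px, additive noise SD 3 on the 8-bit scale. The ground truth of
a simulated field is the circular resultant of the *sampled* angles,
`true_alignment()` = $|\tfrac1n \sum_j e^{2i\theta_j}|$, the brute-force
oracle the image-based coefficient is tested against: across a $\kappa$
sweep from 0 to 100 the pipeline coefficient must track this oracle within
0.1 on average and rank-monotonically in $\kappa$.

What the simulator does *not* emulate: nuclei and stain texture, fiber
curvature, varying section thickness or illumination fields, polarised-light
effects. Passing tests therefore demonstrate that the measurement chain
recovers known orientation structure from trichrome-like colour contrast;
they do not certify performance on degraded or atypically stained real
sections, where the configurable isolation modes and radial band exist to be
adjusted.

## Wound-healing kinetics

Wound areas are taken as measured (segmentation is out of scope). Two
percentage conventions are provided and kept distinct:

* **contraction**: $(IW_{D0} - IW_t)/IW_{D0} \times 100$, the shrinkage of
  the area enclosed by the initial wound edge — 0% at day 0, +100% at full
  closure ($\Delta$ is taken as shrinkage from baseline so contraction
  grows over the healing course);
* **closure**: $A_t/A_{D0} \times 100$, the open area relative to day 0 —
  100% at baseline, falling toward 0%.

For the same area series the two sum to 100%.

Healing curves are fitted with the one-phase decay model
$Y(t) = \text{plateau} + (Y_0 - \text{plateau})\,e^{-kt}$ by bounded
Levenberg–Marquardt least squares ($k \ge 0$, plateau $\ge 0$; tolerance
$10^{-8}$ on the parameters). Fits on half a dozen points are sensitive to
starting values, so initialisation is deterministic: $Y_0$ from the first
observation, plateau from the minimum, $k$ from the slope of a log-linear
regression of $Y - 0.99\,\text{plateau}_\text{init}$ on time. Because it is
not stated whether such fits operate on the raw area or on a percentage,
both are supported: `fit_variable = "area"` (default) and
`"contraction_complement"` (the percentage of baseline area still open,
which rescales $Y_0$ to 100 and leaves $k$ unchanged). A failed optimisation
falls back to a bounded quasi-Newton pass and reports `converged = FALSE`
with the best iterate rather than raising. The simulated default series
mirrors a 6-day ex vivo course: days 0–5, $Y_0 = 10$, plateau 2, $k = 0.8$
per day, measurement noise SD 0.2 (2% of $Y_0$).

## Group statistics

The reporting layer mirrors how such measurements are compared in practice:
a classical two-tailed paired t-test for matched RT$^+$/RT$^-$ sites of the
same donor, and a two-tailed Pearson correlation (p-value from the t
transform) of any metric against months since radiotherapy. No
multiple-testing correction is applied across these few planned
comparisons. Degenerate inputs have explicit contracts: an all-zero
difference vector returns a zero statistic with an undefined p-value; a
non-zero constant difference has no valid t statistic and errors; constant
vectors make the correlation undefined and error.

## Configuration, batching and provenance

`pipeline_config()` gathers every tunable — isolation mode, stretch
percentiles, smoothing $\sigma$, zero floor, radial band, bin count, fit
variable, seed — validates ranges, and rejects unknown keys so typos never
fall back silently to defaults. Configurations load from JSON
(`read_config()`); JSON was chosen as the on-disk format because a TOML
parser is not part of the package's dependency set, and the CLI additionally
accepts YAML when the `yaml` package is available. Every output row carries
a hash of the full configuration, so any two result tables computed under
different settings are distinguishable after the fact. `run_pipeline()`
processes a CSV manifest image by image, records row-level errors without
stopping the batch (a malformed manifest aborts), and is order-invariant:
no state crosses images.

A thin command-line front end (`inst/cli/fibralign`; commands `simulate`,
`analyze`, `batch`, `kinetics`, `compare`) wraps these functions for shell
use; the R functions are the primary interface.

## Numerical choices and edge cases

* **Evenly spaced bins**: for $n$ evenly spaced bins over $[0,\pi)$ the
  doubled angles are evenly spaced over $[0, 2\pi)$ and
  $\sum_k e^{2i\theta_k} = 0$ analytically; floating point leaves a residual
  of order $10^{-16}$, so "exactly 0" is met to machine precision.
* **Ties in the dominant orientation**: the halved argument maps the
  resultant into $[0, \pi)$; an exactly balanced spectrum (resultant length
  below $10^{-9}$) errors rather than returning an arbitrary angle.
* **Non-square images** are center-cropped to the largest square before the
  FFT so both axes share one frequency resolution; rectangular analysis
  would bias the angular binning.
* **Bit depths**: 16-bit input is rescaled to the 8-bit range before colour
  conversion, so Lab-space thresholds are calibrated once.
* **Degenerate inputs** (blank images, constant maps, zero-variance tests,
  too-few timepoints) raise typed errors early, with the failing stage named
  when the full chain is run.

## Scale of the validation suites

The test and acceptance suites run the generator at its default 512$^2$
study scale for the $\kappa$-sweep oracle comparison (8 concentration levels
$\times$ 10 seeds) and rotation checks, and at 160–256 px for unit-level
properties; decay-fit recovery uses 50 simulated series at 2% noise. These
sizes were chosen as the smallest at which the Fourier statistics are stable
(spectral angular resolution scales with fiber length in pixels), and they
keep a full run to a few minutes on one core.

## Known limitations

* The alignment coefficient is a global index; spatially heterogeneous
  sections (scar adjacent to normal dermis) are averaged, not mapped.
* The channel superimposition assumes trichrome-like staining; it is not a
  stain-deconvolution method and no illumination-field correction is
  applied.
* The decay fit treats each series independently; donor-level random
  effects across series are out of scope.
* Simulated fibers are straight; strongly curved collagen would spread the
  spectrum and lower the coefficient relative to a tracing-based method.
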