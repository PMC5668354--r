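---
title: "Models and methods behind mitomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomech)
```

# The physical model

`mitomech` analyzes single mitotic cells rounding against plate confinement:
a tipless AFM cantilever held at a preset height `h_set` above a glass dish,
with the cell squeezed between the two. The cell is treated as a cortical
shell around a liquid core. Under that idealization the confined shape is a
cylinder capped by a rim whose side profile is a half-circle of radius
`r = h/2`, and the Young–Laplace relation makes the excess intracellular
pressure equal to the confining force divided by the flat contact area.

The measured inputs per cell are the equilibrium rounding force `F_eq` (from
the force trace) and the midplane cross-sectional area `A_m` (from the
image). Everything else is geometry:

* `r_m = sqrt(A_m / pi)` — midplane radius.
* `h = h_set + F/k (+ tan(tilt) (r_m + x))` — the true height at the cell
  axis. The `F/k` term undoes the cantilever's own deflection (`k` in N/m);
  the tilt term accounts for the lever being mounted at an angle (10° on
  the rigs this assay was developed for), so the lever sits higher over the
  cell center than at its tip, `x` being the tip-to-cell-edge distance.
  Wedged levers carry a polymer wedge cancelling the tilt; for them the
  tilt term is dropped.
* `r_c = r_m − h/2`, `A_c = pi r_c^2` — contact radius and area.
* `P = F_eq / A_c` — rounding pressure.
* `V = pi h r_c^2 + 2 pi (r_c + 4r/(3pi)) (pi r^2/2)` — Pappus' second
  centroid theorem for the rim (the centroid of the half-disk sits
  `4r/(3pi)` outside the cylinder wall), plus the inner cylinder.

Two structural checks pin the volume formula down: at tangency
(`r_m = h/2`) it reduces exactly to the sphere `4/3 pi (h/2)^3`, and it
agrees with disc-slice numerical integration of the solid of revolution to
better than `1e-6` relative over the whole feasible range (the test suite
and the acceptance script both perform this comparison over 1000 random
geometries).

**The midplane-area convention.** Some published descriptions of this model
print the area relation as `A_m = 2 pi r_m^2`. That factor is inconsistent
with the area of a circle and with the rest of the geometry, but it only
rescales all radii by `sqrt(2)` and cancels in treated-versus-control
comparisons. We default to the circle relation (`convention = "circle"`)
and expose `"as_printed"` for literal reproduction of that variant; the
package takes no position on which was intended, and no result in this
package depends on the choice beyond that global rescaling.

**Degenerate inputs.** `r_m = h/2` exactly is a valid tangent-sphere
geometry and returns `r_c = 0`; computing a pressure on zero contact area
is the error, not the tangency itself. `r_m < h/2` (a cell too small to
span the gap) and volumes below the tangent-sphere bound are rejected with
typed errors.

# Trace processing

Confined mitotic cells relax to their equilibrium rounding force within
tens of seconds. Because the original assay literature does not specify a
plateau-detection rule, the package defines one explicitly:

* windows of length `window_s` (default 10 s) are scanned forward in time;
* the earliest window whose fitted slope magnitude is at or below the
  tolerance is taken, and `F_eq` is the mean over that window;
* the default tolerance is *relative*: 1% of the window mean per 10 s
  (`rel_slope_tol = 1e-3` per second). An absolute `slope_tol` in N/s can
  be supplied instead;
* if no window qualifies the final window is used and the result is flagged
  `equilibrated = FALSE`.

Slope fits use time-weighted least squares, so irregular sampling is
handled without resampling. A deliberate consequence of the window-mean
definition is a small negative bias when the window opens before the
relaxation has fully died out: with the default tolerances and a time
constant of 8 s, recovered equilibrium forces (and hence pressures) sit
about 1–2% below the asymptote. That is well within the assay's biological
scatter and is the documented behaviour of the estimator; analyses that
need the asymptote itself to high precision should tighten
`rel_slope_tol` and record longer traces (the noiseless pipeline-identity
test does exactly this: `rel_slope_tol = 1e-9` on a 240 s trace recovers
pressure and volume to better than `1e-6`).

Drift is modelled as linear in time, following the practice of probing the
bare glass surface at the end of a recording: the apparent force offset
there divided by the elapsed time gives the rate
(`estimate_drift_from_probe()`), which `correct_linear_drift()` subtracts.
Trans-mitotic recordings carry event annotations (NEBD, metaphase plate,
anaphase onset) as data, not as image-derived detections — phase
identification is done by the experimenter; `plateau_pressure()` averages
per-frame Laplace pressures between two events and `phase_durations()`
reports the NEBD-to-plate and plate-to-anaphase intervals in minutes.

# Image quantification

The original screen measured midplane areas with interactive microscope
software and computed cortical enrichment with an unpublished Igor macro.
The package substitutes explicit, parameter-light definitions:

* **Segmentation** — Gaussian smoothing (sigma 1 px), global Otsu
  threshold, largest connected component, hole filling. `A_m` is the mask
  pixel count times the pixel area; boundary-discretization error scales
  like 1/radius and is below 2% for cells at least 20 px in radius.
* **Cortex-to-cytoplasm ratio (MLR/ALR)** — `n_rays` rays (default 72)
  are cast from the mask centroid; per ray the cortex sample is the *peak*
  intensity within ±`band_um` (default 0.7 µm) of the boundary crossing;
  the cytoplasm reference is the median over the 30–60% normalized-radius
  annulus; background is the median outside the mask dilated by twice the
  band. The ratio is the mean over rays of
  `(cortex − background)/(cytoplasm − background)`.

Whether the original macro used peak or mean cortex intensity, and over
what band, is unknown; both are tunable here. Peak sampling makes the
estimator exact on noiseless rings but gives it a small *positive* bias
under shot noise (the maximum of several noisy samples), of order a few
percent at SNR 10 — recovered ratios at that noise level are accurate to
roughly 10%. The cytoplasm annulus does not exclude the chromatin/spindle
region by default because the original procedure describes no such
exclusion. Coordinates follow a fixed convention: 0-based pixel indices,
origin top-left, `(row, col)` order.

# Screen statistics

The screen's decision rules are implemented literally, with all constants
exposed in `screen_thresholds()`:

* raw forces are compared within a measurement round against that round's
  own control cells (daily F-Luc controls), removing day effects;
* each gene × round is tested with a two-sided two-sample *t*-test —
  classic equal-variance Student by default, since the original analysis
  verified control normality and used Student's test; Welch is available;
* a round *passes* when `p ≤ 0.05` **and** the treated/control mean ratio
  deviates from 1 by strictly more than 20%;
* rounds with fewer than 12 treated cells are not countable (the original
  sample-size choice); whether such rounds should instead be pooled is not
  documented, so discarding is the default and configurable;
* a gene is a **primary hit** when, over at least two countable rounds,
  the same-direction success rate is strictly above 50%. Genes whose
  passing rounds split evenly between directions are flagged ambiguous and
  not called — the original procedure does not document this case, and a
  flagged non-call is the conservative reading of "the same phenotype";
* **secondary confirmation** requires an independent reagent to reproduce
  a >20% force *reduction* under the same rules; confirmed genes are
  classified `pressure` (>20% significant pressure change), `volume`
  (>10% significant volume change), `both`, or `force_only`;
* no multiple-testing correction is applied in the calls, reproducing the
  original procedure across ~1000 genes; a Benjamini–Hochberg column is
  emitted alongside the per-round summaries for transparency;
* post-screen comparisons use the Mann–Whitney U test: exact enumeration
  of the U null distribution for combined samples of at most 20 without
  ties, a tie-corrected continuity-corrected normal approximation
  otherwise.

The compound gate (significance *and* ≥20% effect) is what controls the
false-positive rate: at n = 12 and 20% biological CV, a null gene must both
reach p ≤ 0.05 and land >20% from control in the same direction twice —
the simulated null rate over 10,000 genes is far below 0.5%, while a true
50% force reduction is detected with power indistinguishable from 1.

# The synthetic-data generator

The simulator exists so that every pipeline stage has inputs with known
truth. It emulates:

* **Single measurements** — a prescribed pressure `P_true` and volume
  `V_true` are turned into a self-consistent geometry: the height depends
  on the force through deflection (and tilt), the force on the height
  through the contact area; the weak coupling is resolved by fixed-point
  iteration to `1e-9` relative tolerance. The trace is
  `F_eq (1 − e^{−t/tau})` plus Gaussian noise and linear drift; the image
  is a disk with a thin cortical ring at the prescribed MLR/ALR just
  inside the boundary.
* **Trans-mitotic recordings** — a piecewise pressure schedule (baseline,
  linear rise from NEBD to plate, metaphase plateau, post-anaphase decay)
  pushed through the same forward model, with annotations embedded.
* **Screens** — per round, a shared log-normal day effect; per cell, a
  log-normal force around `baseline × day × gene effect`, with matched
  pressure and volume columns; every round carries an F-Luc control group
  and (optionally) an MYH9-like positive control with force effect 0.2.

Defaults were chosen once, as plausible values for STC-arrested mitotic
HeLa cells, because the original publications print no numeric control CV
or baseline: pressure 150 Pa, volume 2500 µm³ (spanning a 10 µm wedged
confinement comfortably), relaxation time constant 8 s (plateau within
10–30 s), baseline force 60 nN, across-cell CV 20% (resembling the visual
scatter of control cells), day-effect SD 0.1 on the log scale, pixel size
0.2 µm, 60 s traces at 10 Hz. Forces are log-normal across cells because
they are positive with substantial CV; within-trace noise is Gaussian.
With the default 14 µm non-wedged geometry the tilt correction raises the
effective height by several µm, so simulations of that configuration need
correspondingly larger cell volumes; the simulator's default is therefore
the wedged 10 µm configuration.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: actomyosin dynamics and osmotic regulation
(pressure is prescribed, not derived from tension), non-circular and
non-convex cell outlines, uneven illumination and out-of-focus light in
images, blebbing, cantilever hydrodynamics, and non-linear drift. Tests
passing on synthetic data demonstrate the *analysis* is correct under the
stated model, not that the model captures every property of a given
instrument.

# Numerical choices and problem sizes

* Unit boundaries: lengths in µm, areas µm², volumes µm³, forces N (nN in
  screen tables, as labelled), pressures Pa; the `F/k` deflection is
  converted to µm explicitly.
* `invert_volume()` solves the volume quadratic in `r_c` in closed form
  and clamps the tiny tangency residue so `r_c = 0` is returned exactly at
  the sphere bound.
* Otsu thresholding operates on the min-max normalized smoothed channel;
  ray marching samples in half-pixel steps with nearest-pixel lookup.
* The exact Mann–Whitney null distribution is built by the standard
  two-index count recursion; p-values are doubled one-sided tail masses,
  clamped at 1.
* Verification sizes, chosen to keep the full suite in a few minutes on a
  single core: 1000 random geometries for the integration and inversion
  checks, 1000 simulated cells for noisy pressure recovery, a 10,000-gene
  null screen and 1000 replicate screens for the power estimate, and
  3–5 replicates per image-noise condition.

# Known limitations

* The equilibrium window mean under-estimates the asymptote by ~1–2% with
  default settings (see above); comparative analyses are unaffected since
  control and treated cells share the bias.
* The ray-peak cortex estimator is biased upward by a few percent under
  shot noise at SNR ≈ 10 and should not be used for absolute enrichment
  claims at lower SNR without adjusting `band_um` or averaging strategy.
* Segmentation assumes one dominant, roughly star-convex cell per field;
  touching cells are not split.
* The non-parallel-plate error of tilted levers beyond the height
  correction is not modelled (the assay's own practice, where it is
  treated as negligible for comparative use).
* No cortex-tension estimation and no elastic or viscoelastic contact
  models are included; the readout is pressure and volume only.
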