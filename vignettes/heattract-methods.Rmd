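---
title: "Methods: hourly heat-stress fields and tract aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hourly heat-stress fields and tract aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the models, the
tunable parameters and why their defaults are what they are, the numerical
choices, what the synthetic scenario does and does not emulate, and the
known limitations.

## The problem

Gridded heat-stress products combine three kinds of inputs with
incompatible resolutions: a *daily* high-resolution surface product
(per-cell temperature extrema and mean dew point), an *hourly* but coarse
reanalysis (full near-surface state plus accumulated longwave radiation),
and a *half-hourly* solar-radiation product on an intermediate grid. The
pipeline harmonizes all three onto the fine reference grid at hourly
cadence, computes Heat Index (HI), wet-bulb globe temperature (WBGT) and
the Universal Thermal Climate Index (UTCI) per cell-hour, and averages
them into census-tract records that health datasets can join on.

All timestamps are UTC throughout. The temporal unit is a 24-hour window
from 12:00 UTC of the previous calendar day to 11:00 UTC of the labelled
day — the convention of the daily constraint product — and consecutive
windows tile time exactly (`prism_day_window()`).

## Temporal reconstruction

Within each window, the coarse hourly temperature at the cell's nearest
coarse neighbour is normalized to its own extrema,

$$f(h) = \frac{T(h) - T_{\min}}{T_{\max} - T_{\min}} \in [0,1],$$

and rescaled to the fine cell's daily constraints,
$T_a(h) = T_{a,\min} + f(h)\,(T_{a,\max} - T_{a,\min})$. Two consequences
are load-bearing and are enforced by tests: the reconstructed day attains
the daily extrema exactly whenever the profile attains 0 and 1, and if the
coarse profile happens to equal the truth's own normalized shape the
reconstruction reproduces the truth field identically.

*Flat source day.* When the coarse day has zero range the normalization is
undefined; we set $f(h) = 0.5$, reconstructing the midpoint of the
constraint range. This is bounded, symmetric, and avoids special-casing
downstream; any choice in $[0,1]$ would conserve the extrema only
accidentally on such days, and a flat source day carries no timing
information to preserve.

*Moisture.* The coarse hourly dew point is shifted additively by
$\Delta T_d = T_{d,\mathrm{mean}} - \overline{T_{d,\mathrm{coarse}}}$ so
its window mean equals the daily mean constraint exactly, then converted
to vapor pressure and capped at saturation with respect to the
reconstructed air temperature. The cap acts in vapor-pressure space, not
by truncating the dew-point series — truncation would break the exact mean
conservation that the additive correction provides, while the cap
guarantees the implied relative humidity never exceeds 100 %.

*Saturation curve.* We use the Buck over-water expression
$e_s(T) = 6.1121\,\exp\!\big((18.678 - T/234.5)\,T/(257.14 + T)\big)$ hPa
(the 1996 coefficients) everywhere in the pipeline: vapor-pressure
reconstruction, relative humidity, the UTCI dryness limit, and station
dew-point conversion in the validation harness. Several Buck variants
differ below the fourth significant digit in the warm range that matters
for heat stress; what matters is using *one* variant consistently, and the
chosen variant is recorded in `heattract_constants()$buck` so it can be
swapped in one place. The wet-bulb/globe solver deliberately keeps the
Liljegren model's own internal saturation curve (the 1981 coefficients
with a 1.004 moist-air enhancement factor) because those constants are
part of the published model we reproduce.

## Spatial interpolation

Pressure, wind components and the longwave fluxes (coarse grid) and the
solar variables (intermediate grid) are moved onto the reference grid by
inverse-distance weighting over the four nearest source points within a
distance cutoff, on planar coordinates.

* **Projection.** Distances are computed in an Albers equal-area conic
  fitted to the data extent (`project_planar()`). For nearest-neighbour
  and IDW purposes any metric projection is admissible; the conic is
  configurable through the `params` argument.
* **Weight exponent.** Weights are $1/d^2$ by default (`idw_power`),
  recorded in the run manifest. Inverse-square is the common default in
  meteorological regridding; the exponent is exposed because nothing in
  the method pins it.
* **Cutoffs.** Defaults are 9000 m for the coarse product and 4000 m for
  the solar product — the native resolutions of those sources — so no
  source point can influence a cell farther away than one source cell.
* **Degeneracies.** Missing neighbour values are ignored with the weights
  renormalized (down to nearest-neighbour weighting when only one valid
  source remains); a target coincident with a source returns that source's
  value exactly rather than an infinite weight; no valid source within the
  cutoff yields a missing value, not an error.

Accumulated longwave radiation (J/m²) is converted to mean hourly flux by
differencing successive accumulations and dividing by 3600 s. At an
accumulation reset (the start of an accumulation day) the accumulated
value itself is the hour's integral, so the first post-reset flux is
`acc/3600`; an unexpected negative difference is clipped to zero with a
warning for the downwelling component (which is physically nonnegative)
and passed through for the net component (which is legitimately signed).
Fluxes are recovered on the full source series *before* any run-window
subsetting so a run starting mid-archive differences correctly.

Half-hourly solar variables are averaged in adjacent pairs; the zenith
angle is averaged in cosine space and converted back
(`aggregate_zenith()`), preserving radiative consistency. A single missing
half-hour falls back to the remaining sample; albedo is an 8-day product
and is constant within any hour.

## Ancillary variables

Relative humidity is $100\,e/e_s(T_a)$ clipped to $[0,100]$ — a numerical
guard only, since the saturation cap runs first. Wind speed is the vector
magnitude of the interpolated components. An optional hypsometric
adjustment rescales interpolated surface pressure from the coarse source
elevation to the fine cell elevation,
$P = P_{\mathrm{ref}} \exp(-g\,\Delta z / (R_d T))$ with $g = 9.80665$
m/s² and $R_d = 287.05$ J/(kg·K): we implement the hydrostatically
consistent sign, under which a target *below* its source receives *higher*
pressure and the transform is exactly its own inverse under swapped
elevations. The adjustment ships off by default (`pressure_adjust`) —
enabling it changes the heat-stress outputs negligibly at these elevation
differences — and applies over land cells only.

## Heat-stress models

**Heat Index** follows the NWS procedure in Fahrenheit internally: the
simple Steadman-average formula, replaced by the Rothfusz regression where
it reaches 80 °F, with the low-humidity (RH < 13 %, 80–112 °F) and
high-humidity (RH > 85 %, 80–87 °F) adjustments. Every input combination
returns a number; the index is not masked outside its nominal regime, so
downstream users decide relevance.

**WBGT** uses the Liljegren energy-balance model with the published
constants (globe: 50.8 mm diameter, emissivity 0.95, albedo 0.05; wick:
7 mm × 25.4 mm, emissivity 0.95, albedo 0.4; surface albedo 0.45; all in
`heattract_constants()$liljegren`). Both sensor temperatures are solved by
the model's damped fixed-point iteration
(`prev := 0.9·prev + 0.1·new`) to a tolerance of 0.02 K with a 50-iteration
cap; a cell-hour that fails to converge is returned missing with a
warning, never silently extrapolated. The supplied 10 m wind is reduced to
the 2 m sensor level by the model's power-law profile whose exponent
depends on a stability class estimated from wind speed and insolation
(rural exponents; at night, with no vertical temperature-gradient
information in the pipeline, the stable classes are used: class 6 below
2.5 m/s, class 4 above). Wind is floored at the model minimum of
0.13 m/s. Nighttime solar geometry is represented by a small negative
zenith-cosine sentinel, $-10^{-4}$ (configurable); the direct-beam
fraction is forced to zero when GHI ≤ 1 W/m² or the sun sits below ~89.5°
zenith, and the zenith cosine is floored at 0.00873 inside the solar term,
as in the published code, so the $1/(2\cos\theta_z)$ geometry factor
cannot blow up at grazing sun.

**Mean radiant temperature** is the fourth-root flux balance with
half-sky/half-ground view factors, shortwave absorptivity 0.7, emissivity
0.97, and the Fanger projected-area factor
$f_p = 0.308\cos\!\big(\gamma(0.998 - \gamma^2/50000)\big)$ of solar
elevation $\gamma$. Surface-emitted longwave is recovered from the input
pair as $L^{\uparrow} = L^{\downarrow} - L^{*}$ (net = down − up).
Negative shortwave inputs are zeroed and the zenith cosine truncated at
zero before use. All-zero radiation yields a physically cold enclosure,
not an error.

**UTCI** evaluates the published sixth-order polynomial (210 terms, the
full degree-6 basis in $T_a$, wind, $T_{mrt}-T_a$, and vapor pressure in
kPa; the coefficient table lives in `R/utci_coefficients.R` and is shared
with the reference implementation that generated the test fixtures).
Validity masking follows the operational limits — $-50 \le T_a \le 50$ °C,
$-30 \le T_{mrt}-T_a \le 70$ °C, $e < 50$ hPa, RH > 5 %, and the
recommended wind restriction $0.5 \le U_{10} \le 17$ m/s — plus
missingness wherever any input is non-finite. The RH > 5 % limit is
evaluated on the clipped relative humidity implied by $(T_a, e)$: the clip
runs first everywhere else in the pipeline, so evaluating the limit on the
same quantity keeps the mask consistent with the values users see. The
tests assert that missingness is *exactly* the union of these violations.

## Tract aggregation

A static lookup assigns each cell centroid to the tract polygon containing
it (even-odd ray casting; no geometry dependency is available, so the
point-in-polygon test is implemented here). Determinism at shared
boundaries comes from processing polygons in sorted identifier order and
never reassigning a claimed cell. Two deliberate choices:

* A tract containing no centroid receives its single nearest cell, so
  every tract appears in every output file — an empty tract-row would
  break health-data joins, which is worse than a slightly borrowed value.
* Area weights are the cosine of cell latitude (cell area on a
  geographic grid); population weights are the raw resampled counts, with
  no additional cosine factor — the latitude factor corrects *area*
  weighting, while population counts are already extensive.

Population on a finer lattice is summed into the containing reference cell
(nearest centroid on a regular grid), conserving the domain total exactly.
A tract-hour whose total population weight is zero falls back to area
weights with a message. Boundary vintages follow the decennial rule (2000
boundaries for 1998–2009, 2010 for 2010–2019, 2020 onward), and the
population year backfills 1998–1999 with the 2000 surface.

Output is one Parquet file per labelled day named
`heatstress_tract_area_and_popweighted_[start]_[label]_popy[YYYY]_v[YYYY].parquet`
with exactly the 15 published columns; the writer refuses anything else.

## Validation harness

Stations are matched to their nearest cell within a threshold consistent
with the grid resolution (800 m for the fine grid, 9 km for a coarse-grid
comparison). Bias is **model − observation** — chosen so a positive bias
reads as a warm model — RMSE is the quadratic mean of the same residuals,
and correlation is Pearson's r over pairs. Window-level estimates are
pooled with matched station-hours as weights: bias and MSE pool linearly
and RMSE is the square root of the pooled MSE, which makes window-pooled
RMSE *identical* to the RMSE over the concatenated pairs when the weights
are the pair counts (asserted exactly in the tests). Pooled correlation is
a weighted mean of window correlations and is descriptive only.

## The synthetic scenario

`truth_scenario()` defines the desk-scale study conditions used by the
tests and the acceptance script: a 20×20 fine grid at 800 m spacing
(~16 km domain at 40° N), a 3×3 coarse grid at 9 km, a 5×5 solar grid at
4 km, five labelled days, twelve tracts, fifteen stations, mean
temperature 24 °C with an 8 °C diurnal range, dew point ~6 °C below the
daily mean, moderate wind and 30 % cloudiness — a plausible midwestern
warm-season week, sized so the full pipeline runs in seconds. Station
noise is homoscedastic Gaussian with σ = 1 °C.

The generator is built so that the degraded coarse product carries the
truth's own diurnal shape (every cell shares the window's time shape, and
normalization removes the amplitude and offset that vary across cells).
That makes end-to-end exact recovery a meaningful test of the
reconstruction plumbing. It also bounds what passing tests show: the
scenario has smooth fields, shared diurnal timing, no fronts, no
terrain-driven inversions, no missing data, and clear-sky-shaped radiation
with constant cloudiness — so the tests demonstrate correctness of the
algorithms, not skill of the product on real weather. Real-data skill can
only be established against station networks, which is what the
validation harness is for.

## Numerical choices and degenerate inputs

* Nearest-neighbour ties break to the lowest source cell id; IDW treats
  distances below 1 nm as coincident.
* The Liljegren iteration freezes each element at its first converged
  value (matching the scalar reference semantics) rather than iterating
  converged elements further.
* `diurnal_profile()` requires exactly 24 finite values; flat days take
  the 0.5 rule above.
* `accumulated_to_flux()` treats the first sample as a reset unless told
  otherwise.
* Aggregation excludes missing member values and renormalizes weights; a
  tract whose members are all missing yields a missing tract value.

## Limitations

* The wet-bulb/globe and UTCI implementations reproduce published
  operational models; they are not re-validated against instrument data
  here. The dual-route tests pin the implementation to an independently
  written reference of the *same* published algorithms.
* The stability-class wind profile uses insolation only; with no vertical
  temperature gradient available, night collapses to the stable classes.
* Centroid assignment does not split cells across tract boundaries
  (fractional areal interpolation is out of scope), and population
  resampling is nearest-cell, not dasymetric.
* The pipeline assumes complete, gap-free input series per run window;
  missing values propagate rather than being imputed.
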