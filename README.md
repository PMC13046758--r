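# heattract

Hourly heat-stress exposure surfaces on a fine reference grid, aggregated to
census-tract boundaries with area and population weights.

Heat-health research increasingly needs exposure metrics that go beyond
dry-bulb temperature — humidity, wind, and radiation jointly determine the
physiological burden of heat — and needs them on the administrative
geographies (census tracts) that health records can legally be linked to.
`heattract` implements the full modelling chain for producing such a
product: it reconstructs hourly near-surface temperature and vapor pressure
on a fine grid from daily constraints plus a coarse hourly diurnal profile,
interpolates ancillary meteorology and solar radiation onto that grid,
computes three heat-stress indices per cell-hour with physically based
models, and averages them into tract-hour records ready for health linkage.

## The models at its core

**Temporal reconstruction.** A coarse hourly temperature day is reduced to a
unitless diurnal shape, f(h) = (T(h) − T_min)/(T_max − T_min) ∈ [0, 1], and
rescaled to the fine grid's daily extrema:

    Ta(h) = Ta_min + f(h) · (Ta_max − Ta_min)

so the fine daily constraints are conserved exactly while the coarse product
supplies the intraday timing. Dew point is corrected additively so its
window mean matches the daily mean constraint, converted to vapor pressure
with the Buck relation, and capped at saturation of the reconstructed air
temperature.

**Heat Index** — the U.S. National Weather Service algorithm: the Rothfusz
regression with its low- and high-humidity adjustment terms, and the simple
Steadman-average formula in the cool regime.

**Wet-Bulb Globe Temperature** — the Liljegren energy-balance model. The
natural wet-bulb temperature solves the wick balance (convection +
radiation = evaporation) and the globe temperature solves the globe balance
(absorbed solar and longwave = convection + emission), both by damped
fixed-point iteration; then

    WBGT = 0.7·Tw + 0.2·Tg + 0.1·Ta

**UTCI** — the published sixth-order polynomial approximation in air
temperature, wind speed, radiant excess (T_mrt − Ta) and vapor pressure,
with the operational validity limits (−50 ≤ Ta ≤ 50 °C, −30 ≤ T_mrt − Ta ≤
70 °C, e < 50 hPa, RH > 5 %, 0.5 ≤ U10 ≤ 17 m/s). Mean radiant temperature
comes from the fourth-root flux balance over half-sky/half-ground longwave
and absorbed shortwave with the standard human absorption (0.7) and
emissivity (0.97) coefficients.

**Aggregation.** Grid-cell centroids are assigned to tract polygons once;
tract-hour values are weighted means using cosine-latitude area weights or
resampled gridded population counts. Output is one Parquet file per output
day in the 15-column published schema.

A synthetic-scenario generator (`truth_scenario()`, `make_fixtures()`)
emulates every input product — daily constraints, coarse hourly reanalysis
with accumulated longwave, half-hourly solar, tract polygons, population,
stations — so the whole pipeline runs and is tested with no external data.

## Worked example

Point computations:

```r
library(heattract)
# hot, sunny afternoon at sea level
heat_index(ta_c = 35, rh = 60)
wb <- wbgt_liljegren(ta_c = 35, rh = 60, ps_pa = 101325, u10 = 3,
                     ghi = 900, f_dir = 0.8, cos_zenith = 0.85)
tmrt <- mean_radiant_temperature(ghi = 900, net_shortwave = 720, dni = 850,
                                 dni_horizontal = 722.5, ldown = 420,
                                 lnet = -50, cos_zenith = 0.85)
utci(ta_c = 35, va = 3, tmrt_c = tmrt, e_hpa = 0.6 * svp_buck(35))
```

prints

```
HI   = 45.1 C
Tw   = 29.6 C, Tg = 49.3 C, WBGT = 34.1 C
Tmrt = 57.0 C
UTCI = 41.3 C
```

— at 35 °C and 60 % humidity the apparent temperature (HI) is ten degrees
above the air temperature; under 900 W/m² of sun the globe runs ~14 °C hot
and the radiant load pushes UTCI into the "very strong heat stress" band,
while WBGT (34 °C) sits above common occupational action limits.

The full pipeline on the default synthetic scenario (a 20×20 cell grid at
800 m, five output days, twelve tracts):

```r
cfg <- heattract_config(seed = 1, out_dir = "out")
res <- run_pipeline(cfg)
basename(res$files[1])
#> "heatstress_tract_area_and_popweighted_2010-07-14_2010-07-15_popy2010_v2010.parquet"
res$records[GEOID == "T001" & time == 21][1]
#>    GEOID year month day time temp_C_used_area HI_C_area WBGT_C_area UTCI_C_area ...
#> 1:  T001 2010     7  14   21         28.15401  29.19247    26.76966    32.16704
```

Each output file holds one 24-hour UTC window (12:00 UTC of the previous
day through 11:00 UTC of the labelled day), 24 records per tract, with
area- and population-weighted temperature, relative humidity, HI, WBGT and
UTCI.

A command-line wrapper ships at `inst/cli/heattract`
(`fixtures | run | aggregate | validate`).

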