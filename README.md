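# greenspill

Greening trends and spill-over effects around tree-planting groves.

Smallholder agroforestry programmes plant many small tree groves
(typically a fraction of a hectare) scattered across agricultural
landscapes. Two questions decide whether such programmes have
landscape-scale impact: do the groves themselves green up relative to
the surrounding farmland, and does the greening *spill over* into
neighbouring land — and if so, how far? `greenspill` answers both from a
stack of dated NDVI rasters, grove polygons and an agricultural mask,
and ships a synthetic-landscape generator with known ground truth so the
whole pipeline is testable without any satellite download.

## Method

For every 30 m pixel, the NDVI time series (2000–2019 by default) is
reduced to a trend statistic in four steps:

1. **Monthly maximum-value composite** — the per-pixel maximum over each
   calendar month's acquisitions, suppressing cloud and aerosol
   contamination;
2. **Decycling** — subtraction of the multi-annual monthly climatology,
   removing the seasonal cycle;
3. **12-month moving average** — smoothing, with positions lacking a
   full window removed (240 months in, 229 out);
4. **Mann–Kendall τ** — Kendall's rank correlation between the smoothed
   anomalies and time (τ = 1 monotone greening, τ = −1 monotone
   browning), computed in compiled code with tau-b tie correction.

Pixels are classified by centroid/buffer rules: **grove** pixels
(centroid within 15 m of a grove polygon), **neighbour rings** 1…17
(centroid within k·30 m of the grove-pixel footprints but not
(k−1)·30 m, out to 510 m), and **other agricultural** land. The mean τ
of the three outermost rings (450/480/510 m) anchors the *local
background* (asymptote); each ring's pixel τ values are tested against
it through a no-intercept categorical regression on ring indicators
(each coefficient is analytically `ring mean − asymptote`). Walking
outward, the first non-significant ring marks where the landscape
reaches background; the spill-over distance is one ring nearer. Areas
are rolled up as groves + immediate ring + extended spill-over rings.

See `vignette("greenspill-methods")` for assumptions, parameter
defaults, SE conventions, and the generator's design.

## Worked example

A fully synthetic scene under the default study conditions: 200 × 200
pixels of 30 m, 5 clusters of 6 groves (median 0.285 ha), a weak
background trend, and a planted grove effect decaying with distance and
vanishing beyond 360 m.

```r
library(greenspill)

sc      <- scenario(cadence = "monthly", seed = 7)
scene   <- simulate_scene(sc)
smooth  <- preprocess_stack(scene$stack, min_valid_in_window = 10)
gpx     <- grove_pixels(scene$groves, scene$grid)
classes <- classify_pixels(gpx, distance_rings(gpx, scene$grid), scene$mask)
trend   <- trend_map(smooth)
fit     <- spillover_fit(trend, classes)
print(trend)
print(fit)
```

```
<trend_map> 200x200@30m, tau defined for 40000/40000 pixels (median 0.169)

  strong_browning moderate_browning moderate_greening   strong_greening
             3215             10862             14969             10954
     unclassified
                0
Grove spill-over fit
  asymptote (local background tau): 0.0927 (se 0.0084, rings 450/480/510 m)
  spill-over distance: 360 m (background from 390 m)
  influenced area: 16.47 ha groves + 19.08 ha immediate + 329.58 ha extended = 365.13 ha
```

The landscape splits into browning and greening pixels around a weakly
positive median τ; the rings nearest the groves test significantly above
the local background out to 360 m — exactly the planted spill-over range
— and beyond 390 m the landscape is indistinguishable from background.
`summary(fit)` prints the per-ring test table, greening fractions per
class and Welch t-tests between classes; `plot(fit)` draws the
distance-decay profile with the asymptote line. `run_pipeline()` runs
the same stages from a config (synthetic or file-based inputs) and
writes all maps, tables and a machine-readable summary;
`inst/cli/greenspill.R` wraps it for the shell.

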