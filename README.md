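# loggrid

Annual monitoring of **deforestation** and **selective-logging disturbance**
in tropical forests from medium-resolution reflectance imagery
(Landsat-class, 30 m), for remote-sensing scientists and forest-monitoring
programmes that need to tell degradation apart from clearing and track it
consistently through time.

The workflow integrates three methods:

1. **Object-based forest masking** — multiresolution region-merging
   segmentation plus an ordered rule set labels forest and non-forest for
   the base year; annual updates add new clearings (≥ 1 ha minimum mapping
   unit) while sub-hectare logging features deliberately stay inside the
   forest polygons.
2. **Linear spectral mixture analysis (LSMA)** — each pixel spectrum
   *y* is decomposed as *y = E f*, *f* on the unit simplex
   (soil/vegetation/shade fractions, fully constrained least squares solved
   exactly by simplex-face enumeration). Forest pixels with soil fraction
   **≥ 10%** are flagged as logging evidence (decks, roads, canopy gaps).
   Scenes are first aligned radiometrically by per-band OLS over
   pseudo-invariant features.
3. **Fixed 300 m grid accounting** — per cell and year, disturbance
   intensity = flagged pixels / forest pixels, classed as very low (1–5%),
   low (5–10%), medium (10–50%) or high (>50%); plus annual
   deforestation/disturbance rates, land-cover change matrices (ha),
   recurrence counts, and stratified-sampling accuracy assessment with
   error matrices (user's/producer's/overall accuracy).

A synthetic-landscape simulator (`simulate_landscape()`) provides per-pixel
ground truth — frontier deforestation, logging decks on a 225 m jittered
lattice, one-pixel roads, canopy gaps, 2-year recovery — so the entire
pipeline is testable end-to-end without any downloads.

## Worked example

```r
library(loggrid)

cfg    <- simulation_config(extent = c(120, 120), n_years = 4, seed = 7)
truth  <- simulate_landscape(cfg)
scenes <- lapply(1:4, function(y) render_scene(truth, y, noise_sd = 0.005))

bundle <- run_pipeline(
  list(scenes = lapply(1:4, function(y)
    list(date = sprintf("%d-07-01", 1999 + y)))),
  scenes = scenes)

bundle$area_summaries[["2002"]]
#>         class area_ha   pct
#> 1  non-forest     295 22.74
#> 2 undisturbed     542 41.85
#> 3    very low      90  6.94
#> 4         low      45  3.47
#> 5      medium     306 23.61
#> 6        high      18  1.39

bundle$rates[, c("from", "to", "deforestation_rate",
                 "disturbance_rate_cell")]
#>   from   to deforestation_rate disturbance_rate_cell
#> 1 2000 2001             0.0245                0.2229
#> 2 2001 2002             0.0221                0.1230
#> 3 2002 2003             0.0254                0.0989

attr(bundle$recurrence, "distribution")
#>  0  1  2  3
#> 47 12 18 21
```

Reading: in 2002, 22.7% of the landscape is non-forest and 23.6% sits in
medium-intensity disturbance cells (10–50% of the cell's forest flagged);
the annual deforestation rate is ~2.2–2.5% of the remaining forest (the
generator's configured 2% plus discretisation), while the cell-level
disturbance rate is 5–10× larger — logging touches far more forest than is
cleared, the core empirical pattern this kind of monitoring exposes. Of the
98 always-fully-forested cells, 51 were disturbed at least once in four
years.

Accuracy assessment on printed counts:

```r
m <- as_error_matrix(matrix(c(57, 18, 16, 134), 2, 2, byrow = TRUE,
       dimnames = list(c("undisturbed", "disturbed"),
                       c("undisturbed", "disturbed"))))
accuracy_metrics(m)$overall_pct
#> [1] 84.88889   # prints as 84.9%
```

## Command line

```sh
Rscript -e 'loggrid::loggrid_cli()' simulate --out scenes/ --years 5 --size 200 --seed 42
Rscript -e 'loggrid::loggrid_cli()' validate --config run.json
Rscript -e 'loggrid::loggrid_cli()' run --config run.json
```

See `vignettes/methods.Rmd` for the model, parameter and design rationale.
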