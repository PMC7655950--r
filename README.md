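# reefscape

Object-based habitat mapping and near-bed current statistics for
cold-water coral (CWC) reefs.

Reef-framework CWCs (e.g. *Desmophyllum pertusum*) are filter feeders:
bottom currents deliver their food, yet flume studies show they capture
prey best at low speeds (≈ 2.5–5 cm s⁻¹). Surveys that pair
centimetre-scale photogrammetry (DEM + orthomosaic) with months of
lander-mounted ADCP records can test how coral cover, coral orientation
and local flow relate in situ. `reefscape` implements that analysis as a
reusable R pipeline:

* **`synth`** — synthetic seabed scenes (DEM, ground-truth facies map over
  LCF/DCF/SC/CR/S, orthomosaic) and ADCP-like records (steady + M2 tidal
  component + noise, attitude with optional lander topple), bit
  reproducible per seed, so every downstream stage is testable against
  known truth.
* **`terrain`** — slope and aspect from a DEM by Horn's 3×3 scheme (the
  standard GIS convention); flat cells are nodata.
* **`obia`** — multiresolution region-merging segmentation
  (Baatz–Schäpe cost `f = (1−w_shape)·Δh_colour + w_shape·Δh_shape`,
  deterministic global mutual-best-fit merging while cost < scale²),
  per-segment features, nearest-neighbour classification in z-scored
  feature space, and confusion-matrix accuracy assessment with Cohen's
  kappa.
* **`currents`** — ADCP CSV ingestion and QC (deployment-margin trimming,
  running-median/MAD despiking, attitude-based topple detection), Table-2
  style site summaries (mean/max speed, strict `<5`, `<10`, `>30` cm s⁻¹
  exceedance, modal direction sector, temperature) and rose tables.
* **`integrate`** — facies proportions, live-coral aspect (circular mean
  over LCF cells + compass sector), the **coral-facing mean current
  speed** (mean speed over records whose flow-toward direction lies
  within ±22.5° of `(aspect + 180°) mod 360` — currents travelling into
  the coral face), percentage reduction against the overall mean,
  feeding-window time fractions at 2.5 and 5 cm s⁻¹, cross-site Spearman
  trends, and CSV/JSON reports.

One convention throughout (embedded in every report): azimuths in degrees
clockwise from north, currents **flow-toward**, aspect = downslope facing
direction.

The package also ships the printed per-site statistics of a seven-site
upper Porcupine Bank Canyon CWC survey (`upbc_site_stats()`) as inputs for
the cross-site arithmetic (coral vs non-coral mean speeds, rank trends,
the 72% reduction at site "d").

## Worked example: a full synthetic site survey

```r
library(reefscape)

# scene with live coral biased onto SE-facing (135 deg) slopes
p <- scene_params(grid_shape = c(96, 96), seed = 11, lcf_aspect_bias = 135,
                  facies_proportions = c(LCF = 0.15, DCF = 0.2, SC = 0.05,
                                         CR = 0.2, S = 0.4),
                  facies_smooth = 4)
sc  <- gen_scene(p)                    # dem + truth facies + orthomosaic
asp <- aspect(sc$dem)
sl  <- slope(sc$dem)$values
sl[is.na(sl)] <- mean(sl, na.rm = TRUE)

# OBIA: segment on colour + elevation, classify on colour + slope
sm  <- segment_scene(c(sc$ortho$bands, list(dem = sc$dem)), scale = 26)
ft  <- compute_features(sm, c(sc$ortho$bands, list(slope = sl)))
truth <- sc$facies$values
maj <- sapply(seq_len(sm$n_segments), function(i) {
  v <- truth[sm$labels$values == i]
  names(facies_legend())[as.integer(names(which.max(table(v))))]
})
splt <- holdout_split(data.frame(id = seq_len(sm$n_segments), class = maj),
                      holdout = 0.3, seed = 2)
ftl <- classify_nn(ft, splt$fit, min_per_class = 2, seg = sm)
fr  <- facies_raster(ftl, sm)
accuracy_assessment(fr, sc$facies)

# currents: steady flow along 135 deg, tide strong enough that the weak
# counterflow travels into the coral faces
ser <- trim_and_despike(gen_adcp(current_params(
  duration_days = 27, steady_speed = 18, steady_heading = 135,
  tidal_amplitude = 24, noise_sd = 2, seed = 12)))
habitat_summary("demo", fr, asp, ser)
```

which prints

```
overall accuracy 98.7%   kappa 0.983   n = 9216

Habitat summary - site demo (coral habitat)
  facies: LCF 15.2%, DCF 19.5%, SC 4.8%, CR 20.1%, S 40.5%
  LCF aspect 136.6 deg (SE; modal SE)
  overall mean 20.2 cm/s; coral-facing mean 5.4 cm/s (73% reduction, n=488)
  feeding windows: 1.1% of time <= 2.5 cm/s, 5.4% <= 5 cm/s (coral-facing)
```

Read: the classifier recovers the generator's facies map almost exactly;
the live-coral aspect estimate (136.6°) recovers the 135° ground truth;
and because the weak tidal counterflow is what travels into the coral
faces, the coral-facing mean (5.4 cm s⁻¹, inside the efficient feeding
range) sits far below the overall mean (20.2 cm s⁻¹) — the qualitative
signature the pipeline is built to measure.

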