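# punctaflow

Image-analysis toolkit for punctate TIRF/confocal fluorescence microscopy of
the kind used to study tethered receptor clusters and local Ca²⁺ signals —
for example IP₃ receptor (IP₃R) puncta held immobile on cortical actin by
KRAP and the Ca²⁺ puffs that arise at them. It is written for cell
biologists who need reproducible, scriptable versions of analyses usually
done with a patchwork of ImageJ plugins:

* **Spot segmentation** — seeded radial growth around local intensity
  maxima with a radial-profile border threshold; sub-pixel
  intensity-weighted centroids.
* **Object-based colocalization** — nearest-neighbour centre-to-centre
  distances between segmented puncta; a punctum pair counts as colocalized
  when its distance is `< 160 nm` (or `< 130 nm` for super-resolution data);
  significance from an object-randomization null (100 iterations) with the
  add-one permutation p-value `p = (1 + #{null ≥ observed})/(n + 1)`. Under
  complete spatial randomness the criterion fraction has the closed form
  `1 − exp(−λπr²)`, which the implementation is calibrated against.
* **Manders split coefficients** against filament (actin) masks, and
  peripheral-annulus / central partitions of cell masks.
* **Single-particle tracking** — min-cost bipartite frame linking with a
  1.5 µm s⁻¹ displacement gate and gap closing; time-averaged MSD fitted as
  `MSD = 4Dt^α`; trajectories of ≥ 45 frames classified immobile when
  `α < 0.1` (subdiffusive/diffusive/directed bands above).
* **FRAP** — mobile fraction `Mf = (F_plateau − F_post)/(F_pre − F_post)`
  from a single-exponential recovery fit.
* **Ca²⁺ puffs** — ΔF/F₀ movies, space-time connected-component event
  detection, single-linkage site mapping, event-to-punctum distances, and
  calibration `[Ca²⁺] = K_D (F − F_min)/(F_max − F)` (K_D = 389 nM for
  Fluo-8).
* **Synthetic data** — generators for two-channel puncta fields with a
  controllable colocalized fraction, filament textures, mixed
  immobile/Brownian/directed movies, FRAP curves and puff movies, all with
  exact ground truth, so every stage is testable without real microscopy
  data.

Built Bioconductor-style: S4 classes (`ImageStack`, `CellMask`,
`SegmentationResult`, `DistanceResult`, `RandomizationNull`,
`TrajectorySet`) with validity checks, accessors and `show` methods;
`EBImage` and `tiff` for standard image operations and I/O.

## Worked example

Segment a synthetic two-channel field (20 × 20 µm, 300 puncta per channel,
30% of channel-A puncta constructed within 80 nm of a channel-B punctum,
SNR 5), measure colocalization, and test it against the randomization null:

```r
library(punctaflow)

mask  <- squareMask(20, 100)                     # 20 um field, 100 nm pixels
field <- makePunctaField(mask, nA = 300, nB = 300,
                         colocFraction = 0.30, seed = 1)

segA <- segmentSpots(field$stackA, smoothSigmaPx = 1)
segB <- segmentSpots(field$stackB, smoothSigmaPx = 1)
segA
#> SegmentationResult: 292 puncta over 1 frame(s)

dr <- nearestNeighbourDistances(segA, segB, criterionNm = 160)
dr
#> DistanceResult: n_A = 292, n_B = 294, 29.5% colocalized at < 160 nm

null <- randomizeNull(segA, segB, mask, nIterations = 100,
                      mode = "point", seed = 2)
null
#> RandomizationNull: 100 iterations, null fraction 0.0578 +/- 0.0133, p = 0.009901
```

The observed 29.5% recovers the constructed 30% within its binomial
sampling error, while randomly relocated puncta colocalize at only ~6% —
the same observed-versus-randomized contrast the method is designed to
quantify; `p = 1/101` is the smallest value a 100-iteration permutation
test can report.

Mobility classification on simulated trajectories (30% immobile with 20 nm
localization noise, 70% Brownian at D = 0.01 µm² s⁻¹):

```r
tr   <- makeTrajectories(mask, 100,
                         c(immobile = 0.3, diffusive = 0.7, directed = 0),
                         locNoiseNm = 20, nFrames = 300, dt = 0.1, seed = 3)
fits <- fitTrajectories(tr, frameIntervalS = 0.1)
table(fits$class)
#>    diffusive     immobile subdiffusive
#>           62           30            8
countImmobile(fits)
#> [1] 30
```

All 30 constructed immobile particles are recovered; the 8 "subdiffusive"
calls are Brownian trajectories whose single-trajectory MSD exponent fell
below 0.8, the known spread of time-averaged MSD fits.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/punctaflow-cli.R` (subcommands `segment`, `coloc`, `track`,
`frap`, `puffs`, `simulate-puncta`).

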