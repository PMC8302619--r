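---
title: "punctaflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{punctaflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaflow)
```

## Scope

punctaflow implements the image-analysis computations used to study
KRAP-tethered, actin-associated, immobile IP~3~ receptor (IP~3~R) clusters
and the Ca^2+^ puffs they produce: seeded radial-growth spot segmentation of
TIRF puncta, object-based colocalization with randomization null models,
single-particle tracking with anomalous-diffusion mobility classification,
FRAP mobile fractions, Ca^2+^-puff detection and site mapping, and
fluorescence-to-[Ca^2+^] calibration. Because the underlying microscopy data
are not publicly deposited, every stage is exercised against a synthetic-data
generator with known ground truth; this vignette records the models, the
parameters that matter, and the design decisions taken where the published
descriptions leave freedom.

## Coordinate and unit conventions

Pixel indices are 0-based, x = column, y = row, and a pixel's centre sits at
its integer index, so position (nm) = index × pixel size. All distances are
reported in nm, times in s, diffusion coefficients in µm²/s. Intensities are
arbitrary fluorescence units (FU). Images are background-corrected by
subtracting, per frame, the mean intensity of a user-supplied region outside
the cell; negative results are clamped to zero because the segmenter assumes
non-negative intensities. Correction is per-frame (removing slow background
drift); the alternative, a single per-movie constant, differs only when the
background drifts, and the per-frame choice is the conservative one.

## Spot segmentation

Segmentation follows a three-step rule per frame:

1. **Seeding.** All local intensity maxima (8-neighbourhood; plateaus reduced
   to their lexicographically lowest pixel, border-touching plateaus
   discarded) above a seed threshold. The threshold is per-image
   configuration; when not given it defaults to the robust rule
   median + *k*·MAD with *k* = 5. For noisy data an optional Gaussian
   pre-filter (`smoothSigmaPx`, typically 1 px) is applied before seeding
   and growth — the same light noise-removal filtering used on raw
   microscopy frames — because at low SNR a threshold 5 SD above background
   otherwise sits exactly at the expected peak height of the dimmest real
   spots. Blurring a Gaussian spot with a Gaussian kernel does not move its
   centre, so centroids are unaffected.
2. **Border threshold.** Mean intensities are computed in concentric
   1-px-wide rings around each seed out to `rMax` (10 px). The border
   threshold is the ring mean at the first radius where the relative drop
   between successive rings falls below `flattenTol` (0.05) — the local
   background shoulder of the spot. The flattening rule is our
   operationalization of "the radial profile defines a border"; it returns
   the pedestal level for spots on flat backgrounds and the outermost ring
   mean when the profile never flattens.
3. **Monotone radial growth.** From each seed, in decreasing intensity
   order, a pixel is accepted iff it is above the border threshold, at most
   as bright as the accepted 4-neighbour through which it is reached, and
   4-adjacent to the region. Seeds are processed in decreasing intensity and
   earlier spots keep contested pixels, so pixel sets are disjoint and the
   procedure is deterministic. The centroid is the intensity-weighted mean
   of accepted pixel positions with border-subtracted weights.

Measured localization precision of this weighted-centroid estimator: below
0.05 px RMS on noiseless isolated Gaussian spots, and ~0.4 px RMS at SNR 5
(peak amplitude five times the background noise SD). That is genuinely
sub-pixel but short of what maximum-likelihood Gaussian fitting would give;
since all downstream criteria operate at 130–160 nm (1–2 px), the weighted
centroid is sufficient and keeps the segmenter faithful to its published
description.

## Object-based colocalization

For each channel-A punctum the Euclidean centre-to-centre distance to the
nearest channel-B punctum is computed from sub-pixel centroids; two puncta
are colocalized when that distance is strictly below the criterion — 160 nm
for TIRF (100 nm pixels) and confocal (160 nm pixels), 130 nm for
super-resolution confocal (65 nm pixels), mirroring one pixel / the lateral
resolution of each modality (`modalityPreset()`).

Significance uses an object-randomization null: each of (by default) 100
iterations relocates every B object to a uniformly random in-mask position —
rigidly moving its whole segmented pixel set, with no overlap between
relocated objects — and recomputes the distances against the fixed A set.
The p-value is the add-one permutation estimator
(1 + #{null fraction ≥ observed}) / (iterations + 1), so it is never exactly
zero and never below 1/101 at 100 iterations. A faster point-approximation
mode relocates centroids only; it is what the closed-form CSR oracle checks:
for complete spatial randomness with intensity λ the expected criterion
fraction is 1 − exp(−λπr²). The mean cumulative distance curve with its
pointwise 2.5/97.5 percentile band is returned for plotting. Whether
relocated objects should additionally preserve the empirical
nearest-neighbour exclusion of real images is unknowable from the published
description; plain uniform non-overlapping placement was chosen.

Filament (actin-like) channels are not amenable to object-based analysis;
they are Gaussian-filtered (σ = 0.5 px) and thresholded — Otsu by default,
absolute FU by configuration — into a mask, against which Manders split
coefficients (fraction of a channel's intensity inside the mask) and
per-region distance analyses are computed. Cell masks can be partitioned
into a peripheral annulus (depth 15 px, i.e. 2.4 µm at 160 nm pixels) and a
central core via the Euclidean distance transform.

## Tracking and mobility classification

Per-frame detections are linked frame-to-frame by exact minimum-total-cost
bipartite matching (Jonker–Volgenant shortest augmenting paths) restricted
to pairs within the displacement gate of 1.5 µm/s × Δt, maximizing the
number of links first; track ends are then joined across up to 2 missing
frames when the implied speed over the gap stays below the same limit. The
matching is deterministic and order-independent, and agrees exactly with
exhaustive enumeration on small frames (a property the test suite checks on
1000 random frames).

Each trajectory of at least 45 frames is classified from its time-averaged
MSD, fitted as log MSD vs log t over the first 10 lags under the
anomalous-diffusion model MSD = 4Dt^α: immobile when α < 0.1, subdiffusive
up to 0.8, diffusive up to 1.2, directed above (band edges configurable).
The 10-lag fit range is standard practice — long lags of a time-averaged MSD
are dominated by noise — and trajectories with numerically zero MSD get
α = 0 (immobile) rather than a fit failure. The published analysis reached
the α < 0.1 rule through a machine-learning trajectory classifier applied
upstream; here the α bands are applied directly, since α is the operative
criterion and the bands are configurable. A 30-s two-colour temporal overlay
(early frame green, late frame magenta, immobile structures white) is
provided for visualization.

With these settings, simulated immobile particles (20 nm localization noise,
300 frames) are classified immobile in ≳95% of cases and Brownian particles
(D = 0.01 µm²/s) diffusive in ≳95% with ensemble mean α ≈ 1.0. Localization
noise biases α downward (a static-error offset in the MSD): at 20 nm noise
on D = 0.01 µm²/s the expected log–log slope over 10 lags drops to ~0.87,
which is why noise-free Brownian trajectories are the right oracle for
α-recovery checks.

## FRAP

Curves are normalized to the mean of (at least 3) pre-bleach frames. The
mobile fraction is M~f~ = (F~plateau~ − F~post~)/(F~pre~ − F~post~) with the
plateau from a single-exponential recovery fit
F(t) = F~post~ + (F~plateau~ − F~post~)(1 − e^−t/τ^), falling back to the
mean of the last 20% of post-bleach frames if the fit fails, and clamped to
[0, 1]. The published analysis delegated this to an ImageJ plugin without
stating the formula; the definition above is the conventional one such
plugins implement. No correction for acquisition photobleaching of the
whole cell is applied (none was described); M~f~ is invariant to rescaling
the raw curve.

## Ca^2+^ puffs and calibration

ΔF/F₀ movies use a per-pixel baseline F₀ averaged over a fixed pre-stimulus
window (50 frames = 2.5 s at 20 frames/s); pixels with non-positive baseline
are masked and reported. The puff detector replaces the published (external)
event-detection software with a transparent equivalent: Gaussian-smooth each
frame (σ = 1 px), threshold ΔF/F₀ (default 0.3), connect supra-threshold
voxels over space-time with 26-connectivity, and keep events spanning at
least 2 frames. Noise can briefly push a decaying event below threshold, so
co-located fragments separated by ≤ 2 frames are merged back. Per event the
peak amplitude is the maximum smoothed ΔF/F₀ and the centroid is the
amplitude-weighted spatial centroid at the peak frame. Event counts are
monotone non-increasing in both thresholds, which is the basis of
threshold-sensitivity controls. Frame smoothing attenuates peak amplitudes
by σ~s~²/(σ~s~² + σ~k~²) (≈ 7% for 600 nm events at 160 nm pixels), partially
offset at finite SNR by the maximum over noisy voxels; the net amplitude
bias stays within 10% across peak ΔF/F₀ of 0.3–1.0 at SNR 5.

Events are grouped into release sites by single-linkage clustering with a
500 nm cutoff (events exactly at the cutoff merge) — the scale of the
within-site wander of successive puff centroids; site centroids are means of
member events. Event-to-punctum distances reuse the colocalization distance
engine.

Fluorescence is calibrated to [Ca^2+^]~c~ by
[Ca^2+^]~c~ = K~D~(F − F~min~)/(F~max~ − F), with K~D~ = 389 nM for Fluo-8;
the function is monotone, errors on saturation (F ≥ F~max~), and round-trips
with its closed-form inverse to machine precision.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions used throughout the tests:

* **Puncta fields**: 20 × 20 µm cells at 100 nm pixels, 300 puncta per
  channel, PSF σ = 150 nm, constructed colocalized fraction 0.30 with
  offsets drawn uniformly in an 80 nm disc (so every constructed pair passes
  the 160 nm criterion with margin), amplitude 100 FU on a 100 FU baseline
  with Poisson shot noise plus Gaussian read noise chosen so peak/background-
  noise SNR = 5. A minimum centre spacing of 4σ keeps spots identifiable to
  the segmenter. By default the spacing is also enforced between *unpaired*
  A puncta and all B puncta, so the generator's colocalization flags
  coincide exactly with the 160 nm criterion applied to the true centroids;
  without that exclusion, chance proximity under CSR (≈ 5.9% at these
  densities) would make the constructed fraction unrecoverable as such.
  Plain CSR placement is available via `crossChannelExclusion = FALSE`.
* **Filaments**: cubic splines through random waypoints, resampled at
  uniform arc length and stamped with a Gaussian cross-section; the truth
  mask is the FWHM footprint of the rendered ridge.
* **Motion**: immobile (fixed position + localization noise), Brownian
  (per-axis step variance 2DΔt) and directed (constant random-direction
  velocity) particles, reflected at the field boundary; a confined class is
  deliberately omitted from the default mix. Defaults D = 0.01 µm²/s,
  v = 0.5 µm/s, Δt = 0.1 s, 300 frames.
* **FRAP**: F(t) = F~post~ + M~f~(F~pre~ − F~post~)(1 − e^−t/τ^) with τ = 10 s
  and 2% Gaussian noise.
* **Puffs**: multiplicative local transients (linear rise over 2 frames,
  exponential decay over 8) with Gaussian spatial profile σ = 600 nm at 20
  frames/s; noise is Gaussian with SD set so that (true peak ΔF/F₀) /
  (per-pixel ΔF/F₀ noise SD) equals the requested SNR — an event-referenced
  definition, so "SNR 5" describes every event size equally. Shot noise is
  omitted in this generator so that the event SNR is exactly controllable.

What the generator does **not** emulate: photobleaching, 3-D PSFs and
defocus, camera gain and fixed-pattern noise, spatially varying background,
clustered (non-CSR) punctum placement, confined motion in the default mix,
and puff kinetics beyond rise/decay. Tests passing on these synthetics
therefore demonstrate algorithmic correctness and calibration under the
stated statistical structure — not robustness to every artefact of real
microscopy, where per-image thresholds (as in the original workflow) remain
the user's responsibility.

All generators are reproducible: a fixed seed yields bit-identical truth and
stacks, and every randomized analysis (the null model, the workflows) takes
an explicit seed and restores the caller's RNG state.

## Numerical choices and degenerate inputs

* Strict "<" at the colocalization criterion; ties at a site-clustering
  cutoff merge (≤).
* Contested segmentation pixels go to the earlier (brighter-seeded) spot.
* The assignment solver pads the gated cost matrix with per-row dummy
  columns costing more than any admissible total distance, so maximum
  cardinality always precedes distance minimization.
* Zero-MSD trajectories → α = 0; movies shorter than 45 frames classify
  nothing and warn; empty frames segment to zero puncta; an empty event list
  yields empty site tables; saturated calibration input is an error, not a
  clamp.
* Problem sizes in the test suite (20 synthetic cells of 300 + 300 puncta
  for colocalization recovery; 100-iteration nulls; 200 trajectories of 300
  frames per motion class; 100 FRAP curves per condition; 20-event puff
  movies) were chosen to give the binomial/ensemble statistics quoted above
  stable margins on a single CPU.
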