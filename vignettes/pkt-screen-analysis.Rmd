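---
title: "Quantifying migratory phenotypes from phagokinetic track screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying migratory phenotypes from phagokinetic track screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pktscreen)
```

## The assay and the analysis problem

In a phagokinetic track (PKT) assay, cells are seeded on a substrate coated
with a thin lawn of discrete latex beads. As a cell migrates it phagocytoses
the beads it crosses, leaving behind a bead-free track that integrates
several hours of movement into a single still image. Because a whole 96-well
plate can be imaged once at the end of the assay (7 h of migration by
default here), the readout scales to genome-scale siRNA screens in a way
live imaging does not.

The analysis chain this package implements runs from raw montage to
validated hit:

1. **Track quantification** — segment bead-free regions in a transmitted
   light whole-well montage (6 × 6 tiles), keep only tracks containing
   exactly one cell, and measure eight morphometric parameters per track.
2. **Plate normalization** — robust Z-scores of per-well medians against
   the plate's pooled mock-transfected control tracks.
3. **Phenotype classification and hit calling** — five rule-sets over raw
   medians and Z-scores define the migratory classes *small*, *small
   round*, *big round*, *long rough* and *long smooth*; a treatment whose
   replicate-averaged profile falls in any class is a primary hit.
4. **Deconvolution validation** — a SMARTpool hit (a pool of four siRNAs)
   is validated when the pool and at least two of the four single siRNAs
   show significant, sign-concordant effects.
5. **Live-cell confirmation** — overlap-based single-cell tracking of
   12-h GFP time-lapse movies (one frame every 12 min), with a
   dual-control nonparametric significance contract.
6. **Morphology profiling** — mock-normalized log2 fold-change profiles of
   single-cell shape features, clustered with Euclidean distance and
   complete linkage.

Every stage is driven by a seeded synthetic-data generator with known
ground truth, so the whole chain is testable without any external images.

## The motility model

The generator's cells follow a constant-speed persistent random walk
(PRW): the cell moves at speed $s$ while its heading angle $\theta$
undergoes rotational diffusion with coefficient $1/P$, giving the velocity
autocorrelation $\langle \mathbf v(t)\cdot\mathbf v(0)\rangle = s^2
e^{-t/P}$ and the classical Fürth mean-squared displacement

$$\mathrm{MSD}(t) \;=\; 2 s^2 P\left(t - P\,(1 - e^{-t/P})\right),$$

ballistic ($s^2t^2$) for $t \ll P$ and diffusive ($2s^2Pt$) for $t \gg P$.
We chose the constant-speed heading formulation over an
Ornstein–Uhlenbeck velocity process deliberately: both are standard
minimal PRW models with the same MSD, but only the constant-speed form has
exact degenerate limits — zero speed gives a perfectly stationary cell, and
infinite persistence with zero turn noise gives a straight line of length
exactly $s\,\Delta t\,n$, which the test suite asserts to $10^{-9}$
relative precision. The walk is integrated on an internal substep grid
(at most $P/50$ per substep) so the sampled ensemble MSD matches the
closed form without discretization bias even at one-sample lags; the suite
checks agreement within 5% across lags spanning both regimes.

An optional `turn_noise` term adds white heading jitter on top of the
rotational diffusion (effective inverse persistence
$1/P + \tau^2/2$); it defaults to 0 so that `persistence_time` alone
controls the MSD. `protrusiveness` only affects rendering: it stamps
small lobes on the cleared-track boundary, raising the measured roughness
without changing the path.

## Rendering and quantification choices

**Bead lawn.** Beads are Poisson-scattered dark puncta (radius 1.5 px) at
a default density of 0.15–0.25 beads/µm²; real lawns are dense, and a
sparse lawn leaves natural bead-free vacancies comparable to genuine
tracks. Pixel scale defaults are 0.65 µm/px for PKT montages (×10
objective) and 0.33 µm/px for time-lapse (×20); both are configurable
because the original acquisitions specify objectives, not scales.

**Segmentation.** The dark-pixel mask is split into beads versus cell
bodies by a morphological opening (anything surviving an opening larger
than a bead is a cell). The bead texture is made solid by a closing whose
radius exceeds the typical bead gap but stays below half the track width;
the complement of this "lawn" yields candidate tracks, cleaned by an
opening, hole-filling and a 50 px² minimum-area floor. Border-touching
regions are flagged and excluded by default, since their morphometry is
truncated. A blank or saturated montage (dark fraction < 1% or > 90%)
returns zero regions with a QC warning rather than an error.

**Single-cell acceptance.** Tracks without a cell body, or with more than
one, are excluded; the cell count per region is the number of opened dark
blobs (≥ 40 px²) assigned to the region by majority overlap of a slightly
dilated blob — centroid assignment alone fails when a cell sits at the
track rim.

**The eight parameters.** Net area is the cleared-pixel count; gross area
the convex-hull area computed over pixel *corners* (guaranteeing
net ≤ gross); major and minor axes come from the second central moments
(ellipse-equivalent, with the 1/12 per-pixel term); axial ratio is their
quotient; the perimeter is the 8-connected boundary chain length with the
Vossepoel–Smeulders corner correction (≈1% accurate on smooth shapes);
roughness is $P^2/(4\pi A)$, clamped below at its theoretical floor of 1
(a perfect disc can raster marginally below 1); solidity is net/gross.
The named assay parameters are net area, major/minor axis, axial ratio
and roughness; gross area, perimeter and solidity complete the set of
eight. The roughness formula is a documented default: the screen's
original quantifier thresholds roughness at 5 without publishing its
formula, so the thresholds and the formula are both overridable through
`phenotype_thresholds()` and `measure_track()`.

## Normalization and classification

Robust Z-scores are computed per plate:
$Z = (\tilde x_{\text{treatment}} - \tilde x_{\text{mock}})
/(1.4826\,\mathrm{MAD}_{\text{mock}})$, with the mock statistics taken
over the pooled *track-level* values of the plate's ≥ 2 mock wells. The
pooling level and the 1.4826 consistency constant are documented choices;
a zero mock MAD raises an error naming the degenerate parameter. Wells
with fewer than 10 accepted tracks are excluded; after replicate
averaging (arithmetic mean of the available replicate Z-scores, at least
2 of the 2 technical × 2 biological wells), knockdowns with fewer than 3
images or fewer than 60 (Hs578T) / 150 (MDA-MB-231) accepted tracks —
summed over replicates — are excluded. Applying the count minima to the
replicate *sum* rather than per replicate is a deliberate reading of the
protocol and is flagged here; the boundary is inclusive everywhere
(exactly 10 tracks, exactly 60/150, exactly 3 images, exactly 2 h all
survive).

The five phenotype rule-sets are applied exactly as printed, raw-value
and Z conditions conjunctive, classes tried in listed order with first
match as primary and all matches retained for audit. Two quirks are kept
as printed rather than "fixed": the big-round class requires an axial
ratio Z below −4 (stricter than small-round's −3), and the long-smooth
class has no Z conditions at all. The raw-value thresholds (8000, 1.7,
2.1, 2.4, 180, 200, 5) are interpreted in the quantifier's native pixel
units. The threshold table is versioned (`printed-v1`) and replaceable,
since the original screen also involved manual curation that is out of
scope here.

Deconvolution validation uses $|Z| \ge 2$ on net area or axial ratio as
the significance criterion — the protocol says only "significant", so the
cut is explicit and configurable — and requires the single siRNA's sign to
match the SMARTpool's on that parameter. Missing singles count as
non-significant and are flagged.

## The feature-level screen simulator

`generate_screen_plates()` bypasses imaging and draws per-track features
directly from log-normal distributions whose medians shift
multiplicatively under planted per-gene effects, with Poisson per-well
track counts (mean 120) so the count-based QC filters are exercisable.
Mock medians sit at net area 10⁴ px², axial ratio 2.0, major axis 220 px,
roughness 3.0 — placed so every raw threshold is live: net area above the
8000 px² cut, axial ratio below the 2.1 long-track cut, roughness on the
smooth side of 5. Track-level noise (σ_log ≈ 0.10–0.15) plus a small
shared well-level jitter (σ_log = 0.02) was fixed once so that the robust
Z denominator (pooled mock track MAD) makes the printed Z thresholds
discriminative: a net-area multiplier of 0.2 lands near Z ≈ −5, while
null wells stay within |Z| ≲ 0.3. The original acquisition parameters
that would pin these values (plating density, bead size distribution) are
not published, so the defaults are the package's own calibration, stated
here once and not revisited.

What the simulator deliberately does *not* model: optical blur and
shading, bead-phagocytosis kinetics, proliferation during the assay,
correlated multi-parameter effects of real knockdowns, and plate-position
effects. Passing tests therefore demonstrate that the *analysis* is
correct and well-calibrated under the stated generative model, not that
segmentation is robust to every real-world imaging artifact.

## Single-cell tracking and statistics

Frames are thresholded at half the frame maximum and touching blobs split
by a distance-map watershed; a frame whose maximum is below 0.1 is blank.
Linking is greedy one-to-one on decreasing pixel overlap with a default
minimum of 1 px (any overlap links, the literal reading of
overlap-based tracking); gaps are not bridged and divisions are not
handled specially — the largest-overlap daughter continues the track, the
other starts a new one. Trajectories shorter than 2 h (11 samples at
12-min spacing, boundary inclusive) are discarded. Per-cell speed is path
length over duration; the directionality ratio is displacement over path
length, reported as 0 for a stationary cell.

Knockdown speed distributions are compared against *two* density-matched
negative-control wells with a Kruskal–Wallis test followed by Dunn's
pairwise post test (pooled-rank z statistics with tie correction,
Bonferroni over the three pairs — Dunn's classical form; the protocol
names only the test family). A knockdown is significant only if it
rejects against both controls at α = 0.05. Group medians are reported
with binomial order-statistic 95% confidence intervals. Groups below 5
cells give an inconclusive verdict rather than a p-value.

## Morphology profiling

Scenes pair a nucleus mask with a cell-body mask; nuclei without an
enclosing body are rejected, mirroring the screen's rejection rule.
Spikes (protrusions) are counted as connected residuals of a
morphological opening (structuring radius `width_max`/2 = 15 px) that
protrude at least `depth_min` = 5 px from the opened body — the
screen never defines "spikes" operationally, so the convexity-residual
definition with these defaults is this package's explicit, configurable
choice. Profiles are per-feature log2 fold changes of the knockdown
median over the pooled median of the plate's 2 mock wells (features:
area, perimeter, form factor, spike count, nucleus area — the original
feature list is unpublished, so this compact default is an explicit
assumption), floored at 10⁻⁶ to guard zero medians. Clustering is
`hclust` complete linkage on Euclidean distances, checked in the suite
against a brute-force agglomerative oracle on small inputs.

## Numerical and testing conventions

* Coordinates are pixel units, origin top-left, `[y, x]` indexing;
  regions are 8-connected.
* All generators take a single integer master seed; per-plate and
  per-well streams are split off by counter-based mixing, so subsets are
  reproducible and identical configurations are bit-identical.
* Rendered track collisions are kept (they happen in real wells) but
  flagged in the ground truth; recovery tests use non-colliding
  configurations, and collided tracks fail the one-cell rule downstream.
* Test problem sizes — a 96-well screen with 80 genes over 2 × 2
  replicates at 20 seeds, one 61-frame movie of 20 cells, 1000 null
  replicates of the dual-control test, a 10⁴-point classifier grid —
  were chosen as the smallest sizes at which the targeted rates
  (sensitivity ≥ 0.9, false-positive rate ≤ 0.05, null size ≤ 0.05,
  power ≥ 0.95) are measured with useful precision.

## Known limitations

* The segmentation stages are documented stand-ins tuned for the
  synthetic renders, not re-implementations of the original tools (the
  PKT quantifier and the watershed-masked-clustering live segmentation).
* Headline screen counts from the original 4198-gene experiment are not
  reproducible from synthetic data; the package's claims are the
  property-based ones its tests measure.
* Manual phenotype curation, druggability filtering and all downstream
  network/expression analyses are out of scope.
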