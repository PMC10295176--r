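---
title: "Envelope-based colocalization of moving vesicles: models, parameters and design choices"
author: "smss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope-based colocalization of moving vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smss)
```

## The problem and the model

Sequentially acquired two-channel images of moving vesicles decorrelate in
intensity space: a lysosome travels a distance comparable to its diameter
between the two channel scans.  `smss` therefore works on *point patterns*:
spot centres of each channel inside a polygonal region of interest (the
traced cell border, nucleus removed as a hole).  Colocalization becomes a
hypothesis test on the bivariate pattern, with two null models:

- **CSR**: channel-2 positions are uniform in the ROI, independent of
  channel 1.
- **Transport**: each channel-2 spot is a channel-1 spot displaced by a
  jump `ℓ(cos θ, sin θ)` with `ℓ ~ LogNormal(μ, σ)` and `θ ~ U[0, 2π)`,
  modelling motion between the two channel acquisitions.  Proposals
  falling outside the ROI are redrawn *in full* (new length and angle);
  the simulated count is then matched to the observed channel-2 count by
  appending uniform points or subsampling.

The summary functions are the nearest-neighbour function `G12` (raw
empirical CDF, no edge correction — its defining sum has none), the
translation-corrected bivariate K-function `K12`, and the pair-correlation
function `g12` estimated with an Epanechnikov kernel.  The translation
weight `b_ij = |Ω|/|Ω ∩ (Ω + v_ij)|` is computed by exact polygon
clipping: the ROI (with holes) is decomposed into signed fan triangles and
pairwise triangle intersections are accumulated, which handles concave
outlines and nucleus holes without rasterization error.  Axis-aligned
rectangles take a closed-form fast path.  Pairs whose displacement yields
zero overlap have no defined weight; they are dropped and counted in the
curve metadata.

## Envelope construction and interpretation

`runSMSS()` simulates N null patterns (default 100), computes their
summary curves with identical estimator settings, and at every distance r
excludes the ⌊αN⌋ values deviating most (in absolute value) from the
pointwise mean, ties broken by simulation index; the min/max of the
remaining values form the envelope (95 retained values at N = 100,
α = 0.05).  The observed curve is not part of the ensemble.  Maximal
r-intervals where the data leave the band are reported as rejections at
level α.

Two caveats are deliberate properties of this construction, documented
rather than "fixed":

- The envelope is *pointwise*.  Scanning many r values inflates the
  family-wise type-I error; even data generated under the null exits the
  band at roughly an α-fraction of grid points.  Global rank envelopes are
  out of scope.
- With matched parameters, transport data are exchangeable with the
  simulations, so coverage at any fixed r is ≈ 1 − α, not 1.

A known identifiability limit is inherited from the geometry: when the
mean spacing of channel-2 spots falls below the jump scale, the CSR and
transport envelopes merge and the two hypotheses cannot be told apart.
The test suite measures this as the mean pointwise Jaccard overlap of the
two bands along a 3-step density ladder at fixed jump scale (10 × 10 µm
window, n = 30/300/3000); the overlap grows monotonically (≈ 0.02 → 0.27
→ 0.81 in the checked configuration).

## Spot detection

Detection uses the undecimated B3-spline à-trous wavelet transform
(kernel [1,4,6,4,1]/16, dilation 2^(j−1), mirror boundary; the
decomposition is exactly additive).  Each selected detail plane is
thresholded at `kSigma` × its robust noise scale (MAD/0.6745); the default
mask is the conjunction of planes 2 and 3, matched to spot diameters of
roughly 3–10 px.  A single thresholded plane of smooth noise occasionally
leaves correlated blobs above the minimum size; the 2∧3 conjunction is the
standard multiscale-correlation remedy and keeps blank noise images
spot-free at the default `kSigma = 3`, `minSize = 5`.  Touching blobs are
split by a watershed on the distance transform (EBImage's hill-climbing
watershed rather than an explicitly seeded variant; it is deterministic
and splits the canonical 6-px dumbbell).  Centres are intensity-weighted
centroids computed on the background-subtracted detail image, which makes
both the count and the centroids exactly invariant to a constant
background offset.  Pixel centres map to continuous µm coordinates with
the image convention (origin top-left, y downward); points exactly on the
ROI border count as inside, so rejection loops terminate deterministically.

## Tracking and trajectory analytics

Frame-to-frame linking solves a dense linear assignment per frame pair
(shortest augmenting paths) with candidate links limited to `maxLink` and
the non-link alternative priced at `maxLink²`; a second assignment closes
gaps of up to `maxGap` skipped frames within `gapDist` (defaults 1 µm, 2
frames, 2 µm).  Merging and splitting are not modelled.  Gap-closed frames
are recorded as gaps and never interpolated: jump distances and MSD pairs
only use sample runs without missing frames, so dropout thins the
statistics instead of biasing them.  "At least 10 time points" counts
detections, not frame span.

The 8-feature descriptor per trajectory: mean, SD, skewness and kurtosis
(non-excess, normal = 3) of the frame-to-frame jump distances;
straightness (net displacement over path length); corrected sinuosity
`2 sqrt(p (1 − c)/(1 + c))/p` with `p` the mean step and `c` the mean
cosine of turning angles; average MSD (time-averaged MSD, mean over lags
1..min(4, n−1) — the lag count is a package choice, configurable); and the
turn-angle correlation.  Features are z-scored before embedding.

Motion classes are found with exact t-SNE (2 components, perplexity 30,
1000 iterations, adaptive gains, fixed seed) followed by DBSCAN
(`minPts = 5`; `eps` from the k-distance elbow unless given).  Neither
stage is available as an installed library here, so both are implemented
in the package; trajectory sets are small (hundreds), making the quadratic
exact t-SNE the simplest correct choice.  Clusters below 4% of
trajectories are flagged and excluded from MSD analysis — mirroring the
practice of dropping near-empty clusters, with the threshold itself a
package choice.  Per cluster, the ensemble MSD (pooled over trajectories
and time origins) is fitted as `ln MSD = ln 4D + α ln t` by least squares
on the log scale, which tames the heteroscedastic large-lag tail; a
nonlinear fit on the linear scale would weight those lags more.  Exponent
thresholds for labels: immobile α < 0.3, subdiffusive < 0.9, diffusive
< 1.3, superdiffusive above, boundaries assigned upward.

## Synthetic data: what it emulates, what it does not

All generators are seed-deterministic and mirror the measured scales:
ROI ≈ 40 × 40 µm cell-like polygon with a nucleus hole, Δt = 0.827 s, 100
frames, lognormal jumps (μ = −1.87, σ = 0.94), D values at the fitted
cluster scales (0.036 µm²/s diffusive).  Pattern kinds: independent CSR,
transport-displaced (sharing the null model's displacement code path, so
generator and test stay in distributional agreement), Thomas-type
clustered, and jittered periodic lattices.  Motion kinds: Brownian
(per-axis increment variance 2DΔt), immobile (pure localization jitter),
subdiffusive (fractional Gaussian increments via circulant embedding,
Hurst H = α₀/2 — a choice; only the target exponent is prescribed), and a
Lévy-walk-like bimodal mode alternating directed runs (1 µm/s, mean 2 s —
an active-transport scale) with diffusive pauses (mean 20 s), yielding the
heavy-tailed jump distribution that motivates the lognormal transport
null.  Spot images are Gaussian blobs plus constant background and Poisson
shot noise.

Passing tests on these fixtures demonstrate estimator correctness and
pipeline behaviour under the stated models.  They do not capture real
data's 3-D character (vesicles leaving the focal plane blur correlation
beyond ≈ 0.5 µm), chromatic aberration, photophysics, or within-track
state switching — all outside the package's scope.

## Numerical choices and degenerate inputs

- Polygon predicates treat boundary points as inside; overlap areas are
  exact up to floating point (~1e−9 relative).
- `g12` grids exclude r = 0 (the 1/(2πr) factor diverges); the default
  grid starts at the bandwidth, with Stoyan's rule
  `h = 0.15/sqrt(n2/|Ω|)` as default bandwidth, and spans a quarter of
  the shorter ROI extent over 512 points.
- Coincident cross-pairs contribute at every r ≥ 0; duplicates are kept.
- Empty patterns raise explicit errors rather than NaN curves; an ROI too
  small for the jump scale aborts the rejection loop after 10⁵ redraws
  with an infeasible-geometry error.
- MSD fits require ≥ 3 positive lags; noiseless curves are recovered to
  machine precision and the fit is exactly scale-equivariant (D scales as
  c², α invariant).
- Per-simulation seeds derive from the master seed by a counter scheme
  and are logged in the envelope metadata; identical configuration and
  seed give byte-identical outputs.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
10⁶ draws for the lognormal MLE recovery, 1000 × 100-frame tracks for the
MSD refit, 200 replicates of 500-point CSR patterns for the closed-form
checks, 100-simulation envelopes on 300-point scenes for the qualitative
control-scene verdicts, and the 30/300/3000 density ladder for the
identifiability property.
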