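---
title: "Resistance mapping from hybrid resistive-pulse and imaging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resistance mapping from hybrid resistive-pulse and imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpmap)
```

## The measurement problem

A resistive-pulse (RP) experiment monitors the ionic current through a
microfluidic channel while insulating particles are advected through it.
Each translocation produces a transient current decrease whose relative
amplitude $\Delta I / I_p$ equals the relative resistance increase
$\Delta R / R_0$ (Ohm's law, constant applied voltage). The amplitude
carries information about particle size, but it also depends on *where* the
particle is — its axial position in channels of varying width, and its
lateral (off-axis) displacement everywhere. The RP signal alone cannot
resolve position. `rpmap` implements the complementary strategy: record a
high-speed image stream simultaneously with the current, detect the
translocation events independently in each stream, align the two clocks,
and attribute every current sample to a position in the channel. Aggregated
over many events this yields a *resistance map* — the mean instantaneous
$\Delta I / I_p$ as a function of channel coordinates — plus the derived
positional statistics (axial profiles, lateral dependence, region ratios).

No raw recordings from this kind of experiment are publicly deposited, so
the package ships a physics-based simulator that generates mutually
consistent current traces and frame stacks from a known ground truth. The
analysis chain never sees the ground truth; the simulator's closed-form
amplitude model is also the oracle that the tests compare against.

## Closed-form amplitude models

Four standard results anchor the analysis (all implemented in
`smythe_amplitude()`, `offaxis_factor()`, `local_delta_r()`,
`amplitude_ratio()`):

* On-axis blockade of a sphere (diameter $d$) in a long cylindrical channel
  (diameter $D$, length $L$):
  $\Delta I / I_p = \frac{d^3}{L D^2}\left[1 - 0.8 (d/D)^3\right]^{-1}$.
* Off-axis enhancement: $\Delta V(y)/\Delta V(0) = 1 + \alpha (y\, d/D)^3$
  with $\alpha$ an empirical coefficient reported in the range 5–7.5.
* Local resistance change at a position with local diameter $D(x_c)$:
  $\Delta R = \frac{4\rho d^3}{\pi D(x_c)^4}\left[1-0.8(d/D(x_c))^3\right]^{-1}$,
  which depends only on the geometry local to the particle.
* Consequently the ratio of relative amplitudes between two regions equals
  the ratio of local resistance changes and is independent of the solution
  resistivity.

Rectangular cross-sections are mapped to cylinders of equal
cross-sectional area, $D_\mathrm{eq} = \sqrt{4wh/\pi}$
(`equivalent_diameter()`), uniformly wherever the formulas need a diameter.
The identity $\Delta R_\mathrm{local} / R_0 =$ on-axis form (with
$R_0 = \rho \int A^{-1} dx$) holds algebraically and is enforced to
$10^{-12}$ relative error in the tests.

### The lateral-displacement convention

The off-axis formula is dimensionally meaningful only if $y$ is
normalised. We take $y_\mathrm{norm}$ = lateral displacement of the
particle *centre* divided by the channel *radius* (0 on axis, 1 at the
wall), so the accessible range ends at wall contact,
$y_\mathrm{norm} \le (D-d)/D$. For rectangular channels the physically
accessible range, $|y_c| \le (w-d)/2$, does not coincide with the
equivalent cylinder's wall-contact bound; the simulator and the
$\alpha$-recovery fit map the accessible *fraction* proportionally:
$y_\mathrm{norm} = \frac{|y_c|}{(w-d)/2}\cdot\frac{D-d}{D}$, so wall
contact maps to wall contact. With this convention the maximal predicted
excess over the three straight study channels (widths 15/25/30 µm, height
20 µm, $d = 10$ µm) spans 6.2 % ($\alpha = 5$, widest channel) to 11.7 %
($\alpha = 7.5$, narrowest), matching the 6–12 % range quoted for these
geometries.

## What the simulator emulates

`generate_dataset()` reproduces the study conditions: 10 µm beads; straight
channels (150 µm long, 15–30 µm wide, 20 µm high) and cavity channels
(17.5/30 and 20/50 µm narrow/wide); current sampled every 4 µs; frames
every 20 µs (50,000 frames/s) with 5 µs exposure; Gaussian current noise,
slow sinusoidal baseline drift, pixel noise; and a small clock-rate
mismatch between the streams.

* **Transport.** Plane-Poiseuille flow in the width dimension only: axial
  velocity $v(y) = v_\mathrm{max}(x)\,[1-(2y/w(x))^2]$, with the centreline
  velocity rescaled by 2D continuity across width changes
  ($v_\mathrm{max}\,w$ constant) and particles following streamlines (their
  relative lateral position $2y/w$ is conserved; in the cavity $y$ scales
  with the local width). The height dimension is ignored because the
  channel height is comparable to the bead diameter, which suppresses
  vertical motion. Because the velocity is piecewise constant in $x$, paths
  are exact piecewise-linear functions of time — no integration error.
  Default $v_\mathrm{max} = 10^5$ µm/s gives 1.5 ms on-axis transits,
  i.e. ~75 frames and ~375 current samples per event, the same
  "short distance travelled between data points" regime as the experiments.
* **Amplitude composition.** At every sample the blockade is the local
  closed form at $x_c(t)$, times the off-axis factor (in straight/narrow
  sections), times a transition envelope. The factors are multiplicative
  because each is individually testable and no joint model is available.
* **Transition zones and access resistance.** Inside each channel end the
  envelope ramps from `access_frac` (default 0.5) of the plateau to 1 over
  a cubic smoothstep of length `ell_t_um` (default 15 µm — larger than the
  bead, as observed); outside, the access blockade decays exponentially
  (default 20 µm). With the default `access_frac = 0.5` the mouth amplitude
  sits exactly at half maximum, so the pulse FWHM coincides with the
  physical transit — the configuration the FWHM-versus-entrance analysis is
  designed to reveal.
* **Cavity lateral dependence.** By default the cavity applies no off-axis
  factor. The optional `"suppressed_near_wall"` mode applies a
  phenomenological cosine taper (default 40 % centre-to-wall) so the
  analytics can be demonstrated to recover an inverted lateral trend; it is
  a knob, not a physical model — the field-theoretic origin of the
  inverted dependence is outside this package's scope.
* **Clocks.** The camera is the reference: frame-start timestamps are
  truthful, detections use mid-exposure times. The current stream's true
  sample times run at $(1+\varepsilon)$ per nominal tick while its
  recorded timestamps are `offset + k·Δ`; skew is therefore expressed
  entirely in the current stream, and the per-event fine offsets recover
  it.
* **Current synthesis.** $I = I_0(1+\mathrm{drift})/(1+a(t)) + \mathcal{N}(0,\sigma)$.
  The division (rather than a first-order $I_0(1-a)$) keeps the measured
  $(I_0-I)/I_p$ exactly equal to $a$, because $\Delta R/R_0 = \Delta I/I_p$
  is an identity of Ohm's law, not an approximation.
* **Reproducibility.** One seed; draws occur in a documented order
  (lateral positions, entry times, current noise, pixel noise per rendered
  frame). Identical seeds give byte-identical outputs. Frames are rendered
  only while a particle is in the field of view (with true frame indices
  kept), since everything else is exactly background.

What the simulator deliberately does not emulate: Brownian lateral
diffusion, particle–particle hydrodynamics, aspherical or deformable
particles, finite-element field distortions, camera vignetting or motion
blur beyond the single mid-exposure sample. Passing tests therefore
demonstrate that the *analysis chain* is correct and unbiased under the
stated noise model — not that the closed-form physics captures every
feature of a real recording.

## Detection choices

**Current stream.** The default low-pass is a centred moving average
(first spectral null at the cutoff, default 10 kHz). A moving average has
linear phase and a *monotone* step response; a Butterworth of useful order
rings at the abrupt resistance steps of cavity boundaries, which corrupts
the narrow/cavity extremum values (`filter_type = "butter"` remains
available). The baseline is a running median over 50 ms, computed twice:
provisionally detected events are masked and bridged before the second
pass so deep pulses cannot drag the baseline. The noise scale
$\hat\sigma$ is MAD-based on event-free residuals. Events open at
$k\hat\sigma$ (default $k = 6$; the Gaussian tail makes false positives
negligible at $2.5\times10^5$ samples/s) and close at half that
(hysteresis 0.5), so pulses merge only if the excursion never falls below
the closing threshold.

Per event, the blockade is normalised as $a = (I_0 - I)/I_p$. Without
position data $I_p$ is the mean current over the pulse's top region
(within 2 % of peak depth, widened by the smoothed-noise scale so the
selection stays symmetric in the noise); with synchronized positions it is
re-estimated from samples within ±50 µm of the channel centre
(`refine_ip`), the position-gated mode. `plateau_amplitude` (a top-region
mean) is the averaging estimator used for quantitative amplitude work —
its bias is below 1 % at $\sigma = a/20$ — while `peak_amplitude` (max of
the Savitzky–Golay-smoothed blockade, capped by the raw maximum so
polynomial overshoot at sharp edges cannot exceed the data) serves
morphology and FWHM. Extrema are zero crossings of the smoothed
derivative, pruned by persistence (pairs closer than
$\max(5\hat\sigma_a, 2\%\ \mathrm{peak})$ are removed) and restricted to
the above-threshold span. Extremum *values* are plateau averages: interior
extrema (the cavity minimum) use the central half between their flanking
extrema — a purely positional selection with no argmin noise bias — and
edge extrema use a quantile-anchored band; each is normalised by its own
local attenuated current so region values equal the local
$\Delta R / R_0$ without cross-region distortion. These choices are why
the wide/narrow ratio distributions centre on the theoretical prediction
instead of a few percent below it.

FWHM is measured between linearly interpolated half-peak crossings of the
smoothed blockade. On ideal rectangular/triangular pulses this is exact to
a fraction of a sample; on the simulator's smooth-mouthed pulses the
filtering chain widens it systematically by ~3 current samples (12 µs),
still below one frame period.

**Image stream.** Template subtraction (template minus frame, so dark
particles give positive response), intensity thresholding (automatic
threshold $5\times$ the MAD noise of the difference images, floor 10 grey
levels), flood-fill labeling (union-find over the sparse above-threshold
pixels; 4- or 8-connectivity, default 8; the 4-connectivity path is
cross-checked against an independent labeling implementation in the
tests), minimum-area filter (a quarter of the expected disk area), and
intensity-weighted centroids (sub-pixel; accurate to < 0.5 px on rendered
disks). Tracking is greedy globally-minimum-distance linking: all
candidate (track, detection) pairs sorted by distance, accepted while both
endpoints are free; tracks end after `max_frame_gap` (default 2) missed
frames. On well-separated scenes the greedy assignment coincides with the
brute-force optimal assignment (enumerated exhaustively in the tests for
up to 5 particles).

**Synchronization.** Coarse alignment scans candidate offsets (the
pairwise event-time differences, quantised to half the matching tolerance)
and keeps the offset maximising the greedy nearest-match count, refined to
the median matched residual; ties break towards the smallest offset. A
single coincidental pair is not accepted as an alignment. The RP event
time used for matching is the smoothed-blockade peak time; the IM event
time is the interpolated instant the particle crosses the channel
midpoint. Fine alignment anchors that midpoint frame to the median-index
sample of the RP event's above-threshold span, one offset per event —
sufficient because the accumulated clock discrepancy is negligible within
a single event. With $\varepsilon = 10^{-5}$ over one second the per-event
total offsets recover the true clock relation to within one frame period.

## Analytics

`build_map()` bins every synchronized `(x_c, y_c, a)` tuple (1 µm default,
matching the ±1 µm profile smoothing; x bins anchored at the entrance
plane, y bins centred on the axis). Samples with more than one particle in
the channel are dropped — superimposed blockades do not represent local
resistance — and the count is logged. Empty bins are absent, never
zero-filled. `axial_profile()` reports the moving mean ±1 sd, the
entrance/exit amplitudes, and the *saturation position*: the smallest
in-channel $x_c$ where the profile first reaches 99 % of its maximum
(`sat_tol = 0.01`; with the default 15 µm smoothstep this sits at ~14 µm,
so a ±2 µm acceptance window around the nominal transition length is
appropriate). `lateral_stats()` produces duration and amplitude profiles
against the event-mean lateral position with quadratic convexity
diagnostics; `fit_offaxis_alpha()` recovers $\alpha$ from the linearised
model $a = a_0(1+\alpha g)$ by OLS ($\hat\alpha$ = slope/intercept).
`ratio_distribution()` forms per-event wide/narrow ratios as interior
minimum over the mean of the two flanking maxima (the entrance-side-only
convention is available via `narrow = "entrance"`); the mean of the two
maxima is the default because the channels are symmetric and it halves the
variance.

## Numerical and degenerate-input behaviour

Domain violations (particle at least as large as the channel, lateral
positions beyond wall contact, non-positive dimensions) raise errors
rather than returning extrapolations. Zero-particle configurations are
valid (pure baseline trace, background-only frames). Events at trace
boundaries are flagged truncated. All-identical event sets make the
amplitude–duration fit report a degenerate flag with undefined $r$ instead
of a spurious slope. `width_profile()` returns `Inf` outside the channel —
the open reservoirs are unbounded, and the sentinel survives arithmetic
(any blockade computed there via the access model, not the local form).

## Problem sizes in the tests

The test-suite simulations use 5–30 events for unit properties and, for
the end-to-end checks, 100 events per condition (amplitude recovery,
synchronization, cavity ratios) and 300 events for the lateral statistics
(three independent 100-event recordings pooled), with 500 trajectory draws
for the passage-time distribution test. These sizes put the Monte-Carlo
standard error of each checked mean well below the acceptance band it must
meet while keeping the whole suite a matter of minutes on one CPU.

## Known limitations

* The transition-envelope and access-resistance shapes are phenomenological
  (smoothstep, exponential); real mouth fields differ in detail, so the
  saturation position is meaningful relative to the model, not an ab-initio
  prediction.
* The equivalent-diameter mapping degrades as the aspect ratio departs from
  square; for the 50 µm-wide cavity (2.5:1) the rectangular resistance
  exceeds the equal-area cylindrical value, and measured ratios shift
  accordingly in real devices.
* FWHM on smooth-mouthed pulses carries the filter-width systematic noted
  above.
* Greedy linking is only guaranteed optimal for well-separated particles;
  crossing or overlapping trajectories are out of scope, as are deformable
  or aspherical particles.
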