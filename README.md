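# rpmap

Positional analysis of resistive-pulse (RP) experiments from simultaneous
electrical and optical recordings of microparticles translocating through
microfluidic channels.

A resistive-pulse sensor reports each particle passage as a transient
current decrease whose relative amplitude ΔI/I_p equals the relative
resistance increase ΔR/R₀. The amplitude depends not only on the
particle/channel size ratio but on the particle's position — axially in
channels of varying width, laterally everywhere — and the current trace
alone cannot resolve position. `rpmap` analyses the hybrid measurement that
can: an ionic-current trace sampled every 4 µs recorded simultaneously with
50,000 frames/s microscopy. It detects translocation events independently
in both streams, aligns the two clocks (a global coarse offset plus a
per-event fine offset that absorbs clock-rate mismatch), attributes every
current sample to a channel position, and aggregates the result into
**resistance maps** and positional statistics.

The quantitative backbone is the set of closed-form Coulter-counter
amplitude models, in the field's standard notation (sphere diameter *d*,
channel diameter *D*, length *L*, resistivity ρ):

- on-axis blockade: ΔI/I_p = d³/(L·D²) · [1 − 0.8(d/D)³]⁻¹
- off-axis enhancement: ΔV(y)/ΔV(0) = 1 + α·(y·d/D)³, α ≈ 5–7.5
- local resistance change: ΔR = 4ρd³/(πD(x_c)⁴) · [1 − 0.8(d/D(x_c))³]⁻¹
- region amplitude ratios: ΔR|₁/ΔR|₂ = (ΔI/I_p)|₁/(ΔI/I_p)|₂, independent of ρ

Rectangular channel sections are mapped to equivalent-area circular
diameters, D_eq = √(4wh/π).

Because raw recordings of this experiment type are not publicly deposited,
the package includes a first-class, fully tested simulator
(`generate_dataset()`) that produces mutually consistent current traces and
frame stacks from a known ground truth: plane-Poiseuille streamline
transport with flux conservation across width changes, the closed-form
blockade applied pointwise with entrance/exit transition zones and access
resistance, independent stream clocks with configurable skew, and
realistic noise on both streams. The analysis chain never sees the ground
truth.

## Worked example

Simulate a short recording of 10 µm beads in a straight 150 × 30 µm
(h = 20 µm) channel, run both detectors, synchronize, and map:

```r
library(rpmap)

geom <- channel_geometry("straight", length_um = 150, width_um = 30)
acq  <- acquisition_model(noise_sd_A = 2e-11)   # SNR ~ 20 at I0 = 50 nA

ds <- generate_dataset(geom, n_particles = 6, duration_s = 0.15, seed = 7,
                       acq = acq, y_frac = 0)        # on-axis beads

trace <- rp_preprocess(ds$trace)                     # filter + baseline
rp    <- rp_characterize(rp_detect_events(trace), trace)
im    <- detect_im_events(ds$frames, geom, expected_diameter_um = 10)
m     <- match_events(rp, im, trace, geom)           # coarse + fine sync

prof <- axial_profile(m)
c(events   = nrow(m),
  mean_amp = mean(m$plateau_amplitude),
  theory   = smythe_amplitude(10, equivalent_diameter(30, 20), 150),
  sat_x_um = attr(prof, "saturation_x"))
#>       events     mean_amp       theory     sat_x_um 
#>  6.000000000  0.009111446  0.009070299 18.000000000
```

All six events are matched across the streams; the mean measured blockade
agrees with the equivalent-diameter on-axis prediction (0.00907) to half a
percent, and the amplitude keeps developing until ~15–18 µm into the
channel — deeper than the bead diameter, the transition-zone signature
(the localisation sharpens to 15 ± 2 µm as events accumulate). The map and
profile plot directly:

```r
library(ggplot2)
autoplot(build_map(m, bin_um = 1))       # resistance map
autoplot(axial_profile(m), L = 150)      # axial amplitude profile
```

For cavity channels, `ratio_distribution()` compares per-event wide/narrow
amplitude ratios against the closed-form prediction
(`cavity_ratio_theory()`; 0.152 for the 20/50 µm channel, 0.324 for
17.5/30 µm), and `lateral_stats()` quantifies the duration and amplitude
dependence on lateral position.

A thin command-line wrapper over the same functions lives at
`inst/cli/rpmap` (subcommands `simulate`, `detect-rp`, `detect-im`, `sync`,
`analyze`, `all`), driven by a YAML config
(`inst/extdata/demo-config.yaml`).

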