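# photopace

Analysis pipelines for light-paced cardiac **muscular thin films (MTFs)**:
engineered bilayer cantilevers — a soft gelatin substrate carrying an
anisotropic cardiomyocyte monolayer — whose curling reports the tissue's
contractile stress. The package is for experimentalists running
photostimulation (or electrical-pacing) assays on such chips who need to
turn three raw readouts into numbers:

* **Cantilever movies → stress traces and twitch statistics.** Movies are
  thresholded (Otsu level frozen from the first frame, largest connected
  component kept), the per-frame horizontal extent of the curled film is
  inverted through circular-arc geometry, `x = L sin(κL)/(κL)`, and the
  Stoney thin-film relation `σ = C·Es·hs²·κ / (6·hf·(1−νs))` converts
  curvature to film stress. Peak detection by topographic prominence then
  yields diastolic/systolic/twitch stress and the contraction frequency
  (median inter-peak interval).
* **Calcium optical-mapping movies → activation maps and conduction
  velocity.** 3×3 spatial filtering, per-pixel ΔF/F normalization,
  half-amplitude activation times with sub-frame interpolation, and the
  activation-time gradient method `v = ∇T/|∇T|²` (speed `1/|∇T|`).
  Wavefront-origin counting on the long-axis projection distinguishes a
  spontaneous edge wave (one front) from a light-spot-triggered wave (two
  counter-propagating fronts).
* **Nuclear orientations → axial circular statistics.** Doubled-angle
  (180°-periodic) mean axis, resultant length, circular s.e.m., nematic
  order parameter and a 10°-bin histogram; orientations can be extracted
  from labeled nuclei masks by image moments.

Stimulus-train bookkeeping (`pulse_width = duty_cycle / frequency`),
stimulate/record protocol schedules, per-nucleus ROS normalization,
Welch/Student condition comparisons with star annotations, and a
deterministic experiment report round out the toolkit.

Because assays like these rarely deposit raw videos, the package ships
**seeded forward models** (cantilever renderer, calcium-wave renderer,
axial orientation sampler) that generate movies with known ground truth;
every inverse pipeline is validated end-to-end by parameter recovery.

## Worked example

Render a 30 s cantilever movie beating at 0.78 Hz with a 5.4 kPa twitch
planted as ground truth, then recover both through the full inverse chain:

```r
library(photopace)

spec <- mechanical_spec()
#> mechanical_spec: L = 3 mm, width = 4 mm, Es = 50 kPa, nu = 0.5,
#>                  hs = 100 um, hf = 18 um, C = 1

truth <- make_stress_trace(frequency = 0.78, diastolic = 1e3,
                           twitch_amplitude = 5.4e3, duration = 30,
                           frame_rate = 100)
mv <- render_cantilever_movie(truth, spec, rows = 16, cols = 516,
                              pixel_size = spec$free_length_L / 500,
                              noise_sd = 0.02, seed = 11)
analyze_cantilever_movie(mv, spec)$summary
#> twitch_summary: 23 beats at 0.781 Hz; diastolic 1.03 kPa,
#>                 systolic 6.40 kPa, twitch 5.37 kPa
```

The planted 0.78 Hz / 5.4 kPa come back as 0.781 Hz / 5.37 kPa: the 23
beats are the complete periods a 0.78 Hz train fits into 30 s, and the
recovered stresses carry the sub-pixel rasterization error of the 6 µm
pixels.

Same game for a light-spot-triggered calcium wave at 3.9 cm/s:

```r
field <- make_activation_field(40, 80, 5e-5, "point", c(20, 40),
                               speed_v = 0.039)
ca <- render_calcium_movie(field, noise_sd = 2.5, seed = 12)  # 5% of dF
map <- analyze_calcium_movie(ca, pacing_frequency = 1)
map$velocity
#> velocity_field: 3200 valid px; mean 4.15 cm/s, median 3.95 cm/s
map$wavefronts$classification
#> [1] "point-source double wave"
```

The median speed (3.95 cm/s, 1.4% off truth) is the robust summary; the
interior point source is correctly classified as a double wavefront. And
the anisotropy of the tissue itself:

```r
nuclei <- sample_orientations(130, mean_angle = 8.89,
                              concentration = 11.5, seed = 13)
circular_summary(nuclei)
#> orientation_summary: n = 130, mean 8.66 deg +/- 0.76 deg (s.e.m.),
#>                      r2 = 0.956, OOP = 0.956
```

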