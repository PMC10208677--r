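---
title: "Methods: quantifying light-paced cardiac muscular thin films"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying light-paced cardiac muscular thin films}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photopace)
```

## The experimental system

A muscular thin film (MTF) is a bilayer cantilever: a soft elastic substrate
(here micro-molded gelatin) carrying an anisotropic monolayer of neonatal
rat ventricular myocytes. When the tissue contracts, the film curls; the
curvature of the film reports the contractile stress of the tissue. Pacing
can be delivered electrically or optically (via a membrane-targeted
phototransducer driven by a pulsed light train), and the tissue's response
is read out three ways:

1. **Contractility** — a stereomicroscope films the curling cantilever from
   above (nominally 100 frames/s, 30 s). The movie is reduced to a film
   stress trace and twitch statistics.
2. **Optical mapping** — a calcium indicator is imaged at high speed
   (nominally 400 frames/s). Per-pixel activation times yield conduction
   velocity and the number and location of wavefront origins, which
   distinguish a spontaneous wave (one front, starting at a cantilever
   edge) from a light-triggered wave (two fronts radiating from the
   stimulation spot).
3. **Tissue architecture** — nuclear orientations relative to the
   micro-molded pattern direction quantify tissue anisotropy.

No raw videos from the original experiments are available, so every inverse
pipeline in this package is validated by *parameter recovery*: a seeded
forward model renders synthetic movies with known ground truth, and the
pipeline must get the planted values back.

## Contractility: from bending movie to stress

### Geometry

The cantilever is modeled as a circular arc of uniform curvature $\kappa$
with its base tangent to the substrate plane. Uniform curvature is the
standard MTF assumption: the tissue applies a distributed moment along the
whole film rather than a tip load. Seen from above, the arc of free length
$L$ presents the horizontal extent

$$x(\kappa) = L\,\frac{\sin(\kappa L)}{\kappa L}, \qquad x(0) = L .$$

$x$ is strictly decreasing in $\kappa$ for $\kappa L \in [0, \pi)$, so the
projection determines the curvature uniquely in that regime;
`curvature_from_projection()` inverts it by bisection on
$\theta = \kappa L \in (0, \pi)$ to an absolute tolerance of $10^{-12}$. At
$\kappa L \ge \pi$ (the film curled past a half-circle) the projection is no
longer injective and both the simulator and the pipeline refuse to operate.

### Stress

Curvature converts to film stress through the classical Stoney thin-film
relation with an explicit multiplicative correction factor,

$$\sigma = C\,\frac{E_s h_s^2}{6\,h_f\,(1-\nu_s)}\,\kappa ,$$

with $E_s, \nu_s, h_s$ the substrate modulus, Poisson ratio and thickness
and $h_f$ the tissue thickness. Published MTF analyses use "modified"
Stoney variants that correct for a finite film/substrate thickness ratio;
those corrections are multiplicative in $\kappa$, so they plug into the
single factor $C$ (`correction_factor_C`, default 1 = classical limit)
without any code change.

### Default mechanics

The substrate mechanics of the original chips are not published, so the
defaults in `mechanical_spec()` are explicit placeholders chosen once, on
physical grounds, and config-exposed:

| parameter | default | rationale |
|---|---|---|
| `free_length_L` | 3 mm | the cut cantilevers are 3 x 4 mm; the shorter side is taken as the free length, the longer as width |
| `substrate_modulus_Es` | 50 kPa | transglutaminase-crosslinked 10% gelatin |
| `substrate_poisson_nu` | 0.5 | incompressible hydrogel |
| `substrate_thickness_hs` | 100 um | drop-cast micro-molded layer |
| `film_thickness_hf` | 18 um | confluent NRVM monolayer |

These values place physiological film stresses (1–9 kPa) at
$\kappa L \approx 0.32$–$2.92$: inside the injective arc regime, away from
the flat-film limit where the projection loses sensitivity (near $x = L$,
$d\sigma/dx \to \infty$, so pixel quantization of a nearly flat film would
dominate the error). With a 500-pixel free length the forward–inverse round
trip recovers a noise-free stress trace to well under 2% RMS.

### Twitch statistics

Peaks of the stress trace are detected by topographic prominence (floor:
20% of the trace's dynamic range — immune to absolute offsets, robust to
noise that simple level crossings are not). Per beat, the diastolic
baseline is the 5th percentile of the inter-peak segment preceding the
peak, which tolerates slow drift; diastolic stress is the mean baseline,
systolic the mean peak, twitch their difference. The contraction frequency
is the reciprocal of the *median* inter-peak interval: a single missed or
spurious beat moves the median by at most one rank, whereas it biases the
mean by a full period over the count. Traces with fewer than two peaks
report frequency 0; a flat trace reports zero beats rather than an error.

The Otsu threshold used to binarize grayscale movies is computed on the
first frame only and frozen for the whole movie: a per-frame threshold
would jitter with the intensity histogram and masquerade as contraction.
After thresholding, only the largest connected component is kept, which
discards debris and reflections.

## Optical mapping

The calcium movie is smoothed with a 3 x 3 uniform spatial filter
(reflection at the borders, so constants are preserved exactly), then each
pixel is normalized to $\Delta F/F_0$ with $F_0$ the pixel's own 10th
percentile — a baseline estimator that needs no quiescent pre-roll and is
invariant to per-pixel gain.

Beats are segmented from peaks of the spatially averaged trace; when the
pacing frequency is known, windows snap to one stimulus period around each
peak. Within a window, a pixel's activation time is the first upward
crossing of 50% of its local amplitude, linearly interpolated between
frames for sub-frame resolution (`half_amplitude`, the default); the
maximum of the centred first difference is available as
`max_derivative` since the two markers differ on asymmetric upstrokes.
Pixels whose window amplitude is below 20% of the frame-wide median carry
no resolvable upstroke and are invalidated. Per-beat maps are rebased to
their window starts and median-combined across beats before
differentiation.

Conduction velocity is the activation-time gradient method: with
$\mathbf{g} = \nabla T$ estimated by central differences (one-sided at
valid-region borders),

$$\mathbf{v} = \frac{\mathbf{g}}{|\mathbf{g}|^2},
  \qquad |\mathbf{v}| = \frac{1}{|\nabla T|} .$$

The alternative componentwise reading (averaging $1/g_x$ and $1/g_y$) is
rejected: either component diverges whenever the front aligns with an
axis. Pixels with $|\mathbf{g}| < 0.5/v_{\max}$ (near-simultaneous
activation: plateaus, wave collisions, the immediate source neighborhood)
or implied speed below $v_{\min}$ are invalidated; the defaults
$v_{\min} = 1$ mm/s and $v_{\max} = 1$ m/s bracket cardiac tissue safely
and are config-exposed. The summary statistic is the median speed over
valid pixels, which is insensitive to the residual heavy tail near
sources.

Wavefront origins are counted on the long-axis projection of the
activation map (per-column minimum over valid rows): local minima of the
5-column-smoothed profile, merged within 2 columns. One minimum at an axis
boundary is an edge wave (one front); one interior minimum is a
point-source wave (two counter-propagating fronts); two or more separated
minima are multiple sources.

## Tissue architecture

Nuclear orientation is axial — a nucleus has no head or tail, so angles
are defined modulo 180 degrees and naive averaging is wrong (the mean of
+89 and −89 degrees is not 0). All statistics therefore double the angles
first: with $z = n^{-1}\sum_k e^{i 2\theta_k}$, the mean axis is
$\arg(z)/2$, the resultant length is $r_2 = |z|$, the axial circular
standard deviation is $\sqrt{-2\ln r_2}/2$ (halved to undo the doubling)
and the standard error of the mean axis divides that by $\sqrt{n}$. When
$r_2 = 0$ (perfectly balanced axes) the mean is undefined and the summary
says so instead of reporting a number. The 2-D nematic order parameter
$S = 2\langle\cos^2(\theta - \bar\theta)\rangle - 1$ is reported alongside
because the MTF literature quotes it, and a 10-degree-bin histogram over
$[-90, 90)$ matches the field's standard presentation.

Orientations are extracted from labeled nuclei masks via second-order
image moments (the major axis of the pixel covariance). Segmentation of
raw DAPI images into labels is deliberately out of scope — it is a
separate, well-served problem — so the input contract is a label image or
an angle table. Nearly isotropic regions, whose principal moments are
equal and whose axis is therefore undefined, are excluded with a warning.

## The forward models

The simulator prescribes ground truth; nothing is emergent. Its defaults
are the study conditions:

* **Stress traces** (`make_stress_trace`): baseline + one twitch per beat,
  linear rise over 20% of the period, half-cosine relaxation over twice the
  rise time, beats fired at the stimulus-train onset grid
  $\{k/f : k < \lfloor \mathrm{duration} \cdot f \rfloor\}$ (only complete
  periods fire, matching the pulse-train accounting). The kernel returns
  exactly to baseline before the next beat so the planted diastolic level
  is well-defined.
* **Cantilever movies** (`render_cantilever_movie`): per frame, invert
  Stoney, project, and rasterize a binary rectangle from a fixed base
  column; optional Gaussian intensity noise is re-binarized at 0.5. 30 s at
  100 frames/s with a 500-pixel free length ($\approx$ 6 um pixels).
* **Calcium movies** (`render_calcium_movie`): per pixel,
  $F_0 + \Delta F \cdot K(t - T(p) - k\,\mathrm{period})$ with a
  linear-rise (20 ms) / exponential-decay (150 ms) transient kernel —
  the simplest shape with a well-defined 50% upstroke, which is all the
  activation detector consumes. Additive i.i.d. Gaussian noise; negative
  samples clip at zero and are counted. 400 frames/s, 3 beats at 1 Hz, on
  a 40 x 80 grid of 50 um pixels (2 x 4 mm field).
* **Orientations** (`sample_orientations`): doubled angles from a von
  Mises law (Best–Fisher sampler), halved and folded to $[-90, 90)$. For
  the recovery experiments the concentration is 11.5, chosen once so that
  the circular s.e.m. at $n = 130$ is $\approx 0.75$ degrees, the
  dispersion scale reported for engineered anisotropic NRVM tissue.

Every stochastic operation takes a mandatory integer seed and is
bit-reproducible. What the forward models do *not* emulate: optics and
camera noise beyond additive Gaussian, motion artifacts, heterogeneous
conduction, indicator photobleaching, and any excitation–contraction
coupling (the stress trace and activation field are inputs, not products
of a membrane model). Passing recovery tests therefore demonstrates that
the *inverse pipelines* are correct and well-conditioned at realistic
noise levels — not that the forward models capture every feature of real
recordings.

## Numerical and design notes

* Bisection rather than a closed form for the sinc inversion: the function
  is monotone on $(0,\pi)$, 60 iterations reach $10^{-12}$, and the
  vectorized loop inverts a 3000-frame trace in milliseconds.
* Projections that exceed $L$ by less than one pixel (rasterization
  round-off of a flat film) are clamped to $L$; larger excesses are an
  error, since they indicate a wrong `free_length_L`.
* Welch's $t$ is the default for condition comparisons (group sizes like
  40 vs 11 cantilevers make the pooled-variance assumption fragile); a
  `student` variant mirrors the classical test. Zero-variance groups fall
  back to flagged conventions ($p = 1$ for equal means, $p = 0$
  otherwise) rather than erroring.
* The tip extent, not the film-area centroid, defines the x-projection;
  the base column defaults to the column of maximal temporal occupancy
  (the base is foreground in every frame).
* Problem sizes in the test suite are scaled to what the recovery
  experiments need: the 20-fixture contractility sweep uses 20 s movies,
  which still hold 6 beats at the slowest rate tested (0.3 Hz).

## Known limitations

* The arc model ignores gravity, buoyancy and inertial ringing of the
  film; fast twitches at high frame rates may show projection dynamics the
  quasi-static model cannot represent.
* Conduction velocity near wave collisions and sources is masked out, not
  modeled; maps dominated by collisions will report few valid pixels.
* The wavefront counter assumes propagation is organized along one axis
  (the cantilever's long axis); spiral or grossly curved fronts need a
  different topology and are out of scope.
* Circular s.e.m. treats nuclei as independent; if nuclei cluster by film,
  a per-film hierarchical analysis would widen the interval.
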