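---
title: "Models and numerical methods in pdtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in pdtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtkit)
```

pdtkit is a desk-scale simulation and analysis toolkit for implantable
photodynamic therapy (PDT): a light-activated drug (photosensitizer)
accumulates in a tumor, an implanted LED delivers metronomic (low-rate,
long-duration) light, and the resulting photochemistry kills tumor cells.
The package models the four quantitative pieces of such a system — light
transport in tissue, tissue heating, dosimetry/regimen comparison, and the
camera-based antenna-selection pipeline that powers the implant wirelessly —
together with synthetic data generators and file I/O so the whole chain can
be exercised and tested without hardware.

This vignette documents the models, their assumptions, the default
parameters, and the numerical and design decisions, in enough detail to
re-derive every check in the test suite.

## 1. Tissue phantom

`build_preset_phantom()` builds a voxelized cube of labeled tissue. The
`"default"` preset is a 20 mm cube (8 cm³, a typical small-animal
dorsal-skin working volume) with a thin epidermis (0.1 mm), a dermis layer
(1.5 mm), and a 4 mm-diameter spherical tumor centered under the
illumination axis, its top 0.5 mm below the dermis. `"homogeneous"` is
all-dermis; `"no-tumor"` omits the sphere. Voxel size must divide the cube
edge exactly; the constructor rejects sizes that do not
(`"does not divide"`), because a partial top layer would silently shift
every depth computation.

Labels are resolved to optical properties (`mu_a`, `mu_s` in mm⁻¹,
anisotropy `g`, refractive index `n`) per wavelength through a lookup
table. The bundled table covers 406, 542, 590 and 652 nm with
absorption and scattering decreasing toward the red, the usual trend for
soft tissue; the values are illustrative defaults, not fits to a specific
tissue, and `set_optical_properties()` / `optical_overrides` in a YAML
config replace them per run. Lookups for a missing (label, wavelength)
pair are an error rather than an interpolation: silent extrapolation of
optical properties is a classic source of plausible-looking nonsense.

```{r phantom}
ph <- build_preset_phantom("default", voxel_size = 0.2)
ph
lookup_properties(ph, "tumor", 652)
```

## 2. Photon transport

`run_transport()` is a weighted-photon voxel Monte Carlo in C++
(hop–drop–spin):

* **Hop** — step lengths are drawn from the exponential free-path
  distribution; the optical depth is consumed voxel by voxel along the
  ray, so heterogeneous media are handled exactly rather than by
  re-sampling at boundaries.
* **Drop** — at each interaction the photon deposits the fraction
  `mu_a / mu_t` of its weight in the current voxel (partial absorption),
  the standard variance-reduction choice.
* **Spin** — new directions are drawn from the Henyey–Greenstein phase
  function with the voxel's `g`.
* **Boundaries** — Fresnel reflection at the outer surface, both on entry
  (specular) and on exit attempts (stochastic internal reflection) when
  the tissue's `n` differs from the ambient index. Exits through the
  illuminated face are tallied as *reflected*, through the opposite face
  as *transmitted*, through the sides as *escaped*.
* **Russian roulette** — photons below weight 10⁻⁴ survive with
  probability 1/10 (weight ×10) or terminate. Roulette conserves energy
  only in expectation, so the tally carries an explicit `roulette_net`
  term; with it the per-run ledger

  absorbed + reflected + transmitted + escaped − roulette_net = 1

  closes to machine precision (`energy_balance_residual()`), far inside
  the 10⁻⁶ acceptance band.

Randomness comes from a self-contained 64-bit Mersenne Twister compiled
into the package (top 53 bits per double), so a given seed yields
bitwise-identical tallies across platforms — R's own RNG is never touched
by the transport kernel.

Derived maps: `fluence_map()` divides absorbed energy density by `mu_a`;
`penetration_depth()` reports the depth below the first sub-surface
on-axis sample at which fluence falls to 1/e of that sample (linear
interpolation between voxel centers), which reproduces the Beer–Lambert
closed form 1/`mu_a` in an absorption-only medium; a truncation flag is
set when the decay is not reached inside the grid.
`tumor_uniformity()` summarizes dose homogeneity over tumor voxels as
1/(1 + CV), where CV is the population coefficient of variation: 1 for a
perfectly flat dose, falling toward 0 as the dose concentrates — a
bounded, scale-free score that ranks regimens without unit bookkeeping.

Verification in the test suite: depth-binned absorption against
`mu_a·exp(−mu_a·z)·Δz` at 10⁵ photons, compared in 0.5 mm depth bins so
the 3-standard-error band is appropriate for the ~10 simultaneous
comparisons it implies (per-0.1 mm-plane testing would run ~50 z-tests and
flag an honest sampler in a double-digit fraction of runs); radial fluence
around an isotropic point source against the diffusion-theory form
`exp(−mu_eff·r)/r` within 15%; and exact energy-ledger closure.

## 3. Thermal simulation

`simulate_temperature()` integrates the (optionally Pennes-perfused)
bioheat equation with an explicit 7-point finite-difference stencil.
Face conductivities between dissimilar voxels use the harmonic mean (the
choice that keeps steady-state flux exact across a material interface).
The time step defaults to half the von Neumann stability bound
ρcΔx²/(6k) minimized over tissues, and steps beyond the bound are
rejected with the computed value. Boundary options: `insulated`,
`fixed` (body temperature), `convective` (Newton cooling with `h_conv`
into `T_ambient`), and `mixed` (convective top face — the illuminated,
air-facing skin — with fixed deep-tissue faces), the default.

Duty-cycled sources follow an `illumination_schedule()`; the on/off phase
is computed with an epsilon guard so that accumulated floating-point
drift over thousands of periods cannot flip a step across the pulse edge.
The suite checks the solver against the lumped closed form
ΔT = Q·t/(ρc) under uniform insulated heating (within 1%), exact stored
heat = injected energy × duty, and a 25%-duty rise that is 0.25× the
constant-mode rise within 5%.

## 4. Dosimetry and regimen scoring

`optical_dose(irradiance_uW_cm2, duration_s)` returns mJ·cm⁻²;
`cumulative_drug_dose()` multiplies a daily dose by days. Totals are
stored exactly; only `schedule_report()`'s display string rounds.
Display follows the conventions of published metronomic-PDT dose tables:
values switch from mJ·cm⁻² to J·cm⁻² at 0.1 J·cm⁻², and J values print
with one decimal at ≥10 (e.g. `12.1 J cm^-2` for a stored 12 096
mJ·cm⁻²) and two below (`0.43 J cm^-2` for a stored 432). Rounding is
standard round-half-even; the exact totals remain available in the report.

`score_regimen()` runs the transport once per light source (deterministic
per-source sub-seeds), combines wavelengths weighted by source power and
the photosensitizer's relative absorbance (`photosensitizer()` bundles
two-band profiles for Hypericin, peaks 590/542 nm, and Foscan, peaks
406/652 nm, as normalized Gaussian mixtures; tabulated spectra are
accepted and renormalized), and reports five criteria:

1. penetration depth (mm, higher better),
2. activation-weighted tumor absorbance fraction (higher better),
3. tumor dose uniformity 1/(1+CV) (higher better),
4. time to reach the target energy, E/(P·duty) (lower better),
5. probe temperature rise from the bioheat solver (lower better).

`rank_regimens()` min–max normalizes each criterion across candidates
(degenerate spread ⇒ all 1), aggregates by weighted mean, and flags
Pareto-dominated candidates. Min–max normalization makes the ranking
invariant under affine rescaling of any criterion; the suite additionally
verifies on random score sets that a dominated candidate never outranks
its dominator.

## 5. Pose-driven antenna selection

The implant is powered by one of four transmission coils (±x, ±y around
the cage); the best coil for a mouse is the one most aligned with its
body axis. The pipeline mirrors a markerless-pose-estimation deployment:

1. **Filter** — keep detections with confidence ≥ 0.6 (boundary value
   kept).
2. **Match** — snouts to tails by maximum-weight bipartite matching with
   score 1/(w·d) for pixel distance d (coincident points take a finite
   cap), and an occlusion veto: if the Bresenham line between the two
   pixels (inclusive endpoints) contains ≥ 5 pixels at intensity ≥ 128,
   the pair scores 0. On a *bright floor with dark animals* a line between
   parts of two different animals crosses open floor and is vetoed, while
   a true within-animal pair lies on the dark body and survives. (With
   the opposite polarity the veto would reject every true pair — each
   animal's own body is the line — so the renderer draws dark ellipses on
   a bright background.)
3. **Solve** — the assignment is solved by an O(n³)
   shortest-augmenting-path algorithm (Jonker–Volgenant style) with a
   lexicographic tie-break, validated against exhaustive permutation
   enumeration in the tests; rectangular instances leave the surplus side
   unmatched.
4. **Select** — the pose vector (tail→snout, unit length) picks the coil
   with maximal dot product. This argmax-dot rule is exactly the
   minimizer of the expected coil–implant distance when the implant's
   elevation is uniform over [0°, 90°): the expected distance is a
   decreasing function of the planar alignment alone, which the suite
   confirms against direct numeric evaluation of the expectation.
5. **Vote** — one coil is active per frame: majority vote over per-mouse
   optima, ties broken by summed alignment then lowest index; frames with
   no usable detections hold the previous coil.

`process_frame()` canonicalizes detection order first, so the result is
invariant under permutation of the input rows.

## 6. Synthetic data generators

`generate_scene()` renders mice as dark filled ellipses (intensity 30) on
a bright floor (220) and emits snout/tail keypoints at the ellipse poles.
`generate_track()` moves them with a bounded random walk over headings
(default speed 2 px/frame, max turn 0.1 rad/frame, wall reflection) and
separation maintenance. Placement enforces a minimum center distance of
2.2 body lengths and the walk holds a mouse in place rather than let two
animals approach closer than 2 body lengths: at that separation the true
snout–tail pairing is provably optimal for the inverse-distance score, so
ground truth is well defined. The noise model applies Gaussian keypoint
jitter (σ = 3 px), missed detections (p = 0.05), Poisson spurious
detections (rate 0.02 per frame) and Beta-distributed confidences
(Beta(9,1) for real parts, Beta(2,3) for spurious ones, which the 0.6
filter then separates imperfectly — as a real detector's scores would).

These generators emulate the *statistics* of a detector's output, not the
detector: there is no video, no appearance model, and no identity
tracking, so accuracy numbers measured on them characterize the selection
logic under the stated noise, not any particular vision model.

Under zero noise the pipeline recovers the ground-truth antenna sequence
exactly (100% over 1000 frames). Under the default noise model the
1000-frame selection accuracy at the canonical seed 1 is 81.9%; across
other seeds it varies roughly 75–83%, because ~80% of frames have a weak
(2-of-5) majority that a single jitter-flipped or missing vote can
overturn. That spread is a property of the prescribed noise level, not of
the matching or voting code.

## 7. File formats and CLI

`read_keypoints()`/`write_keypoints()` support a plain long CSV
(`frame,part,x,y,confidence`) and a DeepLabCut-style wide CSV
(scorer/bodyparts/coords header rows with x/y/likelihood triples).
Frames are 0-based and passed through unchanged; pixel origin is top-left
with y increasing downward. Foreign body-part labels must be mapped to
snout/tail through an explicit alias table; unknown labels are an error.
Volumes round-trip as flat little-endian float64 with a JSON sidecar
(shape, voxel size, axis order); an axis-order mismatch is an explicit
error, never a silent transpose. Images round-trip as ASCII PGM. Every
CLI run writes a JSON run record (command, merged config, seeds) so any
deterministic stage can be reproduced bitwise.

The CLI (`inst/cli/pdtkit.R`) is a thin Rscript dispatcher over the
package API with subcommands `simulate-light`, `simulate-heat`,
`score-regimen`, `dose`, `pose-run`, `synth`; flags override values from
an optional YAML config, and contract violations exit nonzero with a
one-line diagnostic.

## 8. Problem sizes and limitations

Default problem sizes (10⁵ photons, 100³ voxels, 1000-frame tracks,
≤6×6 matching oracles) are chosen so each check runs in seconds to ~1
minute on one CPU core; they are package choices, and every routine
accepts larger inputs.

Known limitations:

* Optical property tables are illustrative defaults, not tissue fits;
  quantitative use requires user-supplied coefficients.
* The transport model has no polarization, fluorescence re-emission, or
  time resolution; sources are surface points (pencil/cone) or interior
  isotropic points.
* The thermal solver is explicit-time and therefore slow for fine grids
  over long durations; metabolic heat is not modeled and perfusion is a
  single uniform sink term.
* The pose generators do not model identity switches, occlusion by cage
  furniture, or detector appearance failure modes.
* Photochemistry (oxygen kinetics, photobleaching) is outside scope; the
  regimen score uses activation-weighted absorbed energy as its proxy.
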