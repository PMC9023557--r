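# pdtkit

Simulation, dosimetry and pose-driven antenna selection for wireless
implantable photodynamic therapy (PDT).

## Background

Metronomic PDT treats a tumor by combining a light-activated drug
(photosensitizer, e.g. Hypericin or Foscan) with long-duration, low-rate
illumination from a miniature LED implanted at the tumor site. Running
such a system on freely moving animals raises four quantitative
questions, and this package models each of them:

1. **Where does the light go?** A voxel Monte Carlo photon transport
   engine (weighted photons, Henyey–Greenstein scattering, Fresnel
   boundaries, Russian roulette with exact energy accounting) computes
   absorption and fluence in a layered skin/tumor phantom, plus derived
   quantities: 1/e penetration depth, tumor absorption fraction, and a
   1/(1+CV) tumor-dose uniformity score.
2. **Does it heat the tissue?** An explicit finite-difference bioheat
   solver (optional Pennes perfusion, duty-cycled sources, insulated /
   fixed / convective / mixed boundaries) bounds the temperature rise.
3. **What dose does a protocol deliver?** Dosimetry arithmetic for
   optical dose (irradiance × time), cumulative drug dose and duty
   cycle, and a five-criterion scorer/ranker for candidate light
   regimens (penetration, activation-weighted tumor absorbance,
   uniformity, time to target energy, temperature rise) with Pareto
   dominance flags.
4. **Which transmit coil powers the implant?** A real-time keypoint
   post-processing pipeline for multi-animal cages: confidence
   filtering, snout–tail association by maximum-weight bipartite
   matching with an image-based occlusion veto, tail→snout pose vectors,
   per-mouse coil selection by maximal alignment, and a per-frame
   majority vote with hold-on-abstention.

A synthetic scene/track generator provides ground-truthed fixtures, and
readers/writers cover DeepLabCut-style CSV, long CSV, PGM images and
flat-binary volumes with JSON metadata. All stochastic components are
seeded and bitwise reproducible (the transport kernel carries its own
64-bit Mersenne Twister).

## Worked example

```r
library(pdtkit)

## 1. Dosimetry of a metronomic protocol: 20 uW/cm2 continuous for
##    7 days with 0.5 mg/kg/day photosensitizer
hyp <- dose_schedule(20, drug_dose_per_day_mg_kg = 0.5, n_days = 7)
str(schedule_report(hyp))
#> List of 3
#>  $ total_optical_mJ_cm2 : num 12096
#>  $ total_optical_display: chr "12.1 J cm^-2"
#>  $ total_drug_mg_kg     : num 3.5

## 2. Light transport in the layered skin/tumor phantom
ph  <- build_preset_phantom("default", voxel_size = 0.5)
src <- light_source(c(10, 10, 0), beam = "cone", wavelength = 652,
                    power_mW = 20)
tl  <- run_transport(ph, src, n_photons = 5e4, seed = 1)
penetration_depth(tl, ph)
#> [1] 0.5037711
#> attr(,"truncated")
#> [1] FALSE
tumor_absorption_fraction(tl, ph)
#> [1] 0.05400064
energy_balance_residual(tl)
#> [1] -2.116085e-13

## 3. Compare a single-band against a dual-band Foscan regimen
ps  <- photosensitizer("foscan")
sch <- illumination_schedule("pulsed", frequency = 25,
                             pulse_width_ms = 10, duration_s = 30)
reg_single <- regimen_spec(ps, list(src), schedule = sch,
                           target_energy_J = 0.5)
reg_dual   <- regimen_spec(ps, list(
  light_source(c(10, 10, 0), wavelength = 406, power_mW = 10),
  light_source(c(10, 10, 0), wavelength = 652, power_mW = 10)),
  schedule = sch, target_energy_J = 0.5)
scores <- lapply(list(single = reg_single, dual = reg_dual),
                 score_regimen, phantom = ph, n_photons = 2e4, seed = 1)
rk <- rank_regimens(scores)
rk$order
#> [1] 1 2
round(rk$raw, 4)
#>        penetration_mm absorbance_fraction uniformity time_to_target_s delta_T_C
#> single         0.5069              0.0150     0.6232         6679.380    0.0207
#> dual           0.4916              0.0432     0.4796         2316.681    0.0283

## 4. Antenna selection on a synthetic five-mouse cage, 1000 frames
track <- generate_track(1000, n_mice = 5, noise = noise_model(), seed = 1)
res   <- process_track(track$detections, frames = 0:999)
selection_accuracy(res$winner, track$truth_winner)
#> [1] 81.9
```

The dual-band regimen activates the tumor almost 3× more per launched
photon (the 406 nm Soret-like band is strongly absorbed) and reaches the
target energy 3× sooner, at the cost of uniformity and a slightly larger
temperature rise; neither candidate Pareto-dominates the other, and with
equal criterion weights the single-band regimen ranks first here.

## Command line

A thin dispatcher over the same API lives at `inst/cli/pdtkit.R`
(installed under `system.file("cli", "pdtkit.R", package = "pdtkit")`):

```sh
Rscript inst/cli/pdtkit.R dose --irradiance 20 --days 7 \
    --drug-per-day 0.5 --out dose.json
Rscript inst/cli/pdtkit.R synth --frames 1000 --mice 5 --seed 1 --out kp.csv
Rscript inst/cli/pdtkit.R pose-run --keypoints kp.csv --frames 1000 \
    --out antenna.csv
```

Subcommands: `simulate-light`, `simulate-heat`, `score-regimen`, `dose`,
`pose-run`, `synth`. Flags override an optional `--config` YAML; every
run writes a JSON run record (command, merged config, seeds). Contract
violations exit nonzero with a one-line diagnostic.

## Documentation

Function documentation is in roxygen comments in `R/`; the methods
vignette (`vignettes/pdtkit-methods.Rmd`) documents the physical models,
default parameters, numerical choices and limitations.
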