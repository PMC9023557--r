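# Finite-difference bioheat simulation under constant or duty-cycled sources.

#' Illumination schedule
#'
#' @param mode `"constant"` or `"pulsed"`
#' @param frequency pulse repetition frequency (Hz; pulsed only)
#' @param pulse_width_ms on-time per period (ms; pulsed only); the pulse
#'   may not exceed one period
#' @param duration_s total simulated/treatment duration (s)
#' @return an `illumination_schedule`
#' @export
illumination_schedule <- function(mode = c("constant", "pulsed"),
                                  frequency = NULL, pulse_width_ms = NULL,
                                  duration_s = 60) {
  mode <- match.arg(mode)
  if (mode == "pulsed") {
    stopifnot(is.numeric(frequency), frequency > 0,
              is.numeric(pulse_width_ms), pulse_width_ms >= 0)
    if (pulse_width_ms * frequency > 1000 + 1e-9)
      stop("pulse width exceeds one period at this frequency")
  }
  structure(list(mode = mode, frequency = frequency,
                 pulse_width_ms = pulse_width_ms, duration_s = duration_s),
            class = "illumination_schedule")
}

#' Duty factor of a schedule
#'
#' Fraction of time the source is on: 1 for constant operation, and
#' frequency x pulse width for pulsed operation (e.g. 25 Hz with a 10 ms
#' pulse gives 0.25, the 25% duty cycle used for duty-cycled LED drive).
#'
#' @param schedule an [illumination_schedule()]
#' @return fraction in \[0, 1\]
#' @export
duty_factor <- function(schedule) {
  stopifnot(inherits(schedule, "illumination_schedule"))
  if (schedule$mode == "constant") return(1)
  schedule$frequency * schedule$pulse_width_ms / 1000
}

#' Explicit-scheme stability bound on dt
#'
#' `dt <= rho * c * dx^2 / (6 k)` for every tissue present in the phantom.
#'
#' @param phantom a `tissue_phantom`
#' @return the tightest bound (s)
#' @export
thermal_stability_bound <- function(phantom) {
  present <- phantom$label_names[sort(unique(as.vector(phantom$labels))) + 1L]
  present <- setdiff(present, "background")
  dx <- phantom$voxel_size / 1000  # m
  bounds <- vapply(present, function(lab) {
    th <- lookup_thermal(phantom, lab)
    th$density * th$specific_heat * dx^2 / (6 * th$conductivity)
  }, numeric(1))
  min(bounds)
}

#' Simulate tissue temperature under a heat source and schedule
#'
#' Explicit forward-Euler 7-point conduction stencil with harmonic-mean
#' face conductivities; the volumetric source switches on/off following
#' the schedule; an optional Pennes perfusion sink
#' `- rho_b c_b w_b (T - T_arterial)` can be enabled via `perfusion`.
#' Background-labeled voxels are excluded from the solve; faces toward
#' them, and grid faces, follow the boundary rule.
#'
#' @param phantom a `tissue_phantom`
#' @param heat_source per-voxel volumetric power at full drive (W m^-3);
#'   array matching the grid (scalars are recycled)
#' @param schedule an [illumination_schedule()]; `duration_s` sets the
#'   simulated span
#' @param dt time step (s); must satisfy [thermal_stability_bound()];
#'   `NULL` picks 0.5 x the bound
#' @param boundary `"mixed"` (illuminated top face convective to ambient,
#'   all other faces clamped to the tissue baseline), `"insulated"`,
#'   `"fixed"` or `"convective"`
#' @param h_conv convective coefficient (W m^-2 K^-1)
#' @param T_ambient,T_fixed ambient and clamp temperatures (C)
#' @param probes named list of 1-based voxel index triplets to trace every
#'   step; defaults to a `tumor_center` probe (grid centre without tumor)
#' @param perfusion enable the Pennes perfusion sink (uses the thermal
#'   table's `perfusion_rate`); off by default
#' @param store_every store the full field every k-th step (0 = final only)
#' @return a `temperature_field`: `times`, `probe_traces` (matrix, one
#'   column per probe), `final` field array, optional `stored` fields
#' @export
simulate_temperature <- function(phantom, heat_source, schedule, dt = NULL,
                                 boundary = c("mixed", "insulated", "fixed",
                                              "convective"),
                                 h_conv = 10, T_ambient = 25, T_fixed = 37,
                                 probes = NULL, perfusion = FALSE,
                                 store_every = 0) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(schedule, "illumination_schedule"))
  if (length(heat_source) == 1)
    heat_source <- array(heat_source, dim = phantom$dims)
  stopifnot(identical(dim(heat_source), as.integer(phantom$dims)))
  if (any(heat_source < 0)) stop("heat source must be non-negative")
  bound <- thermal_stability_bound(phantom)
  if (is.null(dt)) dt <- 0.5 * bound
  if (dt > bound)
    stop(sprintf("dt = %g s violates the explicit stability bound %g s",
                 dt, bound))
  n_steps <- max(1L, as.integer(round(schedule$duration_s / dt)))

  if (is.null(probes)) probes <- list(tumor_center = tumor_center_voxel(phantom))
  pm <- do.call(rbind, lapply(probes, function(p) as.integer(p)))
  if (any(pm < 1) || any(t(pm) > phantom$dims))
    stop("probe voxel index outside the grid")

  labs <- phantom$label_names
  rho <- cp <- kc <- pf <- bl <- numeric(4)
  for (i in seq_along(labs)) {
    hit <- phantom$thermal[phantom$thermal$label == labs[i], ]
    if (nrow(hit) == 0) next
    hit <- hit[nrow(hit), ]
    rho[i] <- hit$density; cp[i] <- hit$specific_heat
    kc[i] <- hit$conductivity; pf[i] <- hit$perfusion_rate
    bl[i] <- hit$baseline_temperature
  }
  bc_code <- match(boundary, c("insulated", "fixed", "convective", "mixed")) - 1L
  sched_mode <- if (schedule$mode == "pulsed") 1L else 0L
  period <- if (sched_mode == 1L) 1 / schedule$frequency else 0
  pulse <- if (sched_mode == 1L) schedule$pulse_width_ms / 1000 else 0

  res <- .fd_bioheat(as.integer(phantom$labels), as.integer(phantom$dims),
                     phantom$voxel_size / 1000, rho, cp, kc, pf, bl,
                     as.numeric(heat_source), dt, n_steps, sched_mode,
                     period, pulse, bc_code, h_conv, T_ambient, T_fixed,
                     bl[which(labs == "dermis")], perfusion, pm,
                     as.integer(store_every))
  colnames(res$probe_trace) <- names(probes)
  stored <- NULL
  if (store_every > 0 && res$n_stored > 0) {
    stored <- list(times = res$stored_times[seq_len(res$n_stored)],
                   fields = lapply(seq_len(res$n_stored), function(j)
                     array(res$stored[, j], dim = phantom$dims)))
  }
  structure(list(times = seq(0, by = dt, length.out = n_steps + 1),
                 probe_traces = res$probe_trace, dt = dt,
                 final = array(res$final, dim = phantom$dims),
                 stored = stored, schedule = schedule),
            class = "temperature_field")
}

#' Range of temperature variation at a probe
#'
#' Max minus min of the traced probe temperature over the simulated span
#' (the temperature-rise criterion of the regimen score).
#'
#' @param field a `temperature_field`
#' @param probe probe name (default: the first probe)
#' @return temperature range (degrees C)
#' @export
temperature_variation_range <- function(field, probe = NULL) {
  stopifnot(inherits(field, "temperature_field"))
  if (is.null(probe)) probe <- colnames(field$probe_traces)[1]
  if (!probe %in% colnames(field$probe_traces))
    stop(sprintf("unknown probe '%s'", probe))
  tr <- field$probe_traces[, probe]
  max(tr) - min(tr)
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("temperature_field: %d steps, dt = %g s, probes: %s\n",
              length(x$times) - 1, x$dt,
              paste(colnames(x$probe_traces), collapse = ", ")))
  invisible(x)
}
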