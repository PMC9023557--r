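# Photosensitizer spectra, five-criterion regimen scoring, and ranking.

#' Photosensitizer presets and custom spectra
#'
#' Presets model the absorption spectrum as a sum of Gaussian peaks with
#' the maximum normalized to 1: `"hypericin"` peaks at 590 and 542 nm,
#' `"foscan"` at 406 and 652 nm, with the 406 nm (Soret-like) band
#' carrying most of the absorbance.  Peak widths and relative amplitudes
#' are documented approximations, not measured spectra; pass `peaks` to
#' override them or supply a tabulated `spectrum`.
#'
#' @param name `"hypericin"`, `"foscan"`, or any label when `peaks` or
#'   `spectrum` is given
#' @param peaks data.frame with columns `center` (nm), `amplitude`,
#'   `width` (Gaussian sigma, nm)
#' @param spectrum data.frame with columns `wavelength`, `absorbance`;
#'   absorbance is renormalized so its maximum is 1; wavelengths outside
#'   the tabulated range are a configuration error at lookup time
#' @return a `photosensitizer`
#' @export
photosensitizer <- function(name = c("hypericin", "foscan"), peaks = NULL,
                            spectrum = NULL) {
  if (is.null(peaks) && is.null(spectrum)) {
    name <- match.arg(name)
    peaks <- switch(name,
      hypericin = data.frame(center = c(590, 542), amplitude = c(1, 0.8),
                             width = 15),
      foscan = data.frame(center = c(406, 652), amplitude = c(1, 0.28),
                          width = c(12, 15)))
  }
  if (!is.null(spectrum)) {
    stopifnot(nrow(spectrum) >= 1, all(spectrum$absorbance >= 0))
    mx <- max(spectrum$absorbance)
    if (mx <= 0) stop("spectrum has no positive absorbance")
    spectrum$absorbance <- spectrum$absorbance / mx
  }
  structure(list(name = if (is.character(name)) name[1] else "custom",
                 peaks = peaks, spectrum = spectrum),
            class = "photosensitizer")
}

#' Relative absorbance of a photosensitizer at given wavelengths
#'
#' @param ps a [photosensitizer()]
#' @param wavelength nm (vectorized)
#' @return relative absorbance in \[0, 1\]
#' @export
relative_absorbance <- function(ps, wavelength) {
  stopifnot(inherits(ps, "photosensitizer"))
  if (!is.null(ps$spectrum)) {
    rng <- range(ps$spectrum$wavelength)
    if (any(wavelength < rng[1] | wavelength > rng[2]))
      stop(sprintf("wavelength outside the tabulated spectrum [%g, %g] nm",
                   rng[1], rng[2]))
    return(stats::approx(ps$spectrum$wavelength, ps$spectrum$absorbance,
                         xout = wavelength)$y)
  }
  pk <- ps$peaks
  val <- vapply(wavelength, function(wl)
    sum(pk$amplitude * exp(-(wl - pk$center)^2 / (2 * pk$width^2))),
    numeric(1))
  grid <- seq(350, 750, by = 0.5)
  mx <- max(vapply(grid, function(wl)
    sum(pk$amplitude * exp(-(wl - pk$center)^2 / (2 * pk$width^2))),
    numeric(1)))
  pmin(1, val / mx)
}

#' Candidate treatment regimen
#'
#' @param ps a [photosensitizer()]
#' @param sources list of [light_source()] objects (>= 1)
#' @param layout source layout tag: `"inner"`, `"outer"` or `"mixed"`
#' @param schedule an [illumination_schedule()]
#' @param target_energy_J tumor energy (J) regarded as the therapeutic
#'   target for the time-to-target criterion; must be supplied by the
#'   user (it is protocol-specific), > 0
#' @return a `regimen_spec`
#' @export
regimen_spec <- function(ps, sources, layout = c("mixed", "inner", "outer"),
                         schedule, target_energy_J) {
  layout <- match.arg(layout)
  stopifnot(inherits(ps, "photosensitizer"), length(sources) >= 1,
            inherits(schedule, "illumination_schedule"), target_energy_J > 0)
  for (s in sources) stopifnot(inherits(s, "light_source"))
  structure(list(ps = ps, sources = sources, layout = layout,
                 schedule = schedule, target_energy_J = target_energy_J),
            class = "regimen_spec")
}

#' Time to deliver a target tumor energy
#'
#' `target_energy / (tumor_absorbed_power x duty)`: wall-clock seconds to
#' accumulate the target at the given duty cycle.
#'
#' @param tumor_absorbed_power_W absorbed power in the tumor (W), > 0
#' @param target_energy_J target energy (J), >= 0
#' @param duty duty factor in (0, 1]
#' @return seconds
#' @export
time_to_target <- function(tumor_absorbed_power_W, target_energy_J, duty = 1) {
  if (target_energy_J == 0) return(0)
  if (tumor_absorbed_power_W <= 0) stop("tumor absorbed power must be > 0")
  if (duty <= 0 || duty > 1) stop("duty must lie in (0, 1]")
  target_energy_J / (tumor_absorbed_power_W * duty)
}

#' Score one regimen against the five criteria
#'
#' Runs one Monte Carlo transport per source, combines the per-wavelength
#' tallies through the photosensitizer spectrum (weighted by source
#' power), and derives: light penetration depth (power-weighted mean over
#' sources, mm), activation-weighted tumor absorbance fraction, tumor
#' dose uniformity, time to the target energy at the schedule's duty
#' factor, and the probe temperature variation from a short bioheat run
#' driven by the full (unweighted) absorption map.
#'
#' @param phantom a `tissue_phantom` configured for every source wavelength
#' @param regimen a [regimen_spec()]
#' @param n_photons photon packets per source
#' @param seed integer; source i uses `seed + i - 1`
#' @param thermal_duration_s span of the bioheat run feeding the
#'   temperature-rise criterion
#' @param thermal_dt bioheat time step (`NULL` = auto)
#' @return a `regimen_score` with fields `penetration_mm`,
#'   `absorbance_fraction`, `uniformity`, `time_to_target_s`, `delta_T_C`
#'   and a logical `unreachable` flag (zero-power regimens)
#' @export
score_regimen <- function(phantom, regimen, n_photons = 20000, seed = 1,
                          thermal_duration_s = 20, thermal_dt = NULL) {
  stopifnot(inherits(regimen, "regimen_spec"))
  srcs <- regimen$sources
  powers <- vapply(srcs, function(s) s$power_mW, numeric(1))
  tallies <- vector("list", length(srcs))
  for (i in seq_along(srcs))
    tallies[[i]] <- run_transport(phantom, srcs[[i]], n_photons, seed + i - 1)

  total_power <- sum(powers)
  act <- relative_absorbance(regimen$ps,
                             vapply(srcs, function(s) s$wavelength, numeric(1)))
  tumor_frac <- vapply(tallies, tumor_absorption_fraction,
                       phantom = phantom, numeric(1))

  if (total_power <= 0) {
    return(structure(list(penetration_mm = 0, absorbance_fraction = 0,
                          uniformity = NA_real_, time_to_target_s = Inf,
                          delta_T_C = 0, unreachable = TRUE,
                          regimen = regimen, seed = seed),
                     class = "regimen_score"))
  }
  w <- powers / total_power
  pen <- sum(w * vapply(tallies, function(tl)
    as.numeric(penetration_depth(tl, phantom)), numeric(1)))
  absorbance <- sum(w * act * tumor_frac)

  act_map <- combine_wavelengths(tallies, regimen$ps, weights = powers)
  unif <- tumor_uniformity(tallies[[1]], phantom, map = act_map)

  duty <- duty_factor(regimen$schedule)
  tumor_power_W <- sum(powers / 1000 * act * tumor_frac)
  ttt <- if (tumor_power_W > 0)
    time_to_target(tumor_power_W, regimen$target_energy_J, duty) else Inf

  # heat source: all absorbed optical power converts to heat (fraction 1)
  vox_m3 <- (phantom$voxel_size / 1000)^3
  q <- array(0, dim = phantom$dims)
  for (i in seq_along(tallies))
    q <- q + tallies[[i]]$absorbed * (powers[i] / 1000) / vox_m3
  field <- simulate_temperature(phantom, q, illumination_schedule(
    regimen$schedule$mode, regimen$schedule$frequency,
    regimen$schedule$pulse_width_ms, duration_s = thermal_duration_s),
    dt = thermal_dt)
  dT <- temperature_variation_range(field)

  structure(list(penetration_mm = pen, absorbance_fraction = absorbance,
                 uniformity = unif, time_to_target_s = ttt, delta_T_C = dT,
                 unreachable = !is.finite(ttt), regimen = regimen,
                 seed = seed),
            class = "regimen_score")
}

#' @export
print.regimen_score <- function(x, ...) {
  cat(sprintf(paste0("regimen_score: penetration %.2f mm | tumor absorbance ",
                     "%.4f | uniformity %.3f | time-to-target %.4g s | ",
                     "dT %.3f C%s\n"),
              x$penetration_mm, x$absorbance_fraction, x$uniformity,
              x$time_to_target_s, x$delta_T_C,
              if (isTRUE(x$unreachable)) " [target unreachable]" else ""))
  invisible(x)
}

.CRITERIA <- c("penetration_mm", "absorbance_fraction", "uniformity",
               "time_to_target_s", "delta_T_C")
.HIGHER_BETTER <- c(TRUE, TRUE, TRUE, FALSE, FALSE)

#' Rank candidate regimens over the five criteria
#'
#' Each criterion is min-max normalized to \[0, 1\] with its good
#' direction up (penetration, absorbance and uniformity ascending;
#' time-to-target and temperature variation descending).  When all
#' candidates tie on a criterion its normalized value is defined as 1.
#' Candidates are ranked by the weighted mean of normalized criteria;
#' Pareto-dominated candidates are flagged so no information is lost to
#' the aggregation.
#'
#' @param scores list of `regimen_score` objects (>= 1)
#' @param weights numeric length 5, one weight per criterion
#' @return list with `raw` and `normalized` data.frames, `aggregate`
#'   scores, `order` (best first) and `pareto_dominated` flags
#' @export
rank_regimens <- function(scores, weights = rep(1, 5)) {
  if (length(scores) == 0) stop("no scores to rank")
  stopifnot(length(weights) == 5, all(weights >= 0), sum(weights) > 0)
  raw <- as.data.frame(do.call(rbind, lapply(scores, function(s)
    unlist(s[.CRITERIA]))))
  names(raw) <- .CRITERIA
  norm <- raw
  for (j in seq_along(.CRITERIA)) {
    x <- raw[[j]]
    fin <- is.finite(x)
    if (!any(fin) || max(x[fin]) == min(x[fin]) && all(fin)) {
      norm[[j]] <- rep(1, length(x)); next
    }
    lo <- min(x[fin]); hi <- max(x[fin])
    n <- if (hi > lo) (x - lo) / (hi - lo) else rep(0, length(x))
    n[!fin] <- 1  # unreachable = worst of a descending-good criterion
    norm[[j]] <- if (.HIGHER_BETTER[j]) n else 1 - n
  }
  agg <- as.numeric(as.matrix(norm) %*% (weights / sum(weights)))
  rawm <- as.matrix(raw)
  # flip descending-good criteria so dominance is "all >=, one >"
  rawm[, !.HIGHER_BETTER] <- -rawm[, !.HIGHER_BETTER]
  dominated <- vapply(seq_len(nrow(rawm)), function(i) {
    any(vapply(seq_len(nrow(rawm)), function(k) {
      k != i && all(rawm[k, ] >= rawm[i, ]) && any(rawm[k, ] > rawm[i, ])
    }, logical(1)))
  }, logical(1))
  list(raw = raw, normalized = norm, aggregate = agg,
       order = order(-agg), pareto_dominated = dominated)
}
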