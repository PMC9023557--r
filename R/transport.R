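# Monte Carlo photon transport and the light-side regimen criteria.

#' Define a light source
#'
#' @param position length-3 numeric, mm; for `"pencil"` and `"cone"` beams
#'   the source sits on the illuminated (z = 0) surface, for
#'   `"isotropic"` it may sit anywhere inside the phantom
#' @param direction initial propagation direction (normalized internally)
#' @param beam `"pencil"`, `"cone"` (LED-like emitter, see `half_angle`)
#'   or `"isotropic"`
#' @param half_angle cone half-angle in degrees (0-90); LEDs default to a
#'   wide 60 degree cone since bare-die emitters are far from collimated
#' @param wavelength nm
#' @param power_mW radiant power (mW), >= 0
#' @return a `light_source` object
#' @export
light_source <- function(position, direction = c(0, 0, 1),
                         beam = c("cone", "pencil", "isotropic"),
                         half_angle = 60, wavelength, power_mW = 1) {
  beam <- match.arg(beam)
  stopifnot(length(position) == 3, length(direction) == 3, power_mW >= 0)
  if (half_angle < 0 || half_angle > 90)
    stop("half_angle must lie in [0, 90] degrees")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero")
  structure(list(position = as.numeric(position),
                 direction = as.numeric(direction) / nrm, beam = beam,
                 half_angle = half_angle, wavelength = wavelength,
                 power_mW = power_mW),
            class = "light_source")
}

.label_property_vectors <- function(phantom, wavelength) {
  labs <- phantom$label_names
  present <- labs[sort(unique(as.vector(phantom$labels))) + 1L]
  out <- list(mu_a = numeric(4), mu_s = numeric(4), g = numeric(4), n = rep(1, 4))
  for (i in seq_along(labs)) {
    if (!labs[i] %in% present) next
    op <- lookup_properties(phantom, labs[i], wavelength)
    out$mu_a[i] <- op$mu_a; out$mu_s[i] <- op$mu_s
    out$g[i] <- op$g; out$n[i] <- op$n
  }
  out
}

#' Run weighted-photon Monte Carlo transport
#'
#' Photons take exponentially distributed hops with mean free path
#' 1/(mu_a + mu_s) of the voxel they traverse (optical depth is consumed
#' voxel-by-voxel, so heterogeneous media are handled exactly), deposit
#' the fraction mu_a/(mu_a + mu_s) of their weight at each interaction,
#' scatter by the Henyey-Greenstein phase function, undergo Fresnel
#' reflection/refraction at the outer surface (specular entry reflection
#' for external beams), and are terminated unbiasedly by Russian roulette
#' below `roulette_threshold`.
#'
#' The returned tally is normalized per launched photon: `absorbed` holds
#' dimensionless energy fractions.  Because roulette conserves energy only
#' in expectation, the tally carries the net roulette weight
#' (`roulette_net`); the exact per-run ledger is
#' `sum(absorbed) + reflected + transmitted + escaped - roulette_net = 1`.
#'
#' @param phantom a [build_preset_phantom()] phantom
#' @param source a [light_source()]
#' @param n_photons number of photon packets (>= 0)
#' @param seed integer RNG seed; identical inputs and seed give bitwise
#'   identical tallies
#' @param roulette_threshold weight below which roulette triggers
#' @param roulette_survival survival multiplier m (survive with
#'   probability 1/m, weight times m)
#' @param ambient_n refractive index of the surrounding medium
#' @return a `photon_tally`
#' @export
run_transport <- function(phantom, source, n_photons, seed,
                          roulette_threshold = 1e-4, roulette_survival = 10,
                          ambient_n = 1.0) {
  stopifnot(inherits(phantom, "tissue_phantom"), inherits(source, "light_source"))
  if (n_photons < 0) stop("n_photons must be >= 0")
  L <- phantom$dims * phantom$voxel_size
  p <- source$position
  if (source$beam == "isotropic") {
    if (any(p < 0) || any(p > L)) stop("isotropic source must lie inside the grid")
  } else {
    if (p[1] < 0 || p[1] > L[1] || p[2] < 0 || p[2] > L[2] || abs(p[3]) > 1e-9)
      stop("surface source must sit on the illuminated z = 0 face of the grid")
  }
  props <- .label_property_vectors(phantom, source$wavelength)
  beam_code <- match(source$beam, c("pencil", "cone", "isotropic")) - 1L
  res <- .mc_transport(as.integer(phantom$labels), as.integer(phantom$dims),
                       phantom$voxel_size, props$mu_a, props$mu_s, props$g,
                       props$n, p, source$direction, beam_code,
                       source$half_angle, as.integer(n_photons),
                       as.integer(seed), roulette_threshold, roulette_survival,
                       ambient_n)
  structure(list(
    absorbed = array(res$absorbed, dim = phantom$dims),
    reflected_fraction = res$reflected,
    transmitted_fraction = res$transmitted,
    escaped_fraction = res$escaped,
    roulette_net = res$roulette_net,
    n_photons = n_photons, seed = seed,
    wavelength = source$wavelength, source = source
  ), class = "photon_tally")
}

#' @export
print.photon_tally <- function(x, ...) {
  cat(sprintf(paste0("photon_tally: %g photons @ %g nm | absorbed %.4f ",
                     "reflected %.4f transmitted %.4f escaped %.4f\n"),
              x$n_photons, x$wavelength, sum(x$absorbed),
              x$reflected_fraction, x$transmitted_fraction, x$escaped_fraction))
  invisible(x)
}

#' Per-voxel fluence from an absorption tally
#'
#' Fluence (J mm^-2 per J launched) is the absorbed energy density divided
#' by the local absorption coefficient: `absorbed / (mu_a * voxel_volume)`.
#'
#' @param tally a `photon_tally`
#' @param phantom the phantom the tally was computed on
#' @return numeric array matching the grid
#' @export
fluence_map <- function(tally, phantom) {
  stopifnot(identical(dim(tally$absorbed), as.integer(phantom$dims)))
  props <- .label_property_vectors(phantom, tally$wavelength)
  mua_vox <- props$mu_a[as.vector(phantom$labels) + 1L]
  a <- as.vector(tally$absorbed)
  bad <- a > 0 & mua_vox == 0
  if (any(bad))
    stop("absorption recorded in a voxel with mu_a = 0; fluence undefined")
  out <- numeric(length(a))
  pos <- mua_vox > 0
  out[pos] <- a[pos] / (mua_vox[pos] * phantom$voxel_size^3)
  array(out, dim = phantom$dims)
}

.on_axis_profile <- function(tally, phantom) {
  fl <- fluence_map(tally, phantom)
  src <- tally$source
  ix <- min(phantom$dims[1], max(1L, floor(src$position[1] / phantom$voxel_size) + 1L))
  iy <- min(phantom$dims[2], max(1L, floor(src$position[2] / phantom$voxel_size) + 1L))
  z <- (seq_len(phantom$dims[3]) - 0.5) * phantom$voxel_size
  list(z = z, fluence = fl[ix, iy, ])
}

#' 1/e light penetration depth along the beam axis
#'
#' Depth below the first sub-surface sample at which the on-axis fluence
#' first falls to 1/e of that sample's value, with linear interpolation
#' between voxel centres.  In a pure Beer-Lambert medium this returns
#' 1/mu_a.  If the fluence never decays below 1/e inside the grid, the
#' grid depth is returned with attribute `truncated = TRUE`.
#'
#' @inheritParams fluence_map
#' @return depth in mm (attribute `truncated` when the grid was too shallow)
#' @export
penetration_depth <- function(tally, phantom) {
  pr <- .on_axis_profile(tally, phantom)
  f <- pr$fluence
  if (f[1] <= 0) stop("no on-axis fluence at the surface; cannot measure depth")
  target <- f[1] / exp(1)
  below <- which(f <= target)
  below <- below[below > 1]
  if (length(below) == 0) {
    out <- pr$z[length(pr$z)] - pr$z[1]
    attr(out, "truncated") <- TRUE
    return(out)
  }
  k <- below[1]
  # linear interpolation between voxel centres k-1 and k
  frac <- (f[k - 1] - target) / (f[k - 1] - f[k])
  z_hit <- pr$z[k - 1] + frac * (pr$z[k] - pr$z[k - 1])
  out <- z_hit - pr$z[1]
  attr(out, "truncated") <- FALSE
  out
}

#' Fraction of launched energy absorbed in the tumor
#'
#' @inheritParams fluence_map
#' @return scalar in \[0, 1\]: sum of per-voxel absorbed fractions over
#'   tumor-labeled voxels
#' @export
tumor_absorption_fraction <- function(tally, phantom) {
  if (!identical(dim(tally$absorbed), as.integer(phantom$dims)))
    stop("tally and phantom grid shapes differ")
  sum(tally$absorbed[label_mask(phantom, "tumor")])
}

#' Uniformity of the absorbed dose over the tumor
#'
#' Scored as 1/(1 + CV) where CV is the coefficient of variation
#' (population standard deviation / mean) of the per-voxel absorbed dose
#' over tumor voxels.  The score lives in \[0, 1\]: 1 for a perfectly flat
#' dose, decreasing as the dose becomes more heterogeneous, and it is
#' invariant under rescaling all doses by a constant.
#'
#' @inheritParams fluence_map
#' @param map optional alternative per-voxel dose array (e.g. a combined
#'   activation map); defaults to the tally's absorbed map
#' @return scalar in \[0, 1\]
#' @export
tumor_uniformity <- function(tally, phantom, map = NULL) {
  dose <- if (is.null(map)) tally$absorbed else map
  v <- dose[label_mask(phantom, "tumor")]
  if (length(v) == 0) stop("phantom has no tumor voxels")
  m <- mean(v)
  if (m <= 0) stop("zero tumor dose everywhere; uniformity undefined")
  cv <- sqrt(mean((v - m)^2)) / m
  1 / (1 + cv)
}

#' Photosensitizer-weighted combination of per-wavelength tallies
#'
#' Voxel-wise sum of absorbed dose times the photosensitizer's relative
#' absorbance at each tally's wavelength, optionally weighted by
#' per-tally launched energy.  Linear in every tally.
#'
#' @param tallies list of `photon_tally` objects sharing one grid shape
#' @param ps a [photosensitizer()]
#' @param weights optional energy weights, one per tally (default 1)
#' @return per-voxel effective activation map (array)
#' @export
combine_wavelengths <- function(tallies, ps, weights = NULL) {
  stopifnot(length(tallies) >= 1)
  if (is.null(weights)) weights <- rep(1, length(tallies))
  stopifnot(length(weights) == length(tallies))
  shp <- dim(tallies[[1]]$absorbed)
  out <- array(0, dim = shp)
  for (i in seq_along(tallies)) {
    tl <- tallies[[i]]
    if (!identical(dim(tl$absorbed), shp)) stop("tallies have mismatched grids")
    out <- out + weights[i] * relative_absorbance(ps, tl$wavelength) * tl$absorbed
  }
  out
}

#' Energy-balance residual of a tally
#'
#' `sum(absorbed) + reflected + transmitted + escaped - roulette_net - 1`;
#' zero to machine precision for any run of the transport engine.
#'
#' @param tally a `photon_tally`
#' @return scalar residual
#' @export
energy_balance_residual <- function(tally) {
  sum(tally$absorbed) + tally$reflected_fraction + tally$transmitted_fraction +
    tally$escaped_fraction - tally$roulette_net - 1
}
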