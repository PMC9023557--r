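# Voxel tissue phantom: geometry presets and optical/thermal property tables.

.LABELS <- c(background = 0L, epidermis = 1L, dermis = 2L, tumor = 3L)

#' Optical properties of one tissue at one wavelength
#'
#' @param mu_a absorption coefficient (mm^-1), >= 0
#' @param mu_s scattering coefficient (mm^-1), >= 0
#' @param g scattering anisotropy (mean cosine of the scattering angle),
#'   strictly between -1 and 1
#' @param n refractive index, >= 1
#' @return a named list of class `optical_properties`
#' @export
optical_properties <- function(mu_a, mu_s, g, n) {
  stopifnot(is.numeric(mu_a), mu_a >= 0, is.numeric(mu_s), mu_s >= 0)
  if (!(g > -1 && g < 1)) stop("anisotropy g must lie strictly in (-1, 1)")
  if (n < 1) stop("refractive index must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' Thermal properties of one tissue
#'
#' @param density kg m^-3
#' @param specific_heat J kg^-1 K^-1
#' @param conductivity W m^-1 K^-1
#' @param perfusion_rate blood perfusion rate (s^-1), >= 0; used only when
#'   the Pennes perfusion sink is switched on in [simulate_temperature()]
#' @param baseline_temperature starting/arterial temperature (degrees C)
#' @return a named list of class `thermal_properties`
#' @export
thermal_properties <- function(density, specific_heat, conductivity,
                               perfusion_rate = 0, baseline_temperature = 37) {
  stopifnot(density > 0, specific_heat > 0, conductivity > 0,
            perfusion_rate >= 0, baseline_temperature > 0)
  structure(list(density = density, specific_heat = specific_heat,
                 conductivity = conductivity, perfusion_rate = perfusion_rate,
                 baseline_temperature = baseline_temperature),
            class = "thermal_properties")
}

#' Default optical property table
#'
#' Illustrative, literature-typical coefficients for skin layers and a
#' generic solid tumor at the four photosensitizer-relevant wavelengths
#' (406, 542, 590, 652 nm).  Both `mu_a` and `mu_s` decrease from the
#' violet (406 nm) to the red (652 nm) end, as is typical of soft tissue.
#' Every entry can be overridden through [set_optical_properties()] or the
#' `optical_table` argument of [build_preset_phantom()]; none of these
#' numbers is a measured constant of any particular experiment.
#'
#' @return data.frame with columns label, wavelength, mu_a, mu_s, g, n
#' @export
default_optical_table <- function() {
  wl <- c(406, 542, 590, 652)
  rbind(
    data.frame(label = "epidermis", wavelength = wl,
               mu_a = c(0.40, 0.25, 0.20, 0.15),
               mu_s = c(5.0, 4.2, 3.8, 3.5), g = 0.85, n = 1.4),
    data.frame(label = "dermis", wavelength = wl,
               mu_a = c(0.25, 0.12, 0.09, 0.06),
               mu_s = c(4.5, 3.6, 3.2, 2.8), g = 0.90, n = 1.4),
    data.frame(label = "tumor", wavelength = wl,
               mu_a = c(0.50, 0.20, 0.15, 0.10),
               mu_s = c(4.0, 3.3, 3.0, 2.6), g = 0.90, n = 1.4),
    data.frame(label = "background", wavelength = wl,
               mu_a = 0, mu_s = 0, g = 0, n = 1.0)
  )
}

#' Default thermal property table
#'
#' Literature-typical values for skin and tumor tissue; perfusion defaults
#' to zero (conduction-only bioheat) and the baseline temperature is 37 C.
#'
#' @return data.frame with columns label, density, specific_heat,
#'   conductivity, perfusion_rate, baseline_temperature
#' @export
default_thermal_table <- function() {
  data.frame(
    label = c("epidermis", "dermis", "tumor", "background"),
    density = c(1100, 1090, 1050, 1.2),
    specific_heat = c(3300, 3400, 3700, 1005),
    conductivity = c(0.21, 0.40, 0.55, 0.026),
    perfusion_rate = c(0, 0, 0, 0),
    baseline_temperature = 37
  )
}

#' Build a preset voxel phantom
#'
#' The `"default"` preset is a 20 x 20 x 20 mm cube (8 cm^3) with a thin
#' epidermis on the illuminated face, a dermis layer beneath it (dermis
#' also fills the remaining bulk), and a spherical tumor (default 4 mm
#' diameter) centred laterally, its top a small gap below the dermis
#' layer boundary.  `"homogeneous"` labels every voxel dermis;
#' `"no-tumor"` is the layered geometry without the sphere.  Voxel
#' coordinates are 0-based; the physical coordinate of voxel (i,j,k) is
#' its centre, and z increases with depth from the illuminated surface.
#'
#' @param preset one of `"default"`, `"homogeneous"`, `"no-tumor"`
#' @param voxel_size edge length of a voxel (mm); must divide the cube
#'   edge evenly
#' @param cube_mm cube edge (mm), default 20
#' @param epidermis_mm,dermis_mm layer thicknesses (mm)
#' @param tumor_diameter_mm tumor sphere diameter (mm)
#' @param tumor_gap_mm gap between the bottom of the dermis layer and the
#'   top of the tumor sphere (mm)
#' @param wavelengths wavelengths (nm) the property table must cover
#' @param optical_table,thermal_table property tables; see
#'   [default_optical_table()], [default_thermal_table()]
#' @return an object of class `tissue_phantom`
#' @export
build_preset_phantom <- function(preset = c("default", "homogeneous", "no-tumor"),
                                 voxel_size = 0.2, cube_mm = 20,
                                 epidermis_mm = 0.1, dermis_mm = 1.5,
                                 tumor_diameter_mm = 4, tumor_gap_mm = 0.5,
                                 wavelengths = c(406, 542, 590, 652),
                                 optical_table = default_optical_table(),
                                 thermal_table = default_thermal_table()) {
  preset <- match.arg(preset)
  if (voxel_size <= 0) stop("voxel_size must be positive")
  nvox <- cube_mm / voxel_size
  if (abs(nvox - round(nvox)) > 1e-9)
    stop(sprintf("voxel_size %g mm does not divide the cube edge %g mm evenly",
                 voxel_size, cube_mm))
  n <- as.integer(round(nvox))
  dims <- c(n, n, n)
  labels <- array(.LABELS[["dermis"]], dim = dims)

  tumor_center <- NULL
  if (preset %in% c("default", "no-tumor")) {
    zc <- (seq_len(n) - 0.5) * voxel_size
    epi <- zc < epidermis_mm
    for (k in which(epi)) labels[, , k] <- .LABELS[["epidermis"]]
  }
  if (preset == "default") {
    r <- tumor_diameter_mm / 2
    center <- c(cube_mm / 2, cube_mm / 2,
                epidermis_mm + dermis_mm + tumor_gap_mm + r)
    if (center[3] + r > cube_mm)
      stop("tumor sphere does not fit inside the phantom")
    cc <- (seq_len(n) - 0.5) * voxel_size
    dx2 <- (cc - center[1])^2
    dz2 <- (cc - center[3])^2
    # voxel centre inside the sphere => tumor
    for (k in which(dz2 <= r^2)) {
      rem <- r^2 - dz2[k]
      sl <- outer(dx2, dx2, "+") <= rem
      lk <- labels[, , k]
      lk[sl] <- .LABELS[["tumor"]]
      labels[, , k] <- lk
    }
    tumor_center <- center
  }

  phantom <- structure(list(
    preset = preset, dims = dims, voxel_size = voxel_size, cube_mm = cube_mm,
    labels = labels, label_names = names(.LABELS),
    optical = optical_table, thermal = thermal_table,
    wavelengths = wavelengths, tumor_center_mm = tumor_center,
    epidermis_mm = epidermis_mm, dermis_mm = dermis_mm
  ), class = "tissue_phantom")
  .check_phantom_tables(phantom)
  phantom
}

.check_phantom_tables <- function(phantom) {
  present <- phantom$label_names[sort(unique(as.vector(phantom$labels))) + 1L]
  for (lab in present) {
    th <- phantom$thermal[phantom$thermal$label == lab, ]
    if (nrow(th) == 0)
      stop(sprintf("no thermal properties configured for label '%s'", lab))
    for (wl in phantom$wavelengths) {
      op <- phantom$optical[phantom$optical$label == lab &
                              phantom$optical$wavelength == wl, ]
      if (nrow(op) == 0)
        stop(sprintf("no optical properties configured for (%s, %g nm)", lab, wl))
    }
  }
  invisible(phantom)
}

#' Look up optical properties for a (label, wavelength) pair
#'
#' @param phantom a `tissue_phantom`
#' @param label tissue label name
#' @param wavelength nm
#' @return an [optical_properties()] object; the last-configured entry
#'   wins when a pair was overridden
#' @export
lookup_properties <- function(phantom, label, wavelength) {
  hit <- phantom$optical[phantom$optical$label == label &
                           phantom$optical$wavelength == wavelength, ]
  if (nrow(hit) == 0)
    stop(sprintf("no optical properties configured for (%s, %g nm)",
                 label, wavelength))
  hit <- hit[nrow(hit), ]  # last write wins
  optical_properties(hit$mu_a, hit$mu_s, hit$g, hit$n)
}

#' Override optical properties for a (label, wavelength) pair
#'
#' Appends an entry to the phantom's optical table; lookups return the
#' most recent entry for the pair.
#'
#' @inheritParams lookup_properties
#' @param mu_a,mu_s,g,n see [optical_properties()]
#' @return the modified phantom
#' @export
set_optical_properties <- function(phantom, label, wavelength, mu_a, mu_s, g, n) {
  optical_properties(mu_a, mu_s, g, n)  # validate
  phantom$optical <- rbind(phantom$optical,
                           data.frame(label = label, wavelength = wavelength,
                                      mu_a = mu_a, mu_s = mu_s, g = g, n = n))
  if (!wavelength %in% phantom$wavelengths)
    phantom$wavelengths <- c(phantom$wavelengths, wavelength)
  phantom
}

#' Look up thermal properties for a label
#' @inheritParams lookup_properties
#' @return a [thermal_properties()] object
#' @export
lookup_thermal <- function(phantom, label) {
  hit <- phantom$thermal[phantom$thermal$label == label, ]
  if (nrow(hit) == 0)
    stop(sprintf("no thermal properties configured for label '%s'", label))
  hit <- hit[nrow(hit), ]
  thermal_properties(hit$density, hit$specific_heat, hit$conductivity,
                     hit$perfusion_rate, hit$baseline_temperature)
}

#' Indices (1-based, array coordinates) of voxels carrying a label
#' @inheritParams lookup_properties
#' @return logical array matching the phantom grid
#' @export
label_mask <- function(phantom, label) {
  code <- .LABELS[[label]]
  if (is.null(code)) stop(sprintf("unknown label '%s'", label))
  phantom$labels == code
}

#' Voxel nearest the tumor centre (1-based i,j,k), or grid centre if no tumor
#' @param phantom a `tissue_phantom`
#' @return integer vector length 3
#' @export
tumor_center_voxel <- function(phantom) {
  if (is.null(phantom$tumor_center_mm))
    return(as.integer(ceiling(phantom$dims / 2)))
  pmin(phantom$dims,
       pmax(1L, as.integer(floor(phantom$tumor_center_mm / phantom$voxel_size)) + 1L))
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("tissue_phantom '%s': %d x %d x %d voxels @ %g mm (%g cm^3)\n",
              x$preset, x$dims[1], x$dims[2], x$dims[3], x$voxel_size,
              prod(x$dims) * x$voxel_size^3 / 1000))
  tab <- table(factor(x$label_names[as.vector(x$labels) + 1L],
                      levels = x$label_names))
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("  %-10s %d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

#' Load a phantom configuration file (YAML) and build the phantom
#'
#' The file may set any argument of [build_preset_phantom()] plus an
#' `optical_overrides` list of entries `{label, wavelength, mu_a, mu_s, g, n}`.
#'
#' @param path YAML file
#' @return a `tissue_phantom`
#' @export
phantom_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg), names(formals(build_preset_phantom)))]
  phantom <- do.call(build_preset_phantom, args)
  for (ov in cfg$optical_overrides) {
    # YAML 1.1 readers coerce a bare key `n` to logical FALSE; map it back
    names(ov)[names(ov) %in% c("FALSE", "F")] <- "n"
    phantom <- set_optical_properties(phantom, ov$label, ov$wavelength,
                                      ov$mu_a, ov$mu_s, ov$g, ov$n)
  }
  phantom
}
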