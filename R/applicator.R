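#' Annular phased-array applicator model
#'
#' Generic ring applicator surrounding the phantom with a water bolus: in 2D,
#' `n_channels` equally spaced line sources on a ring; in 3D, three axial
#' rings of four short z-directed dipoles (a Sigma-Eye-like layout with
#' configurable radius and ring positions). The water bolus fills the space
#' between the sources and the phantom; an outer casing ring carries the
#' applicator-shell properties.
#'
#' @param frequency_hz drive frequency, default 1e8 (100 MHz).
#' @param n_channels number of independent channels (default 12; in 3D must
#'   equal rings x 4).
#' @param bolus_radius_mm outer radius of the water bolus. `NULL` = derived
#'   from the phantom (largest body semi-axis + 45 mm).
#' @param source_radius_mm ring radius of the sources; `NULL` =
#'   `bolus_radius_mm - 12`.
#' @param shell_thickness_mm thickness of the outer casing ring, mm.
#' @param ring_z_mm (3D) axial offsets of the three dipole rings relative to
#'   the phantom center, mm.
#' @return list of class `applicator_model`.
#' @export
applicator_model <- function(frequency_hz = 1e8, n_channels = 12,
                             bolus_radius_mm = NULL, source_radius_mm = NULL,
                             shell_thickness_mm = 5,
                             ring_z_mm = c(-80, 0, 80)) {
  if (n_channels < 1) stop("n_channels must be >= 1")
  structure(list(
    frequency_hz = frequency_hz, n_channels = n_channels,
    bolus_radius_mm = bolus_radius_mm, source_radius_mm = source_radius_mm,
    shell_thickness_mm = shell_thickness_mm, ring_z_mm = ring_z_mm
  ), class = "applicator_model")
}

#' Solver settings
#'
#' @param periods number of drive periods simulated before phasor extraction
#'   over the final period (default 15, sufficient for harmonic steady state).
#' @param pml_cells CPML thickness in cells (default 8).
#' @param mode `"2d"` (transverse line-source model, fast) or `"3d"`.
#' @param courant time step as a fraction of the Courant limit.
#' @param ramp_periods raised-cosine source ramp length, periods.
#' @param air_margin_cells free-space cells between the shell and the PML.
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(periods = 15, pml_cells = 8,
                            mode = c("2d", "3d"), courant = 0.95,
                            ramp_periods = 3, air_margin_cells = 4) {
  mode <- match.arg(mode)
  if (periods < 3) stop("periods must be >= 3 (phasor needs two trailing periods)")
  if (courant <= 0 || courant > 1) stop("courant must be in (0, 1]")
  structure(list(periods = periods, pml_cells = pml_cells, mode = mode,
                 courant = courant, ramp_periods = ramp_periods,
                 air_margin_cells = air_margin_cells),
            class = "solver_settings")
}

# Channel source layout in phantom-centered coordinates (mm).
# 2D: one line source per channel on the ring. 3D: rings x 4 dipoles.
channel_positions <- function(applicator, mode) {
  nch <- applicator$n_channels
  r <- applicator$source_radius_mm
  if (mode == "2d") {
    ang <- 2 * pi * (seq_len(nch) - 1) / nch
    data.frame(channel = seq_len(nch), x = r * cos(ang), y = r * sin(ang),
               z = 0, angle = ang)
  } else {
    n_rings <- length(applicator$ring_z_mm)
    if (nch != 4 * n_rings) {
      stop("3D layout requires n_channels = 4 x number of rings (",
           4 * n_rings, "), got ", nch)
    }
    ang <- rep(c(0, 0.5, 1, 1.5) * pi, times = n_rings)
    zz <- rep(applicator$ring_z_mm, each = 4)
    data.frame(channel = seq_len(nch), x = r * cos(ang), y = r * sin(ang),
               z = zz, angle = ang)
  }
}
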