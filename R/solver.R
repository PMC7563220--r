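#' Assign per-voxel material grids for a phantom under a segmentation scheme
#'
#' Reduces the phantom labels through the scheme, resolves dielectric
#' properties, and embeds the phantom in the computational domain: voxels
#' outside the body but inside the bolus radius get water properties, the
#' casing ring gets applicator-shell properties, and the exterior is free
#' space.
#'
#' @param phantom a `voxel_phantom` (3D) or a [phantom_slice()] (2D).
#' @param scheme a `segmentation_scheme`.
#' @param table a `tissue_table`.
#' @param applicator an [applicator_model()].
#' @param settings a [solver_settings()].
#' @return list of class `material_grids` with `eps_r`, `sigma`, `rho`
#'   (domain arrays), `body` (logical domain mask), `offset` (0-based voxel
#'   offset of the phantom block in the domain), `phantom_dim`, `sources`
#'   (per-channel source cells), and grid metadata.
#' @export
assign_material_grids <- function(phantom, scheme, table = default_tissue_table(),
                                  applicator = applicator_model(),
                                  settings = solver_settings()) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  is2d <- isTRUE(phantom$is_2d)
  if (is2d && settings$mode != "2d") stop("2D phantom slice requires mode '2d'")
  if (!is2d && settings$mode != "3d") stop("3D phantom requires mode '3d'")
  sp <- phantom$spacing_mm

  reduced <- apply_scheme(phantom$labels, scheme)
  labs <- unique(reduced[!is.na(reduced)])
  props <- resolve_properties(labs, table)
  water <- resolve_properties("water", table)
  shell <- resolve_properties("applicator_shell", table)

  pd <- dim(phantom$labels)
  nxp <- pd[1]; nyp <- pd[2]; nzp <- if (is2d) 1L else pd[3]

  # phantom-centered transverse coordinates of phantom voxel centers
  half_x <- nxp * sp / 2; half_y <- nyp * sp / 2

  r_bolus <- applicator$bolus_radius_mm
  if (is.null(r_bolus)) r_bolus <- max(half_x, half_y) + 45
  r_src <- applicator$source_radius_mm
  if (is.null(r_src)) r_src <- r_bolus - 12
  if (r_src >= r_bolus) stop("sources must lie inside the bolus")
  t_shell <- applicator$shell_thickness_mm
  applicator$bolus_radius_mm <- r_bolus
  applicator$source_radius_mm <- r_src

  margin <- (settings$air_margin_cells + settings$pml_cells) * sp
  r_dom <- r_bolus + t_shell + margin
  nxd <- 2L * as.integer(ceiling(r_dom / sp))
  nyd <- nxd
  xs <- (seq_len(nxd) - 0.5) * sp - nxd * sp / 2
  ys <- (seq_len(nyd) - 0.5) * sp - nyd * sp / 2
  ox <- as.integer(round(nxd / 2 - nxp / 2))   # 0-based offsets
  oy <- as.integer(round(nyd / 2 - nyp / 2))

  R2 <- outer(xs^2, ys^2, "+")
  if (is2d) {
    eps <- matrix(1, nxd, nyd); sig <- matrix(0, nxd, nyd)
    rho <- matrix(1.2, nxd, nyd)
    inb <- R2 <= r_bolus^2
    insh <- R2 <= (r_bolus + t_shell)^2 & !inb
    eps[inb] <- water$eps_r; sig[inb] <- water$sigma_eff; rho[inb] <- water$rho
    eps[insh] <- shell$eps_r; sig[insh] <- shell$sigma_eff; rho[insh] <- shell$rho
    body <- matrix(FALSE, nxd, nyd)
    lab <- reduced
    keep <- !is.na(lab)
    pidx <- which(keep, arr.ind = TRUE)
    di <- pidx[, 1] + ox; dj <- pidx[, 2] + oy
    m <- match(lab[keep], props$tissue_id)
    ide <- cbind(di, dj)
    eps[ide] <- props$eps_r[m]; sig[ide] <- props$sigma_eff[m]
    rho[ide] <- props$rho[m]
    body[ide] <- TRUE
    dims <- c(nxd, nyd)
    offset <- c(ox, oy)
  } else {
    oz_cells <- settings$air_margin_cells + settings$pml_cells + 2L
    nzd <- nzp + 2L * oz_cells
    eps <- array(1, c(nxd, nyd, nzd)); sig <- array(0, c(nxd, nyd, nzd))
    rho <- array(1.2, c(nxd, nyd, nzd))
    # bolus/shell cylinder spans the phantom z extent plus a 20 mm margin
    zs <- (seq_len(nzd) - 0.5) * sp
    z0 <- oz_cells * sp - 20; z1 <- (oz_cells + nzp) * sp + 20
    zin <- zs >= z0 & zs <= z1
    inb2 <- R2 <= r_bolus^2
    insh2 <- R2 <= (r_bolus + t_shell)^2 & !inb2
    for (k in which(zin)) {
      ek <- eps[, , k]; sk <- sig[, , k]; rk <- rho[, , k]
      ek[inb2] <- water$eps_r; sk[inb2] <- water$sigma_eff; rk[inb2] <- water$rho
      ek[insh2] <- shell$eps_r; sk[insh2] <- shell$sigma_eff; rk[insh2] <- shell$rho
      eps[, , k] <- ek; sig[, , k] <- sk; rho[, , k] <- rk
    }
    body <- array(FALSE, c(nxd, nyd, nzd))
    lab <- reduced
    keep <- !is.na(lab)
    pidx <- which(keep, arr.ind = TRUE)
    oz <- oz_cells
    ide <- cbind(pidx[, 1] + ox, pidx[, 2] + oy, pidx[, 3] + oz)
    m <- match(lab[keep], props$tissue_id)
    eps[ide] <- props$eps_r[m]; sig[ide] <- props$sigma_eff[m]
    rho[ide] <- props$rho[m]
    body[ide] <- TRUE
    dims <- c(nxd, nyd, nzd)
    offset <- c(ox, oy, oz)
  }

  # source cells (0-based kernel indices); z-directed 3-cell dipoles in 3D
  pos <- channel_positions(applicator, settings$mode)
  src <- lapply(seq_len(nrow(pos)), function(r) {
    i <- as.integer(round((pos$x[r] + nxd * sp / 2) / sp - 0.5))
    j <- as.integer(round((pos$y[r] + nyd * sp / 2) / sp - 0.5))
    if (settings$mode == "2d") {
      data.frame(i = i, j = j, k = 0L, comp = 2L)
    } else {
      zc <- offset[3] + nzp / 2 + pos$z[r] / sp
      k <- as.integer(round(zc)) + (-1:1)
      data.frame(i = i, j = j, k = k, comp = 2L)
    }
  })
  for (s in src) {
    ms <- if (is2d) sig[s$i[1] + 1, s$j[1] + 1] else
      sig[s$i[1] + 1, s$j[1] + 1, s$k[2] + 1]
    me <- if (is2d) eps[s$i[1] + 1, s$j[1] + 1] else
      eps[s$i[1] + 1, s$j[1] + 1, s$k[2] + 1]
    if (!(abs(me - water$eps_r) < 1e-9)) {
      stop("source cell does not lie in the water bolus; ",
           "increase bolus_radius_mm or shrink the phantom")
    }
  }

  structure(list(
    eps_r = eps, sigma = sig, rho = rho, body = body,
    dims = dims, offset = offset, phantom_dim = c(nxp, nyp, nzp),
    spacing_mm = sp, applicator = applicator, settings = settings,
    scheme_name = scheme$name, sources = src
  ), class = "material_grids")
}

#' Low-level 2D FDTD run with arbitrary sources
#'
#' Exposes the 2D transverse-magnetic kernel directly: useful for analytic
#' verification fixtures (plane waves, point sources) that are not applicator
#' layouts. Sources are soft current sources in Ez.
#'
#' @param eps_r,sigma matrices of relative permittivity and conductivity (S/m).
#' @param spacing_mm grid step, mm.
#' @param frequency_hz drive frequency.
#' @param sources data.frame with 0-based columns `i`, `j` and optional
#'   `amp`, `phase`.
#' @param periods,pml_cells,courant,ramp_periods see [solver_settings()].
#' @return list with `phasor` (complex matrix), `phasor_prev`, `dt`,
#'   `steps_per_period`.
#' @export
fdtd_run_2d <- function(eps_r, sigma, spacing_mm, frequency_hz = 1e8,
                        sources, periods = 15, pml_cells = 8,
                        courant = 0.95, ramp_periods = 3) {
  if (is.null(sources$amp)) sources$amp <- 1
  if (is.null(sources$phase)) sources$phase <- 0
  out <- fdtd2d_solve_cpp(eps_r, sigma, spacing_mm / 1000, frequency_hz,
                          as.integer(periods), as.integer(pml_cells),
                          courant, as.integer(sources$i),
                          as.integer(sources$j), sources$amp, sources$phase,
                          ramp_periods)
  list(phasor = complex(real = out$re, imaginary = out$im) |>
         matrix(nrow(eps_r), ncol(eps_r)),
       phasor_prev = complex(real = out$re_prev, imaginary = out$im_prev) |>
         matrix(nrow(eps_r), ncol(eps_r)),
       dt = out$dt, steps_per_period = out$steps_per_period)
}

#' Low-level 3D FDTD run with arbitrary sources
#'
#' @param eps_r,sigma 3D arrays.
#' @param sources data.frame with 0-based `i`, `j`, `k`, `comp` (0 = Ex,
#'   1 = Ey, 2 = Ez) and optional `amp`, `phase`.
#' @inheritParams fdtd_run_2d
#' @return list with complex arrays `ex`, `ey`, `ez`, `ez_prev`, plus `dt`
#'   and `steps_per_period`.
#' @export
fdtd_run_3d <- function(eps_r, sigma, spacing_mm, frequency_hz = 1e8,
                        sources, periods = 15, pml_cells = 8,
                        courant = 0.95, ramp_periods = 3) {
  if (is.null(sources$amp)) sources$amp <- 1
  if (is.null(sources$phase)) sources$phase <- 0
  d <- dim(eps_r)
  out <- fdtd3d_solve_cpp(as.vector(eps_r), as.vector(sigma),
                          as.integer(d), spacing_mm / 1000, frequency_hz,
                          as.integer(periods), as.integer(pml_cells),
                          courant, as.integer(sources$i),
                          as.integer(sources$j), as.integer(sources$k),
                          as.integer(sources$comp), sources$amp,
                          sources$phase, ramp_periods)
  cplx <- function(re, im) array(complex(real = re, imaginary = im), dim = d)
  list(ex = cplx(out$ex_re, out$ex_im), ey = cplx(out$ey_re, out$ey_im),
       ez = cplx(out$ez_re, out$ez_im),
       ez_prev = cplx(out$ez_re_prev, out$ez_im_prev),
       dt = out$dt, steps_per_period = out$steps_per_period)
}

#' Solve the steady-state field of one channel at unit drive
#'
#' Drives the given channel at unit amplitude and zero phase for a fixed
#' number of periods and extracts per-voxel complex phasors by DFT projection
#' over the final period. Deterministic for fixed inputs.
#'
#' @param materials a `material_grids` object.
#' @param channel channel index (1-based).
#' @param full_domain if `TRUE`, return the full computational domain instead
#'   of cropping to the phantom grid.
#' @return For 2D: complex matrix `ez` plus attributes. For 3D: list of
#'   complex arrays `ex`, `ey`, `ez`. Both carry `steady_rel` (relative RMS
#'   difference between the final- and penultimate-period phasors).
#' @export
solve_channel <- function(materials, channel, full_domain = FALSE) {
  stopifnot(inherits(materials, "material_grids"))
  st <- materials$settings
  if (channel < 1 || channel > length(materials$sources)) {
    stop("channel index out of range")
  }
  src <- materials$sources[[channel]]
  src$amp <- 1; src$phase <- 0
  if (st$mode == "2d") {
    out <- fdtd_run_2d(materials$eps_r, materials$sigma, materials$spacing_mm,
                       materials$applicator$frequency_hz, src,
                       periods = st$periods, pml_cells = st$pml_cells,
                       courant = st$courant, ramp_periods = st$ramp_periods)
    steady <- steady_rel(out$phasor, out$phasor_prev)
    ez <- out$phasor
    if (!full_domain) ez <- crop_to_phantom(ez, materials)
    structure(list(ez = ez), steady_rel = steady, mode = "2d")
  } else {
    out <- fdtd_run_3d(materials$eps_r, materials$sigma, materials$spacing_mm,
                       materials$applicator$frequency_hz, src,
                       periods = st$periods, pml_cells = st$pml_cells,
                       courant = st$courant, ramp_periods = st$ramp_periods)
    steady <- steady_rel(out$ez, out$ez_prev)
    f <- out[c("ex", "ey", "ez")]
    if (!full_domain) f <- lapply(f, crop_to_phantom, materials = materials)
    structure(f, steady_rel = steady, mode = "3d")
  }
}

steady_rel <- function(last, prev) {
  denom <- sqrt(mean(Mod(last)^2))
  if (denom == 0) return(0)
  sqrt(mean(Mod(last - prev)^2)) / denom
}

crop_to_phantom <- function(grid, materials) {
  o <- materials$offset; p <- materials$phantom_dim
  if (length(dim(grid)) == 2) {
    grid[(o[1] + 1):(o[1] + p[1]), (o[2] + 1):(o[2] + p[2])]
  } else {
    grid[(o[1] + 1):(o[1] + p[1]), (o[2] + 1):(o[2] + p[2]),
         (o[3] + 1):(o[3] + p[3]), drop = FALSE]
  }
}

#' Solve all channels at unit drive
#'
#' Runs independent unit-drive solves for every channel, in channel order.
#'
#' @inheritParams solve_channel
#' @param progress print per-channel progress.
#' @return object of class `channel_fields`: list with `fields` (one entry
#'   per channel), `mode`, `spacing_mm`, `frequency_hz`, `n_channels`,
#'   `phantom_dim`, `steady_rel` (per channel), `applicator`.
#' @export
solve_all_channels <- function(materials, full_domain = FALSE,
                               progress = FALSE) {
  nch <- materials$applicator$n_channels
  fields <- vector("list", nch)
  steady <- numeric(nch)
  for (ch in seq_len(nch)) {
    t0 <- Sys.time()
    f <- solve_channel(materials, ch, full_domain = full_domain)
    fields[[ch]] <- f
    steady[ch] <- attr(f, "steady_rel")
    if (progress) {
      message(sprintf("channel %d/%d solved in %.1fs (steady %.2e)",
                      ch, nch, as.numeric(Sys.time() - t0, units = "secs"),
                      steady[ch]))
    }
  }
  structure(list(
    fields = fields, mode = materials$settings$mode,
    spacing_mm = materials$spacing_mm,
    frequency_hz = materials$applicator$frequency_hz,
    n_channels = nch, phantom_dim = materials$phantom_dim,
    steady_rel = steady, applicator = materials$applicator,
    scheme_name = materials$scheme_name
  ), class = "channel_fields")
}

#' Validate a channel field set against a phantom
#'
#' Checks one finite field grid per channel with shape equal to the phantom.
#' @param fields a `channel_fields` object.
#' @param phantom the phantom the fields were solved on.
#' @export
validate_channel_fields <- function(fields, phantom) {
  stopifnot(inherits(fields, "channel_fields"))
  if (length(fields$fields) != fields$n_channels) {
    stop("field set must contain one grid per channel")
  }
  pd <- dim(phantom$labels)
  for (ch in seq_along(fields$fields)) {
    g <- if (fields$mode == "2d") fields$fields[[ch]]$ez else
      fields$fields[[ch]]$ez
    gd <- dim(g)
    if (!isTRUE(all.equal(as.integer(gd[seq_along(pd)]), as.integer(pd)))) {
      stop("channel ", ch, " grid shape does not match the phantom")
    }
    if (any(!is.finite(Mod(g)))) stop("channel ", ch, " has non-finite values")
  }
  invisible(fields)
}

#' Save / load a channel field set
#'
#' Fields are persisted as an RDS container holding the complex per-channel
#' grids together with grid metadata (spacing, frequency, channel geometry).
#' @param fields a `channel_fields` object.
#' @param path file path (`.rds`).
#' @export
save_channel_fields <- function(fields, path) {
  stopifnot(inherits(fields, "channel_fields"))
  saveRDS(fields, path)
  invisible(path)
}

#' @rdname save_channel_fields
#' @export
load_channel_fields <- function(path) {
  f <- readRDS(path)
  if (!inherits(f, "channel_fields")) stop("not a channel_fields file")
  f
}
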