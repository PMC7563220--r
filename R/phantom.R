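#' Parameters for the synthetic pelvic phantom generator
#'
#' The generator emulates the anatomical structure a segmentation-sensitivity
#' study needs: an elliptic-cylinder torso with a subcutaneous fat (SAT)
#' shell and muscle bulk, a three-compartment spine and two iliac bone
#' groups (cortical shell, cancellous interior, marrow core), a bladder
#' (wall shell around urine), small- and large-intestine loop structures
#' (wall shell around lumen), visceral fat pockets, and a nested GTV/HTV
#' target at a cervix-, prostate- or rectum-like position in three sizes.
#'
#' @param spacing_mm isotropic voxel edge length, mm (2.5--10).
#' @param body_rx_mm,body_ry_mm torso semi-axes (left-right, anterior-posterior), mm.
#' @param length_mm caudal-cranial extent of the phantom, mm.
#' @param fat_fraction requested fat (SAT + visceral) volume fraction of the
#'   labeled body, 0--0.6. The SAT shell thickness is calibrated to meet it.
#' @param bladder_volume_ml bladder (urine + wall) volume, millilitres.
#' @param tumor_site `"cervix"`, `"prostate"` or `"rectum"`.
#' @param gtv_size `"small"`, `"medium"` or `"large"`; the three sizes are
#'   nested ellipsoids about a common center.
#' @param sex `"female"` or `"male"`; defaults to the site-appropriate sex
#'   (cervix is female, prostate is male, rectum defaults to female).
#' @param htv_margin_mm isotropic margin added to the GTV semi-axes to form
#'   the hyperthermia target volume (HTV), mm.
#' @param visceral_pockets number of visceral fat pockets.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(spacing_mm = 5,
                           body_rx_mm = 160, body_ry_mm = 105,
                           length_mm = 400,
                           fat_fraction = 0.35,
                           bladder_volume_ml = 100,
                           tumor_site = c("cervix", "prostate", "rectum"),
                           gtv_size = c("medium", "small", "large"),
                           sex = NULL,
                           htv_margin_mm = 10,
                           visceral_pockets = 4) {
  tumor_site <- match.arg(tumor_site)
  gtv_size <- match.arg(gtv_size)
  if (is.null(sex)) {
    sex <- switch(tumor_site, cervix = "female", prostate = "male",
                  rectum = "female")
  }
  sex <- match.arg(sex, c("female", "male"))
  if (tumor_site == "cervix" && sex != "female") {
    stop("tumor_site 'cervix' requires sex 'female'")
  }
  if (tumor_site == "prostate" && sex != "male") {
    stop("tumor_site 'prostate' requires sex 'male'")
  }
  if (spacing_mm < 2.5 || spacing_mm > 10) {
    stop("spacing_mm must be within [2.5, 10]")
  }
  if (fat_fraction < 0 || fat_fraction > 0.6) {
    stop("fat_fraction must be within [0, 0.6]")
  }
  structure(list(
    spacing_mm = spacing_mm, body_rx_mm = body_rx_mm, body_ry_mm = body_ry_mm,
    length_mm = length_mm, fat_fraction = fat_fraction,
    bladder_volume_ml = bladder_volume_ml, tumor_site = tumor_site,
    gtv_size = gtv_size, sex = sex, htv_margin_mm = htv_margin_mm,
    visceral_pockets = visceral_pockets
  ), class = "phantom_params")
}

# GTV semi-axes (x, y, z) in mm per size; sizes are nested by construction.
.gtv_semiaxes <- list(
  small  = c(8, 7, 10),
  medium = c(11, 10, 14),
  large  = c(15, 13, 18)
)

#' Generate a synthetic pelvic voxel phantom
#'
#' Deterministic given `(params, seed)`. Labels use the 13-tissue detailed
#' set of [phantom_label_set()]; the GTV and HTV are returned both as labels
#' (GTV only) and as logical masks. HTV voxels outside the GTV keep their
#' native tissue labels: the HTV is an evaluation region, not a material.
#'
#' @param params a [phantom_params()] record.
#' @param seed integer seed controlling the random components (small-intestine
#'   walk, visceral fat pocket placement).
#' @return object of class `voxel_phantom`: list with `labels` (3D character
#'   array, NA outside the body), `gtv_mask`, `htv_mask` (logical arrays),
#'   `spacing_mm`, `origin_mm`, `params`, `seed`.
#' @export
generate_phantom <- function(params, seed = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  sp <- params$spacing_mm
  rx <- params$body_rx_mm; ry <- params$body_ry_mm
  nx <- 2L * (ceiling(rx / sp) + 1L)
  ny <- 2L * (ceiling(ry / sp) + 1L)
  nz <- as.integer(ceiling(params$length_mm / sp))
  origin <- c(-nx * sp / 2, -ny * sp / 2, 0)
  xs <- origin[1] + (seq_len(nx) - 0.5) * sp
  ys <- origin[2] + (seq_len(ny) - 0.5) * sp
  zs <- origin[3] + (seq_len(nz) - 0.5) * sp
  zmid <- mean(range(zs))

  X <- array(rep(xs, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), dim = c(nx, ny, nz))

  body <- (X / rx)^2 + (Y / ry)^2 <= 1
  labels <- array(NA_character_, dim = c(nx, ny, nz))
  labels[body] <- "muscle"

  # Structures are positioned relative to the muscle interior (inner ellipse
  # after the SAT shell); use a provisional shell from the requested fat
  # fraction so the anatomy scales with body composition.
  t0 <- solve_annulus_thickness(params$fat_fraction, rx, ry)
  rxi <- rx - t0; ryi <- ry - t0

  ellipsoid <- function(c0, semi) {
    ((X - c0[1]) / semi[1])^2 + ((Y - c0[2]) / semi[2])^2 +
      ((Z - c0[3]) / semi[3])^2 <= 1
  }
  cylinder <- function(cx, cy, r, z0 = -Inf, z1 = Inf) {
    (X - cx)^2 + (Y - cy)^2 <= r^2 & Z >= z0 & Z <= z1
  }
  stamp <- function(mask, lab) {
    mask[is.na(mask)] <- FALSE
    if (any(mask & !body)) {
      stop("geometry overflow: ", lab, " exceeds the torso")
    }
    labels[mask] <<- lab
  }
  is_muscle <- function() !is.na(labels) & labels == "muscle"

  seed <- as.integer(seed)
  with_local_seed(seed, {
    # --- visceral fat pockets (upper lateral abdomen, away from targets)
    if (params$visceral_pockets > 0) {
      for (k in seq_len(params$visceral_pockets)) {
        side <- if (k %% 2 == 0) 1 else -1
        cx <- side * runif(1, 0.25, 0.5) * rxi
        cy <- runif(1, 0.05, 0.3) * ryi
        cz <- runif(1, 0.55, 0.8) * params$length_mm
        semi <- runif(3, 12, 22)
        stamp(ellipsoid(c(cx, cy, cz), semi) & is_muscle(), "visceral_fat")
      }
    }

    # --- bone groups: spine + two iliac columns, each cortical shell /
    #     cancellous interior / marrow core
    bone_group <- function(cx, cy, r_outer, z0, z1) {
      r_cort <- max(r_outer - 4.5, r_outer * 0.7)
      r_marrow <- max(4, 0.35 * r_outer)
      stamp(cylinder(cx, cy, r_outer, z0, z1), "bone_cortical")
      stamp(cylinder(cx, cy, r_cort, z0, z1), "bone_cancellous")
      stamp(cylinder(cx, cy, r_marrow, z0, z1), "bone_marrow")
    }
    r_spine <- max(8, 0.18 * ryi)
    bone_group(0, -0.75 * ryi, r_spine, -Inf, Inf)
    r_iliac <- max(8, 0.17 * rxi)
    bone_group(-0.62 * rxi, -0.2 * ryi, r_iliac, 0.05 * params$length_mm,
               0.75 * params$length_mm)
    bone_group(0.62 * rxi, -0.2 * ryi, r_iliac, 0.05 * params$length_mm,
               0.75 * params$length_mm)

    # --- large intestine: U-shaped tube (ascending / transverse / descending)
    zl <- params$length_mm
    path_li <- rbind(
      c(-0.5 * rxi, 0.05 * ryi, 0.45 * zl),
      c(-0.5 * rxi, 0.05 * ryi, 0.82 * zl),
      c( 0.5 * rxi, 0.05 * ryi, 0.82 * zl),
      c( 0.5 * rxi, 0.05 * ryi, 0.45 * zl)
    )
    li_outer <- tube_mask(X, Y, Z, path_li, 15)
    li_lumen <- tube_mask(X, Y, Z, path_li, 15 - sp)
    stamp(li_outer, "large_intestine_wall")
    stamp(li_lumen, "large_intestine_lumen")

    # --- small intestine: seeded random-walk tube in an abdominal box
    n_steps <- 50
    pos <- c(0, 0.12 * ryi, 0.55 * zl)
    pts <- matrix(NA_real_, n_steps + 1, 3)
    pts[1, ] <- pos
    lo <- c(-0.4 * rxi, -0.12 * ryi, 0.42 * zl)
    hi <- c( 0.4 * rxi,  0.38 * ryi, 0.78 * zl)
    for (s in seq_len(n_steps)) {
      step <- runif(3, -1, 1) * c(18, 12, 12)
      pos <- pmin(pmax(pos + step, lo), hi)
      pts[s + 1, ] <- pos
    }
    si_outer <- tube_mask(X, Y, Z, pts, 12)
    si_lumen <- tube_mask(X, Y, Z, pts, 12 - sp)
    stamp(si_outer, "small_intestine_wall")
    stamp(si_lumen, "small_intestine_lumen")
  })

  # --- bladder: urine sphere with a closed one-voxel wall shell; the wall is
  #     the 6-adjacency dilation of the urine, so no urine voxel can touch a
  #     non-bladder tissue
  r_blad <- (3 * params$bladder_volume_ml * 1000 / (4 * pi))^(1 / 3)
  c_blad <- c(0, 0.45 * ryi, zmid)
  urine <- ellipsoid(c_blad, rep(r_blad - sp, 3))
  wall <- (dilate6(urine) | ellipsoid(c_blad, rep(r_blad, 3))) & !urine
  stamp(wall, "bladder_wall")
  stamp(urine, "urine")

  # --- GTV / HTV at the site-appropriate position
  gtv_center <- switch(params$tumor_site,
    cervix   = c(0, -0.22 * ryi, zmid),
    prostate = c(0,  0.18 * ryi, zmid - 50),
    rectum   = c(0, -0.50 * ryi, zmid)
  )
  semi <- .gtv_semiaxes[[params$gtv_size]]
  gtv_mask <- ellipsoid(gtv_center, semi)
  htv_mask <- ellipsoid(gtv_center, semi + params$htv_margin_mm)
  if (any(gtv_mask & (urine | wall))) {
    stop("GTV intersects the bladder; adjust site position or bladder volume")
  }
  stamp(gtv_mask, "gtv")

  # --- SAT shell calibrated so (SAT + visceral fat) / body hits fat_fraction
  rho_scaled <- function(t) (X / (rx - t))^2 + (Y / (ry - t))^2
  n_body <- sum(body)
  n_visc <- sum(labels == "visceral_fat", na.rm = TRUE)
  target_sat <- max(params$fat_fraction * n_body - n_visc, 0)
  t_lo <- 0; t_hi <- 0.9 * min(rx, ry)
  for (it in 1:45) {
    t_try <- (t_lo + t_hi) / 2
    n_sat <- sum(body & rho_scaled(t_try) > 1)
    if (n_sat < target_sat) t_lo <- t_try else t_hi <- t_try
  }
  t_sat <- (t_lo + t_hi) / 2
  sat_region <- body & rho_scaled(t_sat) > 1

  in_ring <- labels[sat_region]
  if (any(in_ring != "muscle", na.rm = TRUE)) {
    bad <- unique(in_ring[in_ring != "muscle"])
    stop("geometry overflow: structure(s) ", paste(bad, collapse = ", "),
         " extend into the subcutaneous fat shell")
  }
  labels[sat_region] <- "sat"

  structure(list(
    labels = labels, gtv_mask = gtv_mask, htv_mask = htv_mask,
    spacing_mm = sp, origin_mm = origin,
    gtv_center_mm = gtv_center, sat_thickness_mm = t_sat,
    params = params, seed = seed
  ), class = "voxel_phantom")
}

# Fractional area of an elliptical annulus of thickness t (provisional SAT
# shell used only to scale organ placement before voxel-exact calibration).
solve_annulus_thickness <- function(f, rx, ry) {
  g <- function(t) 1 - (1 - t / rx) * (1 - t / ry) - f
  stats::uniroot(g, c(0, 0.9 * min(rx, ry)))$root
}

# Mask of voxels within `radius` mm of a polyline (rows of `path` are points).
tube_mask <- function(X, Y, Z, path, radius) {
  mask <- array(FALSE, dim = dim(X))
  for (s in seq_len(nrow(path) - 1)) {
    a <- path[s, ]; b <- path[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    tpar <- ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2] + (Z - a[3]) * ab[3]) / len2
    tpar[tpar < 0] <- 0; tpar[tpar > 1] <- 1
    d2 <- (X - (a[1] + tpar * ab[1]))^2 + (Y - (a[2] + tpar * ab[2]))^2 +
      (Z - (a[3] + tpar * ab[3]))^2
    mask <- mask | d2 <= radius^2
  }
  mask
}

# 6-connected (face-adjacency) binary dilation.
dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    r <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by == 1) {
      idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1)
    } else {
      idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax]
    }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  for (ax in 1:3) for (by in c(1, -1)) out <- out | shift(mask, ax, by)
  out
}

#' Volume statistics within the applicator axial extent
#'
#' Per-tissue voxel counts and volume percentages computed only over the
#' labeled voxels whose axial (z) center lies inside `extent_mm`, matching
#' the convention that body composition is evaluated for the volume enclosed
#' by the applicator. Derived aggregates: fat = SAT + visceral fat, bone =
#' cortical + cancellous + marrow.
#'
#' @param phantom a `voxel_phantom`.
#' @param extent_mm numeric length-2, axial interval in mm (phantom z
#'   coordinates). Default: the full phantom extent.
#' @return list of class `volume_stats`: `per_tissue` data.frame (tissue,
#'   count, pct), and `fat_pct`, `muscle_pct`, `bone_pct`, `n_voxels`.
#' @export
compute_volume_stats <- function(phantom, extent_mm = NULL) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  nz <- dim(phantom$labels)[3]
  zs <- phantom$origin_mm[3] + (seq_len(nz) - 0.5) * phantom$spacing_mm
  if (is.null(extent_mm)) extent_mm <- range(zs) + c(-1, 1)
  keep <- zs >= extent_mm[1] & zs <= extent_mm[2]
  if (!any(keep)) stop("applicator extent is disjoint from the phantom")
  lab <- phantom$labels[, , keep, drop = FALSE]
  lab <- lab[!is.na(lab)]
  n <- length(lab)
  levels <- union(phantom_label_set(), sort(unique(lab)))
  counts <- table(factor(lab, levels = levels))
  per_tissue <- data.frame(
    tissue = names(counts),
    count = as.integer(counts),
    pct = 100 * as.integer(counts) / n,
    stringsAsFactors = FALSE
  )
  pct_of <- function(ids) sum(per_tissue$pct[per_tissue$tissue %in% ids])
  structure(list(
    per_tissue = per_tissue,
    fat_pct = pct_of(c("sat", "visceral_fat")),
    muscle_pct = pct_of("muscle"),
    bone_pct = pct_of(c("bone_cortical", "bone_cancellous", "bone_marrow")),
    n_voxels = n,
    extent_mm = extent_mm
  ), class = "volume_stats")
}

#' Ordinary least-squares regression of muscle on fat volume percentage
#'
#' @param stats_df data.frame with columns `fat_pct` and `muscle_pct`.
#' @return list with `slope`, `intercept`, `r_squared` (NaN, with a warning,
#'   when the fat percentage is degenerate).
#' @export
fit_muscle_fat_regression <- function(stats_df) {
  stopifnot(all(c("fat_pct", "muscle_pct") %in% names(stats_df)))
  if (nrow(stats_df) < 3) stop("regression needs at least 3 phantoms")
  if (stats::sd(stats_df$fat_pct) < 0.1) {
    warning("fat percentage is (near-)constant; R^2 undefined")
    return(list(slope = NaN, intercept = NaN, r_squared = NaN))
  }
  fit <- stats::lm(muscle_pct ~ fat_pct, data = stats_df)
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared
  )
}

#' Generate a phantom population spanning a fat-fraction range
#'
#' Builds `n` phantoms whose requested fat fractions are evenly spaced across
#' `fat_fraction_range`, computes their volume statistics, and fits the
#' muscle-versus-fat volume-percentage regression by ordinary least squares.
#'
#' @param n number of phantoms (>= 3).
#' @param fat_fraction_range numeric length-2 within [0, 0.6].
#' @param seed integer; phantom k uses sub-seed `seed + k`.
#' @param params template [phantom_params()]; its `fat_fraction` is overridden.
#' @param keep_phantoms if `FALSE` only the statistics are kept (saves memory).
#' @return list of class `phantom_population`: `phantoms` (or NULL), `stats`
#'   (data.frame with fat/muscle/bone percentages), `regression`.
#' @export
generate_population <- function(n, fat_fraction_range = c(0.2, 0.5),
                                seed = 1L, params = phantom_params(),
                                keep_phantoms = TRUE) {
  if (n < 3) stop("population needs n >= 3")
  fr <- fat_fraction_range
  fracs <- if (diff(range(fr)) == 0) rep(fr[1], n) else
    seq(fr[1], fr[2], length.out = n)
  phantoms <- vector("list", n)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    pk <- params
    pk$fat_fraction <- fracs[k]
    ph <- generate_phantom(pk, seed = as.integer(seed) + k)
    vs <- compute_volume_stats(ph)
    rows[[k]] <- data.frame(
      phantom = k, requested_fat = fracs[k],
      fat_pct = vs$fat_pct, muscle_pct = vs$muscle_pct, bone_pct = vs$bone_pct
    )
    if (keep_phantoms) phantoms[[k]] <- ph
  }
  stats_df <- do.call(rbind, rows)
  reg <- fit_muscle_fat_regression(stats_df)
  structure(list(
    phantoms = if (keep_phantoms) phantoms else NULL,
    stats = stats_df, regression = reg, seed = seed
  ), class = "phantom_population")
}

#' Extract a 2D axial slice of a phantom
#'
#' Returns a 2D phantom (labels and masks as matrices) at the given axial
#' position, by default through the GTV center — the fast test path for the
#' 2D transverse-mode solver.
#'
#' @param phantom a `voxel_phantom`.
#' @param z_mm axial position in mm; default the GTV center.
#' @return object of class `voxel_phantom` with a third dimension of 1 logical
#'   collapsed to matrices and `is_2d = TRUE`.
#' @export
phantom_slice <- function(phantom, z_mm = NULL) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (is.null(z_mm)) z_mm <- phantom$gtv_center_mm[3]
  nz <- dim(phantom$labels)[3]
  zs <- phantom$origin_mm[3] + (seq_len(nz) - 0.5) * phantom$spacing_mm
  k <- which.min(abs(zs - z_mm))
  out <- phantom
  out$labels <- phantom$labels[, , k]
  out$gtv_mask <- phantom$gtv_mask[, , k]
  out$htv_mask <- phantom$htv_mask[, , k]
  out$slice_z_mm <- zs[k]
  out$is_2d <- TRUE
  out
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat("<voxel_phantom> ", paste(d, collapse = " x "),
      " @ ", x$spacing_mm, " mm\n", sep = "")
  cat("  site: ", x$params$tumor_site, " (", x$params$sex, "), GTV size: ",
      x$params$gtv_size, "\n", sep = "")
  cat("  GTV voxels: ", sum(x$gtv_mask), ", HTV voxels: ", sum(x$htv_mask),
      "\n", sep = "")
  invisible(x)
}
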