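#' Per-channel complex drive settings
#'
#' @param amplitude numeric vector of per-channel amplitudes (scale of the
#'   unit drive, dimensionless).
#' @param phase numeric vector of per-channel phases, radians.
#' @return object of class `drive_settings`.
#' @export
drive_settings <- function(amplitude, phase = rep(0, length(amplitude))) {
  if (length(amplitude) != length(phase)) {
    stop("amplitude and phase must have equal length")
  }
  if (any(!is.finite(amplitude)) || any(!is.finite(phase))) {
    stop("drive settings must be finite")
  }
  if (all(amplitude == 0)) stop("at least one channel weight must be nonzero")
  structure(list(amplitude = amplitude, phase = phase,
                 weights = amplitude * exp(1i * phase)),
            class = "drive_settings")
}

#' Combine channel fields under complex drive weights
#'
#' Voxelwise weighted phasor sum of the per-channel unit-drive fields.
#'
#' @param fields a `channel_fields` object.
#' @param drive a [drive_settings()] (or a complex weight vector).
#' @return total complex field: matrix (2D) or list of `ex`, `ey`, `ez` (3D).
#' @export
combine_fields <- function(fields, drive) {
  stopifnot(inherits(fields, "channel_fields"))
  w <- if (inherits(drive, "drive_settings")) drive$weights else as.complex(drive)
  if (length(w) != fields$n_channels) {
    stop("drive has ", length(w), " weights for ", fields$n_channels,
         " channels")
  }
  if (fields$mode == "2d") {
    tot <- fields$fields[[1]]$ez * w[1]
    for (ch in seq_along(w)[-1]) tot <- tot + fields$fields[[ch]]$ez * w[ch]
    tot
  } else {
    tot <- lapply(fields$fields[[1]][c("ex", "ey", "ez")], function(g) g * w[1])
    for (ch in seq_along(w)[-1]) {
      f <- fields$fields[[ch]]
      tot$ex <- tot$ex + f$ex * w[ch]
      tot$ey <- tot$ey + f$ey * w[ch]
      tot$ez <- tot$ez + f$ez * w[ch]
    }
    tot
  }
}

#' Conductivity and density grids of a phantom under a scheme
#'
#' @param phantom a `voxel_phantom` (or 2D slice).
#' @param scheme a `segmentation_scheme`.
#' @param table a `tissue_table`.
#' @return list with `sigma` and `rho` arrays on the phantom grid (0 / NA-free;
#'   zero conductivity and unit density outside the body) plus `body` mask.
#' @export
phantom_sigma_rho <- function(phantom, scheme, table = default_tissue_table()) {
  reduced <- apply_scheme(phantom$labels, scheme)
  body <- !is.na(reduced)
  labs <- unique(reduced[body])
  props <- resolve_properties(labs, table)
  sig <- array(0, dim = dim(reduced))
  rho <- array(1, dim = dim(reduced))
  m <- match(reduced[body], props$tissue_id)
  sig[body] <- props$sigma_eff[m]
  rho[body] <- props$rho[m]
  list(sigma = sig, rho = rho, body = body)
}

#' Compute the SAR map from a combined field
#'
#' SAR = sigma |E|^2 / (2 rho) with |E| the peak phasor magnitude (vector norm
#' over components), in W/kg.
#'
#' @param total combined complex field from [combine_fields()] (matrix for 2D,
#'   list `ex`/`ey`/`ez` for 3D).
#' @param sigma,rho conductivity (S/m) and density (kg/m3) grids congruent
#'   with the field.
#' @param phantom optional `voxel_phantom` supplying the HTV and body masks;
#'   if given, the result is a `sar_map`.
#' @return numeric SAR array, or a `sar_map` (list with `sar`, `htv`,
#'   `healthy`, `body`) when `phantom` is supplied.
#' @export
compute_sar <- function(total, sigma, rho, phantom = NULL) {
  e2 <- if (is.list(total)) {
    Mod(total$ex)^2 + Mod(total$ey)^2 + Mod(total$ez)^2
  } else {
    Mod(total)^2
  }
  if (!all(dim(e2) == dim(sigma)) || !all(dim(e2) == dim(rho))) {
    stop("field and material grids are not congruent")
  }
  sar <- sigma * e2 / (2 * rho)
  if (is.null(phantom)) return(sar)
  body <- !is.na(phantom$labels)
  htv <- phantom$htv_mask & body
  structure(list(sar = sar, htv = htv, healthy = body & !htv, body = body),
            class = "sar_map")
}

#' Mean SAR of the hottest fraction of a region
#'
#' Selects the `ceiling(fraction * n)` voxels of `mask` with the highest SAR
#' and returns their mean. Ties at the cut value are resolved by the
#' deterministic sorted order, so the mean is always over exactly
#' `ceiling(fraction * n)` values.
#'
#' @param sar numeric SAR array or a `sar_map`.
#' @param mask logical mask (same shape), non-empty.
#' @param fraction volume fraction in (0, 1]; 0.01 is the hotspot convention.
#' @return mean SAR of the top fraction, W/kg.
#' @export
hotspot_mean <- function(sar, mask, fraction = 0.01) {
  if (inherits(sar, "sar_map")) sar <- sar$sar
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  v <- sar[mask]
  n <- length(v)
  if (n == 0) stop("mask is empty")
  k <- ceiling(fraction * n)
  mean(sort(v, decreasing = TRUE)[seq_len(k)])
}

#' Target-to-hotspot quotient (THQ)
#'
#' Ratio of the mean SAR in the hyperthermia target volume (HTV) to the mean
#' SAR of the hottest `hotspot_fraction` of healthy tissue (labeled body
#' voxels outside the HTV).
#'
#' @param sar a `sar_map` (from [compute_sar()] with a phantom).
#' @param hotspot_fraction healthy-volume fraction defining the hotspot
#'   (default 0.01, i.e. the hottest 1 percent).
#' @return THQ, dimensionless.
#' @export
compute_thq <- function(sar, hotspot_fraction = 0.01) {
  stopifnot(inherits(sar, "sar_map"))
  if (!any(sar$htv)) stop("HTV mask is empty")
  if (!any(sar$healthy)) stop("healthy-tissue mask is empty")
  num <- mean(sar$sar[sar$htv])
  den <- hotspot_mean(sar$sar, sar$healthy, hotspot_fraction)
  if (den == 0) stop("THQ undefined: zero SAR in the hotspot region")
  num / den
}

#' Absolute relative THQ change, percent
#'
#' `|dTHQ| = |(THQ_n - THQ_ref) / THQ_ref| * 100`, the treatment-quality
#' change of segmentation n against the detailed benchmark.
#'
#' @param thq_n THQ under the reduced segmentation.
#' @param thq_reference THQ of the detailed benchmark (> 0).
#' @export
compute_dthq <- function(thq_n, thq_reference) {
  if (any(thq_reference <= 0)) stop("reference THQ must be positive")
  abs((thq_n - thq_reference) / thq_reference * 100)
}

#' Per-tissue masks from the detailed phantom labels
#'
#' @param phantom a `voxel_phantom`.
#' @param tissues labels to extract; default all present.
#' @return named list of logical masks.
#' @export
tissue_masks <- function(phantom, tissues = NULL) {
  lab <- phantom$labels
  present <- sort(unique(lab[!is.na(lab)]))
  if (is.null(tissues)) tissues <- present
  tissues <- intersect(tissues, present)
  stats::setNames(lapply(tissues, function(t) !is.na(lab) & lab == t), tissues)
}

#' Per-tissue absolute relative difference in top-1 percent SAR
#'
#' For each tissue t, `|dRD|_t = |(M_n,t - M_ref,t) / M_ref,t| * 100` where M
#' is the mean SAR over the hottest `fraction` of the tissue volume. Masks are
#' always taken from the detailed phantom so the same spatial regions are
#' compared across segmentations. Tissues with zero reference SAR are flagged
#' undefined (NA) with a warning.
#'
#' @param sar_n,sar_ref SAR arrays or `sar_map`s on the same grid.
#' @param masks named list of detailed tissue masks ([tissue_masks()]).
#' @param fraction tissue-volume fraction (default 0.01).
#' @return data.frame with columns tissue, m_n, m_ref, drd_pct.
#' @export
compute_drd <- function(sar_n, sar_ref, masks, fraction = 0.01) {
  if (inherits(sar_n, "sar_map")) sar_n <- sar_n$sar
  if (inherits(sar_ref, "sar_map")) sar_ref <- sar_ref$sar
  if (!all(dim(sar_n) == dim(sar_ref))) stop("SAR maps are not congruent")
  rows <- lapply(names(masks), function(t) {
    m_n <- hotspot_mean(sar_n, masks[[t]], fraction)
    m_ref <- hotspot_mean(sar_ref, masks[[t]], fraction)
    drd <- if (m_ref == 0) NA_real_ else abs((m_n - m_ref) / m_ref * 100)
    data.frame(tissue = t, m_n = m_n, m_ref = m_ref, drd_pct = drd)
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$drd_pct))) {
    warning("zero reference SAR for tissue(s): ",
            paste(out$tissue[is.na(out$drd_pct)], collapse = ", "),
            "; |dRD| flagged undefined")
  }
  out
}

#' Boxplot summary statistics
#'
#' Median, quartiles and the 2.5 / 97.5 percentiles, using linear
#' interpolation between closest ranks (R quantile type 7).
#'
#' @param values numeric vector; NAs (undefined |dRD|) are dropped with a
#'   warning.
#' @return named numeric vector: p2.5, q1, median, q3, p97.5.
#' @export
summarize_boxplot <- function(values) {
  if (anyNA(values)) {
    warning("dropping ", sum(is.na(values)), " undefined value(s)")
    values <- values[!is.na(values)]
  }
  if (length(values) == 0) stop("no values to summarize")
  q <- stats::quantile(values, c(0.025, 0.25, 0.5, 0.75, 0.975),
                       names = FALSE, type = 7)
  c(p2.5 = q[1], q1 = q[2], median = q[3], q3 = q[4], p97.5 = q[5])
}

#' Threshold classification of dosimetry changes
#'
#' A segmentation cell is acceptable when its maximum |dTHQ| is at or below
#' 5 percent (the clinical-relevance threshold, corresponding to about a
#' 0.2 degree change in median target temperature); |dRD| values are
#' classified against the 0--20 percent band.
#'
#' @param dthq_pct |dTHQ| values, percent.
#' @param drd_pct optional |dRD| values, percent.
#' @return list with logical `dthq_acceptable` and, when given,
#'   `drd_within_band`.
#' @export
classify_thresholds <- function(dthq_pct, drd_pct = NULL) {
  out <- list(dthq_acceptable = dthq_pct <= 5)
  if (!is.null(drd_pct)) {
    out$drd_within_band <- !is.na(drd_pct) & drd_pct >= 0 & drd_pct <= 20
  }
  out
}

#' Conjugate-phase focusing drive
#'
#' Deterministic baseline drive: unit amplitudes with each channel's phase
#' set to the negative of its field phase at the target point, so all
#' channels add in phase there. Useful as an optimizer-free reference and as
#' the injected starting particle of the swarm.
#'
#' @param fields a `channel_fields` object.
#' @param target_mask logical mask (phantom grid); the focus is its centroid
#'   voxel.
#' @return a [drive_settings()].
#' @export
focus_drive <- function(fields, target_mask) {
  idx <- which(target_mask, arr.ind = TRUE)
  cen <- round(colMeans(idx))
  get_at <- function(f) {
    g <- f$ez
    if (length(dim(g)) == 2) g[cen[1], cen[2]] else g[cen[1], cen[2], cen[3]]
  }
  ph <- vapply(fields$fields, function(f) -Arg(get_at(f)), numeric(1))
  ph <- ph - ph[1]
  drive_settings(rep(1, fields$n_channels), ph %% (2 * pi))
}
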