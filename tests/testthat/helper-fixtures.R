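# Shared fixtures, built lazily and cached for the whole test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Homogeneous muscle disk with a concentric GTV/HTV: the symmetric 2D
# fixture used for ring-array symmetry and optimizer tests.
disk_phantom <- function(radius_mm = 60, spacing = 5, htv_radius_mm = 15) {
  n <- 2L * (as.integer(ceiling(radius_mm / spacing)) + 2L)
  xs <- (seq_len(n) - 0.5) * spacing - n * spacing / 2
  R2 <- outer(xs^2, xs^2, "+")
  lab <- matrix(NA_character_, n, n)
  lab[R2 <= radius_mm^2] <- "muscle"
  gtv <- R2 <= (htv_radius_mm - spacing)^2
  lab[gtv] <- "gtv"
  structure(list(
    labels = lab, gtv_mask = gtv, htv_mask = R2 <= htv_radius_mm^2,
    spacing_mm = spacing, origin_mm = c(-n * spacing / 2, -n * spacing / 2, 0),
    gtv_center_mm = c(0, 0, 0),
    params = list(tumor_site = "cervix", gtv_size = "medium"), seed = 0L,
    is_2d = TRUE
  ), class = "voxel_phantom")
}

disk_fields <- function(n_channels = 12) {
  fixture(paste0("disk_fields_", n_channels), function() {
    ph <- disk_phantom()
    det <- build_scheme("detailed", phantom_label_set())
    mats <- assign_material_grids(
      ph, det, applicator = applicator_model(n_channels = n_channels))
    list(phantom = ph, fields = solve_all_channels(mats))
  })
}

# Synthetic channel field set (random complex grids, no solver): for
# exercising combination/THQ algebra fast.
synthetic_fields <- function(n_channels = 4, nd = c(10, 10), seed = 42) {
  set.seed(seed)
  fields <- lapply(seq_len(n_channels), function(ch) {
    list(ez = matrix(complex(real = rnorm(prod(nd)),
                             imaginary = rnorm(prod(nd))), nd[1], nd[2]))
  })
  structure(list(fields = fields, mode = "2d", spacing_mm = 5,
                 frequency_hz = 1e8, n_channels = n_channels,
                 phantom_dim = c(nd, 1L), steady_rel = rep(0, n_channels),
                 applicator = applicator_model(n_channels = n_channels)),
            class = "channel_fields")
}

synthetic_sar_phantom <- function(nd = c(10, 10)) {
  lab <- matrix("muscle", nd[1], nd[2])
  htv <- matrix(FALSE, nd[1], nd[2])
  htv[4:6, 4:6] <- TRUE
  lab[5, 5] <- "gtv"
  structure(list(labels = lab, gtv_mask = lab == "gtv", htv_mask = htv,
                 spacing_mm = 5, origin_mm = c(0, 0, 0),
                 gtv_center_mm = c(0, 0, 0), params = list(), seed = 0L,
                 is_2d = TRUE), class = "voxel_phantom")
}

# Small pelvic phantom parameters for pipeline-level tests.
small_pelvis_params <- function(...) {
  phantom_params(body_rx_mm = 120, body_ry_mm = 85, length_mm = 300, ...)
}

small_study_config <- function() {
  experiment_config(
    phantom = small_pelvis_params(),
    sites = "cervix", sizes = "medium",
    schemes = c("detailed", "clinical"), drive = "focus", seed = 11)
}

small_study_report <- function() {
  fixture("small_study", function() run_study(small_study_config()))
}

# Phantom family with growing bladder volume: detailed-vs-clinical dosimetry
# under a conjugate-phase focusing drive on the detailed benchmark.
bladder_family_result <- function(volumes = c(50, 150, 250)) {
  fixture("bladder_family", function() {
    det <- build_scheme("detailed", phantom_label_set())
    cli <- build_scheme("clinical", phantom_label_set())
    out <- lapply(volumes, function(vol) {
      pp <- phantom_params(tumor_site = "cervix", gtv_size = "medium",
                           bladder_volume_ml = vol)
      ph <- phantom_slice(generate_phantom(pp, seed = 11))
      fs_d <- solve_all_channels(assign_material_grids(ph, det))
      fs_c <- solve_all_channels(assign_material_grids(ph, cli))
      dr <- focus_drive(fs_d, ph$htv_mask)
      sr_d <- phantom_sigma_rho(ph, det)
      sr_c <- phantom_sigma_rho(ph, cli)
      sm_d <- compute_sar(combine_fields(fs_d, dr), sr_d$sigma, sr_d$rho, ph)
      sm_c <- compute_sar(combine_fields(fs_c, dr), sr_c$sigma, sr_c$rho, ph)
      dd <- suppressWarnings(compute_drd(sm_c, sm_d, tissue_masks(ph)))
      list(volume = vol,
           dthq = compute_dthq(compute_thq(sm_c), compute_thq(sm_d)),
           drd = dd)
    })
    list(volumes = volumes,
         dthq = vapply(out, `[[`, numeric(1), "dthq"),
         drd = do.call(rbind, lapply(out, function(o) {
           cbind(volume = o$volume, o$drd)
         })))
  })
}
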