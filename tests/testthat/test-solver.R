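test_that("material assignment resolves urine per scheme", {
  ph <- phantom_slice(generate_phantom(
    small_pelvis_params(tumor_site = "cervix"), seed = 9))
  ur <- which(ph$labels == "urine", arr.ind = TRUE)[1, ]

  mats_cli <- assign_material_grids(ph, build_scheme("clinical",
                                                     phantom_label_set()))
  o <- mats_cli$offset
  expect_equal(mats_cli$eps_r[ur[1] + o[1], ur[2] + o[2]], 66.0)
  expect_equal(mats_cli$sigma[ur[1] + o[1], ur[2] + o[2]], 0.708)
  expect_equal(mats_cli$rho[ur[1] + o[1], ur[2] + o[2]], 1090)

  mats_bla <- assign_material_grids(ph, build_scheme("bladder",
                                                     phantom_label_set()))
  expect_equal(mats_bla$eps_r[ur[1] + o[1], ur[2] + o[2]], 49.9)
  expect_equal(mats_bla$sigma[ur[1] + o[1], ur[2] + o[2]], 1.750)
  expect_equal(mats_bla$rho[ur[1] + o[1], ur[2] + o[2]], 1024)

  # water bolus just outside the body, air outside the shell
  nb <- dim(mats_cli$eps_r)[1]
  expect_equal(mats_cli$eps_r[3, 3], 1)          # corner: air/PML
  mid <- as.integer(nb / 2)
  edge_col <- mats_cli$eps_r[, mid]
  expect_true(any(abs(edge_col - 80.9) < 1e-9))  # bolus water present

  # unmapped label errors by name
  bad <- ph
  bad$labels[1, 1] <- "mystery_organ"
  expect_error(
    assign_material_grids(bad, build_scheme("clinical", phantom_label_set())),
    "mystery_organ")
})

test_that("zero drive amplitude yields an identically zero field", {
  n <- 50
  eps <- matrix(1, n, n); sig <- matrix(0, n, n)
  out <- fdtd_run_2d(eps, sig, 5, 1e8,
                     data.frame(i = 25, j = 25, amp = 0), periods = 3)
  expect_true(all(out$phasor == 0))
})

test_that("diametrically opposite channels are mirror images on a disk", {
  fx <- disk_fields(12)
  f <- fx$fields
  # channels 4 and 10 sit at +/- 90 degrees: reflection y -> -y maps one
  # field onto the other
  e4 <- f$fields[[4]]$ez
  e10 <- f$fields[[10]]$ez
  mirrored <- e10[, rev(seq_len(ncol(e10)))]
  rel <- sqrt(mean(Mod(e4 - mirrored)^2)) / sqrt(mean(Mod(e4)^2))
  # the Yee staggering is not reflection-symmetric, so agreement is limited
  # by the half-cell offset (a few percent at 5 mm)
  expect_lt(rel, 0.06)
})

test_that("fifteen periods reach harmonic steady state", {
  fx <- disk_fields(12)
  expect_true(all(fx$fields$steady_rel < 0.01))
})

test_that("channel field sets validate shape and finiteness", {
  fx <- disk_fields(12)
  expect_silent(validate_channel_fields(fx$fields, fx$phantom))
  tampered <- fx$fields
  tampered$fields[[3]]$ez <- tampered$fields[[3]]$ez[-1, ]
  expect_error(validate_channel_fields(tampered, fx$phantom), "shape")
  short <- fx$fields
  short$fields <- short$fields[1:5]
  expect_error(validate_channel_fields(short, fx$phantom), "per channel")
})

test_that("single-channel applicator produces a one-grid set", {
  fx <- disk_fields(1)
  expect_length(fx$fields$fields, 1)
  expect_equal(fx$fields$n_channels, 1)
})

test_that("free-space dipole field follows the 1/r envelope", {
  # 1 GHz on a 10 mm grid so the far zone fits in a 64^3 domain
  n <- 64
  eps <- array(1, c(n, n, n)); sig <- array(0, c(n, n, n))
  ctr <- n / 2
  src <- data.frame(i = ctr, j = ctr, k = ctr + (-1:1), comp = 2)
  out <- fdtd_run_3d(eps, sig, 10, 1e9, src, periods = 8, ramp_periods = 2)
  lam_mm <- 300
  i_r <- (ctr + 1 + 5):(n - 10)
  r <- (i_r - (ctr + 1)) * 10
  emag <- sqrt(Mod(out$ez[i_r, ctr + 1, ctr + 1])^2 +
                 Mod(out$ex[i_r, ctr + 1, ctr + 1])^2)
  env <- r * emag
  sel <- r >= 0.45 * lam_mm & r <= 1.4 * lam_mm
  expect_gt(sum(sel), 3)
  expect_lt(max(env[sel]) / min(env[sel]) - 1, 0.10)
})

test_that("3D ring-applicator solve is deterministic with matching shapes", {
  p <- phantom_params(body_rx_mm = 60, body_ry_mm = 50, length_mm = 120,
                      spacing_mm = 10, tumor_site = "rectum", sex = "male",
                      bladder_volume_ml = 30)
  ph <- generate_phantom(p, seed = 2)
  mats <- assign_material_grids(
    ph, build_scheme("detailed", phantom_label_set()),
    applicator = applicator_model(ring_z_mm = c(-30, 0, 30)),
    settings = solver_settings(mode = "3d", periods = 5))
  f1 <- solve_channel(mats, 1)
  f2 <- solve_channel(mats, 1)
  expect_identical(f1$ez, f2$ez)
  expect_equal(dim(f1$ez), dim(ph$labels))
  expect_true(all(is.finite(Mod(f1$ez))))
  expect_true(any(Mod(f1$ez) > 0))
})

test_that("channel fields persist to RDS and back", {
  fx <- disk_fields(1)
  path <- file.path(tempdir(), "fields_test.rds")
  save_channel_fields(fx$fields, path)
  back <- load_channel_fields(path)
  expect_identical(back$fields[[1]]$ez, fx$fields$fields[[1]]$ez)
  expect_equal(back$frequency_hz, 1e8)
})

test_that("user-supplied extra organs flow through schemes and materials", {
  # tissues beyond the tabulated set carry user-supplied properties
  ph <- phantom_slice(generate_phantom(
    small_pelvis_params(tumor_site = "cervix"), seed = 9))
  idx <- which(ph$labels == "muscle")[1:4]
  ph$labels[idx] <- "urethra"

  tab <- default_tissue_table()
  tab <- rbind(tab, data.frame(tissue_id = "urethra", eps_r = 75,
                               sigma_eff = 1.2, rho = 1100))
  tab <- sarsense:::validate_tissue_table(tab)

  labs <- unique(ph$labels[!is.na(ph$labels)])
  det <- build_scheme("detailed", labs)
  cli <- build_scheme("clinical", labs,
                      extra_classes = c(urethra = "high_water"))
  expect_equal(unname(cli$mapping[["urethra"]]), "muscle")

  mats <- assign_material_grids(ph, det, table = tab)
  o <- mats$offset
  ij <- which(ph$labels == "urethra", arr.ind = TRUE)[1, ]
  expect_equal(mats$sigma[ij[1] + o[1], ij[2] + o[2]], 1.2)

  vs3 <- compute_volume_stats(generate_phantom(
    small_pelvis_params(tumor_site = "cervix"), seed = 9))
  expect_equal(sum(vs3$per_tissue$pct), 100, tolerance = 1e-9)
})
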