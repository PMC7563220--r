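test_that("phantom generation is deterministic and GTV sizes nest", {
  p_small <- small_pelvis_params(tumor_site = "cervix", gtv_size = "small")
  p_large <- small_pelvis_params(tumor_site = "cervix", gtv_size = "large")
  a <- generate_phantom(p_small, seed = 5)
  b <- generate_phantom(p_small, seed = 5)
  expect_identical(a$labels, b$labels)
  expect_identical(a$gtv_mask, b$gtv_mask)
  big <- generate_phantom(p_large, seed = 5)
  expect_true(all(big$gtv_mask[a$gtv_mask]))       # small GTV inside large
  expect_false(all(a$gtv_mask[big$gtv_mask]))      # strictly larger
  expect_true(all(a$htv_mask[a$gtv_mask]))         # GTV inside HTV
  # HTV is an evaluation region: voxels outside GTV keep native labels
  ring <- a$htv_mask & !a$gtv_mask
  expect_false(any(a$labels[ring] == "gtv", na.rm = TRUE))
})

test_that("site/sex and parameter validation", {
  expect_error(phantom_params(tumor_site = "prostate", sex = "female"),
               "male")
  expect_error(phantom_params(tumor_site = "cervix", sex = "male"),
               "female")
  expect_error(phantom_params(spacing_mm = 1), "spacing")
  expect_error(phantom_params(spacing_mm = 12), "spacing")
  # site-appropriate default sex
  expect_equal(phantom_params(tumor_site = "prostate")$sex, "male")
  expect_equal(phantom_params(tumor_site = "cervix")$sex, "female")
})

test_that("oversized structures raise a geometry overflow error", {
  p <- small_pelvis_params(tumor_site = "rectum", sex = "male",
                           bladder_volume_ml = 3000)
  expect_error(generate_phantom(p, seed = 1), "overflow|bladder|torso")
})

test_that("volume percentages follow direct voxel counts", {
  # hand-built phantom: 3000 SAT + 7000 muscle voxels
  lab <- array(NA_character_, dim = c(10, 10, 100))
  lab[seq_len(3000)] <- "sat"
  lab[3000 + seq_len(7000)] <- "muscle"
  ph <- structure(list(labels = lab,
                       gtv_mask = array(FALSE, dim(lab)),
                       htv_mask = array(FALSE, dim(lab)),
                       spacing_mm = 5, origin_mm = c(0, 0, 0),
                       params = list(), seed = 0L),
                  class = "voxel_phantom")
  vs <- compute_volume_stats(ph)
  expect_equal(vs$fat_pct, 30)
  expect_equal(vs$muscle_pct, 70)
  expect_equal(sum(vs$per_tissue$pct), 100, tolerance = 1e-9)
  expect_error(compute_volume_stats(ph, extent_mm = c(1e5, 2e5)), "disjoint")
})

test_that("realized fat fraction tracks the request within 3 points", {
  for (f in c(0.25, 0.35, 0.45)) {
    ph <- generate_phantom(small_pelvis_params(fat_fraction = f), seed = 2)
    vs <- compute_volume_stats(ph)
    expect_lt(abs(vs$fat_pct - 100 * f), 3)
  }
})

test_that("bladder wall forms a closed 6-adjacency shell around urine", {
  ph <- generate_phantom(small_pelvis_params(tumor_site = "cervix"), seed = 9)
  lab <- ph$labels
  d <- dim(lab)
  ur <- which(lab == "urine", arr.ind = TRUE)
  expect_gt(nrow(ur), 0)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(nrow(shifts))) {
    nb <- sweep(ur, 2, shifts[s, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    vals <- lab[nb[ok, , drop = FALSE]]
    expect_true(all(vals %in% c("urine", "bladder_wall")),
                label = paste("shift", s))
  }
})

test_that("scheme reduction conserves labeled voxel count", {
  ph <- generate_phantom(small_pelvis_params(), seed = 3)
  n0 <- sum(!is.na(ph$labels))
  for (nm in c("clinical", "bladder", "combined")) {
    red <- apply_scheme(ph$labels, build_scheme(nm, phantom_label_set()))
    expect_equal(sum(!is.na(red)), n0, label = nm)
  }
})

test_that("muscle-fat regression recovers exact collinearity", {
  # oracle: constructed stats with muscle% = 100 - fat% - 6
  df <- data.frame(fat_pct = c(20, 30, 40, 50),
                   muscle_pct = 100 - c(20, 30, 40, 50) - 6)
  reg <- suppressWarnings(fit_muscle_fat_regression(df))  # perfect-fit notice
  expect_equal(reg$slope, -1, tolerance = 1e-9)
  expect_equal(reg$intercept, 94, tolerance = 1e-9)
  expect_equal(reg$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_muscle_fat_regression(df[1:2, ]), "at least 3")
})

test_that("population spans the fat range; degenerate range flagged", {
  pop <- generate_population(4, c(0.25, 0.45), seed = 1,
                             params = small_pelvis_params(),
                             keep_phantoms = FALSE)
  expect_equal(nrow(pop$stats), 4)
  expect_true(all(diff(pop$stats$fat_pct) > 0))
  expect_gt(pop$regression$r_squared, 0.9)
  expect_lt(pop$regression$slope, 0)
  pop2 <- generate_population(4, c(0.25, 0.45), seed = 1,
                              params = small_pelvis_params(),
                              keep_phantoms = FALSE)
  expect_identical(pop$stats, pop2$stats)

  expect_warning(
    d <- generate_population(3, c(0.4, 0.4), seed = 1,
                             params = small_pelvis_params(),
                             keep_phantoms = FALSE),
    "constant")
  expect_true(is.nan(d$regression$r_squared))
})

test_that("phantoms round-trip through NIfTI plus sidecar", {
  ph <- generate_phantom(small_pelvis_params(tumor_site = "rectum"), seed = 4)
  path <- file.path(tempdir(), "phantom_test.nii.gz")
  write_phantom(ph, path)
  back <- read_phantom(path)
  expect_identical(back$labels, ph$labels)
  expect_identical(back$gtv_mask, ph$gtv_mask)
  expect_identical(back$htv_mask, ph$htv_mask)
  expect_equal(back$spacing_mm, ph$spacing_mm)
  expect_equal(back$params$tumor_site, "rectum")
})

test_that("axial slice passes through the GTV", {
  ph <- generate_phantom(small_pelvis_params(tumor_site = "cervix"), seed = 6)
  sl <- phantom_slice(ph)
  expect_true(isTRUE(sl$is_2d))
  expect_true(any(sl$gtv_mask))
  expect_true(any(sl$labels == "urine", na.rm = TRUE))  # bladder in plane
  expect_equal(dim(sl$labels), dim(ph$labels)[1:2])
})
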