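test_that("field combination is linear with global-phase-invariant magnitude", {
  fx <- synthetic_fields(4)
  w <- c(1 + 0i, 0, 0, 0)
  expect_identical(combine_fields(fx, w), fx$fields[[1]]$ez)

  dr <- drive_settings(c(0.5, 1, 0.8, 0.3), c(0, 1.1, -2, 0.4))
  tot <- combine_fields(fx, dr)
  rot <- combine_fields(fx, dr$weights * exp(1i * 0.77))
  expect_equal(Mod(rot), Mod(tot), tolerance = 1e-12)
  dbl <- combine_fields(fx, dr$weights * 2)
  expect_equal(Mod(dbl), 2 * Mod(tot), tolerance = 1e-12)

  expect_error(combine_fields(fx, c(1, 2)), "channels")
  expect_error(drive_settings(c(0, 0)), "nonzero")
  expect_error(drive_settings(c(1, NA)), "finite")
})

test_that("SAR follows sigma |E|^2 / (2 rho)", {
  e <- matrix(100 + 0i, 2, 2)
  sar <- compute_sar(e, matrix(0.708, 2, 2), matrix(1090, 2, 2))
  expect_equal(sar[1, 1], 0.708 * 100^2 / (2 * 1090))  # 3.24770... W/kg
  expect_equal(compute_sar(e, matrix(0, 2, 2), matrix(1090, 2, 2)),
               matrix(0, 2, 2))
  # doubling the field quadruples SAR
  expect_equal(compute_sar(2 * e, matrix(0.708, 2, 2), matrix(1090, 2, 2)),
               4 * sar)
  expect_error(compute_sar(e, matrix(1, 3, 3), matrix(1, 3, 3)), "congruent")
})

test_that("hotspot mean matches the full-sort definition", {
  sar <- array(1:100, dim = c(10, 10))
  mask <- array(TRUE, dim = c(10, 10))
  expect_equal(hotspot_mean(sar, mask, 0.01), 100)        # top-1 voxel
  expect_equal(hotspot_mean(sar, mask, 0.10), mean(91:100))
  expect_equal(hotspot_mean(sar, mask, 1), mean(1:100))   # plain mean
  u <- array(3.7, dim = c(5, 5))
  for (f in c(0.01, 0.2, 1)) {
    expect_equal(hotspot_mean(u, array(TRUE, dim(u)), f), 3.7)
  }
  expect_error(hotspot_mean(sar, array(FALSE, dim(sar))), "empty")
  expect_error(hotspot_mean(sar, mask, 0), "fraction")
})

test_that("THQ equals target mean over healthy top-percent mean", {
  ph <- synthetic_sar_phantom()
  # constructed SAR: 2 W/kg in HTV, healthy has one extreme voxel
  sar <- matrix(1, 10, 10)
  sar[ph$htv_mask] <- 2
  healthy_idx <- which(!ph$htv_mask)
  sar[healthy_idx[1]] <- 4   # 91 healthy voxels -> top 1% = 1 voxel
  sm <- structure(list(sar = sar, htv = ph$htv_mask,
                       healthy = !ph$htv_mask, body = matrix(TRUE, 10, 10)),
                  class = "sar_map")
  expect_equal(compute_thq(sm), 2 / 4)
  # uniform SAR gives THQ = 1 exactly
  smu <- sm; smu$sar <- matrix(5, 10, 10)
  expect_identical(compute_thq(smu), 1)
  smz <- sm; smz$sar <- matrix(0, 10, 10)
  expect_error(compute_thq(smz), "zero SAR")
})

test_that("|dTHQ| and |dRD| arithmetic match the defining formulas", {
  expect_equal(compute_dthq(0.8, 0.8), 0)
  expect_equal(compute_dthq(0.76, 0.8), 5.0, tolerance = 1e-12)
  expect_equal(compute_dthq(0.96, 0.8), 20.0, tolerance = 1e-12)
  expect_error(compute_dthq(0.5, 0), "positive")

  m <- matrix(c(120, 1), 1, 2)
  r <- matrix(c(100, 1), 1, 2)
  masks <- list(a = matrix(c(TRUE, FALSE), 1, 2),
                b = matrix(c(FALSE, TRUE), 1, 2))
  dd <- compute_drd(m, r, masks)
  expect_equal(dd$drd_pct[dd$tissue == "a"], 20.0, tolerance = 1e-12)
  expect_equal(dd$drd_pct[dd$tissue == "b"], 0)
  dd0 <- compute_drd(r, r, masks)
  expect_equal(dd0$drd_pct, c(0, 0))
  rz <- matrix(c(0, 1), 1, 2)
  expect_warning(ddz <- compute_drd(m, rz, masks), "undefined")
  expect_true(is.na(ddz$drd_pct[ddz$tissue == "a"]))
})

test_that("boxplot summaries use linear rank interpolation", {
  expect_equal(summarize_boxplot(10),
               c(p2.5 = 10, q1 = 10, median = 10, q3 = 10, p97.5 = 10))
  s <- summarize_boxplot(1:100)
  # type-7 closed form on 1..100: q_p = 1 + p * 99
  expect_equal(unname(s), 1 + c(0.025, 0.25, 0.5, 0.75, 0.975) * 99)
  expect_equal(unname(s["median"]), 50.5)
  expect_error(suppressWarnings(summarize_boxplot(NA_real_)), "no values")
})

test_that("threshold flags follow the 5 percent and 0-20 percent rules", {
  fl <- classify_thresholds(c(4.7, 5.0, 23.8), drd_pct = c(0, 20, 20.1, NA))
  expect_equal(fl$dthq_acceptable, c(TRUE, TRUE, FALSE))
  expect_equal(fl$drd_within_band, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("scheme-dependent conductivity reaches the SAR map", {
  ph <- phantom_slice(generate_phantom(
    small_pelvis_params(tumor_site = "cervix"), seed = 9))
  ur <- which(ph$labels == "urine")
  sr_cli <- phantom_sigma_rho(ph, build_scheme("clinical", phantom_label_set()))
  sr_bla <- phantom_sigma_rho(ph, build_scheme("bladder", phantom_label_set()))
  expect_true(all(sr_cli$sigma[ur] == 0.708))
  expect_true(all(sr_bla$sigma[ur] == 1.750))
  expect_true(all(sr_cli$sigma[is.na(ph$labels)] == 0))
})
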