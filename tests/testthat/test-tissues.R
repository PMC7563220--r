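test_that("default property table carries the published 100 MHz values", {
  tab <- default_tissue_table()
  expect_equal(nrow(tab), 14)
  muscle <- tab[tab$tissue_id == "muscle", ]
  expect_equal(muscle$eps_r, 66.0)
  expect_equal(muscle$sigma_eff, 0.708)
  expect_equal(muscle$rho, 1090)
  urine <- tab[tab$tissue_id == "urine", ]
  expect_equal(urine$eps_r, 49.9)
  expect_equal(urine$sigma_eff, 1.750)
  expect_equal(urine$rho, 1024)
  # large intestine lumen deliberately carries muscle-identical properties
  lil <- tab[tab$tissue_id == "large_intestine_lumen", ]
  expect_equal(unlist(lil[-1]), unlist(muscle[-1]), ignore_attr = TRUE)
  gtv <- tab[tab$tissue_id == "gtv", ]
  expect_equal(c(gtv$eps_r, gtv$sigma_eff, gtv$rho), c(70.0, 0.750, 1050))
})

test_that("property table validation names the offending tissue", {
  write_tab <- function(recs) {
    path <- tempfile(fileext = ".json")
    jsonlite::write_json(recs, path, auto_unbox = TRUE)
    path
  }
  bad_rho <- write_tab(list(list(tissue_id = "muscle", eps_r = 66,
                                 sigma_eff = 0.7, rho = 0)))
  expect_error(load_property_table(bad_rho), "muscle")
  bad_sig <- write_tab(list(list(tissue_id = "fat", eps_r = 12.7,
                                 sigma_eff = -1, rho = 911)))
  expect_error(load_property_table(bad_sig), "fat")
  missing_field <- write_tab(list(list(tissue_id = "fat", eps_r = 12.7,
                                       rho = 911)))
  expect_error(load_property_table(missing_field), "missing")
  expect_error(load_property_table(tempfile()), "not found")
})

test_that("SAT and visceral fat resolve to fat properties", {
  pr <- resolve_properties(c("sat", "visceral_fat", "fat"))
  expect_equal(pr$eps_r, rep(12.7, 3))
  expect_equal(pr$sigma_eff, rep(0.007, 3))
  expect_error(resolve_properties("kidney"), "kidney")
})

test_that("reduction rules follow the segmentation lists", {
  labs <- phantom_label_set()
  cli <- build_scheme("clinical", labs)
  expect_equal(unname(cli$mapping[["urine"]]), "muscle")
  expect_equal(unname(cli$mapping[["bladder_wall"]]), "muscle")
  expect_equal(unname(cli$mapping[["bone_marrow"]]), "bone_cortical")
  expect_equal(unname(cli$mapping[["sat"]]), "fat")
  expect_setequal(retained_labels(cli),
                  c("fat", "muscle", "bone_cortical", "gtv"))

  bla <- build_scheme("bladder", labs)
  expect_equal(unname(bla$mapping[["urine"]]), "urine")
  expect_equal(unname(bla$mapping[["bladder_wall"]]), "bladder_wall")
  expect_equal(unname(bla$mapping[["small_intestine_wall"]]), "muscle")

  det <- build_scheme("detailed", labs)
  expect_equal(det$mapping, stats::setNames(labs, labs))

  expect_error(build_scheme("bogus", labs))
  expect_error(build_scheme("clinical", c(labs, "kidney")), "kidney")
  ext <- build_scheme("clinical", c(labs, "kidney"),
                      extra_classes = c(kidney = "high_water"))
  expect_equal(unname(ext$mapping[["kidney"]]), "muscle")
})

test_that("every scheme is idempotent, GTV-preserving, and within its list", {
  labs <- phantom_label_set()
  allowed <- list(
    detailed = labs,
    clinical = c("fat", "muscle", "bone_cortical", "gtv"),
    bone_type = c("fat", "muscle", "bone_cortical", "gtv", "bone_marrow",
                  "bone_cancellous"),
    bladder = c("fat", "muscle", "bone_cortical", "gtv", "urine",
                "bladder_wall"),
    intestine = c("fat", "muscle", "bone_cortical", "gtv",
                  "small_intestine_wall", "small_intestine_lumen",
                  "large_intestine_wall", "large_intestine_lumen"),
    bladder_and_intestine = c("fat", "muscle", "bone_cortical", "gtv",
                  "urine", "bladder_wall",
                  "small_intestine_wall", "small_intestine_lumen",
                  "large_intestine_wall", "large_intestine_lumen"),
    combined = c("fat", "muscle", "bone_cortical", "gtv", "bone_marrow",
                 "bone_cancellous", "urine", "bladder_wall",
                 "small_intestine_wall", "small_intestine_lumen",
                 "large_intestine_wall", "large_intestine_lumen")
  )
  for (nm in names(allowed)) {
    sc <- build_scheme(nm, labs)
    once <- apply_scheme(labs, sc)
    twice <- apply_scheme(once, sc)
    expect_identical(once, twice, label = paste(nm, "idempotence"))
    expect_true(all(retained_labels(sc) %in% allowed[[nm]]),
                label = paste(nm, "image"))
    expect_equal(unname(sc$mapping[["gtv"]]), "gtv")
    expect_silent(validate_scheme(sc, labs))
  }
})

test_that("combined retained set is the union of bone_type, bladder, intestine", {
  labs <- phantom_label_set()
  u <- union(retained_labels(build_scheme("bone_type", labs)),
             union(retained_labels(build_scheme("bladder", labs)),
                   retained_labels(build_scheme("intestine", labs))))
  expect_setequal(retained_labels(build_scheme("combined", labs)), u)
})

test_that("shipped scheme JSON files match programmatic construction", {
  labs <- phantom_label_set()
  for (nm in c("detailed", "clinical", "bone_type", "bladder", "intestine",
               "bladder_and_intestine", "combined")) {
    shipped <- load_scheme(nm)
    built <- build_scheme(nm, labs)
    expect_equal(shipped$mapping[labs], built$mapping[labs],
                 label = paste("scheme", nm))
  }
  expect_error(load_scheme("nonexistent_scheme"), "unknown")
})

test_that("validate_scheme catches partial mappings and GTV remapping", {
  sc <- build_scheme("clinical", c("muscle", "gtv"))
  expect_error(validate_scheme(sc, phantom_label_set()), "not total")
  bad <- sc
  bad$mapping[["gtv"]] <- "muscle"
  expect_error(validate_scheme(bad, c("muscle", "gtv")), "GTV")
})
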