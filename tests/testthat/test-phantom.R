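# Phantom geometry: preset fidelity, morphing, truncation, invariants.

tab1 <- list(small = c(287, 200, 275), medium = c(369, 275, 305),
             large = c(420, 310, 375), tavi1 = c(383, 271, 421),
             tavi2 = c(361, 286, 357))
tab2 <- list( # lvedd healthy/dcm (mm), wall healthy/hcm (cm)
  small = c(40.0, 55.6, 0.9, 1.7),
  medium = c(39.8, 65.0, 1.0, 1.7),
  large = c(54.7, 73.4, 1.0, 1.9))

test_that("torso presets reproduce the tabulated width/depth/height at 2 mm", {
  for (sz in names(tab1)) {
    ph <- if (sz %in% c("small", "medium", "large")) {
      fx_phantom(sz, "healthy", 2)
    } else {
      build_torso_phantom(torso_params(sz), heart_params(sz), spacing = 2)
    }
    ext <- measure_torso_extent(ph)
    expect_lt(abs(ext[["width"]] - tab1[[sz]][1]), 2 + 1e-9)
    expect_lt(abs(ext[["depth"]] - tab1[[sz]][2]), 2 + 1e-9)
    expect_lt(abs(dim(ph$labels)[3] * ph$spacing - tab1[[sz]][3]), 2 + 1e-9)
  }
})

test_that("healthy heart dimensions match the tabulated values at 2 mm", {
  for (sz in c("small", "medium", "large")) {
    m <- measure_heart_dimensions(fx_phantom(sz, "healthy", 2))
    expect_lt(abs(m$lvedd - tab2[[sz]][1]), 2 + 1e-9)
    expect_lt(abs(m$wall_thickness - tab2[[sz]][3]), 0.2 + 1e-9)
  }
})

test_that("cardiomyopathy morphs hit the tabulated variant targets", {
  # HCM thickens the wall at fixed epicardium
  for (sz in c("small", "large")) {
    ph <- build_torso_phantom(torso_params(sz), heart_params(sz, "hcm"),
                              spacing = 2)
    m <- measure_heart_dimensions(ph)
    expect_lt(abs(m$wall_thickness - tab2[[sz]][4]), 0.2 + 1e-9)
    expect_true(myocardium_connected(ph))
  }
  # DCM dilates the cavity radially
  ph <- build_torso_phantom(torso_params("small"), heart_params("small", "dcm"),
                            spacing = 2)
  m <- measure_heart_dimensions(ph)
  expect_lt(abs(m$lvedd - tab2$small[2]), 2 + 1e-9)
})

test_that("HCM morph only converts LV blood-pool voxels to myocardium", {
  ph0 <- fx_phantom("small", "healthy", 4)
  ph1 <- apply_cardiomyopathy(ph0, heart_params("small", "hcm"), "hcm")
  L <- ph0$label_names
  changed <- which(ph0$labels != ph1$labels)
  expect_gt(length(changed), 0)
  expect_true(all(ph0$labels[changed] == L["lv_blood"]))
  expect_true(all(ph1$labels[changed] == L["myocardium"]))
})

test_that("DCM morph preserves the apicobasal heart extent", {
  ph0 <- fx_phantom("small", "healthy", 4)
  ph1 <- apply_cardiomyopathy(ph0, heart_params("small", "dcm"), "dcm")
  zext <- function(p) {
    range(which(apply(p$labels == p$label_names["myocardium"], 3, any)))
  }
  expect_lte(max(abs(zext(ph1) - zext(ph0))), 1)
})

test_that("morphs with targets equal to current dimensions are identities", {
  ph0 <- fx_phantom("small", "healthy", 4)
  hp <- heart_params("small")
  hp$target_wall_thickness <- hp$wall_thickness
  hp$target_lvedd <- hp$lvedd
  expect_identical(apply_cardiomyopathy(ph0, hp, "hcm")$labels, ph0$labels)
  expect_identical(apply_cardiomyopathy(ph0, hp, "dcm")$labels, ph0$labels)
})

test_that("HCM target beyond the cavity radius is a geometry error", {
  ph0 <- fx_phantom("small", "healthy", 4)
  hp <- heart_params("small")
  hp$target_wall_thickness <- hp$wall_thickness + hp$lvedd  # > cavity radius
  expect_error(apply_cardiomyopathy(ph0, hp, "hcm"), "geometry error")
})

test_that("labels partition the volume and myocardium is one 6-component", {
  ph <- fx_phantom("small", "healthy", 4)
  tab <- table(ph$labels)
  expect_identical(sum(tab), length(ph$labels))
  expect_true(all(as.integer(names(tab)) %in% ph$label_names))
  expect_true(myocardium_connected(ph))
})

test_that("identical parameters give bit-identical label grids", {
  a <- build_torso_phantom(torso_params("small"), heart_params("small"),
                           spacing = 4)
  b <- build_torso_phantom(torso_params("small"), heart_params("small"),
                           spacing = 4)
  expect_identical(a$labels, b$labels)
})

test_that("too-coarse spacing for the LV wall is a resolution error", {
  expect_error(
    build_torso_phantom(torso_params("small"), heart_params("small"),
                        spacing = 10),
    "resolution")
})

test_that("torso truncation is monotone, idempotent at full height, and
           refuses to clip the heart", {
  ph <- fx_phantom("small", "healthy", 4)
  full <- truncate_torso(ph, 1e6)
  expect_identical(full$labels, ph$labels)
  t80 <- truncate_torso(ph, 80)
  t160 <- truncate_torso(ph, 160)
  expect_lte(sum(t80$labels != 0), sum(t160$labels != 0))
  expect_true(myocardium_connected(t80))
  expect_error(truncate_torso(ph, 20), "myocardium")
})

test_that("phantom NIfTI round trip preserves labels and geometry", {
  ph <- fx_phantom("small", "healthy", 4)
  path <- file.path(tempdir(), "ph_test")
  write_phantom_nifti(ph, path)
  ph2 <- read_phantom_nifti(path)
  expect_identical(ph2$labels, ph$labels)
  expect_equal(ph2$spacing, ph$spacing)
  expect_equal(ph2$origin, ph$origin)
})
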