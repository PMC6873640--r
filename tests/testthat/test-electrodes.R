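# Electrode configurations: solid counts, host-tissue containment,
# rasterization fidelity.

test_that("TV-ICD2 has one shocking solid and two grounds (dual vector)", {
  ph <- fx_phantom("medium", "healthy", 4)
  el <- place_electrodes(ph, "tvicd2")
  expect_length(el$shocking, 1L)
  expect_length(el$ground, 2L)
  expect_gt(length(el$shocking_idx), 0)
  expect_length(intersect(el$shocking_idx, el$ground_idx), 0L)
})

test_that("S-ICD coil stays subcutaneous and outside the heart", {
  ph <- fx_phantom("small", "healthy", 4)
  el <- place_electrodes(ph, "sicd")
  L <- ph$label_names
  coil_labs <- ph$labels[el$shocking_idx]
  expect_true(all(coil_labs %in% c(L["fat"], L["muscle"])))
  heart <- c(L["myocardium"], L["lv_blood"], L["rv_blood"])
  expect_false(any(ph$labels[el$shocking_idx] %in% heart))
  # can voxels all inside the torso
  expect_false(any(ph$labels[el$ground_idx] == L["air"]))
})

test_that("TV coils sit in their blood pools", {
  ph <- fx_phantom("medium", "healthy", 4)
  el <- suppressWarnings(place_electrodes(ph, "tvicd2"))
  L <- ph$label_names
  expect_true(all(ph$labels[el$shocking_voxels$rv_coil] == L["rv_blood"]))
  expect_true(all(ph$labels[el$ground_voxels$svc_coil] == L["svc_blood"]))
})

test_that("rasterized coil volume approximates the analytic cylinder", {
  # RV-coil geometry on a fine standalone grid (0.5 mm)
  solid <- list(p0 = c(0, 0, 10), p1 = c(0, 0, 60), radius = 1.5)
  dims <- c(21L, 21L, 161L)
  idx <- rasterize_cylinder(solid, dims, 0.5, c(-5, -5, 0))
  vol <- length(idx) * 0.5^3
  expect_lt(abs(vol / (pi * 1.5^2 * 50) - 1), 0.2)
})

test_that("cylinder rasterization uses the voxel-centre rule", {
  solid <- list(p0 = c(0.9, 0, 0), p1 = c(3.1, 0, 0), radius = 0.4)
  idx <- rasterize_cylinder(solid, c(5L, 3L, 3L), 1, c(0, -1, -1))
  # centres at x = 1, 2, 3 on the axis line only
  expect_identical(sort(idx), sort(which(array(
    outer(outer(1:5 %in% 2:4, (-1:1) == 0, "&"), (-1:1) == 0, "&"),
    c(5, 3, 3)))))
})

test_that("custom electrode sets validate their index sets", {
  expect_error(electrode_set(integer(0), 1L), "non-empty")
  expect_error(electrode_set(1:3, 3:4), "disjoint")
})
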