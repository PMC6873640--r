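# Experiment drivers: determinism, sweeps, correlations, configuration.

test_that("correlation report recovers exact linear relations", {
  tb <- tibble::tibble(dft_energy_J = 1:6, impedance_ohm = 2 * (1:6),
                       eta = -(1:6))
  r <- correlation_report(tb)
  expect_equal(r$r[r$pair == "dft_energy~impedance"], 1)
  expect_equal(r$r[r$pair == "dft_energy~eta"], -1)
  expect_equal(r$r[r$pair == "impedance~eta"], -1)
  expect_error(correlation_report(tb[1:2, ]), "at least 3")
})

test_that("unknown electrode configuration is a configuration error", {
  cfg <- fx_config(4)
  expect_error(run_configuration(cfg, "small", "healthy", "epicardial"),
               "unknown electrode configuration")
})

test_that("a configuration run is deterministic", {
  cfg <- fx_config(4)
  case <- fx_case("small", "healthy", 4)
  a <- run_configuration(cfg, "small", "healthy", "sicd", case = case)
  b <- run_configuration(cfg, "small", "healthy", "sicd", case = case)
  expect_identical(a, b)
  expect_named(a, c("size", "variant", "config", "dft_voltage_V",
                    "dft_energy_J", "impedance_ohm", "eta", "g5_Vpcm",
                    "reference_voltage_V", "capacitance_uF", "spacing_mm",
                    "n_myocardial_voxels"))
})

test_that("analysis-height sweep keeps DFT constant and eta non-increasing", {
  cfg <- fx_config(4)
  tb <- torso_height_sweep(cfg, "small", "healthy", "sicd",
                           mode = "truncate_analysis")
  expect_equal(length(unique(tb$dft_voltage_V)), 1L)
  expect_true(all(diff(tb$power_heart_W) == 0))
  expect_true(all(diff(tb$eta) <= 1e-12))
  expect_true(all(diff(tb$power_torso_W) >= -1e-12))
})

test_that("domain-truncation sweep raises the DFT as the torso grows", {
  cfg <- experiment_config(spacing = 4, half_heights = c(80, 110, 140))
  tb <- torso_height_sweep(cfg, "small", "healthy", "sicd",
                           mode = "truncate_domain")
  expect_true(all(diff(tb$dft_voltage_V) >= -1e-9))
  expect_gt(tb$dft_voltage_V[3], tb$dft_voltage_V[1])
})

test_that("experiment configuration validates and round-trips through YAML", {
  expect_error(experiment_config(sizes = "giant"), "sizes")
  expect_error(experiment_config(half_heights = c(100, 80)), "half_heights")
  cfg <- experiment_config(spacing = 4, sizes = c("small", "medium"),
                           half_heights = c(90, 120))
  path <- file.path(tempdir(), "cohort.yaml")
  yaml::write_yaml(list(sizes = c("small", "medium"), spacing = 4,
                        half_heights = c(90, 120)), path)
  cfg2 <- read_experiment_config(path)
  expect_equal(cfg2$sizes, cfg$sizes)
  expect_equal(cfg2$spacing, cfg$spacing)
  expect_equal(cfg2$half_heights, cfg$half_heights)
})

test_that("cohort output table is complete", {
  tb <- fx_cohort_4mm()
  expect_s3_class(tb, "shock_cohort")
  expect_identical(nrow(tb), 9L)
  expect_false(anyNA(tb))
  expect_true(all(tb$eta > 0 & tb$eta < 1))
})
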