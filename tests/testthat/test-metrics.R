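# Efficacy metrics: gradient fields, DFT arithmetic, impedance, eta.

test_that("gradient magnitude of ramp and constant fields is exact", {
  n <- c(25, 6, 6); h <- 4
  phi <- array(rep((0:24) * h * 0.5, prod(n[2:3])), n)  # 0.5 V/mm = 5 V/cm
  fld <- fx_field(phi, h)
  mask <- array(TRUE, n)
  gm <- gradient_magnitude(fld, mask)
  expect_lt(max(abs(gm - 5)), 1e-9)
  gm0 <- gradient_magnitude(fx_field(array(3, n), h), mask)
  expect_lt(max(gm0), 1e-12)
  expect_error(gradient_magnitude(fld, array(c(TRUE, rep(FALSE, prod(n) - 1)),
                                             n)),
               "at least two voxels")
})

test_that("a point current source decays as 1/r^2 in a homogeneous medium", {
  L <- shockvec_labels()
  n <- c(61L, 61L, 61L); h <- 2
  lab <- array(L[["muscle"]], n)
  ph <- voxel_phantom(lab, spacing = h)
  ctr <- array(FALSE, n); ctr[31, 31, 31] <- TRUE
  shell <- array(FALSE, n)
  shell[1, , ] <- TRUE; shell[n[1], , ] <- TRUE
  shell[, 1, ] <- TRUE; shell[, n[2], ] <- TRUE
  shell[, , 1] <- TRUE; shell[, , n[3]] <- TRUE
  el <- electrode_set(which(ctr), which(shell))
  md <- conductivity_model()
  inj <- inject_current(ph, NULL, md, el, 1)
  co <- ((1:61) - 31) * h
  r <- sqrt(outer(outer(co^2, co^2, "+"), co^2, "+"))
  mask <- r >= 10 & r <= 24   # away from the source and the grounded box
  gm <- gradient_magnitude(inj, mask)
  sigma <- md$organs[["muscle"]]
  exact <- 1 / (4 * pi * sigma * (r[mask] * 1e-3)^2) / 100  # V/cm
  expect_lt(median(abs(gm / exact - 1)), 0.05)
})

test_that("DFT arithmetic follows the 95%/5 V/cm linear-scaling rule", {
  uf <- fx_uniform_field()       # exactly 5 V/cm at 49 V applied
  myo <- array(TRUE, dim(uf$phantom$labels))
  dft <- compute_dft(uf$field, myo)
  expect_equal(dft$g5, 5, tolerance = 1e-6)
  expect_equal(dft$dft_voltage, 49, tolerance = 1e-6)
  # g5 = 0.5 V/cm at 50 V reference -> DFT 500 V
  n <- c(25, 6, 6); h <- 4
  phi <- array(rep((0:24) * h * 0.05, prod(n[2:3])), n)
  dft2 <- compute_dft(fx_field(phi, h), array(TRUE, n), v_ref = 50)
  expect_equal(dft2$dft_voltage, 500, tolerance = 1e-9)
  # constant field: infinite DFT error
  expect_error(compute_dft(fx_field(array(1, n), h), array(TRUE, n),
                           v_ref = 50),
               "infinite DFT")
})

test_that("the g5 percentile brackets 95% of the myocardial volume", {
  sol <- fx_sicd_2mm("small")
  ph <- sol$case$phantom
  myo <- ph$labels == ph$label_names["myocardium"]
  gm <- gradient_magnitude(sol$field, myo)
  g5 <- compute_dft(sol$field, myo)$g5
  frac <- mean(gm > g5)
  expect_gte(frac, 0.95 - 1 / length(gm))
  expect_lte(mean(gm > g5 * 1.001), 0.95 + 1 / length(gm))
})

test_that("capacitor energy is C V^2 / 2", {
  expect_identical(dft_energy(1000, 100), 50)
  expect_identical(dft_energy(0), 0)
  expect_equal(dft_energy(2000) / dft_energy(1000), 4)
  expect_error(dft_energy(-1), "dft_voltage")
})

test_that("impedance requires a current-injection field", {
  uf <- fx_uniform_field()
  expect_error(compute_impedance(uf$field), "current-injection")
})

test_that("eta equals the myocardial volume fraction in a uniform field", {
  L <- shockvec_labels()
  n <- c(400L, 14L, 14L)
  lab <- array(L[["fat"]], n)
  lab[181:220, , ] <- L[["myocardium"]]   # 10% of the bar
  ph <- voxel_phantom(lab, spacing = 1)
  fb <- fx_uniform_fibres(lab, c(0, 1, 0))  # transverse fibres
  md <- conductivity_model(overrides = c(fat = 0.235))  # match sigma_t
  face <- function(i) { m <- array(FALSE, n); m[i, , ] <- TRUE; which(m) }
  el <- electrode_set(face(1), face(n[1]))
  fl <- solve_laplace(ph, fb, md, el, 50)
  eta <- compute_eta(fl, ph, fb, md)
  expect_lt(abs(eta - 0.1), 1e-3)
})

test_that("eta is a ratio of quadratic forms: voltage-scale invariant and
           additive over regions", {
  sol <- fx_sicd_2mm("small")
  ph <- sol$case$phantom; fb <- sol$case$fibres
  md <- conductivity_model()
  e1 <- compute_eta(sol$field, ph, fb, md, details = TRUE)
  scaled <- fx_field(2 * sol$field$phi, sol$field$spacing,
                     electrodes = sol$field$electrodes)
  e2 <- compute_eta(scaled, ph, fb, md, details = TRUE)
  expect_equal(e1$eta, e2$eta, tolerance = 1e-12)
  expect_equal(e2$power_total, 4 * e1$power_total, tolerance = 1e-12)
  # tau_total = tau_myo + tau_non-myo
  dens <- shockvec:::.joule_density(sol$field, ph, fb, md)
  myo <- ph$labels == ph$label_names["myocardium"]
  expect_equal(sum(dens[myo]) + sum(dens[!myo]), e1$power_total,
               tolerance = 1e-12)
})

test_that("truncated-analysis eta reduces to compute_eta at full height and
           never increases with the analysis height", {
  sol <- fx_sicd_2mm("small")
  ph <- sol$case$phantom; fb <- sol$case$fibres
  md <- conductivity_model()
  full <- eta_truncated_analysis(sol$field, ph, fb, md, 1e6)
  expect_equal(full$eta, compute_eta(sol$field, ph, fb, md),
               tolerance = 1e-12)
  hh <- seq(60, 140, by = 20)
  etas <- vapply(hh, function(x)
    eta_truncated_analysis(sol$field, ph, fb, md, x)$eta, numeric(1))
  expect_true(all(diff(etas) <= 1e-12))
  expect_error(eta_truncated_analysis(sol$field, ph, fb, md, 10),
               "cover the heart")
})
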