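# Field solver: operator structure, analytic oracles, boundary conditions,
# passive bidomain behaviour.

test_that("the assembled operator is self-adjoint and conserving", {
  L <- shockvec_labels()
  set.seed(7)
  lab <- array(sample(c(L[["fat"]], L[["myocardium"]], L[["air"]],
                        L[["lung"]]), 6 * 6 * 6, TRUE), c(6, 6, 6))
  ph <- voxel_phantom(lab, spacing = 3)
  mi <- which(lab == L["myocardium"])
  fv <- matrix(rnorm(3 * length(mi)), ncol = 3)
  fv <- fv / sqrt(rowSums(fv^2))
  fb <- structure(list(fibre = fv, myo_idx = mi, dim = dim(lab)),
                  class = "fibre_field")
  op <- assemble_operator(ph, fb, conductivity_model(), "bulk")
  u <- rnorm(216); v <- rnorm(216)
  lhs <- sum(v * apply_operator(op, u))
  rhs <- sum(u * apply_operator(op, v))
  expect_lt(abs(lhs - rhs), 1e-12 * max(abs(lhs), 1))
  # discrete conservation: constants are in the null space
  expect_lt(max(abs(apply_operator(op, rep(1, 216)))), 1e-14)
})

test_that("homogeneous slab impedance matches L/(sigma A) within 1%", {
  bar <- fx_bar()
  md <- conductivity_model()
  inj <- inject_current(bar$phantom, NULL, md, bar$electrodes, 1)
  R <- compute_impedance(inj)
  sigma <- md$organs[["muscle"]]
  R_true <- (bar$length_mm * 1e-3) / (sigma * bar$area_mm2 * 1e-6)
  expect_lt(abs(R / R_true - 1), 0.01)
  # impedance is independent of the injected current
  R2 <- compute_impedance(inject_current(bar$phantom, NULL, md,
                                         bar$electrodes, 0.1))
  expect_equal(R, R2, tolerance = 1e-6)
})

test_that("layered bars match the series-resistance oracle within 1%", {
  L <- shockvec_labels()
  md <- conductivity_model(overrides = c(liver = 0.5, fat = 0.05,
                                         muscle = 0.25))
  n <- c(200L, 2L, 2L); h <- 0.5
  A <- prod(n[2:3]) * h^2 * 1e-6
  face <- function(i) { m <- array(FALSE, n); m[i, , ] <- TRUE; which(m) }
  el <- electrode_set(face(1), face(n[1]))
  # two layers: 50 mm at 0.5 + 50 mm at 0.05 S/m
  lab <- array(L[["liver"]], n); lab[101:200, , ] <- L[["fat"]]
  R2 <- compute_impedance(inject_current(voxel_phantom(lab, h), NULL, md,
                                         el, 1))
  R2_true <- (0.05 / 0.5 + 0.05 / 0.05) / A
  expect_lt(abs(R2 / R2_true - 1), 0.01)
  # three layers
  lab3 <- array(L[["liver"]], n)
  lab3[68:134, , ] <- L[["muscle"]]
  lab3[135:200, , ] <- L[["fat"]]
  R3 <- compute_impedance(inject_current(voxel_phantom(lab3, h), NULL, md,
                                         el, 1))
  R3_true <- (67 * h * 1e-3 / 0.5 + 67 * h * 1e-3 / 0.25 +
              66 * h * 1e-3 / 0.05) / A
  expect_lt(abs(R3 / R3_true - 1), 0.01)
})

test_that("plate electrodes on a homogeneous cube give the uniform field", {
  uf <- fx_uniform_field()   # 49 V over 98 mm -> exactly 5 V/cm
  gm <- gradient_magnitude(uf$field, array(TRUE, dim(uf$phantom$labels)))
  expect_lt(max(abs(gm - 5)), 1e-6)
  # discrete maximum principle
  expect_gte(min(uf$field$phi), 0)
  expect_lte(max(uf$field$phi), 49)
})

test_that("the Dirichlet solve is linear in the applied voltage", {
  uf <- fx_uniform_field()
  fld2 <- solve_laplace(uf$phantom, NULL, conductivity_model(),
                        uf$electrodes, 98)
  expect_lt(max(abs(2 * uf$field$phi - fld2$phi)), 1e-6 * 98)
})

test_that("injected electrode power equals the Joule volume integral", {
  L <- shockvec_labels()
  md <- conductivity_model(overrides = c(liver = 0.5, fat = 0.05))
  n <- c(120L, 4L, 4L)
  lab <- array(L[["liver"]], n); lab[61:120, , ] <- L[["fat"]]
  ph <- voxel_phantom(lab, 1)
  face <- function(i) { m <- array(FALSE, n); m[i, , ] <- TRUE; which(m) }
  el <- electrode_set(face(1), face(n[1]))
  fl <- solve_laplace(ph, NULL, md, el, 50)
  P_in <- injected_power(ph, NULL, md, fl)
  P_dis <- total_dissipation(fl, ph, NULL, md, exclude_electrodes = FALSE)
  expect_lt(abs(P_in - P_dis) / P_in, 0.01)
})

test_that("a driven myocardial slab reproduces the conductivity anisotropy", {
  L <- shockvec_labels()
  md <- conductivity_model()
  lab <- array(L[["myocardium"]], c(60, 30, 30))
  ph <- voxel_phantom(lab, spacing = 1)
  fb <- fx_uniform_fibres(lab, c(1, 0, 0))
  f1 <- function(i, ax) {
    m <- array(FALSE, dim(lab))
    if (ax == 1) m[i, , ] <- TRUE else m[, i, ] <- TRUE
    which(m)
  }
  R_along <- compute_impedance(inject_current(ph, fb, md,
    electrode_set(f1(1, 1), f1(60, 1)), 1))
  R_cross <- compute_impedance(inject_current(ph, fb, md,
    electrode_set(f1(1, 2), f1(30, 2)), 1))
  sig_l <- 0.24 + 0.24; sig_t <- 0.035 + 0.2
  s_along <- (59e-3) / (R_along * 900e-6)
  s_cross <- (29e-3) / (R_cross * 1800e-6)
  expect_lt(abs(s_along / s_cross - sig_l / sig_t) / (sig_l / sig_t), 0.02)
})

test_that("a non-convergent solve reports its residual", {
  uf <- fx_uniform_field()
  expect_error(
    solve_laplace(uf$phantom, NULL, conductivity_model(), uf$electrodes,
                  50, maxit = 2L),
    "did not converge")
})

test_that("zero applied voltage keeps the bidomain at rest", {
  L <- shockvec_labels()
  lab <- array(L[["fat"]], c(12, 8, 8))
  lab[5:8, 4:5, 4:5] <- L[["myocardium"]]
  ph <- voxel_phantom(lab, spacing = 2)
  fb <- fx_uniform_fibres(lab, c(0, 0, 1))
  face <- function(i) { m <- array(FALSE, dim(lab)); m[i, , ] <- TRUE; which(m) }
  el <- electrode_set(face(1), face(12))
  prm <- bidomain_params(shock_duration = 4, dt = 0.5)
  out <- solve_passive_bidomain(ph, fb, conductivity_model(), prm, el, 0)
  expect_lt(max(abs(out$phi)), 1e-12)
  expect_lt(max(abs(out$vm - (-80))), 1e-9)
})

test_that("a space-clamped voxel relaxes with the membrane time constant", {
  # literal I_ion = Vm/Rm: Vm(t) = Vm_rest * exp(-t / (Rm Cm)); the
  # single-voxel intracellular operator is empty, so the exponential
  # integrator is exact
  L <- shockvec_labels()
  lab <- array(L[["fat"]], c(9, 3, 3))
  lab[5, 2, 2] <- L[["myocardium"]]
  ph <- voxel_phantom(lab, spacing = 2)
  fb <- fx_uniform_fibres(lab, c(1, 0, 0))
  face <- function(i) { m <- array(FALSE, dim(lab)); m[i, , ] <- TRUE; which(m) }
  el <- electrode_set(face(1), face(9))
  prm <- bidomain_params(shock_duration = 30, dt = 0.5, iion_form = "literal")
  out <- solve_passive_bidomain(ph, fb, conductivity_model(), prm, el, 10)
  tau_ms <- 9 * 1  # Rm Cm = 9 kOhm cm^2 * 1 uF/cm^2 = 9 ms
  expect_equal(out$vm, -80 * exp(-30 / tau_ms), tolerance = 1e-9)
})

test_that("the bidomain solve approaches steady state by shock-end", {
  L <- shockvec_labels()
  lab <- array(L[["fat"]], c(16, 10, 10))
  lab[6:11, 3:8, 3:8] <- L[["myocardium"]]
  lab[8:9, 5:6, 5:6] <- L[["lv_blood"]]
  ph <- voxel_phantom(lab, spacing = 2)
  fb <- fx_uniform_fibres(lab, c(0, 0, 1))
  face <- function(i) { m <- array(FALSE, dim(lab)); m[i, , ] <- TRUE; which(m) }
  el <- electrode_set(face(1), face(16))
  out <- solve_passive_bidomain(ph, fb, conductivity_model(),
                                bidomain_params(), el, 50)
  expect_lt(out$steady_rel_change, 0.01)
  expect_true(all(is.finite(out$vm)))
})
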