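# Laplace-Dirichlet scalar fields and the rule-based fibre architecture.

test_that("rotation angle interpolates linearly between the surfaces", {
  expect_equal(rotation_angle(0, 60, -60), 60)
  expect_equal(rotation_angle(1, 60, -60), -60)
  expect_equal(rotation_angle(0.5, 60, -60), 0)
  expect_equal(rotation_angle(c(0.25, 0.75), 60, -60), c(30, -30))
  expect_error(rotation_angle(1.2, 60, -60), "\\[0, 1\\]")
  expect_error(rotation_angle(-0.1, 60, -60), "\\[0, 1\\]")
})

test_that("harmonic field on a 1-D bar is the linear ramp k/(N-1)", {
  n <- 21L
  mask <- array(FALSE, c(n, 1, 1))
  mask[, 1, 1] <- TRUE
  f <- solve_laplace_dirichlet(mask, 1L, n)
  expect_equal(as.vector(f[, 1, 1]), (0:(n - 1)) / (n - 1), tolerance = 1e-7)
  expect_identical(f[1, 1, 1], 0)
  expect_identical(f[n, 1, 1], 1)
})

test_that("harmonic field in a spherical shell matches the 1/r solution", {
  n <- 45L
  h <- 1
  ctr <- (n + 1) / 2
  co <- (1:n - ctr) * h
  r <- sqrt(outer(outer(co^2, co^2, "+"), co^2, "+"))
  r_in <- 10; r_out <- 20
  mask <- r >= r_in & r <= r_out
  # boundary sets: shell voxels face-adjacent to the inner/outer complement
  shift <- shockvec:::shift_array
  adj <- function(m, o) {
    a <- array(FALSE, dim(m))
    for (ax in 1:3) a <- a | shift(o, ax, 1) > 0 | shift(o, ax, -1) > 0
    m & a
  }
  inner <- which(adj(mask, r < r_in))
  outer_b <- which(adj(mask, r > r_out))
  f <- solve_laplace_dirichlet(mask, inner, outer_b, spacing = h)
  # closed-form harmonic between the *effective* (voxelized) boundary radii
  ri <- mean(r[inner]); ro <- mean(r[outer_b])
  interior <- which(mask & r > ri + 3 & r < ro - 3)
  exact <- (1 / ri - 1 / r[interior]) / (1 / ri - 1 / ro)
  expect_lt(max(abs(f[interior] - exact)), 0.02)
  expect_lt(mean(abs(f[interior] - exact)), 0.005)
})

test_that("disconnected mask components are reported", {
  mask <- array(FALSE, c(9, 3, 3))
  mask[1:3, 1, 1] <- TRUE
  mask[7:9, 1, 1] <- TRUE   # island touching neither boundary
  expect_error(solve_laplace_dirichlet(mask, 1L, 3L), "disconnected")
})

test_that("fibre field satisfies the frame and angle rules", {
  case <- fx_case("small", "healthy", 4)
  fb <- case$fibres
  # unit vectors
  expect_lt(max(abs(sqrt(rowSums(fb$fibre^2)) - 1)), 1e-6)
  expect_true(all(fb$d >= 0 & fb$d <= 1))
  # orthonormal local frame
  dot <- function(a, b) abs(rowSums(a * b))
  expect_lt(max(dot(fb$t_hat, fb$ab_hat)), 1e-3)
  expect_lt(max(dot(fb$t_hat, fb$c_hat)), 1e-3)
  expect_lt(max(abs(rowSums(fb$c_hat^2) - 1)), 1e-3)
  # wall tangency: fibres orthogonal to the transmural direction (5 deg)
  expect_lt(quantile(dot(fb$fibre, fb$t_hat), 0.95), sin(5 * pi / 180))
})

test_that("helix angles follow the transmural rule on the LV free wall", {
  case <- fx_case("small", "healthy", 4)
  ph <- case$phantom; fb <- case$fibres
  info <- ph$heart_info
  g <- shockvec:::.phantom_grid(ph)
  ai <- arrayInd(fb$myo_idx, dim(ph$labels))
  P <- cbind(g$xs[ai[, 1]], g$ys[ai[, 2]], g$zs[ai[, 3]])
  loc <- shockvec:::.heart_local(P, info)
  # geometric circumferential and long-axis directions (oracle frame)
  e1 <- info$e1; e2 <- info$e2
  u_th <- outer(-sin(loc$theta), e1) + outer(cos(loc$theta), e2)
  up <- matrix(-info$dirn, nrow(P), 3, byrow = TRUE)  # towards the base
  # LV free wall, cylindrical part, away from RV and apex/base
  ang <- abs(atan2(sin(loc$theta - info$theta0), cos(loc$theta - info$theta0)))
  sel <- ang > (info$theta_w + 0.3) & loc$zb > 0.15 * info$L &
    loc$zb < 0.55 * info$L
  helix <- atan2(rowSums(fb$fibre * up), rowSums(fb$fibre * u_th)) * 180 / pi
  helix <- ifelse(helix > 90, helix - 180, ifelse(helix < -90, helix + 180,
                                                  helix))
  # midwall fibres are circumferential within 10 degrees
  mid <- sel & fb$d > 0.4 & fb$d < 0.6
  expect_lt(mean(abs(helix[mid])), 10)
  # endocardial fibres near +60 degrees (tolerance: voxelized surfaces)
  endo <- sel & fb$d < 0.05
  expect_lt(abs(mean(helix[endo]) - 60), 10)
  # regressing helix angle on depth recovers the -120 degree span within 10%
  fit <- lm(helix[sel] ~ fb$d[sel])
  expect_lt(abs(coef(fit)[2] - (-120)) / 120, 0.1)
})

test_that("negating both surface angles mirrors the fibres about the
           circumferential plane", {
  case <- fx_case("small", "healthy", 4)
  ph <- case$phantom
  fb1 <- case$fibres
  fb2 <- build_fibres(ph, alpha_endo = -60, alpha_epi = 60)
  expect_equal(rowSums(fb1$fibre * fb1$c_hat),
               rowSums(fb2$fibre * fb2$c_hat), tolerance = 1e-9)
  expect_equal(rowSums(fb1$fibre * fb1$ab_hat),
               -rowSums(fb2$fibre * fb2$ab_hat), tolerance = 1e-9)
})
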