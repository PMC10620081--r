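# Solver validation against analytic conduction solutions.

test_that("uniform cube between full-face plates gives the analytic field", {
  ph <- make_cube_phantom(n = 12, side_mm = 100, sigma = 0.3)
  tens <- build_conductivity_tensors(ph)
  sol <- solve_electrode_pair(ph, tens, 2L, 3L, applied_voltage = 1,
                              tolerance = 1e-10)
  expect_lte(sol$residual, 1e-10)
  n <- ph$dim[1]
  Emag <- sqrt(sol$E[, , , 1]^2 + sol$E[, , , 2]^2 + sol$E[, , , 3]^2)
  interior <- Emag[2:(n - 1), , ]
  expect_true(all(abs(interior - 10) / 10 < 0.01))  # 1 V / 0.1 m

  # flux integral: I = sigma * E * A = 0.3 * 10 * 0.01 m^2 = 30 mA
  I <- injected_current(sol, tens, 2L, margin = 2L)
  expect_equal(I, 30, tolerance = 0.01)

  # a closed surface enclosing no electrode carries no net current
  inB <- array(FALSE, ph$dim)
  inB[5:8, 5:8, 5:8] <- TRUE
  expect_lt(abs(tistim:::flux_box_mA(sol, tens, inB)), 0.005 * abs(I))

  # swapping the roles flips the sign of the measured current
  I_ca <- injected_current(sol, tens, 3L, margin = 2L)
  expect_equal(I_ca, -I, tolerance = 1e-6)
})

test_that("current normalization rescales fields by the closed-form factor", {
  ph <- make_cube_phantom(n = 10)
  tens <- build_conductivity_tensors(ph)
  sol <- solve_electrode_pair(ph, tens, 2L, 3L, tolerance = 1e-10)
  I0 <- injected_current(sol, tens)
  n1 <- normalize_to_current(sol, 1, tens)
  expect_equal(n1$E, sol$E / I0, tolerance = 1e-9)
  expect_equal(n1$injected_current_mA, 1)
  # normalizing to the measured current is the identity
  nid <- normalize_to_current(sol, I0, tens)
  expect_equal(nid$E, sol$E, tolerance = 1e-12)
  # doubling the target doubles every field value
  n2 <- normalize_to_current(sol, 2, tens)
  expect_equal(n2$E, 2 * n1$E, tolerance = 1e-12)
  expect_equal(n2$phi, 2 * n1$phi, tolerance = 1e-12)
})

test_that("two-layer slab fields honor current-density continuity", {
  ph <- make_two_layer_phantom(n = 16, sigmas = c(0.3, 0.1))
  tens <- build_conductivity_tensors(ph)
  sol <- solve_electrode_pair(ph, tens, 3L, 4L, tolerance = 1e-10)
  n <- ph$dim[1]
  mid <- ph$dim[2] %/% 2
  E_hi <- abs(sol$E[3:(n / 2 - 1), mid, mid, 1])
  E_lo <- abs(sol$E[(n / 2 + 2):(n - 2), mid, mid, 1])
  expect_true(all(abs(mean(E_lo) / mean(E_hi) - 3) / 3 < 0.01))
  # analytic: E_hi = V / (d * (1 + s1/s2)) with d = half thickness
  E_hi_analytic <- 1 / (0.05 * (1 + 3))
  expect_true(all(abs(E_hi - E_hi_analytic) / E_hi_analytic < 0.01))
})

test_that("solutions are linear in the applied voltage and reciprocal", {
  ph <- make_cube_phantom(n = 8)
  tens <- build_conductivity_tensors(ph)
  s1 <- solve_electrode_pair(ph, tens, 2L, 3L, applied_voltage = 1,
                             tolerance = 1e-10)
  s2 <- solve_electrode_pair(ph, tens, 2L, 3L, applied_voltage = 2,
                             tolerance = 1e-10)
  expect_equal(s2$phi, 2 * s1$phi, tolerance = 1e-8)
  sw <- solve_electrode_pair(ph, tens, 3L, 2L, applied_voltage = 1,
                             tolerance = 1e-10)
  expect_equal(sw$phi, -s1$phi, tolerance = 1e-8)
})

test_that("antipodal patches on a homogeneous sphere give an antisymmetric potential", {
  ph <- make_antipodal_sphere(radius = 40, resolution = 4)
  tens <- build_conductivity_tensors(ph)
  sol <- solve_electrode_pair(ph, tens, 11L, 12L, tolerance = 1e-9)
  phi <- sol$phi
  # mirror x -> -x (grid is symmetric about the center plane)
  mir <- phi[rev(seq_len(dim(phi)[1])), , ]
  ok <- !is.na(phi) & !is.na(mir)
  scale <- max(abs(phi), na.rm = TRUE)
  expect_lt(max(abs(phi[ok] + mir[ok])) / scale, 0.02)

  # charge conservation on a mid-domain box enclosing no electrode
  I <- injected_current(sol, tens, 11L)
  inB <- array(FALSE, ph$dim)
  m <- ph$dim %/% 2
  inB[(m[1] - 3):(m[1] + 3), (m[2] - 3):(m[2] + 3), (m[3] - 3):(m[3] + 3)] <- TRUE
  expect_lt(abs(tistim:::flux_box_mA(sol, tens, inB)), 0.005 * abs(I))
})

test_that("slabs stay within 1% of the analytic field at every resolution", {
  # piecewise-linear slab potentials are representable on any grid, so
  # halving the voxel size must not degrade the (already small) error
  err <- sapply(c(8, 16), function(n) {
    ph <- make_two_layer_phantom(n = n, sigmas = c(0.3, 0.1))
    tens <- build_conductivity_tensors(ph)
    sol <- solve_electrode_pair(ph, tens, 3L, 4L, tolerance = 1e-10)
    mid <- n %/% 2
    E_hi <- mean(abs(sol$E[3:(n / 2 - 1), mid, mid, 1]))
    abs(E_hi - 5) / 5  # analytic: 1 V / (0.05 m * (1 + 3)) = 5 V/m
  })
  expect_true(all(err < 0.01))
  expect_lte(err[2], err[1] + 1e-8)
})

test_that("conductance converges monotonically for an oblique anisotropic slab", {
  # constant tensor tilted 45 degrees to the drive: the potential is no
  # longer linear (insulating side walls deflect the current), so the
  # discretization error is real and must shrink under refinement
  G <- sapply(c(8, 16, 32), function(n) {
    ph <- make_cube_phantom(n = n)
    ph <- make_orientation_field(ph, "uniform", vector = c(1, 1, 0) / sqrt(2))
    tens <- build_conductivity_tensors(ph, sigma_long = 0.2, sigma_trans = 0.05,
                                       anisotropic = c("bulk", "anode", "cathode"))
    sol <- solve_electrode_pair(ph, tens, 2L, 3L, tolerance = 1e-10)
    injected_current(sol, tens, 2L) / sol$applied_voltage
  })
  expect_lt(abs(G[3] - G[2]), abs(G[2] - G[1]))
})

test_that("degenerate geometries are rejected", {
  ph <- make_cube_phantom(n = 8)
  # split the cube into two disconnected conducting blocks
  ph$labels[4:5, , ] <- 0L
  tens <- build_conductivity_tensors(ph)
  expect_error(solve_electrode_pair(ph, tens, 2L, 3L), "disconnected")
  ph2 <- make_cube_phantom(n = 8)
  tens2 <- build_conductivity_tensors(ph2)
  expect_error(solve_electrode_pair(ph2, tens2, 9L, 3L), "empty")
})
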