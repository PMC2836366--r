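test_that("homogeneous space develops no interfacial charge", {
  cell <- standard_cell()
  uniform <- dielectric_medium(1.2, 6.4e-10)
  cell$media <- rep(list(uniform), 5)
  cell <- two_shell_cell(cell$media, cell$cell_shell, cell$organelle_shell)
  sol <- solve_harmonic(cell, standard_stimulus())
  expect_lt(abs(sol$coefficients[["D0"]]), 1e-14)
  expect_lt(abs(transmembrane_cell(sol)), 1e-18)
  expect_lt(abs(transmembrane_organelle(sol)), 1e-18)
})

test_that("zero forcing gives a zero right-hand side and a zero solution", {
  cell <- standard_cell()
  st0 <- magnetic_stimulus(0, 1e4)              # B0 = 0 -> E0 = 0
  sys <- assemble_boundary_system(cell, st0$omega, forcing_field(st0))
  expect_true(all(sys$b == 0))
  sol <- solve_harmonic(cell, st0)
  expect_true(all(sol$coefficients == 0))
  # f = 0 short-circuits: no induction, all-zero solution
  sol0 <- solve_harmonic(cell, magnetic_stimulus(2, 0))
  expect_true(all(sol0$coefficients == 0))
  expect_true(amplitude_and_phase(transmembrane_cell(sol0))$no_polarization)
})

test_that("the solution is exactly linear in B0 and in C", {
  cell <- standard_cell()
  base <- solve_harmonic(cell, magnetic_stimulus(2, 1e4, 0.01))
  b2 <- solve_harmonic(cell, magnetic_stimulus(4, 1e4, 0.01))
  c2 <- solve_harmonic(cell, magnetic_stimulus(2, 1e4, 0.02))
  expect_equal(transmembrane_cell(b2), 2 * transmembrane_cell(base),
               tolerance = 1e-14)
  expect_equal(transmembrane_organelle(c2),
               2 * transmembrane_organelle(base), tolerance = 1e-14)
  # nondimensional coefficients are scale-free
  expect_equal(b2$coefficients, base$coefficients, tolerance = 1e-14)
})

test_that("solved coefficients satisfy all eight boundary equations", {
  sol <- std_solution(1e4)
  sys <- assemble_boundary_system(sol$cell, sol$omega, sol$forcing)
  resid <- abs(sys$A %*% sol$coefficients - sys$b)
  scale <- pmax(abs(sys$A) %*% abs(sol$coefficients), abs(sys$b))
  expect_lt(max(resid / scale), 1e-10)
  # and across the frequency band on a coarse grid
  for (f in 10^seq(0, 8, by = 2)) {
    s <- std_solution(f)
    r <- check_residuals(s)
    expect_lt(attr(r, "max_residual"), 1e-9)
  }
})

test_that("the potential is continuous across every interface", {
  sol <- std_solution(1e4)
  xi <- c(sol$cell$cell_shell$outer_radius,
          sol$cell$cell_shell$inner_radius,
          sol$cell$organelle_shell$outer_radius,
          sol$cell$organelle_shell$inner_radius)
  Rp <- xi[1]
  co <- sol$coefficients
  grow <- c(0, co[["C1"]], co[["C2"]], co[["C3"]], co[["C4"]])
  decay <- c(co[["D0"]], co[["D1"]], co[["D2"]], co[["D3"]], 0)
  for (k in 1:4) {
    x <- xi[k] / Rp
    v_out <- sol$scale * (grow[k] * x + decay[k] / x^2)
    v_in <- sol$scale * (grow[k + 1] * x + decay[k + 1] / x^2)
    expect_lt(rel_err(v_out, v_in), 1e-12)
    # potential_at agrees with the region-wise evaluation at the interface
    expect_equal(potential_at(sol, xi[k], pi / 2, 0), v_in,
                 tolerance = 1e-12)
  }
})

test_that("the scattered potential decays as 1/r^2 outside the cell", {
  sol <- std_solution(1e4)
  Rp <- sol$cell$cell_shell$outer_radius
  r <- Rp * seq(2, 10, length.out = 20)
  v <- vapply(r, function(ri) abs(potential_at(sol, ri, pi / 2, 0)),
              numeric(1))
  slope <- coef(lm(log(v) ~ log(r)))[[2]]
  expect_equal(slope, -2, tolerance = 1e-9)
})

test_that("the potential is finite and zero at the origin and at the poles", {
  sol <- std_solution(1e4)
  expect_identical(potential_at(sol, 0, 1, 1), 0 + 0i)
  expect_equal(abs(transmembrane_cell(sol, theta = 0, phi = 0.3)), 0)
  expect_equal(abs(transmembrane_organelle(sol, theta = pi, phi = 2)), 0)
})

test_that("psi follows the sin(theta)cos(phi) angular pattern exactly", {
  sol <- std_solution(5e4)
  set.seed(42)
  theta <- runif(25, 0.05, pi - 0.05)
  phi <- runif(25, 0, 2 * pi)
  phi <- phi[abs(cos(phi)) > 0.05]
  vals <- mapply(function(t, p)
    transmembrane_cell(sol, t, p) / (sin(t) * cos(p)), theta[seq_along(phi)],
    phi)
  expect_lt(max(abs(vals - vals[1])) / abs(vals[1]), 1e-12)
})

test_that("amplitude and phase conversion follows the stated conventions", {
  expect_equal(amplitude_and_phase(1e-3 + 0i),
               list(amplitude_mV = 1, phase_deg = 0, no_polarization = FALSE))
  p <- amplitude_and_phase(complex(real = 0, imaginary = -1e-3))
  expect_equal(p$amplitude_mV, 1)
  expect_equal(p$phase_deg, -90)
  z <- amplitude_and_phase(0 + 0i)
  expect_true(z$no_polarization)
  expect_true(is.na(z$phase_deg))
  # phase lands in (-180, 180]
  expect_equal(amplitude_and_phase(-2e-3 + 0i)$phase_deg, 180)
})

test_that("the cell-membrane phase approaches -90 degrees at low frequency", {
  sol <- std_solution(1)
  expect_equal(lobe(sol, "cell")$phase_deg, -90, tolerance = 1e-2)
})
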