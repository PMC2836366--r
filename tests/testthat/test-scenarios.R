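test_that("a single-frequency response equals a direct solve", {
  cell <- standard_cell(); st <- standard_stimulus()
  sw <- frequency_response(cell, st, frequencies = 1e4)
  direct <- lobe(solve_harmonic(cell, st), "cell")
  expect_equal(sw$cell_amplitude_mV, direct$amplitude_mV)
  expect_equal(sw$cell_phase_deg, direct$phase_deg)
  expect_equal(sw$amplitude_ratio,
               sw$org_amplitude_mV / sw$cell_amplitude_mV)
})

test_that("organelle polarization rises monotonically with frequency", {
  sw <- frequency_response(standard_cell(), standard_stimulus(),
                           log_frequency_grid(2e3, 2e5, 60))
  expect_true(all(diff(sw$org_amplitude_mV) > 0))
  expect_equal(nrow(sw), length(log_frequency_grid(2e3, 2e5, 60)))
  expect_false(anyNA(as.data.frame(sw)))
})

test_that("membrane removal is idempotent and removes the polarization", {
  cell <- standard_cell()
  bare <- remove_cell_membrane(cell)
  expect_identical(remove_cell_membrane(bare), bare)
  expect_identical(bare$media[[2]], cell$media[[1]])
  expect_identical(bare$media[[3]], cell$media[[1]])
  expect_identical(bare$cell_shell, cell$cell_shell)    # geometry untouched
  noorg <- remove_organelle(cell)
  expect_identical(remove_organelle(noorg), noorg)
  # a virtual shell between identical media accumulates no interfacial
  # charge: its harmonic coefficients equal the surrounding medium's, and
  # what remains of psi is just the homogeneous potential drop over the
  # (nanometre) shell thickness
  sol <- solve_harmonic(noorg, standard_stimulus())
  expect_lt(abs(sol$coefficients[["C3"]] - sol$coefficients[["C2"]]) /
              abs(sol$coefficients[["C2"]]), 1e-10)
  expect_lt(abs(sol$coefficients[["D3"]] - sol$coefficients[["D2"]]) /
              max(abs(sol$coefficients)), 1e-10)
  expect_lt(abs(transmembrane_organelle(sol)) /
              abs(transmembrane_cell(sol)), 1e-3)
  sol_bare <- solve_harmonic(bare, standard_stimulus())
  expect_lt(abs(sol_bare$coefficients[["C1"]]) /
              max(abs(sol_bare$coefficients)), 1e-10)
  expect_lt(abs(transmembrane_cell(sol_bare)) /
              abs(transmembrane_organelle(sol_bare)), 1e-3)
})

test_that("removing the cell membrane matches a single-shell solve", {
  # scenario composition: the bare organelle is a one-shell problem whose
  # outer regions are all extracellular medium
  bare <- remove_cell_membrane(standard_cell())
  st <- standard_stimulus()
  ext <- bare$media[[1]]
  single <- two_shell_cell(
    list(ext, ext, ext, bare$media[[4]], bare$media[[5]]),
    cell_shell = shell_geometry(20e-6, 5e-9),   # inert outer shell
    organelle_shell = bare$organelle_shell)
  a <- transmembrane_organelle(solve_harmonic(bare, st))
  b <- transmembrane_organelle(solve_harmonic(single, st))
  expect_lt(rel_err(a, b), 1e-9)
})

test_that("organelle polarization is insensitive to selected membrane parameters", {
  cell <- standard_cell(); st <- standard_stimulus()
  # organelle membrane thickness across its full range
  sw <- parameter_sweep(cell, st, "d", seq(1e-9, 8e-9, length.out = 8),
                        frequencies = 1e4)
  spread <- diff(range(sw$org_amplitude_mV)) / mean(sw$org_amplitude_mV)
  expect_lt(spread, 0.05)
  # cell membrane conductivity across its full range
  sw2 <- parameter_sweep(cell, st, "sigma_1",
                         10^seq(-8, -6, length.out = 9), frequencies = 1e4)
  spread2 <- diff(range(sw2$org_amplitude_mV)) / mean(sw2$org_amplitude_mV)
  expect_lt(spread2, 0.05)
})

test_that("parameter sweeps validate their grid and flag bad geometry", {
  cell <- standard_cell(); st <- standard_stimulus()
  expect_error(parameter_sweep(cell, st, "bogus", 1), "unknown")
  expect_error(parameter_sweep(cell, st, "f", c(1e3, 2e3)), "stimulus")
  expect_error(parameter_sweep(cell, st, "r", numeric(0)))
  # single-point sweep equals a direct solve
  sw <- parameter_sweep(cell, st, "r", 3e-6, frequencies = 1e4)
  expect_equal(sw$org_amplitude_mV,
               lobe(solve_harmonic(cell, st), "organelle")$amplitude_mV)
  # organelle radius beyond the cell membrane is flagged, not dropped
  sw2 <- parameter_sweep(cell, st, "r", c(3e-6, 9e-6, 11e-6),
                         frequencies = 1e4)
  expect_equal(sw2$valid, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(sw2), 3L)
  expect_true(is.na(sw2$org_amplitude_mV[3]))
})

test_that("the phase-transition radius is scale-free and needs a true bracket", {
  cell <- standard_cell()
  r1 <- phase_transition_radius(cell, magnetic_stimulus(2, 1e3))
  r2 <- phase_transition_radius(cell, magnetic_stimulus(4, 1e3))       # 2x B0
  r3 <- phase_transition_radius(cell, magnetic_stimulus(2, 1e3, 0.02)) # 2x C
  expect_equal(r1, r2, tolerance = 1e-6)
  expect_equal(r1, r3, tolerance = 1e-6)
  expect_error(phase_transition_radius(cell, magnetic_stimulus(2, 1e3),
                                       bracket = c(2e-6, 5e-6)),
               "bracket")
})

test_that("surface maps have the correct nodes, symmetry and scaling", {
  sol <- std_solution(1e4)
  m <- surface_map(sol, "cell", n_theta = 19, n_phi = 37)
  expect_equal(nrow(m), 19 * 37)
  poles <- m$polarization_mV[m$theta_deg %in% c(0, 180)]
  expect_true(all(abs(poles) < 1e-12))
  # antisymmetric under phi -> phi + 180
  eq <- m[m$theta_deg == 90, ]
  at <- function(phi) eq$polarization_mV[eq$phi_deg == phi]
  expect_equal(at(0), -at(180), tolerance = 1e-12)
  expect_equal(at(30), -at(210), tolerance = 1e-12)
  # equator extrema at phi = 0 and 180 with opposite signs
  imax <- which.max(abs(eq$polarization_mV))
  expect_true(eq$phi_deg[imax] %in% c(0, 180, 360))
  # a quarter period later the pattern is in quadrature, not equal
  m2 <- surface_map(sol, "cell", n_theta = 19, n_phi = 37,
                    time_phase = pi / 2)
  expect_false(isTRUE(all.equal(m$polarization_mV, m2$polarization_mV)))
  # linear in B0
  sol2 <- solve_harmonic(standard_cell(), magnetic_stimulus(4, 1e4, 0.01))
  m4 <- surface_map(sol2, "cell", n_theta = 19, n_phi = 37)
  expect_equal(m4$polarization_mV, 2 * m$polarization_mV,
               tolerance = 1e-12)
})
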