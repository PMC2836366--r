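# Shared fixtures: everything is built in code at test time.

std_solution <- function(frequency = 1e4) {
  solve_harmonic(standard_cell(),
                 magnetic_stimulus(2, frequency, axis_offset = 0.01))
}

# |a - b| / |b|
rel_err <- function(a, b) abs(a - b) / abs(b)

# Amplitude (mV) and phase (deg) pair of one membrane at the depolarised lobe.
lobe <- function(solution, membrane = c("cell", "organelle")) {
  membrane <- match.arg(membrane)
  psi <- if (membrane == "cell") transmembrane_cell(solution)
         else transmembrane_organelle(solution)
  amplitude_and_phase(psi)
}
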