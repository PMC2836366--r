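# magnetocell

Analytical model of the transmembrane potentials induced on a spherical
cell **and on its internal organelle** by a sinusoidal magnetic field.

Time-varying magnetic fields — as used in transcranial magnetic stimulation
(TMS) — induce electric fields in tissue by Faraday induction. Those fields
polarize the cytoplasmic membrane, and also the membranes of internal
organelles such as mitochondria, whose large negative membrane potential
(about −180 mV) drives ATP synthesis, calcium handling and apoptosis
signalling. `magnetocell` is for biophysicists and stimulation researchers
who want quantitative answers to: *how much* organelle polarization does a
given field produce, how does the cell membrane *shield* the organelle, and
how do both depend on frequency and on the cell's electrical and
geometrical parameters.

## The model

A spherical cell (outer radius $R_+$, membrane thickness $D$) contains a
concentric spherical organelle (outer radius $r_+$, membrane thickness
$d$). The two thin shells split space into five homogeneous regions with
conductivities $\sigma_i$ and permittivities $\varepsilon_i$
($i = 0$ extracellular, 1 cell membrane, 2 cytoplasm, 3 organelle membrane,
4 organelle interior). Under the quasi-static approximation,
$\vec{E} = -j\omega\vec{A} - \nabla V$ with $\nabla^2 V = 0$ in each
region. The coil's vector potential contributes a uniform forcing field of
complex amplitude $E_0 = -j\omega B_0 C/2$ ($C$ = distance from cell centre
to coil axis), exciting only the degree-1 harmonic:

$$V_n(r,\theta,\phi) = \Big(C_n r + \frac{D_n}{r^2}\Big)\sin\theta\cos\phi.$$

Continuity of $V$ and of the normal current density
$S_i(-\partial V/\partial r - j\omega A_r)$, with complex conductivity
$S_i = \sigma_i + j\omega\varepsilon_i$, yields an 8×8 linear system for the
coefficients. The transmembrane potentials are
$\psi_{cell} = V(R_+)-V(R_-)$ and $\psi_{org} = V(r_+)-V(r_-)$, reported as
amplitude (mV) and phase (degrees relative to $B$, $e^{+j\omega t}$
convention, evaluated at the depolarised equator lobe).

An independent transfer-matrix route (`transfer_matrix_solution()`),
boundary-residual diagnostics (`check_residuals()`) and the classical
single-shell Schwan limit (`schwan_limit()`) verify the solver.

## Worked example

```r
library(magnetocell)

sol <- solve_harmonic(standard_cell(), standard_stimulus())
sol
#> <harmonic_solution> f = 10 kHz, |E0| = 628.319 V/m
#>   psi_cell: 9.397 mV at -91.23 deg
#>   psi_org:  0.08019 mV at -5.69 deg
```

At the TMS-relevant 10 kHz, a 2 T field (coil axis 10 mm away) polarizes
the cell membrane by 9.4 mV — but the organelle membrane by only 0.08 mV:
the low-conductivity cell membrane shields the interior. The −91.23° phase
is the Faraday induction lag of −90° plus a small capacitive contribution.
The frequency dependence:

```r
sw <- frequency_response(standard_cell(), standard_stimulus(),
                         frequencies = c(2e3, 1e4, 1e5, 2e5))
as.data.frame(sw)
#>   frequency_Hz cell_amplitude_mV cell_phase_deg org_amplitude_mV org_phase_deg
#> 1        2e+03             1.880         -90.25         0.003388       -19.478
#> 2        1e+04             9.397         -91.23         0.080194        -5.694
#> 3        1e+05            91.828        -102.10         7.788866       -17.435
#> 4        2e+05           172.273        -113.13        28.904196       -33.140
```

Both polarizations grow with frequency (the induced field is proportional
to $\omega$), and the organelle/cell ratio rises from 0.2% to 17% across
2–200 kHz — the shielding weakens as the membranes' capacitive admittance
grows. Removing the cell membrane (`remove_cell_membrane()`) raises the
10 kHz organelle polarization from 0.08 mV to 2.82 mV. Small organelles
respond with a phase *advance* rather than a lag at low frequency; the
regime boundary sits near an organelle radius of 1.1 µm:

```r
phase_transition_radius(standard_cell()) * 1e6
#> [1] 1.112402
```

## Command line

A thin wrapper over the same functions (after install, see
`system.file("cli", "magnetocell", package = "magnetocell")`):

```sh
magnetocell solve --frequency 10                 # single evaluation, JSON
magnetocell freq-sweep --from 2 --to 200 --out fr.csv
magnetocell param-sweep --parameter sigma_1 --out s1.csv
magnetocell transition-radius --frequency 1
magnetocell validate                             # residuals + cross-check
magnetocell fixtures --n 10 --seed 1             # random parameter sets
```

Configuration files (JSON/YAML, see
`inst/extdata/standard_config.json`) use the conventional units: S/m,
As/Vm, µm, nm, tesla, kHz, mm.

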