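---
title: "The two-shell model of magnetically induced organelle polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-shell model of magnetically induced organelle polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetocell)
```

## The physical problem

A sinusoidally alternating magnetic field — the regime relevant to
transcranial magnetic stimulation (TMS), whose ~100 µs pulse rise times
correspond to an effective frequency of about 10 kHz — induces an electric
field in tissue by Faraday induction. On a cell this field superimposes a
transmembrane potential on the resting potential of the cytoplasmic
membrane, and also on the membranes of internal organelles such as
mitochondria, whose −180 mV inner-membrane potential drives much of their
physiology. `magnetocell` computes both induced potentials analytically for
an idealised but fully solvable geometry: a spherical cell of outer radius
$R_+$ with a thin membrane of thickness $D$, containing a concentric
spherical organelle of outer radius $r_+$ with a membrane of thickness $d$.
The two shells partition space into five homogeneous, isotropic regions
(0 extracellular, 1 cell membrane, 2 cytoplasm, 3 organelle membrane,
4 organelle interior), each with conductivity $\sigma_i$ and permittivity
$\varepsilon_i$.

## Model and solution

Under the quasi-static approximation the induced electric field is
$\vec{E} = -j\omega\vec{A} - \nabla V$, with $\vec{A}$ the coil's magnetic
vector potential and $V$ an electric scalar potential satisfying Laplace's
equation in each charge-free homogeneous region. With the coil axis a
distance $C$ from the cell centre, the axisymmetric vector potential splits,
in the cell-centred spherical frame, into a locally rotational part
(proportional to $r$, with no radial component on any sphere — it forces
nothing) and a uniform part whose complex amplitude is

$$E_0 = -\tfrac{j}{2}\,\omega B_0 C, \qquad |E_0| = \tfrac{1}{2}\omega B_0 C,$$

under the $e^{+j\omega t}$ time convention. Only the degree-1, order-1
spherical harmonic $\sin\theta\cos\phi$ is excited, so in region $n$

$$V_n(r,\theta,\phi) = \left(C_n r + \frac{D_n}{r^2}\right)
  \sin\theta\cos\phi .$$

Regularity at the origin and decay of the scattered potential at infinity
remove one coefficient at each end, leaving eight unknowns
$(D_0, C_1, D_1, C_2, D_2, C_3, D_3, C_4)$. They are fixed by continuity of
$V$ and of the normal current density
$S_i\,(-\partial V/\partial r - j\omega A_r)$ at the four interfaces
$R_+, R_-, r_+, r_-$, where $S_i = \sigma_i + j\omega\varepsilon_i$ is the
complex conductivity and $A_r = \tfrac{1}{2}B_0 C \sin\theta\cos\phi$ is
continuous across every interface. The transmembrane potentials are the
potential differences across each thin shell,

$$\psi_{cell} = V(R_+) - V(R_-), \qquad
  \psi_{org} = V(r_+) - V(r_-),$$

both proportional to $\sin\theta\cos\phi$: maximal on the equator, zero at
the poles.

`solve_harmonic()` assembles and solves the 8×8 complex system numerically
rather than transcribing the closed-form coefficient expressions. The
linear solve is exact to machine precision and immune to transcription
error, and an algorithmically independent route —
`transfer_matrix_solution()`, which propagates the continuous pair
$(V, \partial V/\partial r)$ outward across the interfaces and closes the
system with the far-field condition — serves as a cross-check, not a second
copy of the same algebra. The exact two-term $(r, 1/r^2)$ solution is kept
in both membranes; no thin-shell approximation is made.

## Conventions

Three conventions deserve explicit statement because the literature leaves
them implicit:

* **Time convention** $e^{+j\omega t}$, so pure Faraday induction appears
  as a phase of $-90^\circ$ relative to $B$.
* **Reported amplitude and phase.** The summary amplitude is the analytic
  sphere maximum $|\psi| = |$coefficient of $\sin\theta\cos\phi|$, never a
  grid search. The summary phase is the argument of $\psi$ evaluated at the
  *depolarised* equator lobe ($\theta = 90^\circ$, $\phi = 180^\circ$); the
  opposite lobe is $180^\circ$ out of phase, and the azimuthal orientation
  of the lobes is set by which side of the coil axis the cell sits on — a
  pure rotation with no physical content. With this convention the
  low-frequency cell-membrane phase tends to $-90^\circ$.
* **Radii are outer radii.** The quoted cell radius $R$ and organelle
  radius $r$ are interpreted as $R_+$ and $r_+$; inner radii follow by
  subtracting the membrane thickness. For 5 nm membranes on micrometre
  spheres the distinction is numerically negligible, but a single
  convention must be fixed.

## Parameters

`parameter_ranges()` returns the full table: standard values plus
lower/upper physiological limits for the twelve ranged parameters. The
standard set is a 10 µm cell ($D = 5$ nm) with a 3 µm mitochondrion
($d = 5$ nm), membrane conductivities $3\times10^{-7}$ S/m, membrane
permittivities $4.4\times10^{-11}$ As/Vm, cytoplasm/organelle interior
0.3 S/m and $6.4\times10^{-10}$ As/Vm, extracellular 1.2 S/m, under a 2 T
field at 10 kHz.

The coil-axis offset $C$ is not part of that table, and scales every
amplitude linearly ($\psi$ is exactly linear in both $B_0$ and $C$; phases
are independent of both). The package default is $C = 10$ mm, chosen
because the classical single-shell low-frequency limit
$1.5\,|E_0|\,R_+$ then reproduces the reference cell-membrane amplitude at
10 kHz to within 0.3%. It is exposed in every configuration surface and
never hard-coded.

```{r}
sol <- solve_harmonic(standard_cell(), standard_stimulus())
sol
```

## Scenarios

* `frequency_response()` tabulates amplitude, phase, the organelle/cell
  amplitude ratio and the phase difference over a frequency grid
  (log-spaced, 60 points per decade by default — dense enough that the
  smooth response curves are resolved).
* `remove_cell_membrane()` ($S_1 = S_2 = S_0$) and `remove_organelle()`
  ($S_3 = S_4 = S_2$) implement the membrane-removal comparisons that
  expose the shielding effect of the cytoplasmic membrane. Geometry is
  untouched: the removed shell becomes a virtual interface between
  identical media. Its harmonic coefficients then equal the surrounding
  medium's to machine precision, and the residual $\psi$ across it is the
  ordinary homogeneous potential drop over a few nanometres — about three
  orders of magnitude below the membrane potentials, but not exactly zero.
* `parameter_sweep()` varies one tabulated parameter across its range at
  each frequency of a grid, holding everything else fixed. Grid points that
  violate the geometry (an organelle radius reaching the cell membrane) are
  flagged `valid = FALSE`, never silently dropped.
* `phase_transition_radius()` locates the organelle radius separating the
  two low-frequency phase regimes (lag near $-90^\circ$ for large
  organelles, advance near $+90^\circ$ for small ones). The regime
  classifier is the sign of the imaginary part of $\psi_{org}$ at the
  depolarised lobe — the two regimes differ exactly in that sign, and the
  classifier is scale-free, so the result is invariant under changes of
  $B_0$ and $C$. The crossing is refined by bisection to 0.01 µm at a 1 kHz
  probe frequency (well inside the band where the regimes are distinct).
  The source literature does not define the transition operationally; this
  sign criterion is our operationalisation.
* `surface_map()` evaluates the instantaneous polarization
  $\mathrm{Re}[\psi\, e^{j\tau}]$ on a $(\theta,\phi)$ grid for
  visualisation and export.

## Numerical choices

* **Nondimensionalisation.** Radii are scaled by $R_+$ and coefficients by
  $|E_0| R_+$ before assembly; in raw SI units the growing and decaying
  terms differ by ~18 orders of magnitude and the system would be
  numerically singular. After scaling, the standard system's condition
  number is about $10^5$.
* **Refinement.** One step of iterative refinement follows the LU solve;
  on extreme corners of the parameter space (a 0.3 µm organelle in a
  100 µm cell) the plain solve can lose a digit.
* **Transfer-matrix state.** The oracle propagates $(V, dV/dr)$ — both
  continuous, both of the magnitude of the local potential — rather than
  the (growing, decaying) amplitude pair, which suffers catastrophic
  cancellation across high-contrast membranes. Coefficients are
  reconstructed per region afterwards.
* **Residual normalisation.** Each continuity equation's residual is
  divided by the larger of its two sides' magnitudes, floored at
  $10^{-30}$ (SI) so unforced zero problems report zero rather than 0/0.
* **Degenerate inputs.** $f = 0$ (or $B_0 = 0$, $C = 0$) means no
  induction: the all-zero solution is returned without assembling a
  (singular) system, and the phase of an exactly zero $\psi$ is reported
  as a distinguished no-polarization result rather than a number.
* **Conditioning diagnostics.** Assembly warns when the condition estimate
  exceeds $10^{12}$ and errors on singularity; `check_residuals()` reports
  per-interface residuals and the condition estimate.

## The fixture generator

`random_cell()` draws each ranged parameter independently within its
physiological limits — log-uniformly for the membrane and cytoplasm
conductivities, whose ranges span one to three decades, uniformly
otherwise — and rejects draws whose organelle does not fit strictly inside
the cell (possible only at the extreme corner $r \to 5$ µm, $R \to 5$ µm).
Draws are reproducible under a seed and leave the session's RNG state
untouched.

These fixtures emulate *parameter uncertainty* across the physiological
ranges; they do not emulate what real cells add beyond the model's reach:
non-spherical and off-centre organelles, multiple organelles, the
double-membrane structure of a real mitochondrion, spatial decay of the
coil field, anisotropic or inhomogeneous media, or frequency-dependent
(relaxing) dielectrics. Passing the property suite therefore certifies the
solver over the model's parameter space, not the model's fidelity to any
particular cell.

## Known limitations

* Single-frequency (sinusoidal) stimulation only; TMS pulses are treated
  by their effective rise-time frequency, not as time-domain waveforms.
* Permittivities and conductivities are frequency-independent. Dielectric
  relaxation (relevant above hundreds of MHz) would enter as
  $S = \sigma(\omega) + j\omega\varepsilon(\omega)$; the configuration
  surface keeps $\sigma$ and $\varepsilon$ per region so such a hook could
  be added, but it is deliberately not implemented.
* The organelle is a single concentric shell; the inner/outer mitochondrial
  double membrane is out of scope.
* $B_0$ is uniform over the modelled region — an overestimate for tissue
  far from a real coil, making the computed organelle polarizations upper
  bounds in the TMS context.

## Problem sizes used in the test suite

The verification suite solves the 8×8 system a few thousand times: 200
random-fixture cross-checks between the two solution routes, frequency
grids of at most a few hundred points, and a ~9-step bisection for the
transition radius. The full suite runs in a few seconds on one CPU.
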