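#' Uniform induced forcing field
#'
#' The coil's vector potential, transformed to the cell-centred spherical
#' frame, splits into a locally rotational part (proportional to r, with no
#' radial component on any sphere) and a uniform part proportional to the
#' coil-axis offset C. Only the uniform part forces the boundary-value
#' problem; its complex amplitude under the \eqn{e^{+j\omega t}} time
#' convention is \eqn{E_0 = -j\omega B_0 C / 2}, and the radial
#' vector-potential component entering current continuity is
#' \eqn{A_r = (B_0 C / 2)\sin\theta\cos\phi}.
#'
#' @param stimulus A [magnetic_stimulus()].
#' @return An object of class `forcing_field` with fields `E0` (complex,
#'   V/m) and `omega` (rad/s).
#' @export
forcing_field <- function(stimulus) {
  stopifnot(inherits(stimulus, "magnetic_stimulus"))
  w <- stimulus$omega
  structure(list(
    E0 = complex(real = 0, imaginary = -w * stimulus$B0 * stimulus$axis_offset / 2),
    omega = w
  ), class = "forcing_field")
}

# Nondimensional interface radii (divided by the cell outer radius) in the
# order the boundary conditions are applied: R+, R-, r+, r-.
interface_radii <- function(cell) {
  c(cell$cell_shell$outer_radius, cell$cell_shell$inner_radius,
    cell$organelle_shell$outer_radius, cell$organelle_shell$inner_radius) /
    cell$cell_shell$outer_radius
}

# Complex conductivities of the five regions at omega.
region_conductivities <- function(cell, omega) {
  vapply(cell$media, complex_conductivity, complex(1), omega = omega)
}

# Column index of the growing (c_n) / decaying (d_n) coefficient of region n
# (1-based region index) in the 8-vector (D0, C1, D1, C2, D2, C3, D3, C4).
# Region 0 has no growing term (potential vanishes at infinity); region 4 has
# no decaying term (potential finite at the origin).
.col_grow <- c(NA, 2L, 4L, 6L, 8L)
.col_decay <- c(1L, 3L, 5L, 7L, NA)

#' Assemble the eight-equation boundary system
#'
#' Builds the 8x8 complex linear system whose solution is the set of degree-1
#' harmonic coefficients (D0, C1, D1, C2, D2, C3, D3, C4). Odd rows impose
#' continuity of the scalar potential V at the four interfaces (R+, R-, r+,
#' r-); even rows impose continuity of the normal current density
#' \eqn{S_i(-\partial V/\partial r - j\omega A_r)}, with the coil's radial
#' vector potential identical on both sides of each interface. Radii are
#' nondimensionalised by the cell outer radius and coefficients by
#' \eqn{|E_0| R_+}, so the right-hand side carries the unit forcing phase
#' \eqn{E_0/|E_0| = -j}.
#'
#' @param cell A [two_shell_cell()].
#' @param omega Angular frequency, rad/s; >= 0.
#' @param forcing A [forcing_field()].
#' @param cond_warn Condition-number threshold above which a warning is
#'   emitted.
#' @return A list with `A` (8x8 complex matrix), `b` (length-8 complex
#'   right-hand side), `x` (nondimensional interface radii), `S` (five
#'   complex conductivities) and `unit_forcing`.
#' @export
assemble_boundary_system <- function(cell, omega, forcing,
                                     cond_warn = 1e12) {
  stopifnot(inherits(cell, "two_shell_cell"), omega >= 0,
            inherits(forcing, "forcing_field"))
  x <- interface_radii(cell)
  S <- region_conductivities(cell, omega)
  uf <- if (abs(forcing$E0) > 0) forcing$E0 / abs(forcing$E0) else
    complex(real = 0, imaginary = -1)
  A <- matrix(complex(real = 0), 8L, 8L)
  b <- rep(complex(real = 0), 8L)
  for (k in 1:4) {
    n <- k; m <- k + 1L   # inner-facing pair of regions (1-based indices)
    xk <- x[k]
    i <- 2L * k - 1L      # potential continuity
    if (!is.na(.col_grow[n]))  A[i, .col_grow[n]]  <- xk
    if (!is.na(.col_decay[n])) A[i, .col_decay[n]] <- 1 / xk^2
    if (!is.na(.col_grow[m]))  A[i, .col_grow[m]]  <- -xk
    if (!is.na(.col_decay[m])) A[i, .col_decay[m]] <- -1 / xk^2
    i <- 2L * k           # normal current continuity
    if (!is.na(.col_grow[n]))  A[i, .col_grow[n]]  <- -S[n]
    if (!is.na(.col_decay[n])) A[i, .col_decay[n]] <- 2 * S[n] / xk^3
    if (!is.na(.col_grow[m]))  A[i, .col_grow[m]]  <- S[m]
    if (!is.na(.col_decay[m])) A[i, .col_decay[m]] <- -2 * S[m] / xk^3
    b[i] <- (S[m] - S[n]) * uf * (abs(forcing$E0) > 0)
  }
  kap <- tryCatch(kappa(A, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap)) stop("boundary system is singular")
  if (kap > cond_warn)
    warning(sprintf("boundary system is ill-conditioned (kappa ~ %.2e)", kap))
  list(A = A, b = b, x = x, S = S, unit_forcing = uf)
}

new_harmonic_solution <- function(coefficients, forcing, cell, stimulus) {
  structure(list(coefficients = coefficients, forcing = forcing,
                 cell = cell, stimulus = stimulus, omega = stimulus$omega,
                 scale = abs(forcing$E0) * cell$cell_shell$outer_radius),
            class = "harmonic_solution")
}

#' Solve the two-shell boundary-value problem
#'
#' Computes the eight degree-1 harmonic coefficients for a cell under a
#' sinusoidal magnetic stimulus by direct solution of the assembled boundary
#' system. The solution is linear in both B0 and the coil-axis offset C. At
#' zero frequency there is no induction and the all-zero solution is
#' returned without assembling the system.
#'
#' @param cell A [two_shell_cell()].
#' @param stimulus A [magnetic_stimulus()].
#' @return An object of class `harmonic_solution`: nondimensional
#'   `coefficients` named D0, C1, D1, C2, D2, C3, D3, C4 (scaled by
#'   \eqn{|E_0| R_+}), plus the `forcing`, `cell`, `omega` and the
#'   dimensional `scale` in volts.
#' @export
#' @examples
#' sol <- solve_harmonic(standard_cell(), standard_stimulus())
#' amplitude_and_phase(transmembrane_cell(sol))
solve_harmonic <- function(cell, stimulus) {
  stopifnot(inherits(cell, "two_shell_cell"),
            inherits(stimulus, "magnetic_stimulus"))
  forcing <- forcing_field(stimulus)
  zero <- stats::setNames(rep(complex(real = 0), 8L),
                          c("D0", "C1", "D1", "C2", "D2", "C3", "D3", "C4"))
  if (stimulus$frequency == 0 || abs(forcing$E0) == 0)
    return(new_harmonic_solution(zero, forcing, cell, stimulus))
  sys <- assemble_boundary_system(cell, stimulus$omega, forcing)
  u <- tryCatch(solve(sys$A, sys$b),
                error = function(e) stop("boundary system solve failed: ",
                                         conditionMessage(e)))
  # one step of iterative refinement: with radii spanning two decades the LU
  # solve can lose a digit or two on extreme parameter sets
  u <- u + solve(sys$A, sys$b - sys$A %*% u)
  new_harmonic_solution(stats::setNames(drop(u), names(zero)), forcing, cell,
                        stimulus)
}

#' @export
print.harmonic_solution <- function(x, ...) {
  cat(sprintf("<harmonic_solution> f = %g kHz, |E0| = %g V/m\n",
              x$omega / (2 * pi) / 1e3, abs(x$forcing$E0)))
  cs <- amplitude_and_phase(transmembrane_cell(x))
  os <- amplitude_and_phase(transmembrane_organelle(x))
  cat(sprintf("  psi_cell: %.4g mV at %.2f deg\n", cs$amplitude_mV, cs$phase_deg))
  cat(sprintf("  psi_org:  %.4g mV at %.2f deg\n", os$amplitude_mV, os$phase_deg))
  invisible(x)
}

# Nondimensional (growing, decaying) pair for region n in 0..4.
region_pair <- function(solution, region) {
  g <- .col_grow[region + 1L]; d <- .col_decay[region + 1L]
  c(if (is.na(g)) complex(real = 0) else solution$coefficients[[g]],
    if (is.na(d)) complex(real = 0) else solution$coefficients[[d]])
}

#' Evaluate the scalar potential
#'
#' Evaluates the induced electric scalar potential
#' \eqn{V(r,\theta,\phi) = (C_n r + D_n / r^2)\sin\theta\cos\phi} in the
#' region containing `r`. V is continuous across every interface.
#'
#' @param solution A `harmonic_solution`.
#' @param r Radius, metres; >= 0.
#' @param theta Polar angle, radians.
#' @param phi Azimuthal angle, radians.
#' @return Complex potential in volts.
#' @export
potential_at <- function(solution, r, theta, phi) {
  stopifnot(inherits(solution, "harmonic_solution"), r >= 0)
  if (r == 0) return(complex(real = 0))
  Rp <- solution$cell$cell_shell$outer_radius
  xi <- interface_radii(solution$cell)     # R+, R-, r+, r- (nondim)
  xr <- r / Rp
  region <- findInterval(-xr, -xi)         # 0 outside R+, ..., 4 inside r-
  p <- region_pair(solution, region)
  solution$scale * (p[1] * xr + p[2] / xr^2) * sin(theta) * cos(phi)
}

# Complex factor (volts) multiplying sin(theta)cos(phi) in the
# transmembrane potential of one membrane (1 = cell, 3 = organelle).
tm_coefficient <- function(solution, membrane_region) {
  xi <- interface_radii(solution$cell)
  k <- if (membrane_region == 1L) 1:2 else 3:4
  p <- region_pair(solution, membrane_region)
  solution$scale *
    (p[1] * (xi[k[1]] - xi[k[2]]) + p[2] * (1 / xi[k[1]]^2 - 1 / xi[k[2]]^2))
}

#' Transmembrane potentials
#'
#' The complex transmembrane potential of a membrane is the scalar potential
#' at its outer surface minus that at its inner surface,
#' \eqn{\psi(\theta,\phi) = [V(outer) - V(inner)]}, and is proportional to
#' \eqn{\sin\theta\cos\phi}. The default evaluation point
#' (\eqn{\theta = 90^\circ}, \eqn{\phi = 180^\circ}) is the depolarised
#' equator lobe, where \eqn{|\psi|} attains its maximum over the sphere and
#' whose phase relative to the applied field B is the conventional summary
#' phase (about \eqn{-90^\circ} at low frequency, reflecting Faraday
#' induction).
#'
#' @param solution A `harmonic_solution`.
#' @param theta Polar angle, radians.
#' @param phi Azimuthal angle, radians.
#' @return Complex transmembrane potential in volts.
#' @export
transmembrane_cell <- function(solution, theta = pi / 2, phi = pi) {
  stopifnot(inherits(solution, "harmonic_solution"))
  tm_coefficient(solution, 1L) * sin(theta) * cos(phi)
}

#' @rdname transmembrane_cell
#' @export
transmembrane_organelle <- function(solution, theta = pi / 2, phi = pi) {
  stopifnot(inherits(solution, "harmonic_solution"))
  tm_coefficient(solution, 3L) * sin(theta) * cos(phi)
}

#' Maximum transmembrane amplitude over the sphere
#'
#' \eqn{\max_{\theta,\phi} |\psi|}, i.e. the magnitude of the complex factor
#' multiplying \eqn{\sin\theta\cos\phi} — computed analytically, never by
#' grid search.
#'
#' @param solution A `harmonic_solution`.
#' @param membrane `"cell"` or `"organelle"`.
#' @return Amplitude in volts.
#' @export
max_transmembrane <- function(solution, membrane = c("cell", "organelle")) {
  membrane <- match.arg(membrane)
  abs(tm_coefficient(solution, if (membrane == "cell") 1L else 3L))
}

#' Amplitude and phase of a complex polarization
#'
#' Converts a complex transmembrane potential to presentation units:
#' magnitude in mV and phase in degrees in (-180, 180], measured relative to
#' the applied magnetic field under the \eqn{e^{+j\omega t}} convention. An
#' exactly zero input has no defined phase and is returned as a distinguished
#' no-polarization result (`phase_deg = NA`, `no_polarization = TRUE`).
#'
#' @param psi Complex scalar, volts.
#' @return List with `amplitude_mV`, `phase_deg`, `no_polarization`.
#' @export
amplitude_and_phase <- function(psi) {
  stopifnot(is.complex(psi) || is.numeric(psi), length(psi) == 1L)
  psi <- as.complex(psi)
  if (abs(psi) == 0)
    return(list(amplitude_mV = 0, phase_deg = NA_real_, no_polarization = TRUE))
  list(amplitude_mV = abs(psi) * 1e3,
       phase_deg = Arg(psi) * 180 / pi,
       no_polarization = FALSE)
}

# One-row summary of both membranes at the depolarised lobe; used by the
# sweep scenarios and the CLI.
membrane_summary <- function(solution) {
  cs <- amplitude_and_phase(transmembrane_cell(solution))
  os <- amplitude_and_phase(transmembrane_organelle(solution))
  data.frame(cell_amplitude_mV = cs$amplitude_mV,
             cell_phase_deg = cs$phase_deg,
             org_amplitude_mV = os$amplitude_mV,
             org_phase_deg = os$phase_deg)
}
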