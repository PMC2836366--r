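#' Homogeneous dielectric medium
#'
#' A homogeneous, isotropic medium characterised by its (real, d.c.)
#' conductivity and dielectric permittivity. In the frequency domain the two
#' combine into the complex conductivity \eqn{S = \sigma + j\omega\epsilon},
#' which is what enters the current-continuity boundary conditions.
#'
#' @param conductivity Conductivity \eqn{\sigma} in S/m; must be >= 0.
#' @param permittivity Absolute permittivity \eqn{\epsilon} in F/m (As/Vm);
#'   must be > 0, except that the degenerate zero medium
#'   (conductivity 0, permittivity 0) is allowed as a boundary case.
#' @return An object of class `dielectric_medium`.
#' @seealso [complex_conductivity()]
#' @export
#' @examples
#' saline <- dielectric_medium(1.2, 6.4e-10)
#' complex_conductivity(saline, 2 * pi * 1e4)
dielectric_medium <- function(conductivity, permittivity) {
  stopifnot(is.numeric(conductivity), length(conductivity) == 1L,
            is.numeric(permittivity), length(permittivity) == 1L)
  if (!is.finite(conductivity) || conductivity < 0)
    stop("'conductivity' must be finite and >= 0 (got ", conductivity, ")")
  zero_medium <- conductivity == 0 && permittivity == 0
  if (!zero_medium && (!is.finite(permittivity) || permittivity <= 0))
    stop("'permittivity' must be finite and > 0 (got ", permittivity, ")")
  structure(list(conductivity = conductivity, permittivity = permittivity),
            class = "dielectric_medium")
}

#' @export
print.dielectric_medium <- function(x, ...) {
  cat(sprintf("<dielectric_medium> sigma = %g S/m, epsilon = %g F/m\n",
              x$conductivity, x$permittivity))
  invisible(x)
}

#' Complex conductivity of a medium
#'
#' Returns \eqn{S = \sigma + j\omega\epsilon}: the frequency-domain
#' admittivity combining ohmic conduction and dielectric displacement.
#'
#' @param medium A [dielectric_medium()].
#' @param omega Angular frequency in rad/s; must be >= 0.
#' @return A complex scalar, S/m.
#' @export
complex_conductivity <- function(medium, omega) {
  stopifnot(inherits(medium, "dielectric_medium"),
            is.numeric(omega), length(omega) == 1L, omega >= 0)
  complex(real = medium$conductivity, imaginary = omega * medium$permittivity)
}

#' Thin spherical shell geometry
#'
#' A membrane shell described by its outer radius and thickness; the inner
#' radius is derived as `outer_radius - thickness`.
#'
#' @param outer_radius Outer radius in metres; > 0.
#' @param thickness Shell thickness in metres; 0 < thickness < outer_radius.
#' @return An object of class `shell_geometry` with fields `outer_radius`,
#'   `thickness`, `inner_radius`.
#' @export
shell_geometry <- function(outer_radius, thickness) {
  stopifnot(is.numeric(outer_radius), length(outer_radius) == 1L,
            is.numeric(thickness), length(thickness) == 1L)
  if (!is.finite(outer_radius) || outer_radius <= 0)
    stop("'outer_radius' must be finite and > 0 (got ", outer_radius, ")")
  if (!is.finite(thickness) || thickness <= 0 || thickness >= outer_radius)
    stop("'thickness' must satisfy 0 < thickness < outer_radius (got ",
         thickness, " for outer radius ", outer_radius, ")")
  structure(list(outer_radius = outer_radius, thickness = thickness,
                 inner_radius = outer_radius - thickness),
            class = "shell_geometry")
}

#' @export
print.shell_geometry <- function(x, ...) {
  cat(sprintf("<shell_geometry> outer %g um, thickness %g nm\n",
              x$outer_radius * 1e6, x$thickness * 1e9))
  invisible(x)
}
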