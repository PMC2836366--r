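#' Transfer-matrix solution (independent verification route)
#'
#' Recomputes the degree-1 harmonic coefficients by a route algorithmically
#' independent of the direct 8x8 solve: starting from the innermost region
#' (growing term only, amplitude unknown), the (growing, decaying) pair is
#' propagated outward across each interface with the 2x2 affine continuity
#' map implied by potential and normal-current continuity, and the unknown
#' inner amplitude is then fixed by the far-field condition that the
#' scattered potential carries no growing term in the extracellular region.
#'
#' @param cell A [two_shell_cell()].
#' @param stimulus A [magnetic_stimulus()].
#' @return A `harmonic_solution`, directly comparable with
#'   [solve_harmonic()].
#' @export
transfer_matrix_solution <- function(cell, stimulus) {
  stopifnot(inherits(cell, "two_shell_cell"),
            inherits(stimulus, "magnetic_stimulus"))
  forcing <- forcing_field(stimulus)
  nm <- c("D0", "C1", "D1", "C2", "D2", "C3", "D3", "C4")
  if (stimulus$frequency == 0 || abs(forcing$E0) == 0)
    return(new_harmonic_solution(
      stats::setNames(rep(complex(real = 0), 8L), nm),
      forcing, cell, stimulus))
  S <- region_conductivities(cell, stimulus$omega)
  x <- rev(interface_radii(cell))            # r-, r+, R-, R+ (nondim, outward)
  uf <- forcing$E0 / abs(forcing$E0)

  # The propagated state is the continuous physical pair (V, W = dV/dx),
  # carried outward as an affine function of the unknown innermost growing
  # amplitude a: state = lin * a + off. Crossing an interface leaves V
  # untouched and jumps W through the current-continuity condition
  # S_in (uf - W_in) = S_out (uf - W_out); traversing a region maps the pair
  # through the region's (r, 1/r^2) solution using coefficients normalised
  # to the region's own boundary radii, which keeps every intermediate at
  # the magnitude of the local potential even when the radii span decades.
  lin <- c(1, 1 / x[1]) + 0i                 # region 4: V = a * (y / r-)
  off <- c(0, 0) + 0i
  states <- vector("list", 4L)               # state at inner radius of
                                             # regions 3, 2, 1, 0
  for (k in 1:4) {                           # cross r-, r+, R-, R+
    region_in <- 6L - k                      # 1-based: regions 4,3,2,1
    ratio <- S[region_in] / S[region_in - 1L]
    lin[2] <- ratio * lin[2]
    off[2] <- ratio * off[2] + (1 - ratio) * uf
    states[[k]] <- list(lin = lin, off = off, x = x[k])
    if (k < 4L) {                            # traverse to the next interface
      traverse <- function(st) {
        alpha <- x[k] / x[k + 1L]
        d <- (st[1] - st[2] * x[k]) / 3
        cc <- (st[1] - d) / alpha
        c(cc + d * alpha^2, (cc - 2 * d * alpha^2) / x[k + 1L])
      }
      lin <- traverse(lin); off <- traverse(off)
    }
  }
  # far field: the growing part of the region-0 potential, (2V + W x)/(3x),
  # must vanish
  denom <- 2 * lin[1] + lin[2] * x[4]
  if (abs(denom) == 0) stop("transfer-matrix system is singular")
  a <- -(2 * off[1] + off[2] * x[4]) / denom
  # reconstruct the standard-convention (growing, decaying) pair of each
  # region from its stored state: c = (2V + Wx)/(3x), d = x^2 (V - Wx)/3
  pair_at <- function(st) {
    V <- st$lin[1] * a + st$off[1]
    W <- st$lin[2] * a + st$off[2]
    c((2 * V + W * st$x) / (3 * st$x), st$x^2 * (V - W * st$x) / 3)
  }
  p3 <- pair_at(states[[1]]); p2 <- pair_at(states[[2]])
  p1 <- pair_at(states[[3]]); p0 <- pair_at(states[[4]])
  u <- c(p0[2],                              # D0
         p1[1], p1[2], p2[1], p2[2], p3[1], p3[2],
         a / x[1])                           # C4: V = a y / r-
  new_harmonic_solution(stats::setNames(u, nm), forcing, cell, stimulus)
}

#' Boundary-residual diagnostics
#'
#' Substitutes a solution back into the eight continuity equations —
#' potential and normal current density at each of the four interfaces —
#' evaluated from first principles (not via the assembled matrix). Each
#' residual is normalised by the larger magnitude of the equation's two
#' sides, with an absolute floor of 1e-30 in SI units to avoid division by
#' zero for unforced problems.
#'
#' @param solution A `harmonic_solution`.
#' @return An object of class `residual_report`: data.frame of per-interface
#'   relative residuals with attributes `max_residual` and
#'   `condition_estimate`.
#' @export
check_residuals <- function(solution) {
  stopifnot(inherits(solution, "harmonic_solution"))
  cell <- solution$cell
  x <- interface_radii(cell)                 # R+, R-, r+, r-
  S <- region_conductivities(cell, solution$omega)
  E0a <- abs(solution$forcing$E0)
  uf <- if (E0a > 0) solution$forcing$E0 / E0a else complex(real = 0)
  scale <- solution$scale
  floor_si <- 1e-30
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), floor_si)
  pot <- cur <- numeric(4L)
  for (k in 1:4) {
    po <- region_pair(solution, k - 1L)      # outer region of interface k
    pi_ <- region_pair(solution, k)          # inner region
    V_out <- scale * (po[1] * x[k] + po[2] / x[k]^2)
    V_in  <- scale * (pi_[1] * x[k] + pi_[2] / x[k]^2)
    J_out <- S[k]      * E0a * (-po[1] + 2 * po[2] / x[k]^3 + uf)
    J_in  <- S[k + 1L] * E0a * (-pi_[1] + 2 * pi_[2] / x[k]^3 + uf)
    pot[k] <- rel(V_out, V_in)
    cur[k] <- rel(J_out, J_in)
  }
  cond <- if (E0a > 0 && solution$omega > 0) {
    sys <- assemble_boundary_system(cell, solution$omega, solution$forcing,
                                    cond_warn = Inf)
    kappa(sys$A, exact = TRUE)
  } else NA_real_
  structure(
    data.frame(interface = c("R+", "R-", "r+", "r-"),
               potential_residual = pot, current_residual = cur),
    class = c("residual_report", "data.frame"),
    max_residual = max(pot, cur),
    condition_estimate = cond)
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("<residual_report> max residual %.3e, condition estimate %.3e\n",
              attr(x, "max_residual"), attr(x, "condition_estimate")))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' First-order shelled-sphere (Schwan) limit
#'
#' Closed-form low-frequency approximation for the maximal transmembrane
#' potential of a single shelled sphere in the induced field:
#' \eqn{|\psi| \approx 1.5\,|E_0|\,R_+} with phase
#' \eqn{-90^\circ - \arctan(\omega\tau)}, where
#' \eqn{\tau = R_+ (\epsilon_1/D)(1/\sigma_2 + 1/(2\sigma_0))} is the
#' membrane charging time constant (membrane capacitance per unit area fed
#' by the cytoplasmic and extracellular access resistivities). The -90
#' degrees is the Faraday induction lag. Intended as an asymptotic check of
#' the full solver on an organelle-free cell with a thin, low-conductivity
#' membrane; not a substitute for it.
#'
#' @param cell A [two_shell_cell()]; the organelle regions are ignored
#'   (apply [remove_organelle()] before comparing against the full solver).
#' @param stimulus A [magnetic_stimulus()].
#' @return Complex transmembrane potential (volts) at the depolarised lobe.
#' @export
schwan_limit <- function(cell, stimulus) {
  stopifnot(inherits(cell, "two_shell_cell"),
            inherits(stimulus, "magnetic_stimulus"))
  w <- stimulus$omega
  E0a <- w * stimulus$B0 * stimulus$axis_offset / 2
  Rp <- cell$cell_shell$outer_radius
  cm <- cell$media[[2]]$permittivity / cell$cell_shell$thickness
  tau <- Rp * cm * (1 / cell$media[[3]]$conductivity +
                      1 / (2 * cell$media[[1]]$conductivity))
  phase <- -pi / 2 - atan(w * tau)
  1.5 * E0a * Rp * exp(1i * phase)
}

#' Membrane charging time constant
#'
#' @param cell A [two_shell_cell()].
#' @return Time constant in seconds (see [schwan_limit()]).
#' @export
membrane_time_constant <- function(cell) {
  stopifnot(inherits(cell, "two_shell_cell"))
  cell$cell_shell$outer_radius *
    (cell$media[[2]]$permittivity / cell$cell_shell$thickness) *
    (1 / cell$media[[3]]$conductivity + 1 / (2 * cell$media[[1]]$conductivity))
}
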