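#' Full parameter set of a model configuration
#'
#' Flattens a cell + stimulus pair into the named SI-unit parameter vector
#' (sigma_0..sigma_4, epsilon_0..epsilon_4, R, D, r, d, B0, f, C). Used for
#' provenance metadata on sweep outputs and for configuration round-trips.
#'
#' @param cell A [two_shell_cell()].
#' @param stimulus A [magnetic_stimulus()].
#' @return Named numeric vector, SI units.
#' @export
model_parameters <- function(cell, stimulus) {
  sig <- vapply(cell$media, `[[`, numeric(1), "conductivity")
  eps <- vapply(cell$media, `[[`, numeric(1), "permittivity")
  c(stats::setNames(sig, paste0("sigma_", 0:4)),
    stats::setNames(eps, paste0("epsilon_", 0:4)),
    R = cell$cell_shell$outer_radius, D = cell$cell_shell$thickness,
    r = cell$organelle_shell$outer_radius, d = cell$organelle_shell$thickness,
    B0 = stimulus$B0, f = stimulus$frequency, C = stimulus$axis_offset)
}

new_sweep_result <- function(df, scenario, parameters, axes) {
  structure(df, class = c("sweep_result", "data.frame"),
            scenario = scenario, parameters = parameters, axes = axes,
            version = as.character(utils::packageVersion("magnetocell")))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> scenario '%s', %d grid points over %s\n",
              attr(x, "scenario"), nrow(x),
              paste(attr(x, "axes"), collapse = " x ")))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Logarithmic frequency grid
#'
#' @param from,to Grid limits in Hz; both > 0.
#' @param points_per_decade Grid density (default 60).
#' @return Strictly increasing numeric vector of frequencies in Hz,
#'   including both endpoints.
#' @export
log_frequency_grid <- function(from, to, points_per_decade = 60) {
  stopifnot(from > 0, to > from)
  n <- max(2L, ceiling(log10(to / from) * points_per_decade) + 1L)
  10^seq(log10(from), log10(to), length.out = n)
}

#' Frequency response of both membranes
#'
#' Solves the model at each frequency of a grid and tabulates the maximal
#' amplitude (mV) and the phase (degrees, at the depolarised equator lobe)
#' of the cell- and organelle-membrane transmembrane potentials, plus the
#' organelle/cell amplitude ratio and the phase difference.
#'
#' @param cell A [two_shell_cell()].
#' @param stimulus A [magnetic_stimulus()] supplying B0 and the coil-axis
#'   offset; its own frequency is ignored in favour of the grid.
#' @param frequencies Strictly increasing vector of frequencies in Hz, all
#'   > 0.
#' @return A `sweep_result` data.frame with columns `frequency_Hz`,
#'   `cell_amplitude_mV`, `cell_phase_deg`, `org_amplitude_mV`,
#'   `org_phase_deg`, `amplitude_ratio`, `phase_difference_deg`.
#' @export
frequency_response <- function(cell, stimulus,
                               frequencies = log_frequency_grid(2e3, 2e5)) {
  stopifnot(length(frequencies) >= 1L, all(frequencies > 0),
            !is.unsorted(frequencies, strictly = TRUE))
  rows <- lapply(frequencies, function(f) {
    st <- magnetic_stimulus(stimulus$B0, f, stimulus$axis_offset)
    membrane_summary(solve_harmonic(cell, st))
  })
  df <- do.call(rbind, rows)
  df <- cbind(frequency_Hz = frequencies, df)
  df$amplitude_ratio <- df$org_amplitude_mV / df$cell_amplitude_mV
  df$phase_difference_deg <- wrap_degrees(df$org_phase_deg - df$cell_phase_deg)
  new_sweep_result(df, "frequency_response",
                   model_parameters(cell, stimulus), "frequency_Hz")
}

# Map degrees to (-180, 180].
wrap_degrees <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

#' Membrane-removal scenarios
#'
#' `remove_cell_membrane()` replaces the media of the cell membrane and the
#' cytoplasm (regions 1 and 2) with the extracellular medium, exposing the
#' organelle "bare" to the induced field; `remove_organelle()` replaces the
#' organelle membrane and interior (regions 3 and 4) with the cytoplasm
#' medium. Geometry is untouched, so the removed shell becomes a virtual
#' interface between identical media and carries no transmembrane potential.
#' Both operations are idempotent.
#'
#' @param cell A [two_shell_cell()].
#' @return A new [two_shell_cell()].
#' @export
remove_cell_membrane <- function(cell) {
  stopifnot(inherits(cell, "two_shell_cell"))
  cell$media[[2]] <- cell$media[[1]]
  cell$media[[3]] <- cell$media[[1]]
  two_shell_cell(cell$media, cell$cell_shell, cell$organelle_shell)
}

#' @rdname remove_cell_membrane
#' @export
remove_organelle <- function(cell) {
  stopifnot(inherits(cell, "two_shell_cell"))
  cell$media[[4]] <- cell$media[[3]]
  cell$media[[5]] <- cell$media[[3]]
  two_shell_cell(cell$media, cell$cell_shell, cell$organelle_shell)
}

#' Two-dimensional parameter-by-frequency sweep
#'
#' Varies one model parameter across a grid of values while all others stay
#' at the supplied cell's values, solving at every (value, frequency) pair.
#' Grid points whose parameter value violates the geometry invariants (e.g.
#' an organelle radius reaching the cell membrane) are flagged
#' `valid = FALSE` with NA responses rather than dropped.
#'
#' @param cell Base [two_shell_cell()].
#' @param stimulus A [magnetic_stimulus()] (B0 and axis offset).
#' @param parameter Name of a sweepable parameter row: one of
#'   `sigma_0`..`sigma_4`, `epsilon_0`..`epsilon_4`, `R`, `D`, `r`, `d`.
#' @param values Strictly monotone vector of parameter values, SI units.
#' @param frequencies Strictly increasing frequencies in Hz.
#' @return A `sweep_result` data.frame with the parameter column, a
#'   `frequency_Hz` column, `valid`, and the four membrane response columns.
#' @export
parameter_sweep <- function(cell, stimulus, parameter, values,
                            frequencies = log_frequency_grid(2e3, 2e5)) {
  param_row(parameter)                       # errors on unknown names
  if (parameter %in% c("B0", "f"))
    stop("'", parameter, "' is a stimulus parameter; sweep frequencies via ",
         "the 'frequencies' grid and B0 via the stimulus")
  stopifnot(length(values) >= 1L, length(frequencies) >= 1L,
            all(frequencies > 0))
  if (length(values) > 1L && !(all(diff(values) > 0) || all(diff(values) < 0)))
    stop("'values' must be strictly monotone")
  stopifnot(!is.unsorted(frequencies, strictly = TRUE))
  grid <- expand.grid(value = values, frequency_Hz = frequencies,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    varied <- tryCatch(set_parameter(cell, parameter, grid$value[i]),
                       error = function(e) NULL)
    if (is.null(varied))
      return(data.frame(valid = FALSE, cell_amplitude_mV = NA_real_,
                        cell_phase_deg = NA_real_, org_amplitude_mV = NA_real_,
                        org_phase_deg = NA_real_))
    st <- magnetic_stimulus(stimulus$B0, grid$frequency_Hz[i],
                            stimulus$axis_offset)
    cbind(valid = TRUE, membrane_summary(solve_harmonic(varied, st)))
  })
  df <- cbind(grid, do.call(rbind, rows))
  names(df)[1] <- parameter
  new_sweep_result(df, paste0("parameter_sweep:", parameter),
                   model_parameters(cell, stimulus),
                   c(parameter, "frequency_Hz"))
}

#' Low-frequency phase-transition radius of the organelle
#'
#' At low frequency the phase of the organelle polarization sits in one of
#' two regimes: a lag near -90 degrees (large organelles, as for the cell
#' membrane) or an advance near +90 degrees (small organelles). This locates
#' the organelle outer radius at which the regimes switch, by bisection on
#' the sign of the imaginary part of the organelle polarization at the
#' depolarised lobe.
#'
#' @param cell Base [two_shell_cell()]; all parameters except the organelle
#'   outer radius stay fixed.
#' @param stimulus Probe stimulus; default 1 kHz at the cell's standard B0/C
#'   must lie in the low-frequency band where the two regimes are distinct.
#' @param bracket Length-2 radius interval in metres enclosing the
#'   transition; the endpoints must fall in opposite phase regimes.
#' @param tol Radius tolerance of the bisection, metres (default 0.01 um).
#' @return Transition radius in metres.
#' @export
phase_transition_radius <- function(cell,
                                    stimulus = magnetic_stimulus(2, 1e3),
                                    bracket = c(0.3e-6, 5e-6),
                                    tol = 0.01e-6) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2], tol > 0,
            stimulus$frequency > 0)
  regime <- function(r_outer) {
    sol <- solve_harmonic(set_parameter(cell, "r", r_outer), stimulus)
    sign(Im(transmembrane_organelle(sol)))
  }
  lo <- bracket[1]; hi <- bracket[2]
  s_lo <- regime(lo); s_hi <- regime(hi)
  if (s_lo == s_hi)
    stop("bracket [", lo, ", ", hi, "] m does not enclose a phase-regime ",
         "transition (same regime at both endpoints)")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (regime(mid) == s_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Instantaneous surface polarization map
#'
#' Evaluates the real instantaneous polarization
#' \eqn{\mathrm{Re}[\psi(\theta,\phi)\,e^{j\tau}]} of one membrane over a
#' regular (theta, phi) grid. The pattern follows
#' \eqn{\sin\theta\cos\phi}: zeros at both poles, extrema on the equator at
#' \eqn{\phi = 0} and \eqn{\phi = 180^\circ} with opposite signs
#' (hyperpolarised and depolarised lobes).
#'
#' @param solution A `harmonic_solution`.
#' @param membrane `"cell"` or `"organelle"`.
#' @param n_theta,n_phi Grid resolution (nodes inclusive of both ends).
#' @param time_phase Instant within the cycle, radians (\eqn{\tau = \omega t}).
#' @return A `surface_map` data.frame with `theta_deg`, `phi_deg`,
#'   `polarization_mV` and the complex amplitude split into `re_mV`, `im_mV`.
#' @export
surface_map <- function(solution, membrane = c("cell", "organelle"),
                        n_theta = 37L, n_phi = 73L, time_phase = 0) {
  membrane <- match.arg(membrane)
  stopifnot(inherits(solution, "harmonic_solution"),
            n_theta >= 2L, n_phi >= 2L)
  coef <- tm_coefficient(solution, if (membrane == "cell") 1L else 3L)
  grid <- expand.grid(theta_deg = seq(0, 180, length.out = n_theta),
                      phi_deg = seq(0, 360, length.out = n_phi),
                      KEEP.OUT.ATTRS = FALSE)
  psi <- coef * sin(grid$theta_deg * pi / 180) * cos(grid$phi_deg * pi / 180)
  grid$polarization_mV <- Re(psi * exp(1i * time_phase)) * 1e3
  grid$re_mV <- Re(psi) * 1e3
  grid$im_mV <- Im(psi) * 1e3
  structure(grid, class = c("surface_map", "data.frame"),
            membrane = membrane, time_phase = time_phase,
            parameters = model_parameters(solution$cell, solution$stimulus))
}
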