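#' Two-shell cell model
#'
#' The model geometry: a spherical cell whose thin membrane shell encloses a
#' concentric spherical organelle with its own thin membrane shell. The two
#' shells partition space into five homogeneous, isotropic regions, numbered
#' from the outside in: 0 extracellular medium, 1 cell membrane, 2 cytoplasm,
#' 3 organelle membrane, 4 organelle interior.
#'
#' @param media List of five [dielectric_medium()] objects for regions 0-4.
#' @param cell_shell [shell_geometry()] of the cell membrane.
#' @param organelle_shell [shell_geometry()] of the organelle membrane; its
#'   outer radius must be strictly inside the cytoplasm
#'   (`organelle_shell$outer_radius < cell_shell$inner_radius`).
#' @return An object of class `two_shell_cell`.
#' @export
#' @examples
#' cell <- standard_cell()
#' cell$media[[2]]$conductivity   # cell membrane, 3e-7 S/m
two_shell_cell <- function(media, cell_shell, organelle_shell) {
  if (!is.list(media) || length(media) != 5L ||
      !all(vapply(media, inherits, logical(1), "dielectric_medium")))
    stop("'media' must be a list of five dielectric_medium objects (regions 0-4)")
  stopifnot(inherits(cell_shell, "shell_geometry"),
            inherits(organelle_shell, "shell_geometry"))
  if (organelle_shell$outer_radius >= cell_shell$inner_radius)
    stop("organelle must lie strictly inside the cytoplasm: organelle outer radius ",
         organelle_shell$outer_radius, " m >= cell inner radius ",
         cell_shell$inner_radius, " m")
  structure(list(media = media, cell_shell = cell_shell,
                 organelle_shell = organelle_shell),
            class = "two_shell_cell")
}

#' @export
print.two_shell_cell <- function(x, ...) {
  cat("<two_shell_cell>\n")
  cat(sprintf("  cell:      R+ = %g um, membrane D = %g nm\n",
              x$cell_shell$outer_radius * 1e6, x$cell_shell$thickness * 1e9))
  cat(sprintf("  organelle: r+ = %g um, membrane d = %g nm\n",
              x$organelle_shell$outer_radius * 1e6,
              x$organelle_shell$thickness * 1e9))
  sig <- vapply(x$media, `[[`, numeric(1), "conductivity")
  cat("  sigma (S/m):  ", paste(signif(sig, 3), collapse = ", "), "\n")
  eps <- vapply(x$media, `[[`, numeric(1), "permittivity")
  cat("  epsilon (F/m):", paste(signif(eps, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Sinusoidal magnetic stimulus
#'
#' A spatially uniform, sinusoidally alternating magnetic field
#' \eqn{B = B_0 e^{j\omega t}} directed along the coil axis, with the cell
#' centre at distance `axis_offset` (C) from that axis. The off-axis distance
#' controls the uniform induced electric field at the cell,
#' \eqn{|E_0| = \omega B_0 C / 2}.
#'
#' @param B0 Magnetic flux density amplitude, tesla; >= 0.
#' @param frequency Field frequency in Hz; >= 0.
#' @param axis_offset Distance C from the cell centre to the coil axis,
#'   metres; >= 0. Default 10 mm.
#' @return An object of class `magnetic_stimulus` (fields `B0`, `frequency`,
#'   `axis_offset`, `omega`).
#' @export
magnetic_stimulus <- function(B0, frequency, axis_offset = 0.01) {
  stopifnot(is.numeric(B0), length(B0) == 1L,
            is.numeric(frequency), length(frequency) == 1L,
            is.numeric(axis_offset), length(axis_offset) == 1L)
  if (!is.finite(B0) || B0 < 0) stop("'B0' must be finite and >= 0")
  if (!is.finite(frequency) || frequency < 0)
    stop("'frequency' must be finite and >= 0")
  if (!is.finite(axis_offset) || axis_offset < 0)
    stop("'axis_offset' must be finite and >= 0")
  structure(list(B0 = B0, frequency = frequency, axis_offset = axis_offset,
                 omega = 2 * pi * frequency),
            class = "magnetic_stimulus")
}

#' @export
print.magnetic_stimulus <- function(x, ...) {
  cat(sprintf("<magnetic_stimulus> B0 = %g T, f = %g kHz, C = %g mm\n",
              x$B0, x$frequency / 1e3, x$axis_offset * 1e3))
  invisible(x)
}

#' Model parameter table: standard values and physiological ranges
#'
#' The sixteen physical parameters of the model with their standard values
#' and, where defined, lower/upper physiological limits, in the units in
#' which they are conventionally quoted (`unit` column); `si` is the factor
#' converting the quoted unit to SI. `scale` marks how a parameter is swept
#' or sampled across its range: `"log"` for the membrane/cytoplasm
#' conductivities (ranges spanning decades), `"lin"` otherwise.
#'
#' @return A data.frame with columns `name`, `standard`, `lower`, `upper`,
#'   `scale`, `unit`, `si`.
#' @export
parameter_ranges <- function() {
  data.frame(
    name = c("sigma_0", "sigma_1", "sigma_2", "sigma_3", "sigma_4",
             "epsilon_0", "epsilon_1", "epsilon_2", "epsilon_3", "epsilon_4",
             "R", "D", "r", "d", "B0", "f"),
    standard = c(1.2, 3e-7, 0.3, 3e-7, 0.3,
                 6.4e-10, 4.4e-11, 6.4e-10, 4.4e-11, 6.4e-10,
                 10, 5, 3, 5, 2, 10),
    lower = c(NA, 1e-8, 0.1, 1e-8, 0.1,
              NA, 1.8e-11, 3.5e-10, 1.8e-11, 3.5e-10,
              5, 3, 0.3, 1, NA, 2),
    upper = c(NA, 1e-6, 1.0, 1e-5, 1.0,
              NA, 8.8e-11, 7.0e-10, 8.8e-11, 7.0e-10,
              100, 7, 5, 8, NA, 200),
    scale = c("lin", "log", "log", "log", "log",
              rep("lin", 5), rep("lin", 4), "lin", "lin"),
    unit = c(rep("S/m", 5), rep("As/Vm", 5),
             "um", "nm", "um", "nm", "T", "kHz"),
    si = c(rep(1, 10), 1e-6, 1e-9, 1e-6, 1e-9, 1, 1e3),
    stringsAsFactors = FALSE
  )
}

# Look up one row of the parameter table; errors on unknown names.
param_row <- function(name, ranges = parameter_ranges()) {
  i <- match(name, ranges$name)
  if (is.na(i)) stop("unknown model parameter '", name, "'; known: ",
                     paste(ranges$name, collapse = ", "))
  ranges[i, ]
}

#' Standard cell and stimulus
#'
#' Builds the model with its standard parameter set: cell radius 10 um with a
#' 5 nm membrane, organelle (mitochondrion) radius 3 um with a 5 nm membrane,
#' conductivities/permittivities of the five regions at their standard
#' values, and a 2 T, 10 kHz stimulus with the coil axis 10 mm from the cell.
#' Quoted radii are interpreted as outer radii; inner radii follow by
#' subtracting the membrane thickness.
#'
#' @return `standard_cell()`: a [two_shell_cell()]; `standard_stimulus()`: a
#'   [magnetic_stimulus()].
#' @export
standard_cell <- function() {
  p <- parameter_ranges()
  v <- stats::setNames(p$standard * p$si, p$name)
  two_shell_cell(
    media = list(
      dielectric_medium(v[["sigma_0"]], v[["epsilon_0"]]),
      dielectric_medium(v[["sigma_1"]], v[["epsilon_1"]]),
      dielectric_medium(v[["sigma_2"]], v[["epsilon_2"]]),
      dielectric_medium(v[["sigma_3"]], v[["epsilon_3"]]),
      dielectric_medium(v[["sigma_4"]], v[["epsilon_4"]])
    ),
    cell_shell = shell_geometry(v[["R"]], v[["D"]]),
    organelle_shell = shell_geometry(v[["r"]], v[["d"]])
  )
}

#' @rdname standard_cell
#' @export
standard_stimulus <- function() {
  p <- parameter_ranges()
  magnetic_stimulus(B0 = param_row("B0", p)$standard,
                    frequency = param_row("f", p)$standard * 1e3,
                    axis_offset = 0.01)
}

#' Replace one model parameter
#'
#' Returns a copy of `cell` with a single Table-row parameter set to `value`
#' (in SI units). Geometry invariants are re-validated, so an organelle
#' radius exceeding the cell's inner radius raises an error.
#'
#' @param cell A [two_shell_cell()].
#' @param name One of `sigma_0`..`sigma_4`, `epsilon_0`..`epsilon_4`,
#'   `R`, `D`, `r`, `d`.
#' @param value New value in SI units (S/m, F/m or metres).
#' @return A new [two_shell_cell()].
#' @export
set_parameter <- function(cell, name, value) {
  stopifnot(inherits(cell, "two_shell_cell"))
  m <- regmatches(name, regexec("^(sigma|epsilon)_([0-4])$", name))[[1]]
  if (length(m)) {
    i <- as.integer(m[3]) + 1L
    med <- cell$media[[i]]
    if (m[2] == "sigma") med <- dielectric_medium(value, med$permittivity)
    else med <- dielectric_medium(med$conductivity, value)
    cell$media[[i]] <- med
    return(two_shell_cell(cell$media, cell$cell_shell, cell$organelle_shell))
  }
  cs <- cell$cell_shell; os <- cell$organelle_shell
  switch(name,
    R = cs <- shell_geometry(value, cs$thickness),
    D = cs <- shell_geometry(cs$outer_radius, value),
    r = os <- shell_geometry(value, os$thickness),
    d = os <- shell_geometry(os$outer_radius, value),
    stop("unknown model parameter '", name, "'")
  )
  two_shell_cell(cell$media, cs, os)
}

# Draw one value in [lower, upper] on the row's scale.
sample_in_range <- function(row) {
  if (is.na(row$lower) || is.na(row$upper)) return(row$standard)
  if (row$scale == "log") {
    exp(stats::runif(1, log(row$lower), log(row$upper)))
  } else {
    stats::runif(1, row$lower, row$upper)
  }
}

#' Random cell within the physiological parameter ranges
#'
#' Samples every ranged cell parameter uniformly within its lower/upper
#' limits (log-uniformly for conductivities) and returns a valid
#' [two_shell_cell()]. Parameter combinations that violate the geometry
#' (organelle not strictly inside the cell) are rejected and redrawn; an
#' error is raised if no valid draw is found within `max_tries`.
#'
#' @param ranges Parameter table as returned by [parameter_ranges()];
#'   rows may be edited to tighten or pin ranges (set `lower == upper`
#'   to pin a value).
#' @param seed Optional integer seed; with a fixed seed the draw is
#'   reproducible and the caller's RNG state is left untouched.
#' @param max_tries Rejection-sampling budget.
#' @return A [two_shell_cell()].
#' @export
random_cell <- function(ranges = parameter_ranges(), seed = NULL,
                        max_tries = 1000L) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  cell_params <- c("sigma_0", "sigma_1", "sigma_2", "sigma_3", "sigma_4",
                   "epsilon_0", "epsilon_1", "epsilon_2", "epsilon_3",
                   "epsilon_4", "R", "D", "r", "d")
  for (try in seq_len(max_tries)) {
    v <- vapply(cell_params, function(nm) {
      row <- param_row(nm, ranges)
      sample_in_range(row) * row$si
    }, numeric(1))
    cell <- tryCatch(
      two_shell_cell(
        media = list(
          dielectric_medium(v[["sigma_0"]], v[["epsilon_0"]]),
          dielectric_medium(v[["sigma_1"]], v[["epsilon_1"]]),
          dielectric_medium(v[["sigma_2"]], v[["epsilon_2"]]),
          dielectric_medium(v[["sigma_3"]], v[["epsilon_3"]]),
          dielectric_medium(v[["sigma_4"]], v[["epsilon_4"]])
        ),
        cell_shell = shell_geometry(v[["R"]], v[["D"]]),
        organelle_shell = shell_geometry(v[["r"]], v[["d"]])
      ),
      error = function(e) NULL
    )
    if (!is.null(cell)) return(cell)
  }
  stop("could not draw a geometrically valid cell in ", max_tries,
       " attempts; the supplied ranges appear mutually unsatisfiable")
}
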