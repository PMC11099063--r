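#' Kinetic specification of one cell class
#'
#' Describes the distribution of single-cell adhesion kinetic parameters for
#' one cell type. Rendered curves follow a generalized-logistic
#' rise-to-plateau, the canonical phenomenological shape of RWG adhesion
#' signals: a lag (onset delay), a sigmoidal spreading phase, and a plateau
#' whose height is the cell's adhesion amplitude in picometres of wavelength
#' shift. An optional second phase (a second logistic component) models
#' biphasic adhesion, e.g. late spreading that only separates cell types
#' after the first hour.
#'
#' @param class_name character label of the cell class.
#' @param amplitude_range numeric `c(low, high)` plateau amplitude interval, pm.
#' @param onset_delay `c(mean, sd)` of the adhesion onset delay, minutes.
#' @param rise_time `c(mean, sd)` of the logistic time constant, minutes.
#' @param shape_exponent `c(mean, sd)` of the dimensionless logistic exponent
#'   (larger values sharpen and delay the effective take-off).
#' @param plateau_slope `c(mean, sd)` of the residual post-plateau slope,
#'   pm/min.
#' @param second_phase optional list with elements `amplitude_range`,
#'   `onset_delay`, `rise_time` describing a second logistic component;
#'   `NULL` for single-phase kinetics.
#' @return object of class `class_kinetic_spec`.
#' @export
class_kinetic_spec <- function(class_name,
                               amplitude_range,
                               onset_delay = c(10, 3),
                               rise_time = c(15, 4),
                               shape_exponent = c(1, 0),
                               plateau_slope = c(0, 0),
                               second_phase = NULL) {
  check_that(is.character(class_name) && length(class_name) == 1 &&
               nzchar(class_name), "class_name must be a non-empty string")
  check_that(is.numeric(amplitude_range) && length(amplitude_range) == 2,
             "amplitude_range must be c(low, high)")
  check_that(amplitude_range[1] <= amplitude_range[2],
             "amplitude_range low must be <= high")
  for (nm in c("onset_delay", "rise_time", "shape_exponent", "plateau_slope")) {
    v <- get(nm)
    check_that(is.numeric(v) && length(v) == 2 && v[2] >= 0,
               sprintf("%s must be c(mean, sd) with sd >= 0", nm))
  }
  if (!is.null(second_phase)) {
    check_that(is.list(second_phase) &&
                 all(c("amplitude_range", "onset_delay", "rise_time") %in%
                       names(second_phase)),
               "second_phase needs amplitude_range, onset_delay, rise_time")
    check_that(second_phase$amplitude_range[1] <= second_phase$amplitude_range[2],
               "second_phase amplitude_range low must be <= high")
  }
  structure(
    list(class_name = class_name,
         amplitude_range = as.numeric(amplitude_range),
         onset_delay = as.numeric(onset_delay),
         rise_time = as.numeric(rise_time),
         shape_exponent = as.numeric(shape_exponent),
         plateau_slope = as.numeric(plateau_slope),
         second_phase = second_phase),
    class = "class_kinetic_spec"
  )
}

#' @export
print.class_kinetic_spec <- function(x, ...) {
  cat(sprintf("<class_kinetic_spec> %s: amplitude %g-%g pm, onset %g+-%g min, rise %g+-%g min%s\n",
              x$class_name, x$amplitude_range[1], x$amplitude_range[2],
              x$onset_delay[1], x$onset_delay[2],
              x$rise_time[1], x$rise_time[2],
              if (is.null(x$second_phase)) "" else ", biphasic"))
  invisible(x)
}

#' Default five-class kinetic specifications
#'
#' Phenomenological specs for the five cell lines commonly profiled on
#' single-cell RWG sensors. Endpoint amplitude regions follow the adhesion
#' ranges seen in such data: HeLa spans a wide high-adhesion range
#' (100-1800 pm), MC3T3-E1 preosteoblasts sit in the low-adhesion region,
#' LCLC-103H has a broad endpoint spread (100-1450 pm), MCF-7 carries a
#' distinctive sharp early-phase shape, and MDA-MB-231 is a generic
#' mid-range adherent. The ranges deliberately overlap so classification is
#' nontrivial.
#'
#' @return named list of [class_kinetic_spec()] objects.
#' @export
default_class_specs <- function() {
  list(
    `HeLa` = class_kinetic_spec(
      "HeLa", amplitude_range = c(100, 1800),
      onset_delay = c(8, 3), rise_time = c(20, 5),
      shape_exponent = c(1, 0.2), plateau_slope = c(0.3, 0.2)),
    `LCLC-103H` = class_kinetic_spec(
      "LCLC-103H", amplitude_range = c(100, 1450),
      onset_delay = c(12, 4), rise_time = c(30, 8),
      shape_exponent = c(1, 0.2), plateau_slope = c(0.8, 0.4)),
    `MC3T3-E1` = class_kinetic_spec(
      "MC3T3-E1", amplitude_range = c(100, 500),
      onset_delay = c(15, 5), rise_time = c(25, 6),
      shape_exponent = c(1, 0.2), plateau_slope = c(0.1, 0.1)),
    `MCF-7` = class_kinetic_spec(
      "MCF-7", amplitude_range = c(100, 700),
      onset_delay = c(20, 4), rise_time = c(8, 2),
      shape_exponent = c(4, 0.5), plateau_slope = c(0, 0.1)),
    `MDA-MB-231` = class_kinetic_spec(
      "MDA-MB-231", amplitude_range = c(150, 900),
      onset_delay = c(10, 3), rise_time = c(18, 5),
      shape_exponent = c(1, 0.2), plateau_slope = c(0.2, 0.2))
  )
}

#' Draw one cell's kinetic parameters from a class specification
#'
#' Amplitude is uniform on `amplitude_range`; onset delay, rise time and
#' shape exponent are Gaussian draws truncated at small positive floors so
#' rendered curves are always finite and causal; plateau slope is Gaussian.
#'
#' @param spec a [class_kinetic_spec()].
#' @param seed optional integer; when given the draw is a pure function of
#'   `(spec, seed)`. When `NULL` the current RNG stream is used.
#' @return list with `amplitude`, `onset_delay`, `rise_time`,
#'   `shape_exponent`, `plateau_slope`, and (if biphasic) `amp2`, `onset2`,
#'   `rise2`; plus `class_name`.
#' @export
sample_kinetic_params <- function(spec, seed = NULL) {
  check_that(inherits(spec, "class_kinetic_spec"), "spec must be a class_kinetic_spec")
  draw <- function() {
    p <- list(
      class_name = spec$class_name,
      amplitude = stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2]),
      onset_delay = max(0, stats::rnorm(1, spec$onset_delay[1], spec$onset_delay[2])),
      rise_time = max(0.5, stats::rnorm(1, spec$rise_time[1], spec$rise_time[2])),
      shape_exponent = max(0.2, stats::rnorm(1, spec$shape_exponent[1], spec$shape_exponent[2])),
      plateau_slope = stats::rnorm(1, spec$plateau_slope[1], spec$plateau_slope[2])
    )
    if (!is.null(spec$second_phase)) {
      sp <- spec$second_phase
      p$amp2 <- stats::runif(1, sp$amplitude_range[1], sp$amplitude_range[2])
      p$onset2 <- max(0, stats::rnorm(1, sp$onset_delay[1], sp$onset_delay[2]))
      p$rise2 <- max(0.5, stats::rnorm(1, sp$rise_time[1], sp$rise_time[2]))
    }
    p
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Render one cell's adhesion curve on a time grid
#'
#' Generalized logistic rise-to-plateau, anchored to zero at t = 0:
#' `S(t) = A * (g(t) - g(0)) / (1 - g(0)) + s*t` with
#' `g(t) = (1 + exp(-(t - t_mid)/tau))^(-m)`, where `A` is the plateau
#' amplitude (pm), `tau` the rise time (min), `m` the shape exponent and
#' `s` the residual plateau slope (pm/min). The logistic midpoint is placed
#' at `t_mid = t0 + c(m) * tau` with `c(m) = log(0.03^(-1/m) - 1)`, which
#' pins the curve to 3 percent of its amplitude at the onset delay `t0`
#' for every shape exponent — so "onset" always means the time before which
#' the cell has effectively not started adhering. The zero anchoring keeps
#' `S(0) = 0` exactly, matching zero-offset biosensor signals. A biphasic
#' parameter set adds a second logistic component (`amp2`, `onset2`,
#' `rise2`, m = 1) on top.
#'
#' @param params parameter list from [sample_kinetic_params()].
#' @param time_grid minutes, sorted ascending, starting at 0.
#' @return numeric pm vector, same length as `time_grid`.
#' @export
render_cell_curve <- function(params, time_grid) {
  check_that(length(time_grid) >= 1, "time_grid must be non-empty")
  check_that(!is.unsorted(time_grid, strictly = TRUE),
             "time_grid must be strictly ascending")
  check_that(time_grid[1] == 0, "time_grid must start at 0")
  logistic_part <- function(A, t0, tau, m) {
    if (A == 0) return(numeric(length(time_grid)))
    t_mid <- t0 + log(0.03^(-1 / m) - 1) * tau
    g <- (1 + exp(-(time_grid - t_mid) / tau))^(-m)
    g0 <- (1 + exp(t_mid / tau))^(-m)
    A * (g - g0) / (1 - g0)
  }
  s <- logistic_part(params$amplitude, params$onset_delay,
                     params$rise_time, params$shape_exponent)
  if (!is.null(params$amp2) && params$amp2 != 0) {
    s <- s + logistic_part(params$amp2, params$onset2, params$rise2, 1)
  }
  if (params$amplitude != 0 || !is.null(params$amp2)) {
    s <- s + params$plateau_slope * time_grid
  }
  s
}
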