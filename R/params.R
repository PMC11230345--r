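#' Model parameters for the switching bead system
#'
#' Collects every physical and kinetic constant of the bead model: linear
#' confinement toward the origin, Gaussian excluded-volume repulsion between
#' bead pairs, harmonic crosslink springs, and the continuous-time Markov
#' chain (CTMC) that switches crosslinks on and off.  Binding happens at rate
#' \code{a(r) = affinity_amplitude / (1 + exp(affinity_steepness * (r -
#' affinity_midpoint)))} for a pair at separation \code{r}; every bond breaks
#' at the constant rate \code{c_break}.  Both rates are multiplied by
#' \code{timescale} (the binding-timescale knob, called alpha for the 3-bead
#' model and beta for the many-bead model) and, in simulation, by
#' \code{epsilon^(-scaling_exponent)} to realise the amorphic (q = 0),
#' flexible (q = 1) and rigid (q = 2) scaling regimes.
#'
#' @param n_beads number of beads (positive integer).
#' @param dim spatial dimension, 2 or 3.
#' @param eta confinement strength; the confinement force is \code{-eta * x}.
#' @param a_ev excluded-volume amplitude.
#' @param c_ev excluded-volume squared length scale.
#' @param kappa crosslink spring constant.
#' @param c_break constant bond breaking rate.
#' @param affinity_amplitude,affinity_steepness,affinity_midpoint logistic
#'   affinity-function parameters (see Details).
#' @param timescale binding-timescale multiplier applied to the whole rate
#'   matrix (alpha / beta).
#' @param epsilon thermal noise scale; the noise term is
#'   \code{sqrt(2 * epsilon) dB} per coordinate.
#' @param scaling_exponent q in \{0, 1, 2\}: the power of \code{1/epsilon}
#'   multiplying the switching rates in simulation.
#'
#' @return An object of class \code{"bead_params"} (a named list).
#' @seealso [preset_params()] for the two published parameter sets.
#' @export
bead_params <- function(n_beads, dim, eta, a_ev, c_ev, kappa, c_break,
                        affinity_amplitude, affinity_steepness,
                        affinity_midpoint, timescale = 1, epsilon = 0.05,
                        scaling_exponent = 1) {
  stopifnot(
    length(n_beads) == 1L, n_beads >= 1, n_beads == as.integer(n_beads),
    dim %in% c(2L, 3L),
    # zero turns a force or the binding channel off (calibration runs);
    # rates that would create absorbing states must stay positive
    eta >= 0, a_ev >= 0, c_ev > 0, kappa >= 0, c_break > 0,
    affinity_amplitude >= 0, affinity_steepness > 0, affinity_midpoint > 0,
    timescale > 0, epsilon > 0,
    scaling_exponent %in% c(0L, 1L, 2L)
  )
  structure(list(
    n_beads = as.integer(n_beads), dim = as.integer(dim),
    eta = eta, a_ev = a_ev, c_ev = c_ev, kappa = kappa, c_break = c_break,
    affinity_amplitude = affinity_amplitude,
    affinity_steepness = affinity_steepness,
    affinity_midpoint = affinity_midpoint,
    timescale = timescale, epsilon = epsilon,
    scaling_exponent = as.integer(scaling_exponent)
  ), class = "bead_params")
}

#' Published parameter presets
#'
#' Two presets are provided.  \code{"table1-3bead"} is the dimensionless
#' planar 3-bead model (eta = 1, a_ev = 2, c_ev = 0.5, kappa = 5, c = 0.5,
#' a(x) = 2 / (1 + exp(20 (x - 0.75)))).  \code{"table1-361"} is the
#' dimensional 361-bead nucleolus model in 3-d with lengths in nm and rates
#' in 1/s (eta = 0.002, a_ev = 0.03, c_ev = 30000, kappa = 10, c = 0.01,
#' a(x) = 2 / (1 + exp(20 (x - 75)))).  \code{"reduced-100"} is a
#' desk-scale 100-bead reduction of the 361-bead model for regime sweeps:
#' all parameters match except the confinement, strengthened to
#' eta = 0.005 so that the unbound cloud's mean nearest-neighbor distance
#' matches the full-size system's (about 180 nm) — the reduction preserves
#' the geometry the binding kinetics see, which is what makes the
#' clustering phenomenology transfer.
#'
#' The thermal noise scale is not part of the published table; the defaults
#' here are epsilon = 0.05 for the 3-bead preset (the middle of the range in
#' which flexible clusters are seen) and epsilon = 200 nm^2/s for the
#' dimensional presets, which puts the confinement-limited bead cloud at a
#' few hundred nm, a nucleolus-like size.
#'
#' \code{"landscape-3bead"} is the 3-bead parameter set with a contact-like
#' affinity (steepness 100 instead of 20): the published table's logistic
#' tail at the printed steepness contributes a time-averaged attraction at
#' the confinement/excluded-volume balance distance that is an order of
#' magnitude larger than the restoring margin there, which removes the
#' two-bead-cluster and unbound-triangle fixed points of the averaged
#' field.  Sharpening the affinity to match the contact-like character the
#' many-bead parameter set has at its own geometric scales restores the
#' full cluster fixed-point structure; this preset is the canonical
#' parameter set for the landscape, quasipotential and escape analyses
#' (see the methods vignette for the full argument).
#'
#' @param name one of \code{"table1-3bead"}, \code{"landscape-3bead"},
#'   \code{"table1-361"}, \code{"reduced-100"}.
#' @param ... overrides passed on to the underlying fields (for example
#'   \code{timescale}, \code{epsilon}, \code{scaling_exponent}).
#' @return A \code{"bead_params"} object.
#' @export
preset_params <- function(name = c("table1-3bead", "landscape-3bead",
                                   "table1-361", "reduced-100"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "table1-3bead" = list(
      n_beads = 3L, dim = 2L, eta = 1, a_ev = 2, c_ev = 0.5, kappa = 5,
      c_break = 0.5, affinity_amplitude = 2, affinity_steepness = 20,
      affinity_midpoint = 0.75, timescale = 1, epsilon = 0.05,
      scaling_exponent = 1L),
    "landscape-3bead" = list(
      n_beads = 3L, dim = 2L, eta = 1, a_ev = 2, c_ev = 0.5, kappa = 5,
      c_break = 0.5, affinity_amplitude = 2, affinity_steepness = 100,
      affinity_midpoint = 0.75, timescale = 1, epsilon = 0.05,
      scaling_exponent = 1L),
    "table1-361" = list(
      n_beads = 361L, dim = 3L, eta = 0.002, a_ev = 0.03, c_ev = 30000,
      kappa = 10, c_break = 0.01, affinity_amplitude = 2,
      affinity_steepness = 20, affinity_midpoint = 75, timescale = 1,
      epsilon = 200, scaling_exponent = 0L),
    "reduced-100" = list(
      n_beads = 100L, dim = 3L, eta = 0.005, a_ev = 0.03, c_ev = 30000,
      kappa = 10, c_break = 0.01, affinity_amplitude = 2,
      affinity_steepness = 20, affinity_midpoint = 75, timescale = 1,
      epsilon = 200, scaling_exponent = 0L)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(bead_params, base)
}

#' @export
print.bead_params <- function(x, ...) {
  cat(sprintf("bead model: %d beads in %d-d\n", x$n_beads, x$dim))
  cat(sprintf("  confinement eta=%g, EV (a_ev=%g, c_ev=%g), spring kappa=%g\n",
              x$eta, x$a_ev, x$c_ev, x$kappa))
  cat(sprintf("  binding a(r)=%g/(1+exp(%g(r-%g))), break c=%g\n",
              x$affinity_amplitude, x$affinity_steepness,
              x$affinity_midpoint, x$c_break))
  cat(sprintf("  timescale=%g, epsilon=%g, scaling exponent q=%d\n",
              x$timescale, x$epsilon, x$scaling_exponent))
  invisible(x)
}

#' Effective switching-rate multiplier
#'
#' In simulation every rate of the generator is multiplied by
#' \code{timescale * epsilon^(-scaling_exponent)}; this helper returns that
#' factor.
#'
#' @param params a \code{"bead_params"} object.
#' @return A positive scalar.
#' @export
rate_multiplier <- function(params) {
  params$timescale * params$epsilon^(-params$scaling_exponent)
}

#' Bead configurations
#'
#' A configuration is an \code{n_beads x dim} numeric matrix of positions.
#' \code{as_configuration} validates shape and finiteness;
#' \code{flatten_positions} / \code{unflatten_positions} convert between the
#' matrix form and the concatenated coordinate vector used by gradients,
#' paths and noise (bead-major, axis-minor: the vector is
#' \code{c(t(positions))}, i.e. bead 1's coordinates first).
#'
#' @param positions numeric matrix (or vector reshaped by row).
#' @param params a \code{"bead_params"} object.
#' @return \code{as_configuration}: validated position matrix;
#'   \code{flatten_positions}: numeric vector of length \code{n_beads*dim};
#'   \code{unflatten_positions}: position matrix.
#' @export
as_configuration <- function(positions, params) {
  if (is.null(dim(positions)))
    positions <- matrix(positions, nrow = params$n_beads,
                        ncol = params$dim, byrow = TRUE)
  positions <- as.matrix(positions)
  if (!all(dim(positions) == c(params$n_beads, params$dim)))
    stop("positions must be an n_beads x dim matrix")
  if (!all(is.finite(positions)))
    stop("positions must be finite")
  positions
}

#' @rdname as_configuration
#' @export
flatten_positions <- function(positions) as.vector(t(positions))

#' @rdname as_configuration
#' @export
unflatten_positions <- function(x, params) {
  matrix(x, nrow = params$n_beads, ncol = params$dim, byrow = TRUE)
}
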