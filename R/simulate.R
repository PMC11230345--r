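#' Default timestep for the hybrid integrator
#'
#' Picks the timestep so that both the fastest switching event and the
#' deterministic drift are resolved: \code{dt <= 0.1 / (R * max(a_max, c))}
#' where \code{R = timescale * epsilon^(-q)} is the rate multiplier, capped
#' at 1e-3 time units for the dimensionless (2-d) models and 1e-2 s for the
#' dimensional (3-d) ones.
#'
#' @param params a [bead_params()] object.
#' @return Timestep (scalar).
#' @export
default_dt <- function(params) {
  base <- if (params$dim == 2L) 1e-3 else 1e-2
  rmax <- rate_multiplier(params) *
    max(params$affinity_amplitude, params$c_break)
  min(base, 0.1 / rmax)
}

#' Initial bead configuration
#'
#' Places beads uniformly in a ball whose radius balances the confinement
#' force against the typical excluded-volume force (the maximum pair force
#' \code{a_ev sqrt(c_ev/2) exp(-1/2)} divided by \code{eta}), resampling any
#' bead closer than \code{0.1 sqrt(c_ev)} to another.
#'
#' @param params a [bead_params()] object.
#' @param seed optional RNG seed.
#' @return Position matrix.
#' @export
default_initial <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rad <- params$a_ev * sqrt(params$c_ev / 2) * exp(-0.5) / params$eta
  dmin <- 0.1 * sqrt(params$c_ev)
  n <- params$n_beads; d <- params$dim
  pos <- matrix(0, n, d)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      u <- stats::rnorm(d)
      p <- rad * stats::runif(1)^(1 / d) * u / sqrt(sum(u^2))
      ok <- i == 1L ||
        all(sqrt(rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                            matrix(p, i - 1L, d, byrow = TRUE))^2)) >= dmin)
      if (ok) { pos[i, ] <- p; break }
      if (try == 1000) stop("could not place beads without overlap")
    }
  }
  pos
}

#' One hybrid integrator step (reference implementation)
#'
#' Euler-Maruyama position update
#' \code{x <- x + v(x; s) dt + sqrt(2 epsilon dt) xi} with independent
#' standard-normal noise per coordinate, followed by binding/unbinding
#' events sampled at the updated positions ([sample_events()]).  This is
#' the plain-R reference for the compiled kernel used by [simulate()].
#'
#' @param positions position matrix.
#' @param bonds current binding state.
#' @param params a [bead_params()] object.
#' @param dt timestep.
#' @return List with updated \code{positions} and \code{bonds}.
#' @export
hybrid_step_r <- function(positions, bonds, params, dt) {
  stopifnot(dt > 0)
  positions <- as_configuration(positions, params)
  v <- unflatten_positions(total_drift(positions, bonds, params), params)
  noise <- matrix(stats::rnorm(params$n_beads * params$dim),
                  params$n_beads, params$dim)
  newpos <- positions + v * dt + sqrt(2 * params$epsilon * dt) * noise
  if (!all(is.finite(newpos)))
    stop("non-finite position after step; decrease dt")
  list(positions = newpos,
       bonds = sample_events(newpos, bonds, params, dt))
}

#' Simulate the switching bead dynamics
#'
#' Integrates the overdamped Langevin dynamics with Markov-switching
#' crosslinks (compiled kernel) for a duration \code{T}, recording every
#' \code{record_every}-th step.  All switching rates carry the regime
#' multiplier \code{timescale * epsilon^(-scaling_exponent)}, so the same
#' entry point realises the amorphic (q = 0), flexible (q = 1) and rigid
#' (q = 2) scalings.  With a fixed \code{seed} the trajectory replays
#' bit-identically.
#'
#' @param params a [bead_params()] object.
#' @param T total duration (> 0, or 0 for just the initial frame).
#' @param dt timestep (defaults to [default_dt()]).
#' @param seed optional RNG seed.
#' @param initial initial configuration (defaults to [default_initial()]).
#' @param bonds initial binding state (defaults to all unbound).
#' @param record_every record every this many steps.
#' @param freeze_positions if TRUE the positions never move and only the
#'   binding CTMC runs (used for rate-calibration diagnostics).
#' @return A \code{"switching_trajectory"}: list with \code{times},
#'   \code{positions} (frames x (n_beads*dim) matrix, bead-major),
#'   \code{partners} (frames x n_beads integer matrix, 0 = unbound),
#'   \code{params}, \code{dt}, \code{seed}, \code{record_every}.
#' @export
simulate_beads <- function(params, T, dt = default_dt(params), seed = NULL,
                           initial = NULL, bonds = NULL,
                           record_every = 1L, freeze_positions = FALSE) {
  stopifnot(T >= 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(initial)) initial <- default_initial(params)
  initial <- as_configuration(initial, params)
  if (is.null(bonds)) bonds <- rep(NA_integer_, params$n_beads)
  bonds <- as_binding_state(bonds, params$n_beads)
  R <- rate_multiplier(params)
  pmax_event <- 1 - exp(-R * max(params$affinity_amplitude, params$c_break) * dt)
  if (pmax_event > 0.5)
    warning("event probability per step exceeds 0.5; decrease dt")
  n_steps <- floor(T / dt)
  p0 <- unclass(bonds)
  p0[is.na(p0)] <- 0L
  out <- sim_switching_cpp(initial, p0, unclass(params), dt,
                           as.integer(n_steps), as.integer(record_every),
                           R, freeze_positions)
  structure(list(times = out$times, positions = out$positions,
                 partners = out$partners, params = params, dt = dt,
                 seed = seed, record_every = as.integer(record_every)),
            class = "switching_trajectory")
}

#' @export
print.switching_trajectory <- function(x, ...) {
  cat(sprintf("switching trajectory: %d frames, %d beads in %d-d, dt=%g\n",
              length(x$times), x$params$n_beads, x$params$dim, x$dt))
  invisible(x)
}

#' Trajectory accessors
#'
#' \code{n_frames} gives the number of recorded frames;
#' \code{frame_positions} the position matrix at frame \code{i};
#' \code{frame_bonds} the binding state at frame \code{i}.
#'
#' @param traj a \code{"switching_trajectory"}.
#' @param i frame index (1-based).
#' @return See description.
#' @export
n_frames <- function(traj) length(traj$times)

#' @rdname n_frames
#' @export
frame_positions <- function(traj, i) {
  unflatten_positions(traj$positions[i, ], traj$params)
}

#' @rdname n_frames
#' @export
frame_bonds <- function(traj, i) {
  p <- traj$partners[i, ]
  p[p == 0L] <- NA_integer_
  as_binding_state(p, traj$params$n_beads)
}

#' Frozen-position CTMC simulation (exact jump chain)
#'
#' Simulates the binding CTMC with rates frozen at the given positions by
#' exact (Gillespie) sampling over the enumerated states, independent of
#' the per-timestep thinning used by [simulate_beads()].  Used as an oracle
#' for occupation fractions, mean holding times and the empirical
#' time-averaged force.
#'
#' @param positions position matrix.
#' @param params a [bead_params()] object.
#' @param n_events number of jump events.
#' @param s0 starting state index (default 1, all unbound).
#' @param seed optional RNG seed.
#' @return List with \code{states} (visited state indices, length
#'   n_events+1), \code{holding} (holding times, length n_events) and
#'   \code{states_list} (the enumerated binding states).
#' @export
frozen_ctmc <- function(positions, params, n_events, s0 = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- enumerate_states(params$n_beads)
  S <- transition_rate_matrix(positions, params, states) *
    params$epsilon^(-params$scaling_exponent)
  out <- ctmc_gillespie_cpp(S, as.integer(s0), as.integer(n_events))
  out$states_list <- states
  out
}
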