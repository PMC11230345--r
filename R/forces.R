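#' Deterministic forces of the bead model
#'
#' The drift of the overdamped dynamics is the sum of three forces.
#' \code{confinement_force} is the linear restoring force \code{-eta * x_i}
#' standing in for the nuclear envelope.  \code{excluded_volume_force} is the
#' soft Gaussian repulsion
#' \code{f_i = sum_j a_ev (x_i - x_j) exp(-|x_i - x_j|^2 / c_ev)}.
#' \code{binding_force} is the harmonic crosslink attraction
#' \code{f_i = sum_j kappa b_ij (x_j - x_i)} over currently bound pairs.
#' All three return an \code{n_beads x dim} matrix of per-bead forces.
#'
#' @param positions n_beads x dim position matrix.
#' @param params a [bead_params()] object.
#' @param bonds a [binding_state()] partner vector.
#' @return Per-bead force matrix of the same shape as \code{positions}.
#' @export
confinement_force <- function(positions, params) {
  positions <- as_configuration(positions, params)
  -params$eta * positions
}

#' @rdname confinement_force
#' @export
excluded_volume_force <- function(positions, params) {
  positions <- as_configuration(positions, params)
  n <- params$n_beads
  f <- matrix(0, n, params$dim)
  if (n < 2L) return(f)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- positions[i, ] - positions[j, ]
      g <- params$a_ev * exp(-sum(dx^2) / params$c_ev) * dx
      f[i, ] <- f[i, ] + g
      f[j, ] <- f[j, ] - g
    }
  }
  f
}

#' @rdname confinement_force
#' @export
binding_force <- function(positions, bonds, params) {
  positions <- as_configuration(positions, params)
  bonds <- as_binding_state(bonds, params$n_beads)
  f <- matrix(0, params$n_beads, params$dim)
  for (i in seq_len(params$n_beads)) {
    j <- bonds[i]
    if (!is.na(j))
      f[i, ] <- params$kappa * (positions[j, ] - positions[i, ])
  }
  f
}

#' Per-state drift and potential
#'
#' \code{total_drift} is the full deterministic drift
#' \code{v(x; s) = f_conf + f_EV + f_bond}, returned as the concatenated
#' coordinate vector (bead-major).  It is the negative gradient of the
#' per-state potential returned by \code{state_potential},
#' \deqn{U(x; s) = \sum_i \eta |x_i|^2 / 2
#'   + \sum_{i<j} (a_{ev} c_{ev} / 2) e^{-|x_i - x_j|^2 / c_{ev}}
#'   + \sum_{(i,j) \in s} \kappa |x_i - x_j|^2 / 2,}
#' with the additive constant fixed so every term vanishes at the origin /
#' infinite separation.
#'
#' @inheritParams confinement_force
#' @return \code{total_drift}: numeric vector of length
#'   \code{n_beads * dim}; \code{state_potential}: scalar energy.
#' @export
total_drift <- function(positions, bonds, params) {
  f <- confinement_force(positions, params) +
    excluded_volume_force(positions, params) +
    binding_force(positions, bonds, params)
  flatten_positions(f)
}

#' @rdname total_drift
#' @export
state_potential <- function(positions, bonds, params) {
  positions <- as_configuration(positions, params)
  bonds <- as_binding_state(bonds, params$n_beads)
  u <- params$eta * sum(positions^2) / 2
  n <- params$n_beads
  if (n > 1L) {
    d2 <- as.matrix(stats::dist(positions))^2
    up <- d2[upper.tri(d2)]
    u <- u + sum(params$a_ev * params$c_ev / 2 * exp(-up / params$c_ev))
    for (i in seq_len(n)) {
      j <- bonds[i]
      if (!is.na(j) && j > i)
        u <- u + params$kappa * d2[i, j] / 2
    }
  }
  u
}
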