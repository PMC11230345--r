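#' Hamiltonian matrix of the WKB eigenvalue problem
#'
#' In the scaling regime where switching rates carry one power of
#' 1/epsilon, the WKB ansatz \code{p_s = r_s exp(-W/epsilon)} for the
#' steady-state Fokker-Planck system turns the leading order into the
#' eigenvalue problem
#' \deqn{[A(x, p) + D(p) + \alpha S(x)]\, r = 0,}
#' where \code{p} is the momentum (the gradient of the quasipotential W).
#' \code{A} is the diagonal advection matrix with entries \code{v(x; s) . p}
#' per state, \code{D} is the diagonal diffusion matrix with entries
#' \code{p . p}, and \code{S} is the binding generator.  The assembled
#' matrix is Metzler (nonnegative off-diagonal), so its rightmost
#' eigenvalue is real with a positive eigenvector (Perron theory); W is
#' characterised by that eigenvalue vanishing.
#'
#' @param positions position matrix.
#' @param p concatenated momentum vector (length \code{n_beads * dim}).
#' @param params a [bead_params()] object.
#' @param alpha binding timescale multiplying the generator (defaults to
#'   \code{params$timescale}).
#' @param states enumerated binding states.
#' @param S0 optional precomputed unit-timescale generator at these
#'   positions.
#' @return \code{n_states x n_states} matrix.
#' @export
hamiltonian_matrix <- function(positions, p, params,
                               alpha = params$timescale,
                               states = enumerate_states(params$n_beads),
                               S0 = NULL) {
  positions <- as_configuration(positions, params)
  if (length(p) != params$n_beads * params$dim)
    stop("momentum vector has wrong length")
  if (is.null(S0)) {
    p1 <- params; p1$timescale <- 1
    S0 <- transition_rate_matrix(positions, p1, states)
  }
  adv <- vapply(states, function(s) sum(total_drift(positions, s, params) * p),
                numeric(1L))
  diag_term <- adv + sum(p * p)
  alpha * S0 + diag(diag_term, nrow = length(states))
}

#' Principal (Perron) eigenvalue of a Metzler matrix
#'
#' The rightmost eigenvalue of a Metzler matrix (nonnegative off-diagonal
#' entries) is real and carries an entrywise-nonnegative eigenvector.
#' Returned with the eigenvector normalised to sum one.
#'
#' @param M a square Metzler matrix.
#' @return List with \code{value} (real scalar) and \code{vector}.
#' @export
principal_eigenvalue <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  off <- M; diag(off) <- 0
  if (any(off < -1e-10 * max(1, max(abs(M)))))
    stop("matrix is not Metzler (negative off-diagonal entries)")
  e <- eigen(M)
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  list(value = Re(e$values[i]), vector = v / sum(v))
}

#' Momentum magnitude along a path direction
#'
#' Solves the scalar eikonal condition for the quasipotential slope in the
#' direction of the unit tangent \code{t}: with the momentum ansatz
#' \code{p = lambda t}, the function \code{h(lambda)} = principal
#' eigenvalue of [hamiltonian_matrix()] is convex with \code{h(0) = 0} and
#' slope \code{<v> . t} at the origin.  On uphill segments
#' (\code{<v> . t < 0}) there is a unique positive root, found by
#' bracketing and safeguarded bisection/interpolation; on downhill
#' segments the quasipotential does not grow and lambda = 0.
#'
#' In a single-state (frozen-bond) system this reduces to
#' \code{lambda = -v . t}, so W accumulates exactly the potential
#' difference along a minimum-energy path; as alpha grows large the root
#' approaches \code{-<v> . t} and W approaches the effective potential of
#' the time-averaged field.
#'
#' @param positions position matrix.
#' @param tangent unit vector (concatenated coordinates).
#' @param params a [bead_params()] object.
#' @param alpha binding timescale.
#' @param states enumerated binding states.
#' @param S0 optional precomputed unit-timescale generator.
#' @param tol tolerance on \code{|h(lambda)|}.
#' @return Scalar lambda >= 0 (attributes carry the eigenvalue residual).
#' @export
solve_momentum <- function(positions, tangent, params,
                           alpha = params$timescale,
                           states = enumerate_states(params$n_beads),
                           S0 = NULL, tol = 1e-10) {
  positions <- as_configuration(positions, params)
  nt <- sqrt(sum(tangent^2))
  if (abs(nt - 1) > 1e-8) stop("tangent must be a unit vector")
  if (is.null(S0)) {
    p1 <- params; p1$timescale <- 1
    S0 <- transition_rate_matrix(positions, p1, states)
  }
  drifts <- vapply(states,
                   function(s) sum(total_drift(positions, s, params) * tangent),
                   numeric(1L))
  r0 <- stationary_distribution(S0)
  vbar_t <- sum(r0 * drifts)
  h <- function(lam) {
    M <- alpha * S0 + diag(lam * drifts + lam^2, nrow = length(states))
    principal_eigenvalue(M)$value
  }
  if (vbar_t >= -1e-12) return(structure(0, residual = 0))
  lam_max <- max(1e-8, 2 * max(abs(drifts)))
  tries <- 0L
  while (h(lam_max) <= 0 && tries < 60L) {
    lam_max <- 2 * lam_max
    tries <- tries + 1L
  }
  if (h(lam_max) <= 0)
    stop("failed to bracket the momentum root (h <= 0 up to lambda = ",
         signif(lam_max, 4), ")")
  lo <- 1e-9 * lam_max
  if (h(lo) >= 0) return(structure(0, residual = abs(h(0))))
  root <- stats::uniroot(h, c(lo, lam_max), tol = .Machine$double.eps^0.75)$root
  res <- abs(h(root))
  if (res > tol) {
    # one secant polish using the local slope of h
    dh <- (h(root * (1 + 1e-7) + 1e-12) - h(root)) / (root * 1e-7 + 1e-12)
    if (is.finite(dh) && dh != 0) {
      root2 <- root - h(root) / dh
      if (root2 > 0 && abs(h(root2)) < res) {
        root <- root2
        res <- abs(h(root))
      }
    }
  }
  structure(root, residual = res)
}

#' Quasipotential profile along a transition path
#'
#' Integrates the momentum magnitude along the path,
#' \deqn{W(s) = \int_0^s \lambda(s')\, ds',}
#' by the trapezoidal rule over the images (physical arclength), with
#' \code{W(0) = 0}.  The barrier \code{max W} is the alpha-dependent
#' effective energy barrier entering the Arrhenius law for cluster escape;
#' it grows with the binding timescale alpha and approaches the
#' time-averaged effective-potential barrier as alpha becomes large.
#'
#' Tangents are central differences of the images.  With
#' \code{frozen_state} the switching is clamped to a single binding state
#' (no generator), which is the gradient-system check: W then equals the
#' state-potential difference along the path.
#'
#' @param path a \code{"transition_path"}.
#' @param params a [bead_params()] object (defaults to the path's).
#' @param alpha binding timescale.
#' @param frozen_state optional [binding_state()] clamping the switching.
#' @return A \code{"potential_profile"} with an extra \code{lambda} field.
#' @export
quasipotential_profile <- function(path, params = path$params,
                                   alpha = params$timescale,
                                   frozen_state = NULL) {
  X <- path$images
  n <- nrow(X)
  lam <- numeric(n)
  if (is.null(frozen_state)) {
    states <- enumerate_states(params$n_beads)
    p1 <- params; p1$timescale <- 1
    for (i in seq_len(n)) {
      tg <- path_tangent(X, i)
      pos <- unflatten_positions(X[i, ], params)
      S0 <- transition_rate_matrix(pos, p1, states)
      lam[i] <- solve_momentum(pos, tg, params, alpha, states, S0)
    }
  } else {
    for (i in seq_len(n)) {
      tg <- path_tangent(X, i)
      v <- total_drift(unflatten_positions(X[i, ], params), frozen_state,
                       params)
      vt <- sum(v * tg)
      lam[i] <- if (vt < 0) -vt else 0
    }
  }
  w <- numeric(n)
  ds <- diff(path$arclength)
  for (i in 2:n) w[i] <- w[i - 1L] + 0.5 * (lam[i] + lam[i - 1L]) * ds[i - 1L]
  structure(list(s_norm = path$s_norm, arclength = path$arclength,
                 values = w, barrier = max(w) - w[1L], lambda = lam,
                 alpha = alpha),
            class = "potential_profile")
}

path_tangent <- function(X, i) {
  n <- nrow(X)
  d <- if (i == 1L) X[2L, ] - X[1L, ]
  else if (i == n) X[n, ] - X[n - 1L, ]
  else X[i + 1L, ] - X[i - 1L, ]
  d / sqrt(sum(d^2))
}

#' Arrhenius-law escape-time prediction
#'
#' Asymptotic slope of the log mean escape time in the small-noise limit:
#' \code{log E[tau] ~ barrier / epsilon}.  The prefactor is not predicted;
#' the returned value is meaningful up to an additive constant and as a
#' slope against 1/epsilon.
#'
#' @param barrier nonnegative barrier height (effective potential or
#'   quasipotential).
#' @param epsilon positive noise scale.
#' @return \code{barrier / epsilon}.
#' @export
arrhenius_log_time <- function(barrier, epsilon) {
  if (any(barrier < 0)) stop("barrier must be nonnegative")
  if (any(epsilon <= 0)) stop("epsilon must be positive")
  barrier / epsilon
}
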