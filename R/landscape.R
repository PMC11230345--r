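#' Time-averaged drift field
#'
#' Averages the per-state drift over the binding CTMC's stationary
#' distribution at the current positions:
#' \deqn{\langle v \rangle(x) = \sum_s v(x; s)\, r_s(x),}
#' where r(x) is the normalised null vector of the generator.  This is the
#' deterministic effective force left when the binding fluctuations are
#' averaged out; it is invariant to scaling the generator by any positive
#' constant (so it does not depend on the binding timescale).
#'
#' Only the crosslink-spring term differs between states, so the average is
#' computed as the bond-free drift plus, for every bead pair, the spring
#' force weighted by the total stationary probability of the states
#' containing that bond.
#'
#' @param positions position matrix (or flattened coordinate vector).
#' @param params a [bead_params()] object.
#' @param states enumerated binding states (defaults to enumerating).
#' @return Concatenated drift vector of length \code{n_beads * dim}.
#' @export
averaged_force <- function(positions, params,
                           states = enumerate_states(params$n_beads)) {
  positions <- as_configuration(positions, params)
  S <- transition_rate_matrix(positions, params, states)
  r <- stationary_distribution(S)
  base <- confinement_force(positions, params) +
    excluded_volume_force(positions, params)
  n <- params$n_beads
  w <- matrix(0, n, n)
  for (s in seq_along(states)) {
    bp <- bond_pairs(states[[s]])
    if (nrow(bp))
      for (k in seq_len(nrow(bp))) {
        w[bp[k, 1L], bp[k, 2L]] <- w[bp[k, 1L], bp[k, 2L]] + r[s]
      }
  }
  f <- base
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (w[i, j] > 0) {
          g <- params$kappa * w[i, j] * (positions[j, ] - positions[i, ])
          f[i, ] <- f[i, ] + g
          f[j, ] <- f[j, ] - g
        }
      }
    }
  }
  flatten_positions(f)
}

# force field closure on flattened coordinates, shared by the string method,
# fixed-point search and line integrals
force_function <- function(params, force = c("averaged", "state"),
                           state = NULL,
                           states = NULL) {
  if (is.function(force)) return(force)
  force <- match.arg(force)
  if (force == "averaged") {
    if (is.null(states)) states <- enumerate_states(params$n_beads)
    function(x) averaged_force(unflatten_positions(x, params), params, states)
  } else {
    if (is.null(state)) stop("force = \"state\" requires a binding state")
    function(x) total_drift(unflatten_positions(x, params), state, params)
  }
}

# central finite-difference Jacobian of a vector field
fd_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    e <- numeric(n); e[k] <- h
    J[, k] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

#' Fixed points of the time-averaged drift
#'
#' Relaxes each seed configuration under \code{dx/dt = <v>(x)}, polishes the
#' result to \code{<v> = 0} by Levenberg-Marquardt least squares (which
#' tolerates the rotational zero mode of the radially symmetric system), and
#' classifies the critical point from its sorted pairwise distances and the
#' finite-difference Jacobian spectrum.  Duplicates equal up to global
#' rotation/reflection and bead permutation are merged (they have identical
#' sorted pairwise distances).
#'
#' For the planar 3-bead model the stable fixed points are the unbound large
#' triangle (confinement balancing excluded volume), three equivalent
#' 2-bead clusters (two beads superimposed, one far), and the small-triangle
#' 3-bead cluster held together by rapidly switching bonds.
#'
#' @param params a [bead_params()] object.
#' @param seeds list of seed configurations (defaults to
#'   [default_fp_seeds()]).
#' @param tol residual tolerance on \code{max(abs(<v>))} (default 1e-8).
#' @param max_iter relaxation iteration cap.
#' @return List of fixed points; each is a list with elements
#'   \code{positions}, \code{label}, \code{residual}, \code{eigenvalues}
#'   (Jacobian spectrum), \code{n_unstable} (eigenvalues with positive real
#'   part, the rotational zero mode excluded), \code{pair_distances}
#'   (sorted), and \code{converged}.
#' @export
find_fixed_points <- function(params, seeds = default_fp_seeds(params),
                              tol = 1e-8, max_iter = 5000L) {
  states <- enumerate_states(params$n_beads)
  f <- force_function(params, "averaged", states = states)
  out <- list()
  seen <- character()
  for (seed in seeds) {
    x <- flatten_positions(as_configuration(seed, params))
    # crude gradient-flow relaxation into the basin
    for (it in seq_len(max_iter)) {
      v <- f(x)
      vmax <- max(abs(v))
      if (vmax < 1e-3) break
      x <- x + min(0.05, 0.05 / vmax) * v
    }
    fit <- minpack.lm::nls.lm(par = x, fn = f,
                              control = minpack.lm::nls.lm.control(
                                ftol = 1e-15, ptol = 1e-15, maxiter = 200))
    x <- fit$par
    res <- max(abs(f(x)))
    fp <- classify_critical_point(x, params, f, residual = res,
                                  converged = res < tol)
    key <- paste(round(fp$pair_distances, 5), fp$n_unstable, collapse = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- fp
    }
  }
  not_conv <- vapply(out, function(p) !p$converged, logical(1L))
  if (any(not_conv))
    warning(sum(not_conv), " seed(s) did not reach the fixed-point tolerance")
  out
}

classify_critical_point <- function(x, params, f, residual, converged) {
  pos <- unflatten_positions(x, params)
  d <- sort(as.vector(stats::dist(pos)))
  J <- fd_jacobian(f, x)
  ev <- eigen(J, only.values = TRUE)$values
  scale <- max(abs(ev))
  n_unstable <- sum(Re(ev) > 1e-4 * scale)
  label <- if (params$n_beads == 3L) {
    mid <- params$affinity_midpoint
    area <- triangle_area(pos)
    ascore <- if (d[3] > 0) area / d[3]^2 else 0
    if (n_unstable == 0L) {
      if (d[1] < 0.5 * mid && d[2] > mid) "two-bead-cluster"
      else if (d[3] < mid) "three-bead-cluster"
      else "unbound-triangle"
    } else {
      if (ascore < 0.02) "saddle-collinear" else "saddle-other"
    }
  } else {
    if (n_unstable == 0L) "minimum" else "saddle-other"
  }
  list(positions = pos, label = label, residual = residual,
       eigenvalues = ev, n_unstable = n_unstable, pair_distances = d,
       converged = converged)
}

triangle_area <- function(pos) {
  a <- pos[2, ] - pos[1, ]
  b <- pos[3, ] - pos[1, ]
  if (ncol(pos) == 2L) abs(a[1] * b[2] - a[2] * b[1]) / 2
  else sqrt(sum(crossprod_3d(a, b)^2)) / 2
}

crossprod_3d <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Default fixed-point seed configurations
#'
#' Seeds covering the known critical points of the planar 3-bead model:
#' large and small equilateral triangles centred at the origin, a
#' two-superimposed-plus-far-bead configuration for each pair, and a
#' collinear arrangement.  For other bead counts, random small-dispersion
#' configurations are returned.
#'
#' @param params a [bead_params()] object.
#' @param n_random number of random seeds for non-3-bead systems.
#' @return List of position matrices.
#' @export
default_fp_seeds <- function(params, n_random = 8L) {
  mid <- params$affinity_midpoint
  if (params$n_beads == 3L && params$dim == 2L) {
    tri <- function(rad) {
      ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
      rad * cbind(cos(ang), sin(ang))
    }
    two_plus_one <- function(i, j) {
      k <- setdiff(1:3, c(i, j))
      p <- matrix(0, 3, 2)
      p[i, ] <- c(-0.4 * mid, 0.02 * mid)
      p[j, ] <- c(-0.4 * mid, -0.02 * mid)
      p[k, ] <- c(1.1 * mid, 0)
      p
    }
    list(tri(1.0 * mid), tri(0.25 * mid),
         two_plus_one(1, 2), two_plus_one(1, 3), two_plus_one(2, 3),
         rbind(c(-0.6 * mid, 0), c(0, 0.01 * mid), c(0.6 * mid, 0)))
  } else {
    lapply(seq_len(n_random), function(k) {
      matrix(stats::rnorm(params$n_beads * params$dim, sd = mid),
             params$n_beads, params$dim)
    })
  }
}

# optimal rotation (about the origin) aligning A to B: argmin over R in
# SO(d) of ||A R - B||_F, via SVD of A^T B with the determinant corrected.
# Proper rotations only: allowing reflections would identify mirror-image
# configurations, which collapses strings between bead-permuted endpoints
# (a two-bead swap of a triangle is a reflection).
procrustes_rotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    d <- ncol(R)
    R <- s$u %*% diag(c(rep(1, d - 1L), -1), d) %*% t(s$v)
  }
  R
}

#' Most probable transition path by the string method
#'
#' Discretises a path between two configurations into \code{n_images}
#' images and alternates (i) an explicit Euler relaxation of every interior
#' image under the chosen force field with (ii) reparametrisation to equal
#' arclength spacing, until the maximum image displacement per iteration
#' falls below \code{tol}.  For the rotation-equivariant bead force fields
#' each image is first aligned to its predecessor by an optimal orthogonal
#' rotation/reflection (Procrustes), which pins down the rotational gauge
#' the symmetric system leaves free; without it the string drifts along the
#' symmetry orbit.
#'
#' @param a,b endpoint configurations (position matrices or fixed points
#'   from [find_fixed_points()]).  Endpoints are held fixed, so they should
#'   be (near-)critical points of the field.
#' @param params a [bead_params()] object (may be NULL when \code{force} is
#'   a custom function on flattened coordinates).
#' @param force \code{"averaged"}, \code{"state"} (with \code{state}), or a
#'   function mapping a flattened coordinate vector to a drift vector.
#' @param state binding state for \code{force = "state"}.
#' @param n_images number of images including endpoints (default 64).
#' @param step_size Euler relaxation step.
#' @param tol convergence tolerance on the max image displacement per
#'   iteration.
#' @param max_iter iteration cap.
#' @param align logical: apply the Procrustes gauge (default TRUE for the
#'   model fields, FALSE for a custom force function).
#' @return A \code{"transition_path"}: list with \code{images} (n_images x
#'   n_coords matrix), \code{arclength} (cumulative, physical units),
#'   \code{s_norm} (arclength normalised to \[0, 1\]), \code{converged},
#'   \code{n_iter}, and the force specification.
#' @export
string_method <- function(a, b, params = NULL, force = "averaged",
                          state = NULL, n_images = 64L, step_size = 0.02,
                          tol = 1e-7, max_iter = 5000L,
                          align = !is.function(force)) {
  xa <- path_endpoint(a, params)
  xb <- path_endpoint(b, params)
  if (align && !is.null(params)) {
    # pre-align endpoint b to a so the initial interpolation is short
    A <- unflatten_positions(xb, params)
    B <- unflatten_positions(xa, params)
    xb <- flatten_positions(A %*% procrustes_rotation(A, B))
  }
  if (max(abs(xa - xb)) < 1e-12) stop("endpoints coincide")
  f <- force_function(params, force, state = state)
  n <- as.integer(n_images)
  stopifnot(n >= 3L)
  w <- seq(0, 1, length.out = n)
  X <- outer(1 - w, xa) + outer(w, xb)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    Xold <- X
    for (i in 2:(n - 1L)) X[i, ] <- X[i, ] + step_size * f(X[i, ])
    if (align && !is.null(params)) {
      for (i in 2:n) {
        A <- unflatten_positions(X[i, ], params)
        B <- unflatten_positions(X[i - 1L, ], params)
        X[i, ] <- flatten_positions(A %*% procrustes_rotation(A, B))
      }
    }
    X <- reparametrize_string(X)
    if (max(abs(X - Xold)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("string method did not converge in ", max_iter, " iterations")
  seg <- sqrt(rowSums((X[-1L, , drop = FALSE] - X[-n, , drop = FALSE])^2))
  if (any(seg < 1e-10)) stop("string collapse: adjacent images coincide")
  arc <- c(0, cumsum(seg))
  structure(list(images = X, arclength = arc, s_norm = arc / arc[n],
                 converged = converged, n_iter = iters, force = force,
                 state = state, params = params),
            class = "transition_path")
}

path_endpoint <- function(p, params) {
  if (is.list(p) && !is.null(p$positions)) p <- p$positions
  if (!is.null(params)) flatten_positions(as_configuration(p, params))
  else as.numeric(p)
}

# piecewise-linear reparametrisation of the images to equal arclength
reparametrize_string <- function(X) {
  n <- nrow(X)
  seg <- sqrt(rowSums((X[-1L, , drop = FALSE] - X[-n, , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  if (arc[n] == 0) return(X)
  target <- seq(0, arc[n], length.out = n)
  Xn <- X
  for (k in seq_len(ncol(X)))
    Xn[, k] <- stats::approx(arc, X[, k], xout = target, ties = "ordered")$y
  Xn
}

#' @export
print.transition_path <- function(x, ...) {
  cat(sprintf("transition path: %d images, length %.4g, %s after %d iterations\n",
              nrow(x$images), max(x$arclength),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Effective potential along a transition path
#'
#' Integrates the negative force along the path by the trapezoidal rule,
#' \deqn{U_{eff}(s) = -\int_0^s \langle v \rangle \cdot dx,}
#' gauge-fixed to zero at the first image.  The time-averaged field is not a
#' global gradient (its stationary weights depend on position), but along
#' the most probable transition path this line integral defines the
#' effective barrier entering the Arrhenius law.  On a closed loop the
#' integral need not return to zero; the discrepancy is the non-gradient
#' residual and is reported in the profile as \code{loop_residual} when the
#' path is closed.
#'
#' @param path a [string_method()] result (or any \code{"transition_path"}).
#' @param params a [bead_params()] object (defaults to the one stored in the
#'   path).
#' @param force force field specification, defaulting to the path's own.
#' @param state binding state for \code{force = "state"}.
#' @return A \code{"potential_profile"}: list with \code{s_norm},
#'   \code{arclength}, \code{values}, \code{barrier} (max value minus the
#'   starting value) and optionally \code{loop_residual}.
#' @export
effective_potential_along_path <- function(path, params = path$params,
                                           force = path$force,
                                           state = path$state) {
  f <- force_function(params, force, state = state)
  X <- path$images
  n <- nrow(X)
  F <- t(vapply(seq_len(n), function(i) f(X[i, ]), numeric(ncol(X))))
  u <- numeric(n)
  for (i in 2:n) {
    dx <- X[i, ] - X[i - 1L, ]
    u[i] <- u[i - 1L] - 0.5 * sum((F[i, ] + F[i - 1L, ]) * dx)
  }
  out <- list(s_norm = path$s_norm, arclength = path$arclength,
              values = u, barrier = max(u) - u[1L])
  if (max(abs(X[n, ] - X[1L, ])) < 1e-8) out$loop_residual <- u[n] - u[1L]
  structure(out, class = "potential_profile")
}

#' @export
print.potential_profile <- function(x, ...) {
  cat(sprintf("potential profile over %d images: barrier %.6g\n",
              length(x$values), x$barrier))
  invisible(x)
}

#' Polish the saddle point of a converged string
#'
#' Takes the maximum-energy interior image of a path and Newton-polishes it
#' to a root of the force field (truncated-SVD pseudo-inverse of the
#' finite-difference Jacobian, so the rotational zero mode is harmless:
#' unlike a least-squares descent this converges to the nearest critical
#' point of any index rather than sliding downhill to a minimum).  Verifies
#' that exactly one Jacobian direction has positive real part.
#'
#' @inheritParams effective_potential_along_path
#' @return A classified critical point (see [find_fixed_points()]).
#' @export
refine_saddle <- function(path, params = path$params, force = path$force,
                          state = path$state) {
  f <- force_function(params, force, state = state)
  prof <- effective_potential_along_path(path, params, force, state)
  i <- which.max(prof$values)
  x <- newton_root(f, path$images[i, ])
  res <- max(abs(f(x)))
  fp <- classify_critical_point(x, params, f, residual = res,
                                converged = res < 1e-6)
  if (fp$n_unstable != 1L)
    warning("refined saddle has ", fp$n_unstable,
            " unstable directions (expected 1)")
  fp
}

# damped Newton iteration with a truncated-SVD pseudo-inverse (tolerates
# the rotational null direction of the radially symmetric force fields)
newton_root <- function(f, x, max_iter = 80L, tol = 1e-12,
                        step_cap = 0.25) {
  for (it in seq_len(max_iter)) {
    v <- f(x)
    if (max(abs(v)) < tol) break
    J <- fd_jacobian(f, x)
    s <- svd(J)
    keep <- s$d > 1e-8 * max(s$d)
    dx <- s$v[, keep, drop = FALSE] %*%
      ((t(s$u[, keep, drop = FALSE]) %*% v) / s$d[keep])
    dx <- -as.vector(dx)
    nrm <- sqrt(sum(dx^2))
    if (nrm > step_cap) dx <- dx * step_cap / nrm
    x <- x + dx
  }
  x
}

#' Canonical transition paths of the 3-bead landscape
#'
#' Builds the uphill (minimum-to-saddle) most-probable transition paths of
#' the time-averaged field that organise cluster kinetics:
#' \describe{
#'   \item{\code{"two-bead-exit"}}{from the 2-bead cluster (beads 1-2
#'     bound, bead 3 far) to the exit saddle where bead 3 has approached
#'     the pair.  This saddle is shared by the transitions toward the
#'     3-bead cluster and onward toward a different 2-bead cluster, which
#'     is why those transitions have similar uphill pathways and barrier
#'     heights.}
#'   \item{\code{"three-to-two"}}{from the 3-bead cluster up to the same
#'     exit saddle: the escape of one bead from the cluster, the deepest
#'     and most timescale-sensitive transition.}
#'   \item{\code{"three-to-collinear"}}{from the 3-bead cluster to the
#'     collinear saddle mediating within-cluster rearrangement (bead
#'     exchange without anyone leaving).}
#'   \item{\code{"two-to-two"}}{the full minimum-to-minimum path between
#'     two different 2-bead clusters (passes the exit saddle, the 3-bead
#'     basin, and the mirror saddle); its profile shows the full
#'     double-barrier structure.}
#' }
#' Saddles are located by refining minimum-to-minimum strings and the
#' uphill paths are then re-strung between the minimum and the polished
#' saddle.  Results are cached per parameter set.
#'
#' @param params a 3-bead [bead_params()] object.
#' @param which transition name (see above).
#' @param n_images images for the returned path.
#' @param tol string convergence tolerance.
#' @return A \code{"transition_path"}.
#' @export
canonical_transition <- function(params,
                                 which = c("two-bead-exit", "three-to-two",
                                           "three-to-collinear",
                                           "two-to-two"),
                                 n_images = 64L, tol = 1e-7) {
  which <- match.arg(which)
  key <- cache_key("path", normalize_landscape_params(params),
                   paste(which, n_images, tol))
  if (!is.null(.sb_cache[[key]])) return(.sb_cache[[key]])
  cp <- landscape_critical_points(params, tol = tol)
  pos2 <- orient_two_bead(cp$two_bead$positions, 1L, 2L)
  out <- switch(which,
    "two-bead-exit" = string_method(pos2, cp$exit_saddle$positions, params,
                                    n_images = n_images, tol = tol),
    "three-to-two" = string_method(cp$three_bead$positions,
                                   cp$exit_saddle$positions, params,
                                   n_images = n_images, tol = tol),
    "three-to-collinear" = string_method(cp$three_bead$positions,
                                         cp$collinear_saddle$positions,
                                         params, n_images = n_images,
                                         tol = tol),
    "two-to-two" = string_method(pos2,
                                 orient_two_bead(cp$two_bead$positions,
                                                 1L, 3L),
                                 params, n_images = n_images, tol = tol)
  )
  .sb_cache[[key]] <- out
  out
}

# the averaged field (and so every critical point and path) is invariant
# to the switching timescale, the noise scale and the scaling exponent;
# cache on the normalized parameter set so escape experiments at many
# (alpha, epsilon) share one calibration
normalize_landscape_params <- function(params) {
  params$timescale <- 1
  params$epsilon <- 1
  params$scaling_exponent <- 1L
  params
}

#' Critical points of the 3-bead averaged field
#'
#' Finds and caches the minima (unbound triangle, 2-bead cluster, 3-bead
#' cluster) via [find_fixed_points()] and the two saddles (cluster-exit
#' saddle and collinear rearrangement saddle) via minimum-to-minimum
#' strings polished by Newton iteration.
#'
#' @param params a 3-bead [bead_params()] object.
#' @param n_images images for the saddle-locating strings.
#' @param tol string convergence tolerance.
#' @return List with \code{unbound}, \code{two_bead}, \code{three_bead},
#'   \code{exit_saddle}, \code{collinear_saddle} (classified critical
#'   points) and \code{fixed_points} (the raw list).
#' @export
landscape_critical_points <- function(params, n_images = 48L, tol = 1e-7) {
  if (params$n_beads != 3L || params$dim != 2L)
    stop("the canonical landscape is defined for the planar 3-bead model")
  key <- cache_key("cp", normalize_landscape_params(params), n_images)
  if (!is.null(.sb_cache[[key]])) return(.sb_cache[[key]])
  fps <- find_fixed_points(params)
  labs <- vapply(fps, `[[`, character(1L), "label")
  need <- c("unbound-triangle", "two-bead-cluster", "three-bead-cluster")
  if (!all(need %in% labs))
    stop("averaged field lacks the cluster fixed-point structure (found: ",
         paste(labs, collapse = ", "),
         "); a contact-like affinity such as preset \"landscape-3bead\" ",
         "is required")
  fp_of <- function(lab) fps[[which(labs == lab)[1L]]]
  fpu <- fp_of("unbound-triangle")
  fp2 <- fp_of("two-bead-cluster")
  fp3 <- fp_of("three-bead-cluster")
  # exit saddle from the 2-bead -> 3-bead minimum-to-minimum string
  p23 <- string_method(orient_two_bead(fp2$positions, 1L, 2L),
                       fp3$positions, params, n_images = n_images,
                       tol = tol)
  s_exit <- refine_saddle(p23)
  # collinear saddle from the bead-swap rearrangement string
  p3a <- fp3$positions
  pswap <- string_method(p3a, p3a[c(2L, 1L, 3L), ], params,
                         n_images = n_images, tol = tol)
  s_col <- refine_saddle(pswap)
  out <- list(unbound = fpu, two_bead = fp2, three_bead = fp3,
              exit_saddle = s_exit, collinear_saddle = s_col,
              fixed_points = fps)
  .sb_cache[[key]] <- out
  out
}

cache_key <- function(prefix, params, extra = "") {
  key <- paste(c(vapply(unclass(params), format, character(1L),
                        digits = 15), format(extra)), collapse = "|")
  paste0(prefix, "_", substr(digest_chr(key), 1, 24))
}
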