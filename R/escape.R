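#' Basin-classification thresholds for the planar 3-bead model
#'
#' Builds the geometric thresholds used by [detect_basin()] from the
#' model's own critical points: the fixed points of the time-averaged
#' drift and the two saddles reached from them (the cluster-exit saddle
#' and the collinear saddle of within-cluster rearrangement).  Membership
#' thresholds sit 40% of the way from each minimum's geometry toward the
#' exit saddle (the basin boundary), so the classifier never fires on
#' configurations that have merely rattled around a minimum.  Results are
#' cached per parameter set (the landscape is invariant to the switching
#' timescale and noise scale).
#'
#' @param params a 3-bead [bead_params()] object.
#' @param tol string-method tolerance for the calibration paths.
#' @return List with the threshold vector \code{thr} (tri, close, far,
#'   collinearity score, spread, unbound distance), the critical points,
#'   and the classified \code{fixed_points}.
#' @export
calibrate_basins <- function(params, tol = 1e-6) {
  key <- cache_key("cal", normalize_landscape_params(params))
  if (!is.null(.sb_cache[[key]])) return(.sb_cache[[key]])
  cp <- landscape_critical_points(params, tol = tol)
  d2 <- cp$two_bead$pair_distances
  d3 <- cp$three_bead$pair_distances
  dex <- cp$exit_saddle$pair_distances
  dcol <- cp$collinear_saddle$pair_distances
  d_unb <- mean(cp$unbound$pair_distances)
  thr <- c(
    # compact 3-bead cluster: largest distance 40% of the way from the
    # cluster geometry to the exit saddle, the boundary of the cluster
    # basin (the collinear saddle is interior to the cluster label: both
    # of its downhill ends are 3-bead clusters)
    tri = unname(d3[3] + 0.4 * (dex[3] - d3[3])),
    # a "bound pair" exists while the closest distance is well below the
    # unbound scale (the exit saddle keeps the pair intact, so the pair
    # feature is contrasted with pair dissolution, not with that saddle)
    close = unname(0.4 * d_unb),
    # the third bead is "far" when it is beyond 40% of the way back from
    # the 2-bead minimum to the exit saddle geometry
    far = unname(d2[2] - 0.4 * (d2[2] - dex[2])),
    # collinear rearrangement saddle: near-zero area score with a spread
    # beyond 40% of the way from the cluster core to that saddle
    col = 0.02,
    col_lo = unname(d3[3] + 0.4 * (dcol[3] - d3[3])),
    d_unb = d_unb
  )
  out <- list(thr = thr, critical_points = cp,
              fixed_points = cp$fixed_points)
  .sb_cache[[key]] <- out
  out
}

.sb_cache <- new.env(parent = emptyenv())

# md5 of a character string (via a temp file; tools::md5sum is file-based)
digest_chr <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

# place the two-bead fixed point so that beads i and j form the cluster
orient_two_bead <- function(pos, i, j) {
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  close_pair <- sort(which(d == min(d), arr.ind = TRUE)[1L, ])
  far <- setdiff(1:3, close_pair)
  out <- pos
  out[i, ] <- pos[close_pair[1L], ]
  out[j, ] <- pos[close_pair[2L], ]
  out[setdiff(1:3, c(i, j)), ] <- pos[far, ]
  out
}

#' Classify a 3-bead configuration into a basin
#'
#' Labels a configuration by the basin of attraction it sits in, using the
#' sorted pairwise distances (d1 <= d2 <= d3) and a collinearity score
#' (triangle area / d3^2), checked in order: \code{"two-bead-i-j"} when
#' one pair is close and the third bead far; \code{"collinear"} when
#' nearly collinear and spread beyond the cluster core (the rearrangement
#' saddle's signature); \code{"three-bead"} when all beads are within the
#' cluster threshold; \code{"unbound-triangle"} when all distances are
#' within 10% of the unbound fixed-point distance; \code{"transit"}
#' otherwise.  Invariant to rotations, reflections, and (up to pair
#' relabelling) bead permutations.
#'
#' @param positions 3 x 2 position matrix.
#' @param bonds ignored (classification is geometric); kept for interface
#'   symmetry with the simulator.
#' @param params a [bead_params()] object.
#' @param calibration output of [calibrate_basins()] (computed and cached
#'   if missing).
#' @return Character label.
#' @export
detect_basin <- function(positions, bonds = NULL, params,
                         calibration = calibrate_basins(params)) {
  positions <- as_configuration(positions, params)
  code <- classify3_cpp(matrix(flatten_positions(positions), 1L),
                        calibration$thr)
  basin_label(code)
}

basin_label <- function(code) {
  labs <- c("transit", "unbound-triangle", "two-bead-1-2", "two-bead-1-3",
            "two-bead-2-3", "three-bead", "collinear")
  labs[code + 1L]
}

#' Monte-Carlo escape-time experiment
#'
#' Launches \code{n_runs} trajectories at a cluster fixed point of the
#' 3-bead model (initial bonds drawn from the CTMC stationary distribution
#' at that geometry), integrates the hybrid dynamics, and records the
#' first time each run settles into a different basin (a non-transit,
#' non-start label held for \code{dwell} consecutive checks).  Runs that
#' exhaust \code{max_time} are censored: their elapsed time still counts
#' as exposure.  The mean escape time is the maximum-likelihood estimate
#' \code{tau_hat = (sum of all escape times) / (number of runs executing
#' the designated transition)}.
#'
#' From the 2-bead cluster the designated targets are the other 2-bead
#' clusters and/or the 3-bead cluster; from the 3-bead cluster, a 2-bead
#' cluster or the collinear configuration.
#'
#' @param start \code{"two-bead"} or \code{"three-bead"}.
#' @param targets character vector of target labels counted as the
#'   designated transition (default: the full stopping set of the start).
#' @param stop_labels labels at which a run ends (default: from the 2-bead
#'   cluster, a different 2-bead cluster or the 3-bead cluster; from the
#'   3-bead cluster, a 2-bead cluster or the collinear rearrangement
#'   saddle; the unbound basin always ends a run).  Narrowing this set
#'   turns the experiment into a designated-transition first-passage
#'   measurement (e.g. bead release from the 3-bead cluster, ignoring
#'   collinear rearrangements).
#' @param params a 3-bead [bead_params()] object.
#' @param epsilon,alpha noise scale and binding timescale for this
#'   experiment (default: taken from \code{params}).
#' @param n_runs number of independent runs.
#' @param max_time per-run time budget (default \code{1e4 / alpha}).
#' @param seed optional RNG seed.
#' @param dt timestep (default resolves the fastest event rate).
#' @param check_every basin check interval in steps.
#' @param dwell consecutive checks required to accept a basin change.
#' @return An \code{"escape_result"}; see [escape_result()].
#' @export
escape_experiment <- function(start = c("two-bead", "three-bead"),
                              targets = NULL, stop_labels = NULL, params,
                              epsilon = params$epsilon,
                              alpha = params$timescale,
                              n_runs = 500L, max_time = 1e4 / alpha,
                              seed = NULL, dt = NULL, check_every = 10L,
                              dwell = 10L) {
  start <- match.arg(start)
  par <- params
  par$epsilon <- epsilon
  par$timescale <- alpha
  cal <- calibrate_basins(par)
  if (!is.null(seed)) set.seed(seed)
  labs <- vapply(cal$fixed_points, `[[`, character(1L), "label")
  fp <- cal$fixed_points[[which(labs == switch(start,
    "two-bead" = "two-bead-cluster", "three-bead" = "three-bead-cluster"))[1L]]]
  pos0 <- if (start == "two-bead") orient_two_bead(fp$positions, 1L, 2L)
          else fp$positions
  start_label <- if (start == "two-bead") 2L else 5L
  # the stopping conditions of the experiment: from the 2-bead cluster the
  # run ends at a different 2-bead cluster or the 3-bead cluster; from the
  # 3-bead cluster, at a 2-bead cluster or the collinear rearrangement
  # saddle (the unbound basin also ends a run if reached)
  stop_set <- if (!is.null(stop_labels)) stop_labels
  else if (start == "two-bead")
    c("two-bead-1-3", "two-bead-2-3", "three-bead", "unbound-triangle")
  else c("two-bead-1-2", "two-bead-1-3", "two-bead-2-3", "collinear",
         "unbound-triangle")
  if (is.null(targets)) {
    targets <- if (start == "two-bead")
      c("two-bead-1-3", "two-bead-2-3", "three-bead")
    else c("two-bead-1-2", "two-bead-1-3", "two-bead-2-3", "collinear")
  }
  R <- rate_multiplier(par)
  if (is.null(dt))
    dt <- min(1e-3, 0.1 / (R * max(par$affinity_amplitude, par$c_break)))
  states <- enumerate_states(3L)
  S <- transition_rate_matrix(pos0, par, states)
  probs <- stationary_distribution(S)
  sp <- t(vapply(states, function(s) {
    p <- unclass(s); p[is.na(p)] <- 0L; p
  }, integer(3L)))
  labels_all <- c("transit", "unbound-triangle", "two-bead-1-2",
                  "two-bead-1-3", "two-bead-2-3", "three-bead", "collinear")
  stop_codes <- match(stop_set, labels_all) - 1L
  out <- escape_runs_cpp(pos0, unclass(par), dt, R, max_time,
                         as.integer(check_every), as.integer(dwell),
                         cal$thr, start_label, as.integer(stop_codes),
                         as.integer(n_runs), probs, sp)
  outcome <- ifelse(out$labels < 0L, "censored", basin_label(pmax(out$labels, 0L)))
  escape_result(times = out$times, outcomes = outcome, targets = targets,
                epsilon = epsilon, alpha = alpha, start = start,
                max_time = max_time, dt = dt)
}

#' Escape-time result and its MLE mean
#'
#' Bundles per-run escape times and outcome labels; \code{tau_hat} is the
#' maximum-likelihood mean escape time, the sum of all recorded times
#' (censored exposure included) divided by the number of runs executing
#' the designated transition.  An error is raised when no run succeeds.
#'
#' @param times numeric vector of per-run times.
#' @param outcomes character vector of outcome labels (\code{"censored"}
#'   for runs that hit the time budget).
#' @param targets labels counted as the designated transition.
#' @param epsilon,alpha experiment conditions (optional metadata).
#' @param start,max_time,dt further metadata.
#' @return An object of class \code{"escape_result"} with fields
#'   \code{times}, \code{outcomes}, \code{targets}, \code{n_runs},
#'   \code{n_success}, \code{tau_hat}, \code{epsilon}, \code{alpha}.
#' @export
escape_result <- function(times, outcomes, targets, epsilon = NA_real_,
                          alpha = NA_real_, start = NA_character_,
                          max_time = NA_real_, dt = NA_real_) {
  stopifnot(length(times) == length(outcomes), all(times >= 0))
  n_success <- sum(outcomes %in% targets)
  if (n_success == 0L)
    stop("no successful transitions: tau_hat is undefined")
  structure(list(times = times, outcomes = outcomes, targets = targets,
                 n_runs = length(times), n_success = n_success,
                 tau_hat = sum(times) / n_success,
                 epsilon = epsilon, alpha = alpha, start = start,
                 max_time = max_time, dt = dt),
            class = "escape_result")
}

#' @export
print.escape_result <- function(x, ...) {
  cat(sprintf(
    "escape experiment: %d runs, %d to target, tau_hat = %.4g (eps=%g, alpha=%g)\n",
    x$n_runs, x$n_success, x$tau_hat, x$epsilon, x$alpha))
  invisible(x)
}

#' Arrhenius fit of escape times over a noise grid
#'
#' Ordinary least squares of \code{log(tau_hat)} on \code{1/epsilon}
#' across escape experiments: the fitted slope is the empirical effective
#' energy barrier, comparable to the quasipotential barrier height.
#'
#' @param results list of \code{"escape_result"} objects at three or more
#'   distinct epsilon values.
#' @return List with \code{slope}, \code{intercept}, \code{stderr} (of the
#'   slope) and the underlying \code{data} frame.
#' @export
arrhenius_fit <- function(results) {
  if (length(results) < 3L)
    stop("arrhenius_fit needs at least 3 epsilon values")
  eps <- vapply(results, `[[`, numeric(1L), "epsilon")
  tau <- vapply(results, `[[`, numeric(1L), "tau_hat")
  if (length(unique(eps)) < 3L)
    stop("arrhenius_fit needs at least 3 distinct epsilon values")
  d <- data.frame(inv_eps = 1 / eps, log_tau = log(tau))
  fit <- stats::lm(log_tau ~ inv_eps, data = d)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(stats::coef(fit)["inv_eps"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       stderr = unname(sm["inv_eps", "Std. Error"]),
       data = d)
}
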