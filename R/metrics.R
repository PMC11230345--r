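#' Cluster detection by distance connectivity
#'
#' Partitions beads into the connected components of the graph whose edges
#' join beads closer than \code{r_cluster}; components of size >= 3 are
#' reported as clusters.  The default radius is the affinity midpoint, the
#' separation at which the binding rate is half-maximal.
#'
#' @param positions position matrix.
#' @param r_cluster connection radius (> 0).
#' @param min_size minimum component size counted as a cluster.
#' @return List with \code{membership} (component id per bead, ids ordered
#'   by smallest member), and \code{clusters} (list of bead index vectors,
#'   size >= min_size, in membership order).
#' @export
find_clusters <- function(positions, r_cluster, min_size = 3L) {
  stopifnot(r_cluster > 0)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  adj <- as.matrix(stats::dist(positions)) < r_cluster
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel components deterministically by their smallest member
  first <- tapply(seq_len(n), comp, min)
  relab <- rank(first)
  membership <- as.integer(relab[comp])
  sizes <- tabulate(membership)
  big <- which(sizes >= min_size)
  clusters <- lapply(big, function(k) which(membership == k))
  list(membership = membership, clusters = clusters)
}

# neighbor sets within r_near at a given frame (list of integer vectors)
neighbor_sets <- function(pos, r_near) {
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  lapply(seq_len(nrow(pos)), function(i) which(d[i, ] < r_near))
}

#' Mixing coefficient of a trajectory
#'
#' Mean neighbor-set turnover: for every bead and frame pair (t, t + lag)
#' compute one minus the Jaccard similarity of the bead's neighbor sets
#' (beads within \code{r_near}), then average over beads and frames.
#' Beads with empty neighbor sets at both frames carry no information and
#' are excluded.  0 means frozen neighborhoods (rigid clusters), 1 means
#' complete turnover every lag.
#'
#' @param traj a \code{"switching_trajectory"}.
#' @param lag lag in frames (integer >= 1).
#' @param r_near neighbor radius (defaults to the affinity midpoint).
#' @return Scalar in \[0, 1\].
#' @export
mixing_coefficient <- function(traj, lag,
                               r_near = traj$params$affinity_midpoint) {
  nf <- n_frames(traj)
  lag <- as.integer(lag)
  if (lag < 1L || lag >= nf) stop("lag must be in [1, n_frames - 1]")
  tot <- 0; cnt <- 0L
  sets_prev <- vector("list", nf)
  for (t in seq_len(nf - lag)) {
    if (is.null(sets_prev[[t]]))
      sets_prev[[t]] <- neighbor_sets(frame_positions(traj, t), r_near)
    if (is.null(sets_prev[[t + lag]]))
      sets_prev[[t + lag]] <- neighbor_sets(frame_positions(traj, t + lag),
                                            r_near)
    a <- sets_prev[[t]]; b <- sets_prev[[t + lag]]
    for (i in seq_along(a)) {
      u <- length(union(a[[i]], b[[i]]))
      if (u == 0L) next
      tot <- tot + 1 - length(intersect(a[[i]], b[[i]])) / u
      cnt <- cnt + 1L
    }
    sets_prev[t] <- list(NULL)  # free memory behind the sliding window
  }
  if (cnt == 0L) stop("no bead-frame pairs with nonempty neighbor sets")
  tot / cnt
}

#' Average number of nearby beads
#'
#' Mean over beads and frames of the count of other beads within
#' \code{r_near}.
#'
#' @inheritParams mixing_coefficient
#' @return Nonnegative scalar.
#' @export
avg_nearby_beads <- function(traj,
                             r_near = traj$params$affinity_midpoint) {
  nf <- n_frames(traj)
  tot <- 0
  for (t in seq_len(nf)) {
    d <- as.matrix(stats::dist(frame_positions(traj, t)))
    diag(d) <- Inf
    tot <- tot + mean(rowSums(d < r_near))
  }
  tot / nf
}

#' Unbound and out-of-cluster fractions
#'
#' \code{unbound_fraction} is the fraction of frames in which no bond
#' exists (the s = 1 state of the CTMC); with \code{per_bead = TRUE} it is
#' instead the mean fraction of beads without a bond, the many-bead
#' analogue.  \code{not_in_cluster_fraction} is, for the 3-bead model, the
#' fraction of frames not classified in a cluster basin by
#' [detect_basin()]; for larger systems, the mean fraction of beads not in
#' any size >= 3 cluster.
#'
#' @param traj a \code{"switching_trajectory"}.
#' @param per_bead see description.
#' @param r_cluster cluster radius for the many-bead path.
#' @return Scalar in \[0, 1\].
#' @export
unbound_fraction <- function(traj, per_bead = traj$params$n_beads > 8L) {
  unb <- traj$partners == 0L
  if (per_bead) mean(unb) else mean(rowSums(!unb) == 0L)
}

#' @rdname unbound_fraction
#' @export
not_in_cluster_fraction <- function(traj,
                                    r_cluster = traj$params$affinity_midpoint) {
  if (traj$params$n_beads == 3L && traj$params$dim == 2L) {
    cal <- calibrate_basins(traj$params)
    codes <- classify3_cpp(traj$positions, cal$thr)
    mean(!(codes %in% c(2L, 3L, 4L, 5L)))
  } else {
    nf <- n_frames(traj)
    tot <- 0
    for (t in seq_len(nf)) {
      fc <- find_clusters(frame_positions(traj, t), r_cluster)
      incl <- unlist(fc$clusters)
      tot <- tot + 1 - length(incl) / traj$params$n_beads
    }
    tot / nf
  }
}

#' Mean unbound time and unbound diffusion distance
#'
#' \code{mean_unbound_time} is the mean duration of maximal intervals
#' during which a bead has no bond, over all beads (intervals truncated by
#' the start or end of the recording are censored and excluded).
#' \code{unbound_diffusion_distance} converts it into the typical distance
#' a bead diffuses while unbound, \code{sqrt(prefactor * epsilon *
#' T_unbound)} with the prefactor defaulting to the spatial dimension.
#'
#' @param traj a \code{"switching_trajectory"}.
#' @param params a [bead_params()] object.
#' @param T_unbound mean unbound time.
#' @param prefactor multiplier inside the radical (default \code{dim}).
#' @return Scalar.
#' @export
mean_unbound_time <- function(traj) {
  unb <- traj$partners == 0L
  nf <- nrow(unb)
  if (nf < 3L) stop("trajectory too short to measure unbound intervals")
  dtf <- traj$dt * traj$record_every
  durs <- numeric(0)
  for (i in seq_len(ncol(unb))) {
    r <- rle(unb[, i])
    k <- length(r$lengths)
    if (k >= 3L) {
      inner <- 2:(k - 1L)
      sel <- inner[r$values[inner]]
      if (length(sel)) durs <- c(durs, r$lengths[sel] * dtf)
    }
  }
  if (!length(durs)) stop("no completed unbound intervals observed")
  mean(durs)
}

#' @rdname mean_unbound_time
#' @export
unbound_diffusion_distance <- function(params, T_unbound,
                                       prefactor = params$dim) {
  stopifnot(T_unbound > 0, prefactor > 0)
  sqrt(prefactor * params$epsilon * T_unbound)
}

#' Persistent clusters in a trajectory
#'
#' Tracks size >= 3 clusters across frames: clusters in consecutive frames
#' are the same object when their memberships overlap by at least
#' \code{overlap} (Jaccard).  Returns the lifetime of every tracked
#' cluster chain, used to distinguish transient density fluctuations from
#' persistent clusters.
#'
#' @param traj a \code{"switching_trajectory"}.
#' @param r_cluster connection radius.
#' @param overlap minimum Jaccard overlap to continue a chain.
#' @param max_gap frames a chain may go unmatched (a cluster flickering at
#'   the detection boundary, e.g. its third bead stepping briefly out of
#'   range) before it is closed; the lifetime still counts only to the
#'   last matched frame.
#' @return Numeric vector of chain lifetimes (time units); empty when no
#'   size >= 3 cluster ever forms.
#' @export
cluster_lifetimes <- function(traj,
                              r_cluster = traj$params$affinity_midpoint,
                              overlap = 0.5, max_gap = 2L) {
  nf <- n_frames(traj)
  dtf <- traj$dt * traj$record_every
  active <- list()   # each: list(members, t0, last, gap)
  done <- numeric(0)
  for (t in seq_len(nf)) {
    cl <- find_clusters(frame_positions(traj, t), r_cluster)$clusters
    matched <- rep(FALSE, length(cl))
    nxt <- list()
    for (a in active) {
      best <- 0; bi <- 0L
      for (k in seq_along(cl)) {
        if (matched[k]) next
        jac <- length(intersect(a$members, cl[[k]])) /
          length(union(a$members, cl[[k]]))
        if (jac > best) { best <- jac; bi <- k }
      }
      if (bi > 0L && best >= overlap) {
        matched[bi] <- TRUE
        nxt[[length(nxt) + 1L]] <- list(members = cl[[bi]], t0 = a$t0,
                                        last = (t - 1L) * dtf, gap = 0L)
      } else if (a$gap < max_gap) {
        nxt[[length(nxt) + 1L]] <- list(members = a$members, t0 = a$t0,
                                        last = a$last, gap = a$gap + 1L)
      } else {
        done <- c(done, a$last - a$t0)
      }
    }
    for (k in which(!matched))
      nxt[[length(nxt) + 1L]] <- list(members = cl[[k]],
                                      t0 = (t - 1L) * dtf,
                                      last = (t - 1L) * dtf, gap = 0L)
    active <- nxt
  }
  if (length(active))
    done <- c(done, vapply(active, function(a) a$last - a$t0, numeric(1L)))
  done
}

#' Clustering-regime sweep over the binding timescale
#'
#' Runs one many-bead simulation per value of the binding timescale beta
#' and tabulates the regime metrics: per-bead unbound fraction, mixing
#' coefficient, average nearby beads, out-of-cluster fraction, mean
#' unbound time, unbound diffusion distance, and cluster persistence
#' (count of size >= 3 clusters outliving 10 single-bond lifetimes, and
#' the maximum lifetime).  Slow binding gives the amorphic regime (no
#' persistent clusters, everything unbound); fast binding gives rigid,
#' slowly changing clusters; intermediate timescales give flexible
#' clusters that exchange beads.
#'
#' @param params a many-bead [bead_params()] object (e.g.
#'   \code{preset_params("reduced-100")}).
#' @param beta_grid vector of binding-timescale values.
#' @param T simulation duration per beta.
#' @param seed RNG seed (one stream per beta, derived deterministically).
#' @param n_record target number of recorded frames per run (the recording
#'   stride adapts to the per-beta timestep).
#' @param burn_in_frac fraction of the run discarded before computing
#'   metrics, letting the cloud relax from the initial placement (the
#'   confinement relaxation time is 1/eta, a substantial fraction of
#'   desk-scale runs).
#' @param lag_time mixing-coefficient lag in time units (default T/10,
#'   measured on the post-burn-in window).
#' @param r_near,r_cluster radii (default: affinity midpoint).
#' @return data.frame with one row per beta.
#' @export
regime_sweep <- function(params, beta_grid, T, seed = 1L,
                         n_record = 1200L, burn_in_frac = 0.25,
                         lag_time = T / 10,
                         r_near = params$affinity_midpoint,
                         r_cluster = params$affinity_midpoint) {
  rows <- vector("list", length(beta_grid))
  init <- default_initial(params, seed = seed)
  for (k in seq_along(beta_grid)) {
    beta <- beta_grid[k]
    par <- params
    par$timescale <- beta
    dt <- default_dt(par)
    record_every <- max(1L, ceiling(T / dt / n_record))
    traj <- simulate_beads(par, T, dt = dt, seed = seed + k,
                           initial = init, record_every = record_every)
    traj <- truncate_trajectory(traj, burn_in_frac)
    dtf <- dt * record_every
    lag <- max(1L, round(lag_time / dtf))
    bond_life <- 1 / (rate_multiplier(par) * par$c_break)
    lt <- cluster_lifetimes(traj, r_cluster)
    tu <- tryCatch(mean_unbound_time(traj), error = function(e) NA_real_)
    rows[[k]] <- data.frame(
      beta = beta, dt = dt, T = T,
      unbound_fraction = unbound_fraction(traj, per_bead = TRUE),
      mixing_coefficient = mixing_coefficient(traj, lag, r_near),
      avg_nearby_beads = avg_nearby_beads(traj, r_near),
      not_in_cluster_fraction = not_in_cluster_fraction(traj, r_cluster),
      mean_unbound_time = tu,
      diffusion_distance = if (is.na(tu)) NA_real_
        else unbound_diffusion_distance(par, tu),
      n_persistent_clusters = sum(lt >= 10 * bond_life),
      max_cluster_lifetime = if (length(lt)) max(lt) else 0
    )
  }
  do.call(rbind, rows)
}

# drop the first fraction of recorded frames (equilibration burn-in)
truncate_trajectory <- function(traj, frac) {
  if (frac <= 0) return(traj)
  nf <- n_frames(traj)
  keep <- seq.int(max(1L, floor(nf * frac)), nf)
  traj$times <- traj$times[keep]
  traj$positions <- traj$positions[keep, , drop = FALSE]
  traj$partners <- traj$partners[keep, , drop = FALSE]
  traj
}
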