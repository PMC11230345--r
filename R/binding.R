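#' Binding states (crosslink matchings)
#'
#' The crosslink state of the system is a matching on the beads: each bead is
#' bound to at most one partner.  It is stored as an integer partner vector
#' of length \code{n_beads} with \code{partner[i]} the index bound to bead
#' \code{i} and \code{NA} for unbound, satisfying the involution
#' \code{partner[partner[i]] == i}.
#'
#' @param partner integer vector (NA = unbound), or a 2-column matrix of
#'   bead pairs via \code{bonds_from_pairs}.
#' @param n_beads number of beads.
#' @return An integer partner vector of class \code{"binding_state"}.
#' @export
binding_state <- function(partner, n_beads = length(partner)) {
  as_binding_state(partner, n_beads)
}

#' @rdname binding_state
#' @export
as_binding_state <- function(partner, n_beads) {
  p <- as.integer(partner)
  if (length(p) != n_beads)
    stop("partner vector must have length n_beads")
  b <- which(!is.na(p))
  if (length(b)) {
    if (any(p[b] < 1L | p[b] > n_beads))
      stop("bond references an out-of-range bead index")
    if (any(p[b] == b))
      stop("a bead cannot be bound to itself")
    if (any(p[p[b]] != b))
      stop("partner vector is not an involution (invalid matching)")
  }
  structure(p, class = "binding_state")
}

#' @rdname binding_state
#' @param pairs 2-column matrix/data.frame of bead index pairs (one row per
#'   bond); zero rows give the all-unbound state.
#' @export
bonds_from_pairs <- function(pairs, n_beads) {
  p <- rep(NA_integer_, n_beads)
  if (!is.null(pairs) && NROW(pairs) > 0L) {
    pairs <- as.matrix(pairs)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (!is.na(p[i]) || !is.na(p[j]))
        stop("pairs share a bead: not a matching")
      p[i] <- as.integer(j); p[j] <- as.integer(i)
    }
  }
  as_binding_state(p, n_beads)
}

#' @rdname binding_state
#' @param bonds a binding state.
#' @export
bond_pairs <- function(bonds) {
  i <- which(!is.na(unclass(bonds)))
  i <- i[i < bonds[i]]
  cbind(i = i, j = as.integer(bonds[i]))
}

#' Enumerate all binding states
#'
#' Lists every matching of \code{n_beads} beads (all sets of disjoint bound
#' pairs).  The count is the telephone number of n: 2, 4, 10, 26, 76, ...
#' for n = 2, 3, 4, 5, 6.  The first state is always the all-unbound state;
#' states are ordered by number of bonds, then lexicographically by their
#' sorted pair lists, so state indices are stable across runs.  For the
#' 3-bead system this gives the four states: unbound, 1-2 bound, 1-3 bound,
#' 2-3 bound.
#'
#' Enumeration grows super-exponentially; beyond \code{max_beads} the
#' analysis path is infeasible and only the simulation path (which never
#' enumerates, see [sample_events()]) applies.
#'
#' @param n_beads number of beads.
#' @param max_beads enumeration cap (default 8).
#' @return List of \code{"binding_state"} partner vectors.
#' @export
enumerate_states <- function(n_beads, max_beads = 8L) {
  n_beads <- as.integer(n_beads)
  stopifnot(n_beads >= 1L)
  if (n_beads > max_beads)
    stop("enumeration infeasible for ", n_beads,
         " beads (cap ", max_beads, "); use the simulation path instead")
  # grow matchings by either leaving the smallest available bead unbound or
  # pairing it with each larger available bead; every matching arises once
  grow <- function(avail, pairs) {
    if (length(avail) < 2L) return(list(pairs))
    i <- avail[1L]
    out <- list()
    # bead i stays unbound in this matching
    out <- c(out, grow(avail[-1L], pairs))
    for (j in avail[-1L]) {
      out <- c(out, grow(setdiff(avail, c(i, j)), rbind(pairs, c(i, j))))
    }
    out
  }
  all_pairs <- grow(seq_len(n_beads), matrix(integer(), 0L, 2L))
  # order: bond count, then lexicographic on the flattened sorted pair list
  keys <- vapply(all_pairs, function(p) {
    if (nrow(p) == 0L) return("0")
    o <- order(p[, 1L])
    paste0(nrow(p), "|",
           paste(sprintf("%03d-%03d", p[o, 1L], p[o, 2L]), collapse = ","))
  }, character(1L))
  all_pairs <- all_pairs[order(keys)]
  lapply(all_pairs, bonds_from_pairs, n_beads = n_beads)
}

#' Binding affinity function
#'
#' Logistic binding rate \code{a(r) = amplitude / (1 + exp(steepness * (r -
#' midpoint)))}: near-contact pairs bind at close to \code{amplitude},
#' distant pairs essentially never.  Strictly decreasing in the separation.
#'
#' @param separation nonnegative separation distance(s).
#' @param params a [bead_params()] object.
#' @return Binding rate(s), same length as \code{separation}.
#' @export
affinity <- function(separation, params) {
  if (any(separation < 0)) stop("separation must be nonnegative")
  params$affinity_amplitude /
    (1 + exp(params$affinity_steepness *
               (separation - params$affinity_midpoint)))
}

#' Generator matrix of the binding CTMC
#'
#' Builds the transition-rate (generator) matrix over the enumerated binding
#' states at the current positions, in the column convention: \code{S[s, j]}
#' is the rate from state \code{j} into state \code{s}, and every column
#' sums to zero.  A transition that adds the bond (i, k) carries rate
#' \code{a(|x_i - x_k|)}; one that removes a bond carries the constant rate
#' \code{c_break}; states differing by more than one bond do not communicate.
#' The whole matrix is multiplied by \code{params$timescale}.
#'
#' @param positions position matrix.
#' @param params a [bead_params()] object.
#' @param states enumerated state list from [enumerate_states()].
#' @return \code{n_states x n_states} generator matrix.
#' @export
transition_rate_matrix <- function(positions, params,
                                   states = enumerate_states(params$n_beads)) {
  positions <- as_configuration(positions, params)
  ns <- length(states)
  d <- as.matrix(stats::dist(positions))
  S <- matrix(0, ns, ns)
  keys <- vapply(states, function(s) paste(unclass(s), collapse = ","),
                 character(1L))
  idx <- stats::setNames(seq_len(ns), keys)
  for (j in seq_len(ns)) {
    pj <- unclass(states[[j]])
    free <- which(is.na(pj))
    # bond additions j -> s at affinity rate
    if (length(free) >= 2L) {
      for (a in seq_len(length(free) - 1L)) {
        for (b in (a + 1L):length(free)) {
          i <- free[a]; k <- free[b]
          ps <- pj; ps[i] <- k; ps[k] <- i
          s <- idx[[paste(ps, collapse = ",")]]
          S[s, j] <- S[s, j] + affinity(d[i, k], params)
        }
      }
    }
    # bond removals j -> s at the constant breaking rate
    bp <- bond_pairs(states[[j]])
    if (nrow(bp)) {
      for (k in seq_len(nrow(bp))) {
        ps <- pj; ps[bp[k, 1L]] <- NA_integer_; ps[bp[k, 2L]] <- NA_integer_
        s <- idx[[paste(ps, collapse = ",")]]
        S[s, j] <- S[s, j] + params$c_break
      }
    }
  }
  diag(S) <- -colSums(S)
  params$timescale * S
}

#' Stationary distribution of a generator matrix
#'
#' Returns the normalised null vector r of the generator (column convention,
#' \code{S r = 0}): the long-run fraction of time the frozen-position CTMC
#' spends in each binding state.  Invariant to scaling the generator by any
#' positive constant.
#'
#' @param S generator matrix (columns sum to zero).
#' @return Probability vector of length \code{ncol(S)}.
#' @export
stationary_distribution <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (max(abs(colSums(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S is not a generator: columns do not sum to zero")
  sv <- svd(S)
  n <- ncol(S)
  scale <- max(abs(S))
  if (n > 1L && sv$d[n - 1L] < 1e-10 * scale)
    stop("generator has more than one null direction")
  r <- sv$v[, n]
  r <- r / sum(r)
  if (any(r < -1e-10))
    stop("null vector is not nonnegative; invalid generator")
  r[r < 0] <- 0
  r / sum(r)
}

#' Sample binding/unbinding events over one timestep
#'
#' Advances the binding state across a timestep by Bernoulli thinning with
#' rates frozen at the current positions: each existing bond breaks with
#' probability \code{1 - exp(-R c dt)} and each feasible pair (both beads
#' free) binds with probability \code{1 - exp(-R a(r) dt)}, where \code{R =
#' timescale * epsilon^(-q)} is the regime rate multiplier.  When several
#' proposed bonds share a bead in the same step, proposals are applied in
#' uniformly random order and conflicting ones are dropped, so the result is
#' always a valid matching.  A warning is issued when any single event
#' probability exceeds 0.5 (dt too coarse to resolve the rates).
#'
#' @param positions position matrix.
#' @param bonds current binding state.
#' @param params a [bead_params()] object.
#' @param dt timestep.
#' @return Updated \code{"binding_state"}.
#' @export
sample_events <- function(positions, bonds, params, dt) {
  stopifnot(dt > 0)
  positions <- as_configuration(positions, params)
  p <- unclass(as_binding_state(bonds, params$n_beads))
  R <- rate_multiplier(params)
  pmax_event <- 1 - exp(-R * max(params$affinity_amplitude, params$c_break) * dt)
  if (pmax_event > 0.5)
    warning("event probability per step exceeds 0.5; decrease dt")
  # beads eligible to bind this step: free in the input state (a bond
  # broken within the same step does not free its beads until next step)
  free <- which(is.na(p))
  # break existing bonds
  bp <- bond_pairs(structure(p, class = "binding_state"))
  if (nrow(bp)) {
    die <- stats::runif(nrow(bp)) < 1 - exp(-R * params$c_break * dt)
    for (k in which(die)) {
      p[bp[k, 1L]] <- NA_integer_
      p[bp[k, 2L]] <- NA_integer_
    }
  }
  # propose new bonds among the eligible pairs
  if (length(free) >= 2L) {
    cand <- utils::combn(free, 2L)
    r <- sqrt(rowSums((positions[cand[1L, ], , drop = FALSE] -
                         positions[cand[2L, ], , drop = FALSE])^2))
    hit <- which(stats::runif(ncol(cand)) < 1 - exp(-R * affinity(r, params) * dt))
    if (length(hit)) {
      for (k in sample(hit)) {
        i <- cand[1L, k]; j <- cand[2L, k]
        if (is.na(p[i]) && is.na(p[j])) {
          p[i] <- j; p[j] <- i
        }
      }
    }
  }
  structure(p, class = "binding_state")
}
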