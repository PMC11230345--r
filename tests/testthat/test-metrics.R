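test_that("cluster detection matches a union-find oracle", {
  p <- preset_params("reduced-100")
  set.seed(50)
  # independent oracle: brute-force union-find on the distance graph
  for (k in 1:5) {
    pos <- matrix(stats::rnorm(40 * 3, sd = 120), 40, 3)
    fc <- find_clusters(pos, 75)
    comp <- local({
      n <- nrow(pos); parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      d <- as.matrix(stats::dist(pos))
      for (i in seq_len(n - 1)) for (j in (i + 1):n) if (d[i, j] < 75) {
        ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj
      }
      vapply(seq_len(n), find, integer(1))
    })
    # same partition: membership labels induce identical groupings
    expect_equal(length(unique(fc$membership)), length(unique(comp)))
    expect_true(all(tapply(comp, fc$membership,
                           function(z) length(unique(z))) == 1))
  }
  # edge cases
  far <- matrix(c(0, 0, 0, 1000, 0, 0, 0, 1000, 0), 3, 3, byrow = TRUE)
  expect_length(find_clusters(far, 75)$clusters, 0)
  chain <- cbind(seq(0, 50 * 9, by = 50), 0, 0)
  fcc <- find_clusters(chain, 75)
  expect_length(fcc$clusters, 1)
  expect_equal(fcc$clusters[[1]], 1:10)
})

test_that("mixing coefficient has the frozen and full-turnover limits", {
  p <- bead_params(4, 2, eta = 1, a_ev = 2, c_ev = 0.5, kappa = 5,
                   c_break = 0.5, affinity_amplitude = 2,
                   affinity_steepness = 20, affinity_midpoint = 0.75)
  sq <- rbind(c(0, 0), c(0.5, 0), c(0, 0.5), c(0.5, 0.5))
  frozen <- fake_traj(rep(list(sq), 5), matrix(0L, 5, 4), params = p)
  expect_equal(mixing_coefficient(frozen, lag = 1, r_near = 0.6), 0)
  expect_equal(mixing_coefficient(frozen, lag = 3, r_near = 0.6), 0)
  # alternate between two disjoint pairings: complete turnover at lag 1
  a <- rbind(c(0, 0), c(0.1, 0), c(5, 5), c(5.1, 5))
  b <- rbind(c(0, 0), c(5.1, 5), c(5, 5), c(0.1, 0))
  alt <- fake_traj(list(a, b, a, b), matrix(0L, 4, 4), params = p)
  expect_equal(mixing_coefficient(alt, lag = 1, r_near = 0.5), 1)
  # hand-enumerated Jaccard: bead 2 swaps clusters at frame 2
  x1 <- rbind(c(0, 0), c(0.2, 0), c(3, 0), c(3.2, 0))
  x2 <- rbind(c(0, 0), c(3.1, 0), c(3, 0), c(3.2, 0))
  tr <- fake_traj(list(x1, x2), matrix(0L, 2, 4), params = p)
  # neighbor sets (r = 0.5): frame1: {2},{1},{4},{3}; frame2:
  # {}, {3,4}, {2,4}, {2,3}
  # bead1: union {2}, intersection {} -> 1; bead2: 1 - 0/3 = 1
  # bead3: 1 - 1/2; bead4: 1 - 1/2; mean = (1 + 1 + 0.5 + 0.5)/4
  expect_equal(mixing_coefficient(tr, lag = 1, r_near = 0.5), 0.75)
  expect_error(mixing_coefficient(frozen, lag = 10, r_near = 0.6), "lag")
})

test_that("average nearby beads counts pairs correctly", {
  p <- bead_params(5, 2, eta = 1, a_ev = 2, c_ev = 0.5, kappa = 5,
                   c_break = 0.5, affinity_amplitude = 2,
                   affinity_steepness = 20, affinity_midpoint = 0.75)
  apart <- cbind(seq(0, 40, by = 10), 0)
  tr <- fake_traj(list(apart), matrix(0L, 1, 5), params = p)
  expect_equal(avg_nearby_beads(tr, r_near = 1), 0)
  close_all <- matrix(stats::rnorm(10, sd = 0.01), 5, 2)
  tr2 <- fake_traj(list(close_all), matrix(0L, 1, 5), params = p)
  expect_equal(avg_nearby_beads(tr2, r_near = 1), 4)
  # oracle on a random configuration
  set.seed(51)
  pos <- matrix(stats::rnorm(10, sd = 0.6), 5, 2)
  tr3 <- fake_traj(list(pos), matrix(0L, 1, 5), params = p)
  d <- as.matrix(stats::dist(pos)); diag(d) <- Inf
  expect_equal(avg_nearby_beads(tr3, r_near = 0.75),
               mean(rowSums(d < 0.75)))
})

test_that("unbound and out-of-cluster fractions count frames", {
  p <- p3()
  never <- fake_traj(rep(list(equilateral3(0.5)), 6),
                     matrix(0L, 6, 3), params = p)
  expect_equal(unbound_fraction(never), 1)
  partners <- matrix(0L, 6, 3)
  partners[, 1] <- 2L; partners[, 2] <- 1L
  always <- fake_traj(rep(list(equilateral3(0.5)), 6), partners,
                      params = p)
  expect_equal(unbound_fraction(always), 0)
  # alternating bond trace: exactly half the frames unbound
  alt <- matrix(0L, 6, 3)
  alt[c(1, 3, 5), 1] <- 2L; alt[c(1, 3, 5), 2] <- 1L
  half <- fake_traj(rep(list(equilateral3(0.5)), 6), alt, params = p)
  expect_equal(unbound_fraction(half), 0.5)
  # per-bead variant
  expect_equal(unbound_fraction(half, per_bead = TRUE), 1 - 2 / 6)
})

test_that("mean unbound time and diffusion distance follow their
          definitions", {
  p <- p3()
  # bead 1: unbound intervals of 1 and 3 frames between bound frames
  partners <- matrix(0L, 7, 3)
  bound_frames <- c(1, 3, 7)
  partners[bound_frames, 1] <- 2L
  partners[bound_frames, 2] <- 1L
  # bead 2 follows bead 1; bead 3 never binds (single censored interval)
  tr <- fake_traj(rep(list(equilateral3(0.5)), 7), partners, params = p,
                  dt = 1)
  # completed unbound intervals: frames {2} (length 1) and {4,5,6}
  # (length 3) for beads 1 and 2 -> mean 2
  expect_equal(mean_unbound_time(tr), 2)
  expect_equal(unbound_diffusion_distance(p, 2),
               sqrt(p$dim * p$epsilon * 2))
  expect_equal(unbound_diffusion_distance(p, 2, prefactor = 2 * p$dim),
               sqrt(2) * unbound_diffusion_distance(p, 2))
  # scales as sqrt(epsilon)
  p2 <- p3(epsilon = 4 * p$epsilon)
  expect_equal(unbound_diffusion_distance(p2, 2),
               2 * unbound_diffusion_distance(p, 2))
  expect_error(mean_unbound_time(
    fake_traj(rep(list(equilateral3(0.5)), 4), matrix(0L, 4, 3),
              params = p)), "unbound intervals")
})

test_that("frozen-CTMC unbound holding time matches the analytic mean", {
  p <- p3()
  pos <- equilateral3(0.45)
  S <- transition_rate_matrix(pos, p) *
    p$epsilon^(-p$scaling_exponent)
  exit_rate <- -S[1, 1]  # total binding rate out of the unbound state
  sim <- frozen_ctmc(pos, p, n_events = 3e4, seed = 52)
  hold1 <- sim$holding[sim$states[seq_along(sim$holding)] == 1L]
  expect_gt(length(hold1), 1e4)
  expect_equal(mean(hold1), 1 / exit_rate, tolerance = 0.05)
})

test_that("cluster lifetimes track persistent components", {
  p <- preset_params("reduced-100", n_beads = 6L)
  set.seed(54)
  blob <- rbind(matrix(stats::rnorm(9, sd = 10), 3, 3),
                matrix(stats::rnorm(9, sd = 10), 3, 3) +
                  matrix(rep(c(500, 0, 0), each = 3), 3, 3))
  scattered <- cbind(seq(0, 2500, by = 500), 0, 0)
  frames <- c(rep(list(blob), 5), list(scattered), rep(list(blob), 2))
  tr <- fake_traj(frames, matrix(0L, 8, 6), params = p, dt = 1)
  # strict tracking: persist 4 units, dissolve, reform for 1
  lt0 <- cluster_lifetimes(tr, r_cluster = 75, max_gap = 0L)
  expect_setequal(lt0, c(4, 4, 1, 1))
  # with gap tolerance the one-frame dropout is bridged
  lt2 <- cluster_lifetimes(tr, r_cluster = 75, max_gap = 2L)
  expect_setequal(lt2, c(7, 7))
})

test_that("regime metrics respect their declared ranges", {
  p <- pl(timescale = 5)
  tr <- simulate_beads(p, T = 4, dt = 5e-4, seed = 53, record_every = 10L)
  m <- mixing_coefficient(tr, lag = 50)
  expect_gte(m, 0); expect_lte(m, 1)
  expect_gte(avg_nearby_beads(tr), 0)
  u <- unbound_fraction(tr)
  expect_gte(u, 0); expect_lte(u, 1)
  nc <- not_in_cluster_fraction(tr)
  expect_gte(nc, 0); expect_lte(nc, 1)
})
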