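test_that("averaged force is invariant to the generator timescale", {
  set.seed(20)
  pos <- random_config(p3())
  v1 <- averaged_force(pos, p3(timescale = 0.1))
  v2 <- averaged_force(pos, p3(timescale = 1))
  v3 <- averaged_force(pos, p3(timescale = 10))
  expect_lt(max(abs(v1 - v2)), 1e-12 * max(1, max(abs(v2))))
  expect_lt(max(abs(v3 - v2)), 1e-12 * max(1, max(abs(v2))))
})

test_that("averaged force equals the frozen-CTMC empirical time average", {
  p <- p3()
  pos <- equilateral3(0.45)
  states <- enumerate_states(3)
  sim <- frozen_ctmc(pos, p, n_events = 1e6, seed = 21)
  occ <- tapply(sim$holding, sim$states[seq_along(sim$holding)], sum)
  occ <- as.vector(occ[as.character(1:4)]) / sum(sim$holding)
  v_emp <- Reduce(`+`, lapply(1:4, function(s) {
    occ[s] * total_drift(pos, states[[s]], p)
  }))
  v <- averaged_force(pos, p, states)
  expect_lt(max(abs(v - v_emp)) / max(abs(v)), 0.01)
  # symmetric configuration: total averaged force vanishes
  m <- matrix(v, 3, 2, byrow = TRUE)
  expect_lt(max(abs(colSums(m))), 1e-12)
})

test_that("fixed-point search recovers the cluster landscape", {
  p <- pl()
  cp <- landscape_critical_points(p)
  expect_equal(cp$unbound$label, "unbound-triangle")
  expect_equal(cp$two_bead$label, "two-bead-cluster")
  expect_equal(cp$three_bead$label, "three-bead-cluster")
  expect_equal(cp$exit_saddle$n_unstable, 1L)
  expect_equal(cp$collinear_saddle$n_unstable, 1L)
  for (f in cp$fixed_points) expect_lt(f$residual, 1e-8)
  # unbound triangle: reduced-coordinate oracle (radial balance of the
  # averaged force on the equilateral manifold by 1-d root finding)
  radial <- function(rad) {
    v <- averaged_force(equilateral3(rad), p)
    v[2]  # y-component of the top bead = radial direction
  }
  # bracket inside the zero-affinity zone: below ~0.52 the averaged
  # attraction is switched on and the force turns inward again
  root <- stats::uniroot(radial, c(0.52, 0.7), tol = 1e-12)$root
  expect_equal(cp$unbound$pair_distances[1], root * sqrt(3),
               tolerance = 1e-6)
  # 2-bead cluster: far-bead distance by a 1-d root find on the symmetric
  # two-bound-one-far manifold (pair superimposed at -d/3, far bead 2d/3)
  sepforce <- function(d) {
    pos <- rbind(c(-d / 3, 0), c(-d / 3, 0), c(2 * d / 3, 0))
    v <- averaged_force(pos, p)
    v[5] - v[1]  # relative x-force: far bead minus pair
  }
  root2 <- stats::uniroot(sepforce, c(0.85, 1.05), tol = 1e-12)$root
  expect_equal(cp$two_bead$pair_distances[2], root2, tolerance = 1e-6)
  # the permuted 2-bead minima share geometry and effective potential
  d2 <- cp$two_bead$pair_distances
  expect_equal(d2[2], d2[3], tolerance = 1e-8)
})

test_that("string method solves analytic fixtures", {
  # single-state quadratic potential, endpoints symmetric through the
  # origin: the minimum-energy path is the straight chord
  fq <- function(x) -2 * x
  s <- string_method(c(-1, -1), c(1, 1), force = fq, n_images = 24,
                     step_size = 0.05, tol = 1e-9, align = FALSE)
  dev <- apply(s$images, 1, function(z) {
    a <- c(-1, -1); b <- c(1, 1)
    t <- (z - a) - sum((z - a) * (b - a)) / sum((b - a)^2) * (b - a)
    sqrt(sum(t^2))
  })
  expect_lt(max(dev), 1e-6)
  # double well U = (z^2 - 1)^2 + y^2: path along the z axis, barrier 1
  fdw <- function(x) c(-4 * x[1] * (x[1]^2 - 1), -2 * x[2])
  sd <- string_method(c(-1, 0), c(1, 0), force = fdw, n_images = 48,
                      step_size = 0.02, tol = 1e-9, align = FALSE)
  expect_lt(max(abs(sd$images[, 2])), 1e-6)
  prof <- effective_potential_along_path(sd, params = NULL, force = fdw)
  expect_equal(prof$barrier, 1.0, tolerance = 5e-3)
  expect_equal(prof$values[1], 0)
  # string collapse raises an error
  expect_error(string_method(c(0, 0), c(0, 0), force = fq), "coincide")
})

test_that("single-state effective potential equals the state potential", {
  p <- pl()
  bonds <- bonds_from_pairs(rbind(c(1, 2)), 3)
  a <- rbind(c(-0.1, 0), c(-0.1, 0.02), c(0.9, 0))
  b <- rbind(c(-0.2, 0), c(-0.2, 0.02), c(0.4, 0))
  path <- string_method(a, b, p, force = "state", state = bonds,
                        n_images = 32, tol = 1e-8, align = FALSE)
  prof <- effective_potential_along_path(path)
  du <- vapply(seq_len(nrow(path$images)), function(i) {
    state_potential(unflatten_positions(path$images[i, ], p), bonds, p)
  }, numeric(1))
  du <- du - du[1]
  expect_lt(max(abs(prof$values - du)), 1e-3 * max(1, max(abs(du))))
})

test_that("effective potential and quadrature converge with image count", {
  p <- pl()
  path32 <- canonical_transition(p, "two-bead-exit", n_images = 32)
  path64 <- canonical_transition(p, "two-bead-exit", n_images = 64)
  b32 <- effective_potential_along_path(path32)$barrier
  b64 <- effective_potential_along_path(path64)$barrier
  expect_lt(abs(b64 - b32) / b64, 0.005)
})

test_that("effective potential is timescale invariant along a fixed path", {
  p <- pl()
  path <- canonical_transition(p, "two-bead-exit", n_images = 32)
  b <- vapply(c(0.1, 1, 10), function(al) {
    pa <- pl(timescale = al)
    effective_potential_along_path(path, params = pa)$barrier
  }, numeric(1))
  expect_lt(max(abs(b - b[2])), 1e-12 * b[2])
})

test_that("loop integral reports the non-gradient residual", {
  p <- pl()
  # closed square loop in configuration space around the two-bead region
  base <- rbind(c(-0.3, 0), c(-0.3, 0.05), c(0.62, 0))
  mk <- function(dx, dy) {
    b <- base; b[3, ] <- b[3, ] + c(dx, dy); flatten_positions(b)
  }
  corners <- rbind(mk(0, 0), mk(0.15, 0), mk(0.15, 0.15), mk(0, 0.15),
                   mk(0, 0))
  # densify the loop
  imgs <- NULL
  for (k in 1:4) {
    w <- seq(0, 1, length.out = 9)[-9]
    imgs <- rbind(imgs, outer(1 - w, corners[k, ]) + outer(w, corners[k + 1, ]))
  }
  imgs <- rbind(imgs, corners[5, , drop = FALSE])
  seg <- sqrt(rowSums((imgs[-1, ] - imgs[-nrow(imgs), ])^2))
  path <- structure(list(images = imgs, arclength = c(0, cumsum(seg)),
                         s_norm = c(0, cumsum(seg)) / sum(seg),
                         converged = TRUE, n_iter = 0L, force = "averaged",
                         state = NULL, params = p),
                    class = "transition_path")
  prof <- effective_potential_along_path(path)
  expect_true(!is.null(prof$loop_residual))
  expect_gt(abs(prof$loop_residual), 1e-8)  # the field is not a gradient
})
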