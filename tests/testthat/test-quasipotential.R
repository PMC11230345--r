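test_that("Hamiltonian matrix assembles advection, diffusion and
          switching", {
  p <- pl()
  states <- enumerate_states(3)
  pos <- equilateral3(0.45)
  p1 <- p; p1$timescale <- 1
  S0 <- transition_rate_matrix(pos, p1, states)
  # zero momentum: M = alpha S with Perron root 0 and eigenvector r
  M0 <- hamiltonian_matrix(pos, rep(0, 6), p, alpha = 3, states)
  expect_equal(M0, 3 * S0, tolerance = 1e-12)
  pe <- principal_eigenvalue(M0)
  expect_lt(abs(pe$value), 1e-12)
  expect_equal(pe$vector, stationary_distribution(S0), tolerance = 1e-8)
  # independent element-by-element assembly at a random momentum
  set.seed(30)
  mom <- stats::rnorm(6, sd = 0.3)
  M <- hamiltonian_matrix(pos, mom, p, alpha = 7, states)
  Mref <- 7 * S0
  for (s in 1:4) {
    Mref[s, s] <- Mref[s, s] +
      sum(total_drift(pos, states[[s]], p) * mom) + sum(mom^2)
  }
  expect_equal(M, Mref, tolerance = 1e-12)
  # Metzler structure
  off <- M; diag(off) <- 0
  expect_true(all(off >= 0))
})

test_that("principal eigenvalue agrees with a dense solver on random
          Metzler matrices", {
  set.seed(31)
  for (k in 1:50) {
    M <- matrix(stats::runif(16), 4, 4)
    diag(M) <- stats::rnorm(4, sd = 2)
    pe <- principal_eigenvalue(M)
    ev <- eigen(M, only.values = TRUE)$values
    expect_equal(pe$value, max(Re(ev)), tolerance = 1e-10)
    expect_true(all(pe$vector > -1e-10))
    res <- M %*% pe$vector - pe$value * pe$vector
    expect_lt(max(abs(res)), 1e-8 * max(1, abs(pe$value)))
  }
  # diagonal matrix: max diagonal entry
  expect_equal(principal_eigenvalue(diag(c(-3, 2, 0.5)))$value, 2)
  M <- matrix(c(0, -1, 1, 0), 2, 2)
  expect_error(principal_eigenvalue(M), "Metzler")
})

test_that("momentum solver has the single-state and consistency limits", {
  p <- pl()
  pos <- rbind(c(-0.2, 0), c(-0.2, 0.05), c(0.7, 0))
  set.seed(32)
  tg <- stats::rnorm(6); tg <- tg / sqrt(sum(tg^2))
  states <- enumerate_states(3)
  p1 <- p; p1$timescale <- 1
  S0 <- transition_rate_matrix(pos, p1, states)
  # h'(0) equals <v> . tangent (Hellmann-Feynman) by finite differences
  r0 <- stationary_distribution(S0)
  drifts <- vapply(states, function(s) sum(total_drift(pos, s, p) * tg),
                   numeric(1))
  vbar_t <- sum(r0 * drifts)
  h <- function(lam, alpha = 5) {
    principal_eigenvalue(hamiltonian_matrix(pos, lam * tg, p, alpha,
                                            states, S0))$value
  }
  expect_lt(abs(h(0)), 1e-12)
  dh0 <- (h(1e-6) - h(-1e-6)) / 2e-6
  expect_equal(dh0, vbar_t, tolerance = 1e-5)
  # uphill tangent: root bracketing and the large-alpha limit
  tg_up <- if (vbar_t < 0) tg else -tg
  lam_large <- solve_momentum(pos, tg_up, p, alpha = 1e4, states, S0)
  expect_equal(as.numeric(lam_large), abs(vbar_t), tolerance = 0.01)
  lam5 <- solve_momentum(pos, tg_up, p, alpha = 5, states, S0)
  expect_lte(as.numeric(lam5), abs(vbar_t) + 1e-10)
  expect_lt(attr(lam5, "residual"), 1e-10)
  # downhill tangent gives zero
  expect_equal(as.numeric(solve_momentum(pos, -tg_up, p, alpha = 5,
                                         states, S0)), 0)
})

test_that("h(lambda) is convex along random cases", {
  p <- pl()
  set.seed(33)
  states <- enumerate_states(3)
  p1 <- p; p1$timescale <- 1
  for (k in 1:50) {
    pos <- random_config(p, sd = 0.4)
    tg <- stats::rnorm(6); tg <- tg / sqrt(sum(tg^2))
    alpha <- stats::runif(1, 0.5, 30)
    S0 <- transition_rate_matrix(pos, p1, states)
    h <- function(lam) {
      principal_eigenvalue(hamiltonian_matrix(pos, lam * tg, p, alpha,
                                              states, S0))$value
    }
    l1 <- stats::runif(1, 0, 2); l2 <- stats::runif(1, 0, 2)
    expect_lte(h((l1 + l2) / 2), (h(l1) + h(l2)) / 2 + 1e-9)
  }
})

test_that("frozen-state quasipotential equals the state-potential
          barrier", {
  p <- pl()
  bonds <- bonds_from_pairs(rbind(c(1, 2)), 3)
  a <- rbind(c(-0.1, 0), c(-0.1, 0.02), c(0.9, 0))
  b <- rbind(c(-0.25, 0), c(-0.25, 0.02), c(0.35, 0))
  path <- string_method(a, b, p, force = "state", state = bonds,
                        n_images = 48, tol = 1e-8, align = FALSE)
  qp <- quasipotential_profile(path, p, alpha = 1, frozen_state = bonds)
  du <- vapply(seq_len(nrow(path$images)), function(i) {
    state_potential(unflatten_positions(path$images[i, ], p), bonds, p)
  }, numeric(1))
  climb <- sum(pmax(diff(du), 0))  # total uphill gain along the path
  expect_equal(qp$barrier, climb, tolerance = 0.01 * max(climb, 1e-10))
})

test_that("quasipotential barrier grows with alpha toward the averaged
          barrier", {
  p <- pl()
  path <- canonical_transition(p, "two-bead-exit", n_images = 48)
  ueff <- effective_potential_along_path(path)$barrier
  dw <- vapply(c(1, 5, 20, 100), function(al) {
    quasipotential_profile(path, p, alpha = al)$barrier
  }, numeric(1))
  expect_true(all(diff(dw) > 0))
  expect_lte(dw[4], ueff * (1 + 1e-6))
  expect_lt(abs(dw[4] - ueff) / ueff, 0.05)
})

test_that("Arrhenius prediction is barrier over epsilon", {
  expect_equal(arrhenius_log_time(0, 0.05), 0)
  expect_equal(arrhenius_log_time(0.3, 0.05), 6)
  expect_equal(arrhenius_log_time(0.3, 0.025), 12)
  expect_error(arrhenius_log_time(0.3, 0), "positive")
  expect_error(arrhenius_log_time(-1, 0.05), "nonnegative")
})
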