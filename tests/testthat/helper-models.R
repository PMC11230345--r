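# shared fixtures: presets and small configurations used across tests

p3 <- function(...) preset_params("table1-3bead", ...)
pl <- function(...) preset_params("landscape-3bead", ...)

equilateral3 <- function(rad = 0.5) {
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  rad * cbind(cos(ang), sin(ang))
}

random_config <- function(params, sd = 0.5) {
  matrix(stats::rnorm(params$n_beads * params$dim, sd = sd),
         params$n_beads, params$dim)
}

random_matching <- function(n) {
  sts <- enumerate_states(n)
  sts[[sample(length(sts), 1L)]]
}

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# brute-force matching enumeration: filter all partner arrays that are
# valid involutions (independent oracle for enumerate_states)
brute_force_matchings <- function(n) {
  grids <- rep(list(0:n), n)
  g <- as.matrix(expand.grid(grids))
  ok <- apply(g, 1, function(p) {
    b <- which(p > 0)
    if (any(p[b] == b)) return(FALSE)
    all(p[p[b]] == b)
  })
  sum(ok)
}

# a minimal hand-built trajectory object for metric tests
fake_traj <- function(positions_list, partners, dt = 1, record_every = 1L,
                      params) {
  pos <- t(vapply(positions_list, function(p) as.vector(t(p)),
                  numeric(params$n_beads * params$dim)))
  structure(list(
    times = (seq_along(positions_list) - 1) * dt * record_every,
    positions = pos, partners = partners, params = params, dt = dt,
    seed = NULL, record_every = as.integer(record_every)),
    class = "switching_trajectory")
}
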