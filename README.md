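# switchbeads

Simulation and asymptotic analysis of chromatin bead models in which
condensin-like crosslinks switch on and off as a continuous-time Markov
chain (CTMC). Beads move by overdamped Langevin dynamics,

    dx_i = [ -eta x_i  +  sum_j a_ev (x_i - x_j) exp(-|x_i - x_j|^2 / c_ev)
             + sum_j kappa b_ij (x_j - x_i) ] dt  +  sqrt(2 eps) dB_i,

where the bond matrix `b` is a matching (one partner per bead) whose
pairs form at the distance-dependent rate `a(r) = A / (1 + e^{s (r -
r_half)})` and break at the constant rate `c`, all rates carrying a
timescale knob (alpha/beta) and a power of `1/eps` that selects the
scaling regime. The package is for researchers studying how the
*timescale* of transient crosslinking, relative to thermal noise, tunes
chromatin organisation between three regimes: amorphic (no clusters),
flexible (clusters that exchange beads), and rigid (long-lived clusters).

What it provides:

* `simulate_beads()` — a compiled hybrid Euler–Maruyama / Markov-switching
  integrator (seed-reproducible), with presets for the dimensional
  361-bead nucleolus model, a density-matched 100-bead reduction, and the
  analysable planar 3-bead model (`preset_params()`).
* `enumerate_states()`, `transition_rate_matrix()`,
  `stationary_distribution()` — the binding CTMC over all matchings.
* `averaged_force()`, `find_fixed_points()`, `string_method()`,
  `effective_potential_along_path()` — the time-averaged drift field, its
  cluster fixed points, most-probable transition paths, and the effective
  potential `U_eff` along them.
* `hamiltonian_matrix()`, `solve_momentum()`, `quasipotential_profile()`
  — the WKB eigenvalue problem `[A + D + alpha S] r = 0` giving the
  alpha-dependent quasipotential barrier `dW`, with
  `arrhenius_log_time()` for the `log E[tau] ~ dW / eps` lifetime
  prediction.
* `escape_experiment()`, `arrhenius_fit()` — Monte-Carlo escape times
  from cluster basins and the empirical barrier.
* `mixing_coefficient()`, `find_clusters()`, `cluster_lifetimes()`,
  `regime_sweep()` — clustering-regime metrics for many-bead runs.

## Worked example

Landscape and timescale-dependent barrier of the 3-bead model:

```r
library(switchbeads)
p <- preset_params("landscape-3bead")

cp <- landscape_critical_points(p)
cp$three_bead$pair_distances
#> [1] 0.1819918 0.1819918 0.1819918        # the compact 3-bead cluster
cp$two_bead$pair_distances
#> [1] 0.0000000 0.9464964 0.9464964        # superimposed pair + far bead

path <- canonical_transition(p, "three-to-two")
effective_potential_along_path(path)$barrier
#> [1] 0.4325704                            # time-averaged exit barrier
quasipotential_profile(path, p, alpha = 1)$barrier
#> [1] 0.07569601
quasipotential_profile(path, p, alpha = 10)$barrier
#> [1] 0.2638344                            # barrier grows with alpha
```

Removing a bead from the 3-bead cluster costs 0.43 in units of the
effective potential, but when binding fluctuations are fast-but-finite
(alpha = 1) the quasipotential barrier drops to 0.076 — the crosslink
noise does most of the work, and cluster lifetimes
(`exp(barrier / eps)`) shorten by orders of magnitude. A Monte-Carlo
check of the matching escape statistics:

```r
r <- escape_experiment("two-bead", params = preset_params("landscape-3bead",
                       timescale = 10), epsilon = 0.01, alpha = 10,
                       n_runs = 200, seed = 1)
r
#> escape experiment: 200 runs, 200 to target, tau_hat = 8.301 (eps=0.01, alpha=10)
```

A thin command-line interface over the same functions is installed at
`inst/cli/switchbeads.R` (subcommands `simulate`, `fixed-points`,
`path`, `quasipotential`, `escape`, `metrics`; every run writes a YAML
config echo with its seed and hash).

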