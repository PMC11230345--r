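---
title: "Switching bead models of transient chromatin crosslinking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switching bead models of transient chromatin crosslinking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchbeads)
```

## The model

Condensin-like SMC complexes transiently crosslink chromatin loci. The
package idealises a chromatin region as `n` beads whose positions follow
overdamped Langevin dynamics

$$dx_i = \left[f^c_i + f^{EV}_i + f^{bond}_i\right]dt
  + \sqrt{2\varepsilon}\,dB_i,$$

with a linear confinement force $f^c_i = -\eta x_i$ standing in for the
nuclear envelope, a soft Gaussian excluded-volume repulsion
$f^{EV}_i = \sum_{j\ne i} a_{ev}(x_i - x_j)e^{-|x_i-x_j|^2/c_{ev}}$, and a
harmonic crosslink attraction $f^{bond}_i = \sum_j \kappa b_{ij}(x_j-x_i)$
over the currently bound pairs. The bond indicator matrix $b$ is a
matching (each bead binds at most one partner) and evolves as a
continuous-time Markov chain: a free pair at separation $r$ binds at rate
$a(r) = A/(1+e^{s(r - r_{1/2})})$ and every bond breaks at the constant
rate $c$. Multiplying every rate by the timescale knob $\alpha$ (called
$\beta$ for the many-bead system) and by $\varepsilon^{-q}$,
$q\in\{0,1,2\}$, realises three scaling regimes as $\varepsilon \to 0$:

* `q = 0` — switching is slow relative to thermal noise; the system
  equilibrates within each binding state and no effective attraction
  survives (the *amorphic* regime);
* `q = 1` — binding fluctuations and thermal noise interact; clusters
  form and exchange beads at rates controlled by $\alpha$ (the *flexible*
  regime);
* `q = 2` — binding fluctuations vanish first and only the time-averaged
  attraction remains; clusters are long-lived and insensitive to $\alpha$
  (the *rigid* regime).

Two parameter sets are built in (`preset_params()`): a dimensional
361-bead nucleolus model (lengths in nm, rates in 1/s) and a
dimensionless planar 3-bead model small enough that the four binding
states (all unbound; one bond per pair) can be enumerated and analysed
exactly.

## The averaged field and its fixed points

Freezing positions, the binding CTMC has generator $S(x)$ (columns sum to
zero) and stationary distribution $r(x)$, its normalised null vector.
Averaging the per-state drift $v(x;s)$ over $r(x)$ gives the
deterministic effective force $\langle v\rangle(x) = \sum_s v(x;s)
r_s(x)$, which is invariant to the overall switching timescale. Its
stable fixed points are the observable cluster states of the 3-bead
model: the unbound large triangle (confinement balancing excluded
volume), three equivalent 2-bead clusters (a superimposed bound pair with
the third bead far), and the compact 3-bead cluster held together by
rapidly exchanging bonds. `find_fixed_points()` locates them by
relaxation plus Levenberg–Marquardt polish, and
`landscape_critical_points()` adds the two index-1 saddles: the *exit
saddle* (a third bead at the edge of binding range) and the *collinear
saddle* mediating in-cluster rearrangement.

### A note on the affinity steepness

With the published dimensionless parameters the logistic affinity has a
substantial tail at the distance where confinement balances excluded
volume ($d^\* \approx 0.95$, where $a \approx 0.04$). Because a bound
pair feels the strong spring $\kappa$, even this small stationary bond
probability contributes a time-averaged attraction ($\approx 0.1$–$0.3$
in force units) that is an order of magnitude larger than the restoring
margin near $d^\*$ ($\lesssim 0.01$); under the literal parameters the
averaged field then has a *single* stable fixed point and no cluster
landscape. The many-bead parameter set does not have this problem: at its
own geometric scales (binding midpoint 75 nm, steepness 20/nm) the
affinity is effectively a contact switch with an identically-zero tail.
The package therefore provides `preset_params("landscape-3bead")`,
identical to the printed 3-bead set except for affinity steepness 100
(any value above roughly 40 restores the structure), and uses it as the
canonical parameter set for all landscape, quasipotential and escape
analyses. `"table1-3bead"` keeps the printed steepness for reference.

## Transition paths, effective potential, quasipotential

The most probable escape paths are computed with the simplified string
method: discretise a path into images, alternate relaxation under the
chosen force field with reparametrisation to equal arclength, and align
each image to its predecessor by an optimal *proper* rotation
(reflections are excluded on purpose: a two-bead swap of a triangle is a
reflection, and allowing reflection gauge would contract genuinely
distinct rearrangement paths to a point). Along a path the effective
potential is the line integral $U_{eff}(s) = -\int \langle v\rangle\cdot
dx$; the averaged field is not a global gradient (its stationary weights
depend on position), and `effective_potential_along_path()` reports the
loop residual when handed a closed loop rather than hiding it.

In the `q = 1` scaling a WKB ansatz for the switching Fokker–Planck
system leads to a per-point eigenvalue problem
$[A(x,p) + D(p) + \alpha S(x)]\,r = 0$ with diagonal advection
($v(x;s)\cdot p$ per state) and diffusion ($|p|^2$) matrices. The
assembled matrix is Metzler, so its rightmost eigenvalue is real with a
positive eigenvector, and the quasipotential slope along the path is the
unique positive root $\lambda$ of that Perron eigenvalue with the
momentum ansatz $p = \lambda\,\hat t$ restricted to the path tangent.
Two analytic anchors pin the construction: a single-state (frozen-bond)
system gives $\lambda = -v\cdot\hat t$ so $W$ reproduces the potential
climb exactly, and $\alpha \to \infty$ gives $\lambda \to -\langle
v\rangle\cdot\hat t$ so $W \to U_{eff}$. Because $\lambda \ge 0$, the
profile $W(s) = \int_0^s \lambda\,ds'$ is nondecreasing: on a
minimum-to-saddle path its end value is the escape barrier; on a longer
path it accumulates the total uphill cost, which is why the canonical
paths returned by `canonical_transition()` run from a minimum to its
saddle.

Computed at the canonical parameters, the landscape is strongly
asymmetric: the 2-bead cluster's exit barrier is shallow
($\Delta U_{eff} \approx 0.027$) while the 3-bead cluster's exit is deep
($\approx 0.43$) and strongly $\alpha$-dependent, and the collinear
rearrangement barrier is the smallest of all ($\approx 0.001$) — the
cluster reshuffles its beads far more easily than it releases one, and
removing a bead from the cluster is the transition most sensitive to the
binding timescale.

## Escape experiments

`escape_experiment()` launches trajectories at a cluster fixed point with
bonds drawn from the local stationary distribution, classifies frames
into basins from sorted pairwise distances and a collinearity score
(thresholds calibrated from the model's own critical points: membership
thresholds sit 40% of the way from each minimum's geometry toward the
exit saddle), and stops when a non-transit, non-start basin label holds
for 10 consecutive checks (a saddle-crossing label registers
immediately). The mean escape time is the maximum-likelihood estimate:
total elapsed time, censored runs included, divided by the number of runs
executing the designated transition. `arrhenius_fit()` regresses
$\log\hat\tau$ on $1/\varepsilon$; in the small-noise limit the slope is
the effective barrier.

The Arrhenius comparison is only meaningful when
$\Delta W/\varepsilon \gg 1$. For the shallow 2-bead exit
($\Delta W(\alpha{=}10) \approx 0.026$) that requires
$\varepsilon \lesssim 0.013$; at $\varepsilon \ge 0.03$ escape is
essentially diffusive and the fitted slope is dominated by the prefactor,
not the barrier. The package's validation therefore measures the slope on
$\varepsilon \in \{0.006, \dots, 0.013\}$, chosen in advance by that
asymptotic-validity requirement.

## Many-bead clustering metrics

For the dimensional model, `regime_sweep()` simulates the reduced
100-bead system across a log-spaced grid of binding timescales and
tabulates: per-bead unbound fraction, mean neighbor-set Jaccard turnover
(`mixing_coefficient()` — the package's operationalisation of cluster
mixing), average nearby beads, out-of-cluster fraction, mean unbound
interval and the implied diffusion distance
$\sqrt{d\,\varepsilon\,T_{unbound}}$ (prefactor configurable), and
cluster persistence (distance-graph components of size at least 3 tracked
across frames by 50% membership overlap, with a cluster called
persistent when its chain outlives ten single-bond lifetimes). Slow
binding gives an amorphic dilute cloud; fast binding gives bound pairs
that nucleate persistent multi-bead clusters; intermediate timescales
maximise bead exchange.

The reduced 100-bead preset keeps every parameter of the full 361-bead
model except the confinement, which is strengthened (to 0.005/s) so that
the unbound cloud's mean nearest-neighbor distance matches the full-size
system's (about 180 nm). A naive reduction at the original confinement
produces a cloud 3.6 times less dense, whose beads essentially never
meet the 75 nm binding range — the clustering phenomenology disappears
for a purely geometric reason. Matching the unbound density preserves
the encounter statistics the binding kinetics act on, and with it the
binding-driven condensation of the full model (whose nearest-neighbor
distance collapses from ~185 nm to ~70 nm once binding is switched on).

Numerical choices: the timestep resolves the fastest switching rate
(`default_dt()` keeps per-step event probabilities near 0.1, with a
warning beyond 0.5); binding and unbinding are sampled per step by
Bernoulli thinning with rates frozen at the updated positions, and
conflicting bond proposals within a step are applied in uniformly random
order; a quarter of each sweep run is discarded as burn-in because the
confinement relaxation time $1/\eta$ is a substantial fraction of a
desk-scale run. Sweep durations (T = 1000 s, five decades of the
timescale knob) were chosen so that cluster nucleation — a slow,
encounter-limited process in the dilute dimensional cloud — has time to
complete at the fast end of the grid.

The thermal noise scale of the dimensional presets is not part of the
published parameter table; the default $\varepsilon = 200$ nm²/s puts
the confinement-limited bead cloud at a few hundred nanometres — a
nucleolus-like size — while keeping the excluded-volume barrier between
beads (a few hundred nm² in energy units) crossable, so that beads
actually encounter the 75 nm binding range.

## What the synthetic data do and do not show

All data in the package are generated by its own simulator: there is no
external input. Passing tests therefore demonstrate internal consistency
— the simulator matches its analytic limits (free-diffusion MSD,
exponential bond lifetimes, stationary CTMC occupation), the landscape
machinery matches its oracles (finite-difference gradients, closed-form
stationary vectors, analytic string fixtures), and the Monte-Carlo
escape statistics are consistent with the quasipotential theory in the
regime where the theory applies. They do not validate the bead model
against real chromatin: the model has no chain connectivity (the spring
force linking consecutive beads is deliberately absent), no
hydrodynamics, a single bond per bead, and an idealised logistic binding
rate.

## Known limitations

* The analysis path (averaged force, quasipotential) requires
  enumerating binding states and is capped at 8 beads; the simulation
  path scales to hundreds of beads.
* The momentum ansatz restricts the quasipotential gradient to the path
  tangent on the fixed large-$\alpha$ string; an experimental
  `alpha`-dependent path refinement is not provided because the exact
  construction is not determined by the analysis — the fixed-path
  restriction is exact in both analytic limits and conservative in
  between.
* At $\varepsilon$ comparable to a barrier the basin classifier is
  intentionally conservative (thresholds anchored at 40% toward the exit
  saddle) and escape times are first-passage-to-commitment rather than
  strict Kramers times.
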