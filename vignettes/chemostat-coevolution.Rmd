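---
title: "Modelling bacteria-phage coevolution in a chemostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bacteria-phage coevolution in a chemostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecoevo)
```

## The model

`phagecoevo` simulates a diverse community of bacteria and bacteriophage
coevolving in a well-mixed, single-resource chemostat. The ecological
state is the resource concentration $R$ and the density of every host
strain $N_i$ and phage strain $V_j$:

$$\frac{dR}{dt} = -\omega (R - R_0) - \sum_i \frac{\epsilon \gamma R N_i \delta_i}{R + K}$$

$$\frac{dN_i}{dt} = -\omega N_i + \frac{\gamma R N_i \delta_i}{R + K} - \sum_j \theta_{ij} N_i V_j$$

$$\frac{dV_j}{dt} = -\omega V_j + \sum_i \beta\, \theta_{ij} N_i V_j$$

Fresh medium at supply concentration $R_0$ enters at dilution rate
$\omega$, which also washes out all cells and virions. Hosts grow by
Monod (uptake-saturating) kinetics with maximum uptake $\gamma$ and
half-saturation $K$, scaled by a genotype-dependent factor $\delta_i$.
Infection is mass-action adsorption with coefficient $\theta_{ij}$ and
instantaneous lysis releasing $\beta$ new virions; there is no latent
period and only single infections occur.

Both host and phage genotypes live on the unit interval, binned at
resolution $\rho = 0.01$. A host genotype $h$ maps pleiotropically to
two phenotypes: its resistance trait $\hat h = h$ and its growth factor
$\delta = f(h)$ given by a configurable adaptive landscape. A phage
genotype maps to its infection trait $\hat v = v$. Adsorption follows a
relaxed lock-and-key kernel,
$$\theta_{ij} = \phi\, e^{-s (\hat h_i - \hat v_j)^2},$$
maximal at a perfect genetic match and decaying with distance at a rate
set by the specificity $s$ (large $s$ = specialist phage). A strict
variant ($\theta = \phi$ only at exact bin match) is used for the
analytic theory and is available as `scheme = "strict"`.

Mutation is the only stochastic element. Each timestep, every strain
produces mutants as a Poisson draw with mean equal to its instantaneous
production rate (gross cell production for hosts, virion production for
phage) times the per-particle mutation rate ($M_B$, $M_V$) times the
chemostat volume $L$ and the timestep. Each mutant offsets the parental
genotype by a normal deviate (sd $\sigma_B$ or $\sigma_V$) and is binned;
offsets that round back to the parental bin are dropped, and offsets that
leave $[0,1]$ are skipped and flag the run (ensemble drivers discard
flagged runs). Mutant density ($1/L$ per mutant) is transferred from the
parent population, so mutation reclassifies new particles rather than
creating biomass. Populations falling below 1 cell (or virion) per ml
are removed.

The defaults of `chemostat_params()` are the benchmark parameterisation
used throughout: $\omega = 0.0033\,\mathrm{min^{-1}}$,
$R_0 = 2.2\,\mu g\,ml^{-1}$, $\epsilon = 2.6\times10^{-6}$,
$\gamma = 0.0123$, $K = 4$, $\phi = 0.104\times10^{-8}$, $\beta = 71$,
$s = 100$, $\delta \in [0.8, 1.2]$, $M_B = M_V = 10^{-6}$,
$\sigma_B = \sigma_V = 0.01$, $\Delta t = 10$ min, $L = 1$ ml, founders
at $h = v = 0.2$ with $N = 4.6\times10^4$ and $V = 8.1\times10^5$.

## Adaptive landscapes

Four landscape families map genotype to growth factor:

* **Single peak** (`landscape_single_peak`): piecewise linear from
  $(0, \delta_{min})$ through $(0.5, \delta_{max})$ to
  $(1, \delta_{min})$. The workhorse for diversification studies.
* **Dynamic two-peak** (`landscape_two_peak`): pointwise maximum of the
  static single peak and a second peak whose height increases by a step
  schedule, emulating a changing environment. The default ramp
  (`two_peak_schedule`) raises the second peak, centred at $h = 0.8$, in
  10 equal steps from $\delta_{min}$ to
  $\delta_{max} + 0.1(\delta_{max}-\delta_{min})$, so it overtakes the
  original peak during the run; heights and times are fully
  configurable since no canonical schedule exists.
* **Multi-peak** (`landscape_multi_peak`): $n$ repeated up-down-up
  blocks — anchors $(0,0) \to (b_w/3, b_h) \to (2b_w/3, 0) \to (b_w,
  b_h)$ per block with $b_w = 1/n$, $b_h = (\delta_{max} -
  \delta_{min})/n$, each block starting where the previous ended — a
  saw-toothed increasing gradient with $n$ local optima separated by
  fitness valleys.
* **Rugged slope** (`landscape_rugged_slope`): a linear slope from
  $(0,\delta_{min})$ to $(1,\delta_{max})$ plus i.i.d. uniform noise,
  smoothed by a centred moving average of width `span`. We read the
  noise "amplitude" of 0.2 as peak-to-peak (i.e. $U(-0.1, 0.1)$), which
  keeps the landscape centred on the nominal range; the plausible
  alternative (half-range 0.2) merely doubles the ruggedness scale and
  is available by passing `amplitude = 0.4`. Edge windows of the
  moving average shrink symmetrically rather than clipping
  asymmetrically: a centred mean preserves the underlying linear slope
  exactly, so `amplitude = 0` returns the pure slope for every `span`
  and smoothing only attenuates noise.

Landscapes are tabulated on the $\rho$-grid and evaluated piecewise
constant per bin, because strains only ever exist at bin centres.

```{r landscape-plot, fig.width = 6, fig.height = 4}
plot(landscape_multi_peak(4))
```

## Numerical scheme and per-step order

The ecological equations are integrated with classical RK4 at
$\Delta t = 10$ min; each step then applies mutation and finally the
extinction cull. Mutation uses the post-step state because the mutant
counts derive from instantaneous production rates; culling last prevents
sub-unit "phantom" populations from seeding mutants. Halving the
timestep changes a phage-free benchmark run by well under 0.1% (this is
a test). The initial resource is $R(0) = R_0$ — a fresh-medium
convention; the equilibria do not depend on it.

Two engines implement the identical per-step algorithm: a compiled core
(used by default; a 2×10⁵-step run takes seconds) and a pure-R
reference built literally from the exported module functions
(`rk4_step`, `draw_mutations`, `apply_mutations`, `cull_extinct`). Both
consume R's global RNG stream in the same fixed order (hosts by
ascending bin, then phage), so a seed fully determines a trajectory;
the engines agree to ~10⁻⁹ relative tolerance (they differ only in
floating-point summation order) and their mutation event streams are
identical.

State is held as dense density vectors over the 101 genotype bins. All
per-strain terms vanish at zero density, so the dense representation is
exact, and the compiled core loops only over occupied bins. Because the
kernel depends on traits only through $|\hat h - \hat v|$, adsorption
matrices reduce to a by-distance lookup; strict-match equality is
integer bin comparison, never floating-point.

## Steady-state theory

For a single strain without phage, $dN/dt = 0$ gives the limiting
resource concentration $\bar R = \omega K / (\gamma\delta - \omega)$
(the classical R\*), and $dR/dt = 0$ then gives the carrying capacity
$\bar N$; we implement the algebraically simplified
$\bar N = \omega (R_0 - \bar R)(\bar R + K) / (\epsilon\gamma\delta\bar R)$
and unit-test its equivalence to the nested-fraction form at random
parameter points. With a perfect-match phage, $dV/dt = 0$ pins the host
at $\hat N = \omega/(\beta\phi)$ — independent of $\delta$, and well
below $\bar N$ for the benchmark parameters — while the phage density
$\hat V$ grows with host growth rate: faster-growing hosts support more
phage and suffer more lysis, the kill-the-winner trade-off.

Under strict lock-and-key, the sequential-introduction argument
predicts equilibrium host diversity: strains with descending growth
factors enter one by one, each pinned at $\hat N$ by its phage, drawing
resource down to $\hat R_i$ (the positive root of a quadratic in the
resource balance). The cascade ends at the first strain whose limiting
concentration exceeds the prevailing resource level
($\bar R_i > \hat R_i$): that strain is resource-limited, cannot
support phage, and closes the community at $x = i$ strains. The
equilibrium is independent of introduction order. For the benchmark
parameters and the canonical 11-strain pool $\{1.2, 1.16, \ldots,
0.8\}$:

```{r diversity}
p <- chemostat_params()
steady_state_diversity(seq(1.2, 0.8, by = -0.04), p)
diversity_scan(c(1.7, 2.2, 2.7), seq(1.2, 0.8, by = -0.04), p)
```

Diversity rises with resource supply. A corollary
(`equal_growth_collapse_check`): with *equal* growth rates, the first
strain that establishes without phage draws resource to the shared
$\bar R$, below which every phage-limited competitor declines — so
host-phage coexistence requires growth-rate variation. The simulator
reproduces this: a strict-scheme run seeded with equal-$\delta$ strains
(phage-limited) plus one phage-free strain loses every phage
population. We seed the phage-free strain explicitly because an
all-phage-limited equal-$\delta$ community is a neutrally stable
equilibrium in the deterministic dynamics; the corollary's mechanism
needs the resource-limited invader that mutation would otherwise
eventually supply.

These closed forms double as oracles for the integrator: with mutation
off, simulated single-strain systems converge to $(\bar R, \bar N)$ and
$\hat N$ to near machine precision, and a strict-scheme multi-strain
run equilibrates with every phage-supported host at the same $\hat N$
and the final resource level inside the predicted
$[\bar R_x, \hat R_{x-1}]$ band.

## Observables

`fitness_field` evaluates, for every genotype on the grid, the
per-capita net growth rate a hypothetical strain would experience in
the current environment (host: washout + growth − lysis; phage:
washout + production), with growth and lysis components reported
separately; these are the time-dependent fitness landscapes on which
selection acts, and they flatten over occupied bins as the community
approaches steady state. `growth_lysis_correlation` computes the
Pearson correlation between per-capita growth and lysis rates across
host strains above a density threshold (default >1% of cells; fewer
than three qualifying strains is an error, not a zero): under
kill-the-winner dynamics this correlation is strongly positive and
tightens toward 1 at steady state. `genotype_range` measures standing
variation as $h_{max} - h_{min}$ over the same threshold.
`strain_richness` counts strains as maximal runs of adjacent occupied
bins (one or more empty bins separate clusters) — the natural reading
of "distinct clusters" for branching data; the rule is configurable via
`min_density`. `max_growth_rate` reports the highest landscape $\delta$
(and $\delta\gamma$) in the community, the adaptation measure for
rugged-landscape ensembles. Windowed analyses use `sample_windows`
(first/middle/last 5% of samples by default).

## Experiment drivers and problem sizes

The `run_*` drivers reproduce the study designs at configurable scale;
every driver derives its per-run seeds from one master seed and
excludes range-edge-flagged runs from ensemble statistics. The package
defaults use reduced horizons chosen so each phenomenon is past its
onset but runs stay desk-sized:

* `run_case_study` (single peak, benchmark mutation rates): defaults to
  $T = 5\times10^6$ min. Under the benchmark $M_B = M_V = 10^{-6}$ the
  first host branching typically occurs at $2$–$4\times10^6$ min, so
  markedly shorter horizons show a still-monomorphic community; by
  $5\times10^6$ min every tested seed shows ≥3 host clusters, ≥2 phage
  clusters, and late-window growth-lysis correlations above 0.9. The
  full-scale ($2\times10^7$ min) community reaches ~5 host clusters,
  comparable to the analytic prediction of 6 under strict matching.
* `run_range_scan` (standing variation vs $R_0$, $\delta_{min}$, $s$):
  genotype range responds positively to resource supply and to the
  landscape floor, negatively to specificity. The specificity direction
  is an equilibrium property: generalist-phage communities ($s = 100$)
  diversify slowest, so at sub-equilibrium horizons their range is
  transiently *below* intermediate-specificity cells. The
  $s = 100$-versus-$s = 1000$ contrast acquires its equilibrium sign by
  roughly $T = 10^6$ min (ensemble means), but full monotonicity across
  specificity levels needs multi-million-minute horizons per cell.
* `run_paired_evolvability` / `run_rugged_ensemble`: paired
  with/without-phage runs sharing landscape and seed. Without phage,
  populations hill-climb to the nearest local optimum and stay there;
  with sufficiently specialist phage the lysis gradient around the
  resident exceeds the growth gradient into the valley and the
  community is chased across. In this implementation the benefit
  requires moderately specialist phage (e.g. $s \gtrsim 300$ on the
  4-block multi-peak landscape, where coevolving communities reach the
  global optimum while lone populations stop at the first local peak);
  at $s = 100$ the equilibrium lysis differential over one bin is
  smaller than the growth cost and valleys are not crossed on desk
  timescales. This matches the qualitative pattern that generalist
  phage offer little adaptive benefit on rugged landscapes.
* `run_parameter_sensitivity`, `run_mutation_asymmetry`: one-at-a-time
  robustness and the slow-phage check. With $M_V = 10^{-7}$ versus
  $M_B = 10^{-5}$ phage adaptation is mutation-starved relative to
  their hosts; in this implementation phage nevertheless persist
  through full-length runs, because mutant supply scales with total
  virion production ($\approx \omega V \sim 10^{3\text{–}4}$ per
  minute), which keeps even a $10^{-7}$ rate above the tracking
  threshold while hosts remain confined near the growth peak. Phage
  extinction under rate asymmetry is therefore *not* reproduced here;
  the driver reports persistence per seed so the question stays
  measurable.

## What the generator does and does not emulate

The simulator's synthetic communities capture the core eco-evolutionary
feedbacks: resource competition with R\*-ordering, density-dependent
specialist predation, pleiotropic growth-resistance linkage, and
mutation-limited adaptation on a binned genotype line. They do not
emulate spatial structure, latent periods or multiple infection,
demographic stochasticity in the ecological dynamics (densities are
deterministic between mutation events), recombination, or evolution of
any trait other than the two genotypes. Passing tests therefore
demonstrate internal consistency with the model's assumptions, not
quantitative agreement with laboratory chemostats.

## Numerical and design choices

* Binning: bin index $= \mathrm{round}(h/\rho)$, centres at $0, 0.01,
  \ldots, 1$; with $\sigma = \rho$ about 38% of mutational offsets
  change bin (the normal-tail fraction $2P(Z > 0.5)$), matching the
  premise that most mutations are silent.
* Mutant counts are Poisson because they arise from a production rate
  over an interval; the alternative (deterministic rounding) would
  silence mutation entirely at low rates.
* Mutant density is debited from the parent (reclassification), making
  mutation conservative and testable; the additive alternative would
  inject biomass from nowhere, though at one particle per event the
  dynamical difference is negligible.
* Extinction uses strict inequality (< 1 per ml), so a fresh mutant at
  exactly 1 cell/ml survives its first cull.
* Ties and degenerate inputs: empty rosters are valid (no-phage
  controls); an all-phage-limited pool returns $x = H$ with a flag
  rather than an error; a pool whose best strain cannot establish
  returns $x = 0$.
* Range-edge hits flag the trajectory rather than aborting, so library
  users can inspect flagged runs while ensemble statistics stay clean.

## Limitations

The strict-scheme theory and the relaxed-kernel simulations are not
quantitatively comparable (the Gaussian kernel spreads predation over
neighbouring bins, lowering realised diversity relative to the strict
prediction). Stochastic outcomes at reduced horizons depend on the
mutation-rate regime; the drivers expose `T_total` so users can trade
runtime against convergence. The deterministic ecological core admits
no demographic noise, so rare-strain extinction is purely threshold
driven.
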