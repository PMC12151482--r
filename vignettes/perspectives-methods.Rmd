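---
title: "Noise in proliferating cells: models and methods behind burstdilution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise in proliferating cells: models and methods behind burstdilution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstdilution)
```

## The two perspectives

Fluctuations in the concentration of a gene product can be quantified in two
ways. In the **single-cell (lineage) perspective** one follows one randomly
chosen descendant path through a lineage tree and asks how the concentration
fluctuates along it. In the **population perspective** one pools the
concentrations of *all* live cells of an expanding colony at a fixed time.
The two perspectives agree for a passive, perfectly partitioned protein, but
they diverge whenever expression couples to proliferation or when division
itself injects noise. `burstdilution` implements both perspectives --
exactly where closed forms exist, and by simulation everywhere -- so that the
gap between them can be measured.

## The burst–dilution feedback model

Protein concentration $x(t)$ in a single cell is a piecewise-deterministic
Markov process:

* **Bursts.** Synthesis happens in instantaneous bursts arriving as a Poisson
  process with frequency $\lambda$; each burst increments $x$ by an
  exponential amount with mean $\beta$.
* **Dilution with growth feedback.** Between bursts, cellular growth dilutes
  the concentration. The growth rate is $\gamma/(1+kx)$ -- high concentration
  inhibits growth -- so
  $\mathrm{d}x/\mathrm{d}t = -\gamma x/(1+kx) - d\,x$, where $d \ge 0$ is an
  optional first-order degradation rate for short-lived proteins. Because
  slower growth means slower dilution, $k>0$ acts as *positive* feedback on
  concentration.
* **Division.** Cells divide as a point process with the same state-dependent
  rate $\gamma/(1+kx)$. Daughters inherit the mother's concentration, so in
  the lineage perspective division is invisible; in the population
  perspective it changes the census, favouring fast-dividing
  (low-concentration) cells.

Parameters and units: $\lambda$ (bursts per unit time), $\beta$
(concentration units), $\gamma$ (per unit time; also the division rate at
$x=0$), $k$ (per concentration unit), $d$ (per unit time). All rates are in
inverse model time; there is no wall-clock calibration. Concentration is
continuous and non-negative throughout -- there is no molecule-count mode.

### Exact stationary laws

Both stationary distributions share one functional form,
$p(x) \propto (1+kx)\,e^{-sx}(sx)^{a-1}$, differing in shape $a$ and tilt
$s$:

| perspective | shape | tilt | exists iff |
|---|---|---|---|
| single-cell | $z=\lambda/\gamma$ | $\eta = 1/\beta - \lambda k/\gamma$ | $\lambda k \beta/\gamma < 1$ |
| population | $\xi = z/(k\beta+1)$ | $\rho = 1/\beta - k\xi$ | $(\lambda/\gamma - 1)k\beta < 1$ |

In both cases $s + ka = 1/\beta$, which makes the law an exact two-component
gamma mixture
$p = \beta s\,\Gamma(a, s) + \beta k a\,\Gamma(a+1, s)$ (shape–rate
notation). The package exploits this representation for the cdf, quantiles,
random generation, and exact moments, while the density itself is evaluated
directly from the closed form; adaptive quadrature of the density is kept as
an independent numerical route (`stationary_moments(..., method =
"quadrature")`) and the two must agree to $10^{-8}$ relative -- this
double-entry bookkeeping is the package's guard against transcription errors
in the moment formulas. At $k = 0$ both laws collapse to the gamma
distribution with shape $\lambda/\gamma$ and scale $\beta$, whose
skewness-to-CV ratio is exactly 2.

The population existence region strictly contains the single-cell one: a
population can reach a demographic steady state (fast-growing,
low-concentration cells dominate) even when any individual lineage drifts to
ever higher concentrations. `existence_status()` classifies a parameter set
as `both`, `population_only`, or `neither`; the boundary (tilt exactly zero)
is classified as non-existent.

To compare feedback strengths fairly, the burst frequency can be re-tuned so
the single-cell mean stays fixed:
`burst_frequency_for_mean(m, k, beta, gamma)` returns
$\lambda = \gamma m / (\beta(1 + k\beta + km))$. Along that curve the
single-cell noise rises to the finite limit $1 + 2\beta/m$ while the
population noise and skewness grow without bound
(`strong_feedback_limit()`, `weak_feedback_approx()` cover the two ends).

```{r}
p <- burst_params(burst_frequency_for_mean(100, 0.01, 10, 1),
                  beta = 10, gamma = 1, k = 0.01)
dplyr::bind_rows(stationary_moments(p, "single_cell"),
                 stationary_moments(p, "population"))
```

## The partitioning-noise model

The second noise source is mitotic partitioning. Here expression is
unregulated (constant dilution rate $\gamma$): either deterministic,
$\mathrm{d}x/\mathrm{d}t = \lambda\beta - \gamma x$, or bursty. At division,
one daughter inherits $x^+$ with conditional mean $x$, conditional variance
$\varepsilon x$, and support strictly inside $(0, 2x)$; the other receives
$2x - x^+$.

**Partition kernels.** Only the mean, variance and support of $x^+$ are
constrained by the model; the distribution family is a design choice:

* `beta_matched` (default): $x^+ = 2x B$, $B \sim \mathrm{Beta}(a,a)$ with
  $a = (x/\varepsilon - 1)/2$, matching both moments exactly whenever
  $x > \varepsilon$.
* `binomial_discretized`: $n = \mathrm{round}(x/\varepsilon)$ effective
  molecules, each inherited with probability $1/2$, rescaled to
  concentration on the halved volume ($x^+ = 2x\,m/n$); this reproduces the
  binomial segregation variance $x^2/n = \varepsilon x$. Draws of $m \in
  \{0, n\}$ are rejected to keep the support open.
* When $x \le \varepsilon$ the requested variance $\varepsilon x$ exceeds
  $x^2$, the maximum possible for any distribution on $(0,2x)$ with mean
  $x$; the fallback uses $n = 3$ effective molecules, capping the variance
  near that bound. This is documented behaviour, not a silent rescaling.

**Cell-cycle timing.** Cycle durations are i.i.d. gamma (`timer`), with
squared CV $\mathrm{CV}^2_{\tau}$ (0 = deterministic timer), or set by an
`adder` size rule (below). The timer mean defaults to $\ln 2/\gamma$ for
*every* $\mathrm{CV}^2_\tau$. This choice is load-bearing: exact renewal
analysis of the lineage process gives stationary variance
$\varepsilon \bar x / (2\gamma\langle\tau_d\rangle)$ for *any* cycle-time
distribution with mean $\langle\tau_d\rangle$, so the invariant lineage
noise

$$\mathrm{CV}^2_x = \frac{1}{\bar x}\left(\frac{\varepsilon}{2\ln 2} + \beta\right)$$

(partitioning term plus, in the bursty case, the bursting term
$\beta/\bar x$; `predicted_partition_cv2()`) holds exactly when the mean is
held at $\ln 2/\gamma$. An alternative convention re-calibrates the mean by
the Euler--Lotka relation $2\,\mathbb{E}[e^{-\gamma\tau_d}] = 1$ so the
*population* growth rate stays $\gamma$ for every $\mathrm{CV}^2_\tau$;
`calibrate_cycle_mean()` implements that closed form
($a(2^{1/a}-1)/\gamma$ for shape $a = 1/\mathrm{CV}^2_\tau$) and its value
can be passed to `cycle_model(mean_tau = ...)`. Under that convention the
lineage noise scales as $\varepsilon/(2\gamma\langle\tau_d\rangle\bar x)$
instead and is no longer distribution-invariant; the package defaults to the
fixed mean because the invariance law above is the model's central
single-cell prediction.

In the population, cycle-time randomness *does* matter: noisy cycles
desynchronize colonies, colony sizes fluctuate, and the pooled noise rises
monotonically with $\mathrm{CV}^2_\tau$ -- reaching about twice the lineage
value for exponential cycle times -- while the lineage noise stays flat.
With a deterministic timer the two perspectives carry equal noise.

### Stationarity protocols

The statistics above are properties of the stationary, cycle-phase-averaged
process, and the simulators are set up so that a fixed-time ensemble measures
exactly that:

* **Random initial phase.** The progenitor's first division happens at
  $(1-U)\tau_1$, $U \sim \mathrm{Unif}(0,1)$. With a deterministic timer, a
  synchronized snapshot just after division would give
  $\mathrm{CV}^2 = \tfrac{4}{3}\varepsilon/\bar x$ and just before
  $\tfrac{1}{3}\varepsilon/\bar x$; uniform phase averaging recovers
  $\varepsilon/(2\ln 2\,\bar x)$ exactly.
* **Horizon.** A run of $n$ "generations" ends at $t^\* = n\ln 2/\gamma$
  (equal to $n$ mean cycles under the default timer mean), with divisions at
  times $\le t^\*$ processed; a deterministic-timer colony then holds
  exactly $2^n$ cells.
* **Adder jitter.** A deterministic adder self-synchronizes: with exact
  volume halving and fixed added size, division times converge to integer
  multiples of the doubling time whatever the initial phase, so initial-phase
  randomization cannot provide phase averaging. Adder runs therefore jitter
  the snapshot time uniformly within one final generation (per lineage, or
  per colony), which again measures the phase-stationary statistics.
* **Warm start.** Feedback-model ensembles start at the stationary
  single-cell mean by default and are run past a burn-in of several dilution
  times (the worked examples use $t = 50/\gamma$, i.e. fifty dilution
  times); partitioning ensembles start at the fixed point
  $\lambda\beta/\gamma$ and run 6 generations, after which the residual
  transient in the variance is below half a percent (it contracts by a
  factor $\ge 4$ per division).

**Adder size control.** Cell volume grows exponentially at rate $\gamma$
(configurable); division fires when the added volume since birth reaches a
gamma-distributed threshold (mean and squared CV configurable), uncorrelated
with newborn size; volume halves exactly at division, and concentration is
partitioned via $\varepsilon$ as usual. This is the minimal adder consistent
with added size being uncorrelated with birth size; it restores size
homeostasis that the timer lacks, and introduces mother--daughter cycle-time
correlations. In simulations the population noise again rises with
added-size noise and exceeds the lineage noise, which stays nearly flat.

## Simulation algorithms

* **Lineage, feedback model** (`simulate_lineage_feedback()`,
  `simulate_feedback_ensemble()`): exact event-driven simulation. Burst
  waiting times are exponential at rate $\lambda$; in growth-coupled mode
  (burst rate $\lambda/(1+kx)$) proposals at the bound $\lambda$ are thinned
  with acceptance $1/(1+kx(t))$, which is exact because the rate is bounded.
  Between events the flow is advanced by the closed-form solution of the
  dilution ODE: for $d=0$ the implicit relation
  $\ln x + kx = \ln x_0 + kx_0 - \gamma t$ is solved by a bracketed Newton
  iteration in $\ln x$ (equivalent to the principal Lambert-W branch but
  immune to overflow at large $kx_0$; tolerance $10^{-14}$ relative, root
  bracketed between pure exponential decay and the initial value); with both
  $d>0$ and $k>0$ the flow is integrated numerically
  (`deSolve`, rtol $10^{-12}$). A fixed-step tau-leaping integrator
  (default step $0.01/\gamma$, Poisson number of bursts per step) is kept as
  a cross-check and must agree with the exact scheme within Monte-Carlo
  error. Ensembles are vectorized across replicates. In the non-existence
  regime, trajectories exceeding a configurable cap are flagged
  `diverging`, never an error.
* **Colony** (`simulate_colony()`, `simulate_colonies()`): agent-based.
  Cells are processed in chronological order of birth; within a cell, bursts
  and (for the state-dependent hazard) division proposals compete as
  independent Poisson streams, with division proposals at the bound
  $\gamma$ accepted with probability $1/(1+kx(t))$ -- exact thinning again.
  Timer/adder divisions are scheduled at birth. At division the mother is
  replaced by daughters $x^+$ and $2x - x^+$. All live cells are advanced
  deterministically to the exact stop time for the snapshot. A hard cap on
  cells (default $2^{16}$) truncates loudly (`truncated` flag). Memory is
  controlled by preferring many small colonies (the reference protocol is
  2000 colonies, 6 generations) over one huge colony. Each colony runs on
  an independently derived child seed, so colony counts do not perturb one
  another.
* **Estimators** (`summary_stats()`, `population_stats()`): divisor-$n$
  (population) variance convention, chosen because ensembles are large and
  the target quantities are distribution properties. Degenerate samples have
  $\mathrm{CV}^2 = 0$ and skewness 0 by convention. Bootstrap standard
  errors resample individual values for lineage ensembles and whole colonies
  for population statistics, respecting within-colony dependence.
  `ks_distance()` compares an empirical cdf against the exact law cdf.
  The default estimation protocol is the endpoint ensemble (many replicates
  observed at one late time); `time_average_stats()` provides the ergodic
  alternative -- time-averaging one long trajectory -- as a cross-check, with
  the caveat that its bootstrap errors ignore autocorrelation.

## Numerical choices

* Quadrature: `stats::integrate` on $(0,\infty)$, relative tolerance
  $10^{-12}$ for moment cross-checks, with the integrand written on the log
  scale inside `dstationary()` for stability at extreme shapes.
* Ties in the colony event order are broken by cell id (the birth-ordered
  queue is deterministic given the seed).
* Zero-concentration mothers (possible only on a cold start before the first
  burst) split into two zero daughters; `draw_partition()` itself requires
  $x>0$ per its contract.
* Skewness of a degenerate sample is 0; the boundary of an existence region
  (tilt exactly 0) is treated as non-existent and raises an informative
  error naming the violated condition.

## What the simulations do and do not emulate

The generators emulate the model worlds above: continuous concentration,
instantaneous exponential bursts, memoryless growth feedback, i.i.d. or
adder-controlled cycles, moment-matched partitioning. They do not emulate
mRNA or promoter-state dynamics, extrinsic parameter noise, molecule
discreteness, asymmetric volume division, cell death, or spatial structure.
Agreement of the simulators with the analytic laws therefore validates the
implementation and the derivations -- it does not by itself validate the
model against real single-cell data.

## Default problem sizes

The worked examples and the acceptance workflow use the reference protocol:
5000 independent lineages, 2000 colonies, 6 generations for the partitioning
model; 5000 lineages with burn-in $t = 50/\gamma$ and a few hundred colonies
with a horizon of 12 dilution times for the feedback model. Package tests
exercise the same pipelines at reduced replicate counts (a few hundred to a
few thousand samples), sized so that three bootstrap standard errors still
separate the effects under test.

## Known limitations

* The feedback-model population snapshot converges to the stationary
  population law only as the colony horizon grows; with a single-cell warm
  start, a horizon of 12 dilution times leaves no measurable bias at the
  reference replicate counts, but much shorter horizons will.
* The `max_cells` stop criterion reaches the target census along the
  birth-ordered queue, which can differ by a cell or two from strict
  division-time order in hazard mode.
* Time-dependent (transient) distributions are out of scope: the analytics
  cover stationary laws only, and transients are accessible only through
  simulation.
* The growth-coupled burst mode reports perspective ratios by simulation
  only; no closed form is provided for its stationary law when dilution
  feedback is active as well.
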