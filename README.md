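# burstdilution

Stochastic gene expression looks different depending on where you stand.
Following one cell through time (the **single-cell**, or lineage,
perspective) and pooling all cells of a proliferating colony at one instant
(the **population** perspective) are both legitimate ways to quantify noise
in a protein's concentration — and for growth-coupled or
partitioning-sensitive genes they disagree. `burstdilution` is an R toolkit
for quantifying exactly when and by how much, aimed at people modelling
stress-response programs, toxic or growth-inhibitory proteins, and
division-borne expression noise in microbes.

## The model

Protein concentration `x(t)` in a cell is a piecewise-deterministic Markov
process:

* synthesis bursts arrive at frequency λ and jump `x` up by an
  Exp(mean β) amount;
* between bursts, growth dilutes concentration at rate
  `dx/dt = −γx/(1+kx) − d·x`, where `k` is the strength of growth
  inhibition by the protein (positive feedback on concentration) and `d` an
  optional degradation rate;
* cells divide with the growth rate `γ/(1+kx)` (or on timer/adder cycle
  rules), daughters inheriting the mother's concentration — exactly, or with
  partitioning noise of variance `εx` bounded inside `(0, 2x)`.

The stationary law in each perspective is known in closed form:
`p(x) ∝ (1+kx) e^(−sx)(sx)^(a−1)` with shape `a = λ/γ` and tilt
`s = 1/β − λk/γ` for a lineage, and `a = (λ/γ)/(kβ+1)`,
`s = 1/β − k·a` for the population; each exists only while its tilt is
positive, and the population region strictly contains the single-cell one.
For the partitioning model the lineage noise is
`CV²_x = (ε/(2 ln 2) + β)/x̄`, invariant to cell-cycle-time randomness,
while the population noise grows with it. The package provides the laws
(density/cdf/quantile/sampling), exact moments with an independent
quadrature cross-check, existence classification, exact event-driven lineage
simulators, an agent-based colony simulator (timer, adder, or
state-dependent division; lineage trees exportable as newick), ensemble
estimators with bootstrap errors, and canned comparison experiments.

## Worked example

Hold the single-cell mean at 100 while switching feedback on
(`k = 1/100`, β = 10, γ = 1):

```r
library(burstdilution)

lam <- burst_frequency_for_mean(100, k = 0.01, beta = 10, gamma = 1)
lam
#> [1] 4.761905

p <- burst_params(lam, beta = 10, gamma = 1, k = 0.01)
dplyr::bind_rows(stationary_moments(p, "single_cell"),
                 stationary_moments(p, "population"))
#> # A tibble: 2 × 4
#>   perspective  mean   cv2 skewness
#>   <chr>       <dbl> <dbl>    <dbl>
#> 1 single_cell 100   0.200    0.874
#> 2 population   84.0 0.221    0.919
```

Without feedback a burst frequency of 10 gives the same mean of 100 in both
perspectives; with feedback the population sees a lower mean (84.0: slowly
dividing high-expressers are under-represented) and higher noise
(0.221 vs 0.200). Simulation agrees:

```r
xs <- simulate_feedback_ensemble(p, n = 5000, t_end = 50, seed = 1)
summary_stats(xs$x)[, 1:4]
#> # A tibble: 1 × 4
#>       n  mean   cv2 skewness
#>   <int> <dbl> <dbl>    <dbl>
#> 1  5000  99.8 0.195    0.781

snaps <- simulate_colonies(250, p, stop = list(time = 12), seed = 2,
                           x0 = function(n)
                             rstationary(n, stationary_law(p, "single_cell")))
population_stats(snaps)[, 3:5]
#> # A tibble: 1 × 3
#>    mean   cv2 skewness
#>   <dbl> <dbl>    <dbl>
#> 1  84.3 0.219    0.914
```

For partitioning noise (γ = ln 2, mean 20, ε = 1, exponential cell cycles),
the lineage noise sits at the predicted `ε/(2 ln 2 · 20) ≈ 0.036` no matter
how noisy the cell-cycle time is, while the population noise roughly doubles
it:

```r
res <- run_experiment("cycle_noise_sweep", seed = 1, scale = 0.25)
subset(as.data.frame(res$tables$stats), cv2_tau %in% c(0, 1))[, 1:4]
#>    cv2_tau perspective mean    cv2
#> 1        0 single_cell 20.0 0.0383
#> 2        0  population 20.0 0.0349
#> 3        0 analytic_sc 20.0 0.0361
#> 10       1 single_cell 20.1 0.0388
#> 11       1  population 20.0 0.0719
#> 12       1 analytic_sc 20.0 0.0361
```

A thin command-line interface over the same functions lives in
`inst/scripts/burstdilution-cli.R` (subcommands `analytic`,
`simulate-lineage`, `simulate-colony`, `experiment`).

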