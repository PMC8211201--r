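# netsubsample

How reliable are *global* social-network measures when you haven't
seen every animal, or haven't seen each animal often? `netsubsample`
is an R package for researchers who build animal social networks from
repeated group observations (bats sharing roosts, birds at feeders,
ungulates in herds) and need to know how estimates of overall network
structure — not individual centrality — respond to the two axes of
sampling effort: the number of individuals included and the number of
observations per individual.

## What it computes

Networks are built under the **gambit of the group**: individuals
recorded in the same group (same roost, same day) are associating.
Edges are the half-weight association index

    HWI = x / (x + y_AB + (y_A + y_B) / 2)

where, for a dyad, `x` counts sampling periods together, `y_AB` both
seen but apart, and `y_A`, `y_B` only one seen (the simple-ratio index
is available as a toggle). On these weighted networks the package
computes:

* **Modularity** `Q = (1/2W) Σ_ij (w_ij − s_i s_j / 2W) δ(c_i, c_j)`
  of the partition found by greedy agglomerative modularity
  maximization, with a **Monte-Carlo test**: the data stream is
  reshuffled within days (preserving each day's individuals and group
  sizes), and `p` is the share of randomized networks with `Q` at
  least the observed value.
* **Graph density** and **clustering coefficient** (transitivity) of
  the binarized network.
* **Community assortativity (Rcom)**: observation days are
  bootstrapped, communities re-detected, and Rcom is the discrete
  weighted assortativity of the observed community labels on the
  dyadic co-membership proportions — a `[−1, 1]` measure of confidence
  in community *assignment*, with 0.5 the conventional adequacy
  threshold.
* The **subsampling experiment**: draw a grid of (individuals ×
  observations-per-individual) samples from a balanced reference
  dataset, recompute everything per sample, code the outcomes
  (evidence for structure, acceptable Rcom, correct community count,
  dyadic similarity to the reference), and summarize with linear and
  logistic regressions on the sampling regime.

A synthetic fission-fusion roosting generator with planted community
structure (daily home roosts, fission splits, drifting individuals,
imperfect detection) makes every stage testable with known ground
truth, and can be calibrated so its reference network matches a target
density / modularity / clustering regime.

## Worked example

```r
library(netsubsample)

# a 30-bat colony: 3 communities of 10, 60 days, 6 roost boxes
cfg <- roost_config(n_individuals = 30, community_sizes = c(10, 10, 10),
                    n_days = 60, n_roosts = 6, p_detect = 0.8,
                    p_fission = 0.3, p_drift = 0.2, seed = 1)
pop <- generate_population(cfg)

# balanced reference network: everyone capped at 30 observations
ref <- build_observed(pop$data, min_days = 30, obs_cap = 30,
                      n_rand = 1000, n_boot = 1000, n_repeat = 10, seed = 2)
ref
#> Observed reference network: 30 individuals x 30 obs each
#>   Q = 0.260 (p = 0, 1000 permutations), 3 communities
#>   density = 0.963, clustering = 0.964, Rcom = 0.987 (10 x 1000 bootstraps)
```

The reference colony is significantly modular (no randomized network
reached the observed `Q`, so `p = 0` at 1000 permutations), the three
planted communities are recovered, and community assignment is highly
repeatable (Rcom 0.987). Now subsample it:

```r
res <- run_experiment(ref, individuals_grid = c(10, 20, 30),
                      obs_grid = c(5, 15, 30), n_reps = 20,
                      n_rand = 200, n_boot = 200, seed = 3)
summarize_grid(res, ref)
#>   n_individuals n_obs evidence acceptable_rcom correct_n_comm within_one n_reps
#>            10     5        0               7              1          2     20
#>            10    15       10               8             11         20     20
#>            10    30       19              17             11         20     20
#>            20     5        2              15              0          4     20
#>            20    15       20              10             20         20     20
#>            20    30       20              19             20         20     20
#>            30     5        2               4              0          1     20
#>            30    15       20              20             20         20     20
```

With 5 observations per individual, community structure is almost
never detected no matter how many individuals are included (0–2 of 20
replicates), while 15 observations suffice at 20+ individuals (20 of
20) — observations per individual, not individuals, is the binding
constraint, and adding individuals mainly narrows the spread of the
estimates. The regression summary makes the interaction explicit:

```r
fit_discrepancy_model(res, "delta_n_comm")
#> Linear regression (log1p(delta_n_comm) ~ log(n_individuals) * log(n_obs))
#>                 term coefficient std_error   p_value
#>          (Intercept)     -0.1546   0.65894 8.148e-01
#>        n_individuals      0.9557   0.22991 5.307e-05
#>                n_obs      0.6088   0.26041 2.066e-02
#>  n_individuals:n_obs     -0.5002   0.09242 2.304e-07
#> R-squared = 0.731
```

i.e. at few observations, adding individuals *increases* the error in
the estimated number of communities; the negative interaction shows
more observations per individual neutralize that.

The whole pipeline (generate → reference → experiment → summaries →
regressions, with per-file metadata sidecars) runs from one
configuration object via `run_all(run_config(...))`, with a `"fast"`
profile (200 permutations/bootstraps) for desk-scale work.

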