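---
title: "Global network metrics under subsampling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global network metrics under subsampling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsubsample)
```

## The question the package answers

Animal social networks are almost always estimated from incomplete
data: not every individual is tagged, and tagged individuals are not
detected every day. `netsubsample` quantifies how two distinct axes of
sampling effort — the **number of individuals** included and the
**number of observations per individual** — affect estimates of
*global* network structure: modularity and its significance, the
number of communities, graph density, clustering coefficient, and the
confidence with which individuals can be assorted into communities.

The workflow mirrors how such studies are actually run. A "observed"
reference network is built from all available (balanced) data; then
sub-networks are drawn by randomly discarding individuals and
observations, every metric is recomputed, and each sample is scored
against the reference. The discrepancies, as a function of the
sampling regime, tell a study designer how much data is enough for
each metric.

## The network model

### Gambit of the group and association indices

Associations follow the gambit of the group: individuals recorded in
the same roost on the same day are assumed to associate. The sampling
period is one day; within-day event structure is deliberately ignored.

For each dyad, over all days, we count `x` (together), `y_ab` (both
detected, apart), `y_a` and `y_b` (only one detected). Edges are the
half-weight index

$$\mathrm{HWI} = \frac{x}{x + y_{AB} + \tfrac{1}{2}(y_A + y_B)},$$

chosen because daily detection is incomplete and many days see only
one member of a dyad; the simple-ratio index
`x / (x + y_ab + y_a + y_b)` is available as a toggle
(`association_matrix(..., index = "sri")`). Dyads with a zero
denominator (never detected) get index 0, not `NA`: a fully
disconnected sample network is treated as a real, edgeless network,
which is exactly the degenerate case the outcome codings need
downstream. Because an individual contributes at most one record per
day, the HWI denominator reduces to `(det_A + det_B) / 2`, which is
what the permutation engine exploits (only co-occurrence counts change
under within-day reshuffles).

When a subset of individuals is analysed, counts are computed as if
the unsampled individuals never existed — the record stream is
subsetted first and the indices rebuilt from it. Days on which only
the removed individuals were seen therefore vanish from the `y`
bookkeeping of the retained dyads. This is the natural consequence of
recomputing the index on the subsetted stream; users comparing with
pipelines that freeze per-day effort should be aware of the
difference.

### Global metrics

Graph **density** is the proportion of dyads with a positive index and
the **clustering coefficient** is `3 * triangles / connected triples`,
both computed on the binarized graph (edge iff index > 0). The
edge-counting definitions these names refer to are topological, and
this matches the behaviour of the standard graph-library functions;
whether weights should enter is genuinely ambiguous in parts of the
literature, so the binarized choice is stated here once and used
everywhere.

**Modularity** `Q` of a partition is weighted Newman modularity,

$$Q = \frac{1}{2W}\sum_{ij}\left(w_{ij} -
  \frac{s_i s_j}{2W}\right)\delta(c_i, c_j),$$

with `s_i` node strength and `W` total edge weight. Communities are
found by greedy agglomerative modularity maximization (igraph's
fast-greedy algorithm): merge the pair of communities with the largest
modularity gain until no gain remains, and cut the merge path at its
modularity peak. The algorithm is deterministic for a fixed input, so
identical matrices always give identical partitions. The reported `Q`
of any network is always the modularity of this detected partition,
not of any planted or external labelling. An edgeless matrix returns
the all-singleton partition with `Q = 0` and a degenerate flag.

### The permutation test for community structure

Significance of `Q` is assessed with a day-constrained data-stream
permutation: within each day, detected individuals are reassigned
uniformly at random to that day's roost groups, preserving each day's
individual set and the multiset of group sizes. Each of the `n_rand`
(default 1000) random networks is an independent full reshuffle —
independent draws sample the constrained space uniformly, so no serial
swap chain or burn-in is needed. The Monte-Carlo p-value is the
proportion of random networks whose detected-partition `Q` is at least
the observed `Q`; ties count toward the numerator (the conservative
inclusive reading), and `p < 0.05` is coded as evidence for community
structure. Null distributions of density and clustering are stored
alongside `Q` for inspection, but only `Q` is tested — only its
p-value feeds the downstream codings.

### Community assortativity (Rcom)

Confidence in the *assignment* of individuals to communities — a
different question from whether structure exists — is measured by
bootstrap community assortativity. Observation days are resampled with
replacement (the day is the sampling period, hence the bootstrap
unit), the network is rebuilt and communities re-detected for each of
`n_boot` replicates, and the proportion of replicates co-assigning
each dyad forms a co-membership matrix. Rcom is Newman's discrete
weighted assortativity of the *observed* community labels on that
co-membership network. Measuring consistency dyadically makes label
matching across replicates unnecessary — co-membership is invariant to
label switching. This is the estimator of the bootstrap-assortativity
method this metric originates from (Shizuka & Farine 2016); the
package implements it directly since its reference implementation is
not a dependency.

Rcom lies in `[-1, 1]` (tiny numerical overshoots are clamped, at
tolerance `1e-9`); 1 means dyads are always re-assorted identically,
and 0.5 is the conventional adequacy threshold. Two degenerate cases
are defined rather than propagated as errors: an edgeless observed
network has `r_com = 0`, and an observed partition with a single
community leaves the coefficient 0/0, which is also coded as 0 with a
degenerate flag. For the reference network the whole procedure is
repeated (default 10 times, each with 1000 bootstraps) and the mean
reported, smoothing bootstrap noise in the benchmark value.

## The subsampling experiment

`build_observed()` filters the detection stream to individuals seen on
at least `min_days` days (default 40) and truncates each to exactly
`obs_cap` (default 40) randomly chosen observations, yielding a
balanced dataset: equal effort per individual, though not on the same
days. `run_experiment()` then crosses an individuals grid (default 5,
10, 15, 20, 25, 35, 50, 75, 99) with an observations grid (default 1,
5, 10, 15, 20, 30, 40), draws `n_reps` (default 100) independent
samples per regime — the complete cell is excluded, being the
reference itself — and scores each sample:

* global metrics and their absolute discrepancies from the reference;
* `evidence` — 1 iff the permutation test gives `p < 0.05` on a
  non-degenerate network;
* `r_com` and `acceptable_rcom` — 1 iff `0.5 <= r_com <= r_com_obs`.
  Both ends are closed; boundary inclusion is a convention the package
  fixes since the inequality endpoints are not meaningful at bootstrap
  resolution anyway;
* `similarity` — the proportion of sampled dyads whose same/different
  community status agrees with the reference (a Rand index restricted
  to the sampled individuals);
* degenerate edgeless samples (common at 1 observation per
  individual): `q = 0`, one community per individual, `evidence = 0`,
  `r_com = 0`.

Per-replicate seeds are derived deterministically from the master seed
and the regime coordinates, so the experiment is reproducible and
resumable (`checkpoint_dir` flushes finished regimes to CSV and skips
them on rerun). Permutation and bootstrap budgets are configurable:
the reference analysis budgets are 1000/1000, and `run_config()`'s
`"fast"` profile (200/200) exists because a full grid at 1000/1000 is
a cluster-scale computation, not a desk-scale one.

`summarize_grid()` recounts, per regime, evidence, acceptable Rcom,
the exactly-correct community count, and the within-one count — the
last two because "how many communities" can be scored both strictly
and within a tolerance band of one, and the two framings answer
different design questions.

`fit_discrepancy_model()` and `fit_detection_model()` summarize the
results table: OLS of (log-transformed) absolute discrepancies on
`log(n_individuals) * log(n_obs)`, and logistic regressions of the
binary codings on the untransformed regime variables. Under the log
transform the response uses `log1p`, because discrepancies of exactly
zero occur (a sample can hit the reference community count exactly);
the shifted natural log is domain-valid and order-preserving, and the
choice is surfaced in the `transform` field of the summary. The
clustering-coefficient discrepancy is conventionally fitted
untransformed. Logistic fits refuse single-class responses and
(quasi-)complete separation explicitly rather than returning
unidentifiable coefficients.

## The synthetic generator

There is no public dataset in this problem domain with a known ground
truth, so the package ships a generative stand-in whose structure is
known by construction. A closed population is partitioned into
communities (defaults: 99 individuals, three communities of 33 — the
scale of a well-studied bat maternity colony). Each day:

1. every community gets a "home" roost among `n_roosts` (default 11),
   drawn independently, so two communities may share a roost —
   overlapping roost use is what creates between-community edges even
   without drift; a `disjoint_homes` flag forces separation for
   clean-limit tests;
2. with probability `p_fission` a community splits across two roosts
   for the day, members assigned by fair coin — the minimal mechanism
   that keeps within-community association below 1, as in real
   fission-fusion groups;
3. each individual is detected with probability `p_detect`,
   independently across individuals and days (no roost-level reader
   failure model — the simplest missingness mechanism);
4. a detected individual roosts with its community with probability
   `1 - p_drift`, otherwise at a uniformly random roost.

Drift targets a uniform choice over *all* roosts deliberately: at
`p_drift = 1` every roost choice is then independent and identically
distributed, the days are exchangeable under the within-day
constraint, and the permutation test must reject at its nominal 5%
rate — a calibration property the test suite checks. Excluding the
individual's own community roost from the drift destinations would
leave community-correlated holes in the roost distribution and a
structureless limit that is not actually structureless.

The defaults `p_detect = 0.45`, `p_fission = 0.7`, `p_drift = 0.4`
come from `calibrate_generator()`, a grid search (averaging at least
five simulated seeds per candidate) that matches the balanced
reference network's metrics to a target regime of high density
(0.675), high clustering (0.828) and modest but significant modularity
(0.285) — the regime of a highly connected fission-fusion colony.
With eleven roosts and three communities, home-roost collisions set a
floor on density near 0.76, so the calibrated configuration matches
modularity almost exactly while density and clustering sit within 0.1
of their targets; the calibration object reports these residuals and
never silently claims convergence (a `tolerance = 0` request, which a
stochastic generator cannot meet, simply returns the best candidate
flagged as non-converged).

What the generator does *not* emulate: within-day entry/exit events
(collapsed to one roost per day, as a last-observation-before-sunrise
rule would), spatial roost locations, demographic turnover, roost- or
weather-driven detection failure, and temporal drift in community
membership over the season. Passing tests on generator data therefore
demonstrate the pipeline's statistical behaviour under a known,
stationary social structure — not that any particular field system
satisfies these assumptions.

## Numerical and design choices

* **Determinism.** All randomness flows through explicit seeds;
  `derive_seed()` maps (master seed, coordinates) to child seeds below
  `2^31`, and RNG state is always restored, so library calls never
  perturb a caller's stream. Identical configuration and seed give
  byte-identical result files.
* **Tie-breaking.** Community detection is the deterministic greedy
  agglomeration above; equal-gain merges resolve by the algorithm's
  fixed internal order, so repeated runs cannot disagree.
* **Degenerate inputs.** Edgeless networks, single-community
  partitions, zero-denominator dyads and single-class regression
  responses all have defined, documented behaviour (see above); none
  raise silently-wrong numbers.
* **Problem sizes.** The test suite exercises the full-size scenario
  (99 individuals, 131 days) with a reduced grid (4 x 3 regimes, 20
  replicates, 200 permutations/bootstraps) and uses brute-force
  oracles only on tiny instances (up to 8 individuals, 15 days), sizes
  chosen to keep a complete run of the suite on one CPU comfortable
  while still covering the regimes where the trends of interest
  appear.

## Known limitations

* Greedy agglomeration is a heuristic: it can merge past small, weakly
  separated communities, and its community count is biased downward on
  sparse networks. That bias is part of what the subsampling
  experiment *measures*, so no attempt is made to correct it; but the
  absolute community counts should not be read as estimates of truth.
* The acceptable-Rcom band depends on the reference Rcom, which is
  itself an estimate; with few bootstraps the band's upper edge is
  noisy. Use the repeat-averaged reference (default 10 x 1000) when
  the band matters.
* The regression summaries describe monotone trends on a grid; they
  are descriptive, not causal, and the log-transform choices (natural
  log, `log1p` for responses with zeros) are conventions, surfaced in
  the output rather than hidden.
* One calendar day is the only supported sampling period; systems
  whose grouping dynamics are faster than daily need a different
  collapse rule before this package applies.
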