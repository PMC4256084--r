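---
title: "Modelling signal traffic on directed connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling signal traffic on directed connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(queuenet)
```

## The question and the model

Anatomical connectomes are directed graphs, but most graph statistics
ignore what the edges are *for*: carrying signals. `queuenet` treats a
binary directed connectome as a communication system and measures which
nodes end up handling the traffic. The model is deliberately minimal, so
that everything it reports can be attributed to the network's topology and
edge directionality rather than to assumptions about node heterogeneity:

* **Generation.** Signal units appear as one network-wide Poisson process
  of rate $\lambda$. Each unit draws a uniformly random source and a
  uniformly random destination among the other $N-1$ nodes. (An equivalent
  per-node parameterization, independent processes of rate $\lambda/N$, is
  available via `per_node = TRUE`.)
* **Diffusion.** A unit at node $i$ with out-degree $k_i$ hops to each
  efferent neighbour with probability $1/k_i$ after completing service.
  Units carry no routing knowledge; transport is a random walk absorbed at
  the destination.
* **Queueing.** Every node is a single exponential server (rate $\mu$,
  non-preemptive) with a buffer of $K$ slots. Queueing is
  last-in-first-out: the most recent arrival sits at the front and will be
  served next. When a unit arrives at a full buffer, the *oldest* queued
  unit (the back of the buffer) is ejected from the network and the
  newcomer takes the front; the unit in service is never displaced. LIFO
  with drop-oldest mimics the time-decay of biological signals: stale
  information is the first to be lost.
* **Absorption.** A unit arriving at its destination is removed
  immediately, without occupying the server or buffer.

All nodes and edges are identical — no weights, no per-area capacities —
matching the conventions of unweighted graph analysis.

The node-level metrics are **arrivals** (a count over the measurement
window), **node contents** $n_i(t) = s_i(t) + q_i(t)$ (server indicator
plus queue length, reported as its exact time average), and
**utilization** (fraction of time $s_i = 1$). Arrivals include exogenous
generations, hops from afferent projections, and destination absorptions;
a flag (`count_deliveries = FALSE`) excludes absorptions for sensitivity
analysis, since either accounting is defensible and the choice is recorded
with the run.

## Numerical design of the engine

The simulator is an event-driven C++ core behind `simulate_traffic()`.
Exponential variates are produced by inverse transform, $-\log(u)/\text{rate}$,
from R's Mersenne-Twister stream, so a run is a deterministic function of
`(network, params, seed)`. Simultaneous events are ordered by scheduling
sequence (first scheduled, first processed); on a service completion the
downstream arrival is processed before the next unit at the emptied server
starts service. Time-averages are accumulated from the exact event-time
integrals — uniform resampling (`resample_uniform()`, zero-order hold by
default, linear interpolation selectable) exists for plotting and for
putting replicate runs on a common grid, never for computing the reported
metrics. The ledger identity
`generated = delivered + ejected + residual` is enforced by construction
and asserted, exactly, over thousands of randomized runs in the test
suite; the engine also records per-node maximum queue lengths so the
buffer bound $|q_i| \le K$ is directly checkable.

`scripted_simulate()` replays the identical mechanics with every random
draw replaced by explicit values. Its canonical use is `walkthrough_fixture()`, a
three-node chain with two-slot buffers on which four labelled units
exercise every mechanic (front-of-buffer insertion, displacement of the
oldest unit, onward hops); the test suite pins the full event log of that
replay and cross-checks the engine against an independently coded
straight-line interpreter on random scripts.

Validation against queueing theory uses the two-node reciprocal network:
there each node receives exogenous Poisson arrivals at rate $\lambda/2$,
and because an arrival to a full buffer swaps one unit for another, the
number-in-system is a birth–death chain on $\{0, \dots, K+1\}$ with up-rate
$\lambda/2$ and down-rate $\mu$. Simulated utilization and mean contents
are required to match the stationary law $p_n \propto (\lambda/2\mu)^n$
within three Monte-Carlo standard errors at loads below, at, and above
saturation ($\rho \in \{0.3, 0.8, 1.5\}$, 16 replicates of $T = 5\times10^4$).
A 512-replicate calibration experiment found no detectable bias
(≈ 0.1 standard errors).

## Transient handling

Runs start from an empty network, so an initial transient is excluded.
Counters use the window $[t_\text{transient}, T]$ and time-averages the
(identical in measure) window $(t_\text{transient}, T]$. The default cut
is 2% of $T$ — at the conventional full duration of $2\times10^6$ time
units this is the customary 40,000-unit cut — and
`ensemble_transient_estimate()` automates the ensemble-average rule:
average replicate total-contents series, estimate the stationary level
from the terminal fraction of the average, and report the earliest time
from which the series stays within a tolerance band (default ±5% of the
level) of it. The tolerance is a parameter of the rule, not a canonical
constant; `remove_transient()` recomputes any recorded run on a different
window directly from its event log.

## Null models and inference

Two surrogate families isolate the two candidate explanations for high
traffic:

* `rewire_degree_preserving()` — Markov edge switching (default budget
  $10\,|E|$ attempted swaps, the standard burn-in for switching walks;
  swaps creating self-loops or duplicate edges are rejected and count
  toward the budget). Every node keeps its exact in- and out-degree, so
  any collapse of a node's metric in this ensemble implicates topology
  beyond degree.
* `reverse_fraction()` — flips a uniformly random subset of exactly
  `round(fraction × U)` of the $U$ unidirectional projections (half-up
  rounding; reciprocal pairs untouched). Fraction 1 is the deterministic
  involution that transposes the unidirectional part, and probes the
  causal role of directionality.

`surrogate_ensemble()` regenerates surrogates whose minimum out-degree is
0 (unroutable) with a fresh derived seed, up to a bounded retry count;
whether the original analyses enforced connectedness is unknowable from
the available description, so the policy is explicit and recorded in the
ensemble's attributes. Inference (`null_ensemble_report()`) follows the
R-versus-S design — R runs on the empirical network, one run on each of S
surrogates — with $z = (\bar{x}_\text{emp} - \bar{x}_\text{null}) /
\mathrm{sd}_\text{null}$ and a normal-approximation two-sided p-value; an
empirical percentile p-value is reported alongside because null
distributions over surrogate topologies can be skewed. Large ensembles
(R = S = 100 and beyond) are configurable; the package defaults to
R = S = 20, which the funnel-recovery experiments below show is already
decisive at desk scale.

## The steady/jammed phase boundary

System behaviour is governed by the arrival:service ratio. Below the
transition, total network contents are stationary; above it, the
bottleneck nodes saturate. `phase_map()` classifies each probed $\lambda$
from one recorded run: *jammed* if the OLS slope of the resampled total
contents over the post-transient window drifts by at least `slope_tol`
(default 5%) of the mean level — with a floor of one signal unit so a
near-empty system is never flagged on relative noise — **or** if at least
`loss_tol` (default 5%) of generated units were ejected. The loss
condition is needed because buffers are finite here: a deeply jammed
system does not grow without bound but plateaus near the capacity
$N(K+1)$ while shedding a macroscopic fraction of its load, so a
slope-only rule would misread saturation as stationarity.

## Synthetic data: what it emulates and what it does not

`generate_background()` draws a directed Erdős–Rényi graph and redraws
(bounded retries) until every node has out-degree ≥ 1 — required for
routing — *and* in-degree ≥ 1, which guarantees the fully reversed network
is routable too (reversal exchanges the roles of afferents and efferents).
`plant_funnel()` rewrites chosen relay nodes to the archetypal imbalance:
many afferents (defaults 34 and 41, the degree profile of the macaque
parahippocampal relays), one or two efferents always including the target,
all planted edges forced unidirectional so that the reversal null acts on
every one of them. The homogeneous background isolates the funnel
mechanism by construction; it does not reproduce a real connectome's
degree heterogeneity, clustering, reciprocity (~5% reciprocal pairs at the
default density, versus much higher values in real cortical matrices) or
spatial embedding, so passing the recovery tests demonstrates sensitivity
of the pipeline to planted funnels, not performance on anatomical data.

`synthetic_connectome()` is a harder, *synthetic* stand-in for a collated
macaque matrix, built when the real supplementary dataset is unavailable:
242 nodes and exactly 4090 edges; relay areas TFM (in 34, out 1 → CA1) and
TFL (in 41, out 2 → CA1 and prosubiculum); a rich club of 8 hubs with
5-fold attachment propensity, giving hub degrees in the 60–90 range while
CA1 itself stays unremarkable (in-degree ≈ 17 ≈ the network mean). Only
these documented facts are matched — everything else is weighted-random —
and the object is flagged `synthetic` accordingly.

## Operating points used by the tests and acceptance script

Defaults are $\mu = 1$ and $K = 10$; the generation rate has no canonical
published value, so analyses choose $\lambda$ inside the steady regime via
`phase_map()`. The shipped experiments use:

* funnel recovery: $N = 100$, background out-degree ≈ 5, $\lambda = 0.05$,
  $T = 3000$, R = S = 20. At this operating point the relays run at
  utilizations ≈ 0.4–0.5 (comfortably steady) and the target's arrivals
  z-score versus rewired surrogates is far beyond +3 for every tested
  seed, while the fully reversed network's z collapses below 2 — the
  planted analogue of comparing an empirical network against topology and
  directionality nulls. The reversal comparison is run by treating the
  reversed network as the empirical side against its own degree-preserving
  nulls: at fraction 1 the reversal is deterministic, so it cannot itself
  serve as a null *distribution*.
* stand-in connectome: $\lambda = 0.1$, $T = 2\times10^5$, 20 simulations
  (a deliberate scale-down from the conventional $2\times10^6$; at these
  sizes every reported statistic is already stable across seeds). Rankings
  are computed on ensemble-mean metrics. TFL splits its throughput exactly
  in half between CA1 and prosubiculum, so which of those two edges ranks
  second is a statistical tie; the tests therefore assert that TFM→CA1 is
  the single most-traversed connection, that the three relay efferents are
  the top three, and that the two heaviest CA1-terminating projections are
  the relay ones.

## Degenerate inputs and tie-breaking

Self-loops are rejected at load (the model has no self-projections); an
explicit `drop_self_loops = TRUE` removes them with a warning. Non-binary
entries are errors, never weights. Rankings resolve ties by average rank
with node-label order as the recorded row order; `top_k_edges()` breaks
count ties by `(from, to)` label order. `degree_outlier_scores()` treats a
numerically exact regression as having no outliers (studentized residuals
of an exact fit are noise ratios), and classifies a point whose deletion
makes the fit exact — where studentization degenerates — by its raw
residual sign. `zscore_vs_null()` refuses zero-variance nulls rather than
returning infinities.

## Limitations

Uniform node capacities, unweighted edges, unchanging signal units, no
oscillatory gating or structured (1/f) input, and no spatial constraints
on the null models: all are outside this package's scope. Conclusions
about real anatomies inherit the uncertainty of collated tract-tracing
matrices; the synthetic stand-in exists to exercise the pipeline, and no
statement about the real macaque connectome should be based on it.
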