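---
title: "Quantifying ictogenicity and optimizing virtual resections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ictogenicity and optimizing virtual resections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictonet)
```

## The model

Epilepsy surgery aims to remove the brain tissue that is indispensable for
seizure generation. `ictonet` treats this as a network problem: electrodes
(or brain regions) are nodes of a weighted functional network, and the
propensity of that network to generate seizure-like activity is measured by
simulating excitable dynamics on it. Node `j` carries a canonical theta
neuron,

$$\dot\theta_j = (1 - \cos\theta_j) + (1 + \cos\theta_j)\, I_j(t),$$

with input

$$I_j = I_0 + \xi_j(t) + \frac{K}{N}\sum_i a_{ij}\,
 \bigl[1 - \cos(\theta_i - \theta_s)\bigr],$$

where $a_{ij}$ is the weight of the edge from $i$ to $j$, $K$ a global
coupling scale and $\theta_s$ the stable resting phase. With mean drive
$I_0 < 0$ each node is excitable: it rests at
$\theta_s = -\arccos\!\bigl[(1+I_0)/(1-I_0)\bigr]$ and must be pushed past
the saddle at $\theta_u = -\theta_s$ to fire a full phase rotation, the
model's seizure-like event (a saddle-node-on-invariant-circle scenario).
Defaults are $I_0 = -1.2$ and Gaussian white noise of standard deviation
$\sigma = 0.6$, integrated by Euler–Maruyama with step $\mathrm{d}t = 0.01$
(dimensionless time), so each noise increment carries
$\sigma\sqrt{\mathrm{d}t}$.

**Noise placement and scaling.** The noise enters through $I_j$ only, hence
is multiplied by $(1+\cos\theta_j)$, and $\sigma$ is read as the intensity
of the driving white noise (the SDE reading). The alternative
per-step-deviation reading would leave an activity floor of roughly 0.3 at
zero coupling, making complete elimination of epileptiform activity
($SI = 1$, below) unreachable; under the SDE reading the uncoupled baseline
is essentially silent and the full $SI$ range is attainable, which matches
the observed behaviour of the framework. Any residual constant is absorbed
by the calibration of $K$.

**Classifying epileptiform samples.** The per-sample state uses the saddle
as the dynamical boundary: a node is epileptiform from the moment its phase
crosses $\theta_u$ in the increasing direction until it next crosses
$\theta_s$ in the increasing direction, i.e. while a rotation is in
progress (both checks are wrap-aware). We end the state at the upward
crossing of $\theta_s$ itself rather than at entry into a finite
neighbourhood: a trajectory parked just above $\theta_s$ jitters across it
within a step or two under any nonzero noise, so a neighbourhood radius
would add a parameter without changing the statistics. An alternative
amplitude rule is available (`classifier_config(method =
"amplitude_threshold")`): it thresholds the smoothed phase distance from
rest, $1 - \cos(\theta - \theta_s)$. We use the distance from the resting
phase rather than the raw amplitude $1 - \cos\theta$ because the latter is
already $1 + 1/11 \approx 1.09$ *at rest* for $I_0 = -1.2$, so no fixed
threshold below 2 separates rest from rotation on the raw observable. Note
that on a perpetually rotating phase the saddle rule flags the firing arc
(about 47% of samples at $I_0=-1.2$), while the amplitude rule with a
window spanning a rotation flags it continuously; $K$-calibration absorbs
this bookkeeping difference.

## BNI, calibration, and SI

Brain Network Ictogenicity is the mean fraction of time nodes spend
epileptiform, $BNI = \tfrac1N\sum_i t_i/T$. The global coupling is
calibrated so that the intact network sits at $BNI^{(0)} = 0.5$ — a
reference operating point at which removal effects are maximally visible.
`calibrate_k()` brackets $K$ by doubling and then bisects; all evaluations
during one calibration share a fixed set of noise realizations (common
random numbers), which makes $BNI(K)$ effectively a deterministic monotone
function and lets the bisection converge cleanly. The bisection aims at the
centre of the tolerance band (`aim = 0.5`), leaving margin so that
re-estimating the operating point with fresh noise seeds stays inside the
tolerance; success is judged against the full tolerance (default
$\pm 0.05$).

Removing a node set $X$ (zeroing its rows and columns — virtual resection)
and re-simulating *at the same calibrated K* yields the Set Ictogenicity

$$SI_X = \frac{BNI^{(0)} - BNI^{(X)}}{BNI^{(0)}},$$

clamped at zero and averaged over noise realizations (the mean of
per-realization $SI$, not the $SI$ of mean $BNI$s; at the calibrated
operating point the difference is second order). $SI_X = 1$ means the
removal eliminated epileptiform dynamics; Node Ictogenicity ($NI$) is the
$SI$ of a singleton. $K$ is deliberately *not* recalibrated after removal —
recalibration would restore $BNI$ to 0.5 and erase the very effect being
measured.

Two exact shortcuts make large searches tractable without changing any
result: a removed node receives no coupling, so under common noise its
trajectory equals its isolated ($K = 0$) trajectory, which is simulated
once per realization and reused for every set; and only the surviving
subnetwork is integrated per set (with coupling still normalized by the
full $N$). All search strategies draw from one cached evaluator
(`make_si_evaluator()`), so comparisons between sets and between strategies
are paired.

## Search strategies

Finding the most ictogenic set of each size is combinatorial: an $N$-node
network has $\sum_n \binom{N}{n} = 2^N - 1$ candidate sets ($\approx
10^{12}$ at $N = 40$). The package implements:

* **Exhaustive ground truth** (`ground_truth_search()`), with a hard budget
  that refuses infeasible requests and reports the exact candidate count.
* **Simple ordering**: rank nodes by $NI$ once, add greedily; stop once
  $SI > 0.99$.
* **Recurrent ordering**: re-score the remaining nodes on the perturbed
  network after every removal ($SI$ stays referenced to the original
  $BNI^{(0)}$).
* **Stratified random search**: per-size sample counts proportional to
  $\log\binom{N}{n}$ (denser where the optimum is expected), drawn without
  replacement, budget typically equal to the GA's population × generations.
* **NSGA-II** (`nsga2_search()`): minimizes (set size, $1 - SI$) jointly.
  Individuals are fixed-length binary membership vectors; binary tournament
  on (front rank, crowding distance), uniform crossover (probability 0.9),
  per-bit mutation ($1/N$), elitist $(\mu + \lambda)$ survival. Candidates
  larger than half the network, empty, or containing forbidden nodes get
  penalty objectives $(N + 1, 2)$ *without being simulated*. Initial
  individuals draw a size uniformly up to the cap, then a uniform set of
  that size, covering the size objective from the start. Several
  independent runs (default 8) are pooled through the shared evaluator
  cache.

Convergence across runs is summarized by two proxies: the per-run dominated
hypervolume with respect to the reference point (size cap + 1, 1.1), and
the across-run interquartile range of the best $SI$ per size (converged
when the maximal spread is at most 0.05). These capture the intended
"spread of fronts in objective space" diagnostic in a fully specified form.

Strategies are compared by $\Delta SI(n) = SI_{\mathrm{ref}}(n) -
SI_S(n)$; against the exhaustive reference this is nonnegative by
construction, against the GA it may be negative. The optimal resection is
the smallest set with $SI > 0.99$; all co-optimal sets of that size are
kept, since distinct sets with equal size and $SI$ are clinically
meaningful alternatives (and constraints — forbidden nodes — can force the
GA to propose substitutes).

## Functional network inference

Clinical inputs are multichannel iEEG segments. Preprocessing follows
standard practice: anti-aliased polyphase resampling to 512 Hz, per-sample
median re-reference over artifact-free channels, and a fourth-order
Butterworth band-pass 0.5–150 Hz run forward and backward (zero phase).
Edges are surrogate-corrected mutual information: plug-in MI on
per-channel equiquantile bins ($\lfloor\sqrt{n/5}\rfloor$ bins, capped at
32 — bounded plug-in bias and invariance to monotone rescaling), minus the
95th percentile of the MI over 99 circularly time-shifted surrogates of one
channel (minimum shift 5% of the window), clamped at zero. Circular
shifting preserves each channel's marginal distribution and
autocorrelation while destroying cross-channel alignment, so the
subtracted quantile is the chance level of this estimator on these exact
signals and only dependence in excess of chance survives.

A known limitation, shared with all bivariate functional-connectivity
estimators: in a connected, strongly synchronized network, two-step
neighbours can be as statistically dependent as direct ones, so
individual indirect edges may appear. The package's inference validation
therefore uses fixtures of disjoint coupled components, where the set of
dependent pairs coincides exactly with the planted edges; on connected
fixtures, recovered edge sets should be read as dependence structure, not
anatomy.

## Synthetic data: what it emulates and what it does not

`make_cohort()` emulates the evaluation cohort shape: 13 good-outcome
(Engel I) and 7 poor-outcome (Engel IV) cases. Each case network (16 nodes
by default, directed, weighted) carries a planted ictogenic set: a dense
mutually-coupled clique (weight 1.0) wired to drive a random half of the
remaining nodes (weight 0.6) over a weak random background (weight 0.1,
edge probability 0.15). Good-outcome resections contain the planted set
plus a few extra nodes; poor-outcome resections miss at least half of it.
Outcomes are deterministic given the masks. `make_coupled_signals()` emits
the amplitude observable $1-\cos\theta$ of a theta simulation at
super-critical coupling (default $K = 4N$, comfortably above the
calibration point of the sparse binary topologies generated here) plus
i.i.d. Gaussian sensor noise.

Passing tests on these fixtures shows that the pipeline recovers planted
structure under the model's own dynamics and that the statistics behave as
designed. It does not show robustness to the many features of real iEEG
the fixtures lack: volume conduction, artifacts, nonstationarity, electrode
placement bias, label noise in outcomes, and ictogenic structure that is
not clique-like.

Artificial exemplar topologies (binary): the static model for scale-free
networks — endpoint probabilities $\propto i^{-1/(\gamma-1)}$, edges added
until $N\!\cdot\!\bar d$ directed (or $N\bar d/2$ undirected) edges exist,
giving tail exponent $\gamma$ at fixed mean degree — plus Barabási–Albert
preferential attachment as the alternative generator, exactly
in/out-2-regular random digraphs, and Erdős–Rényi $G(n,m)$. The static
model is the default for directed scale-free networks because it admits a
tunable $\gamma$ at fixed mean degree. Graph metrics: weighted degree,
betweenness on distances $1/w$, clustering on the binarized adjacency
(Fagiolo's directed generalization where needed), and eigenvector
centrality by shifted power iteration (tolerance $10^{-10}$, at most
$10^4$ iterations), undirected networks only — it is not well defined for
directed ones.

## Numerical choices

* The Euler–Maruyama loop is compiled (C++). Trigonometric refreshes use a
  quadrant-reduced polynomial in single precision (error $\sim 10^{-7}$
  rad per step, far below the stochastic forcing and the Euler
  discretization bias). Per-node trajectories are therefore deterministic
  given seeds, but bitwise equivariance under node relabeling does not
  hold (coupling sums accumulate in a different order); relabeling tests
  compare at estimation accuracy instead.
* Noise matrices are generated once per realization (`set.seed` +
  `rnorm`) and shared across all set evaluations, K-bisection steps and
  strategies — the common-random-numbers design that makes rankings
  comparable.
* Phases are wrapped to $(-\pi, \pi]$ each step; crossing detection works
  on the raw increment before wrapping.
* Sub-seeds for every stochastic component derive from a master seed by
  stable string hashing (`derive_seed()`), so adding a pipeline step never
  shifts another step's stream.
* Ties: node-ordering heuristics break NI ties toward the lower index;
  co-optimal sets are all kept, sorted lexicographically.
* Degenerate inputs fail loudly: edgeless networks cannot be calibrated
  (BNI is K-independent), all-forbidden GA runs abort, non-finite phases
  abort with a diagnostic.

## Problem sizes used in the tests

The shipped tests run at desk scale: calibration checks on a 20-node
directed scale-free network at $2\times10^5$ steps and 4 noise
realizations; the exhaustive-vs-GA comparison on five 12-node networks
(sizes 1–6, $10^5$ steps, 2 realizations, population 100, 50 generations,
4 runs); SI-distribution and graph-metric checks on ten 20-node networks
with stratified per-size samples at $2\times10^4$ steps; and the synthetic
cohort at $2\times10^4$ steps with a small GA (population 40, 20
generations, 2 runs). The full-fidelity settings of the underlying study
($4\times10^6$ steps, population 200, 100–150 generations, 8 runs) are
available through the same configuration objects; the desk-scale runs
reproduce the qualitative structure (distribution shape, correlation
signs, GA optimality on enumerable instances) while the exact percentages
of the full-fidelity distributions are expected to differ.

## Known limitations

* $SI$ values are model-based rankings, not predicted seizure-frequency
  changes; their absolute scale depends on the calibration convention.
* The theta model assumes homogeneous node dynamics ($I_0$, $\sigma$
  identical across nodes) and instantaneous coupling.
* MI networks are undirected and bivariate (see above).
* EDF ingestion is not built in; recordings enter as numeric matrices
  (CSV + JSON sidecar) via `read_recording()`.
* The recurrent ordering costs $O(N^2)$ SI evaluations and the GA
  $O(\text{pop}\times\text{gens})$ per run; both remain far below the
  exhaustive count, which is the point.
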