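---
title: "Bayesian inference of neuronal assemblies: model, samplers and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian inference of neuronal assemblies: model, samplers and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroassembly)
```

## The generative model

`neuroassembly` treats a binary population raster `s` (N neurons x M frames)
as the output of a three-step hierarchical Bernoulli process:

1. each neuron i receives an assembly label t_i, drawn categorically with
   probabilities n (the relative assembly sizes);
2. each assembly mu switches on and off independently across frames,
   omega[k, mu] ~ Bernoulli(p_mu) — p_mu is the assembly's *activity*;
3. neuron i fires at frame k with probability lambda_{t_i}(omega[k, t_i]):
   lambda(1) is the *synchrony* (the chance a member is recruited when its
   assembly is on) and lambda(0) the *asynchrony* (its baseline firing
   probability when the assembly is off).

All continuous parameters carry conjugate priors: Beta priors on p and on both
lambdas, and a symmetric Dirichlet on n. Conjugacy lets us integrate them out
analytically, leaving a *collapsed* model over (t, omega) whose marginal
likelihood is a product of Beta-function ratios over small count tables: the
assembly sizes G, the on/off frame counts, and per-assembly 2x2 tables
counting (assembly state, neuron state) co-occurrences. These sufficient
statistics are maintained incrementally, so every sampler conditional costs
O(1) Beta-function evaluations; `suff_stats()` / `update_stats()` expose the
same machinery at the R level and the test suite checks incremental updates
are bit-exact against batch recomputation. All Beta-function arithmetic is in
log space via `lgamma`: the count tables reach N x M and dense Beta values
overflow long before that.

### Hyperparameter defaults

Published applications of this model family do not pin numeric prior values,
so the package defaults to uninformative choices — Beta(1, 1) on p and both
lambdas, Dirichlet weight 1, DP concentration 1 — keeping the posterior
attributable to the data. Informative priors (e.g. expected temporal sparsity
of assembly activation) are a configuration knob (`assembly_hyper()`,
`hyper_from_config()`), not a default.

## Samplers

`gibbs_run()` is a collapsed Gibbs sampler at fixed A: each sweep updates
every omega entry from its two-point conditional, then every membership from
its categorical conditional (leave-one-out count tables), then draws (p,
lambda, n) from their conditional posteriors. Those theta draws are pure
readouts — the collapsed conditionals never depend on them.

`dp_run()` replaces the Dirichlet-multinomial membership prior with a
Dirichlet process, so the number of assemblies is inferred. Memberships move
by single-site Metropolis-Hastings: an existing assembly is proposed with
probability proportional to its occupancy (computed without the neuron being
moved) and a fresh assembly with probability proportional to the
concentration; the move is accepted with the collapsed likelihood ratio.
Assemblies left empty are deleted. By default the chain starts from
uniform-random labels on 1..N, i.e. O(N) initial assemblies that merge as the
chain converges.

**Design choice — the new-assembly state column.** When a fresh assembly is
proposed, its omega column must be drawn from the prior for the
likelihood-ratio acceptance to be exact Metropolis-Hastings. The collapsed
prior on a column is exchangeable (a Beta-Bernoulli mixture), *not* an
i.i.d. Bernoulli at the prior mean; the package therefore draws p* from the
Beta prior and then the column i.i.d. Bernoulli(p*), which is exactly a draw
from the collapsed prior. With this proposal, every move type (existing to
existing, create, delete) satisfies detailed balance, and the test suite
verifies the empirical partition distribution against exhaustive
CRP-weighted enumeration on tiny instances.

**Scan order and reproducibility.** Sites are scanned assembly-major then
frame, neurons in index order; a single seed drives all randomness (the C++
core uses R's RNG), so runs replay exactly.

**Convergence.** The membership transition rate — the fraction of neurons
reassigned per sweep — is the order parameter of the detectable /
non-detectable transition: it vanishes when the posterior freezes on one
partition and stays positive when the data cannot distinguish memberships.
`diagnostics()` flags convergence when the rate stays below 1/N (by default)
for 20 consecutive sweeps. The samplers run a fixed number of sweeps rather
than stopping early: predictable sample counts make the burn-in/thinning
bookkeeping and downstream posterior summaries simpler, and the compiled
sweeps are cheap enough that the bound is unnecessary. Note that a stray
converged-looking singleton can outlive the rate criterion (it reassigns
nobody); at the headline validation scale (N = 500, M = 1000, five planted
assemblies) roughly 2 chains in 10 still carry one such singleton at sweep
300 and merge it within a few hundred more sweeps, so validation runs use
1000 sweeps.

**State-inversion symmetry.** The likelihood is exactly invariant under
inverting one assembly's state column while swapping lambda(0) with lambda(1)
and p with 1 - p, so with symmetric priors each assembly's posterior has two
equivalent orientations and a frozen chain sits in one of them arbitrarily.
Membership inference is unaffected, but feature summaries are not: the
package therefore reports every assembly in its *sparse-activity*
representative (activity below 1/2) in `assembly_summary()`,
`omega_posterior_mean()`, `correlation_graph()` and
`regressor_correlation()`. This matches the field's semantics of "activity"
and the selection thresholds below; an assembly genuinely active in most
frames will appear as its inverted representative.

**Label alignment and membership confidence.** Assembly labels are arbitrary
within each posterior sample. `align_trace()` relabels every sample by greedy
overlap matching against a reference partition (default: the saved sample
with the highest log marginal likelihood). A neuron is *assigned with 99%
confidence* when at least 99% of aligned post-burn-in samples give it the
same assembly (`membership_posterior()`, `free_neurons()`); per-assembly
features are posterior means over aligned samples (`assembly_summary()`).

## Detectability

Recovery depends on the synchrony/asynchrony contrast. When
lambda(1) = lambda(0) the raster carries no information about membership and
the transition rate stays positive; when |lambda(1) - lambda(0)| is large the
true partition is recovered exactly. `phase_grid()` maps this transition;
both "on" assemblies (lambda1 > lambda0) and "off" assemblies
(lambda1 < lambda0, synchronized silences) are detectable, and raising the
assembly activity p enlarges the detectable region at fixed M because more
on-frames are observed.

Two caveats established while characterizing the sampler, relevant to
interpreting phase grids at small problem sizes:

* On the degenerate diagonal the *exact* DP posterior concentrates on one or
  two assemblies — every additional assembly pays an Occam factor through the
  prior mass of its state column — so the end-of-chain transition rate decays
  as the chain coarsens. The persistent-churn signature of non-detectability
  shows in the rate averaged over the chain's sweeps (and in fixed-A runs,
  where exchangeable assemblies keep swapping members indefinitely).
* Single-site membership moves merge redundant assembly fragments slowly when
  the contrast is moderate and assemblies are small (tens of neurons): a
  fragment's state column partially overfits its own members, creating a
  self-fit barrier against moving any single neuron out. At N = 100 with
  mid-range contrasts, 300-sweep chains recover the planted partition in only
  10-70% of replicates; truth-initialized chains stay at the truth, showing
  this is sampler mixing, not non-detectability. Split-merge moves would
  remove the barrier but are out of scope; at the headline scale (N = 500,
  strong contrast) the issue does not arise. Treat scaled-down phase grids as
  conservative lower bounds on detectability.

## Binarization front-end

Raw traces are decomposed by a hidden Markov model into an onset indicator
s_k ~ Bernoulli(q dt), a transient level c_k that decays exponentially
(rate `decay`) between onsets and jumps by a N(0, sigma_C) innovation at an
onset, a baseline b_k performing a Gaussian random walk of scale
sigma_B * sqrt(dt), and N(0, sigma_x) observation noise. Estimation is the
sequential per-step maximum-likelihood rule: at each frame the closed-form
conditional maximizers under "no onset" and "onset" are compared after
weighting by the prior odds (1 - q dt) : q dt, from the initial condition
b_1 = x_1, c_1 = 0. Ties resolve to "no onset". This greedy rule (not a
full-sequence dynamic program) is deliberate: it is fast, deterministic, and
the downstream assembly model only needs the onset frames, not an optimal
continuous decomposition.

`refine_params()` alternates decomposition with moment re-estimates of
(sigma_B, sigma_C, sigma_x, q); two rounds are the default. Each scale is
floored (default 1e-6) and a silent trace floors q at one event per recording
with a flag, because further iteration of the plug-in scheme can collapse:
the MAP baseline trajectory is over-smooth, so its increments systematically
underestimate sigma_B round over round. Two further properties of the greedy
rule matter when quoting q estimates:

* transients whose innovation happens to fall below the detection threshold
  (a few sigma_x) are missed — unavoidable with zero-mean innovations;
* during a long transient tail a noise excursion can hijack the transient
  estimate and spawn catch-up detections, inflating the onset count by
  roughly 10-30% depending on the regime.

Consequently q-hat from detection counts is accurate to within about one
replicate standard deviation, not asymptotically unbiased.

The decision rule compares a two-factor density (no onset) against a
three-factor one (onset), so it is *not invariant under rescaling the trace*:
the onset branch carries an Occam penalty of half the log transient variance
in absolute units. Supply traces in units where transient amplitudes are
order one (dF/F, or binned spike counts) or pass explicit parameters;
`refine_params()` additionally floors the transient scale at the observation
noise scale and only re-estimates it when at least five onsets were detected,
because a variance taken from a couple of spurious noise-sized jumps
collapses the penalty and floods the next round with detections. The package's
recovery benchmark simulates a high-SNR, low-drift regime chosen to resemble
nuclear-GCaMP population imaging — dt = 0.2 s, q = 0.1 /s, decay = 1 /s,
sigma_x = 0.02, sigma_B = 5e-4, sigma_C = 2 (transients about 1.6 dF/F
against 2% observation noise) — where the hit rate for transients of at least
5 sigma_x exceeds 99% and mean q-hat lies well within one replicate SD of the
truth. Spike-train input is first binned into counts (`bin_spikes()`, default
0.6 s) and then decomposed the same way.

## Frame selection and assembly selection

`filter_frames()` keeps frames whose active-cell count strictly exceeds a
threshold, selecting synchrony events. The threshold can be given explicitly
(a typical value for a ~1000-cell tectal recording is 15) or derived from a
null in which each neuron's activity is circularly shifted by an independent
random offset — preserving rates, destroying synchrony — as the smallest
count with null exceedance probability below `null_p` (default 0.02).

`select_assemblies()` keeps assemblies with activity > 0.5% (about one event
per minute at typical volumetric imaging rates), more than 5 member neurons,
synchrony > 5% and asynchrony < 5%, and emits a complete audit table. All
four thresholds are strict inequalities; boundary semantics are not dictated
by any published convention, so strictness is a documented package choice.

## Benchmarking

`generate_multi()` produces datasets *outside* the inference model: a stated
fraction of neurons (default 20%) belongs to up to 2 assemblies and fires at
frame k with probability 1 - prod_a(1 - lambda_a(omega[k, a])) over its
assemblies — a noisy-OR, the only recruitment rule consistent with the
per-assembly meaning of lambda. With `frac_multi = 0` it reduces exactly to
the generative model. Defaults follow the comparison benchmark conditions:
400 neurons, 1000 frames, 5 assemblies, activity 5%, synchrony 50%,
asynchrony 10%.

`performance()` scores any membership map against ground truth through
pairwise co-assignment matrices: +1 when two neurons share at least one
assembly, -1 otherwise, with rho the normalized inner product over the
N(N-1)/2 pairs. It is invariant to relabeling, handles set-valued
memberships, and treats unassigned ("free") neurons as singletons — they are
penalized for missing true partners but never rewarded by chance agreement.
`compare_methods()` is the scoring harness for external baselines (k-means,
PCA-based, spectral pipelines are themselves out of scope).

## Posterior analyses

`correlation_graph()` computes, per posterior sample, Pearson correlations
between aligned assembly state columns (on binary sequences this is the phi
coefficient — no smoothing) and adds an edge when the correlation is positive
in at least 95% of samples; constant columns make a pair's correlation
undefined in that sample and the sample is skipped for the pair.
`assembly_communities()` partitions the graph by edge-betweenness
(Girvan-Newman, via igraph). `spatial_summary()` reports each assembly's
spatial extension E = pi * sqrt(xi1 * xi2), the ellipse area from the XY
covariance eigenvalues, against a null of size-matched random neuron groups.
`regressor_correlation()` correlates assembly activity with an external
covariate (running speed, pupil area, wheel velocity) across posterior
samples, giving a posterior distribution of the coupling.

## Numerical and degenerate-input choices

* All likelihood arithmetic in log space; categorical draws by max-shifted
  exponentiation.
* omega is initialized from its prior (one Beta draw per assembly, then
  i.i.d. Bernoulli) before the first sweep.
* Probability-zero events in `full_log_likelihood()` return -Inf, never an
  error; empty assemblies are legal at fixed A (their conditionals reduce to
  prior predictives) and deleted in DP mode.
* The HMM decision rule resolves exact ties to "no onset"; decompositions are
  pure functions of (trace, parameters).
* `filter_frames()` raises an explicit error when nothing survives, rather
  than returning a 0-column matrix.

## What the synthetic generators do and do not emulate

The generators reproduce the statistical structure the samplers are built
for: conditionally independent Bernoulli firing given assembly states,
i.i.d. assembly activation across frames, exponential-decay transients with
Gaussian noise. Real recordings violate several of these in ways the test
suite does not probe: sustained assembly activations with temporal
autocorrelation (the model recovers these as consecutive on-frames, but the
generator never plants them), rate drift and photobleaching beyond a
random-walk baseline, overlapping spatial signals from segmentation errors,
and neurons whose coupling to an assembly varies over the session. Passing
the simulation benchmarks therefore demonstrates correctness of the
inference machinery under the stated model, not robustness to every failure
mode of real data.

## Problem sizes used in the validation suite

The bundled tests run the headline recovery at N = 500 neurons x M = 1000
frames with five assemblies (10 replicates, 1000 sweeps each), exact-posterior
checks at N = 3, M = 4 against exhaustive enumeration (50,000+ retained
samples), a 5x5 detectability grid at N = 100, M = 1000 with 10 replicates
per cell, and transient-model recovery on 100 traces of 5000 steps. These
sizes were chosen so the full suite completes in minutes on one CPU while
keeping every check at the scale its claim refers to.

## A worked example

```{r example, eval = FALSE}
mod <- assembly_model(rep(1, 5), p = 0.1, lambda0 = 0.08, lambda1 = 0.6)
sim <- simulate_assemblies(mod, N = 500, M = 1000, seed = 1, equal_sizes = TRUE)
tr <- dp_run(sim$s, n_iter = 1000, seed = 2)
tr$A_final                                  # 5
performance(tr$t_final, sim$t)              # 1
head(assembly_summary(tr))
```
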