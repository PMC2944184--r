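---
title: "Detecting early bursts of diversification with divtempo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting early bursts of diversification with divtempo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divtempo)
library(ape)
```

## The question and the model

Adaptive-radiation theory predicts that a clade invading an open
landscape — classically, cichlid fishes colonising a new region — should
speciate explosively at first and slow down as niches fill. On a
time-calibrated, ultrametric phylogeny (a *chronogram*) this leaves a
signature in the *branching times*: under an early burst the internal
nodes crowd toward the root, while under a constant-rate pure-birth
(Yule) process they accumulate log-linearly all the way to the present.

`divtempo` operationalises that comparison. Everything runs off the
branching-time vector: with $n$ tips and internode intervals $g_k$ (the
duration during which exactly $k$ reconstructed lineages exist), define
$T = \sum_{k=2}^{n} k\,g_k$ and partial sums $S_i = \sum_{k=2}^{i} k\,g_k$.
The gamma statistic is

$$\gamma \;=\;
\frac{\tfrac{1}{n-2}\sum_{i=2}^{n-1} S_i \;-\; T/2}
     {T\sqrt{1/\bigl(12(n-2)\bigr)}},$$

standard normal under complete-sampling pure birth. The constant-rates
(CR) test is one-tailed in the slowdown direction only: reject when
$\gamma$ falls strictly below the normal quantile at level $\alpha$
($-1.645$ at $\alpha = 0.05$). Early-burst-like *positive* values are
reported but never "rejected" — the scientific question is about
slowdowns.

```{r gamma-example}
tr <- read_chronogram(text = "((A:1,B:1):1,C:2);")
gamma_statistic(branching_times(tr))
```

## Correcting for incomplete sampling: the MCCR test

Real phylogenies rarely contain every species, and missing taxa are not
neutral: random pruning removes mostly *recent* nodes, dragging
$\gamma$ negative even when the true process is constant-rate. The MCCR
test replaces the analytic null with a simulated one: grow pure-birth
trees at the *assumed true* richness, randomly prune each to the
*sampled* richness, and use the empirical 5% quantile of $\gamma$ as the
critical value. Because the true richness is itself uncertain (taxonomy
is unsettled in most radiations), `richness_sweep()` tabulates the test
across a range of assumed totals — the package default, 90 to 122,
mirrors a radiation in which 90 of a nominal 122 named species were
sequenced.

```{r mccr, eval = FALSE}
sweep <- richness_sweep(gamma_obs = -1.9, n_sampled = 90,
                        n_total_range = 90:122, reps = 10000, seed = 1)
```

Two conventions are fixed so that results are bit-reproducible given a
seed: the critical value is the `ceiling(alpha * reps)`-th smallest null
value, and the p-value uses the permutation-style estimator
$(1 + r)/(\text{reps} + 1)$, which can never be exactly zero. Each sweep
row draws from an independent seed stream derived from the master seed,
so adding rows never perturbs existing ones.

## Node truncation

A complementary robustness check: remove branching events one at a time
from the present backward and recompute $\gamma$ after each removal
(`truncate_profile()`). Sampling is usually most complete near the root,
so if tip-ward under-sampling were manufacturing (or masking) a burst,
the truncated $\gamma$ values would stay or become significant; if they
relax toward zero, the signal was concentrated in the poorly sampled
recent nodes. "Removing" the most recent node means merging its two
daughter lineages — equivalently deleting the smallest branching time
and decrementing $n$ — *not* cutting the tree at a time horizon, which
would shorten tip branches and change every interval. The profile runs
until three tips remain (the smallest $n$ for which $\gamma$ is
defined), and `profile_report()` extracts the settling age: the age of
the last removed node beyond which no deeper truncation rejects.

## Five diversification models and the calibrated ΔAIC rule

`fit_all_models()` fits two rate-constant models — pure birth
($\lambda$) and birth–death in the $(r = \lambda - \mu,\;
a = \mu/\lambda)$ parameterisation — and three rate-variable ones:
density-dependent exponential ($\lambda(i) = \lambda_0 i^{-x}$),
density-dependent logistic ($\lambda(i) = \lambda_0(1 - i/K)$), and
Yule-2-rate ($\lambda_1$ before a shift age $t_s$, $\lambda_2$ after).

The pure-birth family uses the likelihood of the process observed from
the root: with $i$ lineages the waiting time is exponential with total
rate $i\lambda(i)$, each of the $n-2$ post-root branching events
contributes $\log(i\lambda(i))$, and the final interval contributes
survival only, so

$$\ln L = \log (n-1)! + \sum_{i=2}^{n-1} \log \lambda(i)
        - \sum_{i=2}^{n} i\,\lambda(i)\,g_i .$$

Under this conditioning the pure-birth MLE has the closed form
$\hat\lambda = (n-2)/\sum i g_i$, which anchors the numerical fits: DDX
and DDL profile $\lambda_0$ out analytically and optimise only the shape
parameter ($x \in [0, 5]$; $K \in (n, 10^8]$ on a log grid with local
refinement), and Yule-2-rate profiles both rates in closed form over
candidate shift ages placed at interior branching times and interval
midpoints (the likelihood is piecewise in $t_s$, so the optimum over
each piece sits at our evaluation points up to segment-boundary choice).
The birth–death model uses the standard reconstructed-process
likelihood, optimised in $(\log r, \mathrm{logit}\, a)$ from five
starts; its $a \to 0$ limit equals the pure-birth likelihood exactly, so
the two rate-constant fits are properly nested and share the
$\log(n-1)!$ constant — comparing their AICs is legitimate. Users
reconciling absolute $\ln L$ values with implementations that condition
differently should expect a constant offset; all comparisons inside the
package are unaffected.

Because the rate-variable models nest the rate-constant ones, "smallest
AIC wins" rejects constant rates far above its nominal level. The
package instead calibrates the decision:
`calibrate_delta_critical()` simulates pure-birth trees at the observed
richness, fits all five models to each, and returns the $(1-\alpha)$
quantile of $\Delta\mathrm{AIC}_{RC} = \mathrm{AIC}(\text{best
rate-constant}) - \mathrm{AIC}(\text{best rate-variable})$. `compare_models()`
keeps the best rate-constant model unless the observed difference
*strictly* exceeds that threshold.

## Ancestral areas and the focal root

When the radiation of interest is nested inside a wider phylogeny, the
node from which to measure diversification is itself an inference. The
package uses the one-parameter symmetric Markov model (Mk1) for a binary
area coding (1 = focal region, 0 = elsewhere): transition probability
$P(\text{flip}, t) = (1 - e^{-2qt})/2$, likelihood by the pruning
recursion, marginal per-node probabilities by the standard two-pass
algorithm, and the rate $\hat q$ by bounded 1-D optimisation of
$\log q \in [\log 10^{-8}, \log 10]$. The root prior is equal
$(\tfrac12, \tfrac12)$ — with a symmetric chain this is also the
stationary distribution, and no other prior is consistent with the
model's single-parameter symmetry. `find_focal_root()` then returns the
oldest internal node whose marginal probability of the focal state
exceeds a threshold (default 0.95); its clade is the diversification
root downstream. Rate units follow the branch-length units of the input
tree (per million years for a chronogram in My).

```{r mk1-example}
fx <- make_fixtures(seed = 1)
m <- fx$mk1[[3]]
rec <- marginal_states(m$tree, m$states)
rec
find_focal_root(m$tree, rec, focal_state = 1, threshold = 0.9)$found
```

## What the simulator does and does not emulate

`simulate_yule()` grows trees forward conditioned on the tip count, with
the final interval drawn as the $\mathrm{Exp}(n\lambda)$ waiting time to
the unobserved next speciation. That convention is load-bearing: it is
what makes $\gamma$ on complete simulated trees exactly standard normal,
so the simulated null agrees with the analytic one. The birth–death
simulator stops the first time the standing lineage count reaches $n$,
applies the same final-interval rule with total rate $n(\lambda + \mu)$,
rejects replicates that go extinct, and returns the reconstructed tree
of survivors; at $\mu = 0$ it reduces exactly to the Yule construction.
Incomplete sampling is uniformly random tip pruning.

The generator therefore emulates the *chronogram stage* of an empirical
study — true topologies and node ages under known rates — not the data
that precede it. It does not model phylogenetic estimation error,
calibration uncertainty, saturation-compressed deep branches,
clade-biased sampling, or unresolved species complexes. Passing tests
show the inference machinery is correct and well-calibrated under its
own assumptions; they cannot show that a particular empirical chronogram
satisfies those assumptions.

## Numerical and design choices

* **Polytomies** are accepted on input and resolved into zero-length
  bifurcations before any diversification computation; the resulting
  zero intervals are valid limits of every formula used, and the
  resolution is flagged in `branching_times()` output. Ties in node age
  sort stably, carry $g = 0$, and are harmless to $\gamma$.
* **Ultrametricity** is enforced at a relative $10^{-6}$ of the root
  age, which tolerates the rounding that external dating programs
  introduce; the error message names the offending tip (judged against
  the median tip depth).
* **Boundary conventions** are strict everywhere a decision is made:
  the CR and MCCR tests reject only strictly below their critical
  values, and the ΔAIC rule keeps the rate-constant model on ties.
* **Calibration rescaling** (`scale_to_calibration()`) is a linear
  stretch of the whole time axis to pin one node's age — deliberately
  *not* rate smoothing. $\gamma$, being scale-free, is untouched; only
  absolute ages (truncation profiles, rate units) change.
* **Seed management**: every replicated computation derives
  per-replicate seeds from a master seed through a fixed integer map
  (`derive_seed`), kept below $2^{31}$; results are reproducible
  bit-for-bit and replicate streams are independent of each other.
* **Degenerate inputs**: $\gamma$ refuses $n < 3$ and all-zero interval
  sets; monomorphic tip states return the $q = 0$ boundary with a flag
  rather than an error; a focal-root search that finds no qualifying
  node reports the best candidate with `found = FALSE`.

## Problem sizes used in the test suite

The shipped checks run the machinery at the scale of the motivating
study where that is what is being verified — 10,000 complete-sampling
null trees at 90 tips for the critical-value and test-size checks,
2,000-replicate pruned nulls (122 → 90) for the sampling-bias
direction, 1,000 calibration plus 1,000 fresh replicates for the ΔAIC
size, 500 trees for rate recovery, and 100 replicates of 500-tip trees
for Mk1 rate recovery at $q = 0.007$ — and smaller replicate counts
where only correctness of bookkeeping is at stake. Exhaustive
enumeration oracles (all $2^{n-1}$ internal state assignments; all
candidate shift ages) back the likelihood code on trees small enough to
enumerate.

## Known limitations

* The density-dependent models treat the *reconstructed* lineage count
  as the diversity that rates respond to; no time-continuous diversity
  dependence, protracted speciation, or trait-dependent rates.
* The MCCR correction assumes uniformly random missing taxa;
  clade-biased sampling would need a different null.
* Mk1 is symmetric by construction; asymmetric-rate (Mk2) or
  dispersal–extinction–cladogenesis reconstructions are out of scope.
* The birth–death simulator's reject-and-retry conditioning is exact
  enough at $\mu/\lambda \le 0.9$ but is not a conditioned bridge; very
  high relative extinction would need one.
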