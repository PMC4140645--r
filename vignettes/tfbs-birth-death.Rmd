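---
title: "Modeling TFBS turnover with a phylogenetic birth-death process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TFBS turnover with a phylogenetic birth-death process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdtfbs)
```

## The model and its assumptions

`bdtfbs` treats the evolution of a transcription factor's binding motif
inside an orthologous region as a collection of W independent two-state
chains, one per nucleotide site. An unoccupied site acquires the motif
at the birth rate λ (per site-year); an occupied site loses it at the
death rate μ (per occupied site-year). The single-site occupancy
probability P(t) satisfies dP/dt = λ(1 − P) − μP, whose solutions from
the two initial conditions are

$$P_1(t) = \pi + (1-\pi)e^{-(\lambda+\mu)t}, \qquad
  P_0(t) = \pi\,(1 - e^{-(\lambda+\mu)t}), \qquad
  \pi = \frac{\lambda}{\lambda+\mu}.$$

Summing W independent sites gives the count-level chain: a region
holding $m$ occurrences transitions to $n$ after time $t$ with
probability
$$T_{m\to n}(t) \;=\; \sum_j \binom{m}{j} P_1^j (1-P_1)^{m-j}
  \binom{W-m}{\,n-j\,} P_0^{\,n-j} (1-P_0)^{W-m-n+j},$$
the convolution of binomial survival and binomial gain. Leaf counts on
a rooted, time-calibrated phylogeny are then scored by Felsenstein
pruning over count states, with a truncated Poisson(ν) prior on the
root count, and per-region log-likelihoods add across regions.

The key modeling assumptions are: (i) sites within a region are
exchangeable and independent — no positional or sequence-context
effects on gain probability; (ii) rates are constant in time within a
branch (the lineage-specific test relaxes constancy *across*
branches); (iii) only counts matter, so the method needs ortholog
correspondence between regions but no base-level alignment. Assumption
(iii) is the point of the framework: ancestral inference survives
alignment error that would corrupt site-wise methods, at the price of
being blind to same-branch compensatory turnover (a gain and a loss on
the *same* branch cancel in the count). On densely sampled trees with
short branches such events are rare; on sparse, deep trees they matter
(see *Limitations*).

## Parameters that matter

| parameter | meaning | unit | default | rationale |
|---|---|---|---|---|
| λ, μ | birth / death rate | per site-year | estimated | genome-wide magnitudes are ~1e-12–1e-8 |
| W | region width | nucleotide sites | 201 | the (−100,+100) window around a peak summit |
| ν | root-prior mean | occurrences/region | mean observed count | the natural plug-in for "mean motif occurrences per sequence"; overridable |
| n_max | count-state cap | counts | max observed + 5 | counts are almost always 0/1; tail mass is negligible and rows are renormalized (full support available) |
| tol | EM convergence | relative rate change | 1e-4 | convergence is declared on rate stability, not likelihood |
| rate floor | lower rate bound | per site-year | 1e-15 | avoids log(0)/division by zero on event-free classes |

Branch lengths are normalized to years internally (`unit = "My"` inputs
are multiplied by 1e6) so that rates are always per site-year.

## Estimation: classification EM plus likelihood polishing

Rates are initialized from empirical event counts on a linear-cost
(Sankoff) parsimony reconstruction, then iterated: most-likely
ancestral states under the current rates (greedy top-down rule: root
$\arg\max_x \pi_x L_\rho(x)$, child $\arg\max_y T_{x^*\to y}(t_d)
L_d(y)$, ties to the smaller count) → empirical rates (gains over
unoccupied site-time, losses over occupied site-time) → repeat until
the largest relative rate change falls below `tol`. Because the
assignments are hard, likelihood monotonicity is not guaranteed and is
not asserted.

By default the EM estimate is then *polished*: the total pruning
log-likelihood is maximized directly over log-rates (Nelder-Mead,
multi-start from the EM iterate and from the initialization). This
design choice is deliberate. Counting events on hard assignments
undercounts whenever a branch is long enough for within-branch
reversals, or for one site's gain to cancel another's loss inside the
region count; on the bundled 10-taxon tree — whose terminal branches
reach 80–90 My — this bias is substantial for both rates, and the
hard-EM fixed point can drift far from the maximum-likelihood value.
Direct maximization of the actual likelihood is consistent regardless
of branch lengths, and the EM pass still supplies a cheap, nearly
rate-scale-free starting point and an interpretable event-count trace.
`polish = FALSE` exposes the raw classification-EM estimator for study.

## The lineage-specific test

`lineage_lrt()` compares constant rates (2 parameters) against a model
in which a focal branch set shares its own pair (4 parameters,
df = 2). Both models are fitted by EM + polishing and the statistic
$2(\ell_1-\ell_0)$ is floored at 0 and referred to $\chi^2_2$. The
degrees of freedom are a documented default: with the focal set's own
(λ′, μ′) free, two extra parameters is the natural choice. For motif
ranking, a one-sided df = 1 variant frees only the focal birth rate
and uses the boundary mixture $\tfrac12\delta_0 + \tfrac12\chi^2_1$,
with p = 1 whenever λ̂′ ≤ λ̂ — a motif absent from the data can never
look lineage-enriched. The test's empirical type-I error and power are
measured by the acceptance script on null and 10×-birth simulations at
500 regions × W = 50 per replicate.

## Dating sites: the branch-of-origin rule

Reconstructed counts along the root→target path, $c_0,\dots,c_K$ with
$h = c_K$ sites at the target leaf, are converted to per-site origins
by ranking sites $i = 1..h$ and assigning site $i$ the branch entering
the oldest node of the most recent contiguous run of nodes with
$c \ge i$ ending at the leaf; if the run reaches the designated split
node (default in the examples: the human–mouse ancestor), the site is
*ancestral*. Sites are exchangeable, so this oldest-first matching is
the minimal-assumption convention; for 0/1 counts — the dominant case —
it reduces to the obvious rule. A loss followed by a re-gain below the
split dates the site to the re-gain branch: re-gained sites are young.
Regions whose reconstructed ancestral counts exceed the target count
(extra ancestral sites later lost) produce no call for the surplus
sites.

## What the simulator emulates — and what it does not

`simulate_dataset()` runs the generative model forward: root sites are
Bernoulli(π) (`root_mode = "stationary"`, the model-consistent default;
`"empty"` gives pure-gain scenarios) and each site flips along each
branch per $P_1/P_0$. It records the full truth: node counts, per-branch
endpoint gain/loss totals, and per-site origins defined by applying the
origin rule to the true node counts. It emulates the *count* structure
of peak-window data — not sequence evolution: there are no substitution
processes, indels, alignment errors, ChIP-seq noise, or
position-dependent gain probabilities. Tests passing on simulated data
therefore validate the inference machinery under the model's own
assumptions; they do not certify performance on real peaks, where
ortholog identification and motif-count noise add error that the 5%
leaf-noise and branch-length-jitter perturbations only coarsely mimic.
`emit_region_sequences()` closes the loop with the scanner by planting
exact motif occurrences in match-free random backgrounds.

## Numerical choices

* Pruning is scaled per node (factoring out column maxima into a log
  accumulator), so likelihoods do not underflow even on very large
  trees; tables are kept in log space where exposed.
* All time-dependent probabilities come from the closed forms above —
  numerical ODE integration exists only in the test oracles, as does
  the matrix-exponential cross-check of the transition kernel.
* The production likelihood path is a small C++ kernel with
  *site-pattern aggregation*: regions with identical leaf-count vectors
  are collapsed and weighted, and binomial terms come from the ratio
  recurrence. An R reference implementation of the same recursion backs
  the reconstruction tables; the two agree to machine precision and
  both are tested against exhaustive enumeration.
* λ + μ = 0 yields identity dynamics rather than an error; zero-length
  branches give identity transitions.
* Every argmax breaks ties toward the smaller count, making
  reconstructions and rankings deterministic; motif rankings sort by
  (p-value, −statistic, motif string) so input order is irrelevant.
* Scanning treats sequence `N` strictly as a mismatch; the default
  overlap policy keeps a greedy left-to-right non-overlapping hit set
  (an `"all"` policy is available), and a palindromic hit counts once.

## Problem sizes used in validation

The shipped tests validate the kernel against matrix exponentials
(W ≤ 5, 50 random rate/time draws), pruning against enumeration (200
random ≤ 4-leaf instances), both reconstructions against brute-force
oracles (200 instances each), rate recovery at 5000 regions × W = 201
on the 10-taxon tree (both rates within 25%, typically ~1%), LRT
calibration on 500 null replicates and power on 100 shifted replicates,
origin-call consistency at 2000 regions, robustness at 1500 regions,
and motif ranking against 20 decoys at 80 regions. These sizes are the
package's chosen validation scale; the code handles larger inputs.

## Known limitations

* Origin dating of *deep* sites is information-limited on sparsely
  sampled trees: when μ·(tree depth) is appreciable, losses erase the
  out-of-path evidence for an ancestral site, the posterior over deep
  presence becomes bimodal, and the hard reconstruction must pick one
  mode — so a minority of sites land far from their true origin even
  though the exact-match rate stays high. Denser taxon sampling (the
  46-vertebrate setting the method is meant for) mitigates this; the
  10-taxon validation tree is a deliberately hard case.
* Same-branch compensatory turnover is invisible to a count model.
* The Poisson root prior with plug-in ν is a convenience, not an
  estimate of the stationary law; for stationary simulations the two
  are numerically close.
* Classification EM without polishing underestimates both rates on
  long-branch trees (see above); the default therefore polishes.
* IUPAC consensus scanning has no background model; PWM refinement uses
  a log-odds-vs-uniform threshold (default 0) rather than a fitted
  background Markov chain.
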