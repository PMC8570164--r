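---
title: "Estimating marginal likelihoods with parallel power posteriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating marginal likelihoods with parallel power posteriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powerpost)
```

## The problem

Bayesian model comparison ranks models $M$ by their marginal likelihood

$$f(D \mid M) = \int f(D \mid \theta, M)\, f(\theta \mid M)\, d\theta,$$

the likelihood integrated over the prior. Ratios of marginal likelihoods are
Bayes factors. In phylogenetics (and most non-trivial models) this integral
has no closed form, and the two standard Monte Carlo estimators — path
sampling (thermodynamic integration) and stepping-stone sampling — both
require samples from a whole family of *power posterior* distributions

$$f_{\beta}(\theta) \propto f(D \mid \theta)^{\beta} f(\theta), \qquad
  \beta \in [0, 1],$$

which interpolate from the prior ($\beta = 0$) to the posterior
($\beta = 1$). Each of the $K$ powers ("stones") needs its own MCMC run, so
a marginal-likelihood estimate costs roughly $K$ times a posterior analysis.
`powerpost` implements the whole pipeline — schedule, tempered sampler,
estimators — together with the observation that makes it cheap: the $K$
simulations are independent given their starting states, so consecutive
blocks of stones can be farmed out to parallel workers with a single
synchronisation barrier at the end, optionally combined with splitting each
likelihood evaluation over sites.

## The power schedule

Powers are the $i/(K-1)$ quantiles of a Beta$(\alpha, 1)$ distribution,
$\beta_i = (i/(K-1))^{1/\alpha}$, with $\alpha = 0.3$ by default. The
expected log likelihood changes fastest near $\beta = 0$, where the sampling
distribution approaches the prior, so the schedule concentrates most stones
there; with $\alpha = 0.3$ and $K = 100$, over two thirds of the powers lie
below 0.3. `make_powers(K)` includes both endpoints among its $K$ values and
stores them in *execution* order, $\beta = 1$ down to $\beta = 0$: running
posterior-to-prior lets each stone start from the previous stone's final
state, which needs far less per-stone burn-in than dispersing from a cold
start, because adjacent power posteriors are similar.

Tunables: `K` (stones; 30–200 in routine use, more stones reduce the
discretisation error of both estimators) and `alpha` (schedule shape;
`alpha = 1` gives a uniform grid, smaller values push stones toward the
prior).

## The tempered sampler

A Metropolis–Hastings engine samples each stone. A proposal $\theta'$ from
kernel $q$ is accepted with probability

$$\min\left(1,
  \left[\frac{f(D\mid\theta')}{f(D\mid\theta_j)}\right]^{\beta}
  \times \frac{f(\theta')}{f(\theta_j)}
  \times \frac{q(\theta_j\mid\theta')}{q(\theta'\mid\theta_j)}\right),$$

i.e. ordinary MCMC with only the likelihood ratio raised to $\beta$. At
$\beta = 0$ the likelihood term is dropped *before* any arithmetic, so prior
sampling never evaluates the likelihood and never forms $0 \cdot (-\infty)$;
a proposal with $-\infty$ log likelihood at $\beta > 0$ is rejected
immediately for the same reason.

Design choices that were genuinely open:

* **One iteration = one sweep.** Every registered move is applied once, in
  registration order. Reference implementations differ here (some count one
  move per iteration, some several); a fixed sweep order is deterministic
  and makes run length directly comparable across models.
* **Pre-burn-in at the block's first power.** The sequential algorithm
  pre-burns toward the posterior because its first stone is $\beta = 1$. A
  parallel worker's first stone may be far from the posterior, so each
  worker pre-burns at the first (highest) power *of its own block* — that is
  the distribution it actually samples first.
* **Burn-in discards recorded samples, not iterations.** With `L`
  iterations, thinning `T`, and `burnin_frac` $b$, a stone retains
  $n = (1-b)\,L/T$ samples (750 with the defaults `L = 10000`, `T = 10`,
  $b = 0.25$). The constructor rejects configurations where $n$ is not a
  positive integer rather than silently rounding.
* **No tuning during sampling.** Move scales are fixed; adapting them inside
  a sampling phase would break detailed balance.

Three kernels cover the parameter types used here: a sliding window
(symmetric; reflected at finite bounds so it stays symmetric on, e.g., a
probability), a multiplicative scale move for positive parameters (Hastings
term = log of the multiplier), and a Dirichlet move for simplexes centred on
the current value (Hastings term = reverse minus forward Dirichlet log
density). Stationarity of each kernel is verified in the test suite against
known targets, and the tempered acceptance rule is verified by
eigen-analysis of the exact transition matrix of a 3-state toy model.

## Reproducible parallelism

`partition_blocks` splits stones into $M$ consecutive blocks (block $m$
runs stones $K - \lfloor (m-1)K/M \rfloor - 1$ down to
$K - \lfloor mK/M \rfloor$; sizes differ by at most one). Worker $w$ derives
its RNG stream deterministically from the root seed and $w$, and a single
stream threads through its pre-burn-in and stones. Consequences, all tested
bit-for-bit: a 1-worker parallel run equals the sequential runner; a
multi-process run equals an in-process serial emulation of the same plan;
and per-worker sample files are byte-identical across backends. Sample files
are TSV with doubles printed to 17 significant digits, which round-trips
IEEE doubles losslessly. Files are written at stone completion (not
streamed per iteration, which is wasteful on shared filesystems), and a JSON
manifest records each stone's entry RNG state and parameter values so
`resume()` can re-run only incomplete stones, bit-identically.

When $M_{\mathrm{tot}}$ CPUs are available the best split between stone
blocks and per-likelihood site partitioning is
$N = \lfloor\sqrt{M_{\mathrm{tot}}}\rfloor$ CPUs per likelihood
(`allocate_cpus`); leftover CPUs idle rather than making unequal groups.
The cost model behind this is
$E[t_M] = t_1 (\lceil K/M\rceil + 1)/(K + 1)$: each worker runs at most
$\lceil K/M \rceil$ stones plus one pre-burn-in of comparable cost.

## The estimators

Both consume only the $K \times n$ matrix of untempered log-likelihood
samples. Path sampling integrates the mean log likelihood over $\beta$ by
the trapezoidal rule; stepping-stone forms the telescoping product of
importance ratios between adjacent powers, computed in the stabilised form
that subtracts each stone's maximum log-likelihood sample before
exponentiating, so it cannot overflow for real-data magnitudes (the naive
product form is kept as `stepping_stone_naive`, an oracle valid only at
test scale). Each estimate carries per-interval contributions that sum to
the total, for diagnostic plots of where the integral mass sits. Both
estimators re-sort the matrix ascending internally, so stone execution
order is irrelevant, and rows with unequal sample counts are rejected
rather than truncated — a ragged matrix means an upstream failure worth
surfacing. Since both estimators are nearly free given the samples, the
package always offers `estimate_both`; the absolute PS/SS difference is the
standard internal consistency diagnostic.

## Validation models

Two conjugate models with closed-form marginal likelihoods act as oracles
for the entire pipeline: a normal model with known variance (the power
posterior at any $\beta$ is itself normal, so per-stone moments are also
checkable) and a beta-binomial model. Their shipped hyperparameters — a
fixed ten-observation data set for the normal model, $k = 7$ successes in
$n = 20$ trials with a Beta$(2,2)$ prior — are frozen in the package so
validation runs are reproducible; both closed forms are additionally
verified against adaptive quadrature in the tests. At $K = 30$,
$L = 2000$, $T = 4$, 25% per-stone burn-in ($n = 375$), both estimators
recover the analytic values within 0.15 log units in at least 9 of 10
seeds.

## The phylogenetic model

The application domain at desk scale: GTR + 4-category discrete-gamma
likelihood on a fixed rooted tree, evaluated by Felsenstein pruning. Choices:

* **Rate matrix**: $q_{ij} = r_{ij}\pi_j$ (exchangeabilities in canonical
  order AC, AG, AT, CG, CT, GT), rescaled to one expected substitution per
  site at stationarity. Transition probabilities come from the
  eigendecomposition of the reversibly symmetrised matrix.
* **Discrete gamma**: mean-of-category discretisation with quartile cut
  points — the conventional choice — renormalised so the category means
  average exactly 1.
* **Missing data**: gaps, `?` and `N` give all-ones leaf partials; partial
  ambiguity codes (R, Y, ...) resolve to the union of compatible states.
* **Priors**: iid exponential(rate 10) on branch lengths, flat Dirichlet on
  both simplexes, exponential(1) on the gamma shape. Clock models and
  birth–death tree priors are deliberately out of scope: the topology is
  fixed and any proper prior exercises the marginal-likelihood machinery,
  which is what this package reproduces.
* **Topology fixed.** Tree proposals are orthogonal to the power posterior
  machinery and would dominate implementation cost.

Site-partitioned evaluation (`site_partition_log_likelihood`) splits the
columns into $N$ contiguous blocks and combines per-site values in site
order. The partial-likelihood arithmetic is written with explicit
elementwise operations (no BLAS matrix product), so a pattern's likelihood
is bit-identical no matter which block it lands in, and the $N$-block result
equals the single-block result exactly — the property that lets combined
stone/likelihood parallelism change nothing numerically.

The alignment simulator draws root states from $\pi$, assigns each site a
rate category, and evolves states down the tree; it is the fixture
generator for the pruning oracle (exhaustive enumeration over ancestral
states on 3–4 taxon trees) and for the end-to-end run below.

## Problem sizes and what the tests show

The shipped test suite runs: conjugate-model pipelines at $K = 30$,
$L = 2000$ ($n = 375$); a 6-taxon, 300-site GTR+$\Gamma$ end-to-end run at
$K = 20$, $L = 400$, $T = 4$, 20% burn-in ($n = 80$), checking that PS and
SS agree within 0.5 log units and are stable across seeds within 1 log
unit; and exhaustive small-$K$ block-plan checks. These sizes were chosen
so one pipeline run takes minutes, not hours, while Monte Carlo noise stays
below the diagnostic thresholds.

What passing does **not** show: the synthetic data are simulated under the
model that analyses them, with a correct fixed topology, moderate branch
lengths and a single partition. Real alignments bring model misspecification,
topology uncertainty, and much larger $K$ requirements (the phylogenetic
end-to-end check validates internal consistency of the estimators, not
closeness to a known truth, which no phylogenetic model of realistic size
admits). Runtime claims are likewise represented only through the
$E[t_M]$ cost model, not wall-clock benchmarks.

## Known limitations

* Pure-R likelihood: adequate for the desk-scale trees used here; a
  production phylogenetics engine would vectorise partials in compiled code.
* No generalized stepping-stone (reference distributions), no
  variance/standard-error estimators for the estimates, no topology moves,
  no multi-partition models.
* The multi-process backend relies on process forking and falls back to
  in-process execution where forking is unavailable; results are
  bit-identical either way by construction.
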