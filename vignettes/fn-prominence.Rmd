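---
title: "Quantifying the prominence of a priori functional networks with SBM signal-to-noise"
author: "fcprom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the prominence of a priori functional networks with SBM signal-to-noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcprom)
```

## The model

A functional connectome (FC) is an $n \times n$ symmetric matrix of
pairwise association strengths (Pearson correlations) between brain
regions, with entries in $[-1, 1]$ and a zero diagonal (the raw Pearson
diagonal of 1 carries no information and is coerced to 0 on load, so
every edge sum below runs over pairs $u \neq v$). An a priori set of
functional networks is a fixed partition $\sigma$ of the $n$ nodes into
$k$ communities with sizes $\Omega$.

Given a graph $G$ derived from the FC and the partition $\sigma$, both
observed, we treat the pair as a stochastic block model and read its
parameters off by maximum likelihood:

$$p_i = \Omega_i / n, \qquad W = C \oslash C_{\max}, \qquad
  Q = nW, \qquad PQ = n \, \mathrm{diag}(p) \, W .$$

Here $C$ is the per-block-pair edge summary — a plain edge count in
binary mode, a sum of absolute edge weights $|w_{uv}|$ in weighted mode
(absolute values: only the magnitude of a functional coupling matters
for prominence, not its sign) — and $C_{\max}$ counts the node pairs
available to each block pair. $PQ$, the *community profile matrix*, has
entry $(i, j)$ equal to the expected number of community-$j$ neighbours
of a node in community $i$. The degree-scaling factor is fixed at 1
throughout: the prominence question is posed in the constant-degree
(weak-recovery) regime, where the graph need not even be connected.

The prominence statistic is the signal-to-noise ratio of $PQ$'s
spectrum,

$$\mathrm{SNR} = \lambda_2^2 / \lambda_1,$$

with eigenvalues ordered by descending absolute value. $\mathrm{SNR} >
1$ is the Kesten–Stigum criterion: above it, weak recovery of
$\sigma$ — beating the best random guess $\max_i p_i$ by some margin —
is efficiently solvable, so the partition is genuinely encoded in the
graph. If all entries of $W$ are equal, the SBM collapses to an
Erdős–Rényi model, $PQ$ has rank 1, $\lambda_2 = 0$, and the SNR is 0.

For the symmetric two-equal-block model with
$W = \tfrac1n \begin{pmatrix} a & b \\ b & a\end{pmatrix}$ the spectrum
is available in closed form, $\lambda_1 = (a+b)/2$, $\lambda_2 =
(a-b)/2$, hence

$$\mathrm{SNR} = \frac{(a-b)^2}{2(a+b)},$$

implemented as `closedFormSNR()` and used as an analytic oracle: the
full counting + inference + eigensolve pipeline must reproduce it to
$10^{-10}$, and $(a, b) = (6, 2)$ sits exactly on the boundary
$\mathrm{SNR} = 1$.

## The threshold-optimization pipeline

Thresholding an FC at $\tau \in [0, 1]$ retains pairs with $|a_{uv}|
\ge \tau$ — binarized (`thresholdBinarize()`) for vetting, or carrying
the weights $|a_{uv}|$ (`thresholdWeighted()`) for prominence scoring.
`runCohort()` chains the four steps for a cohort of $\Gamma$ subjects:

1. group-average FC (entrywise mean across subjects);
2. *vetting*: binary SNR sweep of the group average over the grid, and
   the weak-recoverability sub-interval $[a_w, b_w]$ — the longest
   contiguous run of grid points with $\mathrm{SNR} > 1$;
3. weighted SNR sweep per subject, yielding individualized optima
   $\tau_{opt}^{\gamma} = \arg\max_\tau \mathrm{SNR}$;
4. weighted sweep of the group average, yielding $\tau_{opt}^{GA}$;
   every optimum is checked for membership in $[a_w, b_w]$.

`nullSNR()` guards against spurious prominence: it repeats the sweep
under size-preserving random shuffles of $\sigma$. For a partition that
reflects real structure the entire null ensemble stays below
$\mathrm{SNR} = 1$ while the true partition's SNR exceeds it, giving
the ordering $0 \le \mathrm{SNR}_{null} < \mathrm{SNR}_{true}$.

`backtest()` juxtaposes the SNR (which evaluates a *fixed* partition)
with objective-function community detection: per threshold it runs
greedy modularity maximization, and records the detected partition's
$Q$ score and its adjusted mutual information (AMI) with the a priori
partition. On planted data the SNR peak and the AMI peak coincide,
while $Q$ keeps its maximum into the fragmented high-threshold regime —
$Q$ rewards fragmentation and cannot pick a threshold for an a priori
partition.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| threshold grid | `tauGrid()` | 0 to 1 step 0.05 (21 points) | discretized line search; user-overridable, grid points computed as exact multiples of the step |
| comparator | thresholding | $\ge$ | an entry equal to $\tau$ is retained, so grid endpoints are reproducible |
| sign handling | `signed=` | magnitude $|a_{uv}|$ | consistent with the absolute-weight block sums; `signed = TRUE` keeps only $a_{uv} \ge \tau$ |
| pair counting | `cmax=` | `"pairs"` | unordered node pairs, self-pairs excluded ($C_{\max}$ diagonal $\Omega_i(\Omega_i-1)/2$) — correct for simple graphs. `"outer"` uses the literal $\Omega\Omega^\top$ (diagonal $\Omega_i^2$, including self-pairs); the two differ only on the diagonal of $W$, by the factor $(\Omega_i - 1)/\Omega_i$ |
| $\alpha$ | `modularityQ()` | 1 | standard resolution parameter of the configuration-model null |
| shuffles | `nullSNR()` | 100, base seed 0 | shuffle $s$ uses seed $+\,s-1$; reproducible |
| agreement score | `backtest(score=)` | `"ami"` | exact hypergeometric chance correction; `"nmi"` available |

## Numerical choices

- **Eigenvalues.** $PQ = n P W$ is not symmetric, but it is similar to
  $S = n P^{1/2} W P^{1/2}$, which is; all eigenvalues are therefore
  real, and we compute them on $S$ with a symmetric solver, avoiding
  the spurious imaginary parts and ordering noise of a nonsymmetric
  solve. $\lambda_1 \ge |\lambda_k|$ by Perron–Frobenius ($S$ is
  nonnegative); $\lambda_2$ — second by absolute value — may be
  negative, and enters squared.
- **Degenerate sweeps.** An empty thresholded graph, a single-community
  partition, or $\lambda_1 \le 10^{-12}$ returns $\mathrm{SNR} = 0$
  rather than an error, so grid sweeps never abort; block pairs with no
  available node pairs (singleton-community diagonals) get $W = 0$.
- **Strictness at the boundary.** Weak recoverability uses the strict
  test $\mathrm{SNR} > 1$. A model placed exactly on the boundary can
  tip either way within floating-point error ($\sim 10^{-16}$); exact
  boundary cases are meaningful only analytically.
- **Ties.** $\arg\max_\tau$ ties resolve to the smallest $\tau$
  (mildest pruning); equal-length super-threshold runs resolve to the
  earliest. A non-contiguous super-threshold set maps to its longest
  run, and the full boolean mask is kept on the interval object.
- **I/O.** Matrices are symmetrized as $(A + A^\top)/2$ when the
  asymmetry is at most $10^{-6}$ (decimal-text round-trip scale) and
  rejected otherwise; result tables carry 10 significant digits so a
  read-back reproduces values within $10^{-9}$. Node indices are
  1-based in files and internally. Community labels are relabeled to
  $1..k$ by order of first appearance, making partitions invariant to
  any injective renaming.

## What the synthetic generator emulates — and what it does not

`sampleFC()` draws each off-diagonal entry independently from a normal
distribution with block-dependent mean ($\mu_{within}$ vs
$\mu_{between}$) and common entry noise `sd`, clipped to $\pm 0.999$;
`sampleCohort()` additionally jitters both block means per subject by
$\mathcal N(0, \texttt{subjectSd})$, with per-subject seeds derived as
`seed + subject`. This gives analytically controlled contrast: expected
block-mean recovery follows normal standard errors, and the SNR of the
planted partition can be predicted from the retained-weight means.

The reference study conditions — the generator defaults — are $\Gamma =
20$ subjects, four blocks of 30 nodes, $\mu_{within} = 0.6$,
$\mu_{between} = 0.1$, entry noise $\mathrm{sd} = 0.02$, subject jitter
$0.1$, seed 7. Rationale: a within/between contrast of 0.6 vs 0.1 is a
strong, realistic separation for FC block structure; 0.02 is the order
of the sampling error of a Pearson correlation estimated from roughly a
thousand time points ($(1 - r^2)/\sqrt{T}$); and a jitter of 0.1
correlation units produces the wide spread of individualized optimal
thresholds that motivates per-subject optimization in the first place.
Problem sizes ($n = 120$ cohorts; $n = 400$ for the null ensemble and
planted-recovery checks; 21-point grids; 100 shuffles; 200 random
instances for the eigensolver cross-check) were chosen so the full
suite runs in about a minute on a laptop core while keeping binomial
standard errors small enough for 3-SE parameter-recovery checks.

What passing tests on these data do **not** show: real FCs are not
two-valued-plus-noise. Their weight distributions are continuous and
heavy-tailed, entries are mutually dependent (they derive from a common
set of time series, and Pearson matrices are constrained toward
positive semidefiniteness), communities are unequal in size and
contrast, and negative correlations are structured rather than noise.
Two visible consequences inside the package: on synthetic group
averages the SNR-vs-$\tau$ curve has an exactly flat plateau (ties are
then resolved to the smallest $\tau$), and the modularity score of the
detected partition plateaus at its ceiling ($3/4$ for four equal
blocks) instead of creeping upward through a gradual fragmentation
regime as it does on real connectomes. Conclusions about real data
should rest on the statistic's analytic properties — which the tests do
verify exactly — not on the generator's realism.

## Design decisions on genuinely open points

- **Vetting in binary mode, optimization in weighted mode.** Vetting is
  defined on the masked (binarized) group average, where $W$ estimates
  a true Bernoulli parameter and the weak-recovery theorem applies
  verbatim; the per-subject optimization uses the weighted SNR, an
  extension of the same statistic to retained absolute weights, used as
  a prominence measure rather than a recovery guarantee. Requesting a
  weighted vetting emits a warning but proceeds.
- **Thresholding on magnitudes.** The weighted block sums use
  $|w_{uv}|$; applying the same convention at the thresholding stage
  keeps the binary and weighted graphs support-identical at equal
  $\tau$ (a tested invariant). Users who want positive-only edges have
  `signed = TRUE`.
- **Empty vetting interval.** The pipeline reports optima with all
  membership flags `FALSE` and a prominent warning instead of aborting:
  an unprominent partition is a result, not an error.
- **Q-maximization heuristic.** Greedy multi-level (Louvain-style)
  local moves + aggregation, seeded through a one-shot node-order
  shuffle for determinism; backed by `igraph::cluster_louvain`, while
  the package's own `modularityQ()` (cross-checked against
  `igraph::modularity`) defines the objective. No consensus clustering:
  the back-test needs a representative heuristic, not the best one.
- **AMI with exact expectation.** The hypergeometric expected-MI is an
  exact finite sum (not Monte-Carlo) — cheap at these $n$ and
  deterministic. Identical partitions return exactly 1; two trivial
  single-community partitions are defined to agree (AMI 1).
- **Weighted-SBM posterior inference is out of scope.** Fitting a full
  weighted SBM by posterior inference is a modeling study of its own;
  the back-test accepts any externally inferred partition via
  `ami(detected, apriori)`, which is the documented adapter.

## Known limitations

- The SNR addresses *weak* recovery only; exact-recovery criteria
  (Chernoff–Hellinger-type distances) are a different, stronger regime
  and are not implemented.
- Degree-corrected SBM variants are not implemented; hub-dominated
  graphs may look prominent or unprominent for degree reasons alone
  (the shuffle null partially controls for this).
- Dense-matrix algorithms throughout: memory is $O(n^2)$ per matrix and
  a 21-point sweep costs 21 block-count products; comfortable to
  $n \sim 10^4$, not beyond.
- The weighted-mode SNR inherits no recovery theorem; it is a
  prominence score, and the package deliberately reports the binary
  vetting interval next to every weighted optimum.
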