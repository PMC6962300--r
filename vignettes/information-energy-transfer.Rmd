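---
title: "Information transfer, energy and pattern overlap on thresholded connectomes"
author: "connectoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information transfer, energy and pattern overlap on thresholded connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoflux)
```

## The model

`connectoflux` studies a one-step signal-propagation model on weighted,
symmetric connectivity matrices. A subject's matrix $w_{ij}$ (typically
inter-regional correlations of resting-state fMRI, or DTI connection
strengths) is reduced to a network of significant connections by a
subject-specific cut-off

$$w_t = \langle |w| \rangle + n\,\sigma_{|w|},$$

where the mean and standard deviation are taken over the absolute
off-diagonal weights and $n$ is the sweep parameter. Connections with
$|w_{ij}| > w_t$ (strictly) survive with their signs; everything else is
removed. Sweeping $n$ moves the network between a noisy regime (all edges,
including weak, unreliable ones) and a fragmented regime (only the strongest
core survives).

Nodes take ternary activation states $\{+1, -1, 0\}$: positive activation,
negative activation (fMRI responses deflect in both directions), and
inactivity. A stimulus $S$ activates each node independently: $+1$ with
probability $p$, $-1$ with probability $p$, inactive otherwise. The one-step
response is

$$r_j = \sigma\!\Big(\sum_{i \ne j} \tilde w_{ij}\, s_i\Big), \qquad
\sigma(x) = \begin{cases} +1 & x > t^* \\ -1 & x < -t^* \\ 0 &
\text{otherwise,} \end{cases}$$

with $\tilde w$ the retained weights and $t^* = \max(w_t, 0)$. Transfer is a
single step: the model deliberately has no iterated dynamics, no stochastic
response noise and no weight learning — it isolates how the *structure* of
the thresholded network shapes an elementary stimulus–response map.

Two conventions deserve explicit statement because the model definition
leaves them open:

* **The response sum uses the thresholded weights.** The network under study
  is the thresholded one; letting sub-threshold weights leak into the
  response would make the threshold sweep incoherent (the adjacency, the
  energies and the topology all live on the retained edges).
* **Negative cut-offs classify by plain sign.** For $w_t < 0$ the three
  branches of $\sigma$ overlap as written ($x > w_t$ and $x < -w_t$ can hold
  simultaneously). Clamping the classification threshold at
  $t^* = \max(w_t, 0)$ removes the contradiction and produces the expected
  flat regime at strongly negative $n$, where the retained network stops
  changing and the responses saturate into dense $\pm 1$ patterns.

## Measured quantities

For each network state (a subject at a threshold $n$ and probability $p$,
driven by $K$ stimuli) the sweep records:

* **Mutual information** (bits): plug-in estimates
  $m(i,j) = H(s_i) + H(r_j) - H(s_i, r_j)$ from the $K$ paired samples, for
  every ordered pair $i \ne j$; per-target means
  $\langle m(j)\rangle = \sum_{i\ne j} m(i,j)/(N-1)$; network value
  $m = \sum_j \langle m(j)\rangle / N$. Base 2 throughout. No bias
  correction is applied: at $K = 100$ the plug-in estimate (bias
  $\approx (|S|-1)(|R|-1)/(2K\ln 2) \approx 0.03$ bits per pair) *is* the
  quantity under study, and all comparisons are made at fixed $K$, so the
  bias cancels across conditions to first order.
* **Energies**: wiring cost $E_W = \sum_{i,j} a_{ij}$ (ordered pairs — each
  undirected edge counts twice; the double-counted convention is kept
  everywhere, so the normalized ratios are internally consistent); bias-free
  Hopfield energy $E_H = -\sum_{i \ne j} r_i \tilde w_{ij} r_j$ (bias terms
  are dropped under node homogeneity); activity cost
  $E_A = \sum_{i \ne j} |r_i \tilde w_{ij} r_j|$, which removes the sign
  cancellation and always bounds $|E_H|$. $E_H$ and $E_A$ are computed per
  response and averaged over the $K$ stimuli; the ratios $E_H/E_W$ and
  $E_W/E_A$ are formed from the batch means, with zero denominators flagged
  (`NA`) rather than thrown.
* **Pattern overlap**: the fraction of nodes in identical states between two
  responses, averaged over all $K(K-1)/2$ pairs. Two inactive nodes count as
  a match — the comparison is between states, not activations — which is
  exactly why overlap climbs toward 1 on over-thresholded, mostly silent
  networks, and also why it is elevated in the saturated low-threshold
  regime. Its interior minimum marks the balanced state.
* **Topology and strengths**: largest-connected-component fraction and
  global transitivity ($3 \times$ triangles / connected triples, computed
  with `igraph`; defined as 0 when no triples exist), consecutive
  differences $\Delta C(i) = C(i) - C(i+1)$ along the ascending grid, and
  absolute node strengths $ns_i = \sum_j |\tilde w_{ij}|$ on the thresholded
  matrix (strengths must respond to the threshold for the sweep to be
  informative).

## The truncated power-law strength model

Heavy-tailed node strengths with an energetic ceiling are modelled as

$$p(ns) \propto (ns_{max} - ns)^{\gamma}, \qquad ns \in [ns_{min}, ns_{max}].$$

The fitting procedure is deliberately simple and deterministic:

* $ns_{min} = \min(ns)$ (the model's lower support bound is not identified
  beyond the sample).
* For each candidate $ns_{max}$ on a 50-point grid spanning
  $(\max(ns)(1+10^{-6}),\ \max(ns) + 2\,\mathrm{range}(ns)]$, the exponent
  has the closed-form conditional maximum-likelihood solution
  $\hat\gamma = 1/\overline{\ln\!\big[(ns_{max}-ns_{min})/(ns_{max}-ns_i)\big]} - 1$.
* The candidate minimizing the two-sided Kolmogorov–Smirnov distance
  $D = \max_k \max(|F(x_{(k)}) - k/n|, |F(x_{(k)}) - (k-1)/n|)$ between the
  model CDF and the empirical CDF is selected — the selection criterion is
  the same statistic that is reported.
* A Gaussian fit (sample mean/sd) to the same data supplies the comparison
  distance `ks_D_normal`.

Estimator recovery from direct samples of the model is part of the test
suite. One honest limitation: when $\gamma$ is large the density vanishes
steeply at the upper endpoint, so $ns_{max}$ itself is only estimable to
$O(n^{-1/(\gamma+1)})$ — about $0.16 \times$ the range at $\gamma = 4$,
$n = 10^4$ — and that endpoint uncertainty propagates into individual
$\hat\gamma$ draws (observed per-fit errors up to $\approx 0.3$, identical
for a profile-likelihood variant, versus $\le 0.09$ when the true endpoint
is supplied). Recovery is therefore asserted on the mean over seeded
replicates; single fits at large $\gamma$ carry irreducible scatter that no
choice of estimator removes.

## Synthetic data: what it emulates, and what it does not

Three generators make every stage runnable without external downloads:

* `random_null_matrix` / `random_null_matrices` — the null ensemble:
  symmetric matrices with i.i.d. weights uniform on $[-1, 1]$, zero
  diagonal. On this ensemble the map $(W, S) \mapsto (-W, S)$ negates the
  Hopfield energy of the responses while preserving the ensemble law, so
  the expected $E_H$ is exactly zero; the Monte-Carlo mean over 1,000
  matrices at $N = 177$ is the package's headline reproduction target
  (`scripts/acceptance.R`).
* `factor_model_matrix` — a brain-*like* stand-in: node time series
  $x_i(t) = a_i g(t) + b_i f_{c(i)}(t) + \varepsilon_i(t)$ with a global
  latent signal carried by a hub subset ($a_i = 0.8$ for a random 10% of
  nodes), four contiguous communities ($b_i = 0.5$), unit noise, $T = 200$
  time points, $N = 120$ nodes; the returned matrix is the Pearson
  correlation matrix of the series. These defaults are fixed once so that
  every test condition is reproducible. Hubs acquire elevated strength
  through their mutual correlations, giving the right-skewed strength
  distributions that drive the long thresholding tail. A caveat on the
  skewness itself: at $N = 120$ the sample third moment is noisy, and
  although hub strengths exceed the bulk at every seed examined, the
  scalar skewness can dip marginally below zero for isolated seeds; tests
  assert the hub elevation per seed and positivity of the mean skewness
  over a seed grid.
* `sample_strengths` — exact inverse-CDF draws from the truncated power
  law, for estimator recovery.

What the factor model does **not** emulate: spatial embedding, anatomical
community layout, subject-to-subject anatomical correspondence, empirical
noise spectra, or the precise strength distribution of real connectomes.
Consequences visible in the sweeps: the synthetic weight tail is strong
enough that the largest component stays intact almost to the end of the
default grid (fragmentation only begins near $n = 2$), so the
mutual-information decline on the sparse side is gentler than on real
matrices and the MI curve has a broad plateau (differences of order
$10^{-4}$ bits across $0.6 \lesssim n \lesssim 1.4$ at $p = 0.05$,
$K = 100$). The interior MI maximum, the interior overlap minimum near it,
the monotone decay of $E_W$ and the component fraction, and the negative
MI–overlap correlation all reproduce; the *exact* grid position of the MI
argmax on that plateau is sensitive to the stimulus stream. Passing sweeps
on synthetic matrices demonstrate that the machinery and the qualitative
mechanism are right — not that any particular printed value for real
connectome collections will be matched.

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `n_grid` | $-2.0$ to $2.0$ step $0.2$ | threshold multipliers (dimensionless sd units); spans the saturated-to-fragmented range on correlation-like matrices |
| `p_values` | $0.1, 0.05, 0.01$ | per-sign activation probability; $0.05$ maximizes transfer and is the reference condition |
| `K` | 100 | stimuli per condition; the plug-in MI at this $K$ is the reported quantity |
| `root_seed` | 1 | all stimulus streams derive from it via fixed per-(subject, $n$, $p$) offsets, so sweeps are bit-reproducible |
| `grid_size` (fit) | 50 | $ns_{max}$ candidates; KS selection is flat near its optimum, so finer grids change little |

## Numerical choices and degenerate inputs

* Diagonals are zeroed on ingestion and excluded from every statistic
  (self-correlations are artifacts); asymmetry beyond $10^{-6}$ warns and
  symmetrizes by averaging — only shape or parse problems are errors.
* $\sigma_{|w|}$ is the sample standard deviation over all $N(N-1)$
  off-diagonal entries; at $N \approx 177$ the sample/population choice is
  negligible but it is fixed for bit-reproducibility.
* Ties at exactly $w_t$ are dropped (strict inequality, as the retention
  rule is written).
* Plug-in MI is clamped at 0 against floating-point cancellation
  (tolerance $10^{-9}$); genuine negatives raise an error.
* Degenerate sweep conditions are values, not crashes: $p = 0$ gives
  $m = 0$ and overlap 1; an empty network flags $E_H/E_W$ as `NA`; an
  all-silent response batch flags $E_W/E_A$; a strength sample that is all
  zeros (over-thresholded) yields `NA` for the fit columns.
* Subjects that fail inside a sweep are skipped with a warning; the sweep
  continues.
* Seeds are kept below $2^{31}$ throughout (`derive_seed`), so any single
  condition can be regenerated in isolation.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data at
the protocol's own scales: the 1,000-matrix null ensemble at $N = 177$ with
$K = 100$ and $n \in \{-1, 0, 1\}$; 20 factor-model subjects across the full
default grid at $p = 0.05$; $10^4$-sample estimator-recovery fits; and
exhaustive $3^N$ enumerations at $N \le 6$ against independent loop oracles.

## Known limitations

* One-step transfer only; no avalanche statistics, no temporal dynamics.
* No inferential statistics on the figure-level correlations (they describe
  mean curves across a matrix collection, not hypothesis tests).
* The strength-model comparison is a two-model KS contest (truncated power
  law vs Gaussian), not a full model-selection study with bootstrap
  $p$-values.
* On the synthetic sweeps the overlap minimum co-varies *positively* with
  $E_W/E_A$ across thresholds (both are U-shaped with nearby minima around
  the optimal state); directions of figure-level correlations that hinge on
  branch asymmetries of real connectome curves should be checked on real
  data rather than assumed from the stand-in.
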