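# connectoflux

Information transfer and energy analysis of thresholded brain connectivity
networks.

## The problem

Resting-state functional connectomes are distributed as N × N symmetric
weight matrices `w_ij` (Pearson correlations between regional fMRI time
series; structural DTI matrices have the same form). Which connections are
"real" depends on a cut-off: keep everything and signal transfer is swamped
by weak, noisy edges; cut too hard and the graph fragments into disconnected
islands. `connectoflux` quantifies what happens to information flow,
energetic cost, activation-pattern redundancy and network structure as a
matrix is swept between those two regimes, for whole collections of
subject-level matrices.

## The model

Each matrix is thresholded at a subject-specific cut-off

    w_t = <|w|> + n * sigma_|w|

(mean and sd of the absolute off-diagonal weights; `n` is the sweep
parameter). Nodes carry ternary activation states {+1, −1, 0}. A random
stimulus `S` activates each node positively or negatively with probability
`p` each, and the one-step response is

    r_j = sigma( sum_i w~_ij * s_i ),    sigma: +1 above t*, −1 below −t*, else 0

over the retained signed weights `w~`, with effective response threshold
`t* = max(w_t, 0)`. For each network state the package measures:

- **Mutual information** `m(i,j) = H(s_i) + H(r_j) − H(s_i, r_j)` (plug-in,
  bits), averaged per target over its N−1 sources and then over targets —
  the efficiency of stimulus→response transfer.
- **Energies**: wiring cost `E_W = Σ a_ij` (ordered pairs), bias-free
  Hopfield energy `E_H = −Σ r_i w~_ij r_j`, activity cost
  `E_A = Σ |r_i w~_ij r_j|`, and the normalized ratios `E_H/E_W`, `E_W/E_A`.
- **Pattern overlap**: mean fraction of nodes in identical states across all
  response pairs (1 − normalized Hamming distance) — redundancy of the
  activation patterns.
- **Structure**: largest-connected-component fraction, global transitivity
  and its consecutive differences, absolute node strengths
  `ns_i = Σ_j |w~_ij|`, and an upper-truncated power-law fit
  `p(ns) ∝ (ns_max − ns)^γ` selected by Kolmogorov–Smirnov distance against
  the data (with a Gaussian fit as the comparison model).

Synthetic generators make the whole pipeline self-contained: a uniform-weight
null ensemble (`w ~ U[−1, 1]`), hub/community factor-model correlation
matrices with right-skewed strengths, and direct samples from the truncated
power law for estimator-recovery tests.

## Worked example

```r
library(connectoflux)

M    <- factor_model_matrix(seed = 8)          # 120-node synthetic connectome
spec <- compute_threshold(M, n = 1)
net  <- apply_threshold(M, spec)

stim <- sample_stimuli(M$N, p = 0.05, K = 100, seed = 101)
resp <- simulate_transfer(net, stim)

network_mi(stim, resp)
energy_report(net, resp)
mean_overlap(resp)
fit_strength_model(node_strengths(net))
```

prints

```
<threshold_spec> n = 1: w_t = 0.174693 (<|w|> = 0.0926994, sd = 0.0819936)
<thresholded_network> N = 120, w_t = 0.174693 (t* = 0.174693), 1210 undirected edges
<mi_summary> network MI m = 0.04008 bits over 120 nodes (node means 0.03481..0.04481)
<energy_report> E_W = 2420, E_H = -195.98, E_A = 281.56 over K = 100 responses
  E_H/E_W = -0.080985, E_W/E_A = 8.5949
<overlap_summary> mean overlap 0.3350 over 4950 pattern pairs
<strength_fit> gamma = 0.124, ns_max = 8.785 on [0.9452, ns_max], n = 120
  KS distance: model 0.1916 vs normal 0.0743
```

One standard deviation above the mean absolute weight, this subject keeps
1,210 of its 7,140 possible edges; each stimulus bit reaches a target with
about 0.04 bits of information; responses agree at a third of the nodes on
average; and the Hopfield energy is strongly negative (structured responses),
at −0.08 per retained ordered connection.

The orchestrated sweep runs this over a subject collection and a threshold /
probability grid:

```r
mats <- lapply(1:20, function(s) factor_model_matrix(seed = s))
tbl  <- run_sweep(mats, n_grid = seq(-2, 2, by = 0.2), p_values = 0.05, K = 100)
agg  <- aggregate_sweep(tbl)
correlate_sweep(agg, "mi", "overlap", p = 0.05)
#> <sweep_correlation> mi vs overlap over 21 thresholds: Pearson r = -0.8625
#>   mi peaks at n = 1; overlap peaks at n = 2
```

Mutual information peaks in the interior of the sweep (n = 1), pattern
overlap bottoms out at the same threshold, and the two anti-correlate across
the sweep — the efficiency/redundancy trade-off around the optimal
intermediate state, where the network is still fully connected
(`lcc_fraction = 1`) with close to the minimum number of connections.

Matrices are read from plain-text N × N grids with
`read_connectivity_matrix()` (whitespace, comma or tab delimited); sweep
tables are written as TSV with `write_sweep_table()`.

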