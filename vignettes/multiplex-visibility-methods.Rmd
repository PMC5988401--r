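---
title: "Multiplex visibility graphs for multivariate signals: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex visibility graphs for multivariate signals: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muxvig)
```

## The model

A uniformly sampled scalar series $y_1, \dots, y_N$ maps to a graph on
$N$ nodes, one per time point. Under the *natural* visibility criterion,
nodes $i < j$ are linked iff

$$y_k < y_i + (y_j - y_i)\,\frac{k - i}{j - i} \quad \text{for all } i < k < j,$$

i.e., the straight segment between the two samples clears every
intermediate sample. Under the *horizontal* criterion the requirement is
$y_k < \min(y_i, y_j)$. Both inequalities are strict: equal values block
horizontal visibility and collinear points block natural visibility,
which is why a pure linear trend maps to the bare chain and the NVG is
exactly invariant under $y \mapsto a\,y + b\,t + c$ with $a > 0$. The
HVG depends only on the ordering of the values, hence is invariant under
any strictly increasing transform, and is always a subgraph of the NVG.
Every graph contains the chain $(i, i+1)$, so interior nodes have degree
at least 2 and the graph is connected.

For an $M$-variate series the $M$ per-signal graphs share the node set
$\{1, \dots, N\}$ because node $t$ *is* time stamp $t$ in every layer.
That natural alignment makes the collection a multiplex network, and it
is what licenses pairing degrees across layers: for layers $\alpha,
\beta$ the pairs $(k^\alpha_t, k^\beta_t)$, $t = 1..N$, define an
empirical joint distribution whose mutual information

$$\mathrm{MI}_{\alpha\beta} = \sum_{k^\alpha}\sum_{k^\beta}
  P(k^\alpha, k^\beta)\,\log\frac{P(k^\alpha, k^\beta)}
  {P(k^\alpha)\,P(k^\beta)}$$

quantifies shared temporal structure. Averaging over all unordered ROI
pairs inside one labeled network gives the per-subject scalar
$\langle \mathrm{MI} \rangle$ that the group statistics consume.

## Estimation choices

**Logarithm base.** Natural log; all outputs are in nats and every file
writer records the base in sidecar metadata. A `base` argument exposes
bits, off by default.

**Plug-in estimator, no bias correction.** Joint and marginal
frequencies over exact integer degrees, no binning, no smoothing, no
Miller–Madow-type correction. The plug-in MI is biased upward at fixed
$N$, but the bias is a shared offset when conditions are compared at the
same $N$, which is the use case here; a correction would buy little and
cost the exact identity $\mathrm{MI}(\alpha,\alpha) = H(\alpha)$ that
the tests lean on.

**Degenerate layers.** A layer with a constant degree sequence has zero
entropy and contributes MI exactly 0 against anything; no NaN can
propagate (the $0 \log 0 := 0$ convention is implemented by summing only
over non-zero joint cells).

**$\langle \mathrm{MI} \rangle$ averaging.** Unordered off-diagonal
pairs only, each counted once; the diagonal (layer entropies) is never
averaged in. A network with a single ROI has no pairs and asking for its
average is an error rather than a silent NA.

**Node identity.** Node ids are 1-based inside R, matching the
language's and igraph's convention; the on-disk edge-list and partition
formats are 0-based, which is the convention of the adjacency/edge-list
consumers these files target. Only the writers/readers translate.

## Constructions and numerics

`nvg_naive` is the reference: for each left endpoint it sweeps right,
maintaining the running maximum slope, which evaluates the criterion
exactly in $O(N^2)$. `nvg_fast` recurses on the segment maximum (the
maximum blocks all sight across it, a consequence of the line at any
interior point being a convex combination of the endpoint values), doing
two running-maximum sweeps per segment; average cost $O(N \log N)$,
degrading gracefully to $O(N^2)$ on monotone series. The two must agree
edge-for-edge, and the test suite enforces this on randomized suites
including constant, monotone, and tied series, where tie handling is
most fragile. `hvg` is the standard monotone-stack construction; a tie
pops the blocking element after linking it, which realizes the strict
criterion exactly. Slope comparisons are done in double precision
without tolerances: the criteria are strict inequalities and introducing
an epsilon would silently redefine them.

## Temporal communities

Each layer is partitioned by the Louvain heuristic, best of `n_runs =
100` restarts (distinct sub-seeds derived from one user seed), keeping
the run with maximal modularity; ties break toward fewer modules, then
the lexicographically smallest label sequence, making the result
deterministic given the seed. Restart-and-select was chosen over
consensus clustering as the simplest scheme that uses all runs'
information relevant to a *best* partition; resolution is fixed at 1 and
exposed. Module labels are renumbered by first appearance along the time
axis, so label 1 is always the earliest regime. Partition similarity is
reported as the Sorensen matrix over module pairs and as NMI with the
$2I/(H_1+H_2)$ normalization; because toolbox implementations disagree
on the normalizer, `max` and `joint` variants are selectable. A
contiguity score (fraction of interior time points whose both neighbors
share their module) is reported but deliberately not thresholded: near-1
values are typical for smooth band-limited signals, but how close is an
empirical matter, not a contract.

## Robust group statistics

The Harrell–Davis estimator weighs the order statistics with
$w_i = I_{i/n}(a, b) - I_{(i-1)/n}(a, b)$, $a = (n+1)q$,
$b = (n+1)(1-q)$, with $I$ the regularized incomplete beta function
(`pbeta`). The Bayesian bootstrap draws flat-Dirichlet observation
weights, evaluates the *weighted* HD median (the Dirichlet cumulative
weights replace the uniform $i/n$ grid in the Beta integral), and
reports the narrowest interval containing 95% of the draws. The shift
function compares two groups at the nine deciles, with simultaneous
bounds $\hat\Delta_q \pm c\,\sqrt{SE_x^2 + SE_y^2}$ using bootstrap
standard errors per group and Wilcox's calibration constant
$c = 80.1/\min(n_x, n_y)^2 + 2.73$ for a familywise type-I error near
0.05 across the nine intervals; the acceptance suite verifies the
realized familywise error by simulation (500 null replicates, $n = 100$
per group, 500 bootstraps — sizes chosen to estimate a 0.05 rate with a
standard error under 0.01). The group test is a covariate-adjusted
F-test via nested linear models on the per-network scalar, with a
Pillai-trace multivariate option over all networks jointly; a covariate
perfectly collinear with the group factor is a hard error, not a silent
drop. The outlier rule flags a point when the median of its pairwise
absolute distances to the rest exceeds 2.24 times the overall median
pairwise distance — a scale-ratio rule that assumes no symmetry; a
MAD-median variant is selectable. The exact outlier and multivariate
procedures in this literature vary between toolboxes, so both are
documented options rather than one canonical choice.

## The synthetic generator

`generate_subject` draws, per network $g$, a latent series $z_g$ and
per-ROI noise $\varepsilon_i$, mixes them as
$x_i = \sqrt{\rho_g}\, z_g + \sqrt{1-\rho_g}\,\varepsilon_i$, band-pass
filters to 0.01–0.08 Hz at $dt = 2$ s (the canonical resting-state
band), and standardizes per ROI. The latent-factor construction was
preferred over a VAR process because $\rho$ *is* the within-network
coupling, giving the MI monotonicity tests an unambiguous ground truth.
Filtering is zero-phase (forward–backward) with an order-4 Butterworth
band-pass; order 4 keeps the out-of-band power under 5% of the total at
the lengths used, which gentler skirts do not. Eight samples at each end
are generated in excess and trimmed before standardization to absorb
filter transients. Cohorts add synthetic age and framewise-displacement
covariates, with an optional per-group FD shift to rehearse covariate
adjustment under confounding. All randomness flows from one master seed
through explicit sub-seed derivation; identical specs produce
bit-identical cohorts.

Desk-scale defaults are $M = 27$ ROIs (three per each of nine networks)
and $T = 150$ time points — sizes at which the full pipeline over
replicate cohorts runs in minutes. The generator emulates band-limited,
cross-correlated Gaussian signals with known group structure; it does
*not* emulate hemodynamics (no HRF convolution), motion artifacts,
scanner drift, non-Gaussian marginals, or spatial autocorrelation
between networks. Passing tests therefore demonstrate that the pipeline
recovers dependence structure it can see, not that real BOLD data
carries that structure; conclusions about real recordings still require
real recordings.

## Known limitations

Directed and weighted visibility variants are out of scope, as are
sequential visibility motifs. The NVG divide-and-conquer worst case is
quadratic (monotone input). The plug-in MI is biased at small $N$ and
comparisons should be made at a common series length. The Louvain
restart scheme optimizes modularity per layer independently; it does not
attempt a joint multilayer partition. The shift-function calibration
constant is the published approximation for independent groups and nine
deciles; other decile grids would need their own calibration.
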