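# muxvig

Multiplex visibility-graph analysis of multivariate time series in R.

`muxvig` is aimed at researchers who want to characterize the joint
dynamics of a set of simultaneously recorded signals — the motivating
case is resting-state fMRI BOLD activity averaged within regions of
interest (ROIs) — without choosing a sliding window, a detrending scheme,
or a parametric model of the signal. Each signal is mapped to a
*visibility graph* whose nodes are its time points; stacking the graphs
of all signals over the shared time axis yields a *multiplex* network,
one layer per ROI, aligned node-for-node by time stamp. Within-signal
structure lives in the topology of each layer; between-signal structure
lives in how similar the layers are.

## The mapping and the statistic

**Natural visibility (NVG).** Time points i < j are connected iff every
intermediate sample lies strictly below the straight segment between
them:

    y_k < y_i + (y_j − y_i) · (k − i)/(j − i)   for all i < k < j.

**Horizontal visibility (HVG).** i and j are connected iff every
intermediate sample is strictly smaller than both endpoints:
`y_k < min(y_i, y_j)`. The HVG is always a subgraph of the NVG; it is
invariant under monotone rescaling, while the NVG is invariant under
affine transforms plus any linear trend. Both graphs contain the
Hamiltonian chain (i, i+1), so they are always connected. The package
ships a quadratic-scan reference construction (`nvg_naive`) and an
O(N log N) divide-and-conquer construction (`nvg_fast`) contracted to
return the identical edge set; `hvg` uses an O(N) monotone stack.

**Interlayer mutual information.** For layers α and β with degree
sequences paired by time stamp, the plug-in estimate of

    MI(α, β) = Σ_kα Σ_kβ P(kα, kβ) · log [ P(kα, kβ) / (P(kα) P(kβ)) ]

(natural log; nats) measures how much the two signals' temporal
structure is shared. Averaging MI over all ROI pairs within a labeled
network (e.g., one of the nine canonical resting-state networks) gives a
per-subject scalar ⟨MI⟩ per network — the quantity compared across
groups with robust statistics: Harrell–Davis quantiles, Bayesian
bootstrap highest-density intervals, two-sample Kolmogorov–Smirnov
distances against their analytic critical values, shift functions with
simultaneous decile confidence bounds, Holm-corrected covariate-adjusted
F-tests, and a pairwise-distance outlier rule.

The package also segments each layer into temporal modules (best of 100
Louvain runs) and compares module structure across ROIs via the Sorensen
index per module pair and normalized mutual information between whole
partitions.

## Worked example

A synthetic two-group cohort in which only the "Limbic" network's
within-network coupling differs between groups (0.3 vs 0.85):

```r
library(muxvig)

networks <- rep(c("Default", "Limbic", "Visual"), each = 3)
coup <- matrix(0.3, 2, 3, dimnames = list(c("control", "patient"),
                                          c("Default", "Limbic", "Visual")))
coup["patient", "Limbic"] <- 0.85
spec <- cohort_spec(n_subjects = c(control = 20L, patient = 20L),
                    M = 9L, T_len = 150L, networks = networks,
                    coupling = coup, seed = 42L)
cohort <- generate_cohort(spec)
report <- run_pipeline(cohort = cohort, seed = 1L, verbose = FALSE)
report
#> multiplex visibility report: 40 subjects, 3 networks (natural visibility, <MI> in nats)
#> networks by largest pairwise group KS:
#>  network max_ks p_covariate_adjusted   p_holm
#>   Limbic   0.80             2.87e-08 8.62e-08
#>   Visual   0.25             4.29e-01 8.59e-01
#>  Default   0.20             6.36e-01 8.59e-01
```

The contrasted network tops the ranking: the KS distance between the two
groups' ⟨MI⟩ distributions is 0.80 (critical value at α = 0.05 for
n = 20 vs 20 is 0.43), and the covariate-adjusted group test survives
Holm correction; the two uncontrasted networks do not separate. The
per-decile view shows the patients' ⟨MI⟩ distribution shifted upward at
every decile:

```r
report$shift[["Limbic:control_vs_patient"]]
#> shift function (x - y), n_x = 20, n_y = 20, 500 bootstraps, crit = 2.930
#>    q decile_x decile_y difference   lower    upper
#>  0.1   0.6633   0.8420    -0.1787 -0.3097 -0.04779
#>  0.5   0.7680   0.9884    -0.2204 -0.3006 -0.14032
#>  0.9   0.8902   1.1494    -0.2592 -0.4231 -0.09535
```

(differences are control − patient in nats; all nine simultaneous
intervals exclude zero, so the separation holds across the whole
distribution, not just its bulk).

`run_pipeline(..., out_dir = "...")` writes every table plus a JSON
report carrying the configuration hash and seeds; re-running with the
same configuration is bit-identical. A command-line wrapper with
`simulate`, `build`, `mi`, `communities`, `compare`, and `pipeline`
subcommands is installed at `system.file("cli", "muxvig", package = "muxvig")`.

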