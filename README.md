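# gliomanet

Multi-stage network inference for grade-specific regulatory modules in
glioma-style expression studies.

## The problem

Low-grade (WHO grade II) and high-grade (grade IV, glioblastoma) gliomas
differ not only in which genes are expressed but in how regulators are
*wired* to their targets. `gliomanet` implements, as a tested R package, a
pipeline for detecting such rewiring and condensing it into a single
high-evidence subnetwork:

1. **Differential expression** — per-gene Welch t-tests between grades,
   Benjamini-Hochberg FDR, selection at |log2 FC| > 1.5 and FDR < 1%.
2. **Interactome modularization** — the protein-protein interaction network
   restricted to signature genes; hubs called by the *percolation score*
   `(S − 1 − S₋ᵥ)/(S − 1)` (normalized shrinkage of the largest component
   when node v is deleted) above mean + 2 SD; first-neighbour expansion and
   greedy-modularity communities; hypergeometric gene-set enrichment at
   FDR < 10%.
3. **Grade-specific co-expression** — ARACNE-style mutual-information
   networks anchored on user-chosen hub genes (the Rho GTPases in the
   motivating study), permutation-calibrated edge significance with an
   exponential tail extrapolation for stringent cutoffs (p < 1e-5),
   data-processing-inequality pruning, and the bounded connectivity
   contrast `d = (k̂_A − k̂_B)/(k̂_A + k̂_B)` with |d| > 0.4 calling a hub
   grade-specific.
4. **Time-course dynamics** — a two-step noise filter, PAM clustering with
   medoid profiles, response-time classes at 50% of the dynamic range
   (rapid / intermediate / delayed), cubic interpolation to 100 points and
   a time-delay Spearman map (lags 13-24 h, significant above ρ = 0.9).
5. **Evidence integration** — node prizes
   `S(v) = score_BUM(p_DE) + β·interactor + γ·coexpr` from a beta-uniform
   mixture fit of DE p-values plus bait-interaction and co-expression
   evidence, and a rooted prize-collecting Steiner tree heuristic that
   extracts the maximum-net-score connected module around a bait gene,
   with permutation significance.
6. **Survival** — Kaplan-Meier curves, log-rank tests, and an
   optimal-cutpoint scan maximizing the Cox score statistic over covariate
   ranks, always reported with a permutation-adjusted p-value.

A synthetic-data module (`make_interactome`, `make_two_condition_expression`,
`make_timecourse`, `make_survival`) generates every input with planted
ground truth, so the whole pipeline is testable offline; the methods
vignette (`vignettes/gliomanet-methods.Rmd`) documents every model,
threshold and design decision.

## A worked example

```r
library(gliomanet)

# a scale-free interactome with 7 + 7 hubs whose wiring switches with grade
net   <- make_interactome(250, attach_m = 3, module_size = 20, seed = 11)
truth <- assign_condition_hubs(net$truth, n_hubs_A = 7, n_hubs_B = 7,
                               n_targets = 10, seed = 12)
sim   <- make_two_condition_expression(truth, n_samples_A = 150,
                                       n_samples_B = 150,
                                       target_corr = 0.8, noise_sd = 0.5,
                                       seed = 13)

netA <- build_hub_network(sim$expr, "gradeII", truth$regulator_ids,
                          alpha = 1e-3, seed = 21)
netB <- build_hub_network(sim$expr, "gradeIV", truth$regulator_ids,
                          alpha = 1e-3, seed = 22)
netA
#> mi_network [gradeII]: 14 hubs, 73 edges (alpha 0.001, n = 150)

prof <- grade_specificity(netA, netB, threshold = 0.4)
table(prof$class)
#>
#> gradeII gradeIV
#>       7       7
```

All 14 hubs land on their planted side: the seven condition-A regulators
are called grade II-specific (d > 0.4) and the seven condition-B regulators
grade IV-specific (d < −0.4) — the connectivity-switch signature the
pipeline is built to detect.

The full demonstration pipeline writes every artifact plus a manifest:

```r
res <- run_pipeline(pipeline_config(out_dir = "demo", global_seed = 1))
#> stage simulate (seed 727382441)
#> stage de
#>   60 genes selected
#> stage ppi (seed 1944729)
#>   4 hubs, 3 communities
#> stage mi (seed 22304)
#>   edges: 69 (gradeII), 76 (gradeIV)
#> stage timecourse (seed 682635304)
#>   38 genes kept, 2 significant lag pairs
#> stage integrate (seed 438779350)
#>   module: 70 nodes, net score 2322.66, p_emp 0.0784, p_param 0.0481
#> stage survival (seed 870249735)
#>   cut at rank 74, log-rank p 2.48e-07 (adjusted 0.00498)
```

Reruns with the same configuration are byte-identical.

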