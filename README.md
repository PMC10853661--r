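# multigsi

Integrated multistage Bayesian genetic stock identification (GSI) for
mixed-stock samples.

## The problem

GSI estimates the contribution of each source population to a mixture —
typically a fishery catch — by comparing the mixture fish's multilocus
genotypes to baseline allele frequencies from known spawning populations.
Genetic baselines are usually developed regionally, with marker panels
that differ between regions, so they cannot simply be merged into one
range-wide, high-resolution baseline.  When a mixture spans a broad area,
the conventional workaround is a hierarchical "hard cut-off" two-step
(HC 2-step) analysis: assign fish to broad reporting groups with a
broad-scale baseline, select those assigned to a sub-region with
probability above a threshold (usually 0.8), and re-analyze only them
against the regional baseline.  Fish misassigned in step one are silently
lost or wrongly included, and step-one uncertainty never reaches the
step-two intervals.

`multigsi` implements the integrated alternative: two stacked Bayesian
mixture models — a broad-scale stage and one stage per regional
baseline — sharing a single Gibbs sampler.  Per iteration, every fish
draws a broad-scale population membership; the fish currently assigned
inside sub-region *r* (the broad populations *B_r*) additionally draw a
regional membership; and all proportion vectors are refreshed from their
Dirichlet full conditionals.  Reporting groups from the two stages are
combined every retained iteration as

    (p_groups outside any region,  p_r[g] * sum(p[b in B_r])  for regional groups g)

which sums to one and carries broad-stage uncertainty into the regional
estimates.  The baselines need share no markers and no populations; each
mixture fish must simply be genotyped (missing loci allowed) at both
marker sets.

The package provides, per its module layout:

* `run_single_gsi()` — classic single-baseline Pella-Masuda sampler and
  its conditional variant (baseline frequencies integrated out into a
  compound Dirichlet-multinomial, `dcdm()`); the conditional sweep runs
  in C++,
* `run_msgsi()` — the integrated multistage sampler (any number of
  disjoint regions),
* `run_hc2step()` — the hard cut-off two-step comparator, threshold and
  rescaling rule configurable,
* `gelman_rubin()`, `effective_size()`, `summary()` — convergence
  diagnostics and the standard report (mean, SD, 90% credible interval,
  R-hat, N_eff),
* `synthetic_scenario()`, `generate_baseline()`, `synthesize_mixture()`
  — an F-model study generator with leave-out mixture synthesis,
* `run_repeated_cv()` — repeated cross-validation reporting per-group
  RMSE, bias, and percent deviation beyond ±0.1, with adequacy flags,
* `inst/cli/multigsi.R` — a command-line front end
  (`simulate`, `fit-single`, `fit-msgsi`, `fit-hc2step`, `evaluate`,
  `summarize`).

## Worked example

Simulate a five-group study (one coastal group, four river groups behind
one regional baseline), synthesize a 205-fish mixture at known
proportions, and fit the multistage model:

```r
library(multigsi)

sc  <- synthetic_scenario(n_broad_loci = 30, n_regional_loci = 40)
st  <- simulate_study(sc, seed = 42)
syn <- synthesize_mixture(st$broad, st$regional, st$region_map,
                          sc$true_group_proportions,
                          sc$mixture_size, seed = 7)

fit <- run_msgsi(syn$mix_broad, syn$mix_regional,
                 syn$broad_base, syn$regional_bases, st$region_map,
                 mcmc = mcmc_config(seed = 5))

summary(fit, truth = syn$truth$proportions)
```

```
       group   true   mean     sd lower_90 upper_90 rhat n_eff
1    Coastal 0.2683 0.2685 0.0304   0.2201    0.319    1  9858
2  LowerTrib 0.0976 0.0984 0.0207   0.0670    0.135    1  9302
3    MidTrib 0.1902 0.1901 0.0272   0.1466    0.236    1  9379
4  UpperTrib 0.1317 0.1319 0.0235   0.0955    0.172    1  9691
5 Headwaters 0.3122 0.3112 0.0319   0.2599    0.364    1  9250
```

Each row is a reporting group: the realized true mixture proportion, the
posterior mean and SD of its estimated proportion, the equal-tailed 90%
credible interval, and the convergence diagnostics (R-hat near 1 and an
effective size near the 10,000 retained-draw cap indicate well-mixed
chains).  The four river groups are resolved by the regional stage; with
40 informative regional markers the estimates sit within about one SD of
the truth.

The same data through the two-step comparator:

```r
hc <- run_hc2step(syn$mix_broad, syn$mix_regional,
                  syn$broad_base, syn$regional_bases, st$region_map,
                  mcmc = mcmc_config(seed = 5), tau = 0.8)
length(hc$selected$Upriver)   # fish passing the 0.8 threshold
#> [1] 150
```

`run_repeated_cv()` compares both methods over replicate mixtures with
random truths and reports whether each group meets the standard adequacy
guidelines (within ±0.1 of truth in >90% of replicates, |bias| <= 0.05,
RMSE <= 0.05).

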