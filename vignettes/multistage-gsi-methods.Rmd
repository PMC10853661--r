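---
title: "Multistage genetic stock identification: model, sampler, and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage genetic stock identification: model, sampler, and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genetic stock identification (GSI) estimates what fraction of a
mixed-stock sample — typically a fishery catch — comes from each
contributing population, by comparing the mixture fish's multilocus
genotypes against baseline allele frequencies from known spawning
populations.  Baselines are usually built regionally, with marker panels
chosen to separate local stocks; those panels rarely coincide across
regions.  When a mixture spans a wide area, managers face a dilemma: a
broad-scale baseline covers everything but cannot resolve fine-scale
reporting groups, while the high-resolution regional baseline covers only
its own sub-region.

`multigsi` implements an integrated multistage estimator for exactly this
situation: a broad-scale mixture model and one regional mixture model per
sub-region run inside a *single* Gibbs sampler, so the uncertainty of each
fish's broad-scale assignment propagates into the regional estimates.  The
package also implements the two building blocks needed to study the
method: the classic single-baseline Bayesian GSI model (in both its fully
Bayesian and conditional forms) and the conventional "hard cut-off"
two-step procedure it is meant to replace, plus convergence diagnostics and
a repeated cross-validation harness.

## The single-baseline model

For baseline population $k$, locus $l$ with $J_l$ alleles and ploidy
$\mathrm{ploidy}_l$, the baseline allele counts $y_{k,l,\cdot}$ are
multinomial with frequencies $q_{k,l,\cdot}$, with a Dirichlet prior with
weight $\beta = 1/J_l$ per allele.  Each mixture fish $m$ carries a latent
membership $z_m \sim \mathrm{Mult}(1, p)$, and its genotype at each locus
is multinomial with the frequencies of its source population.  The mixture
proportions $p$ get a Dirichlet prior $\alpha$.

The Gibbs sweep alternates the standard full conditionals: memberships
from weights $w_{m,k} \propto p_k \prod_{l,j} q_{k,l,j}^{x_{m,l,j}}$,
proportions from $\mathrm{Dirichlet}(\text{counts} + \alpha)$, and (fully
Bayesian variant) frequencies from
$\mathrm{Dirichlet}(y + \beta + \text{assigned mixture counts})$.

The **conditional** variant integrates $q$ out of the genotype likelihood
instead of sampling it: the genotype probability becomes a compound
Dirichlet-multinomial with weights $v = \beta + y$ (`dcdm()`), fixed for
the whole run — baseline frequencies are never updated by mixture fish.
It is the package default: the per-individual likelihood tables are
computed once, the sweep reduces to categorical and Dirichlet draws (the
hot loop is C++), and the estimator avoids feedback of mixture genotypes
into baseline frequencies.  The test suite checks that both variants agree
when the baseline is large enough that $q$ is effectively known.

## The multistage linkage

Let the broad-scale baseline have populations $b = 1..B$, partitioned by a
region map into disjoint sub-regions $B_r$ (covered by regional baseline
$r$ with populations $1..K^{(r)}$) and a remainder $B^*$ with no regional
coverage.  Within one sweep:

1. every fish draws a broad-scale membership $z_m$;
2. for each region, the fish whose *current* $z_m$ lies in $B_r$ — and
   only those — draw a regional membership $z^{(r)}_m$ from the regional
   weights; ineligible fish have the zero membership vector, rebuilt from
   scratch every sweep;
3. $p$ and each $p^{(r)}$ are refreshed from their Dirichlet full
   conditionals (with zero eligible fish, $p^{(r)}$ is a pure prior draw).

At every retained iteration the two stages are combined into one
reporting vector: non-regional broad groups keep their broad proportion,
and each regional group $g$ is reported as
$p^{(r)}_g \cdot \sum_{b \in B_r} p_b$, so the combined vector sums to
one.  Because the regional groups are rescaled by a *draw* of the region
total (not a point estimate), the combined intervals carry the broad-stage
uncertainty — the property the hard cut-off two-step procedure lacks.

Every mixture fish must be genotyped (missing loci are allowed and simply
drop out of the likelihood) at every baseline's marker set; the baselines
themselves need share neither markers nor populations.  Multiple regions
are supported even though the motivating application used one.

### One-way linkage, and what the sampler's posterior actually is

The broad-stage membership weights contain no regional-likelihood term:
information flows from the broad stage down to the regional stage, never
back up.  Two consequences are worth stating plainly:

* the broad-scale marginal posterior is identical to a single-baseline
  analysis of the broad data (the package exploits this: a run with zero
  regions is bit-identical to `run_single_gsi()` at matched seeds);
* the regional stage conditions, at each sweep, on the regional proportion
  vector drawn in the *previous* sweep, whose eligible set may have
  differed.  On realistic mixtures (hundreds of fish, informative
  markers) eligibility is stable and this distinction is far below Monte
  Carlo error; on 3-fish toy instances it is measurable (~0.005–0.01 in
  posterior means against a naively factorized enumeration).  The test
  suite therefore validates the sampler against the *exact* stationary law
  of the algorithm, obtained by treating the joint membership state as a
  finite Markov chain whose transition kernel is computed by numerical
  quadrature.

## The hard cut-off two-step comparator

`run_hc2step()` reproduces the conventional procedure: an independent
broad-scale GSI; selection of the fish assigned to a region with posterior
probability strictly above a threshold $\tau$ (0.8 by default, the
conventional choice; a fish at exactly $\tau$ is excluded); an independent
regional GSI on the selected fish; and a combined report in which regional
draws are rescaled by a *fixed constant*.  The rescaling constant is the
stage-1 posterior mean of the region's total proportion (default), or the
selected-fish fraction (`rescale = "selected_fraction"`).  The published
descriptions of this procedure print combined numbers without stating the
rescaling rule; we chose the stage-1 mean because it reproduces exactly
the procedure's known deficiency — regional credible intervals that omit
stage-1 uncertainty.  If no fish passes the threshold the regional groups
are reported from their prior, with a warning.

## Priors

* Allele frequencies: $\beta = 1/J_l$ per allele (so each locus carries
  one prior observation in total), recomputed after any registry
  extension.
* Proportions: `alpha_mode = "per_group_flat"` (default) gives every
  reporting group equal prior probability — total weight 1 split equally
  among groups, then equally among a group's populations — matching the
  flat reporting-group prior used in practice.  The textbook
  per-population $1/K$ prior is available as `"per_population_flat"`.
  The two disagree when group sizes are unequal; both are exposed because
  the literature uses both.  Regional priors are normalized within each
  region (unit total) so the zero-eligibility prior draw is proper.

## MCMC schedule and diagnostics

The production default is five independent chains of 25,000 iterations,
the first 15,000 discarded and the rest thinned to every fifth draw —
10,000 retained draws, which is also the cap on the reported effective
size.  Chains are initialized from the priors, with per-chain seeds drawn
sequentially from a generator seeded by the master seed, so adding chains
never perturbs earlier chains.

`gelman_rubin()` is the classic (non-split, non-rank-normalized)
potential scale reduction factor, floored at 1 (values below 1 are
estimator noise); a split-chain variant is available behind a flag.
`effective_size()` sums chain-averaged autocorrelations under Geyer's
initial positive monotone sequence and is capped at the retained-draw
total.  Credible intervals are equal-tailed 90% intervals from the 5th and
95th percentiles with linear interpolation between order statistics (R's
default quantile type 7); the tests pin this convention.

## The synthetic-data generator

Real two-baseline case studies are built from proprietary agency
databases, so the package generates its own study systems with the same
structure, using the model's own distributional assumptions (an F-model):
per locus, an ancestral frequency vector is drawn flat; each population's
frequencies are $\mathrm{Dirichlet}(\theta \cdot \text{ancestral})$, with
smaller $\theta$ meaning stronger drift and more informative markers
(expected $F_{ST} \approx 1/(1+\theta)$, a monotonicity the tests check).
Baselines are generated as individual fish so mixtures can be synthesized
by leave-out draws: group sizes are `round(p_g M)` with largest-remainder
correction, source populations are chosen uniformly within a group, and
drawn fish are removed from every baseline copy returned.

Default scenario (a desk-scale analogue of a North-Pacific salmon case
study): five reporting groups — one coastal group with no regional
baseline and four river groups covered by one regional baseline — a
205-fish mixture at proportions (0.27, 0.10, 0.19, 0.13, 0.31), 10
broad-scale and 40 regional diallelic markers, $\theta = 0.3$ at both
stages, and 50 baseline fish per population (5 populations per coastal
group, 4 per regional group).  The broad baseline covers every population
(the regional populations appear in both baselines, sharing their latent
fish); its low regional resolution comes from the small broad marker
panel.  Non-regional fish receive regional-marker genotypes from their own
population's latent frequencies — the *generator* knows them; the model
never imputes genotypes for fish outside a regional baseline's coverage.

What the generator does **not** emulate: linkage disequilibrium, null
alleles, genotyping error, within-group population structure beyond
independent drift, and microsatellite-style mutation.  Passing tests on
these data therefore demonstrate correctness of the estimator under its
own model assumptions, not robustness to real-data artifacts.

The `confuse` option blends one regional group's broad-marker frequencies
toward matched coastal populations, producing the classic failure mode of
the two-step method: that group's fish draw mid-range stage-1 assignment
probabilities, so a hard threshold excludes many of them (and weakly
admits some coastal fish), while the integrated sampler handles them
softly.

## Evaluation harness

`run_repeated_cv()` repeats, with fresh flat-Dirichlet truths each time, a
leave-out cross-validation: synthesize a mixture, prune the drawn fish
from the baselines, fit the requested methods on the *same* data (paired
design), and compare posterior means to the realized true proportions.
Reported per group: RMSE $\sqrt{\tfrac1n\sum_i (Y_i-\hat Y_i)^2}$, bias
(mean of mean estimates minus mean of truths), and percent deviation (the
share of replicates off by strictly more than 0.1), with flags against the
standard baseline-adequacy guidelines (within $\pm0.1$ more than 90% of
the time, $|\text{bias}| \le 0.05$, RMSE $\le 0.05$).  Replicates use the
reduced schedule — five chains of 5,000 iterations, half discarded, no
thinning — which is adequate because only posterior means are compared.

Problem sizes used by the shipped checks: the guideline-recovery
experiment runs 50 replicates of the default five-group scenario with 30
broad and 40 regional markers; the method comparison runs 20 paired
replicates of the confusable-group scenario ($\theta_{broad} = 1$,
blend weight 0.7).  Both finish in a few minutes on one core thanks to the
C++ sweep.

## Numerical choices and edge cases

* Membership draws are made in the log domain; the exported primitive
  normalizes by the row maximum, and the C++ sweep equivalently
  exponentiates each fixed table row once relative to its maximum, so
  underflow cannot occur however many loci contribute.
* A fish with zero likelihood under every population (registry
  misalignment) is a hard error naming the fish, never silently dropped.
* Mixture alleles absent from the baseline registry are an error by
  default; opting into registry extension adds a zero-count allele column
  that carries only prior mass.
* A blank baseline genotype reduces that population's per-locus sample
  size; a half-filled genotype (one of two diploid cells) is an error
  naming row and locus.
* Dirichlet draws with very small shapes can underflow to all-zero gamma
  variates; the draw then falls back to a point mass on the
  heaviest-shape component rather than returning NaN.
* Allele registries are stored sorted and populations in file order of
  first appearance, so repeated loads are bit-identical.

## Known limitations

* The reporting-unit bias that affects all GSI estimators when poorly
  resolved populations are unevenly distributed across groups is not
  corrected; the bootstrap correction developed for single-baseline
  conditional GSI has no multistage counterpart yet.
* The regional stages never inform the broad stage (by construction);
  a mixture dominated by fish distinguishable only at regional markers
  gains nothing at the broad scale.
* Genotype input is hard-call CSV only — no genotype likelihoods, no VCF,
  no microsatellite mobility binning.
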