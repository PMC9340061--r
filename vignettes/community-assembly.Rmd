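---
title: "Inferring community assembly from functional and phylogenetic structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly from functional and phylogenetic structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylassem)
```

## The inference problem

Which processes put a particular set of species together in a community?
Under purely stochastic assembly, a community is a random draw from the
regional species pool. Niche-based processes leave signatures in the
*structure* of co-occurrence: abiotic filtering admits only species whose
traits suit the local environment, so co-occurring species are more similar
than a random draw (convergence); limiting similarity excludes species that
are too alike, so co-occurring species are more dissimilar than a random
draw (divergence). In harsh, water-limited systems such as gravel deserts,
the expectation is strong filtering on functional traits, potentially
combined with phylogenetic divergence when distantly related lineages have
converged on the same stress-tolerant trait values.

`phylassem` implements the complete inference chain for this question:

1. **Phylogenetic signal** of each trait (Blomberg's K with a tip-shuffle
   permutation test) — do related species have similar traits at all?
2. **Community structure**: the standardized effect size of mean pairwise
   distance (SES.MPD), computed per community against a tip-shuffle null,
   separately for each trait, for the combined trait space, and for the
   phylogeny, with a community-wide Wilcoxon departure test.
3. **Environmental drivers**: which site variables explain the variation in
   SES across communities (collinearity screen, forward selection,
   hierarchical partitioning).
4. A **synthetic-data generator** that produces trees, traits, environments
   and communities with known assembly processes, so the whole chain can be
   validated end to end.

## Statistics

### Blomberg's K

For trait vector $x$ over the $n$ tips of a rooted tree with phylogenetic
covariance matrix $V$ (shared root-to-MRCA branch length; `phylo_vcv()`),

$$\hat a = \frac{1^\top V^{-1} x}{1^\top V^{-1} 1}, \qquad
K = \frac{\;\mathrm{MSE}_0/\mathrm{MSE}\;}{\;E[\mathrm{MSE}_0/\mathrm{MSE}]\;},$$

with $\mathrm{MSE}_0 = (x-\hat a)^\top(x-\hat a)/(n-1)$,
$\mathrm{MSE} = (x-\hat a)^\top V^{-1}(x-\hat a)/(n-1)$ and
$E[\mathrm{MSE}_0/\mathrm{MSE}] = [\mathrm{tr}(V) - n/(1^\top V^{-1}1)]/(n-1)$.
$K = 1$ is the Brownian-motion expectation; $K \ll 1$ means close relatives
resemble each other less than Brownian motion predicts. K is invariant to
affine transforms of the trait and to rescaling all branch lengths, and is
exactly 1 on an equal-branch star tree — all three properties are enforced
by tests.

Significance comes from shuffling species labels across the tips: the
one-tailed p-value is $(r+1)/(n_{perm}+1)$, where $r$ counts null statistics
at least as large as the observed K. The add-one rule is standard
Monte-Carlo practice and avoids $p = 0$. The default statistic is K itself
(upper tail); the conventional alternative — the variance of phylogenetically
independent contrasts, lower tail — is available via `statistic = "pic.var"`.
Whether the original analyses used one or the other (or one- vs two-tailed
testing) is typically unstated in applied papers; we expose both and default
to the literal reading. Traits are natural-log transformed and z-scored
before analysis; K's affine invariance makes the standardization itself
harmless, the log matters for variance stabilization of ratio-scale traits.

### SES.MPD under the tip-shuffle null

The mean pairwise distance of a community with $k \ge 2$ members is the
unweighted mean of the $k(k-1)/2$ pairwise distances. For each community,

$$\mathrm{SES.MPD} = \frac{\mathrm{MPD}_{obs} -
\operatorname{mean}(\mathrm{MPD}_{null})}{\operatorname{sd}(\mathrm{MPD}_{null})},$$

where the null relabels the distance matrix with uniform random
permutations of the **full species pool** (every label of the distance
matrix — the regional pool) while holding community membership fixed;
`null_sd` is the sample (n−1) standard deviation, the convention of the
reference SES implementations. Negative SES indicates convergence, positive
divergence.

Design choices worth stating explicitly:

* **Presence-based MPD.** Abundances determine membership only. Abundance
  weighting is deliberately not implemented: the metric is defined over
  "all pairs of species", and weighting is a different estimand.
* **Pool = distance-matrix labels.** A per-site occupancy pool is a
  different null model and out of scope.
* **One seeded permutation stream per metric.** Results are reproducible,
  but permutations are not reused across metrics, which would build in
  cross-metric correlation by construction.
* **Degenerate sites** (richness < 2, or a null with zero spread, e.g. a
  site holding the whole pool) are flagged and excluded from downstream
  tests rather than imputed as SES = 0, which would bias the signed-rank
  statistic toward the null. Zero spread is detected with a relative floor
  (`1e-10` of the null mean) because floating-point summation order leaves
  noise of order 1e-16 in a mathematically zero standard deviation.
* **Exact option.** With `exhaustive = TRUE` the null is enumerated rather
  than sampled: MPD depends only on which $k$ pool members a permutation
  maps into the site, and all $\binom{n}{k}$ subsets are equally likely, so
  the exact null is the subset enumeration. This powers the package's exact
  oracle tests.

Community-wide departure from SES = 0 uses the two-sided one-sample
Wilcoxon signed-rank test (SES distributions are not reliably normal). The
exact distribution is used for $n \le 25$ without ties or zeros, otherwise
the normal approximation with continuity correction; the output records
which was used.

### Environmental drivers

The SES values (response) and the site variables are z-scored. Predictors
with variance inflation factor $\mathrm{VIF}_j = 1/(1-R^2_j) > 3$ are
removed iteratively, highest first (ties break by dropping the later column
— determinism). Forward selection starts from the empty model and adds the
candidate with the smallest partial-F p-value while that p-value is below
$\alpha = 0.05$ (the partial F for one added term equals the added-term
t-test); after every addition all included terms are re-checked and any that
no longer meet $\alpha$ are dropped and logged, so the final model contains
only significant terms.

Hierarchical partitioning then decomposes the selected model's $R^2$
exactly, fitting all $2^p$ subset models: the independent effect of
predictor $i$ averages the $R^2$ increment of adding $i$ over all subset
sizes (levels) of the other predictors, level means weighted equally. This
is the classical averaging scheme, and its defining identity — the
independent effects sum *exactly* to the full-model $R^2$ (the Shapley
efficiency property) — is asserted to 1e-8 in the tests, alongside
agreement with an independently written enumeration over orderings. The
joint effect of a predictor is its univariate $R^2$ minus its independent
effect; it can be negative under suppression and is reported as computed
(with a warning) rather than truncated, because truncation hides exactly
the collinearity pathologies one should see. Enumeration cost is $2^p$, so
the partition refuses more than 12 predictors; run it on the selected set.

## The synthetic-data generator

The generator produces data with the statistical shape of an arid-steppe
community survey, at the scale the analysis expects, so that every stage of
the chain is testable without any external data. Its defaults are the study
conditions; they were fixed once and the tests run against them.

* **Tree**: pure-birth (Yule) tree grown to 44 tips, rescaled to unit depth
  (K and SES are scale-invariant, so depth is a free normalization). Tips
  are assigned to 35 genera by contiguous blocks in ladderized tip order,
  giving compact clade-like genera for the grafting workflow without a
  taxonomy backbone.
* **Traits**: eight traits named after the conventional leaf/root set (SLA,
  LA, LNC, LPC, SRL, RL, RNC, RPC), simulated on the log scale and
  exponentiated, so raw tables are strictly positive and the analysis's log
  transform is exercised. The default process is Ornstein–Uhlenbeck with
  $\alpha = 10$, $\sigma^2 = 1$ on a unit-depth tree — strong enough pull
  that Blomberg's K lands well below 1, the weak-signal regime typical of
  desert floras. Innovations are correlated across traits (r = 0.6 within
  the leaf and root blocks, 0.3 between), emulating the leaf/root-economics
  redundancy that motivates the PCA step. Brownian motion (used for
  calibration tests) draws tips directly from
  $\mathcal N(\theta, \sigma^2 V)$.
* **OU integration**: Euler–Maruyama along each branch with step
  $\min(0.01\,\mathrm{depth},\ 0.05/\alpha)$. The second term is a stiffness
  guard: with step $h$, the discretized stationary variance is
  $\sigma^2 h / (1-(1-\alpha h)^2)$, within ~3% of $\sigma^2/(2\alpha)$ at
  $\alpha h = 0.05$. Tests check distributional stability of the scheme.
* **Environment**: nine variables (Gravel, TSN, TOC, SM, pH, MAP, PS, MAT,
  TS) drawn multivariate normal with corr(Gravel, SM) = −0.5 — the
  gravel-mediated water-availability signature — then affinely mapped to
  plausible field ranges. The correlation matrix is checked for positive
  semidefiniteness up front.
* **Communities**: 183 sites; richness is Poisson (mean 5) truncated to
  [2, pool], matching low-richness desert plots. Assembly is `random`
  (uniform draws), `filter` (Gaussian weights
  $\exp(-(x - \mathrm{opt})^2/2w^2)$ on the first PCA axis of the
  standardized traits), or `limiting` (greedy max–min spacing in trait
  space from a random start). Abundances are log-normal.
* **The filter's environmental link.** The site optimum moves with soil
  moisture (slope 0.5 in pool-SD units), and the filter *width* follows a
  stress gradient, $w_s = 0.5\,e^{0.75\,z(SM)}$: drier sites filter more
  tightly. The width gradient is what gives the SES–moisture relationship a
  defined, positive sign. This is a deliberate design choice: with a
  constant width and a Gaussian pool, the realized strength of filtering is
  essentially independent of where the optimum sits (the within-site trait
  variance is $w^2/(1+w^2)$ regardless), so moving the optimum alone
  produces convergence but no SES–environment gradient. A filter that
  relaxes as water limitation eases is also the ecologically standard
  stress-gradient reading.

What the generator does *not* emulate: spatial structure and dispersal
limitation, plot-within-site nesting, trait measurement error, non-normal
environmental distributions, and phylogenetic signal in the environment
itself. Passing recovery tests therefore show that the estimators detect
the processes they target under clean conditions at realistic sizes — not
that those processes are identifiable in any particular field dataset.

## Genus-level grafting

Species missing from a tree are attached inside their genus, mimicking
backbone-tree tools that place unsampled taxa among congeners: at the genus
crown (MRCA of its tips) as an extra child with branch length equal to the
crown's depth-to-tip — a polytomy that leaves every existing pairwise
distance untouched and keeps ultrametric trees ultrametric — or, for a
monotypic genus (where no crown exists), at the midpoint of the single
tip's branch, forming a cherry. Midpoint insertion is the conventional
fallback; how any particular upstream tool resolved these lengths is not
knowable from published descriptions, so the rule here is a documented,
deterministic stand-in. A genus absent from the tree is an error naming the
unplaceable species; there is no family-level fallback.

## Numerical and interface choices

* Ultrametricity is judged at relative tolerance 1e-6 of tree depth
  (floating-point round-trip safety); Newick output carries 12 significant
  digits so read–write–read preserves distances below 1e-9.
* PCA axes: the default distance uses **all** axes (then combined-trait
  distance equals Euclidean distance on the standardized traits — the only
  parameter-free reading); a cumulative-variance cutoff
  (`axis_rule = "cumvar"`, default 0.80) is available because applied
  papers often retain leading axes without stating how many.
* The trait list is configurable with the 8-trait leaf/root set as the
  default (published applications sometimes alternate between six and eight
  traits; the 8-trait reading matches the fuller tables).
* The natural log (not log10) is used before z-scoring; the base is
  irrelevant after standardization and is stated only for reproducibility.
* All stochastic functions accept a `seed` and are bit-reproducible given
  it; multi-metric wrappers derive independent sub-seeds from the master
  seed.
* `run_pipeline()` writes labelled CSV/Newick/JSON per stage plus a
  manifest with content digests; re-running with the same configuration
  reproduces byte-identical result files, and stages whose outputs match
  their recorded digests under the same config hash are skipped.

## Problem sizes used by the test suite

The validation suite runs at the sizes the package is designed for: K
calibration uses 500 Brownian and 100 strong-OU simulations on a 64-tip
tree; the permutation test's type-I rate uses 200 independent traits at 999
permutations; null calibration of SES uses 500 randomly assembled sites
from a 50-species pool at 999 permutations; process recovery uses 50
replicates per assembly mode at the full 183-site scale; driver recovery
uses 100 replicates at 183 sites. These sizes give the binomial and
Monte-Carlo error bars room inside the asserted bands.

## Known limitations

* The null model is the regional tip shuffle only; independent-swap and
  trial-swap occupancy-preserving nulls are not implemented.
* MPD is the only structure metric (no MNTD/NRI/NTI family).
* Driver models are ordinary least squares; no spatial autocorrelation
  correction or mixed models. Block-level (e.g. climatic vs local) shares
  should be read as sums of member independent effects, which is how they
  are reported.
* Hierarchical partitioning is exact and therefore exponential in the
  number of predictors; it is intended for the post-selection set.
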