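---
title: "Measuring host-symbiont association specificity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring host-symbiont association specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiospec)
```

`symbiospec` analyses two study designs that together characterise how
selectively legume hosts interact with the *Bradyrhizobium* genotypes
available to them: a field survey of genotyped nodule isolates, and a
blocked greenhouse experiment pairing each test plant with a single
strain. This vignette documents the models, the conventions behind every
tunable parameter, what the synthetic-data generators do and do not
emulate, and the design decisions taken where more than one reading of
the standard methods was defensible.

## 1. Genotype calling from aligned sequences

Input alignments (one FASTA per locus) are assumed pre-aligned; the
package performs no alignment. Because indel-containing stretches of the
*ITS* spacer cannot be scored consistently as point differences,
`strip_indel_columns()` removes every column in which *any* sequence
carries a gap. Per-column removal is deterministic and invariant to input
order, which is why it is preferred over any attempt to delimit "indel
regions".

`call_genotypes()` collapses identical post-filter sequences: any single
nucleotide difference separates genotypes. Labels `G1, G2, ...` follow
first appearance. Ambiguous bases (`N`) are excluded from the identity
comparison by default (`ignore_ambiguous = TRUE`), since an `N` carries
no evidence of difference. One subtlety is documented rather than hidden:
N-tolerant identity is not transitive, so with ambiguous bases present
the assignment matches each sequence greedily against genotype
representatives in first-appearance order. For alignments without `N`
the partition is exactly the identical-sequence partition and is
invariant (up to relabeling) under permutation of the input; the test
suite checks this property on random alignments.

`pairwise_differences()` counts differing sites (skipping `N` sites under
the same flag). These raw counts — not model-corrected distances — feed
all population-structure statistics; model-based distances belong to
network/phylogenetic analyses outside this package's scope.

## 2. Link strengths and the Paired Differences Index

The link strength of host $i$ with genotype $j$ is
$P_{ij} = n_{ij}/n_i$, the proportion of the host's genotyped nodules
occupied by genotype $j$. The genotype universe of a link matrix is the
union of genotypes observed in any host at the locus (or an explicitly
supplied pool), so a host is penalised for available genotypes it never
uses.

With the host's link strengths ranked $P_{i1} \ge \dots \ge P_{iN}$,

$$\mathrm{PDI}_i = \frac{\sum_{j=2}^{N} (P_{i1} - P_{ij})}{D}.$$

**Denominator convention.** Two conventions circulate: $D = N - 1$
(partner categories minus one), which bounds the index in $[0, 1]$ on
proportions, and a sample-size denominator (nodules minus one). The
package defaults to partner categories minus one — the convention under
which the perfect specialist scores exactly 1 — and exposes
`denominator =` for the alternative, so either published variant can be
reproduced. Ties at the maximum contribute zero terms and cannot affect
the result. Appending a zero-strength partner *changes* the default
denominator (it adds a partner category); under an explicit denominator
it only adds a $(P_{i1} - 0)$ term. Both behaviours are asserted in the
tests.

The joint PDI averages each genotype's link strength across hosts and
applies the same formula; with one host it reduces to that host's PDI.

## 3. The resampling null

Observed PDIs are compared against preference-free sampling: in each
replicate of `simulate_null_joint_pdi()` every host draws its nodules
multinomially from the pooled genotype frequencies, and the joint PDI of
the replicate is recorded. Defaults follow the canonical survey
comparison: 4 hosts, 20 nodules per host, 1000 replicates, frequencies
taken from the pooled sample.

Two sampling designs are available because the phrase "simulated
20-nodule populations" is ambiguous: `design = "per_host"` (default)
gives every host an independent 20-nodule draw per replicate;
`design = "single"` draws one shared population per replicate. The
per-host reading is the default because the observed joint PDI is
computed from four independently sampled hosts.

**Confidence limits.** The stored 95% limits are limits of the *mean*,
$\bar x \pm 1.96\, s/\sqrt{R}$, whose half-width shrinks as $R^{-1/2}$;
the empirical 2.5/97.5 percentiles of the replicate distribution are
stored alongside and are what `compare_pdi_to_null()` uses to declare an
observed PDI outside the null band, together with a +1-corrected
empirical tail proportion. Reporting both keeps "how precisely is the
null mean known" separate from "where does the null distribution lie".

A degenerate single-genotype pool returns an all-zero distribution: one
genotype admits no specialization.

## 4. Population structure: diversity, Φst, AMOVA

The diversity summary reports, per population pair, the mean
within-population pairwise differences, the raw cross-population mean,
and the corrected between-population value (raw minus the average of the
two within means). The corrected value is a finite-sample estimator: for
two literal copies of the same multiset it equals $-T/n^2$ (with $T$ the
summed base-set distances), slightly below zero, because the cross mean
includes the zero-distance copy pairs. The tests assert this analytic
value rather than pretending the estimator hits zero exactly.

Φst and the AMOVA partition squared pairwise distances. For sets of
isolates, $\mathrm{SSD} = \frac{1}{n}\sum_{i<j} d_{ij}^2$; the total SSD
decomposes exactly into between-group, between-population-within-group
and within-population terms (additivity is tested to $10^{-9}$ against a
brute-force element-by-element oracle). Variance components come from
equating observed and expected mean squares with the standard unbalanced
design coefficients; Φst is the among-component share of the total.
**Negative components are reported as computed, never truncated** —
slightly negative Φst values are legitimate finite-sample outcomes and
appear as such in real surveys.

Permutation schemes are level-appropriate: the total (within) level
permutes isolates freely; the between-populations-within-groups level
permutes isolates only among populations of the same group; the group
level permutes whole populations among groups. All p-values carry the +1
correction and are deterministic under a seed. With few populations the
group-level test has very few distinct relabelings; the result records
`n_group_relabelings` and the print method flags the attainable minimum
p, since a two-genus design with one degree of freedom simply cannot
reach conventional significance regardless of effect size. Degenerate
inputs are defined, not fatal: all-identical sequences give Φst `NA`
with p = 1, and a group containing a single population falls back to the
pooled between-population coefficient with a warning.

The default permutation count is 10,000 for the user-facing statistics;
the pipelines default to 999 to keep full-survey reports fast, and both
are configurable.

## 5. Greenhouse analysis

**Contamination rule.** Controls that formed nodules were
cross-contaminated and are excluded; inoculated plants are never excluded
by this rule. A block whose conspecific controls were all contaminated
has no fitness-effect baseline and raises an error naming the block.

**Fitness effect vs fold increase.** Both response measures are
implemented because both appear in standard use:
$p = (w - w_C)/w$ (bounded above by 1, unbounded below) and the fold
increase $(w - w_C)/w_C$ (bounded below by $-1$). They always agree in
sign. The block baseline $w_C$ is the *mean* of the block's surviving
conspecific controls: designs typically include several controls per
block precisely so the baseline is estimated with low variance, and
exclusions would otherwise make a designated single control ill-defined.

**Block PDIs.** `block_pdi()` applies the paired-difference sum to a
block's per-strain values. Inputs may be negative (strains worse than
control), so no $[0,1]$ bound applies; the statistic is
scale-equivariant ($c\,x \mapsto c\,\mathrm{PDI}$), which the tests
assert. The denominator defaults to strains actually present in the
block minus one; a constant strain count can be fixed via
`denominator =` for cross-block comparability when a design prescribes
it. Across blocks the summary is mean, SE $= s/\sqrt{k}$, and a t-based
95% CI on $k - 1$ degrees of freedom.

**Effect PDIs.** Applying the control-baseline formula to nodule traits
is degenerate — uncontaminated controls have no nodules — so effect
specificity uses transformed trait values directly in the block PDI.
Transforms follow the usual variance-stabilising choices: natural log
for counts (falling back to $\ln(x+1)$ with a logged message when zeros
occur, since $\ln 0$ is undefined and the paper trail should show the
switch) and square root for areas.

**Genotype means, feedback, Mantel.** Per-(host, strain) means use only
non-contaminated, non-missing records; the mean individual nodule area
is computed per plant (total area / count) before averaging, and plants
with zero nodules contribute `NA` rather than a fabricated 0. Missing
nodule data are treated as missing at random and excluded trait-wise,
never imputed. Fitness-feedback correlations are plain Pearson
correlations across strain means with t-based two-sided p-values;
zero-variance components are reported missing. `mantel_test()`
correlates strictly-lower-triangle entries and permutes the rows and
columns of one matrix jointly, sampling uniformly over all relabelings
(identity included, as in the standard implementations — which makes
the sampled p consistent with exhaustive enumeration, at the price that
a self-comparison can exceed $1/(\text{perms}+1)$ by an occasional tie
at $r = 1$).

## 6. What the generators emulate — and what they do not

`simulate_association()` draws each host's nodules multinomially from a
host-specific preference profile over a shared pool (default: 4 hosts,
22 genotypes, $n = 19/18/21/23$ — the canonical survey shape). Profiles
default to symmetric Dirichlet draws with $\alpha = 0.2$: strongly
skewed preferences, the regime in which field hosts plausibly show the
marked specialization the index is designed to detect; $\alpha$ is the
single knob separating specialist ($\alpha \ll 1$) from generalist
($\alpha \gg 1$) communities in the recovery tests. The two genotype
columns are fully linked (same labels at both loci) — a simplification;
real loci recombine and can disagree.

`simulate_sequences()` builds a root sequence, cluster consensuses at
the between-cluster divergence, and genotypes at the within-cluster
divergence (Poisson site counts, no back-mutation model), optionally
injecting gap columns. Defaults (within 2, between 20) plant the
clusters-by-host-genus structure that the Φst/AMOVA stages are meant to
recover. It is *not* a coalescent simulator: no recombination, no rate
heterogeneity, no realistic site-frequency spectrum.

`simulate_greenhouse()` mirrors the 2-host x 31-strain x 10-block x
5-control design: gamma-distributed shoot weights with log-scale host,
inoculation, origin-match, strain, host x strain and block effects;
negative-binomial nodule counts; log-normal per-nodule areas summed to a
total; and a 7% control contamination probability. Default effect
magnitudes put inoculated plants roughly 2.8-3x over controls (log
inoculation effects $\log 3.8$, $\log 3.9$) with modest strain
($\sigma = 0.2$), interaction ($\sigma = 0.3$) and block
($\sigma = 0.15$) variation on the log scale and gamma shape 8. The
generator does not emulate greenhouse realities such as spatial
gradients within blocks, mortality, measurement error in nodule
photography, or genotype-specific contamination.

Consequently, passing recovery tests show the *estimators* behave
correctly under the assumed generative structure — multinomial sampling,
log-scale gamma responses, clustered sequences — not that real surveys
meet those assumptions.

## 7. Problem sizes and numerical conventions in the test suite

The suite verifies the statistics against independent oracles at sizes
where enumeration is exact or Monte-Carlo error is controlled: the PDI
against its brute-force definition on 1000 random vectors; the null
simulator against the exact 21-outcome binomial expectation and the
$R^{-1/2}$ CI-scaling across 250/1000/4000 replicates; AMOVA SSDs
against an element-by-element oracle at up to 16 isolates; Φst at 3+3
isolates against all 20 balanced relabelings and Mantel at $n = 4$
against all 24 permutations; p-value calibration over 200 exchangeable
datasets per statistic; and parameter recovery over 100 generator runs
per planted effect. The end-to-end scenario runs the full default survey
(81 isolates, two loci, 1000 null replicates, 999 permutations) and the
full greenhouse design (720 plants). These sizes are the package's
chosen verification scale; every statistic accepts larger counts.

## 8. Known limitations

* Genotype calling treats sequences as exact strings; sequencing error
  is not modelled, so singleton genotypes and error artefacts are
  indistinguishable at this layer.
* The PDI has no sampling-effort correction; comparisons across hosts
  with very different $n_i$ inherit that sensitivity, and the null
  simulation (which conditions on nodule counts) is the package's only
  guard.
* The group level of a two-genus AMOVA is intrinsically underpowered
  (one degree of freedom, a handful of distinct relabelings); the
  reported attainable minimum p makes this visible instead of letting a
  non-significant group effect be over-read.
* Mantel tests are known to have inflated error rates under strong
  spatial or phylogenetic autocorrelation of the distances; here they
  are applied to strain-level matrices where that structure is mild, but
  the caveat stands.
* The fitness-effect measure divides by the inoculated plant's weight;
  its alternative (dividing by the control) is provided, and analysts
  should state which convention a reported PDI used, as the two scale
  differently for strains far from the baseline.
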