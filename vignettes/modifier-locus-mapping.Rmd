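---
title: "Mapping modifier loci in inbred mouse strain panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping modifier loci in inbred mouse strain panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainscan)
```

## The problem

Pertussis-toxin-induced histamine sensitization in the mouse is a binary
trait (death within 30 minutes of histamine challenge) whose baseline
susceptibility is controlled by allotypes of the histamine H1 receptor
gene *Hrh1*: the susceptible allotype acts dominantly, while strains
homozygous for the resistant allotype are normally protected. Several
wild-derived inbred strains, however, are susceptible *despite* carrying
the resistant allotype — evidence for a dominant modifier locus that
complements the resistant receptor allele but still requires a functional
receptor (receptor-knockout animals are never sensitized).

`strainscan` implements the statistical workflow for discovering and
prioritizing such a modifier:

1. **Susceptibility screen** — pooled dose-response counts per strain,
   tested against a reference strain with a two-sided Fisher exact test.
2. **Backcross linkage scan** — per-marker Pearson chi-square tests of
   genotype (Ho/He) against phenotype in a backcross cohort.
3. **Genotype imputation** — a Viterbi-decoded HMM that copies missing
   calls from phylogenetically similar reference strains.
4. **Mixed-model association** — EMMA-style maximum-likelihood linear
   mixed models with per-SNP likelihood-ratio tests across a strain
   panel, with kinship as a random effect.
5. **Functional prioritization** — ensembles of linear SVMs trained on
   functional-network connectivity, converted to empirical false
   positive rates.
6. **Combined gene score** — per-gene association and functional scores,
   each max-normalized over the positional candidates and summed
   (`s_cg` in [0, 2]).

## Data model and conventions

Inbred strains are homozygous, so genotypes are stored haploid: 0 =
reference allele, 1 = alternate, `NA` = missing. Heterozygous diploid
calls in VCF input violate the inbred assumption and are converted to
missing with a warning; multi-allelic records are skipped. Missingness
is a first-class state, never silently imputed. SNP positions are
1-based; gene intervals (BED) are 0-based half-open. Strain names are
exact, case-sensitive keys and may contain slashes and spaces
(`"BPL/1 J"` is a valid key).

## The exact tests

The susceptibility screen pools affected/tested counts over doses — the
screen asks whether a strain is susceptible at all, not for a
dose-response curve — and compares each strain with the reference by a
two-sided Fisher exact test computed by hypergeometric enumeration in
log space (point-probability method: the p-value sums the probabilities
of all tables, with margins fixed, no more probable than the observed
one). Two-sided testing is deliberate: on the published strain-screen
counts it reproduces every printed p-value after rounding to one
significant figure, while a one-sided test does not (the 3/15-vs-0/13
configuration discriminates: two-sided 0.226, one-sided 0.139).
Displayed p-values are rounded to one significant figure with halves
rounded away from zero (an exact p of 0.35 displays as 0.4), matching
the published tables; raw p-values are always stored alongside.

The linkage scan uses Pearson chi-square without continuity correction —
verified against the published marker table, where the corrected
statistic would disagree (28.8 vs 27.1 at the proximal flanking marker).
Animals missing a genotype are dropped for that marker only, which is
why per-marker totals vary. No multiple-testing adjustment is applied in
this module; the scan reports raw per-marker statistics.

## The mixed model

For phenotype vector $y$ over $n$ strains,
$$ y = X\beta + u + e, \qquad u \sim N(0, \sigma_g^2 K), \qquad
   e \sim N(0, \sigma_e^2 I), $$
with $K$ the strain kinship (identity-by-state proportion over jointly
observed SNPs) and $\delta = \sigma_e^2/\sigma_g^2$. Binary phenotypes
are coded 0/1 and treated as quantitative. Fitting is full maximum
likelihood (not REML), matching the likelihood-ratio testing convention:
each SNP is tested with $2(\ell_1 - \ell_0)$ against $\chi^2_1$, where
both models are ML-fitted on the strains observed at that SNP.

A single eigendecomposition of $K$ reduces every evaluation of the
profile likelihood in $\delta$ to $O(n)$: rotating $y$ and $X$ by the
eigenvectors diagonalizes the covariance, the GLS coefficients and
$\hat\sigma_g^2$ are closed-form given $\delta$, and the profile is
maximized over a log-spaced grid of 100 points on
$\delta \in [10^{-5}, 10^5]$ with each sign change of the (analytic,
envelope-theorem) derivative refined by bisection to $10^{-6}$ on
$\log\delta$. An optimum at a grid edge is flagged as a boundary fit,
not an error. Kinship matrices must be positive semidefinite; a ridge of
$10^{-6}$ is added once if needed and a matrix still indefinite after
that is rejected. Note that pairwise-overlap IBS kinship computed on a
matrix *with* missing calls need not be PSD — the pipeline therefore
estimates kinship from complete-coverage (post-imputation) SNPs, where
IBS is a scaled sum of Gram matrices and PSD by construction.

Two properties of this estimator are worth knowing. First, $\delta$ is
only weakly identified when the kinship eigenvalues are nearly
exchangeable (e.g. kinship estimated from independent random genotypes):
individual fits can collapse to a boundary in either direction, and the
median over replicates is the meaningful summary of variance-component
recovery. Second, with very strong group structure (near-clonal strain
groups) the effective sample size approaches the number of groups and
the $\chi^2_1$ reference for the ML LRT becomes anti-conservative; the
calibration checks therefore estimate type-I error as the mean over
independent phenotype permutations, since all SNPs of one scan share a
permutation and single-permutation false-positive fractions are highly
variable under genotype correlation.

Significance thresholds are reported as Bonferroni ($0.05/n_{tests}$,
"stringent") and fixed 0.05 ("moderate"). For a 13,257-SNP scan
Bonferroni gives $3.77\times10^{-6}$; published analyses of such panels
have quoted $3.81\times10^{-6}$, which matches no obvious test count —
this package always derives the threshold from the actual number of
tests performed.

## Imputation

Hidden states of the HMM are reference strains — the $k$ candidates most
concordant with the target over jointly observed SNPs (ties broken
lexicographically; the target never enters its own panel). Transitions
between adjacent SNPs stay with probability $1-\tau$ and switch to any
other state with probability $\tau/(k-1)$; emissions are $1-\epsilon$
for a matching observed call, $\epsilon$ for a mismatch, and
uninformative (probability 1) when either call is missing. Decoding is
exact Viterbi in log space with ties resolved deterministically (staying
preferred over switching, lower state index otherwise), so imputation
has no randomness at all. Missing target calls take the decoded
reference strain's call and remain missing if that reference is missing
there too; observed calls are never altered.

Defaults ($k = 8$, $\epsilon = 0.01$, $\tau = 0.002$ per adjacent-SNP
interval, constant rather than distance-scaled) are deliberate,
configurable choices: $\epsilon$ at the scale of array/call error rates,
$\tau$ small enough that decoded segments span many SNPs, $k$ large
enough to cover a family group. No published parameterization exists for
this step, so these are package decisions, all exposed in
`hmm_params()`.

## Functional prioritization

Trait gene sets are clustered into modules of fewer than 400 genes by
average-linkage hierarchical clustering on correlation distance between
the genes' network connectivity profiles, cutting the tree at the
shallowest level where every cluster is under the bound and merging
clusters of fewer than 5 genes into their nearest sibling. For each
module, 100 linear-kernel SVMs are trained to separate module genes from
independent balanced samples of genes outside the parent set, using each
gene's connectivity weights to the module genes as features. Costs come
from an iteratively narrowed series: eight log-spaced values on
$[10^{-3}, 10^3]$, re-centered at half width on the CV-accuracy argmax
for three rounds; the final eight values are cycled across the ensemble.

Each SVM contributes out-of-fold decision scores from 10-fold
cross-validation. Two implementation details matter for calibration:
folds are stratified by class, because class-imbalanced training folds
shift the SVM decision offset and bias pooled out-of-fold scores low for
whichever class is over-represented in the held-out fold; and a module
gene's self-connectivity — undefined in a zero-diagonal network — is
imputed with its mean connectivity to the rest of the module rather than
left at zero, which would brand every positive with one artificially
zeroed feature. Both choices were validated on planted-module networks:
with no planted contrast the held-out AUROC is consistent with chance,
and with strong contrast it approaches 1.

A candidate gene's score per module is its mean decision value over the
ensemble; the empirical FPR is the fraction of pooled out-of-fold
*negative* scores at or above it, floored at $1/(n_{null}+1)$ so that
$-\log_{10}(\mathrm{FPR})$ is always finite. The per-gene functional
score is the minimum FPR over all modules of all trait terms (the
gene's maximum functional enrichment). FPR is anti-monotone in score by
construction.

## Combined score

With $a(g)$ the gene's maximum $-\log_{10} p$ over assigned SNPs
(nearest gene within 1 Mb, inclusive; distance zero inside a gene; ties
to the lower-start gene) and $f(g) = -\log_{10}(\mathrm{FPR}_g)$,
$$ s_{cg}(g) = \frac{a(g)}{\max_{g'} a(g')} +
              \frac{f(g)}{\max_{g'} f(g')} , $$
with maxima over all positional candidates in the locus interval
(including the receptor gene itself, when present). $s_{cg}$ is
invariant to positive rescaling of either component, bounded by 2, and
attained exactly at 2 by a gene that carries both maxima. An all-zero
component is dropped (set to zero for every gene) with a warning rather
than dividing by zero. Unassigned SNPs are reported, never silently
discarded.

## The synthetic-data generators

Every pipeline input can be generated in code, with the statistical
structure the analyses assume:

* **Strain panels** (`simulate_strain_panel`) — strains fall into family
  groups; within each ancestral haplotype block every group draws its own
  haplotype (per-SNP divergence from the ancestor), and strains add
  private variation at a within-group rate. Missingness is
  missing-completely-at-random per strain at a rate drawn from a
  configurable interval, a coarse emulation of the strain-biased coverage
  of merged strain-genotype databases. Defaults (5 groups of 10 strains,
  divergence 0.3, within-group diversity 0.02, missing rates
  0.05–0.20) give a 50-strain panel with block-structured kinship.
* **Trait model** (`two_locus_trait_model`) — affected iff carrying a
  dominant susceptible primary allele, or a functional resistant allele
  together with a dominant enhancer allele; primary knockouts are never
  affected; susceptible genotypes express with a configurable penetrance
  (default 0.9).
* **Backcrosses** (`simulate_backcross`) — each animal receives one
  recurrent-parent gamete and one F1 gamete from a Markov recombination
  walk under the Haldane (no-interference) map function, converting
  physical to genetic distance at a configurable rate (default 0.5
  cM/Mb, a standard mouse-scale value; no genetic map is assumed).
* **Networks** (`simulate_network`) — edge weights are Beta-distributed
  with configurable means inside planted modules and elsewhere and a
  common concentration; infinite concentration degenerates to constant
  weights.

All generators are pure functions of (config, seed): identical seeds
give byte-identical artifacts, and no global random state leaks.

What the generators do *not* emulate — and hence what passing tests do
not show about real data: linkage-disequilibrium decay within blocks,
coalescent genealogies, selection, sex chromosomes, genotyping batch
effects, strain-specific error rates, and the scale-free topology and
tissue specificity of real functional networks. Results on synthetic
panels demonstrate correctness of the machinery, not field performance.

## Problem sizes used by the checks

The bundled verification suite runs the null-calibration scan at 2,000
SNPs x 50 strains averaged over 10 permutations, variance-component
recovery at n = 200 strains over 200 simulated traits, Viterbi oracle
equivalence over 200 random instances with up to 4 states and 8 SNPs,
the masking experiment at 500 SNPs x 20 strains over 8 replicates, and
the SVM calibration on 200-gene networks with 25-gene planted modules
and 100-SVM ensembles. The demo pipeline uses a 15-strain, ~150-SNP
panel with a 60-gene network so an end-to-end run takes seconds.

## Known limitations

* The LMM treats binary phenotypes as quantitative (as the association
  methodology it mirrors does); no liability-threshold model.
* ML rather than REML variance components; no per-SNP degrees-of-freedom
  correction, so small panels with extreme structure show the
  anti-conservatism discussed above.
* No interval mapping or LOD scores in the linkage module; no
  multi-locus models in the association module.
* Imputation emits no posterior probabilities (Viterbi only) and assumes
  haploid (inbred) inputs — no phasing.
* Gene identifiers must arrive pre-mapped to the network's namespace;
  no homolog translation is performed.
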