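---
title: "Region-based association tests for quantitative traits in families and populations"
author: "famregion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based association tests for quantitative traits in families and populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famregion)
```

## The problem

Sequencing studies yield many variants per gene, most of them rare, so
testing variants one at a time is hopeless at realistic sample sizes. The
standard answer is a *region test*: one statistic per gene (or window) that
aggregates all its variants. This package implements both major designs for
quantitative traits:

* **Family-based** tests in the FBAT tradition, which condition on parental
  genotypes so that the Mendelian randomness of transmissions — not the
  population distribution of genotypes — provides the null distribution.
  They are immune to population stratification by construction.
* **Population-based** variance-component tests on unrelated individuals:
  a weighted-kernel score test (the SKAT family) and a region-restricted
  genetic-relationship-matrix REML likelihood-ratio test (the GCTA approach
  confined to one region).

It also ships the surrounding machinery an analysis actually needs: variant
prioritization from functional annotation, phenotype residualization,
pedigree handling, a gene-window chromosome scan with Bonferroni control,
and a gene-dropping simulator with a type-I-error / power harness.

## Family-based machinery

For offspring $j$ of nuclear family $i$ with observed dosage $x_{ijm}$ at
marker $m$, the conditional mean $e_{ijm}$ and variance $v_{ijm}$ of
$x_{ijm}$ given the parents follow from Mendelian transmission: a parent
with dosage $d$ transmits the counted allele with probability $d/2$. The
family score vector is

$$U_{im} = \sum_j T_{ij}\,(x_{ijm} - e_{ijm}),$$

with $T$ the adjusted trait residual. Under the no-association null,
$E[U_{im}] = 0$ *conditionally on parental genotypes and traits*, whatever
the trait correlation structure. The offset in the score is zero because
residualization has already centered $T$; raw traits are centered with a
warning.

The four region statistics:

* `fbat_v` — unweighted burden: markers are collapsed into a single score
  before testing; $Z = \sum_i U_i / \sqrt{V}$, two-sided normal p.
* `fbat_m` — multivariate: $Q = U^\top V^- U$ with the Moore–Penrose
  pseudoinverse (relative eigenvalue cutoff $10^{-8}$), df = rank$(V)$,
  upper $\chi^2$ tail. With many markers its df grows and power suffers,
  which is why the motivating analysis did not report it; it is provided
  for completeness.
* `fbat_l` — linear combination: $Z = w^\top U / \sqrt{w^\top V w}$, with
  $w_m$ the sample covariance between the trait residual and the
  conditional-mean genotype $e$. Since $e$ is a function of parental
  genotypes only, the weights use *between-family* information that is
  independent of the transmissions driving $U$ under the null — so
  noninformative families contribute to the weights, and weight estimation
  does not invalidate the test (the type-I-error suite verifies this
  empirically rather than assuming it). Weights estimated from fewer than
  10 offspring are shrunk proportionally toward zero; all-zero weights fall
  back to the unweighted burden with a warning.
* `fbat_lmm` — variance-component permutation test:
  $Q = \sum_m (\sum_i U_{im})^2$, direction-agnostic, so opposite-signed
  effects add instead of cancelling. The exact statistic used in the
  original analysis is unpublished; this quadratic form is our reading of a
  variance-component test within the score framework, and we flag it as
  such. P-values come from Mendelian re-draws: each permutation resamples
  every offspring's genotypes from the conditional distribution given its
  parents and recomputes $Q$; $p = (1 + \#\{Q^* \ge Q\})/(1 + n_{perm})$
  (ties counted conservatively; 1000 permutations by default; the seed is
  an explicit argument, derived from the marker ids when omitted).

### Variance estimation, and why "-e" matters

The model-based variance $V = \sum_{ij} T_{ij}^2 v_{ijm}$ treats
transmissions as independent across offspring, families and markers. That
is exactly right when the markers are unlinked to anything influencing the
trait. But a heritable trait realized on *transmitted genomes* — the
situation in real pedigree data, where the polygenic background lives on
the same chromosomes as the test markers — couples trait similarity among
sibs to their shared transmissions, and the model-based variance
understates Var$(U)$. Single-offspring families are immune (integrating
over unknown parental phase restores independence), but sibships and
extended pedigrees are not.

The empirical ("-e") estimator sums family scores within each pedigree
first and accumulates outer products of the per-pedigree sums,
$\hat V = \sum_p \tilde U_p \tilde U_p^\top$, absorbing arbitrary
dependence among the nuclear families of one pedigree. The simulation
suite reproduces both halves of the story: on the extended-pedigree preset
the model-based burden/linear-combination tests reject a null at well above
the nominal rate while their "-e" versions stay calibrated; on independent
families both agree. `fbat_lmm` resamples within nuclear families and so
shares the model-based limitation on extended pedigrees — it is calibrated
on independent-family designs only, and its output carries a diagnostic
note when a pedigree contributes several families.

Cross-marker conditional covariance within an offspring is taken as zero
(independent transmissions, a linkage-equilibrium approximation): parental
phase is unobserved, and the empirical variance is the recommended guard
whenever that approximation is in doubt.

Families with an ungenotyped parent at a marker are noninformative there
and skipped (the sufficient-statistic treatment of missing parents is
deliberately out of scope); Mendelian-inconsistent offspring are excluded
at the offending marker with a warning.

## Population-based machinery

`skat_test` fits the null linear model of the trait on covariates, then
forms $Q = r^\top K r / (2\hat\sigma^2)$. The default kernel is the
weighted linear kernel $K = GW^2G^\top$ with $w_m$ the Beta$(1,25)$ density
at the marker's MAF — the standard rare-variant upweighting. (The
motivating text prints "beta[0,25]"; Beta$(0,\cdot)$ is not a proper
density, so we read it as Beta$(1,25)$ and record the reading rather than
silently correcting it.) IBS and gaussian kernels are available for
nonlinear effects. The null distribution is the weighted mixture
$\sum_k \lambda_k \chi^2_1$ with $\lambda$ the eigenvalues of
$\tfrac12 P_0 K P_0$; tail probabilities come from numerical inversion of
the characteristic function (the quantity the Davies algorithm computes),
done piecewise with an integration-by-parts truncation bound and validated
against a Monte-Carlo oracle, with Liu–Tang–Zhang moment matching as the
flagged fallback. Missing dosages are mean-imputed per marker here —
never in the FBAT machinery, where conditioning requires observed
transmissions. Monomorphic markers are dropped everywhere a statistic is
computed (the Beta density is unbounded at MAF 0), though the variant
*filter* retains them for reporting.

`skat_o_test` additionally offers the adaptive burden/kernel combination
(minimum p over mixing weights $\rho \in \{0, 0.25, 0.5, 0.75, 1\}$,
calibrated by residual permutation). It is a sensitivity analysis, not the
default: the default-weight kernel test is the primary population-design
statistic, consistent with the motivating comparison where the default
weighting had the highest power.

`gcta_region_test` builds the region GRM $A = ZZ^\top/M$ from standardized
dosages and fits $y = X\beta + u + \varepsilon$, $u \sim N(0,\sigma^2_g A)$
by REML, profiling the likelihood in $h^2 = \sigma^2_g/\sigma^2_{tot}$ over
$[0, 1)$ with a 21-point grid plus local refinement (tolerance $10^{-8}$ on
the log-likelihood; the low-rank eigenstructure of $A$ makes each
evaluation $O(nM)$). $H_0\!: \sigma^2_g = 0$ sits on the boundary, so the
LRT is referred to the mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$;
degenerate fits return LRT 0 and $p = 1$ rather than failing silently.

Both tests expect (approximately) unrelated subjects; `select_unrelated`
supplies founders or a greedy maximal kinship-zero set, and `genotype_pcs`
provides ancestry covariates (sign-fixed by the largest loading) for
`residualize`.

## Phenotype adjustment

`residualize` regresses the trait on an intercept plus caller-chosen
covariates (age, sex, their literal product, medication use, genotype PCs
— whatever the analysis requires; sex and medication are 0/1 coded) and
standardizes the residuals to unit variance. `average_exams` averages each
person's available per-exam residuals and re-standardizes. We standardize
at both steps — per exam and after averaging — because the source analyses
describe "standardized residuals" per exam and an "average residual" trait
without fixing the order; doing both is scale-stable and changes no test
decision (every statistic is invariant to a common trait rescaling).
Persons missing a given exam contribute the exams they have.

## Variant prioritization

`functional_filter` keeps a variant if **any** route qualifies it: splice
or stop class; nonsynonymous with deleteriousness score strictly above 0.5
("above 0.5" is strict); or eQTL evidence at or above 3.4 on the
$-\log_{10} p$ scale (a "cutoff ... used", hence inclusive). Annotation
production (SnpEff, PolyPhen2, eQTL mapping) is upstream of this package;
the filter consumes their table. `maf_summary` reports strict "< bound"
strata. The shipped `inst/extdata/map4_snps.tsv` carries the 28
prioritized candidate-gene variants with their printed MAFs; feeding them
to `maf_summary` reproduces the published "16 (57.1%)" MAF < 5% stratum.
(The printed MAFs actually contain 10 values below 1% where the published
table says 9 — an inconsistency in the source we report but do not
resolve; the < 1% stratum is therefore not used as a check.)

## The simulator and what the tests do (and do not) show

`gene_drop` assigns founder alleles at specified frequencies and drops
them through the pedigree; by default loci segregate independently (no LD,
free recombination). `linked = TRUE` transmits whole parental haplotypes —
a single recombination-free chromosome — which is how we emulate a
polygenic background carried on the same chromosome as the test region.
`sim_replicate` adds the trait: causal-variant effects, a polygenic
component (either multivariate normal with covariance $2\Phi h^2$, or
realized through linked background loci), Gaussian noise, and age/sex
effects that `residualize` later removes.

Scenario presets encode the study conditions:

* `q1like` — null trait with polygenic heritability 0.628 (the observed
  heritability of the null phenotype in the motivating data), 170
  two-parent/three-offspring pedigrees = 850 persons, matching the
  family-sample size (n = 849) of the motivating analysis; 28 markers at
  the published candidate-region MAFs. Used for type-I-error calibration
  of every method at 200 replicates and $\alpha = 0.05$ (the published
  evaluation design), with population tests run on the 340 founders.
* `q1like_extended` — the same null trait on 65 thirteen-person
  three-generation pedigrees (845 persons), polygenic background realized
  through linked loci. This is the scenario in which the model-based FBAT
  variance is expected to fail and the "-e" estimator to hold. The choice
  of *linked* realization is deliberate: with a trait simulated
  independently of the transmissions (the multivariate-normal mode), the
  model-based conditional variance is exactly correct and no inflation can
  appear, so a simulator without linkage would silently fail to probe the
  property at all.
* `map4like` / `map4like_mixed` — power scenarios: 8 causal variants of 28
  (four rare at 0.5 SD per allele, four common at 0.25), same-signed or
  alternating-signed, residual polygenic heritability 0.30. Effect sizes
  were chosen once to put burden-test power in a discriminating mid-to-high
  range at this sample size; they are not estimates of the (unpublished)
  generating model of the motivating data, so published power numbers are
  reproduced qualitatively (orderings), not numerically.

What passing tests show: calibration and ordering properties of the
statistics under idealized inheritance (no LD within the region, exact
pedigree records, complete genotyping, Gaussian traits). What they do not
show: behaviour under realistic LD, genotyping error, pedigree errors,
ascertainment, or non-normal traits — real-data analyses should lean on
the "-e" variance and treat the simulator's verdicts as necessary, not
sufficient.

Problem sizes in the acceptance suite (200 replicates for rate estimates,
50 for the scan, $5\times10^6$ draws for the Monte-Carlo mixture oracle,
$n = 500, M = 30$, 100 replicates for REML recovery) are the package's
chosen desk-scale design; rates at 200 replicates carry exact binomial
95% bands of roughly $\pm 3$ points around 5%.

## Numerical choices

* Pseudoinverse eigenvalue cutoff $10^{-8}\lambda_{max}$ (fbat_m df = rank).
* Characteristic-function inversion: chunked quadrature to a truncation
  point with remainder below $10^{-7}$; eigenvalues below
  $10^{-10}\lambda_{max}$ dropped; Liu fallback is flagged in the result.
* REML: profile likelihood in $h^2$; grid + golden-section refinement;
  boundary LRT mixture; non-finite likelihoods reported as
  non-convergence, never dropped silently.
* Permutation ties count as exceedances (conservative add-one rule).
* Minor-allele orientation is per loaded cohort; ties at MAF 0.5 keep the
  ALT allele. Gene intervals are 0-based half-open; a variant at 1-based
  position $p$ is in a gene iff $start \le p-1 < end$. Overlapping genes
  each receive the variant (union assignment; conservative for discovery).
* The Bonferroni denominator counts only genes actually tested (at least
  one polymorphic marker after filtering), and the scan logs it.

## Interfaces

Every operation is an R function; `famregion_cli()` (and the installed
`inst/cli/famregion` wrapper) exposes `filter`, `fbat`, `poptest`,
`simulate` and `scan` subcommands for shell pipelines, each writing a JSON
provenance sidecar (flags, seed, package version, input checksums).
Configuration is flags-only; the sidecar, not a config file, is the
reproducibility record.

## Known limitations

Dichotomous traits, haplotype-based family tests, missing-parent
sufficient statistics, X-linked inheritance, imputation dosages (VCF DS),
multiallelic decomposition and small-sample moment adjustments for the
kernel test are out of scope. `fbat_lmm` should not be trusted on
extended pedigrees (see above). The greedy unrelated-set selection is
maximal, not guaranteed maximum, on pathological pedigrees.
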