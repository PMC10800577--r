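---
title: "From case-control genotypes to gene-gene interaction networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From case-control genotypes to gene-gene interaction networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(giscan)
```

## The problem

Single-variant association tests miss genetic effects that only appear when
two loci are considered jointly.  `giscan` implements a gene-based
statistical-epistasis workflow for case-control cohorts: every eligible
SNP pair is screened for interaction, surviving pairs receive a logistic
interaction test with an odds ratio, SNP-pair results are collapsed to
gene pairs through a gene-body + promoter annotation, and the resulting
genetic interactions (GIs) are thresholded, signed by risk direction and
summarised as a hub-gene network.  Exhaustive pairwise scans at
genome scale are astronomically large (about $2\times10^8$ gene pairs for
20,000 protein-coding genes, and billions of SNP pairs behind them), which
dictates most of the design below: a cheap screen in front of an expensive
test, gene-level collapsing, and multiple-testing control calibrated to the
assumed universe of tests rather than the tests actually run.

## The two-stage SNP-pair scan

### Stage 1: Kirkwood-superposition screen

For a SNP pair, the data form a $3\times3\times2$ table of genotype
dosages ($g_A, g_B \in \{0,1,2\}$) against phenotype.  The screen compares
the saturated log-likelihood of that table with the log-likelihood under a
Kirkwood superposition approximation (KSA) built purely from the observed
pairwise and single marginals:

$$\hat p(i,j,k) \;\propto\; \frac{p(i,j)\,p(i,k)\,p(j,k)}{p(i)\,p(j)\,p(k)},$$

normalised over the 18 cells, with cells whose required marginals vanish
fixed at zero.  The statistic is $\tau = 2(\mathrm{LL}_{sat} -
\mathrm{LL}_{KSA})$, referred to the upper tail of $\chi^2_4$ (the
$(3-1)(3-1)$ interaction degrees of freedom).  A key property, which the
test suite verifies against an iterative-proportional-fitting oracle on
random tables, is that $\tau$ **upper-bounds** the exact
homogeneous-association likelihood-ratio statistic: the screen can pass
null pairs through, but it never hides a pair the exact 4-df interaction
LR would flag at the same threshold.  That makes a loose screen threshold
safe: the default `screen_alpha = 1e-4` is deliberately weaker than the
nominal GI cutoff of $10^{-5}$ applied downstream.

### Stage 2: logistic interaction test

Pairs with screen $p \le$ `screen_alpha` are refitted by maximum
likelihood:

$$\mathrm{logit}\,P(\mathrm{case}) = \beta_0 + \beta_1 g_A + \beta_2 g_B +
\beta_3\, g_A g_B,$$

with dosages coded 0/1/2.  The reported quantities are the Wald $p$-value
of $\beta_3$ and the interaction odds ratio $\mathrm{OR} = e^{\beta_3}$ —
the OR is the quantity of record because it is directional (risk
increasing vs decreasing) and is what case-control sampling identifies.
The Wald form (rather than a likelihood-ratio test) was chosen because OR
and its standard error are the quantities carried forward; under the null
simulations below the two are indistinguishable in calibration.

Numerical contract: iteratively reweighted least squares
(`stats::glm.fit`) with relative log-likelihood tolerance $10^{-8}$ and at
most 50 iterations; non-convergence or $|\beta_3| > 15$ (a proxy for
quasi-complete separation) yields status `non_converged` with no OR; rank
deficiency (for instance a monomorphic SNP making the interaction column
constant) yields `degenerate`.  Missing genotypes are handled
complete-case per pair — no dosage imputation.

## From SNP pairs to gene pairs

A variant at 1-based position $p$ belongs to a gene iff $p-1$ falls in one
of the gene's 0-based half-open intervals (body or promoter).
Multi-assignment is expected — a SNP can sit in one gene's body and a
neighbour's promoter — and is preserved.  A SNP pair is **intergenic**,
hence eligible, iff both SNPs are assigned and their gene sets are
*disjoint*.  We read "intergenic interaction" as *between two different
genes* rather than "between SNPs outside genes"; the disjointness rule is
the strictest version (a pair sharing even one gene is excluded), which
guarantees every retained interaction genuinely links two genes.

Each eligible SNP pair with an OK fit contributes to every gene pair in
the cross product of its gene sets; per gene pair the SNP pair with the
**minimum Wald p** is kept and its OR carried (ties broken by the
lexicographically smallest SNP-id pair, gene pairs ordered
lexicographically).  The collapsed $p$ is deliberately *not* adjusted for
the number of SNP pairs inside a gene pair — the min-p convention is the
field's, and the downstream multiple-testing control absorbs the
optimism at the gene-pair level.

## Multiple testing, direction and hubs

Significance is controlled against an **assumed** universe of $m$
gene-pair tests, by default the round figure $m = 2\times10^8$ (from
$\binom{20000}{2} = 199{,}990{,}000$): Bonferroni at $\alpha/m$
($2.5\times10^{-10}$ at $\alpha=0.05$) and step-up Benjamini–Hochberg with
total count $m$, untested pairs counting as non-discoveries (with
$9.5\times10^6$ qualifying discoveries this gives the cutoff
$9.5\times10^6 \cdot 0.05 / 2\times10^8 = 2.375\times10^{-3}$).
`estimate_test_count()` derives $m$ from an actual annotation when
preferred.

Direction: OR $> 1$ is "increased risk"; OR $\le 1$ — including exactly 1
— is "decreased or no risk", because the no-effect point belongs with the
no-risk bucket by that bucket's own name.  Hub genes are tallied from the
two-fold GIs (strictly OR $> 2$ or OR $< 0.5$) at the nominal cutoff,
restricted to *intragenic* GIs — both best SNPs assigned to their genes
via **body** intervals — while promoter-mediated GIs stay in the full GI
table.  Degrees count both endpoints, split by direction.

## Quality control

Filters run in a fixed order, each recorded in a reconciling report:

1. **Variant call rate**: removed iff call rate $< 1 -$ `geno`
   (boundary kept: a variant exactly at the threshold survives).
2. **MAF**: removed iff MAF $<$ `maf_min`; all-missing variants go here.
3. **Exact Hardy–Weinberg tests**, stratum-tiered: a variant fails if its
   exact $p < 10^{-5}$ in **both** cases and controls, or $< 10^{-6}$ in
   controls alone, or $< 10^{-10}$ in cases alone (the `"imputed"`
   preset; the `"array"` preset uses $10^{-3}$ in both strata).  The
   both-strata reading of the first tier is a deliberate interpretation:
   a variant out of equilibrium in only one stratum may be signal, not
   artifact.  The test itself is the standard two-sided exact test
   conditional on allele counts (no mid-p correction), summing the
   probabilities of all heterozygote counts no more probable than the
   observed one.
4. **Sample call rate** (`mind`).
5. **Relatedness**: pairwise PI-HAT $= P(\mathrm{IBD}{=}1)/2 +
   P(\mathrm{IBD}{=}2)$ by the method of moments on identity-by-state
   sharing, computed on an LD-pruned panel restricted to MAF $\ge 0.05$
   (rare variants carry almost no IBS information).  Because allele
   frequencies are estimated from the cohort itself, the expected IBS
   probabilities use the finite-sample correction (unbiased allele-count
   products); negative intermediate IBD probabilities are clamped to zero
   before combining and the estimate to $[0,1]$.  Pairs at PI-HAT $\ge$
   0.1875 (half-way between second and third degree) are broken greedily:
   the sample in the most flagged pairs is dropped, ties going to the
   lexicographically largest sample id.  Estimates from fewer than
   `min_variants` (default 200) co-called variants are never acted on —
   at realistic panel sizes (thousands of pruned SNPs) the estimator's
   noise is a few hundredths, but a few hundred variants would produce
   spurious exclusions, so small panels are treated as uninformative
   rather than trusted.

Running `apply_qc` twice equals running it once on all fixtures tested;
this is checked, not assumed, since later sample removals can in
principle re-expose variant filters.

## The synthetic cohort generator

Every statistical guarantee in the test suite is demonstrated on
synthetic cohorts, so what the generator does (and does not) emulate
bounds what the tests show.

The disease model is
$\mathrm{logit}\,P(\mathrm{case}) = \beta_0 + \sum (\beta_1 g_A + \beta_2
g_B + \beta_3 g_A g_B)$ over planted pairs, with $\beta_0 =
\mathrm{logit}$(`baseline_prevalence`) and genotypes drawn
$\mathrm{Binomial}(2, \mathrm{maf})$ under Hardy–Weinberg equilibrium.
Sampling is **retrospective**: population individuals are drawn (in
batches, capped at $10^7$ draws before an explicit quota failure) until
the case and control quotas fill — matching a case-control design, which
is also why the *odds ratio*, not the risk ratio, is the recoverable
quantity and why the follow-up fits the same parameterisation.
Non-causal variants are independent of phenotype and are drawn only for
retained individuals; under a fully null configuration the scheme reduces
exactly to labelling quotas directly.  All randomness flows from the
config's single seed, with the caller's RNG state restored afterwards, so
a config is a complete, replayable description of a study.

Defaults: `baseline_prevalence = 0.01` (a chronic-disease-scale
prevalence, matching the power-analysis convention for such cohorts) and
`maf_range = c(0.05, 0.5)` (common variants, the post-MAF-filter regime
the scan operates in).

The annotation layout places gene $g$'s body at position $g \cdot 10^5$
(0-based), body SNPs at 100-bp spacing, and a 2-kb upstream promoter with
SNPs at 150-bp spacing — arbitrary but fixed and configurable.  One
deviation is deliberate: gene 2 starts 1950 bp after gene 1's body end,
so its promoter overlaps the last 50 bp of gene 1's body and at least one
variant is always assigned to two genes, keeping the multi-assignment
path exercised for every `snps_per_gene >= 1`.

QC stress artifacts are injected on top of a clean cohort, with a
manifest for recall measurement: heterozygote-deficient variants (allele
frequency ~0.5 but only homozygous calls — the exact test rejects these
at any realistic $n$), near-duplicate samples (0.5% of calls
re-randomised; ids suffixed `_dup` so the relatedness tie-break removes
the copy, not the original), and uniform missingness.

**What is not emulated** — and therefore what passing tests do *not*
demonstrate about real data: linkage disequilibrium (variants are
independent, so LD pruning is exercised only by constructed duplicates,
and LD-induced redundancy among GIs is absent), population
stratification and ancestry structure, imputation uncertainty
(hard calls only), X-chromosome dosage, genotyping batch effects, and
realistic allele-frequency spectra.  On real cohorts the scan should be
run after ancestry control, and collapsed GIs near each other deserve an
LD check before interpretation.

## Study conditions used by the checks

The calibration and recovery suites fix their conditions once:

- **Null calibration**: one cohort of 500 cases / 500 controls, 150
  single-SNP genes, MAF 0.2–0.4, giving 11,175 intergenic body-body
  pairs; every pair is sent to the follow-up and the Wald $p$'s empirical
  rejection rate at 0.05 and Kolmogorov–Smirnov uniformity are checked.
- **Recovery**: 200 replicate cohorts of 1000 cases / 1000 controls with
  one planted pair at interaction OR 2 and causal MAF 0.3–0.4 (common
  causal variants, the regime in which a 2000-sample cohort has strong
  power for an interaction of that size); checked for ~95% Wald coverage
  of $\ln 2$ and mean log-OR within 0.05 of it.
- **Ranking**: 100 replicates of the same planted signal among 1080 null
  pairs; the planted SNP pair must survive the default screen and carry
  the smallest Wald $p$ in at least 95% of replicates.
- **QC recall**: 240 samples, 3150 variants (enough for the PI-HAT panel
  to be decisive), 5 injected HWE violators, 2 duplicates, 0.5%
  missingness; 100% artifact recall with zero causal loss.

## Known limitations

- The screen's $\chi^2_4$ reference is asymptotic; with sparse cells
  (rare alleles, small strata) both stages lose calibration before the
  screen's upper-bound property does.
- No covariate adjustment (principal components, sex) in the follow-up
  fit; confounded cohorts need external stratification control first.
- The min-p collapse favours gene pairs containing many SNP pairs; rank
  comparisons between gene pairs of very different SNP content inherit
  that bias, as they do in the underlying convention.
- PI-HAT moment estimates assume the panel approximates independent
  common variants; strong residual LD inflates relatedness estimates.
- Separation-flagged pairs are dropped (`non_converged`), not rescued by
  penalised regression; extremely strong or sparse interactions are
  under-reported rather than over-reported.
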