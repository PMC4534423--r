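---
title: "Methods: two-locus SNP interaction analysis in case-control data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-locus SNP interaction analysis in case-control data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episnp)
```

## The problem

Genome-wide association hits explain a small share of the heritability of
common diseases such as atrial fibrillation (AF). One proposed reservoir of
the missing share is gene–gene interaction: the joint effect of two risk
variants exceeding what their separate effects predict. `episnp` implements
the statistical toolkit for asking that question about a *pair of biallelic
SNPs* in a case-control sample, on both the additive-risk scale (RERI) and
the multiplicative-odds scale (genotypic interaction regression), together
with the supporting machinery: genotype ingestion, Hardy–Weinberg quality
gates, single-locus association, and a penetrance-based simulator for
calibrating every estimator.

Throughout, each SNP is oriented by a declared **risk allele**
(`snp_spec()`), and genotypes are reduced to risk-allele dosages
$g \in \{0, 1, 2\}$. A SNP pair therefore yields nine joint genotypes,
cross-tabulated against case status into a $3 \times 3 \times 2$ table.

## Genotype odds-ratio profile

With the doubly non-risk homozygote (dosage $(0,0)$) as reference, each of
the other eight joint genotypes gets a cross-product odds ratio from the
$2\times2$ table against the reference cell,

$$\mathrm{OR} = \frac{a\,d}{b\,c}, \qquad
\mathrm{CI}_{95} = \exp\!\left(\log \mathrm{OR} \pm 1.96
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right),$$

the Woolf interval, with a two-sided p-value from the uncorrected Pearson
$\chi^2$ on the same table. A zero cell triggers the Haldane–Anscombe
correction (0.5 added to all four cells) unless the caller disables it, in
which case a degenerate table is an error. When subject-level data are
available, adjusted odds ratios come from a *single* logistic regression
with eight genotype indicators plus covariates, not from eight separate
fits — one model per population, which keeps the eight estimates mutually
consistent.

Differences between two genotypes' odds ratios are tested with the
**Breslow–Day homogeneity test** on two strata, each genotype against the
reference. The two strata deliberately share the reference cell's counts:
the comparison the published AF analyses make is "is the OR of the
double-risk genotype larger than that of a single-risk genotype, both
measured against the same baseline", and with this construction the package
reproduces the published homogeneity p-value for the double- versus
single-risk comparison exactly. The test statistic uses the Mantel–Haenszel
common OR and the closed-form root of the per-stratum expected-count
quadratic; the unit tests check it against an independent `uniroot`-based
implementation.

The **synergy summary** compares the doubly risk-homozygous OR with the
*sum* of the two single-risk homozygote ORs. A sum (rather than the more
conventional product) is the additive-scale benchmark used in the source
analyses; the product is reported alongside, clearly labelled, for readers
who prefer the multiplicative benchmark.

## RERI: additive-scale interaction

For exposures $A$ and $B$ with a common reference category, the relative
excess risk due to interaction is

$$\mathrm{RERI} = \mathrm{RR}_{11} - \mathrm{RR}_{10} - \mathrm{RR}_{01} + 1,$$

zero under perfect additivity of excess risks. In a case-control design the
relative risks are replaced by odds ratios; for a disease with prevalence
below about 1% (AF: 0.4–0.8%) the OR approximates the RR closely, and the
simulator's `true_values` let you quantify the residual approximation error
(it is within 2% at a baseline risk of 0.5%).

Because the SNPs are biallelic, three standard exposure contrasts are
predefined (`reri_contrast()`), in $(g_A, g_B)$ dosage notation:

| label | reference | exposed A only | exposed B only | doubly exposed |
|-------|-----------|----------------|----------------|----------------|
| H1 | (0,0) | (1,0) | (0,1) | (1,1) |
| H2 | (0,0) | (2,0) | (0,2) | (2,2) |
| H3 | (1,1) | (2,1) | (1,2) | (2,2) |

H1/H2 ask about one/two copies of each risk allele against the double
non-risk homozygote; H3 asks about one *additional* copy given the doubly
heterozygous baseline.

**Confidence intervals** use the MOVER (method of variance estimates
recovery) construction, which combines the three ORs' asymmetric Woolf
limits into limits for the linear combination
$\theta_1 - \theta_2 - \theta_3 + 1$. The three log-OR estimates are
correlated because their $2\times2$ tables share the reference cell; under
multinomial sampling that covariance is
$1/a_\mathrm{ref} + 1/b_\mathrm{ref}$ (reference case and control counts),
and the correlated-limb MOVER form is the default. This choice was
validated against the published AF tables: the correlated form reproduces
all three printed CIs for the main SNP pair exactly at two decimals, while
the independent form (`correlated = FALSE`, also available) is
systematically wider. For model-based (covariate-adjusted) RERI the same
formula uses the correlations of the indicator coefficients from the
fitted covariance matrix; on count-expanded data without covariates the
two routes agree to $10^{-6}$, which is the module's central oracle
equivalence and is asserted in the tests.

**Significance** comes from a stratified bootstrap: subjects are resampled
with replacement *within* the case and control strata, preserving both
sample sizes — the margins a retrospective design fixes. The default is
10,000 replicates, the scale at which the published bounds were reported. The two-sided percentile p-value is
$2\min(\Pr^*[\mathrm{RERI} \le 0], \Pr^*[\mathrm{RERI} \ge 0])$, floored at
$1/\mathrm{reps}$ (a resampling p-value cannot honestly be zero) and capped
at 1. Replicates with an empty contrast cell are skipped and counted; more
than 10% of them attaches an instability warning. For count-table input the
stratified resample is drawn directly as two multinomials over the nine
cells — exactly equivalent to resampling expanded subjects, and fast enough
for calibration studies. Type-I error of this procedure under an exactly
risk-additive null is confirmed at ≈0.05 in the acceptance suite.

## Genotypic interaction on the multiplicative scale

The Cordell–Clayton decomposition codes each SNP with an additive dosage
term $x \in \{0,1,2\}$ and a dominance (heterozygote indicator) term
$z \in \{0,1\}$, and models

$$\operatorname{logit} P(\text{case}) = \mu + \alpha_A x_A + \delta_A z_A +
\alpha_B x_B + \delta_B z_B + \gamma_{aa} x_A x_B + \gamma_{ad} x_A z_B +
\gamma_{da} z_A x_B + \gamma_{dd} z_A z_B.$$

`interaction_test6()` fits this full model (per-term Wald ORs, global 4-df
likelihood-ratio test against the main-effects model);
`interaction_test5()` fits the reduction without dominance terms and
reports the single additive-by-additive OR. `dominance_reduction_lrt()`
compares any such nested pair, reporting the parameter-count difference as
its df explicitly, because "removing dominance" can mean several different
reductions and the df should never be implicit.

**Coding orientation.** The published AF interaction table was produced by
software that orients the additive dosage by the *minor* allele, not by the
designated risk allele. The two conventions agree when every risk allele is
the minor allele, but flipping exactly one SNP's axis inverts the
additive-by-additive OR ($\hat\gamma_{aa} \mapsto -\hat\gamma_{aa}$ with
main effects present), and for the AF pair one risk allele is the major
allele. `coding_scheme("minor")` — the default — estimates the pooled
allele frequency from the data being fitted and flips any axis whose risk
allele exceeds 0.5; with it the package reproduces every printed unadjusted
interaction OR (all four terms, the global p, and the reduced-model OR).
`coding_scheme("risk")` keeps the risk-allele orientation, which is the
natural choice for simulation studies where truth is defined on the risk
axis; the relabelling invariances (swapping SNP roles transposes the mixed
terms and preserves the global test) are asserted for both.

Logistic fitting is by iteratively reweighted least squares
(`stats::glm`), with frequency weights so that nine-cell count tables fit
identically to expanded subject records (asserted to $10^{-8}$ on the
coefficients). Convergence tolerance is $10^{-10}$ with at most 100
iterations. Quasi-complete separation is a hard error naming the offending
column — the published tables contain no zero cells in fitted models, and
silently penalized estimates would be misleading in this setting — as is a
rank-deficient design.

## Hardy–Weinberg gate

Quality control uses the exact conditional test: with the allele counts
fixed, the p-value sums the probabilities of all heterozygote counts (of
the same parity) no more probable than the one observed. The gate passes
when p > 0.01 in controls, the conventional threshold for candidate-SNP
studies; failure is reported, never fatal. A $\chi^2$ variant is available
for comparison. The exact test is verified against full enumeration. One
practical subtlety the tests document: each study population's controls
pass the gate, but *pooling* heterogeneous strata can fail it (the combined
AF controls show a heterozygote excess at one SNP at p ≈ 0.004), so the
gate should be applied within populations.

## The synthetic cohort generator

`sim_params()` + `simulate_cohort()` generate case-control samples with
exactly the structure the estimators assume, so every stage is testable
without external data:

* two biallelic SNPs in linkage equilibrium (the emulated loci sit on
  different chromosomes), genotypes at HWE given risk-allele frequencies;
* a $3\times3$ penetrance matrix built either on the risk-additive scale
  ($P = b + g_A e_A + g_B e_B + g_A g_B e_{AB}$; out-of-range penetrance is
  an *error*, never clipped silently), on the multiplicative-odds scale
  ($\operatorname{logit} P$ linear in dosages and their product), or given
  explicitly;
* sex and age drawn independently of genotype, with optional log-odds
  disease effects (age effect centered at the age mean);
* retrospective sampling: population draws are assigned status from their
  penetrance and accumulated until exactly `n_cases` and `n_controls` are
  collected, matching the fixed margins of a case-control design. Subject
  order is shuffled so no downstream statistic can depend on it.

Default parameters are the emulated study's conditions: risk-allele
frequencies 0.32 and 0.50 (the combined control-group estimates), per-allele
odds ratios 1.30 and 1.57, baseline risk 0.6% (the middle of the stated
AF prevalence range), 60% males, age 60 ± 10 years, 2,020 cases and 5,315
controls, and no interaction — interaction is what an experiment switches
on. `build_penetrance()` also returns `true_values`: the exact population
genotype frequencies, covariate-marginalized penetrance, true ORs per
genotype, true RERI per contrast, and the true additive-by-additive OR
(the infinite-sample logistic projection, equal to `exp(interaction)` in
multiplicative mode). These are derived by direct arithmetic and
quadrature, independent of any estimator, and the self-consistency
identity (true RERI equals the RERI identity applied to the true ORs) is
asserted exactly.

`simulate_table()` draws the nine-cell counts directly from the
status-conditional genotype laws — the count-level equivalent of
`simulate_cohort()` when no covariates are needed — and makes replicate
studies (coverage, type-I error) cheap. `recovery_suite()` packages the
replicate loop: bias, CI coverage, and rejection rates against the true
values.

What the generator deliberately does **not** emulate: linkage
disequilibrium between the two SNPs, population stratification or
admixture, genotyping error, and covariate-genotype confounding (a switch
for the latter is a possible extension, not a default). Passing tests on
synthetic data therefore demonstrate correctness of the estimators under
the stated sampling model, not robustness to those real-data complications.

## Numerical and design choices

* Complete-case handling is per analysis: single-locus tables drop
  subjects missing that SNP, pairwise tables drop subjects missing either
  SNP. This matches the shifting denominators of the published tables and
  is logged via the crosstab totals.
* Genotype strings parse order- and case-insensitively (`"AG"` ≡ `"ga"`),
  with `/` and `|` separators tolerated and `00`, `--`, `NN`, empty and
  kin treated as missing. Alleles outside the SNP's two declared alleles
  are a coding error, not silent missingness.
* Pearson $\chi^2$ never applies the Yates correction, matching the
  published allelic p-values.
* Raw p-values are reported everywhere; multiple-testing thresholds are a
  reporting annotation, never an alteration of the p-values.
* The bootstrap p floor ($1/\mathrm{reps}$) means the smallest reportable
  p at 10,000 replicates is $10^{-4}$; published bounds at exactly that
  floor correspond to zero crossing replicates.
* Tie-breaking in the exact HWE test ("no more probable than observed")
  uses a $10^{-12}$ relative slack so that equal-probability
  configurations are included regardless of floating-point noise.
* Problem sizes in the test suite (hundreds of replicates at
  1,500–4,000 subjects for calibration; single fits at 25,000–50,000 for
  consistency checks) were chosen to keep Monte-Carlo error well inside
  the asserted tolerance bands while the whole suite runs in well under a
  minute.

## Worked example

```{r example}
tab <- af_example_counts("rs2106261-rs2200733")
prof <- genotype_or_profile(tab)
prof[prof$dosage_a == 2 & prof$dosage_b == 2,
     c("genotype_a", "genotype_b", "or", "ci_low", "ci_high")]

reri_from_counts(tab, "H2")

interaction_test6(tab)
```

## Known limitations

* Only biallelic SNPs and two-locus interactions; no haplotype phase, no
  imputation, no VCF ingestion.
* Adjusted (covariate) analyses require subject-level data; count tables
  support the unadjusted columns only, and the pipeline degrades
  gracefully (skipping with a logged reason) rather than guessing.
* The Breslow–Day comparison with a shared reference uses non-independent
  strata by design; its p-value is a homogeneity measure under that
  construction, not a textbook independent-strata test.
* RERI in terms of ORs inherits the rare-disease approximation; for
  prevalences above a few percent the exaggeration of the OR relative to
  the RR propagates into RERI.
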