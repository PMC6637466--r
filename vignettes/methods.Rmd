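---
title: "Methods: residualized negative-binomial MWAS and bin-matched mQTL-GWAS enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residualized negative-binomial MWAS and bin-matched mQTL-GWAS enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`mwasenrich` implements a methylome-wide association study (MWAS) of a
bounded, right-skewed count trait measured on 450k-style methylation arrays,
together with the downstream analyses that situate such an MWAS among other
summary-statistic resources: cross-dataset sign concordance and p-value shift
tests, gene-set shift enrichment, and a clumped, deduplicated, bin-matched
permutation test for enrichment of CpG-associated mQTLs in GWAS summary
statistics. A synthetic-data module generates every input with known ground
truth, so the whole pipeline is validated end-to-end without any cohort data.

# The two-step association model

Methylation is summarized per CpG as a beta value in $[0,1]$. The association
model is two-step. The first stage regresses each CpG's methylation on the
technical covariates only,

$$\beta_{meth} = \beta_0 + \beta_1\,\mathrm{Slide} + \beta_2\,\mathrm{SampleType}
 + \beta_3\,\mathrm{Plate} + \beta_{4\ldots n}\,\mathrm{CellProportions} + \varepsilon,$$

by ordinary least squares; the residuals $\varepsilon$ are the corrected
methylation values. The second stage regresses the count trait on those
residuals with biological covariates,

$$\mathrm{score} \sim \mathrm{NB}(\mu, \theta), \qquad
  \log \mu = \beta_0 + \beta_1 \varepsilon + \beta_2\,\mathrm{Sex}
  + \beta_3\,\mathrm{PC}_1 + \beta_4\,\mathrm{PC}_2,$$

a negative-binomial (NB) regression with log link, chosen because the trait is
a skewed count. $\beta_1$, its standard error, $z = \beta_1/\mathrm{se}$, and
the two-sided Wald p-value from the standard-normal reference are reported per
CpG. Age is deliberately absent: methylation is measured at birth, the trait
years later, so age cannot confound this direction of analysis.

Two first-stage variants are provided. Model 1 residualizes beta values with
the six standard cord-blood cell fractions; model 2 first converts betas to
M-values, $M = \log_2\!\big(b/(1-b)\big)$ with betas clipped into
$[10^{-6}, 1-10^{-6}]$ (the boundary behaviour is otherwise undefined), and
uses an extended cell set that includes nucleated red blood cells. Model
agreement is assessed by the Pearson correlation of z-scores.

Design details worth stating:

* Cell proportions sum to one, so one cell column is dropped from the design
  (in model 2 the nRBC column is protected from being the dropped one, since
  it is the point of the extended set). Constant columns are dropped too;
  any remaining rank deficiency is an error naming the collinear columns.
* The per-CpG fit is independent of every other CpG, so adding or removing
  probes never changes existing statistics.
* The NB fit is `MASS::glm.nb`, the field-standard fitter whose alternating
  coefficient/theta updates are exactly the estimation scheme this model
  needs; a fit that errors or fails to converge is refit as Poisson and
  flagged `converged = FALSE`. Near the Poisson limit (large theta) the theta
  iteration warnings are expected and harmless.
* A likelihood-ratio p-value is available behind `p_type = "lrt"`; Wald is
  the default because it is the conventional per-coefficient p-value of the
  named fitter.
* The two-step estimator is not identical to a one-step joint NB fit that
  includes the technical covariates directly; on small instances the two
  agree within ~10% relative error (this approximation is tested, not
  hidden).

Diagnostics: the genomic inflation factor is
$\lambda = \mathrm{median}\{\chi^2_1(p)\} / 0.4549$, and effect sizes are
reported in phenotype-SD units as $|\beta_1|/\mathrm{sd}(\mathrm{score})$.
The epigenome-wide significance threshold is the Bonferroni-style
$1\times10^{-7}$ conventional for 450k arrays.

# Cross-dataset statistics

**Sign concordance.** For CpGs below a discovery threshold (default
$10^{-4}$) present in a testing table, the number of effect-direction
agreements is tested against chance with the exact two-sided binomial test at
$p = \tfrac12$ (the p-value sums all outcomes no more likely than the
observed one). CpGs with an exactly zero effect carry no direction; they are
excluded and counted, rather than arbitrarily called discordant.

**P-value shift.** CpGs below a discovery threshold (default $0.01$) are
compared with all other shared CpGs on their testing-table p-values by a
one-sided Wilcoxon rank-sum test (alternative: selected CpGs have lower
p-values). The exact null is enumerated when both groups have at most ten
untied values; otherwise the normal approximation with tie and continuity
corrections is used. The direction is fixed one-sided because the hypothesis
is directional.

**Gene-set shift.** CpGs are mapped to genes through a flattened two-column
annotation. The analysis first restricts to CpGs mapped to any gene of the
testing universe (the genes actually assayed for differential expression) —
CpGs mapped only outside the universe never enter either group — then
compares CpGs touching at least one set gene against the rest with the same
one-sided rank-sum test. A CpG touching both a set and a non-set gene joins
the set group (any-overlap rule). Testing is per CpG; no gene-level
aggregation is performed.

# mQTL-GWAS enrichment

The core bespoke procedure asks whether mQTLs (SNPs associated with CpG
methylation) of trait-associated CpGs sit at lower GWAS p-values than mQTLs
of the remaining CpGs. Three confounders are addressed explicitly:

1. **LD among mQTLs** — the SNP list is clumped greedily: SNPs are ranked by
   ascending GWAS p; each retained index SNP removes every unretained SNP
   within 1000 kb having $r^2 \ge 0.6$ with it. Pairs absent from the LD
   table count as unlinked. Ranking by GWAS p is the standard clumping
   convention.
2. **mQTL count per CpG** — CpGs are binned by their number of mapped SNPs
   into 1–5, 6–10, 11–15, 16–20, 21–25, and 26+. The published bin bounds
   overlap at 15 and 20; the disjoint left-closed reading above is used and
   is configurable in principle (the bin function is a pure mapping).
3. **SNPs shared across CpGs** — exact duplicate (CpG, SNP) pairs are
   collapsed before testing.

After restricting to pairs whose CpG has an MWAS p-value and whose SNP has a
GWAS p-value, pairs are partitioned at an MWAS threshold
$t \in \{0.05, 0.01, 0.005, 0.001\}$ and the statistic is

$$D_t = \overline{P}_{GWAS}(\text{above-}t) - \overline{P}_{GWAS}(\text{below-}t),$$

so positive values mean enrichment of the top CpGs' mQTLs toward low GWAS
p-values. (The sign convention follows the convention that a positive
difference indicates enrichment; the comparator is the set of remaining
pairs, not all pairs.) Significance comes from 10,000 bin-matched null sets:
within each mQTL-count bin, as many CpGs as the observed below-$t$ set
contains in that bin are resampled uniformly without replacement from all
CpGs of that bin; sampled CpGs carry *all* their pairs. Resampling whole CpGs
(not pairs) is what makes bin matching meaningful. The one-sided empirical
p-value is $(1 + \#\{D^{null} \ge D_t\})/(n_{perm}+1)$ — never exactly zero —
and the four thresholds are adjusted together by Benjamini-Hochberg FDR,
significant at FDR < 0.05. Because the below-threshold CpG set is, under the
null, a uniformly random per-bin subset independent of the GWAS, the
permutation test is exact; an isolated 2,000-replicate check measured a
rejection rate of 0.050 at nominal 0.05.

# The synthetic-data generator

The generator emulates the *data model* of a cord-blood array study, not any
particular cohort:

* **Methylation**: logit-scale CpG baselines from a bimodal mixture (so the
  marginal beta distribution has the usual two modes), plus slide, plate and
  sample-type effects (SD `batch_sd`, default 0.25 on the logit scale),
  weighted Dirichlet cell-composition loadings, and i.i.d. measurement noise
  (SD 0.3). Inverse-logit keeps betas strictly inside $(0,1)$. Slides hold 12
  arrays and plates 96 samples by default; assignments are independently
  shuffled, reflecting scrambled processing order and keeping slide and plate
  identifiable side by side.
* **Phenotype**: a negative-binomial count with log-mean built from the
  *standardized first-stage residuals* of the causal CpGs — by construction,
  the estimand of the two-step model — plus a small sex term, censored at the
  questionnaire ceiling (24). The intercept targets a marginal mean of 14.65.
  The published spread (SD 3.44 at mean 14.65) is *under*-dispersed relative
  to Poisson, which no NB can reproduce; the default size parameter is
  therefore large (`nb_dispersion = 100`, SD ≈ 3.9), the closest achievable
  spread, and this gap is a known limitation of the NB data model itself.
* **mQTL map / GWAS / LD**: each CpG draws its mQTL count from a right-skewed
  distribution over 1–40 (defaults mimic "most CpGs have few mQTLs"; the
  distribution is user-overridable since no public joint distribution exists
  to copy); SNPs live in LD blocks of 5 with constant within-block
  $r^2 = 0.9$ and zero across blocks — the simplest structure that makes
  clumping non-trivial. GWAS p-values are $\chi^2_1$ quantiles (uniform under
  the null); mQTLs of causal CpGs draw from a non-central $\chi^2_1$ with
  non-centrality `gwas_enrich_shift`, i.e. mean chi-square $1 + $ shift.
* **Seeds**: one master seed; every generator derives its own stream by fixed
  offsets, so outputs are byte-identical across runs and independent across
  generators.

What the generator does *not* emulate: genotype-level mQTL effect sizes,
relatedness/sibling structure, missing data, probe cross-hybridization
artifacts, realistic LD decay, or under-dispersion of the questionnaire.
Passing tests therefore demonstrate the pipeline's statistical correctness
under its stated model, not robustness to every pathology of real arrays.

# Validation experiments and their sizes

The package ships four canned experiments (`null_mwas_experiment`,
`calibration_experiment`, `recovery_experiment`, `detection_experiment`) used
by both the test suite and `scripts/acceptance.R`. Sizes were chosen so each
experiment finishes in minutes on one core while keeping Monte-Carlo error
well inside the decision margins.

* **Null calibration** — one null MWAS at $n = 700$, 2,000 CpGs: the p-value
  distribution should be uniform (Kolmogorov-Smirnov distance < 0.03) with
  $\lambda \in [0.9, 1.1]$. The questionnaire ceiling censors ~0.6% of null
  draws, which nudges $\lambda$ a few percent below one — visible, tolerated,
  documented. Then 200 independent small replicates ($n = 120$, 200 CpGs, 500
  permutations) measure the type-I error of the shift test and the
  permutation test at $\alpha = 0.05$ against binomial 95% bounds. The
  discovery-side selection for the shift test is drawn from its uniform null
  at the summary level — legitimate because the same run verifies that null
  MWAS p-values are uniform — which keeps 200 end-to-end replicates inside a
  ten-minute footprint.
* **Parameter recovery** — 50 replicates, one causal CpG, effect 0.3 per SD
  of residualized methylation, $n = 700$, phenotype mean 6. The low mean
  keeps the ceiling inactive: with the ceiling active the generating effect
  is simply not the estimand (censoring attenuates any count model), so
  recovery is evaluated where the estimator's consistency is the thing being
  measured. The mean estimate must sit within two Monte-Carlo SEs of 0.3.
* **Signal detection** — 20 replicates of the full pipeline with 50 causal
  CpGs in a polyepigenetic regime (0.1 per SD each; a 50-CpG architecture
  with large per-CpG effects would saturate the bounded questionnaire and is
  not a regime the model can represent), $n = 700$, 600 CpGs, 12,000 SNPs,
  chi-square shift 1.0, 1,000 permutations. The trait GWAS must reach FDR <
  0.05 at MWAS threshold 0.01 or 0.005 in at least 80% of replicates while a
  negative-control GWAS (same map, null p-values) stays non-significant in at
  least 90% — the qualitative positive-vs-negative-control contrast the
  procedure exists to draw.
* **Oracle equivalence** — greedy clumping against a brute-force
  re-implementation on 50-SNP instances; the sampled permutation null against
  full enumeration on a one-bin, 10-CpG instance; BH against the hand
  step-up computation.

# Numerical choices and degenerate inputs

* M-value clipping at $10^{-6}$; p-values of exactly zero are clamped to the
  smallest positive double on read (with a warning) so $\log$ and
  $\chi^2$ quantile transforms stay finite.
* Empty partitions (no CpG below a threshold, empty shift-test groups, an
  exhausted gene universe) return *flagged* results rather than errors;
  configuration mistakes (negative dimensions, rank-deficient designs,
  constant phenotypes) error early with names.
* Ties in rank-sum tests switch the exact branch off; the approximation uses
  tie and continuity corrections.
* Clumping treats missing LD entries as $r^2 = 0$ and counts them; the
  greedy order breaks p-value ties by table order, which is deterministic
  for a fixed input.
* All writers emit a header comment with version, seed and a content hash;
  identical content reproduces identical bytes.

# Known limitations

The NB model cannot represent under-dispersed questionnaires; the ceiling
induces mild censoring that the model does not explicitly handle (visible as
$\lambda$ slightly below one under the null, and as attenuation when the
combined causal signal is large); LD is block-constant rather than decaying;
mQTL effect sizes on methylation are not modeled, only the pairing and GWAS
p-value shift; and the per-CpG fits ignore correlation between CpGs, which is
correct for testing but means the set of sub-threshold CpGs is not a
multivariate selection.
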