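---
title: "Constructing and evaluating genetic risk models for esophageal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and evaluating genetic risk models for esophageal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrisk)
```

## The problem

Esophageal cancer risk in East-Asian populations is shaped jointly by a
handful of well-replicated susceptibility variants (notably in the
alcohol-metabolism genes *ALDH2* and *ADH1B*) and by modifiable exposures
— smoking, drinking, and a family history of the disease. The question
this package operationalizes is whether adding a small genetic panel to
an environmental risk model measurably improves discrimination between
cases and controls, and how to quantify that improvement honestly.

The workflow has four statistical layers:

1. **Candidate screening** — pooling per-study genotype counts across
   published case-control studies into a single odds ratio per SNP.
2. **Case-control verification** — per-SNP association under five
   genetic contrasts, with Hardy-Weinberg checks, false-positive report
   probability, and attributable-risk fractions.
3. **Risk scoring** — a multiplicative weighted genetic risk score
   (wGRS) over the validated SNPs.
4. **Model comparison** — genetic, non-genetic and combined logistic
   models on a 60/40 train/validation split, compared by AUC (DeLong),
   net reclassification improvement, and AIC/BIC.

## The weighted genetic risk score

For one SNP with risk-allele frequency $p$ and per-allele odds ratio
$OR$, the expected unnormalized genotype score under Hardy-Weinberg
equilibrium is

$$W = (1-p)^2 + 2p(1-p)\,OR + p^2\,OR^2,$$

and the genotype scores are $AA = 1/W$, $AB = OR/W$, $BB = OR^2/W$. The
division by $W$ makes the HWE-expected score exactly 1, so the score of
a panel of independent SNPs — the product
$\mathrm{wGRS} = \prod_j s_j$ — also has population mean 1: values above
1 mark above-average genetic load. A missing genotype contributes a
neutral factor of 1, which shrinks that subject's score toward the
population mean rather than discarding the subject.

```{r}
tab <- score_snp(snp_spec("rs_demo", "T", p = 0.3, or = 2))
tab$W
tab$scores
```

Two properties worth knowing. The score is symmetric under relabelling
the risk allele ($p \to 1-p$, $OR \to 1/OR$ assigns the same scores to
the same genotypes), so "risk allele" bookkeeping cannot silently flip
effects. And for a protective allele ($OR < 1$) the homozygous-carrier
score falls below 1 while the non-carrier score rises above it, as it
should.

The per-SNP weight is nominally the per-allele (allelic) OR, which is
what makes $BB = OR^2$ coherent; the shipped example panel instead
carries each SNP's best-fitting-model OR (recessive for rs1042522 and
rs1229984, dominant for rs1801133, rs2274223 and rs671), because those
are the estimates the verification stage produces. Since the wGRS is
used as a relative ranking — quartile contrasts and a logistic
covariate — the distinction affects calibration of the score, not the
discrimination analyses built on it.

## Association statistics

Each SNP is tested under five genotype collapses (allelic,
heterozygous, homozygous, dominant, recessive), with the Woolf log-OR
standard error and a Haldane-Anscombe +0.5 correction only when a zero
cell occurs. HWE in controls is checked by the 1-df Pearson
goodness-of-fit chi-square with the allele frequency estimated from the
counts.

**FPRP.** The false-positive report probability is the posterior
probability that a significant association is false,

$$\mathrm{FPRP} = \frac{\alpha (1-\pi)}{\alpha (1-\pi) + \beta \pi},$$

with $\alpha$ the observed p-value, $\pi$ the prior, and $\beta$ the
power to detect a threshold OR at level $\alpha$ (normal approximation,
direction-matched: protective estimates are tested against the
reciprocal threshold). Priors default to the conventional screening
ladder 0.25 / 0.1 / 0.01 with the 0.5 noteworthiness cutoff. The
threshold OR defaults to 1.5 — a conventional moderate effect — because
no single published value governs it; it is a configurable argument of
`fprp()`.

**Attributable fractions.** $ARP = 100\,(OR-1)/OR$ among carriers of
the risk class and $PARP = 100\,p(OR-1)/(p(OR-1)+1)$ at risk-class
prevalence $p$; both are reported as 0 with a protective flag when
$OR \le 1$, since the exposure-attributable reading only makes sense in
the harmful direction.

## The meta-analysis engine

Study-level 2x2 tables (after genotype collapse) are pooled with the
Mantel-Haenszel fixed-effect estimator
$\sum_i a_i d_i / n_i \,/\, \sum_i b_i c_i / n_i$, with the
Robins-Breslow-Greenland variance for its CI — the standard pairing in
the major meta-analysis packages. Heterogeneity is Cochran's $Q$ with
$I^2 = \max(0, 100\,(Q - df)/Q)$; the engine stays with fixed effects
when $p_Q \ge 0.10$ **or** $I^2 \le 50\%$ (a disjunction — either
condition suffices) and otherwise switches to DerSimonian-Laird random
effects with the moment estimator
$\tau^2 = \max(0, (Q - df)/(\sum w - \sum w^2/\sum w))$. Publication
bias is screened with Begg's rank correlation (normal approximation, no
continuity correction) and Egger's regression (t on $k-2$ df); both are
flagged not-evaluable below $k = 3$. Studies with an arm under 10
subjects or controls failing HWE at 0.05 are excluded with an audit
log entry, mirroring standard inclusion practice.

## The synthetic-data generator

No subject-level data are distributable, so the generator emulates the
study design and is itself first-class, tested code. It
rejection-samples a source population:

- genotypes independent across SNPs, HWE at each panel frequency;
- exposures independent Bernoulli at the control prevalences
  (smoking 0.346, drinking 0.296, family history 0.020);
- disease from a logistic model: baseline logit plus each SNP's log OR
  applied to its model-defining contrast, plus exposure log ORs
  (defaults are the crude ORs implied by the published baseline table:
  smoking 1.509, drinking 1.508, family history 9.057), plus an
  optional smoking x drinking interaction OR (default 1 — no crude
  interaction estimate is published to anchor it);
- sampling continues until the case and control quotas (default
  500/500) are filled; age is then assigned per arm
  (cases $N(63.0, 8.33)$, controls $N(46.8, 11.55)$) since age appears
  in no published model equation, and controls' sex is
  frequency-matched to the realized case sex distribution
  (72.6% male).

**Why baseline logit -5.** Odds ratios are non-collapsible: the
marginal (2x2) OR of one SNP, averaged over the other independent risk
factors, is attenuated relative to the conditional OR it was generated
with, unless the disease is rare. Exact enumeration of the generator's
cell probabilities ($3^5$ genotype times $2^3$ exposure cells) puts the
attenuation at up to 0.056 on the log-OR scale at a baseline logit of
-3, but at most 0.018 at -5 — negligible against the sampling SE of
roughly 0.05 at 5000 cases / 5000 controls. A baseline risk of about
0.7% is also the realistic order for a general-population cancer. This
is why parameter-recovery tests at large $n$ are expected to succeed:
the generator was designed so that the estimand equals the generating
value.

**Risk-allele frequencies.** The reference (CHB) frequencies behind the
published score are not printed in the source; the shipped panel uses
illustrative East-Asian-range values, clearly labelled as such in
`inst/extdata/panel_example.yaml`. Every quantitative claim in the
tests is therefore about recovery of the *generating* configuration,
never about reproducing the study's unpublished genotype data.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, population stratification, genotyping error, exposure
correlation (smokers and drinkers overlap in reality), or age effects
on risk. Passing tests demonstrate the statistical machinery is
correct under the stated design; they do not certify performance on
real cohorts with those complications.

## Risk models and their comparison

The three models replicate the published term sets exactly: genetic
(wGRS only), non-genetic (smoking, family history, and the smoking x
drinking product — with *no* drinking main effect, a non-hierarchical
specification preserved verbatim from the published equation), and
combined (their union). The wGRS enters raw (unstandardized,
untransformed), consistent with the magnitude of the published
combined-model coefficient. Age is excluded because the published
equations contain no age term; `fit_logistic()` accepts any custom
term set where a covariate-adjusted variant is wanted.

The 60/40 split is simple randomization without stratification (the
published 301/299 vs 199/201 arm counts indicate no balancing).
Quartile cutpoints for the wGRS association are computed from
*training-set controls only* and frozen for the validation set,
avoiding leakage; ties at a cutpoint fall into the lower quartile
(left-closed intervals). The quartile model and the trend test (Wald on
an ordinal 1-4 quartile score) adjust for age, smoking, drinking and
family history.

Evaluation: AUC is the Mann-Whitney concordance probability with half
credit for ties, its CI from the DeLong structural-component variance;
paired model AUCs are compared with the DeLong covariance test. The
operating point maximizes Youden's J over thresholds at midpoints
between adjacent distinct scores, breaking ties toward higher
specificity; accuracy and the likelihood ratios are reported at that
threshold, the only self-consistent reading of a table that reports
both. NRI defaults to the category-free (continuous) variant because no
risk-category cutoffs are published — note continuous NRI is generally
larger in magnitude than categorical NRI, so its absolute value is not
comparable across variants; a categorical mode with explicit
thresholds is available. AIC and BIC use the standard definitions
$-2\ell + 2k$ and $-2\ell + k\ln n$. (The published AIC/BIC pairs imply
$k \approx 2$ at $n = 600$, inconsistent with a 5-coefficient model;
the standard definitions are implemented and the printed BICs are not
chased.)

```{r}
spec <- population_spec(n_cases = 250, n_controls = 250)
subjects <- generate_case_control(spec, seed = 11)
report <- run_pipeline(subjects, spec$snps, seed = 11)
report$evaluation[, c("set", "model", "auc", "aic", "bic")]
```

## Numerical and reproducibility choices

- Logistic fits use IRLS (`stats::glm`) tightened to a 1e-10
  convergence tolerance; complete separation and singular designs are
  raised as explicit errors, never returned as silent near-infinite
  coefficients.
- One global seed per run; each pipeline stage derives its own
  substream seed (`stage_seed()`), so adding a stage never perturbs the
  draws of earlier stages, and all outputs are byte-identical under a
  fixed seed.
- Zero cells: Haldane-Anscombe +0.5 applied to all four cells, only
  when a zero occurs, configurable off; with the correction off an
  infinite OR is an explicit error.
- Degenerate inputs (monomorphic SNPs, constant scores, empty
  quartiles, one-class outcomes) are defined behaviours — neutral
  scores, zero Youden index, non-estimable CI flags, errors — not NaN
  propagation.

## Problem sizes used in the test suite

Unit and property tests run at small $n$ (tens to thousands).
Parameter-recovery checks use 5000 cases / 5000 controls, where the
3-SE band around each generating OR is about ±15% — tight enough to
catch contrast or tilting mistakes. The null-coverage experiment uses
500 replicates of a 500/500 cohort with all genetic ORs at 1 (subjects
still scored with the real panel weights), asserting the
highest-vs-lowest quartile CI covers 1 at 95% within 3 binomial SEs.
These sizes were chosen as the smallest that make the statistical
assertions sharp.

## Limitations

- The wGRS weighting assumes independent SNPs; correlated variants
  would double-count shared signal.
- The multiplicative score has no additive (sum-form) variant here.
- Discrimination metrics, not calibration, are in scope: no
  recalibration, decision-curve analysis or IDI.
- Synthetic validation cannot speak to genotyping-platform artefacts
  or population structure in real data.
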