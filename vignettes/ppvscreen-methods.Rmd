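---
title: "Methods: rare-variant collapsing and penetrance-based screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant collapsing and penetrance-based screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppvscreen)
```

## The screening problem

Population genetic screening wants gene–disease pairs where (i) carriers of
rare damaging variants are common enough to be worth looking for, (ii) the
association with disease is statistically unambiguous at population scale,
and (iii) the *positive predictive value* (PPV) — the fraction of carriers
who actually develop the condition, i.e. the empirical penetrance — is high
enough that returning the result to a carrier is actionable. `ppvscreen`
implements that whole decision pipeline for two cohorts of exome-sequenced,
EHR-phenotyped participants: gene-based collapsing of qualifying variants,
phecode phenotype construction, covariate-adjusted association per cohort,
weighted-Z meta-analysis, and a dual-cohort PPV screen.

## Qualifying variants and gene burden

A variant qualifies under the **coding** model when its canonical-transcript
consequence is one of stop_lost, missense_variant, start_lost,
splice_donor_variant, inframe_deletion, frameshift_variant,
splice_acceptor_variant, stop_gained, inframe_insertion; the **LoF** model
keeps only the loss-of-function subset (stop_lost, start_lost,
splice_donor_variant, frameshift_variant, splice_acceptor_variant,
stop_gained). A variant is discarded when an in-silico predictor calls it
benign (PolyPhen score < 0.15 or SIFT score > 0.05) or when its allele
frequency reaches 0.1% in any gnomAD population or locally in the cohort.
Each sample is then coded 1 for a gene if it carries at least one qualifying
variant there, else 0 — the classic dominant carrier-indicator burden.

Decisions where the rule text leaves room, and what we chose:

* *"not PolyPhen or SIFT benign"* is applied with OR semantics — either
  predictor calling the variant benign excludes it. This is the stricter
  reading and matches the intent of enriching for damaging variants; the
  AND reading is available via `screen_thresholds(benign_rule = "both")`.
* Missing predictor scores never count as benign. LoF consequences are not
  scored by PolyPhen/SIFT at all, so treating missing as benign would
  empty the LoF subset out of the coding model — structurally inconsistent
  with the two consequence sets.
* A missing gnomAD population frequency is treated as 0: absence of evidence
  of commonness. Local MAF is allele count over `2 x` called samples.

Exon-level CNV calls are folded into the same burden: an event qualifies
when it has the PASS QC flag, both its exon- and event-level within-cohort
frequencies are below 0.1%, and its type fits the model (deletions of at
least one exon for LoF; deletions or duplications for coding). Gene overlap
is taken from the caller's table as given; no re-intersection with exon
models is attempted.

## Phenotypes

Dated ICD-9/ICD-10/ICD-10-CM diagnoses are mapped through per-dialect
phecode maps; a sample is a case for a phecode if any of its events maps to
it at least once, and one ICD code may set several phecodes. Analysis
phenotypes must have at least one case in the larger cohort and at least 30
cases in the smaller one.

Age at first diagnosis is only trusted when the record shows at least five
years of medical history before the event (or the event falls in the first
five years of life). We apply that rule to age-at-diagnosis only — case
status uses all events — because the history requirement exists to date
onset reliably, not to erase cases. The 60+ "lifetime-risk" stratum is
defined by current age (age at data extraction), not age at diagnosis: the
stratum's purpose is to ask what fraction of older carriers have developed
the condition by now, which is a property of the person's age, not of when
the code was recorded.

## Association: Firth-penalized logistic regression

Each (gene, phecode) pair is tested per cohort by logistic regression of
case status on the burden indicator with covariates age, sex, age×sex,
age², sex×age² (age is standardized internally; the burden estimate and
test are invariant to that affine change). Biobank-scale tools handle
relatedness and stratification with a whole-genome ridge step; at desk
scale, with unrelated synthetic samples, the statistical content of the
test is the penalized regression itself, so the package implements
Firth-penalized logistic regression natively and isolates it behind
`fit_burden_test()` where a different backend could be slotted in.

The Firth penalty (Jeffreys prior, `+ 0.5 log det I(beta)`) keeps estimates
finite under the complete separation that rare carriers produce. The
default p-value is a penalized likelihood-ratio test; importantly, the null
is the *constrained* maximum of the same penalized likelihood (burden
coefficient fixed at zero, full-design penalty), not a refit of the reduced
design with its own penalty — the latter miscalibrates the test badly at
rare-carrier counts. A Wald option exists. Numerical safeguards: Newton
steps are capped at 5 on the coefficient scale (preventing overshoot onto
the flat penalized plateau at separation), with step-halving on the
penalized likelihood; collinear covariates are dropped with a warning; a
constant phenotype or a zero-carrier gene is a signalled error, and the
pair is skipped by the scan.

Alongside the test, each pair gets its 2×2 table (a = carrier cases, b =
carrier controls, c = non-carrier cases, d = non-carrier controls), the
odds ratio (a·d)/(b·c) with the Haldane–Anscombe 0.5 correction applied to
all cells iff any cell is zero, and PPVs for all ages and the 60+ stratum.
PPV with zero carriers in a stratum is undefined and reported `NA`, never 0.
Sex-specific phenotypes can restrict the sample to one sex, dropping the
sex covariate terms. PPVs use all cases, not only history-valid ones: the
history rule dates onset, and penetrance estimation should count every
diagnosed carrier.

## Meta-analysis and the screen

Cohort Z statistics are combined as `z = (w_a z_a + w_b z_b) /
sqrt(w_a² + w_b²)` with `w = sqrt(4 / (1/cases + 1/controls))` — effective
sample size, the standard weighted-Z choice for binary traits whose case
fraction differs between cohorts (raw-n weighting is a config option). A
triple is significant iff it has at least one carrier in *both* cohorts,
its meta p is strictly lower than both per-cohort p-values, and it clears
the Bonferroni level 1e-9. Strict inequality is assumed for the
"better than either cohort" gate where the rule text does not say.

Significant triples pass the screen when PPV ≥ 0.3 in both cohorts, in the
all-ages stratum or the 60+ stratum (60+ passes are kept even when the
all-ages PPV is lower). Two policy details:

* A 60+ cohort-stratum with undefined PPV or fewer than 5 carrier cases is
  not taken at face value. Under the default policy it can pass through
  that cohort's all-ages PPV and the pair is flagged `manual_review`; a
  strict policy (config switch) fails it. This is the documented handling
  for the realistic edge where one cohort's few carrier cases are all
  younger than 60.
* Only risk-increasing (z > 0) associations can be candidates; protective
  hits stay in the full table but are excluded from PPV screening.

Reports keep, per gene, the significant association with the best PPV;
display flags suppress strata with fewer than 5 carrier cases, since tiny
strata produce unreliable PPVs.

## The synthetic two-cohort generator

`generate_cohorts()` emulates the data the analysis assumes, not sequencing
itself: two cohorts of different size, sex ratio (55% / 68% female), age
range (40–69 vs 18–89) and ICD dialect (ICD-9+ICD-10 vs ICD-9+ICD-10-CM);
per-gene carrier draws at configured frequencies; causal genes whose
carriers acquire the target phecode with probability `penetrance` and
non-carriers with `background_prevalence`; dated ICD streams that resolve
back through a bundled synthetic phecode map; CNV events only in the cohort
whose platform calls them. Decoy variants — synonymous, PolyPhen-benign,
gnomAD-common, and locally-common — are interleaved per gene, one per
qualification clause, so each filter is exercised; decoy CNVs carry QC
failures and common frequencies. Every case's first target diagnosis is
placed at least five years after the start of the record (configurable
fraction), and every sample has an unmapped anchor wellness code at record
start so the history rule has an origin to measure from.

Default desk scale: cohorts of 20,000 and 5,000 samples, 50 null genes and
5 causal genes with carrier frequencies 0.4%, 0.3%, 0.25%, 0.2%, 0.1% and
penetrances 0.8, 0.7, 0.6, 0.5, 0.4 — spanning the regime where screening
candidates live while keeping a full pipeline run in tens of seconds. The
weakest gene (0.1%, 0.4) sits near the detection edge on purpose; with ~5
expected carriers in the smaller cohort its PPV estimate is noisy, which is
exactly the situation the 60+/display policies address. Background
phecodes (prevalences 0.2 down to 0.002) give the phenotype filter and the
association scan non-target work; the rarest stays under 30 cases in the
smaller cohort and is dropped by the filter.

One pseudo-random stream per cohort is keyed by (seed, cohort index), and
genes are drawn in truth order, so outputs are byte-identical for a fixed
seed and appending genes does not perturb earlier draws. Age is simulated
as age at extraction; penetrance is lifetime (age-independent) — the
simplest model consistent with a screen that treats the 60+ stratum as a
lifetime-risk proxy. Diagnosis dates are uniform over the history-valid
span of the record.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: linkage structure and haplotypes, relatedness
and population stratification (the reason biobank analyses need
whole-genome ridge adjustment), ICD coding-practice drift between health
systems, age-dependent penetrance, and miscalled genotypes. Cohorts below
~1,000 samples cannot express sub-0.1% frequencies at all (a singleton is
already above the cutoff), so test fixtures keep cohorts above that size.

## Numerical and testing choices

Fisher-exact agreement, KS uniformity of null p-values, and binomial CI
coverage of PPV are checked in the test suite at fixed seeds. Problem
sizes were chosen to keep the default suite in tens of minutes on one CPU:
type-I control uses 20 all-null runs of ~1,000 triples (cohorts 3,000 /
1,500, carrier frequency 0.4%, phenotype prevalence 0.2 — the top of the
realistic frequency range with a common phenotype, where sparse-count
LRT p-values are near-continuous and a KS test is meaningful), and
uniformity itself is checked on 1,000 triples per cohort at 8,000 / 4,000.
Parameter recovery uses 20 replicates of the default design for CI
coverage and 5 full-pipeline replicates for candidate sensitivity.

## Known limitations

* Exactly two cohorts; the weighted-Z formula generalizes but the
  interfaces do not yet.
* No phecode hierarchy roll-ups or PheWAS exclusion ranges; controls are
  simply "phecode absent".
* No heterogeneity statistics (Cochran's Q, I²) in the meta-analysis.
* The regression assumes unrelated samples; with real biobank data the
  test backend should be replaced by a whole-genome-regression tool, which
  is why `fit_burden_test()` is the single substitution point.
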