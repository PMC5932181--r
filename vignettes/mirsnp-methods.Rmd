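---
title: "Methods: integrative prioritization of miRNA binding-site variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative prioritization of miRNA binding-site variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsnptools)
```

## The problem

Most disease-associated variants from genome-wide association studies of
autoimmune disease sit in non-coding sequence.  A variant in a 3'
untranslated region can create or disrupt a microRNA binding site (a
*miRSNP*) and thereby change post-transcriptional repression of a disease
gene.  No single binding-site prediction tool is reliable on its own, and a
prediction is only interesting if the variant is actually associated with
disease.  This package implements a staged evidence-integration pipeline:

1. combine per-tool binding-site predictions into one score,
2. keep variants with genome-wide significant GWAS support in at least two
   diseases (directly, or through a linkage-disequilibrium proxy),
3. annotate survivors with published eQTL evidence, and
4. test whether miRNA and target-mRNA expression correlate, overall and
   within homozygote genotype strata.

## Score combination

Each tool reports a raw score on its own scale, so scores are first
standardized *within tool* over the tool's full score set in the current
run (sample standard deviation).  Standardization over the current
candidate universe, rather than a genome-wide reference distribution, makes
the unit self-contained and is the main caveat when comparing runs on very
different candidate sets.

The combination rule is the complement-product ("naive Bayes") form

$$S = 1 - \prod_i (1 - S_i), \qquad S_i \in [0, 1],$$

which treats the tools as independent witnesses: any single confident tool
drives $S$ up, and $S \ge \max_i S_i$ always.  The rule needs unit-interval
evidence values, but z-scores live on the real line.  We map them through
the standard normal CDF, $S_i = \Phi(z_i)$ — monotone, parameter-free, and
exactly the right scale under the within-tool normal reference implied by
z-scoring.  Rank or min–max mappings would also be defensible; the CDF was
chosen because it needs no extra parameters and is smooth at the tails.
Candidates are kept when $S$ strictly exceeds 0.7 (`nbc_threshold`).

A triple scored by fewer than three tools is combined over the tools
present (an absent tool contributes a factor of 1); there is no
minimum-tool requirement beyond one.  Per-tool effect calls (create versus
disrupt) must be unanimous; any disagreement yields an `ambiguous`
consensus, which downstream concordance calls treat as not applicable.
Tools whose native scale runs opposite to "larger = stronger" can be
flagged in `mirsnp_config(score_sign_flip = ...)`; the default flips none.

## GWAS support and the shared-disease rule

A candidate is supported in a disease if it is itself genome-wide
significant ($P < 5 \times 10^{-8}$, strict) or is an LD proxy
($r^2 \ge 0.8$ inclusive, $D' = 1$ within $10^{-6}$) of a significant lead
SNP for that disease.  Multiple studies of one disease are merged by taking
each rsid's minimum p-value — a deliberately simple rule chosen over formal
meta-analysis because the pipeline consumes summary statistics of
heterogeneous provenance.  When several leads proxy the same candidate, the
highest-$r^2$ partner wins, with ties broken by lexicographically smallest
lead rsid so the output is deterministic.  Proxy-supported candidates keep
their own p-value and odds ratio missing: they were not evaluated by the
study, and inventing statistics for them would be misleading.

Only candidates supported in at least two *distinct* disease labels
survive.  Inflammatory bowel disease, Crohn's disease and ulcerative
colitis are three labels and count separately.

The $D'$ requirement can be switched off
(`mirsnp_config(ld_dprime_required = NA)`) for LD tables that do not report
it.

## eQTL annotation and concordance

eQTL records from all sources are pooled and joined to candidate
(rsid, gene) pairs by exact match; records above FDR 0.05 are dropped at
load.  The package requires the loader contract that `direction` is the
*minor-allele* effect on expression — eQTL sources differ in sign
conventions (z-scores, slopes, allele orientations) and reconciling them is
a data-preparation task, not something the joiner can re-derive.

Concordance formalizes the biological reading: the minor allele disrupting
a binding site releases repression, so *disrupt* is concordant with
minor-allele *up*-regulation, and *create* with *down*-regulation.  Mixed
directions across tissues are reported `ambiguous` rather than
majority-voted; no tissue filter is applied, tissue being annotation only.

## Expression correlation

Pearson correlation with the two-sided t test on $n - 2$ degrees of
freedom, significance at $P < 0.05$ without multiple-testing correction
(the published rule this pipeline mirrors); users can correct downstream —
the full correlation table is returned.  Genotype stratification keeps only
reference homozygotes (dosage 0) and minor-allele homozygotes (dosage 2).
A stratum below `min_stratum_size = 3` (the smallest n with a defined
t test) yields a flagged undefined result rather than an error, so batch
runs proceed; zero-variance inputs are flagged the same way.  Expression
matrices are taken as already log2-scale; `read_expression_matrix(...,
log2_transform = TRUE)` applies a `log2(x + 1)` pseudocount for raw-count
input.

Expression concordance again follows the repression logic: a created site
should show a *negative* miRNA–mRNA correlation, a disrupted one a
positive correlation; only significant correlations are judged.

## The packaged candidate table

A published table of 34 autoimmune-disease miRSNPs ships as two plain-text
TSVs (one row per miRSNP–disease association, one per miRSNP–miRNA
prediction), loaded by `load_table2()` into the same report structure the
pipeline emits, so one `summary()` method computes all counts:

```{r fixture}
summary(load_table2())
```

Values are stored exactly as printed: NA p-values stay missing, duplicated
miRNA names are kept (86 distinct names over 90 rows), minor-allele
frequencies above 0.5 are stored as printed (the defining population of
"minor" is not stated in the source), and an indel allele ("AT") is kept
as a plain string.  One fixture row lists a single disease despite the
two-disease rule; it is preserved as printed and simply counts as printed —
the loader reproduces the table, it does not re-filter it.  Distinct-miRNA
counting uses exact printed names (arm suffixes distinguish mature forms),
which reproduces the source's own totals.

## The synthetic-data generator

`simulate_mirsnp_data()` generates every input table with a planted truth
set so the whole pipeline is testable offline.  Defaults define the study
conditions used throughout the package's tests: 20 true miRSNPs among
2,000 scored variants, 12 disease labels, and 309 samples with genotypes
and both expression profiles (the matched-cohort scale of the public
LCL data the pipeline is designed around).

* **Tool scores** are standard normal within tool on each tool's native
  scale; true triples are shifted by 2.5 on the z scale in every tool, so
  the combined score exceeds 0.7 with probability well above 0.99.
* **GWAS**: planted leads draw $-\log_{10} P$ uniformly from [9, 20]; null
  SNPs draw $P \sim \mathrm{Uniform}(0,1)$.  Each truth either is its own
  reported lead or sits in perfect LD ($r^2 = 1$, $D' = 1$) with one;
  decoy LD pairs have $r^2 < 0.8$ and can never qualify.
* **eQTL** records are planted for flagged truths at FDR 0.01 with the
  direction concordant to the planted effect; decoys at FDR below 0.05.
* **Genotypes** are Hardy–Weinberg binomial dosages with MAF uniform in
  [0.1, 0.5]; genotype coverage is a subset of the expression samples, as
  after real cohort matching.
* **Expression** is Gaussian on the log2 scale (noise sd 1).  Coupled
  truths link target mRNA to miRNA with slope −0.8 among minor-allele
  homozygotes only (mirrored sign for disrupted sites), leaving reference
  homozygotes uncoupled — the genotype-dependent correlation the
  stratified analysis is meant to detect.

The generator emulates the *statistical* structure the pipeline assumes;
it does not emulate realistic LD block structure, population
stratification, read-level sequencing noise, or correlated expression
programs.  Passing tests therefore demonstrate correctness of the decision
rules and engines under the assumed structure, not performance on real
cohort data.

False positives under the null are structurally rare: a null triple passes
the score threshold fairly often (the complement product of three uniform
unit scores exceeds 0.7 with high probability), but must additionally be
genome-wide significant in two diseases, and null p-values are uniform —
so the compound event essentially never happens.  This mirrors the real
design, where the GWAS stage, not the prediction stage, carries the
specificity.

## Numerical choices and problem sizes

The combined score is computed as $1 - \exp(\sum_i \log(1 - S_i))$, exact
for $S_i = 1$ ($\log 0 = -\infty$ gives $S = 1$).  Thresholds are strict
or inclusive exactly as documented (`> 0.7`, `P < 5e-8`, `r2 >= 0.8`,
`D' = 1` within 1e-6, correlation `P < 0.05`).  Determinism: generation is
sequential with a single seed; pipeline stages are pure, with explicit
tie-breaks wherever an ordering is needed.

Test and verification sizes are chosen to exercise each property at desk
scale: the combiner is checked against brute force on 10,000 random score
sets; the Pearson engine against a first-principles oracle and a
1,000-replicate null calibration at $n = 100$; the association filter
against a triple-loop oracle on instances of up to 50 SNPs; end-to-end
recovery on the default 20-truth/2,000-variant bundle; the planted
expression slope by regression across 50 generator seeds at 300 samples;
and the truth-free null across 25 seeds at 300 variants.

## Known limitations

* The unit-interval mapping of harmonized scores is a modeling choice;
  the source analysis never states one.
* Gene matching is by symbol string with no alias dictionary.
* Min-p merging across studies ignores sample overlap and winner's curse.
* The correlation stage reports uncorrected p-values by design.
* z-scoring over the current run's candidate universe makes scores
  run-relative.
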