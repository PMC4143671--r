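---
title: "Weighted FDR control for trio-based association scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted FDR control for trio-based association scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfdrtrio)
```

## The problem

Family-based association tests for quantitative traits are robust to
population stratification, but in small trio samples they are
underpowered relative to population-based regression, and a genome-wide
multiple-testing correction compounds the loss. When an *independent*
population-based scan of the same SNPs is available — for example from
the unrelated subset of the same cohort — its p-values carry information
about which hypotheses are worth spending the error budget on.

`wfdrtrio` implements a weighted false discovery rate procedure that
uses the population scan to reweight the family scan, together with the
full surrounding pipeline: PLINK text ped/map input, SNP and individual
quality control, trio extraction, the two association tests, and a
Mendelian simulator for power evaluation.

## The statistical core

For SNP $j$ of $m$, let $p_{\mathrm{fam},j}$ be the trio-based p-value
and $p_{\mathrm{pop},j}$ the population-based one. The weights are
inverse population p-values normalised to sum to $m$:

$$W_j = \frac{m / p_{\mathrm{pop},j}}{\sum_{k=1}^m 1 / p_{\mathrm{pop},k}},$$

and the weighted statistic is $Q_j = p_{\mathrm{fam},j} / W_j$. The
Benjamini–Hochberg step-up rule is applied to the ordered $Q_{(1)} \le
\dots \le Q_{(m)}$: reject every hypothesis with $Q$ at or below the
largest $Q_{(j)} \le \alpha j / m$. With weights summing to $m$ and the
two p-value sources independent, FDR is controlled at level $\alpha$;
with all weights equal to 1 the procedure is ordinary BH exactly, which
the test suite pins down as an identity.

Reported adjusted p-values are the usual suffix minima of
$m\,Q_{(j)}/j$, capped at 1; the step-up comparison itself uses the raw
$Q$, which may exceed 1. The cap only affects the probability-scale
report, never the rejection set (every capped term is $\ge 1$ either
way).

### Numerical choices

* **Zero population p-values.** $1/p$ is unbounded at 0, so population
  p-values are clamped to a configurable floor (default `1e-300`)
  before inversion. The floor preserves the ordering of any p-value a
  floating-point test can produce while keeping weights finite.
* **Ties.** The BH step (delegated to `stats::p.adjust`) is invariant
  to how ties are broken, and results are returned in the caller's row
  order, so output is reproducible bit for bit.
* **Alignment.** `wfdr_adjust()` refuses mismatched or reordered SNP
  ids rather than silently reordering; `wfdr_pipeline()` is the
  merging front end and drops (with a warning) SNPs present in only one
  source, mirroring the merge of family and population panels.
* **Independence.** The weights are only valid when the population
  p-values come from individuals disjoint from the trio sample. This is
  a contract the software cannot verify from p-values alone; the
  documentation and the command-line front end state it.

## The two association tests

**Population arm.** Per SNP, OLS of MAP on an intercept, the requested
covariates (sex, age, medication indicator, principal components — the
package accepts precomputed PC columns, it does not compute them) and
the additive minor-allele dosage, with a two-sided t-test of the dosage
coefficient on the residual degrees of freedom. Missing genotypes and
covariates are handled by per-SNP complete-case deletion.

**Family arm.** Per SNP and trio, the within-family component
$b_i = g_{\mathrm{off},i} - (g_{\mathrm{fat},i} + g_{\mathrm{mot},i})/2$
has mean zero under Mendelian transmission within every family,
whatever the ancestry, so regressing the offspring phenotype on $b$
(with intercept) is immune to population stratification — the test
statistic is unchanged by shifting whole trios' genotypes, which a unit
test asserts algebraically. The slope is tested on $n_{\mathrm{trios}} - 2$
degrees of freedom. Trios carved from one extended pedigree are treated
as independent; that simplification understates the variance slightly
when many trios share parents, and is the main modelling caveat. The
family test deliberately carries no covariates: covariate adjustment
lives in the population arm only.

With `n_perm > 0` the family test instead reports an empirical p-value
from random permutations of $b$ across trios,
$(1 + \#\{|t^\ast| \ge |t|\}) / (n_{\mathrm{perm}} + 1)$. Label
permutation was chosen over sign-flipping of $b$: both are valid
exchangeability arguments, but the sign-flip randomization distribution
of $|t|$ conditions on fourth moments of $b$ and $y$ and can sit
visibly off the $t$ reference at realistic trio counts, whereas label
permutation tracks the asymptotic test closely — the test suite checks
their agreement to within Monte-Carlo error at 50 trios. The asymptotic
test is the default and is what the simulator uses.

## Quality control and data handling

* Dosage is coded against the minor allele (0/1/2), determined from
  allele counts among pedigree founders when parent-child links exist,
  otherwise among all individuals; a tie at 50% frequency is broken
  toward the lexicographically smaller allele.
* SNP QC drops missingness strictly above the threshold, then MAF
  strictly below it, in that order; boundary values survive both
  filters. Defaults are 0.05 for both, and each panel is QC'd
  separately before panels are merged.
* Individual QC is a missing-fraction cutoff (default 0.1) plus an
  explicit exclusion list for externally flagged outliers. The 0.1
  default is a conventional placeholder, not an estimate of anything.
* Panel merging intersects SNP ids and reconciles allele orientation,
  flipping dosages where the panels disagree on which allele is minor
  and excluding SNPs whose allele sets cannot be reconciled.

## What the simulator emulates

`simulate_trio_genotypes()` draws parental genotypes from
Hardy–Weinberg proportions at a single MAF and transmits alleles
Mendelianly; `simulate_population_genotypes()` draws an unrelated
cohort the same way. Phenotypes follow the linear model
$y = \beta \cdot g + \alpha + \varepsilon$, $\varepsilon \sim N(0,
\sigma^2)$. `run_replication()` builds one full dataset — trio families
sharing one phenotype across $m$ SNPs, and a *fresh* population cohort
per SNP so SNPs stay mutually independent — and runs the entire
pipeline: trio test, population regression, weights, ordinary BH and
weighted BH. Because each SNP's population cohort has its own phenotype
vector, the replication engine calls the shared vectorised regression
core with a per-SNP phenotype matrix; a unit test pins that core to
`population_assoc()` output on a shared-cohort case so the two routes
cannot drift apart.

Defaults are 250 trio families, a 250-person cohort per SNP, one causal
SNP and $\alpha = 0.05$ — the reference design — with MAF 0.3,
$\sigma = 1$ and intercept 0 where the design leaves the values open;
these are ordinary choices for a common variant with a moderate
quantitative effect, set once and reported alongside every result. The
desk-scale default of 4,999 null SNPs and 200 replications keeps a full
power curve recomputable in minutes; the package's own calibration and
power checks use 1,000-SNP nulls at 500 replications and 5,000-SNP
power runs at 400–500 replications per effect size, and the full
49,999-SNP, 1,000-replication design is reachable through the same
configuration object. A `fast_null` mode draws null-SNP p-values
directly from Uniform(0, 1) instead of simulating their genotypes — an
approximation (flagged as such) that makes very large $m$ affordable;
a test checks it against the full pipeline at matched settings.

What the simulator does **not** emulate: linkage disequilibrium between
SNPs, allele-frequency spectra, genotyping error, missingness,
pedigrees deeper than trios, shared environment, or ancestry structure.
Passing power and calibration checks therefore demonstrate the
procedure's behaviour under independence and correct model
specification, not its behaviour on real cohort data, where correlated
tests make both FDR procedures more variable.

Under this model the weighted procedure dominates ordinary FDR at
moderate effect sizes for a transparent reason: with one causal SNP,
the population scan's $1/p$ for that SNP usually dwarfs the summed
inverses of the null SNPs, so the causal weight approaches $m$ and its
family p-value is effectively tested at a nearly uncorrected threshold,
while null weights shrink harmlessly. At very small $\beta$ the
population scan carries no signal and the two procedures coincide up to
noise; at large $\beta$ both saturate.

## Determinism

Every simulator entry point is a pure function of its configuration
once `seed` is set: `power_study()` seeds a single stream and runs all
effect sizes and replications from it, so identical configurations give
byte-identical power tables. The command-line front end exposes one
global `--seed` and records it, together with parameter values and
input file digests, in a `run_manifest.json` next to each output.

## Known limitations

* FDR control with data-driven weights holds under independence of the
  two p-value sources; sample overlap between the trio and population
  sets silently breaks it.
* The inverse-p weighting is the only scheme provided (no grouped,
  monotone or IHW-style weights), and no $\pi_0$ estimation or adaptive
  variant is attempted.
* Only PLINK *text* ped/map input is supported (no bed/bim/fam, VCF or
  dosage formats), and only autosomal, biallelic SNPs.
* The trio test's independence assumption across trios from one
  pedigree, noted above.
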