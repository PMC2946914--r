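---
title: "Methods: EMR phenotyping and GWAS of red blood cell traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMR phenotyping and GWAS of red blood cell traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electronic medical records (EMR) hold decades of complete-blood-count
results, which makes them an attractive source of quantitative phenotypes
for genome-wide association studies of the six red-blood-cell (RBC)
traits: hemoglobin (Hgb, g/dL), hematocrit (Hct, %), RBC count
(x10^12/L), and the derived indices MCV (fL), MCH (pg) and MCHC (%). But
clinical measurements are not research measurements: values drawn during
hospitalizations, active malignancy, marrow-suppressing therapy or after
major blood loss do not reflect a patient's constitutive trait level.
`emrgwas` implements the full path from raw multi-source lab extracts to
association statistics — and, because real EMR data cannot be
redistributed, a synthetic-data generator with per-value ground truth so
that every stage is testable.

## The phenotyping algorithm

1. **Integration.** Raw source tables are merged; records are mapped from
   local test codes to traits, non-numeric results (e.g. "QNS") dropped,
   duplicates on (patient, accession, trait) collapsed, and unit strings
   checked against a per-trait whitelist. A load report accounts for every
   input record — the kept/dropped counts must always reconcile.
2. **Inpatient rule.** A value is inpatient iff some episode of the same
   patient satisfies admit date <= sample date <= discharge date, both
   ends inclusive; dates are compared as whole days. Inpatient values are
   removed unless all of a patient's values for a trait are inpatient, in
   which case they are retained. We apply this rescue per (patient, trait)
   rather than per patient: it is the conservative reading that keeps each
   trait analyzable, and the per-patient variant remains available as an
   argument.
3. **Exclusion windows.** Coded events (ICD-9-CM, procedural ICD-9,
   CPT-4) matching a registry entry open an interval
   `[event - lookback, event + duration]`; chronic categories
   (malignancy, cirrhosis, hereditary anemia, malabsorption, transplant)
   are unbounded on the right. A value is excluded iff its date lies in at
   least one interval of its patient, and every covering category and
   triggering event id is recorded, so the audit log alone reconstructs
   the kept set. Window lengths are configuration, with shipped defaults
   (chronic: lookback 30 d; medications and surgery: 90 d forward, no
   lookback) chosen to be clinically conservative — no authoritative
   lengths exist, so they are declared assumptions, not estimates.
4. **Medication mentions.** Clinical notes are scanned for a lexicon of
   chemotherapeutic/immunosuppressive generic and brand names,
   case-insensitively on word boundaries, with multi-word brand names
   matched as phrases. Negation handling is off by default: for an
   exclusion filter, sensitivity is the safer error direction. The
   shipped registry and lexicon are illustrative examples, documented as
   non-authoritative; production use requires locally curated lists.
5. **Patient drop.** A patient leaves the cohort only when no value of
   any trait survives. Because a CBC panel yields six traits per draw and
   patients have many draws, value-level exclusion rates near one third
   typically translate into single-digit patient loss.

## Aggregation and the association model

The analysis phenotype is the **median** of a patient's kept values per
trait (even counts: mean of the two central order statistics). Cohort
summaries report mean ± SD and [Q1, median, Q3] using linear-interpolation
quantiles (R type 7) — the rule is pinned so the numbers are reproducible
bit for bit. Group contrasts use Welch's unequal-variance t test for
continuous variables and a chi-square test without continuity correction
for proportions; both are deliberate defaults where no single convention
is canonical.

Association is ordinary least squares of the phenotype on minor-allele
dosage with age, sex and PAD (peripheral arterial disease) case status as
covariates:

  y_i = b0 + b g_i + c1 age_i + c2 sex_i + c3 pad_i + e_i.

The SE uses the residual variance with denominator n - p; P values come
from the t distribution with the residual df (exact at small n,
indistinguishable from normal at n ~ 3000). The reported variance
explained is the **partial R-squared**, the incremental fit of the dosage
over the covariate-only model, computed as t^2 / (t^2 + df). Note its
estimand is the variance fraction of the *covariate-adjusted* trait;
calibration experiments that target a nominal variance fraction therefore
plant effects on traits without simulated covariate structure (the model
still adjusts for the covariates). Missing genotypes are handled by
complete-case analysis per marker; markers monomorphic after
complete-case removal are carried with a `constant_genotype` flag, never
silently dropped. A vectorized residualized solver handles
missingness-free markers and is tested to agree with the per-marker QR
fit to 1e-10.

Genomic control uses lambda = median(chi-square) / 0.4549364; adjusted P
values are recomputed from chi-square/lambda, and lambda < 1 is never
applied (no deflation), which is standard practice when genomic control
is a robustness check rather than a correction.

## Genotype quality control

Markers and samples pass QC only when strictly above the thresholds: SNP
call rate > 0.98, sample call rate > 0.98, MAF > 0.05, exact HWE
p > 0.001. The Hardy-Weinberg test is the Levene-Haldane exact test:
two-sided by probability-mass ordering of the heterozygote count under
its conditional distribution given the allele counts, computed by the
stable log-scale ratio recurrence. The step order — external sample
exclusions, sample call rate, marker call rate, MAF, HWE — is fixed and
logged because the order changes the counts. Ancestry, relatedness and
duplicate-concordance screening need external reference data and are
consumed as a supplied sample-exclusion list.

## Statistical power

For a QTL explaining a fraction r2 of trait variance in n samples, the
additive test statistic is asymptotically noncentral chi-square with 1 df
and noncentrality n r2 / (1 - r2); power is the upper tail beyond the
central (1 - alpha) quantile. A simulation route (HWE genotype at a given
MAF, trait with variance fraction exactly r2, full model fit) is provided
as a cross-check; the two agree within Monte-Carlo error. At the design
point n = 3000, r2 = 0.015, alpha = 5e-8 the analytic value is 0.905.
If the QTL fraction is defined on the latent trait while the analyzed
phenotype carries measurement noise (reliability ~0.93 for a median of
six draws at intraclass correlation 0.7), the attenuated power is ~0.86 —
the package computes the unattenuated value and leaves attenuation to the
user's reliability assumptions.

## What the generator emulates — and what it does not

The generator is the package's ground-truth instrument, not a cosmetic
fixture. Design choices:

- **Hgb/Hct/RBC are primary; the indices are derived** per draw via
  MCV = 10 Hct/RBC, MCH = 10 Hgb/RBC, MCHC = 100 Hgb/Hct, before small
  independent reporting noise. This guarantees the physiological coupling
  of a CBC panel; with noise off the identities (and hence
  MCHC = MCH/MCV x 100) hold exactly.
- Default trait means/SDs reproduce a vascular-clinic cohort profile
  (Hgb 14.1/1.3, Hct 41.0/3.6, RBC 4.5/0.4; age 63.2/9.5, 62% male, 49%
  PAD). Because the published index means are rounded, they are not
  exactly consistent with the identities: propagating the printed
  rounding of the primary values bounds the achievable index means
  (e.g. |MCV - 90.5| <= 1.0), and the tests check at those bounds.
- Repeated measures have a configurable intraclass correlation
  (default 0.7 — a plausible value for adult RBC traits, not an estimate
  from any dataset), with the stable and draw-level components sharing a
  strongly coupled correlation structure across the measured trio.
- Covariate effects and planted genetic effects live in the stable
  between-patient component, and the random component is rescaled so the
  configured SD stays the marginal SD. Planted effects use
  beta = sqrt(r2 var / (2 p (1 - p))) at the realized allele frequency.
  An effect planted on one measured trait propagates to the indices
  through the identities — implied pleiotropy that is physiologically
  sensible but means index-level effect sizes are emergent, not
  configured.
- Confounding is planted so that the value-level funnel looks like a real
  EMR cohort: treatment exposure and hospitalizations are anchored on
  draw dates (labs are drawn at the visits where care happens), chronic
  diseases are dated uniformly, and with default rates roughly a quarter
  to a third of values are excluded while only a few percent of patients
  are lost.
- **Truth labels are computed by an independent code path**: a direct
  per-value scan over raw events, episodes and notes, with its own
  tokenizing note matcher — no interval construction, merging or regex
  shared with the filter. The filter is required to match it exactly on
  every fixture.
- Genotypes are independent HWE markers; allele frequencies uniform on
  [0.05, 0.5]. No linkage disequilibrium, no longitudinal drift, no
  sex-chromosome genetics — so passing tests demonstrate algorithmic
  correctness and statistical calibration, not robustness to LD
  structure, batch effects or real clinical-text complexity.

## Numerical choices

- Dates are integer day numbers throughout; all window and episode
  comparisons are closed-interval on whole days.
- The exact HWE recurrence runs on the log scale and normalizes at the
  end; ties in the two-sided mass ordering use a 1e-7 relative tolerance,
  the convention that makes p = 1 exact at the distribution's mode.
- One master seed derives fixed per-stage seeds, so any stage can be
  regenerated independently and whole runs are byte-identical.
- Problem sizes in the test suite (3000 x 10000 null scan, 200 recovery
  replicates, 50 filter fixtures, exhaustive HWE tables to total 50) were
  chosen so the whole suite completes in a few minutes on one CPU while
  keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

- The illustrative registry/lexicon are small; real deployments need
  curated code sets, and NLP here is whole-word matching, not clinical
  NLP (no sections, temporality or dosage parsing).
- Window lengths are assumptions; sensitivity to them should be explored
  with the monotonicity property (larger windows exclude strictly more).
- Repeated measures are collapsed to medians; longitudinal modeling of
  multiple measurements is out of scope.
- No mixed models or kinship correction: population structure is only
  diagnosed (lambda) and robustness-checked (GC adjustment), matching
  the single-site design the package targets.
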