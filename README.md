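# emrgwas

Quantitative-trait GWAS from electronic-medical-record (EMR) phenotypes,
end to end: multi-source lab integration, a billing-code + clinical-note
exclusion algorithm with a complete audit trail, median aggregation of
repeated measures, genotype quality control with the exact
Hardy–Weinberg test, and single-SNP additive association with genomic
control — exercised entirely on a bundled synthetic-data generator with
per-value ground truth.

The package is aimed at statistical-genetics and clinical-informatics
groups who phenotype quantitative traits (here the six red-blood-cell
traits: Hgb, Hct, RBC count, MCV, MCH, MCHC) from clinical repositories
and need every filtering decision to be reproducible and testable.

## The model

For patient *i*, the analysis phenotype is the median of the kept lab
values per trait. Association per marker is ordinary least squares

&nbsp;&nbsp;*y*ᵢ = β₀ + β *g*ᵢ + γ₁ ageᵢ + γ₂ sexᵢ + γ₃ PADᵢ + εᵢ,

with *g* the minor-allele dosage (0/1/2), two-sided P from the t
distribution, and variance explained reported as the partial R² =
t²/(t² + df) over the covariate-only model. Marker QC keeps SNPs with
call rate > 98%, MAF > 0.05 and Levene–Haldane exact HWE p > 0.001;
samples need call rate > 98%. Inflation is diagnosed with
λ_GC = median(χ²)/0.4549 and P values can be GC-adjusted (never
deflated). Power for a QTL explaining a fraction r² of variance uses the
noncentral χ²₁ tail with noncentrality n·r²/(1 − r²), with a simulation
cross-check.

The exclusion algorithm turns coded clinical events (ICD-9-CM,
procedural ICD-9, CPT-4) and lexicon-matched medication mentions in
notes into per-patient exclusion windows (chronic conditions:
right-unbounded; medications/surgery: 90 days forward by default);
values inside any window, or drawn between admission and discharge of a
hospitalization, are excluded — with machine-readable reasons and
triggering event ids for every decision.

## Worked example

The numbered scripts under `analysis/` run a complete study on a
synthetic cohort (800 patients, ~33,500 lab values, 2,000 markers, three
planted QTLs):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_extract_filter.R
Rscript analysis/03_aggregate_qc.R
Rscript analysis/04_association.R
Rscript analysis/05_power_replication.R
```

Stage 2 prints the phenotyping funnel and checks every decision against
the generator's independent truth labels:

```
inpatient-excluded values: 2418 of 33474
NLP medication events: 336 from 527 notes
window-excluded values: 6534
patients dropped (no values left): 63 of 800
decision vs truth concordance: 100.0%
```

About 27% of values are excluded but only 8% of patients are lost —
repeated panels rescue almost everyone. Stage 4 then recovers all three
planted loci at genome-wide significance:

```
 trait      snp chrom      bp   eaf   beta     se         p partial_r2
   HGB snp01500    17 1277773 0.123  0.682 0.0798  7.42e-17     0.0907
   MCH snp00137     2 1297102 0.246  0.503 0.0798  5.25e-10     0.0514
   ...
planted markers recovered at 5e-8: 3 of 3
```

(the planted RBC-count QTL also surfaces on MCV/MCH — effects on a
measured trait propagate to the derived indices through the
hematological identities). Stage 5 prints the power surface; at the
n = 3000 design point a QTL explaining 1.5% of variance is detected
with probability 0.905 (analytic) vs 0.905 ± 0.007 (simulation), and
effect-direction harmonization of the bundled reference associations
against the cross-study catalog is concordant for all 6 directly
comparable rows, including the one reported on the opposite allele.

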