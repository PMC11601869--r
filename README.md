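# cyclaging

Detection of **cyclical aging patterns** in four-timepoint omics data.

Tissue aging is usually modelled as monotone decline. An alternative
hypothesis for the mammary gland is *cyclical aging*: glands at 11 and 19
months of mouse age resemble each other molecularly while glands at 3 and 14
months form the opposing phase, so the tissue alternates between a
pro-oncogenic state (the ages corresponding to the 45- and 65-year peaks of
human breast-cancer incidence) and a rejuvenated state. `cyclaging` provides
the statistical toolkit to test this on replicated 4-age designs, for
computational biologists working with bulk expression, ECM proteomics,
single-cell counts and clinical cohorts:

* **Cyclic gene calling** — per-transition log2 fold changes with unpaired
  (Welch) t-tests and Benjamini–Hochberg q-values; a gene is cyclic when its
  three transition signs alternate (up–down–up or down–up–down) with every
  |log2FC| ≥ τ and every q ≤ q_max.
* **Cyclic protein calling** — presence/absence with a detection floor and a
  majority-of-replicates rule; a protein is cyclic when detected only at the
  2nd and 4th ages of the designated genotype.
* **Timepoint clustering** — average-linkage clustering of per-age profiles
  on correlation distance; the 2-cluster cut tests the 3/14 vs 11/19 pairing.
* **Cell-type annotation** — deterministic marker-panel gating (HS, AV,
  HS-AV, ME) with log2 feature-sum scores, the half-max cutoff convention,
  and luminal-denominator composition ratios.
* **Signature scoring** — single-sample gene-set enrichment (ssGSEA
  running-sum score, α = 0.25), top-tertile stratification, hypergeometric
  over-representation for gene lists.
* **Cohort statistics** — an exact Hartigan dip statistic with Monte-Carlo
  (uniform-null) p-values for age-at-diagnosis bimodality, Kaplan–Meier
  curves, the two-group log-rank test, and two-sided Fisher exact tests.
* **Synthetic-data generators** — seeded simulators for all four data kinds
  with planted truth, so every detector has a closed-loop recovery test, and
  a `run_pipeline()` driver whose manifest makes any run byte-reproducible.

## Worked example

Simulate the published design (4 ages × 5 replicates), call cyclic genes,
and check the phase pairing:

```r
library(cyclaging)

sim   <- simulate_timecourse(n_genes = 1000, n_cyclic_udu = 30,
                             n_cyclic_dud = 30, amplitude = 2,
                             noise_sd = 0.5, seed = 42)
calls <- call_cyclic_genes(transition_stats(sim), tau = 1, q_max = 0.05)
dplyr::count(calls, orientation)
#>   orientation     n
#> 1 DUD            15
#> 2 UDU            21

cluster_timepoints(timepoint_profiles(sim))
#> Timepoint clustering (correlation distance, average linkage)
#> 2-group partition: { 3m, 14m } vs { 11m, 19m }
```

Of 60 planted cyclic genes, 36 survive the joint amplitude-and-significance
rule at these noise settings, with orientations recorded per gene and zero
false calls among the 940 null genes; the per-age transcriptome profiles
pair 3 with 14 months and 11 with 19 months, the cyclical-aging signature.

Cohort stage — score a signature per patient, split at the top tertile, and
test age bimodality and survival:

```r
cohort <- simulate_cohort(n_samples = 300, seed = 42)
scores <- tertile_stratify(score_samples(cohort$expression,
                                         cohort$signature_genes))
d <- dplyr::left_join(cohort$cohort, scores, by = "sample_id")

dip_test(d$age_years[d$group == "high"], n_boot = 999, seed = 1)
#> Hartigan dip test of unimodality
#>   dip = 0.11396,  n = 100,  Monte-Carlo p = 0.001 (999 uniform null draws)
dip_test(d$age_years[d$group == "low"], n_boot = 999, seed = 2)
#> Hartigan dip test of unimodality
#>   dip = 0.01567,  n = 200,  Monte-Carlo p = 0.997 (999 uniform null draws)
logrank_test(d)
#> Log-rank test: chi-square = 12.5897 (1 df), p = 0.0003879
```

The signature-high third of the cohort shows the planted bimodal (45/65)
age-at-diagnosis distribution (dip rejects unimodality at p = 0.001), the
low group does not, and the high group's survival is significantly worse —
the full cohort-level readout of cyclical aging.

See `vignettes/cyclical-aging-methods.Rmd` for the models, parameter
conventions and design decisions, and `run_pipeline()` for the end-to-end
driver (simulate → detect → annotate → score → cohort) with a reproducibility
manifest.

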