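---
title: "Detecting cyclical aging patterns: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cyclical aging patterns: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclaging)
library(dplyr)
```

## The scientific question

Mammary gland aging is usually described as a monotone involution. An
alternative hypothesis is *cyclical aging*: glands at 11 and 19 months of
mouse age (roughly 45 and 65 human years) resemble each other molecularly,
while glands at 3 and 14 months form the opposing phase — so the tissue
alternates between a "pro-oncogenic" state and a "rejuvenated" state rather
than drifting in one direction. This package implements the quantitative
machinery needed to test that hypothesis on four-timepoint designs:

1. calling **cyclic genes** whose expression zigzags across the four ages;
2. calling **cyclic ECM proteins** present only in the 11/19-month phase of
   one genotype;
3. checking that per-timepoint transcriptome profiles **hierarchically pair**
   3/14 against 11/19;
4. annotating mammary epithelial cell types from marker panels and tracking
   their **composition ratios** over age;
5. scoring a cyclic gene signature per patient by **ssGSEA**, splitting a
   cohort at the **top tertile**, and testing **age-at-diagnosis bimodality**
   (Hartigan's dip) and **survival separation** (Kaplan–Meier, log-rank).

Because the motivating study deposited no raw data, every stage is validated
against seeded synthetic data with planted truth; the generators are
first-class, tested code.

## Cyclic gene calling

For a gene measured at ordered ages $t_1 < t_2 < t_3 < t_4$ with $r$
replicates each, the three adjacent transitions get a log2 fold change
(difference of replicate means), a two-sided unpaired t-test (Welch by
default) and a Benjamini–Hochberg q-value computed across genes *within* each
transition. A gene is cyclic when its transition signs alternate —
up–down–up (`UDU`, high in the 11/19 phase) or down–up–down (`DUD`) — and
every transition clears both an amplitude threshold $\tau$ and a
significance threshold on q.

Parameter defaults and rationale:

* $\tau = 1$ log2 unit. The source analysis states no amplitude threshold,
  so it is exposed, logged in the call object, and defaulted to a two-fold
  change per transition.
* $q_{\max} = 0.05$, the conventional FDR cut also used for the proteomics.
* Welch (unequal variance) is the default because pooling assumptions are
  never stated; the pooled Student test is available via `var_equal = TRUE`.
* Both orientations are called and recorded. The narrative description of
  the pattern ("cycles down then up") is ambiguous about the starting
  direction, and the protein result (present at 11 and 19 months) suggests
  the mirror orientation; neither is privileged.
* Degenerate inputs: two zero-variance groups with equal means give $p = 1$;
  with different means $p = 0$ (the noise-free planted case).

Raising $\tau$ or lowering $q_{\max}$ can only remove calls — a monotonicity
property the test suite checks — and negating the matrix swaps the two
orientations exactly.

## Cyclic protein calling

Decellularized-gland proteomics produces intensities with many missing
values. Detection is presence-based: a protein is *detected* in a
genotype-by-age block when at least $k$ replicates are non-missing at or
above a detection floor, with $k = \lceil r/2 \rceil$ (majority rule) by
default, since no peptide-level threshold is stated in the source. A protein
is *cyclic* when it is detected at the 2nd and 4th ages in the designated
genotype, not detected at the 1st and 3rd there, and not detected anywhere
in the control genotype. The call depends on intensities only through
threshold crossings, so it is invariant to replicate order and to any
order-preserving rescaling above the floor.

With 20% missing-at-random dropout and five replicates, the majority rule
detects a truly present block with probability
$P(\mathrm{Bin}(5, 0.8) \ge 3) = 0.942$; a planted cyclic protein must be
detected at both phase ages, so per-protein recall is about
$0.942^2 = 0.89$. Two-group differential abundance (Welch t on log2
intensities, BH across tested proteins, $q < 0.05$) is provided for
intensity-level contrasts; proteins with fewer than two observed replicates
in either group are reported as untested rather than silently dropped.

## Timepoint clustering

Per-age mean profiles over all genes are clustered with average linkage on
correlation distance ($1 - r$), the standard clustergram configuration; the
2-cluster cut is reported as an unordered partition. Under cyclical aging
the partition is $\{3, 14\}$ vs $\{11, 19\}$; under monotone drift the cut
is always contiguous in time (typically splitting off the farthest
endpoint), so the phase-matched partition cannot arise from drift. Ties
merge lowest-index first (the `hclust` convention), and a constant profile
is an error naming the offending age, since its correlation is undefined.

## Cell-type annotation

The interactive cluster gating of the original single-cell analysis is
replaced by a deterministic score-based rule so that results are exactly
reproducible. Each cell gets a $\log_2(1 + \text{panel count sum})$ score
for the hormone-sensing (HS), alveolar (AV) and myoepithelial (ME) panels;
the label is the arg-max panel provided its score reaches the panel's
half-max across cells — the only cutoff convention the source states, reused
here. Cells whose HS and AV scores both pass and lie within a 25% relative
margin are the mixed lineage HS-AV; the margin is not defined operationally
in the source, so it is exposed as a parameter. Proliferating and regulon
gates use the half-max feature-sum rule directly, and their conjunction
flags PPBC-like cells. The nonstandard marker symbol `Bud1` is kept verbatim
from the source feature list; absent genes are skipped with a warning.

Composition ratios use total luminal cells (HS + AV + HS-AV) as the common
denominator, so the three luminal ratios sum to 1 by construction and ME/LE
is unconstrained.

## Signature scoring and cohort statistics

**ssGSEA.** Genes are ranked by decreasing expression (ties broken by stable
gene-id order); the score is the *sum* of running deviations between the
weighted cumulative mass of set genes ($|N - i + 1|^\alpha$, normalised over
the set) and the uniform mass of non-set genes. The sum-of-deviations (not
max-deviation) form is the single-sample convention. $\alpha = 0.25$
follows common ssGSEA practice; the source states neither $\alpha$ nor a
normalisation, so no cross-sample rescaling is applied — the downstream
tertile split is rank-based, making rescaling irrelevant. Mouse-to-human
ortholog mapping is left to a user-supplied two-column table; no ortholog
database is bundled.

**Tertile split.** The top $\lceil n/3 \rceil$ scores are `high`, the rest
`low`; boundary ties resolve by stable sample-id order with a warning.

**Dip test.** The Hartigan–Hartigan dip — the minimal sup-distance between
the empirical CDF and the nearest unimodal CDF — is computed exactly (to
bisection tolerance $10^{-13}$) by a feasibility search: for a candidate
band half-width, a unimodal fit exists iff some mode knot admits a convex
chain through the lower/upper bands to its left and a concave chain to its
right, with compatible values at the junction; the minimal feasible
half-width is found by bisection. The p-value is Monte-Carlo calibrated
against uniform samples of the same size — the classical, slightly
conservative calibration — rather than interpolated lookup tables, which
keeps the test seedable and dependency-free. A precomputed null table
(`dip_null()`) can be shared across many tests of the same sample size.

**Survival.** Kaplan–Meier curves and the two-group log-rank test wrap the
`survival` package (product-limit estimate, events before censorings at tied
times, hypergeometric variance with ties grouped); the test suite pins them
to hand-computed oracles. Fisher's exact test for clinico-pathological
contingency uses the two-sided point-probability rule. Survival times keep
whatever unit the input uses; no conversion is attempted.

**Over-representation.** Enrichment of a gene list against user-supplied GMT
collections is a local hypergeometric upper-tail test with BH adjustment —
a deterministic, offline replacement for web-service enrichment tools.

## The synthetic-data generators

The generators emulate the study conditions so that each detector has a
closed-loop recovery test:

* `simulate_timecourse()` — 4 ages (3, 11, 14, 19 months), 5 replicates, the
  published design size. Planted cyclic genes alternate by `amplitude` (2
  log2 units by default) around a gene-specific baseline
  ($\mathcal{N}(6, 2^2)$ log2 units, typical of log-scale RNA-seq
  abundances); replicate noise is i.i.d. Gaussian, 0.5 log2 units by
  default. The baseline spread matters: it induces the strong inter-age
  correlations real transcriptomes show, on top of which the planted cyclic
  component drives the 3/14 vs 11/19 pairing.
* `simulate_proteome()` — two genotypes, 16 planted phase-restricted
  proteins (the reported count), ~300 background proteins, log2 intensities
  $\mathcal{N}(20, 1.5^2)$ over a floor of 15, and MCAR dropout applied to
  every present measurement, planted and background alike. Intensity-
  dependent dropout is deliberately out of scope: MCAR is the simplest null
  the presence-caller must survive.
* `simulate_cells()` — cells of four types with a planted per-age
  composition that alternates between phases; a cell expresses each own-
  panel marker with probability 1 by default at count
  $1 + \text{Poisson}(9)$, and other genes at a low background rate. With
  zero background the construction is separable and annotation recovers
  every label, which the tests assert exactly.
* `simulate_cohort()` — ages from a 45/65-year bimodal Gaussian mixture for
  the signature-high third and a unimodal 65-year component for the rest;
  exponential survival with hazard 0.10/yr vs 0.05/yr (hazard ratio 2) and
  independent exponential censoring at 0.04/yr; signature genes up-shifted
  by 2 log2 units in high patients.

What the generators do **not** model: library-size variation, count-level
(negative binomial) noise, batch effects, doublets, ambient RNA,
intensity-dependent missingness, and competing risks. Passing tests
therefore demonstrate correctness of the statistical machinery and
recoverability of planted structure under idealised noise — not robustness
to every artefact of real data.

## Numerical choices and reproducibility

* All randomness flows from explicit seeds; generators restore the caller's
  RNG state. `run_pipeline()` derives a named sub-seed per stage from one
  master seed and writes a manifest (parameters, seed, version, checksums);
  a rerun with the same seed is byte-identical, which the tests verify.
* Test and simulation sizes are chosen to make Monte-Carlo error small
  relative to the asserted margins while keeping the default suite fast:
  e.g. 20 seeds × 2000 genes for gene recovery, 100 seeds for protein
  recovery and timepoint pairing, 200/500 seeds for dip power/size with a
  shared 999-draw null table, 1000 simulations for the log-rank type-I
  check.
* The dip statistic is validated in two independent ways: exact closed-form
  anchors (two points give 0.25; equally spaced points give $1/(2n)$) and a
  definitional linear-programming oracle over all candidate mode knots,
  solved by an external exact LP solver in the test suite.

## Known limitations

* Cyclic calling is specific to the 4-timepoint, sign-alternation design; it
  is not a general periodicity test (no cosinor/harmonic modelling).
* The dip computation is $O(m^2 \log 1/\varepsilon)$ per sample ($m$ unique
  values), comfortably fast for cohort-sized samples but not tuned for
  $n \gg 10^4$.
* The uniform-null dip calibration is conservative for peaked unimodal
  alternatives; power statements in the tests are tied to the stated
  mixture separations.
* Marker panels are mouse symbols; applying them to other species requires
  the user's own ortholog mapping, as does the mouse-to-human signature
  transfer.
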