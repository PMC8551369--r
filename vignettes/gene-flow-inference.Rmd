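---
title: "Gene-flow inference in small mapped plant populations: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-flow inference in small mapped plant populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinflow)
```

This vignette is the package's account of its science: what is being
estimated, which conventions were chosen where the literature leaves room,
and what the validation machinery does and does not establish. The running
example is a small stand of a hermaphroditic tropical tree (~100 mapped
adults, a few dozen seedlings, thousands of ddRAD SNPs) — the regime for
which every default in this package was chosen.

## 1. The two routes to dispersal

Gene flow in a plant population can be estimated **directly**, by assigning
parents to seedlings and measuring the realized pollen and seed movement,
or **indirectly**, from the spatial decay of relatedness accumulated over
many generations. The two need not agree: direct estimates reflect the
contemporary, possibly fragmented landscape, indirect ones the historical
population. Comparing them is the scientific payoff, and both are
implemented here over a shared genotype container (`genotype_matrix`:
individuals × biallelic loci, alternate-allele dosage 0/1/2, `NA`
missing).

## 2. Filtering and the MD × MAF grid

SNP filtering settings are treated as an experimental factor, not a fixed
preprocessing step. `make_grid_datasets()` / `run_grid()` rebuild the data
set for every combination of a missing-data ceiling (MD) and a MAF floor
and re-run the analyses per cell, because the motivating analysis showed
that robustness to these settings must be demonstrated per data set rather
than assumed ("no rule of thumb").

Within a cell, `apply_filters()` applies, in order: MD ceiling → MAF floor
→ one SNP per RAD locus → exact Hardy–Weinberg screen → pairwise LD screen.
The order is configurable; this default mirrors the common
assembly-then-population-genetics workflow in which per-locus quality
filters precede the statistical screens. Conventions worth knowing:

* Thresholds are inclusive (a locus at exactly the MAF floor is kept); MAF
  is computed over non-missing genotypes only.
* The one-SNP-per-locus rule keeps the lowest-position SNP of each
  RAD-locus group (the `CHROM` field of a de novo VCF); without a grouping
  key every SNP is its own locus.
* The Hardy–Weinberg test is the exact conditional (Levene) test; the
  p-value is the summed probability of heterozygote counts no more likely
  than the observed one given the allele counts. Monomorphic loci return 1.
* The LD screen uses the composite genotypic correlation r² with the
  χ²₁ approximation on n·r² over complete pairs. The EM-based
  likelihood-ratio test used by some packages would serve the same
  pass/fail role; the composite test was chosen because it is exact on
  dosages, fast at grid scale, and needs no phasing assumptions. Pairs
  with fewer than three complete observations or a constant column are
  flagged and retained.
* "Sequential Bonferroni" is implemented as Holm's step-down procedure
  (`stats::p.adjust(method = "holm")`), its standard modern reading; the
  later member of each flagged LD pair is dropped.

## 3. Relatedness estimators

Three pairwise estimators are provided, all combined across loci as ratios
of sums (sum of per-locus numerators over sum of per-locus denominators,
restricted to loci where both pair members are genotyped) — the convention
that makes multilocus estimates well-behaved when loci differ in
information content, and the one used by the standard SGS software.

* **Loiselle kinship**: per-locus numerator
  (xᵢ−p)(xⱼ−p) + p(1−p)/(N−1), denominator p(1−p), with x the individual
  allele fraction and N the number of frequency-group individuals
  genotyped at the locus.
* **Ritland kinship**: Σₐ xᵢₐxⱼₐ/pₐ − 1 per locus with unit denominator;
  known to be downward biased in the presence of very rare alleles (a
  property the test suite checks directionally).
* **Queller–Goodnight relationship**: the two directional estimates are
  symmetrized by pooling numerators and denominators. Pairs whose pooled
  denominator is zero (e.g. a lone shared heterozygous locus at p = 0.5)
  are undefined and flagged.

**Frequency-group convention.** Allele frequencies are estimated from the
full supplied matrix, *including* the focal pair, unless
`freq_individuals` narrows the group. This matters: the Loiselle
correction term p(1−p)/(N−1) is constructed to offset the sampling
covariance between an individual and a frequency estimate that contains
it. With frequencies from an external reference panel the correction
overshoots by roughly 1/(2N) + 1/(N−1) on the kinship scale (~+0.015 at
N = 100), which would visibly bias calibration; with the pair inside the
frequency group the bias is O(1/N_total). The pedigree calibrations below
validate this choice.

**Calibration.** `simulate_pedigree_pairs()` draws founder genotypes under
Hardy–Weinberg and walks the minimal pedigree of a named relationship.
Expected kinship: parent–offspring and full sibs 0.25, half sibs 0.125,
first cousins 1/16, first cousins once removed 1/32 ≈ 0.0312, second
cousins (shared great-grandparental couple) 1/64 ≈ 0.0156. A
nomenclature note: field usage sometimes labels the 1/32-kinship pedigree
"second cousins" (1/32 is also the *relationship* coefficient of true
second cousins); both pedigrees are provided under unambiguous names, and
published expectations quoted as "second cousin ≈ 0.031" correspond to the
1/32 pedigree, which is what the calibration against that value uses.

Inbreeding is estimated by the multilocus heterozygosity-deficit moment
estimator F̂ᵢ = 1 − Σh/Σ2p(1−p) (ratio of sums over the individual's
loci). Several estimators circulate under "Wright's inbreeding
coefficient"; this one was chosen for its closed form and because it hits
the simulation expectations (selfed offspring of outbred parents ≈ 0.5,
Hardy–Weinberg populations ≈ 0). No claim is made of numerically
reproducing any particular published inbreeding value, whose estimator is
typically unstated.

All multilocus statistics carry delete-one-locus jackknife standard
errors; 95% intervals use the normal multiplier 1.96. Intervals for
derived quantities (N_b, σ) transform the interval endpoints, which is
exact for monotone maps.

## 4. SGS, Sp and indirect dispersal

`sgs()` regresses pairwise kinship on ln(distance) over all distinct pairs
(no class averaging), which is the regression that the Sp statistic is
defined on. Distance classes — equal pair counts per class, ties assigned
deterministically by rank — serve only for the correlogram F(d) and the
first-class mean F₁; explicit class bounds can be supplied to mimic a
published classing. Pairs at distance zero (co-located stems) join the
first class but are excluded from the log-distance regression.

Significance of the slope uses permutation of individual locations among
individuals (equivalent to permuting multilocus genotypes among
coordinates), two-tailed, with the (r+1)/(n+1) estimator.

Derived quantities satisfy their defining algebra exactly:
Sp = −b/(1−F₁); N_b = 1/Sp (positive Sp only — a non-positive Sp means no
positive SGS and the downstream quantities are undefined rather than
coerced); σ = √(N_b/4πD_e) with D_e = D·(N_e/N) converted to
individuals/m². The Q&G relationship is converted to the kinship scale via
R = 2F/(1+F_I), using the sample inbreeding estimate, before entering the
Sp machinery.

**A documented inconsistency.** The packaged cohort reference table for
the motivating stand prints σ values (156.4 m seedlings, 276.9 m adults)
that are *not* reproducible from its own printed Sp and D_e under
σ² = N_b/4πD_e: the formula gives ≈401.8 m for the adult row, and both
printed σ values back-solve to D_e ≈ 0.5 ind/ha rather than the printed
0.237/0.111. The package computes from the formula and asserts the
algebraic round trip plus synthetic recovery, not those two printed
numbers.

**What recovery means here.** On toroidal isolation-by-distance
simulations with known σ (Gaussian pollen and seed kernels, axial scales
σ_true/√1.5 so the gametic dispersal variance averages to σ_true²), the
estimate from 100 sampled individuals at 2,000 loci lands within a factor
of two of truth in ≥80% of replicates — the accuracy class reported for
this estimator generally. The test conditions use σ_true = 15 m at 50
ind/ha on a 9-ha torus (N_b ≈ 14) and 25 generations, sizes chosen to sit
in the regime where the Wright–Malécot approximation holds while keeping
the default test run fast; torus-metric distances are used so the analysis
geometry matches the simulation geometry. A persistent upward bias of
~20–40% is expected and observed, because the regression uses all pairs
including those beyond the distance range where kinship decays linearly in
ln(d).

## 5. Parentage

LOD scores follow the categorical-assignment likelihood framework. Per
locus, the single-parent likelihood is the Mendelian transmission
probability with the unknown parent integrated over Hardy–Weinberg
frequencies; genotyping error enters as independent replacement of each
observed genotype by a random Hardy–Weinberg genotype at rate e (the
classic replacement model; the refinement that distinguishes allelic
dropout from miscalls is out of scope). Consequences worth stating:

* e = 0 recovers hard exclusion: one Mendelian incompatibility gives
  LOD = −∞.
* Per-locus LODs add; loci with missing genotypes (offspring or any
  evaluated candidate) contribute zero.
* The single-parent mixture is (1−e)²·T + (1−(1−e)²)·P₀; the pair mixture
  keeps the single-parent transition terms for the
  one-parent-mistyped cases, so the model stays coherent as e → 0.

Δ is the gap between the two highest LODs among candidates with positive
LOD (equal to the top LOD when it is the only positive one).
`simulate_delta_crit()` calibrates critical values CERVUS-style: offspring
simulated from random parent pairs at the candidate allele frequencies,
each true parent present among candidates with probability
`prop_sampled`, error applied to offspring and sampled-parent genotypes
(applying it to the unrelated candidates would be a no-op distributionally,
so it is skipped), Δ computed exactly as in assignment, and the criterion
set to the smallest threshold at which the success proportion above it
reaches the confidence level (+∞, with a warning, when unattainable —
e.g. with a handful of loci).

Assignment is pair-first: a pair (including self-pairs for hermaphrodites)
whose Δ exceeds the pair criterion wins; otherwise a single candidate by
the single criterion; otherwise no parent. With two distinct parents the
nearer is maternal (seed dispersal) and the farther paternal (pollen
dispersal), the standard assumption when the seed parent is not
observable; exact distance ties break by candidate id order and are
deterministic. A lone assigned parent is maternal, with pollen counted as
immigrant. Seed immigration m_s and pollen immigration m_p are the
fractions of offspring with zero and one assigned parent.

Dispersal distances: seed = offspring↔maternal for every offspring with a
maternal assignment (selfed included); pollen = offspring↔paternal for
two-distinct-parent offspring only, since a selfing event involves no
measurable pollen movement between trees and published pollination
distances exclude them. σ_rt = √(½·var(pollen) + var(seed)) with sample
(n−1) variances. A second documented inconsistency: applying this formula
to the packaged published pollen/seed SDs (42.9, 23.72 m) gives 38.5 m,
not the published 41.8 m — the published variance convention or unrounded
inputs are unknowable, so only the formula and the ratio of printed values
are asserted.

Non-exclusion: the per-locus parent-pair non-exclusion probability is
computed by exact enumeration of all genotype triples under Hardy–Weinberg
(the test suite cross-checks it against Monte-Carlo exclusion
frequencies), combined multiplicatively in log10 space since products over
thousands of SNPs underflow; cryptic gene flow is
C_gf = 1 − (1−P_p)ⁿ via `log1p`/`expm1` for numerical safety.

## 6. The synthetic-data generator

`sim_config()` defaults define the study conditions every other module is
validated under, mirroring the motivating stand: 99 adults of which 34
reproductive, 16 seedlings, a ~125-ha arena (census adult density
0.79 ind/ha; mean inter-adult distance of order 10² m), 3,000 loci with
founder frequencies U(0.05, 0.95), selfing rate 0.375 (the rate observed
in the stand), exponential pollen kernel with 70 m scale and seed kernel
with 20 m scale (the order of the observed 31–147 m pollination and
1–80 m seed-dispersal distances; no kernel family is known for the
species, so the conventional fat-tailed choice is used), genotyping error
0.01, missingness 0.05, MAF ascertainment floor 0.05. Missingness is
completely at random; `degrade()` also accepts per-locus rates to emulate
the heterogeneous locus dropout of RAD data (important when exercising the
MD = 0 grid cells, which would otherwise be empty under uniform MCAR).

What passing tests on these simulations shows: the estimators are
consistent with pedigree truth under Hardy–Weinberg founders, unlinked
loci, MCAR missingness and replacement-model error. What they do not
show: robustness to linked loci, null alleles, informative missingness,
population structure among founders, or kernel misspecification — all out
of scope.

## 7. Numerical and reproducibility conventions

* Every stochastic routine takes an explicit integer seed;
  `run_grid()` derives per-cell seeds from the master seed and the cell
  position, so adding cells never perturbs existing ones, and re-running
  with the same seed is bit-identical.
* Jackknife pseudo-values of a pair whose only shared locus is the deleted
  one are undefined; the pair keeps its overall value for that deletion.
* The exact HWE p-value sums probabilities ≤ p_obs·(1+1e−9) to absorb
  floating-point ties; the test suite pins it to an independent
  recurrence-based enumeration at 1e−12.
* CV% uses the n−1 sample SD over the absolute mean.
* Default test-suite problem sizes (hundreds of loci, tens of
  individuals, 10³ Δ simulations, 5 IBD replicates at 2,000 loci) are the
  package's chosen validation scale: large enough that every calibration
  band quoted above is meaningful at its Monte-Carlo error, small enough
  to keep the default run in minutes.

## 8. Known limitations

Biallelic loci only; no likelihood-based joint pedigree reconstruction or
sibship inference; no allelic-dropout error component; isotropic kernels
and planar (or toroidal) geometry; N_e/N enters as a user-supplied ratio
rather than being estimated; and the indirect σ inherits the documented
upward bias of the all-pairs regression. These bounds are deliberate: the
package implements the published workflow faithfully rather than extending
it.
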