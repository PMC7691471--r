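---
title: "Methods: candidate-region association for steelhead migration timing and age-at-maturity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-region association for steelhead life history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steelheadAssoc)
```

# The scientific problem

Columbia River steelhead (*Oncorhynchus mykiss*) vary in two life-history
traits that managers track closely: **adult migration timing** (when a fish
enters freshwater and when it arrives at its spawning tributary) and
**age-at-maturity** (years at sea before the first return, tightly linked to
fork length). Two genomic regions carry most of the known large-effect
variation: a ~13-marker stretch of chromosome 28 spanning the *GREB1L* and
*ROCK1* genes (migration phenology) and a ~10-marker stretch of chromosome
25 around *SIX6* (ocean age and size). The strength of these associations
differs between the coastal and inland steelhead lineages and between the
sexes, which matters when genotype panels are used to predict life history
for conservation management.

`steelheadAssoc` implements the full analysis chain for this problem —
mark–recapture phenotype derivation, haplotype inference, kinship-aware
association, and haplotype score testing — together with a synthetic-data
module that emulates the study system so that every stage can be exercised
and validated without access to restricted field data.

# Migration-timing phenotypes from PIT-tag histories

Adults are detected at passive integrated transponder (PIT) arrays as they
ascend the river. For each fish the pipeline records the **Bonneville
passage day** (first detection at the Bonneville array, river km 234; a
proxy for freshwater entry) and the **tributary arrival day** (detection at
the most upstream array; a proxy for arrival at the spawning grounds), both
as ordinal days counted from January 1 of the passage year, so an arrival
the following February is day ~397 rather than day ~32.

Detection histories are noisy, and `apply_filters()` removes records whose
arrival day would be wrong or meaningless, in a fixed order so results are
reproducible: histories whose most upstream array is a mainstem dam
(pre-arrival mortalities), a lower-river distribution array (destination
ambiguous), or a thermal-refuge mouth ("dip-ins" seeking cool water);
repeat migrants attempting iteroparous spawning (two Bonneville or two
upstream detections ≥ 300 days apart); records with more than 330 days
between passage and arrival; and, in Bonneville-sampled data, fish with
both passage before ordinal 135 (mid-May) and arrival before ordinal 166
(mid-June), where late winter-run and early summer-run fish of different
spawn years overlap. All thresholds are arguments of `filter_rules()`.
"Mid-May" and "mid-June" are not exact calendar dates in the underlying
protocol, so ordinals 135/166 are package defaults, not constants.

Hood River data (a coastal, winter-run-dominated sample) are handled
differently in two respects. Repeat migrants keep their arrival day and
only drop the passage phenotype. And because late winter-run and very early
summer-run fish from consecutive spawn years co-occur in the same calendar
spring, `spawn_year_align()` adds 365 days to both ordinals of fish passing
before ordinal 121 (May 1) *or* arriving before ordinal 141 (May 21) — a
joint shift that keeps the genotype classes in temporal order
(homozygous-premature < heterozygous < homozygous-mature) and avoids
spurious overdominance. The rule is idempotent: already-aligned values
(≥ 366) are never shifted again. The 330-day lag filter is applied *after*
alignment, because the lag of an aligned pair is unchanged while an
unaligned cross-year pair would be nonsensical. Leap years receive no
special treatment (February 29 is ordinal 60; a one-day discretization
error we accept and document).

From each retained record the pipeline derives 20 phenotypes: the 2 raw
days; 2 compound statistics (lag in days, and migration rate = distance
from Bonneville to the upstream array divided by the lag, with a one-day
divisor when the lag is zero); and 16 group-relative transformations —
each raw day minus the **median** or the **last** (maximum) day of fish
grouped by hydrological unit (HUC) or sub-basin, within a spawn year or
pooled across years. Relative values are differences, not ratios, because
the downstream linear models are translation-based; even-sized group
medians are the mean of the two central values; singleton cells give 0
with a warning. The spawn year of a fish is the year of the spring
following its arrival (arrivals from July 1, ordinal 182, onward belong to
the next spring's spawn year); the "last day" reference is taken within
the grouping cell as constructed.

# Haplotype inference and linkage disequilibrium

Candidate-region markers are tightly linked, so most of their information
is haplotypic. `em_haplotypes()` estimates haplotype frequencies from
unphased diploid genotypes by expectation–maximization over per-individual
compatible haplotype pairs, with **progressive marker insertion**: markers
enter in batches of 6; after each insertion the EM is run to a
log-likelihood tolerance of 1e-5 and haplotype pairs with posterior
probability below 1e-9 are trimmed (each fish always keeps its best pair),
which keeps the pair space tractable for up to ~16 markers. The final
estimate is the best of 100 starts (one uniform, the rest random
Dirichlet) by final log-likelihood; the log-likelihood is asserted
non-decreasing within each EM stage. On instances small enough to
enumerate, the estimate matches an exhaustive-likelihood oracle (see the
test suite).

Per-individual posterior pairs feed three downstream codings:
`phase_best_pair()` (maximal-posterior pair, ties broken by the
lexicographically smaller string pair — with ≤ 13 tightly linked markers
the posteriors are near-deterministic, so this simple rule replaces
graph-HMM phasing as the package's phasing contract),
`haplotype_dosage()` in hard (0/1/2 copies) or expected
(posterior-weighted, in [0, 2]) mode, and the ambiguity-weighted codings
of the score test below.

Pairwise LD (`ld_r2()`) is available as the squared dosage correlation or
from two-locus EM haplotype frequencies (r² = D²/(p~A~q~A~p~B~q~B~)); the
two agree exactly when phase is unambiguous. Samples missing either marker
of a pair are dropped for that pair. `prune_linkage()` prunes for the
neutral set in sliding windows of 50 markers stepped by 5 at r² > 0.9,
dropping the lower-call-rate member of each offending pair (ties: the
later position) — the drop rule is a package choice made for determinism.
Haplotype-block boundaries are analyst inputs, not auto-detected.

# Population-structure covariates

Downstream models need a neutral marker set. Where a curated list is not
supplied, `fst_screen()` provides a transparent screen: per-locus
Weir–Cockerham FST between populations with a permutation null (labels
permuted ≥ 999 times, BH-adjusted, outliers flagged at q ≤ 0.1). It is a
deliberately simple, testable alternative to Bayesian outlier MCMC, which
is outside this package's scope.

From the neutral set, `vanraden_kinship()` builds the genomic relationship
matrix K = ZZ′ / (2Σp~k~(1−p~k~)) (VanRaden method 1; missing dosages
mean-imputed per marker) — the random-effect covariance of the mixed
model — and `pca_covariates()` the top principal components (3 by
default) used as fixed covariates. The kinship method is a documented
package choice; kinship and PCs are re-estimated within each analysis
subset (e.g. one sex or lineage) rather than subset from global matrices.

# Kinship-aware association

The single-marker model is y = Xβ + s·b + u + e with u ~ N(0, σ²~g~K) and
e ~ N(0, σ²~e~I). `fit_null_mlm()` estimates the variance components by
REML, profiling over δ = σ²~e~/σ²~g~ via one eigendecomposition of K: a
100-point log grid on [1e-5, 1e5] refined by bounded scalar optimization
(`reml_profile()` exposes the profile so the optimum can be checked
against dense grid search). `scan_mlm()` then tests each marker by
generalized least squares on data whitened under the null components —
the P3D/EMMAX convention, with exact per-marker REML behind
`p3d = FALSE` — using Wald t-tests, mean-imputing missing dosages at the
tested marker, and reporting Benjamini–Hochberg q-values
(`bh_fdr()`). With K = I the scan reduces exactly to ordinary least
squares, a property the test suite asserts at 1e-8.

The **net R²** of a marker — the variance it explains beyond the
covariate-plus-kinship model — has no single canonical formula, so the
package declares one: on whitened data,
net R² = (RSS~reduced~ − RSS~full~) / RSS~total~, where the reduced model
holds the covariates, the full model adds the marker, and RSS~total~ is
the residual sum of squares about the whitened intercept-only fit. It is
bounded to [0, 1] and invariant to affine rescaling of y.

Covariates follow fixed imputation rules (`covariate_design()`): missing
ocean age → 1.5 years, missing fork length → cohort median, missing
SNP-covariate genotypes → heterozygote (dosage 1); collinear columns are
dropped with a warning. `sequential_covariate_scan()` partitions variance
by adding markers in significance order and reporting each marker's net R²
beyond its predecessors. `group_ld()` clusters markers in near-perfect LD
(single linkage at r² ≥ 0.999; representative = highest call rate, ties to
the smallest position), and `iterative_conditional_scan()` runs forward
selection over group representatives at an FDR threshold with selected
groups as covariates — a transparent surrogate for iterative
model-selection scans whose internals (information-criterion keyways,
native LD pruning) this package deliberately does not reproduce.

# Haplotype score tests

`haplo_score()` relates haplotypes to phenotype **residuals** from a
covariate-only linear model (`glm_residuals()`; Gaussian family — the
phenotypes here are continuous days, centimetres and years, and ocean age
is treated as continuous). For haplotype h, each subject's expected coding
e~i~(h) is the posterior-expected copy count (additive) or the posterior
probability of carrying ≥ 1 copy (dominant); only haplotypes with expected
count ≥ 5 are scored. The score is U~h~ = Σ~i~ r~i~e~i~(h) with variance
s²·‖P e~h~‖², where P projects onto the orthogonal complement of the
covariate space — the covariate adjustment is by projection, a declared
formula. The global statistic is the quadratic form U′V^−^U over scored
haplotypes with a Moore–Penrose inverse (df = rank), which makes it
invariant to dropping any reference haplotype when the complete coding set
is scored.

Significance is by permutation of the residuals across subjects (the
residuals, not the raw phenotypes, are the exchangeable quantity once
covariates are Gaussian-linear): p = (1 + #{perm ≥ obs}) / (1 + n~perm~),
at least 1,000 permutations, continuing until the standard error
√(p(1−p)/n~perm~) falls below 0.05·p, with a cap of 100,000 permutations
(results hitting the cap are flagged unconverged; the cap is a package
addition for guaranteed termination). A fixed seed makes the p-value
reproducible. `haplo_score_slide()` repeats the global test in sliding
3-marker windows, re-estimating haplotypes by EM within each window (the
windowed EM is re-run rather than marginalized from the full-region
table), to localize signal along the region. `score_power()` gives the
1-df chi-square approximation to score-test power: ncp = n·r²/(1−r²).

`kruskal_wallis()` / `kw_by_group()` provide the rank-based per-sub-basin
genotype tests (tie correction always applied — ordinal-day data are
heavily tied; groups of n ≤ 15 are skipped), and `pearson_cor()` the
correlation utility used for comparing ageing methods.

# The synthetic-data module

`scenario_config()` + `simulate_scenario()` generate cohorts with full
truth labels. The packaged haplotype pools (`haplotype_pool()`) are the
published frequency catalogues for the two candidate regions in Columbia
River steelhead — 24 chromosome 28 haplotypes over 13 markers and 18
chromosome 25 haplotypes over 10 markers, with frequency columns for the
mixed Bonneville run (and its lineage subsets) and for the Hood River
coastal sample — so scenario realism is data-anchored. Two haplotypes per
region are drawn independently per fish from the lineage's pool (so
candidate regions are in Hardy–Weinberg and linkage equilibrium between
regions); neutral markers are binomial draws from lineage-specific
frequencies with a logit-normal between-lineage divergence; sex is male
with probability 1/2.67 (females outnumber males 1.67:1 in anadromous
returns); an sdY-style sex marker is included.

**Run timing.** Passage day = lineage baseline + effect × (mature-allele
dosage at the causal marker, marker 6 of the chromosome 28 region) +
N(0, σ~p~). Non-overwintering fish arrive lag~0~ = 7 days later (± 2 d),
with heterozygotes shifted toward the mature homozygotes by a configured
arrival shift — mirroring the observed pattern that heterozygotes initiate
migration at intermediate dates but arrive with the mature fish. In
overwintering scenarios (inland lineage), fish whose passage latent
exceeds ordinal 175 hold over winter and arrive in a next-spring window
(365 + 75 + 0.15 × (passage − 175) ± 12 d), producing the bimodal arrival
distribution characteristic of inland migrants.

**Age and length.** Ocean age follows a latent probit threshold model:
η = β·d~25~·(1 + (m−1)·male) + β~sex~·male + N(0, 1), cut at τ₁/τ₂ into
ages 1/2/3+, with the hard constraint that homozygous-short fish never
reach 3+ ocean. τ₁ and β~sex~ are fixed by two observed anchors — 25% of
homozygous-short females and 50% of homozygous-short males are 1-ocean —
and the sex main effect is a pure threshold shift. Fork length is the
age-class mean (57/72/82 cm) + 4.9 cm for males + N(0, σ~len~).

**Calibration.** The scenario's defining quantities are the variance
shares the causal marker should explain: 0.51 (coastal arrival), 0.08
(inland arrival), 17.0%/11.1% (male/female fork length). At configuration
time the free noise parameters are solved deterministically by moment
matching — closed-form truncated-normal moments for the overwinter
mixture and probit class probabilities for ocean age, with `uniroot()` on
the resulting population R² expressions. No simulation is involved in
calibration, and the realized OLS R² at n = 2000 matches the configured
share within ±0.03 (a tested invariant). Two structural facts fall out of
this calibration and are worth recording. First, with the interior pool's
premature-allele frequency (~0.013), an inland arrival share of 0.08 is
only attainable when the heterozygote class straddles the overwinter
threshold (baseline 130, effect 30 d); a later baseline lets the 365-day
jump swamp arrival variance and no noise level reaches the target. Second,
a pure threshold shift cannot push the female share as far below the male
share as the configured 11.1% vs 17.0%; the male latent effect therefore
carries a multiplier (solved ≈ 1.2) — i.e., the sexes differ by an
amplification of the locus effect, not only by their thresholds, matching
the reading of the sex difference as sex-dependent epistasis rather than
sex-dependent dominance (heterozygote ratios follow the homozygote ones).

**Detection histories.** Each fish gets a home tributary array within its
lineage from a fixed array map (Bonneville at km 234, three mainstem dams,
two thermal-refuge mouths, one lower-distribution array, ten tributary
arrays with HUC/sub-basin/lineage labels) and a history category: clean
(default 90%), mainstem mortality (5%; truncated at a mainstem site),
dip-in only (3%; ends at a refuge mouth), repeat spawner (2%; the whole
migration duplicated ~365 days later). Detections are emitted at the true
days and kept with a configurable detection probability (default 1, under
which the phenotype pipeline recovers the truth exactly and the filter
audit reproduces the planted categories).

**What the generator does not emulate** — and hence what green tests do
not certify about field data: temperature and flow covariates, imperfect
and array-specific detection probabilities, polygenic background (kinship
in the simulated cohorts is essentially empty, so REML routinely and
correctly drives σ²~g~ to the boundary — scans remain exact because
constant whitening weights reduce GLS to OLS), linkage between the two
candidate regions, within-season mortality, age-reading error models, and
real hatchery/wild structure. The synthetic scenarios validate the
*machinery* (estimators, filters, calibration, error control), not the
field conclusions.

# Numerical choices and degenerate inputs

* EM: trimming keeps each fish's best pair, so no fish loses all mass;
  non-convergence in all attempts is an error with diagnostics; the pair
  space per fish is capped (an error suggests filtering missingness).
* REML: grid-boundary optima are returned with a warning; K must be
  symmetric PSD within 1e-8 of its largest eigenvalue.
* Scans: monomorphic markers report β = 0, p = 1, flagged; markers
  collinear with covariates are flagged and skipped with a warning;
  sequential steps whose marker is fully absorbed report net R² = 0.
* Permutations: the p-value floor is 1/(n~perm~+1); fixed seeds restore
  the caller's RNG state afterwards.
* Scores: zero residual variance yields all-zero scores rather than 0/0.
* Kinship/PCA: monomorphic or constant-dosage markers are excluded; an
  all-degenerate panel is an error.
* Degenerate haplotype pools (a single haplotype) skip variance-share
  calibration — there is no genetic variance to calibrate.

# Problem sizes in the validation suite

The suite validates parameter recovery at the study's own scales: 25
seeded replicates of n = 400 for the lineage contrast, 25 replicates of
n = 2000 for the sex-stratified shares, n = 1538 diploids for haplotype
frequency recovery, and 1,600 null replicates for the permutation
type-I-error check — the last chosen so that the acceptance band
0.05 ± 0.015 corresponds to roughly three binomial standard errors of the
measured rejection rate. Smaller cohorts appear where a property does not
need scale (oracle equivalences, tie rules, filter branches).

# Known limitations

Ordinal-day arithmetic ignores leap days. The coastal scenario models a
single migration season, not the full year-round Hood River return. The
iterative conditional scan is a surrogate, not a reimplementation, of
published model-selection methods, and the FST screen is a substitute for
Bayesian outlier detection; both are clearly-specified alternatives rather
than re-creations. Binary/ordinal phenotype families for the score test
are out of scope. The EM is quadratic in the retained pair space and is
intended for candidate regions (≲ 16 markers), not genome-scale phasing.
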