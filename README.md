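# steelheadAssoc

Candidate-region genotype–phenotype association for Columbia River
steelhead (*Oncorhynchus mykiss*) life history: **adult migration timing**
against the chromosome 28 *GREB1L*/*ROCK1* region, and **age/size at
maturity** against the chromosome 25 *SIX6* region. The package is aimed at
fish-genetics analysts who need the full chain from raw PIT-tag detection
histories to association statistics as tested, scriptable R functions — and
at methodologists who want a fully synthetic, truth-labelled replica of the
study system to validate that chain end to end.

## What it computes

**Phenotypes.** Detection histories are filtered (pre-arrival mortalities,
thermal-refuge "dip-ins", repeat migrants, season-overlap records) and
reduced to 20 migration phenotypes per fish: Bonneville passage day and
tributary arrival day (ordinal days), lag and migration rate, and 16
group-relative transforms (day minus the median/last day by HUC/sub-basin,
within or across spawn years). Winter-run samples get a spawn-year
alignment: fish passing before ordinal 121 or arriving before ordinal 141
have 365 added to both days, keeping genotype classes in temporal order.

**Haplotypes.** Frequencies for the 13- and 10-marker candidate regions are
estimated by progressive-insertion EM over per-individual haplotype pairs
(batch size 6, posterior trim 1e-9, 100 restarts), giving posterior pairs,
best-pair phasing, and 0/1/2 or expected haplotype dosages.

**Association.** The mixed linear model `y = Xb + s·b_s + u + e`,
`var(u) = σ²_g K`, with VanRaden kinship from a neutral panel and principal
components as fixed covariates; REML variance components profiled over
`δ = σ²_e/σ²_g` (EMMA-style), P3D scans with Wald tests, BH-FDR, and a
declared net-R² (whitened `(RSS_reduced − RSS_full)/RSS_total`). Sequential
covariate models, near-perfect-LD grouping (r² ≥ 0.999) and an iterative
conditional scan partition variance among linked markers. Haplotype score
statistics on GLM residuals (additive/dominant codings weighted by
posterior ambiguity) get permutation p-values with an SE-based stopping
rule, sliding 3-marker subhaplotype scans, and a chi-square power
approximation. Kruskal–Wallis utilities cover per-sub-basin tests.

**Synthetic data.** `scenario_config()` / `simulate_scenario()` generate
genotypes from the packaged haplotype-frequency catalogues, run-timing and
age/length phenotypes with moment-matched calibration to the scenarios'
configured variance shares (coastal 0.51 / inland 0.08 for arrival day;
17.0% male / 11.1% female for fork length), and PTAGIS-like detection
histories with planted mortalities, dip-ins and repeat spawners — all with
truth labels.

## Worked example

Simulate a coastal cohort, derive phenotypes from its detection histories,
and test the chromosome 28 region:

```r
library(steelheadAssoc)
cfg <- scenario_config("coastal", n = 400, seed = 1)
sim <- simulate_scenario(cfg)

# phenotypes from the detection histories
res <- derive_phenotypes(sim$events, sim$sites, filter_rules("bonaff"))
table(res$audit$reason)
#>       mainstem_last                  ok      repeat_migrant thermal_refuge_last
#>                  16                 373                   5                   6

# kinship + PCs from the neutral panel, restricted to retained fish
G     <- subset_genotypes(sim$genotypes, samples = res$phenotypes$tag_id)
neut  <- subset_genotypes(G, markers = which(G$markers$panel_class == "neutral_candidate"))
K     <- vanraden_kinship(neut)
pcs   <- pca_covariates(neut, 3)
truth <- sim$truth[match(res$phenotypes$tag_id, sim$truth$sample_id), ]
X     <- covariate_design(nrow(G$dosage), sex = truth$male, pcs = pcs$scores)

# kinship-aware scan of the candidate markers
scan <- scan_mlm(res$phenotypes$arrival_day, X, K, G,
                 markers = which(G$markers$panel_class == "chr28_candidate"))
head(scan[order(scan$p), c("marker_id", "beta", "p", "q", "net_r2")], 4)
#>    marker_id  beta        p        q net_r2
#> 4  chr28_m04 -29.6 4.25e-38 1.84e-37  0.361
#> 6  chr28_m06 -29.6 4.25e-38 1.84e-37  0.361
#> 7  chr28_m07 -29.6 4.25e-38 1.84e-37  0.361
#> 10 chr28_m10 -27.2 1.59e-32 4.27e-32  0.316
```

Markers 4/6/7 — the 5′ block around the causal marker — share the top
signal: each premature-allele copy advances arrival by ~30 days, and the
top marker explains 36% of arrival variance in this replicate (the mean
across 25 replicates recovers the configured 51%; single seeds scatter).
The haplotype score test tells the same story at haplotype resolution:

```r
G28 <- subset_genotypes(G, markers = which(G$markers$panel_class == "chr28_candidate"))
em  <- label_haplotypes(em_haplotypes(G28, attempts = 25, seed = 2),
                        haplotype_pool("chr28", "hood_hs"))
r   <- glm_residuals(res$phenotypes$arrival_day, X[, -1])
hs  <- haplo_score(r, em, covariates = X[, -1], seed = 3, n_perm_max = 20000)
hs
#> haplo_score: global stat 140.693 (df 8), perm p = 5e-05 (n = 20000)
#>       haplotype label   coding   freq count_expected       z   p_norm
#> 1 GAGGAGCCGTGTA     I additive 0.6212         463.40   4.544 5.53e-06
#> 8 ACTAGTATACTGT   III additive 0.0642          47.86 -10.884 1.38e-27
#> 7 ACTAGTATACTGA   XIV additive 0.0123           9.14  -4.309 1.64e-05
#> ...
```

The mature haplotype I scores positive (later arrival), the premature
haplotype III and its marker-13 recombinant XIV strongly negative — the
expected direction of the run-timing contrast.

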