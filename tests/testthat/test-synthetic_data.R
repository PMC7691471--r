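# scenario configuration, generators, truth labels, and the full round trip

test_that("generators are pure functions of (config, seed)", {
  cfg <- scenario_config("coastal", n = 50, seed = 61)
  a <- simulate_scenario(cfg, seed = 61)
  b <- simulate_scenario(cfg, seed = 61)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$truth, b$truth)
  expect_identical(a$events, b$events)
  c <- simulate_scenario(cfg, seed = 62)
  expect_false(identical(a$genotypes$dosage, c$genotypes$dosage))
  # CSV bytes identical under a fixed seed
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_detections(a$events, f1)
  write_detections(b$events, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a degenerate frequency vector yields an all-homozygous cohort
           and pool frequencies are recovered at scale", {
  pool1 <- data.frame(label = "I", string = "GAGGAGCCGTGTA", freq = 1)
  cfg <- scenario_config("coastal", n = 30, seed = 63, chr28_pool = pool1)
  gg <- gen_genotypes(cfg)
  expect_true(all(gg$truth$chr28_hap1 == "I" & gg$truth$chr28_hap2 == "I"))
  d28 <- gg$genotypes$dosage[, gg$genotypes$markers$panel_class ==
                               "chr28_candidate"]
  expect_true(all(d28 %in% c(0L, 2L)))
  # coastal pool: haplotype I sample frequency within 3 binomial SE
  cfg2 <- scenario_config("coastal", n = 2000, seed = 64)
  gg2 <- gen_genotypes(cfg2)
  p0 <- cfg2$chr28_pool$freq[cfg2$chr28_pool$label == "I"]
  f_hat <- mean(c(gg2$truth$chr28_hap1, gg2$truth$chr28_hap2) == "I")
  se <- sqrt(p0 * (1 - p0) / (2 * 2000))
  expect_lt(abs(f_hat - p0), 3 * se)
})

test_that("run timing follows the configured structure: constant under
           zero noise/effect and overwintering past the threshold", {
  cfg <- scenario_config("coastal", n = 40, seed = 65)
  cfg$run_timing$effect <- 0
  cfg$run_timing$sigma_passage <- 1e-9
  cfg$run_timing$sigma_lag <- 1e-9
  gg <- gen_genotypes(cfg)
  tr <- gen_run_timing(cfg, gg$truth)
  expect_equal(length(unique(tr$passage_day)), 1L)
  # inland fish passing after day 175 arrive the next spring
  cfg2 <- scenario_config("inland", n = 400, seed = 66)
  gg2 <- gen_genotypes(cfg2)
  tr2 <- gen_run_timing(cfg2, gg2$truth)
  late <- tr2$passage_day > 185          # clear of rounding at the cut
  expect_true(all(tr2$arrival_day[late] > 365))
  direct <- tr2$passage_day < 165
  expect_true(all(tr2$arrival_day[direct] <= 365))
})

test_that("the effect-size dial holds: configured variance share matches
           realized OLS R2 at n = 2000", {
  for (sc in c("coastal", "inland")) {
    cfg <- scenario_config(sc, n = 2000, seed = 67)
    gg <- gen_genotypes(cfg)
    tr <- gen_run_timing(cfg, gg$truth)
    r2 <- summary(lm(tr$arrival_day ~ tr$d28))$r.squared
    expect_equal(r2, cfg$run_timing$target_r2, tolerance = 0.03,
                 label = sprintf("%s realized R2", sc))
  }
})

test_that("age/length truth matches its configured sex-specific
           structure", {
  cfg <- scenario_config("age25", seed = 68)
  gg <- gen_genotypes(cfg)
  tr <- gen_age_length(cfg, gg$truth)
  # hard constraint: homozygous short never 3+ ocean
  expect_equal(sum(tr$ocean_age >= 3 & tr$d25 == 0), 0L)
  # one-ocean fractions of homozygous-short fish by sex, within 3 binomial
  # SE of the configured 50% / 25%
  m0 <- tr$male == 1 & tr$d25 == 0
  f0 <- tr$male == 0 & tr$d25 == 0
  expect_lt(abs(mean(tr$ocean_age[m0] == 1) - 0.50),
            3 * sqrt(0.25 / sum(m0)))
  expect_lt(abs(mean(tr$ocean_age[f0] == 1) - 0.25),
            3 * sqrt(0.25 * 0.75 / sum(f0)))
  # male variance share exceeds female
  r2m <- summary(lm(fork_length ~ d25, tr[tr$male == 1, ]))$r.squared
  r2f <- summary(lm(fork_length ~ d25, tr[tr$male == 0, ]))$r.squared
  expect_gt(r2m, r2f)
  # homozygous-long males larger than same-genotype females
  d2 <- tr$d25 == 2
  expect_equal(mean(tr$fork_length[d2 & tr$male == 1]) -
                 mean(tr$fork_length[d2 & tr$male == 0]),
               4.9, tolerance = 1.0)
})

test_that("detection histories round-trip through the phenotype pipeline
           with truth-category recovery", {
  cfg <- scenario_config("coastal", n = 150, seed = 69)
  sim <- simulate_scenario(cfg)
  res <- derive_phenotypes(sim$events, sim$sites, filter_rules("bonaff"))
  audit <- res$audit[match(sim$truth$sample_id, res$audit$tag_id), ]
  clean <- sim$truth$history_category == "clean"
  # retained set equals the clean set exactly at detection probability 1
  expect_equal(audit$retained, clean)
  expect_true(all(audit$reason[sim$truth$history_category ==
                                 "mainstem_mortality"] == "mainstem_last"))
  expect_true(all(audit$reason[sim$truth$history_category ==
                                 "dip_in_only"] == "thermal_refuge_last"))
  expect_true(all(audit$reason[sim$truth$history_category ==
                                 "repeat_spawner"] == "repeat_migrant"))
  # recovered phenotypes are exact
  ph <- res$phenotypes
  tr <- sim$truth[match(ph$tag_id, sim$truth$sample_id), ]
  expect_equal(ph$passage_day, tr$passage_day)
  expect_equal(ph$arrival_day, tr$arrival_day)
})

test_that("the full pipeline recovers the candidate region: the arrival-day
           top marker is a chromosome 28 marker across seeds", {
  hits <- vapply(1:5, function(s) {
    cfg <- scenario_config("coastal", n = 400, seed = 70 + s)
    gg <- gen_genotypes(cfg, 70 + s)
    tr <- gen_run_timing(cfg, gg$truth, 71 + s)
    G <- gg$genotypes
    neut <- subset_genotypes(G, markers = which(G$markers$panel_class ==
                                                  "neutral_candidate"))
    K <- vanraden_kinship(neut)
    pca <- pca_covariates(neut, 3)
    X <- covariate_design(nrow(tr), sex = tr$male, pcs = pca$scores)
    idx <- which(G$markers$panel_class %in% c("neutral_candidate",
                                              "chr28_candidate"))
    sc <- suppressWarnings(scan_mlm(tr$arrival_day, X, K, G,
                                    markers = idx))
    grepl("chr28", sc$marker_id[which.min(sc$p)])
  }, logical(1))
  expect_true(all(hits))
})

test_that("sex-stratified scans recover a larger male than female share on
           the chromosome 25 scenario", {
  wins <- vapply(1:5, function(s) {
    cfg <- scenario_config("age25", n = 1200, seed = 80 + s)
    gg <- gen_genotypes(cfg, 80 + s)
    tr <- gen_age_length(cfg, gg$truth, 82 + s)
    G <- gg$genotypes
    out <- c(M = NA_real_, F = NA_real_)
    for (sx in c("M", "F")) {
      sel <- which(tr$sex == sx)
      Gs <- subset_genotypes(G, samples = sel)
      neut <- subset_genotypes(Gs, markers = which(Gs$markers$panel_class ==
                                                     "neutral_candidate"))
      K <- vanraden_kinship(neut)
      pca <- pca_covariates(neut, 3)
      X <- covariate_design(length(sel), pcs = pca$scores)
      sc <- suppressWarnings(scan_mlm(tr$fork_length[sel], X, K, Gs,
                                      markers = which(Gs$markers$panel_class ==
                                                        "chr25_candidate")))
      out[sx] <- sc$net_r2[which.min(sc$p)]
    }
    out["M"] > out["F"]
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
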