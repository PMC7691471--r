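# haplotype score statistics, permutation stopping rule, sliding windows,
# and score-test power

test_that("glm_residuals match the normal-equation oracle and degenerate
           cases behave", {
  set.seed(20)
  n <- 40
  X <- cbind(rnorm(n), rnorm(n))
  y <- 2 + X %*% c(1, -0.5) + rnorm(n)
  r <- glm_residuals(y, X)
  Xi <- cbind(1, X)
  r_oracle <- drop(y - Xi %*% solve(crossprod(Xi), crossprod(Xi, y)))
  expect_equal(r, r_oracle, tolerance = 1e-10)
  expect_lt(abs(mean(r)), 1e-10)
  # intercept only: centered y
  expect_equal(glm_residuals(y), drop(y - mean(y)), tolerance = 1e-10)
  # exact linear phenotype: zero residuals
  expect_lt(max(abs(glm_residuals(drop(X %*% c(2, 3)), X))), 1e-10)
  # rank-deficient covariates are dropped with a warning
  expect_warning(glm_residuals(y, cbind(X, X[, 1])), "rank")
})

test_that("haplotype scores single out the causal haplotype and respect the
           minimum-count threshold", {
  cfg <- scenario_config("coastal", n = 250, seed = 51)
  gg <- gen_genotypes(cfg)
  tr <- gen_run_timing(cfg, gg$truth)
  G28 <- subset_genotypes(gg$genotypes,
                          markers = which(gg$genotypes$markers$panel_class ==
                                            "chr28_candidate"))
  fit <- label_haplotypes(em_haplotypes(G28, attempts = 20, seed = 10),
                          haplotype_pool("chr28", "hood_hs"))
  r <- glm_residuals(tr$arrival_day, cbind(tr$male))
  hs <- haplo_score(r, fit, covariates = cbind(tr$male),
                    n_perm_min = 500, n_perm_max = 2000, seed = 11)
  expect_true(all(hs$scores$count_expected >= 5))
  # the premature core haplotype III carries the largest |z|
  top <- hs$scores$label[which.max(abs(hs$scores$z))]
  expect_true(top %in% c("III", "I"))
  expect_lt(hs$perm_p, 0.01)
  # residuals of zero give all-zero scores
  hs0 <- haplo_score(rep(0, fit$n), fit, n_perm_min = 0)
  expect_true(all(hs0$scores$z == 0))
})

test_that("additive and dominant codings coincide for haplotypes without
           expected homozygotes", {
  cfg <- scenario_config("coastal", n = 150, seed = 52)
  gg <- gen_genotypes(cfg)
  tr <- gen_run_timing(cfg, gg$truth)
  G28 <- subset_genotypes(gg$genotypes,
                          markers = which(gg$genotypes$markers$panel_class ==
                                            "chr28_candidate"))
  fit <- em_haplotypes(G28, attempts = 15, seed = 12)
  r <- glm_residuals(tr$arrival_day)
  ha <- haplo_score(r, fit, coding = "additive", n_perm_min = 0)
  hd <- haplo_score(r, fit, coding = "dominant", n_perm_min = 0)
  shared <- intersect(ha$scores$haplotype, hd$scores$haplotype)
  ph <- phase_best_pair(fit)
  for (h in shared) {
    n_hom <- sum(ph$hap1 == h & ph$hap2 == h)
    if (n_hom == 0) {
      za <- ha$scores$z[ha$scores$haplotype == h]
      zd <- hd$scores$z[hd$scores$haplotype == h]
      expect_equal(za, zd, tolerance = 0.05)
    }
  }
})

test_that("the permutation stopping rule honors its SE bound and fixed
           seeds reproduce", {
  set.seed(21)
  r <- rnorm(100)
  stat_fn <- function(Rm) colSums(Rm * r)^2 / sum(r^2)
  obs <- median(replicate(50, stat_fn(matrix(sample(r), ncol = 1))))
  p1 <- permute_pvalue(stat_fn, r, obs, min_perm = 1000, seed = 30)
  expect_equal(p1$n_perm, 1000L)          # mid-null p stops at the minimum
  expect_gt(p1$p, 0.2); expect_lt(p1$p, 0.8)
  expect_true(p1$converged)
  expect_lt(p1$se, 0.05 * p1$p)
  expect_equal(p1$se, sqrt(p1$p * (1 - p1$p) / p1$n_perm))
  p2 <- permute_pvalue(stat_fn, r, obs, min_perm = 1000, seed = 30)
  expect_identical(p1, p2)
  # extreme observed value runs to the cap and is flagged unconverged
  p3 <- permute_pvalue(stat_fn, r, 1e6, min_perm = 200, max_perm = 1000,
                       seed = 31)
  expect_false(p3$converged)
  expect_equal(p3$n_perm, 1000L)
})

test_that("sliding windows localize the signal and count windows
           correctly", {
  cfg <- scenario_config("coastal", n = 200, seed = 53)
  gg <- gen_genotypes(cfg)
  tr <- gen_run_timing(cfg, gg$truth)
  G28 <- subset_genotypes(gg$genotypes,
                          markers = which(gg$genotypes$markers$panel_class ==
                                            "chr28_candidate"))
  r <- glm_residuals(tr$arrival_day)
  sl <- haplo_score_slide(r, G28, window = 3, em_attempts = 8,
                          n_perm_min = 200, n_perm_max = 500, seed = 13)
  expect_equal(nrow(sl), 11L)             # 13 markers, window 3
  expect_equal(sl$start, 1:11)
  # the windows containing the causal marker (6) reach the minimal p;
  # perfect-LD windows tie at the permutation floor
  expect_true(any(sl$perm_p[4:6] == min(sl$perm_p)))
  # monomorphic window reports p = 1
  Gm <- toy_genotypes(matrix(0L, 30, 4))
  sl0 <- haplo_score_slide(rnorm(30), Gm, window = 3, em_attempts = 2,
                           n_perm_min = 100, seed = 14)
  expect_true(all(sl0$perm_p == 1))
})

test_that("score power follows the chi-square approximation and its
           monotonicities", {
  expect_equal(score_power(0.5, 0, 100)$power, 0.05, tolerance = 1e-10)
  # strong haplotype contrast at the coastal sample size: near-certain
  expect_gt(score_power(0.6, 0.36, 354)$power, 0.999)
  expect_lte(score_power(0.5, 0.1, 100)$power,
             score_power(0.5, 0.1, 400)$power)
  expect_lte(score_power(0.5, 0.05, 200)$power,
             score_power(0.5, 0.2, 200)$power)
  expect_error(score_power(0, 0.1, 100))
  expect_error(score_power(0.5, 1, 100))
})

test_that("the global statistic is invariant to dropping a reference
           haplotype from the quadratic form", {
  cfg <- scenario_config("coastal", n = 120, seed = 54)
  gg <- gen_genotypes(cfg)
  tr <- gen_run_timing(cfg, gg$truth)
  G28 <- subset_genotypes(gg$genotypes,
                          markers = which(gg$genotypes$markers$panel_class ==
                                            "chr28_candidate")[1:4])
  fit <- em_haplotypes(G28, attempts = 15, seed = 15)
  r <- glm_residuals(tr$arrival_day)
  # score the complete haplotype set: the additive codings then sum to two
  # per sample, so the projected columns are linearly dependent and the
  # pseudo-inverse quadratic form is reference-free
  hs_all <- haplo_score(r, fit, n_perm_min = 0, min_count = 1e-6)
  E <- steelheadAssoc:::.score_codings(
    fit, which(fit$haplotypes$count_expected >= 1e-6), "additive")
  X <- matrix(1, fit$n, 1)
  Et <- qr.resid(qr(X), E)
  s2 <- sum(r^2) / length(r)
  U <- drop(crossprod(Et, r))
  V <- s2 * crossprod(Et)
  drop_ref <- which.max(colSums(E))
  U2 <- U[-drop_ref]; V2 <- V[-drop_ref, -drop_ref]
  g2 <- drop(t(U2) %*% MASS::ginv(V2) %*% U2)
  expect_equal(hs_all$global_stat, g2, tolerance = 1e-6)
})
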