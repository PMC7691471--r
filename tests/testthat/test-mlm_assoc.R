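# REML variance components, P3D scans, net R2, sequential models,
# LD grouping, the iterative conditional scan, and BH FDR

test_that("REML optimum matches a dense grid search on the n=8 fixture", {
  fx <- fixture_mlm()
  fit <- fit_null_mlm(fx$y, fx$X, fx$K)
  grid <- 10^seq(-5, 5, length.out = 20000)
  ll <- reml_profile(fx$y, fx$X, fx$K, grid)
  expect_gte(fit$reml_loglik, max(ll) - 1e-6)
  expect_equal(fit$reml_loglik, max(ll), tolerance = 1e-6)
  expect_gte(fit$sigma_g2, 0)
  expect_gt(fit$sigma_e2, 0)
  expect_equal(fit$delta, fit$sigma_e2 / fit$sigma_g2, tolerance = 1e-8)
})

test_that("identity kinship collapses the mixed model to OLS", {
  set.seed(10)
  n <- 60
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  s <- rbinom(n, 2, 0.35)
  G <- toy_genotypes(matrix(s, ncol = 1))
  suppressWarnings(sc <- scan_mlm(y, X, diag(n), G))
  co <- summary(lm(y ~ X[, 2] + s))$coefficients["s", ]
  expect_equal(sc$p, unname(co["Pr(>|t|)"]), tolerance = 1e-8)
  expect_equal(sc$beta, unname(co["Estimate"]), tolerance = 1e-8)
  # pure-noise y with arbitrary K: delta at the upper boundary, GLS ~ OLS
  fx <- fixture_mlm(60, 13)
  set.seed(11)
  y0 <- rnorm(60)
  expect_warning(fit0 <- fit_null_mlm(y0, fx$X, fx$K), "boundary")
  expect_gt(fit0$delta, 1e4)
})

test_that("the scan finds a planted additive QTL and handles degenerate
           markers", {
  set.seed(12)
  n <- 400
  m <- 20
  dos <- matrix(rbinom(n * m, 2, 0.4), n, m)
  beta <- sqrt(var(dos[, 7]) * 1)       # QTL at marker 7, ~50% variance
  y <- dos[, 7] * 1 + rnorm(n, 0, sqrt(var(dos[, 7]) * 1))
  G <- toy_genotypes(dos)
  X <- matrix(1, n, 1)
  suppressWarnings(sc <- scan_mlm(y, X, diag(n), G))
  expect_equal(which.min(sc$p), 7L)
  expect_equal(sc$net_r2[7], 0.5, tolerance = 0.08)
  # monomorphic marker flagged, not crashed
  dos2 <- cbind(dos[, 1:3], 1L)
  suppressWarnings(sc2 <- scan_mlm(y, X, diag(n), toy_genotypes(dos2)))
  expect_equal(sc2$note[4], "monomorphic")
  expect_equal(sc2$p[4], 1)
  # SNP identical to a covariate column is reported collinear
  X3 <- cbind(1, dos[, 2])
  expect_warning(sc3 <- scan_mlm(y, X3, diag(n),
                                 toy_genotypes(dos[, 1:3])),
                 "collinear")
  expect_equal(sc3$note[2], "collinear")
})

test_that("net R2 is zero for orthogonal markers, bounded, and invariant to
           affine rescaling of the phenotype", {
  fx <- fixture_mlm(n = 80, seed = 13)
  set.seed(14)
  s <- rbinom(80, 2, 0.5)
  fit <- suppressWarnings(fit_null_mlm(fx$y, fx$X, fx$K))
  r <- net_r2(fx$y, fx$X, fx$K, s, fit)
  expect_gte(r, 0); expect_lte(r, 1)
  r_scaled <- net_r2(5 * fx$y - 3, fx$X, fx$K, s,
                     suppressWarnings(fit_null_mlm(5 * fx$y - 3, fx$X,
                                                   fx$K)))
  expect_equal(r, r_scaled, tolerance = 1e-6)
  # marker orthogonal to the whitened residuals: construct via projection
  set.seed(15)
  n <- 50
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  fit_i <- suppressWarnings(fit_null_mlm(y, X, diag(n)))
  s_orth <- drop(qr.resid(qr(cbind(X, y)), rnorm(n)))
  expect_lt(net_r2(y, X, diag(n), s_orth, fit_i), 1e-10)
})

test_that("sequential covariate models absorb redundant markers and credit
           independent ones", {
  set.seed(16)
  n <- 300
  a <- rbinom(n, 2, 0.5)
  b <- rbinom(n, 2, 0.5)
  y <- a + b + rnorm(n, 0, 1)
  G <- toy_genotypes(cbind(a, a, b))
  X <- matrix(1, n, 1)
  suppressWarnings(
    out <- sequential_covariate_scan(y, X, diag(n), G,
                                     c("m01", "m02", "m03")))
  expect_equal(nrow(out), 3L)
  # duplicate of the first marker explains ~nothing at step 2
  expect_lt(out$net_r2[2], 0.02)
  # independent second QTL keeps its marginal share
  expect_gt(out$net_r2[3], 0.15)
  # empty order
  empty <- sequential_covariate_scan(y, X, diag(n), G, character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("near-perfect-LD grouping is single linkage with call-rate
           representatives", {
  set.seed(17)
  base <- rbinom(80, 2, 0.5)
  other <- rbinom(80, 2, 0.5)
  dup <- base
  dup[1] <- NA                          # lower call rate than base
  G <- toy_genotypes(cbind(base, dup, other))
  gr <- group_ld(G, r2_min = 0.999)
  sizes <- sort(unname(vapply(gr, function(g) length(g$members),
                              integer(1))))
  expect_equal(sizes, c(1L, 2L))
  big <- gr[[which(vapply(gr, function(g) length(g$members), integer(1)) ==
                     2)]]
  expect_equal(big$representative, "m01")   # higher call rate wins
  # independent markers: all singletons
  set.seed(18)
  Gi <- toy_genotypes(matrix(rbinom(60 * 5, 2, 0.5), 60, 5))
  expect_length(group_ld(Gi), 5L)
})

test_that("the iterative conditional scan selects planted QTL groups in
           effect order and stays empty under the null", {
  set.seed(19)
  n <- 300
  a <- rbinom(n, 2, 0.5); b <- rbinom(n, 2, 0.5)
  noise <- matrix(rbinom(n * 6, 2, 0.5), n, 6)
  G <- toy_genotypes(cbind(a, b, noise))
  X <- matrix(1, n, 1)
  y <- 1.0 * a + 0.5 * b + rnorm(n)
  gr <- group_ld(G)
  suppressWarnings(
    res <- iterative_conditional_scan(y, X, diag(n), G, gr))
  expect_equal(res$selected[1:2], c("m01", "m02"))
  # null phenotype: no selection at FDR 0.05 (fixed-seed replicate)
  y0 <- rnorm(n)
  suppressWarnings(
    res0 <- iterative_conditional_scan(y0, X, diag(n), G, gr))
  expect_length(res0$selected, 0L)
})

test_that("BH q-values follow the hand-computed step-up", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.5)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  sc <- c(0.01, 0.2, 0.03)
  expect_true(all(bh_fdr(sc) >= sc))
})

test_that("P3D and per-marker REML agree on the default scenario", {
  cfg <- scenario_config("coastal", n = 400, seed = 42)
  gg <- gen_genotypes(cfg)
  tr <- gen_run_timing(cfg, gg$truth)
  G28 <- subset_genotypes(gg$genotypes,
                          markers = which(gg$genotypes$markers$panel_class ==
                                            "chr28_candidate"))
  neut <- subset_genotypes(gg$genotypes,
                           markers = which(gg$genotypes$markers$panel_class ==
                                             "neutral_candidate"))
  K <- vanraden_kinship(neut)
  X <- covariate_design(400, sex = tr$male)
  suppressWarnings({
    s1 <- scan_mlm(tr$arrival_day, X, K, G28, p3d = TRUE)
    s2 <- scan_mlm(tr$arrival_day, X, K, G28, p3d = FALSE)
  })
  ok <- s1$note == "ok" & s1$p > 1e-300
  expect_true(all(abs(log10(s1$p[ok]) - log10(s2$p[ok])) <=
                    0.05 * pmax(abs(log10(s1$p[ok])), 1)))
})
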