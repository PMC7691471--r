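# shared fixture builders (all data constructed in code)

toy_markers <- function(k, prefix = "m", chrom = "1") {
  marker_table(sprintf("%s%02d", prefix, seq_len(k)), chrom,
               pos = seq_len(k) * 100L,
               ref_allele = rep("A", k), alt_allele = rep("G", k))
}

toy_genotypes <- function(dosage, prefix = "m") {
  dosage <- as.matrix(dosage)
  genotype_matrix(dosage, sprintf("s%03d", seq_len(nrow(dosage))),
                  toy_markers(ncol(dosage), prefix))
}

# minimal site table: Bonneville, one mainstem dam, one refuge mouth, one
# lower-distribution array, tributaries in two HUC/sub-basin groups
toy_sites <- function() {
  site_metadata(
    site_code = c("BON", "DAM1", "REF1", "LOWD", "TRA", "TRB", "TRC"),
    river_km = c(234, 347, 290, 700, 430, 520, 610),
    site_class = c("bonneville", "mainstem_dam", "thermal_refuge",
                   "lower_distribution", "tributary", "tributary",
                   "tributary"),
    huc = c("BON", "DAM", "REF", "LOW", "H1", "H1", "H2"),
    sub_basin = c("Bon", "Dam", "Ref", "Low", "SB1", "SB2", "SB3"),
    lineage = c(NA, NA, NA, NA, "inland", "inland", "inland"))
}

# build a fish_history from (site, day) pairs in calendar year `year`
toy_history <- function(tag, sites_days, year = 2016) {
  st <- toy_sites()
  ev <- data.frame(
    tag_id = tag,
    site_code = names(sites_days),
    river_km = st$river_km[match(names(sites_days), st$site_code)],
    date = as.Date(sprintf("%d-01-01", year)) + unlist(sites_days) - 1,
    stringsAsFactors = FALSE)
  summarize_history(ev, st)
}

# small mixed-model fixture with a real genetic component so the REML
# optimum is interior: y drawn with sigma_g2 = 4, sigma_e2 = 1
fixture_mlm <- function(n = 8, seed = 4) {
  set.seed(seed)
  L <- matrix(rnorm(n * 3), n, 3)
  K <- tcrossprod(L) / 3 + diag(n) * 0.2
  X <- cbind(1, rnorm(n))
  y <- drop(t(chol(4 * K + 1 * diag(n))) %*% rnorm(n)) + X %*% c(2, 0.5)
  list(y = drop(y), X = X, K = K)
}

# exhaustive-likelihood oracle for haplotype frequencies over <= 3 markers:
# maximizes the multinomial-pair likelihood over the full 2^k simplex by
# multi-start quasi-Newton on softmax coordinates
em_enum_oracle <- function(dos, n_starts = 30, seed = 1) {
  k <- ncol(dos)
  haps <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  H <- nrow(haps)
  pair_ok <- function(g, h1, h2) all(haps[h1, ] + haps[h2, ] == g)
  pairs <- lapply(seq_len(nrow(dos)), function(i) {
    g <- dos[i, ]
    idx <- which(outer(seq_len(H), seq_len(H), Vectorize(function(a, b) {
      pair_ok(g, a, b)
    })), arr.ind = TRUE)
    idx
  })
  negll <- function(theta) {
    f <- exp(c(theta, 0)); f <- f / sum(f)
    -sum(vapply(pairs, function(px) {
      log(sum(f[px[, 1]] * f[px[, 2]]))
    }, numeric(1)))
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- stats::rnorm(H - 1, 0, 2)
    o <- stats::optim(th0, negll, method = "BFGS",
                      control = list(maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  f <- exp(c(best$par, 0)); f <- f / sum(f)
  names(f) <- apply(haps, 1, paste, collapse = "")
  list(freq = f, loglik = -best$value)
}
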