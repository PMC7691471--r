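# Haplotype score statistics on GLM residuals with ambiguity-weighted
# dosages, permutation p-values with a relative-standard-error stopping
# rule, sliding-window subhaplotype scores, and score-test power.

#' Residuals from a covariate-only linear model
#'
#' Gaussian-family GLM residuals of a phenotype on non-genetic covariates;
#' the exchangeable quantity scored and permuted by the haplotype score
#' test.  Rank-deficient covariate matrices have their dependent columns
#' dropped with a warning.
#'
#' @param y Numeric phenotype.
#' @param covariates Design matrix (an intercept is added if absent).
#' @return Residual vector (mean ~ 0).
#' @export
glm_residuals <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1) else as.matrix(covariates)
  if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))) {
    X <- cbind(1, X)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient covariates; dependent columns dropped")
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  drop(qr.resid(qx, y))
}

# expected coding value per sample for each scored haplotype:
# additive = posterior-expected copy count; dominant = posterior P(>=1 copy)
.score_codings <- function(fit, hap_idx, coding) {
  p <- fit$pairs
  n <- fit$n
  E <- matrix(0, n, length(hap_idx))
  for (c_j in seq_along(hap_idx)) {
    h <- hap_idx[c_j]
    copies <- (p$hap1 == h) + (p$hap2 == h)
    val <- if (coding == "additive") copies else as.numeric(copies >= 1)
    E[, c_j] <- .acc(p$posterior * val, p$ind, n)
  }
  colnames(E) <- fit$haplotypes$string[hap_idx]
  E
}

#' Haplotype score statistics
#'
#' Scores each sufficiently frequent haplotype against covariate-adjusted
#' phenotype residuals.  For haplotype `h` with per-sample expected coding
#' `e_i(h)` (additive: posterior-expected copies in \[0,2\]; dominant:
#' posterior probability of carrying at least one copy), the score is
#' `U_h = sum_i r_i e_i(h)` with variance `V_h = s2 * ||P e_h||^2`, where
#' `P` projects onto the orthogonal complement of the covariate space and
#' `s2` is the residual variance; `z_h = U_h / sqrt(V_h)`.  The global
#' statistic is the quadratic form `U' V^- U` over all scored haplotypes
#' (Moore-Penrose inverse; df = rank), with significance by permutation of
#' the residuals (see [permute_pvalue()]).
#'
#' @param residuals Residual vector from [glm_residuals()].
#' @param fit A [em_haplotypes()] fit on the same samples (same order).
#' @param coding `"additive"` or `"dominant"`.
#' @param min_count Minimum expected haplotype count to be scored
#'   (default 5).
#' @param covariates Covariate matrix used for the residuals (for the
#'   projection adjustment); intercept-only if `NULL`.
#' @param n_perm_min,rel_se,n_perm_max,seed Permutation controls, see
#'   [permute_pvalue()]; `n_perm_min = 0` skips the permutation p-value.
#' @return An object of class `"haplo_score"`: `scores` (data frame
#'   `haplotype`, `label`, `coding`, `freq`, `count_expected`, `z`,
#'   `p_norm`), `global_stat`, `df`, `perm_p`, `n_perm`, `perm_se`,
#'   `converged`.
#' @export
haplo_score <- function(residuals, fit, coding = c("additive", "dominant"),
                        min_count = 5, covariates = NULL,
                        n_perm_min = 1000, rel_se = 0.05, n_perm_max = 1e5,
                        seed = NULL) {
  coding <- match.arg(coding)
  stopifnot(inherits(fit, "haplo_em"))
  r <- as.numeric(residuals)
  n <- length(r)
  if (n != fit$n) stop("residuals and haplotype fit sample count differ")
  hap_idx <- which(fit$haplotypes$count_expected >= min_count)
  if (!length(hap_idx)) stop("no haplotype reaches the minimum count")
  E <- .score_codings(fit, hap_idx, coding)
  X <- if (is.null(covariates)) matrix(1, n, 1) else as.matrix(covariates)
  if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))) {
    X <- cbind(1, X)
  }
  Et <- qr.resid(qr(X), E)           # covariate-adjusted, centered codings
  keep <- apply(Et, 2, function(e) sum(e^2) > 1e-12)
  if (!all(keep)) {
    warning("degenerate coding for haplotype(s) ",
            paste(colnames(E)[!keep], collapse = ", "), "; skipped")
    hap_idx <- hap_idx[keep]
    Et <- Et[, keep, drop = FALSE]
  }
  s2 <- sum(r^2) / n
  U <- drop(crossprod(Et, r))
  V <- s2 * crossprod(Et)
  z <- ifelse(diag(V) > 0, U / sqrt(diag(V)), 0)   # zero-residual guard
  Vinv <- MASS::ginv(V)
  df <- qr(V)$rank
  gstat <- drop(t(U) %*% Vinv %*% U)
  perm <- list(p = NA_real_, n_perm = 0L, se = NA_real_, converged = NA)
  if (n_perm_min > 0) {
    stat_fn <- function(Rm) {
      Um <- crossprod(Et, Rm)
      colSums(Um * (Vinv %*% Um))
    }
    perm <- permute_pvalue(stat_fn, r, gstat, min_perm = n_perm_min,
                           rel_se = rel_se, max_perm = n_perm_max,
                           seed = seed)
  }
  scores <- data.frame(haplotype = fit$haplotypes$string[hap_idx],
                       label = fit$haplotypes$label[hap_idx],
                       coding = coding,
                       freq = fit$haplotypes$freq[hap_idx],
                       count_expected = fit$haplotypes$count_expected[hap_idx],
                       z = z,
                       p_norm = 2 * stats::pnorm(-abs(z)),
                       stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  structure(list(scores = scores, global_stat = gstat, df = df,
                 perm_p = perm$p, n_perm = perm$n_perm, perm_se = perm$se,
                 converged = perm$converged),
            class = "haplo_score")
}

#' @export
print.haplo_score <- function(x, ...) {
  cat(sprintf("haplo_score: global stat %.3f (df %d), perm p = %s (n = %d)\n",
              x$global_stat, x$df,
              format.pval(x$perm_p, digits = 3), x$n_perm))
  print(x$scores, digits = 3)
  invisible(x)
}

#' Permutation p-value with a relative-standard-error stopping rule
#'
#' Permutes the residual vector across subjects and compares a statistic to
#' its permutation distribution: `p = (1 + #{perm >= observed}) /
#' (1 + n_perm)`.  At least `min_perm` permutations are run; permutation
#' continues in blocks until the standard error
#' `sqrt(p (1 - p) / n_perm)` falls below `rel_se * p`, or `max_perm` is
#' reached (result flagged unconverged).
#'
#' @param stat_fn Function taking an `n x B` matrix of permuted residual
#'   columns and returning `B` statistics (larger = more extreme).
#' @param residuals Residual vector, exchangeable under the null.
#' @param observed Observed statistic.
#' @param min_perm Minimum permutations (default 1000).
#' @param rel_se Stopping threshold on `se / p` (default 0.05).
#' @param max_perm Permutation cap (default 1e5).
#' @param seed Optional seed; a fixed seed makes the p-value reproducible.
#' @param block Permutations drawn per batch.
#' @return List `p`, `n_perm`, `se`, `converged`.
#' @export
permute_pvalue <- function(stat_fn, residuals, observed, min_perm = 1000,
                           rel_se = 0.05, max_perm = 1e5, seed = NULL,
                           block = 1000) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  r <- as.numeric(residuals)
  n <- length(r)
  n_perm <- 0L
  n_ge <- 0L
  repeat {
    b <- if (n_perm < min_perm) max(min_perm - n_perm, 1L)
         else min(block, max_perm - n_perm)
    Rm <- vapply(seq_len(b), function(i) r[sample.int(n)], numeric(n))
    stats_b <- stat_fn(Rm)
    n_ge <- n_ge + sum(stats_b >= observed - 1e-12)
    n_perm <- n_perm + b
    p <- (1 + n_ge) / (1 + n_perm)
    se <- sqrt(p * (1 - p) / n_perm)
    if (n_perm >= min_perm && se < rel_se * p) {
      return(list(p = p, n_perm = n_perm, se = se, converged = TRUE))
    }
    if (n_perm >= max_perm) {
      return(list(p = p, n_perm = n_perm, se = se, converged = FALSE))
    }
  }
}

#' Sliding-window subhaplotype score tests
#'
#' Re-estimates haplotypes by EM within each contiguous window of `window`
#' region markers and computes the global haplotype score statistic with its
#' permutation p-value per window, localizing the association signal along
#' the candidate region.
#'
#' @param residuals Residual vector from [glm_residuals()].
#' @param G A [genotype_matrix()] restricted to the candidate-region markers
#'   in genomic order.
#' @param window Window size in markers (default 3).
#' @param covariates Covariates used for the residuals.
#' @param min_count,coding See [haplo_score()].
#' @param em_attempts EM starts per window (default 20; windows are small).
#' @param n_perm_min,rel_se,n_perm_max Permutation controls.
#' @param seed Optional seed covering EM and permutations.
#' @return Data frame `start`, `size`, `global_stat`, `df`, `perm_p`,
#'   `n_perm`.  Windows with fewer than two distinct haplotypes get
#'   `perm_p = 1`.
#' @export
haplo_score_slide <- function(residuals, G, window = 3, covariates = NULL,
                              min_count = 5, coding = "additive",
                              em_attempts = 20, n_perm_min = 1000,
                              rel_se = 0.05, n_perm_max = 1e5, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- ncol(G$dosage)
  if (window > m) stop("window larger than the marker set")
  starts <- seq_len(m - window + 1L)
  out <- data.frame(start = starts, size = window, global_stat = NA_real_,
                    df = NA_integer_, perm_p = 1, n_perm = 0L)
  for (i in seq_along(starts)) {
    sub <- starts[i]:(starts[i] + window - 1L)
    sd_i <- if (is.null(seed)) NULL else seed + i
    fit <- em_haplotypes(G, markers = sub, attempts = em_attempts,
                         seed = sd_i)
    if (nrow(fit$haplotypes) < 2L ||
        sum(fit$haplotypes$count_expected >= min_count) < 2L) {
      next
    }
    hs <- haplo_score(residuals, fit, coding = coding,
                      min_count = min_count, covariates = covariates,
                      n_perm_min = n_perm_min, rel_se = rel_se,
                      n_perm_max = n_perm_max,
                      seed = if (is.null(sd_i)) NULL else sd_i + 10000L)
    out$global_stat[i] <- hs$global_stat
    out$df[i] <- hs$df
    out$perm_p[i] <- hs$perm_p
    out$n_perm[i] <- hs$n_perm
  }
  out
}

#' Power of the haplotype score test
#'
#' One-degree-of-freedom chi-square approximation for the power to detect a
#' haplotype explaining a fraction `r2` of phenotypic variance at sample
#' size `n`: noncentrality `ncp = n r2 / (1 - r2)`, power
#' `P(chisq_1(ncp) > chisq quantile at 1 - alpha)`.
#'
#' @param freq Haplotype frequency (recorded in the result).
#' @param r2 Variance fraction in \[0,1).
#' @param n Sample size (>= 10).
#' @param alpha Test level (default 0.05).
#' @return Data frame `freq`, `r2`, `n`, `alpha`, `power` (vectorized over
#'   the inputs, recycled to a common length).
#' @export
score_power <- function(freq, r2, n, alpha = 0.05) {
  stopifnot(all(freq > 0 & freq < 1), all(r2 >= 0 & r2 < 1), all(n >= 10))
  len <- max(length(freq), length(r2), length(n), length(alpha))
  freq <- rep_len(freq, len); r2 <- rep_len(r2, len)
  n <- rep_len(n, len); alpha <- rep_len(alpha, len)
  ncp <- n * r2 / (1 - r2)
  crit <- stats::qchisq(1 - alpha, df = 1)
  data.frame(freq = freq, r2 = r2, n = n, alpha = alpha,
             power = stats::pchisq(crit, df = 1, ncp = ncp,
                                   lower.tail = FALSE))
}
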