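# Kinship-aware mixed-linear-model association: EMMA-style REML variance
# components, P3D single-marker scans, net-R2 variance partitioning,
# sequential covariate models, near-perfect-LD grouping with an iterative
# conditional scan, and BH FDR correction.

#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over [stats::p.adjust()] kept as the pipeline's single FDR
#' entry point.
#'
#' @param p Vector of p-values in \[0,1\].
#' @return Monotone step-up q-values.
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Build a fixed-covariate design matrix
#'
#' Assembles the standard covariate set (intercept, sex, principal
#' components, optional ocean-age, fork length and SNP covariates) with the
#' pipeline's imputation rules: missing ocean-age is set to 1.5 years,
#' missing fork length to the cohort median, and missing SNP-covariate
#' genotypes to the heterozygote dosage 1.  Collinear columns are dropped
#' with a warning so the result has full column rank.
#'
#' @param n Number of samples (rows).
#' @param sex Optional 0/1 vector (1 = male).
#' @param pcs Optional matrix of principal-component scores.
#' @param ocean_age,fork_length Optional numeric covariates.
#' @param snp_covariates Optional dosage matrix of SNP covariates.
#' @return Numeric design matrix with an `"(Intercept)"` first column.
#' @export
covariate_design <- function(n, sex = NULL, pcs = NULL, ocean_age = NULL,
                             fork_length = NULL, snp_covariates = NULL) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  add <- function(X, v, nm) {
    v <- as.matrix(v)
    if (nrow(v) != n) stop("covariate '", nm, "' has wrong length")
    if (is.null(colnames(v))) {
      colnames(v) <- if (ncol(v) == 1) nm else paste0(nm, seq_len(ncol(v)))
    }
    cbind(X, v)
  }
  if (!is.null(sex)) X <- add(X, as.numeric(sex), "sex")
  if (!is.null(pcs)) X <- add(X, pcs, "PC")
  if (!is.null(ocean_age)) {
    oa <- as.numeric(ocean_age); oa[is.na(oa)] <- 1.5
    X <- add(X, oa, "ocean_age")
  }
  if (!is.null(fork_length)) {
    fl <- as.numeric(fork_length)
    fl[is.na(fl)] <- stats::median(fl, na.rm = TRUE)
    X <- add(X, fl, "fork_length")
  }
  if (!is.null(snp_covariates)) {
    sc <- as.matrix(snp_covariates); sc[is.na(sc)] <- 1
    X <- add(X, sc, "snp")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    warning("dropping collinear covariate column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  X
}

# restricted log-likelihood profile in delta = sigma_e2 / sigma_g2, given the
# eigendecomposition of K
.reml_ll <- function(delta, lambda, Gam, om, ldXX) {
  n <- length(om); p <- ncol(Gam)
  v <- lambda + delta
  w <- 1 / v
  A <- crossprod(Gam, Gam * w)
  bhat <- solve(A, crossprod(Gam, om * w))
  r <- om - Gam %*% bhat
  rss <- sum(w * r^2)
  sig_g <- rss / (n - p)
  as.numeric(-0.5 * ((n - p) * log(2 * pi * sig_g) + (n - p) +
                       sum(log(v)) +
                       determinant(A, logarithm = TRUE)$modulus - ldXX))
}

#' Restricted log-likelihood profile of the kinship mixed model
#'
#' Evaluates the REML log-likelihood of `y = X b + u + e`,
#' `var(u) = sigma_g^2 K`, `var(e) = sigma_e^2 I`, profiled over
#' `delta = sigma_e^2 / sigma_g^2`.  Exposed so the optimum found by
#' [fit_null_mlm()] can be checked against dense grid search.
#'
#' @param y Response vector.
#' @param X Full-rank fixed-effect design matrix.
#' @param K Symmetric PSD kinship matrix.
#' @param delta Vector of variance ratios at which to evaluate.
#' @return Numeric vector of restricted log-likelihoods.
#' @export
reml_profile <- function(y, X, K, delta) {
  eg <- eigen(K, symmetric = TRUE)
  Gam <- crossprod(eg$vectors, X)
  om <- drop(crossprod(eg$vectors, y))
  ldXX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  vapply(delta, .reml_ll, numeric(1), lambda = eg$values, Gam = Gam,
         om = om, ldXX = ldXX)
}

#' Fit the null kinship mixed model by REML
#'
#' Estimates the variance components of the covariate-only mixed model with
#' the kinship matrix as the random-effect covariance.  The restricted
#' likelihood is profiled over `delta = sigma_e^2 / sigma_g^2` on a 100-point
#' log grid spanning 1e-5..1e5 and refined by bounded scalar optimization
#' around the grid maximum (EMMA-style, via one eigendecomposition of `K`).
#'
#' @param y Response vector (no missing values).
#' @param X Full-rank fixed-effect design matrix (use [covariate_design()]).
#' @param K Symmetric PSD kinship matrix.
#' @param grid_points Number of grid points (default 100).
#' @return An object of class `"mlm_null"`: `sigma_g2`, `sigma_e2`, `delta`,
#'   `reml_loglik`, plus the cached eigendecomposition used for whitening.
#'   Hitting the grid boundary raises a warning and returns the boundary
#'   estimate.
#' @export
fit_null_mlm <- function(y, X, K, grid_points = 100) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(K) != n) stop("dimension mismatch")
  if (n <= ncol(X) + 1) stop("need n > ncol(X) + 1")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("kinship matrix is not symmetric")
  }
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
    stop("kinship matrix is not PSD within tolerance")
  }
  eg$values <- pmax(eg$values, 0)
  Gam <- crossprod(eg$vectors, X)
  om <- drop(crossprod(eg$vectors, y))
  ldXX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  lg <- seq(-5, 5, length.out = grid_points)
  ll <- vapply(10^lg, .reml_ll, numeric(1), lambda = eg$values, Gam = Gam,
               om = om, ldXX = ldXX)
  i <- which.max(ll)
  if (i == 1L || i == grid_points) {
    warning("REML optimum at the delta grid boundary; boundary estimate ",
            "returned")
    opt <- list(maximum = lg[i], objective = ll[i])
  } else {
    opt <- stats::optimize(function(l) {
      .reml_ll(10^l, eg$values, Gam, om, ldXX)
    }, lower = lg[i - 1], upper = lg[i + 1], maximum = TRUE,
    tol = .Machine$double.eps^0.4)
    if (opt$objective < ll[i]) opt <- list(maximum = lg[i], objective = ll[i])
  }
  delta <- 10^opt$maximum
  v <- eg$values + delta
  w <- 1 / v
  A <- crossprod(Gam, Gam * w)
  bhat <- solve(A, crossprod(Gam, om * w))
  rss <- sum(w * (om - Gam %*% bhat)^2)
  sigma_g2 <- rss / (n - ncol(X))
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2,
                 delta = delta, reml_loglik = opt$objective,
                 U = eg$vectors, lambda = eg$values, n = n),
            class = "mlm_null")
}

#' @export
print.mlm_null <- function(x, ...) {
  cat(sprintf(paste0("mlm_null: sigma_g2 = %.4g, sigma_e2 = %.4g ",
                     "(delta = %.4g), REML loglik = %.4f\n"),
              x$sigma_g2, x$sigma_e2, x$delta, x$reml_loglik))
  invisible(x)
}

# whitening transform T such that var(T y) is proportional to I under the
# fitted null: T = diag(1/sqrt(lambda + delta)) U'
.whiten <- function(fit, M) {
  (crossprod(fit$U, M)) / sqrt(fit$lambda + fit$delta)
}

# GLS on whitened data; returns beta/se/p for the last column of the design
.wald_last <- function(yw, Dw) {
  n <- length(yw); p <- ncol(Dw)
  qd <- qr(Dw)
  if (qd$rank < p) return(NULL)
  cf <- qr.coef(qd, yw)
  res <- yw - Dw %*% cf
  s2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qd))
  se <- sqrt(s2 * XtXinv[p, p])
  t <- cf[p] / se
  list(beta = cf[p], se = se,
       p = 2 * stats::pt(-abs(t), df = n - p), rss = sum(res^2))
}

#' Single-marker mixed-model association scan
#'
#' Tests each marker by generalized least squares on data whitened under the
#' null variance components (P3D: the components are estimated once without
#' any SNP and reused for every marker; `p3d = FALSE` re-fits the REML per
#' marker).  Missing dosages at the tested marker are mean-imputed; each
#' marker's net R2 (see [net_r2()]) and BH q-value across the scan are
#' reported.
#'
#' @param y Response vector.
#' @param X Fixed-covariate design matrix (including intercept).
#' @param K Kinship matrix.
#' @param G A [genotype_matrix()].
#' @param markers Marker subset to scan (default: all).
#' @param p3d Reuse null variance components for all markers (default TRUE).
#' @param null_fit Optional pre-computed [fit_null_mlm()] object.
#' @return Data frame `marker_id`, `beta` (per alt-allele copy), `se`, `p`,
#'   `q`, `net_r2`, `note` (`"ok"`, `"monomorphic"` or `"collinear"`).
#' @export
scan_mlm <- function(y, X, K, G, markers = NULL, p3d = TRUE,
                     null_fit = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  Gs <- subset_genotypes(G, markers = markers)
  y <- as.numeric(y); X <- as.matrix(X)
  if (is.null(null_fit)) null_fit <- fit_null_mlm(y, X, K)
  yw <- drop(.whiten(null_fit, y))
  Xw <- .whiten(null_fit, X)
  ones_w <- .whiten(null_fit, matrix(1, length(y), 1))
  rss_tot <- sum(qr.resid(qr(ones_w), yw)^2)
  rss_red <- sum(qr.resid(qr(Xw), yw)^2)
  m <- ncol(Gs$dosage)
  out <- data.frame(marker_id = Gs$markers$marker_id,
                    beta = 0, se = NA_real_, p = 1, q = NA_real_,
                    net_r2 = 0, note = "ok", stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    s <- Gs$dosage[, j]
    if (all(is.na(s)) || stats::var(s, na.rm = TRUE) == 0) {
      out$note[j] <- "monomorphic"
      next
    }
    s[is.na(s)] <- mean(s, na.rm = TRUE)
    if (p3d) {
      sw <- drop(.whiten(null_fit, s))
      res <- .wald_last(yw, cbind(Xw, sw))
      if (is.null(res)) {
        out$note[j] <- "collinear"
        warning("marker ", Gs$markers$marker_id[j],
                " collinear with covariates; skipped")
        next
      }
      out$beta[j] <- res$beta; out$se[j] <- res$se; out$p[j] <- res$p
      out$net_r2[j] <- min(max((rss_red - res$rss) / rss_tot, 0), 1)
    } else {
      fitj <- fit_null_mlm(y, cbind(X, snp = s), K)
      ywj <- drop(.whiten(fitj, y))
      Dwj <- .whiten(fitj, cbind(X, snp = s))
      res <- .wald_last(ywj, Dwj)
      if (is.null(res)) { out$note[j] <- "collinear"; next }
      onesj <- .whiten(fitj, matrix(1, length(y), 1))
      rss_tj <- sum(qr.resid(qr(onesj), ywj)^2)
      rss_rj <- sum(qr.resid(qr(.whiten(fitj, X)), ywj)^2)
      out$beta[j] <- res$beta; out$se[j] <- res$se; out$p[j] <- res$p
      out$net_r2[j] <- min(max((rss_rj - res$rss) / rss_tj, 0), 1)
    }
  }
  out$q <- bh_fdr(out$p)
  out
}

#' Net R2 of one marker in the kinship mixed model
#'
#' The variance in the phenotype explained by adding one marker to the
#' covariate-plus-kinship model, computed on whitened (decorrelated) data:
#' `net_r2 = (RSS_reduced - RSS_full) / RSS_total`, where the reduced model
#' holds the covariates, the full model adds the marker dosage, and
#' `RSS_total` is the residual sum of squares about the whitened
#' intercept-only fit.  Bounded to \[0,1\]; invariant to affine rescaling of
#' `y`.
#'
#' @param y Response vector.
#' @param X Covariate design matrix.
#' @param K Kinship matrix.
#' @param snp Dosage vector (missing values mean-imputed).
#' @param null_fit Optional pre-computed null fit.
#' @return Scalar net R2.
#' @export
net_r2 <- function(y, X, K, snp, null_fit = NULL) {
  y <- as.numeric(y); X <- as.matrix(X)
  if (is.null(null_fit)) null_fit <- fit_null_mlm(y, X, K)
  s <- as.numeric(snp)
  s[is.na(s)] <- mean(s, na.rm = TRUE)
  yw <- drop(.whiten(null_fit, y))
  Xw <- .whiten(null_fit, X)
  sw <- drop(.whiten(null_fit, s))
  ones_w <- .whiten(null_fit, matrix(1, length(y), 1))
  rss_tot <- sum(qr.resid(qr(ones_w), yw)^2)
  rss_red <- sum(qr.resid(qr(Xw), yw)^2)
  rss_full <- sum(qr.resid(qr(cbind(Xw, sw)), yw)^2)
  min(max((rss_red - rss_full) / rss_tot, 0), 1)
}

#' Sequential covariate variance partitioning
#'
#' Given markers ordered by significance, step `t` fits the mixed model with
#' markers `1..t-1` added as fixed covariates (missing covariate genotypes
#' set to the heterozygote dosage 1) and reports the net R2 and p-value of
#' the `t`-th marker: the variance each marker explains beyond the ones
#' before it.
#'
#' @param y,X,K As in [scan_mlm()].
#' @param G A [genotype_matrix()].
#' @param snp_order Character vector of marker ids in testing order.
#' @param null_fit Optional null fit reused for whitening at every step.
#' @return Data frame `step`, `marker_id`, `net_r2`, `p`.
#' @export
sequential_covariate_scan <- function(y, X, K, G, snp_order,
                                      null_fit = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!length(snp_order)) {
    return(data.frame(step = integer(0), marker_id = character(0),
                      net_r2 = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  y <- as.numeric(y); X <- as.matrix(X)
  if (is.null(null_fit)) null_fit <- fit_null_mlm(y, X, K)
  out <- data.frame(step = seq_along(snp_order), marker_id = snp_order,
                    net_r2 = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (t in seq_along(snp_order)) {
    covs <- NULL
    if (t > 1) {
      covs <- G$dosage[, snp_order[seq_len(t - 1)], drop = FALSE]
      covs[is.na(covs)] <- 1
    }
    Xt <- if (is.null(covs)) X else cbind(X, covs)
    qx <- qr(Xt)
    if (qx$rank < ncol(Xt)) {
      warning("collinear SNP covariate dropped at step ", t)
      Xt <- Xt[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    }
    s <- G$dosage[, snp_order[t]]
    s[is.na(s)] <- mean(s, na.rm = TRUE)
    yw <- drop(.whiten(null_fit, y))
    Xw <- .whiten(null_fit, Xt)
    sw <- drop(.whiten(null_fit, s))
    ones_w <- .whiten(null_fit, matrix(1, length(y), 1))
    res <- .wald_last(yw, cbind(Xw, sw))
    if (is.null(res)) {
      # marker fully absorbed by the preceding covariates
      out$net_r2[t] <- 0
      out$p[t] <- 1
      next
    }
    rss_tot <- sum(qr.resid(qr(ones_w), yw)^2)
    rss_red <- sum(qr.resid(qr(Xw), yw)^2)
    out$net_r2[t] <- min(max((rss_red - res$rss) / rss_tot, 0), 1)
    out$p[t] <- res$p
  }
  out
}

#' Group markers in near-perfect LD
#'
#' Single-linkage clustering of markers at a dosage-correlation threshold
#' (default r^2 >= 0.999): two markers join a group when connected by a chain
#' of pairs above the threshold.  Each group is represented by its
#' highest-call-rate member (ties: smallest position).
#'
#' @param G A [genotype_matrix()].
#' @param markers Optional marker subset.
#' @param r2_min Grouping threshold (default 0.999).
#' @return List of groups, each `list(members, representative)` of marker
#'   ids.
#' @export
group_ld <- function(G, markers = NULL, r2_min = 0.999) {
  Gs <- subset_genotypes(G, markers = markers)
  m <- ncol(Gs$dosage)
  R <- ld_matrix(Gs, method = "dosage")
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (!is.na(R[i, j]) && R[i, j] >= r2_min) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  call_rate <- colMeans(!is.na(Gs$dosage))
  lapply(split(seq_len(m), roots), function(ix) {
    rep_ix <- ix[order(-call_rate[ix], Gs$markers$pos[ix])][1]
    list(members = Gs$markers$marker_id[ix],
         representative = Gs$markers$marker_id[rep_ix])
  })
}

#' Iterative conditional scan over LD groups
#'
#' Forward selection over LD-group representatives: at each iteration the
#' representatives not yet selected are scanned with the current selection
#' included as fixed covariates (missing genotypes as heterozygotes); if the
#' best BH q-value falls below `fdr` that group is added, otherwise the scan
#' stops.  A transparent surrogate for model-selection methods that report
#' significant LD groups while conditioning on those already found.
#'
#' @param y,X,K As in [scan_mlm()].
#' @param G A [genotype_matrix()].
#' @param groups Output of [group_ld()].
#' @param fdr Selection threshold on BH q (default 0.05).
#' @param max_iter Iteration cap (default 10; exceeding it warns and returns
#'   the partial result).
#' @return List with `selected` (representative ids in inclusion order) and
#'   `log` (data frame `iteration`, `marker_id`, `p`, `q`, `selected`).
#' @export
iterative_conditional_scan <- function(y, X, K, G, groups, fdr = 0.05,
                                       max_iter = 10) {
  reps <- vapply(groups, `[[`, character(1), "representative")
  selected <- character(0)
  log <- NULL
  null_fit <- fit_null_mlm(as.numeric(y), as.matrix(X), K)
  for (it in seq_len(max_iter)) {
    remaining <- setdiff(reps, selected)
    if (!length(remaining)) break
    covs <- NULL
    if (length(selected)) {
      covs <- G$dosage[, selected, drop = FALSE]
      covs[is.na(covs)] <- 1
    }
    Xt <- if (is.null(covs)) as.matrix(X) else cbind(as.matrix(X), covs)
    qx <- qr(Xt)
    Xt <- Xt[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    sc <- scan_mlm(y, Xt, K, G, markers = remaining, null_fit = null_fit)
    best <- which.min(sc$q)
    hit <- sc$q[best] < fdr & sc$note[best] == "ok"
    log <- rbind(log, data.frame(iteration = it,
                                 marker_id = sc$marker_id,
                                 p = sc$p, q = sc$q,
                                 selected = seq_len(nrow(sc)) == best & hit,
                                 stringsAsFactors = FALSE))
    if (!hit) break
    selected <- c(selected, sc$marker_id[best])
    if (it == max_iter && length(setdiff(reps, selected))) {
      warning("iterative conditional scan reached max_iter; partial result")
    }
  }
  list(selected = selected, log = log)
}
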