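# Neutral-marker covariate machinery: per-locus FST screen, genomic kinship,
# principal-component covariates.

# Weir & Cockerham (1984) per-locus theta from dosages and population labels.
# Returns a vector over loci; monomorphic loci are NA.
.wc_fst <- function(dos, pop) {
  pops <- unique(pop)
  r <- length(pops)
  m <- ncol(dos)
  n_i <- matrix(0, r, m)     # samples genotyped per pop x locus
  p_i <- matrix(0, r, m)     # alt-allele frequency per pop x locus
  h_i <- matrix(0, r, m)     # observed heterozygote fraction
  for (k in seq_len(r)) {
    d <- dos[pop == pops[k], , drop = FALSE]
    n_i[k, ] <- colSums(!is.na(d))
    p_i[k, ] <- colMeans(d, na.rm = TRUE) / 2
    h_i[k, ] <- colMeans(d == 1L, na.rm = TRUE)
  }
  n_bar <- colMeans(n_i)
  nc <- (r * n_bar - colSums(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- colSums(n_i * p_i) / (r * n_bar)
  s2 <- colSums(n_i * sweep(p_i, 2, p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n_i * h_i) / (r * n_bar)
  a <- n_bar / nc *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  fst <- a / denom
  fst[!is.finite(fst) | denom <= 0] <- NA_real_
  mono <- p_bar <= 0 | p_bar >= 1
  fst[mono] <- NA_real_
  fst
}

#' Per-locus FST outlier screen
#'
#' Weir-Cockerham per-locus FST between populations, with outliers flagged by
#' a permutation null: population labels are permuted `n_perm` times, each
#' locus' upper-tail p-value is Benjamini-Hochberg adjusted, and loci with
#' `q <= q_threshold` are flagged.  Loci that are not flagged form a
#' transparent "neutral" set for kinship and PCA (a curated neutral marker
#' list may be supplied instead wherever a neutral set is needed).
#'
#' @param G A [genotype_matrix()].
#' @param pop Population labels, one per sample (at least 2 populations with
#'   at least 5 samples each).
#' @param n_perm Number of label permutations (default 999).
#' @param q_threshold FDR threshold flagging outliers (default 0.1).
#' @param seed Optional seed for the permutations.
#' @return Data frame `marker_id`, `fst`, `p`, `q`, `outlier`; monomorphic
#'   loci carry `NA` and are never flagged.
#' @export
fst_screen <- function(G, pop, n_perm = 999, q_threshold = 0.1, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  pop <- as.character(pop)
  tab <- table(pop)
  if (length(tab) < 2L || any(tab < 5L)) {
    stop("need >= 2 populations with >= 5 samples each")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  dos <- G$dosage
  obs <- .wc_fst(dos, pop)
  ge <- rep(1L, ncol(dos))          # +1 smoothing: null includes observed
  for (b in seq_len(n_perm)) {
    f <- .wc_fst(dos, sample(pop))
    ge <- ge + as.integer(!is.na(f) & !is.na(obs) & f >= obs)
  }
  p <- ge / (n_perm + 1)
  p[is.na(obs)] <- NA_real_
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(marker_id = G$markers$marker_id, fst = obs, p = p, q = q,
             outlier = !is.na(q) & q <= q_threshold,
             stringsAsFactors = FALSE)
}

#' VanRaden genomic kinship matrix
#'
#' VanRaden method-1 genomic relationship matrix from a (neutral) dosage
#' matrix: `K = Z Z' / (2 sum pk (1 - pk))` with `Z` the column-centered
#' dosages (missing dosages mean-imputed per marker) and `pk` the sample
#' alt-allele frequencies.
#'
#' @param G A [genotype_matrix()], typically restricted to neutral markers.
#' @return A symmetric positive semidefinite `n x n` matrix with sample ids
#'   as dimnames and attribute `method = "vanraden1"`.
#' @export
vanraden_kinship <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosage
  p <- colMeans(dos, na.rm = TRUE) / 2
  v <- apply(dos, 2, stats::var, na.rm = TRUE)
  keep <- !is.na(p) & p > 0 & p < 1 & !is.na(v) & v > 0
  if (!any(keep)) {
    stop("all markers monomorphic or constant; kinship undefined")
  }
  dos <- dos[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(dos, 2, 2 * p)
  Z[is.na(Z)] <- 0            # mean imputation after centering
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(G$sample_ids, G$sample_ids)
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8 * max(abs(K))) {
    warning("kinship matrix not PSD within tolerance (min eigenvalue ",
            signif(ev, 3), ")")
  }
  attr(K, "method") <- "vanraden1"
  K
}

#' Principal-component covariates from neutral markers
#'
#' Top principal components of the mean-imputed, centered dosage matrix,
#' used as fixed covariates capturing population structure.
#'
#' @param G A [genotype_matrix()], typically the neutral set.
#' @param p Number of components (default 3; reduced with a warning if it
#'   exceeds the matrix rank).
#' @return List with `scores` (`n x p`, columns `PC1..`), and
#'   `variance_fraction` (eigenvalue share of total variance per axis).
#' @export
pca_covariates <- function(G, p = 3) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosage
  mu <- colMeans(dos, na.rm = TRUE)
  X <- sweep(dos, 2, mu)
  X[is.na(X)] <- 0
  keep <- apply(X, 2, function(z) any(z != 0))
  X <- X[, keep, drop = FALSE]
  pr <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  rank <- sum(pr$sdev > 1e-10 * pr$sdev[1])
  if (p > rank) {
    warning("requested ", p, " components but rank is ", rank, "; reduced")
    p <- rank
  }
  scores <- pr$x[, seq_len(p), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(p))
  rownames(scores) <- G$sample_ids
  list(scores = scores,
       variance_fraction = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(p)])
}
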