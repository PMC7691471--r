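# EM haplotype-frequency estimation with progressive marker insertion.
#
# Haplotypes over the current marker prefix are binary strings in alt-allele
# coding ("0" = ref, "1" = alt).  Per individual we carry the list of ORDERED
# compatible haplotype pairs; ordered pairs make expansion and the E-step
# trivial (prior f1*f2, heterozygous pairs appear in both orders) at the cost
# of a factor <= 2 in memory.

# scatter-accumulate: sum of w by integer group g into a length-ng vector
.acc <- function(w, g, ng) {
  r <- rowsum(w, g)
  out <- numeric(ng)
  out[as.integer(rownames(r))] <- r
  out
}

# ordered extension pairs compatible with a block genotype (0/1/2/NA vector);
# returns a 2-column character matrix of sub-haplotype strings
.block_extensions <- function(g) {
  opts <- lapply(g, function(d) {
    if (is.na(d)) list(c("0", "0"), c("0", "1"), c("1", "0"), c("1", "1"))
    else if (d == 0L) list(c("0", "0"))
    else if (d == 2L) list(c("1", "1"))
    else list(c("0", "1"), c("1", "0"))
  })
  n_opts <- vapply(opts, length, integer(1))
  if (prod(n_opts) > 65536) {
    stop("too many compatible phase assignments for one individual; ",
         "filter missingness first")
  }
  grid <- expand.grid(lapply(n_opts, seq_len), KEEP.OUT.ATTRS = FALSE)
  e1 <- apply(grid, 1, function(ix) {
    paste(vapply(seq_along(ix), function(m) opts[[m]][[ix[m]]][1],
                 character(1)), collapse = "")
  })
  e2 <- apply(grid, 1, function(ix) {
    paste(vapply(seq_along(ix), function(m) opts[[m]][[ix[m]]][2],
                 character(1)), collapse = "")
  })
  cbind(e1, e2)
}

# expand existing ordered pairs by one marker block
.expand_pairs <- function(pairs, block) {
  # pairs: data.frame(ind, h1, h2) with haplotype strings; block: n x b matrix
  pat <- apply(block, 1, function(g) paste(ifelse(is.na(g), "N", g),
                                           collapse = ""))
  ext_by_pat <- lapply(split(seq_len(nrow(block)), pat)[unique(pat)],
                       function(rows) .block_extensions(block[rows[1], ]))
  ext <- ext_by_pat[pat[pairs$ind]]
  reps <- vapply(ext, nrow, integer(1))
  idx <- rep(seq_len(nrow(pairs)), reps)
  emat <- do.call(rbind, ext)
  data.frame(ind = pairs$ind[idx],
             h1 = paste0(pairs$h1[idx], emat[, 1]),
             h2 = paste0(pairs$h2[idx], emat[, 2]),
             stringsAsFactors = FALSE)
}

# one EM run to convergence on a fixed pair list; returns freqs, ll, posteriors
.em_iterate <- function(i1, i2, ind, n_ind, n_hap, f0, tol, max_iter) {
  f <- f0
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    w <- f[i1] * f[i2]
    denom <- .acc(w, ind, n_ind)
    if (any(denom <= 0)) {
      # an individual lost all its mass; re-seed that individual uniformly
      w <- w + 1e-300
      denom <- .acc(w, ind, n_ind)
    }
    ll <- sum(log(denom))
    post <- w / denom[ind]
    f <- (.acc(post, i1, n_hap) + .acc(post, i2, n_hap)) / (2 * n_ind)
    if (is.finite(ll_prev) && ll < ll_prev - 1e-6 * max(1, abs(ll_prev))) {
      stop("internal error: EM log-likelihood decreased")
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      return(list(freq = f, loglik = ll, post = post, iter = it,
                  converged = TRUE))
    }
    ll_prev <- ll
  }
  list(freq = f, loglik = ll_prev, post = post, iter = max_iter,
       converged = FALSE)
}

# full progressive-insertion EM for one start
.em_one_attempt <- function(dos, blocks, trim, tol, max_iter, random_start) {
  n <- nrow(dos)
  pairs <- data.frame(ind = seq_len(n), h1 = "", h2 = "",
                      stringsAsFactors = FALSE)
  res <- NULL
  for (b in seq_along(blocks)) {
    pairs <- .expand_pairs(pairs, dos[, blocks[[b]], drop = FALSE])
    haps <- sort(unique(c(pairs$h1, pairs$h2)))
    i1 <- match(pairs$h1, haps)
    i2 <- match(pairs$h2, haps)
    H <- length(haps)
    f0 <- if (random_start) {
      g <- stats::rgamma(H, shape = 1)
      g / sum(g)
    } else {
      rep(1 / H, H)
    }
    res <- .em_iterate(i1, i2, pairs$ind, n, H, f0, tol, max_iter)
    # trim low-posterior pairs, keeping at least the best pair per individual
    best <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$ind),
                          function(ix) ix[which.max(res$post[ix])]),
                   use.names = FALSE)
    keep <- res$post >= trim
    keep[best] <- TRUE
    pairs <- pairs[keep, , drop = FALSE]
    res$post <- res$post[keep]
    res$post <- res$post / .acc(res$post, pairs$ind, n)[pairs$ind]
    res$haps <- haps
    res$pairs <- pairs
  }
  # recompute frequencies from the trimmed posteriors so they stay on the
  # simplex after renormalization
  haps <- sort(unique(c(res$pairs$h1, res$pairs$h2)))
  i1 <- match(res$pairs$h1, haps)
  i2 <- match(res$pairs$h2, haps)
  freq <- (.acc(res$post, i1, length(haps)) +
           .acc(res$post, i2, length(haps))) / (2 * n)
  list(haps = haps, freq = freq, pairs = res$pairs, post = res$post,
       loglik = res$loglik, converged = res$converged)
}

.hap_letters <- function(bits, markers) {
  alle <- rbind(markers$ref_allele, markers$alt_allele)
  vapply(strsplit(bits, ""), function(b) {
    paste(alle[cbind(as.integer(b) + 1L, seq_along(b))], collapse = "")
  }, character(1))
}

#' EM haplotype-frequency estimation with progressive marker insertion
#'
#' Estimates haplotype frequencies for a set of tightly linked markers from
#' unphased diploid genotypes.  Markers are inserted in batches of
#' `insert_batch`; after each insertion the EM is iterated until the
#' log-likelihood changes by less than `tol`, and haplotype pairs whose
#' posterior probability falls below `trim` are dropped (the posterior is
#' renormalized).  The estimate returned is the best of `attempts` runs
#' (uniform start plus random Dirichlet restarts) by final log-likelihood.
#'
#' @param G A [genotype_matrix()].
#' @param markers Marker subset (indices or ids); default all markers in `G`.
#' @param insert_batch Markers inserted per batch (default 6).
#' @param trim Posterior trimming threshold (default 1e-9).
#' @param tol Log-likelihood convergence tolerance (default 1e-5).
#' @param attempts Number of EM starts (default 100).
#' @param max_iter Iteration cap per EM stage.
#' @param seed Optional integer seed making the whole call deterministic.
#' @return An object of class `"haplo_em"`: a list with
#'   \describe{
#'     \item{haplotypes}{data frame `string` (allele letters), `bits`
#'       (alt-allele coding), `freq` (simplex), `count_expected`
#'       (`freq * 2n`), `label` (`NA` until [label_haplotypes()]).}
#'     \item{pairs}{data frame of per-sample unordered haplotype pairs
#'       (`sample_id`, `hap1`, `hap2` as row indices into `haplotypes`,
#'       `posterior`); posteriors sum to 1 per sample.}
#'     \item{loglik, converged, n, markers}{fit metadata.}
#'   }
#' @export
em_haplotypes <- function(G, markers = NULL, insert_batch = 6, trim = 1e-9,
                          tol = 1e-5, attempts = 100, max_iter = 2000,
                          seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  Gs <- subset_genotypes(G, markers = markers)
  dos <- Gs$dosage
  k <- ncol(dos)
  if (k < 1L) stop("no markers selected")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  blocks <- split(seq_len(k), ceiling(seq_len(k) / insert_batch))
  best <- NULL
  n_conv <- 0L
  for (a in seq_len(attempts)) {
    fit <- .em_one_attempt(dos, blocks, trim, tol, max_iter,
                           random_start = a > 1L)
    if (fit$converged) n_conv <- n_conv + 1L
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (n_conv == 0L) {
    stop("EM failed to converge in any of ", attempts, " attempts ",
         "(best log-likelihood ", signif(best$loglik, 8), ")")
  }
  n <- nrow(dos)
  hap_df <- data.frame(string = .hap_letters(best$haps, Gs$markers),
                       bits = best$haps,
                       freq = best$freq,
                       count_expected = best$freq * 2 * n,
                       label = NA_character_,
                       stringsAsFactors = FALSE)
  # collapse ordered pairs to unordered with summed posteriors
  p <- best$pairs
  i1 <- match(p$h1, best$haps); i2 <- match(p$h2, best$haps)
  a <- pmin(i1, i2); b <- pmax(i1, i2)
  key <- paste(p$ind, a, b)
  first <- !duplicated(key)
  post <- .acc(best$post, match(key, key[first]), sum(first))
  pairs_df <- data.frame(sample_id = Gs$sample_ids[p$ind[first]],
                         ind = p$ind[first],
                         hap1 = a[first], hap2 = b[first],
                         posterior = post,
                         stringsAsFactors = FALSE)
  pairs_df <- pairs_df[order(pairs_df$ind, -pairs_df$posterior), ]
  rownames(pairs_df) <- NULL
  structure(list(haplotypes = hap_df, pairs = pairs_df,
                 loglik = best$loglik, converged = TRUE, n = n,
                 markers = Gs$markers),
            class = "haplo_em")
}

#' @export
print.haplo_em <- function(x, ...) {
  cat(sprintf("haplo_em: %d haplotypes over %d markers, n = %d, loglik = %.4f\n",
              nrow(x$haplotypes), nrow(x$markers), x$n, x$loglik))
  top <- utils::head(x$haplotypes[order(-x$haplotypes$freq), ], 8)
  print(top[, c("string", "freq", "count_expected", "label")], digits = 4)
  invisible(x)
}

#' Label estimated haplotypes against a packaged pool
#'
#' Attaches the roman-numeral labels of a packaged haplotype catalogue
#' (see [haplotype_pool()]) to the haplotypes of a fit whose allele strings
#' match.
#'
#' @param fit A `"haplo_em"` object.
#' @param pool A data frame with `label` and `string` columns.
#' @return The fit with `haplotypes$label` filled where matched.
#' @export
label_haplotypes <- function(fit, pool) {
  stopifnot(inherits(fit, "haplo_em"))
  m <- match(fit$haplotypes$string, pool$string)
  fit$haplotypes$label <- ifelse(is.na(m), NA_character_, pool$label[m])
  fit
}

#' Best-pair phasing from EM posteriors
#'
#' Deterministic phasing: each sample is assigned its maximal-posterior
#' haplotype pair; ties are broken by the lexicographically smaller pair of
#' haplotype strings.
#'
#' @param fit A `"haplo_em"` object.
#' @return A data frame `sample_id`, `hap1`, `hap2` (allele strings,
#'   `hap1 <= hap2`), `posterior` of the chosen pair.
#' @export
phase_best_pair <- function(fit) {
  stopifnot(inherits(fit, "haplo_em"))
  hs <- fit$haplotypes$string
  p <- fit$pairs
  s1 <- pmin(hs[p$hap1], hs[p$hap2])
  s2 <- pmax(hs[p$hap1], hs[p$hap2])
  pick <- unlist(lapply(split(seq_len(nrow(p)), p$ind), function(ix) {
    mx <- max(p$posterior[ix])
    cand <- ix[p$posterior[ix] >= mx - 1e-12]
    cand[order(s1[cand], s2[cand])][1]
  }), use.names = FALSE)
  out <- data.frame(sample_id = p$sample_id[pick],
                    hap1 = s1[pick], hap2 = s2[pick],
                    posterior = p$posterior[pick],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Haplotype copy-number dosage
#'
#' Codes each sample by its number of copies of a target haplotype: `"hard"`
#' counts copies in the best-pair phasing (0/1/2), `"expected"` sums
#' posterior-weighted copies over all retained pairs (a real in \[0,2\]).
#'
#' @param fit A `"haplo_em"` object.
#' @param target Haplotype allele string, or a label present in
#'   `fit$haplotypes$label`.
#' @param mode `"hard"` or `"expected"`.
#' @return Named numeric vector over samples.  If the target haplotype is not
#'   in the table, an all-zero vector with a warning.
#' @export
haplotype_dosage <- function(fit, target, mode = c("hard", "expected")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "haplo_em"))
  hs <- fit$haplotypes$string
  hit <- which(hs == target | (!is.na(fit$haplotypes$label) &
                               fit$haplotypes$label == target))
  samples <- unique(fit$pairs$sample_id)
  if (!length(hit)) {
    warning("target haplotype not in table; returning zero dosages")
    return(stats::setNames(numeric(length(samples)), samples))
  }
  hit <- hit[1]
  if (mode == "hard") {
    ph <- phase_best_pair(fit)
    d <- (ph$hap1 == hs[hit]) + (ph$hap2 == hs[hit])
    return(stats::setNames(as.numeric(d), ph$sample_id))
  }
  p <- fit$pairs
  copies <- (p$hap1 == hit) + (p$hap2 == hit)
  idx <- sort(unique(p$ind))
  d <- .acc(p$posterior * copies, p$ind, max(p$ind))[idx]
  stats::setNames(d, p$sample_id[match(idx, p$ind)])
}
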