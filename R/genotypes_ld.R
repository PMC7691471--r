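#' Construct a marker metadata table
#'
#' @param marker_id Character vector of unique marker names.
#' @param chrom Chromosome of each marker.
#' @param pos 1-based position.
#' @param ref_allele,alt_allele Single-character alleles; dosages count copies
#'   of `alt_allele`.
#' @param panel_class One of `"neutral_candidate"`, `"chr28_candidate"`,
#'   `"chr25_candidate"`, `"sex"`, `"species"`, `"other"`.
#' @param region_index Optional ordinal of the marker within its candidate
#'   region (1..13 for chromosome 28, 1..10 for chromosome 25), ordered by
#'   position; `NA` elsewhere.
#' @return A `data.frame` with one row per marker.
#' @export
marker_table <- function(marker_id, chrom, pos, ref_allele, alt_allele,
                         panel_class = "other", region_index = NA_integer_) {
  cls <- c("neutral_candidate", "chr28_candidate", "chr25_candidate",
           "sex", "species", "other")
  panel_class <- rep_len(panel_class, length(marker_id))
  if (!all(panel_class %in% cls)) stop("invalid panel_class")
  if (anyDuplicated(marker_id)) stop("duplicated marker_id")
  out <- data.frame(marker_id = as.character(marker_id),
                    chrom = as.character(chrom),
                    pos = as.integer(pos),
                    ref_allele = as.character(ref_allele),
                    alt_allele = as.character(alt_allele),
                    panel_class = panel_class,
                    region_index = as.integer(rep_len(region_index,
                                                      length(marker_id))),
                    stringsAsFactors = FALSE)
  for (r in c("chr28_candidate", "chr25_candidate")) {
    i <- which(out$panel_class == r & !is.na(out$region_index))
    if (length(i) > 1 &&
        any(diff(out$region_index[i][order(out$pos[i])]) < 0)) {
      stop("region_index must be ordered by position within ", r)
    }
  }
  out
}

#' Construct a genotype matrix object
#'
#' The central genotype container: an `n x m` integer matrix of alt-allele
#' dosages (0/1/2 or `NA`) with sample identifiers and marker metadata.
#'
#' @param dosage Integer matrix, samples in rows, markers in columns.
#' @param sample_ids Character vector of row identifiers.
#' @param markers Marker table (see [marker_table()]) with one row per column
#'   of `dosage`.
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(dosage, sample_ids, markers) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(markers) != ncol(dosage)) stop("markers/dosage dimension mismatch")
  if (length(sample_ids) != nrow(dosage)) stop("sample_ids length mismatch")
  if (any(!is.na(dosage) & (dosage < 0L | dosage > 2L))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  dimnames(dosage) <- list(as.character(sample_ids), markers$marker_id)
  structure(list(dosage = dosage,
                 sample_ids = as.character(sample_ids),
                 markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf("genotype_matrix: %d samples x %d markers (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage), 100 * miss))
  cat("panel classes:",
      paste(sprintf("%s=%d", names(table(x$markers$panel_class)),
                    table(x$markers$panel_class)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A genotype matrix.
#' @param samples,markers Indices, names or logical vectors selecting rows
#'   (samples) and columns (markers); `NULL` keeps all.
#' @return A genotype matrix.
#' @export
subset_genotypes <- function(x, samples = NULL, markers = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(x$dosage)) else samples
  if (is.character(si)) si <- match(si, x$sample_ids)
  mi <- if (is.null(markers)) seq_len(ncol(x$dosage)) else markers
  if (is.character(mi)) mi <- match(mi, x$markers$marker_id)
  genotype_matrix(x$dosage[si, mi, drop = FALSE],
                  x$sample_ids[si], x$markers[mi, , drop = FALSE])
}

.parse_genotype_cell <- function(cell, ref, alt) {
  # accepts "GG", "G/A", "G|A", "1", "0/1", "" / "NA" / "--" / "00"
  cell <- trimws(cell)
  if (is.na(cell) || cell %in% c("", "NA", "--", "00", "0", "./.")) {
    if (cell %in% c("0")) {
      # bare "0" is ambiguous (dosage 0 vs missing code); treat as dosage
      return(0L)
    }
    return(NA_integer_)
  }
  if (grepl("^[0-9]([/|][0-9])?$", cell)) {
    parts <- as.integer(strsplit(cell, "[/|]")[[1]])
    return(as.integer(sum(parts)))
  }
  a <- strsplit(gsub("[/|]", "", cell), "")[[1]]
  if (length(a) == 1L) a <- rep(a, 2L)  # haploid shorthand -> homozygote
  if (length(a) != 2L || !all(a %in% c(ref, alt))) {
    stop("allele mismatch: genotype '", cell, "' at a ", ref, "/", alt,
         " marker")
  }
  sum(a == alt)
}

#' Load genotypes from a delimited table or a VCF
#'
#' Delimited tables are sample x marker with a header of marker names and the
#' sample identifier in the first column; cells may be allele pairs
#' (`"GG"`, `"G/A"`) or alt-allele dosages.  Minimal VCF v4.2 files (GT field
#' only) are read through \pkg{vcfR}.  Dosages are oriented to count copies of
#' each marker's alt allele from `marker_table`.
#'
#' @param path File path.
#' @param markers Marker table; markers absent from the file are dropped with
#'   a warning, file columns absent from the table are an error.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param sep Field separator for delimited input.
#' @return A [genotype_matrix()].  Monomorphic markers are flagged in the
#'   `"monomorphic"` attribute.
#' @export
load_genotypes <- function(path, markers, format = c("auto", "tsv", "vcf"),
                           sep = "\t") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    G <- .load_genotypes_vcf(path, markers)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = "character")
    sample_ids <- tab[[1]]
    gcols <- names(tab)[-1]
    unknown <- setdiff(gcols, markers$marker_id)
    if (length(unknown)) {
      stop("file markers not in marker table: ",
           paste(unknown, collapse = ", "))
    }
    keep <- markers[markers$marker_id %in% gcols, , drop = FALSE]
    if (nrow(keep) < nrow(markers)) {
      warning(nrow(markers) - nrow(keep),
              " marker(s) in table absent from file; dropped")
    }
    dos <- matrix(NA_integer_, nrow(tab), nrow(keep))
    for (j in seq_len(nrow(keep))) {
      col <- tab[[keep$marker_id[j]]]
      dos[, j] <- vapply(col, .parse_genotype_cell, integer(1),
                         ref = keep$ref_allele[j], alt = keep$alt_allele[j],
                         USE.NAMES = FALSE)
    }
    G <- genotype_matrix(dos, sample_ids, keep)
  }
  mono <- apply(G$dosage, 2, function(d) {
    d <- d[!is.na(d)]
    length(d) == 0L || length(unique(d)) == 1L
  })
  attr(G, "monomorphic") <- G$markers$marker_id[mono]
  G
}

.load_genotypes_vcf <- function(path, markers) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- markers[markers$marker_id %in% ids, , drop = FALSE]
  if (!nrow(keep)) stop("no marker table entries found in VCF")
  ref <- vcfR::getREF(v)[match(keep$marker_id, ids)]
  alt <- vcfR::getALT(v)[match(keep$marker_id, ids)]
  bad <- which(ref != keep$ref_allele | alt != keep$alt_allele)
  if (length(bad)) {
    stop("allele mismatch vs marker table for: ",
         paste(keep$marker_id[bad], collapse = ", "))
  }
  gt <- gt[match(keep$marker_id, ids), , drop = FALSE]
  dos <- t(apply(gt, 1, function(g) {
    g[is.na(g) | g %in% c(".", "./.", ".|.")] <- NA
    vapply(g, function(cell) {
      if (is.na(cell)) return(NA_integer_)
      as.integer(sum(as.integer(strsplit(cell, "[/|]")[[1]])))
    }, integer(1), USE.NAMES = FALSE)
  }))
  genotype_matrix(t(dos), colnames(gt), keep)
}

#' Write genotypes to a delimited table
#'
#' Writes the allele-pair representation (`"GA"` style) used by
#' [load_genotypes()], giving a lossless text round trip.
#'
#' @param G A genotype matrix.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_genotypes <- function(G, path, sep = "\t") {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- G$markers
  cells <- vapply(seq_len(nrow(m)), function(j) {
    d <- G$dosage[, j]
    out <- character(length(d))
    out[is.na(d)] <- "--"
    out[!is.na(d) & d == 0L] <- paste0(m$ref_allele[j], m$ref_allele[j])
    out[!is.na(d) & d == 1L] <- paste0(m$ref_allele[j], m$alt_allele[j])
    out[!is.na(d) & d == 2L] <- paste0(m$alt_allele[j], m$alt_allele[j])
    out
  }, character(nrow(G$dosage)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1L)
  tab <- data.frame(sample_id = G$sample_ids, cells,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- c("sample_id", m$marker_id)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter samples by genotype missingness
#'
#' Samples with a missing-data fraction at or above `max_missing` are removed
#' (the retained set has strictly less than `max_missing` missing data).
#'
#' @param G A genotype matrix.
#' @param max_missing Missingness threshold (default 0.10).
#' @return A genotype matrix with the removed sample ids in attribute
#'   `"removed"`.
#' @export
filter_missing <- function(G, max_missing = 0.10) {
  stopifnot(inherits(G, "genotype_matrix"))
  frac <- rowMeans(is.na(G$dosage))
  drop <- frac >= max_missing
  if (all(drop)) stop("all samples exceed the missingness threshold")
  out <- subset_genotypes(G, samples = which(!drop))
  attr(out, "removed") <- G$sample_ids[drop]
  out
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' Computes r^2 between two markers from samples complete for the pair.  The
#' `"em_haplotype"` method estimates the two-locus haplotype frequencies by EM
#' and returns `D^2 / (pA qA pB qB)`; the `"dosage"` method returns the
#' squared Pearson correlation of dosages.  The two agree exactly when phase
#' is unambiguous in the sample.
#'
#' @param G A genotype matrix.
#' @param i,j Marker indices or ids.
#' @param method `"em_haplotype"` or `"dosage"`.
#' @return r^2 in \[0,1\], or `NA` (with a warning) for a monomorphic marker.
#' @export
ld_r2 <- function(G, i, j, method = c("em_haplotype", "dosage")) {
  method <- match.arg(method)
  if (is.character(i)) i <- match(i, G$markers$marker_id)
  if (is.character(j)) j <- match(j, G$markers$marker_id)
  a <- G$dosage[, i]; b <- G$dosage[, j]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    warning("monomorphic marker in LD pair; r2 undefined")
    return(NA_real_)
  }
  if (method == "dosage") {
    return(stats::cor(a, b)^2)
  }
  .ld_r2_em(a, b)
}

# two-locus EM for r2; haplotype order 00, 01, 10, 11 (alt-allele coding)
.ld_r2_em <- function(a, b) {
  n <- length(a)
  cnt <- table(factor(a, 0:2), factor(b, 0:2))
  pA <- mean(a) / 2; pB <- mean(b) / 2
  # initialize at linkage equilibrium
  f <- c((1 - pA) * (1 - pB), (1 - pA) * pB, pA * (1 - pB), pA * pB)
  f <- pmax(f, 1e-12); f <- f / sum(f)
  dh <- cnt["1", "1"]   # only the double heterozygote is phase-ambiguous
  for (it in 1:500) {
    p_cis <- f[1] * f[4]
    p_tr  <- f[2] * f[3]
    w <- if (p_cis + p_tr > 0) p_cis / (p_cis + p_tr) else 0.5
    h <- c(2 * cnt["0", "0"] + cnt["0", "1"] + cnt["1", "0"] + dh * w,
           2 * cnt["0", "2"] + cnt["0", "1"] + cnt["1", "2"] + dh * (1 - w),
           2 * cnt["2", "0"] + cnt["1", "0"] + cnt["2", "1"] + dh * (1 - w),
           2 * cnt["2", "2"] + cnt["2", "1"] + cnt["1", "2"] + dh * w)
    fn <- unname(h) / (2 * n)
    if (max(abs(fn - f)) < 1e-10) { f <- fn; break }
    f <- fn
  }
  D <- f[4] - (f[3] + f[4]) * (f[2] + f[4])
  pA <- f[3] + f[4]; pB <- f[2] + f[4]
  unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' Pairwise LD matrix
#'
#' @param G A genotype matrix.
#' @param markers Optional marker subset (indices or ids).
#' @param method See [ld_r2()].
#' @return A symmetric m x m matrix of r^2 with unit diagonal for polymorphic
#'   markers; attribute `"method"` records the estimator.
#' @export
ld_matrix <- function(G, markers = NULL, method = c("em_haplotype", "dosage")) {
  method <- match.arg(method)
  Gs <- subset_genotypes(G, markers = markers)
  m <- ncol(Gs$dosage)
  R <- diag(1, m)
  dimnames(R) <- list(Gs$markers$marker_id, Gs$markers$marker_id)
  if (method == "dosage") {
    # suppress sd-zero warnings; handled below
    C <- suppressWarnings(stats::cor(Gs$dosage, use = "pairwise.complete.obs"))
    R <- C^2
    diag(R) <- 1
  } else {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        R[i, j] <- R[j, i] <- suppressWarnings(ld_r2(Gs, i, j, method))
      }
    }
  }
  mono <- apply(Gs$dosage, 2, function(d) length(unique(d[!is.na(d)])) < 2L)
  R[mono, ] <- NA; R[, mono] <- NA
  attr(R, "method") <- method
  R
}

#' Windowed LD pruning
#'
#' Greedy pruning of markers in strong LD, windowed along the genome: within
#' each window of `window` markers the pair with the highest r^2 above
#' `r2_max` loses one member (the one with the lower call rate; ties drop the
#' later position), repeating until no pair exceeds the threshold, then the
#' window slides by `step`.
#'
#' @param G A genotype matrix with markers in genomic order.
#' @param window Window size in markers (default 50).
#' @param step Slide in markers (default 5).
#' @param r2_max Pruning threshold (default 0.9).
#' @param method LD estimator passed to [ld_r2()]; the dosage estimator is
#'   the default for speed.
#' @return Character vector of retained marker ids (in input order), with the
#'   dropped ids in attribute `"dropped"`.
#' @export
prune_linkage <- function(G, window = 50, step = 5, r2_max = 0.9,
                          method = "dosage") {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- ncol(G$dosage)
  call_rate <- colMeans(!is.na(G$dosage))
  pos <- G$markers$pos
  keep <- rep(TRUE, m)
  starts <- unique(c(seq(1L, max(1L, m - window + 1L), by = step)))
  for (s in starts) {
    idx <- s:min(s + window - 1L, m)
    repeat {
      act <- idx[keep[idx]]
      if (length(act) < 2L) break
      R <- ld_matrix(subset_genotypes(G, markers = act), method = method)
      R[lower.tri(R, diag = TRUE)] <- NA
      over <- which(!is.na(R) & R > r2_max, arr.ind = TRUE)
      if (!nrow(over)) break
      top <- over[which.max(R[over]), ]
      a <- act[top[1]]; b <- act[top[2]]
      drop <- if (call_rate[a] < call_rate[b]) a
              else if (call_rate[b] < call_rate[a]) b
              else if (pos[a] >= pos[b]) a else b
      keep[drop] <- FALSE
    }
  }
  out <- G$markers$marker_id[keep]
  attr(out, "dropped") <- G$markers$marker_id[!keep]
  out
}
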