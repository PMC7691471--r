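# Nonparametric per-group genotype tests and simple correlation utilities.

#' Kruskal-Wallis test of a phenotype across genotype classes
#'
#' Rank-based one-way analysis of variance (tie-corrected H statistic via
#' [stats::kruskal.test()]) of a continuous phenotype across genotype
#' classes, used per sub-basin on raw migration-timing phenotypes.  Genotype
#' classes are reported in dosage order (homozygous premature,
#' heterozygote, homozygous mature).
#'
#' @param values Numeric phenotype.
#' @param classes Genotype class per sample (factor or dosage vector).
#' @param min_n Advisory minimum total sample size (default 15); smaller
#'   groups are tested with a warning.
#' @return List of class `"kw_result"`: `H`, `df`, `p`, `n_class` (named
#'   counts), `medians` (per-class medians).  Empty classes are dropped
#'   (with a warning) and reduce `df`; if all values are tied the test is
#'   degenerate and `H = 0`, `p = 1`.
#' @export
kruskal_wallis <- function(values, classes, min_n = 15) {
  ok <- !is.na(values) & !is.na(classes)
  values <- as.numeric(values)[ok]
  cl <- if (is.factor(classes)) classes[ok] else factor(classes[ok])
  present <- levels(cl)[table(cl) > 0]
  if (length(present) < nlevels(cl)) {
    warning("empty genotype class(es) dropped; df reduced")
  }
  cl <- factor(cl, levels = present)
  if (nlevels(cl) < 2L) stop("need >= 2 non-empty genotype classes")
  if (length(values) <= min_n) {
    warning("total n = ", length(values), " at or below the advisory ",
            "minimum (", min_n, ")")
  }
  if (length(unique(values)) == 1L) {
    kt <- list(statistic = 0, parameter = nlevels(cl) - 1L, p.value = 1)
  } else {
    kt <- stats::kruskal.test(values, cl)
  }
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = unname(kt$p.value),
                 n_class = table(cl),
                 medians = tapply(values, cl, stats::median)),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %s\n", x$H, x$df,
              format.pval(x$p, digits = 4)))
  print(rbind(n = x$n_class, median = x$medians))
  invisible(x)
}

#' Pearson correlation with significance test
#'
#' Product-moment correlation via [stats::cor.test()], reporting `r`, `r^2`
#' and the t-test p-value; used e.g. to compare scale-based and
#' parentage-based total-age estimates.
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @return List `r`, `r2`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}

#' Per-sub-basin Kruskal-Wallis scan
#'
#' Runs [kruskal_wallis()] for one marker's genotype classes against a raw
#' phenotype within every group (sub-basin) of sufficient size.
#'
#' @param values Phenotype vector.
#' @param dosage Genotype dosage vector (0/1/2).
#' @param group Sub-basin (or HUC) label per sample.
#' @param min_n Minimum group size tested (default 15, groups at or below
#'   are skipped).
#' @return Data frame `group`, `n`, `H`, `df`, `p`.
#' @export
kw_by_group <- function(values, dosage, group, min_n = 15) {
  out <- NULL
  for (g in unique(group)) {
    sel <- group == g & !is.na(values) & !is.na(dosage)
    if (sum(sel) <= min_n) next
    if (length(unique(dosage[sel])) < 2L) next
    kt <- suppressWarnings(kruskal_wallis(values[sel], dosage[sel],
                                          min_n = 0))
    out <- rbind(out, data.frame(group = g, n = sum(sel), H = kt$H,
                                 df = kt$df, p = kt$p,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(group = character(0), n = integer(0), H = numeric(0),
                      df = integer(0), p = numeric(0))
  }
  out
}
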