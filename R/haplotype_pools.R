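#' Packaged candidate-region haplotype pools
#'
#' Published haplotype catalogues for the two candidate regions: 13 markers
#' spanning the GREB1L/ROCK1 region of chromosome 28 and 10 markers spanning
#' the SIX6 region of chromosome 25.  Each haplotype (roman-numeral label) is
#' an allele string over the region's markers, with frequency estimates from
#' several estimators/sample sets.  Frequencies below the reporting threshold
#' are stored as 0.0005 and absent haplotypes as 0; [haplotype_pool()]
#' renormalizes each column onto the simplex.
#'
#' @format Data frames with one row per haplotype: `label`, `string`
#'   (concatenated marker alleles, 5' to 3'), and one numeric column per
#'   frequency estimate.
#' @name haplotype-pools
#' @keywords internal
NULL

# chromosome 28 (GREB1L/ROCK1), 13 markers
# columns: Bonneville-sample accelerated-EM estimates (all samples and the
# interior/intermediate/coastal subsets), Bonneville progressive-EM (hs) and
# graph-HMM (sh) estimates; the same three estimators for the Hood sample
.chr28_pool_table <- function() {
  txt <- "
label string        bon_hv_all bon_hv_int bon_hv_mid bon_hv_coa bon_hs bon_sh hood_hv hood_hs hood_sh
I     GAGGAGCCGTGTA 0.702 0.717 0.094 0.130 0.696 0.631 0.612 0.614 0.534
II    GAGGAGCTACTGT 0.157 0.161 0     0     0.157 0.115 0.007 0.007 0.005
III   ACTAGTATACTGT 0.024 0.011 0.562 0.481 0.025 0.020 0.067 0.067 0.057
IV    GAGGAGCCGTGTT 0.014 0.014 0     0     0.014 0.070 0.109 0.107 0.147
V     GAGGAGCTACTGA 0.018 0.018 0     0.019 0.018 0.069 0.003 0.003 0.006
VI    GAGGGGCCGTGTA 0.011 0.011 0     0.019 0.010 0.015 0.031 0.031 0.084
VII   GCTGGGCTACTGT 0.017 0.017 0     0     0.017 0.010 0     0     0
VIII  ACGGGGCCGTGTA 0.001 0.001 0     0     0.001 0.003 0.053 0.053 0.051
IX    ACTGGGCCGTGTA 0.002 0.002 0     0     0.003 0.001 0.049 0.049 0.025
X     GCTGGGCTATTGT 0.010 0.011 0     0     0.010 0.006 0     0.001 0
XI    GCTGGGCTACTGA 0.008 0.009 0     0     0.009 0.008 0     0     0
XII   GCTAGTATACTGA 0.008 0.002 0.187 0.167 0.007 0.007 0     0     0
XIII  GAGGGGCCGTGTT 0.001 0.001 0     0     0.001 0.001 0.019 0.019 0.009
XIV   ACTAGTATACTGA 0.003 0     0.094 0.111 0.003 0.009 0.008 0.008 0.021
XV    GCTGGGCCGTGTA 0.002 0.002 0.031 0     0.002 0.018 0.008 0.008 0.008
XVI   GCTGGGCTATTGA 0.003 0.003 0     0     0.003 0     0     0     0
XVII  GAGGAGCCACTGA 0.002 0.002 0     0     0.002 0.0005 0.002 0.002 0
XVIII GCTGAGCTACTGA 0.002 0.002 0     0     0.002 0.002 0     0     0
XIX   GATGAGCCGTGTA 0     0     0     0     0     0.003 0.005 0.005 0.041
XX    GCTAGGCTACTGT 0.001 0.001 0     0     0.001 0.004 0     0     0
XXI   ACGGAGCCGTGTA 0     0     0     0     0     0.001 0     0     0.033
XXII  GAGGAGCTATTGT 0     0     0     0     0     0.006 0     0     0.002
XXIII GCTGAGCCGTGTA 0     0     0     0     0     0.003 0     0     0.002
XXIV  GAGGAGCTATTGA 0     0     0     0     0     0.003 0     0     0.002"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

# chromosome 25 (SIX6), 10 markers
.chr25_pool_table <- function() {
  txt <- "
label string     bon_hv_all bon_hv_int bon_hv_mid bon_hv_coa bon_hs bon_sh
I     CAGCGGAAAC 0.637 0.647 0.156 0.314 0.636  0.584
II    ACTTATGGGG 0.241 0.239 0.437 0.222 0.241  0.194
III   ACTTAGAAAC 0.063 0.063 0.406 0.204 0.063  0.113
IV    CAGCGGGGGG 0.023 0.024 0     0     0.023  0.024
V     CAGCGTGGGG 0.012 0.012 0     0.222 0.012  0.058
VI    ACTTATGAGC 0.011 0.008 0     0     0.011  0.011
VII   ACTTATAAAC 0.005 0.005 0     0.019 0.005  0.001
VIII  CATTAGAAAC 0.003 0.003 0     0     0.003  0.003
IX    ACGCGGAAAC 0.002 0.002 0     0     0.002  0.002
X     CAGCGTAAAC 0.002 0.002 0     0     0.002  0.006
XI    ACTTAGGGGG 0.001 0.001 0     0     0.001  0.001
XII   CAGCGGAAGC 0     0.001 0     0     0.001  0.001
XIII  CAGCGGGAGC 0     0     0     0.019 0.001  0.0005
XIV   AATTATGGGG 0     0     0     0     0.0005 0
XV    ACTTAGAGAC 0     0     0     0     0      0.001
XVI   AATTAGAAAC 0     0     0     0     0      0.0005
XVII  ACTTATAAGC 0     0     0     0     0      0.0005
XVIII CAGCGGGAAC 0     0     0     0     0      0.0005"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

#' Retrieve a packaged haplotype pool
#'
#' Returns the haplotype catalogue of a candidate region with one frequency
#' column selected and renormalized to sum to one (haplotypes with zero
#' frequency are dropped).
#'
#' @param region `"chr28"` (13 GREB1L/ROCK1 markers) or `"chr25"` (10 SIX6
#'   markers).
#' @param column Frequency column to use.  For `"chr28"`:
#'   `"bon_hv_all"`, `"bon_hv_int"`, `"bon_hv_mid"`, `"bon_hv_coa"`,
#'   `"bon_hs"`, `"bon_sh"`, `"hood_hv"`, `"hood_hs"`, `"hood_sh"`; for
#'   `"chr25"` the six `bon_*` columns.  The `*_hv`/`*_hs` columns are the
#'   EM-family estimates (the packaged scenario defaults), `*_sh` the
#'   graph-HMM estimates, retained for reference.
#' @return A data frame with columns `label`, `string`, `freq` (simplex).
#' @examples
#' pool <- haplotype_pool("chr28", "hood_hs")
#' sum(pool$freq)   # 1
#' pool$freq[pool$label == "I"]
#' @export
haplotype_pool <- function(region = c("chr28", "chr25"), column = "bon_hv_all") {
  region <- match.arg(region)
  tab <- if (region == "chr28") .chr28_pool_table() else .chr25_pool_table()
  if (!column %in% names(tab)) {
    stop("unknown frequency column '", column, "' for region ", region)
  }
  out <- data.frame(label = tab$label, string = tab$string,
                    freq = tab[[column]], stringsAsFactors = FALSE)
  out <- out[out$freq > 0, , drop = FALSE]
  out$freq <- out$freq / sum(out$freq)
  rownames(out) <- NULL
  out
}

#' Marker metadata for a packaged candidate region
#'
#' Builds a marker table (see [marker_table()]) for the 13 chromosome 28 or
#' 10 chromosome 25 candidate markers.  Reference alleles are those of
#' haplotype I; positions are evenly spaced synthetic coordinates (the
#' packaged pools carry no physical coordinates).
#'
#' @param region `"chr28"` or `"chr25"`.
#' @return A marker table data frame.
#' @export
region_markers <- function(region = c("chr28", "chr25")) {
  region <- match.arg(region)
  tab <- if (region == "chr28") .chr28_pool_table() else .chr25_pool_table()
  alle <- do.call(rbind, strsplit(tab$string, ""))
  k <- ncol(alle)
  ref <- alle[1, ]
  alt <- vapply(seq_len(k), function(j) {
    a <- setdiff(unique(alle[, j]), ref[j])
    if (length(a) != 1L) stop("marker ", j, " in ", region, " is not biallelic")
    a
  }, character(1))
  chrom <- if (region == "chr28") "28" else "25"
  cls <- if (region == "chr28") "chr28_candidate" else "chr25_candidate"
  marker_table(
    marker_id   = sprintf("%s_m%02d", region, seq_len(k)),
    chrom       = rep(chrom, k),
    pos         = 1000000L + seq_len(k) * 5000L,
    ref_allele  = ref,
    alt_allele  = alt,
    panel_class = rep(cls, k),
    region_index = seq_len(k)
  )
}
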