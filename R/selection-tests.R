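#' Generalized McDonald-Kreitman test
#'
#' Contrasts polymorphic versus divergent site counts in a focal class
#' (e.g. lncRNA exons) against a putatively neutral class on a 2x2 table
#' using a Pearson chi-square test with one degree of freedom (no
#' continuity correction by default; counts are large in intended use).
#'
#' @param table 2x2 numeric matrix: rows = focal/neutral, columns =
#'   polymorphic/divergent.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List with `chi2`, `df` (= 1) and `p`.
#' @examples
#' mk_test(matrix(c(30, 10, 20, 20), 2, byrow = TRUE))  # chi2 = 5.333
#' @export
mk_test <- function(table, correct = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0)) stop("MK table cells must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("MK test undefined: zero margin in the 2x2 table")
  ct <- stats::chisq.test(table, correct = correct)
  list(chi2 = unname(ct$statistic), df = 1L, p = unname(ct$p.value))
}

#' Compare derived-allele-frequency spectra of two site classes
#'
#' Two-sample Kolmogorov-Smirnov comparison of the DAF distributions plus
#' the proportion of sites at low derived frequency (<= `low_threshold`)
#' in each class — an excess of rare derived alleles in the focal class is
#' the signature of purifying selection.
#'
#' @param focal_daf,neutral_daf Numeric DAF vectors in (0,1).
#' @param low_threshold Rare-variant cutoff (default 0.01).
#' @return List: `ks_statistic`, `p_value`, `prop_low_focal`,
#'   `prop_low_neutral`.
#' @export
compare_daf_spectra <- function(focal_daf, neutral_daf,
                                low_threshold = 0.01) {
  if (!length(focal_daf) || !length(neutral_daf))
    stop("both DAF samples must be non-empty")
  ks <- suppressWarnings(stats::ks.test(focal_daf, neutral_daf))
  list(ks_statistic = unname(ks$statistic), p_value = unname(ks$p.value),
       prop_low_focal = mean(focal_daf <= low_threshold),
       prop_low_neutral = mean(neutral_daf <= low_threshold))
}

#' Classify a polarized substitution by base-composition direction
#'
#' @param ancestral,derived Single bases.
#' @return `"GCtoAT"`, `"ATtoGC"`, or `"neutral_class"` (G<->C / A<->T,
#'   which leave composition unchanged).
#' @export
mutation_class <- function(ancestral, derived) {
  assert_bases(c(ancestral, derived))
  if (ancestral == derived) stop("ancestral and derived bases identical")
  sc <- c(A = "W", T = "W", G = "S", C = "S")  # weak/strong
  a <- sc[[ancestral]]; d <- sc[[derived]]
  if (a == "S" && d == "W") return("GCtoAT")
  if (a == "W" && d == "S") return("ATtoGC")
  "neutral_class"
}

#' Bonferroni multiple-testing correction
#'
#' @param p Raw p-values in \[0,1\].
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values `min(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  pmin(1, p * m)
}

#' Minimum selection coefficient visible to selection
#'
#' Under the nearly neutral theory a deleterious mutation is effectively
#' neutral when |Ne*s| is below about one, so the smallest selection
#' coefficient that selection can act upon is approximately `1 / Ne`.
#'
#' @param Ne Effective population size.
#' @return `1 / Ne`.
#' @examples
#' selection_threshold(15000)     # human upper-bound Ne: ~6.7e-5
#' selection_threshold(1450000)   # D. melanogaster
#' @export
selection_threshold <- function(Ne) {
  stopifnot(Ne > 0)
  1 / Ne
}

#' Assemble an MK 2x2 table from site sets
#'
#' Polymorphism = polarised SNPs at the class's positions; divergence =
#' positions where the reference differs from the nearest outgroup and
#' that are not polymorphic.
#'
#' @param bundle A `genome_bundle`.
#' @param polarised Polarised variant table.
#' @param focal_pos,neutral_pos Lists of 1-based positions per chromosome
#'   (named by chromosome).
#' @return 2x2 matrix (rows focal/neutral, cols poly/div).
#' @export
mk_table_from_sites <- function(bundle, polarised, focal_pos, neutral_pos) {
  count_one <- function(pos_list) {
    poly <- 0L; div <- 0L
    for (cn in names(pos_list)) {
      pos <- pos_list[[cn]]
      if (!length(pos)) next
      vp <- polarised$pos[polarised$chrom == cn]
      is_poly <- pos %in% vp
      a <- strsplit(bundle$reference[[cn]], "")[[1]][pos]
      b <- strsplit(bundle$outgroups[[1]][[cn]], "")[[1]][pos]
      ok <- a %in% BASES & b %in% BASES
      poly <- poly + sum(is_poly)
      div <- div + sum(ok & a != b & !is_poly)
    }
    c(poly, div)
  }
  rbind(focal = count_one(focal_pos), neutral = count_one(neutral_pos))
}
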