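#' Codon degeneracy classes under the standard genetic code
#'
#' A coding position is d-fold degenerate when d of the four possible bases
#' at that position encode the same amino acid. Fourfold degenerate sites
#' (all substitutions synonymous) serve as a neutral proxy in mammals;
#' 0-fold sites (every substitution non-synonymous) measure protein
#' constraint.
#'
#' @param codon Character scalar, three bases from A/C/G/T.
#' @param codon_pos Position within the codon, 1, 2 or 3.
#' @return One of `"0-fold"`, `"2-fold"`, `"3-fold"`, `"4-fold"`, or `NA`
#'   (with a warning) when the codon contains an ambiguous base.
#' @examples
#' classify_degeneracy("GGA", 3)  # glycine third position: 4-fold
#' classify_degeneracy("ATG", 2)  # methionine: 0-fold
#' @export
classify_degeneracy <- function(codon, codon_pos) {
  stopifnot(length(codon) == 1L, nchar(codon) == 3L, codon_pos %in% 1:3)
  codon <- toupper(codon)
  nts <- strsplit(codon, "")[[1]]
  if (!all(nts %in% BASES)) {
    warning("ambiguous base in codon '", codon, "'; degeneracy is NA")
    return(NA_character_)
  }
  aa <- GENETIC_CODE_STD[[codon]]
  alt <- setdiff(BASES, nts[codon_pos])
  same <- vapply(alt, function(b) {
    mut <- nts
    mut[codon_pos] <- b
    GENETIC_CODE_STD[[paste(mut, collapse = "")]] == aa
  }, logical(1))
  # d = 1 + number of alternative bases preserving the amino acid,
  # mapped onto the conventional {0,2,3,4}-fold labels
  n_syn <- sum(same)
  c("0-fold", "2-fold", "3-fold", "4-fold")[n_syn + 1L]
}

# standard genetic code as a named list (from Biostrings' table)
GENETIC_CODE_STD <- as.list(Biostrings::GENETIC_CODE)

#' Degeneracy of every position of a coding sequence
#'
#' @param cds Character scalar; in-frame coding sequence (length divisible
#'   by 3) in transcript orientation.
#' @return Character vector of per-position degeneracy labels.
#' @export
cds_degeneracy <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3 == 0)
  if (n == 0L) return(character(0))
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  out <- character(n)
  for (i in seq_along(codons)) {
    for (p in 1:3) {
      out[(i - 1L) * 3L + p] <- suppressWarnings(
        classify_degeneracy(codons[i], p))
    }
  }
  out
}
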