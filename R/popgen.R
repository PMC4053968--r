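#' Build a site-frequency spectrum
#'
#' @param derived_counts Integer vector of derived-allele counts, one per
#'   segregating site, each strictly between 0 and `n`.
#' @param n Haplotype sample size (must be shared by all sites; stratify
#'   before calling otherwise).
#' @param fold If `TRUE`, bin by minor-allele count `min(i, n - i)`.
#' @return An object of class `sfs` with fields `n`, `counts`, `folded`.
#' @export
build_sfs <- function(derived_counts, n, fold = FALSE) {
  stopifnot(n >= 2)
  if (length(derived_counts) &&
      (any(derived_counts <= 0) || any(derived_counts >= n)))
    stop("derived counts must satisfy 0 < i < n; ",
         "stratify samples with different n before building the SFS")
  if (fold) {
    k <- floor(n / 2)
    idx <- pmin(derived_counts, n - derived_counts)
    counts <- tabulate(idx, nbins = k)
  } else {
    counts <- tabulate(derived_counts, nbins = n - 1L)
  }
  structure(list(n = n, counts = counts, folded = fold), class = "sfs")
}

#' Fold an unfolded spectrum
#'
#' Maps derived count i to the minor count `min(i, n - i)`; the central bin
#' (i = n/2 for even n) is counted once. Folding conserves the total number
#' of segregating sites.
#'
#' @param sfs An unfolded `sfs`.
#' @return A folded `sfs`.
#' @export
fold_sfs <- function(sfs) {
  if (sfs$folded) return(sfs)
  n <- sfs$n
  k <- floor(n / 2)
  counts <- integer(k)
  for (i in seq_len(n - 1L)) {
    j <- min(i, n - i)
    counts[j] <- counts[j] + sfs$counts[i]
  }
  structure(list(n = n, counts = counts, folded = TRUE), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(if (x$folded) "folded" else "unfolded", "SFS, n =", x$n,
      ", S =", sum(x$counts), "\n")
  invisible(x)
}

# Tajima (1989) normalizing constants
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Polymorphism summary of a region
#'
#' Computes per-site pairwise diversity piT, Watterson's thetaW and
#' Tajima's D from the derived-allele counts of the segregating sites in a
#' region of L analyzed sites:
#' \deqn{\pi = \sum_s 2 \hat p_s (1-\hat p_s)\, n/(n-1) / L,\quad
#'       \theta_W = S/(a_1 L)}
#' with Tajima's D the normalized difference of the two underlying
#' mutation-rate estimates (NA when S = 0).
#'
#' @param derived_counts Derived (or minor; the statistics are invariant)
#'   allele counts of segregating sites.
#' @param L Number of analyzed sites in the region (>= 1).
#' @param n Haplotype sample size.
#' @return A one-row data.frame: `L`, `S`, `piT`, `thetaW`, `tajD`,
#'   `snp_density`.
#' @export
summarize_region <- function(derived_counts, L, n) {
  if (L < 1) stop("L must be >= 1")
  S <- length(derived_counts)
  k <- tajima_constants(n)
  if (S == 0L) {
    return(data.frame(L = L, S = 0L, piT = 0, thetaW = 0, tajD = NA_real_,
                      snp_density = 0))
  }
  p <- derived_counts / n
  pi_total <- sum(2 * p * (1 - p) * n / (n - 1))
  D <- (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  data.frame(L = L, S = S, piT = pi_total / L, thetaW = S / (k$a1 * L),
             tajD = D, snp_density = S / L)
}

#' Jukes-Cantor corrected divergence between two aligned tracks
#'
#' Counts differing bases over the given positions (columns containing N or
#' a gap in either track are excluded from the aligned total) and applies
#' the multiple-hit correction \eqn{k = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}.
#'
#' @param ref_track,outgroup_track Aligned base strings (same length).
#' @param positions 1-based positions to consider; default all.
#' @return A one-row data.frame: `aligned_sites`, `differences`, `p`, `k`.
#' @export
jc_divergence <- function(ref_track, outgroup_track, positions = NULL) {
  a <- strsplit(ref_track, "")[[1]]
  b <- strsplit(outgroup_track, "")[[1]]
  stopifnot(length(a) == length(b))
  if (is.null(positions)) positions <- seq_along(a)
  if (any(positions < 1L | positions > length(a)))
    stop("positions outside the aligned tracks")
  a <- toupper(a[positions]); b <- toupper(b[positions])
  ok <- a %in% BASES & b %in% BASES
  aligned <- sum(ok)
  diffs <- sum(a[ok] != b[ok])
  p <- if (aligned > 0) diffs / aligned else 0
  data.frame(aligned_sites = aligned, differences = diffs, p = p,
             k = jc_correct(p))
}

#' @rdname jc_divergence
#' @param p Proportion of differing aligned sites, in \[0, 0.75).
#' @export
jc_correct <- function(p) {
  if (any(p >= 0.75)) stop("divergence saturated: p >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Per-locus polymorphism/divergence table by feature class
#'
#' One row per (locus, feature class): analyzed length, segregating sites
#' and the [summarize_region()] estimators plus Jukes-Cantor divergence to
#' the nearest outgroup over that locus's sites of the class. Mirrors the
#' per-locus "average (standard deviation)" presentation used for
#' class-level polymorphism tables.
#'
#' @param polarised Polarised variant table (see [polarize_all()]).
#' @param bundle A `genome_bundle`.
#' @param n Haplotype sample size to summarize at (sites are first
#'   down-filtered to this exact `n_called` when `strict_n = TRUE`,
#'   otherwise counts are used as-is with the nominal n).
#' @param classes Feature classes to tabulate.
#' @return Data frame with columns `locus_id`, `feature_class`, `L`, `S`,
#'   `piT`, `thetaW`, `tajD`, `snp_density`, `k`.
#' @export
locus_popgen_table <- function(polarised, bundle, n,
                               classes = c("cds_exon", "utr5", "utr3",
                                           "pc_intron", "lnc_exon",
                                           "lnc_intron",
                                           "ancestral_repeat")) {
  feats <- bundle$annotation$features
  rows <- list()
  for (cn in names(bundle$chromosomes)) {
    part <- class_partition(bundle$annotation, cn, bundle$chromosomes[[cn]])
    fc <- feats[feats$chrom == cn & feats$feature_class %in% classes, ,
                drop = FALSE]
    vc <- polarised[polarised$chrom == cn, , drop = FALSE]
    for (loc in unique(fc$locus_id)) {
      for (cls in unique(fc$feature_class[fc$locus_id == loc])) {
        fi <- fc[fc$locus_id == loc & fc$feature_class == cls, , drop = FALSE]
        pos <- unlist(lapply(seq_len(nrow(fi)),
                             function(i) (fi$start[i] + 1L):fi$end[i]))
        pos <- pos[part[pos] == cls]  # precedence-masked
        if (!length(pos)) next
        sel <- vc$pos %in% pos
        dc <- round(vc$daf[sel] * n)
        dc <- dc[dc > 0 & dc < n]
        s <- summarize_region(dc, L = length(pos), n = n)
        k <- jc_divergence(bundle$reference[[cn]],
                           bundle$outgroups[[1]][[cn]], pos)$k
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(locus_id = loc, feature_class = cls), s,
                data.frame(k = k))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(locus_id = character(), feature_class = character(),
                      L = integer(), S = integer(), piT = double(),
                      thetaW = double(), tajD = double(),
                      snp_density = double(), k = double()))
  }
  do.call(rbind, rows)
}
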