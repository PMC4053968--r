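# Shared in-code fixtures: a tiny hand-laid annotation and bundle whose
# coordinates are easy to reason about, plus a cached small cohort.

# two-chromosome toy annotation (0-based half-open):
#   chrA, + strand gene: utr5 1000-1150 | cds 1150-1330 | small intron
#     1330-1400 (70 nt) | cds 1400-1550 | intron 1550-2400 | cds 2400-2550
#     | utr3 2550-2750 (CDS total 480 nt, in frame)
#   chrA lncA: exons 5000-5400 / 5900-6500 / 6600-6900 with introns
#     filling the gaps; ancestral repeat 9000-9400
#   chrB, - strand lncB: exons 2000-2400 / 2900-3400 / 3650-4000
toy_features <- function() {
  add_ordinals(feature_table(
    chrom = c(rep("chrA", 13), rep("chrB", 5)),
    start = c(1000L, 1150L, 1330L, 1400L, 1550L, 2400L, 2550L,
              5000L, 5400L, 5900L, 6500L, 6600L, 9000L,
              2000L, 2400L, 2900L, 3400L, 3650L),
    end   = c(1150L, 1330L, 1400L, 1550L, 2400L, 2550L, 2750L,
              5400L, 5900L, 6500L, 6600L, 6900L, 9400L,
              2400L, 2900L, 3400L, 3650L, 4000L),
    strand = c(rep("+", 13), rep("-", 5)),
    feature_class = c("utr5", "cds_exon", "pc_intron", "cds_exon",
                      "pc_intron", "cds_exon", "utr3",
                      "lnc_exon", "lnc_intron", "lnc_exon", "lnc_intron",
                      "lnc_exon", "ancestral_repeat",
                      "lnc_exon", "lnc_intron", "lnc_exon", "lnc_intron",
                      "lnc_exon"),
    locus_id = c(rep("geneA", 7), rep("lncA", 5), "arA",
                 rep("lncB", 5))))
}

toy_annotation <- function() annotation_set(toy_features())

toy_chrom_lengths <- function() c(chrA = 12000L, chrB = 6000L)

random_track <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

toy_bundle <- function(seed = 42L) {
  cl <- toy_chrom_lengths()
  ref <- list(chrA = random_track(cl[["chrA"]], seed),
              chrB = random_track(cl[["chrB"]], seed + 1L))
  genome_bundle(cl, ref, outgroups = list(ref, ref),
                conservation = NULL, annotation = toy_annotation())
}

# small simulated cohort memoized across test files
ci_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_preset("ci"),
                                                  seed = 20260923L)
    cache
  }
})

# brute-force pairwise-difference oracle: explicit haplotype matrix, all
# pairs compared column by column
brute_force_popgen <- function(derived_counts, L, n) {
  S <- length(derived_counts)
  if (S == 0L) return(list(piT = 0, thetaW = 0, tajD = NA_real_))
  H <- vapply(derived_counts, function(ct) c(rep(1L, ct), rep(0L, n - ct)),
              integer(n))
  H <- matrix(H, nrow = n)
  pairs <- utils::combn(n, 2)
  total_diff <- 0
  for (p in seq_len(ncol(pairs))) {
    total_diff <- total_diff + sum(H[pairs[1, p], ] != H[pairs[2, p], ])
  }
  pi_total <- total_diff / ncol(pairs)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(piT = pi_total / L, thetaW = S / (a1 * L), tajD = D)
}
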