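test_that("selected-site frequency density matches its closed form", {
  expect_equal(expected_sfs_density(0, 0.25), 4.0)
  expect_error(expected_sfs_density(0, 1.2), "\\(0,1\\)")
  expect_error(expected_sfs_density(-2, 0), "\\(0,1\\)")
  # spreadsheet-style independent evaluation at gamma = -2, q = 0.5
  g <- -2; q <- 0.5
  by_hand <- (1 - exp(-g * (1 - q))) / ((1 - exp(-g)) * q * (1 - q))
  expect_equal(expected_sfs_density(-2, 0.5), by_hand)
  # stronger selection weights mass toward rare frequencies: the ratio
  # f(0.5)/f(0.05) must fall monotonically as gamma decreases
  ratios <- vapply(c(0, -2, -10), function(gm)
    expected_sfs_density(gm, 0.5) / expected_sfs_density(gm, 0.05),
    numeric(1))
  expect_true(all(diff(ratios) < 0))
  # log-space branch is continuous at the switch point
  expect_equal(expected_sfs_density(-30 - 1e-9, 0.3),
               expected_sfs_density(-30 + 1e-9, 0.3), tolerance = 1e-6)
})

test_that("cohort generation is deterministic and honours the unit pattern", {
  a <- generate_cohort(cohort_preset("ci"), seed = 5)
  b <- generate_cohort(cohort_preset("ci"), seed = 5)
  expect_identical(a$bundle$variants, b$bundle$variants)
  expect_identical(a$bundle$reference, b$bundle$reference)
  expect_identical(a$bundle$outgroups, b$bundle$outgroups)
  expect_identical(a$truth, b$truth)
  no_lnc <- cohort_preset("ci", unit_pattern = c("pc", "ar"))
  c <- generate_cohort(no_lnc, seed = 5)
  expect_false(any(grepl("^lnc",
                         c$bundle$annotation$features$feature_class)))
})

test_that("neutral cohort singleton fraction matches the sampling oracle", {
  cfg <- cohort_preset("ci", n_haplotypes = 20L, theta = 0.007,
                       regimes = lapply(FEATURE_CLASSES,
                                        function(x) selection_regime(gamma = 0)))
  names(cfg$regimes) <- FEATURE_CLASSES
  sim <- generate_cohort(cfg, seed = 99)
  ct <- sim$bundle$variants$allele_count
  S <- length(ct)
  expect_gt(S, 3000)
  # oracle: 1/q density integrated against binomial sampling, conditioned
  # on segregation (independent numeric integration)
  n <- 20L
  p1 <- stats::integrate(function(q) (1 / q) * stats::dbinom(1, n, q),
                         1e-6, 1 - 1e-6)$value
  pseg <- stats::integrate(function(q)
    (1 / q) * (1 - q^n - (1 - q)^n), 1e-6, 1 - 1e-6)$value
  expected <- p1 / pseg
  se <- sqrt(expected * (1 - expected) / S)
  expect_lt(abs(mean(ct == 1L) - expected), 3 * se)
})

test_that("outgroup divergence tracks the configured branch lengths", {
  sim <- ci_cohort()
  b <- sim$bundle
  cfg_d <- c(0.06, 0.12)
  for (og in 1:2) {
    for (cls in c("intergenic", "pc_intron")) {
      pos <- which(class_partition(b$annotation, "chr2L",
                                   b$chromosomes[["chr2L"]]) == cls)
      div <- jc_divergence(b$reference$chr2L, b$outgroups[[og]]$chr2L, pos)
      se <- 3 * sqrt(div$p * (1 - div$p) / div$aligned_sites)
      p_expected <- 0.75 * (1 - exp(-4 / 3 * cfg_d[og]))
      expect_lt(abs(div$p - p_expected), se + 0.003)
    }
    # the strongly selected CDS class diverges much less
    cds <- which(class_partition(b$annotation, "chr2L",
                                 b$chromosomes[["chr2L"]]) == "cds_exon")
    div_cds <- jc_divergence(b$reference$chr2L, b$outgroups[[og]]$chr2L, cds)
    expect_lt(div_cds$p, 0.5 * 0.75 * (1 - exp(-4 / 3 * cfg_d[og])))
  }
})

test_that("emitted class-conditional SFS matches the expected spectrum", {
  n <- 30L
  sel <- simulate_class_sites(selection_regime(gamma = -8), n, 20000L,
                              seed = 7)
  emp <- tabulate(sel$counts, n - 1L) / 20000
  theo <- lncevo:::expected_sampled_sfs(-8, n)
  theo <- theo / sum(theo)
  # Kolmogorov distance between empirical and theoretical spectra
  expect_lt(max(abs(cumsum(emp) - cumsum(theo))), 0.012)
  expect_true(all(sel$counts > 0 & sel$counts < n))
})

test_that("truth report tabulates counts and configured mean selection", {
  empty <- truth_report(data.frame(chrom = character(), pos = integer(),
                                   ancestral = character(),
                                   feature_class = character(),
                                   gamma = double()))
  expect_identical(nrow(empty), 0L)
  two <- truth_report(data.frame(
    chrom = "c", pos = 1:30, ancestral = "A",
    feature_class = rep(c("lnc_exon", "pc_intron"), c(10, 20)),
    gamma = rep(c(-3, 0), c(10, 20))))
  expect_identical(two$n_sites, c(10L, 20L))
  sim <- ci_cohort()
  tr <- truth_report(sim$truth)
  expect_lt(tr$mean_gamma[tr$feature_class == "lnc_exon"], 0)
  expect_identical(tr$mean_gamma[tr$feature_class == "pc_intron"], 0)
  # every emitted SNP has exactly one truth row, ancestral = reference
  expect_identical(nrow(sim$truth), nrow(sim$bundle$variants))
  expect_identical(sim$truth$ancestral, sim$bundle$variants$ref_allele)
})

test_that("cohort annotation is structurally valid", {
  sim <- ci_cohort()
  feats <- sim$bundle$annotation$features
  # multi-exonic loci have introns exactly filling inter-exon gaps
  for (ll in unique(feats$locus_id[feats$feature_class == "lnc_exon"])) {
    f <- feats[feats$locus_id == ll, ]
    f <- f[order(f$start), ]
    expect_true(all(f$start[-1] == f$end[-nrow(f)]))
    expect_identical(unique(f$strand), f$strand[1])
  }
  # lncRNA loci never overlap protein-coding spans
  pc <- feats[feats$feature_class %in%
                c("cds_exon", "utr5", "utr3", "pc_intron"), ]
  ln <- feats[grepl("^lnc", feats$feature_class), ]
  if (nrow(pc) && nrow(ln)) {
    ov <- GenomicRanges::countOverlaps(
      lncevo:::features_as_granges(ln),
      lncevo:::features_as_granges(pc), ignore.strand = TRUE)
    expect_identical(sum(ov), 0L)
  }
})
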