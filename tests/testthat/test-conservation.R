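flat_conservation <- function(len, value) list(chrC = rep(value, len))

test_that("metagene deciles reproduce constant and per-base profiles", {
  feats <- feature_table("chrC", c(100L, 300L, 700L), c(200L, 500L, 900L),
                         "+", "lnc_exon", c("a", "b", "c"), "unique")
  prof <- metagene_profile(feats, flat_conservation(1000L, 0.7),
                           n_boot = 200L, seed = 1L)
  expect_equal(prof$median, rep(0.7, 10))
  expect_equal(prof$lower, prof$upper)
  # a 10-bp feature puts one base per window, transcript-oriented
  sc <- flat_conservation(100L, 0)
  sc$chrC[51:60] <- seq(0.1, 1.0, by = 0.1)
  plus <- feature_table("chrC", 50L, 60L, "+", "lnc_exon", "p", "unique")
  minus <- feature_table("chrC", 50L, 60L, "-", "lnc_exon", "m", "unique")
  pp <- metagene_profile(plus, sc, n_boot = 10L, seed = 1L)
  pm <- metagene_profile(minus, sc, n_boot = 10L, seed = 1L)
  expect_equal(pp$median, seq(0.1, 1.0, by = 0.1))
  expect_equal(pm$median, rev(pp$median))
  expect_error(metagene_profile(plus[0, ], sc), "empty")
})

test_that("decile medians ignore within-decile position shuffles", {
  set.seed(4)
  sc <- list(chrC = stats::runif(500))
  f <- feature_table("chrC", 100L, 400L, "+", "lnc_exon", "x", "unique")
  base <- metagene_profile(f, sc, n_boot = 10L, seed = 2L)
  # shuffle scores inside each 30-base decile
  idx <- lncevo:::decile_windows(300L)
  sc2 <- sc
  for (w in idx) sc2$chrC[100L + w] <- sc$chrC[100L + sample(w)]
  shuf <- metagene_profile(f, sc2, n_boot = 10L, seed = 2L)
  expect_equal(base$median, shuf$median)
})

test_that("exon and intron profiles separate on Beta-score cohorts", {
  set.seed(12)
  n_feat <- 300L
  starts <- seq(0L, by = 200L, length.out = 2L * n_feat)
  len <- sum(200L * 2L * n_feat)
  sc <- numeric(400L * n_feat)
  cls <- rep(c("lnc_exon", "lnc_intron"), n_feat)
  for (i in seq_along(starts)) {
    ab <- if (cls[i] == "lnc_exon") c(3, 4) else c(1, 6)
    sc[(starts[i] + 1L):(starts[i] + 200L)] <- stats::rbeta(200L, ab[1],
                                                            ab[2])
  }
  feats <- feature_table("chrC", starts, starts + 200L, "+", cls,
                         sprintf("l%04d", seq_along(starts)), "unique")
  track <- list(chrC = sc)
  ex <- metagene_profile(feats[feats$feature_class == "lnc_exon", ],
                         track, n_boot = 500L, seed = 3L)
  it <- metagene_profile(feats[feats$feature_class == "lnc_intron", ],
                         track, n_boot = 500L, seed = 3L)
  expect_gte(sum(ex$median > it$median), 9L)
  expect_gte(sum(ex$lower > it$upper), 9L)
})

test_that("control sets are size-matched, gene-distant and reproducible", {
  b <- toy_bundle()
  set.seed(7)
  cons <- list(chrA = stats::runif(12000), chrB = stats::runif(6000))
  lens <- c(100L, 250L)
  c1 <- control_profiles(b$annotation, b$chromosomes, lens, cons,
                         n_sets = 20L, seed = 5L, keep_sets = TRUE)
  c2 <- control_profiles(b$annotation, b$chromosomes, lens, cons,
                         n_sets = 20L, seed = 5L, keep_sets = TRUE)
  expect_identical(c1$band, c2$band)
  genic <- b$annotation$features
  genic <- genic[!genic$feature_class %in% c("ancestral_repeat"), ]
  for (s in c1$sets) {
    expect_identical(s$end - s$start, lens)
    for (i in seq_len(nrow(s))) {
      gaps <- lncevo:::interval_gap(s$start[i], s$end[i],
                                    genic$start[genic$chrom == s$chrom[i]],
                                    genic$end[genic$chrom == s$chrom[i]])
      # gap counts intervening bases: 1000 intervening bases puts the
      # nearest control base 1001 bp from the gene, i.e. > 1 kb away
      expect_true(all(gaps >= 1000L))
    }
  }
})

test_that("single-site resampling detects separation and respects the null", {
  ex <- feature_table("chrC", c(0L, 100L), c(50L, 150L), "+", "lnc_exon",
                      c("e1", "e2"), "unique")
  it <- feature_table("chrC", c(200L, 300L), c(250L, 350L), "+",
                      "lnc_intron", c("i1", "i2"), "unique")
  sc <- flat_conservation(400L, 0.1)
  sc$chrC[1:150] <- 0.9
  sep <- single_site_comparison(ex, it, sc, n_resamples = 100L, seed = 2L)
  expect_identical(sep$p_empirical, 0)
  # identical distributions: empirical p near one half
  set.seed(6)
  sc2 <- list(chrC = stats::runif(400))
  null <- single_site_comparison(ex, it, sc2, n_resamples = 1000L,
                                 seed = 3L)
  expect_gt(null$p_empirical, 0.5 - 3 * sqrt(0.25 / 1000) - 0.15)
  expect_lt(null$p_empirical, 0.5 + 3 * sqrt(0.25 / 1000) + 0.15)
  # a single locus pair still works
  one <- single_site_comparison(ex[1, ], it[1, ], sc, n_resamples = 10L,
                                seed = 1L)
  expect_length(one$exon_medians, 10L)
})

test_that("column information content matches hand-computed entropies", {
  expect_equal(column_information(c("G", "G", "G", "G", "G")), 2)
  expect_equal(column_information(c("A", "C", "G", "T", "A")),
               0.07807191, tolerance = 1e-6)
  expect_true(is.na(column_information(c("A", "-", "N"))))
  expect_true(is.na(column_information(c("A", "C"))))
})

test_that("splice-site profiles score identical alignments at maximum IC", {
  bl <- matrix(rep(strsplit(random_track(101L, 3), "")[[1]], each = 5),
               nrow = 5)
  got <- splice_site_information(list(bl, bl), side = "5prime")
  expect_equal(got$profile$ic, rep(2, 22))
  expect_identical(got$n_skipped, 0L)
  # fewer than 3 ungapped species at the dinucleotide: block skipped
  bad <- bl
  bad[1:3, 51] <- "-"
  got2 <- splice_site_information(list(bl, bad), side = "5prime")
  expect_identical(got2$n_skipped, 1L)
  # 3-prime side reads the 20 intronic columns upstream
  got3 <- splice_site_information(list(bl), side = "3prime")
  expect_identical(got3$profile$offset, c(0:1, -(20:1)))
})

test_that("splice blocks extracted from a cohort carry the donor signal", {
  sim <- ci_cohort()
  bl <- extract_splice_blocks(sim$bundle, "lnc_intron", "5prime", seed = 4L)
  expect_gt(length(bl$blocks), 10L)
  expect_identical(length(bl$control_blocks), length(bl$blocks))
  # reference row of every + strand block shows the GT donor
  plus_gt <- vapply(bl$blocks, function(b)
    paste(b[1, 51:52], collapse = ""), character(1))
  expect_true(all(plus_gt %in% c("GT", "AC")))  # AC = donor on - strand
})
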