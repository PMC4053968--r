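# proxy-test annotation: a lncRNA with one neighbour gene in range
# (introns of 86 and 87 nt), one gene 6 kb away, ancestral repeats at
# graded distances, and a minus-strand gene for trim orientation
proxy_features <- function() {
  add_ordinals(feature_table(
    chrom = "chrP",
    start = c(7000L, 7500L, 7586L, 8086L, 8173L,
              10000L, 10500L, 11000L,
              17500L, 18000L, 18087L,
              12000L, 23000L,
              30000L, 30500L, 30586L,
              32000L, 32400L, 32800L),
    end   = c(7500L, 7586L, 8086L, 8173L, 8673L,
              10500L, 11000L, 11500L,
              18000L, 18087L, 18587L,
              12500L, 23500L,
              30500L, 30586L, 31086L,
              32400L, 32800L, 33200L),
    strand = c(rep("+", 13), rep("-", 3), rep("+", 3)),
    feature_class = c("cds_exon", "pc_intron", "cds_exon", "pc_intron",
                      "cds_exon",
                      "lnc_exon", "lnc_intron", "lnc_exon",
                      "cds_exon", "pc_intron", "cds_exon",
                      "ancestral_repeat", "ancestral_repeat",
                      "cds_exon", "pc_intron", "cds_exon",
                      "lnc_exon", "lnc_intron", "lnc_exon"),
    locus_id = c(rep("geneNear", 5), rep("lncP", 3), rep("geneFar", 3),
                 "arNear", "arFar", rep("geneMinus", 3),
                 rep("lncM", 3))))
}

test_that("small-intron proxies honour length, distance and trimming rules", {
  ann <- annotation_set(proxy_features())
  got <- select_small_introns(ann)
  # geneNear is within 5 kb of lncP: its 86 nt intron qualifies, the
  # 87 nt one does not; geneFar (6 kb from any lncRNA span) is excluded
  near <- got[got$locus_id == "geneNear", ]
  expect_identical(nrow(near), 1L)
  # 86 nt trimmed by 6 + 16 leaves 64 analyzed bases
  expect_identical(near$end - near$start, 64L)
  expect_identical(near$start, 7500L + 6L)
  expect_identical(near$end, 7586L - 16L)
  expect_false("geneFar" %in% got$locus_id)
  # minus-strand intron of geneMinus (direct neighbour of lncM): the
  # transcript-oriented first 6 nt sit at the genomic END
  minus <- got[got$locus_id == "geneMinus", ]
  expect_identical(nrow(minus), 1L)
  expect_identical(minus$start, 30500L + 16L)
  expect_identical(minus$end, 30586L - 6L)
  # trimmed intervals never touch the disallowed edge bases
  expect_true(all(got$end - got$start ==
                    (86L - 22L)[rep(1, nrow(got))]))
  # boundary: an 87 nt intron is excluded outright
  expect_false(any(got$end - got$start == 87L - 22L))
})

test_that("flanking ancestral repeats respect distance and intergenic status", {
  ann <- annotation_set(proxy_features())
  k10 <- select_flanking_ancestral_repeats(ann)
  expect_true("arNear" %in% k10$locus_id)    # 500 bp from lncP
  # arFar is 11.5 kb from lncP (excluded for that pairing) but 8.5 kb
  # from lncM, so it appears only as lncM's flanking repeat
  expect_false("arFar" %in% k10$locus_id[k10$source_lnc == "lncP"])
  expect_true("arFar" %in% k10$locus_id[k10$source_lnc == "lncM"])
  k5 <- select_flanking_ancestral_repeats(ann,
          proxy_spec("ancestral_repeat", max_distance = 5000L))
  k20 <- select_flanking_ancestral_repeats(ann,
          proxy_spec("ancestral_repeat", max_distance = 20000L))
  expect_true("arFar" %in% k20$locus_id)
  # threshold sweep: kept sets grow monotonically
  expect_true(nrow(k5) <= nrow(k10) && nrow(k10) <= nrow(k20))
  # a repeat overlapped by a genic feature is not intergenic
  feats <- proxy_features()
  feats <- rbind(feats, feature_table("chrP", 18010L, 18060L, "+",
                                      "ancestral_repeat", "arGenic",
                                      "unique"))
  kg <- select_flanking_ancestral_repeats(annotation_set(feats))
  expect_false("arGenic" %in% kg$locus_id)
})

test_that("identity masking removes >=90% windows and is idempotent", {
  ref <- paste(rep("A", 100), collapse = "")
  mk_out <- function(mismatch_at) {
    x <- rep("A", 100); x[mismatch_at] <- "C"
    paste(x, collapse = "")
  }
  iv <- data.frame(start = 0L, end = 100L)
  # 19/20 identity window at the start, pure mismatch beyond
  m19 <- mask_conserved_elements(ref, mk_out(c(10, 21:100)), iv)
  expect_identical(nrow(m19), 1L)
  expect_identical(m19$start, 21L)  # windows [1,20] and [2,21] masked
  expect_identical(m19$end, 100L)
  # 17/20 identity nowhere reaches the threshold: nothing masked
  m17 <- mask_conserved_elements(ref, mk_out(c(5, 10, 15, 21:100)), iv)
  expect_identical(m17$start, 0L)
  expect_identical(m17$end, 100L)
  # fully identical flank: everything masked, locus unusable
  mfull <- mask_conserved_elements(ref, ref, iv)
  expect_identical(nrow(mfull), 0L)
  # idempotence
  again <- mask_conserved_elements(ref, mk_out(c(10, 21:100)), m19)
  expect_identical(again$start, m19$start)
  expect_identical(again$end, m19$end)
})

test_that("score masking removes high-score windows only", {
  sc <- c(rep(0.95, 30), rep(0.05, 170))
  iv <- data.frame(start = 0L, end = 200L)
  got <- mask_conserved_by_score(sc, iv, score_threshold = 0.8)
  expect_identical(nrow(got), 1L)
  expect_true(got$start >= 30L && got$end == 200L)
  none <- mask_conserved_by_score(rep(0.1, 200), iv)
  expect_identical(none$start, 0L)
})

test_that("matched-site sampling is uniform, deterministic and guarded", {
  pool <- data.frame(start = 0L, end = 1000L)
  expect_identical(sample_matched_sites(0L, pool), integer(0))
  set.seed(9); a <- sample_matched_sites(50L, pool)
  set.seed(9); b <- sample_matched_sites(50L, pool)
  expect_identical(a, b)
  expect_identical(length(a), 50L)
  expect_true(all(a >= 1L & a <= 1000L) && !anyDuplicated(a))
  # below the minimum usable flank
  small <- sample_matched_sites(10L, data.frame(start = 0L, end = 800L))
  expect_length(small, 0L)
  expect_identical(attr(small, "reason"), "flank_below_min")
  big_n <- sample_matched_sites(1200L, pool)
  expect_identical(attr(big_n, "reason"), "flank_smaller_than_target")
  # per-position inclusion frequency is uniform within binomial bounds
  set.seed(11)
  counts <- integer(1000)
  for (r in 1:2000) {
    s <- sample_matched_sites(50L, pool)
    counts[s] <- counts[s] + 1L
  }
  expected <- 2000 * 50 / 1000
  sd5 <- 5 * sqrt(2000 * 0.05 * 0.95)
  expect_true(all(abs(counts - expected) < sd5))
})
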