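test_that("codon degeneracy matches the standard genetic code", {
  expect_identical(classify_degeneracy("GGA", 3), "4-fold")
  expect_identical(classify_degeneracy("ATG", 2), "0-fold")
  expect_identical(classify_degeneracy("AAA", 3), "2-fold")
  expect_warning(deg <- classify_degeneracy("ANA", 2), "ambiguous")
  expect_true(is.na(deg))
})

test_that("degeneracy agrees with a brute-force translation oracle on all codons", {
  # independent oracle: translate via seqinr and count synonymous mutants
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (codon in codons) {
    aa <- seqinr::translate(strsplit(codon, "")[[1]])
    for (pos in 1:3) {
      nts <- strsplit(codon, "")[[1]]
      n_syn <- sum(vapply(setdiff(bases, nts[pos]), function(b) {
        mut <- nts; mut[pos] <- b
        seqinr::translate(mut) == aa
      }, logical(1)))
      expect_identical(classify_degeneracy(codon, pos),
                       c("0-fold", "2-fold", "3-fold", "4-fold")[n_syn + 1])
    }
  }
})

test_that("site classes follow the precedence rule and strand-aware ordinals", {
  ann <- toy_annotation()
  cl <- toy_chrom_lengths()
  # inside the second of lncA's three exons (middle, by construction)
  got <- assign_site_class("chrA", 6000L, ann, cl)
  expect_identical(got$feature_class, "lnc_exon")
  expect_identical(got$locus_id, "lncA")
  expect_identical(got$ordinal, "middle")
  # gap between genes
  gap <- assign_site_class("chrA", 4000L, ann, cl)
  expect_identical(gap$feature_class, "intergenic")
  expect_true(is.na(gap$locus_id))
  # on the minus-strand lncB, the leftmost genomic exon is the LAST exon
  left <- assign_site_class("chrB", 2100L, ann, cl)
  expect_identical(left$ordinal, "last")
  right <- assign_site_class("chrB", 3700L, ann, cl)
  expect_identical(right$ordinal, "first")
  expect_error(assign_site_class("chrA", 99999L, ann, cl), "bounds")
})

test_that("every position maps to exactly one class, matching point queries", {
  ann <- toy_annotation()
  part <- class_partition(ann, "chrA", 12000L)
  expect_length(part, 12000L)
  expect_true(all(part %in% FEATURE_CLASSES))
  pos <- c(1001L, 1200L, 1400L, 2600L, 5100L, 5500L, 9100L, 11000L)
  point <- assign_site_class("chrA", pos, ann)
  expect_identical(part[pos], point$feature_class)
})

test_that("degeneracy track is non-NA exactly on CDS and in frame", {
  b <- toy_bundle()
  deg <- degeneracy_track(b$annotation, b$reference, "chrA")
  part <- class_partition(b$annotation, "chrA", 12000L)
  cds <- which(part == "cds_exon")
  expect_true(all(!is.na(deg[cds])))
  expect_true(all(is.na(deg[part != "cds_exon"])))
  expect_true(all(deg[cds] %in% c("0-fold", "2-fold", "3-fold", "4-fold")))
})

test_that("VCF loading rejects multiallelic and indel records with a tally", {
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrA,length=12000>",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "chrA\t100\t.\tA\tG\t50\tPASS\tAC=3;AN=10;DP=20",
           "chrA\t200\t.\tC\tT,G\t50\tPASS\tAC=2;AN=10;DP=20",
           "chrA\t300\t.\tG\tC\t50\tPASS\tAC=5;AN=10;DP=22;NI")
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_message(got <- lncevo:::read_snp_vcf(f), "multiallelic")
  expect_identical(nrow(got$variants), 2L)
  expect_identical(got$rejected, 1L)
  expect_identical(got$variants$near_indel, c(FALSE, TRUE))
  expect_identical(got$variants$allele_count, c(3L, 5L))
})

test_that("an empty VCF yields a bundle with zero variants", {
  b <- toy_bundle()
  d <- tempfile()
  write_bundle(b, d)
  b2 <- load_bundle(d)
  expect_identical(nrow(b2$variants), 0L)
})

test_that("bundle write/load round-trips variant and interval content", {
  sim <- ci_cohort()
  d <- tempfile()
  write_bundle(sim$bundle, d)
  b2 <- suppressMessages(load_bundle(d))
  v1 <- sim$bundle$variants; v2 <- b2$variants
  expect_identical(nrow(v1), nrow(v2))
  expect_identical(v1$pos, v2$pos)
  expect_identical(v1$ref_allele, v2$ref_allele)
  expect_identical(v1$alt_allele, v2$alt_allele)
  expect_identical(v1$allele_count, v2$allele_count)
  expect_identical(v1$n_called, v2$n_called)
  expect_identical(v1$near_indel, v2$near_indel)
  # BED half-open convention: a feature [10,20) covers 1-based 11..20
  f1 <- sim$bundle$annotation$features
  f2 <- b2$annotation$features
  key <- function(f) f[order(f$chrom, f$start, f$feature_class),
                       c("chrom", "start", "end", "strand",
                         "feature_class", "locus_id", "ordinal")]
  k1 <- key(f1); k2 <- key(f2)
  rownames(k1) <- rownames(k2) <- NULL
  expect_identical(k1, k2)
  expect_identical(sim$bundle$reference, b2$reference)
})

test_that("bundle construction validates track lengths and bounds", {
  cl <- c(chrA = 100L)
  ref <- list(chrA = random_track(100L, 1))
  expect_error(genome_bundle(cl, list(chrA = random_track(99L, 1)),
                             list()), "length mismatch")
  bad_feat <- feature_table("chrA", 90L, 120L, "+", "lnc_exon", "x")
  expect_error(genome_bundle(cl, ref, list(),
                             annotation = annotation_set(bad_feat)),
               "bounds")
})
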