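#' Construct a validated genome bundle
#'
#' The in-memory container shared by all analysis stages: reference and
#' coordinate-aligned outgroup tracks (gap-free, nearest outgroup first),
#' per-base conservation scores, biallelic population variants and the
#' annotation. All tracks must match the declared chromosome lengths.
#'
#' @param chromosomes Named integer vector of chromosome lengths (bp).
#' @param reference Named character vector, one base string per chromosome.
#' @param outgroups List of reference-like tracks ordered nearest-first.
#' @param conservation List of per-chromosome numeric vectors in \[0,1\]
#'   (NA = missing), or `NULL`.
#' @param variants Data frame of biallelic sites with columns `chrom`,
#'   `pos` (1-based), `ref_allele`, `alt_allele`, `allele_count`,
#'   `n_called`, `coverage`, `qual`, `near_indel`.
#' @param annotation An [annotation_set()].
#' @param indels Optional list of per-chromosome 1-based indel positions
#'   (used only to set `near_indel` flags).
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(chromosomes, reference, outgroups,
                          conservation = NULL, variants = empty_variants(),
                          annotation = annotation_set(empty_features()),
                          indels = NULL) {
  stopifnot(!is.null(names(chromosomes)))
  for (cn in names(chromosomes)) {
    if (nchar(reference[[cn]]) != chromosomes[[cn]])
      stop("reference track length mismatch on ", cn)
    for (og in outgroups) {
      if (nchar(og[[cn]]) != chromosomes[[cn]])
        stop("outgroup track length mismatch on ", cn)
    }
    if (!is.null(conservation) &&
        length(conservation[[cn]]) != chromosomes[[cn]])
      stop("conservation track length mismatch on ", cn)
  }
  feats <- annotation$features
  if (nrow(feats)) {
    if (any(feats$end > chromosomes[feats$chrom]))
      stop("feature interval outside chromosome bounds")
  }
  if (nrow(variants)) {
    validate_variants(variants)
    if (any(variants$pos < 1L | variants$pos > chromosomes[variants$chrom]))
      stop("variant position outside chromosome bounds")
  }
  structure(list(chromosomes = chromosomes, reference = reference,
                 outgroups = outgroups, conservation = conservation,
                 variants = variants, annotation = annotation,
                 indels = indels),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle:", length(x$chromosomes), "chromosome(s),",
      sum(x$chromosomes), "bp,", nrow(x$variants), "variants,",
      nrow(x$annotation$features), "features,",
      length(x$outgroups), "outgroup track(s)\n")
  invisible(x)
}

empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(),
             ref_allele = character(), alt_allele = character(),
             allele_count = integer(), n_called = integer(),
             coverage = integer(), qual = double(),
             near_indel = logical(), stringsAsFactors = FALSE)
}

empty_features <- function() {
  feature_table(character(), integer(), integer(), character(),
                character(), character())
}

validate_variants <- function(v) {
  assert_bases(unique(c(v$ref_allele, v$alt_allele)))
  if (any(v$ref_allele == v$alt_allele)) stop("ref and alt alleles identical")
  if (any(v$allele_count <= 0L | v$allele_count >= v$n_called))
    stop("variants must be segregating: 0 < allele_count < n_called")
  invisible(v)
}

## ---- file input/output -----------------------------------------------

#' Write a genome bundle to standard flat files
#'
#' Writes `reference.fa`, `outgroup_<i>.fa`, `annotation.bed` (BED6, name =
#' `locus|class|ordinal`), `variants.vcf` (site-only records; INFO keys AC,
#' AN, DP, NI), `conservation.bedGraph` and `indels.bed` under `dir`.
#'
#' @param bundle A `genome_bundle`.
#' @param dir Output directory (created if absent).
#' @param what Subset of c("fasta","bed","vcf","bedgraph","indels",
#'   "orthologs") to write; defaults to everything present.
#' @return Invisibly, the named vector of written paths.
#' @export
write_bundle <- function(bundle, dir,
                         what = c("fasta", "bed", "vcf", "bedgraph",
                                  "indels", "orthologs")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  if ("fasta" %in% what) {
    p <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(bundle$reference)), p)
    paths["reference"] <- p
    for (i in seq_along(bundle$outgroups)) {
      p <- file.path(dir, sprintf("outgroup_%d.fa", i))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(unlist(bundle$outgroups[[i]])), p)
      paths[sprintf("outgroup_%d", i)] <- p
    }
  }
  feats <- bundle$annotation$features
  if ("bed" %in% what && nrow(feats)) {
    p <- file.path(dir, "annotation.bed")
    bed <- data.frame(feats$chrom, feats$start, feats$end,
                      paste(feats$locus_id, feats$feature_class,
                            feats$ordinal, sep = "|"),
                      0L, feats$strand)
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths["annotation"] <- p
  }
  if ("vcf" %in% what) {
    p <- file.path(dir, "variants.vcf")
    write_snp_vcf(bundle$variants, bundle$chromosomes, p)
    paths["variants"] <- p
  }
  if ("bedgraph" %in% what && !is.null(bundle$conservation)) {
    p <- file.path(dir, "conservation.bedGraph")
    rows <- lapply(names(bundle$conservation), function(cn) {
      sc <- bundle$conservation[[cn]]
      keep <- !is.na(sc)
      data.frame(chrom = cn, start = which(keep) - 1L,
                 end = which(keep), score = round(sc[keep], 6))
    })
    utils::write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths["conservation"] <- p
  }
  if ("indels" %in% what && !is.null(bundle$indels)) {
    p <- file.path(dir, "indels.bed")
    rows <- lapply(names(bundle$indels), function(cn) {
      ip <- bundle$indels[[cn]]
      if (!length(ip)) return(NULL)
      data.frame(chrom = cn, start = ip - 1L, end = ip)
    })
    utils::write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths["indels"] <- p
  }
  orth <- bundle$annotation$orthologs
  if ("orthologs" %in% what && !is.null(orth)) {
    p <- file.path(dir, "orthologs.tsv")
    utils::write.table(orth, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["orthologs"] <- p
  }
  invisible(paths)
}

# site-only VCF (no genotype columns): allele counts, depth and the
# near-indel flag are carried in INFO
write_snp_vcf <- function(variants, chromosomes, path, ancestral = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chromosomes),
                   as.integer(chromosomes)),
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt allele count among called haplotypes\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Called haplotypes\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Minimum per-strain depth proxy\">",
           "##INFO=<ID=NI,Number=0,Type=Flag,Description=\"Within 10 bp of an indel call\">",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele by outgroup parsimony\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(variants)) {
    info <- sprintf("AC=%d;AN=%d;DP=%d%s", variants$allele_count,
                    variants$n_called, variants$coverage,
                    ifelse(variants$near_indel, ";NI", ""))
    if (!is.null(ancestral)) info <- sprintf("%s;AA=%s", info, ancestral)
    recs <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\t%s",
                    variants$chrom, variants$pos, variants$ref_allele,
                    variants$alt_allele, variants$qual, info)
  } else recs <- character(0)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# read a SNP VCF back into the variants data.frame; multiallelic and indel
# records are rejected (counted), never silently kept
read_snp_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(list(variants = empty_variants(), rejected = 0L))
  multi <- grepl(",", fix$ALT)
  indel <- nchar(fix$REF) != 1L | (nchar(fix$ALT) != 1L & !multi)
  drop <- multi | indel
  n_rej <- sum(drop)
  if (n_rej) {
    message(sum(multi), " multiallelic and ", sum(indel & !multi),
            " indel record(s) rejected from ", basename(path))
  }
  fix <- fix[!drop, , drop = FALSE]
  grab <- function(key) {
    as.integer(vcfR::extract.info(vcf, element = key)[!drop])
  }
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref_allele = fix$REF, alt_allele = fix$ALT,
    allele_count = grab("AC"), n_called = grab("AN"),
    coverage = grab("DP"), qual = as.numeric(fix$QUAL),
    near_indel = grepl("(^|;)NI(;|$)", fix$INFO),
    stringsAsFactors = FALSE)
  aa <- vcfR::extract.info(vcf, element = "AA")[!drop]
  if (!all(is.na(aa))) variants$ancestral_allele <- aa
  list(variants = variants, rejected = n_rej)
}

#' Load a genome bundle from flat files
#'
#' Counterpart of [write_bundle()]: reads FASTA reference/outgroups, BED6
#' annotation, site-only VCF, per-base bedGraph conservation and indel
#' positions. Malformed or multiallelic VCF records are rejected with a
#' message; coordinates are normalized to the internal 0-based half-open
#' convention.
#'
#' @param dir Directory written by [write_bundle()], or a named list of
#'   paths (`reference`, `outgroups`, `annotation`, `variants`,
#'   `conservation`, `indels`, `orthologs`).
#' @return A `genome_bundle`.
#' @export
load_bundle <- function(dir) {
  if (is.character(dir)) {
    og <- sort(list.files(dir, "^outgroup_[0-9]+\\.fa$", full.names = TRUE))
    paths <- list(reference = file.path(dir, "reference.fa"),
                  outgroups = og,
                  annotation = file.path(dir, "annotation.bed"),
                  variants = file.path(dir, "variants.vcf"),
                  conservation = file.path(dir, "conservation.bedGraph"),
                  indels = file.path(dir, "indels.bed"),
                  orthologs = file.path(dir, "orthologs.tsv"))
  } else paths <- dir
  read_fa <- function(p) {
    ss <- Biostrings::readDNAStringSet(p)
    out <- as.list(as.character(ss))
    names(out) <- sub("\\s.*$", "", names(out))
    out
  }
  reference <- read_fa(paths$reference)
  chromosomes <- vapply(reference, nchar, integer(1))
  outgroups <- lapply(paths$outgroups, read_fa)

  feats <- empty_features()
  if (file.exists(paths$annotation)) {
    bed <- rtracklayer::import(paths$annotation, format = "BED")
    meta <- strsplit(bed$name, "|", fixed = TRUE)
    if (any(lengths(meta) != 3L))
      stop("malformed annotation name field in ", paths$annotation)
    feats <- feature_table(
      chrom = as.character(GenomicRanges::seqnames(bed)),
      start = GenomicRanges::start(bed) - 1L,
      end = GenomicRanges::end(bed),
      strand = as.character(GenomicRanges::strand(bed)),
      feature_class = vapply(meta, `[`, "", 2),
      locus_id = vapply(meta, `[`, "", 1),
      ordinal = vapply(meta, `[`, "", 3))
  }
  orth <- NULL
  if (!is.null(paths$orthologs) && file.exists(paths$orthologs)) {
    orth <- utils::read.delim(paths$orthologs, stringsAsFactors = FALSE)
  }
  vv <- if (file.exists(paths$variants)) read_snp_vcf(paths$variants)
        else list(variants = empty_variants(), rejected = 0L)

  conservation <- NULL
  if (!is.null(paths$conservation) && file.exists(paths$conservation)) {
    bg <- rtracklayer::import(paths$conservation, format = "bedGraph")
    conservation <- lapply(names(chromosomes), function(cn) {
      v <- rep(NA_real_, chromosomes[[cn]])
      sel <- as.character(GenomicRanges::seqnames(bg)) == cn
      if (any(sel)) {
        st <- GenomicRanges::start(bg)[sel]; en <- GenomicRanges::end(bg)[sel]
        sc <- bg$score[sel]
        for (i in seq_along(st)) v[st[i]:en[i]] <- sc[i]
      }
      v
    })
    names(conservation) <- names(chromosomes)
  }
  indels <- NULL
  if (!is.null(paths$indels) && file.exists(paths$indels)) {
    ib <- utils::read.table(paths$indels, sep = "\t",
                            col.names = c("chrom", "start", "end"))
    indels <- lapply(names(chromosomes),
                     function(cn) as.integer(ib$end[ib$chrom == cn]))
    names(indels) <- names(chromosomes)
  }
  genome_bundle(chromosomes, reference, outgroups, conservation,
                vv$variants, annotation_set(feats, orth), indels)
}
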