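#' Feature classes in precedence order
#'
#' When a position is covered by more than one annotation (e.g. a lncRNA
#' exon inside an ancestral repeat), the highest-precedence class wins.
#' @export
FEATURE_CLASSES <- c("cds_exon", "utr5", "utr3", "pc_intron",
                     "lnc_exon", "lnc_intron", "ancestral_repeat",
                     "intergenic")

#' Build a validated feature table
#'
#' Intervals are 0-based half-open internally; 1-based coordinates appear
#' only at VCF/text boundaries.
#'
#' @param chrom,start,end,strand,feature_class,locus_id Vectors of equal
#'   length describing each interval.
#' @param ordinal Optional; recomputed with [add_ordinals()] when missing.
#' @return A `data.frame` with one row per interval.
#' @export
feature_table <- function(chrom, start, end, strand, feature_class,
                          locus_id, ordinal = NA_character_) {
  if (length(ordinal) == 1L && length(chrom) != 1L)
    ordinal <- rep(ordinal, length(chrom))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   feature_class = as.character(feature_class),
                   locus_id = as.character(locus_id),
                   ordinal = as.character(ordinal),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("feature with start >= end")
  bad <- setdiff(df$feature_class, FEATURE_CLASSES)
  if (length(bad)) stop("unknown feature_class: ", paste(bad, collapse = ","))
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df
}

#' Assign ordinal exon/intron positions in transcript orientation
#'
#' Each locus's exon series and intron series are ranked 5' to 3' (strand
#' aware) and labelled `first` / `middle` / `last`, or `unique` for a series
#' of one. Classes without a series notion keep `unique`.
#'
#' @param features A feature table.
#' @return The table with the `ordinal` column filled.
#' @export
add_ordinals <- function(features) {
  features$ordinal <- "unique"
  exon_cls <- c("cds_exon", "lnc_exon")
  intron_cls <- c("pc_intron", "lnc_intron")
  for (grp in list(exon_cls, intron_cls)) {
    sel <- features$feature_class %in% grp
    if (!any(sel)) next
    idx <- which(sel)
    for (loc in unique(features$locus_id[idx])) {
      li <- idx[features$locus_id[idx] == loc]
      li <- li[order(features$start[li])]
      if (features$strand[li[1]] == "-") li <- rev(li)
      k <- length(li)
      if (k == 1L) { features$ordinal[li] <- "unique"; next }
      features$ordinal[li] <- c("first", rep("middle", k - 2L), "last")
    }
  }
  features
}

#' Bundle features with an optional ortholog map
#'
#' @param features A feature table ([feature_table()]).
#' @param orthologs Optional two-column data.frame (`species_a`,
#'   `species_b`) of strictly 1-to-1 orthologous locus identifiers.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(features, orthologs = NULL) {
  if (!is.null(orthologs)) {
    stopifnot(ncol(orthologs) >= 2)
    names(orthologs)[1:2] <- c("species_a", "species_b")
    if (anyDuplicated(orthologs$species_a) || anyDuplicated(orthologs$species_b))
      stop("ortholog map must be strictly 1-to-1")
  }
  structure(list(features = features, orthologs = orthologs),
            class = "annotation_set")
}

features_as_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand,
    feature_class = features$feature_class,
    locus_id = features$locus_id,
    ordinal = features$ordinal)
}

#' Classify genomic sites by annotation precedence
#'
#' Every position receives exactly one class under the precedence
#' `cds_exon > utr5/utr3 > pc_intron > lnc_exon > lnc_intron >
#' ancestral_repeat > intergenic`.
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param annotation An `annotation_set`.
#' @param chrom_lengths Named integer vector of chromosome lengths, used
#'   for bounds checking.
#' @return `data.frame` with `feature_class`, `locus_id`, `ordinal`.
#' @export
assign_site_class <- function(chrom, pos, annotation, chrom_lengths = NULL) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  if (!is.null(chrom_lengths)) {
    if (any(pos < 1L | pos > chrom_lengths[chrom]))
      stop("position outside chromosome bounds")
  }
  feats <- annotation$features
  out <- data.frame(feature_class = rep("intergenic", length(pos)),
                    locus_id = NA_character_,
                    ordinal = "unique", stringsAsFactors = FALSE)
  if (nrow(feats) == 0L || length(pos) == 0L) return(out)
  gr <- features_as_granges(feats)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    rank <- match(feats$feature_class[sh], FEATURE_CLASSES)
    ord <- order(qh, rank)
    keep <- ord[!duplicated(qh[ord])]
    out$feature_class[qh[keep]] <- feats$feature_class[sh[keep]]
    out$locus_id[qh[keep]] <- feats$locus_id[sh[keep]]
    out$ordinal[qh[keep]] <- feats$ordinal[sh[keep]]
  }
  out
}

#' Per-position feature class over a whole chromosome
#'
#' @param annotation An `annotation_set`.
#' @param chrom Chromosome name.
#' @param len Chromosome length (bp).
#' @return Character vector of length `len`; element i is the class of
#'   1-based position i under the precedence rule.
#' @export
class_partition <- function(annotation, chrom, len) {
  cls <- rep("intergenic", len)
  feats <- annotation$features
  feats <- feats[feats$chrom == chrom, , drop = FALSE]
  # paint lowest precedence first so higher classes overwrite
  for (fc in rev(FEATURE_CLASSES[FEATURE_CLASSES != "intergenic"])) {
    fi <- feats[feats$feature_class == fc, , drop = FALSE]
    for (i in seq_len(nrow(fi))) {
      cls[(fi$start[i] + 1L):fi$end[i]] <- fc
    }
  }
  cls
}

#' Per-position codon degeneracy over a chromosome
#'
#' CDS exons of each locus are spliced in transcript orientation and read
#' in frame from the annotated CDS start; each genomic CDS position
#' inherits the degeneracy of its codon position.
#'
#' @param annotation An `annotation_set`.
#' @param reference Named character vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @return Character vector (length = chromosome length) of degeneracy
#'   labels, `NA` outside CDS.
#' @export
degeneracy_track <- function(annotation, reference, chrom) {
  seq <- reference[[chrom]]
  len <- nchar(seq)
  out <- rep(NA_character_, len)
  feats <- annotation$features
  cds <- feats[feats$feature_class == "cds_exon" & feats$chrom == chrom, ,
               drop = FALSE]
  chars <- strsplit(seq, "")[[1]]
  for (loc in unique(cds$locus_id)) {
    ex <- cds[cds$locus_id == loc, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    minus <- ex$strand[1] == "-"
    if (minus) ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    gpos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
      p <- (ex$start[i] + 1L):ex$end[i]
      if (minus) rev(p) else p
    }))
    bases <- chars[gpos]
    if (minus) bases <- chartr("ACGT", "TGCA", bases)
    usable <- length(gpos) - length(gpos) %% 3L
    if (usable == 0L) next
    deg <- cds_degeneracy(paste(bases[seq_len(usable)], collapse = ""))
    out[gpos[seq_len(usable)]] <- deg
  }
  out
}
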