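#' Specification of a matched neutral proxy set
#'
#' Defaults follow the analysis conventions: fly small introns are <= 86 nt
#' with the first 6 and last 16 transcript-oriented bases disregarded and
#' must belong to a protein-coding gene directly neighbouring a lncRNA
#' locus within 5 kb; mammalian ancestral repeats are taken within 10 kb
#' (5/20 kb alternates); conservation masking removes windows of >= 20 nt
#' with cross-species identity >= 90%, and a masked flank must retain
#' >= 1,000 nt to be usable.
#'
#' @param kind One of `small_intron`, `ancestral_repeat`, `masked_flank`,
#'   `size_matched_intergenic`.
#' @param max_intron_len,trim5,trim3,max_distance,mask_identity,mask_window,min_flank
#'   Tunables; see Details/defaults.
#' @return A `proxy_spec` list.
#' @export
proxy_spec <- function(kind = c("small_intron", "ancestral_repeat",
                                "masked_flank", "size_matched_intergenic"),
                       max_intron_len = 86L, trim5 = 6L, trim3 = 16L,
                       max_distance = if (match.arg(kind) == "small_intron")
                         5000L else 10000L,
                       mask_identity = 0.90, mask_window = 20L,
                       min_flank = 1000L) {
  kind <- match.arg(kind)
  stopifnot(trim5 + trim3 < max_intron_len, max_distance > 0)
  structure(list(kind = kind, max_intron_len = max_intron_len,
                 trim5 = trim5, trim3 = trim3, max_distance = max_distance,
                 mask_identity = mask_identity, mask_window = mask_window,
                 min_flank = min_flank),
            class = "proxy_spec")
}

# distance between closest edges of two half-open intervals (0 if touching
# or overlapping)
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

# span (min start, max end) of a locus's features
locus_span <- function(features, locus) {
  f <- features[features$locus_id == locus, , drop = FALSE]
  c(chrom = f$chrom[1], start = min(f$start), end = max(f$end))
}

# the protein-coding gene(s) that are direct neighbours (nearest on either
# side) of a lncRNA locus span
direct_neighbour_genes <- function(features, lnc_locus) {
  sp <- locus_span(features, lnc_locus)
  pc <- features[features$feature_class %in%
                   c("cds_exon", "utr5", "utr3", "pc_intron") &
                 features$chrom == sp[["chrom"]], , drop = FALSE]
  if (!nrow(pc)) return(character(0))
  spans <- do.call(rbind, lapply(unique(pc$locus_id), function(g) {
    s <- locus_span(pc, g)
    data.frame(gene = g, start = as.integer(s[["start"]]),
               end = as.integer(s[["end"]]))
  }))
  ls <- as.integer(sp[["start"]]); le <- as.integer(sp[["end"]])
  left <- spans[spans$end <= ls, , drop = FALSE]
  right <- spans[spans$start >= le, , drop = FALSE]
  out <- character(0)
  if (nrow(left)) out <- c(out, left$gene[which.max(left$end)])
  if (nrow(right)) out <- c(out, right$gene[which.min(right$start)])
  out
}

#' Select trimmed small introns near lncRNA loci
#'
#' Keeps protein-coding introns of length <= `max_intron_len` whose gene is
#' a direct neighbour of a lncRNA locus within `max_distance`, trimmed to
#' drop the first `trim5` and last `trim3` bases in transcript orientation.
#'
#' @param annotation An `annotation_set`.
#' @param spec A [proxy_spec()] of kind `small_intron`.
#' @return Feature table of trimmed intron intervals (possibly empty),
#'   with a `source_lnc` column naming the paired lncRNA locus.
#' @export
select_small_introns <- function(annotation, spec = proxy_spec("small_intron")) {
  feats <- annotation$features
  lnc <- unique(feats$locus_id[feats$feature_class == "lnc_exon"])
  out <- list()
  for (ll in lnc) {
    sp <- locus_span(feats, ll)
    genes <- direct_neighbour_genes(feats, ll)
    for (g in genes) {
      gs <- locus_span(feats, g)
      gap <- interval_gap(as.integer(sp[["start"]]), as.integer(sp[["end"]]),
                          as.integer(gs[["start"]]), as.integer(gs[["end"]]))
      if (gap > spec$max_distance) next
      intr <- feats[feats$locus_id == g & feats$feature_class == "pc_intron", ,
                    drop = FALSE]
      intr <- intr[(intr$end - intr$start) <= spec$max_intron_len, ,
                   drop = FALSE]
      if (!nrow(intr)) next
      plus <- intr$strand == "+"
      trimmed <- intr
      trimmed$start <- ifelse(plus, intr$start + spec$trim5,
                              intr$start + spec$trim3)
      trimmed$end <- ifelse(plus, intr$end - spec$trim3,
                            intr$end - spec$trim5)
      trimmed <- trimmed[trimmed$start < trimmed$end, , drop = FALSE]
      if (nrow(trimmed)) {
        trimmed$source_lnc <- ll
        out[[length(out) + 1L]] <- trimmed
      }
    }
  }
  if (!length(out)) {
    e <- empty_features(); e$source_lnc <- character(0); return(e)
  }
  res <- do.call(rbind, out)
  res[!duplicated(res[c("chrom", "start", "end", "source_lnc")]), ,
      drop = FALSE]
}

#' Select ancestral repeats flanking lncRNA loci
#'
#' Keeps ancestral repeats lying within intergenic sequence (precedence
#' class `ancestral_repeat`, i.e. not inside any gene) within
#' `max_distance` of a lncRNA span. Loci with no qualifying repeat are
#' dropped from paired analyses.
#'
#' @param annotation An `annotation_set`.
#' @param spec A [proxy_spec()] of kind `ancestral_repeat`.
#' @return Feature table of kept repeats with `source_lnc`.
#' @export
select_flanking_ancestral_repeats <- function(annotation,
    spec = proxy_spec("ancestral_repeat")) {
  feats <- annotation$features
  ars <- feats[feats$feature_class == "ancestral_repeat", , drop = FALSE]
  genic <- feats[feats$feature_class %in%
                   c("cds_exon", "utr5", "utr3", "pc_intron",
                     "lnc_exon", "lnc_intron"), , drop = FALSE]
  # an AR overlapped by any genic feature is not intergenic
  if (nrow(ars) && nrow(genic)) {
    gr_ar <- features_as_granges(ars); gr_g <- features_as_granges(genic)
    hit <- GenomicRanges::countOverlaps(gr_ar, gr_g, ignore.strand = TRUE)
    ars <- ars[hit == 0L, , drop = FALSE]
  }
  lnc <- unique(feats$locus_id[feats$feature_class == "lnc_exon"])
  out <- list()
  for (ll in lnc) {
    sp <- locus_span(feats, ll)
    cand <- ars[ars$chrom == sp[["chrom"]], , drop = FALSE]
    if (!nrow(cand)) next
    gap <- interval_gap(as.integer(sp[["start"]]), as.integer(sp[["end"]]),
                        cand$start, cand$end)
    cand <- cand[gap <= spec$max_distance, , drop = FALSE]
    if (nrow(cand)) {
      cand$source_lnc <- ll
      out[[length(out) + 1L]] <- cand
    }
  }
  if (!length(out)) {
    e <- empty_features(); e$source_lnc <- character(0); return(e)
  }
  do.call(rbind, out)
}

#' Mask conserved windows of a flanking sequence
#'
#' Masks every position contained in any window of length
#' `spec$mask_window` or more whose reference/outgroup identity is at
#' least `spec$mask_identity`; returns the unmasked sub-intervals.
#' Idempotent by construction.
#'
#' @param ref_track,outgroup_track Aligned chromosome strings.
#' @param intervals Data frame with `start`,`end` (0-based half-open).
#' @param spec A [proxy_spec()].
#' @return Data frame of unmasked sub-intervals (`start`,`end`), carrying
#'   over any other columns of `intervals`.
#' @export
mask_conserved_elements <- function(ref_track, outgroup_track, intervals,
                                    spec = proxy_spec("masked_flank")) {
  a <- strsplit(ref_track, "")[[1]]
  b <- strsplit(outgroup_track, "")[[1]]
  w <- spec$mask_window
  out <- list()
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    len <- e - s
    if (len < w) {  # too short to host a window: nothing maskable
      out[[length(out) + 1L]] <- intervals[i, , drop = FALSE]
      next
    }
    m <- as.integer(a[(s + 1L):e] == b[(s + 1L):e])
    cs <- c(0L, cumsum(m))
    nw <- len - w + 1L
    ident <- (cs[(w + 1L):(len + 1L)] - cs[1:nw]) / w
    masked <- logical(len)
    for (j in which(ident >= spec$mask_identity)) {
      masked[j:(j + w - 1L)] <- TRUE
    }
    r <- rle(!masked)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    keep <- which(r$values)
    for (j in keep) {
      row <- intervals[i, , drop = FALSE]
      row$start <- s + starts[j]; row$end <- s + ends[j]
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(intervals[0, , drop = FALSE])
  do.call(rbind, out)
}

#' Mask conserved windows by conservation score
#'
#' Score-based alternative to [mask_conserved_elements()]: masks every
#' position inside any window of `spec$mask_window` bases whose mean
#' conservation score is at least `score_threshold`. Pairwise identity
#' against a near outgroup cannot separate conserved elements from
#' neutral background when neutral identity itself exceeds the identity
#' cutoff (e.g. at < 10% neutral divergence), so conservation-score
#' masking is the appropriate choice there.
#'
#' @param conservation Per-base score vector for the chromosome.
#' @param intervals Data frame with `start`,`end` (0-based half-open).
#' @param spec A [proxy_spec()].
#' @param score_threshold Mean-score cutoff for masking a window.
#' @return Data frame of unmasked sub-intervals.
#' @export
mask_conserved_by_score <- function(conservation, intervals,
                                    spec = proxy_spec("masked_flank"),
                                    score_threshold = 0.8) {
  w <- spec$mask_window
  out <- list()
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    len <- e - s
    if (len < w) {
      out[[length(out) + 1L]] <- intervals[i, , drop = FALSE]
      next
    }
    sc <- conservation[(s + 1L):e]
    sc[is.na(sc)] <- 0
    cs <- c(0, cumsum(sc))
    nw <- len - w + 1L
    wmean <- (cs[(w + 1L):(len + 1L)] - cs[1:nw]) / w
    masked <- logical(len)
    for (j in which(wmean >= score_threshold)) {
      masked[j:(j + w - 1L)] <- TRUE
    }
    r <- rle(!masked)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    for (j in which(r$values)) {
      row <- intervals[i, , drop = FALSE]
      row$start <- s + starts[j]; row$end <- s + ends[j]
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(intervals[0, , drop = FALSE])
  do.call(rbind, out)
}

#' Sample size-matched neutral positions from a masked flank
#'
#' Draws exactly `n_sites` distinct positions uniformly without
#' replacement from the unmasked flank intervals; the flank must retain at
#' least `spec$min_flank` usable bases, else the locus is excluded.
#'
#' @param n_sites Number of analyzable focal sites to match.
#' @param masked_intervals Unmasked sub-intervals from
#'   [mask_conserved_elements()].
#' @param spec A [proxy_spec()].
#' @return Sorted integer vector of 1-based sampled positions; when the
#'   locus must be excluded, a zero-length vector carrying a `reason`
#'   attribute (`flank_below_min` or `flank_smaller_than_target`).
#' @export
sample_matched_sites <- function(n_sites, masked_intervals,
                                 spec = proxy_spec("masked_flank")) {
  pool <- unlist(lapply(seq_len(nrow(masked_intervals)), function(i) {
    (masked_intervals$start[i] + 1L):masked_intervals$end[i]
  }))
  if (length(pool) < spec$min_flank)
    return(structure(integer(0), reason = "flank_below_min"))
  if (length(pool) < n_sites)
    return(structure(integer(0), reason = "flank_smaller_than_target"))
  if (n_sites == 0L) return(integer(0))
  sort(sample_vec(pool, n_sites))
}
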