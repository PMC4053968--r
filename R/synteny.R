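## Positional-equivalence mapping: lncRNAs paired across species by the
## side and transcriptional orientation they occupy relative to 1-to-1
## orthologous protein-coding anchor genes.

#' Assign the protein-coding anchor of a lncRNA locus
#'
#' The anchor is the nearest flanking protein-coding gene (ties broken
#' toward the smaller distance, then the 5' side in the reference
#' orientation); side and relative orientation are computed strand-aware.
#'
#' @param lnc_locus lncRNA locus identifier.
#' @param annotation An `annotation_set` containing both the lncRNA and
#'   protein-coding features.
#' @return One-row data.frame: `lnc`, `anchor`, `side`
#'   (`5prime_of_gene`/`3prime_of_gene`), `orientation`
#'   (`same`/`opposite`), `distance`; or `NULL` (logged attribute) when no
#'   flanking gene exists.
#' @export
assign_anchor <- function(lnc_locus, annotation) {
  feats <- annotation$features
  sp <- locus_span(feats, lnc_locus)
  lnc_strand <- feats$strand[feats$locus_id == lnc_locus][1]
  genes <- direct_neighbour_genes(feats, lnc_locus)
  if (!length(genes)) return(structure(NULL, reason = "unanchored"))
  cand <- do.call(rbind, lapply(genes, function(g) {
    gs <- locus_span(feats, g)
    gstart <- as.integer(gs[["start"]]); gend <- as.integer(gs[["end"]])
    d <- interval_gap(as.integer(sp[["start"]]), as.integer(sp[["end"]]),
                      gstart, gend)
    gstrand <- feats$strand[feats$locus_id == g][1]
    lnc_left_of_gene <- as.integer(sp[["end"]]) <= gstart
    # lncRNA left of a + gene sits 5' of it; left of a - gene sits 3'
    side <- if (lnc_left_of_gene == (gstrand == "+")) "5prime_of_gene"
            else "3prime_of_gene"
    # the gene lies on the lncRNA's 5' side when it sits upstream of the
    # lncRNA in the lncRNA's own orientation
    gene_left_of_lnc <- gend <= as.integer(sp[["start"]])
    on_lnc_5prime <- gene_left_of_lnc == (lnc_strand == "+")
    data.frame(lnc = lnc_locus, anchor = g, side = side,
               orientation = if (lnc_strand == gstrand) "same" else "opposite",
               distance = d, is5 = on_lnc_5prime,
               stringsAsFactors = FALSE)
  }))
  # nearest; ties toward the lncRNA's 5' side
  cand <- cand[order(cand$distance, -cand$is5), , drop = FALSE]
  cand$is5 <- NULL
  cand[1, , drop = FALSE]
}

#' Anchor every lncRNA locus of an annotation
#'
#' @param annotation An `annotation_set`.
#' @return Data frame of [assign_anchor()] rows; unanchored loci are
#'   reported in the `unanchored` attribute.
#' @export
assign_anchors <- function(annotation) {
  feats <- annotation$features
  lnc <- unique(feats$locus_id[feats$feature_class == "lnc_exon"])
  rows <- list(); missing <- character(0)
  for (ll in lnc) {
    a <- assign_anchor(ll, annotation)
    if (is.null(a)) missing <- c(missing, ll)
    else rows[[length(rows) + 1L]] <- a
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lnc = character(), anchor = character(), side = character(),
               orientation = character(), distance = integer())
  attr(out, "unanchored") <- missing
  out
}

#' Classify positionally equivalent lncRNAs between two species
#'
#' A pair is a positional equivalent (PE) when the two lncRNAs anchor to
#' 1-to-1 orthologous genes on the same side with the same relative
#' orientation; a lncRNA whose anchor has an ortholog that also flanks a
#' lncRNA in the other species, but with side or orientation mismatched,
#' enters the control set. PE and control are disjoint by construction.
#'
#' @param anchors_a,anchors_b [assign_anchors()] tables for each species.
#' @param orthologs Strictly 1-to-1 two-column map (`species_a`,
#'   `species_b`) of anchor gene identifiers.
#' @return List: `pe` (data.frame `lnc_a`, `lnc_b`, `anchor_a`,
#'   `anchor_b`), `control_a`, `control_b` (character vectors of control
#'   lncRNA ids per species).
#' @export
classify_positional_equivalents <- function(anchors_a, anchors_b,
                                            orthologs) {
  names(orthologs)[1:2] <- c("species_a", "species_b")
  if (anyDuplicated(orthologs$species_a) ||
      anyDuplicated(orthologs$species_b))
    stop("ortholog map must be strictly 1-to-1")
  a <- merge(anchors_a, orthologs, by.x = "anchor", by.y = "species_a")
  b <- anchors_b
  m <- merge(a, b, by.x = "species_b", by.y = "anchor",
             suffixes = c("_a", "_b"))
  if (!nrow(m)) {
    return(list(pe = data.frame(lnc_a = character(), lnc_b = character(),
                                anchor_a = character(),
                                anchor_b = character()),
                control_a = character(0), control_b = character(0)))
  }
  is_pe <- m$side_a == m$side_b & m$orientation_a == m$orientation_b
  pe <- data.frame(lnc_a = m$lnc_a[is_pe], lnc_b = m$lnc_b[is_pe],
                   anchor_a = m$anchor[is_pe],
                   anchor_b = m$species_b[is_pe],
                   stringsAsFactors = FALSE)
  list(pe = pe,
       control_a = setdiff(unique(m$lnc_a[!is_pe]), pe$lnc_a),
       control_b = setdiff(unique(m$lnc_b[!is_pe]), pe$lnc_b))
}
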