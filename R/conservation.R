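## Interspecific conservation layer: metagene decile profiles over exons
## and introns with bootstrap confidence intervals, size-matched
## intergenic control bands, single-site resampling, and splice-site
## information content.

# split a feature of length len into n_windows decile index vectors,
# remainder bases assigned to the earlier windows, strand-aware
decile_windows <- function(len, n_windows = 10L, minus = FALSE) {
  base <- len %/% n_windows
  extra <- len %% n_windows
  sizes <- rep(base, n_windows) + c(rep(1L, extra), rep(0L, n_windows - extra))
  idx <- split(seq_len(len), rep(seq_len(n_windows), sizes))
  # on the minus strand the transcript's first window holds the feature's
  # last genomic bases: map positions through len - i + 1
  if (minus) idx <- lapply(idx, function(i) len - i + 1L)
  idx
}

feature_scores <- function(feature_row, conservation) {
  sc <- conservation[[feature_row$chrom]]
  sc[(feature_row$start + 1L):feature_row$end]
}

#' Metagene decile conservation profile
#'
#' Splits each feature into `n_windows` equal strand-oriented portions,
#' takes the median score per portion, and reports per decile the median
#' over features with a percentile-bootstrap confidence interval
#' (bootstrap unit = feature). Features shorter than `n_windows` bp are
#' dropped and counted.
#'
#' @param features Feature table rows to profile.
#' @param conservation Per-chromosome list of per-base scores.
#' @param n_windows Number of portions (default 10).
#' @param n_boot Bootstrap replicates for the 95% CI (study default
#'   10,000).
#' @param seed Integer seed.
#' @return A data.frame with `decile`, `median`, `lower`, `upper`, plus
#'   attributes `n_features` and `n_dropped`.
#' @export
metagene_profile <- function(features, conservation, n_windows = 10L,
                             n_boot = 10000L, seed = 1L) {
  if (nrow(features) == 0L) stop("empty feature set")
  lens <- features$end - features$start
  drop <- lens < n_windows
  kept <- features[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no feature is >= n_windows bp long")
  per_feat <- matrix(NA_real_, nrow(kept), n_windows)
  for (i in seq_len(nrow(kept))) {
    sc <- feature_scores(kept[i, ], conservation)
    idx <- decile_windows(length(sc), n_windows,
                          minus = kept$strand[i] == "-")
    per_feat[i, ] <- vapply(idx, function(j) stats::median(sc[j]),
                            numeric(1))
  }
  set.seed(seed)
  meds <- apply(per_feat, 2, stats::median, na.rm = TRUE)
  nb <- nrow(per_feat)
  boot <- matrix(NA_real_, n_boot, n_windows)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nb, nb, replace = TRUE)
    boot[b, ] <- apply(per_feat[rows, , drop = FALSE], 2, stats::median,
                       na.rm = TRUE)
  }
  out <- data.frame(decile = seq_len(n_windows), median = meds,
                    lower = apply(boot, 2, stats::quantile, 0.025),
                    upper = apply(boot, 2, stats::quantile, 0.975))
  attr(out, "n_features") <- nrow(kept)
  attr(out, "n_dropped") <- sum(drop)
  out
}

# intergenic intervals lying more than `buffer` bp away from any gene
eligible_intergenic <- function(annotation, chrom_lengths, buffer = 1000L) {
  out <- list()
  for (cn in names(chrom_lengths)) {
    part <- class_partition(annotation, cn, chrom_lengths[[cn]])
    genic <- part %in% c("cds_exon", "utr5", "utr3", "pc_intron",
                         "lnc_exon", "lnc_intron")
    near <- genic
    w <- which(genic)
    if (length(w)) {
      lo <- pmax(1L, w - buffer); hi <- pmin(length(part), w + buffer)
      for (i in seq_along(w)) near[lo[i]:hi[i]] <- TRUE
    }
    ok <- part == "intergenic" & !near
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- c(0L, ends[-length(ends)])
    keep <- which(r$values)
    if (length(keep))
      out[[cn]] <- data.frame(chrom = cn, start = starts[keep],
                              end = ends[keep])
  }
  if (!length(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer()))
  do.call(rbind, out)
}

#' Size-matched intergenic control envelope
#'
#' Draws `n_sets` control sets, each containing one intergenic interval
#' per target feature with identical length, sampled uniformly from
#' intergenic sequence lying > 1 kb from any annotated gene; the
#' per-decile 2.5/97.5 percentile envelope of the set medians is the
#' control band.
#'
#' @param annotation,chrom_lengths Annotation and chromosome lengths used
#'   to locate eligible intergenic space.
#' @param target_lengths Lengths (bp) of the target features to match.
#' @param conservation Score tracks.
#' @param n_sets Number of control sets (study default 1,000).
#' @param n_windows Deciles.
#' @param seed Integer seed.
#' @param buffer Exclusion distance around genes (bp).
#' @param keep_sets Also return every sampled interval set (auditing).
#' @return List: `band` (data.frame decile, lower, upper, median),
#'   `intervals_per_set` = length(target_lengths), `sets` (when
#'   requested).
#' @export
control_profiles <- function(annotation, chrom_lengths, target_lengths,
                             conservation, n_sets = 1000L, n_windows = 10L,
                             seed = 1L, buffer = 1000L,
                             keep_sets = FALSE) {
  pool <- eligible_intergenic(annotation, chrom_lengths, buffer)
  if (!nrow(pool)) stop("no eligible intergenic sequence > ", buffer,
                        " bp from genes")
  set.seed(seed)
  sets <- if (keep_sets) vector("list", n_sets) else NULL
  set_medians <- matrix(NA_real_, n_sets, n_windows)
  for (s in seq_len(n_sets)) {
    per_feat <- matrix(NA_real_, length(target_lengths), n_windows)
    for (i in seq_along(target_lengths)) {
      len <- target_lengths[i]
      fits <- pool[(pool$end - pool$start) >= len, , drop = FALSE]
      if (!nrow(fits))
        stop("insufficient intergenic space for a control of length ", len)
      j <- sample.int(nrow(fits), 1L)
      off <- sample.int(fits$end[j] - fits$start[j] - len + 1L, 1L) - 1L
      row <- data.frame(chrom = fits$chrom[j],
                        start = fits$start[j] + off,
                        end = fits$start[j] + off + len)
      sc <- feature_scores(row, conservation)
      idx <- decile_windows(len, n_windows)
      per_feat[i, ] <- vapply(idx, function(k) stats::median(sc[k]),
                              numeric(1))
      if (keep_sets) sets[[s]] <- rbind(sets[[s]], row)
    }
    set_medians[s, ] <- apply(per_feat, 2, stats::median)
  }
  band <- data.frame(decile = seq_len(n_windows),
                     lower = apply(set_medians, 2, stats::quantile, 0.025),
                     median = apply(set_medians, 2, stats::median),
                     upper = apply(set_medians, 2, stats::quantile, 0.975))
  list(band = band, intervals_per_set = length(target_lengths),
       sets = sets)
}

#' Single-site exon/intron conservation comparison
#'
#' Per resample, draws one uniformly chosen site per feature and compares
#' the median exon score to the median intron score; the empirical
#' one-sided p is the fraction of resamples in which the exon median does
#' not exceed the intron median.
#'
#' @param exon_features,intron_features Feature tables.
#' @param conservation Score tracks.
#' @param n_resamples Number of resampling rounds (study default 1,000).
#' @param seed Integer seed.
#' @return List: `exon_medians`, `intron_medians` (per resample),
#'   `p_empirical`.
#' @export
single_site_comparison <- function(exon_features, intron_features,
                                   conservation, n_resamples = 1000L,
                                   seed = 1L) {
  set.seed(seed)
  draw_medians <- function(features) {
    vapply(seq_len(n_resamples), function(b) {
      one <- vapply(seq_len(nrow(features)), function(i) {
        sc <- feature_scores(features[i, ], conservation)
        sc[sample.int(length(sc), 1L)]
      }, numeric(1))
      stats::median(one)
    }, numeric(1))
  }
  ex <- draw_medians(exon_features)
  it <- draw_medians(intron_features)
  list(exon_medians = ex, intron_medians = it,
       p_empirical = mean(ex <= it))
}

#' Shannon information content of alignment columns
#'
#' Per-column information content `IC = 2 - H` bits with
#' `H = -sum p_b log2 p_b` over the observed (ungapped) bases; columns
#' with fewer than `min_bases` ungapped bases are dropped.
#'
#' @param column Character vector of aligned bases (A/C/G/T/N/-).
#' @param min_bases Minimum ungapped bases for a column to count.
#' @return IC in \[0, 2\] bits, or `NA` if the column is dropped.
#' @export
column_information <- function(column, min_bases = 3L) {
  b <- toupper(column)
  b <- b[b %in% BASES]
  if (length(b) < min_bases) return(NA_real_)
  p <- table(b) / length(b)
  h <- -sum(p * log2(p))
  2 - h
}

#' Splice-site information-content profile
#'
#' Computes per-column IC for the splice dinucleotide and the 20 adjacent
#' intronic columns of each aligned block (one block per splice site:
#' several species over 50 nt upstream + the site + 50 nt downstream).
#' Blocks with fewer than 3 ungapped species bases at the dinucleotide
#' itself are skipped and counted.
#'
#' @param blocks List of character matrices (species x alignment columns).
#'   The splice dinucleotide occupies columns 51-52.
#' @param side `"5prime"` (GT; intron extends rightwards) or `"3prime"`
#'   (AG; intron extends leftwards).
#' @return List with `profile` (data.frame `offset`, `ic` averaged over
#'   blocks; offset 0-1 = dinucleotide, then the 20 intronic columns) and
#'   `n_skipped`.
#' @export
splice_site_information <- function(blocks, side = c("5prime", "3prime")) {
  side <- match.arg(side)
  din <- 51:52
  intronic <- if (side == "5prime") 53:72 else 31:50
  cols <- c(din, intronic)
  offsets <- c(0:1, if (side == "5prime") 2:21 else -(20:1))
  skipped <- 0L
  per_block <- list()
  for (bl in blocks) {
    at_din <- apply(bl[, din, drop = FALSE], 2,
                    function(cc) sum(toupper(cc) %in% BASES))
    if (any(at_din < 3L)) { skipped <- skipped + 1L; next }
    per_block[[length(per_block) + 1L]] <-
      vapply(cols, function(j) column_information(bl[, j]), numeric(1))
  }
  if (!length(per_block))
    return(list(profile = data.frame(offset = offsets, ic = NA_real_),
                n_skipped = skipped))
  mat <- do.call(rbind, per_block)
  list(profile = data.frame(offset = offsets,
                            ic = colMeans(mat, na.rm = TRUE)),
       n_skipped = skipped)
}

#' Build splice-site alignment blocks from a bundle
#'
#' For each intron boundary of the requested locus classes, stacks the
#' reference and outgroup tracks over 50 nt either side of the splice
#' dinucleotide into an alignment block (gap-free by construction of the
#' bundle). Also samples an equal number of control blocks centred on
#' random GT (or AG) dinucleotides in intergenic sequence.
#'
#' @param bundle A `genome_bundle`.
#' @param intron_class `"lnc_intron"` or `"pc_intron"`.
#' @param side `"5prime"` or `"3prime"`.
#' @param seed Seed for control sampling.
#' @return List with `blocks` and `control_blocks`.
#' @export
extract_splice_blocks <- function(bundle, intron_class = "lnc_intron",
                                  side = c("5prime", "3prime"), seed = 1L) {
  side <- match.arg(side)
  feats <- bundle$annotation$features
  introns <- feats[feats$feature_class == intron_class, , drop = FALSE]
  tracks <- c(list(bundle$reference), bundle$outgroups)
  get_block <- function(cn, centre_start) {
    # centre_start = 1-based position of the first dinucleotide base;
    # block spans 50 nt upstream + 2 + 49 nt downstream = 101 columns
    lo <- centre_start - 50L; hi <- centre_start + 50L
    if (lo < 1L || hi > bundle$chromosomes[[cn]]) return(NULL)
    do.call(rbind, lapply(tracks, function(tr)
      strsplit(substr(tr[[cn]], lo, hi), "")[[1]]))
  }
  blocks <- list()
  dints <- character(0)
  for (i in seq_len(nrow(introns))) {
    cn <- introns$chrom[i]
    plus <- introns$strand[i] == "+"
    donor_first <- if (plus) introns$start[i] + 1L else introns$end[i] - 1L
    accept_first <- if (plus) introns$end[i] - 1L else introns$start[i] + 1L
    cs <- if (side == "5prime") donor_first else accept_first
    bl <- get_block(cn, cs)
    if (!is.null(bl)) {
      blocks[[length(blocks) + 1L]] <- bl
      dints <- c(dints, paste0(bl[1, 51], bl[1, 52]))
    }
  }
  # control: random occurrences of the same dinucleotide in intergenic
  # sequence, count-matched 1:1 with the real sites
  target <- if (side == "5prime") "GT" else "AG"
  set.seed(seed)
  ctrl <- list()
  pool <- eligible_intergenic(bundle$annotation, bundle$chromosomes,
                              buffer = 0L)
  cand <- list()
  for (j in seq_len(nrow(pool))) {
    cn <- pool$chrom[j]
    seg <- substr(bundle$reference[[cn]], pool$start[j] + 1L, pool$end[j])
    hits <- gregexpr(target, seg, fixed = TRUE)[[1]]
    if (hits[1] != -1L)
      cand[[length(cand) + 1L]] <- data.frame(chrom = cn,
                                              pos = pool$start[j] + hits)
  }
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    take <- sample.int(nrow(cand), min(length(blocks), nrow(cand)))
    for (t in take) {
      bl <- get_block(cand$chrom[t], cand$pos[t])
      if (!is.null(bl)) ctrl[[length(ctrl) + 1L]] <- bl
    }
  }
  list(blocks = blocks, control_blocks = ctrl, dinucleotides = dints)
}
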