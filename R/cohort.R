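## Synthetic two-species cohort generator: lays out a fake genome with
## protein-coding genes, multi-exonic intergenic lncRNAs and ancestral
## repeats, draws segregating sites per feature class from the selected
## equilibrium frequency density under that class's selection regime,
## applies outgroup divergence with class-specific fixation weights, and
## emits per-site ground truth so every downstream stage is testable.

#' Selection regime of one feature class
#'
#' Either a point scaled coefficient `gamma` = 4*Ne*s (0 = neutral,
#' negative = deleterious) or a gamma distribution over |Nes| with
#' (`shape`, `mean`).
#'
#' @param gamma Point-mass scaled coefficient.
#' @param shape,mean Gamma DFE parameters over |Nes|.
#' @return A `selection_regime` list.
#' @export
selection_regime <- function(gamma = NULL, shape = NULL, mean = NULL) {
  if (is.null(gamma)) {
    stopifnot(!is.null(shape), !is.null(mean), shape > 0, mean > 0)
  } else stopifnot(is.null(shape), is.null(mean))
  structure(list(gamma = gamma, shape = shape, mean = mean),
            class = "selection_regime")
}

#' Cohort generator configuration
#'
#' Defaults describe the fly-like study conditions: 162 sampled haplotypes
#' filtered at >= 10 reads and >= 150 unambiguous calls, per-site neutral
#' mutation parameter theta = 0.01, nearer/farther outgroup branch
#' divergences 0.06/0.12 expected substitutions per neutral site, a
#' deleterious lncRNA-exon class (gamma DFE over |Nes|, shape 0.5, mean
#' 20), neutral small introns, and class-specific Beta conservation-score
#' models. See `cohort_preset()` for the human-like variant.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_haplotypes Sample size n.
#' @param theta Per-site neutral population mutation rate 4*Ne*mu.
#' @param regimes Named list of [selection_regime()] per feature class.
#' @param divergences Numeric c(d1, d2), nearer-first outgroup branch
#'   divergences (d1 < d2 < 0.75).
#' @param demography c(r, t2): epoch size ratio and duration; r != 1 is
#'   emulated by scaling theta (documented approximation), default
#'   equilibrium.
#' @param pc_gene,lnc_gene,ar_len,gap_len Layout size distributions.
#' @param coverage_mean,low_cov_frac,low_cov_mean Read-depth model.
#' @param ambig_fail_frac Fraction of sites with too many ambiguous
#'   strain calls (fails the fly called-strain filter).
#' @param qual_mean,qual_sd Call-quality model (the human profile's
#'   default cutoff rejects 0.1% of true sites under this model).
#' @param indel_density Per-bp indel probability (sets near-indel flags).
#' @param conservation_beta Named list of Beta(a, b) parameters per class.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    chrom_lengths = c(chr2L = 500000L, chr2R = 500000L),
    n_haplotypes = 162L,
    theta = 0.01,
    regimes = list(
      cds_exon = selection_regime(shape = 0.3, mean = 500),
      utr5 = selection_regime(shape = 0.3, mean = 5),
      utr3 = selection_regime(shape = 0.3, mean = 8),
      pc_intron = selection_regime(gamma = 0),
      lnc_exon = selection_regime(shape = 0.5, mean = 20),
      lnc_intron = selection_regime(gamma = 0),
      ancestral_repeat = selection_regime(gamma = 0),
      intergenic = selection_regime(gamma = 0)),
    divergences = c(0.06, 0.12),
    demography = c(r = 1, t2 = 0),
    pc_gene = list(n_cds_exons = 4L, cds_len = c(150L, 300L),
                   p_small = 0.7, small_len = c(60L, 86L),
                   intron_len = c(400L, 1200L),
                   utr5_len = 150L, utr3_len = 200L),
    lnc_gene = list(n_exons = c(2L, 4L), exon_len = c(250L, 600L),
                    intron_len = c(150L, 800L)),
    ar_len = c(300L, 800L),
    gap_len = c(1000L, 4000L),
    unit_pattern = c("pc", "lnc", "ar"),
    coverage_mean = 25, low_cov_frac = 0.02, low_cov_mean = 6,
    ambig_fail_frac = 0.02,
    qual_mean = 50, qual_sd = 10,
    indel_density = 5e-4,
    conservation_beta = list(
      cds_exon = c(8, 2), utr5 = c(2, 3), utr3 = c(2, 3),
      pc_intron = c(1, 6), lnc_exon = c(3, 4), lnc_intron = c(1, 6),
      ancestral_repeat = c(1, 8), intergenic = c(1, 8))) {
  stopifnot(n_haplotypes >= 4,
            divergences[1] < divergences[2], divergences[2] < 0.75,
            theta > 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' Named cohort presets
#'
#' `fly-like`: the [cohort_config()] defaults. `human-like`: 348
#' haplotypes, neutral lncRNAs, theta 0.0012, chimp/macaque-style
#' divergences 0.012/0.06. `ci`: a fly-like cohort scaled to a 200 kb
#' genome for fast test runs.
#'
#' @param name Preset name.
#' @param ... Overrides passed to the preset after construction.
#' @return A `cohort_config`.
#' @export
cohort_preset <- function(name = c("fly-like", "human-like", "ci"), ...) {
  name <- match.arg(name)
  cfg <- switch(name,
    "fly-like" = cohort_config(),
    "human-like" = cohort_config(
      n_haplotypes = 348L, theta = 0.0012, divergences = c(0.012, 0.06),
      regimes = list(
        cds_exon = selection_regime(shape = 0.3, mean = 500),
        utr5 = selection_regime(shape = 0.3, mean = 5),
        utr3 = selection_regime(shape = 0.3, mean = 8),
        pc_intron = selection_regime(gamma = 0),
        lnc_exon = selection_regime(gamma = 0),
        lnc_intron = selection_regime(gamma = 0),
        ancestral_repeat = selection_regime(gamma = 0),
        intergenic = selection_regime(gamma = 0))),
    "ci" = cohort_config(
      chrom_lengths = c(chr2L = 200000L)))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

## ---- layout ----------------------------------------------------------

runif_int <- function(n, lo, hi) {
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1L)))
}

# one protein-coding gene as a transcript-order segment list
build_pc_gene <- function(cfg, id) {
  g <- cfg$pc_gene
  ne <- g$n_cds_exons
  cds_len <- 3L * runif_int(ne, g$cds_len[1] %/% 3L, g$cds_len[2] %/% 3L)
  small <- stats::runif(ne - 1L) < g$p_small
  int_len <- ifelse(small, runif_int(ne - 1L, g$small_len[1], g$small_len[2]),
                    runif_int(ne - 1L, g$intron_len[1], g$intron_len[2]))
  segs <- list(list(class = "utr5", len = g$utr5_len))
  for (i in seq_len(ne)) {
    segs[[length(segs) + 1L]] <- list(class = "cds_exon", len = cds_len[i])
    if (i < ne)
      segs[[length(segs) + 1L]] <- list(class = "pc_intron",
                                        len = int_len[i])
  }
  segs[[length(segs) + 1L]] <- list(class = "utr3", len = g$utr3_len)
  list(id = id, segs = segs,
       strand = sample_vec(c("+", "-"), 1L))
}

build_lnc_gene <- function(cfg, id) {
  g <- cfg$lnc_gene
  ne <- runif_int(1L, g$n_exons[1], g$n_exons[2])
  segs <- list()
  for (i in seq_len(ne)) {
    segs[[length(segs) + 1L]] <-
      list(class = "lnc_exon", len = runif_int(1L, g$exon_len[1],
                                               g$exon_len[2]))
    if (i < ne)
      segs[[length(segs) + 1L]] <-
        list(class = "lnc_intron", len = runif_int(1L, g$intron_len[1],
                                                   g$intron_len[2]))
  }
  list(id = id, segs = segs, strand = sample_vec(c("+", "-"), 1L))
}

# place one unit's segments at a genomic cursor; transcript order is
# genomic order on + and reversed on -
place_unit <- function(unit, chrom, cursor) {
  segs <- unit$segs
  if (unit$strand == "-") segs <- rev(segs)
  rows <- list()
  at <- cursor
  for (s in segs) {
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = chrom, start = at, end = at + s$len,
                 strand = unit$strand, feature_class = s$class,
                 locus_id = unit$id, ordinal = NA_character_,
                 stringsAsFactors = FALSE)
    at <- at + s$len
  }
  list(rows = do.call(rbind, rows), cursor = at)
}

# lay out repeated [pc gene, lncRNA, ancestral repeat] units with
# intergenic gaps until each chromosome is filled
layout_genome <- function(cfg) {
  rows <- list()
  counters <- c(pc = 0L, lnc = 0L, ar = 0L)
  pat <- cfg$unit_pattern %||% c("pc", "lnc", "ar")
  placed_total <- 0L
  for (cn in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[cn]]
    cursor <- runif_int(1L, cfg$gap_len[1], cfg$gap_len[2])
    repeat {
      kind <- pat[placed_total %% length(pat) + 1L]
      unit <- switch(kind,
        pc = build_pc_gene(cfg, sprintf("pc%04d", counters["pc"] + 1L)),
        lnc = build_lnc_gene(cfg, sprintf("lnc%04d", counters["lnc"] + 1L)),
        ar = list(id = sprintf("ar%04d", counters["ar"] + 1L),
                  segs = list(list(class = "ancestral_repeat",
                                   len = runif_int(1L, cfg$ar_len[1],
                                                   cfg$ar_len[2]))),
                  strand = "+"))
      size <- sum(vapply(unit$segs, `[[`, 0L, "len"))
      gap_after <- runif_int(1L, cfg$gap_len[1], cfg$gap_len[2])
      if (cursor + size + gap_after > len) break
      placed <- place_unit(unit, cn, cursor)
      rows[[length(rows) + 1L]] <- placed$rows
      cursor <- placed$cursor + gap_after
      counters[kind] <- counters[kind] + 1L
      placed_total <- placed_total + 1L
    }
  }
  if (!length(rows)) stop("infeasible layout: no unit fits a chromosome")
  feats <- do.call(rbind, rows)
  add_ordinals(feature_table(feats$chrom, feats$start, feats$end,
                             feats$strand, feats$feature_class,
                             feats$locus_id))
}

## ---- sequence and SNPs ----------------------------------------------

random_reference <- function(annotation, chrom_lengths) {
  ref <- list()
  for (cn in names(chrom_lengths)) {
    chars <- sample_vec(BASES, chrom_lengths[[cn]], replace = TRUE)
    feats <- annotation$features
    intr <- feats[feats$chrom == cn &
                    feats$feature_class %in% c("pc_intron", "lnc_intron"), ,
                  drop = FALSE]
    # canonical splice dinucleotides in genomic orientation per strand:
    # donor GT / acceptor AG on +, their reverse complement on -
    for (i in seq_len(nrow(intr))) {
      s <- intr$start[i]; e <- intr$end[i]
      if (intr$strand[i] == "+") {
        chars[(s + 1L):(s + 2L)] <- c("G", "T")
        chars[(e - 1L):e] <- c("A", "G")
      } else {
        chars[(s + 1L):(s + 2L)] <- c("C", "T")
        chars[(e - 1L):e] <- c("A", "C")
      }
    }
    ref[[cn]] <- paste(chars, collapse = "")
  }
  ref
}

# per-regime machinery on a fine frequency grid: node |gamma| values,
# node weights (gamma mass or point), per-node segregation intensity and
# conditional q-sampling weights
regime_grid <- function(regime, n, grid_points = 4000L, n_nodes = 200L) {
  q <- (seq_len(grid_points) - 0.5) / grid_points
  pseg <- 1 - q^n - (1 - q)^n
  if (!is.null(regime$gamma)) {
    nodes <- regime$gamma
    node_w <- 1
  } else {
    nodes <- -exp(seq(log(1e-3), log(2000), length.out = n_nodes))
    edges <- c(0, sqrt(exp(seq(log(1e-3), log(2000),
                               length.out = n_nodes))[-n_nodes] *
                         exp(seq(log(1e-3), log(2000),
                                 length.out = n_nodes))[-1L]), Inf)
    node_w <- diff(stats::pgamma(edges, shape = regime$shape,
                                 scale = regime$mean / regime$shape))
  }
  W <- vapply(nodes, function(g) expected_sfs_density(g, q) / grid_points,
              numeric(grid_points))
  I <- colSums(W * pseg)           # segregation intensity per node
  list(q = q, nodes = nodes, node_w = node_w, W = W, I = I, pseg = pseg)
}

# mean relative fixation weight of a regime (divergence scaling)
regime_fixation_weight <- function(regime) {
  if (!is.null(regime$gamma)) return(fixation_weight(regime$gamma))
  n_nodes <- 200L
  nodes <- exp(seq(log(1e-3), log(2000), length.out = n_nodes))
  edges <- c(0, sqrt(nodes[-n_nodes] * nodes[-1L]), Inf)
  w <- diff(stats::pgamma(edges, shape = regime$shape,
                          scale = regime$mean / regime$shape))
  sum(w * fixation_weight(-nodes))
}

# draw truncated-binomial derived counts (0 < c < size) for sites grouped
# by shared grid frequency
draw_seg_counts <- function(qvals, size) {
  out <- integer(length(qvals))
  for (qv in unique(qvals)) {
    idx <- which(qvals == qv)
    pr <- stats::dbinom(seq_len(size - 1L), size, qv)
    out[idx] <- sample_vec(seq_len(size - 1L), length(idx), replace = TRUE,
                           prob = pr)
  }
  out
}

#' Generate a synthetic cohort with ground truth
#'
#' Lays out the genome, draws segregating sites per feature class from
#' the equilibrium selected frequency density under the class's regime
#' (site hosts a SNP with probability theta times the regime's
#' segregation intensity, so deleterious classes are correctly depleted),
#' samples derived counts binomially conditioned on segregation, applies
#' per-branch Jukes-Cantor outgroup substitutions at rate d times the
#' class's mean fixation weight, models coverage / call ambiguity /
#' quality / indels, and draws per-class Beta conservation scores.
#' Deterministic given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List with `bundle` (a `genome_bundle`) and `truth` (data.frame
#'   per SNP: `chrom`, `pos`, `ancestral`, `feature_class`, `gamma`).
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(substream_seed(seed, "layout"))
  annotation <- annotation_set(layout_genome(config))
  set.seed(substream_seed(seed, "reference"))
  reference <- random_reference(annotation, config$chrom_lengths)
  n <- config$n_haplotypes

  # two-epoch emulation: recent expansions raise effective theta for the
  # polymorphism draw (documented approximation; no linkage model)
  r <- unname(config$demography[1])
  theta_eff <- config$theta * r

  set.seed(substream_seed(seed, "snps"))
  grids <- lapply(config$regimes, regime_grid, n = n)
  variants <- list(); truth <- list()
  for (cn in names(config$chrom_lengths)) {
    part <- class_partition(annotation, cn, config$chrom_lengths[[cn]])
    ref_chars <- strsplit(reference[[cn]], "")[[1]]
    for (cls in FEATURE_CLASSES) {
      pos <- which(part == cls)
      if (!length(pos)) next
      gr <- grids[[cls]]
      p_site <- theta_eff * sum(gr$node_w * gr$I)
      hit <- pos[stats::runif(length(pos)) < p_site]
      if (!length(hit)) next
      # node per SNP site, weighted by gamma mass x segregation intensity
      nodep <- gr$node_w * gr$I
      nidx <- sample_vec(seq_along(gr$nodes), length(hit), replace = TRUE,
                         prob = nodep)
      qidx <- integer(length(hit))
      for (k in unique(nidx)) {
        sel <- which(nidx == k)
        qidx[sel] <- sample_vec(seq_along(gr$q), length(sel),
                                replace = TRUE,
                                prob = gr$W[, k] * gr$pseg)
      }
      qv <- gr$q[qidx]
      counts <- draw_seg_counts(qv, n)
      refb <- ref_chars[hit]
      altb <- vapply(refb, function(b) sample_vec(setdiff(BASES, b), 1L),
                     character(1))
      variants[[length(variants) + 1L]] <- data.frame(
        chrom = cn, pos = hit, ref_allele = refb, alt_allele = altb,
        allele_count = counts, n_called = n, coverage = 0L, qual = 0,
        near_indel = FALSE, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = cn, pos = hit, ancestral = refb, feature_class = cls,
        gamma = gr$nodes[nidx], stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(variants)) do.call(rbind, variants) else
    empty_variants()
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), pos = integer(),
               ancestral = character(), feature_class = character(),
               gamma = double())
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  rownames(variants) <- rownames(truth) <- NULL

  # coverage, strain-call ambiguity and quality
  set.seed(substream_seed(seed, "calls"))
  ns <- nrow(variants)
  if (ns) {
    low <- stats::runif(ns) < config$low_cov_frac
    variants$coverage <- as.integer(ifelse(
      low, stats::rpois(ns, config$low_cov_mean),
      stats::rpois(ns, config$coverage_mean)))
    fail <- stats::runif(ns) < config$ambig_fail_frac
    n_called <- rep(n, ns)
    if (any(fail) && n > 150L)
      n_called[fail] <- runif_int(sum(fail), max(4L, n - 62L), 149L)
    # re-draw counts for reduced-call sites so 0 < count < n_called
    for (i in which(fail & n_called < n)) {
      variants$allele_count[i] <-
        draw_seg_counts(variants$allele_count[i] / n, n_called[i])
    }
    variants$n_called <- n_called
    variants$qual <- stats::rnorm(ns, config$qual_mean, config$qual_sd)
  }

  # indels and near-indel flags
  set.seed(substream_seed(seed, "indels"))
  indels <- list()
  for (cn in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[cn]]
    k <- stats::rpois(1L, len * config$indel_density)
    indels[[cn]] <- sort(sample_vec(seq_len(len), min(k, len)))
  }
  if (ns) {
    for (cn in names(indels)) {
      sel <- which(variants$chrom == cn)
      if (!length(sel) || !length(indels[[cn]])) next
      ip <- indels[[cn]]
      i1 <- findInterval(variants$pos[sel], ip)
      d_lo <- ifelse(i1 >= 1L, variants$pos[sel] - ip[pmax(i1, 1L)], Inf)
      d_hi <- ifelse(i1 < length(ip), ip[pmin(i1 + 1L, length(ip))] -
                       variants$pos[sel], Inf)
      variants$near_indel[sel] <- pmin(d_lo, d_hi) <= 10L
    }
  }

  # outgroup tracks: per-branch Jukes-Cantor substitutions at rate
  # d * mean fixation weight of the class
  set.seed(substream_seed(seed, "outgroups"))
  ew <- vapply(config$regimes, regime_fixation_weight, numeric(1))
  outgroups <- lapply(config$divergences, function(d) {
    og <- list()
    for (cn in names(config$chrom_lengths)) {
      part <- class_partition(annotation, cn, config$chrom_lengths[[cn]])
      chars <- strsplit(reference[[cn]], "")[[1]]
      p_sub <- 0.75 * (1 - exp(-4 / 3 * d * ew[part]))
      sub <- which(stats::runif(length(chars)) < p_sub)
      if (length(sub)) {
        chars[sub] <- vapply(chars[sub], function(b)
          sample_vec(setdiff(BASES, b), 1L), character(1))
      }
      og[[cn]] <- paste(chars, collapse = "")
    }
    og
  })

  # conservation scores from per-class Beta models
  set.seed(substream_seed(seed, "conservation"))
  conservation <- list()
  for (cn in names(config$chrom_lengths)) {
    part <- class_partition(annotation, cn, config$chrom_lengths[[cn]])
    sc <- numeric(length(part))
    for (cls in FEATURE_CLASSES) {
      sel <- part == cls
      if (!any(sel)) next
      ab <- config$conservation_beta[[cls]]
      sc[sel] <- stats::rbeta(sum(sel), ab[1], ab[2])
    }
    conservation[[cn]] <- sc
  }

  bundle <- genome_bundle(config$chrom_lengths, reference, outgroups,
                          conservation, variants, annotation, indels)
  list(bundle = bundle, truth = truth)
}

#' Simulate segregating sites of one selection regime
#'
#' Draws exactly `n_sites` segregating derived-allele counts at sample
#' size `n` from the equilibrium selected frequency density under the
#' regime — the same machinery [generate_cohort()] uses per feature
#' class, without the genome layout. Sites are drawn conditional on
#' segregation with gamma values weighted by their polymorphism
#' contribution.
#'
#' @param regime A [selection_regime()].
#' @param n Haplotype sample size.
#' @param n_sites Number of segregating sites to emit.
#' @param seed Integer seed.
#' @return List: `counts` (derived counts, 0 < c < n) and `gamma` (the
#'   per-site scaled coefficient drawn).
#' @export
simulate_class_sites <- function(regime, n, n_sites, seed = 1L) {
  set.seed(substream_seed(seed, "class_sites"))
  gr <- regime_grid(regime, n)
  nodep <- gr$node_w * gr$I
  nidx <- sample_vec(seq_along(gr$nodes), n_sites, replace = TRUE,
                     prob = nodep)
  qidx <- integer(n_sites)
  for (k in unique(nidx)) {
    sel <- which(nidx == k)
    qidx[sel] <- sample_vec(seq_along(gr$q), length(sel), replace = TRUE,
                            prob = gr$W[, k] * gr$pseg)
  }
  list(counts = draw_seg_counts(gr$q[qidx], n), gamma = gr$nodes[nidx])
}

#' Summarize simulator ground truth per feature class
#'
#' @param truth The `truth` table from [generate_cohort()].
#' @param path Optional TSV output path.
#' @return Data frame: `feature_class`, `n_sites`, `mean_gamma`.
#' @export
truth_report <- function(truth, path = NULL) {
  if (nrow(truth) == 0L) {
    out <- data.frame(feature_class = character(), n_sites = integer(),
                      mean_gamma = double())
  } else {
    cls <- sort(unique(truth$feature_class))
    out <- data.frame(
      feature_class = cls,
      n_sites = vapply(cls, function(k) sum(truth$feature_class == k),
                       integer(1)),
      mean_gamma = vapply(cls, function(k)
        mean(truth$gamma[truth$feature_class == k]), numeric(1)),
      row.names = NULL)
  }
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Mirror an annotation into a second species with planted equivalents
#'
#' Copies the annotation under renamed locus identifiers, flips the
#' strand of a fraction of lncRNA loci (their anchor orientation then
#' mismatches, making them controls), and returns the 1-to-1 ortholog map
#' of the protein-coding genes plus the planted truth.
#'
#' @param annotation Species-A `annotation_set`.
#' @param flip_fraction Fraction of lncRNAs to convert into controls.
#' @param seed Integer seed.
#' @return List: `annotation_b`, `orthologs`, `planted_pe`,
#'   `planted_control` (species-A lncRNA ids).
#' @export
mirror_cohort_annotation <- function(annotation, flip_fraction = 0.3,
                                     seed = 1L) {
  set.seed(substream_seed(seed, "mirror"))
  feats <- annotation$features
  fb <- feats
  fb$locus_id <- paste0(fb$locus_id, "_B")
  lnc <- unique(feats$locus_id[feats$feature_class == "lnc_exon"])
  n_flip <- round(flip_fraction * length(lnc))
  flip <- sample_vec(lnc, n_flip)
  for (ll in flip) {
    sel <- fb$locus_id == paste0(ll, "_B")
    fb$strand[sel] <- ifelse(fb$strand[sel] == "+", "-", "+")
  }
  pc <- unique(feats$locus_id[feats$feature_class == "cds_exon"])
  orthologs <- data.frame(species_a = pc, species_b = paste0(pc, "_B"),
                          stringsAsFactors = FALSE)
  list(annotation_b = annotation_set(fb, orthologs),
       orthologs = orthologs,
       planted_pe = setdiff(lnc, flip),
       planted_control = flip)
}
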