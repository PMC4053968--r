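## End-to-end orchestration: simulate -> filter/polarize -> neutral
## proxies -> polymorphism statistics -> selection tests -> DFE ->
## conservation -> synteny -> report, from one configuration with one
## master seed fanned out to per-stage substreams.

#' Build a pipeline run configuration
#'
#' @param cohort A [cohort_config()] (synthetic input), or `NULL` with
#'   `input_dir` set to a directory readable by [load_bundle()].
#' @param input_dir Optional directory of on-disk inputs (exclusive with
#'   `cohort`).
#' @param profile Filter profile name, `"fly"` or `"human"`.
#' @param seed Master seed.
#' @param outdir Output directory.
#' @param n_boot Metagene bootstrap replicates.
#' @param n_control_sets Size-matched intergenic control sets.
#' @param n_resamples Single-site resampling rounds.
#' @param dfe_boot DFE bootstrap replicates.
#' @param Nref DFE grid size.
#' @param stages Character vector of stages to run.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_preset("fly-like"),
                       input_dir = NULL,
                       profile = c("fly", "human"),
                       seed = 1L, outdir = tempfile("lncevo_run_"),
                       n_boot = 1000L, n_control_sets = 100L,
                       n_resamples = 200L, dfe_boot = 20L, Nref = 100L,
                       stages = c("simulate", "polarize", "proxies",
                                  "popgen", "tests", "dfe", "conserve",
                                  "synteny", "report")) {
  profile <- match.arg(profile)
  if (is.null(cohort) == is.null(input_dir))
    stop("exactly one of `cohort` or `input_dir` must be given")
  structure(list(cohort = cohort, input_dir = input_dir,
                 profile = profile, seed = seed, outdir = outdir,
                 n_boot = n_boot, n_control_sets = n_control_sets,
                 n_resamples = n_resamples, dfe_boot = dfe_boot,
                 Nref = Nref, stages = stages),
            class = "run_config")
}

# positions (per chromosome) of a feature class, precedence-masked
class_positions <- function(bundle, cls) {
  out <- list()
  for (cn in names(bundle$chromosomes)) {
    part <- class_partition(bundle$annotation, cn,
                            bundle$chromosomes[[cn]])
    out[[cn]] <- which(part == cls)
  }
  out
}

positions_of_intervals <- function(intervals, chroms) {
  out <- lapply(chroms, function(cn) {
    iv <- intervals[intervals$chrom == cn, , drop = FALSE]
    if (!nrow(iv)) return(integer(0))
    unlist(lapply(seq_len(nrow(iv)),
                  function(i) (iv$start[i] + 1L):iv$end[i]))
  })
  names(out) <- chroms
  out
}

daf_at <- function(polarised, pos_list) {
  unlist(lapply(names(pos_list), function(cn) {
    sel <- polarised$chrom == cn & polarised$pos %in% pos_list[[cn]]
    polarised$daf[sel]
  }))
}

counts_at <- function(polarised, pos_list, n) {
  round(daf_at(polarised, pos_list) * n)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order and writes every report file
#' plus a manifest into `config$outdir`. Rerunning with the same
#' configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of stage results (also serialized to
#'   the output directory by [write_report()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(manifest = list())
  log_stage <- function(stage, info) {
    res$manifest[[length(res$manifest) + 1L]] <<-
      data.frame(stage = stage, seed = substream_seed(config$seed, stage),
                 info = info, stringsAsFactors = FALSE)
  }

  ## simulate / load
  if (!is.null(config$cohort)) {
    sim <- generate_cohort(config$cohort, seed = config$seed)
    bundle <- sim$bundle
    res$truth <- sim$truth
    log_stage("simulate", sprintf("%d variants", nrow(bundle$variants)))
  } else {
    bundle <- load_bundle(config$input_dir)
    log_stage("load", sprintf("%d variants", nrow(bundle$variants)))
  }
  res$bundle <- bundle
  n <- max(bundle$variants$n_called)

  ## filter + polarize
  prof <- filter_profile(config$profile)
  flt <- filter_sites(bundle$variants, prof)
  pol <- polarize_all(flt$kept, bundle)
  polarised <- pol$polarised
  # stratify to the modal sample size so spectra share one n
  polarised <- polarised[polarised$n_called == n, , drop = FALSE]
  res$filter_tally <- flt$tally
  res$polarised <- polarised
  res$n_ambiguous <- pol$n_ambiguous
  res$n <- n
  log_stage("polarize", sprintf("%d polarised, %d ambiguous",
                                nrow(polarised), pol$n_ambiguous))

  ## neutral proxies: small introns + masked-flank matched sampling
  if ("proxies" %in% config$stages) {
    set.seed(substream_seed(config$seed, "proxies"))
    res$small_introns <- select_small_introns(bundle$annotation)
    res$flanking_ars <- select_flanking_ancestral_repeats(bundle$annotation)
    feats <- bundle$annotation$features
    lnc <- unique(feats$locus_id[feats$feature_class == "lnc_exon"])
    spec <- proxy_spec("masked_flank")
    matched <- list(); excluded <- list()
    interg <- eligible_intergenic(bundle$annotation, bundle$chromosomes,
                                  buffer = 0L)
    for (ll in lnc) {
      sp <- locus_span(feats, ll)
      cn <- sp[["chrom"]]
      ls <- as.integer(sp[["start"]]); le <- as.integer(sp[["end"]])
      flank <- interg[interg$chrom == cn &
                        interg$end > ls - 10000L &
                        interg$start < le + 10000L, , drop = FALSE]
      if (!nrow(flank)) { excluded[[ll]] <- "no_flank"; next }
      # score-based masking: identity against a near outgroup cannot
      # separate conserved elements from neutral background when neutral
      # identity exceeds the 90% cutoff (see mask_conserved_by_score)
      masked <- mask_conserved_by_score(bundle$conservation[[cn]], flank,
                                        spec)
      ex <- feats[feats$locus_id == ll &
                    feats$feature_class == "lnc_exon", , drop = FALSE]
      n_sites <- sum(ex$end - ex$start)
      pos <- sample_matched_sites(n_sites, masked, spec)
      if (!is.null(attr(pos, "reason"))) {
        excluded[[ll]] <- attr(pos, "reason"); next
      }
      matched[[ll]] <- list(chrom = cn, positions = pos,
                            exon_positions = positions_of_intervals(
                              ex, cn)[[cn]])
    }
    res$matched_neutral <- matched
    res$proxy_exclusions <- excluded
    log_stage("proxies", sprintf("%d loci matched, %d excluded",
                                 length(matched), length(excluded)))
  }

  ## popgen summary table (per locus x class)
  if ("popgen" %in% config$stages) {
    res$popgen <- locus_popgen_table(polarised, bundle, n)
    log_stage("popgen", sprintf("%d locus-class rows", nrow(res$popgen)))
  }

  ## selection tests: MK + DAF spectra with Bonferroni
  if ("tests" %in% config$stages && length(res$matched_neutral)) {
    neutral_pos <- lapply(names(bundle$chromosomes), function(cn) {
      unlist(lapply(res$matched_neutral, function(m)
        if (m$chrom == cn) m$positions else integer(0)))
    })
    names(neutral_pos) <- names(bundle$chromosomes)
    exon_pos <- lapply(names(bundle$chromosomes), function(cn) {
      unlist(lapply(res$matched_neutral, function(m)
        if (m$chrom == cn) m$exon_positions else integer(0)))
    })
    names(exon_pos) <- names(bundle$chromosomes)
    intron_pos <- class_positions(bundle, "lnc_intron")

    tests <- list()
    mk_ex <- mk_table_from_sites(bundle, polarised, exon_pos, neutral_pos)
    tests$mk_lnc_exon <- c(mk_test(mk_ex),
                           list(table = paste(mk_ex, collapse = ",")))
    mk_in <- mk_table_from_sites(bundle, polarised, intron_pos,
                                 neutral_pos)
    tests$mk_lnc_intron <- c(mk_test(mk_in),
                             list(table = paste(mk_in, collapse = ",")))
    daf_ex <- daf_at(polarised, exon_pos)
    daf_in <- daf_at(polarised, intron_pos)
    daf_ne <- daf_at(polarised, neutral_pos)
    tests$daf_lnc_exon <- compare_daf_spectra(daf_ex, daf_ne)
    tests$daf_lnc_intron <- compare_daf_spectra(daf_in, daf_ne)
    raw_p <- vapply(tests, function(t)
      t$p %||% t$p_value, numeric(1))
    adj <- bonferroni(raw_p)
    for (i in seq_along(tests)) tests[[i]]$p_adjusted <- adj[i]
    res$tests <- tests
    res$daf <- list(lnc_exon = daf_ex, lnc_intron = daf_in,
                    neutral = daf_ne)
    log_stage("tests", sprintf("%d tests, family size %d",
                               length(tests), length(tests)))
  }

  ## DFE from folded spectra: neutral = matched sites, selected = exons
  if ("dfe" %in% config$stages && length(res$daf$neutral)) {
    neutral_sfs <- build_sfs(round(res$daf$neutral * n), n, fold = TRUE)
    selected_sfs <- build_sfs(round(res$daf$lnc_exon * n), n, fold = TRUE)
    demog <- fit_demography(neutral_sfs, Nref = config$Nref)
    dfe <- fit_dfe(selected_sfs, demog, Nref = config$Nref)
    res$dfe <- list(demography = demog[c("r", "t2", "loglik")],
                    shape = dfe$shape, mean = dfe$mean,
                    bins = dfe$bins, boundary = dfe$boundary)
    log_stage("dfe", sprintf("shape %.3g mean %.3g", dfe$shape, dfe$mean))
  }

  ## conservation profiles
  if ("conserve" %in% config$stages && !is.null(bundle$conservation)) {
    feats <- bundle$annotation$features
    ex <- feats[feats$feature_class == "lnc_exon", , drop = FALSE]
    it <- feats[feats$feature_class == "lnc_intron", , drop = FALSE]
    res$metagene <- list(
      lnc_exon = metagene_profile(ex, bundle$conservation,
                                  n_boot = config$n_boot,
                                  seed = substream_seed(config$seed,
                                                        "conserve")),
      lnc_intron = metagene_profile(it, bundle$conservation,
                                    n_boot = config$n_boot,
                                    seed = substream_seed(config$seed,
                                                          "conserve")))
    res$control_band <- control_profiles(
      bundle$annotation, bundle$chromosomes, ex$end - ex$start,
      bundle$conservation, n_sets = config$n_control_sets,
      seed = substream_seed(config$seed, "control"))$band
    res$single_site <- single_site_comparison(
      ex, it, bundle$conservation, n_resamples = config$n_resamples,
      seed = substream_seed(config$seed, "single_site"))
    if (nrow(it) && config$profile == "fly") {
      blocks <- extract_splice_blocks(bundle, "lnc_intron", "5prime",
                                      seed = substream_seed(config$seed,
                                                            "splice"))
      res$splice <- list(
        real = splice_site_information(blocks$blocks, "5prime"),
        control = splice_site_information(blocks$control_blocks, "5prime"))
      log_stage("conserve", sprintf("splice blocks %d",
                                    length(blocks$blocks)))
    } else {
      log_stage("conserve", "splice stage skipped (no introns/human)")
    }
  }

  ## synteny on a mirrored second species
  if ("synteny" %in% config$stages) {
    mir <- mirror_cohort_annotation(bundle$annotation,
                                    seed = config$seed)
    aa <- assign_anchors(bundle$annotation)
    ab <- assign_anchors(mir$annotation_b)
    res$synteny <- classify_positional_equivalents(aa, ab, mir$orthologs)
    res$synteny$planted_pe <- mir$planted_pe
    res$synteny$planted_control <- mir$planted_control
    log_stage("synteny", sprintf("%d PE, %d control",
                                 nrow(res$synteny$pe),
                                 length(res$synteny$control_a)))
  }

  if ("report" %in% config$stages) {
    write_report(res, config$outdir)
    log_stage("report", config$outdir)
  }
  res$manifest <- do.call(rbind, res$manifest)
  utils::write.table(res$manifest, file.path(config$outdir,
                                             "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}

#' Write pipeline summary tables
#'
#' Emits the per-class polymorphism table (per-locus averages with
#' standard deviations), MK and DAF-comparison test tables with
#' Bonferroni-adjusted p-values, the DFE bin report and the metagene
#' profiles.
#'
#' @param res Stage results from [run_pipeline()].
#' @param outdir Output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  w <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(res$popgen)) {
    agg <- do.call(rbind, lapply(split(res$popgen,
                                       res$popgen$feature_class),
      function(d) data.frame(
        feature_class = d$feature_class[1], n_loci = nrow(d),
        piT_mean = mean(d$piT), piT_sd = stats::sd(d$piT),
        thetaW_mean = mean(d$thetaW), thetaW_sd = stats::sd(d$thetaW),
        tajD_mean = mean(d$tajD, na.rm = TRUE),
        tajD_sd = stats::sd(d$tajD, na.rm = TRUE),
        k_mean = mean(d$k), k_sd = stats::sd(d$k))))
    w(agg, "popgen_by_class.tsv")
    w(res$popgen, "popgen_by_locus.tsv")
  }
  if (!is.null(res$tests)) {
    tt <- do.call(rbind, lapply(names(res$tests), function(nm) {
      t <- res$tests[[nm]]
      data.frame(test = nm,
                 statistic = t$chi2 %||% t$ks_statistic,
                 p_raw = t$p %||% t$p_value,
                 p_adjusted = t$p_adjusted,
                 prop_low_focal = t$prop_low_focal %||% NA_real_,
                 prop_low_neutral = t$prop_low_neutral %||% NA_real_)
    }))
    w(tt, "selection_tests.tsv")
  }
  if (!is.null(res$dfe)) {
    jsonlite::write_json(res$dfe, file.path(outdir, "dfe_report.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, file.path(outdir, "dfe_report.json"))
  }
  if (!is.null(res$metagene)) {
    mg <- rbind(cbind(set = "lnc_exon", res$metagene$lnc_exon),
                cbind(set = "lnc_intron", res$metagene$lnc_intron))
    w(mg, "metagene_profiles.tsv")
    if (!is.null(res$control_band)) w(res$control_band,
                                      "metagene_control_band.tsv")
  }
  if (!is.null(res$splice)) {
    sp <- rbind(cbind(set = "splice", res$splice$real$profile),
                cbind(set = "control", res$splice$control$profile))
    w(sp, "splice_information.tsv")
  }
  if (!is.null(res$synteny)) {
    w(res$synteny$pe, "positional_equivalents.tsv")
  }
  invisible(written)
}
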