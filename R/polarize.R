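#' Site filter profiles
#'
#' Two study-style filter profiles. The `fly` profile keeps sites covered
#' by at least `min_coverage` reads and called without base ambiguity in at
#' least `min_called` of the sampled strains; the `human` profile drops
#' SNPs within 10 bp of indel calls and below a call-quality cutoff (a
#' plain configurable stand-in for a false-discovery-controlled threshold).
#'
#' @param name `"fly"` or `"human"`.
#' @param min_coverage,min_called,min_qual Optional overrides.
#' @return A `filter_profile` list.
#' @export
filter_profile <- function(name = c("fly", "human"), min_coverage = NULL,
                           min_called = NULL, min_qual = NULL) {
  name <- match.arg(name)
  prof <- switch(name,
    fly = list(name = "fly", min_coverage = 10L, min_called = 150L,
               drop_near_indel = FALSE, min_qual = -Inf),
    # default qual cutoff calibrated so ~0.1% of true generator sites fail
    human = list(name = "human", min_coverage = 0L, min_called = 0L,
                 drop_near_indel = TRUE, min_qual = 19.1))
  if (!is.null(min_coverage)) prof$min_coverage <- min_coverage
  if (!is.null(min_called)) prof$min_called <- min_called
  if (!is.null(min_qual)) prof$min_qual <- min_qual
  structure(prof, class = "filter_profile")
}

#' Apply a filter profile to population sites
#'
#' @param sites Variant data.frame (see [genome_bundle()]).
#' @param profile A [filter_profile()].
#' @return List with `kept` (the surviving sites) and `tally`, a named
#'   vector of rejection counts by reason (first failing reason recorded;
#'   reasons sum with the kept count to the input size).
#' @export
filter_sites <- function(sites, profile) {
  if (!inherits(profile, "filter_profile")) stop("unknown filter profile")
  reason <- rep(NA_character_, nrow(sites))
  if (profile$drop_near_indel)
    reason[is.na(reason) & sites$near_indel] <- "near_indel"
  reason[is.na(reason) & sites$coverage < profile$min_coverage] <-
    "low_coverage"
  reason[is.na(reason) & sites$n_called < profile$min_called] <-
    "too_few_called"
  reason[is.na(reason) & sites$qual < profile$min_qual] <- "low_qual"
  kept <- sites[is.na(reason), , drop = FALSE]
  tally <- table(factor(reason[!is.na(reason)],
                        levels = c("near_indel", "low_coverage",
                                   "too_few_called", "low_qual")))
  list(kept = kept, tally = c(tally))
}

#' Infer the ancestral allele of one biallelic site by parsimony
#'
#' Strict two-outgroup maximum parsimony: the ancestral state is the base
#' carried identically by both outgroups, provided it is one of the two
#' segregating alleles. Disagreeing outgroups, a third-state base, or any
#' N/gap yield `NA` (ambiguous; such sites are removed downstream). The
#' `"nearest"` policy instead accepts the nearest outgroup's base when the
#' farther outgroup is missing (N/gap) but still rejects contradictions.
#'
#' @param alleles Character vector of the two segregating alleles.
#' @param outgroup_bases Character vector: the aligned base of each
#'   outgroup at the site, nearest first (A/C/G/T/N/-).
#' @param policy `"strict"` (default) or `"nearest"`.
#' @return The ancestral base, or `NA_character_` if ambiguous.
#' @export
polarize_site <- function(alleles, outgroup_bases,
                          policy = c("strict", "nearest")) {
  policy <- match.arg(policy)
  if (length(alleles) != 2L || alleles[1] == alleles[2])
    stop("a biallelic site needs two distinct alleles")
  assert_bases(alleles)
  ob <- toupper(outgroup_bases)
  valid <- ob %in% BASES
  if (policy == "strict") {
    if (!all(valid)) return(NA_character_)
    if (ob[1] != ob[2]) return(NA_character_)
    anc <- ob[1]
  } else {
    if (!any(valid)) return(NA_character_)
    obv <- ob[valid]
    if (length(unique(obv)) > 1L) return(NA_character_)
    anc <- obv[1]
  }
  if (!anc %in% alleles) return(NA_character_)
  anc
}

#' Polarize all sites against the bundle's outgroup tracks
#'
#' Applies [polarize_site()] at every variant position; ambiguous sites
#' are excluded and counted. The derived allele frequency is
#' `derived count / n_called`.
#'
#' @param sites Filtered variant data.frame.
#' @param bundle A `genome_bundle` providing the outgroup tracks.
#' @param policy Passed to [polarize_site()].
#' @return List with `polarised` (sites plus `ancestral_allele`,
#'   `derived_allele`, `daf`) and `n_ambiguous`.
#' @export
polarize_all <- function(sites, bundle, policy = "strict") {
  n <- nrow(sites)
  if (n == 0L) {
    out <- sites
    out$ancestral_allele <- character(0)
    out$derived_allele <- character(0)
    out$daf <- numeric(0)
    return(list(polarised = out, n_ambiguous = 0L))
  }
  anc <- character(n)
  for (cn in unique(sites$chrom)) {
    sel <- which(sites$chrom == cn)
    ob <- vapply(bundle$outgroups, function(og) {
      strsplit(og[[cn]], "")[[1]][sites$pos[sel]]
    }, character(length(sel)))
    if (length(sel) == 1L) ob <- matrix(ob, nrow = 1L)
    for (j in seq_along(sel)) {
      i <- sel[j]
      anc[i] <- polarize_site(c(sites$ref_allele[i], sites$alt_allele[i]),
                              ob[j, ], policy = policy)
    }
  }
  keep <- !is.na(anc)
  out <- sites[keep, , drop = FALSE]
  anc <- anc[keep]
  derived <- ifelse(anc == out$ref_allele, out$alt_allele, out$ref_allele)
  dcount <- ifelse(anc == out$ref_allele, out$allele_count,
                   out$n_called - out$allele_count)
  out$ancestral_allele <- anc
  out$derived_allele <- derived
  out$daf <- dcount / out$n_called
  list(polarised = out, n_ambiguous = sum(!keep))
}
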