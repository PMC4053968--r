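---
title: "Measuring selective constraint on intergenic lncRNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selective constraint on intergenic lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncevo)
```

## The scientific question

Cross-species conservation measures selection integrated over millions
of years. Population polymorphism measures it now: purifying selection
keeps deleterious variants rare, so a selected sequence class shows
fewer segregating sites relative to divergence, an excess of
low-frequency derived alleles, a negative Tajima's D, and a distribution
of fitness effects (DFE) with appreciable mass at |Nes| > 1. `lncevo`
assembles that toolkit for multi-exonic intergenic lncRNAs, where the
central methodological problem is the *neutral reference*: lncRNA loci
sit in genomic neighbourhoods whose mutation rate, base composition and
background selection vary, so every comparison is made against matched
local proxies rather than genome-wide averages.

## Data model and site classes

All intervals are 0-based half-open internally; 1-based coordinates
appear only in VCF records. Every genomic position receives exactly one
feature class under the precedence

`cds_exon > utr5/utr3 > pc_intron > lnc_exon > lnc_intron >
ancestral_repeat > intergenic`,

which resolves, among others, lncRNAs overlapping ancestral repeats
(the lncRNA wins, because repeats are used as neutral intergenic
proxies) and positions that are exonic in one isoform and intronic in
another (exon precedence). Codon degeneracy (0-, 2-, 3-, 4-fold) is
computed from spliced, strand-oriented CDS read in frame. Exons and
introns carry ordinals (`first`/`middle`/`last`/`unique`) assigned in
transcript orientation.

## Filters and polarization

Two filter profiles reflect the two study designs the package emulates.
The fly profile keeps sites with read depth ≥ 10 and ≥ 150 of 162
strains called without ambiguity. The human profile removes SNPs within
10 bp of an indel call and below a quality cutoff; a false-discovery
quality threshold cannot be recomputed without the original read data,
so the cutoff is a plain configurable number whose default (19.1) the
synthetic generator calibrates to reject 0.1% of true sites under its
quality model (Normal(50, 10)).

Ancestral states come from strict two-outgroup maximum parsimony: the
base carried identically by both outgroups is ancestral, provided it is
one of the two segregating alleles; disagreeing outgroups, third-state
bases, and any N or gap make the site ambiguous and it is removed. This
is the most conservative reading of parsimony polarization; a
"nearest-outgroup wins unless contradicted" mode is provided but off by
default. Polarization is symmetric in allele labelling, and the
homoplasy error rate is bounded by the probability of parallel
substitutions on the two outgroup branches (about 10⁻⁴ at branch
divergences 0.02/0.05, which is why recovery against simulator truth
exceeds 99.9%).

## Neutral proxies

Three matched proxy constructions are provided:

* **Trimmed small introns** — protein-coding introns ≤ 86 nt from genes
  that are direct neighbours (nearest flanking gene on either side) of a
  lncRNA locus within 5 kb, with the first 6 and last 16
  transcript-oriented bases discarded (they carry splicing signals).
* **Flanking ancestral repeats** — repeats lying in intergenic sequence
  within 10 kb (5/20 kb alternates) of the lncRNA span; loci without a
  qualifying repeat leave paired analyses.
* **Masked-flank site samples** — for a lncRNA with N analyzable exonic
  sites, exactly N positions drawn uniformly without replacement from
  its intergenic flank after masking conserved elements, provided
  ≥ 1,000 nt of flank survive masking. Matching site counts per locus
  controls local mutation rate and background selection.

Masking has two modes. The identity mode masks every position inside a
window of ≥ 20 nt with reference/outgroup identity ≥ 90%, computed
against the nearer outgroup. That criterion presupposes a comparison
species distant enough that neutral identity falls well below 90%
(human–mouse territory); against a close outgroup — fly vs its sister
species at ~6% divergence, neutral identity ~94% — it degenerately masks
everything. The pipeline therefore uses the second mode on synthetic
cohorts: windows whose mean conservation *score* is ≥ 0.8 are masked.
Synthetic flanks contain no conserved elements, so near-zero masking is
the correct behaviour there, and the identity mode remains available
(and unit-tested) for data with a suitably distant outgroup.

## Polymorphism and divergence estimators

For a region of L analyzed sites with S segregating sites at sample
size n:

$$\pi_T = \frac{1}{L}\sum_s 2\hat p_s(1-\hat p_s)\frac{n}{n-1},\qquad
\theta_W = \frac{S}{a_1 L},\qquad a_1 = \sum_{i=1}^{n-1} 1/i,$$

and Tajima's D is the variance-normalized difference between the π- and
S-based estimates (NA when S = 0, and such loci are excluded from class
averages). Class tables are per-locus averages with standard deviations,
not pooled estimates — pooled mode exists, but per-locus averaging
matches the way class-level polymorphism tables are conventionally
presented and keeps locus-to-locus variance visible. Divergence is
Jukes–Cantor corrected, k = −(3/4) ln(1 − 4p/3), with gap/N columns
excluded from the aligned-site denominator.

All three estimators are checked against a brute-force oracle that
builds the explicit haplotype matrix and counts pairwise differences
over all pairs — agreement is at machine precision on 500 random
instances per run.

## Selection tests

The generalized McDonald–Kreitman test contrasts polymorphic versus
divergent site counts in a focal class against a neutral class with a
Pearson χ²(1), no continuity correction by default (counts are large in
intended use; Yates is switchable). DAF spectra are compared with the
two-sample Kolmogorov–Smirnov test, alongside the proportion of sites
at DAF ≤ 0.01 — the excess-of-rare-variants signature. Substitutions
split into G:C→A:T, A:T→G:C and composition-preserving classes so
composition-driven artefacts can be excluded. All p-values from one
pipeline run form a single Bonferroni family.

## DFE inference from folded spectra

The estimator treats the folded SFS as multinomial conditional on S,
which removes the mutation-rate nuisance parameter from the optimizer.
Expected spectra come from a discrete Wright–Fisher grid of 2·Nref + 1
frequency classes (Nref = 100 by default) with per-copy selection
s = γ/(4·Nref), so the diffusion-scaled coefficient on the grid equals
γ = 4·Ne·s:

1. The equilibrium segregating-site intensity is the analytic diffusion
   density f(q) ∝ (1 − e^{−γ(1−q)}) / ((1 − e^{−γ}) q(1−q)) discretized
   on the grid — the fixed point that iterating the mutation-influx
   recursion converges to, without the chain's O(1/Nref) boundary
   distortion. The discrete-chain fixed point (direct linear solve)
   remains available and is used as an independent cross-check in the
   tests.
2. A two-epoch size change (ratio r, duration t2 in units of 2·N2
   generations) is applied on the fixed grid by the standard diffusion
   rescaling — one grid generation represents r population generations,
   selection scaled by r, mutation influx by r² — for round(t2·2·Nref)
   grid generations. The frequency bands below 1/(4·Nref) and above
   1 − 1/(4·Nref), which the grid cannot represent, are integrated
   analytically and added as tail corrections; with them the neutral
   expected folded spectrum matches the 1/i expectation to < 0.05% at
   n = 10.
3. Sampling n haplotypes is a binomial linear map, followed by folding.
4. A gamma DFE over |Nes| (shape β, mean m) is integrated over 32
   log-spaced quadrature nodes truncated at |γ| = 2·Nref, each node
   weighted by its gamma probability mass **times its polymorphism
   intensity**, so strongly deleterious mass correctly contributes
   almost no segregating sites.

Demography is fitted first on the neutral proxy spectrum, then the DFE
on the selected spectrum with demography fixed; both use Nelder–Mead
from fixed multi-starts on log scale, making runs bit-reproducible. Both
fits include a nested-model guard: the richer model is kept only if it
beats its null (equilibrium; neutrality) by a χ²-based likelihood-ratio
test at the 5% level. Without the guard, sampling noise in spectra of a
few hundred sites reads as spurious expansions or spurious weak
selection; genuinely non-equilibrium or selected data clear the bar by
orders of magnitude. Reported quantities are the |Nes| bin proportions
{<1, 1–10, 10–100, ≥100} from the fitted gamma CDF, with per-locus
bootstrap (default 200 replicates) percentile intervals.

Grid-size sensitivity: the neutral folded spectrum at Nref ∈ {50, 100,
200} changes bin proportions by < 0.1% once tail corrections are
applied; Nref = 100 is the default throughout and is configurable.

## Conservation profiling

Metagene profiles split each feature into 10 equal strand-oriented
portions (remainder bases go to earlier windows — the rule is arbitrary
but fixed and tested), take per-portion medians, and report the median
over features per decile with a percentile bootstrap CI whose resampling
unit is the feature. The control band redraws 1,000 sets of intergenic
intervals, one per target feature with identical length, restricted to
sequence > 1 kb from any gene. Single-site resampling draws one site per
feature per round, which removes length-weighting from the exon/intron
comparison. Splice-site conservation is summarized as per-column
information content IC = 2 − H bits (gaps excluded rather than treated
as a fifth symbol; switchable), for the splice dinucleotide and the 20
adjacent intronic columns, against count-matched control GT/AG
occurrences in flanking intergenic sequence.

## Positional equivalence

Each intergenic lncRNA is anchored to its nearest flanking
protein-coding gene (ties broken toward the smaller distance, then the
lncRNA's 5′ side); the assignment records which side of the *gene* the
lncRNA occupies and their relative transcriptional orientation. Two
lncRNAs in different species are positional equivalents when their
anchors are 1-to-1 orthologs and both side and orientation match;
mismatched side or orientation with an orthologous anchor defines the
control set. "Same location" is interpreted as same flanking side, not
distance-matched — distance is reported but not filtered, since no
distance criterion is defensible a priori. On noise-free mirrored
annotations, recall of planted equivalents is exactly 1 with zero false
pairs, which the tests assert.

## The synthetic cohort: what it does and does not emulate

The generator lays out non-overlapping protein-coding genes, multi-exonic
lncRNAs and ancestral repeats with ≥ 1 kb intergenic gaps, then draws
segregating sites class by class: a site hosts a SNP with probability
θ times the class's segregation intensity under its selection regime,
its population frequency is drawn from the equilibrium selected density
on a fine grid, and the sample count is binomial conditioned on
segregation. Outgroup tracks apply per-branch Jukes–Cantor substitutions
at rate d·w, where w = γ/(1 − e^{−γ}) is the class's mean relative
fixation weight — deleterious classes diverge less, which is what makes
the MK contrast recoverable. Conservation scores are per-class Beta
draws; coverage, strain-call ambiguity, quality and indel proximity
follow simple parametric models sized so a realistic few percent of
sites fail each filter.

Default conditions (fly-like): 162 haplotypes, θ = 0.01/site, outgroup
branch divergences 0.06 and 0.12, and a deleterious lncRNA-exon class
drawn from a gamma DFE with shape 0.5 and mean |Nes| = 20 — the same
canonical regime the DFE recovery analysis simulates. A weaker regime
(mean |Nes| ≈ 1.5, reproducing a ~64/36 neutral/deleterious split) was
considered and rejected a priori on an analytic power calculation: its
population-level KS distance from neutrality at n = 162 is 0.048, below
what a megabase-scale cohort can detect, whereas the chosen regime gives
0.19. The human-like preset uses 348 haplotypes, θ = 0.0012, divergences
0.012/0.06, and fully neutral lncRNAs. The default genome is 1 Mb over
two chromosomes; the `ci` preset scales to 200 kb for fast test runs.

Deliberately not emulated: recombination and linkage (sites are
independent, so background selection exists only through the
locus-matched proxy construction, not as a diversity gradient),
selective sweeps, coalescent genealogical correlation, alignment gaps
and indel divergence in outgroups (tracks are coordinate-identical),
context-dependent mutation, and isoform complexity. Consequently,
passing tests demonstrate that the estimators and tests recover known
inputs under the stated sampling models — not that real data meet those
models. Two-epoch demography appears in the generator only as a θ
rescaling; the inference-side Wright–Fisher transient is exercised
against constructed spectra rather than forward simulation.

## Numerical choices and degenerate inputs

* Frequency draws use a 4,000-point grid — effectively continuous for
  n ≤ 348 samples; the strongly deleterious branch of the density is
  evaluated in log space to avoid overflow below γ ≈ −30.
* `summarize_region` returns D = NA at S = 0; class averages skip NA.
* `jc_correct` raises a saturation error at p ≥ 0.75.
* The MK test refuses tables with a zero margin rather than returning a
  meaningless statistic.
* Folding conserves S exactly, with the central bin at even n counted
  once.
* Every random draw traces to one master seed through per-stage
  substreams (`substream_seed`), so toggling pipeline stages never
  perturbs the others' output.

## Known limitations

Sample-size strata are fixed per analysis: sites called in fewer
haplotypes are filtered out rather than projected down, matching the
called-strains filter design; a hypergeometric projection would recover
those sites but is out of scope. The DFE machinery assumes additive
selection and a gamma family; bimodal DFEs will be summarized by their
best gamma approximation. The adaptive-substitution fraction (α) is not
estimated. Identity-based conserved-element masking requires a distant
outgroup, as discussed above.
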