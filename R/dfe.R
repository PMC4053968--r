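## Distribution-of-fitness-effects inference from folded site frequency
## spectra, jointly with a two-epoch demography, in the style of
## folded-spectrum DFE estimators: a discrete Wright-Fisher grid carries
## the expected spectrum under selection, a gamma distribution over |Nes|
## is integrated by quadrature, and parameters are fitted by multinomial
## maximum likelihood (conditional on the number of segregating sites, so
## mutation-rate scalers drop out of the optimizer).

#' Construct a DFE model
#'
#' @param r Epoch size ratio N2/N1 (> 0; 1 = equilibrium).
#' @param t2 Epoch-2 duration in units of 2*N2 generations (>= 0).
#' @param shape,mean Gamma distribution over |Nes| (both > 0), or instead
#' @param gamma A point-mass scaled coefficient (gamma = 4*Ne*s; negative
#'   = deleterious). Exactly one of `gamma` / (`shape`,`mean`) is used.
#' @param Nref Internal Wright-Fisher grid size (diploid; >= 50).
#' @return A `dfe_model` list.
#' @export
dfe_model <- function(r = 1, t2 = 0, shape = NULL, mean = NULL,
                      gamma = NULL, Nref = 100L) {
  stopifnot(r > 0, t2 >= 0, Nref >= 50)
  if (is.null(gamma)) {
    stopifnot(!is.null(shape), !is.null(mean), shape > 0, mean > 0)
  }
  structure(list(r = r, t2 = t2, shape = shape, mean = mean,
                 gamma = gamma, Nref = as.integer(Nref)),
            class = "dfe_model")
}

# Wright-Fisher transition matrix over 2*Nref+1 count states with
# per-copy selection coefficient s = gamma/(4*Nref) (additive), so the
# diffusion-scaled coefficient 2*M*s equals gamma on the M = 2*Nref grid
wf_matrix <- function(Nref, gamma) {
  M <- 2L * Nref
  s <- gamma / (4 * Nref)
  q <- (0:M) / M
  qs <- q * (1 + s) / (1 + q * s)
  t(vapply(qs, function(p) stats::dbinom(0:M, M, p), numeric(M + 1L)))
}

# stationary interior intensity under unit mutation influx at count 1.
# Default: the analytic diffusion equilibrium (the limit of the influx
# recursion) discretized on the grid, which avoids the chain's O(1/M)
# boundary distortion; method = "chain" instead solves the exact fixed
# point v = T'v + e1 of the discrete recursion (used as a cross-check
# and as the substrate of epoch-2 transients either way). Both are in
# the same units: chain influx 1 per generation ~ density 2 f(q)/M.
wf_stationary_intensity <- function(Nref, gamma,
                                    method = c("analytic", "chain")) {
  method <- match.arg(method)
  M <- 2L * Nref
  if (method == "analytic") {
    q <- (1:(M - 1L)) / M
    return(2 * expected_sfs_density(gamma, q) / M)
  }
  A <- wf_matrix(Nref, gamma)[2:M, 2:M, drop = FALSE]
  c1 <- c(1, rep(0, M - 2L))
  v <- tryCatch(solve(diag(M - 1L) - t(A), c1), error = function(e) NULL)
  if (is.null(v) || any(!is.finite(v)) || any(v < -1e-8)) {
    v <- c1
    for (it in seq_len(50L * M)) {
      v_new <- drop(crossprod(A, v)) + c1
      if (max(abs(v_new - v)) < 1e-8 * max(v_new)) { v <- v_new; break }
      v <- v_new
      if (it == 50L * M) stop("stationary spectrum iteration did not converge")
    }
  }
  pmax(v, 0)
}

# sampled-spectrum contribution of the frequency bands below 1/M and
# above 1-1/M that the discrete grid cannot represent; same units as the
# grid intensities (density 2 f(q)). The low band holds the newest
# mutations, so under a recent size change it scales with the influx.
sfs_tail_intensity <- function(gamma, n, M, lo_scale = 1) {
  k <- floor(n / 2)
  add <- function(qs, dq) {
    f <- 2 * expected_sfs_density(gamma, qs) * dq
    u <- numeric(k)
    for (i in seq_len(n - 1L)) {
      j <- min(i, n - i)
      u[j] <- u[j] + sum(f * stats::dbinom(i, n, qs))
    }
    u
  }
  # each grid point j/M represents the cell (j/M - 1/2M, j/M + 1/2M), so
  # the unrepresented bands are the outer half-cells (0, 1/2M), (1-1/2M, 1)
  np <- 200L
  qlo <- (seq_len(np) - 0.5) / (np * 2L * M)
  qhi <- 1 - rev(qlo)
  lo_scale * add(qlo, 1 / (np * 2L * M)) + add(qhi, 1 / (np * 2L * M))
}

# apply a two-epoch size change on the fixed grid: one grid generation
# stands for r population generations (drift matched), selection is
# scaled by r and mutation influx by r^2; duration t2*2*N2 population
# generations = round(t2 * M) grid generations
wf_apply_epoch2 <- function(v, Nref, gamma, r, t2) {
  G <- as.integer(round(t2 * 2L * Nref))
  if (G == 0L) return(v)
  M <- 2L * Nref
  A <- wf_matrix(Nref, gamma * r)[2:M, 2:M, drop = FALSE]
  At <- t(A)
  c1 <- c(r^2, rep(0, M - 2L))
  for (g in seq_len(G)) v <- drop(At %*% v) + c1
  v
}

# binomial sampling of n haplotypes from grid intensities, folded; kept
# as intensities (per unit influx), NOT normalized, so gamma mixtures
# weight classes by their true polymorphism contribution
fold_sample_matrix <- function(Nref, n) {
  M <- 2L * Nref
  q <- (1:(M - 1L)) / M
  k <- floor(n / 2)
  FS <- matrix(0, k, M - 1L)
  for (i in seq_len(n - 1L)) {
    j <- min(i, n - i)
    FS[j, ] <- FS[j, ] + stats::dbinom(i, n, q)
  }
  # the central class at even n enters the loop once (i = n/2), so it is
  # counted exactly once, matching build_sfs's folding convention
  FS
}

# log-spaced |gamma| quadrature nodes with gamma-density mass weights;
# truncated at 2*Nref (spectra effectively zero beyond), tail mass folded
# into the end nodes
dfe_quadrature <- function(shape, mean, Nref, n_nodes = 32L) {
  gmax <- 2 * Nref
  nodes <- exp(seq(log(1e-3), log(gmax), length.out = n_nodes))
  edges <- c(0, sqrt(nodes[-n_nodes] * nodes[-1L]), Inf)
  w <- diff(stats::pgamma(edges, shape = shape, scale = mean / shape))
  list(nodes = nodes, weights = w)
}

#' Expected folded sample SFS under a DFE model
#'
#' Builds the discrete Wright-Fisher spectrum at the model's grid size,
#' applies the two-epoch size change, samples `n` haplotypes binomially
#' and folds. A gamma DFE is integrated by averaging point-mass spectra
#' over a fixed log-spaced quadrature grid weighted by the gamma density
#' (each node weighted by its polymorphism contribution, so strongly
#' deleterious mass correctly contributes few segregating sites).
#'
#' @param model A [dfe_model()].
#' @param n Haplotype sample size.
#' @return Numeric vector of folded bin proportions (length `floor(n/2)`),
#'   summing to 1.
#' @export
expected_folded_sfs <- function(model, n) {
  FS <- fold_sample_matrix(model$Nref, n)
  M <- 2L * model$Nref
  lo_scale <- if (model$t2 > 0) model$r^2 else 1
  spec_for <- function(g) {
    v <- wf_stationary_intensity(model$Nref, g)
    v <- wf_apply_epoch2(v, model$Nref, g, model$r, model$t2)
    drop(FS %*% v) + sfs_tail_intensity(g, n, M, lo_scale)
  }
  if (!is.null(model$gamma)) {
    u <- spec_for(model$gamma)
  } else {
    qd <- dfe_quadrature(model$shape, model$mean, model$Nref)
    u <- Reduce(`+`, Map(function(g, w) w * spec_for(-g),
                         qd$nodes, qd$weights))
  }
  u / sum(u)
}

# cache of folded-sampled spectrum intensities for each quadrature node
# under a fixed demography; makes gamma-DFE likelihoods a weighted sum
dfe_node_cache <- function(r, t2, n, Nref, n_nodes = 32L) {
  gmax <- 2 * Nref
  nodes <- exp(seq(log(1e-3), log(gmax), length.out = n_nodes))
  FS <- fold_sample_matrix(Nref, n)
  lo_scale <- if (t2 > 0) r^2 else 1
  U <- vapply(nodes, function(g) {
    v <- wf_stationary_intensity(Nref, -g)
    v <- wf_apply_epoch2(v, Nref, -g, r, t2)
    drop(FS %*% v) + sfs_tail_intensity(-g, n, 2L * Nref, lo_scale)
  }, numeric(floor(n / 2)))
  list(nodes = nodes, U = U, Nref = Nref, r = r, t2 = t2, n = n)
}

dfe_mixture_sfs <- function(cache, shape, mean) {
  n_nodes <- length(cache$nodes)
  edges <- c(0, sqrt(cache$nodes[-n_nodes] * cache$nodes[-1L]), Inf)
  w <- diff(stats::pgamma(edges, shape = shape, scale = mean / shape))
  u <- drop(cache$U %*% w)
  u / sum(u)
}

multinom_loglik <- function(counts, p) {
  p <- pmax(p, 1e-300)
  sum(counts * log(p))
}

#' Fit a two-epoch demography to a neutral folded SFS
#'
#' Maximizes the multinomial log-likelihood of the folded bin counts under
#' the neutral expected spectrum over (r, t2), by Nelder-Mead on log scale
#' from 8 fixed starting points.
#'
#' @param neutral_sfs A folded `sfs` (from [build_sfs()] / [fold_sfs()]).
#' @param Nref Wright-Fisher grid size.
#' @param model_select Keep the two-epoch model only when it beats the
#'   equilibrium null by a chi-square(2) likelihood-ratio test at the 5%
#'   level (default TRUE). Guards downstream selection inference against
#'   demographic parameters fitted to sampling noise.
#' @return List: `r`, `t2`, `loglik`, `expected` (fitted proportions).
#' @export
fit_demography <- function(neutral_sfs, Nref = 100L, model_select = TRUE) {
  stopifnot(inherits(neutral_sfs, "sfs"))
  sfs <- if (neutral_sfs$folded) neutral_sfs else fold_sfs(neutral_sfs)
  S <- sum(sfs$counts)
  if (S < 100) warning("fewer than 100 segregating sites; ",
                       "demographic estimates will be unstable")
  n <- sfs$n
  M <- 2L * Nref
  FS <- fold_sample_matrix(Nref, n)
  v0 <- wf_stationary_intensity(Nref, 0)
  A <- wf_matrix(Nref, 0)[2:M, 2:M, drop = FALSE]
  At <- t(A)
  tail_hi <- sfs_tail_intensity(0, n, M, lo_scale = 0)
  tail_lo <- sfs_tail_intensity(0, n, M, lo_scale = 1) - tail_hi
  expected_for <- function(r, t2) {
    G <- as.integer(round(t2 * M))
    v <- v0
    lo_scale <- 1
    if (G > 0L) {
      c1 <- c(r^2, rep(0, M - 2L))
      for (g in seq_len(G)) v <- drop(At %*% v) + c1
      lo_scale <- r^2
    }
    u <- drop(FS %*% v) + lo_scale * tail_lo + tail_hi
    u / sum(u)
  }
  obj <- function(par) {
    r <- exp(par[1]); t2 <- exp(par[2])
    if (r > 20 || r < 0.05 || t2 > 3) return(1e10)
    -multinom_loglik(sfs$counts, expected_for(r, t2))
  }
  starts <- expand.grid(lr = log(c(0.5, 1, 2, 5)), lt = log(c(0.1, 0.8)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                   control = list(maxit = 300, reltol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("demographic optimization failed from all starts")
  r <- exp(best$par[1]); t2 <- exp(best$par[2])
  ll <- -best$value
  if (model_select) {
    ll0 <- multinom_loglik(sfs$counts, expected_for(1, 0))
    if (2 * (ll - ll0) < stats::qchisq(0.95, df = 2)) {
      r <- 1; t2 <- 0; ll <- ll0
    }
  }
  list(r = r, t2 = t2, loglik = ll,
       expected = expected_for(r, t2), Nref = Nref, n = n)
}

#' Fit a gamma DFE to a selected folded SFS under a fixed demography
#'
#' Maximizes the multinomial likelihood over (shape, mean |Nes|) on log
#' scale from fixed multi-starts; node spectra under the demography are
#' precomputed once, so each likelihood evaluation is a weighted sum.
#'
#' @param selected_sfs A folded `sfs` of the selected class.
#' @param demography Result of [fit_demography()] (or a list with `r`,
#'   `t2`).
#' @param Nref Grid size.
#' @param cache Optional precomputed [dfe_node_cache()] (reused across
#'   bootstrap replicates).
#' @param model_select Keep the gamma DFE only when it beats the neutral
#'   null by a chi-square(2) likelihood-ratio test at the 5% level
#'   (default TRUE); otherwise collapse to the effectively-neutral
#'   boundary. Prevents sampling noise in small spectra from reading as
#'   spurious weak selection.
#' @return List: `shape`, `mean`, `loglik`, `bins`
#'   (|Nes| bin proportions via [nes_bin_proportions()]), `boundary`
#'   (TRUE when the optimum sits on the effectively-neutral boundary).
#' @export
fit_dfe <- function(selected_sfs, demography, Nref = 100L, cache = NULL,
                    model_select = TRUE) {
  stopifnot(inherits(selected_sfs, "sfs"))
  sfs <- if (selected_sfs$folded) selected_sfs else fold_sfs(selected_sfs)
  if (is.null(cache))
    cache <- dfe_node_cache(demography$r, demography$t2, sfs$n, Nref)
  obj <- function(par) {
    b <- exp(par[1]); m <- exp(par[2])
    if (b > 20 || b < 0.01 || m > 1e5 || m < 1e-6) return(1e10)
    -multinom_loglik(sfs$counts, dfe_mixture_sfs(cache, b, m))
  }
  starts <- expand.grid(lb = log(c(0.2, 0.5, 1)), lm = log(c(0.3, 5, 50)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-9)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("DFE optimization failed from all starts")
  shape <- exp(best$par[1]); m <- exp(best$par[2])
  ll <- -best$value
  boundary <- m <= 2e-6 || m >= 9e4
  if (model_select) {
    # neutral null: the smallest quadrature node is effectively gamma = 0
    u0 <- cache$U[, 1]
    ll0 <- multinom_loglik(sfs$counts, u0 / sum(u0))
    if (2 * (ll - ll0) < stats::qchisq(0.95, df = 2)) {
      shape <- shape; m <- 1e-6; ll <- ll0; boundary <- TRUE
    }
  }
  list(shape = shape, mean = m, loglik = ll,
       bins = nes_bin_proportions(shape, m),
       boundary = boundary, cache = cache)
}

#' Proportions of mutations per |Nes| bin of a gamma DFE
#'
#' @param shape,mean Gamma parameters over |Nes| (scale = mean/shape).
#' @param edges Bin edges over |Nes|; default `c(0, 1, 10, 100, Inf)`
#'   (effectively neutral, weakly, moderately, strongly deleterious).
#' @return Named numeric vector of bin proportions summing to 1.
#' @examples
#' nes_bin_proportions(1, 1)[1]  # P(|Nes| < 1) = 1 - exp(-1)
#' @export
nes_bin_proportions <- function(shape, mean, edges = c(0, 1, 10, 100, Inf)) {
  stopifnot(shape > 0, mean > 0)
  p <- diff(stats::pgamma(edges, shape = shape, scale = mean / shape))
  names(p) <- paste0("[", edges[-length(edges)], ",",
                     ifelse(is.finite(edges[-1]), edges[-1], "Inf"), ")")
  p
}

#' Bootstrap confidence intervals for the |Nes| bin proportions
#'
#' Resamples selected sites with replacement within each locus, refits
#' the gamma DFE under the fixed demography, and reports the mean and
#' 2.5/97.5 percentile interval of each bin proportion over `B`
#' replicates. Deterministic under `seed`.
#'
#' @param selected_counts Integer vector of derived (or minor) allele
#'   counts of the selected sites.
#' @param locus Locus identifier per site (same length).
#' @param n Haplotype sample size.
#' @param demography Fixed demography (see [fit_dfe()]).
#' @param B Number of bootstrap replicates (>= 2; study default 200).
#' @param seed Integer seed.
#' @param Nref Grid size.
#' @return List: `point` (full-data bin proportions), `mean`, `lower`,
#'   `upper` (per-bin bootstrap summaries), `B`.
#' @export
bootstrap_dfe <- function(selected_counts, locus, n, demography, B = 200L,
                          seed = 1L, Nref = 100L) {
  if (B < 2) stop("B must be >= 2")
  if (length(unique(locus)) < 2) stop("need at least 2 loci to bootstrap")
  stopifnot(length(selected_counts) == length(locus))
  cache <- dfe_node_cache(demography$r, demography$t2, n, Nref)
  point <- fit_dfe(build_sfs(selected_counts, n, fold = TRUE), demography,
                   Nref, cache = cache)
  set.seed(seed)
  by_locus <- split(selected_counts, locus)
  reps <- matrix(NA_real_, B, 4L)
  for (b in seq_len(B)) {
    res <- unlist(lapply(by_locus, function(x)
      x[sample.int(length(x), length(x), replace = TRUE)]))
    fit <- fit_dfe(build_sfs(res, n, fold = TRUE), demography, Nref,
                   cache = cache)
    reps[b, ] <- fit$bins
  }
  list(point = point$bins,
       mean = colMeans(reps),
       lower = apply(reps, 2, stats::quantile, 0.025),
       upper = apply(reps, 2, stats::quantile, 0.975),
       B = B, shape = point$shape, nes_mean = point$mean)
}
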