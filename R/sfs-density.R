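#' Equilibrium density of segregating-site frequencies under selection
#'
#' Relative density of the population frequency q of a derived allele with
#' scaled selection coefficient gamma = 4*Ne*s (additive; negative =
#' deleterious), from standard diffusion theory:
#' \deqn{f(q) \propto \frac{1 - e^{-\gamma(1-q)}}{(1 - e^{-\gamma})\,q(1-q)}}
#' with the continuous neutral limit 1/q at gamma = 0.
#'
#' @param gamma Scaled selection coefficient (scalar).
#' @param q Population frequencies in (0, 1).
#' @return Relative density values (unnormalized).
#' @examples
#' expected_sfs_density(0, 0.25)   # neutral limit: 1/q = 4
#' @export
expected_sfs_density <- function(gamma, q) {
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0,1)")
  if (abs(gamma) < 1e-12) return(1 / q)
  if (gamma < -30) {
    # strongly deleterious limit: (1-e^{-g(1-q)})/(1-e^{-g}) -> e^{g q},
    # evaluated in log space to avoid overflow of the raw exponentials
    return(exp(gamma * q) / (q * (1 - q)))
  }
  num <- -expm1(-gamma * (1 - q))
  den <- -expm1(-gamma)
  num / (den * q * (1 - q))
}

# draw population frequencies from the selected equilibrium density on a
# fine grid (effectively continuous); deterministic under the caller's RNG
sample_sfs_frequency <- function(gamma, n_draws, grid_points = 4000L) {
  if (n_draws == 0L) return(numeric(0))
  q <- (seq_len(grid_points) - 0.5) / grid_points
  w <- expected_sfs_density(gamma, q)
  sample_vec(q, n_draws, replace = TRUE, prob = w)
}

# expected sampled unfolded SFS intensity (counts 1..n-1 per unit influx)
# by numerically integrating the density against binomial sampling
expected_sampled_sfs <- function(gamma, n, grid_points = 4000L) {
  q <- (seq_len(grid_points) - 0.5) / grid_points
  w <- expected_sfs_density(gamma, q) / grid_points
  vapply(seq_len(n - 1L), function(i) {
    sum(w * stats::dbinom(i, n, q))
  }, numeric(1))
}

# mean relative fixation weight of a class: w(gamma) = gamma/(1-exp(-gamma)),
# the ratio of fixation probability to the neutral 1/(2N) limit; 1 at
# gamma = 0, < 1 for deleterious classes (they diverge less)
fixation_weight <- function(gamma) {
  ifelse(abs(gamma) < 1e-12, 1, gamma / (-expm1(-gamma)))
}
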