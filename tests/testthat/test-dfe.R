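neutral_folded_expectation <- function(n) {
  un <- 1 / seq_len(n - 1L)
  fo <- vapply(seq_len(floor(n / 2)), function(j)
    sum(un[unique(c(j, n - j))]), numeric(1))
  fo / sum(fo)
}

test_that("expected folded spectrum is exact for neutrality", {
  ef <- expected_folded_sfs(dfe_model(gamma = 0, Nref = 100L), 10L)
  fo <- neutral_folded_expectation(10L)
  expect_lt(max(abs(ef - fo) / fo), 0.005)
  expect_equal(sum(ef), 1, tolerance = 1e-9)
})

test_that("strong selection shifts the expected spectrum toward singletons", {
  e0 <- expected_folded_sfs(dfe_model(gamma = 0, Nref = 100L), 10L)
  e200 <- expected_folded_sfs(dfe_model(gamma = -200, Nref = 100L), 10L)
  expect_gt(e200[1], e0[1])
  # monotonicity in the DFE mean at fixed shape
  s1 <- expected_folded_sfs(dfe_model(shape = 0.5, mean = 1), 20L)
  s2 <- expected_folded_sfs(dfe_model(shape = 0.5, mean = 10), 20L)
  s3 <- expected_folded_sfs(dfe_model(shape = 0.5, mean = 100), 20L)
  expect_true(s1[1] <= s2[1] && s2[1] <= s3[1])
})

test_that("analytic equilibrium and discrete-chain fixed point agree", {
  # dual route: the chain's linear-solve stationary state against the
  # diffusion density, sampled and folded identically
  FS <- lncevo:::fold_sample_matrix(100L, 20L)
  for (g in c(0, -2, -5, -20)) {
    ua <- drop(FS %*% lncevo:::wf_stationary_intensity(100L, g))
    uc <- drop(FS %*% lncevo:::wf_stationary_intensity(100L, g,
                                                       method = "chain"))
    ua <- ua / sum(ua); uc <- uc / sum(uc)
    # proportions agree absolutely everywhere; relative agreement is
    # checked at weak-to-moderate selection, where no bin is vanishing
    expect_lt(max(abs(ua - uc)), 0.01)
    if (g > -5) expect_lt(max(abs(ua - uc) / ua), 0.02)
  }
})

test_that("expected spectra normalize across a random model sweep", {
  set.seed(5)
  for (i in 1:20) {
    m <- if (i %% 2) dfe_model(gamma = -stats::runif(1, 0, 50),
                               r = stats::runif(1, 0.5, 2),
                               t2 = stats::runif(1, 0, 0.3), Nref = 60L)
         else dfe_model(shape = stats::runif(1, 0.2, 2),
                        mean = stats::runif(1, 0.5, 50), Nref = 60L)
    p <- expected_folded_sfs(m, 12L)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("demographic fit recovers equilibrium and flags expansions", {
  neu <- simulate_class_sites(selection_regime(gamma = 0), 20L, 20000L,
                              seed = 5)
  dem <- fit_demography(build_sfs(neu$counts, 20L, fold = TRUE),
                        Nref = 60L)
  expect_gt(dem$r, 0.8)
  expect_lt(dem$r, 1.25)
  # exaggerated singleton excess reads as an expansion
  base <- round(neutral_folded_expectation(20L) * 5000)
  excess <- base; excess[1] <- round(excess[1] * 1.8)
  dem2 <- fit_demography(structure(list(n = 20L, counts = excess,
                                        folded = TRUE), class = "sfs"),
                         Nref = 60L)
  expect_gt(dem2$r, 1)
  # a flat folded spectrum still yields a finite estimate
  flat <- structure(list(n = 20L, counts = rep(500L, 10L), folded = TRUE),
                    class = "sfs")
  dem3 <- suppressWarnings(fit_demography(flat, Nref = 60L))
  expect_true(is.finite(dem3$r) && is.finite(dem3$t2))
})

test_that("gamma DFE fit recovers generating bin masses", {
  neu <- simulate_class_sites(selection_regime(gamma = 0), 20L, 20000L,
                              seed = 5)
  sel <- simulate_class_sites(selection_regime(shape = 0.5, mean = 20),
                              20L, 20000L, seed = 6)
  dem <- fit_demography(build_sfs(neu$counts, 20L, fold = TRUE),
                        Nref = 100L)
  fit <- fit_dfe(build_sfs(sel$counts, 20L, fold = TRUE), dem,
                 Nref = 100L)
  truth <- nes_bin_proportions(0.5, 20)
  expect_lt(max(abs(fit$bins - truth)), 0.10)
  # neutral data collapse onto the effectively-neutral bin
  nfit <- fit_dfe(build_sfs(neu$counts, 20L, fold = TRUE), dem,
                  Nref = 100L)
  expect_gte(nfit$bins[1], 0.9)
})

test_that("Nes bin proportions follow the gamma distribution", {
  p <- nes_bin_proportions(1, 1)
  expect_equal(unname(p[1]), 1 - exp(-1), tolerance = 1e-9)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_lt(unname(p[4]), 1e-20)  # P(|Nes| >= 100) = exp(-100)
  set.seed(8)
  for (i in 1:10) {
    q <- nes_bin_proportions(stats::runif(1, 0.1, 3),
                             stats::runif(1, 0.1, 100))
    expect_equal(sum(q), 1, tolerance = 1e-9)
    expect_true(all(q >= 0))
  }
})

test_that("locus bootstrap is deterministic, contains the point estimate,
           and tightens with more data", {
  sel <- simulate_class_sites(selection_regime(shape = 0.5, mean = 10),
                              20L, 4000L, seed = 9)
  locus <- rep(seq_len(40L), each = 100L)
  dem <- list(r = 1, t2 = 0)
  expect_error(bootstrap_dfe(sel$counts, locus, 20L, dem, B = 1L),
               "B must be")
  b1 <- bootstrap_dfe(sel$counts, locus, 20L, dem, B = 10L, seed = 3L,
                      Nref = 60L)
  b2 <- bootstrap_dfe(sel$counts, locus, 20L, dem, B = 10L, seed = 3L,
                      Nref = 60L)
  expect_identical(b1$mean, b2$mean)
  expect_true(all(b1$lower <= b1$point + 1e-9) &&
                all(b1$upper >= b1$point - 1e-9))
  # ten-fold more sites: narrower intervals on the dominant bins
  sel10 <- simulate_class_sites(selection_regime(shape = 0.5, mean = 10),
                                20L, 40000L, seed = 9)
  locus10 <- rep(seq_len(40L), each = 1000L)
  b3 <- bootstrap_dfe(sel10$counts, locus10, 20L, dem, B = 10L, seed = 3L,
                      Nref = 60L)
  expect_lt(mean(b3$upper - b3$lower), mean(b1$upper - b1$lower))
})
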