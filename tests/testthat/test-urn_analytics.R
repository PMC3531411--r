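test_that("beta-binomial pmf matches enumeration and normalizes", {
  expect_equal(beta_binomial_pmf(0:3, 3, 1, 1), rep(1 / 4, 4))
  expect_equal(beta_binomial_pmf(0:2, 2, 1, 1), rep(1 / 3, 3))
  # symmetric parameters give a symmetric pmf
  p <- beta_binomial_pmf(0:9, 9, 2, 2)
  expect_equal(p, rev(p))
  for (D in c(10, 1000)) {
    expect_equal(sum(beta_binomial_pmf(0:D, D, 3, 2)), 1, tolerance = 1e-12)
  }
  expect_error(beta_binomial_pmf(4, 3, 1, 1), "out-of-support")
})

test_that("composition CV and its division-free limit are exact", {
  cv <- composition_cv(1, 1, 1)
  # two-point pmf at D = 1: mean 1/2, sd 1/2
  expect_equal(cv$ratio, 1)
  expect_equal(composition_cv(100, 1, 1)$limit_ratio, 1 / sqrt(3))
  # the finite-D ratio approaches the limit monotonically
  rs <- sapply(c(1, 2, 4, 8, 16, 64), function(D) composition_cv(D, 2, 2)$ratio)
  lim <- composition_cv(1, 2, 2)$limit_ratio
  expect_true(all(diff(abs(rs - lim)) < 0))
  # exact finite-size slope on the small symmetric sweep: the limit CV is
  # 1/sqrt(N0 + 1), so the fitted slope is -0.434, not yet the asymptote
  a <- c(1, 2, 4, 8, 16)
  cvs <- sapply(a, function(ai) composition_cv(10, ai, ai)$limit_ratio)
  expect_equal(cvs, 1 / sqrt(2 * a + 1))
  slope_small <- coef(stats::lm(log(cvs) ~ log(2 * a)))[[2]]
  expect_equal(slope_small, -0.434, tolerance = 0.01)
  # the inverse-square-root law is the large-inoculum asymptote
  a <- c(256, 512, 1024, 2048)
  cvs <- sapply(a, function(ai) composition_cv(10, ai, ai)$limit_ratio)
  expect_equal(coef(stats::lm(log(cvs) ~ log(2 * a)))[[2]], -0.5,
               tolerance = 0.01)
})

test_that("rate ratios rationalize to minimal coprime pairs", {
  expect_equal(rationalize_rate_ratio(2), c(k1 = 1L, k2 = 2L))
  expect_equal(rationalize_rate_ratio(1.5), c(k1 = 2L, k2 = 3L))
  k <- rationalize_rate_ratio(pi, tol = 1e-4)
  expect_lte(abs(k["k2"] / k["k1"] - pi), 1e-4 * pi)
  expect_lt(k[["k1"]], 200)  # continued fractions find a small denominator
})

test_that("the generalized urn tracks the jump chain's division law", {
  # rate ratio 3/2 via ball multiplicities (2, 3); equal yields, D fixed
  D <- 15
  n <- 4e4
  urn <- simulate_urn(1, 1, D = D, k1 = 2L, k2 = 3L, n_reps = n, seed = 51)
  sim <- run_ensemble(droplet_spec(c(1, 1), budget = D, rates = c(2, 3)),
                      n_reps = n, seed = 53)
  p_urn <- tabulate(urn + 1L, nbins = D + 1) / n
  p_sim <- tabulate(sim$replicates$d_type1 + 1L, nbins = D + 1) / n
  # two independent empirical laws: compare at 3 pooled binomial SEs per bin
  se <- sqrt(2 * p_sim * (1 - p_sim) / n)
  expect_true(all(abs(p_urn - p_sim) <= pmax(3.5 * se, 4 / n)))
  # equal-rate urn is plain Polya: exact Beta-Binomial check in expectation
  urn1 <- simulate_urn(1, 1, D = 10, n_reps = n, seed = 55)
  expect_lt(abs(mean(urn1) - 5), 3 * sqrt(10 * 11 / 12 / n) + 0.05)
})

test_that("limit sampler reduces to Beta for equal rates", {
  z <- sample_limit_composition(2e4, 1, 1, rho = 1, seed = 61)
  ks <- suppressWarnings(stats::ks.test(z, "punif"))
  expect_gt(ks$p.value, 1e-3)
  z13 <- sample_limit_composition(1e5, 1, 3, rho = 1, seed = 63)
  # Beta(1,3): mean 1/4, var 3/80
  expect_lt(abs(mean(z13) - 0.25), 3 * sqrt(3 / 80 / 1e5))
})

test_that("limit sampler matches long simulations for unequal rates", {
  n <- 1e4
  z_sim <- simulated_scaled_composition(2^12, 1, 1, rho = 0.5, n_reps = n,
                                        seed = 65)
  z_lim <- sample_limit_composition(n, 1, 1, rho = 0.5, seed = 67)
  ks <- suppressWarnings(stats::ks.test(z_sim, z_lim, exact = FALSE))
  expect_lt(unname(ks$statistic), ks_critical(n, n))
  # unequal rates make the composition law asymmetric about 1/2 (the
  # third central moment happens to be tiny, so test symmetry directly)
  ks_sym <- suppressWarnings(stats::ks.test(z_lim, 1 - z_lim, exact = FALSE))
  expect_gt(unname(ks_sym$statistic), ks_critical(n, n))
  z_eq <- sample_limit_composition(n, 2, 2, rho = 1, seed = 68)
  ks_eq <- suppressWarnings(stats::ks.test(z_eq, 1 - z_eq, exact = FALSE))
  expect_lt(unname(ks_eq$statistic), ks_critical(n, n))
})

test_that("yield map reproduces the enumerated variable-yield CDF", {
  sp <- spec_tradeoff_toy()
  expect_equal(yield_map_cdf(0:3, sp), c(1 / 3, 2 / 3, 3 / 4, 1),
               tolerance = 1e-12)
  # equal costs: identity on the uniform problem
  uni <- droplet_spec(c(1, 1), budget = 5)
  expect_equal(yield_map_cdf(0:5, uni), cumsum(rep(1 / 6, 6)),
               tolerance = 1e-12)
  expect_equal(yield_map_cdf(3, sp), 1)
  expect_error(yield_map_cdf(99, sp), "out-of-support")
  # dp engine agrees with the closed-form engine when rates are equal
  for (spec in list(sp, droplet_spec(c(2, 1), 6, yields = c(1, 0.4)))) {
    kmax <- ceiling(spec$budget / spec$costs[1])
    expect_equal(yield_map_cdf(0:kmax, spec, backend = "dp"),
                 yield_map_cdf(0:kmax, spec, backend = "betabinom"),
                 tolerance = 1e-10)
  }
  # unequal rates require the dp engine; mapped CDF tracks the exact one to
  # within the documented one-division discretization slack
  spec <- droplet_spec(c(1, 1), 6, rates = c(1, 2), yields = c(1, 0.5))
  exact <- observable_distribution(forward_dp(spec), "d1")
  cdf_exact <- cumsum(exact$prob[match(0:6, exact$value, nomatch = 0)])
  cdf_map <- yield_map_cdf(0:6, spec, backend = "dp")
  shifted_lo <- c(0, cdf_exact)[1:7]
  expect_true(all(cdf_map >= shifted_lo - 1e-9 & cdf_map <= 1 + 1e-12))
})

test_that("final size law transforms the composition law exactly", {
  sp <- spec_tradeoff_toy()
  fs <- final_size_distribution(sp)
  expect_equal(fs$n_final, c(4, 5))
  expect_equal(fs$prob, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(final_size_distribution(sp, backend = "dp")$prob,
               c(2 / 3, 1 / 3), tolerance = 1e-12)
  # equal costs: point mass at N0 + yield * budget
  uni <- final_size_distribution(droplet_spec(c(1, 1), 5))
  expect_equal(uni$n_final, 7)
  expect_equal(uni$prob, 1)
  # tradeoff: larger d1 means larger n_final (monotone transform)
  m <- final_size_moments(sp, "exact")
  expect_equal(m$mean, 13 / 3, tolerance = 1e-12)
  expect_equal(m$variance, 2 / 9, tolerance = 1e-12)
})

test_that("final-size variance is zero iff yields are equal, and grows with imbalance", {
  vs <- sapply(c(1, 0.8, 0.5, 0.25), function(r)
    final_size_moments(droplet_spec(c(2, 2), 24, rates = c(1, 2),
                                    yields = c(1, r)), "exact")$variance)
  expect_equal(vs[1], 0, tolerance = 1e-20)
  expect_true(all(diff(vs) > 0))
})

test_that("limit-backend moments agree with mean-field at large inocula", {
  spec <- droplet_spec(c(32, 32), budget = 256, rates = c(1, 2),
                       yields = c(1, 0.5))
  det <- solve_stopping_time(spec)
  m <- final_size_moments(spec, "limit", n_samples = 1e4, seed = 71)
  expect_lt(abs(m$mean - det$n_final), 3 * m$sd / sqrt(1e4) + 2)
})

test_that("limit shape ignores division count but keeps the inoculum", {
  rep <- limit_distribution_independence(list(c(1, 1), c(8, 8)), rho = 1,
                                         D_list = c(2^9, 2^11),
                                         n_samples = 5e3, seed = 73)
  expect_true(all(rep$across_D$indistinguishable))
  expect_true(all(rep$across_inocula$distinguishable))
})
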