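test_that("uniform growth follows n_final = n0 + yield * budget", {
  expect_equal(grow_uniform(2, 1, 4)$n_final, 6)
  expect_equal(grow_uniform(1, 2, 3)$n_final, 7)
  small <- grow_uniform(5, 1, 1e-12)
  expect_equal(small$n_final, 5, tolerance = 1e-12)
  expect_equal(small$stop_time, 0, tolerance = 1e-12)
})

test_that("stopping-time solver hits the hand-derived quadratic root", {
  # rates (1,2), costs (1,0.5), budget 4: x = e^T solves x^2 + 2x - 11 = 0
  spec <- spec_ratio2_hand()
  sol <- solve_stopping_time(spec)
  x <- -1 + 2 * sqrt(3)
  expect_equal(sol$stop_time, log(x), tolerance = 1e-10)
  expect_equal(sol$n_final, x + x^2, tolerance = 1e-10)
  # consumed resource is exactly the budget
  consumed <- sum(spec$costs * spec$counts *
                    (exp(spec$rates * sol$stop_time) - 1))
  expect_equal(consumed, 4, tolerance = 1e-9)
  # uniform yield recovers the bookkeeping identity: x^2 + x - 6 = 0, x = 2
  uni <- solve_stopping_time(droplet_spec(c(1, 1), 4, rates = c(1, 2)))
  expect_equal(uni$n_final, 6, tolerance = 1e-10)
  expect_equal(uni$stop_time, log(2), tolerance = 1e-10)
  # reduction to the homogeneous case
  eq <- solve_stopping_time(droplet_spec(c(1, 1), 4))
  expect_equal(eq$n_final, grow_uniform(2, 1, 4)$n_final, tolerance = 1e-10)
  expect_error(solve_stopping_time(droplet_spec(c(1, 1), 4), split = c(0, 0)))
})

test_that("closed form for rate ratio 2 matches the numeric solver", {
  for (r in c(0.25, 0.5, 1, 2)) {
    for (n0 in c(2, 8, 32)) {
      for (S0 in c(10, 100, 1000)) {
        spec <- droplet_spec(c(n0 / 2, n0 / 2), S0, rates = c(1, 2),
                             yields = c(1, r))
        cf <- closed_form_ratio2(spec)
        num <- solve_stopping_time(spec)
        expect_equal(cf$n_final, num$n_final, tolerance = 1e-9)
        expect_equal(cf$stop_time, num$stop_time, tolerance = 1e-9)
      }
    }
  }
  expect_error(closed_form_ratio2(droplet_spec(c(1, 1), 4, rates = c(1, 3))),
               "precondition-violated")
})

test_that("uniform yields make n_final rate-independent", {
  for (rates in list(c(1, 1), c(1, 2), c(1, 3.7))) {
    sol <- solve_stopping_time(droplet_spec(c(2, 2), 10, rates = rates))
    expect_equal(sol$n_final, 4 + 10, tolerance = 1e-9)
  }
})

test_that("small-inoculum expansion converges to the closed form", {
  # relative error against the closed form, measured on the scale of the
  # yield-variability correction itself, vanishes as eps -> 0
  errs <- sapply(c(1e2, 1e4, 1e6), function(S0) {
    spec <- droplet_spec(c(1, 1), S0, rates = c(1, 2), yields = c(1, 0.5))
    cf <- closed_form_ratio2(spec)$n_final
    ex <- expansion_small_eps(spec)$n_final
    baseline <- 2 + 0.5 * S0  # uniform-yield bookkeeping at yield y2
    abs(ex - cf) / abs(cf - baseline)
  })
  expect_lt(errs[3], 1e-2)
  expect_true(all(diff(errs) < 0))
  # uniform yield: the correction vanishes identically
  uni <- expansion_small_eps(droplet_spec(c(2, 2), 50, rates = c(1, 2)))
  expect_equal(uni$n_final, 4 + 50, tolerance = 1e-12)
})

test_that("the inoculum correction scales as sqrt(N0)", {
  S0 <- 1e8
  n0s <- c(2, 8, 32, 128)
  corr <- sapply(n0s, function(n0) {
    spec <- droplet_spec(c(n0 / 2, n0 / 2), S0, rates = c(1, 2),
                         yields = c(1, 0.5))
    # remove the N0-independent and the linear-in-N0 parts by differencing
    closed_form_ratio2(spec)$n_final - 0.5 * S0
  })
  slope <- coef(stats::lm(log(corr) ~ log(n0s)))[[2]]
  expect_equal(slope, 0.5, tolerance = 0.01)
})

test_that("sign of the inoculum dependence follows the yield ratio", {
  n0s <- c(2, 8, 32, 128)
  nf <- function(r) sapply(n0s, function(n0)
    closed_form_ratio2(droplet_spec(c(n0 / 2, n0 / 2), 1024, rates = c(1, 2),
                                    yields = c(1, r)))$n_final)
  expect_true(all(diff(nf(0.5)) > 0))  # tradeoff: increasing
  expect_true(all(diff(nf(2)) < 0))    # positive correlation: decreasing
})

test_that("large-inoculum ensembles agree with the mean-field solution", {
  spec <- droplet_spec(c(32, 32), budget = 256, rates = c(1, 2),
                       yields = c(1, 0.5))
  det <- solve_stopping_time(spec)
  ens <- run_ensemble(spec, n_reps = 1e4, seed = 41)
  se <- sqrt(ens$var_n_final / 1e4)
  expect_lt(abs(ens$mean_n_final - det$n_final), 3 * se + 1)
})
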