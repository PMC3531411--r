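#' Beta-Binomial law of the final composition (Polya's urn)
#'
#' With equal division rates and equal yields, the division sequence is
#' exactly Polya's urn: starting from `a1` and `a2` cells, each division
#' "returns the drawn ball with one more of its color". The number of
#' type-1 divisions out of `D` is therefore Beta-Binomial:
#' `P(d1) = choose(D, d1) * B(a1 + d1, a2 + D - d1) / B(a1, a2)`.
#' This is exact for every finite `D`, not an asymptotic law.
#'
#' @param d1 Integer (vector) number of type-1 divisions, in `0..D`.
#' @param D Total number of divisions (draws).
#' @param a1,a2 Initial cells (balls) of each type; non-negative with
#'   `a1 + a2 >= 1`.
#' @return Probability vector, same length as `d1`.
#' @examples
#' beta_binomial_pmf(0:3, D = 3, a1 = 1, a2 = 1)  # uniform: 1/4 each
#' @export
beta_binomial_pmf <- function(d1, D, a1, a2) {
  stopifnot(D >= 1, a1 >= 0, a2 >= 0, a1 + a2 >= 1)
  if (any(d1 < 0 | d1 > D | d1 != round(d1)))
    stop("out-of-support: d1 must be an integer in [0, D]", call. = FALSE)
  if (a1 == 0) return(as.numeric(d1 == 0))
  if (a2 == 0) return(as.numeric(d1 == D))
  exp(lchoose(D, d1) + lbeta(a1 + d1, a2 + D - d1) - lbeta(a1, a2))
}

#' Coefficient of variation of the final composition
#'
#' Ratio of standard deviation to mean of the type-1 division count under
#' the Beta-Binomial law, and its limit as the number of divisions grows.
#' The limit equals the CV of the Beta(a1, a2) distribution,
#' `sqrt(a2 / (a1 * (a1 + a2 + 1)))`: it does not decay with the number of
#' divisions, and for a symmetric inoculum `a1 = a2 = N0/2` it equals
#' `1 / sqrt(N0 + 1)`, asymptotically the inverse square root of the
#' inoculum size.
#'
#' @inheritParams beta_binomial_pmf
#' @return List with `ratio` (finite-`D` CV of `d1`) and `limit_ratio`
#'   (its `D -> Inf` limit).
#' @examples
#' composition_cv(D = 100, a1 = 1, a2 = 1)  # limit_ratio = 1/sqrt(3)
#' @export
composition_cv <- function(D, a1, a2) {
  stopifnot(D >= 1, a1 > 0, a2 > 0)
  n <- a1 + a2
  m <- D * a1 / n
  v <- D * a1 * a2 * (n + D) / (n^2 * (n + 1))
  list(ratio = sqrt(v) / m, limit_ratio = sqrt(a2 / (a1 * (n + 1))))
}

#' Approximate a rate ratio by a ratio of integers
#'
#' The generalized urn represents a division-rate ratio `k2/k1` with integer
#' ball multiplicities; an arbitrary positive ratio is approximated by the
#' smallest continued-fraction convergent within the requested relative
#' tolerance.
#'
#' @param ratio Positive target ratio (`rate2 / rate1`).
#' @param tol Relative tolerance (default 1e-6).
#' @return Integer vector `c(k1, k2)`, coprime, with
#'   `|k2/k1 - ratio| <= tol * ratio`.
#' @examples
#' rationalize_rate_ratio(1.5)  # c(2, 3)
#' @export
rationalize_rate_ratio <- function(ratio, tol = 1e-6) {
  stopifnot(ratio > 0, tol > 0)
  # continued-fraction convergents of `ratio` = k2/k1
  x <- ratio
  h0 <- 0; h1 <- 1  # numerators
  q0 <- 1; q1 <- 0  # denominators
  for (i in 1:64) {
    a <- floor(x)
    h2 <- a * h1 + h0
    q2 <- a * q1 + q0
    if (q2 > 1e6)
      stop("tolerance-unreachable: denominator exceeds 10^6", call. = FALSE)
    if (abs(h2 / q2 - ratio) <= tol * ratio)
      return(c(k1 = as.integer(q2), k2 = as.integer(h2)))
    frac <- x - a
    if (frac < .Machine$double.eps) break
    x <- 1 / frac
    h0 <- h1; h1 <- h2; q0 <- q1; q1 <- q2
  }
  c(k1 = as.integer(q2), k2 = as.integer(h2))
}

#' Simulate the generalized Polya urn
#'
#' Each cell of type `i` is represented by `k_i` balls of color `i`; a drawn
#' ball is returned with `k_i` additional balls of its color, so the odds of
#' drawing each color stay faithful to the division-rate ratio `k2/k1`.
#'
#' @inheritParams beta_binomial_pmf
#' @param k1,k2 Coprime positive integer reinforcements.
#' @param n_reps Number of independent urns.
#' @param seed Master seed (child stream per urn).
#' @return Integer vector of color-1 draw counts, length `n_reps`.
#' @export
simulate_urn <- function(a1, a2, D, k1 = 1L, k2 = 1L, n_reps = 1L, seed = 1L) {
  stopifnot(a1 >= 0, a2 >= 0, a1 + a2 >= 1, D >= 1, k1 >= 1, k2 >= 1)
  cpp_urn_draws(as.integer(a1), as.integer(a2), as.integer(k1),
                as.integer(k2), as.integer(D), as.integer(n_reps),
                as.double(seed))
}

#' Sample the limiting scaled composition
#'
#' After many divisions the composition, expressed through the scaling
#' variable `z = n1 / (n1 + n2^rho)` with `rho = rate1/rate2`, converges in
#' law to `W1 / (W1 + W2^rho)` where `W1 ~ Gamma(a1, 1)` and
#' `W2 ~ Gamma(a2, 1)` are the Yule-process limits of the two lineages
#' (`n_i(t) * exp(-rate_i * t) -> W_i`). For `rho = 1` this is exactly the
#' Beta(a1, a2) distribution; for `rho != 1` the law has no closed-form
#' density, and the sampler is validated against long jump-chain
#' simulations (see the package tests).
#'
#' @inheritParams beta_binomial_pmf
#' @param rho Positive rate ratio `rate1 / rate2` entering the scaling.
#' @param n Number of samples.
#' @param seed Integer seed (base R RNG).
#' @return Numeric vector of samples in \[0, 1\].
#' @examples
#' z <- sample_limit_composition(1000, a1 = 1, a2 = 1, rho = 1, seed = 1)
#' @export
sample_limit_composition <- function(n, a1, a2, rho = 1, seed = NULL) {
  stopifnot(a1 > 0, a2 > 0, rho > 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  w1 <- stats::rgamma(n, shape = a1, scale = 1)
  w2 <- stats::rgamma(n, shape = a2, scale = 1)
  w1 / (w1 + w2^rho)
}

#' Scaled composition of simulated droplets
#'
#' Computes the scaling variable `z = n1 / (n1 + n2^rho)` from final counts
#' of a uniform-yield jump-chain ensemble run to exactly `D` divisions.
#'
#' @inheritParams beta_binomial_pmf
#' @param rho Rate ratio `rate1/rate2`; the simulation uses rates
#'   `(1, 1/rho)`.
#' @param n_reps Replicates.
#' @param seed Master seed.
#' @return Numeric vector of `n_reps` scaled compositions.
#' @export
simulated_scaled_composition <- function(D, a1, a2, rho = 1, n_reps = 1e4,
                                         seed = 1L) {
  spec <- droplet_spec(c(a1, a2), budget = D, rates = c(1, 1 / rho),
                       yields = c(1, 1))
  ens <- run_ensemble(spec, n_reps = n_reps, seed = seed, mode = "jump")
  n1 <- a1 + ens$replicates$d_type1
  n2 <- a2 + ens$replicates$d_type2
  n1 / (n1 + n2^rho)
}

#' Independence of the limit shape from the number of divisions
#'
#' The scaled-composition distribution converges to a limit that does not
#' depend on the number of divisions but retains the inoculum: empirical
#' distributions at different large `D` are statistically
#' indistinguishable, while distributions for inocula differing in size are
#' distinguishable. Both statements are quantified by two-sample
#' Kolmogorov-Smirnov distances at level `alpha`.
#'
#' @param inocula List of `c(a1, a2)` inocula; the first is compared across
#'   `D_list`, and all pairs are compared at `max(D_list)`.
#' @param rho Rate ratio `rate1/rate2`.
#' @param D_list Two or more large division counts, e.g. `c(2^10, 2^14)`.
#' @param n_samples Samples per empirical distribution.
#' @param seed Master seed.
#' @param alpha KS significance level (default 0.01).
#' @return List of data.frames `across_D` (same inoculum, different `D`)
#'   and `across_inocula` (fixed `D`, different inocula), each with the KS
#'   statistic, the critical value and the verdict.
#' @export
limit_distribution_independence <- function(inocula = list(c(1, 1), c(8, 8)),
                                            rho = 1, D_list = c(2^10, 2^14),
                                            n_samples = 1e4, seed = 1L,
                                            alpha = 0.01) {
  stopifnot(length(D_list) >= 2, length(inocula) >= 1)
  ks_crit <- function(n, m) sqrt(-log(alpha / 2) / 2) * sqrt((n + m) / (n * m))
  a <- inocula[[1L]]
  zs <- lapply(seq_along(D_list), function(i)
    simulated_scaled_composition(D_list[i], a[1], a[2], rho,
                                 n_reps = n_samples, seed = seed + i))
  pairs <- utils::combn(length(D_list), 2)
  across_D <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    stat <- suppressWarnings(
      stats::ks.test(zs[[i1]], zs[[i2]], exact = FALSE))$statistic
    data.frame(D_a = D_list[i1], D_b = D_list[i2], ks = unname(stat),
               crit = ks_crit(n_samples, n_samples),
               indistinguishable = unname(stat) < ks_crit(n_samples, n_samples))
  }))
  across_inocula <- NULL
  if (length(inocula) >= 2) {
    Dmax <- max(D_list)
    zi <- lapply(seq_along(inocula), function(i)
      simulated_scaled_composition(Dmax, inocula[[i]][1], inocula[[i]][2],
                                   rho, n_reps = n_samples,
                                   seed = seed + 100 + i))
    ip <- utils::combn(length(inocula), 2)
    across_inocula <- do.call(rbind, lapply(seq_len(ncol(ip)), function(j) {
      i1 <- ip[1, j]; i2 <- ip[2, j]
      stat <- suppressWarnings(
        stats::ks.test(zi[[i1]], zi[[i2]], exact = FALSE))$statistic
      data.frame(inoculum_a = paste(inocula[[i1]], collapse = "+"),
                 inoculum_b = paste(inocula[[i2]], collapse = "+"),
                 D = Dmax, ks = unname(stat),
                 crit = ks_crit(n_samples, n_samples),
                 distinguishable = unname(stat) >= ks_crit(n_samples, n_samples))
    }))
  }
  list(across_D = across_D, across_inocula = across_inocula, alpha = alpha)
}

# effective total divisions for the yield map: the uniform-yield stopping
# line through the variable-yield line's point at first coordinate d1.
# Under the overshoot rule the crossing count is the ceiling of the
# geometric intersection.
d2_star <- function(d1, spec) {
  rem <- spec$budget - spec$costs[1] * d1
  ifelse(rem > 1e-12, ceiling(rem / spec$costs[2] - 1e-9), 0)
}

#' Cumulative composition law under variable yields
#'
#' Transfers the uniform-yield composition law to a variable-yield
#' population: because trajectories are monotone, every trajectory absorbed
#' on the variable-yield stopping line at first coordinate `<= d1` also
#' crosses the uniform-yield line through the point `(d1, d2*(d1))` of the
#' variable-yield line, where `d2*(d1) = (budget - cost1*d1)/cost2`. The
#' CDF of `d1` therefore equals the uniform-yield CDF with effective total
#' divisions `D_eff(d1) = d1 + ceiling(d2*(d1))` (lattice granularity makes
#' `d2*` generally non-integer; the ceiling matches the overshoot rule, with
#' at most one division of discretization slack for non-commensurate
#' costs).
#'
#' @param d1 Integer(s), type-1 division count.
#' @param spec A two-type [droplet_spec()].
#' @param backend `"betabinom"` (equal division rates; closed form) or
#'   `"dp"` (any rates; exact uniform-yield lattice solver).
#' @return `P(D1 <= d1)` under the variable-yield stopping line.
#' @examples
#' sp <- droplet_spec(c(1, 1), budget = 3, yields = c(1, 0.5))
#' yield_map_cdf(0:3, sp)  # 1/3, 2/3, 3/4, 1
#' @export
yield_map_cdf <- function(d1, spec, backend = c("betabinom", "dp")) {
  validate_droplet(spec)
  stopifnot(spec$n_types == 2L)
  backend <- match.arg(backend)
  if (backend == "betabinom" &&
      abs(spec$rates[1] - spec$rates[2]) > 1e-12 * max(spec$rates))
    stop("precondition-violated: betabinom backend requires equal rates; use backend = \"dp\"",
         call. = FALSE)
  d1max <- max_d1_support(spec)
  if (any(d1 < 0 | d1 > d1max))
    stop("out-of-support: d1 outside [0, ", d1max, "]", call. = FALSE)
  vapply(d1, function(k) {
    Deff <- k + d2_star(k, spec)
    if (Deff <= 0) return(1)
    if (k >= Deff) return(1)
    if (backend == "betabinom") {
      sum(beta_binomial_pmf(0:k, Deff, spec$counts[1], spec$counts[2]))
    } else {
      uni <- droplet_spec(spec$counts, budget = Deff, rates = spec$rates,
                          yields = c(1, 1))
      tab <- observable_distribution(forward_dp(uni), "d1")
      sum(tab$prob[tab$value <= k])
    }
  }, numeric(1))
}

# largest d1 with positive probability: smallest d1 whose pure-type-1
# continuation is already absorbing
max_d1_support <- function(spec) {
  as.integer(ceiling(spec$budget / spec$costs[1] - 1e-9))
}

#' Distribution of the final population size
#'
#' With variable yields each point of the stopping line carries a different
#' total population: `N_f(d1) = N0 + d1 + d2*(d1)`. The law of `d1` from
#' the yield-mapped composition CDF (or directly from the exact lattice
#' solver) is pushed through this map and aggregated over equal sizes.
#'
#' @inheritParams yield_map_cdf
#' @param backend `"map"` (yield-mapping route, Beta-Binomial or DP uniform
#'   solver per `engine`) or `"dp"` (exact variable-yield lattice solver).
#' @param engine Uniform-yield engine for the `"map"` backend.
#' @return A data.frame `n_final`, `prob`.
#' @examples
#' sp <- droplet_spec(c(1, 1), budget = 3, yields = c(1, 0.5))
#' final_size_distribution(sp)  # P(4) = 2/3, P(5) = 1/3
#' @export
final_size_distribution <- function(spec, backend = c("map", "dp"),
                                    engine = c("betabinom", "dp")) {
  validate_droplet(spec)
  stopifnot(spec$n_types == 2L)
  backend <- match.arg(backend)
  engine <- match.arg(engine)
  if (backend == "dp") {
    tab <- observable_distribution(forward_dp(spec), "n_final")
    return(data.frame(n_final = tab$value, prob = tab$prob))
  }
  d1max <- max_d1_support(spec)
  cdf <- yield_map_cdf(0:d1max, spec, backend = engine)
  pmf <- diff(c(0, cdf))
  nf <- sum(spec$counts) + (0:d1max) + d2_star(0:d1max, spec)
  agg <- stats::aggregate(list(prob = pmf), by = list(n_final = nf), FUN = sum)
  agg <- agg[agg$prob > 1e-15, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Moments of the final population size
#'
#' Mean and variance of `N_f`, either exactly from
#' [final_size_distribution()] (backend `"exact"`, within the lattice
#' guard) or in the many-divisions limit by Monte Carlo inversion of the
#' scaling variable (backend `"limit"`): sample the Yule limits
#' `W_i ~ Gamma(a_i, 1)`, solve the stopping-line condition
#' `cost1 * n1 + cost2 * n2 = budget + cost1*a1 + cost2*a2` along the
#' asymptotic trajectory `n1 = W1 * (n2/W2)^rho`, set `d_i = n_i - a_i` and
#' `N_f = N0 + d1 + d2` (for a deterministic inoculum, `W_i -> a_i`, this
#' reduces exactly to the mean-field quadratic). The variance vanishes iff
#' the yields are equal and grows with the yield imbalance.
#'
#' @inheritParams yield_map_cdf
#' @param backend `"exact"` or `"limit"`.
#' @param n_samples Monte Carlo samples for the `"limit"` backend.
#' @param seed Seed for the `"limit"` backend.
#' @return List with `mean`, `variance`, `sd` and `backend`.
#' @export
final_size_moments <- function(spec, backend = c("exact", "limit"),
                               n_samples = 1e4, seed = 1L) {
  validate_droplet(spec)
  stopifnot(spec$n_types == 2L)
  backend <- match.arg(backend)
  if (backend == "exact") {
    d <- final_size_distribution(spec, backend = "dp")
    m <- sum(d$n_final * d$prob)
    v <- sum((d$n_final - m)^2 * d$prob)
    return(list(mean = m, variance = v, sd = sqrt(v), backend = "exact"))
  }
  a1 <- spec$counts[1]; a2 <- spec$counts[2]
  c1 <- spec$costs[1]; c2 <- spec$costs[2]
  rho <- spec$rates[1] / spec$rates[2]
  if (!is.null(seed)) set.seed(seed)
  w1 <- stats::rgamma(n_samples, shape = a1, scale = 1)
  w2 <- stats::rgamma(n_samples, shape = a2, scale = 1)
  # the stopping line in division coordinates, c1*d1 + c2*d2 = budget with
  # d_i = n_i - a_i, becomes a condition on the Yule-limit cell numbers
  Sp <- spec$budget + c1 * a1 + c2 * a2
  nf <- vapply(seq_len(n_samples), function(i) {
    f <- function(n2) c1 * w1[i] * (n2 / w2[i])^rho + c2 * n2 - Sp
    n2 <- stats::uniroot(f, c(0, Sp / c2), tol = 1e-10)$root
    n1 <- w1[i] * (n2 / w2[i])^rho
    n1 + n2
  }, numeric(1))
  list(mean = mean(nf), variance = stats::var(nf), sd = stats::sd(nf),
       backend = "limit")
}
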