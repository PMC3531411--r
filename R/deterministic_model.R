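#' Deterministic growth with a uniform yield
#'
#' For a homogeneous population every division consumes `1/yield` resource,
#' so the final size is fixed by bookkeeping alone:
#' `n_final = n0 + yield * budget`, reached at
#' `stop_time = log(n_final / n0) / rate`.
#'
#' @param n0 Positive initial population size.
#' @param yield Positive yield.
#' @param budget Positive resource budget.
#' @param rate Positive division rate (default 1).
#' @return A `deterministic_solution` list: `stop_time`, `n_final`,
#'   `per_type_final`, `method = "uniform"`.
#' @examples
#' grow_uniform(2, yield = 1, budget = 4)  # n_final = 6
#' @export
grow_uniform <- function(n0, yield, budget, rate = 1) {
  stopifnot(n0 > 0, yield > 0, budget >= 0, rate > 0)
  nf <- n0 + yield * budget
  structure(list(stop_time = log(nf / n0) / rate, n_final = nf,
                 per_type_final = nf, method = "uniform"),
            class = "deterministic_solution")
}

#' Numeric stopping time of the average two-type dynamics
#'
#' While resource remains, each type grows exponentially,
#' `n_i(t) = n_i(0) * exp(rate_i * t)` (division rates follow a step
#' function of the substrate: constant while resource is positive, zero
#' after). The stopping time `T` solves the depletion condition
#' `sum_i cost_i * (n_i(T) - n_i(0)) = budget`, found here by bracketing and
#' bisection (via [stats::uniroot()]) to relative tolerance 1e-12.
#'
#' @param spec A [droplet_spec()] (any number of types); `counts` may be
#'   real-valued halves in this continuum approximation — see `split`.
#' @param split Optional replacement for `spec$counts`, e.g. `c(N0/2, N0/2)`
#'   for the symmetric initial condition of the two-type theory.
#' @return A `deterministic_solution`: `stop_time`, `n_final`,
#'   `per_type_final`, `method = "numeric"`. Consumed resource at
#'   `stop_time` equals the budget within solver tolerance.
#' @examples
#' solve_stopping_time(droplet_spec(c(1, 1), budget = 4,
#'                                  rates = c(1, 2), yields = c(1, 2)))
#' @export
solve_stopping_time <- function(spec, split = NULL) {
  if (is.null(split)) {
    validate_droplet(spec)
    n0 <- spec$counts
  } else {
    n0 <- as.numeric(split)
    stopifnot(length(n0) == spec$n_types, all(n0 >= 0), sum(n0) > 0)
  }
  if (spec$budget <= 0) stop("no-root: budget must be positive", call. = FALSE)
  consumed <- function(t) sum(spec$costs * n0 * (exp(spec$rates * t) - 1))
  f <- function(t) consumed(t) - spec$budget
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  root <- stats::uniroot(f, c(0, hi), tol = .Machine$double.eps^0.75,
                         maxiter = 10000L)
  T <- root$root
  per_type <- n0 * exp(spec$rates * T)
  structure(list(stop_time = T, n_final = sum(per_type),
                 per_type_final = per_type, method = "numeric"),
            class = "deterministic_solution")
}

#' Closed-form final size for division-rate ratio two
#'
#' When the faster type divides exactly twice as fast as the slower
#' (`rates = (lambda, 2*lambda)`), the depletion condition becomes a
#' quadratic in `x = exp(lambda * T)`:
#' `cost2*a2*x^2 + cost1*a1*x - (cost1*a1 + cost2*a2 + budget) = 0`,
#' with `a_i` the initial counts. The physical root `x > 1` gives
#' `n_final = a1*x + a2*x^2` explicitly.
#'
#' @inheritParams solve_stopping_time
#' @return A `deterministic_solution` (`method = "closed_form"`); agrees
#'   with [solve_stopping_time()] to better than 1e-9 relative.
#' @export
closed_form_ratio2 <- function(spec, split = NULL) {
  validate_droplet(spec)
  stopifnot(spec$n_types == 2L)
  if (abs(spec$rates[2] / spec$rates[1] - 2) > 1e-12)
    stop("precondition-violated: division-rate ratio must be exactly 2",
         call. = FALSE)
  n0 <- if (is.null(split)) spec$counts else as.numeric(split)
  a1 <- n0[1]; a2 <- n0[2]
  c1 <- spec$costs[1]; c2 <- spec$costs[2]
  A <- c2 * a2; B <- c1 * a1; C <- -(c1 * a1 + c2 * a2 + spec$budget)
  x <- if (A > 0) (-B + sqrt(B * B - 4 * A * C)) / (2 * A) else -C / B
  structure(list(stop_time = log(x) / spec$rates[1],
                 n_final = a1 * x + a2 * x^2,
                 per_type_final = c(a1 * x, a2 * x^2),
                 method = "closed_form", x = x),
            class = "deterministic_solution")
}

#' Small-inoculum expansion of the rate-ratio-two final size
#'
#' For a symmetric inoculum `a = N0/2` define the dimensionless parameter
#' `eps = a * cost2 / budget`, the inoculum size relative to the number of
#' divisions the budget supports for the faster type. Expanding the physical
#' root of the quadratic of [closed_form_ratio2()] in `sqrt(eps)` gives, with
#' the yield ratio `r = yield2/yield1`,
#' `n_final = yield2*budget * (1 + (1 - r)*sqrt(eps) + eps*(1 + r/2 + r^2/2))`
#' plus corrections of order `eps^(3/2)`. The inoculum enters the leading
#' correction through `sqrt(eps)`, i.e. as `sqrt(N0)`, with a sign set by
#' `1 - r`: positive under a metabolic tradeoff (`r < 1`), negative for
#' positively correlated rate and yield (`r > 1`), and identically zero for
#' a uniform yield, where `n_final = N0 + yield*budget` is recovered
#' exactly.
#'
#' @inheritParams closed_form_ratio2
#' @return A `deterministic_solution` (`method = "expansion"`) with an
#'   additional field `epsilon`.
#' @export
expansion_small_eps <- function(spec, split = NULL) {
  validate_droplet(spec)
  stopifnot(spec$n_types == 2L)
  if (abs(spec$rates[2] / spec$rates[1] - 2) > 1e-12)
    stop("precondition-violated: division-rate ratio must be exactly 2",
         call. = FALSE)
  n0 <- if (is.null(split)) spec$counts else as.numeric(split)
  a <- sum(n0) / 2
  c1 <- spec$costs[1]; c2 <- spec$costs[2]
  r <- c1 / c2  # = yield2 / yield1
  eps <- a * c2 / spec$budget
  y2S0 <- spec$budget / c2
  nf <- y2S0 * (1 + (1 - r) * sqrt(eps) + eps * (1 + r / 2 + r^2 / 2))
  x <- 1 / sqrt(eps) - r / 2 + sqrt(eps) * ((1 + r) / 2 + r^2 / 8)
  structure(list(stop_time = log(x) / spec$rates[1], n_final = nf,
                 per_type_final = c(a * x, nf - a * x),
                 method = "expansion", epsilon = eps),
            class = "deterministic_solution")
}

#' @export
print.deterministic_solution <- function(x, ...) {
  cat("deterministic_solution (", x$method, "): n_final = ",
      format(x$n_final), ", stop_time = ", format(x$stop_time), "\n", sep = "")
  invisible(x)
}
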