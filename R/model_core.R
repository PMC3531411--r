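#' Define one metabolic phenotype
#'
#' A phenotype is characterized by its division rate and its yield with
#' respect to the growth-limiting resource. The yield is the number of
#' divisions supported per unit resource, so each division of this type
#' depletes the resource by `cost = 1/yield`.
#'
#' @param rate Positive division rate (divisions per unit time). Defaults to
#'   1, which fixes the time unit; division-sequence (jump-chain)
#'   distributions depend on rate ratios only.
#' @param yield Positive yield (divisions per unit resource). Defaults to 1,
#'   so the resource budget is measured in divisions of a unit-yield type.
#' @return An object of class `metabolic_type` with fields `rate`, `yield`
#'   and `cost`.
#' @examples
#' metabolic_type(rate = 2, yield = 0.5)
#' @export
metabolic_type <- function(rate = 1, yield = 1) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("invalid-parameter: rate must be a positive finite number", call. = FALSE)
  if (!is.numeric(yield) || length(yield) != 1L || !is.finite(yield) || yield <= 0)
    stop("invalid-parameter: yield must be a positive finite number", call. = FALSE)
  structure(list(rate = rate, yield = yield, cost = 1 / yield),
            class = "metabolic_type")
}

#' Resource cost of one division
#'
#' @param t A [metabolic_type()].
#' @return The amount of resource consumed by one division, `1/yield`.
#' @export
cost_of <- function(t) {
  stopifnot(inherits(t, "metabolic_type"))
  1 / t$yield
}

#' Specify a droplet experiment
#'
#' A droplet is seeded with an inoculum (initial cells of each phenotype) and
#' a finite resource budget; growth proceeds until the resource is exhausted.
#'
#' @param counts Non-negative integer vector, initial cells per type; the
#'   total inoculum must be at least 1.
#' @param budget Positive initial amount of resource.
#' @param rates Positive division rate per type (recycled scalar allowed).
#' @param yields Positive yield per type (recycled scalar allowed).
#' @return An object of class `droplet_spec` with fields `counts`, `budget`,
#'   `rates`, `yields`, `costs` and `n_types`.
#' @examples
#' droplet_spec(counts = c(1, 1), budget = 3, rates = c(1, 1), yields = c(1, 0.5))
#' @export
droplet_spec <- function(counts, budget, rates = 1, yields = 1) {
  counts <- as.numeric(counts)
  k <- length(counts)
  rates <- rep_len(as.numeric(rates), k)
  yields <- rep_len(as.numeric(yields), k)
  spec <- structure(
    list(counts = counts, budget = as.numeric(budget)[1L],
         rates = rates, yields = yields, costs = 1 / yields, n_types = k),
    class = "droplet_spec")
  validate_droplet(spec)
}

#' Validate a droplet specification
#'
#' Checks every invariant of the experiment description and returns the spec
#' unchanged if all hold.
#'
#' @param spec A `droplet_spec`.
#' @return `spec`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending field (condition message prefixed `invalid-parameter`).
#' @export
validate_droplet <- function(spec) {
  if (!inherits(spec, "droplet_spec"))
    stop("invalid-parameter: not a droplet_spec", call. = FALSE)
  k <- length(spec$counts)
  if (k < 1L)
    stop("invalid-parameter: types (empty type list)", call. = FALSE)
  if (length(spec$rates) != k || length(spec$yields) != k)
    stop("invalid-parameter: types (length mismatch between counts, rates, yields)",
         call. = FALSE)
  if (any(!is.finite(spec$counts)) || any(spec$counts < 0) ||
      any(abs(spec$counts - round(spec$counts)) > 1e-9))
    stop("invalid-parameter: counts (must be non-negative integers)", call. = FALSE)
  if (sum(spec$counts) < 1)
    stop("invalid-parameter: inoculum (total initial population must be >= 1)",
         call. = FALSE)
  if (!is.finite(spec$budget) || spec$budget <= 0)
    stop("invalid-parameter: budget (must be positive)", call. = FALSE)
  if (any(!is.finite(spec$rates)) || any(spec$rates <= 0))
    stop("invalid-parameter: rates (must be positive)", call. = FALSE)
  if (any(!is.finite(spec$yields)) || any(spec$yields <= 0))
    stop("invalid-parameter: yields (must be positive)", call. = FALSE)
  if (any(abs(spec$costs * spec$yields - 1) > 1e-9))
    stop("invalid-parameter: costs (cost * yield must equal 1)", call. = FALSE)
  invisible(spec)
}

#' @export
print.droplet_spec <- function(x, ...) {
  cat("droplet_spec:", x$n_types, "type(s), inoculum",
      paste(x$counts, collapse = "+"), "=", sum(x$counts),
      "cells, budget", format(x$budget), "\n")
  cat("  rates: ", paste(format(x$rates), collapse = ", "), "\n", sep = "")
  cat("  yields:", paste(format(x$yields), collapse = ", "), "\n")
  invisible(x)
}

#' Dimensionless parameters of a two-type population
#'
#' Reduces a two-type droplet to the dimensionless parameters of the theory:
#' the division-rate ratio, the yield ratio `r = y2/y1` with type 2
#' relabelled (if needed) as the faster grower, and the small parameter
#' `epsilon` comparing the inoculum to the number of divisions the budget
#' supports. A yield ratio `r < 1` is a metabolic tradeoff (the faster grower
#' is less efficient); `r > 1` means rate and yield are positively
#' correlated.
#'
#' @param spec A two-type `droplet_spec`.
#' @return A list of class `two_type_params` with fields `ratio_rates`
#'   (`>= 1` by the canonical labelling), `ratio_yields` (`r`), `epsilon`
#'   (`= N0 * cost2 / (2 * budget)`), `spec` (the possibly relabelled spec)
#'   and `permutation` (the index map applied to enforce the convention).
#' @export
two_type_params <- function(spec) {
  validate_droplet(spec)
  if (spec$n_types != 2L)
    stop("invalid-parameter: types (two-type analysis requires exactly 2 types)",
         call. = FALSE)
  perm <- if (spec$rates[2] >= spec$rates[1]) c(1L, 2L) else c(2L, 1L)
  if (!identical(perm, c(1L, 2L))) {
    spec <- droplet_spec(spec$counts[perm], spec$budget,
                         spec$rates[perm], spec$yields[perm])
  }
  structure(list(
    ratio_rates = spec$rates[2] / spec$rates[1],
    ratio_yields = spec$yields[2] / spec$yields[1],
    epsilon = sum(spec$counts) * spec$costs[2] / (2 * spec$budget),
    spec = spec,
    permutation = perm), class = "two_type_params")
}

#' Swap the two types of a droplet specification
#'
#' Relabelling indices 1 and 2 (counts, rates and yields together) leaves all
#' distributions invariant up to the corresponding mirror of the support;
#' used in symmetry tests.
#'
#' @param spec A two-type `droplet_spec`.
#' @return The relabelled `droplet_spec`.
#' @export
swap_types <- function(spec) {
  validate_droplet(spec)
  stopifnot(spec$n_types == 2L)
  droplet_spec(rev(spec$counts), spec$budget, rev(spec$rates), rev(spec$yields))
}
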