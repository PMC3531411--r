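#' Exact final-state distribution by exhaustive path enumeration
#'
#' Walks every division sequence of a two-type droplet depth-first,
#' multiplying the step probabilities from [step_probability()] and
#' absorbing trajectories per the overshoot stopping rule. This is the
#' ground-truth oracle for tiny instances.
#'
#' @param spec A two-type [droplet_spec()].
#' @param max_divisions Guard on the maximum possible number of divisions
#'   (default 20); above it the enumeration is refused.
#' @return A `final_state_distribution` whose `table` has columns `d_type1`,
#'   `d_type2`, `n_final`, `consumed`, `prob`; probabilities sum to 1 within
#'   1e-12.
#' @examples
#' enumerate_paths(droplet_spec(c(1, 1), budget = 3, yields = c(1, 0.5)))
#' @export
enumerate_paths <- function(spec, max_divisions = 20L) {
  validate_droplet(spec)
  stopifnot(spec$n_types == 2L)
  if (ceiling(spec$budget / min(spec$costs)) > max_divisions)
    stop("instance-too-large: more than ", max_divisions,
         " divisions possible; raise max_divisions or use forward_dp",
         call. = FALSE)
  acc <- new.env(parent = emptyenv())
  rec <- function(n1, n2, remaining, d1, d2, p) {
    if (remaining <= 0) {
      key <- paste0(d1, ",", d2)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
      return(invisible())
    }
    w1 <- spec$rates[1] * n1
    w2 <- spec$rates[2] * n2
    tot <- w1 + w2
    if (w1 > 0) rec(n1 + 1, n2, remaining - spec$costs[1], d1 + 1, d2, p * w1 / tot)
    if (w2 > 0) rec(n1, n2 + 1, remaining - spec$costs[2], d1, d2 + 1, p * w2 / tot)
    invisible()
  }
  rec(spec$counts[1], spec$counts[2], spec$budget, 0L, 0L, 1)
  keys <- ls(acc)
  dd <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  tab <- data.frame(d_type1 = dd[, 1], d_type2 = dd[, 2],
                    n_final = sum(spec$counts) + dd[, 1] + dd[, 2],
                    consumed = spec$costs[1] * dd[, 1] + spec$costs[2] * dd[, 2],
                    prob = vapply(keys, function(k) acc[[k]], numeric(1)))
  tab <- tab[order(tab$d_type1, tab$d_type2), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, spec = spec, method = "enumerate"),
            class = "final_state_distribution")
}

#' Exact final-state distribution by forward dynamic programming
#'
#' Propagates probability mass over the phenotype lattice `(d1, d2)` along
#' anti-diagonals of constant total divisions. A lattice point is absorbing
#' once its cumulative resource consumption reaches the budget (overshoot
#' rule); mass entering an absorbing point is deposited and never
#' propagated. Because each division increments exactly one coordinate, all
#' predecessors of a diagonal lie on the previous one, so a two-diagonal
#' sweep is exact up to floating-point rounding.
#'
#' @param spec A two-type [droplet_spec()].
#' @param max_divisions Guard on total divisions (default 5000).
#' @return A `final_state_distribution` (method `"dp"`); agrees with
#'   [enumerate_paths()] to 1e-12 wherever both run.
#' @export
forward_dp <- function(spec, max_divisions = 5000L) {
  validate_droplet(spec)
  stopifnot(spec$n_types == 2L)
  smax <- ceiling(spec$budget / min(spec$costs))
  if (smax > max_divisions)
    stop("instance-too-large: up to ", smax, " divisions; guard is ",
         max_divisions, call. = FALSE)
  c1 <- spec$costs[1]; c2 <- spec$costs[2]
  r1 <- spec$rates[1]; r2 <- spec$rates[2]
  a1 <- spec$counts[1]; a2 <- spec$counts[2]
  S0 <- spec$budget
  abs_d1 <- integer(0); abs_d2 <- integer(0); abs_p <- numeric(0)
  cur <- 1  # mass over d1 = 0..s on diagonal s, starting at s = 0
  for (s in 0:smax) {
    d1 <- 0:s
    d2 <- s - d1
    consumed <- c1 * d1 + c2 * d2
    absorbed <- consumed >= S0 - 1e-12
    live <- !absorbed & cur > 0
    if (any(absorbed & cur > 0)) {
      keep <- absorbed & cur > 0
      abs_d1 <- c(abs_d1, d1[keep])
      abs_d2 <- c(abs_d2, d2[keep])
      abs_p <- c(abs_p, cur[keep])
    }
    if (!any(live)) break
    w1 <- r1 * (a1 + d1)
    w2 <- r2 * (a2 + d2)
    p1 <- ifelse(live, w1 / (w1 + w2), 0)
    nxt <- numeric(s + 2)
    m <- ifelse(live, cur, 0)
    nxt[2:(s + 2)] <- m * p1                      # type-1 division: d1 + 1
    nxt[1:(s + 1)] <- nxt[1:(s + 1)] + m * (1 - p1)  # type-2 division
    cur <- nxt
  }
  tab <- data.frame(d_type1 = abs_d1, d_type2 = abs_d2,
                    n_final = sum(spec$counts) + abs_d1 + abs_d2,
                    consumed = c1 * abs_d1 + c2 * abs_d2,
                    prob = abs_p)
  tab <- tab[order(tab$d_type1, tab$d_type2), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, spec = spec, method = "dp"),
            class = "final_state_distribution")
}

#' @export
print.final_state_distribution <- function(x, ...) {
  cat("final_state_distribution (", x$method, "): ", nrow(x$table),
      " support points\n", sep = "")
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("  ...\n")
  invisible(x)
}

#' Reduce a final-state distribution to one observable
#'
#' @param dist A `final_state_distribution`.
#' @param observable One of `"d1"` (type-1 divisions), `"n_final"` (total
#'   final cells) or `"fraction1"` (final fraction of type-1 cells).
#' @return A data.frame `value`, `prob` aggregated over the observable.
#' @export
observable_distribution <- function(dist,
                                    observable = c("d1", "n_final", "fraction1")) {
  observable <- match.arg(observable)
  tab <- dist$table
  v <- switch(observable,
    d1 = tab$d_type1,
    n_final = tab$n_final,
    fraction1 = (dist$spec$counts[1] + tab$d_type1) / tab$n_final)
  agg <- stats::aggregate(list(prob = tab$prob), by = list(value = v), FUN = sum)
  agg[order(agg$value), , drop = FALSE]
}

#' Moments of an observable under a final-state distribution
#'
#' @inheritParams observable_distribution
#' @return List with `mean`, `variance`, `skewness` (0/NaN convention of a
#'   degenerate distribution: variance 0 gives skewness `NaN`).
#' @export
distribution_moments <- function(dist,
                                 observable = c("d1", "n_final", "fraction1")) {
  d <- observable_distribution(dist, observable)
  m <- sum(d$value * d$prob)
  v <- sum((d$value - m)^2 * d$prob)
  sk <- if (v > 0) sum((d$value - m)^3 * d$prob) / v^1.5 else NaN
  list(mean = m, variance = v, skewness = sk)
}

#' Total-variation distance between two distributions of an observable
#'
#' @param a,b `final_state_distribution` objects.
#' @inheritParams observable_distribution
#' @return Half the L1 distance between the induced distributions, in
#'   \[0, 1\].
#' @export
tv_distance <- function(a, b, observable = c("d1", "n_final", "fraction1")) {
  observable <- match.arg(observable)
  da <- observable_distribution(a, observable)
  db <- observable_distribution(b, observable)
  support <- sort(unique(c(da$value, db$value)))
  pa <- da$prob[match(support, da$value)]; pa[is.na(pa)] <- 0
  pb <- db$prob[match(support, db$value)]; pb[is.na(pb)] <- 0
  sum(abs(pa - pb)) / 2
}
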