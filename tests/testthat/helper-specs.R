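# canonical small instances used across the suite
spec_uniform_D3 <- function() droplet_spec(c(1, 1), budget = 3)

# metabolic-tradeoff toy: equal rates, costs (1, 2), budget 3
spec_tradeoff_toy <- function() droplet_spec(c(1, 1), budget = 3,
                                             yields = c(1, 0.5))

# rate-ratio-2 instance with the hand-solvable quadratic x^2 + 2x - 11 = 0
spec_ratio2_hand <- function() droplet_spec(c(1, 1), budget = 4,
                                            rates = c(1, 2), yields = c(1, 2))

# deterministic seed-indexed family of random small two-type specs
random_small_specs <- function(n, seed = 424242) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    droplet_spec(counts = sample(0:3, 2, replace = TRUE) + c(1, 0),
                 budget = sample(3:8, 1),
                 rates = round(runif(2, 0.5, 3), 2),
                 yields = round(runif(2, 0.4, 2.5), 2))
  })
}

# two-sample Kolmogorov-Smirnov critical value at level alpha
ks_critical <- function(n, m, alpha = 0.01) {
  sqrt(-log(alpha / 2) / 2) * sqrt((n + m) / (n * m))
}
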