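# Shared fixtures: published two-component mixture solutions and small
# independent oracles used across the suite.

bd1_fit <- function() {
  mixture_fit(c(22.6, 35.1), c(4.8, 10.1), c(0.669, 0.331), n = 224L)
}

bd2_fit <- function() {
  mixture_fit(c(20.9, 38.2), c(4.1, 11.8), c(0.44, 0.56), n = 279L)
}

whole_fit <- function() {
  mixture_fit(c(21.9, 37.6), c(4.6, 11.5), c(0.55, 0.45), n = 515L)
}

# Draw onset ages from a mixture_fit's parameters, floored at 5 years.
rmix_aao <- function(n, fit, seed) {
  pmax(5, simulate_mixture(n, fit$components$mean, fit$components$sd,
                           fit$components$weight, seed = seed))
}

# Brute-force Pearson chi-square oracle.
chi2_brute <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}
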