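# Independent oracles used across tests.

# Maximum-likelihood fit of a normal truncated to [a, b] (known cut points),
# maximised numerically over (mean, sd). Independent of the Q-Q regression
# route.
truncnorm_mle <- function(x, a, b) {
  nll <- function(p) {
    mu <- p[1L]; sigma <- exp(p[2L])
    z <- pnorm((b - mu) / sigma) - pnorm((a - mu) / sigma)
    if (z <= 0) return(1e10)
    -sum(dnorm(x, mu, sigma, log = TRUE)) + length(x) * log(z)
  }
  fit <- optim(c(mean(x), log(sd(x))), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 2000))
  c(mean = fit$par[1L], sd = exp(fit$par[2L]))
}

# Closed-form population Bowley skewness from a quantile function
bowley_pop <- function(qfun) {
  q <- qfun(c(0.25, 0.5, 0.75))
  (q[3L] + q[1L] - 2 * q[2L]) / (q[3L] - q[1L])
}

# Population skewness delta (raw minus log) for a lognormal(meanlog, sdlog)
delta_pop_lognormal <- function(meanlog, sdlog) {
  bowley_pop(function(p) qlnorm(p, meanlog, sdlog)) -
    bowley_pop(function(p) qnorm(p, meanlog, sdlog))
}

# Population skewness delta for a normal(mean, sd) (raw symmetric, log skewed)
delta_pop_normal <- function(mean, sd) {
  bowley_pop(function(p) qnorm(p, mean, sd)) -
    bowley_pop(function(p) log(qnorm(p, mean, sd)))
}

# A sample of size 4001 whose type-7 quantiles at probabilities k/40 are
# EXACTLY the quantiles of a standard normal truncated to its central 95%
# (grid positions 100k + 1 are integers, so no interpolation occurs).
exact_truncnorm_sample <- function() {
  p <- seq(0, 1, length.out = 4001L)
  qnorm(0.025 + 0.95 * p)
}
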