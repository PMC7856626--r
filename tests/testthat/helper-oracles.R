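# Independent oracles used across the suite.  All are deliberately written
# against first principles (truncated sums, enumeration, quadrature), not
# against the package's own evaluation paths.

# truncated-sum moments of any pmf on 0..upper
moments_by_sum <- function(pmf, upper = 5000) {
  x <- 0:upper
  p <- pmf(x)
  m <- sum(x * p)
  v <- sum((x - m)^2 * p)
  list(mean = m, variance = v, dispersion_index = v / m,
       skewness = sum((x - m)^3 * p) / v^1.5,
       kurtosis = sum((x - m)^4 * p) / v^2,
       mass = sum(p))
}

# INAR(1) one-step transition by direct enumeration of
# thinning-survivors i and innovation arrivals k - i
transition_by_enumeration <- function(k, l, p, inn_pmf) {
  i <- 0:min(k, l)
  sum(choose(l, i) * p^i * (1 - p)^(l - i) * inn_pmf(k - i))
}

# posterior expectation E[f(lambda) | x] under the PQX latent-rate model,
# by adaptive quadrature over the unnormalized posterior
posterior_expectation <- function(x, alpha, theta, f) {
  dens <- function(l) exp(-(1 + theta) * l + x * log(l)) *
    (2 * alpha + theta^2 * l^2)
  norm <- stats::integrate(dens, 0, Inf, rel.tol = 1e-12)$value
  stats::integrate(function(l) f(l) * dens(l), 0, Inf,
                   rel.tol = 1e-12)$value / norm
}

# central-difference gradient
num_grad <- function(fn, at, eps = 1e-6) {
  vapply(seq_along(at), function(i) {
    hi <- at; hi[i] <- at[i] + eps
    lo <- at; lo[i] <- at[i] - eps
    (fn(hi) - fn(lo)) / (2 * eps)
  }, numeric(1))
}

# brute-force set of (weak) local modes of a pmf over 0..upper; works on the
# log scale so deep-tail values are compared with relative precision
modes_by_argmax <- function(pmf, upper = 200, tol = 1e-9) {
  lp <- log(pmf(0:upper))
  which(vapply(seq_along(lp), function(i) {
    left <- if (i == 1) TRUE else lp[i] >= lp[i - 1] - tol
    right <- if (i == length(lp)) TRUE else lp[i] >= lp[i + 1] - tol
    left && right
  }, logical(1))) - 1L
}

# random admissible PQX parameter pairs, reproducible
random_pqx_params <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(alpha = stats::runif(n, 0.01, 8),
             theta = stats::runif(n, 0.1, 5))
}
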