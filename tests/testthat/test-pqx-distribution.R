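test_that("pmf matches closed-form values and mixture-integral oracle", {
  # alpha = 0 reduction: NB(3, theta/(theta+1)); pmf(0) = (1/2)^3
  expect_equal(dpqx(0, 0, 1), 0.125)
  # direct arithmetic: (2*3*1.5*2.5^2 + 1.5^3*2) / (2*4*2.5^3) = 63/125
  expect_equal(dpqx(0, 3, 1.5), 0.504)
  # mixture-integral oracle: integrate Poisson pmf over the quasi-xgamma law
  mix_pmf <- function(x, a, th) {
    stats::integrate(function(l)
      stats::dpois(x, l) * th / (1 + a) * (a + th^2 / 2 * l^2) * exp(-th * l),
      0, Inf, rel.tol = 1e-12)$value
  }
  for (x in c(0, 1, 3, 7))
    expect_equal(dpqx(x, 3, 1.5), mix_pmf(x, 3, 1.5), tolerance = 1e-10)
  expect_error(dpqx(-1, 1, 1), "non-negative")
  expect_error(dpqx(1.5, 1, 1), "non-negative integers")
  expect_error(dpqx(1, -0.1, 1), "alpha")
  expect_error(dpqx(1, 1, 0), "theta")
})

test_that("pmf normalizes and is consistent with the cdf", {
  pars <- random_pqx_params(100)
  for (i in seq_len(nrow(pars))) {
    a <- pars$alpha[i]; th <- pars$theta[i]
    upper <- qpqx(1 - 1e-13, a, th) + 10
    expect_equal(sum(dpqx(0:upper, a, th)) +
                   ppqx(upper, a, th, lower.tail = FALSE), 1,
                 tolerance = 1e-12)
  }
  # cdf(x) - cdf(x-1) = pmf(x) over a window
  a <- 0.7; th <- 1.2
  x <- 1:40
  expect_equal(ppqx(x, a, th) - ppqx(x - 1, a, th), dpqx(x, a, th),
               tolerance = 1e-12)
  expect_equal(ppqx(0, a, th), dpqx(0, a, th))
})

test_that("survival function is cancellation-free down to 1e-11 and beyond", {
  # oracle: log-space summation of the pmf from x+1 upward
  surv_by_sum <- function(x, a, th, terms = 4000) {
    lp <- dpqx((x + 1):(x + terms), a, th, log = TRUE)
    m <- max(lp)
    exp(m) * sum(exp(lp - m))
  }
  a <- pqx_alpha_from_mean(0.5, 5); th <- 5
  for (x in c(5, 10, 15, 20, 30)) {
    s <- ppqx(x, a, th, lower.tail = FALSE)
    expect_gt(s, 0)
    expect_equal(s, surv_by_sum(x, a, th), tolerance = 1e-12)
  }
  # monotone non-increasing tail
  s <- ppqx(0:60, a, th, lower.tail = FALSE)
  expect_true(all(diff(s) <= 0))
  expect_lt(s[61], 1e-11)
  # Table-style spot value at mean-parametrized (mu=0.5, theta=3)
  expect_equal(ppqx_mean(10, 0.5, 3, lower.tail = FALSE), 2.943e-6,
               tolerance = 1e-3)
})

test_that("boundary and limiting reductions hold", {
  th <- 0.8
  # alpha = 0: NB(3, theta/(theta+1)) pointwise
  expect_equal(dpqx(0:60, 0, th),
               stats::dnbinom(0:60, size = 3, prob = th / (th + 1)),
               tolerance = 1e-14)
  # alpha -> Inf: geometric(theta/(theta+1)) in total variation
  tv <- 0.5 * sum(abs(dpqx(0:400, 1e6, th) -
                        stats::dgeom(0:400, th / (th + 1))))
  expect_lt(tv, 1e-4)
})

test_that("closed-form moments agree with truncated sums and DI exceeds 1", {
  pars <- random_pqx_params(40, seed = 7)
  for (i in seq_len(nrow(pars))) {
    a <- pars$alpha[i]; th <- pars$theta[i]
    m <- pqx_moments(a, th)
    o <- moments_by_sum(function(x) dpqx(x, a, th))
    expect_equal(m$mean, o$mean, tolerance = 1e-8)
    expect_equal(m$variance, o$variance, tolerance = 1e-8)
    expect_equal(m$skewness, o$skewness, tolerance = 1e-7)
    expect_equal(m$kurtosis, o$kurtosis, tolerance = 1e-7)
    expect_gt(m$dispersion_index, 1)
  }
  # over-dispersion across a wide random sweep of the admissible region
  big <- random_pqx_params(1000, seed = 11)
  di <- mapply(function(a, th) pqx_moments(a, th)$dispersion_index,
               big$alpha, big$theta)
  expect_true(all(di > 1))
  # frozen spot value, computed from the truncated-sum oracle:
  # DI(0.5, 1.5) = 1 + 7.25/7.875
  expect_equal(pqx_moments(0.5, 1.5)$dispersion_index, 1.9206349,
               tolerance = 1e-7)
  # geometric limit: mean -> (1-p)/p = 1 at theta = 1
  expect_equal(pqx_moments(1e9, 1)$mean, 1, tolerance = 1e-6)
})

test_that("factorial moments match the closed form and direct summation", {
  expect_equal(pqx_fmoment(1, 0.5, 1.5), 3.5 / 2.25)   # the mean
  expect_equal(pqx_fmoment(1, 0, 1), 3)                # NB(3, 1/2) mean
  x <- 0:4000
  p <- dpqx(x, 0.5, 1.5)
  expect_equal(pqx_fmoment(2, 0.5, 1.5), sum(x * (x - 1) * p),
               tolerance = 1e-10)
  expect_equal(pqx_fmoment(2, 0.5, 1.5), 3.8518519, tolerance = 1e-7)
  expect_error(pqx_fmoment(0, 1, 1), "positive integer")
})

test_that("generating functions satisfy their defining identities", {
  a <- 1.3; th <- 0.9
  expect_equal(pqx_pgf(1, a, th), 1, tolerance = 1e-12)
  expect_equal(pqx_pgf(0, a, th), dpqx(0, a, th), tolerance = 1e-12)
  # numeric derivative at s = 1 equals the mean
  eps <- 1e-6
  expect_equal((pqx_pgf(1, a, th) - pqx_pgf(1 - eps, a, th)) / eps,
               pqx_moments(a, th)$mean, tolerance = 1e-5)
  # pgf equals E[s^X] by direct summation
  s <- -0.4
  expect_equal(pqx_pgf(s, a, th), sum(s^(0:500) * dpqx(0:500, a, th)),
               tolerance = 1e-12)
  # mgf equals E[exp(tX)] by direct summation inside the convergence region
  t0 <- 0.2
  expect_equal(pqx_mgf(t0, a, th),
               sum(exp(t0 * (0:800)) * dpqx(0:800, a, th)),
               tolerance = 1e-10)
  expect_error(pqx_mgf(log(th + 1) + 0.1, a, th), "diverges")
})

test_that("mean parametrization substitutes correctly and round-trips", {
  expect_equal(pqx_alpha_from_mean(1, 1.5), 3)
  expect_equal(dpqx_mean(0:30, 1, 1.5), dpqx(0:30, 3, 1.5))
  # the mean of the reparametrized law is mu
  a <- pqx_alpha_from_mean(0.5, 4)
  expect_equal(pqx_moments(a, 4)$mean, 0.5, tolerance = 1e-12)
  expect_error(pqx_alpha_from_mean(1, 3.01), "1 < theta \\* mu < 3")
  expect_error(pqx_alpha_from_mean(1, 1), "1 < theta \\* mu < 3")
})

test_that("NB reference moments match the printed closed forms", {
  m <- nb_moments(0.5, 0.5)
  expect_equal(m$skewness, 3)
  expect_equal(m$mean, 0.5)
  o <- moments_by_sum(function(x) stats::dnbinom(x, size = 0.5, prob = 0.5),
                      upper = 400)
  expect_equal(m$variance, o$variance, tolerance = 1e-10)
  expect_equal(m$kurtosis, o$kurtosis, tolerance = 1e-8)
  # mean-parametrized tail values used in the comparison table
  expect_equal(stats::pnbinom(5, size = 1.5, mu = 1, lower.tail = FALSE),
               0.00973, tolerance = 1e-3)
  expect_equal(stats::pnbinom(10, size = 2, mu = 1, lower.tail = FALSE),
               4.704e-5, tolerance = 1e-3)
})

test_that("random generation is reproducible and matches the exact law", {
  set.seed(99)
  x1 <- rpqx(50, 3, 1.5)
  set.seed(99)
  x2 <- rpqx(50, 3, 1.5)
  expect_identical(x1, x2)
  expect_error(rpqx(0, 1, 1), "positive")

  set.seed(123)
  x <- rpqx(1e5, 3, 1.5)
  # chi-square GOF against the exact pmf at level 0.01
  upper <- qpqx(1 - 20 / length(x), 3, 1.5)
  obs <- tabulate(pmin(x, upper) + 1L, nbins = upper + 1L)
  p <- dpqx(0:(upper - 1), 3, 1.5)
  p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)

  set.seed(321)
  y <- rpqx(1e5, 0.5, 1.5)
  mo <- pqx_moments(0.5, 1.5)
  se <- sqrt(mo$variance / length(y))
  expect_lt(abs(mean(y) - 1.5555556), 3 * se)
})

test_that("quantile function inverts the cdf", {
  a <- 0.6; th <- 1.1
  for (p in c(0, 0.1, 0.5, 0.9, 0.999, 1 - 1e-9)) {
    q <- qpqx(p, a, th)
    expect_gte(ppqx(q, a, th), p)
    if (q > 0) expect_lt(ppqx(q - 1, a, th), p)
  }
})

test_that("modality classification agrees with brute-force argmax", {
  # representative points of all four shape regions, plus boundary curves
  cases <- list(
    list(a = 1, th = 2.5, cat = "unimodal-at-zero"),      # theta >= 2
    list(a = 0.5, th = 1, cat = "unimodal-at-zero"),
    list(a = 0.25, th = 1, cat = "mode-at-one"),          # exact tie {0,1}
    list(a = 0.05, th = 0.5, cat = "unimodal-interior"),
    list(a = 0.01, th = 0.2, cat = "unimodal-interior"),
    list(a = 0.32, th = 0.3, cat = "bimodal"),
    list(a = 0.34, th = 0.5, cat = "unimodal-at-zero"))   # window holds no integer
  for (cs in cases) {
    cl <- pqx_modality(cs$a, cs$th)
    expect_identical(cl$category, cs$cat)
    bf <- modes_by_argmax(function(x) dpqx(x, cs$a, cs$th))
    expect_setequal(cl$modes, bf)
    # the global argmax is always among the reported modes
    pm <- dpqx(0:200, cs$a, cs$th)
    expect_true((which.max(pm) - 1L) %in% cl$modes)
  }
  # randomized sweep across the low-theta region where all shapes occur
  set.seed(5)
  for (i in 1:60) {
    a <- stats::runif(1, 0.01, 1); th <- stats::runif(1, 0.05, 2.5)
    cl <- pqx_modality(a, th)
    bf <- modes_by_argmax(function(x) dpqx(x, a, th), upper = 400)
    expect_setequal(cl$modes, bf)
  }
})
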