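test_that("CML recovers generating parameters and reduces to iid MLE at p=0", {
  set.seed(11)
  m <- inar_model(0.3, innovation("pqx", 0.5, 0.5))
  x <- simulate_inar(m, 500)
  f <- fit_inar(x, "pqx", "cml")
  expect_true(f$converged)
  expect_lt(abs(f$p - 0.3), 3 * f$se[["p"]])
  expect_lt(abs(f$params[["theta"]] - 0.5), 3 * f$se[["theta"]])
  # AIC/BIC identities hold exactly
  expect_equal(f$aic, 2 * 3 + 2 * f$neg_loglik)
  expect_equal(f$bic, 3 * log(length(x)) + 2 * f$neg_loglik)

  # iid data: p-hat collapses toward zero ...
  set.seed(12)
  y <- rpqx(2000, 0.5, 1.5)
  fc <- fit_inar(y, "pqx", "cml")
  fi <- fit_pqx(y, "mle")
  expect_lt(fc$p, 0.05)
  expect_lt(abs(fc$params[["theta"]] - fi$theta), 3 * fi$se[["theta"]])
  # ... and at p = 0 exactly, the conditional likelihood IS the iid
  # likelihood of x[2..T]: same innovation estimates by construction
  law <- innovation("pqx", fi$alpha, fi$theta)
  expect_equal(pqxinar:::inar_cloglik(y, 0, law),
               pqx_loglik(y[-1], fi$alpha, fi$theta), tolerance = 1e-10)
  fi2 <- fit_pqx(y[-1], "mle")
  obj <- function(v) -pqxinar:::inar_cloglik(y, 0,
                                             innovation("pqx", v[1], v[2]))
  opt <- stats::optim(c(fi2$alpha, fi2$theta), obj,
                      control = list(reltol = 1e-12))
  expect_equal(opt$par[1], fi2$alpha, tolerance = 1e-3)
  expect_equal(opt$par[2], fi2$theta, tolerance = 1e-3)
})

test_that("Yule-Walker is self-consistent and fails on under-dispersion", {
  set.seed(13)
  x <- simulate_inar(inar_model(0.3, innovation("pqx", 0.5, 2)), 500)
  f <- fit_inar(x, "pqx", "yw")
  mom <- inarpqx_moments(f$p, f$params[["alpha"]], f$params[["theta"]])
  # construction identity: fitted process mean and DI equal the sample ones
  expect_equal(mom$mean, mean(x), tolerance = 1e-8)
  expect_equal(mom$dispersion_index, series_dispersion_index(x),
               tolerance = 1e-8)
  # an alternating (under-dispersed) series cannot come from PQX innovations
  bad <- rep(c(1L, 0L), 30)
  expect_error(suppressWarnings(fit_inar(bad, "pqx", "yw")), "incompatible")
  expect_error(fit_inar(rep(2L, 50), "pqx"), "constant")
})

test_that("every innovation family fits its own simulated data", {
  set.seed(14)
  cases <- list(
    list(law = innovation("poisson", 3), family = "poisson"),
    list(law = innovation("geometric", 0.3), family = "geometric"),
    list(law = innovation("poisson_lindley", 0.8),
         family = "poisson_lindley"),
    list(law = innovation("nb", size = 2, prob = 0.4), family = "nb"))
  for (cs in cases) {
    x <- simulate_inar(inar_model(0.4, cs$law), 600)
    f <- fit_inar(x, cs$family, "cml")
    expect_true(f$converged, label = cs$family)
    expect_lt(abs(f$p - 0.4), 0.12)
    expect_equal(unname(f$params), unname(cs$law$params),
                 tolerance = 0.35)
  }
})

test_that("model comparison ranks the generating family highly", {
  set.seed(15)
  # well-separated over-dispersed PQX regime vs equi-dispersed Poisson
  m <- inar_model(0.4, innovation("pqx", 0.3, 0.3))
  wins <- 0L
  for (r in 1:10) {
    x <- simulate_inar(m, 300)
    tab <- suppressWarnings(compare_inar(x, c("pqx", "poisson")))
    if (tab$family[1] == "pqx") wins <- wins + 1L
  }
  expect_gte(wins, 8L)

  # Poisson-generated data prefer the 2-parameter Poisson model by BIC
  mp <- inar_model(0.4, innovation("poisson", 3))
  wins <- 0L
  for (r in 1:10) {
    x <- simulate_inar(mp, 300)
    tab <- suppressWarnings(compare_inar(x, c("pqx", "poisson")))
    if (tab$family[which.min(tab$bic)] == "poisson") wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("Pearson residuals are calibrated under the true model", {
  m <- inar_model(0.5, innovation("pqx", 1, 0.7))
  set.seed(16)
  x <- simulate_inar(m, 1e4)
  r <- pearson_residuals(x, m)
  expect_length(r$residuals, length(x) - 1L)
  expect_lt(abs(r$mean), 0.03)
  expect_gt(r$variance, 0.95)
  expect_lt(r$variance, 1.05)
  # whiteness: residual ACF inside the large-sample band
  band <- 1.96 / sqrt(length(x))
  expect_gte(mean(abs(r$acf) < band), 0.8)

  # misspecification direction: inflating theta shrinks the assumed
  # innovation variance, so residual variance rises above 1
  bad <- inar_model(0.5, innovation("pqx", 1, 2))
  rb <- pearson_residuals(x, bad)
  expect_gt(rb$variance, 1.3)
})

test_that("dispersion test calibrates under the null and detects alternatives", {
  # null: Poisson INAR(1); statistic approximately standard normal
  m0 <- inar_model(0.5, innovation("poisson", 3))
  set.seed(17)
  z <- replicate(300, {
    x <- simulate_inar(m0, 500, burn_in = 100)
    unname(overdispersion_test(x)$statistic)
  })
  expect_lt(abs(mean(z)), 0.2)
  expect_lt(abs(stats::sd(z) - 1), 0.2)
  rate <- mean(z > stats::qnorm(0.95))
  expect_gte(rate, 0.02); expect_lte(rate, 0.09)

  # power at the strongly over-dispersed earthquake-like regime, T = 82
  set.seed(18)
  rej <- replicate(25, {
    x <- generate_fixture("earthquake-like", 82)
    overdispersion_test(x)$p.value < 0.05
  })
  expect_gte(mean(rej), 0.9)
})

test_that("one-step forecasts follow the conditional-mean recursion", {
  law <- innovation("pqx", 94.964, 0.238)
  m <- inar_model(0.461, law)
  set.seed(19)
  x <- generate_fixture("earthquake-like", 82)
  f <- forecast_inar(m, x)
  expect_length(f, length(x))
  # first prediction is the stationary mean; spot value from the printed fit
  expect_equal(f[1], inarpqx_moments(0.461, 94.964, 0.238)$mean)
  expect_equal(f[1], 7.945, tolerance = 2e-3)
  expect_equal(law$mean, 4.287, tolerance = 1e-3)   # forecast intercept
  # identity with the conditional mean, pointwise
  expect_equal(f[-1], inar_cond_moments(m, x[-length(x)])$mean)
  # p = 0: every prediction is the innovation mean
  m0 <- inar_model(0, innovation("poisson", 2))
  expect_equal(forecast_inar(m0, c(4L, 1L, 7L)), rep(2, 3))
})
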