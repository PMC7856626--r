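# Fitting and comparing INAR(1) models: conditional maximum likelihood,
# Yule-Walker, information criteria, residual diagnostics, over-dispersion
# testing and one-step forecasting.

# parameter transforms per family: everything positive on log scale,
# probabilities on logit scale.  CML optimizes on the transformed scale.
logit <- function(x) log(x / (1 - x))
invlogit <- function(x) 1 / (1 + exp(-x))

inn_transforms <- list(
  pqx = list(names = c("alpha", "theta"),
             to = function(p) log(pmax(p, 1e-8)),
             from = function(z) exp(z),
             default = c(alpha = 1, theta = 1)),
  poisson = list(names = "lambda",
                 to = function(p) log(p), from = function(z) exp(z),
                 default = c(lambda = 1)),
  poisson_lindley = list(names = "theta",
                         to = function(p) log(p), from = function(z) exp(z),
                         default = c(theta = 1)),
  geometric = list(names = "prob",
                   to = function(p) logit(p), from = function(z) invlogit(z),
                   default = c(prob = 0.5)),
  nb = list(names = c("size", "prob"),
            to = function(p) c(log(p[1]), logit(p[2])),
            from = function(z) c(exp(z[1]), invlogit(z[2])),
            default = c(size = 1, prob = 0.5)))

# moment-based innovation starting values given a preliminary p-hat:
# match the implied innovation mean/variance mu_e = (1-p) xbar,
# s2_e = (1-p^2) s2 - p mu_e.
inn_start <- function(family, x, p) {
  mu_e <- max((1 - p) * mean(x), 1e-3)
  s2_e <- max((1 - p^2) * mean((x - mean(x))^2) - p * mu_e, mu_e * 1.01)
  switch(family,
    poisson = c(lambda = mu_e),
    geometric = c(prob = min(max(1 / (1 + mu_e), 1e-3), 1 - 1e-3)),
    poisson_lindley = {
      # innovation mean (th+2)/(th(th+1)) = mu_e, solved for th > 0
      th <- (1 - mu_e + sqrt((mu_e - 1)^2 + 8 * mu_e)) / (2 * mu_e)
      c(theta = max(th, 1e-3))
    },
    nb = {
      pr <- min(max(mu_e / s2_e, 1e-3), 1 - 1e-3)
      c(size = max(mu_e * pr / (1 - pr), 1e-3), prob = pr)
    },
    pqx = {
      mm <- tryCatch(
        fit_pqx_mm_moments(mu_e, s2_e + mu_e^2),
        error = function(e) NULL)
      if (is.null(mm)) c(alpha = 1, theta = 1 / mu_e) else mm
    })
}

# MM inversion from raw moments (shared by fit_pqx_mm and warm starts)
fit_pqx_mm_moments <- function(m1, m2) {
  root_arg <- 25 * m1^4 + 12 * m1^3 - 12 * m1^2 * m2
  if (root_arg < 0) stop("negative root argument", call. = FALSE)
  alpha <- (-7 * m1^2 + sqrt(root_arg) - 3 * (m1 - m2)) /
    (2 * m1^2 + m1 - m2)
  if (is.na(alpha) || alpha < 0) stop("alpha < 0", call. = FALSE)
  c(alpha = alpha, theta = (alpha + 3) / (m1 * (1 + alpha)))
}

make_law <- function(family, par) do.call(innovation, c(list(family),
                                                        as.list(par)))

# conditional log-likelihood sum_{t=2}^T log P(x_t | x_{t-1})
inar_cloglik <- function(x, p, law) {
  sum(inar_trans_lp(x[-1], x[-length(x)], p, law$logpmf))
}

#' Fit an INAR(1) model to a count series
#'
#' Two estimators are available.  Conditional maximum likelihood
#' (\code{"cml"}) maximizes \eqn{\sum_{t=2}^T \log P(x_t \mid x_{t-1})} over
#' the thinning probability and the innovation parameters, by BFGS on
#' transformed parameters (logit for probabilities, log for positive
#' parameters); standard errors come from the inverse observed information.
#' Yule-Walker (\code{"yw"}, PQX innovations only) equates the lag-1 sample
#' autocorrelation, the sample mean and the sample dispersion index (divisor
#' T) to their theoretical process counterparts; the construction makes the
#' fitted process mean and dispersion index reproduce the sample values
#' exactly.
#'
#' Information criteria use the conditional likelihood:
#' \code{aic = 2k + 2 * neg_loglik} and \code{bic = k log(T) + 2 *
#' neg_loglik} with \code{T} the full series length.
#'
#' A negative lag-1 autocorrelation is clipped to 0 with a warning (the model
#' space is \eqn{p \in [0,1)}); an under-dispersed series makes the
#' Yule-Walker moment inversion fail with an error.
#'
#' @param x vector of non-negative integer counts, length >= 3.
#' @param family innovation family name (see [innovation_families()]).
#' @param method \code{"cml"} or \code{"yw"}.
#' @param init optional named list \code{list(p = , params = )} of starting
#'   values for CML.
#' @return object of class \code{"inar_fit"}: list with \code{model} (an
#'   [inar_model()]), \code{p}, \code{params}, \code{se},
#'   \code{neg_loglik}, \code{aic}, \code{bic}, \code{method},
#'   \code{family}, \code{converged}, \code{n}.
#' @examples
#' set.seed(1)
#' x <- simulate_inar(inar_model(0.3, innovation("pqx", 0.5, 0.5)), 300)
#' fit_inar(x, "pqx", method = "cml")
#' @export
fit_inar <- function(x, family = "pqx", method = c("cml", "yw"),
                     init = NULL) {
  method <- match.arg(method)
  check_counts(x)
  if (length(x) < 3) stop("need at least three observations", call. = FALSE)
  if (all(x == x[1]))
    stop("constant series: degenerate likelihood", call. = FALSE)
  if (method == "yw") return(fit_inar_yw(x, family))
  fit_inar_cml(x, family, init)
}

fit_inar_yw <- function(x, family) {
  if (family != "pqx")
    stop("Yule-Walker estimation is implemented for the PQX family",
         call. = FALSE)
  T_ <- length(x)
  p <- series_acf1(x)
  if (p < 0) {
    warning("negative lag-1 autocorrelation clipped to 0")
    p <- 0
  }
  if (p >= 1) {
    warning("lag-1 autocorrelation >= 1 clipped")
    p <- 1 - 1e-8
  }
  xb <- mean(x)
  di <- series_dispersion_index(x)
  root_arg <- xb * (p - 1) *
    (12 * di - 13 * xb + p * (12 * di + 13 * xb - 12) - 12)
  if (root_arg < 0)
    stop("YW moments incompatible: negative square-root argument ",
         format(root_arg), call. = FALSE)
  alpha <- (-3 * di + 4 * xb + p * (-3 * di - 4 * xb + 3) -
              sqrt(root_arg) + 3) /
    (di - xb + p * (di + xb - 1) - 1)
  if (!is.finite(alpha) || alpha <= 0)
    stop("YW moments incompatible: alpha estimate ", format(alpha),
         " <= 0 (series not over-dispersed enough for PQX innovations)",
         call. = FALSE)
  theta <- (alpha + 3) / (xb * (1 + alpha) * (1 - p))
  law <- innovation("pqx", alpha = alpha, theta = theta)
  nll <- -inar_cloglik(x, p, law)
  k <- 3L
  structure(list(model = inar_model(p, law), p = p,
                 params = c(alpha = alpha, theta = theta),
                 se = c(p = NA_real_, alpha = NA_real_, theta = NA_real_),
                 neg_loglik = nll, aic = 2 * k + 2 * nll,
                 bic = k * log(T_) + 2 * nll, method = "YW",
                 family = "pqx", converged = TRUE, n = T_),
            class = "inar_fit")
}

fit_inar_cml <- function(x, family, init = NULL) {
  tr <- inn_transforms[[family]]
  if (is.null(tr)) stop("no CML transform registered for family '", family,
                        "'", call. = FALSE)
  T_ <- length(x)
  # initialization: YW for PQX when admissible, else clipped ACF plus
  # moment-matched innovation parameters
  p0 <- min(max(series_acf1(x), 1e-3), 0.95)
  par0 <- NULL
  if (family == "pqx" && is.null(init)) {
    yw <- tryCatch(fit_inar_yw(x, "pqx"), error = function(e) NULL,
                   warning = function(w) NULL)
    if (!is.null(yw)) { p0 <- min(max(yw$p, 1e-3), 0.95); par0 <- yw$params }
  }
  if (!is.null(init)) { p0 <- init$p; par0 <- init$params }
  if (is.null(par0)) par0 <- tryCatch(inn_start(family, x, p0),
                                      error = function(e) tr$default)

  obj <- function(z) {
    p <- invlogit(z[1])
    par <- tr$from(z[-1])
    law <- tryCatch(make_law(family, stats::setNames(par, tr$names)),
                    error = function(e) NULL)
    if (is.null(law)) return(1e10)
    ll <- inar_cloglik(x, p, law)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  z0 <- c(logit(p0), tr$to(par0))
  opt <- stats::optim(z0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  p_hat <- invlogit(opt$par[1])
  par_hat <- stats::setNames(tr$from(opt$par[-1]), tr$names)
  law <- make_law(family, par_hat)
  nll <- opt$value
  k <- 1L + length(par_hat)

  # observed information on the natural scale
  nat <- c(p = p_hat, par_hat)
  nat_obj <- function(v) {
    if (v[1] < 0 || v[1] >= 1) return(Inf)
    lw <- tryCatch(make_law(family, stats::setNames(v[-1], tr$names)),
                   error = function(e) NULL)
    if (is.null(lw)) return(Inf)
    ll <- inar_cloglik(x, v[1], lw)
    if (!is.finite(ll)) return(Inf)
    -ll
  }
  se <- rep(NA_real_, k)
  h <- try(stats::optimHess(nat, nat_obj), silent = TRUE)
  if (!inherits(h, "try-error")) {
    v <- try(solve(h), silent = TRUE)
    if (!inherits(v, "try-error") && all(diag(v) > 0)) se <- sqrt(diag(v))
  }
  names(se) <- c("p", tr$names)

  if (opt$convergence != 0)
    warning("CML optimization did not converge; results are flagged")

  structure(list(model = inar_model(p_hat, law), p = p_hat,
                 params = par_hat, se = se, neg_loglik = nll,
                 aic = 2 * k + 2 * nll, bic = k * log(T_) + 2 * nll,
                 method = "CML", family = family,
                 converged = opt$convergence == 0, n = T_),
            class = "inar_fit")
}

#' @export
print.inar_fit <- function(x, ...) {
  cat(sprintf("INAR(1) fit, %s innovations, method %s, T = %d\n",
              x$family, x$method, x$n))
  est <- data.frame(estimate = c(x$p, x$params), se = x$se)
  rownames(est) <- c("p", names(x$params))
  print(format(est, digits = 4))
  cat(sprintf("-logLik %.3f  AIC %.3f  BIC %.3f\n",
              x$neg_loglik, x$aic, x$bic))
  invisible(x)
}

#' @export
coef.inar_fit <- function(object, ...) c(p = object$p, object$params)

#' Compare INAR(1) innovation families on one series
#'
#' Fits each family by conditional maximum likelihood and tabulates the
#' negative conditional log-likelihood, AIC, BIC and the fitted process mean,
#' variance and dispersion index, sorted by AIC (lowest first = preferred
#' model).  Families whose fit fails are kept in the table with NA entries.
#'
#' @param x count series.
#' @param families character vector of innovation family names.
#' @return a data.frame of class \code{"inar_comparison"} with one row per
#'   family; the fitted objects are attached as attribute \code{"fits"}.
#' @examples
#' set.seed(1)
#' x <- simulate_inar(inar_model(0.4, innovation("pqx", 2, 0.4)), 200)
#' compare_inar(x, c("pqx", "poisson"))
#' @export
compare_inar <- function(x, families = c("pqx", "nb", "geometric",
                                         "poisson_lindley", "poisson")) {
  if (length(families) < 2)
    stop("need at least two families to compare", call. = FALSE)
  fits <- lapply(families, function(f)
    tryCatch(fit_inar(x, f, method = "cml"), error = function(e) e))
  rows <- lapply(seq_along(families), function(i) {
    f <- fits[[i]]
    if (inherits(f, "error"))
      return(data.frame(family = families[i], k = NA, neg_loglik = NA,
                        aic = NA, bic = NA, mean = NA, variance = NA,
                        dispersion_index = NA))
    mom <- inar_moments(f$model)
    data.frame(family = families[i], k = 1L + length(f$params),
               neg_loglik = f$neg_loglik, aic = f$aic, bic = f$bic,
               mean = mom$mean, variance = mom$variance,
               dispersion_index = mom$dispersion_index)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  if (any(is.na(tab$aic))) warning("some families failed to fit")
  structure(tab, fits = stats::setNames(fits, families),
            class = c("inar_comparison", "data.frame"))
}

#' Standardized Pearson residuals of a fitted INAR(1) model
#'
#' \deqn{e_t = \frac{x_t - E[X_t \mid x_{t-1}]}
#'   {\sqrt{Var[X_t \mid x_{t-1}]}}, \quad t = 2, \dots, T.}
#' Under a correctly specified model the residuals are uncorrelated with
#' mean near 0 and variance near 1; variance above (below) 1 signals more
#' (less) dispersion in the data than the fitted model allows.
#'
#' @param x count series.
#' @param model an [inar_model()], typically \code{fit$model}.
#' @param lags number of residual autocorrelation lags to report.
#' @return list of class \code{"inar_residuals"} with \code{residuals}
#'   (length T-1), \code{mean}, \code{variance} and \code{acf}.
#' @export
pearson_residuals <- function(x, model, lags = 5L) {
  stopifnot(inherits(model, "inar_model"))
  check_counts(x)
  cm <- inar_cond_moments(model, x[-length(x)])
  e <- (x[-1] - cm$mean) / sqrt(cm$variance)
  ac <- stats::acf(e, lag.max = lags, plot = FALSE)$acf[-1]
  structure(list(residuals = e, mean = mean(e), variance = stats::var(e),
                 acf = as.numeric(ac)),
            class = "inar_residuals")
}

#' @export
print.inar_residuals <- function(x, ...) {
  cat(sprintf("Pearson residuals (n = %d): mean %.4f, variance %.4f\n",
              length(x$residuals), x$mean, x$variance))
  cat("  ACF:", paste(sprintf("%.3f", x$acf), collapse = " "), "\n")
  invisible(x)
}

#' Test a count series for over-dispersion
#'
#' Tests the Poisson INAR(1) null hypothesis (equi-dispersion, DI = 1)
#' against over-dispersion, using the asymptotic normality of the empirical
#' dispersion index of a Poisson INAR(1) process:
#' \eqn{\sqrt{T}(\widehat{DI} - 1) \to N(0,\; 2(1+p^2)/(1-p^2))} with the
#' thinning probability estimated by the (clipped) lag-1 autocorrelation.
#' The returned statistic is the standardized dispersion index and the
#' p-value is one-sided (upper tail).
#'
#' @param x count series, length >= 30 recommended (asymptotic test).
#' @return an object of class \code{"htest"}.
#' @examples
#' set.seed(1)
#' x <- simulate_inar(inar_model(0.5, innovation("poisson", 3)), 200)
#' overdispersion_test(x)
#' @export
overdispersion_test <- function(x) {
  check_counts(x)
  T_ <- length(x)
  if (T_ < 30) warning("asymptotic test; series shorter than 30")
  di <- series_dispersion_index(x)
  p <- min(max(series_acf1(x), 0), 1 - 1e-8)
  sigma2 <- 2 * (1 + p^2) / (1 - p^2)
  z <- sqrt(T_) * (di - 1) / sqrt(sigma2)
  structure(list(statistic = c(z = z),
                 p.value = stats::pnorm(z, lower.tail = FALSE),
                 estimate = c(`dispersion index` = di, `p-hat` = p),
                 alternative = "over-dispersion (dispersion index > 1)",
                 method = "Dispersion-index test against a Poisson INAR(1) null",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' One-step-ahead predictions for an INAR(1) model
#'
#' The first prediction is the unconditional (stationary) process mean; for
#' \eqn{t \ge 2} the prediction is the conditional mean
#' \eqn{\hat p\, x_{t-1} + \hat\mu_\epsilon}.  Predictions are real-valued
#' (not rounded).
#'
#' @param model an [inar_model()].
#' @param x observed count series.
#' @return numeric vector of length \code{length(x)} of one-step predictions.
#' @export
forecast_inar <- function(model, x) {
  stopifnot(inherits(model, "inar_model"))
  check_counts(x)
  c(inar_moments(model)$mean,
    inar_cond_moments(model, x[-length(x)])$mean)
}
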