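# Estimation for iid PQX samples: MLE, method of moments, EM.

#' Log-likelihood and score of an iid PQX sample
#'
#' \code{pqx_loglik} evaluates
#' \deqn{\ell(\alpha,\theta) = \sum_i \log[2\alpha\theta(\theta+1)^2 +
#'   \theta^3(x_i+1)(x_i+2)] - n\log[2(\alpha+1)] -
#'   \log(\theta+1)\sum_i(x_i+3)}
#' which equals \code{sum(dpqx(x, alpha, theta, log = TRUE))}.
#' \code{pqx_score} returns the exact gradient
#' \eqn{(\partial\ell/\partial\alpha, \partial\ell/\partial\theta)}.
#'
#' @param x vector of non-negative integer observations.
#' @inheritParams dpqx
#' @return \code{pqx_loglik} a scalar; \code{pqx_score} a named numeric
#'   vector \code{c(alpha = , theta = )}.
#' @export
pqx_loglik <- function(x, alpha, theta) {
  check_pqx_params(alpha, theta)
  check_counts(x)
  sum(log(2 * alpha * theta * (theta + 1)^2 +
            theta^3 * (x + 1) * (x + 2))) -
    length(x) * log(2 * (alpha + 1)) - log1p(theta) * sum(x + 3)
}

#' @rdname pqx_loglik
#' @export
pqx_score <- function(x, alpha, theta) {
  check_pqx_params(alpha, theta)
  check_counts(x)
  a <- alpha; th <- theta
  den <- 2 * a * th * (th + 1)^2 + th^3 * (x + 1) * (x + 2)
  d_alpha <- sum(2 * th * (th + 1)^2 / den) - length(x) / (a + 1)
  d_theta <- sum((4 * a * (th + 1) * th + 2 * a * (th + 1)^2 +
                    3 * th^2 * (x + 1) * (x + 2)) / den) -
    sum(x + 3) / (th + 1)
  c(alpha = d_alpha, theta = d_theta)
}

# Conditional expectations of the latent mixing rate --------------------------

#' Posterior expectations of the latent rate in the PQX model
#'
#' Under the mixed-Poisson representation each observation carries a latent
#' rate \eqn{\lambda_i}.  Given \eqn{x} and current parameters, the
#' conditional expectations used by the EM algorithm are
#' \itemize{
#'  \item \code{t}: \eqn{E[\lambda^2/(2\alpha + \theta^2\lambda^2) \mid x]},
#'  \item \code{s}: \eqn{E[1/(2\alpha + \theta^2\lambda^2) \mid x]},
#'  \item \code{u}: \eqn{E[\lambda \mid x]},
#'  \item \code{w}: the posterior probability that \eqn{\lambda} came from the
#'    exponential component of the quasi-xgamma mixture
#'    (\code{w = 2 * alpha * s}).
#' }
#' All are available in closed form.
#'
#' @param x vector of non-negative integer observations.
#' @inheritParams dpqx
#' @return list with numeric vectors \code{t}, \code{s}, \code{u}, \code{w}.
#' @export
pqx_posterior_expectations <- function(x, alpha, theta) {
  check_pqx_params(alpha, theta)
  check_counts(x)
  a <- alpha; th <- theta
  den <- 2 * a * (1 + th)^2 + th^2 * (x + 1) * (x + 2)
  t <- (x + 1) * (x + 2) / den
  s <- (1 + th)^2 / den
  u <- (x + 1) * (2 * a * (1 + th)^2 + th^2 * (x + 2) * (x + 3)) /
    ((1 + th) * den)
  list(t = t, s = s, u = u, w = 2 * a * (1 + th)^2 / den)
}

# Method of moments ----------------------------------------------------------

fit_pqx_mm <- function(x) {
  m1 <- mean(x)
  m2 <- mean(x^2)
  root_arg <- 25 * m1^4 + 12 * m1^3 - 12 * m1^2 * m2
  if (root_arg < 0)
    stop("moments incompatible with PQX: negative square-root argument ",
         "25*m1^4 + 12*m1^3 - 12*m1^2*m2 = ", format(root_arg),
         call. = FALSE)
  alpha <- (-7 * m1^2 + sqrt(root_arg) - 3 * (m1 - m2)) /
    (2 * m1^2 + m1 - m2)
  if (is.na(alpha) || alpha < 0)
    stop("moments incompatible with PQX: alpha estimate ", format(alpha),
         " < 0 (sample is under-dispersed for this family)", call. = FALSE)
  theta <- (alpha + 3) / (m1 * (1 + alpha))
  if (theta <= 0)
    stop("moments incompatible with PQX: theta estimate ", format(theta),
         " <= 0", call. = FALSE)
  c(alpha = alpha, theta = theta)
}

#' Asymptotic variance of the moment estimator of theta
#'
#' For fixed \code{alpha} the method-of-moments estimator of \code{theta} is
#' consistent and asymptotically normal:
#' \eqn{\sqrt{n}(\hat\theta - \theta) \to N(0, v^2(\theta))} with
#' \deqn{v^2(\theta) = \theta^2[\alpha(8+\alpha) + (\alpha+1)(\alpha+3)\theta
#'   + 3] / (\alpha+3)^2.}
#' It is also positively biased in finite samples (Jensen's inequality on the
#' strictly convex map from the sample mean).
#'
#' @inheritParams dpqx
#' @return the asymptotic variance \eqn{v^2(\theta)}.
#' @examples
#' pqx_mm_avar(0.5, 1.5)
#' @export
pqx_mm_avar <- function(alpha, theta) {
  check_pqx_params(alpha, theta)
  theta^2 * (alpha * (8 + alpha) + (alpha + 1) * (alpha + 3) * theta + 3) /
    (alpha + 3)^2
}

# EM -------------------------------------------------------------------------

# One EM pass: complete data are (x_i, lambda_i, z_i) with z_i the
# quasi-xgamma mixture-component indicator.  E-step needs w_i = P(z_i = 1 | x)
# and u_i = E[lambda_i | x]; the M-step is then closed form:
#   alpha <- w_bar / (1 - w_bar),   theta <- (3 - 2 w_bar) / u_bar.
fit_pqx_em <- function(x, init, tol = 1e-8, max_iter = 5000) {
  a <- init[["alpha"]]; th <- init[["theta"]]
  ll_old <- pqx_loglik(x, a, th)
  monotone <- TRUE
  converged <- FALSE
  for (h in seq_len(max_iter)) {
    e <- pqx_posterior_expectations(x, a, th)
    wb <- mean(e$w); ub <- mean(e$u)
    if (!is.finite(wb) || wb < 0 || wb >= 1 || !is.finite(ub) || ub <= 0)
      stop("EM numerical failure at iteration ", h,
           ": w_bar = ", format(wb), ", u_bar = ", format(ub), call. = FALSE)
    a_new <- wb / (1 - wb)
    th_new <- (3 - 2 * wb) / ub
    ll <- pqx_loglik(x, a_new, th_new)
    if (ll < ll_old - 1e-8) monotone <- FALSE
    step <- max(abs(c(a_new - a, th_new - th)) / pmax(abs(c(a, th)), 1e-12))
    a <- a_new; th <- th_new; ll_old <- ll
    if (step < tol) { converged <- TRUE; break }
  }
  list(par = c(alpha = a, theta = th), loglik = ll_old,
       converged = converged, iterations = h, monotone = monotone)
}

# MLE ------------------------------------------------------------------------

fit_pqx_mle <- function(x, init) {
  # optimize on the log scale to keep both parameters positive
  nll <- function(lp) -pqx_loglik(x, exp(lp[1]), exp(lp[2]))
  gr <- function(lp) {
    s <- pqx_score(x, exp(lp[1]), exp(lp[2]))
    -s * exp(lp)                          # chain rule d/d log(par)
  }
  lp0 <- log(pmax(c(init[["alpha"]], init[["theta"]]), 1e-6))
  opt <- stats::optim(lp0, nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  par <- exp(opt$par)
  names(par) <- c("alpha", "theta")
  list(par = par, loglik = -opt$value, converged = opt$convergence == 0,
       iterations = opt$counts[["function"]])
}

# observed information on the natural scale, via the Hessian of the negative
# log-likelihood at the estimate
pqx_obs_se <- function(x, par) {
  h <- try(stats::optimHess(par, function(p) {
    if (any(p <= 0)) return(Inf)
    -pqx_loglik(x, p[1], p[2])
  }), silent = TRUE)
  if (inherits(h, "try-error")) return(c(alpha = NA_real_, theta = NA_real_))
  v <- try(solve(h), silent = TRUE)
  if (inherits(v, "try-error") || any(diag(v) <= 0))
    return(c(alpha = NA_real_, theta = NA_real_))
  se <- sqrt(diag(v))
  names(se) <- c("alpha", "theta")
  se
}

#' Fit the PQX distribution to an iid count sample
#'
#' Estimates \code{(alpha, theta)} by maximum likelihood (\code{"mle"},
#' BFGS on log-transformed parameters with the analytic score), the
#' closed-form method of moments (\code{"mm"}) or an EM algorithm
#' (\code{"em"}, exact E- and M-steps under the mixture representation of the
#' latent rate; the observed-data log-likelihood is non-decreasing across
#' iterations).
#'
#' Standard errors for \code{"mle"} and \code{"em"} come from the inverse
#' observed information (numerically differenced Hessian at the estimate);
#' method-of-moments results carry no likelihood-based standard errors.
#' Unless supplied, the optimizer is initialized at the method-of-moments
#' estimate when it is admissible, otherwise at
#' \code{(alpha = 1, theta = 1/mean(x))}.
#'
#' @param x vector of non-negative integer observations, length >= 2.
#' @param method one of \code{"mle"}, \code{"mm"}, \code{"em"}.
#' @param init optional named vector \code{c(alpha = , theta = )} of starting
#'   values.
#' @param conf_level confidence level for the Wald intervals (default 0.95).
#' @param tol EM convergence tolerance on the maximum relative parameter
#'   change.
#' @param max_iter maximum EM iterations.
#' @return an object of class \code{"pqx_fit"}: a list with components
#'   \code{alpha}, \code{theta}, \code{se}, \code{conf_int}, \code{loglik},
#'   \code{method}, \code{converged}, \code{iterations}, \code{n}.
#' @examples
#' set.seed(1)
#' x <- rpqx(500, alpha = 0.5, theta = 1.5)
#' fit_pqx(x, method = "mle")
#' @export
fit_pqx <- function(x, method = c("mle", "mm", "em"), init = NULL,
                    conf_level = 0.95, tol = 1e-8, max_iter = 5000) {
  method <- match.arg(method)
  check_counts(x)
  if (length(x) < 2) stop("need at least two observations", call. = FALSE)
  if (all(x == 0))
    stop("all-zero sample: the likelihood is maximized on the boundary ",
         "theta -> Inf", call. = FALSE)
  if (all(x == x[1]))
    stop("sample is constant: the likelihood is degenerate", call. = FALSE)

  if (is.null(init)) {
    init <- tryCatch(fit_pqx_mm(x),
                     error = function(e) c(alpha = 1, theta = 1 / mean(x)))
  } else {
    init <- c(alpha = unname(init[["alpha"]]), theta = unname(init[["theta"]]))
  }

  res <- switch(method,
    mm = {
      par <- fit_pqx_mm(x)
      list(par = par, loglik = pqx_loglik(x, par[1], par[2]),
           converged = TRUE, iterations = 0L)
    },
    mle = fit_pqx_mle(x, init),
    em = fit_pqx_em(x, init, tol = tol, max_iter = max_iter))

  if (!res$converged && method != "mm")
    warning("estimation did not converge; results are flagged")

  se <- if (method == "mm") c(alpha = NA_real_, theta = NA_real_)
        else pqx_obs_se(x, res$par)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- rbind(alpha = res$par[["alpha"]] + c(-1, 1) * z * se[["alpha"]],
              theta = res$par[["theta"]] + c(-1, 1) * z * se[["theta"]])
  colnames(ci) <- c("lower", "upper")

  structure(list(alpha = res$par[["alpha"]], theta = res$par[["theta"]],
                 se = se, conf_int = ci, loglik = res$loglik,
                 method = toupper(method), converged = res$converged,
                 iterations = res$iterations, n = length(x)),
            class = "pqx_fit")
}

#' @export
print.pqx_fit <- function(x, ...) {
  cat(sprintf("PQX fit (%s), n = %d\n", x$method, x$n))
  est <- data.frame(estimate = c(x$alpha, x$theta), se = x$se,
                    row.names = c("alpha", "theta"))
  print(format(est, digits = 4))
  cat(sprintf("log-likelihood: %.4f   converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}

#' @export
coef.pqx_fit <- function(object, ...) {
  c(alpha = object$alpha, theta = object$theta)
}

#' @export
logLik.pqx_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}
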