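#' @keywords internal
"_PACKAGE"

# Parameter validation -------------------------------------------------------

# alpha = 0 is admitted: the law then reduces to NB(3, theta/(theta+1)).
check_pqx_params <- function(alpha, theta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("'alpha' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0)
    stop("'theta' must be a single positive number", call. = FALSE)
  invisible(TRUE)
}

check_counts <- function(x, what = "x") {
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("'%s' must be numeric and non-missing", what), call. = FALSE)
  if (any(x < 0) || any(x != floor(x)))
    stop(sprintf("'%s' must contain non-negative integers", what),
         call. = FALSE)
  invisible(TRUE)
}

#' The Poisson-quasi-xgamma (PQX) distribution
#'
#' Probability mass function, distribution function, quantile function and
#' random generation for the PQX distribution with shape/mixing parameter
#' \code{alpha} and rate parameter \code{theta}.
#'
#' The PQX law arises by mixing a Poisson rate over a quasi-xgamma
#' distribution, itself a two-component mixture of an exponential(\code{theta})
#' and a gamma(3, \code{theta}) with mixing weight
#' \code{alpha / (alpha + 1)} on the exponential component.  Its pmf is
#' \deqn{P(X = x) = \frac{2\alpha\theta(\theta+1)^2 +
#'   \theta^3 (x+1)(x+2)}{2(\alpha+1)(\theta+1)^{x+3}}, \quad x = 0, 1, \dots}
#' The distribution is always over-dispersed.  \code{alpha = 0} gives the
#' negative binomial NB(3, \eqn{\theta/(\theta+1)}) and \code{alpha ->
#' Inf} the geometric(\eqn{\theta/(\theta+1)}) limit.
#'
#' The survival function is evaluated through the exact closed complement of
#' the cdf in log space, so upper-tail probabilities are accurate at any
#' magnitude (no \code{1 - cdf} cancellation).
#'
#' Random generation uses the mixture representation: with probability
#' \code{alpha/(alpha+1)} the latent rate is exponential(\code{theta}),
#' otherwise gamma(3, \code{theta}); the draw is then Poisson at that rate.
#'
#' @param x,q vector of non-negative integer quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param alpha shape/mixing parameter, \code{alpha >= 0}.
#' @param theta rate parameter, \code{theta > 0}.
#' @param log,log.p logical; if TRUE, probabilities are returned on the log
#'   scale.
#' @param lower.tail logical; if TRUE (default) probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#' @return \code{dpqx} the pmf, \code{ppqx} the cdf (or survival function),
#'   \code{qpqx} quantiles, \code{rpqx} integer draws.
#' @examples
#' dpqx(0:5, alpha = 3, theta = 1.5)
#' ppqx(5, alpha = 3, theta = 1.5, lower.tail = FALSE)
#' qpqx(0.99, alpha = 0.5, theta = 1.5)
#' rpqx(10, alpha = 0.5, theta = 1.5)
#' @export
dpqx <- function(x, alpha, theta, log = FALSE) {
  check_pqx_params(alpha, theta)
  check_counts(x)
  lp <- log(2 * alpha * theta * (theta + 1)^2 +
              theta^3 * (x + 1) * (x + 2)) -
    log(2 * (alpha + 1)) - (x + 3) * log1p(theta)
  if (log) lp else exp(lp)
}

# log survival log P(X > x), exact closed complement of the cdf
pqx_lsurv <- function(x, alpha, theta) {
  log(2 * alpha * (theta + 1)^2 +
        theta * (x + 3) * (theta * (x + 2) + 2) + 2) -
    log(2 * (alpha + 1)) - (x + 3) * log1p(theta)
}

#' @rdname dpqx
#' @export
ppqx <- function(q, alpha, theta, lower.tail = TRUE, log.p = FALSE) {
  check_pqx_params(alpha, theta)
  if (!is.numeric(q) || anyNA(q)) stop("'q' must be numeric", call. = FALSE)
  q <- floor(q)
  ls <- ifelse(q < 0, 0, pqx_lsurv(pmax(q, 0), alpha, theta))
  if (lower.tail) {
    p <- -expm1(ls)
    if (log.p) log(p) else p
  } else {
    if (log.p) ls else exp(ls)
  }
}

#' @rdname dpqx
#' @export
qpqx <- function(p, alpha, theta) {
  check_pqx_params(alpha, theta)
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("'p' must be probabilities in [0, 1]", call. = FALSE)
  vapply(p, function(pp) {
    if (pp <= 0) return(0)
    hi <- 8L
    while (ppqx(hi, alpha, theta) < pp && is.finite(hi)) hi <- hi * 2L
    lo <- 0L
    while (lo < hi) {          # smallest x with F(x) >= pp
      mid <- (lo + hi) %/% 2L
      if (ppqx(mid, alpha, theta) >= pp) hi <- mid else lo <- mid + 1L
    }
    as.numeric(lo)
  }, numeric(1))
}

#' @rdname dpqx
#' @export
rpqx <- function(n, alpha, theta) {
  check_pqx_params(alpha, theta)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  lam <- ifelse(stats::runif(n) < alpha / (alpha + 1),
                stats::rexp(n, rate = theta),
                stats::rgamma(n, shape = 3, rate = theta))
  stats::rpois(n, lam)
}

# Mean parametrization -------------------------------------------------------

#' Mean parametrization of the PQX distribution
#'
#' The PQX law can be rewritten so that one parameter is exactly the mean
#' \code{mu}, via the substitution
#' \eqn{\alpha = (3 - \theta\mu) / (\theta\mu - 1)}, valid for
#' \eqn{1 < \theta\mu < 3}.  This enables like-for-like tail and shape
#' comparisons with the mean-parametrized negative binomial
#' (\code{prob = mu / (mu + size)}, i.e. \code{dnbinom(x, size, mu = mu)}).
#'
#' @param mu mean, \code{mu > 0}.
#' @param theta rate parameter, \code{theta > 0}, with
#'   \code{1 < theta * mu < 3}.
#' @inheritParams dpqx
#' @return \code{pqx_alpha_from_mean} the implied \code{alpha};
#'   \code{dpqx_mean} and \code{ppqx_mean} the pmf and cdf of the
#'   mean-parametrized law.
#' @examples
#' pqx_alpha_from_mean(1, 1.5)   # 3
#' ppqx_mean(5, mu = 1, theta = 1.5, lower.tail = FALSE)
#' @export
pqx_alpha_from_mean <- function(mu, theta) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0)
    stop("'mu' must be a single positive number", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0)
    stop("'theta' must be a single positive number", call. = FALSE)
  tm <- theta * mu
  if (tm <= 1 || tm >= 3)
    stop("mean parametrization requires 1 < theta * mu < 3 (got theta * mu = ",
         format(tm), ")", call. = FALSE)
  (3 - tm) / (tm - 1)
}

#' @rdname pqx_alpha_from_mean
#' @export
dpqx_mean <- function(x, mu, theta, log = FALSE) {
  dpqx(x, pqx_alpha_from_mean(mu, theta), theta, log = log)
}

#' @rdname pqx_alpha_from_mean
#' @export
ppqx_mean <- function(q, mu, theta, lower.tail = TRUE, log.p = FALSE) {
  ppqx(q, pqx_alpha_from_mean(mu, theta), theta,
       lower.tail = lower.tail, log.p = log.p)
}

# Moments --------------------------------------------------------------------

#' Moments and shape measures of the PQX distribution
#'
#' \code{pqx_fmoment} returns the r-th factorial moment
#' \eqn{E[X(X-1)\cdots(X-r+1)] = [\Gamma(r+3) + 2\alpha\Gamma(r+1)] /
#' [2\theta^r(\alpha+1)]}.  \code{pqx_moments} returns the mean, variance,
#' dispersion index (always > 1), skewness and kurtosis in closed form.
#'
#' @param r order of the factorial moment, a positive integer.
#' @inheritParams dpqx
#' @return \code{pqx_fmoment} a scalar; \code{pqx_moments} a list with
#'   components \code{mean}, \code{variance}, \code{dispersion_index},
#'   \code{skewness}, \code{kurtosis}.
#' @examples
#' pqx_fmoment(1, alpha = 0.5, theta = 1.5)  # the mean
#' pqx_moments(alpha = 0.5, theta = 1.5)
#' @export
pqx_fmoment <- function(r, alpha, theta) {
  check_pqx_params(alpha, theta)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 1 || r != floor(r))
    stop("'r' must be a positive integer", call. = FALSE)
  (gamma(r + 3) + 2 * alpha * gamma(r + 1)) / (2 * theta^r * (alpha + 1))
}

#' @rdname pqx_fmoment
#' @export
pqx_moments <- function(alpha, theta) {
  check_pqx_params(alpha, theta)
  a <- alpha; th <- theta
  m <- (a + 3) / (th * (a + 1))
  v <- (a^2 + (a + 1) * (a + 3) * th + 8 * a + 3) / ((a + 1)^2 * th^2)
  di <- 1 + (a * (a + 8) + 3) / ((a + 1) * (a + 3) * th)
  core <- 8 * a + 3 * th + 4 * a * th + a^2 * th + a^2 + 3
  skew <- (a^3 * th^2 + 3 * a^3 * th + 2 * a^3 + 5 * a^2 * th^2 +
             27 * a^2 * th + 30 * a^2 + 7 * a * th^2 + 33 * a * th +
             18 * a + 3 * th^2 + 9 * th + 6) / core^1.5
  kurt <- (a^4 * th^3 + 10 * a^4 * th^2 + 18 * a^4 * th + 9 * a^4 +
             6 * a^3 * th^3 + 94 * a^3 * th^2 + 264 * a^3 * th + 192 * a^3 +
             12 * a^2 * th^3 + 206 * a^2 * th^2 + 516 * a^2 * th + 306 * a^2 +
             10 * a * th^3 + 170 * a * th^2 + 360 * a * th + 216 * a +
             3 * th^3 + 48 * th^2 + 90 * th + 45) / core^2
  list(mean = m, variance = v, dispersion_index = di,
       skewness = skew, kurtosis = kurt)
}

#' Generating functions of the PQX distribution
#'
#' Probability generating function \eqn{G(s) = E[s^X]} and moment generating
#' function \eqn{M(t) = G(e^t)}.  The mgf diverges for
#' \eqn{e^t \ge \theta + 1}.
#'
#' @param s argument of the pgf, \code{|s| <= 1}.
#' @param t argument of the mgf, with \code{exp(t) < theta + 1}.
#' @inheritParams dpqx
#' @return the generating function value(s).
#' @examples
#' pqx_pgf(1, 0.5, 1.5)      # 1
#' pqx_pgf(0, 0.5, 1.5)      # pmf at zero
#' @export
pqx_pgf <- function(s, alpha, theta) {
  check_pqx_params(alpha, theta)
  if (any(abs(s) > 1)) stop("pgf requires |s| <= 1", call. = FALSE)
  theta / (1 + alpha) *
    (theta^2 / (theta - s + 1)^3 + alpha / (theta - s + 1))
}

#' @rdname pqx_pgf
#' @export
pqx_mgf <- function(t, alpha, theta) {
  check_pqx_params(alpha, theta)
  if (any(exp(t) >= theta + 1))
    stop("mgf diverges for exp(t) >= theta + 1", call. = FALSE)
  s <- exp(t)
  theta / (1 + alpha) *
    (theta^2 / (theta - s + 1)^3 + alpha / (theta - s + 1))
}

# Modality -------------------------------------------------------------------

#' Classify the shape of a PQX distribution
#'
#' The ratio of successive probabilities \eqn{P(X=x+1)/P(X=x)} exceeds 1
#' exactly on the interval between the two roots of a concave quadratic, so
#' the pmf can be increasing on an interior window.  Depending on where that
#' window sits the law is unimodal at zero, unimodal with an interior mode at
#' \eqn{\lceil x_0^{**}\rceil}, bimodal with local modes at 0 and
#' \eqn{\lceil x_0^{**}\rceil}, or (on a boundary curve of the parameter
#' space) has tied modes at 0 and 1.
#'
#' When \eqn{x_0^{**}} is an exact integer the ratio equals one there and two
#' adjacent support points carry equal probability; both are reported as
#' modes.
#'
#' @inheritParams dpqx
#' @return a list of class \code{"pqx_modality"} with components
#'   \code{category} (one of \code{"unimodal-at-zero"}, \code{"mode-at-one"},
#'   \code{"unimodal-interior"}, \code{"bimodal"}), \code{modes} (integer
#'   vector of local modes) and \code{x_star} (the upper root
#'   \eqn{x_0^{**}}, \code{NA} when the ratio never reaches 1).
#' @examples
#' pqx_modality(1, 2.5)      # unimodal at zero
#' pqx_modality(0.25, 1)     # tied modes at 0 and 1
#' pqx_modality(0.34, 0.5)   # bimodal
#' @export
pqx_modality <- function(alpha, theta) {
  check_pqx_params(alpha, theta)
  a <- alpha; th <- theta
  # pmf increasing at integer x iff q(x) > 0 where
  # q(x) = (2+x)(3+x) th^2 + 2 a (1+th)^2 - (1+th)[(1+x)(2+x) th^2 + 2a(1+th)^2]
  # q is a concave quadratic with roots x0* <= x0**.
  disc <- 1 - 8 * a * ((1 + th) / (2 + th))^2
  x_lo <- x_hi <- NA_real_
  if (disc >= 0) {
    x_lo <- (2 - 3 * th) / (2 * th) - (th + 2) / (2 * th) * sqrt(disc)
    x_hi <- (2 - 3 * th) / (2 * th) + (th + 2) / (2 * th) * sqrt(disc)
  }
  # sign of P(X=x+1) - P(X=x), up to a positive factor; exact polynomial
  # arithmetic, so ties are detected exactly rather than through the pmf
  up <- function(x)
    (2 + x) * (3 + x) * th^2 + 2 * a * (1 + th)^2 -
    (1 + th) * ((1 + x) * (2 + x) * th^2 + 2 * a * (1 + th)^2)
  # the pmf is strictly decreasing beyond x_hi; scan the finite window for
  # weak local maxima (tied plateau points are all reported)
  top <- if (is.na(x_hi) || x_hi < 0) 1L else as.integer(ceiling(x_hi)) + 2L
  modes <- integer(0)
  for (m in 0:top) {
    left_ok <- if (m == 0L) TRUE else up(m - 1) >= 0
    if (left_ok && up(m) <= 0) modes <- c(modes, m)
  }
  category <- if (identical(modes, 0L)) "unimodal-at-zero"
  else if (identical(modes, c(0L, 1L))) "mode-at-one"
  else if (0L %in% modes) "bimodal"
  else "unimodal-interior"
  structure(list(category = category, modes = modes, x_star = x_hi),
            class = "pqx_modality")
}

#' @export
print.pqx_modality <- function(x, ...) {
  cat("PQX shape:", x$category, "\n")
  cat("  modes:", paste(x$modes, collapse = ", "), "\n")
  if (!is.na(x$x_star)) cat("  upper ratio root x0** =", format(x$x_star), "\n")
  invisible(x)
}

# Negative binomial reference ------------------------------------------------

#' Closed-form moments of the negative binomial reference family
#'
#' The NB law with dispersion parameter \code{size} and success probability
#' \code{prob} (pmf \eqn{\Gamma(y+size)/[\Gamma(y+1)\Gamma(size)]
#' (1-p)^{size} p^y}) is the standard benchmark for over-dispersed counts;
#' its pmf/cdf/rng are available as \code{stats::dnbinom(y, size, 1 - prob)}
#' etc.  This helper returns the textbook mean, variance, skewness and
#' kurtosis used for shape comparisons; for the mean-parametrized version use
#' \code{stats::dnbinom(y, size, mu = mu)}.
#'
#' @param size dispersion parameter, > 0.
#' @param prob success probability in (0, 1).
#' @return list with \code{mean}, \code{variance}, \code{dispersion_index},
#'   \code{skewness}, \code{kurtosis}.
#' @examples
#' nb_moments(0.5, 0.5)$skewness   # 3
#' @export
nb_moments <- function(size, prob) {
  if (size <= 0 || prob <= 0 || prob >= 1)
    stop("'size' must be > 0 and 'prob' in (0, 1)", call. = FALSE)
  list(mean = size * prob / (1 - prob),
       variance = size * prob / (1 - prob)^2,
       dispersion_index = 1 / (1 - prob),
       skewness = (1 + prob) / sqrt(size * prob),
       kurtosis = 3 + 6 / size + (1 - prob)^2 / (size * prob))
}
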