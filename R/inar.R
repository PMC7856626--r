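# INAR(1) machinery: binomial thinning, simulation, transition probabilities
# and exact process moments, generic in the innovation law.

#' Binomial thinning
#'
#' The thinning operator of integer-valued autoregression:
#' \eqn{p \circ x = \sum_{j=1}^{x} Z_j} with iid Bernoulli(\code{p}) counting
#' variables, i.e. a binomial(\code{x}, \code{p}) draw.  Thinning of zero is
#' zero.
#'
#' @param x vector of non-negative integers.
#' @param p thinning probability in [0, 1].
#' @return integer vector of thinned values, one per element of \code{x}.
#' @examples
#' rthin(c(0, 10, 20), 0.3)
#' @export
rthin <- function(x, p) {
  check_counts(x)
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a probability in [0, 1]", call. = FALSE)
  stats::rbinom(length(x), x, p)
}

#' Specify an INAR(1) model
#'
#' An INAR(1) process follows the recursion
#' \eqn{X_t = p \circ X_{t-1} + \epsilon_t}, a homogeneous Markov chain on
#' the non-negative integers; \eqn{\circ} is binomial thinning and the
#' innovations \eqn{\epsilon_t} are iid from \code{law}.  The process is
#' stationary for \eqn{0 \le p < 1}.
#'
#' @param p thinning (autoregression) probability in [0, 1).
#' @param law an [innovation()] law.
#' @return object of class \code{"inar_model"}.
#' @examples
#' m <- inar_model(0.3, innovation("pqx", alpha = 0.5, theta = 0.5))
#' inar_moments(m)
#' @export
inar_model <- function(p, law) {
  if (length(p) != 1L || is.na(p) || p < 0 || p >= 1)
    stop("'p' must lie in [0, 1): the process is non-stationary at p = 1",
         call. = FALSE)
  stopifnot(inherits(law, "innovation"))
  structure(list(p = p, innovation = law), class = "inar_model")
}

#' @export
print.inar_model <- function(x, ...) {
  cat(sprintf("INAR(1) model: thinning p = %.4f\n", x$p))
  print(x$innovation)
  mom <- inar_moments(x)
  cat(sprintf("  process mean %.4f, variance %.4f, DI %.4f\n",
              mom$mean, mom$variance, mom$dispersion_index))
  invisible(x)
}

#' Simulate an INAR(1) path
#'
#' Iterates thinning plus an innovation draw.  The chain is started from an
#' innovation draw and a burn-in is discarded, which (with geometric mixing
#' at rate \code{p}) makes the retained path effectively stationary.
#'
#' @param model an [inar_model()].
#' @param n length of the returned series.
#' @param burn_in number of initial steps to discard (default 500).
#' @return integer vector of length \code{n}.
#' @examples
#' m <- inar_model(0.3, innovation("poisson", lambda = 2))
#' set.seed(1)
#' x <- simulate_inar(m, 200)
#' @export
simulate_inar <- function(model, n, burn_in = 500) {
  stopifnot(inherits(model, "inar_model"))
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  n <- as.integer(n); burn_in <- as.integer(burn_in)
  eps <- model$innovation$sample(n + burn_in)
  out <- integer(n + burn_in)
  x <- model$innovation$sample(1L)
  for (t in seq_len(n + burn_in)) {
    x <- stats::rbinom(1L, x, model$p) + eps[t]
    out[t] <- x
  }
  out[(burn_in + 1L):(burn_in + n)]
}

#' One-step transition probabilities of an INAR(1) chain
#'
#' \deqn{P(X_t = k \mid X_{t-1} = l) = \sum_{i=0}^{\min(k,l)}
#'   \binom{l}{i} p^i (1-p)^{l-i}\, P(\epsilon = k - i).}
#' Each row (fixed \code{l}) is a proper distribution over \code{k}.
#' Evaluation is by log-sum-exp over the thinning convolution, so the
#' log-scale values remain usable at large counts.
#'
#' @param model an [inar_model()].
#' @param k vector of arrival states (non-negative integers).
#' @param l vector of departure states, recycled against \code{k}.
#' @param log logical; return log probabilities?
#' @return numeric vector of (log) transition probabilities.
#' @examples
#' m <- inar_model(0.4, innovation("poisson", lambda = 1))
#' inar_transition(m, k = 2, l = 3)
#' sum(inar_transition(m, k = 0:50, l = 3))  # 1
#' @export
inar_transition <- function(model, k, l, log = FALSE) {
  stopifnot(inherits(model, "inar_model"))
  check_counts(k, "k"); check_counts(l, "l")
  nn <- max(length(k), length(l))
  k <- rep_len(k, nn); l <- rep_len(l, nn)
  lp <- inar_trans_lp(k, l, model$p, model$innovation$logpmf)
  if (log) lp else exp(lp)
}

# vectorized log transition probability; shared with the CML objective.
# builds the (pair x i) matrix of log binomial-thinning terms plus innovation
# log-pmf and reduces by log-sum-exp.
inar_trans_lp <- function(k, l, p, logpmf) {
  m <- pmin(k, l)
  imax <- max(m)
  lt <- matrix(-Inf, nrow = length(k), ncol = imax + 1L)
  for (i in 0:imax) {
    act <- m >= i
    if (!any(act)) break
    lt[act, i + 1L] <- stats::dbinom(i, l[act], p, log = TRUE) +
      logpmf(k[act] - i)
  }
  mx <- apply(lt, 1L, max)
  mx + log(rowSums(exp(lt - mx)))
}

#' Stationary moments of an INAR(1) process
#'
#' Mean \eqn{\mu_\epsilon/(1-p)}, variance
#' \eqn{(p\mu_\epsilon + \sigma^2_\epsilon)/(1-p^2)} and dispersion index
#' \eqn{(DI_\epsilon + p)/(1+p)} of the stationary process, in terms of the
#' innovation moments.  With Poisson innovations the process stays
#' equi-dispersed (DI = 1) for every \code{p}.
#'
#' @param model an [inar_model()].
#' @return list with \code{mean}, \code{variance}, \code{dispersion_index}.
#' @export
inar_moments <- function(model) {
  stopifnot(inherits(model, "inar_model"))
  p <- model$p
  mu <- model$innovation$mean
  s2 <- model$innovation$variance
  list(mean = mu / (1 - p),
       variance = (p * mu + s2) / (1 - p^2),
       dispersion_index = (s2 / mu + p) / (1 + p))
}

#' Closed-form stationary moments of the INARPQX(1) process
#'
#' With PQX(\code{alpha}, \code{theta}) innovations the stationary mean,
#' variance and dispersion index have the closed forms
#' \deqn{\mu_X = \frac{\alpha+3}{\theta(\alpha+1)(1-p)}, \quad
#'   DI_X = 1 + \frac{\alpha(\alpha+8)+3}
#'   {\theta(\alpha+1)(\alpha+3)(1+p)},}
#' identical to the generic [inar_moments()] composed with [pqx_moments()].
#'
#' @param p thinning probability in [0, 1).
#' @inheritParams dpqx
#' @return list with \code{mean}, \code{variance}, \code{dispersion_index}.
#' @examples
#' inarpqx_moments(0.461, 94.964, 0.238)
#' @export
inarpqx_moments <- function(p, alpha, theta) {
  check_pqx_params(alpha, theta)
  a <- alpha; th <- theta
  list(mean = (a + 3) / (th * (a + 1) * (1 - p)),
       variance = (a^2 * (th + th * p + 1) + 4 * a * (th + th * p + 2) +
                     3 * (th + th * p + 1)) / (th^2 * (a + 1)^2 * (1 - p^2)),
       dispersion_index = 1 + (a * (a + 8) + 3) /
         (th * (a + 1) * (a + 3) * (1 + p)))
}

#' Conditional mean and variance of an INAR(1) process
#'
#' Given the previous count, \eqn{E[X_t \mid x_{t-1}] = p\,x_{t-1} +
#' \mu_\epsilon} and \eqn{Var[X_t \mid x_{t-1}] = p(1-p)\,x_{t-1} +
#' \sigma^2_\epsilon}.  These equal the mean and variance of the transition
#' row at \code{x_prev} and drive both the Pearson residuals and one-step
#' forecasting.
#'
#' @param model an [inar_model()].
#' @param x_prev vector of previous counts.
#' @return list with numeric vectors \code{mean} and \code{variance}.
#' @export
inar_cond_moments <- function(model, x_prev) {
  stopifnot(inherits(model, "inar_model"))
  check_counts(x_prev, "x_prev")
  p <- model$p
  list(mean = p * x_prev + model$innovation$mean,
       variance = p * (1 - p) * x_prev + model$innovation$variance)
}
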