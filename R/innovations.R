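# Innovation laws for the INAR(1) layer.  Each family is registered as a
# constructor returning a common contract (log-pmf, moments, sampler), so the
# process machinery is family-agnostic and new families can be plugged in.

.inn_registry <- new.env(parent = emptyenv())

#' Register an innovation family
#'
#' Adds a family to the open registry used by [innovation()].  The
#' constructor receives the family parameters and must return a list with
#' components \code{params} (named numeric), \code{logpmf} (function of a
#' non-negative integer vector), \code{mean}, \code{variance} (scalars) and
#' \code{sample} (function of \code{n}).  The INAR layer never looks past
#' this contract.
#'
#' @param name family identifier (string).
#' @param constructor function building the law from its parameters.
#' @return invisibly, the name.
#' @export
register_innovation_family <- function(name, constructor) {
  stopifnot(is.character(name), length(name) == 1L, is.function(constructor))
  assign(name, constructor, envir = .inn_registry)
  invisible(name)
}

#' List registered innovation families
#' @return character vector of family names.
#' @export
innovation_families <- function() sort(ls(.inn_registry))

#' Construct an innovation law
#'
#' Builds the distribution of the arrival term of an INAR(1) process.
#' Built-in families and their parameters:
#' \describe{
#'   \item{\code{"pqx"}}{\code{alpha >= 0}, \code{theta > 0} (see [dpqx()]).}
#'   \item{\code{"poisson"}}{\code{lambda > 0}.}
#'   \item{\code{"poisson_lindley"}}{\code{theta > 0}; pmf
#'     \eqn{\theta^2 (k+\theta+2) / (\theta+1)^{k+3}}.}
#'   \item{\code{"geometric"}}{success probability \code{prob} in (0,1); pmf
#'     \eqn{p(1-p)^k} on k = 0, 1, ...}
#'   \item{\code{"nb"}}{\code{size > 0}, \code{prob} in (0,1); pmf
#'     \eqn{\binom{size+k-1}{k} (1-p)^k p^{size}}.}
#' }
#'
#' @param family family name; see [innovation_families()].
#' @param ... family parameters, passed to the registered constructor.
#' @return an object of class \code{"innovation"} with components
#'   \code{family}, \code{params}, \code{logpmf}, \code{mean},
#'   \code{variance}, \code{dispersion_index}, \code{sample}.
#' @examples
#' law <- innovation("pqx", alpha = 0.5, theta = 1.5)
#' innovation_pmf(law, 0:5)
#' law$mean
#' @export
innovation <- function(family, ...) {
  if (!exists(family, envir = .inn_registry, inherits = FALSE))
    stop("unknown innovation family '", family, "'; registered: ",
         paste(innovation_families(), collapse = ", "), call. = FALSE)
  ctor <- get(family, envir = .inn_registry)
  law <- ctor(...)
  law$family <- family
  law$dispersion_index <- law$variance / law$mean
  class(law) <- "innovation"
  law
}

#' Evaluate an innovation pmf
#' @param law an [innovation()] object.
#' @param k vector of non-negative integers.
#' @param log logical; return log probabilities?
#' @return numeric vector of (log) probabilities.
#' @export
innovation_pmf <- function(law, k, log = FALSE) {
  stopifnot(inherits(law, "innovation"))
  check_counts(k, "k")
  lp <- law$logpmf(k)
  if (log) lp else exp(lp)
}

#' @export
print.innovation <- function(x, ...) {
  cat(sprintf("innovation law '%s' (%s)\n", x$family,
              paste(names(x$params), signif(x$params, 4),
                    sep = " = ", collapse = ", ")))
  cat(sprintf("  mean %.4f, variance %.4f, dispersion index %.4f\n",
              x$mean, x$variance, x$dispersion_index))
  invisible(x)
}

# Built-in families ------------------------------------------------------------

register_innovation_family("pqx", function(alpha, theta) {
  check_pqx_params(alpha, theta)
  mom <- pqx_moments(alpha, theta)
  list(params = c(alpha = alpha, theta = theta),
       logpmf = function(k) dpqx(k, alpha, theta, log = TRUE),
       mean = mom$mean, variance = mom$variance,
       sample = function(n) rpqx(n, alpha, theta))
})

register_innovation_family("poisson", function(lambda) {
  stopifnot(length(lambda) == 1L, lambda > 0)
  list(params = c(lambda = lambda),
       logpmf = function(k) stats::dpois(k, lambda, log = TRUE),
       mean = lambda, variance = lambda,
       sample = function(n) stats::rpois(n, lambda))
})

register_innovation_family("poisson_lindley", function(theta) {
  stopifnot(length(theta) == 1L, theta > 0)
  # Poisson mixed over a Lindley(theta) rate; Lindley is the mixture
  # theta/(theta+1) * Exp(theta) + 1/(theta+1) * Gamma(2, theta)
  m <- (theta + 2) / (theta * (theta + 1))
  v <- m + (theta^2 + 4 * theta + 2) / (theta^2 * (theta + 1)^2)
  list(params = c(theta = theta),
       logpmf = function(k)
         2 * log(theta) + log(k + theta + 2) - (k + 3) * log1p(theta),
       mean = m, variance = v,
       sample = function(n) {
         lam <- ifelse(stats::runif(n) < theta / (theta + 1),
                       stats::rexp(n, theta),
                       stats::rgamma(n, shape = 2, rate = theta))
         stats::rpois(n, lam)
       })
})

register_innovation_family("geometric", function(prob) {
  stopifnot(length(prob) == 1L, prob > 0, prob < 1)
  list(params = c(prob = prob),
       logpmf = function(k) stats::dgeom(k, prob, log = TRUE),
       mean = (1 - prob) / prob, variance = (1 - prob) / prob^2,
       sample = function(n) stats::rgeom(n, prob))
})

register_innovation_family("nb", function(size, prob) {
  stopifnot(length(size) == 1L, size > 0,
            length(prob) == 1L, prob > 0, prob < 1)
  list(params = c(size = size, prob = prob),
       logpmf = function(k) stats::dnbinom(k, size = size, prob = prob,
                                           log = TRUE),
       mean = size * (1 - prob) / prob,
       variance = size * (1 - prob) / prob^2,
       sample = function(n) stats::rnbinom(n, size = size, prob = prob))
})
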