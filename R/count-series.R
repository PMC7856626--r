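# Count-series utilities: sample-moment accessors, readers/writers and the
# synthetic fixture generator.

#' Sample moments of a count series
#'
#' \code{series_dispersion_index} is the ratio of the sample variance
#' (divisor T) to the sample mean.  \code{series_acf1} is the lag-1
#' autocorrelation in the moment-estimator form used by Yule-Walker fitting:
#' \eqn{\sum_{t=2}^T (x_t-\bar x)(x_{t-1}-\bar x) /
#'   \sum_{t=1}^T (x_t-\bar x)^2.}
#'
#' @param x vector of non-negative integer counts, length >= 2.
#' @return a scalar.
#' @export
series_dispersion_index <- function(x) {
  check_counts(x)
  if (length(x) < 2) stop("need at least two observations", call. = FALSE)
  m <- mean(x)
  mean((x - m)^2) / m
}

#' @rdname series_dispersion_index
#' @export
series_acf1 <- function(x) {
  check_counts(x)
  if (length(x) < 2) stop("need at least two observations", call. = FALSE)
  m <- mean(x)
  d <- x - m
  sum(d[-1] * d[-length(x)]) / sum(d^2)
}

#' Read and write count series
#'
#' Series are stored as single-column CSV or whitespace-delimited text, one
#' count per line, with one optional header line.  Blank lines are ignored.
#' Negative, fractional or non-numeric entries raise a parse error naming the
#' offending line.
#'
#' @param path file path.
#' @param x vector of non-negative integer counts.
#' @param header for \code{write_count_series}, an optional column name to
#'   write as a header line (\code{NULL} for none).
#' @return \code{read_count_series} an integer vector;
#'   \code{write_count_series} invisibly, the path.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_count_series(c(3L, 5L, 2L), f, header = "count")
#' read_count_series(f)
#' @export
read_count_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0) stop("no data in ", path, call. = FALSE)
  vals <- trimws(lines[keep])
  start <- 1L
  if (suppressWarnings(is.na(as.numeric(vals[1])))) start <- 2L  # header
  if (start > length(vals)) stop("no data rows in ", path, call. = FALSE)
  out <- integer(length(vals) - start + 1L)
  for (j in seq_along(out)) {
    v <- suppressWarnings(as.numeric(vals[start + j - 1L]))
    line_no <- keep[start + j - 1L]
    if (is.na(v))
      stop("line ", line_no, ": not a number ('", vals[start + j - 1L], "')",
           call. = FALSE)
    if (v < 0) stop("line ", line_no, ": negative count", call. = FALSE)
    if (v != floor(v))
      stop("line ", line_no, ": fractional value ", v, call. = FALSE)
    out[j] <- as.integer(v)
  }
  out
}

#' @rdname read_count_series
#' @export
write_count_series <- function(x, path, header = NULL) {
  check_counts(x)
  lines <- as.character(as.integer(x))
  if (!is.null(header)) lines <- c(header, lines)
  writeLines(lines, path)
  invisible(path)
}

#' Generate synthetic count-series fixtures
#'
#' Seeded generators for the data settings the package is exercised on.
#' \code{"earthquake-like"} simulates an INARPQX(1) process at
#' \code{p = 0.461}, \code{alpha = 94.964}, \code{theta = 0.238}: a
#' stationary, strongly over-dispersed monthly-count regime (long-run mean
#' about 7.95, dispersion index about 3.99, lag-1 autocorrelation 0.461)
#' emulating a monthly earthquake-frequency series.  It is a synthetic
#' stand-in: the original catalog counts are not redistributed.
#' \code{"iid-pqx"} draws an iid PQX sample (defaults
#' \code{alpha = 0.5, theta = 1.5}); \code{"custom"} simulates a
#' user-supplied [inar_model()].
#'
#' @param kind one of \code{"earthquake-like"}, \code{"iid-pqx"},
#'   \code{"custom"}.
#' @param n series length, >= 2.
#' @param alpha,theta PQX parameters for \code{kind = "iid-pqx"}.
#' @param model an [inar_model()] for \code{kind = "custom"}.
#' @return integer vector of counts.
#' @examples
#' set.seed(1)
#' x <- generate_fixture("earthquake-like", 82)
#' mean(x); series_dispersion_index(x)
#' @export
generate_fixture <- function(kind = c("earthquake-like", "iid-pqx", "custom"),
                             n, alpha = 0.5, theta = 1.5, model = NULL) {
  kind <- match.arg(kind)
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  switch(kind,
    "earthquake-like" = simulate_inar(
      inar_model(0.461, innovation("pqx", alpha = 94.964, theta = 0.238)), n),
    "iid-pqx" = rpqx(n, alpha, theta),
    "custom" = {
      if (!inherits(model, "inar_model"))
        stop("'model' must be an inar_model for kind = 'custom'",
             call. = FALSE)
      simulate_inar(model, n)
    })
}
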