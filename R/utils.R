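`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @keywords internal
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

## symmetric PD check via Cholesky; tol guards tiny asymmetries from arithmetic
is_pd <- function(m, tol = 1e-10) {
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) return(FALSE)
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  ok
}

## log-determinant of a PD matrix from its Cholesky factor; NA if not PD
logdet_pd <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  2 * sum(log(diag(ch)))
}

stop_nrsem <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_nrsem <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
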