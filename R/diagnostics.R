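## Pre-model data diagnostics: multivariate normality, outliers, sampling
## adequacy, clustering, common-method bias.

check_numeric_matrix <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m)) stop_nrsem("data must be numeric")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  m
}

#' Mardia's multivariate kurtosis with critical ratio
#'
#' b2p is the mean of squared Mahalanobis distances of each observation from
#' the centroid; under multivariate normality its expectation is p(p + 2)
#' and the critical ratio (b2p - p(p + 2)) / sqrt(8 p (p + 2) / n) is
#' asymptotically standard normal. The non-normality verdict applies the
#' screening rule used with SEM: kurtosis above 7 together with a critical
#' ratio above 5.
#'
#' @param data numeric matrix/data.frame (rows with NA dropped).
#' @return list with `b2p`, `expected`, `cr`, `n`, `p`, `nonnormal`.
#' @export
mardia_kurtosis <- function(data) {
  m <- check_numeric_matrix(data)
  n <- nrow(m); p <- ncol(m)
  if (n <= p) stop_nrsem("need n > p (n = %d, p = %d)", n, p)
  S <- stats::cov(m)                      # n - 1 denominator
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    sds <- sqrt(diag(S))
    cn <- colnames(m) %||% paste0("V", seq_len(p))
    stop_nrsem("singular covariance matrix; near-constant/collinear columns: %s",
               paste(cn[sds < 1e-10], collapse = ", "))
  }
  d2 <- stats::mahalanobis(m, colMeans(m), S)
  b2p <- mean(d2^2)
  expected <- p * (p + 2)
  cr <- (b2p - expected) / sqrt(8 * p * (p + 2) / n)
  list(b2p = b2p, expected = expected, excess = b2p - expected, cr = cr,
       n = n, p = p, nonnormal = b2p > 7 && cr > 5)
}

#' Multivariate outliers by Mahalanobis distance
#'
#' Squared Mahalanobis distance per record, upper-tail chi-square p-value
#' with df = number of variables, and a flag at `alpha`.
#'
#' @param data numeric matrix/data.frame; rows with any NA get NA distance.
#' @param alpha flagging level (default 0.001).
#' @return list with per-record `d2`, `p`, logical `flag`, and `n_flagged`.
#' @export
mahalanobis_outliers <- function(data, alpha = 0.001) {
  m <- as.matrix(data)
  cc <- stats::complete.cases(m)
  mc <- m[cc, , drop = FALSE]
  p <- ncol(mc)
  S <- stats::cov(mc)
  if (!is_pd(S)) stop_nrsem("singular covariance matrix")
  d2 <- rep(NA_real_, nrow(m))
  d2[cc] <- stats::mahalanobis(mc, colMeans(mc), S)
  pv <- stats::pchisq(d2, df = p, lower.tail = FALSE)
  flag <- !is.na(pv) & pv < alpha
  list(d2 = d2, p = pv, flag = flag, n_flagged = sum(flag),
       df = p, alpha = alpha)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Contrasts zero-order correlations r with anti-image partial correlations
#' q: KMO = sum r^2 / (sum r^2 + sum q^2) over distinct pairs, overall and
#' per variable. For two variables the partials equal the marginals, so KMO
#' is exactly 0.5.
#'
#' @param data numeric data (rows with NA dropped) or a correlation matrix.
#' @return list with `overall` and per-variable `msa`.
#' @export
kmo <- function(data) {
  R <- if (is.matrix(data) && nrow(data) == ncol(data) &&
           max(abs(diag(data) - 1)) < 1e-8) data
       else stats::cor(check_numeric_matrix(data))
  p <- ncol(R)
  if (p < 2) stop_nrsem("need at least 2 variables")
  Rinv <- tryCatch(solve(R), error = function(e)
    stop_nrsem("correlation matrix is not invertible"))
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * tcrossprod(d)              # partial correlations (off-diagonal)
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  overall <- sum(R0^2) / (sum(R0^2) + sum(Q^2))
  msa <- colSums(R0^2) / (colSums(R0^2) + colSums(Q^2))
  names(msa) <- colnames(R)
  list(overall = overall, msa = msa)
}

#' Bartlett's test of sphericity
#'
#' Tests a correlation matrix against the identity:
#' chi-square = -(n - 1 - (2p + 5)/6) * log|R| with df = p(p - 1)/2.
#'
#' @param R correlation matrix (or raw data, from which it is computed).
#' @param n sample size (required when `R` is a correlation matrix).
#' @return list with `chisq`, `df`, `p`.
#' @export
bartlett_sphericity <- function(R, n = NULL) {
  if (!(is.matrix(R) && nrow(R) == ncol(R) && max(abs(diag(R) - 1)) < 1e-8)) {
    m <- check_numeric_matrix(R)
    n <- nrow(m)
    R <- stats::cor(m)
  }
  if (is.null(n)) stop_nrsem("n is required with a correlation matrix input")
  p <- ncol(R)
  ld <- logdet_pd(R)
  if (is.na(ld)) stop_nrsem("correlation matrix is not positive definite")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * ld
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' One-way intraclass correlation ICC(1)
#'
#' ANOVA estimator: (MSB - MSW) / (MSB + (k0 - 1) MSW), with k0 the
#' effective average cluster size. Values below 0.1 for every clustering
#' variable support a single-level (classical) SEM.
#'
#' @param x numeric outcome vector.
#' @param cluster cluster labels (same length).
#' @return list with `icc`, `msb`, `msw`, `k0`, `n_clusters`.
#' @export
icc1 <- function(x, cluster) {
  ok <- !is.na(x) & !is.na(cluster)
  x <- x[ok]; cluster <- factor(cluster[ok])
  J <- nlevels(cluster)
  if (J < 2) stop_nrsem("need at least 2 clusters")
  N <- length(x)
  nj <- tabulate(cluster)
  k0 <- (N - sum(nj^2) / N) / (J - 1)
  fit <- stats::aov(x ~ cluster)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  list(icc = icc, msb = msb, msw = msw, k0 = k0, n_clusters = J)
}

#' ICC report over several outcomes and clustering variables
#'
#' @param data data.frame with outcome columns.
#' @param outcomes names of numeric outcome columns.
#' @param clusters names of clustering columns.
#' @param threshold verdict threshold (default 0.1).
#' @return data.frame of ICCs with an overall `classical_sem_ok` attribute.
#' @export
icc_report <- function(data, outcomes, clusters, threshold = 0.1) {
  rows <- expand.grid(outcome = outcomes, cluster = clusters,
                      stringsAsFactors = FALSE)
  rows$icc <- mapply(function(o, cl) icc1(data[[o]], data[[cl]])$icc,
                     rows$outcome, rows$cluster)
  rows$below_threshold <- rows$icc < threshold
  attr(rows, "classical_sem_ok") <- all(rows$below_threshold)
  rows
}

#' Harman's one-factor test for common method bias
#'
#' Share of total variance captured by a single factor extracted from all
#' items; below 50 percent is read as no common-method-bias signal. The
#' default extraction is the first principal component of the correlation
#' matrix; `method = "pa"` uses one-factor principal-axis extraction
#' (squared multiple correlations as initial communalities).
#'
#' @param items numeric data.frame/matrix of all items.
#' @param method `"pc"` (default) or `"pa"`.
#' @return list with `share` (in \[0, 1\]), `method`, `cmb` verdict.
#' @export
harman_single_factor <- function(items, method = c("pc", "pa")) {
  method <- match.arg(method)
  m <- check_numeric_matrix(items)
  if (ncol(m) < 3) stop_nrsem("need at least 3 items")
  sds <- apply(m, 2, stats::sd)
  if (any(sds < 1e-12))
    stop_nrsem("constant item column(s): %s",
               paste(colnames(m)[sds < 1e-12], collapse = ", "))
  R <- stats::cor(m)
  p <- ncol(R)
  if (method == "pc") {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    share <- ev[1] / p
  } else {
    ## principal-axis: iterate communalities on the reduced correlation matrix
    h2 <- 1 - 1 / diag(solve(R))
    for (i in 1:50) {
      Rr <- R; diag(Rr) <- h2
      e <- eigen(Rr, symmetric = TRUE)
      lambda <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
      h2_new <- pmin(lambda^2, 1)
      if (max(abs(h2_new - h2)) < 1e-6) { h2 <- h2_new; break }
      h2 <- h2_new
    }
    share <- sum(h2) / p
  }
  list(share = share, method = method, cmb = share >= 0.5)
}

#' Run the standard pre-model diagnostic battery
#'
#' @param data data.frame.
#' @param items item columns entering the measurement model.
#' @param outcomes outcome columns for the ICC check.
#' @param clusters clustering variable columns for the ICC check.
#' @param alpha outlier flagging level.
#' @return list of reports (`normality`, `outliers`, `adequacy`,
#'   `bartlett`, `icc`, `cmb`).
#' @export
run_diagnostics <- function(data, items, outcomes = NULL, clusters = NULL,
                            alpha = 0.001) {
  item_data <- data[items]
  res <- list(
    normality = mardia_kurtosis(item_data),
    outliers = mahalanobis_outliers(item_data, alpha),
    adequacy = kmo(item_data),
    bartlett = bartlett_sphericity(item_data),
    cmb = harman_single_factor(item_data)
  )
  if (!is.null(outcomes) && !is.null(clusters))
    res$icc <- icc_report(data, outcomes, clusters)
  res
}
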