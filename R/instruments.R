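## Two-stage least squares and instrument diagnostics, from first principles
## (regression algebra via QR): no dedicated IV package is assumed.

## residual maker: residuals of each column of y on the column space of X
## (X may be NULL -> y itself, after optional centering via intercept column)
resid_on <- function(y, X) {
  y <- as.matrix(y)
  if (is.null(X) || ncol(X) == 0) return(y)
  qr_x <- qr(X)
  y - qr.fitted(qr_x, y)
}

#' Two-stage least squares for one structural equation
#'
#' @param data data.frame of observed variables.
#' @param outcome name of the dependent variable.
#' @param endo names of endogenous regressors.
#' @param exo names of included exogenous regressors (an intercept is always
#'   included).
#' @param instruments names of excluded instruments.
#' @return list with `coef` (named vector: intercept, endo, exo),
#'   `residuals`, `n`, and the design pieces used by the diagnostics.
#' @export
tsls <- function(data, outcome, endo, exo = character(), instruments) {
  need <- c(outcome, endo, exo, instruments)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_nrsem("unknown columns: %s", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[need]), need, drop = FALSE]
  n <- nrow(d)
  if (length(instruments) < length(endo))
    stop_nrsem("under-identified: %d instrument(s) for %d endogenous regressor(s)",
               length(instruments), length(endo))
  y <- as.matrix(d[[outcome]])
  Yendo <- as.matrix(d[endo])
  X1 <- cbind(`(Intercept)` = 1, as.matrix(d[, exo, drop = FALSE]))
  colnames(X1) <- c("(Intercept)", exo)
  Z <- as.matrix(d[instruments])
  if (n <= ncol(X1) + length(endo))
    stop_nrsem("too few rows (n = %d) for the regressors", n)
  Zfull <- cbind(X1, Z)
  if (qr(Zfull)$rank < ncol(Zfull)) stop_nrsem("collinear instruments/regressors")
  ## first stage: project endogenous regressors on all exogenous columns
  Yhat <- qr.fitted(qr(Zfull), Yendo)
  X2 <- cbind(Yhat, X1)
  colnames(X2) <- c(endo, colnames(X1))
  fit <- qr(X2)
  if (fit$rank < ncol(X2)) stop_nrsem("second-stage design is rank deficient")
  beta <- qr.coef(fit, y)[, 1]
  ## residuals use the *actual* endogenous regressors
  res <- as.numeric(y - cbind(Yendo, X1) %*% beta[c(endo, colnames(X1))])
  list(coef = beta, residuals = res, n = n, endo = endo, exo = exo,
       instruments = instruments, X1 = X1, Z = Z, Yendo = Yendo)
}

#' Cragg-Donald statistic for instrument strength
#'
#' Minimum-eigenvalue first-stage statistic; for a single endogenous
#' regressor it equals the first-stage F test of the excluded instruments.
#' Values above 10 are conventionally read as "strong".
#'
#' @inheritParams tsls
#' @return list with `F`, `n`, `n_instruments`, `strong` (F > 10).
#' @export
cragg_donald_f <- function(data, outcome, endo, exo = character(), instruments) {
  ts <- tsls(data, outcome, endo, exo, instruments)
  X1 <- ts$X1; Z <- ts$Z; Yendo <- ts$Yendo
  n <- ts$n; L <- ncol(Z); K <- ncol(Yendo)
  ## partial the included exogenous variables out of both blocks
  Yp <- resid_on(Yendo, X1)
  Zp <- resid_on(Z, X1)
  V <- resid_on(Yp, Zp)                         # first-stage residuals
  Svv <- crossprod(V) / (n - ncol(X1) - L)
  ev <- tryCatch(chol(Svv), error = function(e) NULL)
  if (is.null(ev)) stop_nrsem("collinear endogenous regressors in first stage")
  ## concentration matrix / L: min eigenvalue generalizes the first-stage F
  G <- solve(t(ev), t(crossprod(Yp, Zp) %*% solve(crossprod(Zp)) %*% crossprod(Zp, Yp)) %*% solve(ev))
  Fstat <- min(Re(eigen(G, only.values = TRUE)$values)) / L
  list(F = Fstat, n = n, n_instruments = L, n_endogenous = K,
       strong = Fstat > 10)
}

#' Sargan overidentification test of instrument validity
#'
#' Homoskedastic Sargan statistic: n times the R-squared of the 2SLS
#' residual regressed on all exogenous columns, chi-square with
#' (#instruments - #endogenous regressors) degrees of freedom. With zero
#' degrees of freedom (just-identified equation) the test is undefined and
#' the result says so instead of returning a number.
#'
#' @inheritParams tsls
#' @return list with `J`, `df`, `p`, `defined`, `valid` (p > 0.05 when
#'   defined).
#' @export
sargan_hansen <- function(data, outcome, endo, exo = character(), instruments) {
  ts <- tsls(data, outcome, endo, exo, instruments)
  df <- length(instruments) - length(endo)
  if (df <= 0)
    return(list(J = NA_real_, df = 0L, p = NA_real_, defined = FALSE,
                valid = NA, note = "test undefined (df = 0): just-identified"))
  u <- ts$residuals
  Zfull <- cbind(ts$X1, ts$Z)
  e <- resid_on(u, Zfull)
  r2 <- 1 - sum(e^2) / sum((u - mean(u))^2)
  J <- ts$n * r2
  p <- stats::pchisq(J, df, lower.tail = FALSE)
  list(J = J, df = as.integer(df), p = p, defined = TRUE, valid = p > 0.05)
}

#' Instrument diagnostics for every loop equation of a system
#'
#' Runs [cragg_donald_f()] and [sargan_hansen()] per loop equation, using
#' the other loop variables' instruments as the excluded instrument set for
#' the equation's endogenous regressors.
#'
#' @param data data.frame holding (composite) scores for every system
#'   variable.
#' @param system a [structural_system()] with an instrument map.
#' @return data.frame, one row per loop equation: F, J, p and verdicts, plus
#'   a `remedy` note for weak/invalid rows.
#' @export
instrument_report <- function(data, system) {
  stopifnot(inherits(system, "structural_system"))
  if (is.null(system$instruments)) stop_nrsem("system has no instrument map")
  rows <- lapply(system$loop, function(y) {
    rhs <- system$equations[[y]]
    endo <- intersect(rhs, system$loop)
    exo <- setdiff(rhs, endo)
    iv <- unique(unlist(system$instruments[endo], use.names = FALSE))
    iv <- setdiff(iv, rhs)
    cd <- cragg_donald_f(data, y, endo, exo, iv)
    sj <- sargan_hansen(data, y, endo, exo, iv)
    weak <- !cd$strong
    invalid <- isTRUE(sj$defined) && !isTRUE(sj$valid)
    data.frame(equation = y, endogenous = paste(endo, collapse = ","),
               instruments = paste(iv, collapse = ","),
               cragg_donald_F = cd$F, strong = cd$strong,
               sargan_J = sj$J, sargan_df = sj$df, sargan_p = sj$p,
               valid = if (sj$defined) sj$valid else NA,
               remedy = if (weak || invalid)
                 "consider deleting a non-recursive path into this equation"
               else "")
  })
  do.call(rbind, rows)
}
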