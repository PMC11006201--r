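## ML estimation of the compiled model. The objective is the covariance ML
## discrepancy F(theta) = log|Sigma| + tr(S Sigma^-1) - log|S| - p with
## Sigma from the RAM matrices; the analytic gradient uses
##   W = Sigma^-1 - Sigma^-1 S Sigma^-1,  V = filter'(W)filter,
##   dF/dA = 2 E' V M,   dF/dS = E' V E  (off-diagonals doubled),
## with E = (I - A)^-1 and M = E S_ram E'. All matrices are small (tens of
## variables), so plain dense algebra is fast enough for bootstrap use.

make_objective <- function(model, S_samp, theta0) {
  p <- model$p
  t_all <- model$t
  obs <- seq_len(p)
  ldS <- logdet_pd(S_samp)
  if (is.na(ldS)) stop_nrsem("sample covariance matrix is not positive definite")
  pr <- model$params
  isA <- pr$matrix_name == "A"
  iA <- which(isA); iS <- which(!isA)
  A_idx <- cbind(pr$row[iA], pr$col[iA])
  S_idx <- cbind(pr$row[iS], pr$col[iS])
  S_diag <- pr$row[iS] == pr$col[iS]
  I_t <- diag(t_all)
  penalty <- function(theta) {
    d <- theta - theta0
    list(F = 1e10 * (1 + sum(d * d)), grad = 2e10 * d, ok = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  compute <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) return(cache$val)
    A <- model$A_val; Sm <- model$S_val
    A[A_idx] <- theta[iA]
    Sm[S_idx] <- theta[iS]
    Sm[S_idx[, c(2, 1), drop = FALSE]] <- theta[iS]
    E <- tryCatch(solve(I_t - A), error = function(e) NULL)
    val <- if (is.null(E)) penalty(theta) else {
      M <- E %*% Sm %*% t(E)
      Sigma <- M[obs, obs, drop = FALSE]
      ch <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(ch)) penalty(theta) else {
        Sigma_inv <- chol2inv(ch)
        Fv <- 2 * sum(log(diag(ch))) + sum(Sigma_inv * S_samp) - ldS - p
        W <- Sigma_inv - Sigma_inv %*% S_samp %*% Sigma_inv
        V <- matrix(0, t_all, t_all)
        V[obs, obs] <- W
        EtV <- t(E) %*% V
        gA <- 2 * (EtV %*% M)
        gS <- EtV %*% E
        grad <- numeric(length(theta))
        grad[iA] <- gA[A_idx]
        gs <- 2 * gS[S_idx]
        gs[S_diag] <- gS[S_idx][S_diag]
        grad[iS] <- gs
        list(F = Fv, grad = grad, ok = TRUE)
      }
    }
    cache$theta <- theta
    cache$val <- val
    val
  }
  list(fn = function(theta) compute(theta)$F,
       gr = function(theta) compute(theta)$grad)
}

start_values <- function(model, S_samp) {
  vars <- model$vars; p <- model$p
  sds <- sqrt(diag(S_samp))
  proxy_sd <- vapply(vars, function(v) {
    if (v %in% model$observed) sds[v]
    else {
      inds <- model$indicators[[v]]
      if (length(inds)) sds[inds[1]] else 1
    }
  }, 0)
  pr <- model$params
  theta <- numeric(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    i <- pr$row[k]; j <- pr$col[k]
    vi <- vars[i]; vj <- vars[j]
    if (pr$matrix_name[k] == "A") {
      is_loading <- vj %in% model$latent && vi %in% (model$indicators[[vj]] %||% character())
      theta[k] <- if (is_loading) 0.7 * proxy_sd[vi] / proxy_sd[vj] else 0
    } else {
      if (i == j) {
        theta[k] <- if (vi %in% model$observed && !(vi %in% model$endo_structural) &&
                        !any(model$A_free[i, ] | model$A_val[i, ] != 0))
          S_samp[vi, vi]                       # exogenous observed: full variance
        else 0.5 * proxy_sd[vi]^2              # residual / latent variance
      } else {
        theta[k] <- if (vi %in% model$observed && vj %in% model$observed)
          0.5 * S_samp[vi, vj] else 0
      }
    }
  }
  theta
}

#' Fit a structural equation model by maximum likelihood
#'
#' Estimates the model by minimizing the covariance ML discrepancy with a
#' quasi-Newton search (analytic gradient), on complete cases. Standard
#' errors come from the numerical Hessian of the discrepancy
#' (2/(n-1) * H^-1). Negative estimated variances (Heywood cases) raise a
#' warning naming the offending variable.
#'
#' @param model a model-description string or a [sem_model()].
#' @param data data.frame; rows with missing values in model variables are
#'   dropped (complete-case estimation).
#' @param se compute standard errors (skipped inside the bootstrap).
#' @param start optional start vector (defaults to moment-based heuristics).
#' @param control passed to [stats::nlminb()] control.
#' @return an object of class `nrsem_fit`: estimates, standard errors, the
#'   chi-square against the saturated model, baseline chi-square, fit
#'   indices (CMIN/DF, CFI, TLI, RMSEA, AIC) and convergence metadata.
#' @export
fit_sem <- function(model, data, se = TRUE, start = NULL, control = list()) {
  if (is.character(model)) model <- sem_model(model, data)
  stopifnot(inherits(model, "sem_model"))
  d <- data[model$observed]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= model$q)
    stop_nrsem("n = %d not greater than the free parameter count q = %d", n, model$q)
  S_samp <- stats::cov(as.matrix(d))
  p <- model$p
  df <- p * (p + 1) / 2 - model$q
  if (df < 0) stop_nrsem("negative degrees of freedom (q = %d > %d moments)",
                         model$q, p * (p + 1) / 2)
  theta0 <- start %||% start_values(model, S_samp)
  obj <- make_objective(model, S_samp, theta0)
  ctrl <- utils::modifyList(list(iter.max = 1000, eval.max = 2000), control)
  opt <- stats::nlminb(theta0, obj$fn, obj$gr, control = ctrl)
  if (opt$objective >= 1e9) {
    ## penalty region: retry from a damped start
    opt2 <- stats::nlminb(theta0 * 0.5, obj$fn, obj$gr, control = ctrl)
    if (opt2$objective < opt$objective) opt <- opt2
    if (opt$objective >= 1e9)
      stop_nrsem("estimation failed: implied covariance never positive definite")
  }
  theta <- opt$par
  grad_norm <- sqrt(sum(obj$gr(theta)^2))
  Fv <- max(opt$objective, 0)
  chisq <- (n - 1) * Fv
  ## baseline (independence) model has closed-form ML fit
  F_b <- sum(log(diag(S_samp))) - logdet_pd(S_samp)
  chisq_b <- (n - 1) * F_b
  df_b <- p * (p - 1) / 2
  idx <- fit_indices(chisq, df, chisq_b, df_b, n, model$q)
  est <- stats::setNames(theta, model$params$label)
  vc <- NULL; ses <- rep(NA_real_, length(theta))
  if (se) {
    H <- tryCatch(stats::optimHess(theta, obj$fn, obj$gr), error = function(e) NULL)
    if (!is.null(H)) {
      Hi <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Hi)) {
        vc <- 2 * Hi / (n - 1)
        ses <- suppressWarnings(sqrt(diag(vc)))
        dimnames(vc) <- list(model$params$label, model$params$label)
      }
    }
    if (is.null(vc)) warn_nrsem("Hessian not invertible; standard errors unavailable")
  }
  ## Heywood screen: negative variance estimates
  var_par <- model$params$matrix_name == "S" & model$params$row == model$params$col
  neg <- var_par & theta < 0
  if (any(neg))
    warn_nrsem("Heywood case: negative variance estimate for %s",
               paste(model$vars[model$params$row[neg]], collapse = ", "))
  conv <- list(code = opt$convergence, message = opt$message,
               iterations = opt$iterations, gradient_norm = grad_norm)
  if (opt$convergence != 0 && grad_norm > 1e-3)
    warn_nrsem("optimizer did not report convergence (code %d, |grad| = %.2e)",
               opt$convergence, grad_norm)
  names(ses) <- model$params$label
  pt <- model$params
  pt$est <- theta; pt$se <- ses
  pt$lhs <- model$vars[pt$row]; pt$rhs <- model$vars[pt$col]
  structure(list(model = model, est = est, se = ses, vcov = vc,
                 S = S_samp, n = n, F = Fv, chisq = chisq, df = df,
                 chisq_baseline = chisq_b, df_baseline = df_b,
                 indices = idx, q = model$q, p_star = p,
                 param_table = pt, convergence = conv,
                 loglik = -0.5 * (n - 1) * (Fv + logdet_pd(S_samp) + p)),
            class = "nrsem_fit")
}

#' @export
print.nrsem_fit <- function(x, ...) {
  cat(sprintf("nrsem fit: %d observed variables, %d free parameters, n = %d\n",
              x$p_star, x$q, x$n))
  cat(sprintf("  chi-square = %.3f on %d df (CMIN/DF = %s)\n", x$chisq, x$df,
              if (x$df > 0) sprintf("%.2f", x$indices$cmin_df) else "undefined"))
  cat(sprintf("  CFI = %.3f  TLI = %s  RMSEA = %s  AIC = %.1f\n",
              x$indices$cfi,
              if (is.na(x$indices$tli)) "undef" else sprintf("%.3f", x$indices$tli),
              if (is.na(x$indices$rmsea)) "undef" else sprintf("%.4f", x$indices$rmsea),
              x$indices$aic))
  invisible(x)
}

#' Incremental and absolute fit indices
#'
#' CFI = 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0);
#' TLI = (chisq_b/df_b - chisq/df) / (chisq_b/df_b - 1);
#' RMSEA = sqrt(max(chisq - df, 0) / (df (n - 1)));
#' AIC = chisq + 2q (so comparisons match common SEM-software output);
#' CMIN/DF = chisq/df. TLI and RMSEA are NA when df = 0.
#'
#' @param chisq,df fitted model chi-square and degrees of freedom.
#' @param chisq_b,df_b baseline (independence) model values.
#' @param n sample size.
#' @param q free parameter count.
#' @return list with `cmin_df`, `cfi`, `tli`, `rmsea`, `aic`.
#' @export
fit_indices <- function(chisq, df, chisq_b, df_b, n, q) {
  num <- max(chisq - df, 0)
  den <- max(chisq_b - df_b, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (df > 0 && df_b > 0 && chisq_b / df_b > 1)
    (chisq_b / df_b - chisq / df) / (chisq_b / df_b - 1) else NA_real_
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n - 1))) else NA_real_
  list(cmin_df = if (df > 0) chisq / df else NA_real_,
       cfi = cfi, tli = tli, rmsea = rmsea, aic = chisq + 2 * q)
}

#' Bootstrap the fitted model
#'
#' Resamples rows with replacement, refits (warm-started at the full-data
#' estimate), and returns the replicate parameter draws with percentile
#' confidence intervals. Failed replicates (non-convergence or degenerate
#' resample) are dropped and counted; more than 20 percent failures is an
#' error suggesting model revision.
#'
#' @param fit an [fit_sem()] result.
#' @param data the data used for the fit.
#' @param n_boot number of bootstrap samples.
#' @param seed RNG seed (results are reproducible for a fixed seed).
#' @param conf confidence level for the percentile intervals.
#' @return object of class `nrsem_boot`: `draws` (replicates x parameters),
#'   `ci` (lower/upper per parameter), `n_failed`, `seed`.
#' @export
bootstrap_fit <- function(fit, data, n_boot = 3000, seed = 1, conf = 0.95) {
  stopifnot(inherits(fit, "nrsem_fit"))
  if (n_boot < 2) warn_nrsem("n_boot = %d gives a degenerate interval", n_boot)
  model <- fit$model
  d <- data[model$observed]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, model$q,
                  dimnames = list(NULL, model$params$label))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rb <- tryCatch(
      suppressWarnings(fit_sem(model, d[idx, , drop = FALSE], se = FALSE,
                               start = fit$est,
                               control = list(iter.max = 300))),
      error = function(e) NULL)
    if (is.null(rb)) failed <- failed + 1L else draws[b, ] <- rb$est
  }
  if (failed > 0.2 * n_boot)
    stop_nrsem("%d of %d bootstrap replicates failed; revise the model", failed, n_boot)
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  a <- (1 - conf) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  structure(list(draws = draws, ci = ci, n_failed = failed,
                 n_requested = n_boot, seed = seed, conf = conf),
            class = "nrsem_boot")
}

#' Compare fitted models on shared data
#'
#' Ranks models by AIC and reports all five criteria (AIC, CMIN/DF, CFI,
#' TLI, RMSEA), flagging disagreements among them. Models fitted to
#' different sample sizes are not comparable and raise an error.
#'
#' @param fits named list of [fit_sem()] results.
#' @return data.frame ordered by AIC with a `selected` marker; attribute
#'   `criteria_agree` says whether the five criteria rank the same model
#'   first.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  ns <- vapply(fits, function(f) as.numeric(f[["n"]]), 0)
  if (length(unique(ns)) != 1)
    stop_nrsem("models were fitted to different sample sizes (%s): not comparable",
               paste(ns, collapse = ", "))
  obs <- lapply(fits, function(f) sort(f$model$observed))
  if (length(unique(obs)) != 1)
    stop_nrsem("models cover different observed variable sets: not comparable")
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  tab <- data.frame(
    model = nm,
    aic = vapply(fits, function(f) f$indices$aic, 0),
    cmin_df = vapply(fits, function(f) f$indices$cmin_df %||% NA_real_, 0),
    cfi = vapply(fits, function(f) f$indices$cfi, 0),
    tli = vapply(fits, function(f) f$indices$tli, 0),
    rmsea = vapply(fits, function(f) f$indices$rmsea, 0))
  tab <- tab[order(tab$aic), ]
  tab$selected <- c(TRUE, rep(FALSE, nrow(tab) - 1))
  if (tab$aic[1] == tab$aic[2]) {
    tab$selected[1:2] <- NA            # explicit tie
    attr(tab, "tie") <- TRUE
  }
  best_by <- c(aic = which.min(tab$aic), cmin_df = which.min(tab$cmin_df),
               cfi = which.max(tab$cfi), tli = which.max(tab$tli),
               rmsea = which.min(tab$rmsea))
  attr(tab, "criteria_agree") <- length(unique(best_by)) == 1
  rownames(tab) <- NULL
  tab
}
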