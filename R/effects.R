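#' Total-effect matrices of a linear simultaneous system
#'
#' With endogenous coefficient matrix B (entry \[i, j\] = direct effect of
#' endogenous j on endogenous i) and exogenous matrix Gamma, total effects
#' are T_endo = (I - B)^-1 - I and T_exo = (I - B)^-1 Gamma: the closed form
#' of the infinite path series through the feedback loop, which converges
#' iff the spectral radius of B is below 1.
#'
#' @param B square endogenous->endogenous coefficient matrix.
#' @param Gamma exogenous->endogenous coefficient matrix (optional).
#' @return list with `endogenous` (T_endo) and `exogenous` (T_exo or NULL).
#' @export
total_effects <- function(B, Gamma = NULL) {
  B <- as.matrix(B)
  if (nrow(B) != ncol(B)) stop_nrsem("B must be square")
  rho <- max(Mod(eigen(B, only.values = TRUE)$values))
  if (rho >= 1)
    stop_nrsem("feedback loop non-convergent: spectral radius of B is %.3f >= 1", rho)
  Einv <- solve(diag(nrow(B)) - B)
  T_endo <- Einv - diag(nrow(B))
  dimnames(T_endo) <- dimnames(B)
  T_exo <- NULL
  if (!is.null(Gamma)) {
    Gamma <- as.matrix(Gamma)
    T_exo <- Einv %*% Gamma
    dimnames(T_exo) <- dimnames(Gamma)
  }
  list(endogenous = T_endo, exogenous = T_exo)
}

## pull B and Gamma (structural part) out of a fitted model
extract_structural <- function(fit) {
  model <- fit$model
  mats <- fill_matrices(model, fit$est)
  endo <- model$endo_structural
  ## structural exogenous: regressors of structural equations that are not
  ## themselves structural outcomes
  preds <- unique(unlist(lapply(endo, function(y) {
    i <- model$ix[[y]]
    model$vars[model$A_free[i, ] | model$A_val[i, ] != 0]
  })))
  exo <- setdiff(preds, endo)
  ## drop loadings: an indicator's incoming edge is not a structural path
  exo <- setdiff(exo, unlist(model$indicators))
  B <- mats$A[endo, endo, drop = FALSE]
  Gamma <- mats$A[endo, exo, drop = FALSE]
  list(B = B, Gamma = Gamma, endo = endo, exo = exo)
}

effect_components <- function(B, Gamma) {
  te <- total_effects(B, Gamma)
  endo <- rownames(B); exo <- colnames(Gamma)
  rows <- expand.grid(predictor = c(exo, endo), outcome = endo,
                      stringsAsFactors = FALSE)
  rows$direct <- mapply(function(pr, out) {
    if (pr %in% endo) B[out, pr] else Gamma[out, pr]
  }, rows$predictor, rows$outcome)
  rows$total <- mapply(function(pr, out) {
    if (pr %in% endo) te$endogenous[out, pr] else te$exogenous[out, pr]
  }, rows$predictor, rows$outcome)
  rows$indirect <- rows$total - rows$direct
  rows[c("predictor", "outcome", "direct", "indirect", "total")]
}

#' Direct, indirect, and total effect table with bootstrap intervals
#'
#' One row per (predictor, outcome) pair over the structural part of the
#' fitted model. Direct effects are the B/Gamma entries; totals come from
#' [total_effects()]; indirect = total - direct, so additivity holds by
#' construction (including loop-amplified effects through the reciprocal
#' paths). With a bootstrap result, percentile intervals are computed by
#' applying the same decomposition to every replicate.
#'
#' @param fit an [fit_sem()] result with at least one structural regression.
#' @param boot optional [bootstrap_fit()] result for the same model.
#' @param conf confidence level for percentile intervals.
#' @return data.frame of class `effect_table` with point estimates and,
#'   when `boot` is given, `*_lower`/`*_upper` percentile bounds.
#' @export
effect_table <- function(fit, boot = NULL, conf = 0.95) {
  st <- extract_structural(fit)
  if (!length(st$endo)) stop_nrsem("model has no structural regressions")
  tab <- effect_components(st$B, st$Gamma)
  tab$ci_available <- FALSE
  if (!is.null(boot)) {
    stopifnot(inherits(boot, "nrsem_boot"))
    if (!nrow(boot$draws)) {
      warn_nrsem("no bootstrap replicates available; point estimates only")
    } else {
      model <- fit$model
      reps <- lapply(seq_len(nrow(boot$draws)), function(b) {
        fb <- fit; fb$est <- boot$draws[b, ]
        stb <- extract_structural(fb)
        ec <- tryCatch(effect_components(stb$B, stb$Gamma),
                       error = function(e) NULL)    # non-convergent loop draw
        ec
      })
      reps <- Filter(Negate(is.null), reps)
      a <- (1 - conf) / 2
      for (comp in c("direct", "indirect", "total")) {
        m <- vapply(reps, `[[`, numeric(nrow(tab)), comp)
        qs <- apply(m, 1, stats::quantile, probs = c(a, 1 - a), names = FALSE)
        tab[[paste0(comp, "_lower")]] <- qs[1, ]
        tab[[paste0(comp, "_upper")]] <- qs[2, ]
      }
      tab$ci_available <- TRUE
    }
  }
  class(tab) <- c("effect_table", "data.frame")
  attr(tab, "standardized") <- FALSE
  tab
}

#' Standardize an effect table
#'
#' Rescales every effect by SD(predictor)/SD(outcome) using model-implied
#' variances, so effects are in standard-deviation units. Additivity
#' (total = direct + indirect) is preserved because all three components
#' are scaled by the same factor.
#'
#' @param table an [effect_table()].
#' @param fit the fit the table came from (source of implied variances), or
#'   a named numeric vector of variances.
#' @return the standardized `effect_table`.
#' @export
standardize_effects <- function(table, fit) {
  stopifnot(inherits(table, "effect_table"))
  v <- if (is.numeric(fit)) fit else diag(implied_covariance(fit, full = TRUE))
  need <- unique(c(table$predictor, table$outcome))
  miss <- setdiff(need, names(v))
  if (length(miss)) stop_nrsem("no implied variance for: %s", paste(miss, collapse = ", "))
  if (any(v[need] <= 0)) stop_nrsem("non-positive implied variance")
  fac <- sqrt(v[table$predictor]) / sqrt(v[table$outcome])
  cols <- intersect(c("direct", "indirect", "total",
                      "direct_lower", "direct_upper", "indirect_lower",
                      "indirect_upper", "total_lower", "total_upper"),
                    names(table))
  for (cl in cols) table[[cl]] <- table[[cl]] * fac
  attr(table, "standardized") <- TRUE
  table
}
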