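#' Define a population model for synthetic questionnaire data
#'
#' Describes the data-generating process: a simultaneous structural system
#' over endogenous constructs (with a feedback loop), latent exogenous
#' constructs, observed covariates, and a graded-response measurement model
#' (Gaussian indicator thresholded at ordered cutpoints).
#'
#' @param n record count.
#' @param B endogenous coefficient matrix (entry \[i, j\]: j -> i); its
#'   spectral radius must be below 1 and diagonal zero.
#' @param Gamma matrix of exogenous effects on the endogenous constructs;
#'   columns named for latent exogenous constructs and covariates.
#' @param Psi disturbance covariance (symmetric positive definite).
#' @param Phi covariance of the latent exogenous constructs.
#' @param covariates named list of covariate distributions: each either
#'   `list(type = "bernoulli", p = )` or
#'   `list(type = "categorical", values = , probs = )`.
#' @param measurement named list per measured construct:
#'   `list(items =, loadings =, error_sd =, item_min =, thresholds = )`
#'   where `thresholds` is a list of strictly increasing cutpoints per item.
#' @param missing_rate per-cell MCAR missingness applied to predictor
#'   columns only (covariates and exogenous-construct items); in \[0, 0.05).
#' @param seed default RNG seed used by [generate_dataset()].
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n, B, Gamma, Psi, Phi, covariates,
                            measurement = list(), missing_rate = 0, seed = NULL) {
  endo <- rownames(B)
  stopifnot(!is.null(endo), identical(rownames(B), colnames(B)))
  if (any(diag(B) != 0)) stop_nrsem("diag(B) must be zero (no self-regression)")
  rho <- max(Mod(eigen(B, only.values = TRUE)$values))
  if (rho >= 1) stop_nrsem("spectral radius of B is %.3f >= 1", rho)
  if (max(abs(Psi - t(Psi))) > 1e-10 || max(abs(Phi - t(Phi))) > 1e-10)
    stop_nrsem("Psi and Phi must be symmetric")
  if (min(eigen(Psi, only.values = TRUE)$values) < -1e-10 ||
      min(eigen(Phi, only.values = TRUE)$values) < -1e-10)
    stop_nrsem("Psi and Phi must be positive semidefinite")
  if (missing_rate < 0 || missing_rate >= 0.05)
    stop_nrsem("missing_rate must be in [0, 0.05)")
  latent_exo <- rownames(Phi) %||% character()
  stopifnot(identical(colnames(Gamma), c(latent_exo, names(covariates))))
  for (cn in names(measurement)) {
    mm <- measurement[[cn]]
    for (th in mm$thresholds %||% list())
      if (is.unsorted(th, strictly = TRUE))
        stop_nrsem("thresholds for an item of %s are not strictly increasing", cn)
  }
  structure(list(n = n, B = B, Gamma = Gamma, Psi = Psi, Phi = Phi,
                 endogenous = endo, latent_exo = latent_exo,
                 covariates = covariates, measurement = measurement,
                 missing_rate = missing_rate, seed = seed),
            class = "population_spec")
}

covariate_moments <- function(cv) {
  switch(cv$type,
    bernoulli = c(mean = cv$p, var = cv$p * (1 - cv$p)),
    categorical = {
      mu <- sum(cv$values * cv$probs)
      c(mean = mu, var = sum(cv$probs * (cv$values - mu)^2))
    },
    stop_nrsem("unknown covariate type '%s'", cv$type))
}

#' Closed-form population moments of a population spec
#'
#' Means and covariance of the endogenous and exogenous scores implied by
#' eta = (I - B)^-1 (Gamma xi + zeta), with covariates independent of each
#' other and of the latent exogenous constructs.
#'
#' @param spec a [population_spec()].
#' @return list with `mu` (all structural variables) and `V` (their
#'   covariance, endogenous first).
#' @export
population_moments <- function(spec) {
  endo <- spec$endogenous
  xi_names <- colnames(spec$Gamma)
  k_lat <- length(spec$latent_exo)
  cov_m <- vapply(spec$covariates, covariate_moments, c(mean = 0, var = 0))
  V_xi <- matrix(0, length(xi_names), length(xi_names),
                 dimnames = list(xi_names, xi_names))
  if (k_lat) V_xi[seq_len(k_lat), seq_len(k_lat)] <- spec$Phi
  if (length(spec$covariates))
    diag(V_xi)[k_lat + seq_along(spec$covariates)] <- cov_m["var", ]
  mu_xi <- c(rep(0, k_lat), if (length(spec$covariates)) cov_m["mean", ] else NULL)
  names(mu_xi) <- xi_names
  Einv <- solve(diag(length(endo)) - spec$B)
  mu_eta <- as.numeric(Einv %*% spec$Gamma %*% mu_xi)
  names(mu_eta) <- endo
  V_eta <- Einv %*% (spec$Gamma %*% V_xi %*% t(spec$Gamma) + spec$Psi) %*% t(Einv)
  C_eta_xi <- Einv %*% spec$Gamma %*% V_xi
  V <- rbind(cbind(V_eta, C_eta_xi), cbind(t(C_eta_xi), V_xi))
  dimnames(V) <- list(c(endo, xi_names), c(endo, xi_names))
  list(mu = c(mu_eta, mu_xi), V = V)
}

#' Simulate structural-level scores from a population spec
#'
#' Draws the exogenous variables and disturbances and solves the
#' simultaneous system eta = (I - B)^-1 (Gamma xi + zeta) exactly, so the
#' endogenous scores satisfy the feedback loop by construction.
#'
#' @param spec a [population_spec()].
#' @param n number of records (default `spec$n`).
#' @return matrix of scores, columns: endogenous constructs, latent
#'   exogenous constructs, covariates.
#' @export
simulate_latent <- function(spec, n = spec$n) {
  stopifnot(inherits(spec, "population_spec"))
  endo <- spec$endogenous
  IA <- diag(length(endo)) - spec$B
  if (abs(det(IA)) < 1e-12)
    stop_nrsem("(I - B) is singular: feedback loop among {%s} has no solution",
               paste(endo, collapse = ", "))
  k_lat <- length(spec$latent_exo)
  xi_lat <- if (k_lat) {
    L <- chol(spec$Phi + diag(1e-12, k_lat))
    matrix(stats::rnorm(n * k_lat), n, k_lat) %*% L
  } else matrix(0, n, 0)
  xi_cov <- vapply(spec$covariates, function(cv) {
    switch(cv$type,
      bernoulli = stats::rbinom(n, 1, cv$p),
      categorical = sample(cv$values, n, replace = TRUE, prob = cv$probs))
  }, numeric(n))
  if (!length(spec$covariates)) xi_cov <- matrix(0, n, 0)
  xi <- cbind(xi_lat, xi_cov)
  colnames(xi) <- colnames(spec$Gamma)
  zeta <- matrix(stats::rnorm(n * length(endo)), n) %*% chol(spec$Psi + diag(1e-12, length(endo)))
  eta <- t(solve(IA, t(xi %*% t(spec$Gamma) + zeta)))
  colnames(eta) <- endo
  cbind(eta, xi)
}

#' Discretize continuous construct scores into Likert items
#'
#' Graded-response generation: each item's continuous indicator is
#' loading x score + Gaussian error; the observed value is the item minimum
#' plus the count of thresholds the indicator exceeds.
#'
#' @param scores matrix from [simulate_latent()] (construct columns).
#' @param spec a [population_spec()] with a `measurement` block.
#' @param continuous return the continuous indicators instead of ordinal
#'   values (for studies of the thresholding step itself).
#' @return data.frame of item responses.
#' @export
discretize_items <- function(scores, spec, continuous = FALSE) {
  out <- list()
  for (cn in names(spec$measurement)) {
    mm <- spec$measurement[[cn]]
    sc <- scores[, cn]
    for (j in seq_along(mm$items)) {
      ind <- mm$loadings[j] * sc + stats::rnorm(length(sc), 0, mm$error_sd[j])
      out[[mm$items[j]]] <- if (continuous) ind else {
        th <- mm$thresholds[[j]]
        if (is.unsorted(th, strictly = TRUE))
          stop_nrsem("non-monotone thresholds for item %s", mm$items[j])
        (mm$item_min[j] %||% 0) + rowSums(outer(ind, th, `>`))
      }
    }
  }
  as.data.frame(out)
}

#' Generate a synthetic questionnaire dataset
#'
#' Full pipeline: structural scores, item discretization, covariate
#' columns, and MCAR missingness confined to predictor columns. The truth
#' (the spec) is attached as attribute `"truth"`. Deterministic for a fixed
#' seed.
#'
#' @param spec a [population_spec()].
#' @param seed RNG seed (default `spec$seed`, else 1).
#' @param indicators `"ordinal"` (default) for Likert items,
#'   `"continuous"` for the underlying indicators, or `"latent"` to observe
#'   the structural scores directly (no measurement error).
#' @return data.frame with `n` rows; item values within their declared
#'   range or missing.
#' @export
generate_dataset <- function(spec, seed = spec$seed %||% 1L,
                             indicators = c("ordinal", "continuous", "latent")) {
  stopifnot(inherits(spec, "population_spec"))
  indicators <- match.arg(indicators)
  set.seed(seed)
  scores <- simulate_latent(spec)
  cov_cols <- as.data.frame(scores[, names(spec$covariates), drop = FALSE])
  if (indicators == "latent") {
    dat <- cbind(as.data.frame(scores[, c(spec$endogenous, spec$latent_exo),
                                      drop = FALSE]), cov_cols)
    predictor_cols <- c(spec$latent_exo, names(spec$covariates))
  } else {
    items <- discretize_items(scores, spec, continuous = indicators == "continuous")
    dat <- cbind(items, cov_cols)
    exo_items <- unlist(lapply(spec$measurement[intersect(names(spec$measurement),
                                                          spec$latent_exo)],
                               `[[`, "items"), use.names = FALSE)
    predictor_cols <- c(exo_items, names(spec$covariates))
  }
  if (spec$missing_rate > 0 && length(predictor_cols)) {
    for (cl in predictor_cols) {
      hit <- stats::runif(nrow(dat)) < spec$missing_rate
      dat[hit, cl] <- NA
    }
  }
  attr(dat, "truth") <- spec
  dat
}
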