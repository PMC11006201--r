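## shared fixtures and small independent oracles used across test files

## a minimal two-construct population spec with a reciprocal loop
tiny_loop_spec <- function(b12 = 0.5, b21 = 0.5, psi = diag(2), n = 1000) {
  B <- matrix(c(0, b12, b21, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("y1", "y2"), c("y1", "y2")))
  Gamma <- matrix(0, 2, 1, dimnames = list(c("y1", "y2"), "x1"))
  dimnames(psi) <- dimnames(B)
  Phi <- matrix(1, 1, 1, dimnames = list("x1", "x1"))
  population_spec(n = n, B = B, Gamma = Gamma, Psi = psi, Phi = Phi,
                  covariates = list(), missing_rate = 0)
}

## independent rank oracle: singular values of the reduced matrix
svd_rank <- function(m, tol = 1e-8) {
  if (!nrow(m) || !ncol(m)) return(0L)
  sum(svd(m)$d > tol)
}

## reduced matrix for the rank condition, recomputed independently
reduce_system <- function(sysmat, i) {
  red <- sysmat[-i, sysmat[i, ] == 0, drop = FALSE]
  red[rowSums(abs(red)) > 0, , drop = FALSE]
}

## random sparse 0/1 system over m loop equations and k exogenous columns
random_system_matrix <- function(m, k, density = 0.4) {
  sm <- matrix(rbinom(m * (m + k), 1, density), m, m + k)
  diag(sm[, seq_len(m)]) <- 1L             # own variable always present
  rownames(sm) <- paste0("y", seq_len(m))
  colnames(sm) <- c(paste0("y", seq_len(m)), paste0("x", seq_len(k)))
  sm
}

## simulate a simple one-factor dataset
one_factor_data <- function(n, loadings, seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  f <- rnorm(n)
  X <- sapply(loadings, function(l) l * f + rnorm(n, 0, sqrt(max(1 - l^2, 0.1))))
  colnames(X) <- paste0("v", seq_along(loadings))
  as.data.frame(X)
}

## IV test-bed: y = b*w + x + u, first stage w = pi*z + x + v, cor(u,v) = rho
iv_data <- function(n, pi1 = 1, rho = 0.5, n_z = 1, invalid = 0) {
  z <- matrix(rnorm(n * n_z), n, n_z)
  x <- rnorm(n)
  uv <- matrix(rnorm(2 * n), n) %*% chol(matrix(c(1, rho, rho, 1), 2))
  w <- pi1 * rowSums(z) / sqrt(n_z) + 0.5 * x + uv[, 2]
  y <- 0.5 * w + 0.8 * x + invalid * z[, 1] + uv[, 1]
  d <- data.frame(y = y, w = w, x = x)
  for (j in seq_len(n_z)) d[[paste0("z", j)]] <- z[, j]
  d
}
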