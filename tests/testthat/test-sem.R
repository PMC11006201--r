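## helper: set a parameter vector by label
theta_by_label <- function(model, values) {
  th <- numeric(model$q)
  names(th) <- model$params$label
  th[names(values)] <- values
  th
}

test_that("implied covariance matches the structural-form closed form", {
  ## two latents in a reciprocal loop, one exogenous latent, 6 indicators
  mt <- "
    f1 =~ a1 + a2
    f2 =~ b1 + b2
    fx =~ c1 + c2
    f1 ~ f2 + fx
    f2 ~ f1 + fx
    f1 ~~ f2
  "
  d <- as.data.frame(matrix(rnorm(60), 10,
                            dimnames = list(NULL, c("a1","a2","b1","b2","c1","c2"))))
  m <- sem_model(mt, d)
  vals <- c("f1=~a2" = 0.8, "f2=~b2" = 1.2, "fx=~c2" = 0.9,
            "f1~f2" = 0.5, "f2~f1" = 0.4, "f1~fx" = 0.6, "f2~fx" = -0.3,
            "f1~~f1" = 0.5, "f2~~f2" = 0.7, "f1~~f2" = 0.1, "fx~~fx" = 1.5,
            "a1~~a1" = 0.3, "a2~~a2" = 0.4, "b1~~b1" = 0.5, "b2~~b2" = 0.6,
            "c1~~c1" = 0.2, "c2~~c2" = 0.3)
  th <- theta_by_label(m, vals)
  Sig <- implied_covariance(m, th)
  ## independent oracle: Lambda (I-B)^-1 (Gamma Phi Gamma' + Psi) (I-B)^-T Lambda' + Theta
  B <- matrix(c(0, 0.5, 0.4, 0), 2, 2, byrow = TRUE)
  Gam <- matrix(c(0.6, -0.3), 2, 1)
  Phi <- matrix(1.5, 1, 1)
  Psi <- matrix(c(0.5, 0.1, 0.1, 0.7), 2, 2)
  Ly <- rbind(c(1, 0), c(0.8, 0), c(0, 1), c(0, 1.2))
  Lx <- rbind(1, 0.9)
  Ty <- diag(c(0.3, 0.4, 0.5, 0.6)); Tx <- diag(c(0.2, 0.3))
  E <- solve(diag(2) - B)
  Veta <- E %*% (Gam %*% Phi %*% t(Gam) + Psi) %*% t(E)
  Cyx <- E %*% Gam %*% Phi
  Syy <- Ly %*% Veta %*% t(Ly) + Ty
  Sxx <- Lx %*% Phi %*% t(Lx) + Tx
  Syx <- Ly %*% Cyx %*% t(Lx)
  oracle <- rbind(cbind(Syy, Syx), cbind(t(Syx), Sxx))
  dimnames(oracle) <- list(c("a1","a2","b1","b2","c1","c2"),
                           c("a1","a2","b1","b2","c1","c2"))
  expect_equal(Sig[rownames(oracle), rownames(oracle)], oracle, tolerance = 1e-12)
  expect_equal(Sig, t(Sig))               # symmetry to machine precision
  ## B = 0, Gamma = 0, identity loadings, zero errors -> Sigma_yy = Psi
  mt2 <- "y1 ~~ y2"
  d2 <- data.frame(y1 = rnorm(5), y2 = rnorm(5))
  m2 <- sem_model(mt2, d2)
  th2 <- theta_by_label(m2, c("y1~~y1" = 2, "y2~~y2" = 3, "y1~~y2" = 0.5))
  expect_equal(implied_covariance(m2, th2),
               matrix(c(2, .5, .5, 3), 2, dimnames = list(c("y1","y2"), c("y1","y2"))))
  ## singular loop errors
  vals_bad <- vals; vals_bad["f1~f2"] <- 1; vals_bad["f2~f1"] <- 1
  expect_error(implied_covariance(m, theta_by_label(m, vals_bad)), "singular")
})

test_that("the ML discrepancy has its closed form, floor, and uniqueness", {
  S <- matrix(c(2, .3, .3, 1), 2)
  expect_equal(ml_discrepancy(S, S)$F, 0)
  ## scalar case: S = 2, Sigma = 1 -> F = 1 - ln 2
  expect_equal(ml_discrepancy(matrix(2), matrix(1))$F, 1 - log(2),
               tolerance = 1e-12)
  expect_equal(ml_discrepancy(matrix(2), matrix(1), n = 101)$chisq,
               100 * (1 - log(2)))
  ## F >= 0 on random PD pairs, zero only at equality
  set.seed(41)
  for (i in 1:50) {
    p <- sample(2:5, 1)
    A1 <- matrix(rnorm(p * p), p); S1 <- crossprod(A1) + diag(p) * 0.1
    A2 <- matrix(rnorm(p * p), p); S2 <- crossprod(A2) + diag(p) * 0.1
    expect_gt(ml_discrepancy(S1, S2)$F, 0)
    expect_equal(ml_discrepancy(S1, S1)$F, 0, tolerance = 1e-10)
  }
  expect_error(ml_discrepancy(matrix(-1), matrix(1)), "positive definite")
})

test_that("chi-square at a correctly specified model follows its reference distribution", {
  lam <- c(0.9, 0.8, 0.7, 0.75, 0.85, 0.65)
  set.seed(40)
  stats <- replicate(200, {
    d <- one_factor_data(500, lam, seed = NULL)
    f <- suppressWarnings(fit_sem("f =~ v1 + v2 + v3 + v4 + v5 + v6", d, se = FALSE))
    f$chisq
  })
  df <- 6 * 7 / 2 - 12                    # 9
  expect_equal(mean(stats), df, tolerance = 0.1 * df)
  expect_gt(var(stats), df)               # chi-square variance is 2 df
  expect_lt(var(stats), 4 * df)
})

test_that("structural parameters of the study regime are recovered at n = 2000", {
  spec <- default_population_spec(n = 2000, missing_rate = 0)
  d <- generate_dataset(spec, seed = 42, indicators = "latent")
  fit <- fit_sem(analysis_model(spec, level = "latent"), d, se = FALSE)
  tr <- truth_structural(spec, "latent")
  expect_true(all(abs(fit$est[names(tr)] - tr) < 0.15))
  expect_equal(fit$convergence$code, 0)
})

test_that("a saturated model fits perfectly and degenerate baselines are safe", {
  set.seed(43)
  d <- as.data.frame(matrix(rnorm(300 * 3), ncol = 3))
  names(d) <- c("y1", "y2", "x1")
  ## recursive saturated system: q = 6 = moments
  fit <- fit_sem("y1 ~ y2 + x1\ny2 ~ x1", d, se = FALSE)
  expect_equal(fit$df, 0)
  expect_equal(fit$chisq, 0, tolerance = 1e-6)
  expect_equal(fit$indices$cfi, 1)
  expect_true(is.na(fit$indices$rmsea))
  ## index arithmetic spot values
  idx <- fit_indices(260, 100, 14000, 120, 1373, 70)
  expect_equal(idx$rmsea, sqrt(160 / 137200), tolerance = 1e-12)
  expect_equal(idx$cfi, 1 - 160 / 13880, tolerance = 1e-12)
  expect_equal(idx$aic, 260 + 140)
  idx2 <- fit_indices(100, 100, 100, 100, 500, 10)
  expect_equal(idx2$cfi, 1)               # chisq = df: floor definition
  expect_equal(idx2$rmsea, 0)
})

test_that("fits are invariant to row order and deterministic", {
  spec <- default_population_spec(n = 600, missing_rate = 0)
  d <- generate_dataset(spec, seed = 44, indicators = "latent")
  mt <- analysis_model(spec, level = "latent")
  f1 <- fit_sem(mt, d, se = FALSE)
  set.seed(99)
  f2 <- fit_sem(mt, d[sample(nrow(d)), ], se = FALSE)
  ## row order only enters through floating-point summation in cov();
  ## estimates agree far below any scientifically meaningful digit
  expect_lt(max(abs(f1$est - f2$est)), 1e-6)
  expect_lt(abs(f1$chisq - f2$chisq), 1e-6)
  f3 <- fit_sem(mt, d, se = FALSE)
  expect_identical(f1$est, f3$est)         # bitwise deterministic rerun
})

test_that("bootstrap intervals are reproducible and cover the estimate", {
  spec <- default_population_spec(n = 500, missing_rate = 0)
  d <- generate_dataset(spec, seed = 45, indicators = "latent")
  mt <- "depression ~ anxiety + stress + support\nanxiety ~ depression + stress + physical_trauma"
  fit <- fit_sem(mt, d, se = FALSE)
  b1 <- bootstrap_fit(fit, d, n_boot = 60, seed = 7)
  b2 <- bootstrap_fit(fit, d, n_boot = 60, seed = 7)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_fit(fit, d, n_boot = 60, seed = 8)
  expect_false(identical(b1$ci, b3$ci))
  ## percentile intervals bracket the point estimate for nearly all parameters
  inside <- fit$est >= b1$ci[, "lower"] & fit$est <= b1$ci[, "upper"]
  expect_gte(mean(inside), 0.95)
  expect_warning(bootstrap_fit(fit, d, n_boot = 1, seed = 1), "degenerate")
})

test_that("model comparison ranks by AIC and flags ties", {
  spec <- default_population_spec(n = 800, missing_rate = 0)
  d <- generate_dataset(spec, seed = 46, indicators = "latent")
  true_m <- "somatic ~ depression + anxiety + stress"
  ## over-pruned alternative over the same observed variables
  pruned <- "somatic ~ depression\nanxiety ~~ stress"
  f1 <- fit_sem(true_m, d, se = FALSE)
  f2 <- fit_sem(pruned, d, se = FALSE)
  cmp <- compare_models(list(true = f1, pruned = f2))
  expect_equal(cmp$model[1], "true")
  expect_true(cmp$selected[1])
  tie <- compare_models(list(a = f1, b = f1))
  expect_true(isTRUE(attr(tie, "tie")))
  f3 <- f2; f3$n <- f3$n - 1
  expect_error(compare_models(list(f1, f3)), "sample sizes")
  ## AIC prefers the true model in most replications
  set.seed(47)
  wins <- mean(replicate(60, {
    dd <- generate_dataset(default_population_spec(n = 500, missing_rate = 0),
                           seed = sample.int(1e6, 1), indicators = "latent")
    g1 <- fit_sem(true_m, dd, se = FALSE)
    g2 <- fit_sem(pruned, dd, se = FALSE)
    g1$indices$aic < g2$indices$aic
  }))
  expect_gte(wins, 0.9)
})

test_that("Heywood cases and structural misuse are reported", {
  d <- one_factor_data(60, c(0.95, 0.9, 0.9), seed = 48)
  d$v1 <- d$v1 * 3
  ## tiny sample, near-unit loadings: occasionally negative uniqueness; at
  ## minimum the fit must either converge cleanly or warn, never silently fail
  f <- tryCatch(suppressWarnings(fit_sem("f =~ v1 + v2 + v3", d, se = FALSE)),
                error = function(e) NULL)
  expect_false(is.null(f))
  expect_equal(f$df, 0)                    # just-identified single construct
  expect_equal(f$chisq, 0, tolerance = 1e-5)
  expect_error(fit_sem("y ~ y", data.frame(y = rnorm(10))), "itself|parse")
  expect_error(sem_model("f =~ q1 + q2", data.frame(a = 1:5)), "neither observed")
})
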