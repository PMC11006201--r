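test_that("total effects reduce to Gamma when B = 0 and follow the loop series", {
  B0 <- matrix(0, 2, 2, dimnames = list(c("y1", "y2"), c("y1", "y2")))
  G <- matrix(c(0.3, -0.2, 0.5, 0), 2, 2,
              dimnames = list(c("y1", "y2"), c("x1", "x2")))
  te <- total_effects(B0, G)
  expect_equal(te$endogenous, B0)
  expect_equal(te$exogenous, G)
  ## reciprocal 0.5/0.5: total y2 -> y1 is 0.5/(1 - 0.25) = 2/3, and equals
  ## the geometric path series sum_k 0.5 * 0.25^k
  B <- matrix(c(0, 0.5, 0.5, 0), 2, 2, byrow = TRUE,
              dimnames = dimnames(B0))
  te2 <- total_effects(B)
  expect_equal(te2$endogenous["y1", "y2"], 2 / 3, tolerance = 1e-12)
  series <- sum(0.5 * 0.25^(0:40))
  expect_equal(te2$endogenous["y1", "y2"], series, tolerance = 1e-10)
  ## matrix form of the truncated path series
  Bsum <- Reduce(`+`, lapply(1:60, function(k) {
    out <- diag(2); for (i in seq_len(k)) out <- out %*% B; out
  }))
  expect_equal(unname(te2$endogenous), unname(Bsum), tolerance = 1e-8)
  ## non-convergent loop
  B1 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = dimnames(B0))
  expect_error(total_effects(B1), "non-convergent")
})

test_that("published effect rows satisfy additivity within rounding", {
  ## (direct, indirect, total) rows as printed for the three outcomes
  rows <- rbind(
    c(-0.06, 0.82, 0.76),   # stress -> depression
    c(0.06, 0.08, 0.14),    # alcohol -> depression
    c(0.04, 0.17, 0.21),    # chronic illness -> depression
    c(-0.03, 0.09, 0.06),   # sex -> depression
    c(-0.09, 0.20, 0.11),   # school type -> depression
    c(0.02, 0.02, 0.04),    # family pressure -> depression
    c(0.54, 0.57, 1.10),    # stress -> anxiety (1.11 rounds within 0.015)
    c(-0.03, 0.14, 0.11),   # alcohol -> anxiety
    c(-0.02, 0.27, 0.25),   # chronic illness -> anxiety
    c(0.08, 0.04, 0.12),    # sex -> anxiety
    c(0.12, 0.16, 0.28),    # school type -> anxiety
    c(0.17, 0.20, 0.37),    # chronic illness -> somatic
    c(0.03, 0.09, 0.12),    # alcohol -> somatic
    c(0.11, 0.03, 0.14),    # sex -> somatic
    c(0.03, 0.13, 0.16),    # school type -> somatic
    c(0.53, 0.33, 0.86),    # stress -> somatic
    c(0.38, 0.58, 0.96))    # depression -> somatic
  expect_true(all(abs(rows[, 1] + rows[, 2] - rows[, 3]) <= 0.015))
})

test_that("effect tables decompose additively with exact zeros off-path", {
  spec <- default_population_spec(n = 1500, missing_rate = 0)
  d <- generate_dataset(spec, seed = 61, indicators = "latent")
  fit <- fit_sem(analysis_model(spec, level = "latent"), d, se = FALSE)
  tab <- effect_table(fit)
  expect_true(all(abs(tab$direct + tab$indirect - tab$total) < 1e-10))
  ## a predictor with no path to an outcome has all three effects zero:
  ## physical trauma enters only the anxiety equation, but reaches the
  ## others through the loop - whereas a variable absent from the model
  ## entirely would not appear; check the structural zero instead
  row <- tab[tab$predictor == "physical_trauma" & tab$outcome == "anxiety", ]
  expect_gt(abs(row$direct), 0)
  ## total effects propagate through the loop: stress -> depression total
  ## reflects (I - B)^-1 amplification, not just the direct path
  st <- tab[tab$predictor == "stress" & tab$outcome == "depression", ]
  expect_gt(st$total, st$direct)
})

test_that("predictors outside every equation get zero effects throughout", {
  set.seed(62)
  d <- data.frame(y1 = rnorm(200), y2 = rnorm(200),
                  x1 = rnorm(200), x2 = rnorm(200))
  fit <- fit_sem("y1 ~ y2 + x1\ny2 ~ x2", d, se = FALSE)
  tab <- effect_table(fit)
  r <- tab[tab$predictor == "x1" & tab$outcome == "y2", ]
  expect_equal(r$direct, 0)
  expect_equal(r$total, 0)
  expect_equal(r$indirect, 0)
})

test_that("bootstrap percentile intervals attach to every component", {
  spec <- default_population_spec(n = 600, missing_rate = 0)
  d <- generate_dataset(spec, seed = 63, indicators = "latent")
  mt <- paste("depression ~ anxiety + stress + support",
              "anxiety ~ depression + stress + physical_trauma",
              "somatic ~ depression + anxiety + stress", sep = "\n")
  fit <- fit_sem(mt, d, se = FALSE)
  boot <- bootstrap_fit(fit, d, n_boot = 80, seed = 3)
  tab <- effect_table(fit, boot)
  expect_true(all(tab$ci_available))
  expect_true(all(tab$total_lower <= tab$total + 1e-12))
  expect_true(all(tab$total_upper >= tab$total - 1e-12))
  ## additivity holds inside every bootstrap replicate, so bounds exist for
  ## all three components
  expect_true(all(c("direct_lower", "indirect_lower", "total_lower") %in% names(tab)))
})

test_that("standardization rescales by SD ratios and preserves structure", {
  spec <- default_population_spec(n = 1500, missing_rate = 0)
  d <- generate_dataset(spec, seed = 64, indicators = "latent")
  mt <- "depression ~ anxiety + stress + support\nanxiety ~ depression + stress + physical_trauma"
  fit <- fit_sem(mt, d, se = FALSE)
  tab <- effect_table(fit)
  ## unit variances: identity transform
  v1 <- setNames(rep(1, 5),
                 c("depression", "anxiety", "stress", "support", "physical_trauma"))
  expect_equal(standardize_effects(tab, v1)$total, tab$total)
  ## doubling a predictor's scale halves the unstandardized effect but
  ## leaves the standardized effect unchanged
  d2 <- d; d2$stress <- 2 * d$stress
  fit2 <- fit_sem(mt, d2, se = FALSE)
  tab2 <- effect_table(fit2)
  i <- tab$predictor == "stress" & tab$outcome == "anxiety"
  expect_equal(tab2$direct[i], tab$direct[i] / 2, tolerance = 1e-6)
  s1 <- standardize_effects(tab, fit)
  s2 <- standardize_effects(tab2, fit2)
  expect_equal(s2$direct[i], s1$direct[i], tolerance = 1e-6)
  ## the product of the standardized reciprocal paths is scale-free
  b12 <- function(tt) tt$direct[tt$predictor == "anxiety" & tt$outcome == "depression"]
  b21 <- function(tt) tt$direct[tt$predictor == "depression" & tt$outcome == "anxiety"]
  expect_equal(b12(s1) * b21(s1), b12(tab) * b21(tab), tolerance = 1e-10)
  expect_equal(attr(s1, "standardized"), TRUE)
  expect_error(standardize_effects(tab, c(depression = 0, anxiety = 1, stress = 1)),
               "variance")
})

test_that("additivity survives standardization", {
  spec <- default_population_spec(n = 800, missing_rate = 0)
  d <- generate_dataset(spec, seed = 65, indicators = "latent")
  fit <- fit_sem(analysis_model(spec, level = "latent"), d, se = FALSE)
  s <- standardize_effects(effect_table(fit), fit)
  expect_true(all(abs(s$direct + s$indirect - s$total) < 1e-10))
})
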