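## Default study population: an adolescent mental-health survey regime with
## a depression <-> anxiety feedback loop, somatic symptoms downstream of
## both, latent stress and social support, and binary/ordinal covariates.
## Structural coefficients follow the published unstandardized direct
## effects of the motivating study; measurement defaults (loadings 0.7,
## symptom-skewed thresholds, reliability ~0.55 per item) are modeling
## choices documented in the methods vignette.

study_gamma <- function() {
  cols <- c("stress", "support", "alcohol", "chronic_illness", "sex",
            "school_type", "physical_trauma", "academic_ability",
            "death_of_loved_one", "family_pressure", "study_time",
            "extra_tutoring", "physical_activity", "family_mental_illness")
  G <- matrix(0, 3, length(cols),
              dimnames = list(c("depression", "anxiety", "somatic"), cols))
  G["depression", ] <- c(-0.06, -0.13, 0.06, 0.04, -0.03, -0.09, 0, 0,
                         0.03, 0.02, 0, 0, 0, 0)
  G["anxiety", ] <- c(0.54, 0, -0.03, -0.02, 0.08, 0.12, 0.06, -0.03,
                      0, 0, 0, 0, 0, 0)
  G["somatic", ] <- c(0.53, 0, 0.03, 0.17, 0.11, 0.03, 0, 0,
                      0, 0, 0, 0, 0, 0)
  G
}

study_covariates <- function() {
  bern <- function(p) list(type = "bernoulli", p = p)
  list(alcohol = bern(0.3575), chronic_illness = bern(0.103),
       sex = bern(0.6113), school_type = bern(0.1022),
       physical_trauma = bern(0.2197),
       academic_ability = list(type = "categorical", values = 1:5,
                               probs = c(0.10, 0.20, 0.30, 0.25, 0.15)),
       death_of_loved_one = bern(0.25), family_pressure = bern(0.50),
       study_time = bern(0.50), extra_tutoring = bern(0.30),
       physical_activity = bern(0.1624), family_mental_illness = bern(0.0732))
}

#' Default population spec for the adolescent mental-health study regime
#'
#' Reciprocal depression<->anxiety paths of 0.74 each, somatic symptoms
#' regressed on both (0.38, 0.06), published direct covariate effects,
#' latent stress and social support (variance 1, correlation -0.3),
#' independent disturbances (variance 0.3), and a graded-response
#' measurement model: PHQ-9A (9 items, 0-3), GAD-7 (7, 0-3), SSS-8 (8,
#' 0-4), PSS-10 (10, 0-4), OSSS-3 (3 items, 1-4 / 1-5), all loadings 0.7.
#'
#' @param n record count (default 1379, the study's respondent count).
#' @param missing_rate per-cell MCAR rate on predictor columns (default
#'   2e-4, giving roughly half a percent of incomplete records).
#' @param loading common item loading (default 0.7).
#' @return a [population_spec()].
#' @export
default_population_spec <- function(n = 1379, missing_rate = 2e-4,
                                    loading = 0.7) {
  B <- matrix(0, 3, 3, dimnames = list(c("depression", "anxiety", "somatic"),
                                       c("depression", "anxiety", "somatic")))
  B["depression", "anxiety"] <- 0.74
  B["anxiety", "depression"] <- 0.74
  B["somatic", "depression"] <- 0.38
  B["somatic", "anxiety"] <- 0.06
  Psi <- diag(0.3, 3); dimnames(Psi) <- dimnames(B)
  Phi <- matrix(c(1, -0.3, -0.3, 1), 2, 2,
                dimnames = list(c("stress", "support"), c("stress", "support")))
  spec <- population_spec(n = n, B = B, Gamma = study_gamma(), Psi = Psi,
                          Phi = Phi, covariates = study_covariates(),
                          missing_rate = 0)
  mom <- population_moments(spec)
  item_sets <- list(
    depression = list(prefix = "phq", k = 9, min = 0, z = c(-0.3, 0.75, 1.5)),
    anxiety = list(prefix = "gad", k = 7, min = 0, z = c(-0.3, 0.75, 1.5)),
    somatic = list(prefix = "sss", k = 8, min = 0, z = c(-0.5, 0.4, 1.1, 1.8)),
    stress = list(prefix = "pss", k = 10, min = 0, z = c(-1.2, -0.1, 1.0, 1.9)),
    support = list(prefix = "oss", k = 3, min = 1,
                   z = list(c(-1.2, 0, 1.2), c(-1.5, -0.5, 0.5, 1.5),
                            c(-1.5, -0.5, 0.5, 1.5))))
  measurement <- lapply(names(item_sets), function(cn) {
    s <- item_sets[[cn]]
    v <- mom$V[cn, cn]; mu <- mom$mu[[cn]]
    lam <- rep(loading, s$k)
    err <- 0.905 * lam * sqrt(v)        # per-item reliability ~0.55
    sd_ind <- sqrt(lam^2 * v + err^2)
    thr <- lapply(seq_len(s$k), function(j) {
      z <- if (is.list(s$z)) s$z[[j]] else s$z
      lam[j] * mu + z * sd_ind[j]
    })
    list(items = paste0(s$prefix, seq_len(s$k)), loadings = lam,
         error_sd = err, item_min = rep(s$min, s$k), thresholds = thr)
  })
  names(measurement) <- names(item_sets)
  population_spec(n = n, B = B, Gamma = study_gamma(), Psi = Psi, Phi = Phi,
                  covariates = study_covariates(), measurement = measurement,
                  missing_rate = missing_rate)
}

#' Item map of the default study constructs
#' @return named list construct -> item columns.
#' @export
study_constructs <- function() {
  list(depression = paste0("phq", 1:9), anxiety = paste0("gad", 1:7),
       somatic = paste0("sss", 1:8), stress = paste0("pss", 1:10),
       support = paste0("oss", 1:3))
}

#' The hypothesized structural system of the default study
#'
#' Three-variable feedback loop (depression, anxiety, somatic symptoms)
#' with unique instruments per loop variable; used by the identification
#' and instrument-diagnostic stages before fitting.
#'
#' @return a [structural_system()].
#' @export
study_system <- function() {
  common <- c("stress", "alcohol", "chronic_illness", "sex", "school_type")
  structural_system(
    endogenous = c("depression", "anxiety", "somatic"),
    exogenous = c("stress", "support", "alcohol", "chronic_illness", "sex",
                  "school_type", "physical_trauma", "academic_ability",
                  "death_of_loved_one", "family_pressure", "study_time",
                  "extra_tutoring", "physical_activity", "family_mental_illness"),
    equations = list(
      depression = c("anxiety", "somatic", common, "support",
                     "death_of_loved_one", "family_pressure"),
      anxiety = c("depression", "somatic", common, "physical_trauma",
                  "academic_ability"),
      somatic = c("depression", "anxiety", common, "study_time",
                  "extra_tutoring")),
    loop = c("depression", "anxiety", "somatic"),
    instruments = list(
      depression = c("support", "death_of_loved_one", "family_pressure"),
      anxiety = c("physical_trauma", "academic_ability"),
      somatic = c("study_time", "extra_tutoring")))
}

## model text for a system + construct map; measured constructs with more
## than 3 items are represented by pre-computed parcel columns <name>_p1..k
model_from_system <- function(system, constructs, k = 3,
                              psi_free = character()) {
  lines <- character()
  used <- intersect(names(constructs), system$variables)
  for (cn in used) {
    items <- constructs[[cn]]
    inds <- if (length(items) > 3)
      paste0(cn, "_p", seq_len(min(if (length(items) < 6) 2 else k, length(items))))
    else items
    lines <- c(lines, paste(cn, "=~", paste(inds, collapse = " + ")))
  }
  for (y in names(system$equations))
    lines <- c(lines, paste(y, "~", paste(system$equations[[y]], collapse = " + ")))
  lines <- c(lines, psi_free)
  paste(lines, collapse = "\n")
}

#' Append parcel columns for the default study constructs
#'
#' @param data generated dataset with item columns.
#' @param constructs construct->items map (default [study_constructs()]).
#' @param k parcels per construct (constructs under 6 items get 2; 3-item
#'   constructs keep their items).
#' @return data.frame with `<construct>_p<i>` parcel-mean columns appended.
#' @export
prepare_analysis_data <- function(data, constructs = study_constructs(), k = 3) {
  add_parcels(data, constructs, k = k)$data
}

#' Model description for analysing data from a population spec
#'
#' Builds the correctly specified analysis model for [generate_dataset()]
#' output: at `"parcel"` level, constructs are latent with parcel-mean
#' indicators; at `"latent"` level the structural scores are observed
#' directly. Regressions follow the nonzero pattern of the spec's B and
#' Gamma; disturbance covariances are included for the pairs in `psi_pairs`.
#'
#' @param spec a [population_spec()].
#' @param level `"parcel"` or `"latent"`.
#' @param k parcels per construct.
#' @param psi_pairs character vector of `"a ~~ b"` lines to free disturbance
#'   covariances (default none: uncorrelated disturbances).
#' @return model-description string for [fit_sem()].
#' @export
analysis_model <- function(spec, level = c("parcel", "latent"), k = 3,
                           psi_pairs = character()) {
  level <- match.arg(level)
  lines <- character()
  if (level == "parcel") {
    for (cn in names(spec$measurement)) {
      items <- spec$measurement[[cn]]$items
      inds <- if (length(items) > 3)
        paste0(cn, "_p", seq_len(min(if (length(items) < 6) 2 else k, length(items))))
      else items
      lines <- c(lines, paste(cn, "=~", paste(inds, collapse = " + ")))
    }
  }
  pattern <- cbind(spec$B, spec$Gamma)
  for (y in rownames(pattern)) {
    rhs <- colnames(pattern)[pattern[y, ] != 0]
    if (length(rhs)) lines <- c(lines, paste(y, "~", paste(rhs, collapse = " + ")))
  }
  paste(c(lines, psi_pairs), collapse = "\n")
}

#' True structural coefficients on the fitted (marker) scale
#'
#' When a latent construct's scale is set by fixing its marker indicator's
#' loading to 1, the construct is rescaled by its true marker loading m;
#' coefficients transform as b*_ij = (m_i/m_j) b_ij for latent predictors
#' and g*_i = m_i g for observed covariates. At `"latent"` level (construct
#' scores observed directly) the truth is returned unchanged.
#'
#' @param spec a [population_spec()].
#' @param level `"parcel"` (markers are parcel means of equally loaded
#'   items, so m = the common item loading) or `"latent"` (m = 1).
#' @return named numeric vector, names matching fitted parameter labels
#'   (`outcome~predictor`).
#' @export
truth_structural <- function(spec, level = c("parcel", "latent")) {
  level <- match.arg(level)
  m <- stats::setNames(rep(1, length(c(spec$endogenous, spec$latent_exo))),
                       c(spec$endogenous, spec$latent_exo))
  if (level == "parcel")
    for (cn in names(m))
      if (!is.null(spec$measurement[[cn]]))
        m[cn] <- spec$measurement[[cn]]$loadings[1]
  out <- c()
  pattern <- cbind(spec$B, spec$Gamma)
  for (y in rownames(pattern)) for (v in colnames(pattern)) {
    val <- pattern[y, v]
    if (val == 0) next
    scale <- m[y] / (if (v %in% names(m)) m[v] else 1)
    out[paste0(y, "~", v)] <- val * scale
  }
  out
}
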