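#' Staged sample-size planner for structural equation models
#'
#' Rule-of-thumb planner: n0 = q * r participants (r per free parameter),
#' inflated by a design effect for multistage sampling, then by an expected
#' non-response fraction (rounded up).
#'
#' @param q number of free parameters.
#' @param r participants per parameter; the conventional range is 5 to 20
#'   (values outside it warn but do not error).
#' @param deff design effect (>= 1).
#' @param nonresponse expected non-response fraction in \[0, 1).
#' @return list of class `design_plan` with `n_base`, `n_design`, `n_final`
#'   and the inputs.
#' @export
#' @examples
#' plan_sample_size(134, r = 5, deff = 2, nonresponse = 0.05) # 670, 1340, 1407
plan_sample_size <- function(q, r = 5, deff = 1, nonresponse = 0) {
  stopifnot(q >= 1, r >= 1, deff >= 1, nonresponse >= 0, nonresponse < 1)
  if (r < 5 || r > 20)
    warn_nrsem("r = %s is outside the conventional 5-20 per-parameter range", r)
  n0 <- q * r
  n1 <- n0 * deff
  nf <- ceiling(n1 * (1 + nonresponse))
  structure(list(q = q, r = r, deff = deff, nonresponse = nonresponse,
                 n_base = n0, n_design = n1, n_final = nf),
            class = "design_plan")
}

#' @export
print.design_plan <- function(x, ...) {
  cat(sprintf("design plan: q = %d x r = %s -> %s; x deff %s -> %s; + %s%% non-response -> %s\n",
              x$q, x$r, x$n_base, x$deff, x$n_design,
              100 * x$nonresponse, x$n_final))
  invisible(x)
}

#' Default pipeline configuration for the study regime
#'
#' @param n_boot bootstrap replicates for the final fit.
#' @param seed RNG seed for the bootstrap.
#' @param k parcels per construct.
#' @param psi_free optional `"a ~~ b"` lines freeing disturbance covariances.
#' @param remediate drop reciprocal paths whose instruments test weak or
#'   invalid, then refit (the standard treatment for a faulty instrument).
#' @return configuration list for [run_pipeline()].
#' @export
default_config <- function(n_boot = 300, seed = 1, k = 3,
                           psi_free = character(), remediate = TRUE) {
  list(constructs = study_constructs(), system = study_system(),
       covariates = names(study_covariates()), k = k, n_boot = n_boot,
       seed = seed, alpha = 0.001, max_missing = 0.05,
       psi_free = psi_free, remediate = remediate)
}

## composite scores (item means) for the system variables measured by items
add_composites <- function(data, constructs) {
  for (cn in names(constructs))
    data[[cn]] <- rowMeans(data[constructs[[cn]]], na.rm = FALSE)
  data
}

#' Run the full analysis pipeline
#'
#' Stages, in order: column validation; scale scoring; listwise deletion
#' (guarded); pre-model diagnostics; identification (order, rank, unique
#' instruments) -- a failed rank condition stops the pipeline before any
#' fitting; instrument strength/validity on composite scores, with optional
#' remediation that deletes reciprocal paths whose instruments are weak or
#' invalid; parceling; ML fit; bootstrap; effect decomposition.
#'
#' @param data item-level dataset (e.g. from [generate_dataset()]).
#' @param config list from [default_config()].
#' @return list with every stage's output and a `log` of stage verdicts.
#' @export
run_pipeline <- function(data, config = default_config()) {
  log <- character()
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  constructs <- config$constructs
  system <- config$system

  ## 1: validation
  item_cols <- unlist(constructs, use.names = FALSE)
  need <- c(item_cols, config$covariates)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_nrsem("validation failed, unknown column(s): %s",
               paste(miss, collapse = ", "))
  say("validation: %d analysis columns present", length(need))

  ## 2: scoring
  scored <- score_dataset(data)
  say("scoring: %d scale totals computed", sum(grepl("_total$", names(scored))))

  ## 3: missing handling
  analysis <- apply_listwise(cbind(data[need]), max_fraction = config$max_missing)
  say("listwise deletion: %d of %d records retained (%.2f%% dropped)",
      nrow(analysis), nrow(data), 100 * attr(analysis, "fraction_dropped"))

  ## 4: diagnostics
  diagnostics <- run_diagnostics(analysis, items = item_cols, alpha = config$alpha)
  say("diagnostics: Mardia kurtosis %.1f (CR %.1f, %s); %d outliers at p<%g; KMO %.2f; Harman share %.1f%%",
      diagnostics$normality$b2p, diagnostics$normality$cr,
      if (diagnostics$normality$nonnormal) "non-normal" else "normal",
      diagnostics$outliers$n_flagged, config$alpha,
      diagnostics$adequacy$overall, 100 * diagnostics$cmb$share)
  if (diagnostics$normality$nonnormal)
    say("diagnostics: non-normality -> bootstrap percentile intervals retained")

  ## 5: identification (must pass before any fit)
  ident <- check_identification(system)
  say("identification: order %s, rank %s, unique instruments %s -> %s",
      if (all(ident$order$pass)) "pass" else "fail",
      if (all(ident$rank$pass)) "pass" else "fail",
      if (is.null(ident$instruments)) "n/a"
      else if (all(ident$instruments$pass)) "pass" else "fail",
      if (ident$identified) "identified" else "NOT identified")
  if (!ident$identified)
    stop_nrsem("pipeline stopped: structural system is not identified (rank condition)")

  ## 6: instrument diagnostics on composite scores, with remediation
  composites <- add_composites(analysis, constructs)
  ivrep <- instrument_report(composites, system)
  dropped <- character()
  if (isTRUE(config$remediate)) {
    repeat {
      bad <- ivrep[!ivrep$strong | (!is.na(ivrep$valid) & !ivrep$valid), , drop = FALSE]
      if (!nrow(bad)) break
      ## delete the reciprocal paths into each failing equation whose own
      ## instrument sets are weak; a dissolved loop ends the iteration
      changed <- FALSE
      for (y in bad$equation) {
        for (v in intersect(system$equations[[y]], system$loop)) {
          iv_v <- setdiff(system$instruments[[v]] %||% character(),
                          system$equations[[y]])
          weak_v <- if (!length(iv_v)) TRUE else {
            cdv <- tryCatch(cragg_donald_f(composites, y, v,
                                           setdiff(system$equations[[y]],
                                                   system$loop), iv_v),
                            error = function(e) list(strong = FALSE))
            !cdv$strong
          }
          if (weak_v) {
            system$equations[[y]] <- setdiff(system$equations[[y]], v)
            dropped <- c(dropped, paste0(y, "<-", v))
            say("remediation: deleted non-recursive path %s <- %s (weak/invalid instruments)", y, v)
            changed <- TRUE
          }
        }
      }
      if (!changed) break
      ## recompute the loop membership and retest
      still_loop <- Filter(function(y) {
        any(system$loop %in% system$equations[[y]]) &&
          any(vapply(setdiff(system$loop, y),
                     function(o) y %in% system$equations[[o]], TRUE))
      }, system$loop)
      system$loop <- still_loop
      if (length(system$loop) < 2) {
        say("remediation: loop dissolved; continuing with a recursive system")
        break
      }
      ivrep <- instrument_report(composites, system)
    }
  }

  ## 7: parcels + fit
  prepared <- prepare_analysis_data(analysis, constructs, k = config$k)
  mtext <- model_from_system(system, constructs, k = config$k,
                             psi_free = config$psi_free)
  fit <- fit_sem(mtext, prepared)
  say("fit: chi-square %.1f on %d df; CFI %.3f; RMSEA %.4f; AIC %.1f",
      fit$chisq, fit$df, fit$indices$cfi, fit$indices$rmsea, fit$indices$aic)

  ## 8: bootstrap + effects
  boot <- NULL
  if (config$n_boot > 0) {
    boot <- bootstrap_fit(fit, prepared, n_boot = config$n_boot,
                          seed = config$seed)
    say("bootstrap: %d replicates (%d failed)", config$n_boot, boot$n_failed)
  }
  effects <- effect_table(fit, boot)
  say("effects: %d predictor-outcome decompositions", nrow(effects))

  list(scored = scored, analysis = analysis, diagnostics = diagnostics,
       identification = ident, instruments = ivrep,
       dropped_paths = dropped, system = system, model = mtext,
       fit = fit, boot = boot, effects = effects, log = log)
}
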