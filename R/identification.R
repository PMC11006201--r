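#' Declare a simultaneous structural system
#'
#' Encodes the structural part of a non-recursive model as named equations:
#' which endogenous variables sit in the feedback loop, which variables enter
#' each equation, and which exogenous variables serve as instruments for each
#' loop variable. The variable roster used for exclusion counting is the
#' union of everything declared here.
#'
#' @param endogenous character vector of endogenous variable names.
#' @param exogenous character vector of exogenous variable names.
#' @param equations named list: for each endogenous variable, the character
#'   vector of its regressors (endogenous and/or exogenous).
#' @param loop endogenous variables participating in the feedback loop
#'   (default: all endogenous variables that appear as regressors of each
#'   other).
#' @param instruments optional named list mapping each loop variable to the
#'   exogenous variables that instrument it (i.e. enter its own equation but
#'   no other loop equation).
#' @return an object of class `structural_system`.
#' @export
structural_system <- function(endogenous, exogenous, equations,
                              loop = NULL, instruments = NULL) {
  all_vars <- c(exogenous, endogenous)
  if (anyDuplicated(all_vars)) stop_nrsem("duplicated variable names")
  if (!all(names(equations) %in% endogenous))
    stop_nrsem("equations declared for non-endogenous variables: %s",
               paste(setdiff(names(equations), endogenous), collapse = ", "))
  for (lhs in names(equations)) {
    rhs <- equations[[lhs]]
    undeclared <- setdiff(rhs, all_vars)
    if (length(undeclared))
      stop_nrsem("equation for %s references undeclared variable(s): %s",
                 lhs, paste(undeclared, collapse = ", "))
    if (lhs %in% rhs) stop_nrsem("%s regresses on itself", lhs)
  }
  if (is.null(loop)) {
    loop <- Filter(function(y) {
      others <- setdiff(names(equations), y)
      y %in% unlist(equations[others]) &&
        any(others %in% equations[[y]])
    }, names(equations))
  }
  reciprocal <- any(vapply(names(equations), function(y)
    any(vapply(setdiff(names(equations), y), function(z)
      y %in% (equations[[z]] %||% character()) &&
        z %in% (equations[[y]] %||% character()), TRUE)), TRUE))
  if (reciprocal && length(loop) < 2)
    stop_nrsem("a reciprocal path exists but fewer than 2 loop variables are declared")
  structure(list(endogenous = endogenous, exogenous = exogenous,
                 equations = equations, loop = loop,
                 instruments = instruments, variables = all_vars),
            class = "structural_system")
}

#' Build the 0/1 system matrix of a structural system
#'
#' Rows are the loop-endogenous equations; columns are all declared
#' variables. An entry is 1 when the column variable appears in that row's
#' equation or is the row's own endogenous variable; 0 marks an excluded
#' variable.
#'
#' @param system a [structural_system()].
#' @return 0/1 matrix with dimnames.
#' @export
build_system_matrix <- function(system) {
  stopifnot(inherits(system, "structural_system"))
  rows <- system$loop
  if (!length(rows)) stop_nrsem("system has no loop equations")
  vars <- system$variables
  m <- matrix(0L, nrow = length(rows), ncol = length(vars),
              dimnames = list(rows, vars))
  for (y in rows) m[y, c(system$equations[[y]], y)] <- 1L
  m
}

#' Order condition (necessary counting rule) per loop equation
#'
#' An equation passes when its number of excluded variables (declared roster
#' minus variables appearing in the equation, minus the dependent variable
#' itself) is at least m - 1, where m is the number of endogenous variables
#' in the loop.
#'
#' @param system a [structural_system()].
#' @return data.frame with `equation`, `excluded`, `required`, `pass`.
#' @export
order_condition <- function(system) {
  m <- build_system_matrix(system)
  n_endo <- length(system$loop)
  excluded <- rowSums(m == 0L)
  data.frame(equation = rownames(m), excluded = as.integer(excluded),
             required = n_endo - 1L, pass = excluded >= n_endo - 1L,
             row.names = NULL)
}

#' Rank condition (sufficient rule) on the system matrix
#'
#' For each loop equation: delete its row and every column carrying a 1 in
#' that row, drop all-zero rows from the remainder, and take the linear-
#' algebra rank of what is left (computed by QR with tolerance 1e-8, exact
#' for 0/1 entries; duplicate or linearly dependent rows are thereby
#' discounted automatically). The equation passes when the rank is at least
#' m - 1.
#'
#' @param sysmat a 0/1 system matrix from [build_system_matrix()], or a
#'   [structural_system()].
#' @return data.frame with `equation`, `rank`, `required`, `pass`.
#' @export
rank_condition <- function(sysmat) {
  if (inherits(sysmat, "structural_system")) sysmat <- build_system_matrix(sysmat)
  if (!is.matrix(sysmat) || !nrow(sysmat)) stop_nrsem("empty system matrix")
  m <- nrow(sysmat)
  res <- lapply(seq_len(m), function(i) {
    keep_cols <- sysmat[i, ] == 0L
    red <- sysmat[-i, keep_cols, drop = FALSE]
    red <- red[rowSums(abs(red)) > 0, , drop = FALSE]
    r <- if (!nrow(red) || !ncol(red)) 0L else qr(red, tol = 1e-8)$rank
    data.frame(equation = rownames(sysmat)[i], rank = as.integer(r),
               required = m - 1L, pass = r >= m - 1L)
  })
  do.call(rbind, res)
}

#' Check that each loop variable has a unique instrument
#'
#' A loop variable passes when at least one of its assigned instruments is
#' (i) a regressor in its own equation, (ii) excluded from every other loop
#' equation, and (iii) not assigned to any other loop variable. An
#' instrument that appears in another loop equation is an invalid
#' assignment and raises an error.
#'
#' @param system a [structural_system()] with an `instruments` map.
#' @return data.frame with `variable`, `unique_instruments` (comma-joined)
#'   and `pass`.
#' @export
check_unique_instruments <- function(system) {
  stopifnot(inherits(system, "structural_system"))
  instr <- system$instruments
  if (is.null(instr)) stop_nrsem("system has no instrument map")
  loop <- system$loop
  res <- lapply(loop, function(y) {
    iv <- instr[[y]] %||% character()
    others <- setdiff(loop, y)
    for (v in iv)
      if (!(v %in% system$equations[[y]]))
        stop_nrsem("instrument %s for %s does not enter %s's equation", v, y, y)
    shared <- unlist(instr[others], use.names = FALSE)
    uniq <- setdiff(iv, shared)              # assigned to this variable only
    for (v in uniq) {
      bad <- others[vapply(others, function(o) v %in% system$equations[[o]], TRUE)]
      if (length(bad))
        stop_nrsem("instrument %s for %s also appears in the equation of %s",
                   v, y, paste(bad, collapse = ", "))
    }
    data.frame(variable = y,
               unique_instruments = paste(uniq, collapse = ","),
               pass = length(uniq) >= 1)
  })
  do.call(rbind, res)
}

#' Full identification report
#'
#' Combines the unique-instrument check (when an instrument map is present),
#' the order condition, and the rank condition; the overall verdict is
#' "identified" iff the rank condition (the sufficient rule) passes for
#' every loop equation.
#'
#' @param system a [structural_system()].
#' @return list of class `identification_report` with elements
#'   `system_matrix`, `order`, `rank`, `instruments` (or NULL) and
#'   `identified`.
#' @export
check_identification <- function(system) {
  sm <- build_system_matrix(system)
  ord <- order_condition(system)
  rk <- rank_condition(sm)
  iv <- if (!is.null(system$instruments)) {
    tryCatch(check_unique_instruments(system), error = function(e)
      data.frame(variable = system$loop, unique_instruments = "",
                 pass = FALSE, note = conditionMessage(e)))
  } else NULL
  structure(list(system_matrix = sm, order = ord, rank = rk,
                 instruments = iv, identified = all(rk$pass)),
            class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat("Identification report\n")
  cat("  order condition: ", if (all(x$order$pass)) "pass" else "FAIL", "\n")
  cat("  rank condition:  ", if (all(x$rank$pass)) "pass" else "FAIL",
      " (ranks ", paste(x$rank$rank, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$instruments))
    cat("  unique instruments: ",
        if (all(x$instruments$pass)) "pass" else "FAIL", "\n")
  cat("  verdict: ", if (x$identified) "identified" else "NOT identified", "\n")
  invisible(x)
}

#' The three-equation depression/anxiety/somatic system
#'
#' The structural system of the motivating adolescent mental-health study:
#' depression, anxiety and somatic symptoms in a feedback loop, seventeen
#' exogenous predictors, and unique instruments per loop variable (death of
#' a loved one, social support and family academic pressure for depression;
#' physical trauma and self-rated academic ability for anxiety; study time
#' and extra tutoring for somatic symptoms).
#'
#' @return a [structural_system()].
#' @export
adolescent_system <- function() {
  exo <- c("alcohol", "chronic_illness", "physical_activity", "family_mental_illness",
           "sex", "school_type", "age", "residence", "grade", "death_of_loved_one",
           "social_support", "physical_trauma", "study_time", "extra_tutoring",
           "family_pressure", "academic_ability", "stress")
  common <- c("alcohol", "chronic_illness", "physical_activity",
              "family_mental_illness", "school_type", "stress")
  structural_system(
    endogenous = c("depression", "anxiety", "somatic"),
    exogenous = exo,
    equations = list(
      depression = c(common, "death_of_loved_one", "social_support",
                     "family_pressure", "anxiety", "somatic"),
      anxiety = c(common, "physical_trauma", "academic_ability",
                  "depression", "somatic"),
      somatic = c(common, "study_time", "extra_tutoring",
                  "depression", "anxiety")),
    loop = c("depression", "anxiety", "somatic"),
    instruments = list(
      depression = c("death_of_loved_one", "social_support", "family_pressure"),
      anxiety = c("physical_trauma", "academic_ability"),
      somatic = c("study_time", "extra_tutoring"))
  )
}
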