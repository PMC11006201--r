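## Compact model-description language, one statement per line:
##   construct =~ item1 + item2 + 1*item3     measurement (loadings)
##   outcome   ~  pred1 + pred2               structural regression
##   a ~~ b                                   free (co)variance
##   a ~~ 0.5*a                               fixed (co)variance
## '#' starts a comment. The first listed indicator of a construct is fixed
## to 1 for scale-setting unless another loading or the construct variance
## is fixed explicitly.

parse_model <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parse_rhs <- function(rhs) {
    terms <- trimws(unlist(strsplit(rhs, "+", fixed = TRUE)))
    terms <- terms[nzchar(terms)]
    fixed <- rep(NA_real_, length(terms))
    var <- terms
    has_star <- grepl("*", terms, fixed = TRUE)
    if (any(has_star)) {
      parts <- strsplit(terms[has_star], "*", fixed = TRUE)
      fixed[has_star] <- vapply(parts, function(p) as.numeric(p[[1]]), 0)
      var[has_star] <- vapply(parts, function(p) trimws(p[[2]]), "")
    }
    data.frame(var = var, fixed = fixed)
  }
  stmts <- lapply(lines, function(ln) {
    for (op in c("=~", "~~", "~")) {
      pos <- regexpr(op, ln, fixed = TRUE)
      if (pos > 0) {
        lhs <- trimws(substr(ln, 1, pos - 1))
        rhs <- trimws(substr(ln, pos + nchar(op), nchar(ln)))
        if (!nzchar(lhs) || !nzchar(rhs)) stop_nrsem("malformed line: '%s'", ln)
        return(list(op = op, lhs = lhs, rhs = parse_rhs(rhs)))
      }
    }
    stop_nrsem("cannot parse model line: '%s'", ln)
  })
  stmts
}

#' Compile a model description against a dataset
#'
#' Translates the model language into reticular-action-model (RAM) form: an
#' asymmetric path matrix A (loadings and regressions), a symmetric
#' (co)variance matrix S over all variables (observed then latent), and the
#' filter onto the observed variables. Free/fixed masks and parameter labels
#' are set up here; estimation happens in [fit_sem()].
#'
#' Defaults: every variable gets a free variance; covariances are free among
#' all exogenous variables (no incoming path) and otherwise only where
#' declared with `~~`; the first indicator of each construct is fixed to 1.
#'
#' @param model model-description string (see [fit_sem()]) or a parsed model.
#' @param data data.frame whose columns define the observed variables.
#' @return an object of class `sem_model`.
#' @export
sem_model <- function(model, data) {
  stmts <- if (is.character(model)) parse_model(model) else model
  latent <- unique(vapply(Filter(function(s) s$op == "=~", stmts),
                          `[[`, "", "lhs"))
  mentioned <- unique(c(
    vapply(stmts, `[[`, "", "lhs"),
    unlist(lapply(stmts, function(s) s$rhs$var))))
  observed <- mentioned[mentioned %in% names(data)]
  unknown <- setdiff(mentioned, c(observed, latent))
  if (length(unknown))
    stop_nrsem("variable(s) neither observed in data nor defined as latent: %s",
               paste(unknown, collapse = ", "))
  ## keep observed variables in data-column order for a stable layout
  observed <- names(data)[names(data) %in% observed]
  vars <- c(observed, latent)
  t_all <- length(vars)
  p <- length(observed)
  ix <- stats::setNames(seq_len(t_all), vars)

  A_free <- matrix(FALSE, t_all, t_all, dimnames = list(vars, vars))
  A_val <- matrix(0, t_all, t_all, dimnames = list(vars, vars))
  S_free <- matrix(FALSE, t_all, t_all, dimnames = list(vars, vars))
  S_val <- matrix(0, t_all, t_all, dimnames = list(vars, vars))
  S_set <- matrix(FALSE, t_all, t_all)        # explicitly declared via ~~

  indicators <- stats::setNames(vector("list", length(latent)), latent)
  regressions <- character()

  for (s in stmts) {
    i <- ix[[s$lhs]]
    for (k in seq_len(nrow(s$rhs))) {
      v <- s$rhs$var[k]; fx <- s$rhs$fixed[k]
      j <- ix[[v]]
      if (s$op == "=~") {            # lhs is the construct, path lhs -> var
        if (is.na(fx)) A_free[j, i] <- TRUE else A_val[j, i] <- fx
        indicators[[s$lhs]] <- c(indicators[[s$lhs]], v)
        if (!is.na(fx)) attr(indicators[[s$lhs]], "has_fixed") <- TRUE
      } else if (s$op == "~") {      # path var -> lhs
        if (i == j) stop_nrsem("%s cannot regress on itself", s$lhs)
        if (is.na(fx)) A_free[i, j] <- TRUE else A_val[i, j] <- fx
        regressions <- c(regressions, s$lhs)
      } else {                       # ~~ (co)variance
        if (is.na(fx)) { S_free[i, j] <- S_free[j, i] <- TRUE }
        else { S_free[i, j] <- S_free[j, i] <- FALSE
               S_val[i, j] <- S_val[j, i] <- fx }
        S_set[i, j] <- S_set[j, i] <- TRUE
      }
    }
  }

  ## scale-setting: fix the first loading of each construct unless the user
  ## fixed a loading (or the construct variance) themselves
  for (l in latent) {
    inds <- indicators[[l]]
    if (is.null(inds)) next
    li <- ix[[l]]
    any_fixed <- isTRUE(attr(inds, "has_fixed")) ||
      (S_set[li, li] && !S_free[li, li])
    if (!any_fixed) {
      j <- ix[[inds[1]]]
      A_free[j, li] <- FALSE
      A_val[j, li] <- 1
    }
  }

  ## default variances: free for every variable unless fixed explicitly
  for (v in vars) {
    i <- ix[[v]]
    if (!S_set[i, i]) S_free[i, i] <- TRUE
  }
  ## default covariances among exogenous variables (no incoming path)
  exo <- vars[vapply(vars, function(v) {
    i <- ix[[v]]
    !any(A_free[i, ] | A_val[i, ] != 0)      # nothing points into v
  }, TRUE)]
  if (length(exo) > 1) {
    for (a in seq_along(exo)[-1]) for (b in seq_len(a - 1)) {
      i <- ix[[exo[a]]]; j <- ix[[exo[b]]]
      if (!S_set[i, j]) S_free[i, j] <- S_free[j, i] <- TRUE
    }
  }

  ## parameter table
  params <- list()
  for (j in seq_len(t_all)) for (i in seq_len(t_all))
    if (A_free[i, j])
      params[[length(params) + 1]] <-
        data.frame(matrix_name = "A", row = i, col = j,
                   label = if (j > p && i <= p && !is.null(indicators[[vars[j]]]) &&
                                vars[i] %in% indicators[[vars[j]]])
                     paste0(vars[j], "=~", vars[i])
                   else paste0(vars[i], "~", vars[j]))
  for (i in seq_len(t_all)) for (j in seq_len(i))
    if (S_free[i, j])
      params[[length(params) + 1]] <-
        data.frame(matrix_name = "S", row = i, col = j,
                   label = paste0(vars[j], "~~", vars[i]))
  params <- do.call(rbind, params)
  structure(list(vars = vars, observed = observed, latent = latent,
                 p = p, t = t_all, ix = ix,
                 A_free = A_free, A_val = A_val,
                 S_free = S_free, S_val = S_val,
                 indicators = lapply(indicators, as.character),
                 endo_structural = unique(regressions),
                 params = params, q = nrow(params)),
            class = "sem_model")
}

## fill A and S from a parameter vector
fill_matrices <- function(model, theta) {
  A <- model$A_val; S <- model$S_val
  pr <- model$params
  isA <- pr$matrix_name == "A"
  A[cbind(pr$row[isA], pr$col[isA])] <- theta[isA]
  iS <- which(!isA)
  S[cbind(pr$row[iS], pr$col[iS])] <- theta[iS]
  S[cbind(pr$col[iS], pr$row[iS])] <- theta[iS]
  list(A = A, S = S)
}

#' Model-implied covariance matrix of the observed variables
#'
#' RAM form: with E = (I - A)^-1, the covariance of all variables is
#' M = E S E' and the observed block is the implied covariance. Equivalent
#' to the usual structural-form expression
#' Sigma_yy = Lambda (I - B)^-1 (Gamma Phi Gamma' + Psi) (I - B)^-T Lambda' + Theta.
#'
#' @param model a [sem_model()].
#' @param theta parameter vector (defaults taken from a fit via
#'   [implied_covariance.nrsem_fit]).
#' @param full return the covariance over latent variables too.
#' @return implied covariance matrix (observed block, or full).
#' @export
implied_covariance <- function(model, theta, full = FALSE) {
  if (inherits(model, "nrsem_fit")) {
    if (missing(theta)) theta <- model$est
    model <- model$model
  }
  mats <- fill_matrices(model, theta)
  IA <- diag(model$t) - mats$A
  E <- tryCatch(solve(IA), error = function(e) NULL)
  if (is.null(E)) {
    loop <- model$endo_structural
    stop_nrsem("(I - B) is singular: the feedback loop among {%s} is non-invertible",
               paste(loop, collapse = ", "))
  }
  M <- E %*% mats$S %*% t(E)
  dimnames(M) <- list(model$vars, model$vars)
  if (full) M else M[seq_len(model$p), seq_len(model$p), drop = FALSE]
}

#' Maximum-likelihood discrepancy between sample and implied covariance
#'
#' F = log|Sigma| + tr(S Sigma^-1) - log|S| - p; chi-square = (n - 1) F.
#' Non-negative, and zero exactly when Sigma equals S.
#'
#' @param S sample covariance matrix.
#' @param Sigma model-implied covariance matrix.
#' @param n sample size (for the chi-square; optional).
#' @return list with `F` and (when `n` given) `chisq`.
#' @export
ml_discrepancy <- function(S, Sigma, n = NULL) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  p <- ncol(S)
  ldS <- logdet_pd(S); ldSig <- logdet_pd(Sigma)
  if (is.na(ldS) || is.na(ldSig))
    stop_nrsem("S and Sigma must both be positive definite")
  Fv <- ldSig + sum(diag(S %*% chol2inv(chol(Sigma)))) - ldS - p
  Fv <- max(Fv, 0)                     # guard tiny negative rounding
  out <- list(F = Fv)
  if (!is.null(n)) out$chisq <- (n - 1) * Fv
  out
}
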