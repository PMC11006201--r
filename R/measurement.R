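#' Confirmatory factor analysis of a set of constructs
#'
#' Builds and fits a measurement-only model: each item loads on exactly one
#' construct (first loading fixed to 1), construct covariances free,
#' uncorrelated errors. Structural paths are absent, so this is [fit_sem()]
#' with a pure loading structure.
#'
#' @param constructs named list mapping construct name to its item columns.
#' @param data data.frame of item responses.
#' @param ... passed to [fit_sem()].
#' @return an `nrsem_fit`.
#' @export
#' @examples
#' \donttest{
#' dat <- generate_dataset(default_population_spec(n = 500), seed = 1)
#' fit <- fit_cfa(list(stress = paste0("pss", 1:10)), dat)
#' }
fit_cfa <- function(constructs, data, ...) {
  stopifnot(is.list(constructs), !is.null(names(constructs)))
  for (cn in names(constructs))
    if (length(constructs[[cn]]) < 2 && length(constructs) < 2)
      stop_nrsem("construct %s has fewer than 2 indicators", cn)
  txt <- paste(vapply(names(constructs), function(cn)
    paste(cn, "=~", paste(constructs[[cn]], collapse = " + ")), ""),
    collapse = "\n")
  fit_sem(txt, data, ...)
}

#' Factorial (loading-balanced) item parcels
#'
#' Assigns a construct's items to `k` parcels by the item-to-construct
#' balance rule: sort items by absolute loading, descending (ties broken by
#' item order), then deal them to parcels in serpentine order
#' (1..k, k..1, ...), so each parcel mixes strong and weak indicators.
#' Parcel scores are the means of their constituent items. When loadings
#' are not supplied they are estimated from a one-factor ML fit
#' ([stats::factanal()]; first principal component if that fails).
#'
#' @param data data.frame holding the item columns.
#' @param items character vector of the construct's items.
#' @param k number of parcels; `k = length(items)` returns one item per
#'   parcel (identity).
#' @param loadings optional numeric vector of item loadings (same order as
#'   `items`).
#' @param prefix name prefix for parcel score columns.
#' @return list with `plan` (list of item character vectors per parcel),
#'   `loadings` used, and `scores` (data.frame of parcel means, NA when a
#'   constituent item is missing).
#' @export
make_parcels <- function(data, items, k = 3, loadings = NULL,
                         prefix = "parcel") {
  if (k < 2) stop_nrsem("k = %d parcels cannot keep the construct latent", k)
  if (k > length(items)) stop_nrsem("more parcels (%d) than items (%d)", k, length(items))
  if (is.null(loadings)) {
    m <- as.matrix(data[items])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    loadings <- tryCatch(
      as.numeric(stats::factanal(m, factors = 1)$loadings),
      error = function(e) {
        e1 <- eigen(stats::cor(m), symmetric = TRUE)
        as.numeric(e1$vectors[, 1] * sqrt(e1$values[1]))
      })
  }
  stopifnot(length(loadings) == length(items))
  ord <- order(-abs(loadings), seq_along(items))   # ties: item order
  serp <- rep(c(seq_len(k), rev(seq_len(k))), length.out = length(items))
  plan <- split(items[ord], serp)[as.character(seq_len(k))]
  plan <- lapply(plan, function(it) it[order(match(it, items))])
  names(plan) <- paste0(prefix, seq_len(k))
  scores <- as.data.frame(lapply(plan, function(it)
    rowMeans(data[it], na.rm = FALSE)))
  list(plan = plan, loadings = stats::setNames(loadings, items), scores = scores)
}

#' Append parcel scores for several constructs
#'
#' @param data data.frame with item columns.
#' @param constructs named list construct -> items.
#' @param k parcels per construct (scalar or named vector); constructs with
#'   fewer than 6 items default to 2 parcels, at most the item count.
#' @return list with `data` (input plus `<construct>_p<i>` columns) and
#'   `plans` per construct.
#' @export
add_parcels <- function(data, constructs, k = 3) {
  plans <- list()
  for (cn in names(constructs)) {
    items <- constructs[[cn]]
    kc <- if (length(k) > 1) k[[cn]] else k
    kc <- min(kc, length(items))
    if (length(items) < 6) kc <- min(2, length(items)) # small scales: 2 parcels
    if (length(items) <= 3) {                          # too small to parcel
      plans[[cn]] <- list(plan = as.list(stats::setNames(items, items)))
      next
    }
    pc <- make_parcels(data, items, k = kc, prefix = paste0(cn, "_p"))
    names(pc$scores) <- paste0(cn, "_p", seq_len(kc))
    data <- cbind(data, pc$scores)
    plans[[cn]] <- pc
  }
  list(data = data, plans = plans)
}
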