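#' Define a questionnaire scale
#'
#' A scale is a set of item columns with a common response range, an optional
#' binary screening cutoff on the total score, and optional ordered severity
#' bands. Totals are plain item sums; a total is missing whenever any
#' constituent item is missing (no proration).
#'
#' @param name scale name.
#' @param items character vector of item column names.
#' @param item_min,item_max per-item response range (recycled to all items).
#' @param cutoff optional screening cutoff: flag positive iff total >= cutoff.
#' @param bands optional data.frame with columns `label`, `lo`, `hi` giving
#'   non-overlapping, ordered severity bands on the total score.
#' @return an object of class `scale_definition`.
#' @export
#' @examples
#' phq <- scale_definition("PHQ-9A", paste0("phq", 1:9), 0, 3, cutoff = 10)
scale_definition <- function(name, items, item_min = 0, item_max,
                             cutoff = NULL, bands = NULL) {
  stopifnot(is.character(items), length(items) >= 1)
  item_min <- rep_len(item_min, length(items))
  item_max <- rep_len(item_max, length(items))
  if (any(item_max <= item_min)) stop_nrsem("item_max must exceed item_min")
  tot_lo <- sum(item_min); tot_hi <- sum(item_max)
  if (!is.null(cutoff) && (cutoff < tot_lo || cutoff > tot_hi))
    stop_nrsem("cutoff %s outside total-score range [%s, %s]", cutoff, tot_lo, tot_hi)
  if (!is.null(bands)) {
    stopifnot(all(c("label", "lo", "hi") %in% names(bands)))
    bands <- bands[order(bands$lo), , drop = FALSE]
    if (any(bands$hi < bands$lo)) stop_nrsem("band hi < lo")
    if (nrow(bands) > 1 && any(bands$lo[-1] <= bands$hi[-nrow(bands)]))
      stop_nrsem("bands overlap")
    if (min(bands$lo) < tot_lo || max(bands$hi) > tot_hi)
      stop_nrsem("bands exceed the attainable total range [%s, %s]", tot_lo, tot_hi)
  }
  structure(list(name = name, items = items, item_min = item_min,
                 item_max = item_max, cutoff = cutoff, bands = bands,
                 total_range = c(tot_lo, tot_hi)),
            class = "scale_definition")
}

#' Built-in definitions of the five survey instruments
#'
#' PHQ-9A (depression, 9 items 0-3, positive at total >= 10), GAD-7 (anxiety,
#' 7 items 0-3, positive at >= 10), SSS-8 (somatic symptom burden, 8 items
#' 0-4, severity bands low 4-7 / medium 8-11 / high 12-15 / very high 16-32,
#' with totals below 4 labelled minimal), PSS-10 (perceived stress, 10 items
#' 0-4, bands low 0-13 / moderate 14-26 / high 27-40) and OSSS-3 (social
#' support; first item 1-4, remaining items 1-5, bands poor 3-8 / moderate
#' 9-11 / strong 12-14).
#'
#' @return named list of [scale_definition()] objects.
#' @export
builtin_scales <- function() {
  band_df <- function(label, lo, hi) data.frame(label = label, lo = lo, hi = hi)
  list(
    phq9a = scale_definition("PHQ-9A", paste0("phq", 1:9), 0, 3, cutoff = 10,
      bands = band_df(c("minimal", "mild", "moderate", "moderately severe", "severe"),
                      c(0, 5, 10, 15, 20), c(4, 9, 14, 19, 27))),
    gad7 = scale_definition("GAD-7", paste0("gad", 1:7), 0, 3, cutoff = 10,
      bands = band_df(c("minimal", "mild", "moderate", "severe"),
                      c(0, 5, 10, 15), c(4, 9, 14, 21))),
    sss8 = scale_definition("SSS-8", paste0("sss", 1:8), 0, 4,
      bands = band_df(c("minimal", "low", "medium", "high", "very high"),
                      c(0, 4, 8, 12, 16), c(3, 7, 11, 15, 32))),
    pss10 = scale_definition("PSS-10", paste0("pss", 1:10), 0, 4,
      bands = band_df(c("low", "moderate", "high"),
                      c(0, 14, 27), c(13, 26, 40))),
    osss3 = scale_definition("OSSS-3", paste0("oss", 1:3),
      item_min = c(1, 1, 1), item_max = c(4, 5, 5),
      bands = band_df(c("poor", "moderate", "strong"),
                      c(3, 9, 12), c(8, 11, 14)))
  )
}

#' Score a scale by summing its items
#'
#' @param responses data.frame containing the item columns.
#' @param scale a [scale_definition()].
#' @return numeric vector of totals; `NA` where any constituent item is
#'   missing.
#' @export
score_scale <- function(responses, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  missing_cols <- setdiff(scale$items, names(responses))
  if (length(missing_cols))
    stop_nrsem("missing item columns for %s: %s", scale$name,
               paste(missing_cols, collapse = ", "))
  m <- as.matrix(responses[scale$items])
  bad <- which(!is.na(m) & (sweep(m, 2, scale$item_min, `<`) |
                            sweep(m, 2, scale$item_max, `>`)), arr.ind = TRUE)
  if (nrow(bad))
    stop_nrsem("out-of-range values in %s: row %s item %s (first of %d)",
               scale$name, bad[1, 1], scale$items[bad[1, 2]], nrow(bad))
  totals <- rowSums(m)      # NA propagates when any item is NA
  as.numeric(totals)
}

#' Classify scale totals into screening flags and severity bands
#'
#' @param totals numeric vector of totals from [score_scale()].
#' @param scale the [scale_definition()] used.
#' @return data.frame with `total`, `flag` (logical, if the scale has a
#'   cutoff) and `band` (character, if the scale has bands). A total falling
#'   in no band is labelled `"unbanded"`.
#' @export
classify_scale <- function(totals, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  out <- data.frame(total = totals)
  if (!is.null(scale$cutoff)) out$flag <- totals >= scale$cutoff
  if (!is.null(scale$bands)) {
    b <- scale$bands
    band <- rep(NA_character_, length(totals))
    for (i in seq_len(nrow(b)))
      band[!is.na(totals) & totals >= b$lo[i] & totals <= b$hi[i]] <- b$label[i]
    band[!is.na(totals) & is.na(band)] <- "unbanded"
    out$band <- band
  }
  out
}

#' Prevalence of a binary flag with a confidence interval
#'
#' @param flags logical vector (NA allowed; dropped).
#' @param conf confidence level.
#' @param method `"wilson"` (default) or `"exact"` (Clopper-Pearson via
#'   [stats::binom.test()]).
#' @return list with `prevalence` (proportion), `lower`, `upper`, `n`, `x`,
#'   and `method`.
#' @export
prevalence <- function(flags, conf = 0.95, method = c("wilson", "exact")) {
  method <- match.arg(method)
  flags <- flags[!is.na(flags)]
  n <- length(flags)
  if (n == 0) stop_nrsem("no non-missing flags: prevalence undefined")
  x <- sum(flags)
  ci <- if (method == "wilson") wilson_interval(x, n, conf)
        else as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int)
  list(prevalence = x / n, lower = ci[[1]], upper = ci[[2]],
       n = n, x = x, method = method)
}

#' Listwise deletion with a guard on the dropped fraction
#'
#' Drops records with any missing value in `vars`, but only when the dropped
#' fraction does not exceed `max_fraction`; otherwise refuses, reporting the
#' fraction, so that a heavier missing-data mechanism is handled deliberately
#' rather than silently.
#'
#' @param data data.frame.
#' @param vars columns considered analysis variables (default: all).
#' @param max_fraction largest tolerable dropped fraction, in (0, 0.5].
#' @return the complete-case data.frame, with attributes `n_dropped` and
#'   `fraction_dropped`.
#' @export
apply_listwise <- function(data, vars = names(data), max_fraction = 0.05) {
  stopifnot(max_fraction > 0, max_fraction <= 0.5)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop_nrsem("unknown analysis columns: %s", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[vars])
  frac <- mean(!keep)
  if (frac > max_fraction)
    stop_nrsem(paste0("%.1f%% of records are incomplete, above the %.1f%% limit; ",
                      "listwise deletion refused - consider imputation or a ",
                      "missing-data model"), 100 * frac, 100 * max_fraction)
  out <- data[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "fraction_dropped") <- frac
  out
}

#' Score all built-in instruments on a dataset
#'
#' Convenience wrapper: totals, screening flags and severity bands for every
#' scale in [builtin_scales()] whose items are present in `data`.
#'
#' @param data data.frame of item responses.
#' @return data.frame of per-record totals (`<scale>_total`), flags and bands.
#' @export
score_dataset <- function(data) {
  defs <- builtin_scales()
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (nm in names(defs)) {
    def <- defs[[nm]]
    if (!all(def$items %in% names(data))) next
    totals <- score_scale(data, def)
    cls <- classify_scale(totals, def)
    out[[paste0(nm, "_total")]] <- totals
    if (!is.null(cls$flag)) out[[paste0(nm, "_flag")]] <- cls$flag
    if (!is.null(cls$band)) out[[paste0(nm, "_band")]] <- cls$band
  }
  out
}
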