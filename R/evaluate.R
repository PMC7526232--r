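#' Per-recording confusion table
#'
#' Cross-tabulates predicted against reference presence labels on a matched
#' recording set. Positive means the reference tag is present.
#'
#' @param pred,ref Data frames with columns `recording_id` and `present`
#'   (logical). The two recording sets must coincide.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, ref) {
  if (!setequal(pred$recording_id, ref$recording_id) ||
      nrow(pred) != nrow(ref)) {
    stop("prediction and reference cover different recording sets",
         call. = FALSE)
  }
  m <- dplyr::inner_join(
    dplyr::select(pred, "recording_id", pred = "present"),
    dplyr::select(ref, "recording_id", ref = "present"),
    by = "recording_id"
  )
  confusion_counts(m$pred, m$ref)
}

confusion_counts <- function(pred, ref) {
  tibble::tibble(
    tp = sum(pred & ref), fp = sum(pred & !ref),
    tn = sum(!pred & !ref), fn = sum(!pred & ref)
  )
}

#' Percent-agreement metrics from a confusion table
#'
#' PPA (positive percent agreement) and NPA (negative percent agreement) are
#' the sensitivity/specificity analogs used when the reference standard is
#' expert annotation: `ppa = tp / (tp + fn)`, `npa = tn / (tn + fp)`. The
#' reported TPR equals PPA under the default definition; a precision-style
#' alternative `tp / (tp + fp)` is available because both conventions appear
#' in the applied literature. Metrics with a zero denominator are `NA`
#' (undefined), never 0.
#'
#' @param ct A confusion table from [confusion()].
#' @param tpr_definition `"ppa"` (default) or `"precision"`.
#' @return A one-row tibble with `ppa`, `npa`, `tpr`.
#' @export
ppa_npa <- function(ct, tpr_definition = c("ppa", "precision")) {
  tpr_definition <- match.arg(tpr_definition)
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  ppa <- rat(ct$tp, ct$tp + ct$fn)
  npa <- rat(ct$tn, ct$tn + ct$fp)
  tpr <- if (tpr_definition == "ppa") ppa else rat(ct$tp, ct$tp + ct$fp)
  tibble::tibble(ppa = ppa, npa = npa, tpr = tpr)
}

#' ROC operating points over score cutoffs
#'
#' Enumerates every achievable operating point of the strict-`>` labelling
#' rule: one point per distinct score value plus a sentinel point just below
#' the minimum score (the only way to call every recording positive; its
#' cutoff may fall below 0 when the minimum score is 0). Points are returned
#' in increasing cutoff order; `(1 - npa, ppa)` traces the ROC curve.
#'
#' @param data A data frame of per-recording results.
#' @param score,truth Unquoted columns of `data`: the continuous score and
#'   the logical reference label. Both at least one positive and one
#'   negative reference label are required.
#' @param tpr_definition Passed to [ppa_npa()].
#' @return A tibble of class `auscultr_roc` with columns `cutoff`, `tp`,
#'   `fp`, `tn`, `fn`, `ppa`, `npa`, `tpr`.
#' @examples
#' d <- tibble::tibble(s = c(0, 0.3, 0.5), y = c(FALSE, TRUE, TRUE))
#' roc(d, s, y)
#' @export
roc <- function(data, score, truth, tpr_definition = c("ppa", "precision")) {
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ truth }})
  stopifnot(is.numeric(s), is.logical(y), length(s) == length(y))
  if (all(y) || !any(y)) {
    stop("reference labels must include at least one positive and one ",
         "negative recording", call. = FALSE)
  }
  distinct <- sort(unique(s))
  sentinel <- if (length(distinct) > 1) {
    distinct[1] - min(diff(distinct)) / 2
  } else {
    distinct[1] - 0.01
  }
  cutoffs <- c(sentinel, distinct)
  pts <- dplyr::bind_rows(lapply(cutoffs, function(cut) {
    ct <- confusion_counts(s > cut, y)
    dplyr::bind_cols(tibble::tibble(cutoff = cut), ct,
                     ppa_npa(ct, tpr_definition))
  }))
  class(pts) <- c("auscultr_roc", class(pts))
  pts
}

#' Optimal cutoff interval from ROC operating points
#'
#' Selects the operating point maximizing the criterion (default
#' Youden-style `ppa + npa`, balancing the two agreements), breaking ties
#' toward higher NPA and then lower cutoff, and reports the maximal
#' contiguous cutoff interval over which the confusion table is unchanged:
#' `[cutoff_lo, cutoff_hi)` where `cutoff_hi` is the next distinct score
#' above (or 1 at the top of the scale).
#'
#' @param points An `auscultr_roc` tibble from [roc()].
#' @param criterion A function of `(ppa, npa)` returning the value to
#'   maximize; default `ppa + npa`.
#' @return A one-row tibble with `cutoff_lo`, `cutoff_hi`, `ppa`, `npa`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
optimal_cutoff_interval <- function(points,
                                    criterion = function(ppa, npa) ppa + npa) {
  stopifnot(nrow(points) >= 1)
  val <- criterion(points$ppa, points$npa)
  val[is.na(val)] <- -Inf
  best <- which(val == max(val))
  if (length(best) > 1) {
    best <- best[order(-points$npa[best], points$cutoff[best])][1]
  }
  hi <- if (nrow(points) == 1) {
    points$cutoff[best] # single candidate: degenerate interval
  } else if (best < nrow(points)) {
    points$cutoff[best + 1]
  } else {
    1
  }
  tibble::tibble(
    cutoff_lo = points$cutoff[best], cutoff_hi = hi,
    ppa = points$ppa[best], npa = points$npa[best],
    tp = points$tp[best], fp = points$fp[best],
    tn = points$tn[best], fn = points$fn[best]
  )
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two raters' tag vectors:
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e`
#' computed from the product of the raters' marginal category frequencies.
#' If both raters assign a single identical category throughout, `p_e = 1`
#' and kappa is defined as 1 by convention (with a message), since observed
#' agreement is perfect.
#'
#' @param tags_a,tags_b Equal-length vectors (logical, character or factor)
#'   of category assignments for the same recordings.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(tags_a, tags_b) {
  stopifnot(length(tags_a) == length(tags_b), length(tags_a) > 0)
  levels_all <- sort(unique(c(as.character(tags_a), as.character(tags_b))))
  a <- factor(as.character(tags_a), levels = levels_all)
  b <- factor(as.character(tags_b), levels = levels_all)
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / n) * (table(b) / n))
  if (isTRUE(all.equal(p_e, 1))) {
    message("both raters constant and identical; kappa = 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Summarize a cohort manifest, Table-1 style
#'
#' Participant-level demographics (median and IQR for age and weight,
#' percent female) and per-group counts with integer percentages of
#' participants, plus recording-level accounting.
#'
#' @param manifest A [cohort_manifest()] tibble.
#' @return A list of class `cohort_summary`: `n_participants`,
#'   `n_recordings` (non-excluded), `n_recordings_total`, `demographics`
#'   (one-row tibble: median/IQR age and weight, `pct_female`), and `groups`
#'   (tibble with `group`, `n`, `pct`).
#' @export
cohort_summary <- function(manifest) {
  stopifnot(nrow(manifest) > 0)
  parts <- dplyr::distinct(
    manifest, .data$participant_id, .data$group, .data$sex,
    .data$age_years, .data$weight_kg
  )
  n <- nrow(parts)
  iqr <- function(x) diff(stats::quantile(x, c(0.25, 0.75), names = FALSE))
  demo <- tibble::tibble(
    age_median = stats::median(parts$age_years),
    age_iqr = iqr(parts$age_years),
    weight_median = stats::median(parts$weight_kg),
    weight_iqr = iqr(parts$weight_kg),
    n_female = sum(parts$sex == "female"),
    pct_female = round(100 * sum(parts$sex == "female") / n)
  )
  groups <- parts |>
    dplyr::count(.data$group) |>
    dplyr::mutate(pct = round(100 * .data$n / .env$n))
  structure(
    list(
      n_participants = n,
      n_recordings = sum(!manifest$excluded),
      n_recordings_total = nrow(manifest),
      demographics = demo,
      groups = groups
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d participants, %d analyzable recordings (of %d)\n",
              x$n_participants, x$n_recordings, x$n_recordings_total))
  cat(sprintf("  age %.1f y (IQR %.1f), weight %.1f kg (IQR %.1f), %d%% female\n",
              x$demographics$age_median, x$demographics$age_iqr,
              x$demographics$weight_median, x$demographics$weight_iqr,
              x$demographics$pct_female))
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf("  %-20s %2d (%d%%)\n", x$groups$group[i], x$groups$n[i],
                x$groups$pct[i]))
  }
  invisible(x)
}
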