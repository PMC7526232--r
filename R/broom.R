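#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation object
#'
#' Returns every ROC operating point as one tibble row: device, sound type,
#' cutoff, confusion counts and PPA/NPA/TPR.
#'
#' @param x An `auscultr_eval` from [evaluate_scores()].
#' @param ... Ignored.
#' @exportS3Method generics::tidy
tidy.auscultr_eval <- function(x, ...) {
  out <- x$points
  class(out) <- class(tibble::tibble())
  out
}

#' Glance at an evaluation object
#'
#' One-row summary: number of recordings evaluated, strata counts, and the
#' range of optimized PPA/NPA across device x sound strata.
#'
#' @param x An `auscultr_eval` from [evaluate_scores()].
#' @param ... Ignored.
#' @exportS3Method generics::glance
glance.auscultr_eval <- function(x, ...) {
  tibble::tibble(
    n_recordings = x$n_recordings,
    n_strata = nrow(x$optimal),
    min_optimal_ppa = min(x$optimal$ppa),
    max_optimal_ppa = max(x$optimal$ppa),
    min_optimal_npa = min(x$optimal$npa),
    max_optimal_npa = max(x$optimal$npa)
  )
}
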