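#' Severity weights and overall-severity quantile thresholds
#'
#' The cumulative score weights each error proportion by the severity of the
#' error: by default 0.2 for severity "a" (low), 0.5 for "b" (medium) and 1.0
#' for "c" (severe), down-weighting less severe errors. Overall severity
#' levels are derived from quantiles of each annotator's own score
#' distribution; `q_low` and `q_high` (defaults 0.5 and 0.75) are the two
#' thresholds.
#'
#' @param w_a,w_b,w_c Non-negative severity weights. A warning (not an error)
#'   is issued when they are not non-decreasing, since an inverted weighting
#'   is almost certainly a mistake but may be wanted in sensitivity analyses.
#' @param q_low,q_high Quantile thresholds, `0 < q_low < q_high < 1`.
#' @return A `weight_config` list with elements `weights` (named numeric over
#'   `a`, `b`, `c`) and `quantiles` (named numeric `low`, `high`).
#' @export
weight_config <- function(w_a = 0.2, w_b = 0.5, w_c = 1.0,
                          q_low = 0.5, q_high = 0.75) {
  stopifnot(w_a >= 0, w_b >= 0, w_c >= 0)
  if (!(w_a <= w_b && w_b <= w_c)) {
    warning("severity weights are not non-decreasing (w_a <= w_b <= w_c)",
            call. = FALSE)
  }
  if (!(q_low > 0 && q_low < q_high && q_high < 1)) {
    stop("quantile thresholds must satisfy 0 < q_low < q_high < 1",
         call. = FALSE)
  }
  structure(
    list(weights = c(a = w_a, b = w_b, c = w_c),
         quantiles = c(low = q_low, high = q_high)),
    class = "weight_config"
  )
}

#' Per-cell proportion of errors
#'
#' For each annotation and each (region, error type, severity) cell, the
#' proportion of errors is the number of erroneous parts divided by the number
#' of parts of that region present, or expected present given the number of
#' people and what is or should be visible. A region that is not visible
#' (expected count 0) carries proportion 0 by convention; validation
#' guarantees it also carries no error counts.
#'
#' @param set An [annotation_set()]; must validate cleanly.
#' @param check Run [validate_annotations()] first (default `TRUE`).
#' @return Sparse tibble with columns `image_id`, `annotator`, `region`,
#'   `error_type`, `severity`, `count`, `expected_count`, `pe`. Cells absent
#'   from the result have proportion 0.
#' @export
error_proportions <- function(set, check = TRUE) {
  stopifnot(inherits(set, "annotation_set"))
  if (check) stop_if_invalid(set)
  set$errors |>
    dplyr::left_join(set$expected, by = c("image_id", "annotator", "region")) |>
    dplyr::mutate(
      pe = ifelse(.data$expected_count == 0L, 0,
                  .data$count / .data$expected_count)
    )
}

#' Severity-weighted cumulative score per annotation
#'
#' The cumulative score of an image annotation is the sum, over all 25
#' (region, error type) cells, of the severity-weighted error proportions:
#' `C = sum_ij (w_a * PE_ija + w_b * PE_ijb + w_c * PE_ijc)`. Each proportion
#' lies in \[0, 1\], so the score lies in \[0, 25 * w_c\]; 0 means no error
#' was recorded anywhere. Double annotations are scored independently per
#' (image, annotator) — there is no reconciliation or averaging.
#'
#' @param set An [annotation_set()]; must validate cleanly.
#' @param weights A [weight_config()].
#' @param check Run [validate_annotations()] first (default `TRUE`).
#' @return Tibble with one row per annotation: `image_id`, `model`, `prompt`,
#'   `annotator`, `person_count`, `cumulative`. The weight configuration is
#'   attached as attribute `"weights"` for downstream use.
#' @seealso [overall_severity()], [summarize_annotations()]
#' @export
cumulative_scores <- function(set, weights = weight_config(), check = TRUE) {
  stopifnot(inherits(set, "annotation_set"), inherits(weights, "weight_config"))
  pe <- error_proportions(set, check = check)
  w <- weights$weights
  contrib <- pe |>
    dplyr::mutate(term = unname(w[.data$severity]) * .data$pe) |>
    dplyr::summarise(cumulative = sum(.data$term),
                     .by = c("image_id", "annotator"))
  scores <- set$annotations |>
    dplyr::left_join(contrib, by = c("image_id", "annotator")) |>
    dplyr::mutate(cumulative = dplyr::coalesce(.data$cumulative, 0))
  attr(scores, "weights") <- weights
  scores
}

#' Overall error severity level per annotation
#'
#' Categorises each scored annotation as overall severity `low`, `medium` or
#' `high` using quantiles of the cumulative-score distribution *of that
#' annotator's own annotations*: scores at or below the annotator's `q_low`
#' quantile (default 0.5) are `low`, scores at or below the `q_high` quantile
#' (default 0.75) are `medium`, and scores above it are `high`. Quantiles use
#' linear interpolation between order statistics (R's default type 7);
#' thresholds are always computed on the annotator's full score set, never
#' per model or prompt stratum, so one annotator's thresholds can never
#' influence another's labels.
#'
#' @param scores Output of [cumulative_scores()].
#' @param weights A [weight_config()] supplying the quantile thresholds;
#'   defaults to the configuration attached to `scores`.
#' @return `scores` with an added ordered factor column `severity_level`
#'   (`low < medium < high`).
#' @export
overall_severity <- function(scores, weights = NULL) {
  if (is.null(weights)) weights <- attr(scores, "weights")
  if (is.null(weights)) weights <- weight_config()
  stopifnot(inherits(weights, "weight_config"), "cumulative" %in% names(scores))
  counts <- table(scores$annotator)
  if (any(counts < 2L)) {
    stop("quantile thresholds are undefined for annotator(s) with fewer ",
         "than 2 scored images: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  q <- weights$quantiles
  out <- scores |>
    dplyr::mutate(
      .q_low = stats::quantile(.data$cumulative, q[["low"]], type = 7),
      .q_high = stats::quantile(.data$cumulative, q[["high"]], type = 7),
      .by = "annotator"
    ) |>
    dplyr::mutate(
      severity_level = factor(
        ifelse(.data$cumulative <= .data$.q_low, "low",
               ifelse(.data$cumulative <= .data$.q_high, "medium", "high")),
        levels = c("low", "medium", "high"), ordered = TRUE
      )
    ) |>
    dplyr::select(-".q_low", -".q_high")
  attr(out, "weights") <- weights
  out
}
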