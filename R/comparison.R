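#' Group summaries of cumulative scores and severity aggregates
#'
#' Aggregates a scored annotation set along one dimension. For `"model"` and
#' `"prompt"` the annotations are partitioned by label and each group gets
#' its annotation count, the mean and sample variance (n - 1) of the
#' cumulative scores, and the per-severity aggregate scores: the *unweighted*
#' sums of error proportions over all annotations and all (region, error
#' type) cells of the group. For `"error_type"` and `"region"` only the
#' severity aggregates are returned (summed over the complementary index),
#' since the cumulative score is a per-image quantity, not a per-cell one.
#'
#' All annotations enter as independent observations, including both copies
#' of double-annotated images; with the reference study design this gives
#' n = 100 per model and n = 30 per prompt.
#'
#' With default weights the aggregates and the mean are linked by the
#' identity `(0.2 * agg_a + 0.5 * agg_b + 1.0 * agg_c) / n = mean`, which is
#' useful as an internal consistency check of published summary tables.
#'
#' @param set An [annotation_set()]; must validate cleanly.
#' @param by Grouping dimension: `"model"`, `"prompt"`, `"error_type"` or
#'   `"region"`.
#' @param weights A [weight_config()].
#' @return Tibble with columns `dimension`, `label`, `n`, `mean`, `variance`,
#'   `agg_a`, `agg_b`, `agg_c`. `mean`/`variance` are `NA` for the per-cell
#'   dimensions.
#' @export
summarize_annotations <- function(set,
                                  by = c("model", "prompt", "error_type",
                                         "region"),
                                  weights = weight_config()) {
  stopifnot(inherits(set, "annotation_set"))
  by <- match.arg(by)
  stop_if_invalid(set)
  pe <- error_proportions(set, check = FALSE)

  if (by %in% c("model", "prompt")) {
    scores <- cumulative_scores(set, weights, check = FALSE)
    stats_tbl <- scores |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data$cumulative),
        variance = stats::var(.data$cumulative),
        .by = dplyr::all_of(by)
      )
    pe_lab <- pe |>
      dplyr::left_join(set$annotations[c("image_id", "annotator", "model",
                                         "prompt")],
                       by = c("image_id", "annotator"))
    agg <- pe_lab |>
      dplyr::summarise(agg = sum(.data$pe),
                       .by = c(dplyr::all_of(by), "severity")) |>
      tidyr::pivot_wider(names_from = "severity", values_from = "agg",
                         names_prefix = "agg_", values_fill = 0)
    out <- dplyr::left_join(stats_tbl, agg, by = by)
  } else {
    grp_counts <- pe |>
      dplyr::summarise(agg = sum(.data$pe),
                       .by = c(dplyr::all_of(by), "severity")) |>
      tidyr::pivot_wider(names_from = "severity", values_from = "agg",
                         names_prefix = "agg_", values_fill = 0)
    out <- grp_counts |>
      dplyr::mutate(n = nrow(set$annotations), mean = NA_real_,
                    variance = NA_real_)
  }
  for (col in paste0("agg_", severity_levels())) {
    if (!col %in% names(out)) out[[col]] <- 0
  }
  out |>
    dplyr::mutate(dimension = by) |>
    dplyr::rename(label = dplyr::all_of(by)) |>
    dplyr::select("dimension", "label", "n", "mean", "variance",
                  "agg_a", "agg_b", "agg_c") |>
    dplyr::arrange(.data$label)
}

#' Welch's two-sample t test from summary statistics
#'
#' The unequal-variance t statistic
#' `t = (mean1 - mean2) / sqrt(var1/n1 + var2/n2)` with degrees of freedom by
#' the Welch–Satterthwaite approximation and a two-sided p value from the t
#' distribution. Operating on summary statistics makes published group
#' summaries directly testable without the underlying observations.
#'
#' @param mean1,var1,n1 Mean, sample variance (n - 1 denominator) and size of
#'   the first group.
#' @param mean2,var2,n2 Likewise for the second group.
#' @return A `welch_result` list with elements `t`, `df`, `p`.
#' @examples
#' welch_t(3.96, 6.1, 30, 0.82, 0.42, 30)
#' @export
welch_t <- function(mean1, var1, n1, mean2, var2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, var1 >= 0, var2 >= 0)
  if (var1 == 0 && var2 == 0) {
    stop("both group variances are 0; the t statistic is undefined",
         call. = FALSE)
  }
  se2_1 <- var1 / n1
  se2_2 <- var2 / n2
  t <- (mean1 - mean2) / sqrt(se2_1 + se2_2)
  df <- (se2_1 + se2_2)^2 /
    (se2_1^2 / (n1 - 1) + se2_2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  structure(list(t = t, df = df, p = p), class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t test: t = %.3f, df = %.2f, p = %.3g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Welch test between two groups of an annotation set
#'
#' Convenience wrapper: summarises the set along `by`, extracts the two
#' labelled groups and runs [welch_t()] on their cumulative-score means and
#' variances. No multiple-testing correction is applied; when used for many
#' comparisons, adjust the returned p values (e.g. with [stats::p.adjust()]).
#'
#' @param set An [annotation_set()].
#' @param by `"model"` or `"prompt"`.
#' @param label1,label2 Group labels present in the set.
#' @param weights A [weight_config()].
#' @return A `welch_result` (see [welch_t()]).
#' @export
compare_groups <- function(set, by = c("model", "prompt"), label1, label2,
                           weights = weight_config()) {
  by <- match.arg(by)
  s <- summarize_annotations(set, by = by, weights = weights)
  pick <- function(lab) {
    row <- s[s$label == lab, ]
    if (nrow(row) == 0) {
      stop(sprintf("no %s labelled '%s' in the annotation set", by, lab),
           call. = FALSE)
    }
    if (row$n < 2) {
      stop(sprintf("%s '%s' has fewer than 2 annotations", by, lab),
           call. = FALSE)
    }
    row
  }
  g1 <- pick(label1)
  g2 <- pick(label2)
  welch_t(g1$mean, g1$variance, g1$n, g2$mean, g2$variance, g2$n)
}
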