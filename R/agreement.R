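#' Reliability data for agreement analysis
#'
#' A reliability matrix is the standard input shape for chance-corrected
#' agreement coefficients: a partial mapping from (unit, rater) to an observed
#' value, together with the measurement level of the values. Missing
#' (unit, rater) pairs are simply absent rows; units observed by fewer than
#' two raters contribute nothing to observed disagreement but are retained.
#'
#' @param data Data frame with columns `unit`, `rater`, `value`. `value` may
#'   be numeric (interval), an ordered factor or numeric (ordinal), or any
#'   atomic type (nominal).
#' @param level Measurement level: `"nominal"`, `"ordinal"` or `"interval"`.
#' @return A `reliability_matrix` object.
#' @export
reliability_matrix <- function(data, level = c("nominal", "ordinal", "interval")) {
  level <- match.arg(level)
  data <- tibble::as_tibble(data)
  miss <- setdiff(c("unit", "rater", "value"), names(data))
  if (length(miss) > 0) {
    stop("reliability data is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data <- data[!is.na(data$value), c("unit", "rater", "value")]
  if (anyDuplicated(data[c("unit", "rater")])) {
    stop("multiple values for the same (unit, rater)", call. = FALSE)
  }
  if (level == "interval" && !is.numeric(data$value)) {
    stop("interval-level values must be numeric", call. = FALSE)
  }
  structure(list(data = data, level = level), class = "reliability_matrix")
}

#' @export
print.reliability_matrix <- function(x, ...) {
  cat(sprintf("<reliability_matrix> %d values, %d units, %d raters, level %s\n",
              nrow(x$data), length(unique(x$data$unit)),
              length(unique(x$data$rater)), x$level))
  invisible(x)
}

#' Krippendorff's alpha
#'
#' Chance-corrected inter-rater agreement, `alpha = 1 - D_o / D_e`, computed
#' via the coincidence-matrix formulation, which handles missing values and
#' any number of raters. All values assigned to the same unit are paired;
#' each pair contributes `1 / (m_u - 1)` to the coincidence matrix, where
#' `m_u` is the number of values the unit received. Observed disagreement
#' `D_o` averages the squared difference function over coincidences; expected
#' disagreement `D_e` averages it over all pairings of the pooled marginal
#' values.
#'
#' Difference functions by measurement level, for categories `v`, `v'`:
#' * nominal — 0 if `v == v'`, else 1;
#' * ordinal — squared cumulative rank-frequency distance,
#'   `(sum of marginal frequencies of the categories between v and v'
#'   inclusive, minus half the frequencies of v and v')^2`;
#' * interval — `(v - v')^2`. Interval alpha is therefore invariant under
#'   affine transformations of the values.
#'
#' @param matrix A [reliability_matrix()].
#' @return Alpha in \[-1, 1\]. 1 is perfect agreement, 0 is the chance level,
#'   negative values indicate systematic disagreement.
#' @section Errors:
#' Alpha is undefined when no unit carries two or more values (no pairable
#' data) or when every observed value is identical (expected disagreement 0);
#' both raise an error of class `anatscore_alpha_undefined`.
#' @references Krippendorff, K. (2019). Content Analysis: An Introduction to
#'   Its Methodology, 4th ed. Sage.
#' @export
krippendorff_alpha <- function(matrix) {
  stopifnot(inherits(matrix, "reliability_matrix"))
  d <- matrix$data
  if (length(unique(d$value)) < 2) {
    stop_alpha_undefined("all observed values are identical; expected disagreement is 0")
  }
  m_u <- table(d$unit)
  pairable <- names(m_u)[m_u >= 2L]
  if (length(pairable) == 0) {
    stop_alpha_undefined("no unit was rated by two or more raters")
  }
  d <- d[d$unit %in% pairable, ]

  # categories in a canonical order; for ordinal data the sort order of the
  # values defines the ranking (numeric or ordered-factor inputs both sort
  # correctly)
  if (is.factor(d$value)) {
    cats <- levels(droplevels(d$value))
    val_idx <- match(as.character(d$value), cats)
  } else {
    cats <- sort(unique(d$value))
    val_idx <- match(d$value, cats)
  }
  k <- length(cats)

  # coincidence matrix: counts of ordered value pairs within units,
  # weighted by 1 / (m_u - 1)
  cm <- matrix(0, k, k)
  for (u in unique(d$unit)) {
    idx <- val_idx[d$unit == u]
    m <- length(idx)
    tab <- tabulate(idx, nbins = k)
    pairs <- outer(tab, tab) - diag(tab, nrow = k)
    cm <- cm + pairs / (m - 1)
  }
  n_c <- rowSums(cm)
  n <- sum(n_c)

  delta <- switch(matrix$level,
    nominal = 1 - diag(k),
    interval = outer(as.numeric(cats), as.numeric(cats), function(a, b) (a - b)^2),
    ordinal = ordinal_delta(n_c)
  )
  d_o <- sum(cm * delta) / n
  d_e <- sum(outer(n_c, n_c) * delta) / (n * (n - 1))
  if (d_e == 0) {
    stop_alpha_undefined("expected disagreement is 0 after dropping unpairable units")
  }
  1 - d_o / d_e
}

# squared cumulative rank-frequency distances from coincidence marginals
ordinal_delta <- function(n_c) {
  k <- length(n_c)
  cum <- cumsum(n_c)
  delta <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      lo <- min(a, b); hi <- max(a, b)
      between <- cum[hi] - if (lo > 1) cum[lo - 1] else 0
      delta[a, b] <- (between - (n_c[a] + n_c[b]) / 2)^2
    }
  }
  delta
}

stop_alpha_undefined <- function(msg) {
  stop(structure(
    class = c("anatscore_alpha_undefined", "error", "condition"),
    list(message = paste0("Krippendorff's alpha undefined: ", msg),
         call = NULL)
  ))
}

#' Build a reliability matrix for one agreement variant
#'
#' Agreement between annotators is assessed on the double-annotated subset of
#' an annotation set, on three alternative representations ("variants") of
#' the annotation results:
#'
#' * `"cumulative_score"` — one unit per double-annotated image; the value is
#'   the annotator's cumulative score; interval level.
#' * `"overall_severity"` — one unit per double-annotated image; the value is
#'   the annotator's overall severity level (low < medium < high, computed
#'   from that annotator's full score distribution); ordinal level.
#' * `"binary_category"` — one unit per (image, region x error-type cell),
#'   25 units per double-annotated image; the value is 1 if the annotator
#'   recorded any error in the cell at any severity, else 0; nominal level.
#'
#' Images annotated once contribute no units.
#'
#' @param set An [annotation_set()] containing double-annotated images.
#' @param scores Output of [cumulative_scores()] on `set`; computed on the
#'   fly when `NULL`.
#' @param variant One of `"cumulative_score"`, `"overall_severity"`,
#'   `"binary_category"`.
#' @param weights A [weight_config()]; used when scores or severity levels
#'   must be computed.
#' @return A [reliability_matrix()] with raters = annotators.
#' @export
build_variant_matrix <- function(set,
                                 variant = c("cumulative_score",
                                             "overall_severity",
                                             "binary_category"),
                                 scores = NULL,
                                 weights = weight_config()) {
  stopifnot(inherits(set, "annotation_set"))
  variant <- match.arg(variant)
  dbl <- doubled_images(set)
  if (length(dbl) == 0) {
    stop("annotation set contains no double-annotated images", call. = FALSE)
  }
  if (is.null(scores)) scores <- cumulative_scores(set, weights)

  if (variant == "cumulative_score") {
    d <- scores[scores$image_id %in% dbl, ]
    return(reliability_matrix(
      tibble::tibble(unit = d$image_id, rater = d$annotator,
                     value = d$cumulative),
      level = "interval"
    ))
  }

  if (variant == "overall_severity") {
    sev <- overall_severity(scores, weights)
    d <- sev[sev$image_id %in% dbl, ]
    return(reliability_matrix(
      tibble::tibble(unit = d$image_id, rater = d$annotator,
                     value = as.integer(d$severity_level)),
      level = "ordinal"
    ))
  }

  # binary_category: dense 25-cell presence vector per annotation
  ann <- set$annotations[set$annotations$image_id %in% dbl,
                         c("image_id", "annotator")]
  grid <- tidyr::expand_grid(ann, region = body_regions(),
                             error_type = error_types())
  present <- set$errors |>
    dplyr::filter(.data$count > 0L) |>
    dplyr::distinct(.data$image_id, .data$annotator, .data$region,
                    .data$error_type) |>
    dplyr::mutate(value = 1L)
  d <- grid |>
    dplyr::left_join(present,
                     by = c("image_id", "annotator", "region", "error_type")) |>
    dplyr::mutate(value = dplyr::coalesce(.data$value, 0L),
                  unit = paste(.data$image_id, .data$region,
                               .data$error_type, sep = "::"))
  reliability_matrix(
    tibble::tibble(unit = d$unit, rater = d$annotator, value = d$value),
    level = "nominal"
  )
}

#' Pairwise inter-rater agreement
#'
#' Computes Krippendorff's alpha for every unordered pair of annotators that
#' shares at least one double-annotated unit, restricted to the units both
#' members of the pair annotated (no chaining through third raters), and the
#' arithmetic mean of the defined pairwise alphas. Pairs for which alpha is
#' undefined (e.g. both raters gave identical values everywhere, leaving no
#' value variation) are reported with `NA` rather than failing.
#'
#' @inheritParams build_variant_matrix
#' @return An `agreement_result`: list with elements `variant`, `pairwise`
#'   (tibble `annotator1`, `annotator2`, `n_units`, `alpha`) and `average`.
#' @export
pairwise_agreement <- function(set,
                               variant = c("cumulative_score",
                                           "overall_severity",
                                           "binary_category"),
                               scores = NULL,
                               weights = weight_config()) {
  variant <- match.arg(variant)
  rm <- build_variant_matrix(set, variant, scores = scores, weights = weights)
  d <- rm$data
  raters <- sort(unique(d$rater))
  if (length(raters) < 2) {
    stop("need at least two annotators with double-annotated units",
         call. = FALSE)
  }
  combos <- utils::combn(raters, 2, simplify = FALSE)
  rows <- lapply(combos, function(pr) {
    sub <- d[d$rater %in% pr, ]
    shared <- names(which(table(sub$unit) == 2L))
    if (length(shared) == 0) return(NULL)
    sub <- sub[sub$unit %in% shared, ]
    alpha <- tryCatch(
      krippendorff_alpha(reliability_matrix(sub, level = rm$level)),
      anatscore_alpha_undefined = function(e) NA_real_
    )
    tibble::tibble(annotator1 = pr[1], annotator2 = pr[2],
                   n_units = length(shared), alpha = alpha)
  })
  pairwise <- dplyr::bind_rows(rows)
  if (nrow(pairwise) == 0) {
    stop("no annotator pair shares a double-annotated unit", call. = FALSE)
  }
  structure(
    list(variant = variant, pairwise = pairwise,
         average = mean(pairwise$alpha, na.rm = TRUE)),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> variant: %s\n", x$variant))
  print(x$pairwise)
  cat(sprintf("average alpha: %.3f\n", x$average))
  invisible(x)
}
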