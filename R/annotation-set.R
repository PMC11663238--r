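#' Construct an annotation set
#'
#' An `annotation_set` is the package's central container: one annotator's full
#' error assessment of one generated image is one *annotation*, and a set holds
#' any number of them (including double annotations of the same image by two
#' annotators). It is a list of three tibbles in long format:
#'
#' * `annotations` — one row per (image_id, annotator): `image_id`, `model`,
#'   `prompt`, `annotator`, `person_count`.
#' * `expected` — one row per (image_id, annotator, region): `expected_count`,
#'   the number of parts of that region present or expected present
#'   (the denominator of the proportion-of-errors statistic). Regions absent
#'   from the input are filled in with 0 (region not visible, e.g. feet
#'   cropped out of frame).
#' * `errors` — one row per (image_id, annotator, region, error_type,
#'   severity) with a positive `count` of erroneous parts. Absent rows mean
#'   count 0, so files and tibbles stay sparse.
#'
#' The constructor enforces the closed taxonomy (unknown region, error-type or
#' severity labels are an error), coerces count columns to integer, drops
#' zero-count error rows, and sorts all three tables into a canonical order so
#' that written files are deterministic and diffable. Numeric consistency
#' rules (counts within denominators, no duplicates, label coherence across
#' annotators of the same image) are checked by [validate_annotations()], not
#' here, so that a malformed set can be constructed, inspected and reported
#' on.
#'
#' @param annotations Data frame with columns `image_id`, `model`, `prompt`,
#'   `annotator`, `person_count`.
#' @param expected Data frame with columns `image_id`, `annotator`, `region`,
#'   `expected_count`. May omit rows (filled with 0) but not columns.
#' @param errors Data frame with columns `image_id`, `annotator`, `region`,
#'   `error_type`, `severity`, `count`, or `NULL` for an error-free set.
#' @return An object of class `annotation_set`.
#' @seealso [validate_annotations()], [read_annotations()], [cumulative_scores()]
#' @export
annotation_set <- function(annotations, expected = NULL, errors = NULL) {
  ann <- tibble::as_tibble(annotations)
  need <- c("image_id", "model", "prompt", "annotator", "person_count")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    stop("annotations is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ann <- ann[need]
  ann$image_id <- as.character(ann$image_id)
  ann$model <- as.character(ann$model)
  ann$prompt <- as.character(ann$prompt)
  ann$annotator <- as.character(ann$annotator)
  ann$person_count <- as.integer(ann$person_count)
  ann <- dplyr::arrange(ann, .data$image_id, .data$annotator)

  if (is.null(expected)) {
    expected <- tibble::tibble(
      image_id = character(), annotator = character(),
      region = character(), expected_count = integer()
    )
  }
  exp <- tibble::as_tibble(expected)
  need <- c("image_id", "annotator", "region", "expected_count")
  miss <- setdiff(need, names(exp))
  if (length(miss) > 0) {
    stop("expected is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  exp <- exp[need]
  exp$image_id <- as.character(exp$image_id)
  exp$annotator <- as.character(exp$annotator)
  exp$region <- as.character(exp$region)
  check_labels(exp$region, body_regions(), "region")
  exp$expected_count <- as.integer(exp$expected_count)
  # complete to the full (annotation x region) grid; absent = not visible = 0
  grid <- tidyr::expand_grid(
    ann[c("image_id", "annotator")],
    region = body_regions()
  )
  exp <- dplyr::left_join(grid, exp,
                          by = c("image_id", "annotator", "region"),
                          relationship = "many-to-many")
  exp$expected_count[is.na(exp$expected_count)] <- 0L
  exp <- dplyr::arrange(
    exp, .data$image_id, .data$annotator,
    match(.data$region, body_regions())
  )

  if (is.null(errors)) {
    errors <- tibble::tibble(
      image_id = character(), annotator = character(), region = character(),
      error_type = character(), severity = character(), count = integer()
    )
  }
  err <- tibble::as_tibble(errors)
  need <- c("image_id", "annotator", "region", "error_type", "severity", "count")
  miss <- setdiff(need, names(err))
  if (length(miss) > 0) {
    stop("errors is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  err <- err[need]
  for (col in c("image_id", "annotator", "region", "error_type", "severity")) {
    err[[col]] <- as.character(err[[col]])
  }
  check_labels(err$region, body_regions(), "region")
  check_labels(err$error_type, error_types(), "error type")
  check_labels(err$severity, severity_levels(), "severity")
  err$count <- as.integer(err$count)
  err <- err[is.na(err$count) | err$count != 0L, ]
  err <- dplyr::arrange(
    err, .data$image_id, .data$annotator,
    match(.data$region, body_regions()),
    match(.data$error_type, error_types()),
    match(.data$severity, severity_levels())
  )

  structure(
    list(annotations = ann, expected = exp, errors = err),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  n_ann <- nrow(x$annotations)
  n_img <- length(unique(x$annotations$image_id))
  dbl <- doubled_images(x)
  cat(sprintf(
    "<annotation_set> %d annotations of %d images (%d double-annotated)\n",
    n_ann, n_img, length(dbl)
  ))
  cat(sprintf(
    "  models: %s\n  prompts: %d\n  annotators: %s\n  nonzero error cells: %d\n",
    paste(sort(unique(x$annotations$model)), collapse = ", "),
    length(unique(x$annotations$prompt)),
    paste(sort(unique(x$annotations$annotator)), collapse = ", "),
    nrow(x$errors)
  ))
  invisible(x)
}

#' Images annotated by exactly two distinct annotators
#'
#' @param set An [annotation_set()].
#' @return Character vector of image ids.
#' @export
doubled_images <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  tab <- table(set$annotations$image_id)
  names(tab)[tab == 2L]
}

#' Validate an annotation set
#'
#' Checks every structural and numeric invariant of the annotation model and
#' returns a tibble of violations (empty when the set is consistent). Rules:
#'
#' * `duplicate_annotation` — (image_id, annotator) must be unique.
#' * `duplicate_error_cell` — at most one error row per
#'   (image_id, annotator, region, error_type, severity).
#' * `orphan_error` — every error row must belong to an annotation.
#' * `negative_count` / `negative_expected` — counts are non-negative.
#' * `person_count` — at least one person per image.
#' * `expected_exceeds_anatomy` — a region's expected count cannot exceed
#'   person_count times the anatomical maximum ([region_part_counts()]).
#' * `count_exceeds_expected` — for each (region, error_type), the error
#'   counts summed over severities cannot exceed the region's expected part
#'   count; this is what keeps every error proportion in \[0, 1\]. A region
#'   with expected count 0 therefore admits no errors.
#' * `inconsistent_image_labels` — two annotations of one image must agree on
#'   model and prompt (person_count may differ: it is an annotator judgement).
#'
#' @param set An [annotation_set()].
#' @return Tibble with columns `image_id`, `annotator`, `rule`, `detail`;
#'   zero rows iff the set is valid.
#' @export
validate_annotations <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  v <- list()
  add <- function(image_id, annotator, rule, detail) {
    tibble::tibble(
      image_id = as.character(image_id), annotator = as.character(annotator),
      rule = rule, detail = detail
    )
  }

  ann <- set$annotations
  dup <- ann |>
    dplyr::count(.data$image_id, .data$annotator) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    v[[length(v) + 1]] <- add(dup$image_id, dup$annotator,
                              "duplicate_annotation",
                              sprintf("%d rows for this (image, annotator)", dup$n))
  }

  bad_pc <- ann[is.na(ann$person_count) | ann$person_count < 1L, ]
  if (nrow(bad_pc) > 0) {
    v[[length(v) + 1]] <- add(bad_pc$image_id, bad_pc$annotator, "person_count",
                              sprintf("person_count = %s", bad_pc$person_count))
  }

  lab <- ann |>
    dplyr::distinct(.data$image_id, .data$model, .data$prompt) |>
    dplyr::count(.data$image_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(lab) > 0) {
    v[[length(v) + 1]] <- add(lab$image_id, NA_character_,
                              "inconsistent_image_labels",
                              "model/prompt differ across annotators of this image")
  }

  exp <- dplyr::inner_join(set$expected, ann,
                           by = c("image_id", "annotator"),
                           relationship = "many-to-many")
  bad_exp <- exp[is.na(exp$expected_count) | exp$expected_count < 0L, ]
  if (nrow(bad_exp) > 0) {
    v[[length(v) + 1]] <- add(bad_exp$image_id, bad_exp$annotator,
                              "negative_expected",
                              sprintf("%s expected_count = %s",
                                      bad_exp$region, bad_exp$expected_count))
  }
  caps <- region_part_counts()
  over <- exp[!is.na(exp$expected_count) &
                exp$expected_count > exp$person_count * caps[exp$region], ]
  if (nrow(over) > 0) {
    v[[length(v) + 1]] <- add(over$image_id, over$annotator,
                              "expected_exceeds_anatomy",
                              sprintf("%s expected_count %d > %d persons x %d",
                                      over$region, over$expected_count,
                                      over$person_count, caps[over$region]))
  }

  err <- set$errors
  if (nrow(err) > 0) {
    dup <- err |>
      dplyr::count(.data$image_id, .data$annotator, .data$region,
                   .data$error_type, .data$severity) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(dup) > 0) {
      v[[length(v) + 1]] <- add(dup$image_id, dup$annotator,
                                "duplicate_error_cell",
                                sprintf("(%s, %s, %s) appears %d times",
                                        dup$region, dup$error_type,
                                        dup$severity, dup$n))
    }

    orphan <- dplyr::anti_join(err, ann, by = c("image_id", "annotator"))
    if (nrow(orphan) > 0) {
      v[[length(v) + 1]] <- add(orphan$image_id, orphan$annotator,
                                "orphan_error",
                                "error row without a matching annotation")
    }

    neg <- err[is.na(err$count) | err$count < 0L, ]
    if (nrow(neg) > 0) {
      v[[length(v) + 1]] <- add(neg$image_id, neg$annotator, "negative_count",
                                sprintf("(%s, %s, %s) count = %s", neg$region,
                                        neg$error_type, neg$severity, neg$count))
    }

    cell <- err |>
      dplyr::summarise(
        n_cell = sum(.data$count),
        .by = c("image_id", "annotator", "region", "error_type")
      ) |>
      dplyr::left_join(set$expected,
                       by = c("image_id", "annotator", "region"),
                       relationship = "many-to-many")
    bad <- cell[!is.na(cell$n_cell) & !is.na(cell$expected_count) &
                  cell$n_cell > cell$expected_count, ]
    if (nrow(bad) > 0) {
      v[[length(v) + 1]] <- add(bad$image_id, bad$annotator,
                                "count_exceeds_expected",
                                sprintf("(%s, %s): %d errors > %d parts expected",
                                        bad$region, bad$error_type,
                                        bad$n_cell, bad$expected_count))
    }
  }

  if (length(v) == 0) {
    return(tibble::tibble(image_id = character(), annotator = character(),
                          rule = character(), detail = character()))
  }
  dplyr::bind_rows(v)
}

# internal: stop with the first few violations when a computation requires
# a valid set
stop_if_invalid <- function(set) {
  viol <- validate_annotations(set)
  if (nrow(viol) > 0) {
    shown <- utils::head(viol, 5)
    stop(sprintf(
      "annotation set has %d validation violation(s), e.g.:\n%s",
      nrow(viol),
      paste(sprintf("  [%s/%s] %s: %s", shown$image_id, shown$annotator,
                    shown$rule, shown$detail), collapse = "\n")
    ), call. = FALSE)
  }
  invisible(set)
}
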