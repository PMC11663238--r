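#' Read an annotation set from CSV or JSON
#'
#' Two on-disk formats are supported (see Details). Both are validated on
#' read: unknown region / error-type / severity labels, duplicate rows and
#' error counts exceeding the expected part count all raise an error naming
#' the offending record, so a set returned by this function always satisfies
#' [validate_annotations()].
#'
#' @details
#' **CSV (long format).** One row per nonzero error cell with columns
#' `image_id, model, prompt, annotator, person_count, region, error_type,
#' severity, count`, plus one companion expectation row per (annotation,
#' region) carrying `error_type = "_expected"`, `severity = "_"` and
#' `count` = the expected part count. An annotation with no errors is
#' represented by its expectation rows alone. UTF-8, comma delimiter,
#' header row required.
#'
#' **JSON.** An array of annotation objects:
#' `{image_id, model, prompt, annotator, person_count,
#'   expected: {region: count, ...}, errors: [{region, type, severity, count}]}`.
#'
#' In both formats a missing error cell means count 0.
#'
#' @param path File to read.
#' @param format `"csv"`, `"json"`, or `"auto"` (default) to infer from the
#'   file extension.
#' @param validate If `TRUE` (default), stop when the parsed set violates an
#'   annotation-model invariant.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, format = c("auto", "csv", "json"),
                             validate = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  set <- switch(format,
    csv = read_annotations_csv(path),
    json = read_annotations_json(path)
  )
  if (validate) stop_if_invalid(set)
  set
}

csv_columns <- c("image_id", "model", "prompt", "annotator", "person_count",
                 "region", "error_type", "severity", "count")

read_annotations_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      image_id = readr::col_character(),
      model = readr::col_character(),
      prompt = readr::col_character(),
      annotator = readr::col_character(),
      person_count = readr::col_integer(),
      region = readr::col_character(),
      error_type = readr::col_character(),
      severity = readr::col_character(),
      count = readr::col_integer()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  miss <- setdiff(csv_columns, names(raw))
  if (length(miss) > 0) {
    stop("annotation CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop(sprintf("malformed annotation CSV: row %d, column %s: expected %s, got '%s'",
                 prob$row[1], prob$col[1], prob$expected[1], prob$actual[1]),
         call. = FALSE)
  }

  is_exp <- raw$error_type == "_expected"
  if (any(is_exp & raw$severity != "_")) {
    bad <- which(is_exp & raw$severity != "_")[1]
    stop(sprintf("row %d: expectation rows must carry severity '_', got '%s'",
                 bad, raw$severity[bad]), call. = FALSE)
  }
  err_rows <- raw[!is_exp, ]
  for (chk in list(list(col = "region", allowed = body_regions()),
                   list(col = "error_type", allowed = error_types()),
                   list(col = "severity", allowed = severity_levels()))) {
    vals <- err_rows[[chk$col]]
    bad <- which(!vals %in% chk$allowed)
    if (length(bad) > 0) {
      stop(sprintf("error row for image '%s': unknown %s label '%s'",
                   err_rows$image_id[bad[1]], chk$col, vals[bad[1]]),
           call. = FALSE)
    }
  }
  bad_region <- which(!raw$region[is_exp] %in% body_regions())
  if (length(bad_region) > 0) {
    stop(sprintf("expectation row for image '%s': unknown region label '%s'",
                 raw$image_id[is_exp][bad_region[1]],
                 raw$region[is_exp][bad_region[1]]), call. = FALSE)
  }

  annotations <- dplyr::distinct(
    raw, .data$image_id, .data$model, .data$prompt, .data$annotator,
    .data$person_count
  )
  expected <- raw[is_exp, c("image_id", "annotator", "region", "count")]
  names(expected)[names(expected) == "count"] <- "expected_count"
  dup_exp <- expected |>
    dplyr::count(.data$image_id, .data$annotator, .data$region) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup_exp) > 0) {
    stop(sprintf("duplicate expectation rows for image '%s', annotator '%s', region '%s'",
                 dup_exp$image_id[1], dup_exp$annotator[1], dup_exp$region[1]),
         call. = FALSE)
  }
  errors <- err_rows[c("image_id", "annotator", "region", "error_type",
                       "severity", "count")]
  annotation_set(annotations, expected, errors)
}

read_annotations_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(recs)) {
    stop("annotation JSON must be an array of annotation objects", call. = FALSE)
  }
  need <- c("image_id", "model", "prompt", "annotator", "person_count")
  ann <- vector("list", length(recs))
  exp <- vector("list", length(recs))
  err <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    miss <- setdiff(need, names(r))
    if (length(miss) > 0) {
      stop(sprintf("annotation object %d is missing field(s): %s",
                   i, paste(miss, collapse = ", ")), call. = FALSE)
    }
    ann[[i]] <- tibble::tibble(
      image_id = as.character(r$image_id), model = as.character(r$model),
      prompt = as.character(r$prompt), annotator = as.character(r$annotator),
      person_count = as.integer(r$person_count)
    )
    if (!is.null(r$expected) && length(r$expected) > 0) {
      exp[[i]] <- tibble::tibble(
        image_id = as.character(r$image_id),
        annotator = as.character(r$annotator),
        region = names(r$expected),
        expected_count = as.integer(unlist(r$expected, use.names = FALSE))
      )
    }
    if (!is.null(r$errors) && length(r$errors) > 0) {
      rows <- lapply(r$errors, function(e) {
        miss <- setdiff(c("region", "type", "severity", "count"), names(e))
        if (length(miss) > 0) {
          stop(sprintf("error object under image '%s' is missing field(s): %s",
                       r$image_id, paste(miss, collapse = ", ")), call. = FALSE)
        }
        tibble::tibble(
          image_id = as.character(r$image_id),
          annotator = as.character(r$annotator),
          region = as.character(e$region), error_type = as.character(e$type),
          severity = as.character(e$severity), count = as.integer(e$count)
        )
      })
      err[[i]] <- dplyr::bind_rows(rows)
    }
  }
  annotation_set(dplyr::bind_rows(ann), dplyr::bind_rows(exp),
                 dplyr::bind_rows(err))
}

#' Write an annotation set to CSV or JSON
#'
#' Output is deterministic: rows are emitted in the canonical order
#' (image_id, annotator, region, error type, severity), so two writes of the
#' same set are byte-identical and `write_annotations()` followed by
#' [read_annotations()] round-trips exactly. See [read_annotations()] for the
#' formats.
#'
#' @param set An [annotation_set()].
#' @param path Output file.
#' @param format `"csv"`, `"json"`, or `"auto"` (infer from extension).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(set, "annotation_set"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    write_annotations_csv(set, path)
  } else {
    write_annotations_json(set, path)
  }
  invisible(path)
}

write_annotations_csv <- function(set, path) {
  meta <- set$annotations
  exp_rows <- set$expected |>
    dplyr::left_join(meta, by = c("image_id", "annotator")) |>
    dplyr::mutate(error_type = "_expected", severity = "_",
                  count = .data$expected_count)
  err_rows <- set$errors |>
    dplyr::left_join(meta, by = c("image_id", "annotator"))
  out <- dplyr::bind_rows(exp_rows[csv_columns], err_rows[csv_columns])
  out <- dplyr::arrange(
    out, .data$image_id, .data$annotator,
    .data$error_type != "_expected",  # expectations first within an annotation
    match(.data$region, body_regions()),
    match(.data$error_type, error_types()),
    match(.data$severity, severity_levels())
  )
  readr::write_csv(out, path, progress = FALSE)
}

write_annotations_json <- function(set, path) {
  recs <- lapply(seq_len(nrow(set$annotations)), function(i) {
    a <- set$annotations[i, ]
    exp <- set$expected[set$expected$image_id == a$image_id &
                          set$expected$annotator == a$annotator, ]
    exp <- exp[order(match(exp$region, body_regions())), ]
    err <- set$errors[set$errors$image_id == a$image_id &
                        set$errors$annotator == a$annotator, ]
    rec <- list(
      image_id = a$image_id, model = a$model, prompt = a$prompt,
      annotator = a$annotator, person_count = a$person_count,
      expected = as.list(stats::setNames(exp$expected_count, exp$region))
    )
    rec$errors <- lapply(seq_len(nrow(err)), function(j) {
      list(region = err$region[j], type = err$error_type[j],
           severity = err$severity[j], count = err$count[j])
    })
    rec
  })
  json <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
}
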