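#' The anatomical error taxonomy
#'
#' The rubric is a fixed 5 x 5 x 3 grid: five anatomical regions, five error
#' types and three ordinal severities. The orderings returned here are part of
#' the contract — every vectorised computation in the package (scoring,
#' agreement matrices, synthetic generation) relies on them.
#'
#' @return A character vector of labels, in canonical order.
#' @examples
#' body_regions()
#' error_types()
#' severity_levels()
#' @name taxonomy
NULL

#' @rdname taxonomy
#' @export
body_regions <- function() {
  c("face", "torso", "hands", "limbs", "feet")
}

#' @rdname taxonomy
#' @export
error_types <- function() {
  c("proportion", "extra", "orientation", "configuration", "missing")
}

#' @rdname taxonomy
#' @export
severity_levels <- function() {
  c("a", "b", "c")
}

#' Canonical per-person part counts
#'
#' Anatomical maxima per person: one face, one torso, two hands, four limbs,
#' two feet. Used to bound the expected part count of a region given the
#' number of people in an image, and by the synthetic generator to derive
#' denominators from person counts and visibility.
#'
#' @return Named integer vector over [body_regions()].
#' @export
region_part_counts <- function() {
  c(face = 1L, torso = 1L, hands = 2L, limbs = 4L, feet = 2L)
}

# internal: assert a label vector is drawn from a closed set
check_labels <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown %s label(s): %s (allowed: %s)",
      what, paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}
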