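#' Randomised allocation of images to annotators
#'
#' Distributes a set of generated images across an annotation team under the
#' constraints of a double-annotation design:
#'
#' * a fraction `double_fraction` of the images (rounded half to even) is
#'   annotated by exactly two *distinct* annotators, the rest by one;
#' * doubled images are chosen by stratified sampling over the
#'   (model, prompt) cells, so the reliability subset covers models and
#'   prompts evenly;
#' * within every (model, prompt) stratum each annotator's number of
#'   annotation slots is within 1 of the proportional share, so models and
#'   prompts are spread evenly over annotators;
#' * total per-annotator loads differ by at most 1;
#' * the plan is a deterministic function of `seed`.
#'
#' The algorithm builds the multiset of annotation slots (each image once,
#' doubled images twice), splits each stratum's slots into floor/ceiling
#' shares — directing the remainder slots to the currently least-loaded
#' annotators, which keeps the global loads within 1 — and then places each
#' doubled image's two slots with the two annotators holding the most
#' remaining capacity in that stratum, which is always feasible and
#' guarantees distinct annotators.
#'
#' With the reference study design (240 images = 3 models x 10 prompts x 8
#' images, 4 annotators, fraction 0.25) this yields 300 annotation slots, 75
#' per annotator, with 60 doubled images.
#'
#' @param images Data frame with columns `image_id` (unique), `model`,
#'   `prompt`.
#' @param annotators Character vector of annotator ids (>= 2 unless
#'   `double_fraction` is 0 and one annotator suffices).
#' @param double_fraction Fraction of images to double-annotate, in \[0, 1).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return An `allocation_plan`: list with `assignments` (tibble `image_id`,
#'   `model`, `prompt`, `annotator`, one row per slot), `doubled` (character
#'   vector of double-annotated image ids) and `seed`.
#' @export
allocate_annotations <- function(images, annotators, double_fraction = 0.25,
                                 seed = 1L) {
  images <- tibble::as_tibble(images)
  miss <- setdiff(c("image_id", "model", "prompt"), names(images))
  if (length(miss) > 0) {
    stop("images is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(images$image_id)) {
    stop("image_id values must be unique", call. = FALSE)
  }
  annotators <- as.character(annotators)
  if (length(annotators) < 1) stop("need at least one annotator", call. = FALSE)
  stopifnot(double_fraction >= 0, double_fraction < 1)
  n <- nrow(images)
  n_doubled <- round(double_fraction * n)  # round half to even
  if (n_doubled > 0 && length(annotators) < 2) {
    stop("double annotation requires at least two annotators", call. = FALSE)
  }

  plan <- withr::with_seed(seed, {
    strata <- split(seq_len(n), paste(images$model, images$prompt, sep = "\r"))

    # stratified choice of doubled images: largest-remainder apportionment of
    # n_doubled over strata, then simple random sampling within each stratum
    sizes <- vapply(strata, length, integer(1))
    quota <- n_doubled * sizes / n
    base <- floor(quota)
    rem <- n_doubled - sum(base)
    if (rem > 0) {
      ord <- order(-(quota - base), stats::runif(length(quota)))
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    doubled_idx <- unlist(lapply(seq_along(strata), function(s) {
      if (base[s] == 0) return(integer(0))
      idx <- strata[[s]]
      idx[sample.int(length(idx), base[s])]
    }), use.names = FALSE)
    doubled_ids <- images$image_id[doubled_idx]

    A <- length(annotators)
    load <- stats::setNames(numeric(A), annotators)
    rows <- vector("list", length(strata))
    for (s in sample(seq_along(strata))) {
      idx <- strata[[s]]
      ids <- images$image_id[idx]
      dbl <- intersect(ids, doubled_ids)
      single <- setdiff(ids, dbl)
      k <- length(single) + 2L * length(dbl)

      # floor share to everyone, remainder slots to the least-loaded
      cap <- rep(k %/% A, A)
      r <- k %% A
      if (r > 0) {
        pick <- order(load, stats::runif(A))[seq_len(r)]
        cap[pick] <- cap[pick] + 1L
      }
      names(cap) <- annotators

      assigned_img <- character(0)
      assigned_ann <- character(0)
      # doubled images first: two distinct annotators with most remaining
      # capacity (feasible because stratum capacities differ by at most 1)
      for (im in sample(dbl, length(dbl))) {
        pick <- order(-cap, stats::runif(A))[1:2]
        if (cap[pick[2]] < 1) {
          stop("internal error: cannot place doubled image with distinct annotators")
        }
        cap[pick] <- cap[pick] - 1L
        assigned_img <- c(assigned_img, im, im)
        assigned_ann <- c(assigned_ann, annotators[pick])
      }
      # singles fill the remaining capacity in random order
      slots <- sample(rep(annotators, times = cap))
      assigned_img <- c(assigned_img, sample(single, length(single)))
      assigned_ann <- c(assigned_ann, slots)
      load <- load + tabulate(factor(assigned_ann, levels = annotators),
                              nbins = A)
      rows[[s]] <- tibble::tibble(image_id = assigned_img,
                                  annotator = assigned_ann)
    }
    list(assignments = dplyr::bind_rows(rows), doubled = doubled_ids)
  })

  assignments <- plan$assignments |>
    dplyr::left_join(images, by = "image_id") |>
    dplyr::select("image_id", "model", "prompt", "annotator") |>
    dplyr::arrange(.data$image_id, .data$annotator)
  structure(
    list(assignments = assignments, doubled = sort(plan$doubled),
         seed = as.integer(seed)),
    class = "allocation_plan"
  )
}

#' @export
print.allocation_plan <- function(x, ...) {
  loads <- table(x$assignments$annotator)
  cat(sprintf(
    "<allocation_plan> %d slots over %d images (%d doubled), seed %d\n",
    nrow(x$assignments), length(unique(x$assignments$image_id)),
    length(x$doubled), x$seed
  ))
  cat("  loads:", paste(sprintf("%s=%d", names(loads), loads), collapse = " "),
      "\n")
  invisible(x)
}
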