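#' Reference study design: generator models
#'
#' Default model parameters for the synthetic annotation generator. Each
#' model has a per-cell base error rate (the probability that any given
#' anatomical part carries an error of a given type, uniform over the 25
#' region x error-type cells unless a rate matrix is supplied to
#' [synthetic_config()]) and a severity mix (the probabilities that an error
#' is graded a, b or c). The defaults emulate three text-to-image generators
#' with distinct error profiles: a stronger commercial model whose errors are
#' mostly mild, and two weaker models with higher rates and a heavier tail of
#' severe errors.
#'
#' @return Tibble with columns `model`, `rate`, `mix_a`, `mix_b`, `mix_c`.
#' @export
study_models <- function() {
  tibble::tibble(
    model = c("dalle3", "sdxl", "cascade"),
    rate  = c(0.0758, 0.1201, 0.1416),
    mix_a = c(0.537, 0.337, 0.334),
    mix_b = c(0.275, 0.298, 0.280),
    mix_c = c(0.188, 0.365, 0.386)
  )
}

#' Reference study design: prompts
#'
#' The ten prompt scenarios of the reference design, spanning single people,
#' couples and groups of five. `person_count` is the number of people the
#' prompt asks for, `difficulty` a multiplier on the per-cell error rate
#' (group scenes and unusual body constellations are harder for generators;
#' the multipliers average 1 so per-model means are unchanged), and the
#' `vis_*` columns give the fraction of each region's parts visible in a
#' typical framing (e.g. feet are often cropped out of waist-up scenes).
#'
#' @return Tibble with columns `prompt`, `person_count`, `difficulty`,
#'   `vis_face`, `vis_torso`, `vis_hands`, `vis_limbs`, `vis_feet`.
#' @export
study_prompts <- function() {
  p <- tibble::tibble(
    prompt = c("salto", "jogging", "baby", "hugging", "wrestling",
               "sauna", "physician", "pizza", "beach", "volleyball"),
    person_count = c(1L, 1L, 2L, 2L, 2L, 2L, 2L, 3L, 5L, 5L),
    difficulty = c(1.05, 0.55, 0.52, 0.60, 1.06, 0.75, 0.65, 0.90, 2.52, 1.40),
    vis_face = 1, vis_torso = 1, vis_hands = 1, vis_limbs = 1,
    vis_feet = c(1, 1, 0.5, 0.5, 1, 1, 0.5, 0.5, 1, 1)
  )
  p
}

#' Configuration for the synthetic annotation generator
#'
#' Bundles and validates every generative parameter. The defaults reproduce
#' the reference study design: 3 models x 10 prompts x 8 images = 240 images,
#' 4 annotators, a 25% double-annotation fraction (300 annotations, 75 per
#' annotator, 60 doubled images) and a moderate annotator-disagreement noise.
#'
#' @param models Tibble as returned by [study_models()]: columns `model`,
#'   `rate` (per-cell error probability in \[0, 1\]), `mix_a`, `mix_b`,
#'   `mix_c` (severity mix; normalised to sum to 1).
#' @param prompts Tibble as returned by [study_prompts()].
#' @param n_images Images generated per (model, prompt) cell.
#' @param annotators Character vector of annotator ids.
#' @param double_fraction Fraction of images double-annotated, in \[0, 1).
#' @param annotator_noise Probability that the second annotator of a doubled
#'   image flips the presence of any given (region, error-type) cell relative
#'   to the first annotation: an observed error is missed, or a spurious
#'   single error is reported. 0 gives identical double annotations (alpha
#'   1); 0.5 gives independent cell presences (alpha near 0).
#' @param seed Integer seed; generation is a deterministic function of the
#'   configuration.
#' @param rate_matrices Optional named list (by model label) of 5 x 5
#'   matrices (regions x error types, in taxonomy order) of per-cell rates,
#'   overriding the uniform `rate` column for those models.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(models = study_models(),
                             prompts = study_prompts(),
                             n_images = 8L,
                             annotators = paste0("ann", 1:4),
                             double_fraction = 0.25,
                             annotator_noise = 0.25,
                             seed = 1L,
                             rate_matrices = NULL) {
  models <- tibble::as_tibble(models)
  prompts <- tibble::as_tibble(prompts)
  miss <- setdiff(c("model", "rate", "mix_a", "mix_b", "mix_c"), names(models))
  if (length(miss) > 0) {
    stop("models is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  need <- c("prompt", "person_count", "difficulty", paste0("vis_", body_regions()))
  miss <- setdiff(need, names(prompts))
  if (length(miss) > 0) {
    stop("prompts is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(
    all(models$rate >= 0 & models$rate <= 1),
    all(models$mix_a >= 0), all(models$mix_b >= 0), all(models$mix_c >= 0),
    all(prompts$person_count >= 1), all(prompts$difficulty > 0),
    n_images >= 1, length(annotators) >= 1,
    double_fraction >= 0, double_fraction < 1,
    annotator_noise >= 0, annotator_noise <= 1
  )
  vis <- as.matrix(prompts[paste0("vis_", body_regions())])
  stopifnot(all(vis >= 0 & vis <= 1))
  tot <- models$mix_a + models$mix_b + models$mix_c
  stopifnot(all(tot > 0))
  models$mix_a <- models$mix_a / tot
  models$mix_b <- models$mix_b / tot
  models$mix_c <- models$mix_c / tot
  if (!is.null(rate_matrices)) {
    bad <- setdiff(names(rate_matrices), models$model)
    if (length(bad) > 0) {
      stop("rate_matrices for unknown model(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (m in rate_matrices) {
      stopifnot(is.matrix(m), dim(m) == c(5L, 5L), all(m >= 0 & m <= 1))
    }
  }
  structure(
    list(models = models, prompts = prompts, n_images = as.integer(n_images),
         annotators = as.character(annotators),
         double_fraction = double_fraction,
         annotator_noise = annotator_noise, seed = as.integer(seed),
         rate_matrices = rate_matrices),
    class = "synthetic_config"
  )
}

# per-cell rate for a model, as a named 25-row tibble (region x error_type)
cell_rates <- function(config, model) {
  grid <- tidyr::expand_grid(region = body_regions(),
                             error_type = error_types())
  rm <- config$rate_matrices[[model]]
  if (!is.null(rm)) {
    grid$rate <- rm[cbind(match(grid$region, body_regions()),
                          match(grid$error_type, error_types()))]
  } else {
    grid$rate <- config$models$rate[config$models$model == model]
  }
  grid
}

#' Generate a synthetic annotation set
#'
#' Simulates the full annotation pipeline: a corpus of images per
#' (model, prompt) cell, a seeded constrained allocation of images to
#' annotators via [allocate_annotations()], and per-annotation error draws.
#' For each image, the expected part count of region `i` is
#' `round(person_count x per-person parts x visibility)`; for each of the 25
#' (region, error-type) cells, the total error count is
#' `Binomial(m_i, min(1, rate x difficulty))` and is then split across
#' severities by the model's severity mix, so counts never exceed the
#' denominator and every generated set passes [validate_annotations()] with
#' zero violations. The second annotation of a doubled image is the first
#' with each cell's error presence independently flipped with probability
#' `annotator_noise` (a flipped-on cell receives a single error with severity
#' drawn from the mix).
#'
#' @param config A [synthetic_config()].
#' @return An [annotation_set()] with the generating config attached as
#'   attribute `"config"` and the allocation plan as attribute `"plan"`.
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  prompts <- config$prompts
  images <- tidyr::expand_grid(
    model = config$models$model,
    prompt = prompts$prompt,
    rep = seq_len(config$n_images)
  )
  images$image_id <- sprintf("%s-%s-%02d", images$model, images$prompt,
                             images$rep)
  images <- images[c("image_id", "model", "prompt")]

  plan <- allocate_annotations(images, config$annotators,
                               double_fraction = config$double_fraction,
                               seed = config$seed)

  parts <- region_part_counts()
  w_seed <- config$seed + 1L

  draws <- withr::with_seed(w_seed, {
    cells <- dplyr::bind_rows(lapply(config$models$model, function(m) {
      dplyr::mutate(cell_rates(config, m), model = m)
    }))
    grid <- images |>
      dplyr::left_join(prompts, by = "prompt") |>
      dplyr::left_join(cells, by = "model",
                       relationship = "many-to-many") |>
      dplyr::left_join(config$models[c("model", "mix_a", "mix_b", "mix_c")],
                       by = "model")
    vis <- as.matrix(grid[paste0("vis_", body_regions())])
    grid$visibility <- vis[cbind(seq_len(nrow(grid)),
                                 match(grid$region, body_regions()))]
    grid$m <- as.integer(round(grid$person_count * parts[grid$region] *
                                 grid$visibility))
    grid$p <- pmin(1, grid$rate * grid$difficulty)
    grid$n_tot <- stats::rbinom(nrow(grid), grid$m, grid$p)
    grid$n_a <- stats::rbinom(nrow(grid), grid$n_tot, grid$mix_a)
    rest <- grid$n_tot - grid$n_a
    pb <- ifelse(grid$mix_b + grid$mix_c > 0,
                 grid$mix_b / (grid$mix_b + grid$mix_c), 0)
    grid$n_b <- stats::rbinom(nrow(grid), rest, pb)
    grid$n_c <- rest - grid$n_b

    # annotator assignment: the first annotator of an image records the base
    # draw, the second (doubled images) a noise-perturbed copy
    slots <- plan$assignments |>
      dplyr::mutate(copy = dplyr::row_number(), .by = "image_id")
    base_cells <- grid[c("image_id", "region", "error_type",
                         "m", "p", "n_tot", "n_a", "n_b", "n_c",
                         "mix_a", "mix_b", "mix_c")]
    slot_cells <- slots |>
      dplyr::left_join(base_cells, by = "image_id",
                       relationship = "many-to-many")

    second <- slot_cells$copy == 2L
    if (any(second) && config$annotator_noise > 0) {
      eps <- config$annotator_noise
      flip <- second & stats::runif(nrow(slot_cells)) < eps
      had <- slot_cells$n_tot > 0L
      # flipped off: clear the cell
      off <- flip & had
      slot_cells$n_a[off] <- 0L
      slot_cells$n_b[off] <- 0L
      slot_cells$n_c[off] <- 0L
      # flipped on (only possible when parts are visible): one error with
      # severity drawn from the model's mix
      on <- flip & !had & slot_cells$m > 0L
      if (any(on)) {
        u <- stats::runif(sum(on))
        sev_a <- u < slot_cells$mix_a[on]
        sev_b <- !sev_a & u < slot_cells$mix_a[on] + slot_cells$mix_b[on]
        slot_cells$n_a[on] <- as.integer(sev_a)
        slot_cells$n_b[on] <- as.integer(sev_b)
        slot_cells$n_c[on] <- as.integer(!sev_a & !sev_b)
      }
    }
    slot_cells
  })

  ann <- plan$assignments |>
    dplyr::left_join(prompts[c("prompt", "person_count")], by = "prompt")
  expected <- draws |>
    dplyr::distinct(.data$image_id, .data$annotator, .data$region, .data$m) |>
    dplyr::rename(expected_count = "m")
  errors <- draws |>
    dplyr::select("image_id", "annotator", "region", "error_type",
                  a = "n_a", b = "n_b", c = "n_c") |>
    tidyr::pivot_longer(cols = c("a", "b", "c"), names_to = "severity",
                        values_to = "count") |>
    dplyr::filter(.data$count > 0L)

  set <- annotation_set(
    ann[c("image_id", "model", "prompt", "annotator", "person_count")],
    expected, errors
  )
  attr(set, "config") <- config
  attr(set, "plan") <- plan
  set
}

#' Parameter recovery report for a synthetic annotation set
#'
#' Checks the generator against its own closed-form expectations. Under the
#' binomial error model the expected error proportion of a visible cell is
#' `min(1, rate x difficulty)`, so the expected cumulative score of an image
#' is `sum over visible cells of p_cell x (mix . weights)`; with a uniform
#' rate `r`, full visibility, unit difficulty and a pure severity-c mix this
#' reduces to `25 r`. The report compares the per-model empirical mean
#' cumulative score (over all annotations) with this expectation, and — when
#' the set contains doubled images — the average pairwise binary-category
#' alpha with the configured annotator noise. The expectation refers to the
#' noise-free base draws; it is exact for `annotator_noise = 0` and remains a
#' close approximation for moderate noise.
#'
#' @param set An [annotation_set()] produced by [generate_annotations()].
#' @param config The generating [synthetic_config()]; defaults to the one
#'   attached to `set`.
#' @param weights A [weight_config()].
#' @return A `recovery_report` list: `models` (tibble `model`, `n`,
#'   `empirical_mean`, `expected_mean`, `se`) and `agreement` (tibble
#'   `variant`, `average_alpha`, `annotator_noise`, or `NULL` when the set
#'   has no doubled images).
#' @export
recover_parameters <- function(set, config = attr(set, "config"),
                               weights = weight_config()) {
  stopifnot(inherits(set, "annotation_set"),
            inherits(config, "synthetic_config"))
  parts <- region_part_counts()
  wbar_by_model <- stats::setNames(
    config$models$mix_a * weights$weights[["a"]] +
      config$models$mix_b * weights$weights[["b"]] +
      config$models$mix_c * weights$weights[["c"]],
    config$models$model
  )

  expected_by_model <- vapply(config$models$model, function(m) {
    rates <- cell_rates(config, m)
    per_prompt <- vapply(seq_len(nrow(config$prompts)), function(i) {
      pr <- config$prompts[i, ]
      vis <- as.numeric(pr[paste0("vis_", body_regions())])
      mm <- round(pr$person_count * parts * vis)
      visible <- stats::setNames(mm > 0, body_regions())
      p <- pmin(1, rates$rate * pr$difficulty)
      sum(p[visible[rates$region]])
    }, numeric(1))
    mean(per_prompt) * wbar_by_model[[m]]
  }, numeric(1))

  scores <- cumulative_scores(set, weights)
  emp <- scores |>
    dplyr::summarise(
      n = dplyr::n(),
      empirical_mean = mean(.data$cumulative),
      se = stats::sd(.data$cumulative) / sqrt(dplyr::n()),
      .by = "model"
    ) |>
    dplyr::mutate(expected_mean = unname(expected_by_model[.data$model])) |>
    dplyr::select("model", "n", "empirical_mean", "expected_mean", "se") |>
    dplyr::arrange(.data$model)

  agreement <- NULL
  if (length(doubled_images(set)) > 0 && length(config$annotators) >= 2) {
    agr <- pairwise_agreement(set, "binary_category", scores = scores,
                              weights = weights)
    agreement <- tibble::tibble(
      variant = "binary_category",
      average_alpha = agr$average,
      annotator_noise = config$annotator_noise
    )
  }
  structure(list(models = emp, agreement = agreement),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$models)
  if (!is.null(x$agreement)) print(x$agreement)
  invisible(x)
}
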