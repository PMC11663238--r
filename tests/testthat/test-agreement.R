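rm_from_vectors <- function(r1, r2, level = "nominal") {
  n <- length(r1)
  reliability_matrix(
    tibble::tibble(unit = rep(seq_len(n), 2),
                   rater = rep(c("r1", "r2"), each = n),
                   value = c(r1, r2)),
    level = level
  )
}

test_that("perfect agreement with value variation gives alpha 1", {
  rm <- rm_from_vectors(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(krippendorff_alpha(rm), 1)
  rmi <- rm_from_vectors(c(1.5, 2.5, 9, 4), c(1.5, 2.5, 9, 4), "interval")
  expect_equal(krippendorff_alpha(rmi), 1)
})

test_that("alpha matches the brute-force oracle on every small binary matrix", {
  # all 2-rater binary matrices with 1..4 units: 340 cases
  for (n_units in 1:4) {
    combos <- expand.grid(rep(list(0:1), 2 * n_units))
    for (row in seq_len(nrow(combos))) {
      v <- as.numeric(combos[row, ])
      r1 <- v[seq_len(n_units)]
      r2 <- v[n_units + seq_len(n_units)]
      df <- tibble::tibble(unit = rep(seq_len(n_units), 2),
                           rater = rep(c("r1", "r2"), each = n_units),
                           value = c(r1, r2))
      expected <- oracle_alpha(df, "nominal")
      got <- tryCatch(
        krippendorff_alpha(reliability_matrix(df, "nominal")),
        anatscore_alpha_undefined = function(e) NA_real_
      )
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
})

test_that("alpha matches the oracle on random multi-rater matrices at all levels", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      n_units <- sample(3:8, 1)
      n_raters <- sample(2:4, 1)
      df <- expand.grid(unit = seq_len(n_units), rater = seq_len(n_raters))
      df$value <- sample(1:4, nrow(df), replace = TRUE)
      # knock out some observations to exercise missing-value handling
      df <- df[stats::runif(nrow(df)) > 0.25, ]
      for (level in c("nominal", "ordinal", "interval")) {
        expected <- oracle_alpha(df, level)
        got <- tryCatch(
          krippendorff_alpha(reliability_matrix(df, level)),
          anatscore_alpha_undefined = function(e) NA_real_
        )
        if (is.na(expected)) {
          expect_true(is.na(got))
        } else {
          expect_equal(got, expected, tolerance = 1e-10)
        }
      }
    }
  })
})

test_that("interval alpha is invariant under affine transformation of values", {
  withr::with_seed(5, {
    r1 <- stats::rnorm(20)
    r2 <- r1 + stats::rnorm(20, sd = 0.4)
  })
  a1 <- krippendorff_alpha(rm_from_vectors(r1, r2, "interval"))
  a2 <- krippendorff_alpha(rm_from_vectors(3.2 * r1 - 7, 3.2 * r2 - 7,
                                           "interval"))
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("nominal alpha approaches 2p - 1 for uniform binary raters", {
  p_agree <- 0.8
  n <- 2000
  withr::with_seed(202, {
    r1 <- stats::rbinom(n, 1, 0.5)
    agree <- stats::rbinom(n, 1, p_agree)
    r2 <- ifelse(agree == 1, r1, 1 - r1)
  })
  alpha <- krippendorff_alpha(rm_from_vectors(r1, r2))
  expect_lt(abs(alpha - (2 * p_agree - 1)), 0.05)
})

test_that("independent random ratings give alpha near zero", {
  withr::with_seed(303, {
    r1 <- stats::rbinom(500, 1, 0.5)
    r2 <- stats::rbinom(500, 1, 0.5)
  })
  expect_lt(abs(krippendorff_alpha(rm_from_vectors(r1, r2))), 0.1)
})

test_that("degenerate matrices raise the undefined-alpha condition", {
  expect_error(krippendorff_alpha(rm_from_vectors(c(1, 1), c(1, 1))),
               class = "anatscore_alpha_undefined")
  # no unit has two observations
  rm <- reliability_matrix(
    tibble::tibble(unit = 1:4, rater = "r1", value = c(1, 2, 1, 2)),
    "nominal"
  )
  expect_error(krippendorff_alpha(rm), class = "anatscore_alpha_undefined")
})

test_that("variant matrices have the design's unit counts and levels", {
  set <- generate_annotations(synthetic_config(seed = 21))
  expect_equal(length(doubled_images(set)), 60)
  mc <- build_variant_matrix(set, "cumulative_score")
  expect_equal(length(unique(mc$data$unit)), 60)
  expect_equal(mc$level, "interval")
  ms <- build_variant_matrix(set, "overall_severity")
  expect_equal(length(unique(ms$data$unit)), 60)
  expect_equal(ms$level, "ordinal")
  mb <- build_variant_matrix(set, "binary_category")
  expect_equal(length(unique(mb$data$unit)), 60 * 25)
  expect_equal(mb$level, "nominal")
  # singly-annotated images contribute no units
  expect_false(any(setdiff(set$annotations$image_id, doubled_images(set)) %in%
                     mc$data$unit))
})

test_that("the binary variant is severity-blind", {
  ann <- data.frame(image_id = "i1", model = "m", prompt = "p",
                    annotator = c("a1", "a2"), person_count = 1)
  exp <- expand.grid(image_id = "i1", annotator = c("a1", "a2"),
                     region = "hands", stringsAsFactors = FALSE)
  exp$expected_count <- 2
  err <- data.frame(image_id = "i1", annotator = "a1", region = "hands",
                    error_type = "extra", severity = "a", count = 1)
  set <- annotation_set(ann, exp, err)
  mb <- build_variant_matrix(set, "binary_category")
  cell <- mb$data[mb$data$unit == "i1::hands::extra", ]
  expect_equal(sort(cell$value), c(0L, 1L))  # a1 saw it (even at severity a)
})

test_that("identical double annotations give alpha 1 on value-preserving variants", {
  set <- fixture_small_set(seed = 13, noise = 0)
  for (variant in c("cumulative_score", "binary_category")) {
    res <- pairwise_agreement(set, variant)
    defined <- res$pairwise$alpha[!is.na(res$pairwise$alpha)]
    expect_true(length(defined) > 0)
    expect_equal(defined, rep(1, length(defined)))
    expect_lte(nrow(res$pairwise), choose(3, 2))
  }
  # the overall-severity variant thresholds scores per annotator, so two
  # identical annotations can still receive different levels when the
  # annotators' personal score distributions differ; on a study-sized set
  # agreement stays high but need not be perfect
  big <- generate_annotations(synthetic_config(annotator_noise = 0, seed = 13))
  sev <- pairwise_agreement(big, "overall_severity")
  expect_true(all(sev$pairwise$alpha > 0.6, na.rm = TRUE))
  expect_true(any(sev$pairwise$alpha < 1))
})

test_that("pairwise restriction uses only units both raters annotated", {
  set <- generate_annotations(synthetic_config(seed = 31))
  res <- pairwise_agreement(set, "cumulative_score")
  expect_lte(nrow(res$pairwise), choose(4, 2))
  expect_equal(res$average, mean(res$pairwise$alpha, na.rm = TRUE))
  # unit counts per pair sum to the number of doubled images
  expect_equal(sum(res$pairwise$n_units), 60)
})
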