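# Brute-force Krippendorff alpha: explicit enumeration of all value pairs
# within units (observed) and over the pooled values (expected). Kept loop-
# based and free of any code shared with the package implementation so it can
# serve as an independent oracle. Returns NA when alpha is undefined.
oracle_alpha <- function(df, level = "nominal") {
  units <- split(df$value, df$unit)
  units <- units[vapply(units, length, 1L) >= 2]
  if (length(units) == 0) return(NA_real_)
  pooled <- unlist(units, use.names = FALSE)
  n <- length(pooled)

  if (level == "ordinal") {
    cats <- sort(unique(pooled))
    freq <- vapply(cats, function(cc) sum(pooled == cc), numeric(1))
    delta_fun <- function(v1, v2) {
      if (v1 == v2) return(0)
      i1 <- which(cats == v1); i2 <- which(cats == v2)
      lo <- min(i1, i2); hi <- max(i1, i2)
      (sum(freq[lo:hi]) - (freq[i1] + freq[i2]) / 2)^2
    }
  } else if (level == "interval") {
    delta_fun <- function(v1, v2) (v1 - v2)^2
  } else {
    delta_fun <- function(v1, v2) as.numeric(v1 != v2)
  }

  d_o_num <- 0
  for (vals in units) {
    m <- length(vals)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j) d_o_num <- d_o_num + delta_fun(vals[i], vals[j]) / (m - 1)
      }
    }
  }
  d_o <- d_o_num / n

  d_e_num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d_e_num <- d_e_num + delta_fun(pooled[i], pooled[j])
    }
  }
  d_e <- d_e_num / (n * (n - 1))
  if (d_e == 0) return(NA_real_)
  1 - d_o / d_e
}

# one-person annotation with hands (m = 2) carrying one severe configuration
# error and face (m = 1) one mild proportion error; cumulative score 0.7 at
# default weights
fixture_hand_face <- function() {
  annotation_set(
    annotations = data.frame(image_id = "img1", model = "m", prompt = "p",
                             annotator = "a1", person_count = 1),
    expected = data.frame(
      image_id = "img1", annotator = "a1",
      region = c("face", "torso", "hands", "limbs", "feet"),
      expected_count = c(1, 1, 2, 4, 2)
    ),
    errors = data.frame(
      image_id = "img1", annotator = "a1",
      region = c("hands", "face"),
      error_type = c("configuration", "proportion"),
      severity = c("c", "a"), count = c(1, 1)
    )
  )
}

# a small valid multi-annotator set built by the generator
fixture_small_set <- function(seed = 7, noise = 0.2) {
  cfg <- synthetic_config(
    models = study_models()[1:2, ],
    prompts = study_prompts()[c(2, 9), ],
    n_images = 6, annotators = paste0("a", 1:3),
    double_fraction = 0.25, annotator_noise = noise, seed = seed
  )
  generate_annotations(cfg)
}

# assert every allocation-plan invariant: exact doubled count, 1 or 2 distinct
# annotators per image, and global load balance within 1
check_plan_invariants <- function(plan, images, n_annotators, double_fraction) {
  asg <- plan$assignments
  n <- nrow(images)
  n_doubled <- round(double_fraction * n)
  expect_equal(length(plan$doubled), n_doubled)
  expect_equal(nrow(asg), n + n_doubled)
  per_img <- tapply(asg$annotator, asg$image_id, function(a) {
    c(slots = length(a), distinct = length(unique(a)))
  })
  for (img in names(per_img)) {
    k <- per_img[[img]]
    if (img %in% plan$doubled) {
      expect_equal(unname(k["slots"]), 2)
      expect_equal(unname(k["distinct"]), 2)
    } else {
      expect_equal(unname(k["slots"]), 1)
    }
  }
  loads <- table(factor(asg$annotator))
  expect_lte(max(loads) - min(loads), 1)
}
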