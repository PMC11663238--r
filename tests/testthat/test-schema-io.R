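write_lines_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

header <- "image_id,model,prompt,annotator,person_count,region,error_type,severity,count"

test_that("a CSV with only expectation rows yields an error-free annotation", {
  path <- write_lines_csv(c(
    header,
    "img1,m1,p1,a1,1,face,_expected,_,1",
    "img1,m1,p1,a1,1,torso,_expected,_,1",
    "img1,m1,p1,a1,1,hands,_expected,_,2",
    "img1,m1,p1,a1,1,limbs,_expected,_,4",
    "img1,m1,p1,a1,1,feet,_expected,_,2"
  ))
  set <- read_annotations(path)
  expect_equal(nrow(set$annotations), 1)
  expect_equal(nrow(set$errors), 0)
  expect_equal(sum(set$expected$expected_count), 10)
  expect_equal(cumulative_scores(set)$cumulative, 0)
})

test_that("unknown taxonomy labels are rejected with the offending record named", {
  bad_sev <- write_lines_csv(c(
    header,
    "img1,m1,p1,a1,1,face,_expected,_,1",
    "img1,m1,p1,a1,1,face,proportion,d,1"
  ))
  expect_error(read_annotations(bad_sev), "severity.*'d'")
  bad_region <- write_lines_csv(c(
    header,
    "img1,m1,p1,a1,1,arms,_expected,_,2"
  ))
  expect_error(read_annotations(bad_region), "region.*'arms'")
})

test_that("write then read round-trips a full synthetic set in both formats", {
  set <- generate_annotations(synthetic_config(seed = 11))
  expect_equal(length(unique(set$annotations$image_id)), 240)
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_annotations(set, path)
    back <- read_annotations(path)
    expect_identical(back$annotations, set$annotations)
    expect_identical(back$expected, set$expected)
    expect_identical(back$errors, set$errors)
  }
})

test_that("writes are deterministic and an empty set gives a header-only CSV", {
  set <- fixture_small_set()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(set, p1)
  write_annotations(set, p2)
  expect_identical(readLines(p1), readLines(p2))

  empty <- annotation_set(data.frame(
    image_id = character(), model = character(), prompt = character(),
    annotator = character(), person_count = integer()
  ))
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(empty, p3)
  expect_identical(readLines(p3), header)
})

test_that("validation flags counts exceeding the expected part count", {
  set <- annotation_set(
    annotations = data.frame(image_id = "img1", model = "m", prompt = "p",
                             annotator = "a1", person_count = 1),
    expected = data.frame(image_id = "img1", annotator = "a1",
                          region = "hands", expected_count = 2),
    errors = data.frame(image_id = "img1", annotator = "a1",
                        region = "hands", error_type = "configuration",
                        severity = "c", count = 3)
  )
  v <- validate_annotations(set)
  expect_equal(nrow(v), 1)
  expect_equal(v$rule, "count_exceeds_expected")

  # severities of one cell are summed before comparing with the denominator
  set2 <- annotation_set(
    annotations = data.frame(image_id = "img1", model = "m", prompt = "p",
                             annotator = "a1", person_count = 1),
    expected = data.frame(image_id = "img1", annotator = "a1",
                          region = "hands", expected_count = 2),
    errors = data.frame(image_id = "img1", annotator = "a1",
                        region = "hands", error_type = "configuration",
                        severity = c("a", "b", "c"), count = 1)
  )
  expect_equal(validate_annotations(set2)$rule, "count_exceeds_expected")
})

test_that("an error in a region with expected count 0 is a violation", {
  set <- annotation_set(
    annotations = data.frame(image_id = "img1", model = "m", prompt = "p",
                             annotator = "a1", person_count = 1),
    expected = data.frame(image_id = "img1", annotator = "a1",
                          region = "face", expected_count = 0),
    errors = data.frame(image_id = "img1", annotator = "a1",
                        region = "face", error_type = "missing",
                        severity = "a", count = 1)
  )
  v <- validate_annotations(set)
  expect_true("count_exceeds_expected" %in% v$rule)
})

test_that("expected counts beyond the anatomical maximum are violations", {
  set <- annotation_set(
    annotations = data.frame(image_id = "img1", model = "m", prompt = "p",
                             annotator = "a1", person_count = 2),
    expected = data.frame(image_id = "img1", annotator = "a1",
                          region = "hands", expected_count = 5)
  )
  v <- validate_annotations(set)
  expect_equal(v$rule, "expected_exceeds_anatomy")
})

test_that("generator output always validates cleanly", {
  for (seed in c(1, 99)) {
    set <- fixture_small_set(seed = seed)
    expect_equal(nrow(validate_annotations(set)), 0)
  }
})

test_that("single-field corruptions of a valid file are caught, never crash", {
  set <- fixture_small_set(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(set, path)
  clean <- readLines(path)
  body_rows <- seq(2, length(clean))

  corruptions <- list(
    function(f) { f[5] <- "-3"; f },          # negative count
    function(f) { f[9] <- "999"; f },         # count way past denominator
    function(f) { f[6] <- "tentacles"; f },   # unknown region
    function(f) { f[8] <- "z"; f },           # unknown severity
    function(f) { f[7] <- "smudge"; f },      # unknown error type
    function(f) { f[9] <- "NA"; f },          # missing count
    function(f) { f[9] <- "1.5"; f }          # non-integer count
  )
  withr::with_seed(42, {
    for (k in 1:40) {
      row <- sample(body_rows, 1)
      fields <- strsplit(clean[row], ",", fixed = TRUE)[[1]]
      mangle <- corruptions[[sample(length(corruptions), 1)]]
      lines <- clean
      lines[row] <- paste(mangle(fields), collapse = ",")
      p <- tempfile(fileext = ".csv")
      writeLines(lines, p)
      outcome <- tryCatch(suppressWarnings({
        s <- read_annotations(p, validate = FALSE)
        if (nrow(validate_annotations(s)) > 0) "violation" else "valid"
      }), error = function(e) "error")
      expect_true(outcome %in% c("valid", "violation", "error"))
      # mangled enum labels and counts must never slip through silently
      if (grepl("tentacles|smudge|,z,|-3", lines[row])) {
        expect_true(outcome %in% c("violation", "error"))
      }
      unlink(p)
    }
  })
})

test_that("duplicate annotations and error cells are reported", {
  ann <- data.frame(image_id = c("i1", "i1"), model = "m", prompt = "p",
                    annotator = "a1", person_count = 1)
  set <- annotation_set(ann)
  expect_true("duplicate_annotation" %in% validate_annotations(set)$rule)

  set2 <- annotation_set(
    data.frame(image_id = "i1", model = "m", prompt = "p",
               annotator = "a1", person_count = 1),
    data.frame(image_id = "i1", annotator = "a1", region = "hands",
               expected_count = 2),
    data.frame(image_id = "i1", annotator = "a1", region = "hands",
               error_type = "extra", severity = "a", count = c(1, 1))
  )
  expect_true("duplicate_error_cell" %in% validate_annotations(set2)$rule)
})
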