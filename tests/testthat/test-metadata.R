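test_that("a fully specified sidecar reads with zero findings", {
  m <- pet_metadata(valid_sidecar_fields())
  txt <- write_pet_sidecar(m)
  rd <- read_pet_sidecar(txt)
  expect_identical(nrow(rd$findings), 0L)
  expect_identical(nrow(validate_pet_metadata(rd$metadata, n_volumes = 3)),
                   0L)
})

test_that("the n/a sentinel is legal only for mass and specific activity", {
  ok <- read_pet_sidecar(write_pet_sidecar(pet_metadata(
    valid_sidecar_fields(InjectedMass = "n/a",
                         SpecificRadioactivity = "n/a"))))
  expect_identical(nrow(ok$findings), 0L)
  expect_identical(
    nrow(check_required_fields(ok$metadata)), 0L)

  bad <- read_pet_sidecar(write_pet_sidecar(pet_metadata(
    valid_sidecar_fields(InjectedRadioactivity = "n/a"))))
  expect_true("PET108" %in% bad$findings$code)

  variant <- read_pet_sidecar(write_pet_sidecar(pet_metadata(
    valid_sidecar_fields(InjectedMass = "N/A"))))
  expect_true("PET128" %in% variant$findings$code)
})

test_that("required-field checking honours the conditional decay field", {
  full <- pet_metadata(valid_sidecar_fields())
  expect_identical(nrow(check_required_fields(full)), 0L)

  # ImageDecayCorrectionTime is required exactly when corrected
  m1 <- pet_metadata(valid_sidecar_fields(ImageDecayCorrectionTime = NULL))
  f1 <- check_required_fields(m1)
  expect_true(any(f1$code == "PET105" &
                    grepl("ImageDecayCorrectionTime", f1$message)))
  m2 <- pet_metadata(valid_sidecar_fields(ImageDecayCorrected = FALSE,
                                          ImageDecayCorrectionTime = NULL))
  expect_identical(nrow(check_required_fields(m2)), 0L)

  m3 <- pet_metadata(valid_sidecar_fields(TimeZero = NULL))
  expect_true(any(check_required_fields(m3)$code == "PET105"))
})

test_that("unit strings must match the SI schema exactly", {
  expect_identical(nrow(check_units(pet_metadata(valid_sidecar_fields()))),
                   0L)
  f <- check_units(pet_metadata(valid_sidecar_fields(Units = "kBq/ml")))
  expect_identical(f$code, "PET106")
  expect_match(f$message, "Bq/mL")
  f2 <- check_units(pet_metadata(valid_sidecar_fields(
    FrameDurationUnits = "min")))
  expect_identical(f2$code, "PET106")
  expect_match(f2$message, "'s'")
})

test_that("frame timing allows gaps but rejects mismatch, disorder, overlap", {
  base <- function(starts, durs) {
    pet_metadata(valid_sidecar_fields(FrameTimesStart = starts,
                                      FrameDuration = durs))
  }
  expect_identical(
    nrow(check_frame_timing(base(c(0, 60, 120), c(60, 60, 60)), 3)), 0L)
  # a gap is missing data within the run, not an error
  expect_identical(
    nrow(check_frame_timing(base(c(0, 60, 300), c(60, 60, 60)), 3)), 0L)
  expect_identical(
    check_frame_timing(base(c(0, 60), c(60, 60)), 3)$code,
    "PET109")
  # mismatched lists against a 3-volume image: both length rules fire
  expect_identical(
    check_frame_timing(base(c(0, 60), c(60, 60, 60)), 3)$code,
    c("PET109", "PET109"))
  expect_identical(
    check_frame_timing(base(c(0, 120, 60), c(60, 60, 60)), 3)$code,
    "PET110")
  expect_identical(
    check_frame_timing(base(c(0, 60, 120), c(90, 60, 60)), 3)$code,
    "PET111")
  expect_identical(
    check_frame_timing(base(c(0, 60, 120), c(60, -5, 60)), 3)$code,
    "PET131")
})

test_that("type mismatches surface as findings, non-JSON raises", {
  rd <- read_pet_sidecar('{"ScanStart": "zero", "ImageDecayCorrected": 1}')
  expect_setequal(rd$findings$code, "PET130")
  expect_identical(nrow(rd$findings), 2L)
  expect_error(read_pet_sidecar("not json at all {"),
               class = "petbids_format_error")
  expect_error(read_pet_sidecar('["array","not","object"]'),
               class = "petbids_format_error")
})

test_that("write/read round trip preserves all fields including unknown keys", {
  withr::with_seed(7, {
    for (i in 1:25) {
      extra <- setNames(list(stats::runif(1), random_label(),
                             sample(c(TRUE, FALSE), 1)),
                        paste0("X", random_label(), 1:3))
      fields <- c(valid_sidecar_fields(
        InjectedRadioactivity = stats::runif(1, 1e8, 1e9),
        ScanStart = stats::runif(1, -60, 60),
        FrameTimesStart = cumsum(stats::runif(4, 1, 100)),
        FrameDuration = stats::runif(4, 0.5, 1)), extra)
      m <- pet_metadata(fields)
      rd <- read_pet_sidecar(write_pet_sidecar(m))
      back <- unclass(rd$metadata)
      expect_setequal(names(back), names(fields))
      for (k in names(fields)) {
        expect_equal(back[[k]], unclass(fields[[k]]), tolerance = 0,
                     info = k)
      }
    }
  })
})

test_that("single-frame lists stay arrays through the round trip", {
  m <- pet_metadata(valid_sidecar_fields(FrameTimesStart = 0,
                                         FrameDuration = 300))
  txt <- write_pet_sidecar(m)
  expect_match(txt, "\\[\\s*0\\s*\\]")
  rd <- read_pet_sidecar(txt)
  expect_identical(nrow(check_frame_timing(rd$metadata, 1)), 0L)
})

test_that("time-anchor conventions are warnings, not errors", {
  f <- validate_pet_metadata(pet_metadata(
    valid_sidecar_fields(ScanStart = 30, InjectionStart = 90)))
  expect_true(any(f$code == "PET123" & f$severity == "warning"))
  f2 <- validate_pet_metadata(pet_metadata(
    valid_sidecar_fields(ImageDecayCorrectionTime = 60)))
  expect_true(any(f2$code == "PET125" & f2$severity == "warning"))
  expect_false(any(f2$severity == "error"))
})

test_that("field checks are pure and deterministically ordered", {
  m <- pet_metadata(valid_sidecar_fields(Units = "mCi/cc", TimeZero = NULL,
                                         FrameTimesStart = c(0, 0, 60)))
  f1 <- validate_pet_metadata(m)
  f2 <- validate_pet_metadata(m)
  expect_identical(f1, f2)
  expect_identical(f1$code, sort(f1$code))
})
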