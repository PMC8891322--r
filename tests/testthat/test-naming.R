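test_that("file names parse into ordered entities, suffix and extension", {
  a <- parse_artifact_name("sub-01_ses-baseline_pet.nii.gz")
  expect_identical(a$entities, c(sub = "01", ses = "baseline"))
  expect_identical(a$suffix, "pet")
  expect_identical(a$extension, ".nii.gz")

  b <- parse_artifact_name("sub-01_recording-manual_blood.tsv")
  expect_identical(b$entities, c(sub = "01", recording = "manual"))
  expect_identical(b$suffix, "blood")
  expect_identical(b$extension, ".tsv")

  c <- parse_artifact_name("sub-01_trc-cimbi36_rec-acdyn_pet.json")
  expect_identical(c$entities,
                   c(sub = "01", trc = "cimbi36", rec = "acdyn"))
  expect_identical(c$extension, ".json")
})

test_that("each malformation raises its own parse error class", {
  expect_error(parse_artifact_name("sub-01_rec-ac dyn_pet.nii"),
               class = "petbids_error_bad_label")
  expect_error(parse_artifact_name("sub-01_badtoken_pet.nii"),
               class = "petbids_error_malformed_token")
  expect_error(parse_artifact_name("sub-01_echo-3_pet.nii"),
               class = "petbids_error_unknown_entity")
  expect_error(parse_artifact_name("sub-01_sub-02_pet.nii"),
               class = "petbids_error_duplicate_entity")
  expect_error(parse_artifact_name("sub-01.nii"),
               class = "petbids_error_missing_suffix")
  expect_error(parse_artifact_name("sub-01_ses-a_trc-x.nii"),
               class = "petbids_error_missing_suffix")
  expect_error(parse_artifact_name("sub-01_pet.mat"),
               class = "petbids_error_bad_extension")
  expect_error(parse_artifact_name("ses-a_pet.nii"),
               class = "petbids_error_missing_sub")
  expect_error(parse_artifact_name("sub-01_run-0_pet.nii"),
               class = "petbids_error_bad_label")
})

test_that("composition is canonical and enforces pairing invariants", {
  expect_identical(
    compose_artifact_name(artifact_name(c(sub = "01"), "pet", ".nii.gz")),
    "sub-01_pet.nii.gz")
  expect_identical(
    compose_artifact_name(
      artifact_name(c(run = "2", sub = "01", ses = "rescan"), "pet",
                    ".nii")),
    "sub-01_ses-rescan_run-2_pet.nii")
  # scrambled insertion order composes identically to sorted order
  sorted <- artifact_name(c(sub = "01", ses = "a", run = "1"), "pet", ".nii")
  scrambled <- artifact_name(c(run = "1", sub = "01", ses = "a"), "pet",
                             ".nii")
  expect_identical(compose_artifact_name(sorted),
                   compose_artifact_name(scrambled))

  expect_error(artifact_name(c(sub = "01", recording = "manual"), "pet",
                             ".nii"),
               class = "petbids_error_invariant")
  expect_error(artifact_name(c(sub = "01"), "blood", ".nii"),
               class = "petbids_error_invariant")
  expect_error(artifact_name(c(sub = "01"), "pet", ".tsv"),
               class = "petbids_error_invariant")
})

test_that("reserved rec and recording labels classify correctly", {
  expect_identical(classify_rec_label("acdyn"), "acdyn")
  expect_identical(classify_rec_label("acstat"), "acstat")
  expect_identical(classify_rec_label("nacdyn"), "nacdyn")
  expect_identical(classify_rec_label("nacstat"), "nacstat")
  expect_identical(classify_rec_label("osem3d"), "custom")
  expect_identical(classify_recording_label("manual"), "manual")
  expect_identical(classify_recording_label("autosampler"), "autosampler")
  expect_identical(classify_recording_label("venous"), "custom")
})

test_that("parse/compose round-trips 1000 random names and is idempotent", {
  withr::with_seed(20260924, {
    for (i in 1:1000) {
      a <- random_artifact()
      name <- compose_artifact_name(a)
      b <- parse_artifact_name(name)
      expect_true(a == b)
      # canonicalisation is idempotent
      expect_identical(compose_artifact_name(parse_artifact_name(name)),
                       name)
    }
  })
})

test_that("parser agrees with the brute-force tokenizer on an exhaustive sweep", {
  # exhaustive enumeration over a small alphabet of tokens: valid entities,
  # an unknown key, a duplicate, a malformed token and a bad run index
  tokens <- c("sub-01", "ses-a", "trc-x", "run-2", "run-0", "recording-manual",
              "foo-1", "bada", "sub-02")
  suffixes <- c("pet", "blood")
  exts <- c(".nii", ".tsv", ".json")
  n_checked <- 0L
  n_valid <- 0L
  for (k in 1:2) {
    combos <- utils::combn(length(tokens), k, simplify = FALSE)
    for (idx in combos) {
      for (perm in list(idx, rev(idx))) {
        for (suf in suffixes) {
          for (ext in exts) {
            name <- paste0(paste(tokens[perm], collapse = "_"), "_",
                           suf, ext)
            expected <- tokenizer_oracle(name)
            got <- tryCatch(
              compose_artifact_name(parse_artifact_name(name)),
              petbids_name_error = function(e) NULL)
            expect_identical(got, expected, info = name)
            n_checked <- n_checked + 1L
            if (!is.null(expected)) n_valid <- n_valid + 1L
          }
        }
      }
    }
  }
  expect_gt(n_checked, 500)
  expect_gt(n_valid, 20)
})

test_that("vectorised parsing returns a tidy table", {
  tbl <- parse_artifact_names(c("sub-01_ses-a_pet.nii.gz",
                                "sub-02_recording-manual_blood.tsv",
                                "garbage.xyz"))
  expect_s3_class(tbl, "tbl_df")
  expect_identical(tbl$valid, c(TRUE, TRUE, FALSE))
  expect_identical(tbl$sub, c("01", "02", NA))
  expect_identical(tbl$recording, c(NA, "manual", NA))
})
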