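make_manual_table <- function(n = 6) {
  t <- sort(sample(0:3600, n))
  plasma <- stats::runif(n, 100, 5e4)
  pf <- sort(stats::runif(n), decreasing = TRUE)
  tibble::tibble(
    time = as.numeric(t),
    plasma_radioactivity = plasma,
    whole_blood_radioactivity = 1.05 * plasma,
    metabolite_parent_fraction = pf,
    metabolite_polar_fraction = (1 - pf) * 0.5)
}

full_meta <- function(recording = "manual") {
  blood_metadata(recording, plasma_avail = TRUE, whole_blood_avail = TRUE,
                 metabolite_avail = TRUE)
}

test_that("a complete manual record round-trips with zero findings", {
  withr::with_seed(11, {
    tab <- make_manual_table()
    out <- write_blood_record(full_meta(), tab)
    rd <- read_blood_record(out$json, out$tsv)
    expect_identical(nrow(rd$findings), 0L)
    expect_identical(names(rd$table), names(tab))
    expect_identical(rd$table$time, tab$time)
  })
})

test_that("declaration/presence mismatches are found in both directions", {
  withr::with_seed(12, {
    tab <- make_manual_table()
    # declared but the column is missing
    out <- write_blood_record(full_meta(),
                              dplyr::select(tab, -"plasma_radioactivity"))
    rd <- read_blood_record(out$json, out$tsv)
    expect_true(any(rd$findings$code == "PET116" &
                      rd$findings$severity == "error"))
    # present but no descriptor
    meta_wb <- blood_metadata("autosampler", whole_blood_avail = TRUE)
    out2 <- write_blood_record(meta_wb, tab)
    rd2 <- read_blood_record(out2$json, out2$tsv)
    expect_true(any(rd2$findings$code == "PET117" &
                      rd2$findings$severity == "warning"))
  })
})

test_that("table-level faults get precise findings", {
  json <- write_blood_record(full_meta(), make_manual_table())$json

  rd <- read_blood_record(json, "time\twhole_blood_radioactivity\n60\t5\n30\t6\n")
  expect_true("PET113" %in% rd$findings$code)

  rd2 <- read_blood_record(json, "plasma_radioactivity\n5\n")
  expect_true("PET112" %in% rd2$findings$code)

  rd3 <- read_blood_record(json, "time\tplasma_radioactivity\n0\tfast\n")
  f <- rd3$findings[rd3$findings$code == "PET114", ]
  expect_identical(nrow(f), 1L)
  expect_match(f$message, "plasma_radioactivity")
  expect_match(f$message, "row 1")

  rd4 <- read_blood_record(
    json, "time\tmetabolite_parent_fraction\n0\t1.4\n")
  expect_true("PET115" %in% rd4$findings$code)

  rd5 <- read_blood_record(json, "time\tplasma_radioactivity\n0\tN/A\n")
  expect_true("PET128" %in% rd5$findings$code)
})

test_that("written TSVs use the n/a sentinel and survive exact round trips", {
  tab <- tibble::tibble(time = c(0, 30),
                        metabolite_parent_fraction = c(NA, 0.8))
  out <- write_blood_record(
    blood_metadata("manual", metabolite_avail = TRUE), tab)
  expect_match(out$tsv, "\tn/a\n")

  # header-only table
  empty <- write_blood_record(blood_metadata("manual"),
                              tibble::tibble(time = numeric()))
  expect_identical(empty$tsv, "time\n")

  # randomly generated tables reproduce every double bit-exactly
  withr::with_seed(13, {
    for (i in 1:50) {
      tab <- make_manual_table(n = sample(2:10, 1))
      tab$plasma_radioactivity[sample(nrow(tab), 1)] <- NA
      out <- write_blood_record(full_meta(), tab)
      back <- read_blood_record(out$json, out$tsv)$table
      for (cn in names(tab)) {
        expect_identical(back[[cn]], tab[[cn]], info = cn)
      }
    }
  })
})

test_that("merge takes the union of times, manual plasma, autosampler whole blood", {
  manual <- tibble::tibble(
    time = c(300, 600),
    plasma_radioactivity = c(1000, 800),
    whole_blood_radioactivity = c(1100, 900),
    metabolite_parent_fraction = c(0.9, 0.7))
  auto <- tibble::tibble(
    time = seq(0, 600, by = 10),
    whole_blood_radioactivity = seq(0, 600, by = 10) + 0.5)

  merged <- suppressWarnings(merge_recordings(manual, auto))
  # set-union oracle for the row count
  expect_identical(nrow(merged), length(union(manual$time, auto$time)))
  expect_identical(merged$time, sort(union(manual$time, auto$time)))
  # continuous device wins at shared times
  expect_identical(merged$whole_blood_radioactivity[merged$time == 300],
                   300.5)
  expect_warning(merge_recordings(manual, auto),
                 class = "petbids_merge_tiebreak")
  # manual-only columns survive, NA elsewhere
  expect_identical(merged$plasma_radioactivity[merged$time == 600], 800)
  expect_true(is.na(merged$plasma_radioactivity[merged$time == 10]))
})

test_that("merge identities, duplicates and monotonicity", {
  manual <- make_manual_table()
  empty <- tibble::tibble(time = numeric(),
                          whole_blood_radioactivity = numeric())
  expect_identical(merge_recordings(manual, empty), manual)

  # shared time with equal whole-blood values collapses to one row
  one <- tibble::tibble(time = 300, whole_blood_radioactivity = 5)
  expect_identical(nrow(merge_recordings(one, one)), 1L)

  # disagreeing duplicates within one table raise
  dup <- tibble::tibble(time = c(60, 60),
                        whole_blood_radioactivity = c(1, 2))
  expect_error(merge_recordings(dup, empty),
               class = "petbids_merge_conflict")

  withr::with_seed(14, {
    for (i in 1:20) {
      a <- make_manual_table(sample(2:8, 1))
      b <- tibble::tibble(time = as.numeric(sort(sample(0:4000,
                                                        sample(2:20, 1)))),
                          whole_blood_radioactivity = stats::runif(1))
      b$whole_blood_radioactivity <- stats::runif(nrow(b))
      m <- suppressWarnings(merge_recordings(a, b))
      expect_true(all(diff(m$time) > 0))
      expect_identical(nrow(m), length(union(a$time, b$time)))
    }
  })
})
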