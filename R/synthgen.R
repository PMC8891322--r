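# Deterministic synthetic dynamic-PET datasets: tiny 4D NIfTI images filled
# with voxelised time-activity curves, complete _pet.json sidecars, blood
# recording pairs and an anatomical T1w with the gradient-correction flag.
# Kinetics are a fixed two-exponential family with seeded uniform parameters
# — a test fixture generator, with no claim of biological fidelity.

#' Describe a synthetic study
#'
#' Defaults describe a single-subject carbon-11 bolus study: injection at scan
#' start (both anchors 0), eight non-overlapping frames spanning 720 s,
#' manual blood samples at eight discrete times, autosampler coverage of
#' 0–600 s in 10 s steps, and an 8x8x8 voxel grid.
#'
#' @param n_subjects Number of subjects (`sub-01`, `sub-02`, ...).
#' @param sessions Character vector of session labels (empty = no session
#'   layer).
#' @param tracer Tracer name for the sidecar (`TracerName`).
#' @param trc_label Optional `trc-<label>` entity for the file names; `NULL`
#'   omits the entity (single-tracer study).
#' @param radionuclide Radionuclide; its half-life is looked up with
#'   [half_life_of()] unless `half_life` is given.
#' @param half_life Half-life in seconds; overrides the registry lookup.
#' @param frame_times_start,frame_durations Frame scheme in seconds
#'   (non-overlapping, chronological).
#' @param blood One of `"none"`, `"manual"`, `"manual+autosampler"`.
#' @param with_anat Also write an anatomical T1w image and sidecar.
#' @param grid 3D image grid (kept tiny so suites stay fast).
#' @param seed Integer seed fixing every random draw.
#' @return An object of class `study_spec`.
#' @export
#' @examples
#' study_spec(n_subjects = 2, blood = "manual")
study_spec <- function(n_subjects = 1,
                       sessions = character(),
                       tracer = "CIMBI-36",
                       trc_label = NULL,
                       radionuclide = "11C",
                       half_life = NULL,
                       frame_times_start = c(0, 60, 120, 180, 240, 360,
                                             480, 600),
                       frame_durations = c(60, 60, 60, 60, 120, 120,
                                           120, 120),
                       blood = c("none", "manual", "manual+autosampler"),
                       with_anat = TRUE,
                       grid = c(8L, 8L, 8L),
                       seed = 1L) {
  blood <- match.arg(blood)
  stopifnot(n_subjects >= 1, length(grid) == 3L, all(grid >= 1),
            length(frame_times_start) == length(frame_durations),
            length(frame_times_start) >= 1)
  if (any(diff(frame_times_start) <= 0)) {
    abort("frame scheme must be chronological", class = "petbids_bad_spec")
  }
  if (any(frame_durations <= 0)) {
    abort("frame durations must be positive", class = "petbids_bad_spec")
  }
  n <- length(frame_times_start)
  if (n > 1L && any(frame_times_start[-n] + frame_durations[-n] >
                    frame_times_start[-1])) {
    abort("frame scheme must be non-overlapping", class = "petbids_bad_spec")
  }
  if (is.null(half_life)) half_life <- half_life_of(radionuclide)
  structure(list(
    n_subjects = as.integer(n_subjects), sessions = as.character(sessions),
    tracer = tracer, trc_label = trc_label, radionuclide = radionuclide,
    half_life = half_life, frame_times_start = as.numeric(frame_times_start),
    frame_durations = as.numeric(frame_durations), blood = blood,
    with_anat = isTRUE(with_anat), grid = as.integer(grid),
    seed = as.integer(seed)), class = "study_spec")
}

#' @export
print.study_spec <- function(x, ...) {
  cat("<study_spec> ", x$n_subjects, " subject(s), ",
      if (length(x$sessions)) paste(x$sessions, collapse = "/") else
        "single session", ", ", length(x$frame_times_start),
      " frames, blood=", x$blood, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# seeded kinetic parameters for one subject/session; all draws flow from
# spec$seed plus a deterministic stream index so subjects differ but rerun
# identically
draw_kinetics <- function(spec, stream = 0L) {
  withr::with_seed(spec$seed + 1000L * stream, {
    list(
      amplitude = stats::runif(1, 2e4, 6e4),     # Bq/mL scale
      k_in = stats::runif(1, 0.008, 0.02),       # 1/s, uptake
      k_out = stats::runif(1, 3e-4, 1.2e-3),     # 1/s, clearance
      k_parent = stats::runif(1, 1e-3, 3e-3),    # 1/s, metabolism
      parent_floor = stats::runif(1, 0.05, 0.2)
    )
  })
}

# two-exponential activity curve (rising then clearing), >= 0 everywhere
biexp_activity <- function(t, k) {
  k$amplitude * (exp(-k$k_out * t) - exp(-k$k_in * t)) *
    (t >= 0)
}

# monotonically non-increasing parent fraction starting at 1
parent_fraction_curve <- function(t, k) {
  (1 - k$parent_floor) * exp(-k$k_parent * pmax(t, 0)) + k$parent_floor
}

#' Simulate a regional time-activity curve
#'
#' One activity value per frame (evaluated at the frame midpoint) from the
#' seeded two-exponential family. Linear in `region_scale`; deterministic
#' given the spec's seed.
#'
#' @param spec A [study_spec()].
#' @param region_scale Non-negative multiplier on the regional amplitude.
#' @param stream Integer stream index (one per subject/session) so distinct
#'   regions draw distinct, reproducible parameters.
#' @return Numeric vector of frame activities in Bq/mL.
#' @export
#' @examples
#' simulate_tac(study_spec(seed = 7))
simulate_tac <- function(spec, region_scale = 1, stream = 0L) {
  stopifnot(inherits(spec, "study_spec"), region_scale >= 0)
  k <- draw_kinetics(spec, stream)
  mid <- spec$frame_times_start + spec$frame_durations / 2
  region_scale * biexp_activity(mid, k)
}

synth_pet_sidecar <- function(spec) {
  pet_metadata(
    TracerName = spec$tracer,
    TracerRadionuclide = spec$radionuclide,
    InjectedRadioactivity = 3.7e8,
    InjectedRadioactivityUnits = "Bq",
    InjectedMass = 0.5,
    InjectedMassUnits = "ug",
    SpecificRadioactivity = 7.4e14,
    SpecificRadioactivityUnits = "Bq/g",
    Units = "Bq/mL",
    TimeZero = "10:00:00",
    ScanStart = 0,
    InjectionStart = 0,
    FrameTimesStart = spec$frame_times_start,
    FrameDuration = spec$frame_durations,
    ImageDecayCorrected = TRUE,
    ImageDecayCorrectionTime = 0,
    ReconstructionDescription = "synthetic 3D iterative reconstruction"
  )
}

# deterministic radial spatial weight in [0, 1] over the grid
spatial_weights <- function(grid) {
  ax <- map(grid, function(n) {
    x <- seq_len(n) - (n + 1) / 2
    x / max(abs(x), 1)
  })
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  exp(-1.5 * r2)
}

synth_blood_tables <- function(spec, stream) {
  k <- draw_kinetics(spec, stream)
  end <- max(spec$frame_times_start + spec$frame_durations)
  manual_t <- unique(round(seq(15, max(end - 20, 30), length.out = 8)))
  plasma <- biexp_activity(manual_t, k)
  pf <- parent_fraction_curve(manual_t, k)
  # fixed blood-to-plasma ratio of 1.05 keeps whole blood above the
  # parent-compound activity (plasma * parent fraction) at every sample
  manual <- tibble(
    time = as.numeric(manual_t),
    plasma_radioactivity = plasma,
    whole_blood_radioactivity = 1.05 * plasma,
    metabolite_parent_fraction = pf,
    metabolite_polar_fraction = (1 - pf) * 0.6)
  auto_t <- seq(0, min(600, end), by = 10)
  auto <- tibble(
    time = as.numeric(auto_t),
    whole_blood_radioactivity = 1.05 * biexp_activity(auto_t, k))
  list(manual = manual, autosampler = auto)
}

write_json_file <- function(x, path) {
  txt <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = 4,
                                       digits = I(17)))
  writeLines(txt, path, useBytes = TRUE)
}

#' Generate a compliant synthetic PET-BIDS dataset
#'
#' Writes a full dataset tree: `dataset_description.json`, `README`,
#' `participants.tsv`, per-subject (and per-session) `pet/` directories with
#' a 4D float32 NIfTI of voxelised time-activity curves plus its `_pet.json`
#' sidecar, blood recording pairs per the spec, and an `anat/` T1w with the
#' `NonLinearGradientCorrection` flag. Output validates with zero errors and
#' is byte-identical across runs of the same spec.
#'
#' @param spec A [study_spec()].
#' @param out_root Target directory; must be absent or empty unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into (and clearing) an existing directory.
#' @return A tibble summarising the layout: `path`, `kind`, `bytes`.
#' @export
generate_dataset <- function(spec, out_root, overwrite = FALSE) {
  stopifnot(inherits(spec, "study_spec"))
  if (dir.exists(out_root) && length(list.files(out_root,
                                                all.files = TRUE,
                                                no.. = TRUE))) {
    if (!overwrite) {
      abort(paste0("output directory '", out_root,
                   "' is not empty (use overwrite = TRUE)"),
            class = "petbids_out_root_exists")
    }
    unlink(out_root, recursive = TRUE)
  }
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

  subjects <- sprintf("sub-%02d", seq_len(spec$n_subjects))
  write_json_file(list(
    Name = paste0("Synthetic ", spec$tracer, " dynamic PET study"),
    BIDSVersion = "1.6.0",
    DatasetType = "raw",
    Authors = list("petbids synthetic data generator"),
    GeneratedBy = list(list(Name = "petbids", Version = "0.1.0"))),
    file.path(out_root, "dataset_description.json"))
  writeLines(c(
    paste0("Synthetic dynamic PET dataset (", spec$tracer, ", [",
           spec$radionuclide, "])."),
    "",
    "Generated deterministically for software testing; image voxels hold",
    "a two-exponential time-activity curve modulated by a radial spatial",
    "profile. Not biological data."),
    file.path(out_root, "README"))
  writeLines(c("participant_id\tage\tsex",
               paste0(subjects, "\t", 20 + 2 * seq_along(subjects),
                      "\t", rep(c("F", "M"), length.out =
                                  length(subjects)))),
             file.path(out_root, "participants.tsv"))

  sessions <- if (length(spec$sessions)) spec$sessions else NA_character_
  stream <- 0L
  for (si in seq_along(subjects)) {
    sub <- subjects[si]
    for (ses in sessions) {
      stream <- stream + 1L
      sub_label <- substring(sub, 5L)
      ents <- c(sub = sub_label)
      rel <- sub
      if (!is.na(ses)) {
        ents <- c(ents, ses = ses)
        rel <- file.path(rel, paste0("ses-", ses))
      }
      if (!is.null(spec$trc_label)) ents <- c(ents, trc = spec$trc_label)
      pet_dir <- file.path(out_root, rel, "pet")
      dir.create(pet_dir, recursive = TRUE, showWarnings = FALSE)

      base <- compose_artifact_name(
        artifact_name(ents, "pet", ".nii.gz"))
      img_path <- file.path(pet_dir, base)
      json_path <- file.path(
        pet_dir, compose_artifact_name(artifact_name(ents, "pet", ".json")))

      tac <- simulate_tac(spec, 1, stream)
      w <- spatial_weights(spec$grid)
      vol <- array(0, dim = c(spec$grid, length(tac)))
      for (f in seq_along(tac)) vol[, , , f] <- w * tac[f]
      img <- RNifti::asNifti(vol, datatype = "float")
      RNifti::writeNifti(img, img_path)
      write_pet_sidecar(synth_pet_sidecar(spec), json_path)

      if (spec$blood != "none") {
        tabs <- synth_blood_tables(spec, stream)
        man_ents <- c(ents, recording = "manual")
        write_blood_record(
          blood_metadata("manual", plasma_avail = TRUE,
                         whole_blood_avail = TRUE, metabolite_avail = TRUE),
          tabs$manual,
          json_path = file.path(pet_dir, compose_artifact_name(
            artifact_name(man_ents, "blood", ".json"))),
          tsv_path = file.path(pet_dir, compose_artifact_name(
            artifact_name(man_ents, "blood", ".tsv"))))
        if (spec$blood == "manual+autosampler") {
          auto_ents <- c(ents, recording = "autosampler")
          write_blood_record(
            blood_metadata("autosampler", whole_blood_avail = TRUE),
            tabs$autosampler,
            json_path = file.path(pet_dir, compose_artifact_name(
              artifact_name(auto_ents, "blood", ".json"))),
            tsv_path = file.path(pet_dir, compose_artifact_name(
              artifact_name(auto_ents, "blood", ".tsv"))))
        }
      }

      if (spec$with_anat) {
        anat_dir <- file.path(out_root, rel, "anat")
        dir.create(anat_dir, recursive = TRUE, showWarnings = FALSE)
        anat_ents <- ents[intersect(c("sub", "ses"), names(ents))]
        t1 <- RNifti::asNifti(array(w * 1000, dim = spec$grid),
                              datatype = "float")
        RNifti::writeNifti(t1, file.path(
          anat_dir, compose_artifact_name(
            artifact_name(anat_ents, "T1w", ".nii.gz"))))
        write_json_file(list(NonLinearGradientCorrection = TRUE),
                        file.path(anat_dir, compose_artifact_name(
                          artifact_name(anat_ents, "T1w", ".json"))))
      }
    }
  }

  files <- list.files(out_root, recursive = TRUE, all.files = FALSE)
  tibble(path = files,
         kind = dplyr::case_when(
           grepl("\\.nii(\\.gz)?$", files) ~ "image",
           grepl("\\.json$", files) ~ "json",
           grepl("\\.tsv$", files) ~ "tsv",
           TRUE ~ "text"),
         bytes = file.size(file.path(out_root, files)))
}
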