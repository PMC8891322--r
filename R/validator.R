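# Whole-dataset validation: walk the tree, apply the structural, naming,
# metadata, blood and timeline rules, and emit a deterministic report.
# Findings are sorted by (path, code); two runs on the same tree are
# byte-identical.

ROOT_FILES_OK <- c("dataset_description.json", "README", "README.md",
                   "README.txt", "participants.tsv", "participants.json",
                   "CHANGES", "LICENSE", ".bidsignore")

rel_path <- function(root, path) {
  p <- sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", root)), "",
           path)
  p <- sub("^/+", "", p)
  if (!nzchar(p)) "." else p
}

read_json_or_null <- function(path) {
  tryCatch(jsonlite::fromJSON(paste(readLines(path, warn = FALSE,
                                              encoding = "UTF-8"),
                                    collapse = "\n"),
                              simplifyVector = TRUE),
           error = function(e) NULL)
}

nifti_volume_count <- function(path) {
  hdr <- tryCatch(RNifti::niftiHeader(path), error = function(e) NULL)
  if (is.null(hdr)) return(NULL)
  d <- hdr$dim
  if (d[1] >= 4L) d[5] else 1L
}

#' Validate a PET-BIDS dataset tree
#'
#' Applies the full rule set to a dataset directory: root-level files
#' (dataset description, README, participants), subject/session directory
#' naming, file-name grammar, PET sidecar presence and field-level checks,
#' frame timing against the image volume count, blood recording pair
#' cross-checks, the anatomical gradient-correction requirement, reserved
#' label warnings, and the time-zero / decay-reference conventions. See
#' [petbids_codes()] for the taxonomy and [explain_code()] for rationale.
#'
#' @param root Dataset root directory.
#' @return An object of class `petbids_report`: list with `findings` (tibble
#'   sorted by path then code), `ok` (`TRUE` iff no error-severity
#'   findings), and `root`.
#' @export
#' @examples
#' root <- file.path(tempdir(), "demo-ds")
#' generate_dataset(study_spec(blood = "manual", seed = 3), root,
#'                  overwrite = TRUE)
#' validate_dataset(root)
validate_dataset <- function(root) {
  if (!dir.exists(root)) {
    abort(paste0("dataset root '", root, "' does not exist"),
          class = "petbids_missing_root")
  }
  f <- no_findings()
  add <- function(code, message, path = ".") {
    f <<- bind_rows(f, new_finding(code, message, path))
  }

  # --- R1/R2: root files -------------------------------------------------
  dd_path <- file.path(root, "dataset_description.json")
  if (!file.exists(dd_path)) {
    add("PET101", "dataset_description.json is missing")
  } else if (is.null(read_json_or_null(dd_path))) {
    add("PET101", "dataset_description.json is not parseable JSON",
        "dataset_description.json")
  }
  if (!any(file.exists(file.path(root, c("README", "README.md",
                                         "README.txt"))))) {
    add("PET102", "no README describing the dataset")
  }
  if (!file.exists(file.path(root, "participants.tsv"))) {
    add("PET127", "participants.tsv is missing")
  }

  # --- R3: directory layout ---------------------------------------------
  entries <- list.files(root, all.files = FALSE)
  dirs <- entries[dir.exists(file.path(root, entries))]
  subj_dirs <- dirs[grepl("^sub-[A-Za-z0-9]+$", dirs)]
  for (d in setdiff(dirs, subj_dirs)) {
    add("PET103", paste0("directory '", d,
                         "' is not a sub-<label> subject directory"), d)
  }

  dataset_has_pet <- FALSE
  pet_dirs <- character()
  for (sd in subj_dirs) {
    inner <- list.files(file.path(root, sd))
    inner_dirs <- inner[dir.exists(file.path(root, sd, inner))]
    ses_dirs <- inner_dirs[grepl("^ses-[A-Za-z0-9]+$", inner_dirs)]
    mod_dirs <- inner_dirs[inner_dirs %in% c("pet", "anat")]
    for (d in setdiff(inner_dirs, c(ses_dirs, mod_dirs))) {
      add("PET103", paste0("directory '", d,
                           "' is neither ses-<label> nor a modality"),
          file.path(sd, d))
    }
    leafs <- c(file.path(sd, mod_dirs),
               unlist(map(ses_dirs, function(ss) {
                 mods <- list.files(file.path(root, sd, ss))
                 mods <- mods[dir.exists(file.path(root, sd, ss, mods))]
                 for (d in setdiff(mods, c("pet", "anat"))) {
                   add("PET103", paste0("directory '", d,
                                        "' is not a modality directory"),
                       file.path(sd, ss, d))
                 }
                 file.path(sd, ss, mods[mods %in% c("pet", "anat")])
               })))
    pet_dirs <- c(pet_dirs, leafs)
  }

  decay_refs <- numeric()

  # --- per-modality-directory checks ------------------------------------
  for (leaf in pet_dirs) {
    dirpath <- file.path(root, leaf)
    files <- list.files(dirpath)
    parsed <- list()
    for (fn in files) {
      a <- tryCatch(parse_artifact_name(fn),
                    petbids_name_error = function(e) e)
      relf <- file.path(leaf, fn)
      if (inherits(a, "condition")) {
        add("PET120", paste0("invalid file name: ", conditionMessage(a)),
            relf)
        next
      }
      parsed[[fn]] <- a
      # entities must match the directory chain
      parts <- strsplit(leaf, "/", fixed = TRUE)[[1]]
      dir_sub <- substring(parts[1], 5L)
      dir_ses <- if (length(parts) == 3L) substring(parts[2], 5L) else NULL
      if (!identical(unname(a$entities[["sub"]]), dir_sub)) {
        add("PET129", paste0("file sub-", a$entities[["sub"]],
                             " lies in directory of sub-", dir_sub), relf)
      }
      file_ses <- if ("ses" %in% names(a$entities))
        unname(a$entities[["ses"]]) else NULL
      if (!identical(file_ses, dir_ses)) {
        add("PET129", "ses entity does not match the session directory",
            relf)
      }
      if ("rec" %in% names(a$entities) &&
          classify_rec_label(a$entities[["rec"]]) == "custom") {
        add("PET121", paste0("rec label '", a$entities[["rec"]],
                             "' is not one of the four reserved values"),
            relf)
      }
      if ("recording" %in% names(a$entities) &&
          classify_recording_label(a$entities[["recording"]]) == "custom") {
        add("PET122", paste0("recording label '",
                             a$entities[["recording"]],
                             "' is not one of the two reserved values"),
            relf)
      }
    }

    is_pet_img <- map_lgl(parsed, function(a)
      a$suffix == "pet" && a$extension %in% c(".nii", ".nii.gz"))
    is_pet_json <- map_lgl(parsed, function(a)
      a$suffix == "pet" && a$extension == ".json")
    if (any(is_pet_img) || any(is_pet_json)) dataset_has_pet <- TRUE

    stem_of <- function(a) {
      paste(paste0(names(a$entities), "-", unname(a$entities)),
            collapse = "_")
    }

    # R4/R5: every PET image needs its sidecar; sidecar contents checked
    for (fn in names(parsed)[is_pet_img]) {
      a <- parsed[[fn]]
      relf <- file.path(leaf, fn)
      mate <- paste0(stem_of(a), "_pet.json")
      if (!(mate %in% names(parsed))) {
        add("PET104", paste0("image '", fn, "' has no _pet.json sidecar"),
            relf)
      }
    }
    for (fn in names(parsed)[is_pet_json]) {
      a <- parsed[[fn]]
      relf <- file.path(leaf, fn)
      rd <- tryCatch(read_pet_sidecar(file.path(dirpath, fn), path = relf),
                     petbids_format_error = function(e) NULL)
      if (is.null(rd)) {
        add("PET119", "sidecar is not parseable JSON", relf)
        next
      }
      f <- bind_rows(f, rd$findings)
      m <- rd$metadata
      # volume count from the paired image, when present and non-empty
      n_vol <- NULL
      img_name <- intersect(paste0(stem_of(a), c("_pet.nii.gz",
                                                 "_pet.nii")),
                            names(parsed))
      if (length(img_name)) {
        img_path <- file.path(dirpath, img_name[1])
        if (file.size(img_path) == 0) {
          add("PET126", "zero-byte NIfTI file; volume checks skipped",
              file.path(leaf, img_name[1]))
        } else {
          n_vol <- nifti_volume_count(img_path)
        }
      }
      f <- bind_rows(f,
                     check_required_fields(m, relf),
                     check_units(m, relf),
                     check_frame_timing(m, n_vol, relf),
                     check_time_anchor(m, relf))
      if (isTRUE(m$ImageDecayCorrected) &&
          is_scalar_number(m$ImageDecayCorrectionTime)) {
        decay_refs <- c(decay_refs, m$ImageDecayCorrectionTime)
      }
    }

    # R6: blood pairs
    is_blood_json <- map_lgl(parsed, function(a)
      a$suffix == "blood" && a$extension == ".json")
    is_blood_tsv <- map_lgl(parsed, function(a)
      a$suffix == "blood" && a$extension == ".tsv")
    blood_stems_json <- map_chr(parsed[is_blood_json], stem_of)
    blood_stems_tsv <- map_chr(parsed[is_blood_tsv], stem_of)
    for (fn in names(parsed)[is_blood_json]) {
      st <- stem_of(parsed[[fn]])
      if (!(st %in% blood_stems_tsv)) {
        add("PET118", paste0("'", fn, "' has no matching _blood.tsv"),
            file.path(leaf, fn))
      }
    }
    for (fn in names(parsed)[is_blood_tsv]) {
      st <- stem_of(parsed[[fn]])
      if (!(st %in% blood_stems_json)) {
        add("PET118", paste0("'", fn, "' has no matching _blood.json"),
            file.path(leaf, fn))
        next
      }
      json_fn <- names(parsed)[is_blood_json][match(st, blood_stems_json)]
      rec <- tryCatch(
        read_blood_record(file.path(dirpath, json_fn),
                          file.path(dirpath, fn),
                          path = file.path(leaf, fn)),
        petbids_format_error = function(e) NULL)
      if (is.null(rec)) {
        add("PET119", "blood sidecar is not parseable JSON",
            file.path(leaf, json_fn))
      } else {
        f <- bind_rows(f, rec$findings)
      }
    }

    # R7: anat sidecars must state NonLinearGradientCorrection
    if (basename(leaf) == "anat") {
      anat_imgs <- names(parsed)[map_lgl(parsed, function(a)
        a$suffix != "blood" && a$extension %in% c(".nii", ".nii.gz"))]
      for (fn in anat_imgs) {
        a <- parsed[[fn]]
        mate <- paste0(stem_of(a), "_", a$suffix, ".json")
        relf <- file.path(leaf, fn)
        doc <- if (mate %in% names(parsed))
          read_json_or_null(file.path(dirpath, mate)) else NULL
        if (is.null(doc) || !is.logical(doc$NonLinearGradientCorrection) ||
            length(doc$NonLinearGradientCorrection) != 1L ||
            is.na(doc$NonLinearGradientCorrection)) {
          add("PET107",
              paste0("anatomical image '", fn, "' does not state ",
                     "NonLinearGradientCorrection (required when PET data ",
                     "are present)"),
              relf)
        }
      }
    }
  }

  # R10: mixed decay references across the dataset
  if (length(unique(decay_refs)) > 1L) {
    add("PET124",
        paste0("decay-corrected images reference different time points (",
               paste(sort(unique(decay_refs)), collapse = ", "), " s)"))
  }

  # anat rules only bind when PET data exist; drop PET107 otherwise
  if (!dataset_has_pet) f <- filter(f, .data$code != "PET107")

  f <- sort_findings(distinct(f))
  structure(list(findings = f,
                 ok = !any(f$severity == "error"),
                 root = root),
            class = "petbids_report")
}

#' @export
print.petbids_report <- function(x, ...) {
  g <- glance(x)
  cat("PET-BIDS validation of ", x$root, "\n",
      "  ", if (x$ok) "OK" else "NOT OK", ": ", g$n_errors, " error(s), ",
      g$n_warnings, " warning(s)\n", sep = "")
  if (nrow(x$findings)) {
    cat(format_report_lines(x), sep = "\n")
  }
  invisible(x)
}

format_report_lines <- function(x) {
  with(x$findings, paste0(severity, " ", code, " ", path, ": ", message))
}

#' @export
tidy.petbids_report <- function(x, ...) x$findings

#' @export
glance.petbids_report <- function(x, ...) {
  tibble(ok = x$ok,
         n_findings = nrow(x$findings),
         n_errors = sum(x$findings$severity == "error"),
         n_warnings = sum(x$findings$severity == "warning"))
}

report_to_json <- function(x, strict = FALSE) {
  ok <- if (strict) nrow(x$findings) == 0L else x$ok
  as.character(jsonlite::toJSON(list(
    report_version = 1L,
    root = x$root,
    ok = ok,
    strict = strict,
    findings = x$findings), auto_unbox = TRUE, pretty = 4, digits = I(17)))
}
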