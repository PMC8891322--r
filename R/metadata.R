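# The _pet.json sidecar: tracer identity, dose, timing relative to time zero,
# frame definition, and the decay-correction state of the image.
#
# Schema table (the required set this package validates against):
#   TracerName, TracerRadionuclide           text
#   InjectedRadioactivity                    number > 0
#   InjectedRadioactivityUnits               "Bq"
#   InjectedMass                             number > 0 or "n/a"
#   InjectedMassUnits                        "ug"
#   SpecificRadioactivity                    number > 0 or "n/a"
#   SpecificRadioactivityUnits               "Bq/g"
#   Units                                    "Bq/mL" (image voxel units)
#   TimeZero                                 clock time "HH:MM:SS"
#   ScanStart, InjectionStart                seconds relative to TimeZero
#   FrameTimesStart                          seconds, strictly increasing
#   FrameDuration                            seconds, all > 0
#   ImageDecayCorrected                      boolean
#   ImageDecayCorrectionTime                 seconds (required iff corrected)
# ReconstructionDescription and *Units companions for time fields are
# optional. "n/a" is legal only for InjectedMass and SpecificRadioactivity.

pet_required_fields <- function(m = NULL) {
  req <- c("TracerName", "TracerRadionuclide",
           "InjectedRadioactivity", "InjectedRadioactivityUnits",
           "InjectedMass", "InjectedMassUnits",
           "SpecificRadioactivity", "SpecificRadioactivityUnits",
           "Units", "TimeZero", "ScanStart", "InjectionStart",
           "FrameTimesStart", "FrameDuration", "ImageDecayCorrected")
  if (!is.null(m) && isTRUE(m$ImageDecayCorrected)) {
    req <- c(req, "ImageDecayCorrectionTime")
  }
  req
}

NA_PERMITTED_FIELDS <- c("InjectedMass", "SpecificRadioactivity")

pet_unit_expectations <- function() {
  c(InjectedRadioactivityUnits = "Bq",
    InjectedMassUnits = "ug",
    SpecificRadioactivityUnits = "Bq/g",
    Units = "Bq/mL",
    FrameTimesStartUnits = "s",
    FrameDurationUnits = "s",
    ScanStartUnits = "s",
    InjectionStartUnits = "s")
}

#' Construct PET sidecar metadata
#'
#' Wraps a named list of sidecar fields into a `pet_metadata` object. No
#' validation happens here; use [check_required_fields()], [check_units()],
#' [check_frame_timing()] or [validate_pet_metadata()]. Unknown fields are
#' preserved verbatim for round-tripping.
#'
#' @param ... Sidecar fields as name = value pairs, or a single named list.
#' @return An object of class `pet_metadata`.
#' @export
pet_metadata <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1]])) {
    dots <- dots[[1]]
  }
  if (length(dots) && (is.null(names(dots)) || any(!nzchar(names(dots))))) {
    abort("all pet_metadata fields must be named",
          class = "petbids_bad_metadata")
  }
  structure(dots, class = "pet_metadata")
}

#' @export
print.pet_metadata <- function(x, ...) {
  cat("<pet_metadata> ", length(unclass(x)), " fields\n", sep = "")
  cat(write_pet_sidecar(x))
  cat("\n")
  invisible(x)
}

#' @export
tidy.pet_metadata <- function(x, ...) {
  fields <- unclass(x)
  tibble(field = names(fields),
         value = map_chr(fields, function(v) paste(format(v), collapse = ", ")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_scalar_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# per-field type predicates; fields allowing the "n/a" sentinel accept it here
# (the sentinel's legality is the n/a policy's business, not the type check)
pet_type_checks <- function() {
  num_or_na <- function(x) is_scalar_number(x) || is_na_sentinel(x) ||
    is_na_case_variant(x)
  list(
    TracerName = is_scalar_string,
    TracerRadionuclide = is_scalar_string,
    InjectedRadioactivity = num_or_na,
    InjectedRadioactivityUnits = is_scalar_string,
    InjectedMass = num_or_na,
    InjectedMassUnits = is_scalar_string,
    SpecificRadioactivity = num_or_na,
    SpecificRadioactivityUnits = is_scalar_string,
    Units = is_scalar_string,
    TimeZero = function(x) is_scalar_string(x) &&
      grepl("^[0-2][0-9]:[0-5][0-9]:[0-5][0-9](\\.[0-9]+)?$", x),
    ScanStart = is_scalar_number,
    InjectionStart = is_scalar_number,
    FrameTimesStart = function(x) is.numeric(x) && !anyNA(x),
    FrameDuration = function(x) is.numeric(x) && !anyNA(x),
    ImageDecayCorrected = is_scalar_flag,
    ImageDecayCorrectionTime = is_scalar_number,
    ReconstructionDescription = is_scalar_string
  )
}

check_types <- function(m, path = ".") {
  checks <- pet_type_checks()
  out <- no_findings()
  for (field in intersect(names(checks), names(m))) {
    if (!checks[[field]](m[[field]])) {
      out <- bind_rows(out, new_finding(
        "PET130",
        paste0("field '", field, "' has an invalid type or format"),
        path))
    }
  }
  sort_findings(out)
}

check_na_policy <- function(m, path = ".") {
  out <- no_findings()
  for (field in names(unclass(m))) {
    v <- m[[field]]
    if (is_na_case_variant(v)) {
      out <- bind_rows(out, new_finding(
        "PET128",
        paste0("field '", field, "': missing-value sentinel must be the ",
               "literal lowercase 'n/a', got '", v, "'"),
        path))
    } else if (is_na_sentinel(v) && !(field %in% NA_PERMITTED_FIELDS)) {
      out <- bind_rows(out, new_finding(
        "PET108",
        paste0("'n/a' is not permitted for field '", field,
               "' (only InjectedMass and SpecificRadioactivity)"),
        path))
    }
  }
  sort_findings(out)
}

#' Read a _pet.json sidecar
#'
#' Parses the sidecar into a [pet_metadata()] object, preserving unknown keys
#' verbatim. Type mismatches and misuse of the `"n/a"` sentinel are returned
#' as findings, never thrown; only input that is not JSON at all raises.
#'
#' @param x A file path, or a JSON string.
#' @param path Dataset-relative path recorded in findings (defaults to the
#'   file path when `x` is one).
#' @return A list with elements `metadata` (a `pet_metadata`) and `findings`
#'   (a findings tibble with columns code, severity, path, message).
#' @export
read_pet_sidecar <- function(x, path = NULL) {
  txt <- if (length(x) == 1L && !grepl("[{\n]", x) && file.exists(x)) {
    if (is.null(path)) path <- x
    paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  path <- path %||% "."
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = TRUE),
    error = function(e) abort(paste0("not a JSON document: ",
                                     conditionMessage(e)),
                              class = "petbids_format_error")
  )
  if (!is.list(doc)) {
    abort("a PET sidecar must be a JSON object",
          class = "petbids_format_error")
  }
  m <- pet_metadata(doc)
  findings <- sort_findings(bind_rows(check_types(m, path),
                                      check_na_policy(m, path)))
  list(metadata = m, findings = findings)
}

# fields serialised as JSON arrays even at length 1
PET_ARRAY_FIELDS <- c("FrameTimesStart", "FrameDuration")

#' Write a _pet.json sidecar
#'
#' Canonical serialisation: UTF-8, 4-space indentation, keys sorted
#' alphabetically; frame lists stay JSON arrays even with a single frame.
#' `read_pet_sidecar(write_pet_sidecar(m))` reproduces every field.
#'
#' @param m A [pet_metadata()] object (or named list).
#' @param path Optional file path; when given the JSON is also written there.
#' @return The JSON text, invisibly when `path` is given.
#' @export
write_pet_sidecar <- function(m, path = NULL) {
  fields <- unclass(m)
  fields <- fields[order(names(fields))]
  for (f in intersect(PET_ARRAY_FIELDS, names(fields))) {
    if (length(fields[[f]]) == 1L) fields[[f]] <- I(fields[[f]])
  }
  txt <- jsonlite::toJSON(fields, auto_unbox = TRUE, pretty = 4,
                          digits = I(17), null = "null")
  txt <- as.character(txt)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Check the presence of required sidecar fields
#'
#' One error finding per missing required field; the `"n/a"` sentinel counts
#' as present only where it is permitted (injected mass, specific
#' radioactivity). `ImageDecayCorrectionTime` is required exactly when
#' `ImageDecayCorrected` is true.
#'
#' @param m A [pet_metadata()] object.
#' @param path Dataset-relative path recorded in findings.
#' @return A findings tibble.
#' @export
check_required_fields <- function(m, path = ".") {
  out <- no_findings()
  for (field in pet_required_fields(m)) {
    v <- m[[field]]
    present <- !is.null(v) &&
      !(is_na_sentinel(v) && !(field %in% NA_PERMITTED_FIELDS))
    if (!present) {
      out <- bind_rows(out, new_finding(
        "PET105", paste0("required field '", field, "' is missing"), path))
    }
  }
  sort_findings(out)
}

#' Check sidecar unit strings
#'
#' Radioactivity concentration must be exactly `"Bq/mL"` and time units
#' exactly `"s"`; dose fields use the schema's fixed SI strings. Each
#' deviation is an error finding naming the field and the expected unit.
#'
#' @inheritParams check_required_fields
#' @return A findings tibble.
#' @export
check_units <- function(m, path = ".") {
  expect <- pet_unit_expectations()
  out <- no_findings()
  for (field in intersect(names(expect), names(unclass(m)))) {
    v <- m[[field]]
    if (!is_scalar_string(v) || v != expect[[field]]) {
      out <- bind_rows(out, new_finding(
        "PET106",
        paste0("field '", field, "' must be '", expect[[field]],
               "', got '", paste(format(v), collapse = ","), "'"),
        path))
    }
  }
  sort_findings(out)
}

#' Check frame timing against the image
#'
#' Frames are stored chronologically: start times must be strictly
#' increasing, durations positive, frames non-overlapping (gaps are allowed —
#' an interrupted acquisition is missing data within the run, not a new run),
#' and both lists must match the image volume count when known.
#'
#' @inheritParams check_required_fields
#' @param n_volumes Number of volumes in the 4D image, or `NULL` when the
#'   image is unavailable (length checks against the image are then skipped).
#' @return A findings tibble.
#' @export
check_frame_timing <- function(m, n_volumes = NULL, path = ".") {
  out <- no_findings()
  fts <- m$FrameTimesStart
  fd <- m$FrameDuration
  if (!is.numeric(fts) || !is.numeric(fd)) return(out)
  if (length(fts) != length(fd)) {
    out <- bind_rows(out, new_finding(
      "PET109",
      paste0("FrameTimesStart has ", length(fts), " entries but ",
             "FrameDuration has ", length(fd)),
      path))
  }
  if (!is.null(n_volumes) && length(fts) != n_volumes) {
    out <- bind_rows(out, new_finding(
      "PET109",
      paste0("image has ", n_volumes, " volumes but FrameTimesStart has ",
             length(fts), " entries"),
      path))
  }
  if (length(fts) > 1L && any(diff(fts) <= 0)) {
    out <- bind_rows(out, new_finding(
      "PET110", "FrameTimesStart is not strictly increasing", path))
  }
  if (any(fd <= 0)) {
    out <- bind_rows(out, new_finding(
      "PET131", "FrameDuration entries must all be positive", path))
  }
  n <- min(length(fts), length(fd))
  if (n > 1L && all(diff(fts[seq_len(n)]) > 0)) {
    ends <- fts[seq_len(n - 1L)] + fd[seq_len(n - 1L)]
    if (any(ends > fts[2:n])) {
      out <- bind_rows(out, new_finding(
        "PET111", "frames overlap: a frame ends after the next one starts",
        path))
    }
  }
  sort_findings(out)
}

# warning-level timeline conventions: one anchor at 0; decay correction to 0
check_time_anchor <- function(m, path = ".") {
  out <- no_findings()
  ss <- m$ScanStart
  is_ <- m$InjectionStart
  if (is_scalar_number(ss) && is_scalar_number(is_) && ss != 0 && is_ != 0) {
    out <- bind_rows(out, new_finding(
      "PET123",
      "neither ScanStart nor InjectionStart equals 0; time zero should be one of the two",
      path))
  }
  if (isTRUE(m$ImageDecayCorrected) &&
      is_scalar_number(m$ImageDecayCorrectionTime) &&
      m$ImageDecayCorrectionTime != 0) {
    out <- bind_rows(out, new_finding(
      "PET125",
      paste0("ImageDecayCorrectionTime is ", m$ImageDecayCorrectionTime,
             " s, not the dataset time zero"),
      path))
  }
  sort_findings(out)
}

#' Run every field-level check on PET metadata
#'
#' Convenience composition of the type, n/a-policy, required-field, unit,
#' frame-timing and time-anchor checks, in deterministic order.
#'
#' @inheritParams check_frame_timing
#' @return A findings tibble sorted by (path, code).
#' @export
validate_pet_metadata <- function(m, n_volumes = NULL, path = ".") {
  sort_findings(bind_rows(
    check_types(m, path),
    check_na_policy(m, path),
    check_required_fields(m, path),
    check_units(m, path),
    check_frame_timing(m, n_volumes, path),
    check_time_anchor(m, path)
  ))
}
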