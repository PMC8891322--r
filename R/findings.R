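# Rule taxonomy shared by the metadata, blood and dataset validators.
#
# Severity policy: rules the standard phrases as hard requirements
# (sidecar presence, SI units, the n/a policy, gradient-correction flag)
# are errors; "should"-style recommendations (README, time-zero anchoring,
# reserved labels) are warnings.

finding_registry <- function() {
  tibble::tribble(
    ~code,    ~severity, ~title,                          ~explanation,
    "PET101", "error",   "MISSING_DATASET_DESCRIPTION",
    "dataset_description.json must exist at the dataset root and be parseable JSON; it carries the generic dataset information and credit to the data authors.",
    "PET102", "warning", "MISSING_README",
    "A free-form README describing the dataset (e.g. known issues such as excessive head movement) should accompany the dataset root.",
    "PET103", "error",   "INVALID_DIRECTORY_NAME",
    "Top-level data directories must be named sub-<label>, session layers ses-<label>, and modality directories 'pet' or 'anat'; labels are alphanumeric.",
    "PET104", "error",   "MISSING_PET_SIDECAR",
    "Every _pet NIfTI image requires a _pet.json sidecar with the same base name in the same directory, detailing the acquisition metadata.",
    "PET105", "error",   "MISSING_REQUIRED_FIELD",
    "A required PET sidecar field is absent. The required set covers tracer identity, dose, timing, frame definition and decay-correction state.",
    "PET106", "error",   "NON_SI_UNITS",
    "SI units are mandatory: radioactivity concentration exactly 'Bq/mL', time exactly 's'; dose fields use the schema's fixed SI strings.",
    "PET107", "error",   "MISSING_GRADIENT_CORRECTION_FIELD",
    "When PET data are present, anatomical MRI sidecars must state NonLinearGradientCorrection explicitly: MR images must be unwarped (or declared not) to co-register with PET.",
    "PET108", "error",   "NA_NOT_PERMITTED",
    "The 'n/a' sentinel is valid only for InjectedMass and SpecificRadioactivity (unmeasurable for some tracers, e.g. [18F]FDG); any other required field must carry a value.",
    "PET109", "error",   "FRAME_LENGTH_MISMATCH",
    "FrameTimesStart and FrameDuration must have one entry per image volume.",
    "PET110", "error",   "NON_CHRONOLOGICAL_FRAMES",
    "Frames are stored in chronological order: FrameTimesStart must be strictly increasing.",
    "PET111", "error",   "OVERLAPPING_FRAMES",
    "Frames may not overlap (a frame must end before the next starts); gaps are allowed and represent missing data within a run.",
    "PET112", "error",   "MISSING_TIME_COLUMN",
    "Every blood TSV table requires a 'time' column on the single reference time scale (seconds relative to time zero).",
    "PET113", "error",   "NON_MONOTONIC_TIME",
    "The blood 'time' column must be strictly increasing.",
    "PET114", "error",   "NON_NUMERIC_CELL",
    "Blood TSV cells must be numbers or the literal 'n/a' sentinel.",
    "PET115", "error",   "FRACTION_OUT_OF_RANGE",
    "Metabolite fractions are proportions and must lie in [0, 1] where not 'n/a'.",
    "PET116", "error",   "DECLARED_NOT_PRESENT",
    "Blood metadata declares a quantity as available but the TSV table has no corresponding column.",
    "PET117", "warning", "PRESENT_NOT_DECLARED",
    "A blood TSV column has no descriptor in the JSON metadata; every column should be described (name, description, SI units).",
    "PET118", "error",   "UNPAIRED_BLOOD_FILE",
    "Blood recordings come in pairs: a _blood.json metadata sidecar and a _blood.tsv sample table with the same base name.",
    "PET119", "error",   "MALFORMED_JSON",
    "A JSON sidecar could not be parsed.",
    "PET120", "error",   "INVALID_FILENAME",
    "A file name does not follow the entity grammar (key-value pairs joined by hyphens, separated by underscores, with a known suffix and extension).",
    "PET121", "warning", "NON_RESERVED_REC_LABEL",
    "rec-<label> has four reserved values (acdyn, acstat, nacdyn, nacstat, for attenuation-corrected / non-corrected dynamic / static reconstructions); other labels are permitted but flagged.",
    "PET122", "warning", "NON_RESERVED_RECORDING_LABEL",
    "recording-<label> for blood data has two reserved values (autosampler, manual); other labels are permitted but flagged.",
    "PET123", "warning", "NO_TIME_ZERO_ANCHOR",
    "Time zero is defined as injection start or scan start, so at least one of InjectionStart, ScanStart should equal 0.",
    "PET124", "warning", "MIXED_DECAY_REFERENCE",
    "Decay-corrected images in the dataset reference different correction time points; PET and blood data should optimally all be decay-corrected to the one time zero.",
    "PET125", "warning", "DECAY_CORRECTION_TIME_NONZERO",
    "ImageDecayCorrectionTime differs from time zero; data are decay-corrected, but not to the dataset's reference time point.",
    "PET126", "warning", "ZERO_BYTE_IMAGE",
    "A NIfTI file is empty (zero bytes, as in published example trees); volume-count checks are skipped for it.",
    "PET127", "warning", "MISSING_PARTICIPANTS",
    "participants.tsv with participant-specific information is customary at the dataset root.",
    "PET128", "error",   "NA_CASE_VARIANT",
    "The missing-value sentinel is the literal lowercase 'n/a'; case variants (N/A, NA, ...) are rejected for bit-exact interoperability.",
    "PET129", "error",   "ENTITY_DIRECTORY_MISMATCH",
    "File name entities (sub, ses) must match the directory they live in.",
    "PET130", "error",   "TYPE_INVALID",
    "A sidecar field has the wrong JSON type (e.g. text where a number is required, or a non-boolean decay-correction flag).",
    "PET131", "error",   "NONPOSITIVE_FRAME_DURATION",
    "Every FrameDuration entry must be a positive number of seconds."
  )
}

.registry_env <- new.env(parent = emptyenv())

registry <- function() {
  if (is.null(.registry_env$tbl)) .registry_env$tbl <- finding_registry()
  .registry_env$tbl
}

#' Validation rule codes
#'
#' The stable code/severity taxonomy applied by [validate_dataset()] and the
#' field-level checkers. Codes never change meaning between releases.
#'
#' @return A tibble with columns `code`, `severity`, `title`, `explanation`.
#' @export
#' @examples
#' petbids_codes()
petbids_codes <- function() registry()

#' Explain a validation finding code
#'
#' @param code A single code such as `"PET101"`.
#' @return A single string: the rule title and its rationale.
#' @export
#' @examples
#' explain_code("PET107")
explain_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  reg <- registry()
  i <- match(code, reg$code)
  if (is.na(i)) {
    abort(paste0("Unknown validation code: ", code),
          class = "petbids_unknown_code")
  }
  paste0(code, " [", reg$severity[i], "] ", reg$title[i], ": ",
         reg$explanation[i])
}

# empty findings table (the common currency of all check_* functions)
no_findings <- function() {
  tibble(code = character(), severity = character(),
         path = character(), message = character())
}

new_finding <- function(code, message, path = ".") {
  reg <- registry()
  i <- match(code, reg$code)
  if (anyNA(i)) stop("unregistered finding code: ", code[which(is.na(i))[1]])
  tibble(code = code, severity = reg$severity[i], path = path,
         message = message)
}

sort_findings <- function(f) arrange(f, .data$path, .data$code)
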