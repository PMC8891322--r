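# Entity grammar for PET file names: key-value pairs joined by hyphens and
# separated by underscores, a suffix, and an extension. PET adds the tracer
# (trc), reconstruction (rec) and blood recording (recording) entities to the
# familiar sub/ses/task/run set.

# canonical entity order (order of introduction of the entities)
ENTITY_ORDER <- c("sub", "ses", "task", "trc", "rec", "run", "recording")

KNOWN_SUFFIXES <- c("pet", "blood", "T1w")
KNOWN_EXTENSIONS <- c(".nii.gz", ".nii", ".json", ".tsv")

#' Reserved reconstruction labels
#'
#' The four reserved values of the `rec-<label>` entity: attenuation-corrected
#' dynamic (`acdyn`) and static (`acstat`) reconstructions, and their
#' non-attenuation-corrected counterparts (`nacdyn`, `nacstat`).
#'
#' @return A character vector of the four reserved labels.
#' @export
rec_kinds <- function() c("acdyn", "acstat", "nacdyn", "nacstat")

#' Reserved blood recording labels
#'
#' The two reserved values of the `recording-<label>` entity:
#' `autosampler` (continuous whole-blood monitoring) and `manual`
#' (discrete drawn samples).
#'
#' @return A character vector of the two reserved labels.
#' @export
recording_kinds <- function() c("autosampler", "manual")

name_abort <- function(msg, subclass, token = NULL) {
  abort(msg, class = c(subclass, "petbids_name_error"), token = token)
}

valid_label <- function(x) grepl("^[A-Za-z0-9]+$", x)

# shared invariant checks for a parsed or constructed artifact name
validate_artifact <- function(entities, suffix, extension) {
  if (!("sub" %in% names(entities))) {
    name_abort("the sub entity is mandatory in every file name",
               "petbids_error_missing_sub")
  }
  if (anyDuplicated(names(entities))) {
    dup <- names(entities)[duplicated(names(entities))][1]
    name_abort(paste0("duplicate entity key: ", dup),
               "petbids_error_duplicate_entity", token = dup)
  }
  bad_key <- setdiff(names(entities), ENTITY_ORDER)
  if (length(bad_key)) {
    name_abort(paste0("unknown entity key: ", bad_key[1]),
               "petbids_error_unknown_entity", token = bad_key[1])
  }
  bad_lab <- names(entities)[!valid_label(unname(entities))]
  if (length(bad_lab)) {
    name_abort(
      paste0("illegal characters in label of entity '", bad_lab[1],
             "': labels are non-empty [A-Za-z0-9]"),
      "petbids_error_bad_label", token = bad_lab[1])
  }
  if ("run" %in% names(entities)) {
    run <- entities[["run"]]
    if (!grepl("^[0-9]+$", run) || as.integer(run) < 1L) {
      name_abort(paste0("run index must be a positive integer, got '",
                        run, "'"),
                 "petbids_error_bad_label", token = "run")
    }
  }
  if (!valid_label(suffix)) {
    name_abort(paste0("invalid suffix: '", suffix, "'"),
               "petbids_error_missing_suffix", token = suffix)
  }
  if (!(extension %in% KNOWN_EXTENSIONS)) {
    name_abort(paste0("unknown extension: '", extension, "'"),
               "petbids_error_bad_extension", token = extension)
  }
  if (suffix == "blood" && !(extension %in% c(".json", ".tsv"))) {
    name_abort("suffix 'blood' pairs only with .json or .tsv",
               "petbids_error_invariant")
  }
  if (suffix == "pet" && !(extension %in% c(".nii", ".nii.gz", ".json"))) {
    name_abort("suffix 'pet' pairs only with .nii, .nii.gz or .json",
               "petbids_error_invariant")
  }
  if ("recording" %in% names(entities) && suffix != "blood") {
    name_abort("the recording entity is only valid with the _blood suffix",
               "petbids_error_invariant")
  }
  invisible(TRUE)
}

#' Construct an artifact name
#'
#' Builds a validated `artifact_name` object from an entity set, a suffix and
#' an extension. Entities may be given in any order; they are stored in the
#' canonical order sub, ses, task, trc, rec, run, recording.
#'
#' @param entities Named character vector mapping entity keys to labels,
#'   e.g. `c(sub = "01", ses = "baseline")`.
#' @param suffix File suffix: `"pet"`, `"blood"`, `"T1w"`, or another
#'   alphanumeric suffix.
#' @param extension One of `".nii"`, `".nii.gz"`, `".json"`, `".tsv"`.
#' @return An object of class `artifact_name`.
#' @export
#' @examples
#' artifact_name(c(sub = "01", trc = "cimbi36"), "pet", ".nii.gz")
artifact_name <- function(entities, suffix, extension) {
  entities <- vapply(entities, as.character, character(1))
  validate_artifact(entities, suffix, extension)
  entities <- entities[intersect(ENTITY_ORDER, names(entities))]
  structure(list(entities = entities, suffix = suffix,
                 extension = extension),
            class = "artifact_name")
}

#' Parse a PET-BIDS file name
#'
#' Splits a bare file name into its ordered entity set, suffix and extension.
#' Parsing is loss-free: [compose_artifact_name()] applied to the result
#' reproduces the canonical form of the input.
#'
#' Malformed tokens (no hyphen), unknown entity keys, duplicate keys, illegal
#' label characters, a missing suffix and an unknown extension each raise a
#' distinct condition class (all inheriting from `petbids_name_error`).
#'
#' @param name A bare file name (no directory components).
#' @return An `artifact_name` object.
#' @export
#' @examples
#' parse_artifact_name("sub-01_ses-baseline_pet.nii.gz")
#' parse_artifact_name("sub-01_recording-manual_blood.tsv")
parse_artifact_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name != basename(name)) {
    name_abort("expected a bare file name without directory components",
               "petbids_error_not_bare")
  }
  # longest-match extension (.nii.gz before .nii)
  ext <- NULL
  for (e in KNOWN_EXTENSIONS) {
    if (endsWith(name, e)) { ext <- e; break }
  }
  if (is.null(ext)) {
    name_abort(paste0("unknown or missing extension in '", name, "'"),
               "petbids_error_bad_extension", token = name)
  }
  stem <- substr(name, 1L, nchar(name) - nchar(ext))
  if (!nzchar(stem)) {
    name_abort("empty file name stem", "petbids_error_missing_suffix")
  }
  tokens <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(tokens) < 2L) {
    name_abort(paste0("no suffix token in '", name,
                      "' (need at least sub-<label>_<suffix>)"),
               "petbids_error_missing_suffix", token = stem)
  }
  suffix <- tokens[length(tokens)]
  if (grepl("-", suffix, fixed = TRUE)) {
    name_abort(paste0("missing suffix: last token '", suffix,
                      "' is a key-value pair"),
               "petbids_error_missing_suffix", token = suffix)
  }
  ent_tokens <- tokens[-length(tokens)]
  keys <- character(0)
  labels <- character(0)
  for (tok in ent_tokens) {
    if (!grepl("-", tok, fixed = TRUE)) {
      name_abort(paste0("malformed token '", tok,
                        "': entity tokens are key-value pairs joined by a hyphen"),
                 "petbids_error_malformed_token", token = tok)
    }
    cut <- regexpr("-", tok, fixed = TRUE)
    keys <- c(keys, substr(tok, 1L, cut - 1L))
    labels <- c(labels, substr(tok, cut + 1L, nchar(tok)))
  }
  entities <- setNames(labels, keys)
  artifact_name(entities, suffix, ext)
}

#' Compose a canonical PET-BIDS file name
#'
#' Deterministic inverse of [parse_artifact_name()]: entities are emitted in
#' the canonical order regardless of construction order.
#'
#' @param a An `artifact_name` object.
#' @return A single string.
#' @export
#' @examples
#' compose_artifact_name(artifact_name(c(run = "2", sub = "01"), "pet", ".nii"))
compose_artifact_name <- function(a) {
  stopifnot(inherits(a, "artifact_name"))
  validate_artifact(a$entities, a$suffix, a$extension)
  ents <- a$entities[intersect(ENTITY_ORDER, names(a$entities))]
  paste0(paste(paste0(names(ents), "-", unname(ents)), collapse = "_"),
         "_", a$suffix, a$extension)
}

#' @export
format.artifact_name <- function(x, ...) compose_artifact_name(x)

#' @export
print.artifact_name <- function(x, ...) {
  cat("<artifact_name> ", compose_artifact_name(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.artifact_name` <- function(e1, e2) {
  identical(unclass(e1)[c("entities", "suffix", "extension")],
            unclass(e2)[c("entities", "suffix", "extension")])
}

#' Classify a reconstruction label
#'
#' Maps a `rec-<label>` value onto the reserved set
#' (`acdyn`, `acstat`, `nacdyn`, `nacstat`); anything else is `"custom"`.
#' Reserved values are not exhaustive: custom labels parse fine and are
#' downgraded to a warning by the dataset validator.
#'
#' @param label An entity label.
#' @return One of `"acdyn"`, `"acstat"`, `"nacdyn"`, `"nacstat"`, `"custom"`.
#' @export
#' @examples
#' classify_rec_label("acdyn")
#' classify_rec_label("osem3d")
classify_rec_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (label %in% rec_kinds()) label else "custom"
}

#' Classify a blood recording label
#'
#' @param label An entity label.
#' @return `"manual"`, `"autosampler"`, or `"custom"`.
#' @export
#' @examples
#' classify_recording_label("manual")
#' classify_recording_label("venous")
classify_recording_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (label %in% recording_kinds()) label else "custom"
}

#' Parse many file names into a tibble
#'
#' Vectorised wrapper around [parse_artifact_name()]; invalid names yield a
#' row with `valid = FALSE` instead of an error, which suits dataset-level
#' summaries.
#'
#' @param names Character vector of bare file names.
#' @return A tibble with one row per name: `name`, one column per entity key,
#'   `suffix`, `extension`, `valid`.
#' @export
parse_artifact_names <- function(names) {
  rows <- map(names, function(nm) {
    a <- tryCatch(parse_artifact_name(nm), petbids_name_error = function(e) NULL)
    if (is.null(a)) {
      return(tibble(name = nm, suffix = NA_character_,
                    extension = NA_character_, valid = FALSE))
    }
    ent <- as.list(a$entities)
    tibble(name = nm, !!!ent, suffix = a$suffix,
           extension = a$extension, valid = TRUE)
  })
  out <- bind_rows(rows)
  keep_order <- c("name", intersect(ENTITY_ORDER, names(out)),
                  "suffix", "extension", "valid")
  out[, keep_order]
}

#' @export
tidy.artifact_name <- function(x, ...) {
  parse_artifact_names(compose_artifact_name(x))[, -1]
}
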