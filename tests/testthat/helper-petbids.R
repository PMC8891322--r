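# Shared fixtures and independent oracles.

# ---- independent brute-force tokenizer oracle for the filename grammar ----
# Split on "_", split each entity token on its first "-", then apply the
# grammar rules directly. Returns the canonical name, or NULL for a reject.
# Deliberately shares no code with parse_artifact_name().
oracle_order <- c("sub", "ses", "task", "trc", "rec", "run", "recording")

tokenizer_oracle <- function(name) {
  exts <- c(".nii.gz", ".nii", ".json", ".tsv")
  ext <- NULL
  for (e in exts) if (endsWith(name, e)) { ext <- e; break }
  if (is.null(ext)) return(NULL)
  stem <- substr(name, 1, nchar(name) - nchar(ext))
  toks <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(toks) < 2) return(NULL)
  suffix <- toks[length(toks)]
  if (!grepl("^[A-Za-z0-9]+$", suffix)) return(NULL)
  keys <- labs <- character(0)
  for (tok in toks[-length(toks)]) {
    hy <- regexpr("-", tok, fixed = TRUE)
    if (hy < 1) return(NULL)
    keys <- c(keys, substr(tok, 1, hy - 1))
    labs <- c(labs, substr(tok, hy + 1, nchar(tok)))
  }
  if (anyDuplicated(keys)) return(NULL)
  if (!all(keys %in% oracle_order)) return(NULL)
  if (!all(grepl("^[A-Za-z0-9]+$", labs))) return(NULL)
  if (!("sub" %in% keys)) return(NULL)
  if ("run" %in% keys) {
    r <- labs[keys == "run"]
    if (!grepl("^[0-9]+$", r) || as.integer(r) < 1) return(NULL)
  }
  if (suffix == "blood" && !ext %in% c(".json", ".tsv")) return(NULL)
  if (suffix == "pet" && !ext %in% c(".nii", ".nii.gz", ".json")) return(NULL)
  if ("recording" %in% keys && suffix != "blood") return(NULL)
  ord <- order(match(keys, oracle_order))
  paste0(paste(paste0(keys[ord], "-", labs[ord]), collapse = "_"),
         "_", suffix, ext)
}

# ---- random valid artifact names ----
random_label <- function() {
  n <- sample(1:6, 1)
  paste(sample(c(letters, LETTERS, 0:9), n, replace = TRUE), collapse = "")
}

random_artifact <- function() {
  suffix <- sample(c("pet", "blood", "T1w"), 1)
  ext <- switch(suffix,
                pet = sample(c(".nii", ".nii.gz", ".json"), 1),
                blood = sample(c(".json", ".tsv"), 1),
                T1w = sample(c(".nii", ".nii.gz", ".json"), 1))
  keys <- "sub"
  optional <- c("ses", "task", "trc", "rec", "run")
  if (suffix == "blood") optional <- c(optional, "recording")
  keys <- c(keys, optional[stats::runif(length(optional)) < 0.4])
  ents <- vapply(keys, function(k) {
    if (k == "run") as.character(sample(1:9, 1)) else random_label()
  }, character(1))
  # scrambled construction order exercises canonicalisation
  ents <- ents[sample(seq_along(ents))]
  artifact_name(ents, suffix, ext)
}

# ---- a complete, valid sidecar field list ----
valid_sidecar_fields <- function(...) {
  base <- list(
    TracerName = "CIMBI-36",
    TracerRadionuclide = "11C",
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
    FrameTimesStart = c(0, 60, 120),
    FrameDuration = c(60, 60, 60),
    ImageDecayCorrected = TRUE,
    ImageDecayCorrectionTime = 0)
  utils::modifyList(base, list(...), keep.null = FALSE)
}

# ---- dataset fixtures ----
make_dataset <- function(..., dir = withr::local_tempdir(
                           .local_envir = parent.frame())) {
  spec <- study_spec(...)
  root <- file.path(dir, "ds")
  generate_dataset(spec, root, overwrite = TRUE)
  root
}

edit_json <- function(path, fn) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  doc <- fn(doc)
  for (f in c("FrameTimesStart", "FrameDuration")) {
    if (!is.null(doc[[f]]) && length(doc[[f]]) == 1) doc[[f]] <- I(doc[[f]])
  }
  txt <- if (length(doc) == 0) "{}" else
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 4,
                                  digits = I(17)))
  writeLines(txt, path, useBytes = TRUE)
}

first_file <- function(root, pattern) {
  hits <- list.files(root, pattern = pattern, recursive = TRUE,
                     full.names = TRUE)
  stopifnot(length(hits) >= 1)
  hits[1]
}

# ---- the single-fault mutation catalogue (used by validator + acceptance) --
# each entry: fault injector + the code the report must contain
mutation_catalogue <- function() {
  list(
    PET101 = function(root) unlink(file.path(root,
                                             "dataset_description.json")),
    PET102 = function(root) unlink(file.path(root, "README")),
    PET103 = function(root) file.rename(file.path(root, "sub-01"),
                                        file.path(root, "subject-01")),
    PET104 = function(root) unlink(first_file(root, "_pet\\.json$")),
    PET105 = function(root) edit_json(first_file(root, "_pet\\.json$"),
                                      function(d) { d$TimeZero <- NULL; d }),
    PET106 = function(root) edit_json(first_file(root, "_pet\\.json$"),
                                      function(d) { d$Units <- "kBq/ml"; d }),
    PET107 = function(root) edit_json(
      first_file(root, "_T1w\\.json$"),
      function(d) { d$NonLinearGradientCorrection <- NULL; d }),
    PET108 = function(root) edit_json(
      first_file(root, "_pet\\.json$"),
      function(d) { d$InjectedRadioactivity <- "n/a"; d }),
    PET109 = function(root) edit_json(
      first_file(root, "_pet\\.json$"),
      function(d) { d$FrameTimesStart <- d$FrameTimesStart[-1]; d }),
    PET110 = function(root) edit_json(
      first_file(root, "_pet\\.json$"),
      function(d) { d$FrameTimesStart <- rev(d$FrameTimesStart); d }),
    PET113 = function(root) {
      tsv <- first_file(root, "recording-manual_blood\\.tsv$")
      lines <- readLines(tsv)
      lines[c(2, 3)] <- lines[c(3, 2)]
      writeLines(lines, tsv)
    },
    PET118 = function(root) unlink(first_file(root,
                                              "recording-manual_blood\\.tsv$")),
    PET120 = function(root) {
      img <- first_file(root, "_pet\\.nii\\.gz$")
      # "badtoken" has no hyphen: malformed entity token
      file.rename(img, file.path(dirname(img),
                                 "sub-01_badtoken_pet.nii.gz"))
    },
    PET127 = function(root) unlink(file.path(root, "participants.tsv")),
    PET128 = function(root) edit_json(
      first_file(root, "_pet\\.json$"),
      function(d) { d$InjectedMass <- "N/A"; d })
  )
}

# run the CLI with stdout and messages swallowed; return the exit code
capture_cli <- function(args) {
  code <- NULL
  utils::capture.output(code <- suppressMessages(petbids_cli(args)))
  code
}

# codes that may legitimately co-occur with a given injected fault
# (removing a file can orphan its mate; a renamed image orphans nothing
# but its sidecar mate check flips direction)
mutation_allowed_extras <- function() {
  list(PET103 = "PET129",  # renamed subject dir: entity/directory mismatch
       # illegal sentinel leaves the required field without a usable value
       PET108 = "PET105")
}
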