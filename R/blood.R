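# Blood recording pairs: a _blood.json sidecar describing which quantities
# were measured (with per-column descriptors) and a _blood.tsv table of timed
# samples, all on the single reference time scale relative to time zero.
#
# Canonical column names (the quantities of the exemplary manual table):
#   time                         s, relative to time zero
#   plasma_radioactivity         Bq/mL
#   whole_blood_radioactivity    Bq/mL
#   metabolite_parent_fraction   dimensionless, in [0, 1]
#   metabolite_polar_fraction    dimensionless, in [0, 1]

BLOOD_COLUMNS <- c("time", "plasma_radioactivity", "whole_blood_radioactivity",
                   "metabolite_parent_fraction", "metabolite_polar_fraction")

BLOOD_COLUMN_UNITS <- c(
  time = "s",
  plasma_radioactivity = "Bq/mL",
  whole_blood_radioactivity = "Bq/mL",
  metabolite_parent_fraction = "unitless",
  metabolite_polar_fraction = "unitless")

# which availability flag vouches for which column
AVAIL_COLUMN_MAP <- list(
  PlasmaAvail = "plasma_radioactivity",
  WholeBloodAvail = "whole_blood_radioactivity",
  MetaboliteAvail = "metabolite_parent_fraction")

#' Construct blood recording metadata
#'
#' @param recording `"manual"`, `"autosampler"`, or a custom label.
#' @param plasma_avail,whole_blood_avail,metabolite_avail Which quantities
#'   this recording provides.
#' @param columns A tibble with columns `column`, `description`, `units`
#'   describing every TSV column. Defaults to descriptors for the canonical
#'   columns implied by the availability flags (plus `time`).
#' @return An object of class `blood_metadata`.
#' @export
blood_metadata <- function(recording = "manual",
                           plasma_avail = FALSE,
                           whole_blood_avail = FALSE,
                           metabolite_avail = FALSE,
                           columns = NULL) {
  if (is.null(columns)) {
    cols <- "time"
    if (plasma_avail) cols <- c(cols, "plasma_radioactivity")
    if (whole_blood_avail) cols <- c(cols, "whole_blood_radioactivity")
    if (metabolite_avail) cols <- c(cols, "metabolite_parent_fraction",
                                    "metabolite_polar_fraction")
    columns <- default_column_descriptors(cols)
  }
  stopifnot(is.data.frame(columns),
            all(c("column", "description", "units") %in% names(columns)))
  structure(list(recording = recording,
                 plasma_avail = isTRUE(plasma_avail),
                 whole_blood_avail = isTRUE(whole_blood_avail),
                 metabolite_avail = isTRUE(metabolite_avail),
                 columns = as_tibble(columns)),
            class = "blood_metadata")
}

default_column_descriptors <- function(cols) {
  desc <- c(
    time = "Sample time relative to time zero",
    plasma_radioactivity = "Radioactivity concentration in plasma",
    whole_blood_radioactivity = "Radioactivity concentration in whole blood",
    metabolite_parent_fraction = "Fraction of plasma radioactivity from the unmetabolised parent compound",
    metabolite_polar_fraction = "Fraction of plasma radioactivity from polar metabolites")
  tibble(column = cols,
         description = unname(desc[cols]),
         units = unname(BLOOD_COLUMN_UNITS[cols]))
}

#' @export
print.blood_metadata <- function(x, ...) {
  cat("<blood_metadata> recording=", x$recording,
      " plasma=", x$plasma_avail,
      " whole_blood=", x$whole_blood_avail,
      " metabolite=", x$metabolite_avail, "\n", sep = "")
  print(x$columns)
  invisible(x)
}

blood_meta_to_json <- function(meta) {
  doc <- list(
    PlasmaAvail = meta$plasma_avail,
    WholeBloodAvail = meta$whole_blood_avail,
    MetaboliteAvail = meta$metabolite_avail,
    RecordingType = meta$recording)
  for (i in seq_len(nrow(meta$columns))) {
    doc[[meta$columns$column[i]]] <- list(
      Description = meta$columns$description[i],
      Units = meta$columns$units[i])
  }
  doc <- doc[order(names(doc))]
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 4,
                                digits = I(17)))
}

blood_meta_from_json <- function(doc) {
  col_keys <- names(doc)[map_lgl(doc, function(v)
    is.list(v) && any(c("Description", "Units") %in% names(v)))]
  columns <- tibble(
    column = col_keys,
    description = map_chr(col_keys, function(k)
      doc[[k]]$Description %||% NA_character_),
    units = map_chr(col_keys, function(k) doc[[k]]$Units %||% NA_character_))
  blood_metadata(
    recording = doc$RecordingType %||% "manual",
    plasma_avail = isTRUE(doc$PlasmaAvail),
    whole_blood_avail = isTRUE(doc$WholeBloodAvail),
    metabolite_avail = isTRUE(doc$MetaboliteAvail),
    columns = columns)
}

# render doubles so that as.numeric() recovers them bit-exactly, while
# keeping short decimals short (0.5 stays "0.5", not 17 digits)
format_double_roundtrip <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i])) { out[i] <- NA_character_; next }
    s <- format(x[i], digits = 15, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) != x[i]) s <- sprintf("%.17g", x[i])
    out[i] <- s
  }
  out
}

render_blood_tsv <- function(table) {
  stopifnot(is.data.frame(table))
  header <- paste(names(table), collapse = "\t")
  if (nrow(table) == 0L) return(paste0(header, "\n"))
  cells <- map(table, function(col) {
    s <- format_double_roundtrip(as.numeric(col))
    ifelse(is.na(s), NA_SENTINEL, s)
  })
  body <- do.call(paste, c(cells, sep = "\t"))
  paste0(header, "\n", paste(body, collapse = "\n"), "\n")
}

#' Read a blood recording pair
#'
#' Parses the `_blood.json` metadata and the `_blood.tsv` sample table
#' together and cross-validates them: quantities declared available must have
#' a TSV column (`DECLARED_NOT_PRESENT`), every column should carry a
#' descriptor (`PRESENT_NOT_DECLARED`), the `time` column must exist and be
#' strictly increasing, cells must be numbers or the `"n/a"` sentinel, and
#' metabolite fractions must lie in \[0, 1\].
#'
#' @param json A file path or JSON string (the `_blood.json` sidecar).
#' @param tsv A file path or TSV text (the `_blood.tsv` table).
#' @param path Dataset-relative path recorded in findings.
#' @return A list with `metadata` (a [blood_metadata()]), `table` (a tibble
#'   with numeric columns; `"n/a"` becomes `NA`), and `findings`.
#' @export
read_blood_record <- function(json, tsv, path = ".") {
  json_txt <- slurp_maybe_file(json)
  tsv_txt <- slurp_maybe_file(tsv)
  doc <- tryCatch(jsonlite::fromJSON(json_txt, simplifyVector = FALSE),
                  error = function(e)
                    abort(paste0("not a JSON document: ",
                                 conditionMessage(e)),
                          class = "petbids_format_error"))
  meta <- blood_meta_from_json(doc)
  findings <- no_findings()

  raw <- readr::read_tsv(I(tsv_txt), col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = character())
  tab <- tibble(.rows = nrow(raw))
  for (cn in names(raw)) {
    cell <- raw[[cn]]
    vals <- suppressWarnings(as.numeric(cell))
    is_na_cell <- cell == NA_SENTINEL
    variant <- tolower(cell) %in% c("n/a", "na") & !is_na_cell
    bad <- is.na(vals) & !is_na_cell & !variant
    for (r in which(variant)) {
      findings <- bind_rows(findings, new_finding(
        "PET128",
        paste0("column '", cn, "', row ", r, ": sentinel must be lowercase ",
               "'n/a', got '", cell[r], "'"),
        path))
    }
    for (r in which(bad)) {
      findings <- bind_rows(findings, new_finding(
        "PET114",
        paste0("column '", cn, "', row ", r, ": '", cell[r],
               "' is not a number or 'n/a'"),
        path))
    }
    vals[is_na_cell | variant] <- NA_real_
    tab[[cn]] <- vals
  }

  if (!("time" %in% names(tab))) {
    findings <- bind_rows(findings, new_finding(
      "PET112", "blood table has no 'time' column", path))
  } else {
    tm <- tab$time[!is.na(tab$time)]
    if (length(tm) > 1L && any(diff(tm) <= 0)) {
      findings <- bind_rows(findings, new_finding(
        "PET113", "'time' column is not strictly increasing", path))
    }
  }

  for (fr in intersect(c("metabolite_parent_fraction",
                         "metabolite_polar_fraction"), names(tab))) {
    v <- tab[[fr]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      findings <- bind_rows(findings, new_finding(
        "PET115", paste0("column '", fr, "' has values outside [0, 1]"),
        path))
    }
  }

  avail_flags <- c(PlasmaAvail = meta$plasma_avail,
                   WholeBloodAvail = meta$whole_blood_avail,
                   MetaboliteAvail = meta$metabolite_avail)
  for (flag in names(AVAIL_COLUMN_MAP)) {
    col <- AVAIL_COLUMN_MAP[[flag]]
    if (avail_flags[[flag]] && !(col %in% names(tab))) {
      findings <- bind_rows(findings, new_finding(
        "PET116",
        paste0("metadata declares ", flag, " but the table has no '",
               col, "' column"),
        path))
    }
  }
  undeclared <- setdiff(names(tab), meta$columns$column)
  for (cn in undeclared) {
    findings <- bind_rows(findings, new_finding(
      "PET117",
      paste0("table column '", cn, "' has no descriptor in the metadata"),
      path))
  }

  list(metadata = meta, table = tab, findings = sort_findings(findings))
}

slurp_maybe_file <- function(x) {
  if (length(x) == 1L && !grepl("[{\n\t]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
}

#' Write a blood recording pair
#'
#' Inverse of [read_blood_record()]: produces the JSON sidecar text and the
#' TSV text (tab-separated, LF line endings, header row, `"n/a"` sentinels,
#' and decimal rendering that re-parses to the identical double).
#'
#' @param meta A [blood_metadata()] object.
#' @param table A data frame of samples; `NA` cells become `"n/a"`.
#' @param json_path,tsv_path Optional file paths to also write to.
#' @return A list with elements `json` and `tsv` (character).
#' @export
write_blood_record <- function(meta, table, json_path = NULL,
                               tsv_path = NULL) {
  stopifnot(inherits(meta, "blood_metadata"), is.data.frame(table))
  if (nrow(table) > 0L && "time" %in% names(table)) {
    tm <- table$time[!is.na(table$time)]
    if (length(tm) > 1L && any(diff(tm) <= 0)) {
      abort("blood table 'time' must be strictly increasing",
            class = "petbids_blood_invariant")
    }
  }
  json <- blood_meta_to_json(meta)
  tsv <- render_blood_tsv(table)
  if (!is.null(json_path)) writeLines(json, json_path, useBytes = TRUE)
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "wb")
    writeChar(tsv, con, eos = NULL)
    close(con)
  }
  list(json = json, tsv = tsv)
}

#' Merge manual and autosampler blood tables
#'
#' Union of time points on the shared reference scale, sorted by time. At a
#' time point present in both recordings the autosampler's whole-blood value
#' wins (the continuous device is the authority for whole blood) and a
#' warning is emitted; plasma and metabolite columns come from the manual
#' samples. No interpolation is performed — the standard stores measurements,
#' not derived curves.
#'
#' @param manual,autosampler Blood sample tibbles with a `time` column.
#'   Duplicate time points within one table must agree, or an error is
#'   raised; agreeing duplicates collapse to one row.
#' @return A tibble with the union of time points and columns.
#' @export
merge_recordings <- function(manual, autosampler) {
  stopifnot(is.data.frame(manual), is.data.frame(autosampler))
  manual <- collapse_duplicate_times(manual, "manual")
  autosampler <- collapse_duplicate_times(autosampler, "autosampler")
  if (nrow(autosampler) == 0L) return(as_tibble(manual))
  if (nrow(manual) == 0L) return(as_tibble(autosampler))

  wb <- "whole_blood_radioactivity"
  shared <- intersect(manual$time, autosampler$time)
  if (wb %in% names(manual) && wb %in% names(autosampler) &&
      length(shared)) {
    mv <- manual[[wb]][match(shared, manual$time)]
    av <- autosampler[[wb]][match(shared, autosampler$time)]
    clash <- !is.na(mv) & !is.na(av) & mv != av
    if (any(clash)) {
      warn(paste0("whole-blood values disagree at t = ",
                  paste(shared[clash], collapse = ", "),
                  " s; keeping the autosampler values"),
           class = "petbids_merge_tiebreak")
    }
  }

  merged <- full_join(autosampler, manual, by = "time",
                      suffix = c(".auto", ".manual"))
  out <- tibble(time = merged$time)
  all_cols <- union(names(autosampler), names(manual))
  for (cn in setdiff(all_cols, "time")) {
    a <- merged[[paste0(cn, ".auto")]] %||% merged[[cn]]
    m <- merged[[paste0(cn, ".manual")]] %||% merged[[cn]]
    out[[cn]] <- if (cn == wb) coalesce(a, m) else coalesce(m, a)
  }
  arrange(out, .data$time)
}

collapse_duplicate_times <- function(tab, label) {
  tab <- as_tibble(tab)
  if (nrow(tab) == 0L || !("time" %in% names(tab))) return(tab)
  if (!anyDuplicated(tab$time)) return(arrange(tab, .data$time))
  groups <- split(tab, tab$time)
  rows <- map(groups, function(g) {
    u <- distinct(g)
    if (nrow(u) > 1L) {
      abort(paste0("conflicting ", label, " samples at duplicate time ",
                   g$time[1], " s"),
            class = "petbids_merge_conflict")
    }
    u
  })
  arrange(bind_rows(rows), .data$time)
}
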