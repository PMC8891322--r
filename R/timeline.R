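# The single-time-scale convention: every PET frame, blood sample and dose
# assay is expressed in seconds relative to one "time zero" (injection start
# or scan start), and radioactivity is decay-corrected to that point using
# A_corr = A_meas * 2^(dt / T_half).

#' Radionuclide half-life reference table
#'
#' Half-lives of radionuclides in common PET use, in seconds. These are
#' standard nuclear reference values shipped for convenience; supply your own
#' half-life through [decay_context()] when precision matters for your
#' isotope batch.
#'
#' @return A tibble with columns `radionuclide` (canonical form, e.g. `"11C"`)
#'   and `half_life_s`.
#' @export
#' @examples
#' radionuclide_half_lives()
radionuclide_half_lives <- function() {
  tibble::tribble(
    ~radionuclide, ~half_life_s,
    "11C",   1221.84,    # 20.364 min
    "13N",    597.9,     # 9.965 min
    "15O",    122.24,
    "18F",   6586.26,    # 109.771 min
    "64Cu", 45721.4,     # 12.7004 h
    "68Ga",  4062.6,     # 67.71 min
    "82Rb",    75.45,
    "89Zr", 282276.0,    # 78.41 h
    "124I", 360806.4     # 4.176 d
  )
}

# "C-11", "[11C]", "c11" -> "11C"
normalize_radionuclide <- function(x) {
  x <- toupper(gsub("[^A-Za-z0-9]", "", x))
  m <- regmatches(x, regexec("^([A-Z]+)([0-9]+)$|^([0-9]+)([A-Z]+)$", x))[[1]]
  if (length(m) == 0L || !nzchar(m[1])) return(x)
  if (nzchar(m[2])) paste0(m[3], substr(m[2], 1, 1),
                           tolower(substr(m[2], 2, nchar(m[2]))))
  else paste0(m[4], substr(m[5], 1, 1), tolower(substr(m[5], 2, nchar(m[5]))))
}

#' Look up a radionuclide half-life
#'
#' @param radionuclide Radionuclide name in any common spelling
#'   (`"11C"`, `"C-11"`, `"[11C]"`, ...).
#' @return Half-life in seconds.
#' @export
#' @examples
#' half_life_of("C-11")
half_life_of <- function(radionuclide) {
  key <- normalize_radionuclide(radionuclide)
  reg <- radionuclide_half_lives()
  i <- match(key, reg$radionuclide)
  if (is.na(i)) {
    abort(paste0("unknown radionuclide '", radionuclide,
                 "'; supply half_life directly via decay_context()"),
          class = "petbids_unknown_radionuclide")
  }
  reg$half_life_s[i]
}

#' Decay-correction context
#'
#' Bundles the radionuclide half-life with the dataset's time-zero
#' convention. All correction arithmetic is in seconds.
#'
#' @param half_life Half-life in seconds (> 0).
#' @param time_zero Which event anchors the reference time scale:
#'   `"injection_start"` or `"scan_start"`.
#' @return An object of class `decay_context`.
#' @export
#' @examples
#' decay_context(half_life_of("11C"), "injection_start")
decay_context <- function(half_life,
                          time_zero = c("injection_start", "scan_start")) {
  if (!is.numeric(half_life) || length(half_life) != 1L ||
      is.na(half_life) || half_life <= 0) {
    abort("half_life must be a single positive number of seconds",
          class = "petbids_bad_half_life")
  }
  time_zero <- match.arg(time_zero)
  structure(list(half_life = as.numeric(half_life), time_zero = time_zero),
            class = "decay_context")
}

#' @export
print.decay_context <- function(x, ...) {
  cat("<decay_context> half-life ", x$half_life, " s, time zero = ",
      x$time_zero, "\n", sep = "")
  invisible(x)
}

as_half_life <- function(ctx) {
  if (inherits(ctx, "decay_context")) return(ctx$half_life)
  if (is.numeric(ctx) && length(ctx) == 1L && !is.na(ctx) && ctx > 0) {
    return(as.numeric(ctx))
  }
  abort("expected a decay_context or a positive half-life in seconds",
        class = "petbids_bad_half_life")
}

#' Decay-correction factor to time zero
#'
#' Multiplying a measured activity by this factor references it back to time
#' zero: `factor = 2^(elapsed_s / half_life)`. Negative elapsed times
#' (samples drawn before time zero) are legal and give factors below 1.
#' The factor satisfies `factor(0) == 1` and the group property
#' `factor(a + b) == factor(a) * factor(b)`.
#'
#' @param elapsed_s Seconds since time zero (vectorised; may be negative).
#' @param ctx A [decay_context()] (or a bare half-life in seconds).
#' @return Positive numeric vector, same length as `elapsed_s`.
#' @export
#' @examples
#' ctx <- decay_context(1221.84)
#' decay_correction_factor(c(0, 1221.84, 600), ctx)
decay_correction_factor <- function(elapsed_s, ctx) {
  hl <- as_half_life(ctx)
  2^(elapsed_s / hl)
}

#' Re-reference decay-corrected values to a new time zero
#'
#' Values already decay-corrected to one reference point are re-expressed
#' relative to another by the constant factor
#' `2^((old_zero_offset_s - new_zero_offset_s) / half_life)`; both offsets are
#' on the same arbitrary scale. Identical offsets give the identity.
#'
#' @param values Numeric vector of decay-corrected activities.
#' @param old_zero_offset_s Offset of the current reference point, seconds.
#' @param new_zero_offset_s Offset of the desired reference point, seconds.
#' @param ctx A [decay_context()] (or a bare half-life in seconds).
#' @return Numeric vector corrected to the new reference point.
#' @export
rereference_correction <- function(values, old_zero_offset_s,
                                   new_zero_offset_s, ctx) {
  hl <- as_half_life(ctx)
  values * 2^((old_zero_offset_s - new_zero_offset_s) / hl)
}

#' Decay-correct an injected dose to injection time
#'
#' The injected dose is always referenced to the moment of injection: an
#' assay performed `measurement_offset_s` seconds after injection is scaled
#' by `2^(measurement_offset_s / half_life)` (assays before injection have
#' negative offsets and scale down).
#'
#' @param measured_activity Assayed activity (e.g. Bq).
#' @param measurement_offset_s Signed seconds from injection to the assay.
#' @param ctx A [decay_context()] (or a bare half-life in seconds).
#' @return The dose at injection time, same units as `measured_activity`.
#' @export
#' @examples
#' dose_at_injection(150e6, 300, decay_context(6586.26))
dose_at_injection <- function(measured_activity, measurement_offset_s, ctx) {
  hl <- as_half_life(ctx)
  measured_activity * 2^(measurement_offset_s / hl)
}
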