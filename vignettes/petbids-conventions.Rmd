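---
title: "Conventions, models and design choices in petbids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conventions, models and design choices in petbids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petbids)
```

`petbids` implements a working toolkit for PET neuroimaging datasets in the
BIDS layout. This vignette is the package's own account of the conventions
it enforces, the choices made where the layout leaves room, and what the
test fixtures do and do not demonstrate.

## The single time scale and the decay model

A dynamic PET experiment is defined on one reference time scale anchored at
*time zero* — either injection start or scan start. Every quantity the
package handles (frame start times, blood sample times, the decay-correction
reference of the image) is a signed number of seconds relative to that
anchor; the anchor's wall-clock time lives in the `TimeZero` sidecar field
as `"HH:MM:SS"` text. Keeping every duration and offset in seconds means
all arithmetic happens in one unit; there are deliberately no minute-based
interfaces anywhere.

Radioactive decay follows the standard exponential law. With half-life
$T_{1/2} > 0$ (seconds), a measurement made $\Delta t$ seconds after time
zero is corrected back to time zero by

$$A_\mathrm{corr} = A_\mathrm{meas} \cdot 2^{\Delta t / T_{1/2}},$$

implemented in `decay_correction_factor()`. Properties that follow directly
and are verified in the test suite: the factor is 1 at $\Delta t = 0$, 2 at
one half-life, strictly increasing, multiplicative over time intervals
(`factor(a+b) == factor(a)·factor(b)` to within $10^{-12}$ relative), and
below 1 for samples drawn *before* time zero — negative elapsed times are
legal (pre-injection blanks). Re-referencing values that are already
corrected to one anchor onto another is multiplication by the single
constant $2^{(t_\mathrm{old} - t_\mathrm{new})/T_{1/2}}$
(`rereference_correction()`), and the injected dose is always referenced to
the moment of injection (`dose_at_injection()`).

The half-life is never hard-coded: `decay_context()` carries it explicitly,
and `radionuclide_half_lives()` ships a small registry of standard nuclear
reference values (carbon-11 1221.84 s, fluorine-18 6586.26 s, ...) purely
for convenience. `shift_time_zero()` needs a half-life to re-reference
blood activities when moving the anchor between scan start and injection
start; because its natural inputs are a sidecar and blood tables, it looks
the half-life up from `TracerRadionuclide` by default and accepts an
explicit `ctx` override. The shift itself subtracts one constant from every
time field, so all inter-event intervals are preserved exactly and the
operation is an involution up to floating point (verified at $10^{-9}$
relative tolerance).

## The sidecar schema

The upstream specification defers its full field catalogue to a living
document; to keep validation self-contained this package fixes one schema
table (enforced by `check_required_fields()`, `check_units()`,
`check_frame_timing()`):

| field | type / unit | notes |
|---|---|---|
| `TracerName`, `TracerRadionuclide` | text | |
| `InjectedRadioactivity` (+`Units`) | number, `"Bq"` | |
| `InjectedMass` (+`Units`) | number or `"n/a"`, `"ug"` | sentinel allowed |
| `SpecificRadioactivity` (+`Units`) | number or `"n/a"`, `"Bq/g"` | sentinel allowed |
| `Units` | `"Bq/mL"` | image voxel values |
| `TimeZero` | `"HH:MM:SS"` | wall clock of the anchor |
| `ScanStart`, `InjectionStart` | s relative to time zero | one should be 0 |
| `FrameTimesStart`, `FrameDuration` | s, arrays | chronological, non-overlapping |
| `ImageDecayCorrected` | boolean | |
| `ImageDecayCorrectionTime` | s | required iff corrected |

Unit strings are matched exactly: radioactivity concentration must be the
string `"Bq/mL"` and time units `"s"`. The dose-field unit strings (`"Bq"`,
`"ug"`, `"Bq/g"`) are this package's SI-coherent choices; they are checked
as exact strings so that two compliant datasets are bit-comparable.

The `"n/a"` sentinel marks unmeasurable values and is legal **only** for
injected mass and specific activity (some tracers' injected mass is too low
to measure). It is the literal lowercase three characters in JSON and TSV
alike; case variants (`"N/A"`, `"NA"`) get their own finding (`PET128`)
rather than silent acceptance, because interoperability of shared datasets
is worth more than leniency. Unknown sidecar keys are preserved verbatim
and produce no finding: forward compatibility.

Frame timing permits gaps (an interrupted acquisition — a subject leaving
the scanner briefly — is missing data within a run, not a new run) but
rejects overlap, disorder, non-positive durations, and any mismatch with
the image volume count.

## Blood recordings

A recording is a JSON/TSV pair. Canonical machine column names are fixed
here as lower_snake_case (`time`, `plasma_radioactivity`,
`whole_blood_radioactivity`, `metabolite_parent_fraction`,
`metabolite_polar_fraction`) since the layout names the quantities but not
the column spellings. Cross-validation runs in both directions: a declared
quantity without its column is an error (`PET116`); a column without a
descriptor is a warning (`PET117`) — extra measured data is not a
compliance failure.

`merge_recordings()` takes the set union of time points, no interpolation:
the standard stores measurements, and resampling belongs to analysis
pipelines. At a time point present in both recordings the autosampler's
whole-blood value wins (the continuous device is the authority for whole
blood) with an R warning; plasma and metabolite values always come from the
manual samples. Duplicate times *within* one input with disagreeing values
are an error — there is no principled tie-break for a device disagreeing
with itself; equal duplicates collapse silently.

## Validation severity policy

Rules the layout phrases as hard requirements are errors: sidecar presence,
the SI unit strings, the n/a policy, frame-timing consistency, and
`NonLinearGradientCorrection` on anatomical MRI whenever PET data are
present (the MR image must be unwarped — or declared not — to co-register
with PET). Recommendations are warnings: README and `participants.tsv`
presence, a time-zero anchor at 0, reserved `rec`/`recording` labels,
decay correction referencing a non-zero time point, and mixed
decay-correction references across a dataset. Zero-byte NIfTI images (as
found in published example trees) validate with a warning and skip the
volume-count check. Findings are sorted by `(path, code)` so two runs on
the same tree produce identical reports. Sidecar inheritance from upper
directory levels is not implemented: the validator requires a
same-directory sidecar.

The entity order in composed names is fixed as `sub, ses, task, trc, rec,
run, recording` (the order the entities are introduced); parsing accepts
any order and canonicalises. Non-reserved `rec`/`recording` labels parse
fine and are downgraded to warnings — reserved values are reserved, not
exhaustive. Labels are restricted to `[A-Za-z0-9]`, `run` must be a
positive integer, unknown entity keys are a parse error, and `.nii.gz` is
matched longest-first as a single two-part extension. Whether `task`/`trc`
may co-occur with `recording` on blood files is left open upstream; any
combination satisfying the structural invariants is accepted.

## The synthetic generator

`study_spec()`/`generate_dataset()` exist so every other module is testable
with no download. The defaults are the package's fixed study conditions: a
single-subject carbon-11 bolus study, injection at scan start (both anchors
0), eight non-overlapping frames spanning 720 s, an 8×8×8 voxel float32
grid, manual samples at eight discrete times, autosampler coverage of
0–600 s in 10 s steps. Kinetics are a two-exponential family
$A(t) = C\,(e^{-k_\mathrm{out}t} - e^{-k_\mathrm{in}t})$ with parameters
drawn from seeded uniform ranges ($C \in [2,6]\times10^4$ Bq/mL,
$k_\mathrm{in} \in [0.008, 0.02]$ s⁻¹, $k_\mathrm{out} \in [3, 12]\times
10^{-4}$ s⁻¹); the parent fraction decays monotonically from 1 to a floor
in $[0.05, 0.2]$, and whole blood is a fixed 1.05 × plasma so that whole
blood always dominates the parent-compound activity. Every draw flows from
the spec's seed, NIfTI data are 32-bit float with no scaling-slope tricks,
and the same spec yields byte-identical files.

What this emulates: the directory grammar, complete metadata, physically
plausible curve shapes on the shared time scale. What it does not:
scanner noise, attenuation, scatter, motion, reconstruction artefacts, or
any biological fidelity of the kinetic parameters. A green generator ↔
validator contract therefore demonstrates the *layout* logic, not that the
validator would accept or reject any particular real scanner's output.

## Numerical choices

* JSON is written UTF-8, 4-space indent, alphabetically sorted keys, with
  17 significant digits so every double re-parses bit-exactly; frame lists
  stay JSON arrays even at length 1.
* TSV doubles are rendered at 15 significant digits and promoted to 17 only
  when 15 would not round-trip, keeping files human-readable while
  `write → read` reproduces values to 0 ulp.
* Degenerate inputs: empty blood tables write a header-only TSV; a
  zero-scale region gives an all-zero TAC; shifting time zero onto the
  current anchor returns the input unchanged.
* Test tolerances: $10^{-12}$ relative for decay identities (float
  round-off accumulates over a product of two exponentials), $10^{-9}$ for
  the shift involution, exact (`identical`) for I/O round trips.

## Problem sizes

The suites run entirely on generated data: grammar properties over 1000
random names plus an exhaustive small-alphabet sweep against a brute-force
tokenizer oracle; 50 randomized study specs for the generator ↔ validator
contract; 15 single-fault mutations; tiny image grids (≤ 8³ voxels,
≤ 8 frames). These sizes were chosen so the whole default suite completes
in under a minute while still exercising every rule; they are stated here
as the package's own test design.

## Known limitations

Conversion from DICOM/ECAT, upload workflows, pharmacokinetic modeling and
derivative layouts are out of scope. Dispersion/delay correction of
autosampler curves and plasma-to-whole-blood modeling are analysis
concerns, not storage concerns, and are deliberately absent. The validator
checks only the PET-relevant subset of the wider BIDS family; non-PET
modalities beyond the anatomical gradient-correction rule are not modelled.
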