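---
title: "Building a psychosocial JEM and job strain index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a psychosocial JEM and job strain index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jemkit)
```

## The model

A job exposure matrix assigns every worker sharing an occupational title the
same exposure estimate, derived from survey respondents holding that title.
`jemkit` builds such a matrix for psychosocial exposures and condenses it
into a job strain index following Karasek's Demand-Control model: jobs are
cross-classified by psychological demands and decision latitude (control),
and the *high strain* combination — high demands with low control — is the
primary adverse category.

The construction rests on three assumptions worth stating explicitly:

* **Relative, not absolute, exposure.** Every dichotomization in the
  pipeline is a median split of the observed distribution (individual
  responses first, occupation-level shares second). The index says "more
  adverse than the typical job", not "above a clinically validated
  threshold". This makes the index self-calibrating across survey vintages
  but means thresholds move if the input population changes.
* **Within-cell homogeneity.** All workers in one (JEM group, gender) cell
  receive identical exposures; inter-individual variation within an
  occupation is deliberately averaged away. Codes that share a JEM group
  are exact duplicates of each other by construction.
* **Item-level complete-case estimation.** Missing responses are dropped
  per item from both the median and the share, which is unbiased when item
  nonresponse is unrelated to the response value (the generator's missing
  data are MCAR by design; real nonresponse need not be).

## Pipeline and conventions

1. **Orientation alignment.** Each item carries an `adverse_high` flag.
   Protective items (e.g. "decide how to go about the work") are reflected,
   `x -> scale_min + scale_max - x`, so "larger = more adverse" holds
   uniformly. The default item file codes the five opportunity-type control
   items as protective and monotonous work as adverse; these orientations
   are documented coding assumptions, configurable in the YAML item file,
   not survey facts.
2. **Individual cut-offs.** Per item, the cut-off is the median of aligned
   non-missing responses pooled over all waves, genders and occupations. A
   respondent is exposed iff the aligned value is *strictly greater* than
   the cut-off: with a median of 2 on the 1–5 frequency scale, values 3–5
   are exposed and a response at the median is not. For even counts the
   median is the midpoint of the two central order statistics; on integer
   scales a half-integer cut-off combined with the strict rule is
   equivalent to "above the lower central value", so the convention never
   creates boundary ambiguity.
3. **Shares.** Within each (group, gender) cell,
   `share = 100 * exposed / non-missing`. The boundary semantics are exact:
   0 iff no non-missing respondent is exposed, 100 iff all are.
4. **Occupation classification.** Per item, the cut-off is the unweighted
   median of shares across group–gender *cells*; a cell is exposed iff its
   share strictly exceeds it. Ties (e.g. all cells equal) classify nobody —
   consistent with the individual-level strict rule.
5. **Strain.** The demand index counts exposed demand items (0–4), the
   control index counts exposed control items coded as adversity (0–6).
   High demand and low control are again strict median splits across fully
   observed rows, and the four quadrants partition those rows; `job_strain`
   is exactly the high-strain quadrant.

## Tunable parameters

| parameter | where | default | rationale |
|---|---|---|---|
| `scale_min`/`scale_max` | item config | 1–5 | five-point frequency scales of the source items |
| `adverse_high` | item config | explicit per item | orientation is substantive; only demand items default (to `TRUE`) |
| `n_min` | `build_jem()` | 10 respondents | below this, a share is suppressed to missing — "no data" must stay distinct from "0% exposed" |
| `stratify_by_gender` | `build_jem()` | `TRUE` | the index is designed to merge on occupation code *and* gender |
| `per_wave` | `compute_cutoffs()` | `FALSE` | one pooled median per item keeps a single fixed reference point across waves |
| `median_over` | `assign_occupation_exposure()` | `"cells"` | shares are defined at cell level; `"codes"` would implicitly weight groups by how many codes they contain |
| `policy` | `convert_codes()` | `"strict"` | crosswalks without an official key can introduce errors; silent resolution (`first_match`, `expand_rows`) is opt-in |

Where the design was genuinely open we chose and documented rather than
guessed silently: cut-offs are pooled over waves (a per-wave option exists
but defaults off, since a single reference point is what makes the matrix a
stable lookup); the share median is taken over cells; and the index is
exported in all three natural forms — binary `job_strain`, the four
quadrants, and the continuous demand/control counts — with the binary flag
designated primary, because downstream register studies overwhelmingly use
the dichotomous strain exposure while the counts preserve information for
sensitivity analyses.

## What the generator emulates — and what it does not

`simulation_scenario()` defaults mirror the structure the method is built
for: 333 occupation codes in 268 JEM groups, five survey waves (2006–2019),
and 16 respondents per (group, gender, wave) cell, i.e. roughly 43,000
respondents in total. Responses are drawn by a two-point construction: an
exposed draw lands uniformly on aligned values strictly above the intended
cut-off (2), a non-exposed draw at or below it, so
`P(aligned > cutoff)` equals the cell's generating probability *exactly*.
When the mean generating probability is below 0.5 the pooled empirical
median lands on the intended cut-off, and the full pipeline recovers the
generating probabilities up to binomial noise. Default cell probabilities
are drawn uniformly on [0.05, 0.45] — realistic exposure prevalences that
also satisfy this condition; missingness defaults to 2% MCAR.

The generator deliberately does not emulate: sampling weights or
calibration, panel/rotation structure, interview mode effects, informative
nonresponse, or correlated items within respondent (responses are
conditionally independent given the cell). Passing recovery tests therefore
demonstrates that the *pipeline* is correct, not that median-split JEM
estimates are unbiased under realistic survey complications.

## Numerical and degenerate-input choices

* Shares are stored at full precision; rounding (1 decimal by default for
  the matrix) happens only on export. The strain-index export defaults to
  full precision so the file round-trips exactly.
* Occupation codes are fixed-width 4-character strings, zero-padded on
  every entry point — codes are identifiers, and integer parsing would
  corrupt leading zeros.
* An item with zero non-missing responses is an error (no cut-off is
  defensible); a cell with zero non-missing flags gets a missing share.
* A single cell is its own share median and hence non-exposed; identically
  tied shares classify nobody. All-zero exposure yields universal
  `low_strain`.
* Rows with any missing constituent flag get missing indices and quadrant,
  and are excluded from the index medians.
* Duplicate (code, gender) keys in the merge index are an error, never a
  silent row fan-out; register merges preserve row count exactly and report
  unmatched codes separately from unmatched gender cells.

## Verification strategy and problem sizes

The test suite checks every stage against an independent brute-force
re-computation (explicit loops and sorts) on 200 random fixtures of up to
50 group–gender cells, exact to the last flag and quadrant; parameter
recovery is tested at 500 respondents per cell across 100 cells, requiring
99% of cell shares within three binomial standard errors of truth; and the
boundary biconditionals (share 0 ⇔ none exposed, 100 ⇔ all exposed) are
tested in both directions. These sizes give the recovery test sub-percent
standard errors while keeping the whole suite comfortably fast on a
laptop.

## Known limitations

* The matrix is a fixed reference point: adding survey waves shifts pooled
  medians and can re-classify occupations; any update must re-document its
  thresholds.
* Median splits discard dose information and can be unstable for items
  whose distribution is concentrated at the median.
* Self-reported exposures risk same-source bias when later merged with
  self-reported or health outcomes.
* The crosswalk machinery applies a user-supplied key; it cannot conjure
  an authoritative correspondence where none exists, and hierarchical
  (3-digit prefix) fallback matching is intentionally out of scope.
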