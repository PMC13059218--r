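# Occupational-code crosswalk application and linkage of occupation-level
# exposures onto individual-level register-style data.

#' Construct and validate a crosswalk key
#'
#' A 4-digit source-to-target occupation-code mapping. Duplicated
#' (source, target) pairs are rejected; sources mapping to two or more
#' targets are permitted and enumerable with [ambiguous_sources()] — no
#' official correspondence key exists between the two classification
#' versions this emulates, so ambiguity must be handled explicitly (see
#' [convert_codes()]).
#'
#' @param pairs data frame with columns `source_code`, `target_code`.
#' @param provenance free-text note on where the key came from.
#' @return a `crosswalk_key` tibble.
#' @export
crosswalk_key <- function(pairs, provenance = "") {
  pairs <- as_tibble(pairs)
  if (!all(c("source_code", "target_code") %in% names(pairs))) {
    stop("crosswalk needs columns source_code, target_code", call. = FALSE)
  }
  pairs <- pairs[c("source_code", "target_code")]
  pairs$source_code <- pad_code(pairs$source_code)
  pairs$target_code <- pad_code(pairs$target_code)
  if (anyNA(pairs$source_code) || anyNA(pairs$target_code)) {
    stop("crosswalk contains missing codes", call. = FALSE)
  }
  dup <- duplicated(pairs)
  if (any(dup)) {
    stop("duplicated (source, target) pair(s): ",
         paste(unique(pairs$source_code[dup]), collapse = ", "),
         call. = FALSE)
  }
  pairs <- arrange(pairs, .data$source_code, .data$target_code)
  structure(pairs, class = c("crosswalk_key", class(tibble())),
            provenance = provenance)
}

#' @export
print.crosswalk_key <- function(x, ...) {
  amb <- ambiguous_sources(x)
  cat(sprintf("<crosswalk_key> %d pairs, %d sources (%d ambiguous)\n",
              nrow(x), dplyr::n_distinct(x$source_code), length(amb)))
  print(as_tibble(unclass(x)), ...)
  invisible(x)
}

#' Source codes with two or more candidate targets
#' @param key a [crosswalk_key()].
#' @return character vector of ambiguous source codes.
#' @export
ambiguous_sources <- function(key) {
  stopifnot(inherits(key, "crosswalk_key"))
  sort(unique(key$source_code[duplicated(key$source_code)]))
}

#' Load a crosswalk key from CSV
#' @param path CSV with header columns `source_code`, `target_code`.
#' @param provenance free-text note; defaults to the file path.
#' @return a validated [crosswalk_key()].
#' @export
load_crosswalk <- function(path, provenance = path) {
  if (!file.exists(path)) stop("crosswalk not found: ", path, call. = FALSE)
  crosswalk_key(read.csv(path, colClasses = "character", check.names = FALSE),
                provenance = provenance)
}

#' Write a crosswalk key to CSV
#' @param key a [crosswalk_key()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crosswalk <- function(key, path) {
  stopifnot(inherits(key, "crosswalk_key"))
  write.csv(as.data.frame(key), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Convert occupation codes through a crosswalk key
#'
#' Codes absent from the key pass through unchanged and are counted as
#' unconverted. Ambiguous sources (two or more candidate targets) are
#' handled per `policy`:
#' \describe{
#'   \item{strict}{(default) error naming the ambiguous codes — the unofficial
#'     key may introduce errors, so silent resolution is opt-in;}
#'   \item{first_match}{deterministically pick the lexicographically first
#'     target, with one warning listing the ambiguous sources converted;}
#'   \item{expand_rows}{emit one output row per candidate target, with the
#'     candidate count as provenance.}
#' }
#'
#' @param codes character vector of 4-digit codes (zero-padded on entry).
#' @param key a [crosswalk_key()].
#' @param policy `"strict"`, `"first_match"` or `"expand_rows"`.
#' @return a `code_conversion` tibble with columns `input_row`,
#'   `source_code`, `target_code`, `converted`, `n_candidates` (one row per
#'   input under strict/first_match; one per candidate under expand_rows).
#'   The conversion report is retrievable with [conversion_report()].
#' @export
convert_codes <- function(codes, key,
                          policy = c("strict", "first_match", "expand_rows")) {
  policy <- match.arg(policy)
  stopifnot(inherits(key, "crosswalk_key"))
  if (nrow(key) == 0L) stop("empty crosswalk key", call. = FALSE)
  codes <- pad_code(codes)
  amb <- ambiguous_sources(key)
  amb_seen <- sort(unique(codes[codes %in% amb]))
  if (policy == "strict" && length(amb_seen)) {
    stop("ambiguous source code(s) under strict policy: ",
         paste(amb_seen, collapse = ", "), call. = FALSE)
  }

  cand <- count(key, .data$source_code, name = "n_candidates")
  inp <- tibble(input_row = seq_along(codes), source_code = codes)
  if (policy == "expand_rows") {
    out <- left_join(inp, as_tibble(unclass(key)), by = "source_code",
                     relationship = "many-to-many")
  } else {
    first <- key %>%
      group_by(.data$source_code) %>%
      summarise(target_code = min(.data$target_code), .groups = "drop")
    out <- left_join(inp, first, by = "source_code")
    if (policy == "first_match" && length(amb_seen)) {
      warning("ambiguous source code(s) resolved to first target: ",
              paste(amb_seen, collapse = ", "), call. = FALSE)
    }
  }
  out$converted <- !is.na(out$target_code)
  out$target_code[!out$converted] <- out$source_code[!out$converted]
  out <- left_join(out, cand, by = "source_code")
  out$n_candidates[is.na(out$n_candidates)] <- 0L
  report <- list(policy = policy,
                 n_input = length(codes),
                 n_converted = sum(codes %in% key$source_code),
                 n_unconverted = sum(!codes %in% key$source_code),
                 ambiguous_sources_seen = amb_seen)
  structure(out, class = c("code_conversion", class(tibble())),
            report = report)
}

#' Report attached to a code conversion or merge
#' @param x a `code_conversion` from [convert_codes()].
#' @return the report list.
#' @export
conversion_report <- function(x) attr(x, "report")

#' Normalize gender codes to the two-level female/male factor
#'
#' Register sources encode gender inconsistently; values are lower-cased,
#' trimmed and looked up in an explicit mapping. Unmappable values raise an
#' error rather than silently becoming a third stratum.
#'
#' @param x character or numeric vector of gender codes.
#' @param mapping named character vector from lower-case source value to
#'   `"female"` or `"male"`.
#' @return character vector of `"female"` / `"male"`; `NA` stays `NA`.
#' @export
normalize_gender <- function(x, mapping = c(female = "female", f = "female",
                                            woman = "female", "2" = "female",
                                            male = "male", m = "male",
                                            man = "male", "1" = "male")) {
  if (!all(mapping %in% .gender_levels)) {
    stop("mapping values must be 'female' or 'male'", call. = FALSE)
  }
  key <- tolower(trimws(as.character(x)))
  out <- unname(mapping[key])
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop("unmappable gender value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Merge occupation-level exposures onto register microdata
#'
#' Left join on (occupation_code, gender): the register row count is
#' preserved exactly; unmatched rows keep missing exposure columns and are
#' flagged in the `matched` column. The index table must be unique per
#' (code, gender) — duplicates are an error, never silently multiplied into
#' the register.
#'
#' @param register tibble with `occupation_code` and `gender` columns (plus
#'   anything else, typically `person_id`).
#' @param index the exported JEM + strain table (e.g. from
#'   [export_strain_index()] or [read_strain_index()]).
#' @return list with `data` (merged tibble, stably sorted on `person_id`
#'   when present) and `report` (a `merge_report`: input rows, matched,
#'   unmatched by unknown code, unmatched by missing gender cell).
#' @export
merge_exposures <- function(register, index) {
  register <- as_tibble(register)
  index <- as_tibble(index)
  for (d in list(register, index)) {
    if (!all(c("occupation_code", "gender") %in% names(d))) {
      stop("both tables need occupation_code and gender columns",
           call. = FALSE)
    }
  }
  register$occupation_code <- pad_code(register$occupation_code)
  index$occupation_code <- pad_code(index$occupation_code)
  idx_key <- paste(index$occupation_code, index$gender)
  if (anyDuplicated(idx_key)) {
    stop("index table has duplicate (occupation_code, gender) key(s): ",
         paste(unique(idx_key[duplicated(idx_key)]), collapse = "; "),
         call. = FALSE)
  }
  merged <- left_join(register, index, by = c("occupation_code", "gender"))
  reg_key <- paste(register$occupation_code, register$gender)
  code_known <- register$occupation_code %in% index$occupation_code
  cell_known <- reg_key %in% idx_key
  merged$matched <- cell_known
  if ("person_id" %in% names(merged)) {
    merged <- arrange(merged, .data$person_id)
  }
  report <- structure(list(
    n_input_rows = nrow(register),
    n_matched = sum(cell_known),
    n_unmatched_code = sum(!code_known),
    n_unmatched_gender_cell = sum(code_known & !cell_known),
    policy_used = "left_join_exact"), class = "merge_report")
  list(data = merged, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("<merge_report>\n",
      sprintf("  input rows:              %d\n", x$n_input_rows),
      sprintf("  matched:                 %d\n", x$n_matched),
      sprintf("  unmatched (unknown code):%d\n", x$n_unmatched_code),
      sprintf("  unmatched (gender cell): %d\n", x$n_unmatched_gender_cell),
      sprintf("  policy: %s\n", x$policy_used), sep = "")
  invisible(x)
}

#' Write a merge report to a text file
#' @param report a `merge_report` from [merge_exposures()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_merge_report <- function(report, path) {
  stopifnot(inherits(report, "merge_report"))
  writeLines(c(sprintf("input rows: %d", report$n_input_rows),
               sprintf("matched: %d", report$n_matched),
               sprintf("unmatched (code not in index): %d",
                       report$n_unmatched_code),
               sprintf("unmatched (gender cell absent): %d",
                       report$n_unmatched_gender_cell),
               sprintf("policy: %s", report$policy_used)), path)
  invisible(path)
}
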