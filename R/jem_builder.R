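# JEM construction: per-item median cut-offs on the aligned scale,
# strict-greater dichotomization, and exposure-share aggregation within
# (JEM group, gender) cells.

#' Align a response to the adverse-high orientation
#'
#' Items where larger raw values mean *less* adverse exposure (e.g. frequent
#' opportunity to decide how to work) are reflected onto the adverse-high
#' scale: `scale_min + scale_max - value`. Items already adverse-high pass
#' through unchanged.
#'
#' @param value ordinal response(s); `NA` allowed.
#' @param item a single-row slice of an [item_set()].
#' @return aligned value(s) on the same scale.
#' @examples
#' it <- default_item_set()
#' align_response(5, it[it$item_id == "decide_how", ])  # reflected to 1
#' @export
align_response <- function(value, item) {
  stopifnot(nrow(item) == 1L)
  ok <- is.na(value) | (value >= item$scale_min & value <= item$scale_max)
  if (!all(ok)) {
    stop(sprintf("response out of range [%d, %d] for item '%s': %s",
                 item$scale_min, item$scale_max, item$item_id,
                 paste(unique(value[!ok]), collapse = ", ")), call. = FALSE)
  }
  if (item$adverse_high) value else item$scale_min + item$scale_max - value
}

# Long form with aligned values; validates ranges for all items at once.
.aligned_long <- function(survey, item_set) {
  missing_items <- setdiff(item_set$item_id, names(survey))
  if (length(missing_items)) {
    stop("survey lacks item column(s): ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  id_cols <- intersect(c("respondent_id", "wave", "occupation_code", "gender"),
                       names(survey))
  long <- tidyr::pivot_longer(as_tibble(survey)[c(id_cols, item_set$item_id)],
                              cols = all_of(item_set$item_id),
                              names_to = "item_id", values_to = "value")
  long <- left_join(long,
                    item_set[c("item_id", "scale_min", "scale_max",
                               "adverse_high")],
                    by = "item_id")
  bad <- !is.na(long$value) &
    (long$value < long$scale_min | long$value > long$scale_max)
  if (any(bad)) {
    off <- unique(long$item_id[bad])
    stop("out-of-range responses for item(s): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  long$aligned <- ifelse(long$adverse_high, long$value,
                         long$scale_min + long$scale_max - long$value)
  long
}

#' Compute per-item median cut-offs
#'
#' For each item, the cut-off is the median of the aligned non-missing
#' responses pooled over all waves and respondents (and both genders). For an
#' even count the median is the midpoint of the two central order statistics
#' (possibly a half-integer); combined with the strict-greater exposure rule
#' this is equivalent, on integer scales, to "above the lower central value".
#'
#' @param survey survey tibble (see [read_survey()] for the schema).
#' @param item_set an [item_set()].
#' @param per_wave if `TRUE`, compute one cut-off per (wave, item) instead of
#'   pooling over waves.
#' @return a `cutoff_table` tibble with columns `item_id`, `cutoff`, `n_used`
#'   (plus `wave` when `per_wave = TRUE`).
#' @export
compute_cutoffs <- function(survey, item_set, per_wave = FALSE) {
  long <- .aligned_long(survey, item_set)
  keys <- if (per_wave) c("wave", "item_id") else "item_id"
  tab <- long %>%
    group_by(across(all_of(keys))) %>%
    summarise(cutoff = median(.data$aligned, na.rm = TRUE),
              n_used = sum(!is.na(.data$aligned)), .groups = "drop")
  empty <- unique(tab$item_id[tab$n_used == 0L])
  if (length(empty)) {
    stop("no non-missing responses for item(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  structure(tab, class = c("cutoff_table", class(tibble())),
            per_wave = per_wave)
}

#' Dichotomize respondents at the item cut-offs
#'
#' A respondent is exposed on an item when the aligned response is *strictly*
#' greater than the item's cut-off; a response equal to the cut-off is
#' non-exposed. Missing responses yield missing flags.
#'
#' @param survey survey tibble.
#' @param cutoffs a `cutoff_table` from [compute_cutoffs()].
#' @param item_set an [item_set()].
#' @param valid_codes optional vector of known occupation codes; respondents
#'   with other codes trigger a warning (not an error).
#' @return an `exposure_flags` tibble: `respondent_id`, `wave`,
#'   `occupation_code`, `gender`, then one logical column per item
#'   (`TRUE` exposed, `FALSE` non-exposed, `NA` missing).
#' @export
dichotomize <- function(survey, cutoffs, item_set, valid_codes = NULL) {
  stopifnot(inherits(cutoffs, "cutoff_table"))
  uncovered <- setdiff(item_set$item_id, cutoffs$item_id)
  if (length(uncovered)) {
    stop("cutoff table does not cover item(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  if (!is.null(valid_codes)) {
    stray <- setdiff(unique(survey$occupation_code), pad_code(valid_codes))
    if (length(stray)) {
      warning("occupation code(s) not in validation list: ",
              paste(stray, collapse = ", "), call. = FALSE)
    }
  }
  long <- .aligned_long(survey, item_set)
  join_keys <- if (isTRUE(attr(cutoffs, "per_wave"))) {
    c("wave", "item_id")
  } else {
    "item_id"
  }
  long <- left_join(long, as_tibble(unclass(cutoffs))[c(join_keys, "cutoff")],
                    by = join_keys)
  long$flag <- long$aligned > long$cutoff
  id_cols <- intersect(c("respondent_id", "wave", "occupation_code", "gender"),
                       names(long))
  flags <- tidyr::pivot_wider(long[c(id_cols, "item_id", "flag")],
                              names_from = "item_id", values_from = "flag")
  flags <- flags[c(id_cols, item_set$item_id)]
  structure(flags, class = c("exposure_flags", class(tibble())),
            items = item_set$item_id)
}

#' Construct exposure flags from pre-dichotomized data
#'
#' For data already carrying exposed / non-exposed indicators (e.g. imported
#' from another dichotomization), wraps a data frame as the `exposure_flags`
#' object [build_jem()] consumes.
#'
#' @param df data frame with `occupation_code`, `gender` and one logical
#'   column per item (`TRUE` exposed, `NA` missing).
#' @param items character vector of item columns (default: all logical
#'   columns).
#' @return an `exposure_flags` tibble.
#' @export
exposure_flags <- function(df, items = NULL) {
  df <- as_tibble(df)
  if (!all(c("occupation_code", "gender") %in% names(df))) {
    stop("exposure flags need occupation_code and gender columns",
         call. = FALSE)
  }
  if (is.null(items)) {
    items <- names(df)[vapply(df, is.logical, logical(1))]
  }
  if (!length(items)) stop("no item flag columns found", call. = FALSE)
  for (it in items) {
    if (!is.logical(df[[it]])) {
      stop("flag column must be logical: ", it, call. = FALSE)
    }
  }
  df$occupation_code <- pad_code(df$occupation_code)
  structure(df, class = c("exposure_flags", class(tibble())), items = items)
}

#' Build the Job Exposure Matrix
#'
#' Aggregates exposure flags into shares within (JEM group, gender) cells:
#' for each cell and item, `share = 100 * exposed / (exposed + non-exposed)`
#' over non-missing flags. A share of 0 means no non-missing respondent in
#' the cell is exposed; 100 means all are. Cells whose non-missing count for
#' an item falls below `n_min` are suppressed to a missing share — "too few
#' to estimate" is deliberately distinct from "0% exposed". Respondents whose
#' occupation code is absent from the group map are excluded and reported.
#'
#' @param flags an `exposure_flags` tibble from [dichotomize()].
#' @param group_map a [jem_group_map()].
#' @param stratify_by_gender compute separate cells per gender (default
#'   `TRUE`; the index is designed to merge on occupation code *and* gender).
#' @param n_min minimum non-missing cell size below which shares are
#'   suppressed to `NA` (default 10).
#' @return a `jem_matrix`: one row per (jem_group_id, gender) with columns
#'   `share_<item>` (percent, 0–100) and `n_<item>` (non-missing counts);
#'   attribute `excluded` reports unmapped codes, see [jem_build_log()].
#' @export
build_jem <- function(flags, group_map, stratify_by_gender = TRUE,
                      n_min = 10L) {
  stopifnot(inherits(flags, "exposure_flags"),
            inherits(group_map, "jem_group_map"))
  if (nrow(flags) == 0L) stop("empty exposure flags", call. = FALSE)
  items <- attr(flags, "items")
  df <- as_tibble(flags)
  df$occupation_code <- pad_code(df$occupation_code)
  unmapped <- setdiff(unique(df$occupation_code), group_map$occupation_code)
  excluded <- df %>%
    filter(.data$occupation_code %in% unmapped) %>%
    count(.data$occupation_code, name = "n_rows")
  df <- left_join(df, group_map, by = "occupation_code")
  df <- filter(df, !is.na(.data$jem_group_id))
  if (nrow(df) == 0L) {
    stop("group map covers none of the observed occupation codes",
         call. = FALSE)
  }
  if (!stratify_by_gender) df$gender <- "all"

  long <- tidyr::pivot_longer(df[c("jem_group_id", "gender", items)],
                              cols = all_of(items),
                              names_to = "item_id", values_to = "flag")
  cells <- long %>%
    group_by(.data$jem_group_id, .data$gender, .data$item_id) %>%
    summarise(n_exposed = sum(.data$flag, na.rm = TRUE),
              n_nonmissing = sum(!is.na(.data$flag)), .groups = "drop") %>%
    mutate(share = ifelse(.data$n_nonmissing < max(n_min, 1L), NA_real_,
                          100 * .data$n_exposed / .data$n_nonmissing))
  wide <- tidyr::pivot_wider(
    cells[c("jem_group_id", "gender", "item_id", "share", "n_nonmissing")],
    names_from = "item_id",
    values_from = c("share", "n_nonmissing"))
  names(wide) <- sub("^n_nonmissing_", "n_", names(wide))
  wide <- wide[c("jem_group_id", "gender",
                 paste0("share_", items), paste0("n_", items))]
  wide <- arrange(wide, .data$jem_group_id, .data$gender)
  structure(wide, class = c("jem_matrix", class(tibble())),
            items = items, n_min = as.integer(n_min),
            stratified = stratify_by_gender, excluded = excluded,
            n_suppressed = sum(cells$n_nonmissing < max(n_min, 1L)))
}

#' @export
print.jem_matrix <- function(x, ...) {
  cat(sprintf("<jem_matrix> %d cells x %d items (n_min = %d, %d suppressed)\n",
              nrow(x), length(attr(x, "items")), attr(x, "n_min"),
              attr(x, "n_suppressed")))
  print(as_tibble(unclass(x)), ...)
  invisible(x)
}

#' Build-log report for a JEM
#'
#' @param jem a `jem_matrix` from [build_jem()].
#' @return character vector of report lines (codes excluded, cells
#'   suppressed).
#' @export
jem_build_log <- function(jem) {
  stopifnot(inherits(jem, "jem_matrix"))
  excluded <- attr(jem, "excluded")
  lines <- c(
    sprintf("JEM build: %d cells, %d items, n_min = %d",
            nrow(jem), length(attr(jem, "items")), attr(jem, "n_min")),
    sprintf("cell-item shares suppressed (n < n_min): %d",
            attr(jem, "n_suppressed")),
    sprintf("occupation codes excluded (not in group map): %d",
            nrow(excluded)))
  if (nrow(excluded) > 0L) {
    lines <- c(lines, sprintf("  %s (%d rows)", excluded$occupation_code,
                              excluded$n_rows))
  }
  lines
}

#' Expand group-level shares to occupation codes
#'
#' Every occupation code inherits its JEM group's shares verbatim, one row
#' per (code, gender); codes sharing a group therefore carry identical
#' exposure estimates, item by item. Codes whose group is absent from the
#' matrix propagate missing shares.
#'
#' @param jem a `jem_matrix` from [build_jem()].
#' @param group_map the [jem_group_map()] the matrix was built from.
#' @return a `code_shares` tibble: `occupation_code`, `jem_group_id`,
#'   `gender`, `share_<item>`, `n_<item>`.
#' @export
expand_to_codes <- function(jem, group_map) {
  stopifnot(inherits(jem, "jem_matrix"), inherits(group_map, "jem_group_map"))
  genders <- unique(jem$gender)
  grid <- tidyr::expand_grid(group_map, gender = genders)
  out <- left_join(grid, as_tibble(unclass(jem)),
                   by = c("jem_group_id", "gender"))
  out <- arrange(out, .data$occupation_code, .data$gender)
  structure(out, class = c("code_shares", class(tibble())),
            items = attr(jem, "items"), n_min = attr(jem, "n_min"))
}

# Survey / matrix IO -------------------------------------------------------

#' Read survey microdata from CSV
#'
#' Expected header: `respondent_id, wave, occupation_code, gender,` one
#' column per item id. Missing responses are empty fields. Occupation codes
#' are zero-padded on read.
#'
#' @param path CSV path.
#' @param item_set an [item_set()]; its items must all be present.
#' @return a survey tibble.
#' @export
read_survey <- function(path, item_set) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE,
                 colClasses = c(respondent_id = "character",
                                occupation_code = "character",
                                gender = "character"))
  missing_items <- setdiff(item_set$item_id, names(df))
  if (length(missing_items)) {
    stop("survey file lacks item column(s): ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  df$occupation_code <- pad_code(df$occupation_code)
  for (it in item_set$item_id) df[[it]] <- as.integer(df[[it]])
  as_tibble(df)
}

#' Write survey microdata to CSV
#' @param survey survey tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  write.csv(as.data.frame(survey), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a JEM (or its code expansion) to CSV
#'
#' Shares are stored at full precision in memory; rounding is applied only
#' here, on export.
#'
#' @param x a `jem_matrix` or `code_shares` object.
#' @param path output CSV path.
#' @param digits decimal places for shares on export (default 1); `NA` for
#'   full precision.
#' @param log_path optional path for the build-log report (only for
#'   `jem_matrix` input).
#' @return `path`, invisibly.
#' @export
write_jem <- function(x, path, digits = 1, log_path = NULL) {
  df <- as.data.frame(x)
  share_cols <- grep("^share_", names(df), value = TRUE)
  if (!is.na(digits)) {
    df[share_cols] <- lapply(df[share_cols], round, digits = digits)
  }
  write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(log_path) && inherits(x, "jem_matrix")) {
    writeLines(jem_build_log(x), log_path)
  }
  invisible(path)
}
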