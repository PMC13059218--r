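# Occupation-level dichotomization of exposure shares and the Karasek
# demand-control strain classification.
#
# Control items are coded as *adversity* (exposed = low control), so a single
# strict "greater than the median" rule applies uniformly across both
# dimensions; quadrant labels translate the result back into Karasek
# terminology (high_strain / active / passive / low_strain).

#' Classify occupations as exposed / non-exposed per item
#'
#' For each item the cut-off is the unweighted median of exposure shares
#' across distinct (JEM group, gender) cells — not across expanded
#' occupation codes, which would weight large groups by their code count
#' (switchable via `median_over`). An occupation-gender cell is exposed on an
#' item when its share is *strictly* greater than the cut-off; shares equal
#' to the cut-off are non-exposed, and missing (suppressed) shares propagate
#' to missing flags.
#'
#' @param code_shares a `code_shares` table from [expand_to_codes()], or a
#'   `jem_matrix` (rows are then classified at group level).
#' @param item_set an [item_set()].
#' @param median_over `"cells"` (default: distinct group-gender cells) or
#'   `"codes"` (rows of the expanded code table).
#' @param share_cutoffs optional tibble `(item_id, cutoff)` to use fixed
#'   cut-offs instead of recomputing them.
#' @return an `occupation_exposure` tibble: key columns plus one logical
#'   `exp_<item>` column per item; the cut-offs used are attached and
#'   retrievable with [share_cutoffs()].
#' @export
assign_occupation_exposure <- function(code_shares, item_set,
                                       median_over = c("cells", "codes"),
                                       share_cutoffs = NULL) {
  median_over <- match.arg(median_over)
  items <- item_set$item_id
  df <- as_tibble(code_shares)
  share_cols <- paste0("share_", items)
  absent <- setdiff(share_cols, names(df))
  if (length(absent)) {
    stop("share table lacks item column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty share table", call. = FALSE)

  if (is.null(share_cutoffs)) {
    basis <- if (median_over == "cells" && "jem_group_id" %in% names(df)) {
      distinct(df[c("jem_group_id", "gender", share_cols)])
    } else {
      df
    }
    share_cutoffs <- tibble(
      item_id = items,
      cutoff = vapply(share_cols,
                      function(cl) median(basis[[cl]], na.rm = TRUE),
                      numeric(1), USE.NAMES = FALSE))
  } else {
    share_cutoffs <- as_tibble(share_cutoffs)[c("item_id", "cutoff")]
    uncovered <- setdiff(items, share_cutoffs$item_id)
    if (length(uncovered)) {
      stop("share_cutoffs does not cover item(s): ",
           paste(uncovered, collapse = ", "), call. = FALSE)
    }
  }

  key_cols <- intersect(c("occupation_code", "jem_group_id", "gender"),
                        names(df))
  out <- df[key_cols]
  for (i in seq_along(items)) {
    cut_i <- share_cutoffs$cutoff[share_cutoffs$item_id == items[i]]
    out[[paste0("exp_", items[i])]] <- df[[share_cols[i]]] > cut_i
  }
  structure(out, class = c("occupation_exposure", class(tibble())),
            items = items, share_cutoffs = share_cutoffs)
}

#' Median-of-shares cut-offs used for occupation classification
#' @param x an `occupation_exposure` from [assign_occupation_exposure()].
#' @return tibble `(item_id, cutoff)`.
#' @export
share_cutoffs <- function(x) attr(x, "share_cutoffs")

#' Combine demand and control into the job strain classification
#'
#' `demand_index` counts exposed demand items (0–4 with the default set);
#' `control_index` counts exposed control items coded as adversity, i.e. low
#' control (0–6). An occupation-gender row is `high_demand` when its demand
#' index is strictly greater than the median demand index across fully
#' observed rows, and `low_control` analogously. The four Karasek quadrants
#' follow: high demand + low control = `high_strain` (the binary `job_strain`
#' flag), high demand only = `active`, low control only = `passive`,
#' neither = `low_strain`. Rows with any missing constituent flag get missing
#' indices and quadrant.
#'
#' @param occ_exposures an `occupation_exposure` from
#'   [assign_occupation_exposure()].
#' @param item_set an [item_set()].
#' @return a `strain_table` tibble keyed like the input, retaining the
#'   `exp_<item>` columns and adding `demand_index`, `control_index`,
#'   `high_demand`, `low_control`, `strain_quadrant`, `job_strain`.
#' @export
compute_strain <- function(occ_exposures, item_set) {
  stopifnot(inherits(occ_exposures, "occupation_exposure"))
  df <- as_tibble(occ_exposures)
  if (nrow(df) == 0L) stop("empty occupation exposure table", call. = FALSE)
  d_cols <- paste0("exp_", item_set$item_id[item_set$dimension == "demand"])
  c_cols <- paste0("exp_", item_set$item_id[item_set$dimension == "control"])
  absent <- setdiff(c(d_cols, c_cols), names(df))
  if (length(absent)) {
    stop("exposure flags missing for item(s): ",
         paste(sub("^exp_", "", absent), collapse = ", "), call. = FALSE)
  }
  # rowSums without na.rm: any missing constituent flag voids the index
  df$demand_index <- as.integer(rowSums(df[d_cols]))
  df$control_index <- as.integer(rowSums(df[c_cols]))
  complete <- !is.na(df$demand_index) & !is.na(df$control_index)
  if (!any(complete)) {
    stop("no fully observed rows to anchor the index medians", call. = FALSE)
  }
  med_d <- median(df$demand_index[complete])
  med_c <- median(df$control_index[complete])
  df$high_demand <- df$demand_index > med_d
  df$low_control <- df$control_index > med_c
  df$strain_quadrant <- dplyr::case_when(
    df$high_demand & df$low_control ~ "high_strain",
    df$high_demand & !df$low_control ~ "active",
    !df$high_demand & df$low_control ~ "passive",
    !df$high_demand & !df$low_control ~ "low_strain")
  df$job_strain <- df$high_demand & df$low_control
  structure(df, class = c("strain_table", class(tibble())),
            items = attr(occ_exposures, "items"),
            share_cutoffs = attr(occ_exposures, "share_cutoffs"),
            index_medians = c(demand = med_d, control = med_c))
}

#' @export
print.strain_table <- function(x, ...) {
  med <- attr(x, "index_medians")
  cat(sprintf(paste0("<strain_table> %d rows; index medians: demand %.1f,",
                     " control %.1f\n"), nrow(x), med["demand"],
              med["control"]))
  print(as_tibble(unclass(x)), ...)
  invisible(x)
}

#' Export the combined JEM + job strain index with a codebook
#'
#' Writes one flat table, one row per (occupation code, gender), combining
#' the exposure shares with the occupation-level flags, indices and strain
#' quadrant, plus a generated plain-text codebook listing every variable,
#' its type, range and construction. The two inputs must be keyed
#' identically.
#'
#' @param strain a `strain_table` from [compute_strain()].
#' @param code_shares the `code_shares` table the strain table was derived
#'   from.
#' @param path output CSV path.
#' @param codebook_path optional codebook path (default: `path` with a
#'   `_codebook.md` suffix).
#' @param digits decimal places for shares on export; `NA` (default) keeps
#'   full precision so the file round-trips exactly.
#' @return the merged tibble, invisibly.
#' @export
export_strain_index <- function(strain, code_shares, path,
                                codebook_path = NULL, digits = NA) {
  stopifnot(inherits(strain, "strain_table"))
  if (nrow(strain) == 0L) stop("empty strain table", call. = FALSE)
  items <- attr(strain, "items")
  sh <- as_tibble(code_shares)
  st <- as_tibble(strain)
  key <- intersect(c("occupation_code", "jem_group_id", "gender"),
                   intersect(names(sh), names(st)))
  if (!length(key)) stop("no common key columns", call. = FALSE)
  kp <- function(d) do.call(paste, c(d[key], sep = "\r"))
  if (!setequal(kp(sh), kp(st)) || nrow(sh) != nrow(st)) {
    stop("strain table and share table are not keyed identically",
         call. = FALSE)
  }
  out <- left_join(sh[c(key, paste0("share_", items))], st, by = key)
  front <- intersect(c("occupation_code", "gender", "jem_group_id"), names(out))
  out <- out[c(front, setdiff(names(out), front))]
  share_cols <- paste0("share_", items)
  if (!is.na(digits)) {
    out[share_cols] <- lapply(out[share_cols], round, digits = digits)
  }
  write.csv(as.data.frame(out), path, row.names = FALSE, na = "")
  if (is.null(codebook_path)) {
    codebook_path <- sub("\\.csv$", "", path)
    codebook_path <- paste0(codebook_path, "_codebook.md")
  }
  writeLines(.render_codebook(out, items, attr(strain, "share_cutoffs")),
             codebook_path)
  invisible(out)
}

#' Read an exported JEM + strain index table
#'
#' @param path CSV written by [export_strain_index()].
#' @return a tibble with codes re-padded and logical/integer columns
#'   restored.
#' @export
read_strain_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path, call. = FALSE)
  df <- as_tibble(read.csv(path, check.names = FALSE,
                           colClasses = c(occupation_code = "character",
                                          gender = "character")))
  df$occupation_code <- pad_code(df$occupation_code)
  for (cl in grep("^exp_|^high_demand$|^low_control$|^job_strain$",
                  names(df), value = TRUE)) {
    df[[cl]] <- as.logical(df[[cl]])
  }
  for (cl in intersect(c("demand_index", "control_index"), names(df))) {
    df[[cl]] <- as.integer(df[[cl]])
  }
  df
}

.render_codebook <- function(tab, items, cutoffs) {
  var_line <- function(name, type, range, desc) {
    sprintf("- `%s` (%s; %s): %s", name, type, range, desc)
  }
  lines <- c(
    "# Codebook: psychosocial JEM and occupational job strain index",
    "",
    sprintf("One row per (occupation_code, gender); %d rows, %d variables.",
            nrow(tab), ncol(tab)),
    "",
    "## Key variables",
    var_line("occupation_code", "character", "4-digit, zero-padded",
             "occupational classification code"),
    var_line("gender", "character", "female/male",
             "gender stratum of the JEM cell"),
    if ("jem_group_id" %in% names(tab)) {
      var_line("jem_group_id", "character", "group id",
               "JEM group the code belongs to; codes in one group share all exposure values")
    },
    "",
    "## Exposure shares",
    "Percent of surveyed respondents in the JEM cell classified exposed",
    "(aligned response strictly above the pooled item median); missing when",
    "the cell was suppressed for small size.",
    vapply(items, function(it) {
      var_line(paste0("share_", it), "numeric", "0-100",
               paste("share exposed on", it))
    }, character(1)),
    "",
    "## Occupation-level exposure flags",
    "TRUE when the cell's share strictly exceeds the median share across",
    "group-gender cells for that item:",
    vapply(items, function(it) {
      cut_i <- cutoffs$cutoff[cutoffs$item_id == it]
      var_line(paste0("exp_", it), "logical",
               sprintf("cut-off %.4g%%", cut_i),
               paste("occupation exposed on", it))
    }, character(1)),
    "",
    "## Strain index",
    var_line("demand_index", "integer", "0-4",
             "count of exposed psychological demand items"),
    var_line("control_index", "integer", "0-6",
             "count of exposed (adverse / low) control items"),
    var_line("high_demand", "logical", "TRUE/FALSE",
             "demand_index strictly above its median across occupations"),
    var_line("low_control", "logical", "TRUE/FALSE",
             "control_index strictly above its median across occupations"),
    var_line("strain_quadrant", "character",
             "high_strain/active/passive/low_strain",
             "Karasek demand-control quadrant"),
    var_line("job_strain", "logical", "TRUE/FALSE",
             "high demand AND low control (equals quadrant high_strain)"))
  unlist(lines[!vapply(lines, is.null, logical(1))])
}
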