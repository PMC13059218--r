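# Item-set and JEM group-map configuration: the structural skeleton every
# downstream stage validates against.

#' Construct and validate an item set
#'
#' An item set is the ordered collection of survey items used to build the
#' exposure matrix. Each item carries a dimension (`"demand"` or `"control"`),
#' an ordinal scale range, and an adverse-orientation flag: `adverse_high =
#' TRUE` when larger raw values mean more adverse exposure, `FALSE` when the
#' item must be aligned by reflection (see [align_response()]).
#'
#' @param items data frame with columns `item_id`, `label`, `dimension`,
#'   `scale_min`, `scale_max`, `adverse_high`.
#' @param name short name for the set.
#' @return an `item_set`: a tibble with one row per item.
#' @seealso [default_item_set()], [load_item_set()]
#' @export
item_set <- function(items, name = "custom") {
  items <- as_tibble(items)
  required <- c("item_id", "label", "dimension", "scale_min", "scale_max",
                "adverse_high")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols)) {
    stop("item set is missing fields: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  items <- items[required]
  if (nrow(items) == 0L) stop("item set has no items", call. = FALSE)
  items$item_id <- as.character(items$item_id)
  items$label <- as.character(items$label)
  items$dimension <- as.character(items$dimension)
  items$scale_min <- as.integer(items$scale_min)
  items$scale_max <- as.integer(items$scale_max)
  items$adverse_high <- as.logical(items$adverse_high)

  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup)) {
    stop("duplicate item_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_dim <- setdiff(items$dimension, c("demand", "control"))
  if (length(bad_dim)) {
    stop("unknown dimension value: ", paste(bad_dim, collapse = ", "),
         " (must be 'demand' or 'control')", call. = FALSE)
  }
  bad_scale <- items$item_id[is.na(items$scale_min) | is.na(items$scale_max) |
                               items$scale_min >= items$scale_max]
  if (length(bad_scale)) {
    stop("scale_min must be < scale_max for item(s): ",
         paste(bad_scale, collapse = ", "), call. = FALSE)
  }
  if (anyNA(items$adverse_high)) {
    stop("adverse_high must be TRUE or FALSE for every item", call. = FALSE)
  }
  structure(items, class = c("item_set", class(tibble())),
            set_name = as.character(name)[1])
}

#' @export
print.item_set <- function(x, ...) {
  cat(sprintf("<item_set '%s'> %d items (%d demand, %d control)\n",
              attr(x, "set_name"), nrow(x),
              sum(x$dimension == "demand"), sum(x$dimension == "control")))
  print(as_tibble(unclass(x)), ...)
  invisible(x)
}

#' Load an item set from a YAML configuration file
#'
#' The config is a human-editable YAML document with a `name` and an `items`
#' list; each item states `item_id`, `label`, `dimension`, `scale_min`,
#' `scale_max` and `adverse_high`. `adverse_high` may be omitted for demand
#' items (it defaults to `TRUE`: frequent demands are adverse) but must be
#' stated explicitly for control items, whose orientation is a substantive
#' coding decision.
#'
#' @param path path to the YAML file.
#' @return a validated [item_set()].
#' @export
load_item_set <- function(path) {
  if (!file.exists(path)) stop("item config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$items) || !length(cfg$items)) {
    stop("config has no 'items' list: ", path, call. = FALSE)
  }
  rows <- lapply(cfg$items, function(it) {
    for (f in c("item_id", "dimension", "scale_min", "scale_max")) {
      if (is.null(it[[f]])) {
        stop("item entry missing field '", f, "' in ", path, call. = FALSE)
      }
    }
    if (is.null(it$adverse_high)) {
      if (identical(it$dimension, "demand")) {
        it$adverse_high <- TRUE
      } else {
        stop("adverse_high must be stated explicitly for control item '",
             it$item_id, "'", call. = FALSE)
      }
    }
    tibble(item_id = it$item_id,
           label = it$label %||% it$item_id,
           dimension = it$dimension,
           scale_min = it$scale_min,
           scale_max = it$scale_max,
           adverse_high = it$adverse_high)
  })
  item_set(bind_rows(rows), name = cfg$name %||% "unnamed")
}

#' Write an item set back to YAML
#'
#' Inverse of [load_item_set()]: `load_item_set(write_item_set(x, p))` gives
#' a set equal to `x`.
#'
#' @param x an [item_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_item_set <- function(x, path) {
  stopifnot(inherits(x, "item_set"))
  doc <- list(
    name = attr(x, "set_name"),
    items = lapply(seq_len(nrow(x)), function(i) {
      list(item_id = x$item_id[i], label = x$label[i],
           dimension = x$dimension[i],
           scale_min = x$scale_min[i], scale_max = x$scale_max[i],
           adverse_high = x$adverse_high[i])
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' The packaged default 10-item demand-control set
#'
#' Four psychological demand items (quantitative demands, conflicting ways of
#' doing things, insufficient resources, contradictory requests) and six job
#' control / decision-latitude items (decide how, decide pace, important
#' decisions, use skills, develop skills, monotonous work), all on 1–5
#' frequency scales.
#'
#' @return an [item_set()] with 10 items.
#' @export
default_item_set <- function() {
  load_item_set(system.file("extdata", "qpsnordic10_items.yaml",
                            package = "jemkit", mustWork = TRUE))
}

# Group map ----------------------------------------------------------------

#' Construct and validate an occupation-code to JEM-group map
#'
#' Every 4-digit occupation code must map to exactly one JEM group; several
#' codes may share a group (the matrix then assigns those occupations
#' identical exposures by construction).
#'
#' @param map data frame with columns `occupation_code`, `jem_group_id`.
#' @return a `jem_group_map` tibble.
#' @export
jem_group_map <- function(map) {
  map <- as_tibble(map)
  if (!all(c("occupation_code", "jem_group_id") %in% names(map))) {
    stop("group map needs columns occupation_code, jem_group_id",
         call. = FALSE)
  }
  map <- map[c("occupation_code", "jem_group_id")]
  map$occupation_code <- pad_code(map$occupation_code)
  map$jem_group_id <- as.character(map$jem_group_id)
  if (anyNA(map$occupation_code) || anyNA(map$jem_group_id)) {
    stop("group map contains missing codes or group ids", call. = FALSE)
  }
  map <- distinct(map)
  multi <- unique(map$occupation_code[duplicated(map$occupation_code)])
  if (length(multi)) {
    stop("occupation code(s) mapped to more than one group: ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  structure(map, class = c("jem_group_map", class(tibble())))
}

#' @export
print.jem_group_map <- function(x, ...) {
  cat(sprintf("<jem_group_map> %d occupation codes in %d JEM groups\n",
              nrow(x), dplyr::n_distinct(x$jem_group_id)))
  print(as_tibble(unclass(x)), ...)
  invisible(x)
}

#' Number of distinct codes and groups in a map
#' @param map a [jem_group_map()].
#' @return named integer vector with elements `codes` and `groups`.
#' @export
group_map_counts <- function(map) {
  stopifnot(inherits(map, "jem_group_map"))
  c(codes = nrow(map), groups = dplyr::n_distinct(map$jem_group_id))
}

#' Load a group map from CSV
#'
#' Expects a UTF-8 CSV with header columns `occupation_code`,
#' `jem_group_id`; codes are zero-padded to 4 characters on read.
#'
#' @param path path to the CSV file.
#' @return a validated [jem_group_map()].
#' @export
load_group_map <- function(path) {
  if (!file.exists(path)) stop("group map not found: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  jem_group_map(df)
}

#' Write a group map to CSV
#' @param map a [jem_group_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(map, path) {
  stopifnot(inherits(map, "jem_group_map"))
  write.csv(as.data.frame(map), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
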