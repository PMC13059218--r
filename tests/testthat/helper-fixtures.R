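# Fixture builders used across the suite. Everything is generated in code
# under fixed seeds; no data files.

# Plain data.frame with no custom attributes, for content comparisons.
strip_tbl <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  rownames(x) <- NULL
  x
}

# Minimal custom item sets ---------------------------------------------------

one_item_set <- function(id = "quantitative_demands", adverse_high = TRUE,
                         scale_min = 1L, scale_max = 5L,
                         dimension = "demand") {
  item_set(data.frame(item_id = id, label = id, dimension = dimension,
                      scale_min = scale_min, scale_max = scale_max,
                      adverse_high = adverse_high),
           name = "one")
}

small_item_set <- function() {
  item_set(data.frame(
    item_id = c("d1", "d2", "c1", "c2", "c3"),
    label = c("d1", "d2", "c1", "c2", "c3"),
    dimension = c("demand", "demand", "control", "control", "control"),
    scale_min = 1L, scale_max = 5L,
    adverse_high = c(TRUE, TRUE, FALSE, FALSE, TRUE)),
    name = "small")
}

# One-item survey with given raw responses, all in one (code, gender) cell.
responses_survey <- function(values, code = "1000", gender = "female") {
  tibble::tibble(respondent_id = sprintf("R%03d", seq_along(values)),
                 wave = 2006L, occupation_code = code, gender = gender,
                 quantitative_demands = as.integer(values))
}

identity_map <- function(codes) {
  jem_group_map(data.frame(occupation_code = codes,
                           jem_group_id = paste0("G", codes)))
}

# Hand-built exposure flags: one row per respondent, logical item columns.
flags_fixture <- function(code, gender, ...) {
  cols <- list(...)
  n <- length(cols[[1]])
  df <- tibble::tibble(respondent_id = sprintf("R%03d", seq_len(n)),
                       occupation_code = code, gender = gender)
  for (nm in names(cols)) df[[nm]] <- cols[[nm]]
  exposure_flags(df, items = names(cols))
}

# Random end-to-end fixture: survey + group map + item set, small enough for
# brute-force re-computation (<= 50 group-gender cells).
rand_fixture <- function(seed) {
  set.seed(seed)
  items <- if (seed %% 3 == 0) default_item_set() else small_item_set()
  n_groups <- sample(2:8, 1)
  n_extra <- sample(0:4, 1)
  groups <- sprintf("G%02d", seq_len(n_groups))
  codes <- sprintf("%04d", sample(100:9999, n_groups + n_extra))
  map <- jem_group_map(data.frame(
    occupation_code = codes,
    jem_group_id = groups[c(seq_len(n_groups),
                            sample(n_groups, n_extra, replace = TRUE))]))
  n_per_cell <- sample(3:8, 1)
  persons <- expand.grid(occupation_code = codes,
                         gender = c("female", "male"),
                         draw = seq_len(n_per_cell),
                         stringsAsFactors = FALSE)
  survey <- tibble::tibble(
    respondent_id = sprintf("R%04d", seq_len(nrow(persons))),
    wave = sample(c(2006L, 2009L), nrow(persons), replace = TRUE),
    occupation_code = persons$occupation_code,
    gender = persons$gender)
  for (i in seq_len(nrow(items))) {
    v <- sample(items$scale_min[i]:items$scale_max[i], nrow(persons),
                replace = TRUE)
    v[runif(nrow(persons)) < 0.05] <- NA_integer_
    survey[[items$item_id[i]]] <- as.integer(v)
  }
  list(survey = survey, map = map, items = items)
}
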